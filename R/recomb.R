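# DCJ recombination enumeration on concrete genome pairs. A DCJ applied to
# one genome cuts two sites (adjacencies or telomeres); when the two sites
# lie on different components of the relational diagram the operation is a
# recombination of those components. For every possible DCJ this module
# reports the DCJ-cost ||rho|| (from the change in AB-cycle and AB-path
# counts), the indel cost delta-lambda (from the indel potentials before
# and after), and their sum, the DCJ-indel cost delta-d.

# All single DCJ moves on an adjacency set, with the cut sites recorded.
dcj_moves <- function(adj) {
  res <- list()
  A <- adj$adjacencies
  Tl <- adj$telomeres
  nA <- length(A)
  add <- function(adjacencies, telomeres, cut1, cut2) {
    res[[length(res) + 1L]] <<- list(
      state = list(adjacencies = adjacencies, telomeres = telomeres),
      cut1 = cut1, cut2 = cut2)
  }
  cutA <- function(x) list(type = "adjacency", ext = x)
  cutT <- function(x) list(type = "telomere", ext = x)
  if (nA >= 2L)
    for (i in seq_len(nA - 1L)) for (j in seq((i + 1L), nA)) {
      p <- A[[i]]; q <- A[[j]]; rest <- A[-c(i, j)]
      add(c(rest, list(sort(c(p[1], q[1])), sort(c(p[2], q[2])))), Tl, cutA(p), cutA(q))
      add(c(rest, list(sort(c(p[1], q[2])), sort(c(p[2], q[1])))), Tl, cutA(p), cutA(q))
    }
  if (nA >= 1L)
    for (i in seq_len(nA)) for (t in Tl) {
      p <- A[[i]]; rest <- A[-i]
      add(c(rest, list(sort(c(p[1], t)))), c(setdiff(Tl, t), p[2]), cutA(p), cutT(t))
      add(c(rest, list(sort(c(p[2], t)))), c(setdiff(Tl, t), p[1]), cutA(p), cutT(t))
    }
  if (length(Tl) >= 2L)
    for (i in seq_len(length(Tl) - 1L)) for (j in seq(i + 1L, length(Tl))) {
      add(c(A, list(sort(c(Tl[i], Tl[j])))), Tl[-c(i, j)], cutT(Tl[i]), cutT(Tl[j]))
    }
  for (i in seq_len(nA))
    add(A[-i], c(Tl, A[[i]]), cutA(A[[i]]), NULL)
  res
}

# vertex id of an extremity key in a diagram
ext_vertex_id <- function(diagram, side, key) {
  p <- ext_parts(key)
  vt <- diagram$vertices
  vt$id[vt$owner == side & !is.na(vt$marker) & vt$marker == p$marker &
        vt$occ == p$occ & vt$end == p$end]
}

# component index containing a cut site
cut_component <- function(diagram, comps, side, cut) {
  if (cut$type == "telomere") {
    v <- ext_vertex_id(diagram, side, cut$ext)
    for (k in seq_along(comps)) if (v %in% comps[[k]]$vertices) return(k)
  } else {
    v1 <- ext_vertex_id(diagram, side, cut$ext[1])
    v2 <- ext_vertex_id(diagram, side, cut$ext[2])
    ed <- diagram$edges
    e <- which(ed$kind == "adjacency" & ed$genome == side &
               ed$v1 == min(v1, v2) & ed$v2 == max(v1, v2))
    for (k in seq_along(comps)) if (e %in% comps[[k]]$edges) return(k)
  }
  NA_integer_
}

comp_label <- function(cp) paste0(cp$cls, ":", cp$run_signature)

#' Enumerate DCJ operations on one genome of a pair and their costs
#'
#' @param A,B singular `dcj_genome` objects.
#' @param side `"A"` or `"B"`: the genome the DCJ is applied to.
#' @return data frame with one row per DCJ: the components cut (indices
#'   into `decompose(build_relational(A, B))`), the DCJ-cost `rho`, the
#'   indel cost `delta_lambda`, their sum `delta_d`, and the classes of the
#'   resultant components.
#' @export
recombination_costs <- function(A, B, side = "A") {
  dg <- build_relational(A, B)
  comps <- decompose(dg)
  cs <- components_summary(comps)
  c0 <- sum(cs$cls == "AB_cycle")
  i0 <- sum(cs$cls == "AB_path")
  l0 <- sum(indel_potential(cs$Lambda))
  g <- if (side == "A") A else B
  moves <- dcj_moves(genome_adjacencies(g))
  rows <- lapply(moves, function(mv) {
    g2 <- genome_from_adjacencies(mv$state, name = g$name)
    dg2 <- if (side == "A") build_relational(g2, B) else build_relational(A, g2)
    comps2 <- decompose(dg2)
    cs2 <- components_summary(comps2)
    c1 <- sum(cs2$cls == "AB_cycle")
    i1 <- sum(cs2$cls == "AB_path")
    dc <- c1 - c0
    di <- i1 - i0
    rho <- if (dc == 1L || di == 2L) 0L
           else if (dc == 0L && di == 0L) 1L
           else if (dc == -1L || di == -2L) 2L
           else NA_integer_
    dl <- sum(indel_potential(cs2$Lambda)) - l0
    # resultants: components of the new diagram holding the cut extremities
    ends <- unlist(lapply(list(mv$cut1, mv$cut2), function(ct)
      if (is.null(ct)) NULL else ct$ext))
    vids <- unlist(lapply(ends, function(k) ext_vertex_id(dg2, side, k)))
    rks <- unique(unlist(lapply(vids, function(v)
      which(vapply(comps2, function(cp) v %in% cp$vertices, logical(1))))))
    data.frame(
      side = side,
      comp1 = cut_component(dg, comps, side, mv$cut1),
      comp2 = if (is.null(mv$cut2)) NA_integer_
              else cut_component(dg, comps, side, mv$cut2),
      rho = rho, delta_lambda = dl, delta_d = rho + dl,
      resultants = paste(sort(vapply(comps2[rks], comp_label, "")), collapse = "+"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Best (lowest DCJ-indel cost) recombination of two specific components
#'
#' Enumerates DCJs in both genomes whose two cuts fall on the two given
#' components of the relational diagram and returns the minimum
#' `delta_d = ||rho|| + delta_lambda` together with the full table.
#'
#' @param A,B singular `dcj_genome` objects.
#' @param comp1,comp2 component indices (as in
#'   `decompose(build_relational(A, B))`).
#' @return list with `min_delta_d` and the table of candidate operations.
#' @export
best_recombination <- function(A, B, comp1, comp2) {
  tab <- rbind(recombination_costs(A, B, "A"), recombination_costs(A, B, "B"))
  hit <- !is.na(tab$comp2) &
    ((tab$comp1 == comp1 & tab$comp2 == comp2) |
     (tab$comp1 == comp2 & tab$comp2 == comp1))
  cand <- tab[hit, , drop = FALSE]
  if (nrow(cand) == 0L) stop("no recombination cuts both components")
  list(min_delta_d = min(cand$delta_d), table = cand)
}
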