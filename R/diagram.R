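# Relational diagrams. For two genomes A and B the diagram has one vertex
# per marker-extremity occurrence; adjacency edges follow the chromosome
# structure, extremity edges connect same-marker same-end occurrences
# across genomes (all candidate pairs in the multi-relational case), and
# indel edges join head and tail of every occurrence of a marker that is
# over-represented on its side. Capping adds 4 p* cap vertices, cap
# adjacencies on every telomere, a* artificial adjacencies on the side with
# fewer linear chromosomes, and the complete bipartite set of cap extremity
# edges, so that consistent decompositions consist of cycles only.

#' Build the (capped) multi-relational diagram of two genomes
#'
#' @param A,B `dcj_genome` objects.
#' @param capped logical; add cap vertices/edges so that every consistent
#'   decomposition is a cycle decomposition.
#' @return object of class `dcj_diagram` with fields `vertices` (data frame:
#'   id, owner, marker, occ, end, chrom, pos), `edges` (data frame: kind in
#'   adjacency/artificial/extremity/indel/cap, genome, v1, v2, sib, marker,
#'   aocc, bocc, chrom), `capped`, and `census`.
#' @export
build_multi_relational <- function(A, B, capped = FALSE) {
  cn <- census(A, B)
  occA <- occurrence_table(A)
  occB <- occurrence_table(B)
  nA <- nrow(occA)
  nB <- nrow(occB)

  vertex_block <- function(occ, owner, offset) {
    n <- nrow(occ)
    data.frame(
      id = offset + seq_len(2L * n),
      owner = owner,
      marker = rep(occ$marker, each = 2L),
      occ = rep(occ$occ, each = 2L),
      end = rep(c("t", "h"), n),
      chrom = rep(occ$chrom, each = 2L),
      pos = rep(occ$pos, each = 2L),
      stringsAsFactors = FALSE)
  }
  VA <- vertex_block(occA, "A", 0L)
  VB <- vertex_block(occB, "B", 2L * nA)
  vertices <- rbind(VA, VB)

  # id of the tail/head vertex of occurrence row r of a genome table
  vid <- function(owner, row, end) {
    base <- if (owner == "A") 0L else 2L * nA
    base + 2L * (row - 1L) + if (end == "t") 1L else 2L
  }

  ek <- list()  # accumulating edge rows
  add_edge <- function(kind, genome, v1, v2, sib = NA_integer_,
                       marker = NA_character_, aocc = NA_integer_,
                       bocc = NA_integer_, chrom = NA_integer_) {
    ek[[length(ek) + 1L]] <<- list(kind = kind, genome = genome,
                                   v1 = min(v1, v2), v2 = max(v1, v2), sib = sib,
                                   marker = marker, aocc = aocc, bocc = bocc,
                                   chrom = chrom)
    length(ek)
  }

  telomeres <- list(A = integer(0), B = integer(0))
  for (side in c("A", "B")) {
    g <- if (side == "A") A else B
    occ <- if (side == "A") occA else occB
    for (ci in seq_along(g$chromosomes)) {
      rows <- which(occ$chrom == ci)
      k <- length(rows)
      right_end <- ifelse(occ$strand[rows] > 0L, "h", "t")
      left_end <- ifelse(occ$strand[rows] > 0L, "t", "h")
      if (k > 1L)
        for (i in seq_len(k - 1L))
          add_edge("adjacency", side,
                   vid(side, rows[i], right_end[i]),
                   vid(side, rows[i + 1L], left_end[i + 1L]), chrom = ci)
      if (g$chromosomes[[ci]]$circular) {
        add_edge("adjacency", side,
                 vid(side, rows[k], right_end[k]),
                 vid(side, rows[1L], left_end[1L]), chrom = ci)
      } else {
        telomeres[[side]] <- c(telomeres[[side]],
                               vid(side, rows[1L], left_end[1L]),
                               vid(side, rows[k], right_end[k]))
      }
    }
  }

  # extremity edges (all candidate pairs per common marker) with siblings
  for (m in cn$common) {
    ra <- which(occA$marker == m)
    rb <- which(occB$marker == m)
    for (i in ra) for (j in rb) {
      et <- add_edge("extremity", NA_character_,
                     vid("A", i, "t"), vid("B", j, "t"),
                     marker = m, aocc = occA$occ[i], bocc = occB$occ[j])
      eh <- add_edge("extremity", NA_character_,
                     vid("A", i, "h"), vid("B", j, "h"),
                     marker = m, aocc = occA$occ[i], bocc = occB$occ[j])
      ek[[et]]$sib <- eh
      ek[[eh]]$sib <- et
    }
  }

  # indel edges on every occurrence of an over-represented marker
  for (i in which(cn$deltaPhi[occA$marker] > 0L))
    add_edge("indel", "A", vid("A", i, "t"), vid("A", i, "h"),
             marker = occA$marker[i], chrom = occA$chrom[i])
  for (j in which(cn$deltaPhi[occB$marker] < 0L))
    add_edge("indel", "B", vid("B", j, "t"), vid("B", j, "h"),
             marker = occB$marker[j], chrom = occB$chrom[j])

  if (capped && cn$p_star > 0L) {
    p2 <- 2L * cn$p_star
    base <- 2L * (nA + nB)
    cap_ids <- list(A = base + seq_len(p2), B = base + p2 + seq_len(p2))
    caps <- data.frame(
      id = c(cap_ids$A, cap_ids$B),
      owner = rep(c("A", "B"), each = p2),
      marker = NA_character_, occ = rep(seq_len(p2), 2L),
      end = "cap", chrom = NA_integer_, pos = NA_integer_,
      stringsAsFactors = FALSE)
    vertices <- rbind(vertices, caps)
    for (side in c("A", "B")) {
      tl <- telomeres[[side]]
      for (i in seq_along(tl))
        add_edge("adjacency", side, tl[i], cap_ids[[side]][i])
      # surplus caps on the side with fewer linear chromosomes are paired
      # by artificial adjacencies
      n_used <- length(tl)
      if (n_used < p2)
        for (i in seq(n_used + 1L, p2, by = 2L))
          add_edge("artificial", side, cap_ids[[side]][i], cap_ids[[side]][i + 1L])
    }
    for (i in cap_ids$A) for (j in cap_ids$B)
      add_edge("cap", NA_character_, i, j)
  }

  edges <- do.call(rbind, lapply(ek, function(e)
    data.frame(e, stringsAsFactors = FALSE)))
  rownames(edges) <- NULL
  structure(list(vertices = vertices, edges = edges, capped = capped,
                 census = cn, telomeres = telomeres,
                 A = A, B = B),
            class = "dcj_diagram")
}

#' Build the relational diagram of two singular genomes
#'
#' Rejects genome pairs with duplicated common markers (use
#' [build_multi_relational()] for those). For singular genomes the
#' multi-relational diagram coincides with the classical relational diagram:
#' every vertex has degree one or two and the diagram decomposes into paths
#' and cycles.
#'
#' @inheritParams build_multi_relational
#' @return a `dcj_diagram`.
#' @export
build_relational <- function(A, B, capped = FALSE) {
  cn <- census(A, B)
  if (!is_singular_pair(cn))
    stop("genomes have duplicated common markers; use build_multi_relational()")
  build_multi_relational(A, B, capped = capped)
}

#' @export
print.dcj_diagram <- function(x, ...) {
  cat(if (x$capped) "Capped multi-relational" else "Multi-relational",
      "diagram:", nrow(x$vertices), "vertices,", nrow(x$edges), "edges\n")
  print(table(x$edges$kind))
  invisible(x)
}

# --- decomposition into components ------------------------------------------

#' Decompose a selected edge set into components
#'
#' The selected set must contain all adjacency and artificial adjacency
#' edges and induce degree at most two on every vertex. Components are the
#' connected pieces: cycles and paths. For every component the run count
#' Lambda, the run signature, the transition count and the class are
#' computed.
#'
#' @param diagram a `dcj_diagram`.
#' @param selected integer or logical index into `diagram$edges`; defaults
#'   to all edges (valid for relational diagrams of singular genomes).
#' @return list of components; each has fields `edges`, `vertices`,
#'   `is_cycle`, `cls` (AB_cycle, circular_singleton, AA_path, BB_path,
#'   AB_path), `Lambda`, `run_signature`, `transitions`, `indel_enclosing`,
#'   `linear_singleton`.
#' @export
decompose <- function(diagram, selected = NULL) {
  ed <- diagram$edges
  if (is.null(selected)) selected <- seq_len(nrow(ed))
  if (is.logical(selected)) selected <- which(selected)
  forced <- which(ed$kind %in% c("adjacency", "artificial"))
  if (!all(forced %in% selected))
    stop("selected set must contain all (artificial) adjacency edges")
  nv <- nrow(diagram$vertices)
  deg <- tabulate(c(ed$v1[selected], ed$v2[selected]), nbins = nv)
  if (any(deg > 2L)) stop("vertex of degree > 2 under the selected edge set")

  # incidence: up to two (edge, neighbour) slots per vertex
  inc_e <- matrix(NA_integer_, nv, 2L)
  inc_v <- matrix(NA_integer_, nv, 2L)
  slot <- integer(nv)
  for (e in selected) {
    a <- ed$v1[e]; b <- ed$v2[e]
    slot[a] <- slot[a] + 1L; inc_e[a, slot[a]] <- e; inc_v[a, slot[a]] <- b
    slot[b] <- slot[b] + 1L; inc_e[b, slot[b]] <- e; inc_v[b, slot[b]] <- a
  }

  owner <- diagram$vertices$owner
  visited <- rep(FALSE, nv)
  comps <- list()

  walk <- function(start) {
    vs <- start
    es <- integer(0)
    v <- start
    prev_e <- NA_integer_
    repeat {
      visited[v] <<- TRUE
      nxt <- NA_integer_
      for (s in seq_len(slot[v])) {
        e <- inc_e[v, s]
        if (!identical(e, prev_e)) { nxt <- s; break }
      }
      if (is.na(nxt)) break
      e <- inc_e[v, nxt]
      u <- inc_v[v, nxt]
      es <- c(es, e)
      if (u == start) return(list(vertices = vs, edges = es, cycle = TRUE))
      vs <- c(vs, u)
      prev_e <- e
      v <- u
    }
    list(vertices = vs, edges = es, cycle = FALSE)
  }

  # paths first (start at degree<=1 vertices), then cycles
  for (v in c(which(deg <= 1L), which(deg == 2L))) {
    if (visited[v]) next
    w <- walk(v)
    comps[[length(comps) + 1L]] <- w
  }

  lapply(comps, function(w) classify_component(diagram, w, owner))
}

classify_component <- function(diagram, w, owner) {
  ed <- diagram$edges
  kinds <- ed$kind[w$edges]
  has_cross <- any(kinds %in% c("extremity", "cap"))
  # ordered genome sides of indel edges along the walk
  sides <- ed$genome[w$edges][kinds == "indel"]

  if (w$cycle) {
    cls <- if (has_cross) "AB_cycle" else "circular_singleton"
    runs <- collapse_runs(sides, cyclic = TRUE)
  } else {
    ends <- owner[c(w$vertices[1L], w$vertices[length(w$vertices)])]
    cls <- if (all(ends == "A")) "AA_path"
           else if (all(ends == "B")) "BB_path"
           else "AB_path"
    if (cls == "AB_path" && ends[1L] != "A") {
      # AB-paths are read from the A endpoint
      w$vertices <- rev(w$vertices)
      w$edges <- rev(w$edges)
      sides <- rev(sides)
    }
    runs <- collapse_runs(sides, cyclic = FALSE)
  }
  Lambda <- length(runs)
  sig <- run_signature(runs, cls)
  transitions <- if (w$cycle) {
    if (Lambda <= 1L) 0L else Lambda
  } else {
    max(Lambda - 1L, 0L)
  }
  list(edges = w$edges, vertices = w$vertices, is_cycle = w$cycle,
       cls = cls, Lambda = Lambda, run_signature = sig,
       runs = runs, transitions = transitions,
       indel_enclosing = Lambda >= 1L,
       linear_singleton = !w$cycle && !has_cross && length(w$edges) > 0L)
}

# merge consecutive same-side indel edges into runs; cyclically for cycles
collapse_runs <- function(sides, cyclic) {
  if (length(sides) == 0L) return(character(0))
  r <- rle(sides)$values
  if (cyclic && length(r) > 1L && r[1L] == r[length(r)])
    r <- r[-length(r)]
  if (cyclic && length(r) > 1L && all(r == r[1L]))
    r <- r[1L]
  r
}

run_signature <- function(runs, cls) {
  L <- length(runs)
  if (L == 0L) return("e")
  if (L == 1L) return(runs)
  if (L %% 2L == 1L) return(runs[1L])
  # even number of runs: alternating, signature from the first run;
  # for AA-/BB-paths AB and BA are equivalent (reading direction is free),
  # canonicalized to "AB"
  if (cls %in% c("AA_path", "BB_path", "AB_cycle", "circular_singleton")) return("AB")
  paste0(runs[1L], if (runs[1L] == "A") "B" else "A")
}

#' One-row-per-component summary
#' @param comps result of [decompose()].
#' @return data frame with class, Lambda, run signature, transition count.
#' @export
components_summary <- function(comps) {
  data.frame(
    cls = vapply(comps, `[[`, "", "cls"),
    Lambda = vapply(comps, `[[`, 0L, "Lambda"),
    run_signature = vapply(comps, `[[`, "", "run_signature"),
    transitions = vapply(comps, `[[`, 0L, "transitions"),
    indel_enclosing = vapply(comps, `[[`, TRUE, "indel_enclosing"),
    linear_singleton = vapply(comps, `[[`, TRUE, "linear_singleton"),
    n_edges = vapply(comps, function(cp) length(cp$edges), 0L),
    stringsAsFactors = FALSE)
}

# --- sibling sets and consistent decompositions -----------------------------

#' Enumerate all maximal sibling sets of a multi-relational diagram
#'
#' A maximal sibling set corresponds to a maximal matching of the
#' occurrences of each common marker (an injection from the minority side
#' into the majority side). Intended for desk-scale oracle use; refuses
#' when the number of matchings exceeds `max_sets`.
#'
#' @param diagram a `dcj_diagram`.
#' @param max_sets guard on the total number of maximal sibling sets.
#' @return list of matchings; each matching is a data frame with columns
#'   marker, aocc, bocc. Use [sibling_edges()] to map to edge indices.
#' @export
sibling_sets <- function(diagram, max_sets = 100000) {
  cn <- diagram$census
  total <- 1
  for (m in cn$common) {
    p <- min(cn$phiA[m], cn$phiB[m])
    q <- max(cn$phiA[m], cn$phiB[m])
    total <- total * prod(seq(q - p + 1L, q))
    if (total > max_sets)
      stop("matching space exceeds guard (", max_sets, " sibling sets)")
  }
  per_marker <- lapply(cn$common, function(m) {
    pa <- cn$phiA[m]; pb <- cn$phiB[m]
    if (pa <= pb) {
      lapply(perms_k_of_n(pb, pa), function(sel)
        data.frame(marker = m, aocc = seq_len(pa), bocc = sel,
                   stringsAsFactors = FALSE))
    } else {
      lapply(perms_k_of_n(pa, pb), function(sel)
        data.frame(marker = m, aocc = sel, bocc = seq_len(pb),
                   stringsAsFactors = FALSE))
    }
  })
  combos <- list(data.frame(marker = character(0), aocc = integer(0),
                            bocc = integer(0), stringsAsFactors = FALSE))
  for (opts in per_marker) {
    combos <- unlist(lapply(combos, function(base)
      lapply(opts, function(o) rbind(base, o))), recursive = FALSE)
  }
  combos
}

# all ordered selections of k distinct elements of 1..n
perms_k_of_n <- function(n, k) {
  if (k == 0L) return(list(integer(0)))
  out <- list()
  rec <- function(chosen, remaining) {
    if (length(chosen) == k) {
      out[[length(out) + 1L]] <<- chosen
      return()
    }
    for (x in remaining) rec(c(chosen, x), setdiff(remaining, x))
  }
  rec(integer(0), seq_len(n))
  out
}

#' Map a matching to the corresponding sibling edge indices
#' @param diagram a `dcj_diagram`.
#' @param matching data frame (marker, aocc, bocc) as from [sibling_sets()].
#' @return integer vector of extremity-edge indices (both ends per pair).
#' @export
sibling_edges <- function(diagram, matching) {
  ed <- diagram$edges
  idx <- integer(0)
  if (nrow(matching) == 0L) return(idx)
  for (r in seq_len(nrow(matching))) {
    hit <- which(ed$kind == "extremity" &
                 ed$marker == matching$marker[r] &
                 ed$aocc == matching$aocc[r] &
                 ed$bocc == matching$bocc[r])
    idx <- c(idx, hit)
  }
  sort(idx)
}

#' Consistent decomposition induced by a sibling set (and capping set)
#'
#' Step (i): adjacency and artificial adjacency edges plus the sibling set
#' (plus the capping set, if any). Step (ii): the indel edge of every
#' occurrence left unmatched by the sibling set is added. (Matched
#' occurrences never take their indel edge, even when both their
#' extremities are telomeres of degree one; this keeps the decomposition
#' identical to the relational diagram of the matched singular genomes.)
#'
#' @param diagram a `dcj_diagram`.
#' @param sibling integer indices of selected extremity edges.
#' @param capping integer indices of selected cap extremity edges.
#' @return integer vector: the selected edge set.
#' @export
induce_decomposition <- function(diagram, sibling, capping = integer(0)) {
  ed <- diagram$edges
  sel <- c(which(ed$kind %in% c("adjacency", "artificial")), sibling, capping)
  nv <- nrow(diagram$vertices)
  cross <- sel[ed$kind[sel] %in% c("extremity", "cap")]
  cross_deg <- tabulate(c(ed$v1[cross], ed$v2[cross]), nbins = nv)
  for (e in which(ed$kind == "indel")) {
    if (cross_deg[ed$v1[e]] == 0L && cross_deg[ed$v2[e]] == 0L)
      sel <- c(sel, e)
  }
  sort(sel)
}

#' Enumerate all maximal capping sets of a capped diagram
#'
#' A maximal capping set is a perfect matching between A-cap and B-cap
#' vertices. Oracle use only; factorially many in p*.
#' @param diagram a capped `dcj_diagram`.
#' @param max_sets guard.
#' @return list of integer vectors of cap-edge indices.
#' @export
capping_sets <- function(diagram, max_sets = 100000) {
  if (!diagram$capped) stop("diagram is not capped")
  ed <- diagram$edges
  cap_edges <- which(ed$kind == "cap")
  if (length(cap_edges) == 0L) return(list(integer(0)))
  acaps <- sort(unique(ed$v1[cap_edges]))
  bcaps <- sort(unique(ed$v2[cap_edges]))
  n <- length(acaps)
  if (factorial(n) > max_sets) stop("capping space exceeds guard")
  lookup <- function(a, b) cap_edges[ed$v1[cap_edges] == a & ed$v2[cap_edges] == b]
  lapply(perms_k_of_n(n, n), function(p)
    vapply(seq_len(n), function(i) lookup(acaps[i], bcaps[p[i]]), integer(1)))
}

#' Export a diagram in GraphViz DOT format (debugging aid)
#' @param diagram a `dcj_diagram`.
#' @param selected optional highlighted edge subset.
#' @return character vector of DOT lines.
#' @export
diagram_to_dot <- function(diagram, selected = NULL) {
  vt <- diagram$vertices
  ed <- diagram$edges
  lab <- ifelse(is.na(vt$marker), paste0("cap", vt$occ, vt$owner),
                paste0(vt$marker, ".", vt$occ, vt$end, vt$owner))
  style <- c(adjacency = "solid", artificial = "dashed", extremity = "solid",
             indel = "bold", cap = "dotted")
  col <- rep("black", nrow(ed))
  if (!is.null(selected)) col[selected] <- "red"
  c("graph diagram {",
    sprintf("  v%d [label=\"%s\"];", vt$id, lab),
    sprintf("  v%d -- v%d [style=%s color=%s];",
            ed$v1, ed$v2, style[ed$kind], col),
    "}")
}
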