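# Brute-force references used to validate the ILP and the closed form:
# exhaustive enumeration over maximal sibling sets (each evaluated through
# the singular closed form on the matched singular genomes) and a
# breadth-first DCJ sorter for tiny canonical instances.

#' Minimum DCJ-indel distance over all maximal matchings (oracle)
#'
#' Enumerates every maximal sibling set of the multi-relational diagram,
#' builds the corresponding matched singular genomes (matched occurrences
#' share a fresh composite identifier, unmatched excess occurrences become
#' exclusive markers) and evaluates the singular closed form; returns the
#' minimum.
#'
#' @param A,B `dcj_genome` objects.
#' @param max_sets guard on the number of matchings to enumerate.
#' @return minimum distance (integer).
#' @export
min_over_matchings <- function(A, B, max_sets = 100000) {
  dg <- build_multi_relational(A, B)
  sets <- sibling_sets(dg, max_sets = max_sets)
  best <- Inf
  for (mt in sets) {
    pair <- matched_singular_genomes(A, B, mt)
    d <- distance_singular(pair$A, pair$B)$distance
    if (d < best) best <- d
  }
  as.integer(best)
}

#' Matched singular genomes induced by a matching
#'
#' Matched occurrence pairs receive the identifier `marker@rank`; unmatched
#' occurrences of common markers and occurrences of exclusive markers
#' receive unique exclusive identifiers, so the resulting pair is singular
#' with the same DCJ-indel distance contribution.
#'
#' @param A,B `dcj_genome` objects.
#' @param matching data frame (marker, aocc, bocc) from [sibling_sets()].
#' @return list with singular genomes `A` and `B`.
#' @export
matched_singular_genomes <- function(A, B, matching) {
  relabel <- function(g, side) {
    occ <- occurrence_table(g)
    key <- paste(occ$marker, occ$occ)
    mkey <- if (side == "A") paste(matching$marker, matching$aocc)
            else paste(matching$marker, matching$bocc)
    rank <- match(key, mkey)
    new <- ifelse(is.na(rank),
                  paste0(occ$marker, "@x", side, occ$occ),
                  paste0(occ$marker, "@", rank))
    chroms <- lapply(seq_along(g$chromosomes), function(ci) {
      rows <- occ$chrom == ci
      chromosome(paste0(ifelse(occ$strand[rows] < 0L, "-", ""), new[rows]),
                 circular = g$chromosomes[[ci]]$circular)
    })
    genome(g$name, chroms)
  }
  list(A = relabel(A, "A"), B = relabel(B, "B"))
}

#' True DCJ distance by breadth-first search (oracle)
#'
#' Explores genome states under all DCJ operations (rewiring two
#' adjacencies either way, adjacency + telomere, joining two telomeres,
#' splitting an adjacency) until genome `B` is reached. Requires canonical
#' input: singular genomes over identical marker content.
#'
#' @param A,B `dcj_genome` objects with identical singular marker content.
#' @param max_radius guard on the search depth.
#' @return minimum number of DCJ operations (integer).
#' @export
bfs_dcj_distance <- function(A, B, max_radius = 10L) {
  cn <- census(A, B)
  if (length(cn$exclusive) > 0L || !is_singular_pair(cn))
    stop("BFS sorter needs canonical genomes (identical singular content)")
  target <- adjacency_state_key(genome_adjacencies(B))
  start <- genome_adjacencies(A)
  if (adjacency_state_key(start) == target) return(0L)
  frontier <- list(start)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  assign(adjacency_state_key(start), TRUE, envir = seen)
  for (depth in seq_len(max_radius)) {
    nxt <- list()
    for (st in frontier) {
      for (nb in dcj_neighbor_states(st)) {
        key <- adjacency_state_key(nb)
        if (key == target) return(depth)
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- nb
        }
      }
    }
    frontier <- nxt
    if (length(frontier) == 0L) break
  }
  stop("BFS radius guard (", max_radius, ") exceeded")
}
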