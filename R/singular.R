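# Closed-form DCJ-indel distance for singular genomes:
#   d(A,B) = |G| - c - i/2 + sum_C lambda(C) - delta,
# where c counts AB-cycles, i counts AB-paths, lambda is the indel
# potential of a component and delta is the total deduction obtained by
# greedily applying the chained path-recombination groups.

#' Indel potential of a component
#'
#' The minimum number of indels chargeable to a component with `Lambda`
#' runs after optimally grouping its runs with DCJs: 0 for an indel-free
#' component, otherwise `ceiling((Lambda + 1) / 2)`.
#'
#' @param Lambda non-negative integer vector of run counts.
#' @return integer vector.
#' @export
indel_potential <- function(Lambda) {
  if (any(Lambda < 0)) stop("Lambda must be non-negative")
  ifelse(Lambda == 0L, 0L, as.integer(ceiling((Lambda + 1) / 2)))
}

#' Transition count of a cycle
#'
#' Number of indel-free stretches flanked by indel edges of opposite
#' genomes in a cycle with `Lambda` runs: 0 when `Lambda <= 1`, otherwise
#' `Lambda`. Satisfies `indel_potential(L) == transition_count(L)/2 + (L >= 1)`.
#'
#' @param Lambda non-negative integer vector of run counts.
#' @return integer vector.
#' @export
transition_count <- function(Lambda) {
  if (any(Lambda < 0)) stop("Lambda must be non-negative")
  ifelse(Lambda <= 1L, 0L, as.integer(Lambda))
}

# The eight deducting-relevant path types:
#   W  = AA-path, even number of runs (signature AB)
#   Wbar = AA-path, odd runs starting/ending in A; Wund = odd runs in B
#   M, Mbar, Mund = same for BB-paths
#   Z  = AB-path with signature AB; N = AB-path with signature BA
PATH_TYPES <- c("W", "Wbar", "Wund", "M", "Mbar", "Mund", "Z", "N")

#' Deducting path-type counts of a component list
#'
#' Classifies paths into the eight types that can take part in deducting
#' recombinations. Linear singletons are AA-/BB-paths with a single A-/B-run
#' and enter as Wbar/Mund accordingly.
#'
#' @param comps component list from [decompose()].
#' @return named integer vector over `W, Wbar, Wund, M, Mbar, Mund, Z, N`.
#' @export
path_type_counts <- function(comps) {
  counts <- stats::setNames(integer(8), PATH_TYPES)
  for (cp in comps) {
    L <- cp$Lambda
    if (cp$is_cycle || L == 0L) next
    type <- switch(cp$cls,
      AA_path = if (L %% 2L == 0L) "W" else if (cp$run_signature == "A") "Wbar" else "Wund",
      BB_path = if (L %% 2L == 0L) "M" else if (cp$run_signature == "A") "Mbar" else "Mund",
      AB_path = if (L %% 2L == 1L) NA_character_
                else if (cp$run_signature == "AB") "Z" else "N",
      NA_character_)
    if (!is.na(type)) counts[type] <- counts[type] + 1L
  }
  counts
}

# Chained recombination groups, applied top-down. Each row: the multiset of
# source path types consumed by one application of the group. Within a part
# all groups are exclusive once the earlier parts have been applied.
RECOMB_GROUPS <- list(
  P = list(c("W", "M")),
  Q = list(c("W", "W", "Mbar", "Mund"),
           c("M", "M", "Wbar", "Wund")),
  T = list(c("W", "Z", "Mbar"), c("W", "N", "Mund"),
           c("W", "W", "Mbar"), c("W", "W", "Mund"),
           c("M", "N", "Wbar"), c("M", "Z", "Wund"),
           c("M", "M", "Wbar"), c("M", "M", "Wund")),
  S = list(c("Z", "N"), c("Wbar", "Mbar"), c("Wund", "Mund"),
           c("W", "Mbar"), c("W", "Mund"), c("Wbar", "M"), c("Wund", "M"),
           c("W", "Z"), c("W", "N"), c("M", "Z"), c("M", "N"),
           c("W", "W"), c("M", "M")),
  M = list(c("Z", "Z", "Wund", "Mbar"),
           c("N", "N", "Wbar", "Mund")),
  N = list(c("Z", "Wund", "Mbar"), c("N", "Wbar", "Mund"),
           c("Z", "Z", "Wund"), c("Z", "Z", "Mbar"),
           c("N", "N", "Wbar"), c("N", "N", "Mund"))
)
RECOMB_DEDUCTION <- c(P = 2L, Q = 3L, T = 2L, S = 1L, M = 2L, N = 1L)

#' Greedy deduction over the chained recombination groups
#'
#' Applies the recombination groups top-down (parts P, Q, T, S, M, N; each
#' application consumes its source paths), returning the per-part counts
#' and the total deduction `delta = 2P + 3Q + 2T + S + 2M + N`.
#'
#' @param counts named vector of path-type counts as from
#'   [path_type_counts()]; alternatively pass individual counts via `...`.
#' @param ... named individual counts (`W`, `Wbar`, `Wund`, `M`, `Mbar`,
#'   `Mund`, `Z`, `N`) if `counts` is missing.
#' @return list with per-part application counts `P, Q, T, S, M, N` and
#'   `delta`.
#' @examples
#' greedy_delta(W = 2, Mbar = 1, Mund = 1)$delta  # 3, one Q group
#' @export
greedy_delta <- function(counts = NULL, ...) {
  if (is.null(counts)) counts <- unlist(list(...))
  full <- stats::setNames(integer(8), PATH_TYPES)
  if (length(counts)) {
    if (is.null(names(counts)) || !all(names(counts) %in% PATH_TYPES))
      stop("counts must be named with the eight path types")
    full[names(counts)] <- as.integer(counts)
  }
  if (any(full < 0L)) stop("negative path-type count")
  applied <- stats::setNames(integer(length(RECOMB_GROUPS)), names(RECOMB_GROUPS))
  for (part in names(RECOMB_GROUPS)) {
    for (grp in RECOMB_GROUPS[[part]]) {
      need <- table(grp)
      k <- min(full[names(need)] %/% as.integer(need))
      if (k > 0L) {
        full[names(need)] <- full[names(need)] - k * as.integer(need)
        applied[part] <- applied[part] + k
      }
    }
  }
  out <- as.list(applied)
  out$delta <- sum(RECOMB_DEDUCTION * applied)
  out
}

#' DCJ-indel distance of singular genomes (closed form)
#'
#' @param A,B singular `dcj_genome` objects (every common marker occurs
#'   exactly once in each genome; exclusive markers are unrestricted).
#' @return object of class `dcj_singular_distance`: a list with `distance`
#'   and the breakdown `n_common`, `c` (AB-cycles), `i` (AB-paths),
#'   `sum_lambda`, `delta`, plus the greedy deduction and the component
#'   summary.
#' @export
distance_singular <- function(A, B) {
  dg <- build_relational(A, B)
  comps <- decompose(dg)
  cs <- components_summary(comps)
  cc <- sum(cs$cls == "AB_cycle")
  ii <- sum(cs$cls == "AB_path")
  sum_lambda <- sum(indel_potential(cs$Lambda))
  ded <- greedy_delta(path_type_counts(comps))
  n_common <- length(dg$census$common)
  d <- n_common - cc - ii / 2 + sum_lambda - ded$delta
  structure(list(distance = as.integer(d), n_common = n_common,
                 c = cc, i = ii, sum_lambda = sum_lambda,
                 delta = ded$delta, deduction = ded,
                 components = cs),
            class = "dcj_singular_distance")
}

#' @export
print.dcj_singular_distance <- function(x, ...) {
  cat("DCJ-indel distance (singular):", x$distance, "\n")
  cat("|G| =", x$n_common, " c =", x$c, " i =", x$i,
      " sum lambda =", x$sum_lambda, " delta =", x$delta, "\n")
  invisible(x)
}
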