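# Indel potential, transition counts, greedy deduction, closed-form distance.

test_that("indel potential follows the run-count formula", {
  expect_equal(indel_potential(0), 0L)
  expect_equal(indel_potential(1), 1L)
  expect_equal(indel_potential(4), 3L)
  expect_equal(indel_potential(0:6), c(0L, 1L, 2L, 2L, 3L, 3L, 4L))
  expect_error(indel_potential(-1), "non-negative")
})

test_that("transition count vanishes up to one run, then equals it", {
  expect_equal(transition_count(0), 0L)
  expect_equal(transition_count(1), 0L)
  expect_equal(transition_count(4), 4L)
  # lambda(L) = aleph(L)/2 + [L >= 1] for all run counts
  L <- 0:50
  expect_equal(indel_potential(L),
               as.integer(transition_count(L) / 2 + (L >= 1)))
})

test_that("greedy deduction reproduces the reference group deductions", {
  expect_equal(greedy_delta()$delta, 0L)
  d1 <- greedy_delta(W = 1, M = 1)
  expect_equal(d1$P, 1L)
  expect_equal(d1$delta, 2L)
  d2 <- greedy_delta(W = 2, Mbar = 1, Mund = 1)
  expect_equal(d2$Q, 1L)
  expect_equal(d2$delta, 3L)
  d3 <- greedy_delta(Z = 1, N = 1)
  expect_equal(d3$S, 1L)
  expect_equal(d3$delta, 1L)
  expect_error(greedy_delta(c(bogus = 1)), "path types")
})

test_that("greedy deduction equals the brute-force optimum over the
           recombination operations", {
  set.seed(61)
  types <- c("W", "Wbar", "Wund", "M", "Mbar", "Mund", "Z", "N")
  for (i in 1:400) {
    counts <- stats::setNames(integer(8), types)
    k <- sample(1:5, 1)
    counts[sample(types, k)] <- sample(0:3, k, replace = TRUE)
    expect_equal(greedy_delta(counts)$delta,
                 delta_bruteforce(counts),
                 info = paste(names(counts), counts, collapse = " "))
  }
})

test_that("path types are read off the component classification", {
  fx <- make_fixture("fig7")
  counts <- path_type_counts(decompose(build_relational(fx$A, fx$B)))
  expect_equal(unname(counts[c("W", "Mbar", "Mund")]), c(2L, 1L, 1L))
  expect_equal(sum(counts), 4L)
  expect_equal(greedy_delta(counts)$delta, 3L)
})

test_that("closed-form distance matches hand-checked instances", {
  fx <- make_fixture("fig6")
  ds <- distance_singular(fx$A, fx$B)
  expect_equal(ds$distance, 4L)
  expect_equal(ds$c, 0L)
  expect_equal(ds$i, 0L)
  expect_equal(ds$delta, 0L)

  A <- genome("A", list(chromosome(c("1", "2", "3"), circular = TRUE)))
  B <- genome("B", list(chromosome(c("1", "-2", "3"), circular = TRUE)))
  expect_equal(distance_singular(A, B)$distance, 1L)

  f7 <- make_fixture("fig7")
  d7 <- distance_singular(f7$A, f7$B)
  expect_equal(d7$delta, 3L)
  expect_equal(d7$sum_lambda, 6L)
  expect_equal(d7$distance, 7L)
})

test_that("distance is zero exactly on equal genomes and symmetric", {
  set.seed(71)
  for (i in 1:20) {
    p <- random_singular_pair()
    expect_equal(distance_singular(p$A, p$A)$distance, 0L)
    d <- distance_singular(p$A, p$B)$distance
    expect_equal(d, distance_singular(p$B, p$A)$distance)
    if (d == 0L) expect_true(genomes_equal(p$A, p$B))
    if (genomes_equal(p$A, p$B)) expect_equal(d, 0L)
  }
})

test_that("distance respects the cycle/path upper bound and the
           circular-genome formula", {
  set.seed(81)
  for (i in 1:20) {
    p <- random_singular_pair()
    ds <- distance_singular(p$A, p$B)
    bound <- ds$n_common - ds$c - ds$i / 2 + ds$sum_lambda
    expect_lte(ds$distance, bound)
    expect_gte(ds$distance, 0L)
    # no indel-enclosing path -> no deduction
    if (all(!ds$components$indel_enclosing[ds$components$cls %in%
                                           c("AA_path", "BB_path", "AB_path")]))
      expect_equal(ds$delta, 0L)
  }
  # circular-only pairs: distance = |G| - c + sum lambda (diagram is cycles only)
  for (i in 1:10) {
    p <- random_singular_pair(p_circular = 1)
    ds <- distance_singular(p$A, p$B)
    expect_equal(ds$i, 0L)
    expect_equal(ds$delta, 0L)
    expect_equal(ds$distance, ds$n_common - ds$c + ds$sum_lambda)
  }
})

test_that("non-singular input is rejected", {
  fx <- make_fixture("sec2_running")
  expect_error(distance_singular(fx$A, fx$B), "duplicated common marker")
})
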