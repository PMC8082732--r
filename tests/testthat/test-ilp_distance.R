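# ILP model construction contracts and solved distances.

test_that("model shape: cap edge count, sibling rows, no s-variables
           without circular chromosomes", {
  p <- list(A = genome("A", list(c("1", "2", "x"))),
            B = genome("B", list(c("2", "1", "y"))))
  dg <- build_multi_relational(p$A, p$B, capped = TRUE)
  ed <- dg$edges
  # one linear chromosome each: p* = 1, complete bipartite 2x2 cap edges
  expect_equal(sum(ed$kind == "cap"), 4L)
  m <- build_ilp(dg)
  expect_length(m$s_vars, 0L)
  # adjacency edges are fixed, not free variables
  expect_true(all(is.na(m$x_of[ed$kind %in% c("adjacency", "artificial")])))
  expect_true(all(!is.na(m$x_of[ed$kind %in% c("extremity", "indel", "cap")])))
  expect_error(build_ilp(build_multi_relational(p$A, p$B)), "capped")
})

test_that("LP relaxation bounds the integer optimum from above", {
  fx <- make_fixture("sec2_running")
  m <- build_ilp(build_multi_relational(fx$A, fx$B, capped = TRUE))
  ilp <- solve_ilp(m)
  lp <- solve_ilp(m, relax = TRUE)
  expect_gte(lp$objective + 1e-9, ilp$objective)
})

test_that("identity genomes solve to distance zero", {
  fx <- make_fixture("sec2_running")
  s <- distance_natural(fx$A, fx$A)
  expect_equal(s$distance, 0L)
  expect_equal(s$status, "optimal")
  # all cycles in the decoded decomposition are indel-free
  expect_true(all(s$components$Lambda == 0L))
})

test_that("ILP distance equals the closed form on random singular pairs", {
  set.seed(91)
  for (i in 1:30) {
    p <- random_singular_pair()
    expect_equal(distance_natural(p$A, p$B)$distance,
                 distance_singular(p$A, p$B)$distance,
                 info = paste(write_genomes(list(p$A, p$B)), collapse = " / "))
  }
})

test_that("ILP distance equals the exhaustive matching minimum on the
           duplicated running example", {
  fx <- make_fixture("fig5")
  s <- distance_natural(fx$A, fx$B)
  expect_equal(s$status, "optimal")
  expect_equal(s$distance, min_over_matchings(fx$A, fx$B))
  expect_equal(s$duplicate_occurrences,
               sum(c(2L, 2L, 2L) , 3L, 3L))  # A: 3,4,5 twice; B: 1,3 thrice
  expect_equal(s$max_multiplicity, 3L)
})

test_that("decoded solutions reproduce the objective from component
           statistics", {
  set.seed(101)
  for (i in 1:12) {
    p <- random_natural_pair(max_occ = 6)
    s <- distance_natural(p$A, p$B)
    cs <- s$components
    obj <- sum(cs$Lambda == 0L & cs$cls == "AB_cycle") -
      sum(cs$transitions[cs$cls == "AB_cycle"]) / 2 -
      sum(cs$cls == "circular_singleton")
    expect_equal(obj, s$objective)
    expect_equal(s$distance, s$n_star + s$p_star - s$objective)
  }
})

test_that("distance is invariant under chromosome reversal and rotation", {
  set.seed(111)
  fx <- make_fixture("sec2_running")
  d0 <- distance_natural(fx$A, fx$B)$distance
  # reverse the chromosome of A
  toksA <- rev(paste0(ifelse(fx$A$chromosomes[[1]]$strand < 0, "", "-"),
                      fx$A$chromosomes[[1]]$marker))
  Arev <- genome("A", list(toksA))
  expect_equal(distance_natural(Arev, fx$B)$distance, d0)
  # circular rotation of a circular pair
  A <- genome("A", list(chromosome(c("1", "2", "3", "x"), circular = TRUE)))
  B <- genome("B", list(chromosome(c("1", "3", "-2", "y"), circular = TRUE)))
  Brot <- genome("B", list(chromosome(c("-2", "y", "1", "3"), circular = TRUE)))
  expect_equal(distance_natural(A, B)$distance,
               distance_natural(A, Brot)$distance)
})

test_that("restricting to a fixed sibling set can only increase the
           distance", {
  set.seed(121)
  for (i in 1:6) {
    p <- random_natural_pair(max_occ = 6)
    s <- distance_natural(p$A, p$B)
    dg <- build_multi_relational(p$A, p$B)
    for (mt in sibling_sets(dg, max_sets = 5000)) {
      msg <- matched_singular_genomes(p$A, p$B, mt)
      expect_lte(s$distance, distance_singular(msg$A, msg$B)$distance)
    }
  }
})

test_that("genomes sharing no markers are legal and cost only indels", {
  A <- genome("A", list(c("a1", "a2")))
  B <- genome("B", list(c("b1", "b2", "b3")))
  s <- distance_natural(A, B)
  # one deletion of the whole A-run, one insertion of the whole B-run
  expect_equal(s$distance, 2L)
})

test_that("circular singletons are charged one indel each", {
  A <- genome("A", list(chromosome(c("1", "2"), circular = TRUE),
                        chromosome(c("x1", "x2"), circular = TRUE)))
  B <- genome("B", list(chromosome(c("1", "2"), circular = TRUE)))
  s <- distance_natural(A, B)
  expect_equal(s$distance, 1L)
  expect_equal(sum(s$components$cls == "circular_singleton"), 1L)
})
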