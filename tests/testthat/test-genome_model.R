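# Genome parsing/writing, marker census arithmetic, PHYLIP output.

test_that("UniMoG parsing handles linear/circular chromosomes and signs", {
  gs <- parse_genomes(c(">A", "1 -6 5 3 |", "4 2 |"), text = TRUE)
  expect_named(gs, "A")
  A <- gs$A
  expect_length(A$chromosomes, 2L)
  expect_equal(A$chromosomes[[1]]$marker, c("1", "6", "5", "3"))
  expect_equal(A$chromosomes[[1]]$strand, c(1L, -1L, 1L, 1L))
  expect_false(A$chromosomes[[1]]$circular)
  expect_equal(length(A$chromosomes[[2]]$marker), 2L)

  circ <- parse_genomes(">X\n1 2 )", text = TRUE)$X
  expect_true(circ$chromosomes[[1]]$circular)
  # comments and attached terminators
  gs2 <- parse_genomes(c("# header comment", ">Y", "1 2| # trailing"), text = TRUE)
  expect_equal(length(gs2$Y$chromosomes[[1]]$marker), 2L)
})

test_that("malformed genome files are rejected", {
  expect_error(parse_genomes(c(">A", "1 2"), text = TRUE), "unterminated")
  expect_error(parse_genomes(c(">A", "|"), text = TRUE), "empty chromosome")
  expect_error(parse_genomes(c(">A", "1 |", ">A", "2 |"), text = TRUE), "duplicate")
  expect_error(parse_genomes(c("1 2 |"), text = TRUE), "before any")
  expect_error(chromosome(c("a(b")), "reserved")
  expect_error(chromosome(character(0)), "empty")
})

test_that("parse-write round trip is the identity on canonical genomes", {
  set.seed(101)
  for (i in 1:25) {
    p <- random_singular_pair()
    lines <- write_genomes(list(p$A, p$B))
    back <- parse_genomes(lines, text = TRUE)
    expect_true(genomes_equal(back$A, p$A))
    expect_true(genomes_equal(back$B, p$B))
    # bit-exact round trip of the serialized form
    expect_identical(write_genomes(back), lines)
  }
})

test_that("circular chromosomes compare equal under rotation and reversal", {
  a <- genome("G", list(chromosome(c("1", "2", "3"), circular = TRUE)))
  b <- genome("G", list(chromosome(c("2", "3", "1"), circular = TRUE)))
  c <- genome("G", list(chromosome(c("-3", "-2", "-1"), circular = TRUE)))
  expect_true(genomes_equal(a, b))
  expect_true(genomes_equal(a, c))
  d <- genome("G", list(chromosome(c("1", "-2", "3"), circular = TRUE)))
  expect_false(genomes_equal(a, d))
})

test_that("census reproduces the running-example multiplicity table", {
  fx <- make_fixture("sec2_running")
  cn <- census(fx$A, fx$B)
  expect_equal(unname(cn$deltaPhi[c("1", "2", "3", "4", "5", "6", "7")]),
               c(-2L, 0L, -1L, 1L, 2L, -1L, -1L))
  expect_setequal(cn$common, c("1", "2", "3", "4"))
  expect_equal(cn$n_star, 5L)
  tab <- as.data.frame(cn)
  expect_equal(tab$deltaPhi[tab$marker == "5"], 2L)
})

test_that("census invariants hold: symmetry, self-comparison, n* bound", {
  set.seed(7)
  for (i in 1:20) {
    p <- random_natural_pair()
    cn <- census(p$A, p$B)
    rc <- census(p$B, p$A)
    expect_equal(cn$n_star, rc$n_star)
    expect_equal(unname(cn$deltaPhi), unname(-rc$deltaPhi[names(cn$deltaPhi)]))
    expect_lte(cn$n_star, min(sum(cn$phiA), sum(cn$phiB)))
    expect_equal(cn$p_star, max(cn$kappaA, cn$kappaB))
    expect_equal(cn$a_star, abs(cn$kappaA - cn$kappaB))
    self <- census(p$A, p$A)
    expect_true(all(self$deltaPhi == 0L))
    expect_equal(self$n_star, sum(self$phiA))
    expect_equal(self$a_star, 0L)
  }
})

test_that("PHYLIP matrix writing and reading round-trip", {
  lines <- write_distance_matrix(c("A", "B"), matrix(c(0, 4, 4, 0), 2))
  expect_equal(lines[1], "2")
  expect_match(lines[2], "^A\\s+0 4$")
  back <- read_distance_matrix(lines, text = TRUE)
  expect_equal(unname(back), matrix(c(0, 4, 4, 0), 2))
  one <- write_distance_matrix("A", matrix(0, 1, 1))
  expect_equal(read_distance_matrix(one, text = TRUE)[1, 1], 0)
  expect_error(write_distance_matrix(c("A", "B"), matrix(c(0, 1, 2, 0), 2)),
               "symmetric")
  expect_error(write_distance_matrix(c("A", "B"), matrix(c(1, 2, 2, 0), 2)),
               "diagonal")
  set.seed(3)
  D <- matrix(sample(0:50, 16), 4)
  D <- D + t(D); diag(D) <- 0
  nm <- c("dbus", "dmel", "dsec", "dyak")
  expect_equal(unname(read_distance_matrix(write_distance_matrix(nm, D),
                                           text = TRUE)), D)
})
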