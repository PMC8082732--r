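# Diagram construction, component decomposition, runs, sibling sets.

test_that("relational diagram of the two-chromosome example has the
           reference component census", {
  fx <- make_fixture("fig1")
  cs <- components_summary(decompose(build_relational(fx$A, fx$B)))
  expect_equal(sum(cs$cls == "AB_cycle"), 1L)
  expect_equal(sum(cs$cls == "AB_path"), 2L)
  expect_equal(sum(cs$cls == "AA_path"), 1L)
  expect_equal(sum(cs$cls == "BB_path"), 1L)
  # the BB-path is the linear singleton chromosome of exclusive markers
  expect_true(cs$linear_singleton[cs$cls == "BB_path"])
  expect_equal(cs$Lambda[cs$cls == "AB_cycle"], 2L)
})

test_that("self-comparison of a linear genome yields the expected parts", {
  A <- genome("A", list(c("1", "2", "3")))
  cs <- components_summary(decompose(build_relational(A, A)))
  expect_equal(sum(cs$cls == "AB_path"), 2L)
  expect_equal(sum(cs$cls == "AB_cycle"), 2L)
  expect_true(all(cs$Lambda == 0L))
  # each cycle holds two extremity edges and two adjacencies
  expect_equal(sort(cs$n_edges[cs$cls == "AB_cycle"]), c(4L, 4L))
})

test_that("canonical two-chromosome pair decomposes into AA- and BB-paths", {
  fx <- make_fixture("fig6")
  cs <- components_summary(decompose(build_relational(fx$A, fx$B)))
  expect_equal(sum(cs$cls == "AA_path"), 2L)
  expect_equal(sum(cs$cls == "BB_path"), 2L)
  expect_equal(sum(cs$cls == "AB_cycle"), 0L)
})

test_that("capped multi-relational diagram has 4 p* cap vertices and the
           indel edges follow the sign of Delta-Phi", {
  fx <- make_fixture("sec2_running")
  dg <- build_multi_relational(fx$A, fx$B, capped = TRUE)
  expect_equal(nrow(dg$vertices), 16L + 20L + 4L)
  expect_equal(dg$census$p_star, 1L)
  expect_equal(dg$census$a_star, 0L)
  ed <- dg$edges
  expect_setequal(unique(ed$marker[ed$kind == "indel" & ed$genome == "A"]),
                  c("4", "5"))
  expect_setequal(unique(ed$marker[ed$kind == "indel" & ed$genome == "B"]),
                  c("1", "3", "6", "7"))
  # one indel edge per occurrence of an over-represented marker
  expect_equal(sum(ed$kind == "indel" & ed$genome == "A" & ed$marker == "5"), 2L)
  expect_equal(sum(ed$kind == "indel" & ed$genome == "B" & ed$marker == "1"), 3L)
  # complete bipartite cap edges: (2 p*)^2
  expect_equal(sum(ed$kind == "cap"), 4L)
})

test_that("for singular genomes the multi-relational diagram reduces to the
           relational diagram", {
  set.seed(21)
  for (i in 1:10) {
    p <- random_singular_pair()
    d1 <- build_relational(p$A, p$B)
    d2 <- build_multi_relational(p$A, p$B, capped = FALSE)
    expect_identical(d1$edges, d2$edges)
    expect_identical(d1$vertices, d2$vertices)
  }
  fx <- make_fixture("sec2_running")
  expect_error(build_relational(fx$A, fx$B), "duplicated common marker")
})

test_that("telomere and AB-path counts are even in every relational diagram", {
  set.seed(31)
  for (i in 1:25) {
    p <- random_singular_pair()
    dg <- build_relational(p$A, p$B)
    cs <- components_summary(decompose(dg))
    expect_equal(sum(cs$cls == "AB_path") %% 2L, 0L)
    expect_equal((length(dg$telomeres$A) + length(dg$telomeres$B)) %% 2L, 0L)
  }
})

test_that("a component with runs B,A,B,A counts four runs", {
  # a BB-path alternating B- and A-runs twice
  A <- genome("A", list(c("c2", "x1", "c1"), c("c4", "x2", "c3")))
  B <- genome("B", list(c("y1", "c1"), c("c2", "y2", "c3"), "c4"))
  cs <- components_summary(decompose(build_relational(A, B)))
  bb <- cs[cs$cls == "BB_path", ]
  expect_equal(bb$Lambda, 4L)
  expect_equal(bb$run_signature, "AB")
  expect_equal(indel_potential(bb$Lambda), 3L)
})

test_that("indel-free components have no runs and no transitions", {
  fx <- make_fixture("fig6")
  cs <- components_summary(decompose(build_relational(fx$A, fx$B)))
  expect_true(all(cs$Lambda == 0L))
  expect_true(all(cs$transitions == 0L))
  expect_true(all(!cs$indel_enclosing))
})

test_that("decompose() rejects degree-3 selections and missing adjacencies", {
  fx <- make_fixture("sec2_running")
  dg <- build_multi_relational(fx$A, fx$B)
  expect_error(decompose(dg), "degree > 2")
  ed <- dg$edges
  not_all_adj <- setdiff(seq_len(nrow(ed)), which(ed$kind == "adjacency")[1])
  expect_error(decompose(dg, not_all_adj), "adjacency")
})

test_that("sibling sets enumerate injections per common marker", {
  A <- genome("A", list(c("1")))
  B <- genome("B", list(c("1", "1", "1")))
  dg <- build_multi_relational(A, B)
  expect_length(sibling_sets(dg), 3L)
  p <- random_singular_pair()
  expect_length(sibling_sets(build_multi_relational(p$A, p$B)), 1L)
  fx <- make_fixture("fig5")
  # Phi products: marker 1 (1 vs 3), 3 (2 vs 3), 4 (2 vs 1), 2 (1 vs 1)
  expect_length(sibling_sets(build_multi_relational(fx$A, fx$B)), 3L * 6L * 2L)
  expect_error(sibling_sets(build_multi_relational(fx$A, fx$B), max_sets = 5),
               "guard")
})

test_that("induced consistent decompositions equal the relational diagram of
           the matched singular genomes", {
  set.seed(41)
  for (i in 1:12) {
    p <- random_natural_pair(max_occ = 6)
    dg <- build_multi_relational(p$A, p$B)
    sets <- sibling_sets(dg, max_sets = 5000)
    for (mt in sets[seq_len(min(4, length(sets)))]) {
      sel <- induce_decomposition(dg, sibling_edges(dg, mt))
      cs1 <- components_summary(decompose(dg, sel))
      msg <- matched_singular_genomes(p$A, p$B, mt)
      cs2 <- components_summary(decompose(build_relational(msg$A, msg$B)))
      key <- function(cs) sort(paste(cs$cls, cs$Lambda, cs$run_signature))
      expect_equal(key(cs1), key(cs2))
    }
  }
})

test_that("capped consistent decompositions consist of cycles only", {
  set.seed(51)
  for (i in 1:8) {
    p <- random_cappable_pair()
    dg <- build_multi_relational(p$A, p$B, capped = TRUE)
    mt <- sibling_sets(dg, max_sets = 5000)[[1]]
    P <- capping_sets(dg, max_sets = 5000)[[1]]
    comps <- decompose(dg, induce_decomposition(dg, sibling_edges(dg, mt), P))
    expect_true(all(vapply(comps, `[[`, TRUE, "is_cycle")))
    expect_equal(sum(lengths(lapply(comps, `[[`, "vertices"))),
                 nrow(dg$vertices))
  }
})

test_that("DOT export emits one line per vertex and edge", {
  fx <- make_fixture("fig6")
  dg <- build_relational(fx$A, fx$B)
  dot <- diagram_to_dot(dg)
  expect_equal(length(dot), nrow(dg$vertices) + nrow(dg$edges) + 2L)
})
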