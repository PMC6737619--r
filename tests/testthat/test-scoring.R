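make_scored <- function(Q, l_s = rep(100L, length(Q))) {
  data.frame(query_id = sprintf("s%d", seq_along(Q)), l_s = l_s,
             gap_bp = 0L, aligned_query_bp = l_s, lambda = l_s,
             m_s = 0L, eps_s = 0, assigned_chrom = "chr1",
             R = 1, P = 0, L = 1, Q = Q, stringsAsFactors = FALSE)
}

test_that("reward is the aligned fraction of non-gap bases", {
  sc <- seq_set(c(s1 = paste0(strrep("A", 450), strrep("N", 100),
                              strrep("C", 450))))$s1
  expect_equal(gap_bp(sc), 100L)
  full <- scaffscore:::new_chain("s1", 1000L, rbind(
    aln_row(q_start = 0, q_end = 450),
    aln_row(q_start = 550, q_end = 1000, r_start = 550)))
  expect_equal(reward(sc, full), 1.0)

  nogap <- seq_set(c(s1 = strrep("A", 1000)))$s1
  half <- scaffscore:::new_chain("s1", 1000L,
                                 aln_row(q_start = 0, q_end = 450))
  expect_equal(reward(nogap, half), 0.45)

  empty <- scaffscore:::new_chain("s1", 1000L, aln_row()[0, ])
  expect_equal(reward(nogap, empty), 0)

  allgap <- seq_set(c(s1 = strrep("N", 50)), min_gap_len = 10)$s1
  expect_warning(r <- reward(allgap, empty), "non-gap")
  expect_equal(r, 0)
})

test_that("penalty is log base 100 of unexplained misassemblies", {
  expect_equal(penalty(0, 0), 0)
  expect_equal(penalty(1, 0), 0)     # difference must exceed 1
  expect_equal(penalty(5, 4.5), 0)
  expect_equal(penalty(100, 0), 1)   # log100(100)
  expect_equal(penalty(10, 0), 0.5)  # log100(10)
  expect_equal(penalty(110, 10), 1)
  expect_gt(penalty(1000, 0), penalty(100, 0))
})

test_that("length scaling rewards scaffolds approaching the shortest chromosome", {
  theta <- 1e6
  expect_equal(length_scaling(theta, theta), 1)
  expect_equal(length_scaling(5 * theta, theta), 1)
  expect_equal(length_scaling(theta / 10, theta), 0.5)
  expect_equal(length_scaling(theta / 100, theta), 1 / 3)
  ls <- 10^(2:6)
  vals <- length_scaling(ls, theta)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals > 0 & vals <= 1))
})

test_that("scaffold quality combines its three components exactly", {
  expect_equal(scaffold_quality(1, 0, 1), 1)
  expect_equal(scaffold_quality(1, 1, 1), 0.5)
  expect_equal(scaffold_quality(0.8, 0, 0.5), 0.4)
  set.seed(8)
  R <- runif(20); P <- rexp(20); L <- runif(20)
  Q <- scaffold_quality(R, P, L)
  expect_equal(Q, L * R / (1 + P))
  expect_true(all(Q >= 0 & Q <= 1))
})

test_that("quality-distribution curve area matches hand-computed trapezoids", {
  perfect <- make_scored(Q = c(1, 1, 1))
  qa <- quality_curve_area(perfect)
  expect_equal(qa$delta, 1)
  expect_true(all(qa$curve$value == 1))

  worthless <- make_scored(Q = c(0, 0))
  expect_equal(quality_curve_area(worthless)$delta, 0.005)

  # lengths 100 at Q=1 and 300 at Q=0.5:
  # 50 trapezoids at 1, one at (1 + 0.25)/2, 49 at 0.25
  mixed <- make_scored(Q = c(1, 0.5), l_s = c(100L, 300L))
  expect_equal(quality_curve_area(mixed)$delta, 0.62875)
})

test_that("both curves are non-increasing step functions with exact areas", {
  set.seed(9)
  scores <- make_scored(Q = round(runif(30), 3),
                        l_s = sample(50:500, 30, replace = TRUE))
  qa <- quality_curve_area(scores)
  expect_true(all(diff(qa$curve$value) <= 0))
  expect_true(all(qa$curve$value >= 0 & qa$curve$value <= 1))
  v <- qa$curve$value
  expect_equal(qa$delta, sum((v[-1] + v[-101]) / 2) * 0.01)
})

test_that("coverage curve measures reference unions at each quality threshold", {
  ref <- toy_reference(2, 10000, seed = 3)
  tiling <- tiling_assembly(ref, per_chrom = 1)  # whole-chromosome scaffolds
  chains <- filter_chains(tiling$truth)
  scores <- score_scaffolds(tiling$scaffolds, chains, ref)
  expect_true(all(scores$Q == 1))
  cc <- coverage_curve_area(scores, chains, ref)
  expect_equal(cc$omega, 1)
  expect_equal(cc$phi, 20000)

  # no alignments at all
  un <- seq_set(c(u1 = strrep("A", 500)))
  s0 <- score_scaffolds(un, list(), ref)
  cc0 <- coverage_curve_area(s0, list(), ref)
  expect_equal(cc0$omega, 0)
  expect_equal(cc0$phi, 0)

  # half the reference covered by one perfect scaffold: constant 0.5 curve
  half <- list(scaffolds = structure(tiling$scaffolds[1], class = "seq_set"),
               truth = tiling$truth[tiling$truth$query_id ==
                                      seq_ids(tiling$scaffolds)[1], ])
  ch2 <- filter_chains(half$truth)
  s2 <- score_scaffolds(half$scaffolds, ch2, ref)
  cc2 <- coverage_curve_area(s2, ch2, ref)
  expect_equal(cc2$omega, 0.5)
  expect_true(all(cc2$curve$value == 0.5))
})

test_that("inverted redundancy is the union-over-sum reference ratio", {
  disjoint <- make_scored(Q = c(1, 1), l_s = c(100L, 100L))
  expect_equal(inverted_redundancy(disjoint, phi = 200), 1)

  # two 100 bp alignments overlapping by 50 bp on the reference
  overl <- make_scored(Q = c(1, 1), l_s = c(100L, 100L))
  expect_equal(inverted_redundancy(overl, phi = 150), 0.75)

  # k identical scaffolds over the same region
  k <- 4
  same <- make_scored(Q = rep(1, k), l_s = rep(100L, k))
  expect_equal(inverted_redundancy(same, phi = 100), 1 / k)

  none <- make_scored(Q = 0)
  none$lambda <- 0
  expect_warning(p <- inverted_redundancy(none, phi = 0), "undefined")
  expect_equal(p, 0)
})

test_that("assembly quality is the geometric mean of its components", {
  expect_equal(assembly_quality(1, 1, 1), 1)
  expect_equal(assembly_quality(0.512, 1, 1), 0.8)
  expect_equal(assembly_quality(0, 0.9, 0.9), 0)
  set.seed(10)
  for (i in 1:10) {
    x <- runif(3)
    expect_equal(assembly_quality(x[1], x[2], x[3]),
                 (x[1] * x[2] * x[3])^(1 / 3))
  }
})

test_that("scores are invariant under scaffold reordering and renaming", {
  ref <- toy_reference(3, 20000, seed = 6)
  sim <- sample_scaffolds(ref, mean_len = 2000, sd_len = 200,
                          coverage_fold = 0.8, seed = 7)
  base <- score_truth(sim, ref)

  # reorder
  perm <- rev(seq_along(sim$scaffolds))
  reord <- sim
  reord$scaffolds <- structure(sim$scaffolds[perm], class = "seq_set")
  reord$truth <- sim$truth[rev(seq_len(nrow(sim$truth))), ]
  sc_r <- score_truth(reord, ref)
  expect_equal(sc_r$quality, base$quality)
  expect_equal(sc_r$delta, base$delta)
  expect_equal(sc_r$omega, base$omega)
  expect_equal(sc_r$pi, base$pi)

  # rename
  ren <- sim
  map <- stats::setNames(sprintf("renamed_%03d", seq_along(sim$scaffolds)),
                         seq_ids(sim$scaffolds))
  ren$truth$query_id <- unname(map[ren$truth$query_id])
  ren$scaffolds <- structure(lapply(sim$scaffolds, function(e) {
    e$id <- unname(map[e$id]); e
  }), names = unname(map), class = "seq_set")
  sc_n <- score_truth(ren, ref)
  expect_equal(sc_n$quality, base$quality)
})

test_that("unaligned scaffolds dilute the quality curve but keep Q in range", {
  ref <- toy_reference(2, 10000, seed = 12)
  tl <- tiling_assembly(ref, 1)
  extra <- seq_set(c(orphan = strrep("ACGT", 500)))
  scaffolds <- structure(c(tl$scaffolds, extra), class = "seq_set")
  chains <- filter_chains(tl$truth)
  sc <- score_assembly(scaffolds, chains, ref)
  orow <- sc$scaffolds[sc$scaffolds$query_id == "orphan", ]
  expect_equal(orow$Q, 0)
  expect_equal(orow$R, 0)
  # orphan length feeds the denominator: curve below 1 at high thresholds
  expect_lt(sc$delta, 1)
  expect_equal(sc$omega, 1)  # coverage unaffected
  expect_true(all(sc$scaffolds$Q >= 0 & sc$scaffolds$Q <= 1))
})
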