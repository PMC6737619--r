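test_that("chromosome fragmentation tiles the chromosome exactly once", {
  chrom <- seq_set(c(c1 = strrep("ACGT", 25)))$c1  # 100 bp
  frags <- fragment_chromosome(chrom, seed = 1, min_len = 25, max_len = 25)
  expect_equal(frags$start, c(0L, 25L, 50L, 75L))
  expect_equal(frags$end, c(25L, 50L, 75L, 100L))

  ref <- toy_reference(1, 50000, seed = 2)
  f1 <- fragment_chromosome(ref[[1]], seed = 9, min_len = 2000,
                            max_len = 8000)
  expect_equal(sum(f1$length), ref[[1]]$length)
  expect_equal(f1$start[-1], f1$end[-nrow(f1)])  # contiguous
  f2 <- fragment_chromosome(ref[[1]], seed = 9, min_len = 2000,
                            max_len = 8000)
  expect_identical(f1, f2)  # deterministic given seed
  # chromosome shorter than min_len: one fragment
  short <- seq_set(c(s = strrep("A", 1000)))$s
  expect_equal(nrow(fragment_chromosome(short, 1, 5000, 9000)), 1L)
})

test_that("artifact observations re-evaluate relocations across the threshold grid", {
  # chain with one breakpoint of |d| = 5000: artifact 1 below, 0 at/above
  tab <- aln_tab(aln_row(q_start = 0, q_end = 1000, r_start = 0),
                 aln_row(q_start = 1000, q_end = 2000, r_start = 6000))
  chains <- list(f1 = filter_chain(tab))
  grid <- c(1000, 4900, 5000, 8000)
  obs <- artifact_observations(chains, c(f1 = 2000L), t_grid = grid)
  expect_equal(obs$eps, c(1, 1, 0, 0))
  expect_equal(obs$t, grid)
  expect_equal(unique(obs$chrom), "chr1")

  # single perfect alignment: zero artifact at every threshold
  perf <- list(p = filter_chain(aln_row(q_end = 1000)))
  obs2 <- artifact_observations(perf, c(p = 1000L), t_grid = grid)
  expect_true(all(obs2$eps == 0))

  # cardinality: |grid| x |fragments| observations
  both <- c(chains, perf)
  obs3 <- artifact_observations(both, c(f1 = 2000L, p = 1000L),
                                t_grid = seq(100, 1000, 100))
  expect_equal(nrow(obs3), 20L)
})

test_that("unaligned fragments contribute zero artifact with a warning", {
  chains <- list(f0 = filter_chain(aln_row()[0, ]))
  expect_warning(
    obs <- artifact_observations(chains, c(f0 = 500L), t_grid = c(100, 200)),
    "no alignments")
  expect_equal(obs$eps, c(0L, 0L))
  expect_true(all(is.na(obs$chrom)))
})

test_that("least squares recovers planted artifact-model coefficients", {
  grid <- expand.grid(l = seq(50000, 1000000, length.out = 20),
                      t = seq(100, 10000, 100))
  planted <- c(alpha = 1e-6, beta = -1e-4, k = 0.5)
  obs <- data.frame(chrom = "chr1", l = grid$l, t = grid$t,
                    eps = planted["alpha"] * grid$l +
                      planted["beta"] * grid$t + planted["k"])
  model <- fit_artifact_model(obs)
  expect_equal(model$alpha, 1e-6, tolerance = 1e-6)
  expect_equal(model$beta, -1e-4, tolerance = 1e-6)
  expect_equal(model$intercept, 0.5, tolerance = 1e-6)
})

test_that("degenerate artifact designs fall back gracefully", {
  grid <- expand.grid(l = c(1000, 2000, 3000), t = c(100, 200))
  zero <- data.frame(chrom = "c", l = grid$l, t = grid$t, eps = 0)
  m0 <- fit_artifact_model(zero)
  expect_equal(unlist(m0[, c("alpha", "beta", "intercept")]),
               c(alpha = 0, beta = 0, intercept = 0), tolerance = 1e-12)

  const <- data.frame(chrom = "c", l = grid$l, t = grid$t, eps = 7)
  mc <- fit_artifact_model(const)
  expect_equal(mc$alpha, 0, tolerance = 1e-12)
  expect_equal(mc$beta, 0, tolerance = 1e-12)
  expect_equal(mc$intercept, 7, tolerance = 1e-10)

  # constant l and t: rank deficient -> intercept-only with warning
  rd <- data.frame(chrom = "c", l = 1000, t = 100, eps = c(1, 2, 3))
  expect_warning(mrd <- fit_artifact_model(rd), "rank-deficient")
  expect_equal(unlist(mrd[, c("alpha", "beta", "intercept")]),
               c(alpha = 0, beta = 0, intercept = 2))
})

test_that("noisy estimates tighten as observations grow", {
  planted <- c(a = 2e-6, b = -5e-5, k = 1)
  gen <- function(n, seed) {
    set.seed(seed)
    l <- runif(n, 5e4, 1e6)
    t <- sample(seq(100, 10000, 100), n, replace = TRUE)
    data.frame(chrom = "c", l = l, t = t,
               eps = planted["a"] * l + planted["b"] * t + planted["k"] +
                 rnorm(n, sd = 0.3))
  }
  err <- vapply(c(200, 20000), function(n) {
    m <- fit_artifact_model(gen(n, seed = n))
    abs(m$alpha - planted["a"]) / planted["a"]
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("expected artifact is a clamped linear prediction", {
  model <- structure(
    data.frame(chrom = c("chr1", "chr2"), alpha = c(1e-6, 0),
               beta = c(0, 0), intercept = c(0, -1)),
    class = c("artifact_model", "data.frame"))
  expect_equal(expected_artifact(model, "chr1", 2e6, 1000), 2.0)
  expect_equal(expected_artifact(model, "chr2", 5e6, 1000), 0)  # clamp
  expect_warning(v <- expected_artifact(model, "chrX", 1e6, 1000),
                 "no artifact model")
  expect_equal(v, 0)
  expect_equal(expected_artifact(NULL, "chr1", 1e6, 1000), 0)
  # monotone in length when alpha > 0
  ls <- c(1e5, 1e6, 1e7)
  vals <- vapply(ls, function(l) expected_artifact(model, "chr1", l, 1000),
                 numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("self-consistent truth calibration yields near-zero coefficients", {
  ref <- toy_reference(2, 40000, seed = 5)
  cal <- calibrate_reference(ref, seed = 3, min_len = 3000, max_len = 9000,
                             t_grid = seq(100, 2000, 100))
  expect_equal(sort(cal$model$chrom), c("chr1", "chr2"))
  expect_true(all(abs(cal$model$alpha) < 1e-12))
  expect_true(all(abs(cal$model$beta) < 1e-12))
  expect_true(all(abs(cal$model$intercept) < 1e-12))
  expect_true(all(cal$observations$eps == 0))
})

test_that("calibration coefficients persist through the TSV round trip", {
  model <- fit_artifact_model(data.frame(
    chrom = rep(c("chr1", "chr2"), each = 6),
    l = rep(c(1e5, 5e5, 1e6), 4),
    t = rep(c(100, 1000), 6),
    eps = c(1:6 / 10, 2:7 / 10)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_calibration(model, f)
  back <- read_calibration(f)
  expect_equal(back$chrom, model$chrom)
  expect_equal(back$alpha, model$alpha, tolerance = 1e-12)
  expect_equal(back$beta, model$beta, tolerance = 1e-12)
  expect_equal(back$intercept, model$intercept, tolerance = 1e-12)
})
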