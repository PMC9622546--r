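# gPPI design and contrasts, partial Spearman correlation, sliding-window
# dynamics.

test_that("zscore normalises and is affine-invariant", {
  set.seed(70)
  x <- stats::rnorm(50, 10, 4)
  z <- zscore(x)
  expect_equal(mean(z), 0)
  expect_equal(stats::sd(z), 1)
  expect_equal(zscore(3 * x + 7), z)
  expect_equal(z, (x - mean(x)) / stats::sd(x))
  expect_error(zscore(rep(2, 10)), "zero variance")
})

test_that("gPPI interaction columns are the elementwise product", {
  sched <- build_dynamic_run_schedule(seed = 14)
  set.seed(71)
  seed_ts <- stats::rnorm(280)
  base <- build_design(sched)
  G <- build_gppi_design(base, seed_ts)
  sz <- zscore(seed_ts)
  cond_cols <- attr(base, "condition_cols")
  for (lev in names(cond_cols)) {
    expect_equal(unname(G[, paste0("ppi_", lev)]),
                 unname(sz * base[, cond_cols[lev]]))
  }
  expect_equal(unname(G[, "seed"]), sz)
  expect_equal(length(attr(G, "ppi_cols")), length(cond_cols))
  expect_error(build_gppi_design(base, seed_ts[1:100]))
})

test_that("centred seed of zero variance is rejected, zero products flagged", {
  sched <- build_dynamic_run_schedule(seed = 14)
  base <- build_design(sched)
  expect_error(build_gppi_design(base, rep(1, 280)), "zero variance")
})

test_that("zero-noise gPPI contrast equals the injected coupling difference", {
  sched <- build_dynamic_run_schedule(seed = 14)
  bp <- bold_sim_params(noise_sd = 0, drift_amp = 0)
  sim <- simulate_bold_dataset(sched, bp, seed = 3)
  base <- build_design(sched, sim$motion)
  G <- suppressWarnings(build_gppi_design(base, sim$roi$rAI))
  g <- suppressWarnings(
    gppi_contrast(sim$roi$mPFC, G, dyn_conditions_d1, dyn_conditions_d2))
  expect_equal(g$estimate, 0.6 - 0.2, tolerance = 1e-6)
})

test_that("partial Spearman handles the canonical cases", {
  set.seed(72)
  z <- stats::rnorm(30)
  x <- stats::rnorm(30)
  expect_equal(partial_spearman(x, x, z), 1)
  # mutually independent long samples decorrelate
  set.seed(73)
  expect_lt(abs(partial_spearman(stats::rnorm(1000), stats::rnorm(1000),
                                 stats::rnorm(1000))), 0.1)
  expect_true(is.na(partial_spearman(rep(1, 10), stats::rnorm(10),
                                     stats::rnorm(10))))
  # conditioning variable identical to x: undefined
  expect_true(is.na(partial_spearman(x, stats::rnorm(30), x)))
  expect_error(partial_spearman(1:3, 1:3, 1:3), "at least 4")
})

test_that("partial Spearman equals the residual-rank oracle on 5-point windows", {
  set.seed(74)
  for (i in 1:200) {
    x <- stats::rnorm(5)
    y <- stats::rnorm(5)
    z <- stats::rnorm(5)
    expect_equal(partial_spearman(x, y, z),
                 partial_spearman_oracle(x, y, z), tolerance = 1e-12)
  }
  # tied values handled by average ranks, still matching the oracle
  for (i in 1:100) {
    x <- sample(1:3, 5, replace = TRUE)
    y <- sample(1:3, 5, replace = TRUE)
    z <- sample(1:3, 5, replace = TRUE)
    got <- partial_spearman(x, y, z)
    want <- partial_spearman_oracle(x, y, z)
    if (is.na(want) || stats::sd(x) == 0 || stats::sd(y) == 0 ||
        stats::sd(z) == 0) next
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("partial Spearman is symmetric and monotone-invariant", {
  set.seed(75)
  x <- stats::rnorm(40)
  y <- stats::rnorm(40)
  z <- stats::rnorm(40)
  r <- partial_spearman(x, y, z)
  expect_equal(partial_spearman(y, x, z), r)
  expect_equal(partial_spearman(exp(x), y^3 + 2 * y, atan(z)), r)
})

test_that("sliding window counts, clips and Fisher-transforms", {
  set.seed(76)
  n <- 40
  x <- stats::rnorm(n)
  y <- stats::rnorm(n)
  z <- stats::rnorm(n)
  sc <- sliding_partial_correlation(x, y, z)
  expect_equal(attr(sc, "window_len"), 5L)
  expect_equal(nrow(sc), n)
  # counting oracle: n - 4 interior centers, NA only at the edges or where
  # the window itself is rank-degenerate
  interior <- 3:(n - 2)
  expect_length(interior, n - 4L)
  expect_true(all(is.na(sc$r[c(1, 2, n - 1, n)])))
  for (c0 in interior) {
    idx <- (c0 - 2):(c0 + 2)
    expect_equal(is.na(sc$r[c0]),
                 is.na(partial_spearman_oracle(x[idx], y[idx], z[idx])))
  }
  expect_equal(sc$z, atanh(pmin(pmax(sc$r, -(1 - 1e-7)), 1 - 1e-7)))
  # identical series: clipped maximum at every defined center
  sx <- sliding_partial_correlation(x, x, z)
  expect_true(all(sx$z[!is.na(sx$z)] == atanh(1 - 1e-7)))
  # Fisher z is odd
  expect_equal(atanh(-0.4), -atanh(0.4))
  expect_error(sliding_partial_correlation(x, y, z, window_len_s = 2),
               "at least 3")
})

test_that("constant stretches give missing windows, not failures", {
  x <- c(rep(1, 10), stats::rnorm(10))
  y <- stats::rnorm(20)
  z <- stats::rnorm(20)
  sc <- sliding_partial_correlation(x, y, z)
  expect_true(all(is.na(sc$r[3:8])))
  expect_true(any(!is.na(sc$r)))
})

test_that("identical groups yield no flagged correlation differences", {
  set.seed(77)
  m <- matrix(stats::rnorm(8 * 8), 8, 8)
  cmp <- compare_correlation_dynamics(m, m, times_s = seq(6, 20, 2))
  expect_true(all(!cmp$flag))
  expect_equal(nrow(cmp), 8L)
  # missing pairs are dropped pairwise
  m2 <- m
  m2[1, ] <- NA
  cmp2 <- compare_correlation_dynamics(m, m2)
  expect_true(all(cmp2$n == 7L))
})
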