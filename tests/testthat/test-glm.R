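# HRF, design construction, GLM fitting, FDR, percent signal change,
# epochs and event-related averages.

test_that("canonical HRF peaks at 4-6 s and refines consistently", {
  dense <- canonical_hrf(0.01)
  td <- attr(dense, "times_s")
  expect_gte(td[which.max(dense)], 4)
  expect_lte(td[which.max(dense)], 6)
  expect_equal(max(dense), 1, tolerance = 1e-6) # peak-normalised
  expect_gt(sum(dense), 0)
  # TR sampling equals subsampling the dense kernel
  coarse <- canonical_hrf(2)
  expect_equal(as.numeric(coarse),
               as.numeric(dense)[match(attr(coarse, "times_s"), td)])
  expect_error(canonical_hrf(-1), "configuration error")
  expect_error(canonical_hrf(2, params = list(a1 = -6, b1 = 1, a2 = 16,
                                              b2 = 1, ratio = 6)),
               "configuration error")
})

test_that("a single-trial boxcar column equals the shifted kernel sum", {
  sched <- build_dynamic_run_schedule(seed = 4)
  h <- canonical_hrf(2)
  X <- build_design(sched)
  dyn <- which(sched$trial_type %in% c("dynamic_E1NE2", "dynamic_E2NE1"))
  one <- dyn[1]
  lab <- trial_conditions(sched)[one]
  # direct convolution oracle for that condition's trials
  rows <- which(trial_conditions(sched) == lab)
  n <- attr(sched, "n_volumes")
  want <- numeric(n)
  for (i in rows) {
    on_tr <- sched$onset[i] / 2
    for (k in seq_len(5)) { # 10-s boxcar = 5 TRs
      shift <- on_tr + k - 1
      idx <- seq_along(h) + shift
      keep <- idx <= n
      want[idx[keep]] <- want[idx[keep]] + h[keep]
    }
  }
  expect_equal(unname(X[, paste0("cond_", lab)]), want, tolerance = 1e-12)
})

test_that("design carries the Fourier set, motion confounds and intercept", {
  sched <- build_dynamic_run_schedule(seed = 4)
  motion <- matrix(stats::rnorm(280 * 6), 280, 6)
  X <- build_design(sched, motion)
  expect_equal(sum(grepl("^fourier_", colnames(X))), 6L) # 3 cycles
  expect_equal(sum(grepl("^motion_", colnames(X))), 6L)
  expect_equal(sum(colnames(X) == "intercept"), 1L)
  # Fourier columns orthogonal to the intercept and pairwise on a full grid
  fb <- X[, grepl("^fourier_", colnames(X))]
  expect_equal(colSums(fb), rep(0, 6), tolerance = 1e-9, ignore_attr = TRUE)
  g <- crossprod(fb)
  expect_equal(g - diag(diag(g)), matrix(0, 6, 6), tolerance = 1e-9,
               ignore_attr = TRUE)
  # motion columns are detrended: orthogonal to a linear trend
  mo <- X[, grepl("^motion_", colnames(X))]
  tl <- seq_len(280)
  expect_equal(as.numeric(crossprod(mo, tl - mean(tl))), rep(0, 6),
               tolerance = 1e-6)
  expect_error(build_design(sched, motion[1:100, ]), "expected 280")
})

test_that("conditions without coverage yield flagged all-zero columns", {
  sched <- build_dynamic_run_schedule(seed = 4)
  # label a zero-duration pseudo-trial: its boxcar never switches on
  sched$duration[1] <- 0
  conds <- trial_conditions(sched)
  conds[1] <- "empty_cond"
  expect_warning(
    expect_warning(X <- build_design(sched, conditions = conds),
                   "all-zero"),
    "rank-deficient") # an empty column is also flagged as rank deficiency
  expect_true("cond_empty_cond" %in% attr(X, "zero_cols"))
  expect_true(all(X[, "cond_empty_cond"] == 0))
})

test_that("GLM betas and t match a from-scratch matrix-algebra oracle", {
  set.seed(50)
  n <- 50
  X <- cbind(intercept = 1, a = stats::rnorm(n), b = stats::rnorm(n))
  y <- X %*% c(2, 1.5, -0.5) + stats::rnorm(n, 0, 0.3)
  cvec <- c(0, 1, -1)
  fit <- fit_glm(as.numeric(y), X, contrasts = list(ab = cvec))
  b_or <- solve(t(X) %*% X) %*% t(X) %*% y
  expect_equal(unname(fit$betas), as.numeric(b_or), tolerance = 1e-10)
  res <- y - X %*% b_or
  s2 <- sum(res^2) / (n - 3)
  t_or <- (cvec %*% b_or) / sqrt(s2 * t(cvec) %*% solve(t(X) %*% X) %*% cvec)
  expect_equal(fit$contrasts$t, as.numeric(t_or), tolerance = 1e-10)
  expect_equal(fit$dof, n - 3)
  # zero contrast gives t = 0
  fit0 <- fit_glm(as.numeric(y), X, contrasts = list(zero = c(0, 0, 0)))
  expect_equal(fit0$contrasts$t, 0)
})

test_that("singular designs fall back to the pseudo-inverse with a warning", {
  set.seed(51)
  X <- cbind(1, stats::rnorm(30))
  X <- cbind(X, X[, 2]) # duplicated column
  y <- stats::rnorm(30)
  expect_warning(fit <- fit_glm(y, X), "pseudo-inverse")
  expect_true(is.finite(fit$sigma2))
})

test_that("prewhitening removes AR(1) residual autocorrelation", {
  set.seed(52)
  n <- 300
  X <- cbind(intercept = 1, x = as.numeric(stats::arima.sim(list(ar = 0.5), n)))
  noise <- as.numeric(stats::arima.sim(list(ar = 0.4), n))
  y <- as.numeric(X %*% c(1, 0.5)) + noise
  fit <- fit_glm(y, X, prewhiten = TRUE)
  res <- fit$residuals
  expect_lt(abs(stats::cor(res[-1], res[-n])), 0.1)
  expect_gt(fit$ar1_rho, 0.2)
})

test_that("FDR step-up follows the hand-applied rule", {
  expect_equal(fdr_threshold(c(0.01, 0.02, 0.03, 0.5), 0.05),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(fdr_threshold(rep(0.001, 10), 0.05)))
  expect_equal(fdr_threshold(numeric(0), 0.05), logical(0))
  # monotone in q
  p <- c(0.001, 0.01, 0.04, 0.2, 0.8)
  r1 <- fdr_threshold(p, 0.01)
  r2 <- fdr_threshold(p, 0.1)
  expect_true(all(r2[r1]))
})

test_that("percent signal change matches the formula and its invariances", {
  set.seed(53)
  x <- stats::rnorm(100, mean = 50, sd = 3)
  psc <- percent_signal_change(x)
  expect_equal(psc, 100 * (x - mean(x)) / mean(x))
  expect_equal(mean(psc), 0)
  expect_equal(percent_signal_change(rep(7, 10)), rep(0, 10))
  expect_equal(percent_signal_change(3 * x), psc) # gain invariance
  expect_error(percent_signal_change(c(-1, 1)), "mean is zero")
})

test_that("a single-trial epoch is the raw delayed segment", {
  sched <- build_dynamic_run_schedule(seed = 4)
  series <- stats::rnorm(280)
  dyn <- which(sched$trial_type %in% c("dynamic_E1NE2", "dynamic_E2NE1"))
  ep <- trial_epochs(series, sched, trials = dyn[1])
  i0 <- (sched$onset[dyn[1]] + 6) / 2 + 1
  expect_equal(as.numeric(ep[1, ]), series[i0:(i0 + 7)])
  expect_equal(attr(ep, "times_s"), seq(6, 20, by = 2))
  # trials running past the scan are dropped with a warning
  short <- series[1:60]
  expect_warning(trial_epochs(short, sched, trials = dyn), "dropped")
})

test_that("identical groups produce no flagged timepoints", {
  sched <- build_dynamic_run_schedule(seed = 4)
  set.seed(60)
  eps <- lapply(1:8, function(s) {
    series <- stats::rnorm(280)
    m <- trial_epochs(series, sched)
    list(a = m, b = m)
  })
  era <- event_related_average(eps)
  expect_true(all(!era$stats$flag))
  expect_equal(era$average$mean[era$average$group == "a"],
               era$average$mean[era$average$group == "b"])
})

test_that("an injected amplitude difference is flagged inside the window", {
  # direction-2 conditions respond more than direction-1 at the default SNR
  sched <- build_dynamic_run_schedule(seed = 4)
  conds <- trial_conditions(sched)
  bp <- bold_sim_params()
  eps <- lapply(1:10, function(s) {
    sim <- simulate_bold_dataset(sched, bp, seed = 700 + s)
    psc <- percent_signal_change(sim$roi$rFFA)
    list(d2 = trial_epochs(psc, sched, which(conds %in% dyn_conditions_d2)),
         d1 = trial_epochs(psc, sched, which(conds %in% dyn_conditions_d1)))
  })
  era <- event_related_average(eps)
  expect_true(any(era$stats$flag))
  # the d2 mean exceeds the d1 mean in the heart of the response window
  mid <- era$average$time_s %in% c(10, 12, 14)
  d2m <- era$average$mean[era$average$group == "d2" & mid]
  d1m <- era$average$mean[era$average$group == "d1" & mid]
  expect_true(all(d2m > d1m))
})
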