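# Synthetic observer and BOLD generator: closed-loop identities,
# determinism, noise structure.

noiseless <- function(h = 0)
  observer_params(h_shift = h, motor_sd = 0, miss_prob = 0,
                  false_alarm_prob = 0)

test_that("noiseless unbiased observer reports map back to the static borders", {
  s <- build_dynamic_run_schedule(seed = 3)
  obs <- noiseless(0)
  band <- implied_neutral_band(obs)
  expect_equal(unname(band), c(-20, 20))
  ex <- extract_neutral_intervals(simulate_dynamic_reports(s, obs), s)
  expect_equal(ex$n_excluded, 0L)
  expect_true(all(ex$intervals$p1_s < ex$intervals$p2_s))
  tp <- dynamic_transition_points(ex$intervals)
  # entering border has the sign of the source side, leaving border the target
  expect_true(all(tp$p1_pos[tp$direction == 1] == band["lo"]))
  expect_true(all(tp$p2_pos[tp$direction == 1] == band["hi"]))
  expect_true(all(tp$p1_pos[tp$direction == 2] == band["hi"]))
  expect_true(all(tp$p2_pos[tp$direction == 2] == band["lo"]))
})

test_that("injected shift propagates exactly through the noiseless loop", {
  s <- build_dynamic_run_schedule(seed = 3)
  for (h in c(-10, 5, 20)) {
    ex <- extract_neutral_intervals(simulate_dynamic_reports(s, noiseless(h)), s)
    tp <- dynamic_transition_points(ex$intervals)
    expect_equal(tp$p2_pos[tp$direction == 1], rep(20 + h, 3))
    expect_equal(tp$p2_pos[tp$direction == 2], rep(-20 - h, 3))
  }
})

test_that("all presses are missed when miss_prob is 1", {
  s <- build_dynamic_run_schedule(seed = 3)
  obs <- observer_params(h_shift = 0, motor_sd = 0, miss_prob = 0.999999,
                         false_alarm_prob = 0)
  resp <- simulate_dynamic_reports(s, obs)
  expect_equal(nrow(resp), 0L)
})

test_that("reports and classifications are deterministic given the seed", {
  s <- build_dynamic_run_schedule(seed = 3)
  obs <- observer_params()
  expect_identical(simulate_dynamic_reports(s, obs, seed = 9),
                   simulate_dynamic_reports(s, obs, seed = 9))
  ss <- build_static_run_schedule("sadness-happiness", seed = 2)
  expect_identical(simulate_static_classifications(ss, obs, seed = 9),
                   simulate_static_classifications(ss, obs, seed = 9))
})

test_that("steep classifier labels probe frames by position", {
  ss <- build_static_run_schedule("anger-happiness", seed = 5)
  obs <- observer_params(static_slope = 50, static_center_lo = -50,
                         static_center_hi = 50)
  cls <- simulate_static_classifications(ss, obs, seed = 1)
  pos <- signed_position(cls$frame_index)
  # frames strictly inside (-50, 50) are always neutral: positions -20..20
  expect_true(all(cls$choice[abs(pos) < 50] == "N"))
  expect_true(all(cls$choice[pos == -100] == "E-"))
  expect_true(all(cls$choice[pos == 100] == "E+"))
})

test_that("control trials false-alarm at the configured rate only", {
  s <- build_dynamic_run_schedule(seed = 3)
  obs <- observer_params(h_shift = 0, motor_sd = 0, miss_prob = 0,
                         false_alarm_prob = 1)
  resp <- simulate_dynamic_reports(s, obs)
  ctrl <- which(s$trial_type == "control_NNN")
  expect_true(all(ctrl %in% resp$trial_id))
  expect_equal(sum(resp$trial_id %in% ctrl), 2L * length(ctrl))
})

test_that("zero-noise single-condition BOLD is the convolved boxcar", {
  sched <- build_dynamic_run_schedule(seed = 2)
  conds <- ifelse(sched$trial_type == "fixation", NA, "task")
  rois <- c("rAI", "tgt", "WM")
  bt <- matrix(c(1, 2, 0), 3, 1, dimnames = list(rois, "task"))
  bp <- bold_sim_params(roi_names = rois, seed_roi = "rAI",
                        noise_roi = "WM", beta_task = bt,
                        beta_ppi = bt * 0, noise_sd = 0, drift_amp = 0,
                        baseline = 0)
  sim <- simulate_bold_dataset(sched, bp, conditions = conds, seed = 1)
  on <- sched$onset[!is.na(conds)]
  off <- (sched$onset + sched$duration)[!is.na(conds)]
  u <- vapply((0:279) * 2, function(t) as.numeric(any(t >= on & t < off)),
              numeric(1))
  xc <- hrf_convolve(u, canonical_hrf(2))
  expect_equal(sim$roi$tgt, 2 * xc, tolerance = 1e-12)
  expect_equal(sim$roi$tgt, 2 * sim$roi$rAI, tolerance = 1e-12)
  expect_true(all(sim$roi$WM == 0))
})

test_that("ar1_rho = 0 leaves no residual lag-1 autocorrelation", {
  sched <- build_dynamic_run_schedule(seed = 2)
  bp <- zero_ppi_params()
  bp$ar1_rho <- 0
  bp$drift_amp <- 0
  sim <- simulate_bold_dataset(sched, bp, seed = 42)
  X <- build_design(sched, sim$motion)
  res <- fit_glm(sim$roi$mPFC, X)$residuals
  r1 <- stats::cor(res[-1], res[-length(res)])
  expect_lt(abs(r1), 0.1)
})

test_that("BOLD simulation is bit-identical under a fixed seed", {
  sched <- build_dynamic_run_schedule(seed = 2)
  a <- simulate_bold_dataset(sched, bold_sim_params(), seed = 8)
  b <- simulate_bold_dataset(sched, bold_sim_params(), seed = 8)
  expect_identical(a$roi, b$roi)
  expect_identical(a$motion, b$motion)
})
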