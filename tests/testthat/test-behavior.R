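# Behavioural core: exclusion rule, transition points, static inflection,
# metric classification, antisymmetry.

mini_sched <- function() build_dynamic_run_schedule(seed = 12)

test_that("trials with fewer than two presses are excluded and counted", {
  s <- mini_sched()
  dyn <- which(s$trial_type %in% c("dynamic_E1NE2", "dynamic_E2NE1"))
  # hand-built responses: 2 presses for most, 1 or 0 for a few
  one_press <- dyn[1:3]
  no_press <- dyn[4:5]
  full <- setdiff(dyn, c(one_press, no_press))
  resp <- rbind(
    do.call(rbind, lapply(full, function(i)
      data.frame(trial_id = i, press_s = c(3.1, 6.0)))),
    data.frame(trial_id = one_press, press_s = 4.2))
  ex <- extract_neutral_intervals(resp, s)
  expect_equal(ex$n_trials, 24L)
  expect_equal(ex$n_excluded, 5L)
  expect_equal(ex$excluded_fraction, 5 / 24)
  expect_equal(nrow(ex$intervals) + ex$n_excluded, ex$n_trials)
  expect_true(all(ex$intervals$p1_s == 3.1 & ex$intervals$p2_s == 6.0))
})

test_that("transition points average the borders within groups", {
  ints <- data.frame(
    participant = 1L, pair = "sadness-anger", direction = 1L,
    p1_pos = c(-25, -15), p2_pos = c(10, 30))
  tp <- dynamic_transition_points(ints)
  expect_equal(tp$p1_pos, -20)
  expect_equal(tp$p2_pos, 20)
  expect_equal(tp$n, 2L)
  # single trial passes through unchanged
  tp1 <- dynamic_transition_points(ints[1, ])
  expect_equal(tp1$p2_pos, 10)
})

test_that("static inflection finds the extreme modal-neutral frames", {
  # deterministic classifier with boundaries at +/-50: frames 33..49 neutral
  obs <- observer_params(static_slope = 50, static_center_lo = -50,
                         static_center_hi = 50)
  ss <- build_static_run_schedule("anger-happiness", seed = 9)
  cls <- simulate_static_classifications(ss, obs, seed = 2)
  si <- static_inflection(cls)
  expect_equal(si$lo_pos, -20)
  expect_equal(si$hi_pos, 20)
  expect_equal(si$lo_pos, -si$hi_pos) # symmetric observer
  # all-neutral reports span the full axis
  all_n <- data.frame(frame_index = rep(static_probe_frames(), 2),
                      choice = "N")
  si2 <- static_inflection(all_n)
  expect_equal(c(si2$lo_pos, si2$hi_pos), c(-100, 100))
  # no neutral-modal frame propagates a missing marker
  no_n <- data.frame(frame_index = rep(c(1L, 81L), each = 3),
                     choice = rep(c("E-", "E+"), each = 3))
  si3 <- static_inflection(no_n)
  expect_true(is.na(si3$lo_pos) && is.na(si3$hi_pos))
  # the neutral-percentage curve is exported
  expect_named(si$neutral_pct, c("frame_index", "signed_pct", "pct_neutral"))
  expect_equal(si$neutral_pct$pct_neutral[si$neutral_pct$frame_index == 41],
               100)
})

test_that("hysteresis metric follows the sign rule with tolerance", {
  m <- hysteresis_metric(c(30, 10, 5, 11, NA), c(10, 10, 15, 10, 10))
  expect_equal(m$value, c(20, 0, -10, 1, NA))
  expect_equal(m$label, c("positive", "none", "negative", "none", NA))
  # tolerance is configurable
  expect_equal(hysteresis_metric(11, 10, tol = 0.5)$label, "positive")
  # direction-2 inflections sit on the negative axis; absolute values used
  expect_equal(hysteresis_metric(-40, -20)$value, 20)
})

test_that("negating the injected shift flips the classification", {
  dyn <- lapply(1:2, function(r) build_dynamic_run_schedule(seed = 20 + r))
  stat <- lapply(seq_along(emotion_pairs()), function(i)
    build_static_run_schedule(emotion_pairs()[i], seed = 30 + i))
  res_pos <- simulate_participant_behavior(
    observer_params(h_shift = 15, motor_sd = 0, miss_prob = 0,
                    false_alarm_prob = 0), dyn, stat, seed0 = 500)
  res_neg <- simulate_participant_behavior(
    observer_params(h_shift = -15, motor_sd = 0, miss_prob = 0,
                    false_alarm_prob = 0), dyn, stat, seed0 = 500)
  expect_true(all(res_pos$label == "positive"))
  expect_true(all(res_neg$label == "negative"))
  expect_equal(res_pos$value, -res_neg$value)
})

test_that("dominance classification groups directions by positive majority", {
  hyst <- expand.grid(participant = 1:10, pair = emotion_pairs(),
                      direction = 1:2, stringsAsFactors = FALSE)
  hyst$value <- ifelse(hyst$direction == 2, 15, 0)
  hyst$label <- ifelse(hyst$direction == 2, "positive", "none")
  # make one pair symmetric: both directions positive
  sel <- hyst$pair == "anger-happiness"
  hyst$value[sel] <- 12
  hyst$label[sel] <- "positive"
  g <- dominance_groups(hyst)
  expect_setequal(g$A, c("sadness.anger_d2", "sadness.happiness_d2"))
  expect_setequal(g$B, c("sadness.anger_d1", "sadness.happiness_d1"))
  tab <- g$table
  expect_true(all(tab$dominant_positive[tab$pair == "anger-happiness"]))
})
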