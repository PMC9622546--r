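# Shared fixtures and independent oracles, built in code at test time.

# Brute-force inverse frame-timing map: scan the cumulative frame onsets.
brute_force_time_to_frame <- function(t_ms, params = morph_params()) {
  durs <- frame_duration_ms(seq_len(params$n_frames), params)
  onsets <- cumsum(c(0, durs))
  vapply(t_ms, function(t) {
    f <- findInterval(t + 1e-9, onsets)
    min(f, params$n_frames)
  }, numeric(1))
}

# Residual-rank regression oracle for the partial Spearman correlation:
# correlate the residuals of rank(x) ~ rank(z) and rank(y) ~ rank(z).
partial_spearman_oracle <- function(x, y, z) {
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  ex <- stats::residuals(stats::lm(rx ~ rz))
  ey <- stats::residuals(stats::lm(ry ~ rz))
  # a perfect rank fit leaves only roundoff: the partial is undefined
  if (stats::sd(ex) < 1e-8 || stats::sd(ey) < 1e-8) return(NA_real_)
  stats::cor(ex, ey)
}

# One simulated participant of the behavioural recovery study: three
# dynamic and three static runs, the hysteresis pipeline, returns the
# per-group results table.
simulate_participant_behavior <- function(obs, dyn_scheds, stat_scheds,
                                          seed0, tol = 1.25) {
  ints <- do.call(rbind, lapply(seq_along(dyn_scheds), function(r) {
    resp <- simulate_dynamic_reports(dyn_scheds[[r]], obs, seed = seed0 + r)
    extract_neutral_intervals(resp, dyn_scheds[[r]])$intervals
  }))
  tp <- dynamic_transition_points(ints)
  sb <- do.call(rbind, lapply(seq_along(stat_scheds), function(i) {
    cls <- simulate_static_classifications(stat_scheds[[i]], obs,
                                           seed = seed0 + 100 + i)
    si <- static_inflection(cls)
    data.frame(pair = emotion_pairs()[i], lo_pos = si$lo_pos,
               hi_pos = si$hi_pos)
  }))
  hysteresis_results(tp, sb, tol = tol)
}

# Subject-level (three concatenated runs) gPPI contrast at the default
# noise model; returns c(estimate, t).
subject_gppi_unit <- function(bp, seed, scheds, condA, condB,
                              target = "mPFC") {
  sims <- lapply(seq_along(scheds), function(r)
    simulate_bold_dataset(scheds[[r]], bp, seed = seed * 10 + r))
  gd <- lapply(seq_along(scheds), function(r)
    build_gppi_design(build_design(scheds[[r]], sims[[r]]$motion),
                      sims[[r]]$roi[[bp$seed_roi]]))
  y <- unlist(lapply(sims, function(s) s$roi[[target]]), use.names = FALSE)
  g <- gppi_contrast(y, concat_run_designs(gd), condA, condB)
  c(estimate = g$estimate, t = g$t)
}

dyn_conditions_d1 <- c("anger.happiness_d1", "sadness.anger_d1",
                       "sadness.happiness_d1")
dyn_conditions_d2 <- sub("_d1", "_d2", dyn_conditions_d1)

zero_ppi_params <- function() {
  rois <- c("rAI", "rFFA", "rSTS", "mPFC", "WM")
  conds <- c(dyn_conditions_d1, dyn_conditions_d2, "control")
  b <- default_beta_ppi(rois, conds)
  b[, ] <- 0
  bold_sim_params(beta_ppi = b)
}
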