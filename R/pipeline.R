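# End-to-end synthetic study: simulate -> behaviour -> GLM/PSC -> gPPI ->
# sliding-window correlation dynamics -> report.

#' Concatenate per-run designs into a fixed-effects design
#'
#' Stacks runs with shared condition (and gPPI) columns and run-specific
#' nuisance blocks: intercept, Fourier and motion columns of run r are kept
#' only on run r's rows and renamed \code{run<r>_*}.
#'
#' @param designs List of \code{design_matrix} objects with identical
#'   shared-column names.
#' @param shared_prefixes Column-name prefixes treated as shared across
#'   runs.
#' @return A \code{design_matrix} covering all runs.
#' @export
concat_run_designs <- function(designs,
                               shared_prefixes = c("cond_", "ppi_", "seed")) {
  is_shared <- function(nms) Reduce(`|`, lapply(shared_prefixes, startsWith,
                                                x = nms))
  nms <- colnames(designs[[1L]])
  shared <- nms[is_shared(nms)]
  rows <- vapply(designs, nrow, integer(1))
  offsets <- cumsum(c(0L, rows))
  total <- sum(rows)
  shared_block <- do.call(rbind, lapply(designs, function(d)
    unclass(d)[, shared, drop = FALSE]))
  nuis_blocks <- lapply(seq_along(designs), function(r) {
    d <- unclass(designs[[r]])
    nn <- colnames(d)[!is_shared(colnames(d))]
    blk <- matrix(0, total, length(nn),
                  dimnames = list(NULL, paste0("run", r, "_", nn)))
    blk[(offsets[r] + 1L):offsets[r + 1L], ] <- d[, nn, drop = FALSE]
    blk
  })
  x <- do.call(cbind, c(list(shared_block), nuis_blocks))
  structure(x,
            condition_cols = attr(designs[[1L]], "condition_cols"),
            ppi_cols = attr(designs[[1L]], "ppi_cols"),
            tr_s = attr(designs[[1L]], "tr_s"), n_volumes = total,
            run_starts = offsets[seq_along(designs)] + 1L,
            class = c("design_matrix", "matrix"))
}

#' Classify direction dominance of positive hysteresis
#'
#' Counts hysteresis labels per pair x direction across participants. A
#' direction is "dominant" when positive labels form a strict majority of
#' its non-missing labels. The contrast groups follow the usual design:
#' within each pair with exactly one dominant direction, the dominant one
#' joins group A and the other group B; if no pair is asymmetric the
#' directions with the larger mean metric per pair are taken as A.
#'
#' @param hyst Hysteresis results table ([hysteresis_results()], all
#'   participants).
#' @return List: \code{table} (per pair x direction counts, mean value,
#'   dominance), \code{A}, \code{B} (condition labels, e.g.
#'   \code{"sadness.anger_d2"}).
#' @export
dominance_groups <- function(hyst) {
  key <- interaction(hyst$pair, hyst$direction, drop = TRUE)
  parts <- split(hyst, key)
  tab <- do.call(rbind, lapply(parts, function(g) {
    lab <- g$label[!is.na(g$label)]
    data.frame(pair = g$pair[1L], direction = g$direction[1L],
               n = length(lab), n_positive = sum(lab == "positive"),
               n_negative = sum(lab == "negative"),
               n_none = sum(lab == "none"),
               mean_value = mean(g$value, na.rm = TRUE),
               dominant_positive = sum(lab == "positive") > length(lab) / 2)
  }))
  tab <- tab[order(tab$pair, tab$direction), ]
  rownames(tab) <- NULL
  cond_of <- function(p, d) sprintf("%s_d%d", gsub("-", ".", p), d)
  a <- character(0)
  b <- character(0)
  for (p in unique(tab$pair)) {
    sub <- tab[tab$pair == p, ]
    if (sum(sub$dominant_positive) == 1L) {
      a <- c(a, cond_of(p, sub$direction[sub$dominant_positive]))
      b <- c(b, cond_of(p, sub$direction[!sub$dominant_positive]))
    }
  }
  if (!length(a) || !length(b)) {
    for (p in unique(tab$pair)) {
      sub <- tab[tab$pair == p, ]
      hi <- which.max(sub$mean_value)
      a <- c(a, cond_of(p, sub$direction[hi]))
      b <- c(b, cond_of(p, sub$direction[-hi]))
    }
  }
  list(table = tab, A = a, B = b)
}

draw_seeds <- function(n) sample.int(.Machine$integer.max - 1L, n)

#' Run the full synthetic-study pipeline
#'
#' Simulates the configured number of participants through the complete
#' chain — run schedules, button-press reports and static classifications,
#' neutral-interval extraction and the hysteresis metric, direction
#' dominance, multi-ROI BOLD simulation, first-level (fixed-effects
#' concatenated) GLM contrasts with FDR across ROIs, percent signal change
#' and event-related averages, gPPI contrasts with a random-effects group
#' test, and sliding-window partial Spearman correlation dynamics — and
#' returns (optionally writes) a reproducible report. Identical
#' configurations produce byte-identical outputs.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Optional output directory; created if missing. TSV
#'   results plus JSON summary and sidecars are written there.
#' @param quiet Suppress per-stage log messages.
#' @return A report list (invisible when \code{out_dir} is given):
#'   \code{behavior}, \code{groups}, \code{glm}, \code{era}, \code{ppi},
#'   \code{sliding}, \code{timing_s}.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         quiet = TRUE) {
  t_start <- proc.time()[["elapsed"]]
  stage_t <- c()
  tick <- local({
    last <- t_start
    function(name) {
      now <- proc.time()[["elapsed"]]
      stage_t[[name]] <<- round(now - last, 2)
      last <<- now
      if (!quiet) message(sprintf("[%s] done in %.2f s", name,
                                  stage_t[[name]]))
    }
  })
  params <- do.call(morph_params, config$morph)
  npar <- config$n_participants
  nrun <- config$n_dynamic_runs
  pairs <- emotion_pairs()

  seeds <- with_seed(config$seed, list(
    dyn_sched = draw_seeds(nrun),
    stat_sched = draw_seeds(length(pairs)),
    beh = matrix(draw_seeds(npar * (nrun + length(pairs))), nrow = npar),
    bold = matrix(draw_seeds(npar * nrun), nrow = npar),
    h_dev = draw_seeds(1L)))

  dyn_sched <- lapply(seq_len(nrun), function(r)
    build_dynamic_run_schedule(seeds$dyn_sched[r], config$actors,
                               config$tr_s, config$volumes$dynamic))
  stat_sched <- lapply(seq_along(pairs), function(i)
    build_static_run_schedule(pairs[i], seeds$stat_sched[i], config$actors,
                              config$tr_s, config$volumes$static, params))
  tick("schedules")

  oc <- config$observer
  h_base <- h_shift_matrix(oc$h_shift)
  h_dev <- with_seed(seeds$h_dev,
                     array(stats::rnorm(npar * 6L, 0, oc$h_between_sd),
                           dim = c(npar, 3L, 2L)))
  hyst <- list()
  n_trials_total <- 0L
  n_excluded_total <- 0L
  for (s in seq_len(npar)) {
    hs <- h_base + h_dev[s, , ]
    obs <- observer_params(h_shift = hs, motor_sd = oc$motor_sd,
                           miss_prob = oc$miss_prob,
                           false_alarm_prob = oc$false_alarm_prob,
                           static_slope = oc$static_slope,
                           static_center_lo = oc$static_center_lo,
                           static_center_hi = oc$static_center_hi)
    ints <- list()
    for (r in seq_len(nrun)) {
      resp <- simulate_dynamic_reports(dyn_sched[[r]], obs, params,
                                       seed = seeds$beh[s, r])
      ex <- extract_neutral_intervals(resp, dyn_sched[[r]], params)
      n_trials_total <- n_trials_total + ex$n_trials
      n_excluded_total <- n_excluded_total + ex$n_excluded
      ints[[r]] <- ex$intervals
    }
    ints <- do.call(rbind, ints)
    ints$participant <- s
    tp <- dynamic_transition_points(ints)
    stat <- do.call(rbind, lapply(seq_along(pairs), function(i) {
      cls <- simulate_static_classifications(
        stat_sched[[i]], obs, params, seed = seeds$beh[s, nrun + i])
      si <- static_inflection(cls, params)
      data.frame(participant = s, pair = pairs[i], lo_pos = si$lo_pos,
                 hi_pos = si$hi_pos)
    }))
    hyst[[s]] <- hysteresis_results(tp, stat, config$tol)
  }
  hyst <- rbind_rows(hyst)
  excluded_fraction <- n_excluded_total / n_trials_total

  direction_tests <- do.call(rbind, lapply(pairs, function(p) {
    v1 <- hyst$value[hyst$pair == p & hyst$direction == 1L]
    v2 <- hyst$value[hyst$pair == p & hyst$direction == 2L]
    w <- wilcoxon_signed_rank(v1, v2)
    data.frame(pair = p, z = w$z, p = w$p, n = w$n)
  }))
  grp <- dominance_groups(hyst)
  tick("behavior")

  bc <- config$bold
  bp <- bold_sim_params(noise_sd = bc$noise_sd, ar1_rho = bc$ar1_rho,
                        drift_amp = bc$drift_amp, motion_sd = bc$motion_sd,
                        baseline = bc$baseline)
  rois <- setdiff(bp$roi_names, bp$noise_roi)
  hrf <- canonical_hrf(config$tr_s, bp$hrf_params)
  task_est <- matrix(NA_real_, npar, length(rois),
                     dimnames = list(NULL, rois))
  ppi_est <- numeric(npar)
  sub_epochs <- stats::setNames(
    lapply(rois, function(r) vector("list", npar)), rois)
  slide_a <- NULL
  slide_b <- NULL
  for (s in seq_len(npar)) {
    sims <- lapply(seq_len(nrun), function(r)
      simulate_bold_dataset(dyn_sched[[r]], bp, seed = seeds$bold[s, r]))
    designs <- lapply(seq_len(nrun), function(r)
      build_design(dyn_sched[[r]], sims[[r]]$motion, hrf = hrf))
    xcat <- concat_run_designs(designs)
    w_task <- contrast_weights(xcat, grp$A, grp$B, prefix = "cond_")
    for (roi in rois) {
      ycat <- unlist(lapply(sims, function(sm) sm$roi[[roi]]),
                     use.names = FALSE)
      fit <- fit_glm(ycat, xcat, contrasts = list(ab = w_task),
                     prewhiten = TRUE)
      task_est[s, roi] <- fit$contrasts$estimate[1L]
    }
    gdesigns <- lapply(seq_len(nrun), function(r)
      build_gppi_design(designs[[r]], sims[[r]]$roi[[bp$seed_roi]]))
    gcat <- concat_run_designs(gdesigns)
    ycat <- unlist(lapply(sims, function(sm) sm$roi[["mPFC"]]),
                   use.names = FALSE)
    ppi_est[s] <- gppi_contrast(ycat, gcat, grp$A, grp$B)$estimate

    for (r in seq_len(nrun)) {
      sched <- dyn_sched[[r]]
      conds <- trial_conditions(sched)
      tr_a <- which(conds %in% grp$A)
      tr_b <- which(conds %in% grp$B)
      for (roi in rois) {
        psc <- percent_signal_change(sims[[r]]$roi[[roi]])
        ea <- trial_epochs(psc, sched, tr_a, config$delay_s, config$window_s)
        eb <- trial_epochs(psc, sched, tr_b, config$delay_s, config$window_s)
        comb <- function(a, b)
          structure(rbind(a, b), times_s = attr(b, "times_s"))
        prev <- sub_epochs[[roi]][[s]]
        sub_epochs[[roi]][[s]] <- list(
          dominant = comb(prev$dominant, ea),
          nondominant = comb(prev$nondominant, eb))
      }
      spc <- sliding_partial_correlation(
        sims[[r]]$roi[[bp$seed_roi]], sims[[r]]$roi[["mPFC"]],
        sims[[r]]$roi[[bp$noise_roi]], config$sliding_window_s,
        config$tr_s)
      za <- trial_epochs(spc$z, sched, tr_a, config$delay_s, config$window_s)
      zb <- trial_epochs(spc$z, sched, tr_b, config$delay_s, config$window_s)
      if (r == 1L && s == 1L) {
        slide_a <- matrix(NA_real_, npar, ncol(za))
        slide_b <- matrix(NA_real_, npar, ncol(zb))
        slide_times <- attr(za, "times_s")
      }
      slide_a[s, ] <- if (r == 1L) 0 else slide_a[s, ]
      slide_b[s, ] <- if (r == 1L) 0 else slide_b[s, ]
      slide_a[s, ] <- slide_a[s, ] + colMeans(za, na.rm = TRUE) / nrun
      slide_b[s, ] <- slide_b[s, ] + colMeans(zb, na.rm = TRUE) / nrun
    }
  }
  tick("bold_first_level")

  glm_group <- do.call(rbind, lapply(rois, function(roi) {
    g <- rfx_group_test(task_est[, roi])
    data.frame(roi = roi, mean = g$mean, t = g$t, p_t = g$p_t, z = g$z,
               p_wilcoxon = g$p_wilcoxon)
  }))
  glm_group$fdr_reject <- fdr_threshold(glm_group$p_t, config$alpha)

  era <- lapply(rois, function(roi) {
    keep <- !vapply(sub_epochs[[roi]], is.null, logical(1))
    event_related_average(sub_epochs[[roi]][keep], alpha = config$alpha)
  })
  names(era) <- rois

  ppi_group <- rfx_group_test(ppi_est)
  slide_cmp <- compare_correlation_dynamics(slide_a, slide_b,
                                            times_s = slide_times,
                                            alpha = config$alpha)
  tick("group_level")

  report <- list(
    config = config, seed = config$seed,
    behavior = list(excluded_fraction = excluded_fraction,
                    hysteresis = hyst, group_table = grp$table,
                    direction_tests = direction_tests),
    groups = list(A = grp$A, B = grp$B),
    glm = list(subject_contrasts = task_est, group = glm_group),
    era = era,
    ppi = list(subject_estimates = ppi_est, group = ppi_group),
    sliding = list(comparison = slide_cmp,
                   group_mean = data.frame(
                     time_s = slide_times,
                     z_dominant = colMeans(slide_a),
                     z_nondominant = colMeans(slide_b))),
    timing_s = as.list(stage_t))

  if (!is.null(out_dir)) {
    write_pipeline_outputs(report, dyn_sched, stat_sched, out_dir)
    tick("write_outputs")
    report$timing_s <- as.list(stage_t)
    return(invisible(report))
  }
  report
}

era_long <- function(era) {
  do.call(rbind, lapply(names(era), function(roi)
    cbind(roi = roi, era[[roi]]$average)))
}

write_pipeline_outputs <- function(report, dyn_sched, stat_sched, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- report$config
  seed <- report$seed
  emit <- function(df, name, extra = NULL) {
    path <- file.path(out_dir, name)
    utils::write.table(format(df, digits = 12, trim = TRUE,
                              scientific = FALSE),
                       path, sep = "\t", quote = FALSE, na = ".",
                       row.names = FALSE, fileEncoding = "UTF-8")
    write_sidecar(path, cfg, seed, extra)
  }
  for (r in seq_along(dyn_sched)) {
    p <- file.path(out_dir, sprintf("events_dynamic_run%d.tsv", r))
    write_events(dyn_sched[[r]], p)
    write_sidecar(p, cfg, seed)
  }
  for (i in seq_along(stat_sched)) {
    p <- file.path(out_dir, sprintf("events_static_run%d.tsv", i))
    write_events(stat_sched[[i]], p)
    write_sidecar(p, cfg, seed)
  }
  emit(report$behavior$hysteresis, "behavior_hysteresis.tsv")
  emit(report$behavior$group_table, "behavior_group.tsv")
  emit(report$behavior$direction_tests, "behavior_direction_tests.tsv")
  emit(report$glm$group, "glm_group.tsv",
       extra = list(contrast = list(A = report$groups$A,
                                    B = report$groups$B)))
  emit(era_long(report$era), "era.tsv")
  emit(data.frame(participant = seq_along(report$ppi$subject_estimates),
                  ppi_contrast = report$ppi$subject_estimates), "ppi.tsv")
  emit(report$sliding$comparison, "sliding_comparison.tsv")
  emit(report$sliding$group_mean, "sliding_group_mean.tsv")
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(list(
    config_hash = config_hash(cfg), seed = seed, package = "emohyst",
    version = as.character(utils::packageVersion("emohyst")),
    excluded_fraction = report$behavior$excluded_fraction,
    groups = report$groups,
    direction_tests = report$behavior$direction_tests,
    glm_group = report$glm$group,
    ppi_group = report$ppi$group,
    sliding_flagged_times_s =
      report$sliding$comparison$time_s[report$sliding$comparison$flag]
  ), summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
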