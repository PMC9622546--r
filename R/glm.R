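# ROI-level GLM machinery: HRF, design matrices, first-level fits,
# contrasts, FDR thresholding, percent signal change, event-related
# averages, random-effects group tests.

#' Canonical double-gamma hemodynamic response function
#'
#' h(t) = Gamma(t; a1, b1) - Gamma(t; a2, b2)/ratio with the usual
#' canonical parameters (response peaking at (a1-1) b1 = 5 s, undershoot at
#' 15 s, peak/undershoot ratio 6), truncated at \code{duration_s} and
#' normalised so the continuous kernel peaks at 1 (the peak is located on a
#' 1-ms grid, so samplings at different rates share the same scale).
#'
#' @param tr_s Sampling interval, seconds.
#' @param params List with shape/scale pairs \code{a1}, \code{b1},
#'   \code{a2}, \code{b2} and \code{ratio}.
#' @param duration_s Kernel support, seconds.
#' @return Sampled kernel with attribute \code{times_s}.
#' @export
canonical_hrf <- function(tr_s = 2,
                          params = list(a1 = 6, b1 = 1, a2 = 16, b2 = 1,
                                        ratio = 6),
                          duration_s = 32) {
  if (tr_s <= 0) stop("configuration error: tr_s must be positive")
  with(params, if (a1 <= 0 || b1 <= 0 || a2 <= 0 || b2 <= 0 || ratio <= 0)
    stop("configuration error: invalid HRF parameters"))
  hfun <- function(t)
    stats::dgamma(t, shape = params$a1, scale = params$b1) -
    stats::dgamma(t, shape = params$a2, scale = params$b2) / params$ratio
  peak <- max(hfun(seq(0, duration_s, by = 1e-3)))
  times <- seq(0, duration_s, by = tr_s)
  structure(hfun(times) / peak, times_s = times, class = "hrf_kernel")
}

#' Convolve a regressor with an HRF kernel
#'
#' Discrete causal convolution truncated to the input length; regressor and
#' kernel must share the sampling interval.
#'
#' @param u Numeric input series (e.g. a condition boxcar sampled at TR).
#' @param kernel Sampled HRF, e.g. from [canonical_hrf()].
#' @return Numeric series of \code{length(u)}.
#' @export
hrf_convolve <- function(u, kernel) {
  n <- length(u)
  as.numeric(stats::convolve(c(u, numeric(length(kernel))),
                             rev(as.numeric(kernel)),
                             type = "open"))[seq_len(n)]
}

#' Condition label of each trial in a schedule
#'
#' Dynamic transition trials are labelled by emotion pair and direction
#' (e.g. \code{"sadness.anger_d2"}), control transitions \code{"control"},
#' static trials \code{"face_emotional"}/\code{"face_neutral"}; fixation is
#' left unmodelled (NA).
#'
#' @param schedule A \code{run_schedule}.
#' @return Character vector, one label per trial row.
#' @export
trial_conditions <- function(schedule) {
  tt <- schedule$trial_type
  out <- rep(NA_character_, nrow(schedule))
  dyn <- tt %in% dynamic_types
  out[dyn] <- sprintf("%s_d%d", gsub("-", ".", schedule$pair[dyn]),
                      schedule$direction[dyn])
  out[tt == "control_NNN"] <- "control"
  out[tt == "static_image"] <- "face_emotional"
  out[tt == "static_neutral"] <- "face_neutral"
  out
}

fourier_basis <- function(n, n_cycles = 3L) {
  t <- seq_len(n) - 1L
  cols <- lapply(seq_len(n_cycles), function(k)
    cbind(sin(2 * pi * k * t / n), cos(2 * pi * k * t / n)))
  x <- do.call(cbind, cols)
  colnames(x) <- as.vector(rbind(paste0("fourier_sin", seq_len(n_cycles)),
                                 paste0("fourier_cos", seq_len(n_cycles))))
  x
}

detrend_linear <- function(x) {
  t <- seq_along(x)
  stats::residuals(stats::lm.fit(cbind(1, t), x))
}

condition_boxcars <- function(schedule, conditions = trial_conditions(schedule)) {
  n <- attr(schedule, "n_volumes")
  tr <- attr(schedule, "tr_s")
  vt <- (seq_len(n) - 1L) * tr
  levs <- sort(unique(stats::na.omit(conditions)))
  u <- sapply(levs, function(lev) {
    rows <- which(conditions == lev)
    on <- rep(0, n)
    for (i in rows)
      on[vt >= schedule$onset[i] - 1e-9 &
           vt < schedule$onset[i] + schedule$duration[i] - 1e-9] <- 1
    on
  })
  colnames(u) <- levs
  u
}

#' Build a first-level design matrix
#'
#' One HRF-convolved boxcar per experimental condition, a GLM-Fourier
#' high-pass set (sine/cosine pairs at 1..\code{n_cycles} cycles per run),
#' six linearly detrended head-motion confounds when supplied, and an
#' intercept. Empty condition columns and rank deficiencies are flagged in
#' attributes (and as warnings) rather than silently dropped.
#'
#' @param schedule A \code{run_schedule}.
#' @param motion Optional data frame/matrix of 6 motion parameters per TR.
#' @param conditions Trial condition labels (default [trial_conditions()]).
#' @param hrf Sampled HRF kernel (default [canonical_hrf()] at the
#'   schedule's TR).
#' @param n_cycles Number of Fourier high-pass cycles (default 3).
#' @return A \code{design_matrix}: numeric matrix with attributes
#'   \code{condition_cols}, \code{tr_s}, \code{n_volumes},
#'   \code{zero_cols}, \code{flagged_cols}.
#' @export
build_design <- function(schedule, motion = NULL, conditions = NULL,
                         hrf = NULL, n_cycles = 3L) {
  n <- attr(schedule, "n_volumes")
  tr <- attr(schedule, "tr_s")
  if (is.null(conditions)) conditions <- trial_conditions(schedule)
  if (is.null(hrf)) hrf <- canonical_hrf(tr)
  u <- condition_boxcars(schedule, conditions)
  xc <- apply(u, 2L, hrf_convolve, kernel = hrf)
  colnames(xc) <- paste0("cond_", colnames(u))
  parts <- list(intercept = rep(1, n), xc, fourier_basis(n, n_cycles))
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n)
      stop("motion table has ", nrow(motion), " rows; expected ", n)
    md <- apply(motion, 2L, detrend_linear)
    colnames(md) <- paste0("motion_", seq_len(ncol(md)))
    parts <- c(parts, list(md))
  }
  x <- do.call(cbind, parts)
  colnames(x)[1L] <- "intercept"
  zero_cols <- colnames(x)[apply(x, 2L, function(col) all(col == 0))]
  if (length(zero_cols))
    warning("all-zero design columns: ", paste(zero_cols, collapse = ", "))
  qx <- qr(x)
  flagged <- character(0)
  if (qx$rank < ncol(x)) {
    flagged <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    warning("rank-deficient design; offending columns: ",
            paste(flagged, collapse = ", "))
  }
  structure(x, condition_cols = stats::setNames(colnames(xc), colnames(u)),
            tr_s = tr, n_volumes = n, zero_cols = zero_cols,
            flagged_cols = flagged, class = c("design_matrix", "matrix"))
}

#' Ordinary-least-squares GLM fit with contrasts
#'
#' Plain OLS by default. With \code{prewhiten = TRUE} the fit additionally
#' corrects for AR(1) serial correlation by iterated Cochrane-Orcutt
#' whitening: the lag-1 autocorrelation of the residuals (small-sample bias
#' corrected) is estimated, response and design are transformed, and the
#' fit repeated until the residual autocorrelation is negligible. The
#' transform restarts at each run boundary (attribute \code{run_starts} of
#' the design, as set by [concat_run_designs()]), so concatenated runs are
#' whitened within run. Contrast t statistics from the whitened fit are
#' approximately valid under AR(1) noise, where naive OLS t values are
#' anti-conservative.
#'
#' @param y Numeric response series (one ROI), length = rows of \code{X}.
#' @param X A \code{design_matrix} (or plain numeric matrix with column
#'   names).
#' @param contrasts Optional named list of contrast vectors; each either a
#'   full-length numeric vector over columns or a named vector matched to
#'   column names (unnamed columns get weight 0).
#' @param prewhiten Correct for AR(1) residual autocorrelation.
#' @param max_iter Maximum Cochrane-Orcutt iterations.
#' @return A \code{glm_fit} list: \code{betas}, \code{sigma2}, \code{dof},
#'   \code{rank}, \code{residuals}, \code{ar1_rho} (total autocorrelation
#'   removed; 0 without prewhitening), and \code{contrasts} (data frame
#'   with estimate, se, t, p).
#' @export
fit_glm <- function(y, X, contrasts = NULL, prewhiten = FALSE,
                    max_iter = 3L) {
  run_starts <- attr(X, "run_starts")
  X <- unclass(X)
  stopifnot(length(y) == nrow(X))
  rho_total <- 0
  if (prewhiten) {
    if (is.null(run_starts)) run_starts <- 1L
    n <- length(y)
    first <- rep(FALSE, n)
    first[run_starts] <- TRUE
    lagged <- c(1L, seq_len(n - 1L))
    for (k in seq_len(max_iter)) {
      b0 <- qr.coef(qr(X), y)
      b0[is.na(b0)] <- 0
      res <- y - as.numeric(X %*% b0)
      ss <- sum(res^2)
      if (ss < 1e-12) break
      pair <- !first
      rho <- sum(res[pair] * res[lagged[pair]]) / ss
      rho <- rho + (1 + 3 * rho) / n
      if (abs(rho) < 0.01) break
      scale1 <- sqrt(max(1 - rho^2, 1e-8))
      yw <- ifelse(first, scale1 * y, y - rho * y[lagged])
      Xw <- X - rho * X[lagged, , drop = FALSE]
      Xw[first, ] <- scale1 * X[first, , drop = FALSE]
      y <- yw
      X <- Xw
      rho_total <- rho_total + rho
    }
  }
  qx <- qr(X)
  r <- qx$rank
  if (r < ncol(X)) {
    warning("singular design: using the Moore-Penrose pseudo-inverse")
    xtx_inv <- MASS::ginv(crossprod(X))
    b <- as.numeric(xtx_inv %*% crossprod(X, y))
  } else {
    xtx_inv <- chol2inv(chol(crossprod(X)))
    b <- as.numeric(qr.coef(qx, y))
  }
  names(b) <- colnames(X)
  res <- y - as.numeric(X %*% b)
  dof <- length(y) - r
  sigma2 <- sum(res^2) / dof
  ctab <- NULL
  if (!is.null(contrasts)) {
    ctab <- do.call(rbind, lapply(names(contrasts), function(nm) {
      cvec <- expand_contrast(contrasts[[nm]], colnames(X))
      est <- sum(cvec * b)
      se2 <- sigma2 * as.numeric(t(cvec) %*% xtx_inv %*% cvec)
      if (all(cvec == 0)) {
        data.frame(contrast = nm, estimate = 0, se = 0, t = 0, p = 1)
      } else {
        se <- sqrt(max(se2, 0))
        tval <- if (se > 0) est / se else sign(est) * Inf
        data.frame(contrast = nm, estimate = est, se = se, t = tval,
                   p = 2 * stats::pt(-abs(tval), dof))
      }
    }))
  }
  structure(list(betas = b, sigma2 = sigma2, dof = dof, rank = r,
                 residuals = res, ar1_rho = rho_total, contrasts = ctab),
            class = "glm_fit")
}

expand_contrast <- function(cvec, cols) {
  if (is.null(names(cvec))) {
    stopifnot(length(cvec) == length(cols))
    return(as.numeric(cvec))
  }
  missing <- setdiff(names(cvec), cols)
  if (length(missing))
    stop("contrast names not in design: ", paste(missing, collapse = ", "))
  out <- stats::setNames(rep(0, length(cols)), cols)
  out[names(cvec)] <- cvec
  as.numeric(out)
}

#' Contrast weights over condition columns
#'
#' Builds a named contrast vector averaging the condition regressors in
#' \code{plus} minus those in \code{minus} (e.g. directions with dominant
#' positive hysteresis vs the rest).
#'
#' @param design A \code{design_matrix} (used for its condition-column map).
#' @param plus,minus Character vectors of condition labels.
#' @param prefix Column prefix the labels map to (\code{"cond_"} for task
#'   regressors, \code{"ppi_"} for interaction regressors).
#' @return Named numeric contrast vector.
#' @export
contrast_weights <- function(design, plus, minus = character(0),
                             prefix = "cond_") {
  cols <- colnames(design)
  p_cols <- paste0(prefix, plus)
  m_cols <- paste0(prefix, minus)
  missing <- setdiff(c(p_cols, m_cols), cols)
  if (length(missing))
    stop("conditions not in design: ", paste(missing, collapse = ", "))
  w <- c(stats::setNames(rep(1 / length(p_cols), length(p_cols)), p_cols),
         if (length(m_cols))
           stats::setNames(rep(-1 / length(m_cols), length(m_cols)), m_cols))
  w
}

#' Benjamini-Hochberg FDR threshold
#'
#' @param p Numeric vector of p values in [0, 1].
#' @param q FDR level.
#' @return Logical rejection mask (step-up rule at level \code{q}).
#' @export
fdr_threshold <- function(p, q = 0.05) {
  if (!length(p)) return(logical(0))
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  out <- stats::p.adjust(p, method = "BH") <= q
  out & !is.na(out)
}

#' Percent signal change of a time series
#'
#' 100 (x - mean(x)) / mean(x), the standard normalisation of ROI BOLD time
#' courses to their temporal mean.
#'
#' @param x Numeric series with nonzero mean.
#' @return Numeric series (mean zero by construction).
#' @export
percent_signal_change <- function(x) {
  m <- mean(x)
  if (!is.finite(m) || abs(m) < 1e-12)
    stop("cannot compute percent signal change: series mean is zero")
  100 * (x - m) / m
}

#' Extract peristimulus epochs of a series
#'
#' Samples the series at \code{onset + delay_s + tau} for
#' \code{tau = 0, tr, ..., window_s}, i.e. a hemodynamically delayed
#' peristimulus window (default 6 to 20 s after trial onset at TR 2 s).
#' Trials whose window exceeds the run are dropped with a warning.
#'
#' @param series Numeric per-TR series (e.g. percent signal change).
#' @param schedule The \code{run_schedule} the series belongs to.
#' @param trials Integer row indices of the trials to epoch (default: all
#'   dynamic transition trials).
#' @param delay_s Hemodynamic delay, seconds; must be a multiple of TR.
#' @param window_s Window length beyond the delay, seconds.
#' @return Matrix trials x timepoints with attribute \code{times_s}
#'   (peristimulus times \code{delay_s + tau}) and rownames = trial ids.
#' @export
trial_epochs <- function(series, schedule, trials = NULL, delay_s = 6,
                         window_s = 14) {
  tr <- attr(schedule, "tr_s")
  n <- length(series)
  if (abs(delay_s / tr - round(delay_s / tr)) > 1e-9)
    stop("delay_s must be a multiple of the TR")
  if (is.null(trials))
    trials <- which(schedule$trial_type %in% dynamic_types)
  tau <- seq(0, window_s, by = tr)
  times <- delay_s + tau
  idx_of <- function(i) round((schedule$onset[i] + times) / tr) + 1L
  keep <- vapply(trials, function(i) max(idx_of(i)) <= n && min(idx_of(i)) >= 1L,
                 logical(1))
  if (any(!keep))
    warning(sum(!keep), " trial(s) dropped: epoch window exceeds the run")
  trials <- trials[keep]
  out <- t(vapply(trials, function(i) series[idx_of(i)], numeric(length(times))))
  rownames(out) <- trials
  structure(out, times_s = times)
}

#' Event-related average with within-subject error bars
#'
#' Averages peristimulus epochs within participant for each trial group,
#' then across participants, reporting the within-subject SEM (subject
#' offsets removed across the group x time cells) and, for exactly two
#' groups, a paired Wilcoxon signed-rank flag per timepoint.
#'
#' @param subject_epochs List over subjects; each element a named list of
#'   epoch matrices (one per group, as from [trial_epochs()], row-bound
#'   over runs beforehand if needed).
#' @param alpha Flagging level for the per-timepoint group comparison.
#' @return A list: \code{average} (long data frame \code{group},
#'   \code{time_s}, \code{mean}, \code{sem}), \code{stats} (per-timepoint
#'   \code{time_s}, \code{z}, \code{p}, \code{flag}; NULL unless two
#'   groups), \code{subject_means} (array subjects x groups x time).
#' @export
event_related_average <- function(subject_epochs, alpha = 0.05) {
  groups <- names(subject_epochs[[1L]])
  times <- attr(subject_epochs[[1L]][[1L]], "times_s")
  if (is.null(times)) times <- seq_len(ncol(subject_epochs[[1L]][[1L]]))
  n_sub <- length(subject_epochs)
  sm <- array(NA_real_, dim = c(n_sub, length(groups), length(times)),
              dimnames = list(NULL, groups, NULL))
  for (s in seq_len(n_sub))
    for (g in groups) {
      m <- subject_epochs[[s]][[g]]
      if (!is.null(m) && nrow(m)) sm[s, g, ] <- colMeans(m)
    }
  avg <- do.call(rbind, lapply(groups, function(g)
    data.frame(group = g, time_s = times,
               mean = apply(sm[, g, , drop = FALSE], 3L, mean, na.rm = TRUE))))
  sems <- vapply(seq_along(times), function(ti) {
    m <- sm[, , ti, drop = FALSE]
    dim(m) <- dim(m)[1:2]
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (length(groups) >= 2L && nrow(m) >= 2L) within_subject_sem(m)
    else rep(NA_real_, length(groups))
  }, numeric(length(groups)))
  avg$sem <- as.vector(t(sems))
  stats_df <- NULL
  if (length(groups) == 2L) {
    stats_df <- do.call(rbind, lapply(seq_along(times), function(ti) {
      a <- sm[, 1L, ti]
      b <- sm[, 2L, ti]
      ok <- stats::complete.cases(a, b)
      if (sum(ok) >= 5L) {
        w <- wilcoxon_signed_rank(a[ok], b[ok])
        data.frame(time_s = times[ti], z = w$z, p = w$p,
                   flag = is.finite(w$p) && w$p < alpha)
      } else data.frame(time_s = times[ti], z = NA_real_, p = NA_real_,
                        flag = FALSE)
    }))
  }
  list(average = avg, stats = stats_df, subject_means = sm)
}

#' Random-effects group test of per-subject contrast values
#'
#' One-sample t test across subjects plus the nonparametric Wilcoxon
#' signed-rank test against zero. Zero-variance samples are flagged as
#' degenerate instead of erroring.
#'
#' @param values Numeric vector, one contrast estimate per subject.
#' @return List: \code{n}, \code{mean}, \code{t}, \code{p_t}, \code{z},
#'   \code{p_wilcoxon}, \code{degenerate}.
#' @export
rfx_group_test <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 5L) warning("fewer than 5 subjects in the group test")
  if (stats::sd(values) == 0) {
    m <- mean(values)
    return(list(n = n, mean = m, t = if (m == 0) NaN else sign(m) * Inf,
                p_t = NA_real_, z = NA_real_, p_wilcoxon = if (m == 0) 1 else NA_real_,
                degenerate = TRUE))
  }
  tt <- stats::t.test(values)
  w <- wilcoxon_signed_rank(values, 0)
  list(n = n, mean = mean(values), t = unname(tt$statistic),
       p_t = tt$p.value, z = w$z, p_wilcoxon = w$p,
       degenerate = w$degenerate)
}
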