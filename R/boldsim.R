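# Generative model of multi-ROI BOLD with known task amplitudes and
# condition-modulated seed coupling (the counterpart of the gPPI analysis).

#' BOLD simulation parameters
#'
#' Multi-ROI generative model: every ROI responds to the HRF-convolved
#' condition boxcars with amplitudes \code{beta_task}; target ROIs
#' additionally receive condition-modulated coupling with the seed ROI,
#' \code{beta_ppi[r, c] * z(seed) * X_c}, formed at the hemodynamic level
#' exactly as the gPPI analysis assumes. Structured noise is AR(1) with
#' lag-1 autocorrelation \code{ar1_rho} and stationary SD \code{noise_sd},
#' plus slow cosine drift (1 and 2 cycles per run, random phase, amplitude
#' \code{drift_amp}) that the 3-cycle GLM-Fourier set can absorb. Head
#' motion is simulated as six independent random walks with step SD
#' \code{motion_sd} (a nuisance table; it does not enter the signal).
#'
#' @param roi_names ROI columns to generate. Defaults to the right anterior
#'   insula (seed), right FFA, right STS, medial prefrontal cortex, and a
#'   white-matter noise ROI.
#' @param seed_roi Name of the seed ROI.
#' @param noise_roi Name of the pure-noise (conditioning) ROI.
#' @param beta_task,beta_ppi Optional ROI x condition matrices; when NULL,
#'   defaults are built per schedule by [default_beta_task()] /
#'   [default_beta_ppi()].
#' @param noise_sd,ar1_rho,drift_amp,motion_sd Noise model parameters.
#' @param hrf_params Double-gamma parameters (see [canonical_hrf()]).
#' @param baseline Additive constant (raw signal level) per ROI.
#' @param seed Default RNG seed.
#' @return An object of class \code{bold_sim_params}.
#' @export
bold_sim_params <- function(roi_names = c("rAI", "rFFA", "rSTS", "mPFC", "WM"),
                            seed_roi = "rAI", noise_roi = "WM",
                            beta_task = NULL, beta_ppi = NULL,
                            noise_sd = 1, ar1_rho = 0.3, drift_amp = 1,
                            motion_sd = 0.02,
                            hrf_params = list(a1 = 6, b1 = 1, a2 = 16,
                                              b2 = 1, ratio = 6),
                            baseline = 100, seed = 1L) {
  stopifnot(abs(ar1_rho) < 1, noise_sd >= 0, motion_sd >= 0,
            seed_roi %in% roi_names, noise_roi %in% roi_names)
  structure(list(roi_names = roi_names, seed_roi = seed_roi,
                 noise_roi = noise_roi, beta_task = beta_task,
                 beta_ppi = beta_ppi, noise_sd = noise_sd,
                 ar1_rho = ar1_rho, drift_amp = drift_amp,
                 motion_sd = motion_sd, hrf_params = hrf_params,
                 baseline = baseline, seed = as.integer(seed)),
            class = "bold_sim_params")
}

#' Default task amplitudes per ROI and condition
#'
#' Face-processing visual regions (rFFA, rSTS) respond more to direction-2
#' dynamic transitions (where positive hysteresis dominates under the
#' default observer), the right anterior insula less; mPFC responds equally
#' in both directions; control transitions drive all face-responsive ROIs
#' at half amplitude; the white-matter ROI carries no task signal.
#'
#' @param roi_names,conditions Character vectors naming rows and columns.
#' @return ROI x condition matrix of amplitudes (percent-signal units).
#' @export
default_beta_task <- function(roi_names, conditions) {
  b <- matrix(0, length(roi_names), length(conditions),
              dimnames = list(roi_names, conditions))
  d1 <- grepl("_d1$", conditions)
  d2 <- grepl("_d2$", conditions)
  ctl <- conditions == "control"
  face <- conditions %in% c("face_emotional", "face_neutral")
  for (r in roi_names) {
    if (r == "WM") next
    gain <- switch(r, rFFA = c(1.0, 1.3), rSTS = c(1.0, 1.3),
                   rAI = c(1.1, 0.8), c(1.0, 1.0))
    b[r, d1] <- gain[1L]
    b[r, d2] <- gain[2L]
    b[r, ctl] <- 0.5
    b[r, face] <- 1.0
  }
  b
}

#' Default seed-coupling modulation per ROI and condition
#'
#' Only the mPFC is coupled with the seed (right anterior insula), and more
#' strongly during direction-1 transitions — i.e. coupling is weaker when
#' positive hysteresis dominates, the effect the connectivity analysis is
#' meant to recover.
#'
#' @inheritParams default_beta_task
#' @return ROI x condition matrix of interaction amplitudes.
#' @export
default_beta_ppi <- function(roi_names, conditions) {
  b <- matrix(0, length(roi_names), length(conditions),
              dimnames = list(roi_names, conditions))
  if ("mPFC" %in% roi_names) {
    b["mPFC", grepl("_d1$", conditions)] <- 0.6
    b["mPFC", grepl("_d2$", conditions)] <- 0.2
  }
  b
}

ar1_noise <- function(n, sd, rho) {
  if (sd == 0) return(rep(0, n))
  e <- stats::rnorm(n)
  x <- if (rho == 0) e else as.numeric(stats::filter(e, rho, "recursive"))
  x * sd * sqrt(1 - rho^2)
}

#' Simulate a multi-ROI BOLD dataset for a run
#'
#' Generates the seed ROI as task signal plus AR(1) noise, z-scores the
#' *observed* seed, and builds each remaining ROI as task signal +
#' condition-modulated seed coupling + drift + AR(1) noise, plus a constant
#' baseline. A six-column random-walk motion table and the full ground
#' truth are returned for recovery testing.
#'
#' @param schedule A \code{run_schedule} whose TR grid covers all trials.
#' @param params A [bold_sim_params()] object.
#' @param conditions Trial condition labels (default [trial_conditions()]).
#' @param seed RNG seed (defaults to \code{params$seed}).
#' @return A list of class \code{bold_sim}: \code{roi} (data frame, one
#'   column per ROI, one row per TR), \code{motion} (6-column data frame),
#'   \code{truth} (list with \code{beta_task}, \code{beta_ppi},
#'   \code{conditions}, \code{seed_roi}, \code{noise_roi}).
#' @export
simulate_bold_dataset <- function(schedule, params = bold_sim_params(),
                                  conditions = NULL, seed = params$seed) {
  n <- attr(schedule, "n_volumes")
  tr <- attr(schedule, "tr_s")
  if (is.null(n) || is.null(tr))
    stop("configuration error: schedule lacks a TR grid")
  if (max(schedule$onset + schedule$duration) > n * tr + 1e-9)
    stop("configuration error: TR grid does not cover all trials")
  if (is.null(conditions)) conditions <- trial_conditions(schedule)
  hrf <- canonical_hrf(tr, params$hrf_params)
  u <- condition_boxcars(schedule, conditions)
  xc <- apply(u, 2L, hrf_convolve, kernel = hrf)
  colnames(xc) <- colnames(u)
  levs <- colnames(xc)
  bt <- if (is.null(params$beta_task))
    default_beta_task(params$roi_names, levs) else params$beta_task
  bp <- if (is.null(params$beta_ppi))
    default_beta_ppi(params$roi_names, levs) else params$beta_ppi
  stopifnot(all(params$roi_names %in% rownames(bt)),
            all(levs %in% colnames(bt)))
  with_seed(seed, {
    seed_y <- as.numeric(xc %*% bt[params$seed_roi, levs]) +
      ar1_noise(n, params$noise_sd, params$ar1_rho)
    sz <- if (stats::sd(seed_y) > 0) zscore(seed_y) else rep(0, n)
    t_idx <- seq_len(n) - 1L
    roi <- sapply(params$roi_names, function(r) {
      if (r == params$seed_roi) return(seed_y)
      y <- as.numeric(xc %*% bt[r, levs]) +
        as.numeric((sz * xc) %*% bp[r, levs])
      if (params$drift_amp > 0) {
        ph <- stats::runif(2L, 0, 2 * pi)
        y <- y + params$drift_amp *
          (cos(2 * pi * t_idx / n + ph[1L]) +
             0.5 * cos(4 * pi * t_idx / n + ph[2L]))
      }
      y + ar1_noise(n, params$noise_sd, params$ar1_rho)
    })
    motion <- sapply(1:6, function(j)
      cumsum(stats::rnorm(n, 0, params$motion_sd)))
  })
  colnames(motion) <- paste0("motion_", 1:6)
  roi <- as.data.frame(roi + params$baseline)
  structure(list(roi = roi, motion = as.data.frame(motion),
                 truth = list(beta_task = bt, beta_ppi = bp,
                              conditions = levs,
                              seed_roi = params$seed_roi,
                              noise_roi = params$noise_roi)),
            class = "bold_sim")
}
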