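# Synthetic observer: behavioural generator with known ground-truth
# hysteresis shifts.

#' Synthetic observer parameters
#'
#' The observer carries (i) a three-way ordinal psychometric model of the
#' static classification task — logistic category boundaries at
#' \code{static_center_lo}/\code{static_center_hi} on the signed stimulus
#' axis with steepness \code{static_slope} — and (ii) a ground-truth
#' hysteresis displacement \code{h_shift} (percent, per pair x direction)
#' that delays both borders of its perceived-neutral interval along the
#' trajectory during dynamic trials. Positive \code{h_shift} means the
#' percept persists: the switch to the alternative percept happens later
#' than in the no-history (static) case.
#'
#' @param h_shift Scalar, or 3 x 2 matrix (rows = [emotion_pairs()],
#'   columns = directions 1:2), percent along the signed axis.
#' @param motor_sd Motor noise SD added to each press time, seconds.
#' @param miss_prob Probability that an individual border press is omitted.
#' @param false_alarm_prob Probability that a neutral-to-neutral control
#'   trial nonetheless yields a pair of presses.
#' @param static_slope Psychometric steepness, per percent.
#' @param static_center_lo,static_center_hi Signed positions of the
#'   negative/neutral and neutral/positive category boundaries.
#' @param seed Default RNG seed for the simulators.
#' @return An object of class \code{observer_params}.
#' @export
observer_params <- function(h_shift = default_h_shift(), motor_sd = 0.1,
                            miss_prob = 0.05, false_alarm_prob = 0.05,
                            static_slope = 1, static_center_lo = -30,
                            static_center_hi = 30, seed = 1L) {
  stopifnot(miss_prob >= 0, miss_prob < 1, motor_sd >= 0,
            false_alarm_prob >= 0, false_alarm_prob <= 1,
            static_slope > 0, static_center_lo < static_center_hi)
  obs <- list(h_shift = h_shift_matrix(h_shift), motor_sd = motor_sd,
              miss_prob = miss_prob, false_alarm_prob = false_alarm_prob,
              static_slope = static_slope,
              static_center_lo = static_center_lo,
              static_center_hi = static_center_hi, seed = as.integer(seed))
  class(obs) <- "observer_params"
  obs
}

#' Default ground-truth hysteresis shifts
#'
#' Positive hysteresis in both directions for the anger-happiness pair and
#' in direction 2 only for the two sadness pairs, mimicking the asymmetric
#' dominance typically seen with these transitions.
#'
#' @return A 3 x 2 matrix (pairs x directions) of shifts in percent.
#' @export
default_h_shift <- function() {
  m <- matrix(c(10, 10,
                0, 15,
                0, 15), nrow = 3L, byrow = TRUE,
              dimnames = list(emotion_pairs(), c("1", "2")))
  m
}

h_shift_matrix <- function(h) {
  if (is.matrix(h)) {
    stopifnot(nrow(h) == 3L, ncol(h) == 2L)
    dimnames(h) <- list(emotion_pairs(), c("1", "2"))
    return(h)
  }
  stopifnot(is.numeric(h), length(h) == 1L)
  matrix(h, 3L, 2L, dimnames = list(emotion_pairs(), c("1", "2")))
}

#' Three-way classification probabilities of the observer
#'
#' Ordinal logistic model: P(E-) = logit^-1(slope (c_lo - s)),
#' P(E+) = logit^-1(slope (s - c_hi)), P(N) the remainder (floored at zero
#' and renormalised for extreme slope/boundary combinations).
#'
#' @param obs An [observer_params()] object.
#' @param signed_pct Signed stimulus positions.
#' @return A matrix with columns \code{E-}, \code{N}, \code{E+}.
#' @export
choice_probs <- function(obs, signed_pct) {
  p_lo <- stats::plogis(obs$static_slope * (obs$static_center_lo - signed_pct))
  p_hi <- stats::plogis(obs$static_slope * (signed_pct - obs$static_center_hi))
  p_n <- pmax(0, 1 - p_lo - p_hi)
  pr <- cbind(`E-` = p_lo, N = p_n, `E+` = p_hi)
  pr / rowSums(pr)
}

#' Implied neutral band of the observer on the probe-frame grid
#'
#' The signed positions of the earliest and latest probe frames that the
#' observer's classifier labels neutral by modal choice in the noise-free
#' limit. These are the observer's operational no-history borders: its
#' dynamic neutral-interval borders at zero hysteresis shift coincide with
#' them, which makes the hysteresis metric unbiased for the injected shift.
#'
#' @param obs An [observer_params()] object.
#' @param params A [morph_params()] object.
#' @return Numeric \code{c(lo, hi)} in signed percent (NA if no probe frame
#'   is modal-neutral).
#' @export
implied_neutral_band <- function(obs, params = morph_params()) {
  s <- signed_position(static_probe_frames(params), params)
  pr <- choice_probs(obs, s)
  neutral <- pr[, "N"] >= pmax(pr[, "E-"], pr[, "E+"])
  if (!any(neutral)) return(c(lo = NA_real_, hi = NA_real_))
  c(lo = min(s[neutral]), hi = max(s[neutral]))
}

# Time (s from trial onset) at which the trajectory of `direction` first
# reaches signed position `pos`; the press lands mid-way through that
# frame's display interval. NA if the position is never reached.
border_press_time <- function(pos, direction, params = morph_params()) {
  step <- params$step_pct
  k <- params$neutral_frame_index
  if (direction == 1L) {
    f <- k + ceiling(pos / step - 1e-9)
    if (f > params$n_frames) return(NA_real_)
    f <- max(f, 1L)
    shown <- f
  } else {
    f <- k + floor(pos / step + 1e-9)
    if (f < 1L) return(NA_real_)
    f <- min(f, params$n_frames)
    shown <- params$n_frames + 1L - f
  }
  (frame_onset_ms(shown, params) + frame_duration_ms(shown, params) / 2) / 1000
}

#' Simulate button-press reports for a dynamic run
#'
#' For each dynamic transition trial the observer's perceived-neutral
#' borders are its implied static borders displaced along the trajectory by
#' the trial's ground-truth \code{h_shift}; each border is converted to a
#' press time through the frame-timing map, jittered by motor noise,
#' truncated to the 10-s trial window, and omitted independently with
#' probability \code{miss_prob}. Control (neutral-to-neutral) trials yield a
#' spurious press pair with probability \code{false_alarm_prob}.
#'
#' @param schedule A dynamic \code{run_schedule}.
#' @param obs An [observer_params()] object.
#' @param params A [morph_params()] object.
#' @param seed RNG seed (defaults to \code{obs$seed}).
#' @return A data frame of presses with columns \code{trial_id} (row index
#'   into the schedule) and \code{press_s} (seconds from trial onset),
#'   sorted within trial.
#' @export
simulate_dynamic_reports <- function(schedule, obs, params = morph_params(),
                                     seed = obs$seed) {
  if (!identical(attr(schedule, "run_kind"), "dynamic"))
    stop("schedule is not a dynamic run")
  band <- implied_neutral_band(obs, params)
  if (any(is.na(band)))
    stop("observer has no neutral band on the probe grid")
  with_seed(seed, {
    out <- vector("list", nrow(schedule))
    for (i in seq_len(nrow(schedule))) {
      tt <- schedule$trial_type[i]
      presses <- numeric(0)
      if (tt %in% c("dynamic_E1NE2", "dynamic_E2NE1")) {
        d <- schedule$direction[i]
        h <- obs$h_shift[schedule$pair[i], as.character(d)]
        pos <- if (d == 1L) c(band["lo"] + h, band["hi"] + h)
               else         c(band["hi"] - h, band["lo"] - h)
        t12 <- vapply(pos, border_press_time, numeric(1),
                      direction = d, params = params)
        t12 <- t12 + stats::rnorm(2L, 0, obs$motor_sd)
        keep <- !is.na(t12) & stats::runif(2L) >= obs$miss_prob
        presses <- pmin(pmax(t12[keep], 0), 9.999)
      } else if (tt == "control_NNN") {
        if (stats::runif(1L) < obs$false_alarm_prob)
          presses <- sort(stats::runif(2L, 0, 10))
      }
      if (length(presses))
        out[[i]] <- data.frame(trial_id = i, press_s = unname(sort(presses)))
    }
    res <- rbind_rows(out)
    if (is.null(res))
      res <- data.frame(trial_id = integer(0), press_s = numeric(0))
    res
  })
}

#' Simulate three-way classifications for a static run
#'
#' Each static image trial is classified as negative (E-), neutral (N), or
#' positive (E+) by sampling from the observer's psychometric probabilities
#' at the frame's signed position.
#'
#' @inheritParams simulate_dynamic_reports
#' @param schedule A static \code{run_schedule}.
#' @return Data frame with columns \code{trial_id}, \code{frame_index},
#'   \code{choice} (one of \code{"E-"}, \code{"N"}, \code{"E+"}).
#' @export
simulate_static_classifications <- function(schedule, obs,
                                            params = morph_params(),
                                            seed = obs$seed) {
  if (!identical(attr(schedule, "run_kind"), "static"))
    stop("schedule is not a static run")
  img <- which(schedule$trial_type == "static_image")
  s <- signed_position(schedule$frame_index[img], params)
  pr <- choice_probs(obs, s)
  with_seed(seed, {
    u <- stats::runif(length(img))
    cum1 <- pr[, 1L]
    cum2 <- pr[, 1L] + pr[, 2L]
    choice <- ifelse(u < cum1, "E-", ifelse(u < cum2, "N", "E+"))
  })
  data.frame(trial_id = img, frame_index = schedule$frame_index[img],
             choice = choice)
}
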