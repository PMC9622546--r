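#' Morph-sequence parameters
#'
#' Describes one dynamic facial-expression morph: a source emotion (E1)
#' ramping linearly down to a neutral expression and then up to a target
#' emotion (E2), in steps of \code{step_pct} percent per frame. With the
#' default 2.5\% step there are 40 intermediate frames on each side of the
#' shared neutral frame, i.e. 81 frames in total. Middle frames are shown
#' for \code{mid_frame_ms} each; the two endpoint frames (full E1 / full E2)
#' are held for \code{endpoint_frame_ms}, so a default trial lasts
#' 79 x 113.92 + 2 x 500 = 9,999.68 ms, i.e. 10 s.
#'
#' @param step_pct Emotion-percentage increment between consecutive frames.
#'   Must divide 100 evenly.
#' @param mid_frame_ms Display duration of each non-endpoint frame (ms).
#' @param endpoint_frame_ms Display duration of the first and last frame (ms).
#' @return An object of class \code{morph_params}: a list with fields
#'   \code{n_frames}, \code{step_pct}, \code{mid_frame_ms},
#'   \code{endpoint_frame_ms}, \code{neutral_frame_index} and the derived
#'   total \code{trial_ms}.
#' @examples
#' p <- morph_params()
#' p$n_frames            # 81
#' p$neutral_frame_index # 41
#' @export
morph_params <- function(step_pct = 2.5, mid_frame_ms = 113.92,
                         endpoint_frame_ms = 500) {
  stopifnot(is.numeric(step_pct), length(step_pct) == 1L, step_pct > 0,
            mid_frame_ms > 0, endpoint_frame_ms > 0)
  n_side <- 100 / step_pct
  if (abs(n_side - round(n_side)) > 1e-9)
    stop("step_pct must divide 100 evenly")
  n_side <- as.integer(round(n_side))
  p <- list(
    n_frames = 2L * n_side + 1L,
    step_pct = step_pct,
    mid_frame_ms = mid_frame_ms,
    endpoint_frame_ms = endpoint_frame_ms,
    neutral_frame_index = n_side + 1L
  )
  p$trial_ms <- (p$n_frames - 2L) * mid_frame_ms + 2 * endpoint_frame_ms
  class(p) <- "morph_params"
  p
}

#' @export
print.morph_params <- function(x, ...) {
  cat(sprintf(
    "Morph sequence: %d frames, %.2f%%/frame, neutral at frame %d\n",
    x$n_frames, x$step_pct, x$neutral_frame_index))
  cat(sprintf("  frame durations: %.2f ms (mid), %.0f ms (endpoints); trial %.2f ms\n",
              x$mid_frame_ms, x$endpoint_frame_ms, x$trial_ms))
  invisible(x)
}

check_frame_index <- function(frame_index, params) {
  if (any(!is.finite(frame_index)) ||
      any(frame_index < 1L) || any(frame_index > params$n_frames) ||
      any(frame_index != round(frame_index)))
    stop("frame_index out of bounds: must be an integer in [1, ",
         params$n_frames, "]")
  invisible(TRUE)
}

#' Emotion mixture of a morph frame
#'
#' Returns the emotion composition (percent source emotion E1, neutral N,
#' target emotion E2) of one or more frames of the morph sequence. Frames up
#' to the neutral midpoint blend E1 with neutral; frames from the midpoint
#' on blend neutral with E2; exactly one of E1/E2 can be nonzero.
#'
#' @param frame_index 1-based frame index (vectorised).
#' @param params A [morph_params()] object.
#' @return A data frame with columns \code{frame_index}, \code{e1_pct},
#'   \code{n_pct}, \code{e2_pct}.
#' @examples
#' frame_composition(c(17, 41, 65))
#' @export
frame_composition <- function(frame_index, params = morph_params()) {
  check_frame_index(frame_index, params)
  k <- params$neutral_frame_index
  e1 <- ifelse(frame_index <= k, 100 - params$step_pct * (frame_index - 1), 0)
  e2 <- ifelse(frame_index >= k, params$step_pct * (frame_index - k), 0)
  data.frame(frame_index = as.integer(frame_index),
             e1_pct = e1, n_pct = 100 - e1 - e2, e2_pct = e2)
}

#' Signed stimulus position of a morph frame
#'
#' Maps a frame to a single signed axis, \code{e2_pct - e1_pct}, running
#' from -100 (full source emotion) through 0 (neutral) to +100 (full target
#' emotion). All behavioural quantities (neutral-interval borders, static
#' inflections, the hysteresis metric) live on this axis.
#'
#' @inheritParams frame_composition
#' @return Numeric vector of signed percentages in [-100, 100].
#' @export
signed_position <- function(frame_index, params = morph_params()) {
  check_frame_index(frame_index, params)
  params$step_pct * (frame_index - params$neutral_frame_index)
}

#' Frame display onsets and durations
#'
#' @inheritParams frame_composition
#' @return Onset (or duration) of each frame in ms from trial onset.
#' @export
frame_onset_ms <- function(frame_index, params = morph_params()) {
  check_frame_index(frame_index, params)
  ifelse(frame_index == 1L, 0,
         params$endpoint_frame_ms + (frame_index - 2L) * params$mid_frame_ms)
}

#' @rdname frame_onset_ms
#' @export
frame_duration_ms <- function(frame_index, params = morph_params()) {
  check_frame_index(frame_index, params)
  ifelse(frame_index %in% c(1L, params$n_frames),
         params$endpoint_frame_ms, params$mid_frame_ms)
}

#' Frame on screen at a given time
#'
#' Inverse of the frame timing map: which frame of the (forward-played)
#' morph sequence is on screen \code{t_ms} milliseconds after trial onset.
#' Piecewise: the first endpoint frame covers [0, 500) ms, middle frames
#' follow at \code{mid_frame_ms} each, the remainder of the 10-s window is
#' the last endpoint frame.
#'
#' @param t_ms Time from trial onset in milliseconds, in [0, 10000).
#' @param params A [morph_params()] object.
#' @return Integer frame indices.
#' @export
time_to_frame <- function(t_ms, params = morph_params()) {
  limit <- round(params$trial_ms, -3)
  if (any(!is.finite(t_ms)) || any(t_ms < 0) || any(t_ms >= limit))
    stop("t_ms out of bounds: must lie in [0, ", limit, ") ms")
  k <- floor((t_ms - params$endpoint_frame_ms) / params$mid_frame_ms + 1e-9)
  f <- ifelse(t_ms < params$endpoint_frame_ms, 1L,
              ifelse(k <= params$n_frames - 3L, k + 2L, params$n_frames))
  as.integer(f)
}

#' Frame displayed at a given time for a stimulation direction
#'
#' Direction 1 plays the morph forward (E1 -> N -> E2); direction 2 plays it
#' in reverse (E2 -> N -> E1), i.e. the displayed frame index is mirrored.
#'
#' @inheritParams time_to_frame
#' @param direction 1 or 2.
#' @export
displayed_frame <- function(t_ms, direction, params = morph_params()) {
  stopifnot(all(direction %in% c(1L, 2L)))
  f <- time_to_frame(t_ms, params)
  d <- rep_len(as.integer(direction), length(f))
  as.integer(ifelse(d == 1L, f, params$n_frames + 1L - f))
}

#' Probe frames used in the static classification task
#'
#' The nine frames whose snapshots are shown in the static control runs:
#' the two endpoints, and frames at 80/60/20 percent source emotion, the
#' neutral midpoint, and 20/60/80 percent target emotion.
#'
#' @param params A [morph_params()] object.
#' @return Integer vector of nine frame indices (default
#'   1, 9, 17, 33, 41, 49, 65, 73, 81).
#' @export
static_probe_frames <- function(params = morph_params()) {
  k <- params$neutral_frame_index
  off <- round(c(-1, -0.8, -0.6, -0.2, 0, 0.2, 0.6, 0.8, 1) * (k - 1L))
  as.integer(k + off)
}

#' Composition table of the static probe frames
#'
#' @param params A [morph_params()] object.
#' @param frames Frame indices to tabulate (defaults to the probe frames).
#' @return A data frame of frame compositions with signed positions.
#' @export
morph_frame_table <- function(params = morph_params(),
                              frames = static_probe_frames(params)) {
  out <- frame_composition(frames, params)
  out$signed_pct <- signed_position(frames, params)
  out
}
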