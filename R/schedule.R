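# Run schedules for the dynamic-transition and static-classification tasks.

#' Emotion pairs used for the dynamic transitions
#'
#' @return Character vector of the three source-target emotion pairs.
#' @export
emotion_pairs <- function() {
  c("anger-happiness", "sadness-anger", "sadness-happiness")
}

# rbind a list of data frames, ignoring NULL entries; NULL when all are.
rbind_rows <- function(lst) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (!length(lst)) return(NULL)
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

new_run_schedule <- function(rows, run_kind, tr_s, n_volumes) {
  trials <- do.call(rbind, rows)
  trials$onset <- cumsum(c(0, trials$duration))[seq_len(nrow(trials))]
  trials <- trials[, c("onset", "duration", "trial_type", "pair",
                       "direction", "actor_id", "frame_index")]
  rownames(trials) <- NULL
  total <- sum(trials$duration)
  if (total > n_volumes * tr_s + 1e-9)
    warning(sprintf(
      "schedule lasts %.1f s but the scan covers only %d x %.1f = %.1f s",
      total, n_volumes, tr_s, n_volumes * tr_s))
  structure(trials, run_kind = run_kind, tr_s = tr_s, n_volumes = n_volumes,
            class = c("run_schedule", "data.frame"))
}

sched_row <- function(trial_type, duration, pair = NA_character_,
                      direction = NA_integer_, actor_id = NA_integer_,
                      frame_index = NA_integer_) {
  data.frame(onset = NA_real_, duration = duration, trial_type = trial_type,
             pair = pair, direction = as.integer(direction),
             actor_id = as.integer(actor_id),
             frame_index = as.integer(frame_index))
}

#' Build a dynamic-transitions run schedule
#'
#' One run holds 24 dynamic transition trials (4 repetitions of each of the
#' 3 emotion pairs x 2 stimulation directions), organised as three sequences
#' of eight transitions each interleaved with neutral-to-neutral control
#' transitions, with 10-s fixation blocks at run start (opening the first
#' sequence), before each later sequence, and at run end. Every condition
#' lasts 10 s. Trial order is pseudo-randomised so that no two consecutive
#' dynamic transitions use the same actor.
#'
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @param actors Integer ids of available actors (at least two).
#' @param tr_s Repetition time of the accompanying scan, seconds.
#' @param n_volumes Functional volumes acquired in the run.
#' @return A \code{run_schedule}: a data frame of trials (columns
#'   \code{onset}, \code{duration}, \code{trial_type}, \code{pair},
#'   \code{direction}, \code{actor_id}, \code{frame_index}) with attributes
#'   \code{run_kind}, \code{tr_s}, \code{n_volumes}.
#' @export
build_dynamic_run_schedule <- function(seed = 1L, actors = 1:7, tr_s = 2,
                                       n_volumes = 280L) {
  if (length(actors) < 2L)
    stop("configuration error: need at least 2 actors to avoid consecutive ",
         "dynamic transitions of the same actor")
  conds <- expand.grid(pair = emotion_pairs(), direction = 1:2, rep = 1:4,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  with_seed(seed, {
    conds <- conds[sample.int(nrow(conds)), ]
    dyn_actor <- integer(nrow(conds))
    prev <- NA_integer_
    for (i in seq_len(nrow(conds))) {
      pool <- setdiff(actors, prev)
      dyn_actor[i] <- pool[sample.int(length(pool), 1L)]
      prev <- dyn_actor[i]
    }
    ctrl_actor <- sample(actors, nrow(conds), replace = TRUE)
  })
  rows <- list(sched_row("fixation", 10))
  idx <- 0L
  for (s in 1:3) {
    if (s > 1L) rows <- c(rows, list(sched_row("fixation", 10)))
    for (j in 1:8) {
      idx <- idx + 1L
      tt <- if (conds$direction[idx] == 1L) "dynamic_E1NE2" else "dynamic_E2NE1"
      rows <- c(rows, list(
        sched_row(tt, 10, conds$pair[idx], conds$direction[idx],
                  dyn_actor[idx]),
        sched_row("control_NNN", 10, actor_id = ctrl_actor[idx])))
    }
  }
  rows <- c(rows, list(sched_row("fixation", 10)))
  new_run_schedule(rows, "dynamic", tr_s, n_volumes)
}

#' Build a static-classification run schedule
#'
#' One run presents 12 repetitions of the 9 probe frames taken from the
#' dynamic transitions of a single emotion pair (108 image trials), each
#' followed by a 2-s neutral snapshot, in three blocks of 36 image/neutral
#' pairs. 10-s fixation blocks open the run (and its first block), precede
#' blocks 2 and 3, and close the run.
#'
#' @param pair One of [emotion_pairs()].
#' @param seed Integer seed; deterministic given the seed.
#' @param actors Integer actor ids to sample snapshots from.
#' @param tr_s,n_volumes Scan timing (defaults 2 s, 249 volumes).
#' @param params A [morph_params()] object (probe frames derive from it).
#' @return A \code{run_schedule} (see [build_dynamic_run_schedule()]).
#' @export
build_static_run_schedule <- function(pair, seed = 1L, actors = 1:7,
                                      tr_s = 2, n_volumes = 249L,
                                      params = morph_params()) {
  if (!pair %in% emotion_pairs())
    stop("unknown emotion pair: ", pair)
  frames <- rep(static_probe_frames(params), times = 12L)
  with_seed(seed, {
    frames <- frames[sample.int(length(frames))]
    img_actor <- sample(actors, length(frames), replace = TRUE)
    neu_actor <- sample(actors, length(frames), replace = TRUE)
  })
  rows <- list()
  idx <- 0L
  for (b in 1:3) {
    rows <- c(rows, list(sched_row("fixation", 10)))
    for (j in 1:36) {
      idx <- idx + 1L
      rows <- c(rows, list(
        sched_row("static_image", 2, pair, actor_id = img_actor[idx],
                  frame_index = frames[idx]),
        sched_row("static_neutral", 2, pair, actor_id = neu_actor[idx])))
    }
  }
  rows <- c(rows, list(sched_row("fixation", 10)))
  new_run_schedule(rows, "static", tr_s, n_volumes)
}

#' @export
print.run_schedule <- function(x, ...) {
  cat(sprintf("%s run schedule: %d trials, %.1f s stimulation, %d volumes @ TR %.1f s\n",
              attr(x, "run_kind"), nrow(x), sum(x$duration),
              attr(x, "n_volumes"), attr(x, "tr_s")))
  print(utils::head(as.data.frame(x), 8L))
  if (nrow(x) > 8L) cat("  ...", nrow(x) - 8L, "more trials\n")
  invisible(x)
}

#' Validate a run schedule against the protocol invariants
#'
#' Checks contiguity/non-overlap of trials, condition counts (24 dynamic
#' trials, 4 per pair x direction, in dynamic runs; 108 image trials, 12 per
#' probe frame, in static runs), trial durations, and the no-consecutive-
#' same-actor constraint for dynamic transitions.
#'
#' @param schedule A \code{run_schedule}.
#' @return Invisibly \code{TRUE}; stops with a message on violation.
#' @export
validate_run_schedule <- function(schedule) {
  ends <- schedule$onset + schedule$duration
  if (any(abs(schedule$onset[-1] - ends[-length(ends)]) > 1e-9))
    stop("trials are not contiguous")
  kind <- attr(schedule, "run_kind")
  dyn <- schedule[schedule$trial_type %in% c("dynamic_E1NE2", "dynamic_E2NE1"), ]
  if (identical(kind, "dynamic")) {
    if (nrow(dyn) != 24L) stop("expected 24 dynamic trials, found ", nrow(dyn))
    tab <- table(dyn$pair, dyn$direction)
    if (any(tab != 4L)) stop("expected 4 trials per pair x direction")
    if (any(dyn$duration != 10)) stop("dynamic trials must last 10 s")
    ctrl <- schedule$trial_type == "control_NNN"
    if (any(schedule$duration[ctrl] != 10)) stop("control trials must last 10 s")
    if (any(diff(dyn$actor_id) == 0L))
      stop("two consecutive dynamic transitions share an actor")
  } else if (identical(kind, "static")) {
    img <- schedule[schedule$trial_type == "static_image", ]
    if (nrow(img) != 108L) stop("expected 108 static image trials, found ",
                                nrow(img))
    if (any(table(img$frame_index) != 12L))
      stop("expected 12 repetitions of each probe frame")
    if (any(schedule$duration[schedule$trial_type %in%
                              c("static_image", "static_neutral")] != 2))
      stop("static trials must last 2 s")
  }
  invisible(TRUE)
}
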