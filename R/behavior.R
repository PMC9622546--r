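# Behavioural core: neutral-interval extraction, transition points, the
# hysteresis metric and its classification, and group statistics.

dynamic_types <- c("dynamic_E1NE2", "dynamic_E2NE1")

#' Extract perceived-neutral intervals from button presses
#'
#' Participants press once when the expression stops looking like the
#' source emotion (P1, neutral onset) and once when it starts looking like
#' the target emotion (P2, neutral offset). Trials with fewer than two
#' presses cannot define a neutral interval and are excluded and counted.
#' Press times are mapped to signed stimulus positions through the frame
#' timing map, mirrored for direction-2 (reverse-played) trials.
#'
#' @param responses Data frame of presses (\code{trial_id}, \code{press_s}),
#'   as produced by [simulate_dynamic_reports()] or read from a response TSV.
#' @param schedule The dynamic \code{run_schedule} the responses refer to.
#' @param params A [morph_params()] object.
#' @return A list: \code{intervals} (data frame with \code{trial_id},
#'   \code{pair}, \code{direction}, \code{p1_s}, \code{p2_s}, \code{p1_pos},
#'   \code{p2_pos}), \code{n_trials}, \code{n_excluded},
#'   \code{excluded_fraction}.
#' @export
extract_neutral_intervals <- function(responses, schedule,
                                      params = morph_params()) {
  dyn <- which(schedule$trial_type %in% dynamic_types)
  rows <- vector("list", length(dyn))
  n_excl <- 0L
  for (j in seq_along(dyn)) {
    i <- dyn[j]
    pr <- sort(responses$press_s[responses$trial_id == i])
    if (length(pr) < 2L) {
      n_excl <- n_excl + 1L
      next
    }
    d <- schedule$direction[i]
    p12 <- c(pr[1L], pr[length(pr)])
    pos <- signed_position(displayed_frame(p12 * 1000, d, params), params)
    rows[[j]] <- data.frame(trial_id = i, pair = schedule$pair[i],
                            direction = d, p1_s = p12[1L], p2_s = p12[2L],
                            p1_pos = pos[1L], p2_pos = pos[2L])
  }
  intervals <- rbind_rows(rows)
  if (is.null(intervals))
    intervals <- data.frame(trial_id = integer(0), pair = character(0),
                            direction = integer(0), p1_s = numeric(0),
                            p2_s = numeric(0), p1_pos = numeric(0),
                            p2_pos = numeric(0))
  list(intervals = intervals, n_trials = length(dyn), n_excluded = n_excl,
       excluded_fraction = if (length(dyn)) n_excl / length(dyn) else NA_real_)
}

#' Per-group dynamic transition points
#'
#' Averages the two neutral-interval borders over trials within each
#' participant x pair x direction cell (grouping columns are taken from
#' those present in \code{intervals}). The P2 border — the switch to the
#' alternative percept — is the dynamic inflection used by the hysteresis
#' metric.
#'
#' @param intervals Interval data frame (optionally with a
#'   \code{participant} column) as returned by
#'   [extract_neutral_intervals()], possibly row-bound over runs.
#' @return Data frame with the grouping columns, mean \code{p1_pos},
#'   mean \code{p2_pos} and trial count \code{n}.
#' @export
dynamic_transition_points <- function(intervals) {
  by_cols <- intersect(c("participant", "pair", "direction"),
                       names(intervals))
  if (!length(by_cols)) stop("intervals carry no grouping columns")
  key <- interaction(intervals[by_cols], drop = TRUE, lex.order = TRUE)
  parts <- split(intervals, key)
  out <- lapply(parts, function(g) {
    cbind(g[1L, by_cols, drop = FALSE],
          data.frame(p1_pos = mean(g$p1_pos), p2_pos = mean(g$p2_pos),
                     n = nrow(g)))
  })
  res <- rbind_rows(out)
  res[do.call(order, res[by_cols]), , drop = FALSE]
}

#' Static (no-history) inflection points
#'
#' A probe frame counts as "reported neutral" when N is its modal choice
#' over the repetitions (ties resolved in favour of N). The signed
#' positions of the earliest and latest such frames estimate the borders of
#' the no-history neutral range; the per-frame percentage of neutral
#' reports is returned alongside so that other thresholds can be applied.
#'
#' @param classifications Data frame (\code{frame_index}, \code{choice})
#'   for one participant and one emotion pair, possibly row-bound over runs.
#' @param params A [morph_params()] object.
#' @return A list with \code{lo_pos}, \code{hi_pos} (signed percent, NA
#'   when no frame is modal-neutral) and \code{neutral_pct} (data frame
#'   \code{frame_index}, \code{signed_pct}, \code{pct_neutral}).
#' @export
static_inflection <- function(classifications, params = morph_params()) {
  frames <- sort(unique(classifications$frame_index))
  s <- signed_position(frames, params)
  stats <- t(vapply(frames, function(f) {
    ch <- classifications$choice[classifications$frame_index == f]
    c(n_lo = sum(ch == "E-"), n_n = sum(ch == "N"), n_hi = sum(ch == "E+"))
  }, numeric(3)))
  neutral <- stats[, "n_n"] >= pmax(stats[, "n_lo"], stats[, "n_hi"]) &
    stats[, "n_n"] > 0
  curve <- data.frame(frame_index = frames, signed_pct = s,
                      pct_neutral = 100 * stats[, "n_n"] / rowSums(stats))
  if (!any(neutral))
    return(list(lo_pos = NA_real_, hi_pos = NA_real_, neutral_pct = curve))
  list(lo_pos = min(s[neutral]), hi_pos = max(s[neutral]),
       neutral_pct = curve)
}

#' Hysteresis metric and classification
#'
#' The metric is the difference between the absolute perceptual switch to
#' the alternative percept in a stimulation direction and the absolute
#' switch in the no-history case: \code{value = |dynamic| - |static|}.
#' Values beyond \code{+tol} are labelled \code{"positive"} (the switch
#' happened later than without history, i.e. the percept persisted), below
#' \code{-tol} \code{"negative"}, otherwise \code{"none"}. The default
#' tolerance is half a morph step.
#'
#' @param dynamic_inflection Signed position of the dynamic switch (the
#'   mean P2 border). Vectorised.
#' @param static_inflection Signed position of the no-history switch on the
#'   same (target) side.
#' @param tol Equality tolerance in percent (default 1.25).
#' @return Data frame with \code{value} and \code{label}; NA inputs
#'   propagate to NA.
#' @export
hysteresis_metric <- function(dynamic_inflection, static_inflection,
                              tol = 1.25) {
  stopifnot(tol >= 0)
  value <- abs(dynamic_inflection) - abs(static_inflection)
  label <- ifelse(is.na(value), NA_character_,
                  ifelse(value > tol, "positive",
                         ifelse(value < -tol, "negative", "none")))
  data.frame(value = value, label = label)
}

#' Per-participant hysteresis results table
#'
#' Joins dynamic transition points with static inflections and applies the
#' hysteresis metric. The no-history switch for direction 1 (towards the
#' target emotion E2) is the upper static border; for direction 2 (towards
#' E1) the lower one.
#'
#' @param transition_points Output of [dynamic_transition_points()]
#'   (columns \code{participant} optional, \code{pair}, \code{direction},
#'   \code{p1_pos}, \code{p2_pos}).
#' @param static_borders Data frame with matching \code{participant}/
#'   \code{pair} columns plus \code{lo_pos}, \code{hi_pos}.
#' @param tol Tolerance passed to [hysteresis_metric()].
#' @return Data frame: grouping columns, \code{dynamic_inflection},
#'   \code{static_inflection}, \code{value}, \code{label}.
#' @export
hysteresis_results <- function(transition_points, static_borders,
                               tol = 1.25) {
  by_cols <- intersect(c("participant", "pair"), names(transition_points))
  res <- merge(transition_points, static_borders, by = by_cols,
               all.x = TRUE, sort = FALSE)
  res$dynamic_inflection <- res$p2_pos
  res$static_inflection <- ifelse(res$direction == 1L, res$hi_pos,
                                  res$lo_pos)
  m <- hysteresis_metric(res$dynamic_inflection, res$static_inflection, tol)
  out_cols <- c(intersect(c("participant", "pair", "direction"), names(res)),
                "dynamic_inflection", "static_inflection")
  out <- cbind(res[out_cols], m)
  out[do.call(order, out[intersect(c("participant", "pair", "direction"),
                                   names(out))]), , drop = FALSE]
}

#' Wilcoxon signed-rank test
#'
#' Paired two-tailed signed-rank test with the conventions used for
#' behavioural hysteresis comparisons: zero differences are dropped, the
#' exact null distribution is enumerated for n <= 25 when the absolute
#' differences are untied, and a tie-corrected, continuity-corrected normal
#' approximation is used otherwise. The standardised statistic Z is always
#' reported.
#'
#' @param x,y Paired samples (\code{y} may be a scalar, e.g. 0 to test a
#'   one-sample location).
#' @return A list: \code{statistic} (V, sum of positive ranks), \code{z},
#'   \code{p}, \code{n} (pairs after dropping zeros), \code{exact},
#'   \code{degenerate}.
#' @export
wilcoxon_signed_rank <- function(x, y = 0) {
  if (length(y) == 1L) y <- rep(y, length(x))
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  d <- x[ok] - y[ok]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = NA_real_, z = NA_real_, p = 1, n = 0L,
                exact = FALSE, degenerate = TRUE))
  if (n < 5L)
    warning("fewer than 5 nonzero differences; test has little power")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- if (sigma2 > 0) (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2) else 0
  if (!ties && n <= 25L) {
    p_lo <- stats::psignrank(v, n)
    p_hi <- stats::psignrank(v - 1, n, lower.tail = FALSE)
    p <- min(1, 2 * min(p_lo, p_hi))
    exact <- TRUE
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  list(statistic = v, z = z, p = p, n = n, exact = exact,
       degenerate = sigma2 <= 0)
}

#' Within-subject standard error of the mean
#'
#' Removes between-subject offsets before computing per-condition SEMs:
#' each row (subject) is recentred to the grand mean, the per-condition SD
#' over subjects is divided by sqrt(n), and the Morey bias factor
#' sqrt(C/(C-1)) is applied for C conditions.
#'
#' @param m Numeric matrix, subjects in rows, conditions in columns.
#' @return Numeric vector of one SEM per condition.
#' @export
within_subject_sem <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  c_ <- ncol(m)
  if (n < 2L) stop("need at least 2 subjects")
  if (c_ < 2L) {
    warning("single condition: returning the plain SEM")
    return(stats::sd(m[, 1L]) / sqrt(n))
  }
  centred <- m - rowMeans(m) + mean(m)
  apply(centred, 2L, stats::sd) / sqrt(n) * sqrt(c_ / (c_ - 1))
}
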