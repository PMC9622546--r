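# Readers/writers (BIDS-style TSV, JSON/YAML config) and output sidecars.

events_columns <- c("onset", "duration", "trial_type", "pair", "direction",
                    "actor_id", "frame_index")

#' Write / read a BIDS-style events table
#'
#' Tab-separated, UTF-8, \code{"."} for missing values, fixed column order
#' (\code{onset, duration, trial_type, pair, direction, actor_id,
#' frame_index}); all times in seconds. \code{write_events} /
#' \code{read_events} round-trip a schedule losslessly (scan metadata is
#' restored from the \code{run_kind}, \code{tr_s}, \code{n_volumes}
#' arguments).
#'
#' @param schedule A \code{run_schedule} (or plain trial data frame with
#'   the events columns).
#' @param path File path.
#' @return \code{read_events}: a \code{run_schedule} when scan metadata is
#'   supplied, otherwise a plain data frame. \code{write_events}: the path,
#'   invisibly.
#' @export
write_events <- function(schedule, path) {
  df <- as.data.frame(schedule)[, events_columns]
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = ".",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_events
#' @param run_kind,tr_s,n_volumes Optional scan metadata to restore the
#'   \code{run_schedule} attributes.
#' @export
read_events <- function(path, run_kind = NULL, tr_s = NULL,
                        n_volumes = NULL) {
  df <- utils::read.delim(path, sep = "\t", na.strings = ".",
                          stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(events_columns, names(df))
  if (length(missing))
    stop("missing required column: ", paste(missing, collapse = ", "))
  df <- df[, events_columns]
  for (col in c("onset", "duration")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("malformed value in column '%s' at line %d of %s",
                   col, bad[1L] + 1L, path))
    if (anyNA(v))
      stop(sprintf("missing value in column '%s' at line %d of %s", col,
                   which(is.na(v))[1L] + 1L, path))
    df[[col]] <- v
  }
  for (col in c("direction", "actor_id", "frame_index")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("malformed value in column '%s' at line %d of %s",
                   col, bad[1L] + 1L, path))
    df[[col]] <- v
  }
  if (!is.null(run_kind))
    df <- structure(df, run_kind = run_kind, tr_s = tr_s,
                    n_volumes = n_volumes,
                    class = c("run_schedule", "data.frame"))
  df
}

#' Write / read ROI time-series and motion tables
#'
#' Plain TSV with one row per TR; ROI tables carry one named column per
#' region, motion tables six columns.
#'
#' @param x Data frame (TRs x ROIs, or TRs x 6 motion parameters).
#' @param path File path.
#' @export
write_roi_series <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_roi_series
#' @export
read_roi_series <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Default pipeline configuration
#'
#' All tunables of the synthetic study and its analysis in one nested
#' list: protocol constants (TR 2 s; 280/249 volumes; 2.5\% morph step),
#' study size (17 participants, 3 dynamic + 3 static runs), observer
#' parameters, BOLD noise model, the hysteresis equality tolerance
#' (1.25\%, half a morph step), the hemodynamic delay (6 s), and the
#' master seed.
#'
#' @return Nested list, JSON/YAML-serialisable.
#' @export
default_config <- function() {
  list(
    seed = 20220720L,
    n_participants = 17L,
    n_dynamic_runs = 3L,
    actors = 1:7,
    morph = list(step_pct = 2.5, mid_frame_ms = 113.92,
                 endpoint_frame_ms = 500),
    tr_s = 2,
    volumes = list(dynamic = 280L, static = 249L),
    observer = list(motor_sd = 0.1, miss_prob = 0.05,
                    false_alarm_prob = 0.05, static_slope = 1,
                    static_center_lo = -30, static_center_hi = 30,
                    h_shift = default_h_shift(), h_between_sd = 5),
    bold = list(noise_sd = 1, ar1_rho = 0.3, drift_amp = 1,
                motion_sd = 0.02, baseline = 100),
    tol = 1.25,
    delay_s = 6,
    window_s = 14,
    sliding_window_s = 10,
    alpha = 0.05
  )
}

#' Read / write a pipeline configuration (JSON or YAML by extension)
#'
#' @param path File path ending in \code{.json}, \code{.yaml} or
#'   \code{.yml}.
#' @return The configuration list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else stop("unsupported config format: .", ext)
  hs <- cfg$observer$h_shift
  if (!is.null(hs) && !is.matrix(hs) && is.list(hs)) {
    # stored as one (direction-1, direction-2) pair per emotion pair
    m <- do.call(rbind, hs[emotion_pairs()])
    cfg$observer$h_shift <- h_shift_matrix(m)
  }
  cfg
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  hs <- config$observer$h_shift
  if (is.matrix(hs)) {
    hs <- h_shift_matrix(hs)
    config$observer$h_shift <-
      stats::setNames(lapply(seq_len(nrow(hs)), function(i) unname(hs[i, ])),
                      rownames(hs))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(config, path)
  } else stop("unsupported config format: .", ext)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       matrix = "columnmajor")
  unname(tools::md5sum(tmp))
}

#' Write a JSON sidecar next to an output file
#'
#' Records the configuration hash, the seed and the package version, so
#' every output is traceable to the exact run that produced it. No
#' timestamps are written: outputs of identical runs are byte-identical.
#'
#' @param data_path Path of the data file the sidecar describes.
#' @param config Configuration list.
#' @param seed Master seed of the run.
#' @param extra Optional named list of additional metadata.
#' @export
write_sidecar <- function(data_path, config, seed, extra = NULL) {
  side <- paste0(tools::file_path_sans_ext(data_path), ".json")
  meta <- c(list(config_hash = config_hash(config), seed = seed,
                 package = "emohyst",
                 version = as.character(utils::packageVersion("emohyst"))),
            extra)
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(side)
}
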