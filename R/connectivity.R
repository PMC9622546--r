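# Generalized PPI at ROI level and sliding-window partial Spearman
# correlation dynamics.

#' Z-score a series
#'
#' @param x Numeric series with nonzero variance.
#' @return Series with mean 0 and SD 1.
#' @export
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-score: zero variance")
  (x - mean(x)) / s
}

#' Build a generalized-PPI design
#'
#' Extends a first-level design with the z-scored seed time course (the
#' physiological regressor) and one interaction regressor per condition:
#' the elementwise, TR-by-TR product of the z-scored seed and that
#' condition's HRF-convolved task regressor. The interaction is formed at
#' the hemodynamic level — no deconvolution — which is appropriate for
#' block designs.
#'
#' @param base A \code{design_matrix} from [build_design()] (condition and
#'   nuisance columns, motion confounds included there).
#' @param seed_ts Numeric seed-ROI series, one value per TR.
#' @return A \code{design_matrix} with extra columns \code{seed} and
#'   \code{ppi_<condition>}, and attribute \code{ppi_cols}.
#' @export
build_gppi_design <- function(base, seed_ts) {
  stopifnot(length(seed_ts) == nrow(base))
  cond_cols <- attr(base, "condition_cols")
  if (is.null(cond_cols)) stop("base design carries no condition columns")
  sz <- zscore(seed_ts)
  ppi <- sapply(cond_cols, function(cl) sz * base[, cl])
  colnames(ppi) <- paste0("ppi_", names(cond_cols))
  x <- cbind(unclass(base), seed = sz, ppi)
  qx <- qr(x)
  flagged <- character(0)
  if (qx$rank < ncol(x)) {
    flagged <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    warning("rank-deficient gPPI design; offending columns: ",
            paste(flagged, collapse = ", "))
  }
  structure(x,
            condition_cols = cond_cols,
            ppi_cols = stats::setNames(colnames(ppi), names(cond_cols)),
            tr_s = attr(base, "tr_s"), n_volumes = attr(base, "n_volumes"),
            run_starts = attr(base, "run_starts"),
            flagged_cols = flagged, class = c("design_matrix", "matrix"))
}

#' gPPI contrast between condition sets
#'
#' Fits the target ROI on a gPPI design and contrasts the interaction
#' (coupling) betas of \code{condA} minus \code{condB}, each averaged over
#' its set.
#'
#' @param target_ts Numeric target-ROI series.
#' @param ppi_design Output of [build_gppi_design()].
#' @param condA,condB Character vectors of condition labels.
#' @param prewhiten Correct for AR(1) residual autocorrelation (see
#'   [fit_glm()]); on by default since the contrast's t value is the point
#'   of this analysis.
#' @return List: \code{estimate} (coupling difference), \code{se},
#'   \code{t}, \code{p}, \code{fit} (the full \code{glm_fit}).
#' @export
gppi_contrast <- function(target_ts, ppi_design, condA, condB,
                          prewhiten = TRUE) {
  w <- contrast_weights(ppi_design, condA, condB, prefix = "ppi_")
  fit <- fit_glm(target_ts, ppi_design, contrasts = list(ppi = w),
                 prewhiten = prewhiten)
  ct <- fit$contrasts[1L, ]
  list(estimate = ct$estimate, se = ct$se, t = ct$t, p = ct$p, fit = fit)
}

#' Partial Spearman correlation
#'
#' Rank correlation between \code{x} and \code{y} after removing the
#' rank-linear contribution of a nuisance series: all three series are
#' converted to average ranks and the first-order partial correlation
#' formula is applied, r = (r_xy - r_xz r_yz) / sqrt((1-r_xz^2)(1-r_yz^2)).
#'
#' @param x,y Series of interest.
#' @param z_nuis Nuisance series conditioned on.
#' @return The partial correlation in [-1, 1]; NA when undefined (any
#'   constant series, or |r_xz| or |r_yz| at 1).
#' @export
partial_spearman <- function(x, y, z_nuis) {
  n <- length(x)
  stopifnot(length(y) == n, length(z_nuis) == n)
  if (n < 4L) stop("need at least 4 samples")
  if (anyNA(x) || anyNA(y) || anyNA(z_nuis)) return(NA_real_)
  rx <- rank(x)
  ry <- rank(y)
  rz <- rank(z_nuis)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0 || stats::sd(rz) == 0)
    return(NA_real_)
  rxy <- stats::cor(rx, ry)
  rxz <- stats::cor(rx, rz)
  ryz <- stats::cor(ry, rz)
  den <- (1 - rxz^2) * (1 - ryz^2)
  if (den <= 1e-12) return(NA_real_)
  r <- (rxy - rxz * ryz) / sqrt(den)
  min(1, max(-1, r))
}

#' Sliding-window partial Spearman correlation with Fisher z
#'
#' Computes [partial_spearman()] in a centred sliding window (10 s at TR
#' 2 s = 5 samples; window length is forced odd) and Fisher-transforms the
#' coefficients, z = atanh(r), with |r| clipped at 1 - 1e-7 to avoid
#' infinities. Centers whose window is incomplete, or whose window is
#' degenerate, yield NA rather than failing.
#'
#' @param x,y Series of interest (per TR).
#' @param z_nuis Nuisance series.
#' @param window_len_s Window length in seconds (default 10).
#' @param tr_s Sampling interval in seconds (default 2).
#' @return Data frame with one row per TR: \code{center} (TR index),
#'   \code{time_s}, \code{r}, \code{z}; attributes \code{window_len} (in
#'   samples) and \code{clip}.
#' @export
sliding_partial_correlation <- function(x, y, z_nuis, window_len_s = 10,
                                        tr_s = 2) {
  n <- length(x)
  stopifnot(length(y) == n, length(z_nuis) == n)
  w <- 2L * floor(round(window_len_s / tr_s) / 2) + 1L
  if (w < 3L) stop("window must span at least 3 samples")
  half <- (w - 1L) %/% 2L
  clip <- 1 - 1e-7
  r <- rep(NA_real_, n)
  if (n >= w) {
    for (c0 in (half + 1L):(n - half)) {
      idx <- (c0 - half):(c0 + half)
      r[c0] <- partial_spearman(x[idx], y[idx], z_nuis[idx])
    }
  }
  z <- atanh(pmin(pmax(r, -clip), clip))
  structure(data.frame(center = seq_len(n), time_s = (seq_len(n) - 1L) * tr_s,
                       r = r, z = z),
            window_len = w, clip = clip)
}

#' Compare correlation dynamics between two trial groups
#'
#' Per peristimulus timepoint, a paired two-tailed Wilcoxon signed-rank
#' test across subjects on Fisher-z correlation values, dropping incomplete
#' pairs pairwise.
#'
#' @param group_a,group_b Numeric matrices, subjects x timepoints, rows
#'   paired (e.g. per-subject mean sliding-z epochs for the two groups).
#' @param times_s Optional peristimulus times for the columns.
#' @param alpha Flagging level.
#' @return Data frame per timepoint: \code{time_s}, \code{n},
#'   \code{mean_diff}, \code{z}, \code{p}, \code{flag}.
#' @export
compare_correlation_dynamics <- function(group_a, group_b, times_s = NULL,
                                         alpha = 0.05) {
  stopifnot(all(dim(group_a) == dim(group_b)))
  nt <- ncol(group_a)
  if (is.null(times_s)) times_s <- seq_len(nt)
  out <- lapply(seq_len(nt), function(ti) {
    a <- group_a[, ti]
    b <- group_b[, ti]
    ok <- stats::complete.cases(a, b)
    if (sum(ok) >= 5L) {
      w <- wilcoxon_signed_rank(a[ok], b[ok])
      data.frame(time_s = times_s[ti], n = sum(ok),
                 mean_diff = mean(a[ok] - b[ok]), z = w$z, p = w$p,
                 flag = is.finite(w$p) && w$p < alpha)
    } else {
      data.frame(time_s = times_s[ti], n = sum(ok), mean_diff = NA_real_,
                 z = NA_real_, p = NA_real_, flag = FALSE)
    }
  })
  do.call(rbind, out)
}
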