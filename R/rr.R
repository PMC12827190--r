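# RR-interval series: computation from peak times, statistical outlier
# flagging (mu_RR +/- n*sigma_RR, population moments, evaluated once),
# correction by linear interpolation over the pre-correction cumulative time
# axis, and even resampling of the tachogram for spectral analysis.

rr_series_new <- function(rr, x, outlier_mask, corrected, rr_corrected, stats) {
  structure(list(rr = rr, x = x, outlier_mask = outlier_mask,
                 corrected = corrected, rr_corrected = rr_corrected,
                 stats = stats),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d intervals over %.1f s, %d flagged%s\n",
              length(x$rr), x$x[length(x$x)], sum(x$outlier_mask),
              if (x$corrected) ", corrected" else ""))
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$rr)

# working values: corrected if available
rr_values <- function(series) {
  if (isTRUE(series$corrected)) series$rr_corrected else series$rr
}

#' RR intervals from detected peaks
#'
#' \code{RR_i = t_{i+1} - t_i} with the cumulative time axis
#' \code{x_i = sum(RR_1..RR_i)} measured from the first detected peak.
#'
#' @param peaks a \code{peak_set} (or a numeric vector of peak times in
#'   seconds) with at least 3 peaks.
#' @return An \code{rr_series} (uncorrected, no outliers flagged).
#' @export
compute_rr <- function(peaks) {
  times <- if (inherits(peaks, "peak_set")) peaks$times else as.numeric(peaks)
  if (length(times) < 3L)
    stopf("need at least 3 peaks to form an RR series (got %d)", length(times),
          class = "mecg_insufficient_beats")
  if (any(diff(times) <= 0)) stopf("peak times must be strictly increasing")
  rr <- diff(times)
  rr_series_new(rr, cumsum(rr), rep(FALSE, length(rr)), FALSE, NULL, NULL)
}

#' Flag aberrant RR intervals
#'
#' An interval is an outlier when it falls outside
#' \code{[mu_RR - n*sigma_RR, mu_RR + n*sigma_RR]}, with population mean and
#' SD computed once over all intervals of the original series.
#'
#' @param series an uncorrected \code{rr_series}.
#' @param n threshold multiplier (default 1.5, both sides).
#' @return The series with \code{outlier_mask} populated.
#' @export
flag_rr_outliers <- function(series, n = 1.5) {
  stopifnot(inherits(series, "rr_series"))
  if (isTRUE(series$corrected)) stopf("series already corrected")
  mu <- mean(series$rr)
  sigma <- pop_sd(series$rr)
  series$outlier_mask <- series$rr < mu - n * sigma | series$rr > mu + n * sigma
  series$stats <- list(mu_RR = mu, sigma_RR = sigma, n_multiplier = n)
  series
}

#' Correct flagged RR intervals
#'
#' Flagged intervals are replaced by linear interpolation of RR against the
#' pre-correction cumulative time axis between the nearest unflagged
#' neighbours; runs of consecutive flags are bridged by one linear segment,
#' and a flagged first/last interval takes the nearest valid value (constant
#' extension). The cumulative axis itself is never recomputed, so the
#' physiological timing of the series is preserved and no data points are
#' trimmed.
#'
#' @param series an \code{rr_series} with \code{outlier_mask} populated.
#' @return The corrected series (\code{corrected = TRUE}).
#' @export
correct_rr <- function(series) {
  stopifnot(inherits(series, "rr_series"))
  mask <- series$outlier_mask
  if (all(mask))
    stopf("all %d intervals flagged as outliers; series unusable", length(mask),
          class = "mecg_unusable_series")
  rr_c <- series$rr
  if (any(mask)) {
    valid <- which(!mask)
    if (length(valid) == 1L) {
      rr_c[mask] <- series$rr[valid]
    } else {
      rr_c[mask] <- stats::approx(series$x[valid], series$rr[valid],
                                  xout = series$x[mask], rule = 2)$y
    }
  }
  series$rr_corrected <- rr_c
  series$corrected <- TRUE
  series
}

#' Evenly resampled tachogram
#'
#' Natural cubic spline through \code{(x_i, RR_i)} of the corrected series,
#' evaluated at \code{n_points} evenly spaced abscissae over
#' \code{[x_1, x_last]}. The resulting uniform rate,
#' \code{(n_points - 1) / span}, is reported exactly (about 2.4 Hz for a
#' 6-minute recording at the default 850 points).
#'
#' @param series a corrected \code{rr_series} with at least 4 intervals.
#' @param n_points interpolation length (default 850).
#' @return An object of class \code{tachogram}: \code{values}, \code{rate},
#'   \code{n_points}, \code{span}.
#' @export
resample_tachogram <- function(series, n_points = 850) {
  stopifnot(inherits(series, "rr_series"))
  if (!isTRUE(series$corrected))
    stopf("tachogram requires a corrected series (run flag_rr_outliers + correct_rr)")
  if (length(series$rr) < 4L)
    stopf("need at least 4 intervals for cubic spline interpolation",
          class = "mecg_spline_error")
  span <- c(series$x[1], series$x[length(series$x)])
  xs <- seq(span[1], span[2], length.out = n_points)
  vals <- stats::spline(series$x, series$rr_corrected, xout = xs,
                        method = "natural")$y
  structure(list(values = vals, rate = (n_points - 1) / diff(span),
                 n_points = n_points, span = span, times = xs),
            class = "tachogram")
}

#' @export
print.tachogram <- function(x, ...) {
  cat(sprintf("<tachogram> %d points @ %.4g Hz over [%.2f, %.2f] s\n",
              x$n_points, x$rate, x$span[1], x$span[2]))
  invisible(x)
}

#' Write an RR series as CSV
#'
#' Columns: \code{interval_index}, \code{x_s}, \code{rr_s},
#' \code{outlier_flag}, \code{rr_corrected_s}.
#' @param series an \code{rr_series}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_rr_csv <- function(series, path) {
  utils::write.csv(data.frame(
    interval_index = seq_along(series$rr), x_s = series$x, rr_s = series$rr,
    outlier_flag = series$outlier_mask,
    rr_corrected_s = if (isTRUE(series$corrected)) series$rr_corrected else NA_real_),
    path, row.names = FALSE)
  invisible(path)
}

#' Write a tachogram as CSV
#'
#' Columns: \code{t_s}, \code{rr_s}.
#' @param tach a \code{tachogram}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_tachogram_csv <- function(tach, path) {
  utils::write.csv(data.frame(t_s = tach$times, rr_s = tach$values),
                   path, row.names = FALSE)
  invisible(path)
}
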