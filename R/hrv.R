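# HRV indices: time-domain metrics on the corrected RR series, Welch PSD of
# the evenly resampled tachogram with VLF/LF/HF band powers, a Morlet CWT
# spectrogram for time-frequency inspection, and peak-triggered waveform
# averaging.

HRV_BANDS <- list(VLF = c(0.0033, 0.04), LF = c(0.04, 0.15), HF = c(0.15, 0.4))

#' Time-domain HRV metrics
#'
#' SDNN (population SD of the corrected RR intervals; many HRV tools use the
#' 1/(N-1) form, this package uses 1/N throughout), RMSSD (root mean square
#' of successive differences), mean RR, coefficient of variation, and a 95%
#' interval given by the 2.5th/97.5th percentiles of the RR values. \code{sd}
#' duplicates \code{sdnn} (the two indices coincide on a corrected series)
#' and is reported for completeness.
#'
#' @param series a corrected \code{rr_series} with at least 2 intervals.
#' @return An object of class \code{hrv_time_metrics}.
#' @export
time_domain_metrics <- function(series) {
  stopifnot(inherits(series, "rr_series"))
  rr <- rr_values(series)
  if (length(rr) < 2L)
    stopf("need at least 2 intervals", class = "mecg_insufficient_data")
  m <- mean(rr)
  s <- pop_sd(rr)
  structure(list(
    mean_rr = m, sdnn = s, sd = s,
    rmssd = sqrt(mean(diff(rr)^2)),
    cv = s / m,
    ci95 = unname(stats::quantile(rr, c(0.025, 0.975), type = 7))),
    class = "hrv_time_metrics")
}

#' @export
print.hrv_time_metrics <- function(x, ...) {
  cat(sprintf("mean RR %.3f s | SDNN %.4f s | RMSSD %.4f s | CV %.4f | 95%% [%.3f, %.3f] s\n",
              x$mean_rr, x$sdnn, x$rmssd, x$cv, x$ci95[1], x$ci95[2]))
  invisible(x)
}

trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Welch power spectral density of a tachogram
#'
#' Averaged modified periodograms: Hamming window, segment length 256,
#' per-segment constant detrending, no overlap, one-sided density scaling.
#' Band powers are trapezoid integrals of the PSD over the VLF
#' (0.0033-0.04 Hz), LF (0.04-0.15 Hz) and HF (0.15-0.4 Hz) bands.
#' \code{vlf_interpretable} is \code{FALSE} unless the tachogram spans at
#' least ten cycles of the VLF lower edge (about 50 min), so it is always
#' \code{FALSE} for the 5-6 min recordings this pipeline targets.
#'
#' @param tach a \code{tachogram} (or any list with \code{values},
#'   \code{rate}, optionally \code{span}).
#' @param segment segment length in samples (default 256); shrunk with a
#'   warning when the tachogram is shorter.
#' @return An object of class \code{spectral_result}: \code{freqs},
#'   \code{psd}, \code{band_powers}, \code{vlf_interpretable}.
#' @export
welch_psd <- function(tach, segment = 256) {
  x <- tach$values
  fs <- tach$rate
  n <- length(x)
  if (n == 0L) stopf("empty tachogram", class = "mecg_empty_input")
  if (n < segment) {
    warning(sprintf("tachogram (%d points) shorter than segment (%d); shrinking segment",
                    n, segment))
    segment <- n
  }
  m <- segment
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(m - 1)) / m)  # periodic Hamming
  nseg <- n %/% m
  nfreq <- m %/% 2 + 1
  acc <- numeric(nfreq)
  for (k in seq_len(nseg)) {
    seg <- x[((k - 1) * m + 1):(k * m)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg)[1:nfreq])^2 / (fs * sum(w^2))
    dbl <- 2:(if (m %% 2 == 0) nfreq - 1 else nfreq)
    P[dbl] <- 2 * P[dbl]
    acc <- acc + P
  }
  psd <- acc / nseg
  freqs <- (0:(nfreq - 1)) * fs / m
  band_powers <- vapply(HRV_BANDS, function(b) {
    sel <- freqs >= b[1] & freqs <= b[2]
    trapz(freqs[sel], psd[sel])
  }, numeric(1))
  span_s <- if (!is.null(tach$span)) diff(tach$span) else n / fs
  structure(list(freqs = freqs, psd = psd, band_powers = band_powers,
                 vlf_interpretable = span_s >= 10 / HRV_BANDS$VLF[1],
                 segment = m, n_segments = nseg),
            class = "spectral_result")
}

#' @export
print.spectral_result <- function(x, ...) {
  cat(sprintf("<spectral_result> %d bins to %.3g Hz | VLF %.3g%s | LF %.3g | HF %.3g\n",
              length(x$freqs), max(x$freqs), x$band_powers[["VLF"]],
              if (x$vlf_interpretable) "" else " (not interpretable)",
              x$band_powers[["LF"]], x$band_powers[["HF"]]))
  invisible(x)
}

#' Morlet continuous wavelet spectrogram
#'
#' Magnitude scalogram of the trace using the analytic Morlet wavelet
#' (centre-frequency parameter 6) on a log-spaced frequency grid. QRS
#' complexes appear as recurrent high-power bursts aligned with R-peaks.
#'
#' @param trace a [cardiac_trace()].
#' @param freq_range frequency limits in Hz (default 0.5-45); must lie inside
#'   (0, Nyquist).
#' @param n_scales number of scales (default 64).
#' @return A numeric matrix (scales x time) with attributes \code{freqs}
#'   (Hz, ascending) and \code{times} (s).
#' @export
cwt_spectrogram <- function(trace, freq_range = c(0.5, 45), n_scales = 64) {
  stopifnot(inherits(trace, "cardiac_trace"))
  nyq <- trace$rate / 2
  if (freq_range[1] <= 0 || freq_range[2] >= nyq || freq_range[1] >= freq_range[2])
    stopf("freq_range must lie inside (0, %g Hz)", nyq, class = "mecg_spec_error")
  w0 <- 6
  freqs <- exp(seq(log(freq_range[1]), log(freq_range[2]), length.out = n_scales))
  scales <- w0 / (2 * pi * freqs)  # seconds
  x <- trace$values
  n <- length(x)
  nfft <- stats::nextn(2 * n, 2)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  omega <- 2 * pi * trace$rate * c(0:(nfft / 2), -(nfft / 2 - 1):-1) / nfft
  out <- matrix(0, n_scales, n)
  for (j in seq_len(n_scales)) {
    s <- scales[j]
    psi <- pi^(-0.25) * sqrt(2 * pi * s * trace$rate) *
      exp(-(s * omega - w0)^2 / 2) * (omega > 0)
    out[j, ] <- Mod(stats::fft(X * psi, inverse = TRUE)[1:n]) / nfft
  }
  structure(out, freqs = freqs, times = (seq_len(n) - 1) / trace$rate)
}

#' Peak-triggered average waveform
#'
#' Mean across fixed-length windows centred on each R-peak; peaks whose
#' window would run past either end of the trace are skipped and counted.
#'
#' @param trace a [cardiac_trace()].
#' @param peaks a \code{peak_set} detected on the trace.
#' @param half_window_s half window length in seconds (default 0.4, covering
#'   P-QRS-T at normal rates).
#' @return Numeric vector of length \code{2*round(half_window_s*rate) + 1}
#'   with attributes \code{times} (s, centred on 0), \code{n_used},
#'   \code{n_skipped}.
#' @export
peak_averaged_waveform <- function(trace, peaks, half_window_s = 0.4) {
  stopifnot(inherits(trace, "cardiac_trace"), inherits(peaks, "peak_set"))
  hw <- round(half_window_s * trace$rate)
  n <- length(trace$values)
  ok <- peaks$indices - hw >= 1 & peaks$indices + hw <= n
  if (sum(ok) < 3L)
    stopf("only %d peaks have complete windows; at least 3 required", sum(ok),
          class = "mecg_insufficient_data")
  win <- vapply(peaks$indices[ok],
                function(i) trace$values[(i - hw):(i + hw)], numeric(2 * hw + 1))
  structure(rowMeans(win), times = (-hw:hw) / trace$rate,
            n_used = sum(ok), n_skipped = sum(!ok))
}

#' HRV metrics as JSON
#'
#' Bundles time-domain metrics and band powers into the flat JSON layout
#' \code{{sdnn_s, rmssd_s, sd_s, mean_rr_s, cv, ci95_low_s, ci95_high_s,
#' vlf_power, lf_power, hf_power, vlf_interpretable}}.
#'
#' @param metrics an \code{hrv_time_metrics}.
#' @param spectral optional \code{spectral_result}.
#' @param path optional output file; when NULL the JSON string is returned.
#' @return JSON string (invisibly if written to file).
#' @export
write_metrics_json <- function(metrics, spectral = NULL, path = NULL) {
  out <- list(sdnn_s = metrics$sdnn, rmssd_s = metrics$rmssd, sd_s = metrics$sd,
              mean_rr_s = metrics$mean_rr, cv = metrics$cv,
              ci95_low_s = metrics$ci95[1], ci95_high_s = metrics$ci95[2])
  if (!is.null(spectral)) {
    out$vlf_power <- unname(spectral$band_powers[["VLF"]])
    out$lf_power <- unname(spectral$band_powers[["LF"]])
    out$hf_power <- unname(spectral$band_powers[["HF"]])
    out$vlf_interpretable <- spectral$vlf_interpretable
  }
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
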