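#' Bandpass filter specification
#'
#' Zero-phase FIR bandpass design parameters. The filter is a Hamming-windowed
#' linear-phase FIR whose length follows the standard transition-bandwidth
#' rule: the transition band is \code{min(max(0.25*f, 2 Hz), f)} at the low
#' edge and \code{min(max(0.25*f, 2 Hz), nyquist - f)} at the high edge, and
#' the number of taps is \code{3.3 / (narrowest transition / rate)}, rounded
#' up to odd. The -6 dB points sit half a transition band outside the stated
#' passband edges.
#'
#' @param low_cut lower passband edge in Hz (default 0.5).
#' @param high_cut upper passband edge in Hz (default 45).
#' @return An object of class \code{filter_spec}.
#' @export
filter_spec <- function(low_cut = 0.5, high_cut = 45) {
  if (!is_scalar_num(low_cut) || !is_scalar_num(high_cut) ||
      low_cut <= 0 || high_cut <= low_cut)
    stopf("need 0 < low_cut < high_cut", class = "mecg_spec_error")
  structure(list(low_cut = low_cut, high_cut = high_cut,
                 window = "hamming", phase = "zero_phase", length_rule = "auto"),
            class = "filter_spec")
}

fir_design <- function(spec, rate) {
  nyq <- rate / 2
  if (spec$high_cut >= nyq)
    stopf("high_cut (%g Hz) must be below Nyquist (%g Hz)", spec$high_cut, nyq,
          class = "mecg_spec_error")
  trans_lo <- min(max(0.25 * spec$low_cut, 2), spec$low_cut)
  trans_hi <- min(max(0.25 * spec$high_cut, 2), nyq - spec$high_cut)
  ntaps <- ceiling(3.3 * rate / min(trans_lo, trans_hi))
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  f1 <- max(spec$low_cut - trans_lo / 2, 0)
  f2 <- min(spec$high_cut + trans_hi / 2, nyq * 0.999)
  h <- signal::fir1(ntaps - 1, c(f1, f2) / nyq, type = "pass",
                    window = signal::hamming(ntaps))
  # force exact null at DC (baseline must not leak through)
  h - sum(h) / length(h)
}

# odd (point-symmetric) reflection padding, zero fill past one full reflection
pad_reflect <- function(x, p) {
  n <- length(x)
  k <- min(p, n - 1)
  left <- if (k > 0) 2 * x[1] - x[(k + 1):2] else numeric(0)
  right <- if (k > 0) 2 * x[n] - x[(n - 1):(n - k)] else numeric(0)
  c(rep(0, p - k), left, x, right, rep(0, p - k))
}

# zero-phase application of a symmetric odd-length FIR by FFT convolution
# with group-delay compensation and reflection padding at the edges
apply_fir_zerophase <- function(x, h) {
  L <- length(h)
  half <- (L - 1) / 2
  n <- length(x)
  xp <- pad_reflect(x, half)
  m <- length(xp) + L - 1
  nfft <- stats::nextn(m, 2)
  X <- stats::fft(c(xp, rep(0, nfft - length(xp))))
  H <- stats::fft(c(h, rep(0, nfft - L)))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
  # full conv of padded signal: original sample i sits at offset half (pad)
  # + half (delay) + i
  y[(2 * half + 1):(2 * half + n)]
}

#' Resample a recording or trace to a lower rate
#'
#' Fourier-domain resampling (spectrum truncation), the anti-aliased method
#' used by standard MEG toolchains. Only downsampling (or the identity) is
#' supported; output length is \code{round(n * target / original)}.
#'
#' @param x a [multichannel_recording()] or [cardiac_trace()].
#' @param target_rate target sampling rate in Hz (default 600).
#' @return Object of the same class at \code{target_rate}.
#' @export
resample_signal <- function(x, target_rate = 600) UseMethod("resample_signal")

#' @export
resample_signal.multichannel_recording <- function(x, target_rate = 600) {
  out <- resample_matrix(x$samples, x$rate, target_rate)
  multichannel_recording(out, target_rate, x$channel_names, x$channel_roles)
}

#' @export
resample_signal.cardiac_trace <- function(x, target_rate = 600) {
  out <- resample_matrix(matrix(x$values, nrow = 1), x$rate, target_rate)
  cardiac_trace(drop(out), target_rate, source = x$source)
}

resample_matrix <- function(samples, rate, target_rate) {
  if (!is_scalar_num(target_rate) || target_rate <= 0)
    stopf("target_rate must be positive")
  if (target_rate > rate)
    stopf("upsampling (%g -> %g Hz) not supported", rate, target_rate,
          class = "mecg_unsupported_direction")
  if (target_rate == rate) return(samples)
  n <- ncol(samples)
  r <- target_rate / rate
  # pad by ~1 s of odd reflection to suppress periodic wrap-around; keep the
  # pad a multiple of the rate ratio's denominator so it maps to whole
  # output samples
  p <- round(rate)
  if (abs(rate - round(rate)) < 1e-9 && abs(target_rate - round(target_rate)) < 1e-9) {
    q <- round(rate) / gcd_int(round(rate), round(target_rate))
    p <- as.integer(q * ceiling(p / q))
  }
  out_n <- round(n * r)
  t(apply(samples, 1, function(x) {
    xp <- pad_reflect(x, p)
    y <- fft_resample(xp, round(length(xp) * r))
    y[(round(p * r) + 1):(round(p * r) + out_n)]
  }))
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

# downsample a real vector to length m by truncating its spectrum
fft_resample <- function(x, m) {
  n <- length(x)
  X <- stats::fft(x)
  Y <- complex(length.out = m)
  half <- floor(m / 2)
  Y[1:(half + 1)] <- X[1:(half + 1)]
  if (half > 1) Y[(m - half + 2):m] <- X[(n - half + 2):n]
  if (m %% 2 == 0) Y[half + 1] <- Re(X[half + 1]) # fold Nyquist bin real
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Zero-phase FIR bandpass
#'
#' Applies the Hamming-window FIR described by [filter_spec()] with exact
#' zero phase (single-pass convolution of a linear-phase kernel with the
#' group delay removed). Edges are padded by odd reflection; the first and
#' last half-filter-length samples still carry boundary transients.
#'
#' @param x a [multichannel_recording()] or [cardiac_trace()].
#' @param spec a [filter_spec()]; default 0.5-45 Hz.
#' @return Filtered object of the same class.
#' @export
bandpass <- function(x, spec = filter_spec()) UseMethod("bandpass")

#' @export
bandpass.multichannel_recording <- function(x, spec = filter_spec()) {
  h <- fir_design(spec, x$rate)
  out <- t(apply(x$samples, 1, apply_fir_zerophase, h = h))
  multichannel_recording(out, x$rate, x$channel_names, x$channel_roles)
}

#' @export
bandpass.cardiac_trace <- function(x, spec = filter_spec()) {
  h <- fir_design(spec, x$rate)
  cardiac_trace(apply_fir_zerophase(x$values, h), x$rate, source = x$source)
}

#' Baseline-correct and normalize a cardiac trace
#'
#' Subtracts the mean and divides by the maximum absolute value, so R-peaks
#' sit near +/-1 and downstream amplitude thresholds are scale-free.
#'
#' @param trace a [cardiac_trace()].
#' @return A normalized [cardiac_trace()] (\code{normalized = TRUE}).
#' @export
baseline_normalize <- function(trace) {
  stopifnot(inherits(trace, "cardiac_trace"))
  v <- trace$values - mean(trace$values)
  s <- max(abs(v))
  if (s <= 1e-12 * max(1, abs(mean(trace$values))))
    stopf("constant trace cannot be normalized", class = "mecg_degenerate_signal")
  cardiac_trace(v / s, trace$rate, source = trace$source, normalized = TRUE)
}
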