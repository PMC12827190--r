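# Two-stage threshold R-peak detection: candidate local maxima with a
# minimum inter-peak distance, then an adaptive amplitude gate
# mu_A - n*sigma_A <= A_i <= mu_A + n*sigma_A computed over the candidates
# (population formulas, single pass).

peak_set <- function(indices, times, amplitudes, rate, params, stats) {
  structure(list(indices = indices, times = times, amplitudes = amplitudes,
                 rate = rate, params = params, stats = stats),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks @ %g Hz", length(x$indices), x$rate))
  if (!is.null(x$stats))
    cat(sprintf(" (mu_A=%.4g, sigma_A=%.4g)", x$stats$mu_A, x$stats$sigma_A))
  cat("\n")
  invisible(x)
}

#' @export
length.peak_set <- function(x) length(x$indices)

# strict local maxima with plateau handling: a run of equal values is a peak
# if flanked by strictly lower values on both sides; the first sample of the
# plateau is reported. Endpoints are never peaks.
local_maxima <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  mid <- 2:(k - 1L)
  is_pk <- r$values[mid] > r$values[mid - 1L] & r$values[mid] > r$values[mid + 1L]
  starts[mid][is_pk]
}

#' Candidate R-peak detection
#'
#' Finds local maxima and enforces a minimum inter-peak distance: peaks are
#' visited in order of decreasing amplitude (ties: earlier first) and a
#' candidate is kept only if no already-kept peak lies closer than
#' \code{min_distance_s}. Population mean and SD of the retained candidate
#' amplitudes are recorded for the second-stage gate.
#'
#' @param trace a [cardiac_trace()].
#' @param min_distance_s minimum inter-peak distance in seconds (default 0.5).
#' @return A \code{peak_set}; empty (zero peaks) if the trace has no interior
#'   local maximum.
#' @export
find_candidate_peaks <- function(trace, min_distance_s = 0.5) {
  stopifnot(inherits(trace, "cardiac_trace"))
  if (length(trace$values) < 2L) stopf("trace too short")
  idx <- local_maxima(trace$values)
  params <- list(min_distance_s = min_distance_s, n_amp = NA_real_)
  if (length(idx) == 0L)
    return(peak_set(integer(0), numeric(0), numeric(0), trace$rate, params, NULL))
  amp <- trace$values[idx]
  d_min <- min_distance_s * trace$rate  # in samples
  ord <- order(-amp, idx)
  keep <- logical(length(idx))
  kept_idx <- numeric(0)
  for (j in ord) {
    if (length(kept_idx) == 0L || min(abs(kept_idx - idx[j])) >= d_min) {
      keep[j] <- TRUE
      kept_idx <- c(kept_idx, idx[j])
    }
  }
  idx <- idx[keep]
  amp <- amp[keep]
  stats <- list(mu_A = mean(amp), sigma_A = pop_sd(amp))
  peak_set(idx, (idx - 1) / trace$rate, amp, trace$rate, params, stats)
}

#' Amplitude gating of candidate peaks
#'
#' Retains the candidates whose amplitude lies inside
#' \code{[mu_A - n*sigma_A, mu_A + n*sigma_A]}, with the statistics taken
#' from the candidate set in a single pass (no recomputation after removal).
#'
#' @param peaks a \code{peak_set} from [find_candidate_peaks()].
#' @param n threshold multiplier (default 2, both sides).
#' @return The filtered \code{peak_set}.
#' @export
filter_peaks_by_amplitude <- function(peaks, n = 2) {
  stopifnot(inherits(peaks, "peak_set"))
  if (length(peaks$indices) == 0L)
    stopf("candidate set is empty", class = "mecg_empty_input")
  mu <- peaks$stats$mu_A
  sigma <- peaks$stats$sigma_A
  keep <- peaks$amplitudes >= mu - n * sigma & peaks$amplitudes <= mu + n * sigma
  if (!any(keep))
    stopf("all %d candidate peaks rejected by the amplitude gate; consider a larger n",
          length(peaks$indices), class = "mecg_empty_result")
  out <- peaks
  out$indices <- peaks$indices[keep]
  out$times <- peaks$times[keep]
  out$amplitudes <- peaks$amplitudes[keep]
  out$params$n_amp <- n
  out
}

#' Two-stage R-peak detection
#'
#' Polarity correction (the trace is negated when |min| > |max|, since the
#' sign of an ICA component is arbitrary), candidate maxima with enforced
#' spacing, then the adaptive amplitude gate. At least three retained peaks
#' are required for downstream RR work.
#'
#' @param trace a [cardiac_trace()]; normalization recommended.
#' @param min_distance_s minimum inter-peak distance in seconds.
#' @param n amplitude-gate multiplier.
#' @return A \code{peak_set} with at least three peaks; the applied polarity
#'   is recorded in \code{$params$polarity}.
#' @export
detect_rpeaks <- function(trace, min_distance_s = 0.5, n = 2) {
  stopifnot(inherits(trace, "cardiac_trace"))
  flipped <- abs(min(trace$values)) > abs(max(trace$values))
  if (flipped)
    trace <- cardiac_trace(-trace$values, trace$rate, source = trace$source)
  cand <- find_candidate_peaks(trace, min_distance_s)
  if (length(cand$indices) == 0L)
    stopf("no candidate peaks found", class = "mecg_insufficient_beats")
  pk <- filter_peaks_by_amplitude(cand, n)
  if (length(pk$indices) < 3L)
    stopf("only %d peaks retained; at least 3 required", length(pk$indices),
          class = "mecg_insufficient_beats")
  pk$params$polarity <- if (flipped) "inverted" else "original"
  pk
}

#' Write detected peaks as CSV
#'
#' Columns: \code{index} (1-based sample), \code{time_s}, \code{amplitude}.
#' @param peaks a \code{peak_set}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_peaks_csv <- function(peaks, path) {
  utils::write.csv(data.frame(index = peaks$indices, time_s = peaks$times,
                              amplitude = peaks$amplitudes),
                   path, row.names = FALSE)
  invisible(path)
}
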