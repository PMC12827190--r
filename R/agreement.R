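# M-ECG vs I-ECG agreement machinery: sequential peak pairing with the
# signal-quality gate, detection benchmarking within a tolerance window,
# dynamic time warping of RR series, Lin's concordance, and the statistical
# comparison suite.

#' Sequential peak pairing and signal-quality gate
#'
#' Each M-ECG peak is paired, in order, to its nearest I-ECG peak at or after
#' the previously consumed one (each I-ECG peak used at most once; equidistant
#' ties go to the earlier peak). Pairs with absolute offset above
#' \code{misalign_threshold_s} count as misaligned. Beat count agreement is
#' \code{100 * min(n_m, n_i) / max(n_m, n_i)}. The quality gate passes when
#' fewer than 3\% of pairs are misaligned AND beat count agreement is at
#' least 98\%; recordings failing the gate are considered to have
#' insufficient cardiac signal quality for HRV computation.
#'
#' @param m,i \code{peak_set}s (or numeric vectors of peak times in seconds)
#'   for the M-ECG and I-ECG channels.
#' @param misalign_threshold_s offset above which a pair is misaligned
#'   (default 0.02 s).
#' @param max_misaligned_pct,min_beat_agreement_pct gate thresholds
#'   (defaults 3 and 98).
#' @return An object of class \code{alignment_report}.
#' @export
pair_peaks_sequential <- function(m, i, misalign_threshold_s = 0.02,
                                  max_misaligned_pct = 3,
                                  min_beat_agreement_pct = 98) {
  mt <- if (inherits(m, "peak_set")) m$times else as.numeric(m)
  it <- if (inherits(i, "peak_set")) i$times else as.numeric(i)
  if (length(mt) == 0L || length(it) == 0L)
    stopf("empty peak set", class = "mecg_empty_input")
  pairs_m <- numeric(0); pairs_i <- numeric(0)
  j <- 1L
  for (t in mt) {
    if (j > length(it)) break
    cand <- j:length(it)
    d <- abs(it[cand] - t)
    k <- cand[which.min(d)]  # which.min takes the first (earlier) on ties
    pairs_m <- c(pairs_m, t); pairs_i <- c(pairs_i, it[k])
    j <- k + 1L
  }
  offsets <- abs(pairs_m - pairs_i)
  n_mis <- sum(offsets > misalign_threshold_s)
  pct <- 100 * n_mis / length(offsets)
  agree <- 100 * min(length(mt), length(it)) / max(length(mt), length(it))
  structure(list(
    pairs = data.frame(m_time = pairs_m, i_time = pairs_i, offset_s = offsets),
    n_misaligned = n_mis, pct_misaligned = pct,
    offset_mean = mean(offsets), offset_sd = pop_sd(offsets),
    beat_count_agreement = agree,
    passes_gate = pct < max_misaligned_pct && agree >= min_beat_agreement_pct,
    misalign_threshold_s = misalign_threshold_s),
    class = "alignment_report")
}

#' @export
print.alignment_report <- function(x, ...) {
  cat(sprintf("<alignment_report> %d pairs | %.2f%% misaligned (>%g s) | beat agreement %.2f%% | gate: %s\n",
              nrow(x$pairs), x$pct_misaligned, x$misalign_threshold_s,
              x$beat_count_agreement, if (x$passes_gate) "PASS" else "FAIL"))
  invisible(x)
}

#' Benchmark detected peaks against a reference
#'
#' In-order greedy matching within \code{±tolerance_s}: each detected
#' (M-ECG) peak matches the nearest unused reference peak at or after the
#' previously matched one, provided the offset is within tolerance. Matched
#' peaks are true positives; unmatched detected peaks are false positives;
#' unmatched reference peaks are false negatives.
#'
#' @param m a \code{peak_set} (or times vector) of detected peaks.
#' @param i the reference \code{peak_set} (or times vector); non-empty.
#' @param tolerance_s matching tolerance (default 0.05 s).
#' @return An object of class \code{benchmark_report} with counts
#'   \code{tp, fp, fn} and rates \code{sensitivity, ppv, f1} (0 when
#'   undefined).
#' @export
benchmark_detection <- function(m, i, tolerance_s = 0.05) {
  mt <- if (inherits(m, "peak_set")) m$times else as.numeric(m)
  it <- if (inherits(i, "peak_set")) i$times else as.numeric(i)
  if (length(it) == 0L) stopf("empty reference peak set", class = "mecg_empty_input")
  tp <- 0L; j <- 1L
  for (t in mt) {
    if (j <= length(it)) {
      cand <- j:length(it)
      d <- abs(it[cand] - t)
      k <- cand[which.min(d)]
      if (abs(it[k] - t) <= tolerance_s) {
        tp <- tp + 1L
        j <- k + 1L
      }
    }
  }
  fp <- length(mt) - tp
  fn <- length(it) - tp
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (sens + ppv > 0) 2 * sens * ppv / (sens + ppv) else 0
  structure(list(tp = tp, fp = fp, fn = fn, sensitivity = sens, ppv = ppv,
                 f1 = f1, tolerance_s = tolerance_s),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("<benchmark_report> TP %d FP %d FN %d | sens %.4f | PPV %.4f | F1 %.4f (±%g s)\n",
              x$tp, x$fp, x$fn, x$sensitivity, x$ppv, x$f1, x$tolerance_s))
  invisible(x)
}

#' Dynamic time warping distance between RR series
#'
#' Classic unconstrained DTW with squared-difference local cost; returns the
#' square root of the minimal accumulated cost along the optimal warping
#' path (seconds), the convention of the dtaidistance library. Zero for
#' identical series; tolerant of length differences.
#'
#' @param rr_a,rr_b corrected \code{rr_series} (or numeric vectors),
#'   length >= 2.
#' @return Non-negative distance in seconds.
#' @export
dtw_distance <- function(rr_a, rr_b) {
  a <- if (inherits(rr_a, "rr_series")) rr_values(rr_a) else as.numeric(rr_a)
  b <- if (inherits(rr_b, "rr_series")) rr_values(rr_b) else as.numeric(rr_b)
  n <- length(a); m <- length(b)
  if (n < 1L || m < 1L) stopf("empty series", class = "mecg_empty_input")
  prev <- c(0, rep(Inf, m))
  for (i in seq_len(n)) {
    cur <- rep(Inf, m + 1)
    for (j in seq_len(m)) {
      cur[j + 1] <- (a[i] - b[j])^2 + min(prev[j], prev[j + 1], cur[j])
    }
    prev <- cur
  }
  sqrt(prev[m + 1])
}

#' Lin's concordance correlation coefficient
#'
#' \code{2*s_xy / (s_x^2 + s_y^2 + (mean_x - mean_y)^2)} with population
#' moments; penalizes both imprecision and systematic bias.
#'
#' @param x,y paired numeric vectors.
#' @return CCC in [-1, 1].
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stopf("x and y must be paired vectors of length >= 2")
  mx <- mean(x); my <- mean(y)
  sxy <- mean((x - mx) * (y - my))
  den <- mean((x - mx)^2) + mean((y - my)^2) + (mx - my)^2
  if (den == 0)
    stopf("CCC undefined: both series constant and equal", class = "mecg_undefined_statistic")
  2 * sxy / den
}

#' Statistical comparison of M-ECG and I-ECG RR series
#'
#' Element-wise statistics (Spearman correlation, RMSE, MAE, Bland-Altman
#' mean difference M-I with 1.96-SD limits of agreement, Mann-Whitney U on
#' the RR distributions) are computed after truncating both series to their
#' common length; DTW is the length-tolerant comparison and uses the full
#' series. A second Mann-Whitney U compares the Welch PSD values over the
#' common frequency grid when spectra are supplied. Lin's CCC is computed on
#' per-window mean RR and per-window RMSSD over non-overlapping windows of
#' \code{ccc_window} consecutive intervals (trailing partial window
#' dropped); at least two complete windows are required.
#'
#' @param rr_m,rr_i corrected \code{rr_series} (or numeric vectors).
#' @param psd_m,psd_i optional \code{spectral_result}s.
#' @param ccc_window window length in intervals (default 30).
#' @return An object of class \code{comparison_stats}.
#' @export
comparison_stats <- function(rr_m, rr_i, psd_m = NULL, psd_i = NULL,
                             ccc_window = 30) {
  vm0 <- if (inherits(rr_m, "rr_series")) rr_values(rr_m) else as.numeric(rr_m)
  vi0 <- if (inherits(rr_i, "rr_series")) rr_values(rr_i) else as.numeric(rr_i)
  L <- min(length(vm0), length(vi0))
  if (L < 2L) stopf("need at least 2 paired intervals", class = "mecg_insufficient_data")
  vm <- vm0[1:L]; vi <- vi0[1:L]
  if (pop_sd(vm) == 0 || pop_sd(vi) == 0)
    stopf("Spearman correlation undefined: constant RR series",
          class = "mecg_undefined_statistic")
  rho <- stats::cor(vm, vi, method = "spearman")
  d <- vm - vi
  md <- mean(d); sdd <- pop_sd(d)
  mwu_rr <- suppressWarnings(stats::wilcox.test(vm, vi, exact = FALSE, correct = FALSE))
  mwu_psd <- NULL
  if (!is.null(psd_m) && !is.null(psd_i)) {
    k <- min(length(psd_m$psd), length(psd_i$psd))
    mwu_psd <- suppressWarnings(
      stats::wilcox.test(psd_m$psd[1:k], psd_i$psd[1:k], exact = FALSE, correct = FALSE))
  }
  nw <- L %/% ccc_window
  ccc_mean <- ccc_rmssd <- NA_real_
  if (nw >= 2L) {
    wstat <- function(v, f) vapply(seq_len(nw), function(k) {
      f(v[((k - 1) * ccc_window + 1):(k * ccc_window)])
    }, numeric(1))
    rmssd1 <- function(v) sqrt(mean(diff(v)^2))
    ccc_mean <- lin_ccc(wstat(vm, mean), wstat(vi, mean))
    ccc_rmssd <- lin_ccc(wstat(vm, rmssd1), wstat(vi, rmssd1))
  }
  structure(list(
    n_paired = L,
    spearman_rho = rho,
    rmse_s = sqrt(mean(d^2)), mae_s = mean(abs(d)),
    bland_altman = list(mean_diff_s = md,
                        loa_upper_s = md + 1.96 * sdd,
                        loa_lower_s = md - 1.96 * sdd),
    mwu_rr = list(statistic = unname(mwu_rr$statistic), p = mwu_rr$p.value),
    mwu_psd = if (is.null(mwu_psd)) NULL else
      list(statistic = unname(mwu_psd$statistic), p = mwu_psd$p.value),
    ccc_mean_rr = ccc_mean, ccc_rmssd = ccc_rmssd, n_windows = nw,
    dtw_distance_s = dtw_distance(vm0, vi0)),
    class = "comparison_stats")
}

#' @export
print.comparison_stats <- function(x, ...) {
  cat(sprintf("<comparison_stats> n=%d | rho %.3f | RMSE %.4g s | MAE %.4g s | DTW %.4g s\n",
              x$n_paired, x$spearman_rho, x$rmse_s, x$mae_s, x$dtw_distance_s))
  cat(sprintf("  Bland-Altman %.4g s [%.4g, %.4g] | MWU(RR) U=%.1f p=%.3f | CCC meanRR %.3f, RMSSD %.3f (%d windows)\n",
              x$bland_altman$mean_diff_s, x$bland_altman$loa_lower_s,
              x$bland_altman$loa_upper_s, x$mwu_rr$statistic, x$mwu_rr$p,
              x$ccc_mean_rr, x$ccc_rmssd, x$n_windows))
  invisible(x)
}

#' Write a bundled agreement report as JSON
#'
#' @param alignment an \code{alignment_report}.
#' @param benchmark a \code{benchmark_report}.
#' @param stats a \code{comparison_stats}.
#' @param path optional output file.
#' @return JSON string (invisibly if written).
#' @export
write_agreement_json <- function(alignment = NULL, benchmark = NULL,
                                 stats = NULL, path = NULL) {
  strip <- function(x) if (is.null(x)) NULL else unclass(x)
  al <- strip(alignment)
  if (!is.null(al)) al$pairs <- NULL
  out <- list(alignment = al, benchmark = strip(benchmark),
              comparison = strip(stats))
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
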