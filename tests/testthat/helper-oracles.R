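# Independent brute-force oracles. These deliberately re-derive every
# quantity from its definition with naive loops, sharing no code with the
# package implementation.

# literal two-stage detector: scan for local maxima (plateau -> first
# sample), repeatedly drop the smaller of any pair closer than min_dist
# (ties: keep the earlier), then apply the mu +/- n*sigma amplitude band
# with population statistics computed on the spacing-enforced candidates.
oracle_detect <- function(v, rate, min_distance_s = 0.5, n = 2) {
  if (abs(min(v)) > abs(max(v))) v <- -v
  cand <- integer(0)
  i <- 2L
  while (i <= length(v) - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < length(v) && v[j + 1L] == v[i]) j <- j + 1L
      if (j < length(v) && v[j + 1L] < v[i]) cand <- c(cand, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(cand) == 0L) return(integer(0))
  d_min <- min_distance_s * rate
  # visit candidates in order of decreasing amplitude (ties: earlier first),
  # keeping each one only if every already-kept peak is at least d_min away
  remaining <- cand
  kept <- integer(0)
  while (length(remaining) > 0L) {
    top <- 1L
    for (k in seq_along(remaining)) {
      if (v[remaining[k]] > v[remaining[top]]) top <- k
    }
    p <- remaining[top]
    remaining <- remaining[-top]
    ok <- TRUE
    for (q in kept) if (abs(q - p) < d_min) ok <- FALSE
    if (ok) kept <- c(kept, p)
  }
  kept <- sort(kept)
  amps <- v[kept]
  mu <- sum(amps) / length(amps)
  sigma <- sqrt(sum((amps - mu)^2) / length(amps))
  kept[amps >= mu - n * sigma & amps <= mu + n * sigma]
}

# exhaustive DTW: enumerate every monotone warping path recursively,
# minimal accumulated squared difference, sqrt at the end
oracle_dtw <- function(a, b) {
  n <- length(a); m <- length(b)
  best <- Inf
  recur <- function(i, j, acc) {
    acc <- acc + (a[i] - b[j])^2
    if (acc >= best) return(invisible())
    if (i == n && j == m) { best <<- acc; return(invisible()) }
    if (i < n) recur(i + 1L, j, acc)
    if (j < m) recur(i, j + 1L, acc)
    if (i < n && j < m) recur(i + 1L, j + 1L, acc)
    invisible()
  }
  recur(1L, 1L, 0)
  sqrt(best)
}

# definitional time-domain / agreement statistics via explicit loops
oracle_stats <- function(x, y) {
  N <- length(x)
  mx <- 0; for (v in x) mx <- mx + v; mx <- mx / N
  sdnn <- 0; for (v in x) sdnn <- sdnn + (v - mx)^2; sdnn <- sqrt(sdnn / N)
  rmssd <- 0
  for (i in 1:(N - 1)) rmssd <- rmssd + (x[i + 1] - x[i])^2
  rmssd <- sqrt(rmssd / (N - 1))
  rmse <- 0; mae <- 0; md <- 0
  for (i in 1:N) {
    d <- x[i] - y[i]
    rmse <- rmse + d^2; mae <- mae + abs(d); md <- md + d
  }
  rmse <- sqrt(rmse / N); mae <- mae / N; md <- md / N
  sdd <- 0
  for (i in 1:N) sdd <- sdd + (x[i] - y[i] - md)^2
  sdd <- sqrt(sdd / N)
  list(mean = mx, sdnn = sdnn, rmssd = rmssd, cv = sdnn / mx,
       ci95 = unname(stats::quantile(x, c(0.025, 0.975), type = 7)),
       rmse = rmse, mae = mae,
       ba = c(md, md + 1.96 * sdd, md - 1.96 * sdd))
}

expect_rel_equal <- function(got, want, tol = 1e-12) {
  scale <- max(abs(want), 1e-300)
  expect_lt(max(abs(got - want)) / scale, tol)
}
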