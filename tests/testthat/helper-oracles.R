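# Independent brute-force oracles and shared fixtures. Oracles are written
# as plain loops over definitions, deliberately independent of the package's
# vectorized implementations.

brute_median_nn <- function(nn) {
  s <- sort(nn)
  n <- length(s)
  if (n == 0L) return(NA_real_)
  if (n %% 2L == 1L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
}

brute_rmssd <- function(nn) {
  if (length(nn) < 2L) return(NA_real_)
  acc <- 0
  for (i in 2:length(nn)) acc <- acc + (nn[i] - nn[i - 1L])^2
  sqrt(acc / (length(nn) - 1L))
}

brute_pnn5 <- function(nn, thr = 5) {
  if (length(nn) < 2L) return(NA_real_)
  hits <- 0
  for (i in 2:length(nn)) if (abs(nn[i] - nn[i - 1L]) > thr) hits <- hits + 1
  100 * hits / (length(nn) - 1L)
}

brute_auc <- function(scores, is_pos) {
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  acc <- 0
  for (p in pos) for (q in neg) acc <- acc + (p > q) + 0.5 * (p == q)
  acc / (length(pos) * length(neg))
}

brute_chisq <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  acc <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / n
    if (e > 0) acc <- acc + (tab[i, j] - e)^2 / e
  }
  acc
}

# beat_series / skna_derived built directly from NN values, for feature tests
beats_from_nn <- function(nn_ms, t0 = 0) {
  times <- t0 + cumsum(c(100, nn_ms)) / 1000
  b <- adreflex:::new_beat_series(times)
  clean_nn(b, tol = 10)  # effectively no rejection
}

flat_skna <- function(duration_s, rate = 20, level = 0.25) {
  adreflex:::new_skna_derived(
    filtered = NULL, rectified = NULL,
    iskna = rep(level, duration_s * rate), rate = rate,
    baseline_mu = level, baseline_sigma = level / 10,
    bursts = data.frame(start_s = numeric(0), end_s = numeric(0),
                        peak_uv = numeric(0)))
}

# toy tail-cuff BP recording: constant baseline, one triangular excursion
# peaking (exactly delta above baseline) at the end of the stimulus minute
toy_bp_recording <- function(sbp0 = 120, map0 = 100, delta_sbp = 0,
                             delta_map = 0, onset = 120, duration = 60,
                             total = 600) {
  times <- seq(0, total, by = 30)
  shape <- numeric(length(times))
  ramp <- times >= onset & times <= onset + duration
  shape[ramp] <- (times[ramp] - onset) / duration
  post <- times > onset + duration
  shape[post] <- pmax(0, 1 - (times[post] - onset - duration) / 120)
  structure(list(
    animal_id = "toy", trial_day = 1L, duration_s = total,
    channels = list(
      bp = data.frame(time_s = times, sbp = sbp0 + delta_sbp * shape,
                      dbp = NA_real_, map = map0 + delta_map * shape),
      temperature = NULL, ecg = NULL, skna = NULL),
    annotations = list(), truth = list()), class = "ad_recording")
}

# toy beat series with bradycardia from `onset + duration/2` onwards
toy_brady_beats <- function(onset = 120, duration = 60, total = 600,
                            nn_base = 150, slow_frac = 0.15) {
  t <- 0; times <- c()
  while (t < total) {
    nn <- if (t >= onset + duration / 2 && t < onset + duration + 120)
      nn_base * (1 + slow_frac) else nn_base
    t <- t + nn / 1000
    times <- c(times, t)
  }
  clean_nn(adreflex:::new_beat_series(times))
}

toy_bursts_skna <- function(times) {
  adreflex:::new_skna_derived(
    filtered = NULL, rectified = NULL, iskna = NULL, rate = 20,
    baseline_mu = 0.25, baseline_sigma = 0.02,
    bursts = data.frame(start_s = times, end_s = times + 0.3,
                        peak_uv = rep(3, length(times))))
}

# memoized fixtures (built once per test run)
.fixtures <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- sim_config(seed = 3, n_animals = 6, trial_days = c(7L, 9L))
    recs <- simulate_cohort(cfg)
    .fixtures$small <- list(cfg = cfg, recs = recs,
                            windows = cohort_windows(recs, cfg))
  }
  .fixtures$small
}

full_cohort <- function() {
  if (is.null(.fixtures$full)) {
    cfg <- sim_config(seed = 1)
    recs <- simulate_cohort(cfg)
    w <- sample_windows(suppressWarnings(cohort_windows(recs, cfg)),
                        2200, seed = 1)
    .fixtures$full <- list(cfg = cfg, recs = recs, windows = w)
  }
  .fixtures$full
}
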