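fs <- 10000

test_that("skNA band-pass rejects out-of-band tones and passes in-band tones", {
  t <- (0:(6 * fs - 1)) / fs
  tone50 <- sin(2 * pi * 50 * t)
  tone700 <- sin(2 * pi * 700 * t)
  r50 <- sqrt(mean(bandpass_zero_phase(tone50, fs, 500, 1000, 4)^2)) /
    sqrt(mean(tone50^2))
  r700 <- sqrt(mean(bandpass_zero_phase(tone700, fs, 500, 1000, 4)^2)) /
    sqrt(mean(tone700^2))
  expect_lt(r50, 0.01)
  expect_gte(r700, 0.90)
  expect_equal(bandpass_zero_phase(numeric(2 * fs), fs, 500, 1000, 4),
               numeric(2 * fs))
})

test_that("filtering commutes with time reversal (zero phase)", {
  set.seed(5)
  x <- rnorm(30000)
  for (band in list(c(0.5, 100), c(500, 1000))) {
    a <- bandpass_zero_phase(x, fs, band[1], band[2])
    b <- rev(bandpass_zero_phase(rev(x), fs, band[1], band[2]))
    expect_lt(max(abs(a - b)) / max(abs(a)), 1e-6)
  }
})

test_that("filter_signals validates channels and sampling limits", {
  cfg <- sim_config(seed = 2)
  rec <- simulate_recording(cfg, "rat01", 7, list(), duration_s = 10,
                            render = FALSE)
  expect_error(filter_signals(rec), "ecg")
  expect_error(bandpass_zero_phase(rnorm(1000), fs = 1000, low = 500,
                                   high = 900), "band edge")
})

test_that("R peaks are recovered from synthetic ECG and refine to truth", {
  cfg <- sim_config(seed = 6, baseline_hr_sd = 0)
  rec <- simulate_recording(cfg, "rat01", 7, list(), duration_s = 30)
  flt <- filter_signals(rec)
  bs <- detect_r_peaks(flt$ecg, fs)
  truth <- rec$truth$beats
  hits <- vapply(truth, function(b)
    any(abs(bs$r_peak_times - b) <= 0.005), logical(1))
  expect_gte(mean(hits), 0.99)
  expect_lte(length(bs$r_peak_times) - sum(hits), 1)
})

test_that("constant signals yield no peaks, exact spacing yields exact RR", {
  expect_warning(bs0 <- detect_r_peaks(numeric(3 * fs), fs), "no R peaks")
  expect_length(bs0$r_peak_times, 0)
  expect_true(bs0$no_peaks)

  beats <- seq(0.2, 29.75, by = 0.150)
  ecg <- render_ecg(beats, 30, fs, noise_sd = 0.02, seed = 8)
  ecgf <- bandpass_zero_phase(ecg, fs, 0.5, 100, 2)
  bs <- detect_r_peaks(ecgf, fs)
  expect_equal(length(bs$r_peak_times), length(beats))
  expect_true(all(abs(bs$rr_ms - 150) <= 0.2))
})

test_that("R-peak sensitivity does not increase with ECG noise", {
  beats <- NULL
  sens <- vapply(c(0.05, 0.35, 0.7), function(ns) {
    cfg <- sim_config(seed = 13, noise_sd_ecg = ns, baseline_hr_sd = 0)
    rec <- simulate_recording(cfg, "rat01", 7, list(), duration_s = 20)
    bs <- detect_r_peaks(bandpass_zero_phase(rec$channels$ecg, fs, 0.5, 100),
                         fs)
    truth <- rec$truth$beats
    mean(vapply(truth, function(b)
      any(abs(bs$r_peak_times - b) <= 0.005), logical(1)))
  }, numeric(1))
  expect_true(all(diff(sens) <= 0.005))
})

test_that("NN cleaning rejects intervals far from the running median", {
  b <- adreflex:::new_beat_series(cumsum(c(1, rep(0.15, 5))))
  b <- clean_nn(b)
  expect_equal(b$nn_ms, rep(150, 5))
  expect_length(b$rejected_idx, 0)

  rr <- c(150, 150, 300, 150, 150)
  b2 <- adreflex:::new_beat_series(cumsum(c(1, rr / 1000)))
  b2 <- clean_nn(b2)
  expect_equal(b2$rejected_idx, 3L)
  expect_equal(b2$nn_ms, rep(150, 4))

  # both intervals deviate > 20% from their common median: nothing survives
  b3 <- adreflex:::new_beat_series(cumsum(c(1, 0.1, 0.2)))
  expect_error(clean_nn(b3), "signal quality")
})

test_that("clean simulated beats are almost never rejected and match truth NN", {
  cfg <- sim_config(seed = 17, noise_sd_ecg = 0.005)
  rec <- simulate_recording(cfg, "rat01", 7, list(), duration_s = 160)
  bs <- detect_r_peaks(bandpass_zero_phase(rec$channels$ecg, fs, 0.5, 100),
                       fs)
  bs <- clean_nn(bs)
  expect_gt(length(bs$rr_ms), 900)
  expect_lte(length(bs$rejected_idx) / length(bs$rr_ms), 0.01)
  truth_nn <- diff(rec$truth$beats) * 1000
  n <- min(length(bs$nn_ms), length(truth_nn))
  expect_lt(max(abs(bs$nn_ms[seq_len(n)] - truth_nn[seq_len(n)])), 1)
})

test_that("iskNA is a moving average with folded-normal baseline", {
  const <- integrate_skna(rep(3, 2 * fs), fs)
  expect_true(all(abs(const$iskna - 3) < 1e-12))

  set.seed(31)
  sigma <- 2
  noise <- rnorm(20 * fs, 0, sigma)
  skd <- integrate_skna(noise, fs)
  expect_lt(abs(mean(skd$iskna) - sigma * sqrt(2 / pi)) /
              (sigma * sqrt(2 / pi)), 0.05)

  expect_error(integrate_skna(rnorm(100), fs), "integration window")

  bursts <- data.frame(start = 5, end = 5.2, amp = 8)
  x <- render_skna(bursts, 10, fs, noise_sd = 1, seed = 2)
  skd2 <- integrate_skna(bandpass_zero_phase(x, fs, 500, 1000, 4), fs)
  ipk <- which.max(skd2$iskna)
  expect_gte((ipk - 1) / fs, 4.9)
  expect_lte((ipk - 1) / fs, 5.3)
})

test_that("burst detection thresholds, merges and degrades gracefully", {
  level <- 0.25
  skd <- adreflex:::new_skna_derived(NULL, NULL,
                                     iskna = rep(level, 10 * fs), rate = fs,
                                     baseline_mu = level,
                                     baseline_sigma = 0.02)
  expect_equal(nrow(detect_bursts(skd)$bursts), 0)

  # two supra-threshold intervals separated by 50 ms merge into one burst
  isk <- rep(level, 2 * fs)
  isk[(0.5 * fs):(0.58 * fs)] <- 1
  isk[(0.63 * fs):(0.71 * fs)] <- 1
  skd2 <- adreflex:::new_skna_derived(NULL, NULL, iskna = isk, rate = fs,
                                      baseline_mu = level,
                                      baseline_sigma = 0.02)
  expect_equal(nrow(detect_bursts(skd2)$bursts), 1)

  skd3 <- adreflex:::new_skna_derived(NULL, NULL, iskna = isk, rate = fs,
                                      baseline_mu = level,
                                      baseline_sigma = 0)
  expect_warning(db3 <- detect_bursts(skd3), "degenerate")
  expect_equal(nrow(db3$bursts), 1)
})

test_that("raising the burst threshold never increases the burst count", {
  set.seed(12)
  starts <- cumsum(runif(15, 2, 5))
  bursts <- data.frame(start = starts, end = starts + runif(15, 0.1, 0.6),
                       amp = 5 * exp(rnorm(15, 0, 0.25)))
  x <- render_skna(bursts, max(bursts$end) + 3, fs, noise_sd = 1, seed = 14)
  skd <- integrate_skna(bandpass_zero_phase(x, fs, 500, 1000, 4), fs)
  counts <- vapply(c(2, 3, 4, 6, 10),
                   function(k) nrow(detect_bursts(skd, k = k)$bursts),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})
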