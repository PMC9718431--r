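test_that("hand-computed HRV values on tiny NN sequences", {
  sk <- flat_skna(15)
  w1 <- window_features(beats_from_nn(c(150, 150, 150)), sk)
  expect_equal(w1$rmssd[1], 0)
  expect_equal(w1$pnn5[1], 0)
  expect_equal(w1$median_nn[1], 150)

  w2 <- window_features(beats_from_nn(c(150, 160, 150)), sk)
  expect_equal(w2$rmssd[1], 10)   # diffs (10, -10): RMS = 10
  expect_equal(w2$pnn5[1], 100)
  expect_equal(w2$median_nn[1], 150)

  w3 <- window_features(beats_from_nn(c(150, 154, 150)), sk)
  expect_equal(w3$pnn5[1], 0)     # |diffs| = 4 ms, not > 5
})

test_that("window HRV features match brute-force formulas on random series", {
  set.seed(77)
  for (rep in 1:100) {
    nn <- runif(sample(3:40, 1), 80, 300)
    w <- window_features(beats_from_nn(nn), flat_skna(15),
                         duration_s = 15)
    expect_equal(w$median_nn[1], brute_median_nn(nn), tolerance = 1e-12)
    expect_equal(w$rmssd[1], brute_rmssd(nn), tolerance = 1e-12)
    expect_equal(w$pnn5[1], brute_pnn5(nn), tolerance = 1e-12)
  }
})

test_that("HRV invariances: shift, bounds, equivariance", {
  set.seed(42)
  for (rep in 1:25) {
    nn <- runif(20, 100, 250)
    w <- window_features(beats_from_nn(nn), flat_skna(15), duration_s = 15)
    w_shift <- window_features(beats_from_nn(nn + 40), flat_skna(15),
                               duration_s = 15)
    expect_equal(w_shift$rmssd[1], w$rmssd[1], tolerance = 1e-9)
    expect_equal(w_shift$median_nn[1], w$median_nn[1] + 40,
                 tolerance = 1e-9)
    expect_gte(w$pnn5[1], 0); expect_lte(w$pnn5[1], 100)
    expect_gte(w$rmssd[1], 0)
  }
})

test_that("successive differences never span a rejected interval", {
  # RR 150,150,450,150,150,160: the 450 is rejected; the 150->150 pair around
  # it must not contribute a (150-450) difference
  rr <- c(150, 150, 450, 150, 150, 160)
  b <- clean_nn(adreflex:::new_beat_series(cumsum(c(0.5, rr / 1000))))
  expect_equal(b$rejected_idx, 3L)
  w <- window_features(b, flat_skna(15), duration_s = 15)
  # surviving adjacent pairs: (150,150), (150,150), (150,160)
  expect_equal(w$rmssd[1], sqrt(mean(c(0, 0, 10)^2)))
  expect_equal(w$pnn5[1], 100 * 1 / 3)
})

test_that("per-window burst counts partition the detected bursts", {
  sc <- small_cohort()
  rec <- sc$recs[[1]]
  beats <- truth_beat_series(rec)
  skd <- truth_skna_series(rec, sc$cfg)
  skd$bursts <- data.frame(start_s = rec$truth$bursts$start,
                           end_s = rec$truth$bursts$end,
                           peak_uv = rec$truth$bursts$amp)
  w <- window_features(beats, skd, 15, duration_s = rec$duration_s)
  covered <- sum(skd$bursts$start_s < max(w$end_s))
  expect_equal(sum(w$n_bursts), covered)
})

test_that("min-max scaling: midpoint, degenerate group, exact range, inverse", {
  w <- data.frame(animal_id = "a", trial_day = 1L,
                  n_bursts = c(2, 4, 6), iskna_avg = c(3, 3, 3),
                  median_nn = c(150, 160, 170), rmssd = c(1, 2, 4),
                  pnn5 = c(0, 50, 100))
  expect_warning(st <- fit_scaling(w), "constant")
  sw <- apply_scaling(w, st)
  expect_equal(sw$n_bursts_norm, c(0, 0.5, 1))
  expect_equal(sw$iskna_avg_norm, c(0, 0, 0))
  expect_equal(min(sw$median_nn_norm), 0)
  expect_equal(max(sw$median_nn_norm), 1)
  inv <- invert_scaling(sw, st, features = c("n_bursts", "median_nn",
                                             "rmssd", "pnn5"))
  expect_equal(inv$rmssd, w$rmssd, tolerance = 1e-9)
  expect_equal(inv$median_nn, w$median_nn, tolerance = 1e-9)

  w2 <- w; w2$animal_id <- "b"
  expect_error(apply_scaling(w2, st), "no scaling state")
})

test_that("train-only scaling leakage is quantified by the audit", {
  sc <- small_cohort()
  w <- sc$windows
  set.seed(1)
  tr <- sample(nrow(w), floor(0.7 * nrow(w)))
  st <- fit_scaling(w[tr, ])
  aud <- audit_scaling(w[-tr, ], st)
  expect_true(all(aud$frac_outside >= 0))
  expect_gt(sum(aud$n_below + aud$n_above), 0)  # leakage-free scaling overflows
  # same-day scaling never leaves [0,1]
  st_all <- fit_scaling(w)
  aud_all <- audit_scaling(w, st_all)
  expect_equal(sum(aud_all$frac_outside), 0)
})

test_that("chi-squared ranking: zero for uninformative, n for perfect split", {
  set.seed(9)
  n <- 40
  w <- data.frame(
    label = rep(c("a", "b"), each = n / 2),
    perfect = c(runif(n / 2, 0, 1), runif(n / 2, 10, 11)),
    constant = rep(5, n),
    noise = rnorm(n)
  )
  r <- select_features(w, features = c("perfect", "constant", "noise"),
                       labels = w$label, k = 2)
  expect_equal(r$feature[1], "perfect")
  expect_equal(r$statistic[r$feature == "constant"], 0)
  expect_equal(r$statistic[1], n, tolerance = 1e-9)
  # cross-check against a brute-force contingency computation
  bins <- cut(w$perfect, quantile(w$perfect, seq(0, 1, 0.25)),
              include.lowest = TRUE)
  expect_equal(r$statistic[1], brute_chisq(table(bins, w$label)),
               tolerance = 1e-9)
  expect_warning(select_features(w, features = c("perfect", "noise"),
                                 labels = w$label, k = 5), "returning all")
})

test_that("the five signature features outrank a constant decoy on the cohort", {
  sc <- small_cohort()
  w <- sc$windows
  w$decoy <- 1.0
  r <- select_features(w, features = c(adreflex:::FEATURE_NAMES, "decoy"),
                       labels = w$label, k = 5)
  expect_false("decoy" %in% attr(r, "selected"))
  expect_true(all(r$statistic[r$feature != "decoy"] >
                    r$statistic[r$feature == "decoy"]))
})

test_that("extended feature bank is finite where windows are unflagged", {
  sc <- small_cohort()
  rec <- sc$recs[[1]]
  beats <- truth_beat_series(rec)
  skd <- truth_skna_series(rec, sc$cfg)
  skd$bursts <- data.frame(start_s = rec$truth$bursts$start,
                           end_s = rec$truth$bursts$end,
                           peak_uv = rec$truth$bursts$amp)
  ef <- extended_features(beats, skd, duration_s = rec$duration_s)
  ok <- !ef$flagged
  expect_gt(sum(ok), 10)
  num <- ef[ok, c("mean_nn", "sdnn", "pnn10", "iskna_max", "burst_total_s")]
  expect_true(all(is.finite(as.matrix(num))))
})
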