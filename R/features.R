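# Windowed sympathovagal features: burst count and average iskNA (sympathetic),
# medianNN, RMSSD and pnn5 (vagal), on 15-s windows with per-trial-day
# min-max scaling.

FEATURE_NAMES <- c("n_bursts", "iskna_avg", "median_nn", "rmssd", "pnn5")

hrv_from_nn <- function(nn, idx = seq_along(nn)) {
  # idx carries original adjacency: differences never span a rejected interval
  if (length(nn) == 0L)
    return(c(median_nn = NA_real_, rmssd = NA_real_, pnn5 = NA_real_))
  d <- diff(nn)[diff(idx) == 1L]
  c(median_nn = median(nn),
    rmssd = if (length(d)) sqrt(mean(d^2)) else NA_real_,
    pnn5 = if (length(d)) 100 * mean(abs(d) > 5) else NA_real_)
}

#' Extract per-window raw features
#'
#' Partitions time into non-overlapping half-open windows `[t, t+window_s)`
#' from t = 0 and computes, per window: the number of detected bursts whose
#' start lies in the window, the mean iskNA, and medianNN / RMSSD / pnn5 from
#' the NN intervals whose terminating beat lies in the window. Windows with
#' fewer than 3 NN intervals are flagged (`flagged = TRUE`) for downstream
#' exclusion.
#'
#' @param beats a cleaned `beat_series` (see [clean_nn()]).
#' @param skd a `skna_derived` with bursts detected.
#' @param window_s window length, seconds (default 15).
#' @param duration_s total covered time; defaults to the extent of the iskNA
#'   trace.
#' @return data.frame, one row per window: `window_index`, `start_s`,
#'   `end_s`, the five features, `n_nn`, `flagged`.
#' @export
window_features <- function(beats, skd, window_s = 15, duration_s = NULL) {
  stopifnot(inherits(beats, "beat_series"), inherits(skd, "skna_derived"))
  if (is.null(beats$nn_ms)) stop("beats must be cleaned with clean_nn() first",
                                 call. = FALSE)
  if (window_s <= 0) stop("window_s must be > 0", call. = FALSE)
  duration_s <- duration_s %||% (length(skd$iskna) / skd$rate)
  n_win <- floor(duration_s / window_s)
  if (n_win < 1L) stop("recording shorter than one window", call. = FALSE)
  bursts <- skd$bursts %||% data.frame(start_s = numeric(0))
  burst_win <- floor(bursts$start_s / window_s) + 1L
  nn_win <- floor(beats$nn_end_s / window_s) + 1L
  iw <- floor((seq_along(skd$iskna) - 1) / skd$rate / window_s) + 1L

  out <- lapply(seq_len(n_win), function(w) {
    sel <- which(nn_win == w)
    hv <- hrv_from_nn(beats$nn_ms[sel], beats$nn_idx[sel])
    data.frame(
      window_index = w,
      start_s = (w - 1) * window_s,
      end_s = w * window_s,
      n_bursts = sum(burst_win == w),
      iskna_avg = mean(skd$iskna[iw == w]),
      median_nn = hv[["median_nn"]],
      rmssd = hv[["rmssd"]],
      pnn5 = hv[["pnn5"]],
      n_nn = length(sel),
      flagged = length(sel) < 3L
    )
  })
  do.call(rbind, out)
}

#' Fit per-trial-day min-max scaling
#'
#' Observes the min and max of each feature within each (animal, trial day)
#' group — normalization "from the same trial day", so a wearable-scale
#' deployment would not need cross-day calibration. A group-constant feature
#' (max = min) maps to 0 with a warning.
#'
#' @param windows data.frame of feature windows with `animal_id`,
#'   `trial_day` and the feature columns.
#' @param features feature column names.
#' @return data.frame of class `scaling_state`: one row per
#'   (animal_id, trial_day, feature) with `min` and `max`.
#' @export
fit_scaling <- function(windows, features = FEATURE_NAMES) {
  stopifnot(all(c("animal_id", "trial_day", features) %in% names(windows)))
  groups <- unique(windows[, c("animal_id", "trial_day")])
  if (any(table(windows$animal_id, windows$trial_day) == 1L))
    stop("need >= 2 windows per (animal, trial day) group", call. = FALSE)
  out <- list()
  for (g in seq_len(nrow(groups))) {
    sel <- windows$animal_id == groups$animal_id[g] &
      windows$trial_day == groups$trial_day[g]
    for (f in features) {
      v <- windows[[f]][sel]
      v <- v[is.finite(v)]
      mn <- min(v); mx <- max(v)
      if (mx == mn)
        warning(sprintf("feature '%s' constant in group %s/day %d; scales to 0",
                        f, groups$animal_id[g], groups$trial_day[g]))
      out[[length(out) + 1L]] <- data.frame(
        animal_id = groups$animal_id[g], trial_day = groups$trial_day[g],
        feature = f, min = mn, max = mx)
    }
  }
  structure(do.call(rbind, out), class = c("scaling_state", "data.frame"))
}

scaling_lookup <- function(state, animal_id, trial_day, feature) {
  i <- which(state$animal_id == animal_id & state$trial_day == trial_day &
               state$feature == feature)
  if (length(i) != 1L)
    stop(sprintf("no scaling state for %s/day %s/%s", animal_id,
                 trial_day, feature), call. = FALSE)
  state[i, ]
}

#' Apply min-max scaling
#'
#' `(x - min) / (max - min)` per (animal, trial day, feature), clipped to
#' `[0, 1]` when applied outside the fitted range (relevant in `train-only`
#' scaling mode). Scaled columns are named `<feature>_norm`.
#'
#' @param windows feature windows.
#' @param state a `scaling_state` from [fit_scaling()].
#' @param features feature column names.
#' @param clip clip out-of-range values to `[0, 1]`.
#' @return `windows` with `<feature>_norm` columns added.
#' @export
apply_scaling <- function(windows, state, features = FEATURE_NAMES,
                          clip = TRUE) {
  keys <- unique(windows[, c("animal_id", "trial_day")])
  for (f in features) windows[[paste0(f, "_norm")]] <- NA_real_
  for (g in seq_len(nrow(keys))) {
    sel <- windows$animal_id == keys$animal_id[g] &
      windows$trial_day == keys$trial_day[g]
    for (f in features) {
      st <- scaling_lookup(state, keys$animal_id[g], keys$trial_day[g], f)
      rng <- st$max - st$min
      v <- if (rng > 0) (windows[[f]][sel] - st$min) / rng else
        rep(0, sum(sel))
      windows[[paste0(f, "_norm")]][sel] <- if (clip) clip01(v) else v
    }
  }
  windows
}

#' Invert min-max scaling
#'
#' @inheritParams apply_scaling
#' @return `windows` with features recovered from their `_norm` columns.
#' @export
invert_scaling <- function(windows, state, features = FEATURE_NAMES) {
  keys <- unique(windows[, c("animal_id", "trial_day")])
  for (g in seq_len(nrow(keys))) {
    sel <- windows$animal_id == keys$animal_id[g] &
      windows$trial_day == keys$trial_day[g]
    for (f in features) {
      st <- scaling_lookup(state, keys$animal_id[g], keys$trial_day[g], f)
      windows[[f]][sel] <- st$min +
        windows[[paste0(f, "_norm")]][sel] * (st$max - st$min)
    }
  }
  windows
}

#' Audit scaling leakage
#'
#' Same-day min-max scaling uses each trial day's full data, so normalization
#' statistics leak across any later train/test split. Under `train-only`
#' scaling the test set can fall outside the fitted `[min, max]`; this audit
#' quantifies how often.
#'
#' @param windows feature windows (typically a held-out set).
#' @param state a `scaling_state` fitted on other windows.
#' @param features feature column names.
#' @return data.frame per feature: `n`, `n_below`, `n_above`,
#'   `frac_outside`.
#' @export
audit_scaling <- function(windows, state, features = FEATURE_NAMES) {
  un <- apply_scaling(windows, state, features, clip = FALSE)
  out <- lapply(features, function(f) {
    v <- un[[paste0(f, "_norm")]]
    v <- v[is.finite(v)]
    data.frame(feature = f, n = length(v),
               n_below = sum(v < 0), n_above = sum(v > 1),
               frac_outside = mean(v < 0 | v > 1))
  })
  do.call(rbind, out)
}

#' Rank features by chi-squared association with class
#'
#' Discretizes each feature into quartile bins and computes the (uncorrected)
#' chi-squared statistic of the bin x class contingency table; features are
#' ranked by the statistic and the top `k` returned.
#'
#' @param windows feature windows.
#' @param features candidate feature column names.
#' @param labels class label per window (defaults to `windows$label`).
#' @param k number of features to return.
#' @return data.frame ranked by `statistic`, with attribute `"selected"`
#'   holding the top-k names.
#' @export
select_features <- function(windows, features = FEATURE_NAMES,
                            labels = windows$label, k = 5) {
  if (length(unique(labels)) < 2L)
    stop("need >= 2 classes", call. = FALSE)
  if (length(features) < k) {
    warning(sprintf("only %d features available (< k = %d); returning all",
                    length(features), k))
    k <- length(features)
  }
  stat <- vapply(features, function(f) {
    v <- windows[[f]]
    ok <- is.finite(v)
    br <- unique(quantile(v[ok], probs = seq(0, 1, 0.25), names = FALSE))
    if (length(br) < 2L) return(0)
    bins <- cut(v[ok], breaks = br, include.lowest = TRUE)
    tab <- table(bins, labels[ok])
    if (nrow(tab) < 2L) return(0)
    suppressWarnings(unname(chisq.test(tab, correct = FALSE)$statistic))
  }, numeric(1))
  out <- data.frame(feature = features, statistic = stat)
  out <- out[order(-out$statistic), ]
  rownames(out) <- NULL
  attr(out, "selected") <- head(out$feature, k)
  out
}

#' Extended candidate feature bank
#'
#' A documented superset of time-domain HRV statistics, burst morphology and
#' iskNA distribution summaries computed per window, used to exercise
#' [select_features()]. It makes no claim of matching any particular
#' published 36-feature bank.
#'
#' @param beats a cleaned `beat_series`.
#' @param skd a `skna_derived` with bursts detected.
#' @param window_s window length, seconds.
#' @param duration_s total covered time.
#' @return data.frame: the five core features plus `mean_nn`, `sdnn`,
#'   `min_nn`, `max_nn`, `pnn10`, `iskna_max`, `iskna_q90`, `iskna_sd`,
#'   `burst_total_s`, `burst_peak_max`.
#' @export
extended_features <- function(beats, skd, window_s = 15, duration_s = NULL) {
  base <- window_features(beats, skd, window_s, duration_s)
  duration_s <- duration_s %||% (length(skd$iskna) / skd$rate)
  bursts <- skd$bursts %||% data.frame(start_s = numeric(0),
                                       end_s = numeric(0),
                                       peak_uv = numeric(0))
  bw <- floor(bursts$start_s / window_s) + 1L
  nn_win <- floor(beats$nn_end_s / window_s) + 1L
  iw <- floor((seq_along(skd$iskna) - 1) / skd$rate / window_s) + 1L
  ext <- lapply(base$window_index, function(w) {
    nn <- beats$nn_ms[nn_win == w]
    idx <- beats$nn_idx[nn_win == w]
    d <- if (length(nn) > 1L) diff(nn)[diff(idx) == 1L] else numeric(0)
    isk <- skd$iskna[iw == w]
    bsel <- which(bw == w)
    data.frame(
      mean_nn = if (length(nn)) mean(nn) else NA_real_,
      sdnn = if (length(nn) > 1L) sd(nn) else NA_real_,
      min_nn = if (length(nn)) min(nn) else NA_real_,
      max_nn = if (length(nn)) max(nn) else NA_real_,
      pnn10 = if (length(d)) 100 * mean(abs(d) > 10) else NA_real_,
      iskna_max = max(isk), iskna_q90 = quantile(isk, 0.9, names = FALSE),
      iskna_sd = sd(isk),
      burst_total_s = sum(bursts$end_s[bsel] - bursts$start_s[bsel]),
      burst_peak_max = if (length(bsel)) max(bursts$peak_uv[bsel]) else 0
    )
  })
  cbind(base, do.call(rbind, ext))
}
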