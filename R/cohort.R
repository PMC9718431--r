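# Cohort-scale feature assembly: truth-derived beat and iskNA series per
# recording, 15-s windows, stimulus labels, and deterministic subsampling to
# a target data-point count.

#' Assemble labeled feature windows for a simulated cohort
#'
#' For each recording, builds truth-derived beat and iskNA series, extracts
#' 15-s windows, and labels each window with the stimulus class occupying at
#' least `label_overlap` of it: `ad` for distension trials that pass the
#' blood-pressure labeling criteria, `startle`, `tail_pinch`, or `none`
#' (failed distensions carry no AD event and stay `none`, giving the
#' classifier realistic sympathetic-surge negatives). Only windows within
#' `retain_pre_s` before a stimulus onset through `retain_post_s` after its
#' offset are kept, and flagged (beat-poor) windows are dropped.
#'
#' @param recordings list of `ad_recording` objects (event-level is fine).
#' @param config the [sim_config()] used to create them.
#' @param criteria an [ad_criteria()] for the AD window labels.
#' @param window_s window length, seconds.
#' @param retain_pre_s,retain_post_s retention margins around each stimulus.
#' @return data.frame: ids, window timing, the five raw features, `n_nn`,
#'   `flagged`, `label`, `context` (the nearby stimulus kind) and
#'   `truth_label` (labels from simulator ground truth instead of the BP
#'   criteria).
#' @export
cohort_windows <- function(recordings, config, criteria = ad_criteria(),
                           window_s = 15, retain_pre_s = 60,
                           retain_post_s = 120) {
  out <- list()
  for (rec in recordings) {
    beats <- truth_beat_series(rec)
    skd <- truth_skna_series(rec, config)
    skd$bursts <- data.frame(start_s = rec$truth$bursts$start,
                             end_s = rec$truth$bursts$end,
                             peak_uv = rec$truth$bursts$amp)
    wf <- window_features(beats, skd, window_s, duration_s = rec$duration_s)
    wf$animal_id <- rec$animal_id
    wf$trial_day <- rec$trial_day
    wf$label <- "none"
    wf$truth_label <- "none"
    wf$context <- "none"
    keep <- rep(FALSE, nrow(wf))
    for (i in seq_along(rec$annotations)) {
      a <- rec$annotations[[i]]
      if (a$kind == "none") next
      near <- wf$start_s >= a$onset_s - retain_pre_s &
        wf$start_s < a$onset_s + a$duration_s + retain_post_s
      keep <- keep | near
      wf$context[near] <- a$kind
      ov <- pmin(wf$end_s, a$onset_s + a$duration_s) -
        pmax(wf$start_s, a$onset_s)
      in_stim <- ov >= 0.5 * window_s
      if (!any(in_stim)) next
      truth_kind <- if (a$kind == "crd") {
        if (rec$truth$annotations[[i]]$is_ad) "ad" else "none"
      } else a$kind
      wf$truth_label[in_stim] <- truth_kind
      if (a$kind == "crd") {
        lb <- label_trial(rec, a, skd, beats, criteria)
        wf$label[in_stim] <- if (lb$is_ad) "ad" else "none"
      } else {
        wf$label[in_stim] <- a$kind
      }
    }
    out[[length(out) + 1L]] <- wf[keep & !wf$flagged, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Deterministically subsample windows to a target count
#'
#' Keeps every stimulus-labeled window and thins the `none` class (or, if
#' stimulus windows alone exceed `n`, thins all classes proportionally) to
#' reach exactly `n` rows.
#'
#' @param windows output of [cohort_windows()].
#' @param n target number of windows.
#' @param seed integer seed for the thinning draw.
#' @return `windows` with exactly `min(n, nrow(windows))` rows.
#' @export
sample_windows <- function(windows, n = 2200, seed = 1L) {
  if (nrow(windows) <= n) return(windows)
  is_stim <- windows$label != "none"
  n_stim <- sum(is_stim)
  with_seed(derive_seed(seed, 4242), {
    if (n_stim <= n) {
      keep_none <- sample(which(!is_stim), n - n_stim)
      idx <- sort(c(which(is_stim), keep_none))
    } else {
      idx <- sort(sample(which(is_stim), n))
    }
    windows[idx, , drop = FALSE]
  })
}

#' Normalized feature matrix for classification
#'
#' Applies per-trial-day (or train-only) min-max scaling and returns the
#' model inputs.
#'
#' @param windows labeled feature windows.
#' @param features feature columns to use.
#' @param scaling `"same-day"` fits min/max on all windows of each trial day;
#'   `"train-only"` fits on the rows flagged in `train_idx` only.
#' @param train_idx row indices of the training set (for `train-only`).
#' @return list: `x` (numeric matrix of `<feature>_norm` columns), `y`
#'   (label factor), `windows` (with `_norm` columns), `state`.
#' @export
feature_matrix <- function(windows, features = FEATURE_NAMES,
                           scaling = c("same-day", "train-only"),
                           train_idx = NULL) {
  scaling <- match.arg(scaling)
  fit_on <- if (scaling == "train-only") {
    if (is.null(train_idx)) stop("train-only scaling needs train_idx",
                                 call. = FALSE)
    windows[train_idx, , drop = FALSE]
  } else windows
  state <- fit_scaling(fit_on, features)
  windows <- apply_scaling(windows, state, features)
  x <- as.matrix(windows[, paste0(features, "_norm")])
  colnames(x) <- features
  list(x = x, y = factor(windows$label), windows = windows, state = state)
}
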