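# Clinical ground-truth labeling of colorectal-distension trials: a trial
# constitutes AD when SBP rises by >= 15 mmHg and MAP by >= 10 mmHg over the
# pre-stimulus baseline, preceded by sympathetic bursts and followed by
# bradycardia.

#' AD labeling criteria
#'
#' @param sbp_delta_min minimum systolic rise, mmHg (inclusive).
#' @param map_delta_min minimum mean-arterial rise, mmHg (inclusive).
#' @param require_bradycardia require a significant heart-rate drop during
#'   the vagal phase.
#' @param require_preceding_sympathetic require at least one detected burst
#'   between stimulus onset and the SBP peak.
#' @param baseline_window_s seconds of pre-onset BP used as reference.
#' @param search_post_s how far past stimulus offset the BP peak may occur
#'   (operationalizes "rapid" increase).
#' @param map_mode `"conjunctive"` (MAP criterion required, default) or
#'   `"audit"` (MAP delta reported but not required).
#' @return list of class `ad_criteria`.
#' @export
ad_criteria <- function(sbp_delta_min = 15, map_delta_min = 10,
                        require_bradycardia = TRUE,
                        require_preceding_sympathetic = TRUE,
                        baseline_window_s = 120,
                        search_post_s = 120,
                        map_mode = c("conjunctive", "audit")) {
  if (sbp_delta_min <= 0 || map_delta_min <= 0)
    stop("thresholds must be > 0", call. = FALSE)
  structure(list(sbp_delta_min = sbp_delta_min,
                 map_delta_min = map_delta_min,
                 require_bradycardia = isTRUE(require_bradycardia),
                 require_preceding_sympathetic =
                   isTRUE(require_preceding_sympathetic),
                 baseline_window_s = baseline_window_s,
                 search_post_s = search_post_s,
                 map_mode = match.arg(map_mode)),
            class = "ad_criteria")
}

#' Label one distension trial as AD / not-AD
#'
#' Computes the SBP and MAP rises (peak within the stimulus epoch plus
#' `search_post_s`, minus the mean over the `baseline_window_s` before
#' onset), tests for bradycardia during the vagal phase (mean HR below the
#' baseline mean minus two standard errors) and for a preceding sympathetic
#' burst, and applies the conjunction. The full criteria breakdown is always
#' returned so threshold sensitivity can be audited.
#'
#' @param recording an `ad_recording` (its `channels$bp` table is used).
#' @param annotation the `crd` [stim_annotation()] being judged.
#' @param skd `skna_derived` with detected bursts (needed when
#'   `require_preceding_sympathetic`).
#' @param beats cleaned `beat_series` (needed when `require_bradycardia`).
#' @param criteria an [ad_criteria()].
#' @param trial_id identifier recorded in the label.
#' @return list of class `ad_event_label`: `trial_id`, `is_ad`, `delta_sbp`,
#'   `delta_map`, `bradycardia_observed`, `sympathetic_precedes`,
#'   `t_sbp_peak`, and the criteria used.
#' @export
label_trial <- function(recording, annotation, skd = NULL, beats = NULL,
                        criteria = ad_criteria(), trial_id = NULL) {
  stopifnot(inherits(annotation, "stim_annotation"))
  if (annotation$kind != "crd")
    stop("label_trial judges colorectal-distension (crd) annotations",
         call. = FALSE)
  bp <- recording$channels$bp
  on <- annotation$onset_s
  base_sel <- bp$time_s >= on - criteria$baseline_window_s & bp$time_s < on
  search_sel <- bp$time_s >= on &
    bp$time_s <= on + annotation$duration_s + criteria$search_post_s
  if (sum(base_sel) < 2L || sum(search_sel) < 2L)
    stop("insufficient BP samples around onset (tail-cuff cadence is 30 s); ",
         "need >= 2 baseline and >= 2 stimulus-epoch samples", call. = FALSE)
  base_sbp <- mean(bp$sbp[base_sel])
  base_map <- mean(bp$map[base_sel])
  ipk <- which(search_sel)[which.max(bp$sbp[search_sel])]
  t_peak <- bp$time_s[ipk]
  delta_sbp <- bp$sbp[ipk] - base_sbp
  delta_map <- max(bp$map[search_sel]) - base_map

  brady <- NA
  if (criteria$require_bradycardia) {
    if (is.null(beats) || is.null(beats$nn_ms))
      stop("require_bradycardia = TRUE needs a cleaned beat series",
           call. = FALSE)
    hr_base <- 60000 / beats$nn_ms[beats$nn_end_s >=
                                     on - criteria$baseline_window_s &
                                     beats$nn_end_s < on]
    vg0 <- on + annotation$duration_s / 2
    vg1 <- on + annotation$duration_s + criteria$search_post_s
    hr_vagal <- 60000 / beats$nn_ms[beats$nn_end_s >= vg0 &
                                      beats$nn_end_s < vg1]
    if (length(hr_base) < 2L || length(hr_vagal) < 2L) {
      warning("too few beats to assess bradycardia; flag set FALSE")
      brady <- FALSE
    } else {
      se <- sd(hr_base) / sqrt(length(hr_base))
      brady <- mean(hr_vagal) < mean(hr_base) - 2 * se
    }
  }

  precedes <- NA
  if (criteria$require_preceding_sympathetic) {
    if (is.null(skd) || is.null(skd$bursts))
      stop("require_preceding_sympathetic = TRUE needs detected bursts",
           call. = FALSE)
    precedes <- any(skd$bursts$start_s >= on & skd$bursts$start_s <= t_peak)
  }

  is_ad <- delta_sbp >= criteria$sbp_delta_min
  if (criteria$map_mode == "conjunctive")
    is_ad <- is_ad && delta_map >= criteria$map_delta_min
  if (criteria$require_bradycardia) is_ad <- is_ad && isTRUE(brady)
  if (criteria$require_preceding_sympathetic)
    is_ad <- is_ad && isTRUE(precedes)

  structure(list(
    trial_id = trial_id %||% sprintf("%s_d%s_t%.0f",
                                     recording$animal_id %||% "trial",
                                     recording$trial_day %||% 0, on),
    is_ad = is_ad, delta_sbp = delta_sbp, delta_map = delta_map,
    bradycardia_observed = brady, sympathetic_precedes = precedes,
    t_sbp_peak = t_peak, criteria = criteria
  ), class = "ad_event_label")
}

#' @export
print.ad_event_label <- function(x, ...) {
  cat(sprintf("<ad_event_label> %s: %s (dSBP %+.1f, dMAP %+.1f, brady %s, symp %s)\n",
              x$trial_id, if (x$is_ad) "AD" else "not AD",
              x$delta_sbp, x$delta_map, x$bradycardia_observed,
              x$sympathetic_precedes))
  invisible(x)
}

#' AD conversion rate of a set of labeled trials
#'
#' @param labels list of `ad_event_label` objects, a data.frame with an
#'   `is_ad` column, or a logical vector.
#' @param conf_level confidence level of the binomial interval.
#' @return list: `rate`, `n_ad`, `n`, `ci` (exact binomial).
#' @export
cohort_ad_rate <- function(labels, conf_level = 0.95) {
  is_ad <- if (is.data.frame(labels)) labels$is_ad
  else if (is.logical(labels)) labels
  else vapply(labels, `[[`, logical(1), "is_ad")
  if (length(is_ad) == 0L) stop("no labels supplied", call. = FALSE)
  bt <- binom.test(sum(is_ad), length(is_ad), conf.level = conf_level)
  list(rate = mean(is_ad), n_ad = sum(is_ad), n = length(is_ad),
       ci = as.numeric(bt$conf.int))
}

#' Label every distension trial of a cohort
#'
#' Runs [label_trial()] over each `crd` annotation using truth-derived beat
#' and iskNA series (see [truth_beat_series()], [truth_skna_series()]).
#'
#' @param recordings list of `ad_recording` objects.
#' @param config the [sim_config()] used to create them.
#' @param criteria an [ad_criteria()].
#' @return data.frame: one row per trial with deltas, flags, `is_ad` and the
#'   simulator's ground-truth flag `truth_is_ad`.
#' @export
label_cohort <- function(recordings, config, criteria = ad_criteria()) {
  rows <- list()
  for (rec in recordings) {
    beats <- truth_beat_series(rec)
    skd <- truth_skna_series(rec, config)
    skd$bursts <- data.frame(start_s = rec$truth$bursts$start,
                             end_s = rec$truth$bursts$end,
                             peak_uv = rec$truth$bursts$amp)
    for (i in seq_along(rec$annotations)) {
      a <- rec$annotations[[i]]
      if (a$kind != "crd") next
      lb <- label_trial(rec, a, skd, beats, criteria,
                        trial_id = sprintf("%s_d%d_a%d", rec$animal_id,
                                           rec$trial_day, i))
      rows[[length(rows) + 1L]] <- data.frame(
        trial_id = lb$trial_id, animal_id = rec$animal_id,
        trial_day = rec$trial_day, annotation_idx = i,
        onset_s = a$onset_s,
        delta_sbp = lb$delta_sbp, delta_map = lb$delta_map,
        bradycardia_observed = lb$bradycardia_observed,
        sympathetic_precedes = lb$sympathetic_precedes,
        is_ad = lb$is_ad,
        truth_is_ad = rec$truth$annotations[[i]]$is_ad)
    }
  }
  do.call(rbind, rows)
}
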