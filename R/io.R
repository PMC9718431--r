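# Recording bundle I/O: one CSV per channel plus a JSON metadata sidecar
# (channel specs, annotations, ground truth, config hash).

#' Write a recording bundle
#'
#' Writes `ecg.csv` / `skna.csv` (columns `time_s`, `value`; only when the
#' waveforms are rendered), `bp.csv` (`time_s`, `sbp`, `dbp`, `map`),
#' `temperature.csv`, and `meta.json`.
#'
#' @param rec an `ad_recording`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_recording_bundle <- function(rec, dir) {
  stopifnot(inherits(rec, "ad_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fs <- 10000
  for (ch in c("ecg", "skna")) {
    v <- rec$channels[[ch]]
    if (is.null(v)) next
    write.csv(data.frame(time_s = (seq_along(v) - 1) / fs, value = v),
              file.path(dir, paste0(ch, ".csv")), row.names = FALSE)
  }
  write.csv(rec$channels$bp, file.path(dir, "bp.csv"), row.names = FALSE)
  write.csv(rec$channels$temperature, file.path(dir, "temperature.csv"),
            row.names = FALSE)
  meta <- list(
    animal_id = rec$animal_id, trial_day = rec$trial_day,
    duration_s = rec$duration_s, config_hash = rec$config_hash,
    seed = rec$seed,
    specs = rec$specs,
    annotations = lapply(rec$annotations, unclass),
    truth = list(beats = rec$truth$beats, bursts = rec$truth$bursts,
                 bp = rec$truth$bp,
                 baseline_hr_bpm = rec$truth$baseline_hr_bpm,
                 nn0_ms = rec$truth$nn0_ms,
                 annotations = rec$truth$annotations)
  )
  write_json_file(meta, file.path(dir, "meta.json"))
  invisible(dir)
}

read_channel_csv <- function(path, cols) {
  df <- tryCatch(read.csv(path), error = function(e)
    stop(sprintf("cannot parse '%s': %s", path, conditionMessage(e)),
         call. = FALSE))
  if (!all(cols %in% names(df)))
    stop(sprintf("'%s' is missing columns: %s", path,
                 paste(setdiff(cols, names(df)), collapse = ", ")),
         call. = FALSE)
  for (cc in cols) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      stop(sprintf("non-numeric value in '%s', column '%s', row %d",
                   path, cc, bad %||% 1L), call. = FALSE)
    }
    if (anyNA(v))
      stop(sprintf("missing value in '%s', column '%s', row %d",
                   path, cc, which(is.na(v))[1]), call. = FALSE)
  }
  df
}

#' Read a recording bundle
#'
#' @param dir directory written by [write_recording_bundle()].
#' @return an `ad_recording` (waveform channels present only if their CSVs
#'   exist).
#' @export
read_recording_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = FALSE)
  channels <- list(ecg = NULL, skna = NULL)
  for (ch in c("ecg", "skna")) {
    p <- file.path(dir, paste0(ch, ".csv"))
    if (file.exists(p)) channels[[ch]] <- read_channel_csv(p,
                                                           c("time_s",
                                                             "value"))$value
  }
  channels$bp <- read_channel_csv(file.path(dir, "bp.csv"),
                                  c("time_s", "sbp", "dbp", "map"))
  channels$temperature <- read_channel_csv(file.path(dir, "temperature.csv"),
                                           c("time_s", "value"))
  ann <- lapply(meta$annotations, function(a)
    stim_annotation(a$kind, a$onset_s, a$duration_s, a$recovery_s))
  df_from_rows <- function(rows) {
    if (length(rows) == 0L) return(data.frame())
    do.call(rbind, lapply(rows, function(r)
      as.data.frame(lapply(r, function(v) v %||% NA),
                    stringsAsFactors = FALSE)))
  }
  truth <- meta$truth
  truth$beats <- as.numeric(unlist(truth$beats))
  truth$bursts <- df_from_rows(truth$bursts)
  truth$bp <- df_from_rows(truth$bp)
  truth$annotations <- lapply(truth$annotations, function(a) {
    a$symp_onset_s <- a$symp_onset_s %||% NA_real_
    a$vagal_onset_s <- a$vagal_onset_s %||% NA_real_
    a
  })
  structure(list(
    animal_id = meta$animal_id, trial_day = as.integer(meta$trial_day),
    duration_s = meta$duration_s, channels = channels,
    specs = df_from_rows(meta$specs), annotations = ann, truth = truth,
    seed = meta$seed, config_hash = meta$config_hash
  ), class = "ad_recording")
}
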