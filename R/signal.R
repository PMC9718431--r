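# Signal conditioning: zero-phase band-pass filtering, R-peak detection,
# NN-interval cleaning, iskNA integration, and sympathetic burst detection.

#' Zero-phase Butterworth band-pass filter
#'
#' Applies the squared magnitude response of a Butterworth design (the same
#' response a forward-backward IIR pass realizes) on the FFT grid of the
#' mirror-padded signal. This is exactly zero-phase and exactly symmetric
#' under time reversal, with no forward-backward edge transients; beat and
#' burst timestamps are therefore unbiased.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param low,high band edges in Hz; either may be `NULL` for low-/high-pass.
#' @param order Butterworth order per edge.
#' @return filtered signal, same length as `x`.
#' @export
bandpass_zero_phase <- function(x, fs, low = NULL, high = NULL, order = 2) {
  n <- length(x)
  if (n < 8L) stop("signal too short to filter", call. = FALSE)
  if (!is.null(high) && fs < 2 * high)
    stop(sprintf("sampling rate %g Hz is below twice the upper band edge %g Hz",
                 fs, high), call. = FALSE)
  pad <- min(n - 1L, as.integer(round(2 * fs)))
  # grow the (symmetric) padding to a 2-3-5-smooth FFT length; symmetric
  # padding preserves exact time-reversal symmetry, smooth lengths keep the
  # mixed-radix FFT fast
  smooth <- stats::nextn(n + 2L * pad, c(2L, 3L, 5L))
  if ((smooth - n) %% 2L == 1L) smooth <- stats::nextn(smooth + 1L,
                                                       c(2L, 3L, 5L))
  if ((smooth - n) %/% 2L <= n - 1L) pad <- (smooth - n) %/% 2L
  xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  np <- length(xp)
  w <- 2 * pi * (seq_len(np) - 1L) / np
  gain <- rep(1, np)
  resp <- function(filt) {
    z <- exp(-1i * w)
    num <- Reduce(function(acc, bk) acc * z + bk, filt$b, accumulate = FALSE)
    den <- Reduce(function(acc, ak) acc * z + ak, filt$a, accumulate = FALSE)
    Mod(num / den)^2
  }
  if (!is.null(low) && !is.null(high)) {
    gain <- resp(signal::butter(order, c(low, high) / (fs / 2),
                                type = "pass"))
  } else if (!is.null(high)) {
    gain <- resp(signal::butter(order, high / (fs / 2), type = "low"))
  } else if (!is.null(low)) {
    gain <- resp(signal::butter(order, low / (fs / 2), type = "high"))
  }
  y <- Re(fft(fft(xp) * gain, inverse = TRUE)) / np
  y[(pad + 1L):(pad + n)]
}

#' Condition raw ECG and skNA channels
#'
#' ECG is band-passed 0.5-100 Hz; skNA is band-passed 500-1000 Hz (the
#' neuECG band separating stellate-ganglion nerve spikes from cardiac
#' content). Both filters are zero-phase.
#'
#' @param recording an `ad_recording` with rendered waveform channels.
#' @param ecg_band,skna_band band edges in Hz.
#' @return list with elements `ecg` and `skna` (filtered signals) and `fs`.
#' @export
filter_signals <- function(recording, ecg_band = c(0.5, 100),
                           skna_band = c(500, 1000)) {
  stopifnot(inherits(recording, "ad_recording"))
  fs <- 10000
  for (ch in c("ecg", "skna")) {
    if (is.null(recording$channels[[ch]]))
      stop(sprintf("channel '%s' is missing (event-level recording? see render_recording())",
                   ch), call. = FALSE)
  }
  list(
    ecg = bandpass_zero_phase(recording$channels$ecg, fs,
                              low = ecg_band[1], high = ecg_band[2],
                              order = 2),
    skna = bandpass_zero_phase(recording$channels$skna, fs,
                               low = skna_band[1], high = skna_band[2],
                               order = 4),
    fs = fs
  )
}

new_beat_series <- function(r_peak_times, no_peaks = FALSE) {
  r_peak_times <- as.numeric(r_peak_times)
  if (is.unsorted(r_peak_times, strictly = TRUE))
    stop("r_peak_times must be strictly increasing", call. = FALSE)
  rr_ms <- diff(r_peak_times) * 1000
  structure(list(
    r_peak_times = r_peak_times,
    rr_ms = rr_ms,
    rr_end_s = if (length(r_peak_times) > 1L) r_peak_times[-1L] else numeric(0),
    nn_ms = NULL, nn_idx = NULL, nn_end_s = NULL,
    rejected_idx = integer(0),
    no_peaks = no_peaks
  ), class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats, %d RR, %s NN (%d rejected)%s\n",
              length(x$r_peak_times), length(x$rr_ms),
              if (is.null(x$nn_ms)) "un-cleaned" else
                as.character(length(x$nn_ms)),
              length(x$rejected_idx),
              if (isTRUE(x$no_peaks)) " [no peaks found]" else ""))
  invisible(x)
}

#' Detect R peaks in filtered rodent ECG
#'
#' Pan-Tompkins-style detection adapted to rat heart rates: squared
#' derivative, 30 ms moving-window integration, adaptive threshold, 100 ms
#' refractory period, with the R time refined to the local ECG maximum.
#'
#' @param ecg_filtered band-passed ECG (see [filter_signals()]).
#' @param sampling_rate Hz.
#' @param integration_ms integration window, ms.
#' @param refractory_ms minimum beat separation, ms.
#' @return a `beat_series` with `r_peak_times` (s) and `rr_ms`; empty with
#'   `no_peaks = TRUE` (and a warning) if nothing is found.
#' @export
detect_r_peaks <- function(ecg_filtered, sampling_rate,
                           integration_ms = 30, refractory_ms = 100) {
  fs <- sampling_rate
  n <- length(ecg_filtered)
  if (n < 2 * fs) stop("need at least 2 s of signal", call. = FALSE)
  energy <- moving_average(c(0, diff(ecg_filtered))^2,
                           round(integration_ms / 1000 * fs))
  thr <- max(0.25 * quantile(energy, 0.999, names = FALSE),
             6 * median(energy))
  above <- energy > thr
  if (!any(above)) {
    warning("no R peaks found; returning empty beat series")
    return(new_beat_series(numeric(0), no_peaks = TRUE))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  reg <- cbind(starts[r$values], ends[r$values])
  # candidate = energy argmax per supra-threshold region
  cand <- apply(reg, 1L, function(ij) {
    ij[1] + which.max(energy[ij[1]:ij[2]]) - 1L
  })
  # refine to the ECG local maximum, then enforce the refractory period
  half <- round(0.015 * fs)
  peak <- vapply(cand, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    lo + which.max(ecg_filtered[lo:hi]) - 1L
  }, numeric(1))
  o <- order(peak)
  peak <- peak[o]
  amp <- ecg_filtered[peak]
  refr <- refractory_ms / 1000 * fs
  keep <- logical(length(peak))
  last <- -Inf
  for (i in seq_along(peak)) {
    if (peak[i] - last >= refr) {
      keep[i] <- TRUE; last <- peak[i]
    } else if (amp[i] > amp[which(keep)[sum(keep)]]) {
      # replace the previous peak if this one is taller within the refractory
      keep[which(keep)[sum(keep)]] <- FALSE
      keep[i] <- TRUE; last <- peak[i]
    }
  }
  times <- unique((peak[keep] - 1L) / fs)
  new_beat_series(times)
}

#' Reject ectopic/artifact RR intervals
#'
#' An RR interval deviating more than `tol` (default 20%) from the running
#' median (window `k` beats) is rejected; survivors form the normal-to-normal
#' (NN) sequence. Original adjacency is retained so successive-difference
#' statistics never span a rejected interval.
#'
#' @param beats a `beat_series`.
#' @param tol fractional deviation from the running median.
#' @param k running-median window (beats, odd).
#' @return the `beat_series` with `nn_ms`, `nn_idx`, `nn_end_s`,
#'   `rejected_idx` populated.
#' @export
clean_nn <- function(beats, tol = 0.2, k = 11L) {
  stopifnot(inherits(beats, "beat_series"))
  rr <- beats$rr_ms
  if (length(rr) == 0L) stop("rr_ms is empty", call. = FALSE)
  kk <- min(as.integer(k), length(rr))
  if (kk %% 2L == 0L) kk <- kk - 1L
  med <- if (kk >= 3L) runmed(rr, kk, endrule = "median") else rep(median(rr),
                                                                   length(rr))
  bad <- abs(rr - med) > tol * med
  if (all(bad))
    stop("all RR intervals rejected; check signal quality", call. = FALSE)
  beats$nn_ms <- rr[!bad]
  beats$nn_idx <- which(!bad)
  beats$nn_end_s <- beats$rr_end_s[!bad]
  beats$rejected_idx <- which(bad)
  beats
}

new_skna_derived <- function(filtered, rectified, iskna, rate,
                             baseline_mu, baseline_sigma, bursts = NULL) {
  structure(list(
    filtered = filtered, rectified = rectified, iskna = iskna, rate = rate,
    baseline_mu = baseline_mu, baseline_sigma = baseline_sigma,
    bursts = bursts
  ), class = "skna_derived")
}

#' @export
print.skna_derived <- function(x, ...) {
  cat(sprintf("<skna_derived> %d iskNA samples @ %g Hz, baseline %.3g +/- %.3g uV, %s bursts\n",
              length(x$iskna), x$rate, x$baseline_mu, x$baseline_sigma,
              if (is.null(x$bursts)) "undetected" else
                as.character(nrow(x$bursts))))
  invisible(x)
}

#' Integrate rectified skNA
#'
#' iskNA is the 100 ms moving average of the rectified (absolute-value)
#' band-passed skNA. Baseline statistics are the median and MAD (scaled by
#' 1.4826) of the iskNA over stimulus-free time, used downstream as the
#' burst-detection reference.
#'
#' @param skna_filtered band-passed skNA, uV.
#' @param sampling_rate Hz.
#' @param window_ms integration window, ms.
#' @param annotations optional list of [stim_annotation()]; baseline
#'   statistics then exclude each stimulus epoch plus 120 s after it.
#' @return a `skna_derived` object (bursts not yet detected).
#' @export
integrate_skna <- function(skna_filtered, sampling_rate, window_ms = 100,
                           annotations = NULL) {
  fs <- sampling_rate
  win <- round(window_ms / 1000 * fs)
  if (length(skna_filtered) < win)
    stop("recording shorter than the integration window", call. = FALSE)
  rectified <- abs(skna_filtered)
  iskna <- moving_average(rectified, win)
  tt <- (seq_along(iskna) - 1) / fs
  base <- rep(TRUE, length(iskna))
  for (a in annotations %||% list()) {
    base[tt >= a$onset_s & tt < a$onset_s + a$duration_s + 120] <- FALSE
  }
  if (!any(base)) base <- rep(TRUE, length(iskna))
  new_skna_derived(filtered = skna_filtered, rectified = rectified,
                   iskna = iskna, rate = fs,
                   baseline_mu = median(iskna[base]),
                   baseline_sigma = mad(iskna[base]))
}

#' Detect sympathetic bursts in the iskNA trace
#'
#' A burst is a maximal interval where iskNA exceeds
#' `baseline_mu + k * baseline_sigma`; excursions separated by less than
#' `merge_gap_ms` are merged, and merged excursions shorter than
#' `min_duration_ms` are discarded.
#'
#' @param skd a `skna_derived` from [integrate_skna()].
#' @param k threshold multiplier on the baseline MAD.
#' @param min_duration_ms minimum burst duration, ms.
#' @param merge_gap_ms merge gap, ms.
#' @return the `skna_derived` with `bursts` populated
#'   (`start_s`, `end_s`, `peak_uv`).
#' @export
detect_bursts <- function(skd, k = 3, min_duration_ms = 50,
                          merge_gap_ms = 100) {
  stopifnot(inherits(skd, "skna_derived"))
  fs <- skd$rate
  if (skd$baseline_sigma <= 0) {
    warning("degenerate baseline (sigma = 0); using absolute floor threshold")
    thr <- skd$baseline_mu * 2 + .Machine$double.eps
  } else {
    thr <- skd$baseline_mu + k * skd$baseline_sigma
  }
  above <- skd$iskna > thr
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      peak_uv = numeric(0))
  if (!any(above)) { skd$bursts <- empty; return(skd) }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  s <- starts[r$values]; e <- ends[r$values]
  # merge excursions separated by < merge_gap
  gap <- merge_gap_ms / 1000 * fs
  grp <- cumsum(c(TRUE, (s[-1L] - e[-length(e)]) >= gap))
  out_s <- as.integer(tapply(s, grp, min))
  out_e <- as.integer(tapply(e, grp, max))
  dur_ok <- (out_e - out_s + 1L) >= min_duration_ms / 1000 * fs
  out_s <- out_s[dur_ok]; out_e <- out_e[dur_ok]
  peak <- vapply(seq_along(out_s), function(i)
    max(skd$iskna[out_s[i]:out_e[i]]), numeric(1))
  skd$bursts <- data.frame(start_s = (out_s - 1L) / fs,
                           end_s = (out_e - 1L) / fs,
                           peak_uv = peak)
  skd
}
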