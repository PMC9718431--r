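#' Channel specifications for the recording array
#'
#' The four non-invasive channels and their package-default sampling rates:
#' ECG and skin nerve activity (skNA) at 10 kHz, tail-cuff blood pressure one
#' sample every 30 s, and skin temperature at 2 Hz.
#'
#' @return data.frame with columns `name`, `sampling_rate` (Hz), `units`.
#' @export
channel_specs <- function() {
  data.frame(
    name = c("ecg", "skna", "bp", "temperature"),
    sampling_rate = c(10000, 10000, 1 / 30, 2),
    units = c("mV", "uV", "mmHg", "degC"),
    stringsAsFactors = FALSE
  )
}

#' Stimulus annotation
#'
#' One stimulus epoch within a recording: colorectal distension (`crd`, the
#' AD trigger), acoustic startle, tail pinch, or an explicit non-stimulus
#' epoch. Stimuli last one minute and are followed by a recovery period
#' during which no other stimulus may start.
#'
#' @param kind one of `"crd"`, `"startle"`, `"tail_pinch"`, `"none"`.
#' @param onset_s onset in seconds from recording start (>= 0).
#' @param duration_s stimulus duration in seconds (default 60).
#' @param recovery_s recovery period in seconds (default 600).
#' @return list of class `stim_annotation`.
#' @export
stim_annotation <- function(kind, onset_s, duration_s = 60, recovery_s = 600) {
  kind <- match.arg(kind, c("crd", "startle", "tail_pinch", "none"))
  if (!is.numeric(onset_s) || onset_s < 0)
    stop("onset_s must be >= 0", call. = FALSE)
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be > 0", call. = FALSE)
  if (!is.numeric(recovery_s) || recovery_s < 0)
    stop("recovery_s must be >= 0", call. = FALSE)
  structure(list(kind = kind, onset_s = as.numeric(onset_s),
                 duration_s = as.numeric(duration_s),
                 recovery_s = as.numeric(recovery_s)),
            class = "stim_annotation")
}

validate_schedule <- function(schedule) {
  if (length(schedule) == 0L) return(invisible(schedule))
  for (a in schedule) {
    if (!inherits(a, "stim_annotation"))
      stop("schedule entries must be stim_annotation objects", call. = FALSE)
  }
  on <- vapply(schedule, `[[`, numeric(1), "onset_s")
  en <- on + vapply(schedule, `[[`, numeric(1), "duration_s") +
    vapply(schedule, `[[`, numeric(1), "recovery_s")
  o <- order(on)
  on <- on[o]; en <- en[o]
  if (length(on) > 1L && any(on[-1L] < en[-length(en)]))
    stop("stimulus annotations overlap (including recovery periods)",
         call. = FALSE)
  invisible(schedule)
}

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic cohort: a spinal-cord-injured
#' rat cohort tested on post-injury days 7, 9, 11 and 14, three colorectal
#' distensions per day plus randomized startle and tail-pinch trials. Effect
#' directions follow the AD signature: a sympathetic surge (burst rate and
#' iskNA rise) at trigger onset, a vagal surge (RMSSD/pnn5 rise) lagged by
#' `vagal_lag_s`, bradycardia, and an SBP ramp of `sbp_delta["ad"]` mmHg.
#' About `ad_success_prob` of distensions cross the blood-pressure thresholds.
#'
#' @param seed integer master seed; all randomness derives from it.
#' @param n_animals number of animals in the cohort.
#' @param trial_days post-injury testing days.
#' @param baseline_hr_bpm,baseline_hr_sd animal-level baseline heart rate
#'   distribution (beats per minute).
#' @param burst_rate_base baseline sympathetic burst rate, bursts/min.
#' @param burst_rate_ad burst rate during the initial AD sympathetic surge,
#'   bursts/min (tapers to a quarter over the second half of the stimulus).
#' @param burst_rate_startle burst rate during acoustic startle, bursts/min.
#' @param iskna_gain_tailpinch multiplicative burst-amplitude factor for tail
#'   pinch (burst rate itself is unchanged).
#' @param vagal_lag_s delay from sympathetic-surge onset to vagal-surge onset.
#' @param ad_bradycardia_frac fractional NN-interval lengthening (heart-rate
#'   drop) during the AD vagal phase.
#' @param startle_tachycardia_frac fractional heart-rate rise during startle.
#' @param sbp_delta named numeric: peak SBP rise (mmHg) per stimulus kind.
#' @param noise_sd_ecg ECG additive noise SD, mV.
#' @param noise_sd_skna skNA broadband noise SD, uV.
#' @param ad_success_prob probability a distension crosses both BP thresholds.
#' @param baseline_s pre-stimulus baseline length per recording, seconds.
#' @param nn_sd_ms,nn_ar AR(1) beat-to-beat NN variability: innovation SD (ms)
#'   and autoregressive coefficient.
#' @param vagal_var_mult,startle_var_mult,tailpinch_var_mult multipliers on NN
#'   variability during the AD vagal phase, startle, and tail pinch (vagal
#'   inhibition) respectively.
#' @param burst_amp_uv mean burst packet amplitude, uV.
#' @param burst_dur_range burst packet duration range, seconds.
#' @param bp_noise_sd tail-cuff measurement noise SD, mmHg.
#' @param vagal_extend_s how far past stimulus offset the vagal phase persists.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_animals = 13L,
                       trial_days = c(7L, 9L, 11L, 14L),
                       baseline_hr_bpm = 400,
                       baseline_hr_sd = 20,
                       burst_rate_base = 2,
                       burst_rate_ad = 20,
                       burst_rate_startle = 15,
                       iskna_gain_tailpinch = 2.0,
                       vagal_lag_s = 30,
                       ad_bradycardia_frac = 0.15,
                       startle_tachycardia_frac = 0.10,
                       sbp_delta = c(ad = 20, startle = 7, tail_pinch = 5,
                                     none = 0),
                       noise_sd_ecg = 0.05,
                       noise_sd_skna = 1.0,
                       ad_success_prob = 0.7,
                       baseline_s = 120,
                       nn_sd_ms = 3,
                       nn_ar = 0.5,
                       vagal_var_mult = 3,
                       startle_var_mult = 2,
                       tailpinch_var_mult = 0.5,
                       burst_amp_uv = 5,
                       burst_dur_range = c(0.1, 1.0),
                       bp_noise_sd = 1.5,
                       vagal_extend_s = 60) {
  rates <- c(burst_rate_base, burst_rate_ad, burst_rate_startle)
  if (any(rates < 0)) stop("burst rates must be nonnegative", call. = FALSE)
  stopifnot_scalar_prob(ad_success_prob, "ad_success_prob")
  if (any(sbp_delta < 0)) stop("sbp_delta entries must be >= 0", call. = FALSE)
  cfg <- list(
    seed = as.integer(seed), n_animals = as.integer(n_animals),
    trial_days = as.integer(trial_days),
    baseline_hr_bpm = baseline_hr_bpm, baseline_hr_sd = baseline_hr_sd,
    burst_rate_base = burst_rate_base, burst_rate_ad = burst_rate_ad,
    burst_rate_startle = burst_rate_startle,
    iskna_gain_tailpinch = iskna_gain_tailpinch,
    vagal_lag_s = vagal_lag_s, ad_bradycardia_frac = ad_bradycardia_frac,
    startle_tachycardia_frac = startle_tachycardia_frac,
    sbp_delta = sbp_delta, noise_sd_ecg = noise_sd_ecg,
    noise_sd_skna = noise_sd_skna, ad_success_prob = ad_success_prob,
    baseline_s = baseline_s, nn_sd_ms = nn_sd_ms, nn_ar = nn_ar,
    vagal_var_mult = vagal_var_mult, startle_var_mult = startle_var_mult,
    tailpinch_var_mult = tailpinch_var_mult, burst_amp_uv = burst_amp_uv,
    burst_dur_range = burst_dur_range, bp_noise_sd = bp_noise_sd,
    vagal_extend_s = vagal_extend_s
  )
  structure(cfg, class = "sim_config")
}

config_hash <- function(config) {
  # stable content hash of the flattened config (text-level, no binary deps)
  s <- paste(names(unlist(config)), unlist(config), sep = "=", collapse = ";")
  v <- utf8ToInt(s)
  h <- 5381
  for (chunk in split(v, ceiling(seq_along(v) / 4096))) {
    h <- sum(c(h, chunk * seq_along(chunk))) %% 2147483647
  }
  sprintf("%010d", as.integer(h))
}

animal_key <- function(animal_id) {
  sum(utf8ToInt(as.character(animal_id))) %% 100003
}

# ---- truth generation ------------------------------------------------------

# NN-interval segments: piecewise mean multiplier and variability multiplier
# (with linear ramp for the vagal phase, whose surge builds toward the end
# of the AD episode).
nn_segments <- function(config, schedule, truth_ann) {
  segs <- list()
  for (i in seq_along(schedule)) {
    a <- schedule[[i]]
    ta <- truth_ann[[i]]
    if (a$kind == "crd") {
      # vagal surge builds from vagal_lag_s after onset toward the end of
      # the episode, then decays back over the first vagal_extend_s of
      # recovery (HR and HRV return to pre-AD levels after the stimulus)
      vstart <- a$onset_s + config$vagal_lag_s
      voff <- a$onset_s + a$duration_s
      scale <- if (ta$is_ad) 1 else 0.3  # failed trials: attenuated vagal phase
      vmax <- 1 + (config$vagal_var_mult - 1) * scale
      mmax <- 1 + config$ad_bradycardia_frac * scale
      segs[[length(segs) + 1L]] <- list(
        start = vstart, end = voff,
        mean_mult = mmax, var0 = 1, var1 = vmax)
      segs[[length(segs) + 1L]] <- list(
        start = voff, end = voff + config$vagal_extend_s,
        mean_mult = mmax, var0 = vmax, var1 = 1)
    } else if (a$kind == "startle") {
      segs[[length(segs) + 1L]] <- list(
        start = a$onset_s, end = a$onset_s + a$duration_s,
        mean_mult = 1 - config$startle_tachycardia_frac,
        var0 = config$startle_var_mult, var1 = config$startle_var_mult)
    } else if (a$kind == "tail_pinch") {
      segs[[length(segs) + 1L]] <- list(
        start = a$onset_s, end = a$onset_s + a$duration_s,
        mean_mult = 1,
        var0 = config$tailpinch_var_mult, var1 = config$tailpinch_var_mult)
    }
  }
  segs
}

seg_lookup <- function(t, segs, field_default = 1) {
  mm <- rep(field_default, length(t))
  vv <- rep(1, length(t))
  for (s in segs) {
    in_seg <- t >= s$start & t < s$end
    if (any(in_seg)) {
      mm[in_seg] <- s$mean_mult
      frac <- (t[in_seg] - s$start) / (s$end - s$start)
      vv[in_seg] <- s$var0 + (s$var1 - s$var0) * frac
    }
  }
  list(mean_mult = mm, var_mult = vv)
}

gen_beats <- function(duration_s, nn0_ms, segs, config, seed) {
  with_seed(seed, {
    n_est <- ceiling(duration_s / (nn0_ms / 1000) * 1.4) + 50L
    innov <- rnorm(n_est, 0, config$nn_sd_ms * sqrt(1 - config$nn_ar^2))
    e <- as.numeric(stats::filter(innov, config$nn_ar, method = "recursive"))
    # provisional times at baseline mean locate each beat's segment; a second
    # pass re-evaluates multipliers at the realized times
    nn <- rep(nn0_ms, n_est)
    for (pass in 1:2) {
      t_end <- cumsum(nn) / 1000
      lk <- seg_lookup(t_end, segs)
      nn <- pmax(nn0_ms * 0.4, nn0_ms * lk$mean_mult + e * lk$var_mult)
    }
    t_end <- cumsum(nn) / 1000
    keep <- t_end < duration_s
    t_end[keep]
  })
}

gen_bursts <- function(duration_s, config, schedule, seed) {
  # piecewise-constant Poisson rate (bursts/min) with kind-specific surges;
  # the AD surge is front-loaded: full rate for the first half of the
  # stimulus, a quarter rate for the second half
  pieces <- data.frame(start = 0, end = duration_s,
                       rate = config$burst_rate_base, gain = 1)
  for (a in schedule) {
    if (a$kind == "crd") {
      half <- a$onset_s + a$duration_s / 2
      pieces <- rbind(pieces,
        data.frame(start = a$onset_s, end = half,
                   rate = config$burst_rate_ad, gain = 1),
        data.frame(start = half, end = a$onset_s + a$duration_s,
                   rate = config$burst_rate_ad / 4, gain = 1))
    } else if (a$kind == "startle") {
      pieces <- rbind(pieces,
        data.frame(start = a$onset_s, end = a$onset_s + a$duration_s,
                   rate = config$burst_rate_startle, gain = 1))
    } else if (a$kind == "tail_pinch") {
      pieces <- rbind(pieces,
        data.frame(start = a$onset_s, end = a$onset_s + a$duration_s,
                   rate = config$burst_rate_base,
                   gain = config$iskna_gain_tailpinch))
    }
  }
  stim_start <- vapply(schedule, `[[`, numeric(1), "onset_s")
  stim_end <- stim_start + vapply(schedule, `[[`, numeric(1), "duration_s")
  in_stimulus <- function(t) {
    hit <- rep(FALSE, length(t))
    for (j in seq_along(stim_start))
      hit <- hit | (t >= stim_start[j] & t < stim_end[j])
    hit
  }
  with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(pieces))) {
      p <- pieces[i, ]
      len <- p$end - p$start
      k <- rpois(1L, p$rate / 60 * len)
      if (k == 0L) next
      st <- sort(p$start + runif(k) * len)
      if (i == 1L && length(stim_start) > 0L) {
        # the baseline piece spans the recording; stimulus epochs are governed
        # by their own pieces, so baseline draws landing there are dropped
        st <- st[!in_stimulus(st)]
        if (length(st) == 0L) next
      }
      k <- length(st)
      dur <- runif(k, config$burst_dur_range[1], config$burst_dur_range[2])
      amp <- config$burst_amp_uv * p$gain * exp(rnorm(k, 0, 0.25))
      out[[length(out) + 1L]] <- data.frame(start = st, dur = dur, amp = amp)
    }
    if (length(out) == 0L)
      return(data.frame(start = numeric(0), end = numeric(0),
                        amp = numeric(0)))
    b <- do.call(rbind, out)
    b <- b[order(b$start), , drop = FALSE]
    # enforce separation so bursts remain resolvable events: drop any burst
    # starting before the previous accepted burst's end + 150 ms
    keep <- logical(nrow(b)); last_end <- -Inf
    for (i in seq_len(nrow(b))) {
      if (b$start[i] >= last_end + 0.15) {
        keep[i] <- TRUE
        last_end <- b$start[i] + b$dur[i]
      }
    }
    b <- b[keep, , drop = FALSE]
    b$end <- pmin(b$start + b$dur, duration_s)
    b <- b[b$start < duration_s, c("start", "end", "amp")]
    rownames(b) <- NULL
    b
  })
}

gen_bp_truth <- function(duration_s, config, schedule, truth_ann, seed) {
  with_seed(seed, {
    sbp0 <- rnorm(1, 120, 5)
    dbp0 <- rnorm(1, 85, 4)
    times <- seq(0, duration_s, by = 30)
    sbp <- rep(sbp0, length(times))
    dbp <- rep(dbp0, length(times))
    tau <- 90  # post-stimulus decay constant, s
    for (i in seq_along(schedule)) {
      a <- schedule[[i]]
      ta <- truth_ann[[i]]
      if (ta$delta_sbp == 0) next
      rel <- times - a$onset_s
      shape <- numeric(length(times))
      ramp <- rel >= 0 & rel <= a$duration_s
      shape[ramp] <- rel[ramp] / a$duration_s
      post <- rel > a$duration_s
      shape[post] <- exp(-(rel[post] - a$duration_s) / tau)
      sbp <- sbp + ta$delta_sbp * shape
      dbp <- dbp + ta$delta_dbp * shape
    }
    sbp_m <- sbp + rnorm(length(times), 0, config$bp_noise_sd)
    dbp_m <- dbp + rnorm(length(times), 0, config$bp_noise_sd)
    map_m <- dbp_m + (sbp_m - dbp_m) / 3
    list(
      measured = data.frame(time_s = times, sbp = sbp_m, dbp = dbp_m,
                            map = map_m),
      clean = data.frame(time_s = times, sbp = sbp, dbp = dbp,
                         map = dbp + (sbp - dbp) / 3),
      sbp0 = sbp0, dbp0 = dbp0)
  })
}

draw_annotation_truth <- function(config, schedule, seed) {
  with_seed(seed, {
    lapply(schedule, function(a) {
      kind <- a$kind
      is_ad <- FALSE
      if (kind == "crd") {
        is_ad <- runif(1) < config$ad_success_prob
        if (is_ad) {
          dsbp <- max(rnorm(1, config$sbp_delta[["ad"]], 2.5), 15.5)
        } else {
          # failed distension: sympathetic surge retained, BP ramp attenuated
          # below both thresholds
          dsbp <- runif(1, 4, 12)
        }
        ddbp <- 0.70 * dsbp
      } else if (kind == "startle") {
        dsbp <- max(rnorm(1, config$sbp_delta[["startle"]], 1.5), 0)
        ddbp <- 0.14 * dsbp
      } else if (kind == "tail_pinch") {
        dsbp <- max(rnorm(1, config$sbp_delta[["tail_pinch"]], 1.5), 0)
        ddbp <- 0.07 * dsbp
      } else {
        dsbp <- 0; ddbp <- 0
      }
      dmap <- ddbp + (dsbp - ddbp) / 3
      list(kind = kind, onset_s = a$onset_s, duration_s = a$duration_s,
           is_ad = is_ad, delta_sbp = dsbp, delta_dbp = ddbp,
           delta_map = dmap,
           symp_onset_s = if (kind == "none") NA_real_ else a$onset_s,
           vagal_onset_s = if (kind == "crd")
             a$onset_s + config$vagal_lag_s else NA_real_)
    })
  })
}

#' Simulate one multi-channel recording
#'
#' Generates ground truth (beat times from an AR(1) NN-interval process,
#' Poisson burst events, a blood-pressure curve) for one animal-day under the
#' given stimulus schedule, then renders the 10 kHz ECG/skNA waveforms unless
#' `render = FALSE` (event-level recordings keep the BP and temperature
#' channels plus full truth, and can be materialized later with
#' [render_recording()]).
#'
#' @param config a [sim_config()].
#' @param animal_id animal identifier.
#' @param trial_day post-injury day index.
#' @param schedule list of [stim_annotation()]; must be non-overlapping
#'   including recovery periods.
#' @param duration_s optional recording length; defaults to covering the
#'   schedule plus recovery, or `baseline_s` for an empty schedule.
#' @param render logical; render the 10 kHz waveform channels.
#' @return list of class `ad_recording` with elements `animal_id`,
#'   `trial_day`, `channels`, `specs`, `annotations`, `truth`, `config_hash`.
#' @export
simulate_recording <- function(config, animal_id = "rat01", trial_day = 7L,
                               schedule = list(), duration_s = NULL,
                               render = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  validate_schedule(schedule)
  if (is.null(duration_s)) {
    duration_s <- if (length(schedule) == 0L) config$baseline_s else
      max(vapply(schedule, function(a) a$onset_s + a$duration_s +
                   min(a$recovery_s, 300), numeric(1)))
  }
  akey <- animal_key(animal_id)
  seed_animal <- derive_seed(config$seed, akey)
  seed_rec <- derive_seed(config$seed, akey, trial_day)

  hr <- with_seed(seed_animal,
                  rnorm(1, config$baseline_hr_bpm, config$baseline_hr_sd))
  nn0 <- 60000 / hr

  truth_ann <- draw_annotation_truth(config, schedule,
                                     derive_seed(seed_rec, 1))
  segs <- nn_segments(config, schedule, truth_ann)
  beats <- gen_beats(duration_s, nn0, segs, config, derive_seed(seed_rec, 2))
  bursts <- gen_bursts(duration_s, config, schedule, derive_seed(seed_rec, 3))
  bp <- gen_bp_truth(duration_s, config, schedule, truth_ann,
                     derive_seed(seed_rec, 4))

  temp <- with_seed(derive_seed(seed_rec, 5), {
    n <- floor(duration_s * 2)
    e <- as.numeric(stats::filter(rnorm(n, 0, 0.02), 0.995,
                                  method = "recursive"))
    data.frame(time_s = (seq_len(n) - 1) / 2, value = 34 + e)
  })

  rec <- structure(list(
    animal_id = animal_id, trial_day = as.integer(trial_day),
    duration_s = duration_s,
    channels = list(ecg = NULL, skna = NULL, bp = bp$measured,
                    temperature = temp),
    specs = channel_specs(),
    annotations = schedule,
    truth = list(beats = beats, bursts = bursts, bp = bp$clean,
                 baseline_hr_bpm = hr, nn0_ms = nn0,
                 sbp0 = bp$sbp0, dbp0 = bp$dbp0,
                 annotations = truth_ann),
    seed = seed_rec,
    config_hash = config_hash(config)
  ), class = "ad_recording")
  if (render) rec <- render_recording(rec, config)
  rec
}

#' @export
print.ad_recording <- function(x, ...) {
  cat(sprintf("<ad_recording> %s day %d, %.0f s, %d beats, %d bursts, %d stimuli%s\n",
              x$animal_id, x$trial_day, x$duration_s, length(x$truth$beats),
              nrow(x$truth$bursts), length(x$annotations),
              if (is.null(x$channels$ecg)) " (event-level)" else ""))
  invisible(x)
}

#' Simulate the full cohort
#'
#' One recording per animal x trial day. Each recording's schedule holds three
#' colorectal distensions with 10-minute recoveries plus one acoustic-startle
#' and one tail-pinch trial, in a seeded randomized order after a
#' `baseline_s` lead-in.
#'
#' @param config a [sim_config()].
#' @param render render 10 kHz waveforms (default `FALSE`: event-level truth
#'   plus BP/temperature channels, suitable for cohort-scale analysis).
#' @return list of `ad_recording` objects.
#' @export
simulate_cohort <- function(config, render = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  recs <- list()
  for (i in seq_len(config$n_animals)) {
    animal_id <- sprintf("rat%02d", i)
    for (day in config$trial_days) {
      kinds <- c("crd", "crd", "crd", "startle", "tail_pinch")
      ord <- with_seed(derive_seed(config$seed, animal_key(animal_id),
                                   day, 99), sample.int(5L))
      kinds <- kinds[ord]
      onsets <- config$baseline_s + (seq_along(kinds) - 1) * 660
      schedule <- mapply(function(k, o) stim_annotation(k, o),
                         kinds, onsets, SIMPLIFY = FALSE)
      names(schedule) <- NULL
      recs[[length(recs) + 1L]] <-
        simulate_recording(config, animal_id, day, schedule, render = render)
    }
  }
  recs
}

# ---- waveform rendering ----------------------------------------------------

qrs_template <- function(fs) {
  # stylized rat PQRST at 10 kHz; R apex exactly at offset 0
  t <- seq(-0.05, 0.08, by = 1 / fs)
  g <- function(a, mu, s) a * exp(-((t - mu)^2) / (2 * s^2))
  w <- g(0.08, -0.035, 0.005) +  # P
    g(-0.15, -0.010, 0.003) +    # Q
    g(1.00, 0.000, 0.004) +      # R
    g(-0.25, 0.010, 0.003) +     # S
    g(0.15, 0.045, 0.012)        # T
  list(w = w, center = which.max(w), t = t)
}

#' Render a synthetic ECG waveform from beat times
#'
#' Places a stylized PQRST template at each beat time (R apex on the beat
#' sample) over slow baseline wander plus white noise.
#'
#' @param beat_times R-peak times, seconds.
#' @param duration_s signal length, seconds.
#' @param fs sampling rate, Hz.
#' @param noise_sd additive noise SD, mV.
#' @param seed integer seed.
#' @return numeric vector of `duration_s * fs` samples (mV).
#' @export
render_ecg <- function(beat_times, duration_s, fs = 10000, noise_sd = 0.05,
                       seed = 1L) {
  n <- floor(duration_s * fs)
  tpl <- qrs_template(fs)
  x <- with_seed(seed, rnorm(n, 0, noise_sd))
  tt <- (seq_len(n) - 1) / fs
  x <- x + 0.05 * sin(2 * pi * 0.5 * tt + 0.3)
  bi <- round(beat_times * fs) + 1L
  for (k in seq_along(tpl$w)) {
    idx <- bi + (k - tpl$center)
    ok <- idx >= 1L & idx <= n
    if (any(ok)) x[idx[ok]] <- x[idx[ok]] + tpl$w[k]
  }
  x
}

#' Render a synthetic skNA waveform from burst intervals
#'
#' Broadband Gaussian noise plus amplitude-modulated band-limited (500-1000
#' Hz) noise packets with Hann envelopes over each burst interval.
#'
#' @param bursts data.frame with columns `start`, `end`, `amp` (uV).
#' @param duration_s signal length, seconds.
#' @param fs sampling rate, Hz.
#' @param noise_sd broadband noise SD, uV.
#' @param seed integer seed.
#' @return numeric vector of `duration_s * fs` samples (uV).
#' @export
render_skna <- function(bursts, duration_s, fs = 10000, noise_sd = 1.0,
                        seed = 1L) {
  n <- floor(duration_s * fs)
  bf <- signal::butter(4, c(500, 1000) / (fs / 2), type = "pass")
  with_seed(seed, {
    x <- rnorm(n, 0, noise_sd)
    if (!is.null(bursts) && nrow(bursts) > 0L) {
      for (i in seq_len(nrow(bursts))) {
        i0 <- max(1L, round(bursts$start[i] * fs) + 1L)
        i1 <- min(n, round(bursts$end[i] * fs))
        m <- i1 - i0 + 1L
        if (m < 16L) next
        carrier <- as.numeric(signal::filtfilt(bf, rnorm(m + 400L)))
        carrier <- carrier[201:(200 + m)]
        carrier <- carrier / max(sd(carrier), 1e-12)
        env <- 0.5 * (1 - cos(2 * pi * seq_len(m) / (m + 1)))
        x[i0:i1] <- x[i0:i1] + bursts$amp[i] * env * carrier
      }
    }
    x
  })
}

#' Materialize the 10 kHz waveform channels of an event-level recording
#'
#' @param rec an `ad_recording` from [simulate_recording()] or
#'   [simulate_cohort()].
#' @param config the [sim_config()] used to create it.
#' @return the recording with `channels$ecg` and `channels$skna` filled.
#' @export
render_recording <- function(rec, config) {
  stopifnot(inherits(rec, "ad_recording"))
  rec$channels$ecg <- render_ecg(rec$truth$beats, rec$duration_s,
                                 fs = 10000, noise_sd = config$noise_sd_ecg,
                                 seed = derive_seed(rec$seed, 6))
  rec$channels$skna <- render_skna(rec$truth$bursts, rec$duration_s,
                                   fs = 10000,
                                   noise_sd = config$noise_sd_skna,
                                   seed = derive_seed(rec$seed, 7))
  rec
}

# ---- truth-derived series (event-level analysis path) ----------------------

#' Beat series from simulator ground truth
#'
#' Builds the artifact-cleaned beat series directly from the generator's true
#' beat times, bypassing waveform rendering and R-peak detection. Used for
#' cohort-scale analysis where rendering hours of 10 kHz signal is
#' unnecessary; the detector path is validated against this truth on short
#' rendered recordings.
#'
#' @param rec an `ad_recording`.
#' @return a `beat_series` (see [detect_r_peaks()]).
#' @export
truth_beat_series <- function(rec) {
  stopifnot(inherits(rec, "ad_recording"))
  clean_nn(new_beat_series(rec$truth$beats))
}

#' Integrated-skNA series from simulator ground truth
#'
#' Reconstructs the iskNA envelope analytically at a coarse rate: the
#' rectified-noise floor plus each burst's Hann-envelope contribution, with
#' truth burst intervals attached. `sqrt(2/pi)` is the folded-normal mean of
#' unit Gaussian noise; the in-band share of the broadband noise floor is
#' `sqrt(500/5000)` for the 500-1000 Hz band at 10 kHz.
#'
#' @param rec an `ad_recording`.
#' @param config the [sim_config()] used to create it.
#' @param rate output sampling rate of the envelope, Hz.
#' @return a `skna_derived` object (see [integrate_skna()]).
#' @export
truth_skna_series <- function(rec, config, rate = 20) {
  stopifnot(inherits(rec, "ad_recording"))
  n <- floor(rec$duration_s * rate)
  tt <- (seq_len(n) - 0.5) / rate
  base_mu <- config$noise_sd_skna * sqrt(500 / 5000) * sqrt(2 / pi)
  iskna <- rep(base_mu, n)
  b <- rec$truth$bursts
  if (nrow(b) > 0L) {
    for (i in seq_len(nrow(b))) {
      inb <- tt >= b$start[i] & tt < b$end[i]
      if (any(inb)) {
        frac <- (tt[inb] - b$start[i]) / (b$end[i] - b$start[i])
        env <- 0.5 * (1 - cos(2 * pi * frac))
        iskna[inb] <- iskna[inb] + b$amp[i] * env * sqrt(2 / pi)
      }
    }
  }
  jit <- with_seed(derive_seed(rec$seed, 8),
                   rnorm(n, 0, base_mu * 0.05))
  iskna <- pmax(iskna + jit, 0)
  new_skna_derived(filtered = NULL, rectified = NULL, iskna = iskna,
                   rate = rate, baseline_mu = base_mu,
                   baseline_sigma = base_mu * 0.05,
                   bursts = data.frame(start_s = b$start, end_s = b$end,
                                       peak_uv = b$amp * sqrt(2 / pi) +
                                         base_mu))
}
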