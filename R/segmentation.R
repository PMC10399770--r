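## pulse segmentation: envelope extraction, pulse delimitation, grouping of
## pulses into Single / Serial Click events

bandpass_samples <- function(x, sample_rate, band = c(500, 10000)) {
  if (is.null(band)) return(x)
  nyq <- sample_rate / 2
  lo <- band[1L] / nyq
  hi <- min(band[2L], 0.95 * nyq) / nyq
  if (lo <= 0 || lo >= hi) return(x)
  bf <- signal::butter(4, c(lo, hi), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Amplitude envelope of a recording window
#'
#' Magnitude of the analytic signal after an optional band-pass
#' (500–10,000 Hz by default, the bandwidth of the click-type sounds),
#' smoothed by a centered moving average. The envelope of a pure in-band
#' tone is flat (within a few percent away from the edges) and scales
#' linearly with the signal.
#'
#' @param rec a [recording].
#' @param window optional `c(start, end)` span in seconds; default whole
#'   recording.
#' @param smoothing moving-average width in seconds (default 0.2 ms).
#' @param band band-pass edges in Hz, or `NULL` to skip filtering.
#' @return Numeric non-negative envelope, one value per window sample.
#' @export
extract_envelope <- function(rec, window = NULL, smoothing = 2e-4,
                             band = c(500, 10000)) {
  if (smoothing < 0)
    stop_cavesong("smoothing must be >= 0", "cavesong_parameter_error")
  fs <- rec$sample_rate
  n <- length(rec$samples)
  if (is.null(window)) {
    i0 <- 1L; i1 <- n
  } else {
    i0 <- as.integer(floor(window[1L] * fs)) + 1L
    i1 <- as.integer(ceiling(window[2L] * fs))
    if (i0 < 1L || i1 > n || i1 < i0)
      stop_cavesong("window outside recording", "cavesong_bounds_error")
  }
  x <- rec$samples[i0:i1]
  x <- bandpass_samples(x, fs, band)
  env <- analytic_magnitude(x)
  if (smoothing > 0) env <- moving_average(env, round(smoothing * fs))
  env
}

#' Delimit pulses around a detection
#'
#' Extracts the envelope in a window around a detected event and returns
#' the maximal runs where the envelope stays at or above
#' `boundary_fraction` of the local peak; runs separated by less than
#' `merge_gap` are merged. An empty list is returned when nothing rises
#' above the local noise floor.
#'
#' @param rec a [recording].
#' @param around detection onset time in seconds (e.g. a row of a
#'   `detections` data frame).
#' @param boundary_fraction fraction of the local envelope peak delimiting
#'   a pulse (default 0.1, i.e. -20 dB).
#' @param merge_gap runs closer than this (s) are merged (default 1 ms).
#' @param window `c(before, after)` seconds around `around` to analyze;
#'   the default covers a full serial click train.
#' @param smoothing,band passed to [extract_envelope()].
#' @param noise_factor runs are discarded unless their envelope peak
#'   exceeds `noise_factor` times the median envelope (the local noise
#'   floor).
#' @param noise_mult the run threshold is raised to `noise_mult` times the
#'   median envelope when the nominal `boundary_fraction` level would sit
#'   inside the noise.
#' @param extrapolate when the run threshold had to be raised above the
#'   nominal boundary level, extend each pulse offset down to the nominal
#'   level by extrapolating the fitted envelope decay slope (the standard
#'   decay-time extrapolation used when a tail is buried in noise).
#' @return A data frame of class `pulses` with columns `onset`, `offset`,
#'   `peak_amplitude`, `peak_time` (seconds in the source recording).
#' @export
find_pulses <- function(rec, around, boundary_fraction = 0.1,
                        merge_gap = 1e-3, window = c(0.02, 0.35),
                        smoothing = 2e-4, band = c(500, 10000),
                        noise_factor = 4, noise_mult = 3,
                        extrapolate = TRUE) {
  if (boundary_fraction <= 0 || boundary_fraction >= 1)
    stop_cavesong("boundary_fraction must be in (0, 1)",
                  "cavesong_parameter_error")
  if (is.list(around) || is.data.frame(around)) around <- around$time_s[1L]
  fs <- rec$sample_rate
  t0 <- max(0, around - window[1L])
  t1 <- min(duration(rec), around + window[2L])
  i0 <- as.integer(floor(t0 * fs)) + 1L
  i1 <- as.integer(ceiling(t1 * fs))
  t0 <- (i0 - 1L) / fs
  xb <- bandpass_samples(rec$samples[i0:i1], fs, band)
  env <- analytic_magnitude(xb)
  if (smoothing > 0) env <- moving_average(env, round(smoothing * fs))
  peak <- max(env)
  med <- stats::median(env)
  floor_lvl <- max(noise_factor * med, 1e-8)
  if (peak < floor_lvl) return(empty_pulses())
  thr_nom <- boundary_fraction * peak
  thr <- max(thr_nom, noise_mult * med)
  above <- env >= thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  on <- starts[runs$values]
  off <- ends[runs$values]
  if (!length(on)) return(empty_pulses())
  # merge runs separated by < merge_gap
  gap_smp <- merge_gap * fs
  keep_on <- on[1L]; keep_off <- off[1L]
  if (length(on) > 1L) {
    for (i in 2L:length(on)) {
      if (on[i] - keep_off[length(keep_off)] < gap_smp) {
        keep_off[length(keep_off)] <- off[i]
      } else {
        keep_on <- c(keep_on, on[i]); keep_off <- c(keep_off, off[i])
      }
    }
  }
  # drop residual runs that never clear the noise floor
  pk_amp <- numeric(length(keep_on)); pk_t <- numeric(length(keep_on))
  on_s <- numeric(length(keep_on)); off_s <- numeric(length(keep_on))
  ok <- logical(length(keep_on))
  noise_limited <- extrapolate && thr > thr_nom * (1 + 1e-9)
  for (i in seq_along(keep_on)) {
    seg <- env[keep_on[i]:keep_off[i]]
    pk_amp[i] <- max(seg)
    pk_idx <- keep_on[i] + which.max(seg) - 1L
    pk_t[i] <- t0 + (pk_idx - 1L) / fs
    ok[i] <- pk_amp[i] >= floor_lvl
    on_s[i] <- t0 + (keep_on[i] - 1L) / fs
    off_s[i] <- t0 + keep_off[i] / fs
    if (extrapolate && ok[i]) {
      # Near the -20 dB level the tail envelope is lifted by noise, which
      # delays the raw crossing (increasingly so for slower decays), and a
      # raised run threshold hides the crossing entirely. In both regimes
      # the offset is therefore read off a decay model: the slope is
      # fitted above the geometric mean of threshold and peak (the lower
      # tail is noise-flattened and would bias the slope) and the thr_nom
      # crossing of the model replaces the raw one, capped by the raw
      # crossing plus a few run widths and by the next run's onset.
      run_w <- (keep_off[i] - keep_on[i] + 1L) / fs
      thr_hi <- sqrt(thr * pk_amp[i])
      tail_idx <- pk_idx:keep_off[i]
      tail_idx <- tail_idx[env[tail_idx] >= thr_hi]
      if (length(tail_idx) >= 3L && keep_off[i] - pk_idx >= 3L) {
        tt <- (tail_idx - pk_idx) / fs
        fit <- stats::lm.fit(cbind(1, tt), log(env[tail_idx]))
        slope <- fit$coefficients[2L]
        if (is.finite(slope) && slope < 0) {
          off_model <- pk_t[i] + log(pk_amp[i] / thr_nom) / -slope
          cap <- off_s[i] + 3 * run_w
          if (i < length(keep_on))
            cap <- min(cap, t0 + (keep_on[i + 1L] - 1L) / fs)
          off_s[i] <- min(max(off_model, pk_t[i]), cap)
        }
      }
      if (noise_limited) {
        # Onset: a sharp attack carries an analytic-envelope pre-tail of
        # magnitude ~ peak / (pi * omega * dt); extend the onset from the
        # crossing at thr down to the thr_nom crossing of that model, with
        # the carrier frequency estimated from zero crossings in the run.
        zc <- sum(diff(sign(xb[keep_on[i]:keep_off[i]])) != 0)
        f_hat <- zc / (2 * run_w)
        if (is.finite(f_hat) && f_hat > 0) {
          k <- pk_amp[i] / (pi * 2 * pi * f_hat)
          ext_on <- min(k * (1 / thr_nom - 1 / thr), 1 / f_hat)
          if (i > 1L)
            ext_on <- min(ext_on, (keep_on[i] - 1L - keep_off[i - 1L]) / fs)
          on_s[i] <- on_s[i] - max(0, ext_on)
        }
      }
    }
  }
  res <- data.frame(onset = on_s,
                    offset = off_s,
                    peak_amplitude = pk_amp, peak_time = pk_t)
  res <- res[ok, , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("pulses", "data.frame"))
}

empty_pulses <- function() {
  structure(data.frame(onset = numeric(0), offset = numeric(0),
                       peak_amplitude = numeric(0), peak_time = numeric(0)),
            class = c("pulses", "data.frame"))
}

# union of pulses found around several detections, with overlapping
# duplicates collapsed (a serial train triggers several detections)
merge_pulse_sets <- function(pulse_sets) {
  all <- do.call(rbind, lapply(pulse_sets, as.data.frame))
  if (is.null(all) || nrow(all) == 0L) return(empty_pulses())
  all <- all[order(all$onset), , drop = FALSE]
  keep <- rep(TRUE, nrow(all))
  last_off <- all$offset[1L]
  for (i in seq_len(nrow(all))[-1L]) {
    if (all$onset[i] < last_off - 1e-9) keep[i] <- FALSE
    else last_off <- all$offset[i]
  }
  res <- all[keep, , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("pulses", "data.frame"))
}

#' Group pulses into Single and Serial Click events
#'
#' Applies the click typology rule: consecutive pulses whose onset-to-onset
#' spacing is at most `serial_gap` form one serial event; an ungrouped
#' pulse is a Single Click if its duration is below `single_max_duration`
#' (20 ms) and the nearest neighbouring pulse is more than `isolation_gap`
#' (1 s) away. Pulses satisfying neither rule are emitted as events of type
#' `"unclassified"`. Every input pulse appears in exactly one output event.
#'
#' @param pulses a `pulses` data frame (time-sorted).
#' @param single_max_duration maximum Single-Click duration in seconds
#'   (default 0.020).
#' @param isolation_gap minimum isolation of a Single Click in seconds
#'   (default 1).
#' @param serial_gap maximum onset-to-onset spacing within a serial train
#'   in seconds (default 0.2 — an order of magnitude above the typical
#'   ~15–20 ms interpulse and an order below the 1 s isolation rule).
#' @param source_id identifier of the source recording.
#' @return A list of class `sound_events`; each element is a `sound_event`
#'   list with `event_type`, `pulses` (data frame), `window` (start, end)
#'   and `source_id`.
#' @export
assemble_events <- function(pulses, single_max_duration = 0.02,
                            isolation_gap = 1, serial_gap = 0.2,
                            source_id = "") {
  p <- as.data.frame(pulses)
  if (nrow(p) == 0L) return(structure(list(), class = "sound_events"))
  if (is.unsorted(p$onset))
    stop_cavesong("pulses must be time-sorted", "cavesong_parameter_error")
  gaps <- diff(p$onset)
  grp <- cumsum(c(1, as.integer(gaps > serial_gap)))
  events <- vector("list", max(grp))
  for (g in seq_len(max(grp))) {
    rows <- p[grp == g, , drop = FALSE]
    if (nrow(rows) >= 2L) {
      type <- "serial"
    } else {
      dur <- rows$offset - rows$onset
      # distance to nearest pulse outside the group (silent interval)
      others <- p[grp != g, , drop = FALSE]
      before <- rows$onset[1L] - others$offset[others$offset <= rows$onset[1L]]
      after <- others$onset[others$onset >= rows$offset[1L]] - rows$offset[1L]
      iso <- min(c(before, after, Inf))
      type <- if (dur < single_max_duration && iso > isolation_gap)
        "single" else "unclassified"
    }
    events[[g]] <- structure(
      list(event_type = type, pulses = rows,
           window = c(rows$onset[1L], rows$offset[nrow(rows)]),
           source_id = source_id),
      class = "sound_event")
  }
  structure(events, class = "sound_events")
}

#' @export
print.sound_event <- function(x, ...) {
  cat(sprintf("<sound_event> %s: %d pulse(s), [%.4f, %.4f) s\n",
              x$event_type, nrow(x$pulses), x$window[1L], x$window[2L]))
  invisible(x)
}

#' @export
print.sound_events <- function(x, ...) {
  types <- vapply(x, `[[`, character(1), "event_type")
  cat(sprintf("<sound_events> %d events (%d single, %d serial, %d unclassified)\n",
              length(x), sum(types == "single"), sum(types == "serial"),
              sum(types == "unclassified")))
  invisible(x)
}

#' Full segmentation of a recording from its detections
#'
#' Finds pulses around every detection, collapses duplicates (a serial
#' train triggers several correlation maxima), and assembles Single /
#' Serial Click events.
#'
#' @param rec a [recording].
#' @param detections a `detections` data frame from [detect_events()].
#' @param ... passed to [find_pulses()] and [assemble_events()] (matching
#'   argument names are routed to the right function).
#' @return A `sound_events` list.
#' @export
segment_events <- function(rec, detections, ...) {
  dots <- list(...)
  fp_args <- dots[names(dots) %in% names(formals(find_pulses))]
  ae_args <- dots[names(dots) %in% names(formals(assemble_events))]
  sets <- lapply(detections$time_s, function(t)
    do.call(find_pulses, c(list(rec = rec, around = t), fp_args)))
  pulses <- merge_pulse_sets(sets)
  do.call(assemble_events,
          c(list(pulses = pulses, source_id = rec$label), ae_args))
}
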