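#' Click sound specification
#'
#' Parameters of a single synthetic click pulse: a sinusoidal carrier at the
#' dominant frequency under a short envelope. Defaults follow the scale of
#' cavefish Single Clicks (dominant frequency near 2 kHz, duration near
#' 5 ms). The default envelope is an exponentially decaying sinusoid with
#' decay constant `duration/5`, mimicking short broadband biological clicks.
#'
#' @param dominant_freq carrier / dominant frequency in Hz.
#' @param duration_ms click duration in milliseconds (> 0).
#' @param amplitude linear peak amplitude in (0, 1] (0 gives silence).
#' @param envelope `"exp"` (exponential decay), `"hann"`, or `"none"`.
#' @return An object of class `click_spec`.
#' @export
click_spec <- function(dominant_freq = 2000, duration_ms = 5,
                       amplitude = 0.8, envelope = c("exp", "hann", "none")) {
  envelope <- match.arg(envelope)
  if (duration_ms <= 0)
    stop_cavesong("duration_ms must be > 0", "cavesong_parameter_error")
  if (amplitude < 0 || amplitude > 1)
    stop_cavesong("amplitude must be in [0, 1]", "cavesong_parameter_error")
  structure(list(dominant_freq = dominant_freq, duration_ms = duration_ms,
                 amplitude = amplitude, envelope = envelope),
            class = "click_spec")
}

#' Serial click (pulse train) specification
#'
#' A train of `pulse_count` identical click pulses. `interpulse_ms` is the
#' onset-to-onset spacing; the silent gap between pulses is therefore
#' `interpulse_ms - duration_ms` (the default 20 ms spacing with 5 ms pulses
#' yields ~15 ms silent gaps, the scale reported for cavefish Serial
#' Clicks). `jitter_fraction` is the relative standard deviation of the
#' onset-to-onset spacing (Gaussian).
#'
#' @param pulse_count number of pulses (>= 2).
#' @param interpulse_ms onset-to-onset pulse spacing in milliseconds.
#' @param pulse a [click_spec] for the individual pulses.
#' @param jitter_fraction relative SD of the spacing (>= 0).
#' @return An object of class `serial_spec`.
#' @export
serial_spec <- function(pulse_count = 8, interpulse_ms = 20,
                        pulse = click_spec(), jitter_fraction = 0) {
  if (pulse_count < 2)
    stop_cavesong("pulse_count must be >= 2", "cavesong_parameter_error")
  if (interpulse_ms <= pulse$duration_ms)
    stop_cavesong("interpulse_ms must exceed the pulse duration (no overlap)",
                  "cavesong_parameter_error")
  if (jitter_fraction < 0)
    stop_cavesong("jitter_fraction must be >= 0", "cavesong_parameter_error")
  structure(list(pulse_count = as.integer(pulse_count),
                 interpulse_ms = interpulse_ms, pulse = pulse,
                 jitter_fraction = jitter_fraction),
            class = "serial_spec")
}

#' Synthesize one click waveform
#'
#' @param spec a [click_spec].
#' @param sample_rate sampling rate in Hz.
#' @return Numeric waveform of `round(duration * rate)` samples whose peak
#'   absolute amplitude equals `spec$amplitude` and whose windowed spectrum
#'   peaks at `spec$dominant_freq`.
#' @export
synth_click <- function(spec, sample_rate = 44100) {
  if (spec$dominant_freq >= sample_rate / 2)
    stop_cavesong("dominant_freq must be below the Nyquist frequency",
                  "cavesong_parameter_error")
  n <- round_half_up(spec$duration_ms / 1000 * sample_rate)
  n <- max(1L, as.integer(n))
  t <- (0:(n - 1L)) / sample_rate
  w <- sin(2 * pi * spec$dominant_freq * t)
  env <- switch(spec$envelope,
    exp  = exp(-t / (spec$duration_ms / 1000 / 5)),
    hann = hann_window(n),
    none = rep(1, n))
  w <- w * env
  peak <- max(abs(w))
  if (peak > 0 && spec$amplitude > 0) w <- w * (spec$amplitude / peak)
  else w[] <- 0
  w
}

#' Synthesize a serial click (pulse train)
#'
#' Pulse onsets are spaced `interpulse_ms` apart with optional Gaussian
#' jitter on each spacing; spacings are redrawn (bounded retries) if jitter
#' would make consecutive pulses overlap. Onsets are quantized to the sample
#' grid, and the returned onsets are the exact placed positions.
#'
#' @param spec a [serial_spec].
#' @param sample_rate sampling rate in Hz.
#' @param max_retries retries allowed when jitter causes pulse overlap.
#' @return A list with `waveform`, `onsets` (seconds, relative to the first
#'   sample of the waveform), `sample_rate` and `pulse_samples`.
#' @export
synth_serial <- function(spec, sample_rate = 44100, max_retries = 100L) {
  k <- spec$pulse_count
  dur_s <- spec$pulse$duration_ms / 1000
  ip_s <- spec$interpulse_ms / 1000
  gaps <- NULL
  for (i in seq_len(max_retries + 1L)) {
    g <- ip_s * (1 + spec$jitter_fraction * stats::rnorm(k - 1L))
    if (all(g > dur_s)) { gaps <- g; break }
  }
  if (is.null(gaps))
    stop_cavesong("jitter produced overlapping pulses in every retry",
                  "cavesong_scheduling_error")
  onsets <- c(0, cumsum(gaps))
  on_idx <- round_half_up(onsets * sample_rate)
  pulse <- synth_click(spec$pulse, sample_rate)
  np <- length(pulse)
  w <- numeric(max(on_idx) + np)
  for (j in seq_len(k)) {
    idx <- (on_idx[j] + 1L):(on_idx[j] + np)
    w[idx] <- w[idx] + pulse
  }
  list(waveform = w, onsets = on_idx / sample_rate,
       sample_rate = sample_rate, pulse_samples = np)
}

#' Soundscape specification
#'
#' Describes a synthetic recording: stationary background noise (white or
#' pink) at a given RMS, plus click or serial-click events scheduled at
#' known times. Single clicks must be isolated from any neighbouring event
#' by at least `isolation_gap` seconds so that the ground truth is
#' unambiguous under the Single-Click isolation rule.
#'
#' @param duration_s total duration in seconds.
#' @param events list of `list(time = seconds, spec = click_spec|serial_spec)`.
#' @param noise_rms linear RMS of the background noise (>= 0).
#' @param noise_model `"pink"` (1/f spectral shaping) or `"white"`.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param isolation_gap minimum separation (s) enforced around single clicks.
#' @return An object of class `soundscape_spec`.
#' @export
soundscape_spec <- function(duration_s, events = list(), noise_rms = 0.01,
                            noise_model = c("pink", "white"), seed = 1L,
                            isolation_gap = 1) {
  noise_model <- match.arg(noise_model)
  if (duration_s <= 0)
    stop_cavesong("duration_s must be > 0", "cavesong_parameter_error")
  if (noise_rms < 0)
    stop_cavesong("noise_rms must be >= 0", "cavesong_parameter_error")
  structure(list(duration_s = duration_s, events = events,
                 noise_rms = noise_rms, noise_model = noise_model,
                 seed = as.integer(seed), isolation_gap = isolation_gap),
            class = "soundscape_spec")
}

#' Effective pulse boundaries of a clean waveform
#'
#' Onset and offset (seconds, relative to the waveform start) where the
#' analytic envelope crosses `fraction` of its peak — the operational
#' definition of pulse boundaries used throughout segmentation, and the
#' quantity the generator records as ground truth (an exponentially
#' decaying click's envelope reaches the -20 dB point well before the
#' nominal synthesis length).
#'
#' @param waveform numeric waveform (clean, noise-free).
#' @param sample_rate sampling rate in Hz.
#' @param fraction envelope fraction defining the boundary (default 0.1).
#' @return `c(onset, offset)` in seconds.
#' @export
effective_bounds <- function(waveform, sample_rate, fraction = 0.1) {
  # zero-pad so the circular FFT Hilbert transform cannot wrap, and keep
  # the padded surroundings: the analytic envelope of a sharp attack
  # genuinely extends slightly before the first carrier sample, so the
  # onset may be (slightly) negative
  pad <- max(256L, length(waveform))
  env <- analytic_magnitude(c(numeric(pad), waveform, numeric(pad)))
  above <- which(env >= fraction * max(env))
  c(above[1L] - 1L - pad, above[length(above)] - pad) / sample_rate
}

event_span_s <- function(ev) {
  if (inherits(ev$spec, "click_spec")) ev$spec$duration_ms / 1000
  else (ev$spec$pulse_count - 1L) * ev$spec$interpulse_ms / 1000 +
    ev$spec$pulse$duration_ms / 1000
}

#' Synthesize a soundscape with exact ground truth
#'
#' Renders the scheduled events into seeded background noise and returns the
#' recording together with an [annotations] ground truth and a per-event
#' truth table carrying exact pulse onsets and both interpulse definitions
#' (onset-to-onset spacing and silent gap).
#'
#' @param spec a [soundscape_spec].
#' @param sample_rate sampling rate in Hz (default 44.1 kHz, the package's
#'   canonical rate).
#' @param label label for the generated recording.
#' @return A list of class `soundscape` with elements `recording`,
#'   `annotations` and `truth` (list, one entry per event: `time`, `type`,
#'   `pulse_onsets`, `pulse_offsets`, `interpulse_onset_ms`,
#'   `interpulse_gap_ms`, `snr`).
#' @export
synth_soundscape <- function(spec, sample_rate = 44100, label = "synthetic") {
  n <- as.integer(round(spec$duration_s * sample_rate))
  ev_times <- vapply(spec$events, function(e) e$time, numeric(1))
  ord <- order(ev_times)
  events <- spec$events[ord]

  with_seed(spec$seed, {
    noise <- if (spec$noise_rms > 0) {
      nz <- switch(spec$noise_model,
                   white = stats::rnorm(n),
                   pink = pink_noise(n, sample_rate))
      nz * (spec$noise_rms / sqrt(mean(nz^2)))
    } else numeric(n)

    x <- noise
    truth <- vector("list", length(events))
    spans <- matrix(0, nrow = length(events), ncol = 2L)
    for (i in seq_along(events)) {
      ev <- events[[i]]
      t0 <- ev$time
      if (inherits(ev$spec, "click_spec")) {
        w <- synth_click(ev$spec, sample_rate)
        eb <- effective_bounds(w, sample_rate)
        onsets <- eb[1L]
        offsets <- eb[2L]
        type <- "single"; pc <- 1L
        ip_on <- NA_real_; ip_gap <- NA_real_
      } else if (inherits(ev$spec, "serial_spec")) {
        s <- synth_serial(ev$spec, sample_rate)
        w <- s$waveform
        eb <- effective_bounds(synth_click(ev$spec$pulse, sample_rate),
                               sample_rate)
        onsets <- s$onsets + eb[1L]
        offsets <- s$onsets + eb[2L]
        type <- "serial"; pc <- ev$spec$pulse_count
        ip_on <- mean(diff(s$onsets)) * 1000
        ip_gap <- mean(onsets[-1L] - offsets[-length(offsets)]) * 1000
      } else {
        stop_cavesong("event spec must be a click_spec or serial_spec",
                      "cavesong_parameter_error")
      }
      i0 <- round_half_up(t0 * sample_rate)
      if (i0 < 0 || i0 + length(w) > n)
        stop_cavesong(sprintf("event %d does not fit within the soundscape",
                              i), "cavesong_scheduling_error")
      t0q <- i0 / sample_rate
      idx <- (i0 + 1L):(i0 + length(w))
      x[idx] <- x[idx] + w
      spans[i, ] <- c(t0q, t0q + length(w) / sample_rate)
      truth[[i]] <- list(time = t0q, type = type, pulse_count = pc,
                         pulse_onsets = t0q + onsets,
                         pulse_offsets = t0q + offsets,
                         interpulse_onset_ms = ip_on,
                         interpulse_gap_ms = ip_gap,
                         spec = ev$spec)
    }

    # ground-truth SNR in the standard analysis band (500-10,000 Hz):
    # RMS of the band-passed mixture over the effective pulse window(s),
    # relative to the band-passed background noise RMS
    band <- c(500, 10000)
    noise_inband_rms <- if (spec$noise_rms > 0) {
      chunk <- noise[seq_len(min(n, 2097152L))]
      sqrt(mean(bandpass_samples(chunk, sample_rate, band)^2))
    } else 0
    pad <- round(0.01 * sample_rate)
    for (i in seq_along(truth)) {
      tr <- truth[[i]]
      a <- pmax(1L, round_half_up(tr$pulse_onsets * sample_rate) + 1L)
      b <- pmin(n, round_half_up(tr$pulse_offsets * sample_rate))
      lo <- max(1L, min(a) - pad)
      hi <- min(n, max(b) + pad)
      xb <- bandpass_samples(x[lo:hi], sample_rate, band)
      ms <- mapply(function(p, q) mean(xb[(p - lo + 1L):(q - lo + 1L)]^2),
                   a, b)
      truth[[i]]$snr <- if (noise_inband_rms > 0)
        sqrt(mean(ms)) / noise_inband_rms else Inf
    }

    if (length(events) > 1L) {
      gaps <- spans[-1L, 1L] - spans[-nrow(spans), 2L]
      if (any(gaps < 0))
        stop_cavesong("scheduled events overlap", "cavesong_scheduling_error")
      types <- vapply(truth, `[[`, character(1), "type")
      near_single <- (types[-1L] == "single" | types[-length(types)] == "single")
      if (any(near_single & gaps < spec$isolation_gap))
        stop_cavesong(sprintf(
          "single clicks must be isolated by >= %g s", spec$isolation_gap),
          "cavesong_scheduling_error")
    }

    ann <- annotations(
      time_s = vapply(truth, `[[`, numeric(1), "time"),
      event_type = vapply(truth, `[[`, character(1), "type"),
      pulse_count = vapply(truth, `[[`, integer(1), "pulse_count"),
      recording_id = label)
    structure(list(recording = recording(x, sample_rate, label = label),
                   annotations = ann, truth = truth),
              class = "soundscape")
  })
}

# 1/f-shaped noise from seeded white noise: amplitude spectrum 1/sqrt(f)
# above `f_floor` (Hz), flat below it so the variance is not swamped by
# near-DC components (hydrophone band floors around 20 Hz). Long signals
# are built from independent spectrally shaped blocks combined by
# sqrt-Hann overlap-add (50% overlap) so variance stays stationary.
pink_noise <- function(n, sample_rate = 44100, f_floor = 20,
                       block = 2^20L) {
  shape_block <- function(m) {
    wht <- stats::rnorm(m)
    X <- stats::fft(wht)
    k <- as.double(0:(m - 1L))
    f <- pmin(k, m - k) * as.double(sample_rate) / m
    g <- 1 / sqrt(pmax(f, f_floor))
    g[1L] <- 0
    x <- Re(stats::fft(X * g, inverse = TRUE) / m)
    x / stats::sd(x)
  }
  if (n <= block) return(shape_block(n))
  hop <- block %/% 2L
  w <- sqrt(hann_window(block))
  out <- numeric(n + 2L * block)
  pos <- 0L
  while (pos < n + hop) {
    out[(pos + 1L):(pos + block)] <- out[(pos + 1L):(pos + block)] +
      shape_block(block) * w
    pos <- pos + hop
  }
  # drop the leading ramp where only one window contributes
  out[(hop + 1L):(hop + n)]
}

#' Draw event times with a guaranteed minimum separation
#'
#' Uniformly distributed times on `[edge, duration - edge]` subject to a
#' minimum gap, via the spacing construction (sorted uniforms plus fixed
#' gaps). Uses the ambient RNG; seed with [set.seed()] or [with_seed()].
#'
#' @param n number of times.
#' @param duration_s total duration (s).
#' @param min_gap minimum separation between consecutive times (s).
#' @param edge margin kept clear at both ends (s).
#' @return Sorted numeric vector of `n` times.
#' @export
random_event_times <- function(n, duration_s, min_gap = 1.05, edge = 0.5) {
  slack <- duration_s - 2 * edge - (n - 1) * min_gap
  if (slack <= 0)
    stop_cavesong("duration too short for n events at this minimum gap",
                  "cavesong_scheduling_error")
  edge + sort(stats::runif(n)) * slack + (seq_len(n) - 1) * min_gap
}

#' Convenience: a soundscape of identical single clicks at random times
#'
#' @param n_clicks number of clicks.
#' @param duration_s soundscape duration (s).
#' @param click a [click_spec] shared by all events.
#' @param noise_rms background noise RMS.
#' @param noise_model `"pink"` or `"white"`.
#' @param seed integer seed controlling both event times and noise.
#' @param min_gap minimum event separation (s).
#' @return A [soundscape_spec].
#' @export
click_soundscape_spec <- function(n_clicks, duration_s, click = click_spec(),
                                  noise_rms = 0.01,
                                  noise_model = "pink", seed = 1L,
                                  min_gap = 1.05) {
  times <- with_seed(seed, random_event_times(n_clicks, duration_s, min_gap))
  events <- lapply(times, function(t) list(time = t, spec = click))
  # derived seed kept within the signed 32-bit range
  soundscape_spec(duration_s, events, noise_rms = noise_rms,
                  noise_model = noise_model,
                  seed = as.integer((as.double(seed) + 1000003) %%
                                      2147483647))
}
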