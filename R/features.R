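## acoustic parameter extraction: the 3 Single-Click and 5 Serial-Click
## parameters used for population comparison

#' Acoustic parameters of a Single Click
#'
#' Computes the three Single-Click parameters: duration (from the pulse
#' boundaries, ms), dominant frequency (peak of the Hann-windowed magnitude
#' spectrum of the band-passed event window, zero-padded to at least
#' `pad_to` points, restricted to the analysis band) and SNR. SNR is the
#' linear ratio RMS(event window) / RMS(noise window), both band-passed
#' to the analysis band (out-of-band noise is irrelevant to in-band
#' clicks and would otherwise dominate the short-window RMS under
#' low-frequency-heavy ambience); the noise window is a same-length span
#' immediately preceding the event (shifted earlier past any window
#' listed in `exclude`). It is invariant under
#' global amplitude scaling; with literally zero noise it is capped at
#' `snr_cap` and flagged.
#'
#' @param event a `sound_event` of type `"single"`.
#' @param rec the source [recording].
#' @param band analysis band in Hz.
#' @param pad_to minimum FFT length (default 4096, ~10.8 Hz resolution at
#'   44.1 kHz).
#' @param exclude optional two-column matrix/data frame of windows
#'   (start, end) the noise window must not overlap (other events).
#' @param guard gap (s) left between the noise window and the event onset.
#' @param snr_cap cap substituted for an infinite ratio.
#' @param db if `TRUE`, SNR is returned in decibels.
#' @return A one-row data frame: `duration_ms`, `dominant_frequency_hz`,
#'   `snr` (attribute `snr_capped` set when the cap was applied).
#' @export
click_features <- function(event, rec, band = c(500, 10000), pad_to = 4096,
                           exclude = NULL, guard = 0.02, snr_cap = 1e6,
                           db = FALSE) {
  pulse <- event$pulses[1L, ]
  fs <- rec$sample_rate
  i0 <- max(1L, round_half_up(pulse$onset * fs) + 1L)
  i1 <- min(length(rec$samples), round_half_up(pulse$offset * fs))
  if (i1 - i0 < 1L)
    stop_cavesong("event window shorter than 2 samples",
                  "cavesong_degenerate_event")
  x <- rec$samples[i0:i1]
  dur_ms <- (pulse$offset - pulse$onset) * 1000

  xb <- bandpass_samples(x, fs, band)
  domfreq <- dominant_frequency(xb, fs, band, pad_to)

  len <- i1 - i0 + 1L
  nw0 <- noise_window(rec, pulse$onset, len, exclude, guard)
  sig_rms <- sqrt(mean(banded_window(rec, i0, len, band)^2))
  noi_rms <- sqrt(mean(banded_window(rec, nw0, len, band)^2))
  capped <- FALSE
  snr <- if (noi_rms == 0) { capped <- TRUE; snr_cap }
         else min(sig_rms / noi_rms, snr_cap)
  if (db) snr <- 20 * log10(snr)
  out <- data.frame(duration_ms = dur_ms, dominant_frequency_hz = domfreq,
                    snr = snr)
  attr(out, "snr_capped") <- capped
  out
}

dominant_frequency <- function(x, fs, band = c(500, 10000), pad_to = 4096) {
  n <- length(x)
  xw <- x * hann_window(n)
  m <- max(pad_to, stats::nextn(n, 2L))
  spec <- Mod(stats::fft(c(xw, numeric(m - n))))[1:(m %/% 2L + 1L)]
  freqs <- (0:(m %/% 2L)) * fs / m
  inb <- freqs >= band[1L] & freqs <= band[2L]
  if (!any(inb)) inb <- rep(TRUE, length(freqs))
  freqs[inb][which.max(spec[inb])]
}

# band-passed samples [i0, i0+len-1], filtered with surrounding context
# so the zero-phase filter transients fall outside the window
banded_window <- function(rec, i0, len, band, context = 0.01) {
  if (is.null(band)) return(rec$samples[i0:(i0 + len - 1L)])
  fs <- rec$sample_rate
  pad <- round(context * fs)
  lo <- max(1L, i0 - pad)
  hi <- min(length(rec$samples), i0 + len - 1L + pad)
  v <- bandpass_samples(rec$samples[lo:hi], fs, band)
  v[(i0 - lo + 1L):(i0 - lo + len)]
}

# start index of a same-length noise span just before `onset`, shifted
# earlier past any excluded window; falls back to the span following the
# event
noise_window <- function(rec, onset, len, exclude = NULL, guard = 0.02) {
  fs <- rec$sample_rate
  end <- onset - guard
  repeat {
    start <- end - len / fs
    if (start < 0) break
    if (is.null(exclude) || nrow(exclude) == 0L) break
    ov <- which(exclude[, 1L] < end & exclude[, 2L] > start)
    if (!length(ov)) break
    end <- min(exclude[ov, 1L]) - guard
  }
  if (end - len / fs >= 0)
    return(max(1L, round_half_up((end - len / fs) * fs) + 1L))
  # no room before the event: use the span after it
  min(length(rec$samples) - len,
      round_half_up((onset + guard) * fs) + len) + 1L
}

#' Acoustic parameters of a Serial Click
#'
#' The five Serial-Click parameters: pulse number, mean pulse duration
#' (ms), mean interpulse duration (ms, silent gap from each pulse offset to
#' the next onset), total duration (first onset to last offset, ms), and
#' pulse rate (pulses per second, `pulse_number / total_duration`; set
#' `rate_from_interpulse = TRUE` for the alternative `1 / mean interpulse
#' spacing` definition).
#'
#' @param event a `sound_event` of type `"serial"` (>= 2 pulses).
#' @param rate_from_interpulse use `1 / mean(onset-to-onset spacing)` for
#'   the pulse rate instead of `pulse_number / total_duration`.
#' @return A one-row data frame: `pulse_number`, `mean_pulse_duration_ms`,
#'   `mean_interpulse_duration_ms`, `pulse_rate_hz`, `total_duration_ms`.
#' @export
serial_features <- function(event, rate_from_interpulse = FALSE) {
  p <- event$pulses
  if (nrow(p) < 2L)
    stop_cavesong("serial event needs >= 2 pulses", "cavesong_parameter_error")
  if (any(p$onset[-1L] < p$offset[-nrow(p)]))
    stop_cavesong("overlapping pulses", "cavesong_invariant_violation")
  n <- nrow(p)
  total_s <- p$offset[n] - p$onset[1L]
  gaps_s <- p$onset[-1L] - p$offset[-n]
  rate <- if (rate_from_interpulse) 1 / mean(diff(p$onset))
          else n / total_s
  data.frame(pulse_number = n,
             mean_pulse_duration_ms = mean(p$offset - p$onset) * 1000,
             mean_interpulse_duration_ms = mean(gaps_s) * 1000,
             pulse_rate_hz = rate,
             total_duration_ms = total_s * 1000)
}

#' Build labeled feature tables from segmented events
#'
#' One row per event, split by event type (unclassified events are
#' skipped). Rows whose feature extraction fails are dropped with a
#' message. The result carries the group label needed for population
#' comparisons.
#'
#' @param events a `sound_events` list (or plain list of `sound_event`s).
#' @param recordings a [recording], or a named list of recordings keyed by
#'   the events' `source_id`.
#' @param group a single group label, or a named character vector keyed by
#'   `source_id`.
#' @param ... passed to [click_features()].
#' @return A list of class `feature_tables` with elements `single` and
#'   `serial`, each a `feature_table` data frame (columns: `event_id`,
#'   `group`, then the feature columns).
#' @export
build_feature_table <- function(events, recordings, group, ...) {
  get_rec <- function(id) {
    if (inherits(recordings, "recording")) return(recordings)
    r <- recordings[[id]]
    if (is.null(r))
      stop_cavesong(paste0("unresolvable source_id: ", id),
                    "cavesong_labeling_error")
    r
  }
  get_group <- function(id) {
    if (length(group) == 1L && is.null(names(group))) return(group)
    g <- if (id %in% names(group)) group[[id]] else NULL
    if (is.null(g) || is.na(g))
      stop_cavesong(paste0("unknown group label for: ", id),
                    "cavesong_labeling_error")
    g
  }
  singles <- list(); serials <- list(); dropped <- 0L
  for (i in seq_along(events)) {
    ev <- events[[i]]
    id <- sprintf("%s#%d", ev$source_id, i)
    row <- tryCatch({
      if (ev$event_type == "single")
        cbind(data.frame(event_id = id,
                         group = get_group(ev$source_id),
                         stringsAsFactors = FALSE),
              click_features(ev, get_rec(ev$source_id), ...))
      else if (ev$event_type == "serial")
        cbind(data.frame(event_id = id,
                         group = get_group(ev$source_id),
                         stringsAsFactors = FALSE),
              serial_features(ev))
      else NULL
    }, error = function(e) {
      # labeling problems are a hard error; only feature-measurement
      # failures on individual events are dropped
      if (inherits(e, "cavesong_labeling_error")) stop(e)
      dropped <<- dropped + 1L
      NULL
    })
    if (is.null(row)) next
    if (ev$event_type == "single") singles[[length(singles) + 1L]] <- row
    else serials[[length(serials) + 1L]] <- row
  }
  if (dropped > 0L)
    message(sprintf("build_feature_table: dropped %d event(s) with failed features",
                    dropped))
  mk <- function(rows, type, cols) {
    df <- if (length(rows)) do.call(rbind, rows) else
      stats::setNames(as.data.frame(matrix(nrow = 0L, ncol = length(cols) + 2L)),
                      c("event_id", "group", cols))
    rownames(df) <- NULL
    structure(df, event_type = type,
              class = c("feature_table", "data.frame"))
  }
  structure(list(
    single = mk(singles, "single",
                c("duration_ms", "dominant_frequency_hz", "snr")),
    serial = mk(serials, "serial",
                c("pulse_number", "mean_pulse_duration_ms",
                  "mean_interpulse_duration_ms", "pulse_rate_hz",
                  "total_duration_ms"))),
    class = "feature_tables")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %s: %d events, %d group(s)\n",
              attr(x, "event_type"), nrow(x),
              length(unique(x$group))))
  NextMethod()
}

feature_columns <- function(table) {
  setdiff(names(table), c("event_id", "group"))
}

#' Correlation-based variable reduction with sample-size adequacy
#'
#' Greedily retains features so that no retained pair exceeds
#' `max_abs_correlation` in absolute Spearman rank correlation, preferring
#' features with higher absolute loading on the first principal axis of
#' the standardized table. The adequacy report flags groups with fewer
#' than `per_variable` (default 10) times the retained variable count —
#' the usual minimum sample size rule for multivariate analyses.
#'
#' @param table a `feature_table`.
#' @param max_abs_correlation retention threshold in (0, 1].
#' @param required optional number of variables that must remain
#'   available; error if more than the table offers.
#' @param per_variable rows required per retained variable and group.
#' @return A list of class `variable_reduction`: `selected` (feature
#'   names), `adequacy` (data frame: group, n, required, adequate) and
#'   `loadings` (PC1 loadings used for the preference order).
#' @export
reduce_variables <- function(table, max_abs_correlation = 0.9,
                             required = NULL, per_variable = 10) {
  if (nrow(table) == 0L)
    stop_cavesong("empty feature table", "cavesong_parameter_error")
  if (max_abs_correlation <= 0 || max_abs_correlation > 1)
    stop_cavesong("max_abs_correlation must be in (0, 1]",
                  "cavesong_parameter_error")
  feats <- feature_columns(table)
  if (!is.null(required) && required > length(feats))
    stop_cavesong("required exceeds the number of available features",
                  "cavesong_parameter_error")
  X <- as.matrix(table[, feats, drop = FALSE])
  sds <- apply(X, 2L, stats::sd)
  keep_cols <- sds > 0
  Xs <- scale(X[, keep_cols, drop = FALSE])
  pc1 <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)$rotation[, 1L]
  pref <- names(sort(abs(pc1), decreasing = TRUE))
  rho <- stats::cor(X[, keep_cols, drop = FALSE], method = "spearman")
  selected <- character(0)
  for (f in pref) {
    if (!length(selected) ||
        all(abs(rho[f, selected]) <= max_abs_correlation))
      selected <- c(selected, f)
  }
  counts <- base::table(table$group)
  adequacy <- data.frame(group = names(counts),
                         n = as.integer(counts),
                         required = per_variable * length(selected))
  adequacy$adequate <- adequacy$n >= adequacy$required
  structure(list(selected = selected, adequacy = adequacy, loadings = pc1),
            class = "variable_reduction")
}

#' @export
print.variable_reduction <- function(x, ...) {
  cat("<variable_reduction> retained:", paste(x$selected, collapse = ", "),
      "\n")
  flagged <- x$adequacy[!x$adequacy$adequate, , drop = FALSE]
  if (nrow(flagged))
    cat("  inadequate sample size:",
        paste(sprintf("%s (n=%d < %d)", flagged$group, flagged$n,
                      flagged$required), collapse = ", "), "\n")
  else cat("  all groups meet the 10x-variables sample-size rule\n")
  invisible(x)
}
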