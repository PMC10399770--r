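# Shared helpers for the test suite.

# Independent per-lag normalized correlation oracle (direct definition:
# zero-mean, energy-normalized template against every same-length window).
brute_force_correlation <- function(x, tmpl) {
  m <- length(tmpl)
  n <- length(x)
  t0 <- tmpl - mean(tmpl)
  et <- sum(t0^2)
  out <- numeric(n - m + 1L)
  for (k in seq_len(n - m + 1L)) {
    w <- x[k:(k + m - 1L)]
    w0 <- w - mean(w)
    den <- sqrt(sum(w0^2) * et)
    out[k] <- if (den > 0) sum(w0 * t0) / den else 0
  }
  out
}

# Template cut from the first embedded truth pulse of a soundscape.
first_truth_template <- function(ss) {
  tr <- ss$truth[[1L]]
  extract_template(ss$recording, max(0, tr$pulse_onsets[1L]),
                   tr$pulse_offsets[1L])
}

# For each feature-table row, the index of the closest truth event.
truth_rows <- function(ft, ev, truth) {
  idx <- as.integer(sub(".*#", "", ft$event_id))
  tt <- vapply(truth, `[[`, numeric(1), "time")
  vapply(idx, function(i) which.min(abs(tt - ev[[i]]$window[1L])),
         integer(1))
}

# Detections data frame straight from generator truth (for tests that
# validate segmentation/features independently of the detector).
detections_from_truth <- function(ss) {
  data.frame(time_s = vapply(ss$truth, `[[`, numeric(1), "time"),
             score = 1)
}

# A one-feature table for the statistics tests.
sig_table <- function(values, groups) {
  structure(data.frame(event_id = sprintf("e%d", seq_along(values)),
                       group = groups, v = values,
                       stringsAsFactors = FALSE),
            class = c("feature_table", "data.frame"))
}

# A feature table of single-click parameters for one population of
# clicks, built through segmentation + feature extraction.
population_features <- function(n_clicks, duration_s, click, noise_rms,
                                seed, group) {
  ss <- synth_soundscape(
    click_soundscape_spec(n_clicks, duration_s, click,
                          noise_rms = noise_rms, seed = seed))
  ev <- segment_events(ss$recording, detections_from_truth(ss))
  build_feature_table(ev, ss$recording, group)$single
}
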