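make_event <- function(onsets, offsets, type, source_id = "synthetic") {
  structure(list(event_type = type,
                 pulses = data.frame(onset = onsets, offset = offsets,
                                     peak_amplitude = 1,
                                     peak_time = (onsets + offsets) / 2),
                 window = c(onsets[1L], offsets[length(offsets)]),
                 source_id = source_id),
            class = "sound_event")
}

test_that("serial parameters follow their defining arithmetic", {
  # 8 pulses of 5 ms separated by 10 ms silent gaps
  on <- seq(0, by = 0.015, length.out = 8)
  ev <- make_event(on, on + 0.005, "serial")
  f <- serial_features(ev)
  expect_identical(f$pulse_number, 8L)
  expect_equal(f$mean_pulse_duration_ms, 5)
  expect_equal(f$mean_interpulse_duration_ms, 10)
  expect_equal(f$total_duration_ms, 7 * 15 + 5)
  expect_equal(f$pulse_rate_hz, 8 / 0.110)

  ev2 <- make_event(c(0, 0.020), c(0.004, 0.024), "serial")
  f2 <- serial_features(ev2)
  expect_equal(f2$total_duration_ms, 24)
  expect_equal(f2$pulse_rate_hz, 2 / 0.024)
  # alternative rate definition: 1 / mean onset-to-onset spacing
  f3 <- serial_features(ev2, rate_from_interpulse = TRUE)
  expect_equal(f3$pulse_rate_hz, 1 / 0.020)
})

test_that("single-click parameters recover the planted frequency and scale-invariant SNR", {
  cs <- click_spec(2000, 5, 0.5)
  ss <- synth_soundscape(soundscape_spec(
    4, list(list(time = 1.5, spec = cs)), noise_rms = 0.02, seed = 41))
  ev <- segment_events(ss$recording, data.frame(time_s = 1.5, score = 1))
  expect_identical(ev[[1L]]$event_type, "single")
  f <- click_features(ev[[1L]], ss$recording)
  expect_equal(f$dominant_frequency_hz, 2000, tolerance = 15)
  tr <- ss$truth[[1L]]
  expect_equal(f$duration_ms,
               (tr$pulse_offsets[1L] - tr$pulse_onsets[1L]) * 1000,
               tolerance = 0.6)
  # scaling the whole recording leaves snr, frequency and duration alone
  scaled <- recording(ss$recording$samples * 12, ss$recording$sample_rate)
  ev_s <- segment_events(scaled, data.frame(time_s = 1.5, score = 1))
  f_s <- click_features(ev_s[[1L]], scaled)
  expect_equal(f_s$snr, f$snr, tolerance = 1e-6)
  expect_equal(f_s$dominant_frequency_hz, f$dominant_frequency_hz)
  expect_equal(f_s$duration_ms, f$duration_ms, tolerance = 1e-6)
  # sign flip leaves the duration alone
  flipped <- recording(-ss$recording$samples, ss$recording$sample_rate)
  ev_f <- segment_events(flipped, data.frame(time_s = 1.5, score = 1))
  expect_equal(click_features(ev_f[[1L]], flipped)$duration_ms,
               f$duration_ms, tolerance = 1e-6)
})

test_that("zero background noise caps the SNR and flags it", {
  cs <- click_spec(2000, 5, 0.5)
  ss <- synth_soundscape(soundscape_spec(
    4, list(list(time = 1.5, spec = cs)), noise_rms = 0, seed = 42))
  ev <- make_event(ss$truth[[1L]]$pulse_onsets,
                   ss$truth[[1L]]$pulse_offsets, "single")
  f <- click_features(ev, ss$recording, band = NULL)
  expect_identical(f$snr, 1e6)
  expect_true(attr(f, "snr_capped"))
})

test_that("degenerate event windows are refused", {
  r <- recording(stats::rnorm(44100), 44100)
  ev <- make_event(0.5, 0.5 + 1e-6, "single")
  expect_error(click_features(ev, r), class = "cavesong_degenerate_event")
  ev2 <- make_event(0.5, 0.504, "serial")
  expect_error(serial_features(ev2), class = "cavesong_parameter_error")
})

test_that("feature tables partition events by type and keep group labels", {
  on <- seq(0, by = 0.015, length.out = 8) + 2
  events <- structure(list(
    make_event(2, 2.004, "single"),
    make_event(on, on + 0.005, "serial"),
    make_event(5, 5.004, "single")),
    class = "sound_events")
  r <- recording(stats::rnorm(44100 * 6) * 0.01, 44100, label = "synthetic")
  ft <- build_feature_table(events, r, "Pachon")
  expect_identical(nrow(ft$single), 2L)
  expect_identical(nrow(ft$serial), 1L)
  expect_true(all(ft$single$group == "Pachon"))
  expect_identical(
    sort(names(ft$serial)),
    sort(c("event_id", "group", "pulse_number", "mean_pulse_duration_ms",
           "mean_interpulse_duration_ms", "pulse_rate_hz",
           "total_duration_ms")))

  empty <- build_feature_table(structure(list(), class = "sound_events"),
                               r, "Pachon")
  expect_identical(nrow(empty$single), 0L)
  expect_true("duration_ms" %in% names(empty$single))
})

test_that("unknown group labels are a hard error, not a dropped row", {
  ev <- structure(list(make_event(2, 2.004, "single", source_id = "recA")),
                  class = "sound_events")
  r <- recording(stats::rnorm(44100 * 3) * 0.01, 44100, label = "recA")
  expect_error(
    build_feature_table(ev, list(recA = r), c(recB = "Pachon")),
    class = "cavesong_labeling_error")
})

test_that("variable reduction removes redundant columns and checks sample adequacy", {
  set.seed(43)
  n <- 25
  a <- stats::rnorm(n)
  tab <- structure(
    data.frame(event_id = sprintf("e%d", 1:n), group = "g1",
               f1 = a, f2 = 2 * a + 1, f3 = stats::rnorm(n)),
    class = c("feature_table", "data.frame"))
  red <- reduce_variables(tab, max_abs_correlation = 0.9)
  expect_true(sum(c("f1", "f2") %in% red$selected) == 1L)
  expect_true("f3" %in% red$selected)
  # 25 rows with 2 retained variables: 25 >= 20, adequate;
  # with 3 variables it would not be (25 < 30)
  expect_true(red$adequacy$adequate[red$adequacy$group == "g1"])
  red3 <- reduce_variables(tab, max_abs_correlation = 1)
  expect_identical(length(red3$selected), 3L)
  expect_false(red3$adequacy$adequate[1L])

  ortho <- structure(
    data.frame(event_id = sprintf("e%d", 1:n), group = "g1",
               f1 = stats::rnorm(n), f2 = stats::rnorm(n)),
    class = c("feature_table", "data.frame"))
  red2 <- reduce_variables(ortho, max_abs_correlation = 0.9)
  expect_identical(sort(red2$selected), c("f1", "f2"))
})

test_that("recovered parameter medians stay within 10 percent at Table-1 SNR", {
  cs <- click_spec(2000, 5, 0.05)
  eb <- effective_bounds(synth_click(cs, 44100), 44100)
  ss <- synth_soundscape(click_soundscape_spec(
    12, 20, cs, noise_rms = 0.0025, seed = 44))
  ev <- segment_events(ss$recording, detections_from_truth(ss))
  ft <- build_feature_table(ev, ss$recording, "g")$single
  rows <- truth_rows(ft, ev, ss$truth)
  rel <- function(m, t) abs(m - t) / t
  dur_err <- rel(ft$duration_ms, diff(eb) * 1000)
  frq_err <- rel(ft$dominant_frequency_hz, 2000)
  snr_err <- rel(ft$snr, vapply(ss$truth[rows], `[[`, numeric(1), "snr"))
  expect_lt(stats::median(dur_err), 0.10)
  expect_lt(stats::median(frq_err), 0.10)
  expect_lt(stats::median(snr_err), 0.10)
})
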