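test_that("the matched filter equals the per-lag normalized correlation oracle", {
  ss <- synth_soundscape(click_soundscape_spec(
    2, 4, click_spec(2000, 5, 0.05), noise_rms = 0.01, seed = 21))
  rec <- recording(ss$recording$samples[1:22050], 44100)
  tmpl <- first_truth_template(ss)
  trace <- matched_filter(rec, tmpl)
  oracle <- brute_force_correlation(rec$samples, tmpl$waveform)
  expect_identical(length(trace$values), length(oracle))
  expect_lt(max(abs(trace$values - oracle)), 1e-9)
})

test_that("correlation is invariant under global amplitude scaling and bounded by one", {
  ss <- synth_soundscape(click_soundscape_spec(
    3, 5, click_spec(2000, 5, 0.05), noise_rms = 0.01, seed = 22))
  tmpl <- first_truth_template(ss)
  t1 <- matched_filter(ss$recording, tmpl)
  scaled <- recording(ss$recording$samples * 37.5, 44100)
  t2 <- matched_filter(scaled, tmpl)
  expect_lt(max(abs(t1$values - t2$values)), 1e-9)
  expect_true(all(t1$values >= -1 & t1$values <= 1))
})

test_that("a template correlates perfectly at its own source position", {
  ss <- synth_soundscape(click_soundscape_spec(
    3, 5, click_spec(2000, 5, 0.05), noise_rms = 0.01, seed = 23))
  tmpl <- first_truth_template(ss)
  trace <- matched_filter(ss$recording, tmpl)
  expect_equal(max(trace$values), 1, tolerance = 1e-9)
})

test_that("all planted clicks are detected within 2 ms at a comfortable SNR", {
  ss <- synth_soundscape(click_soundscape_spec(
    50, 70, click_spec(2000, 5, 0.1), noise_rms = 0.01, seed = 24))
  tmpl <- first_truth_template(ss)
  dets <- detect_events(matched_filter(ss$recording, tmpl), 0.5)
  expect_gte(nrow(dets), 50L)
  truth_t <- ss$annotations$time_s
  for (t in truth_t) expect_lt(min(abs(dets$time_s - t)), 0.002)
  # the 50 strongest detections are exactly the planted clicks
  top <- dets$time_s[order(-dets$score)[1:50]]
  for (t in truth_t) expect_lt(min(abs(top - t)), 0.002)
})

test_that("no two detections are closer than the suppression window", {
  ss <- synth_soundscape(click_soundscape_spec(
    20, 30, click_spec(2000, 5, 0.05), noise_rms = 0.01, seed = 25))
  tmpl <- first_truth_template(ss)
  dets <- detect_events(matched_filter(ss$recording, tmpl), 0.3,
                        min_separation = 0.05)
  expect_true(all(diff(dets$time_s) >= 0.05 - 1e-12))
})

test_that("raising the threshold never increases the number of detections", {
  ss <- synth_soundscape(click_soundscape_spec(
    20, 30, click_spec(2000, 5, 0.05), noise_rms = 0.01, seed = 26))
  tmpl <- first_truth_template(ss)
  trace <- matched_filter(ss$recording, tmpl)
  counts <- vapply(c(0.3, 0.4, 0.5, 0.6, 0.8),
                   function(th) nrow(detect_events(trace, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection scoring applies one-to-one greedy matching arithmetic", {
  truth <- data.frame(time_s = c(1, 2, 3))
  dets <- data.frame(time_s = c(1.004, 1.006, 2.5, 3.002),
                     score = c(0.9, 0.8, 0.7, 0.6))
  m <- score_detections(dets, truth, tolerance = 0.01)
  # 1.004 takes truth 1 (closer); 1.006 is then unmatched; 2.5 matches
  # nothing; 3.002 takes truth 3 -> TP 2, FP 2, FN 1
  expect_identical(m$tp, 2L)
  expect_identical(m$fp, 2L)
  expect_identical(m$fn, 1L)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 2 / 3)

  empty <- score_detections(data.frame(time_s = numeric(0),
                                       score = numeric(0)), truth)
  expect_identical(empty$tp, 0L)
  expect_true(empty$precision_undefined)
  expect_equal(empty$precision, 0)
})

test_that("supervised tuning meets the precision target and predict reproduces it", {
  ss <- synth_soundscape(click_soundscape_spec(
    40, 60, click_spec(2000, 5, 0.05), noise_rms = 0.01, seed = 27))
  tmpl <- first_truth_template(ss)
  det <- tune_threshold(ss$recording, tmpl, ss$annotations, target = 0.95)
  expect_s3_class(det, "tuned_detector")
  expect_gte(det$tuning_metrics$precision, 0.95)
  expect_true(det$threshold > 0 && det$threshold <= 1)
  # the sweep must contain dominated operating points too
  expect_true(nrow(det$sweep) >= 1L)
  redo <- predict(det, ss$recording)
  m <- score_detections(redo, ss$annotations)
  expect_equal(m$precision, det$tuning_metrics$precision)
  expect_equal(m$recall, det$tuning_metrics$recall)
})

test_that("the recall criterion picks the highest threshold that still meets the target", {
  ss <- synth_soundscape(click_soundscape_spec(
    30, 45, click_spec(2000, 5, 0.05), noise_rms = 0.01, seed = 28))
  tmpl <- first_truth_template(ss)
  dp <- tune_threshold(ss$recording, tmpl, ss$annotations,
                       criterion = "recall")
  expect_gte(dp$tuning_metrics$recall, 0.95)
  above <- dp$sweep$threshold > dp$threshold + 1e-12
  expect_true(all(dp$sweep$recall[above] < 0.95))
})

test_that("an unreachable tuning target fails loudly with the sweep attached", {
  ss <- synth_soundscape(click_soundscape_spec(
    10, 15, click_spec(2000, 5, 0.05), noise_rms = 0.01, seed = 29))
  tmpl <- first_truth_template(ss)
  # truth deliberately placed where no clicks are: precision vs these
  # annotations can never reach the target
  fake <- annotations(ss$annotations$time_s + 0.45,
                      ss$annotations$event_type)
  err <- tryCatch(
    tune_threshold(ss$recording, tmpl, fake, target = 0.95),
    cavesong_tuning_failure = function(e) e)
  expect_s3_class(err, "cavesong_tuning_failure")
  expect_true(!is.null(err$sweep))
})

test_that("templates must carry energy and stay under 100 ms", {
  expect_error(click_template(numeric(221), 44100),
               class = "cavesong_parameter_error")
  expect_error(click_template(stats::rnorm(8820), 44100),
               class = "cavesong_parameter_error")
})
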