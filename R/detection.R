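#' Click reference templates
#'
#' The reference signal for matched filtering: a short click excerpt, in
#' practice one click chosen by ear from a recording. Templates must have
#' nonzero energy and last at most 100 ms.
#'
#' @param waveform numeric amplitude vector.
#' @param sample_rate sampling rate in Hz.
#' @param source free-text provenance (recording id + time span).
#' @return An object of class `click_template`.
#' @export
click_template <- function(waveform, sample_rate, source = "") {
  waveform <- as.numeric(waveform)
  if (sum((waveform - mean(waveform))^2) <= 0)
    stop_cavesong("template has zero energy", "cavesong_parameter_error")
  if (length(waveform) / sample_rate > 0.1)
    stop_cavesong("template longer than 100 ms", "cavesong_parameter_error")
  structure(list(waveform = waveform, sample_rate = sample_rate,
                 source = as.character(source)),
            class = "click_template")
}

#' Cut a template out of a recording
#'
#' @param rec a [recording].
#' @param start,end time span in seconds (half-open).
#' @return A [click_template].
#' @export
extract_template <- function(rec, start, end) {
  i0 <- max(1L, as.integer(floor(start * rec$sample_rate)) + 1L)
  i1 <- min(length(rec$samples), as.integer(ceiling(end * rec$sample_rate)))
  if (i1 <= i0)
    stop_cavesong("empty template span", "cavesong_parameter_error")
  click_template(rec$samples[i0:i1], rec$sample_rate,
                 source = sprintf("%s [%.4f, %.4f)", rec$label, start, end))
}

## valid-mode linear convolution by overlap-save FFT blocks
fft_conv_valid <- function(x, r) {
  L <- length(r)
  nx <- length(x)
  nv <- nx - L + 1L
  if (nx + L - 1L <= 2^18) {
    m <- stats::nextn(nx + L - 1L, 2L)
    y <- Re(stats::fft(stats::fft(c(x, numeric(m - nx))) *
                       stats::fft(c(r, numeric(m - L))), inverse = TRUE)) / m
    return(y[L:(L + nv - 1L)])
  }
  bfft <- 2^21L
  step <- bfft - L + 1L
  rf <- stats::fft(c(r, numeric(bfft - L)))
  out <- numeric(nv)
  s <- 1L
  while (s <= nv) {
    seg <- x[s:min(nx, s + bfft - 1L)]
    if (length(seg) < bfft) seg <- c(seg, numeric(bfft - length(seg)))
    cc <- Re(stats::fft(stats::fft(seg) * rf, inverse = TRUE)) / bfft
    take <- min(step, nv - s + 1L)
    out[s:(s + take - 1L)] <- cc[L:(L + take - 1L)]
    s <- s + take
  }
  out
}

#' Matched filtering of a recording against a click template
#'
#' Slides the reference click over the recording and computes, at every
#' sample lag, the zero-mean, energy-normalized correlation coefficient
#' between the template and the recording window starting there. An exact
#' noise-free copy of the template scores 1.0 at its onset; a sign-flipped
#' copy scores -1.0; windows with zero energy are assigned 0. Values are
#' invariant under positive rescaling of the recording. Computed by
#' frequency-domain convolution with running-sum window normalization.
#'
#' @param rec a [recording].
#' @param template a [click_template]; resampled to the recording's rate if
#'   needed.
#' @return An object of class `correlation_trace`: `values` (one coefficient
#'   per candidate onset sample, in \[-1, 1\]), `sample_rate`, `alignment`
#'   (seconds added to `(i-1)/sample_rate` to map index `i` to onset time).
#' @export
matched_filter <- function(rec, template) {
  if (!isTRUE(all.equal(template$sample_rate, rec$sample_rate))) {
    tr <- resample(recording(template$waveform, template$sample_rate),
                   rec$sample_rate)
    template <- click_template(tr$samples, rec$sample_rate, template$source)
  }
  x <- rec$samples
  t0 <- template$waveform - mean(template$waveform)
  L <- length(t0)
  n <- length(x)
  if (L > n)
    stop_cavesong("template longer than recording", "cavesong_parameter_error")
  et <- sum(t0^2)

  num <- fft_conv_valid(x, rev(t0))
  c1 <- cumsum(x)
  s1 <- c1[L:n] - c(0, c1[seq_len(n - L)])
  rm(c1)
  c2 <- cumsum(x * x)
  s2 <- c2[L:n] - c(0, c2[seq_len(n - L)])
  rm(c2)
  ew <- s2 - s1^2 / L
  rm(s1, s2)
  den <- sqrt(pmax(ew, 0) * et)
  vals <- numeric(length(num))
  ok <- den > 1e-300 & ew > 1e-14 * et
  vals[ok] <- num[ok] / den[ok]
  vals <- pmin(1, pmax(-1, vals))
  structure(list(values = vals, sample_rate = rec$sample_rate,
                 alignment = 0),
            class = "correlation_trace")
}

#' @export
print.correlation_trace <- function(x, ...) {
  cat(sprintf("<correlation_trace> %d lags at %g Hz, max %.3f\n",
              length(x$values), x$sample_rate, max(x$values)))
  invisible(x)
}

# all local maxima of v at or above `floor`; returns index vector
local_maxima_above <- function(v, floor) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  core <- which(v[2:(n - 1L)] >= floor &
                v[2:(n - 1L)] >= v[1:(n - 2L)] &
                v[2:(n - 1L)] > v[3:n]) + 1L
  core
}

# greedy non-maximum suppression: keep the higher-scoring peak when two are
# closer than min_sep (times must be sorted ascending). Peaks are visited in
# descending score order; accepting one removes every surviving neighbour
# within min_sep through a doubly linked list, so each peak is touched once.
suppress_peaks <- function(times, scores, min_sep) {
  n <- length(times)
  if (n == 0L || min_sep <= 0) return(seq_along(times))
  nxt <- if (n > 1L) c(2:n, 0L) else 0L
  prv <- 0:(n - 1L)
  alive <- rep(TRUE, n)
  keep <- logical(n)
  for (i in order(-scores)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    j <- nxt[i]
    while (j != 0L && times[j] - times[i] < min_sep) {
      alive[j] <- FALSE
      nxt[i] <- nxt[j]
      if (nxt[j] != 0L) prv[nxt[j]] <- i
      j <- nxt[i]
    }
    j <- prv[i]
    while (j != 0L && times[i] - times[j] < min_sep) {
      alive[j] <- FALSE
      prv[i] <- prv[j]
      if (prv[j] != 0L) nxt[prv[j]] <- i
      j <- prv[i]
    }
  }
  which(keep)
}

#' Detect events as correlation maxima
#'
#' Returns the local maxima of a correlation trace at or above `threshold`,
#' greedily keeping the higher-scoring peak whenever two peaks fall within
#' `min_separation` of each other. Raising the threshold never increases
#' the number of detections.
#'
#' @param trace a `correlation_trace` from [matched_filter()].
#' @param threshold correlation threshold in (0, 1].
#' @param min_separation minimum time between reported detections (s);
#'   default 20 ms, one Single-Click maximum duration.
#' @return A data frame of class `detections` with columns `time_s` (onset
#'   estimate) and `score`, sorted by time. May have zero rows.
#' @export
detect_events <- function(trace, threshold, min_separation = 0.02) {
  if (threshold <= 0 || threshold > 1)
    stop_cavesong("threshold must be in (0, 1]", "cavesong_parameter_error")
  if (min_separation < 0)
    stop_cavesong("min_separation must be >= 0", "cavesong_parameter_error")
  idx <- local_maxima_above(trace$values, threshold)
  times <- (idx - 1L) / trace$sample_rate + trace$alignment
  scores <- trace$values[idx]
  keep <- suppress_peaks(times, scores, min_separation)
  keep <- keep[order(times[keep])]
  structure(data.frame(time_s = times[keep], score = scores[keep]),
            class = c("detections", "data.frame"))
}

#' Score detections against ground-truth annotations
#'
#' One-to-one greedy matching by ascending time difference within
#' `tolerance`; unmatched detections count as false positives, unmatched
#' truths as false negatives. When a ratio is undefined (no detections, or
#' no truths) it is reported as 0 and flagged.
#'
#' @param dets a `detections` data frame (columns `time_s`, `score`).
#' @param truth an [annotations] object (or data frame with `time_s`).
#' @param tolerance matching tolerance in seconds (> 0).
#' @return An object of class `detection_metrics`: counts `tp`, `fp`, `fn`,
#'   ratios `precision` and `recall`, `matching_tolerance`, and logical
#'   flags `precision_undefined`, `recall_undefined`.
#' @export
score_detections <- function(dets, truth, tolerance = 0.01) {
  if (tolerance <= 0)
    stop_cavesong("tolerance must be > 0", "cavesong_parameter_error")
  dt <- dets$time_s
  tt <- sort(truth$time_s)
  pairs_i <- integer(0); pairs_j <- integer(0); pairs_d <- numeric(0)
  if (length(dt) && length(tt)) {
    for (i in seq_along(dt)) {
      lo <- findInterval(dt[i] - tolerance, tt) + 1L
      hi <- findInterval(dt[i] + tolerance, tt)
      if (hi >= lo) {
        js <- lo:hi
        pairs_i <- c(pairs_i, rep(i, length(js)))
        pairs_j <- c(pairs_j, js)
        pairs_d <- c(pairs_d, abs(dt[i] - tt[js]))
      }
    }
  }
  tp <- 0L
  used_d <- logical(length(dt)); used_t <- logical(length(tt))
  for (k in order(pairs_d)) {
    i <- pairs_i[k]; j <- pairs_j[k]
    if (!used_d[i] && !used_t[j]) {
      used_d[i] <- TRUE; used_t[j] <- TRUE; tp <- tp + 1L
    }
  }
  fp <- length(dt) - tp
  fn <- length(tt) - tp
  precision_undefined <- (tp + fp) == 0L
  recall_undefined <- (tp + fn) == 0L
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = if (precision_undefined) 0 else tp / (tp + fp),
                 recall = if (recall_undefined) 0 else tp / (tp + fn),
                 matching_tolerance = tolerance,
                 precision_undefined = precision_undefined,
                 recall_undefined = recall_undefined),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf(
    "<detection_metrics> TP %d  FP %d  FN %d | precision %.3f%s  recall %.3f%s (tol %.3g s)\n",
    x$tp, x$fp, x$fn, x$precision,
    if (x$precision_undefined) " (undefined)" else "",
    x$recall, if (x$recall_undefined) " (undefined)" else "",
    x$matching_tolerance))
  invisible(x)
}

#' Supervised threshold tuning on an annotated segment
#'
#' Mirrors the supervised refinement step of the automated extraction
#' workflow: run the matched filter on an annotated segment, sweep the
#' achievable classification thresholds (the unique suppressed-peak scores
#' above `score_floor`), and pick the operating point whose metrics satisfy
#' the tuning criterion. The criterion follows the rule that at least
#' `target` (default 95\%) of the signals the detector reports must be true
#' signals, accepting a reduced total number of reported signals:
#' `criterion = "precision"` selects the lowest threshold with precision >=
#' `target` (maximizing recall subject to it); `criterion = "recall"`
#' selects the highest threshold with recall >= `target`. Both metrics are
#' always computed and stored. Deterministic given a fixed segment.
#'
#' @param rec a [recording] (the tuning segment, or a longer recording with
#'   `segment` giving the annotated span).
#' @param template a [click_template].
#' @param truth an [annotations] object covering the segment.
#' @param target tuning target in (0, 1); default 0.95.
#' @param segment optional `c(start, end)` seconds restricting tuning to a
#'   sub-span of `rec`.
#' @param criterion `"precision"` (default) or `"recall"`.
#' @param min_separation peak suppression window (s).
#' @param tolerance truth-matching tolerance (s); default 10 ms.
#' @param score_floor lowest candidate threshold considered.
#' @return An object of class `tuned_detector` with fields `template`,
#'   `threshold`, `min_separation`, `criterion`, `target`,
#'   `tuning_metrics` (a `detection_metrics`), and the sweep table
#'   `sweep` (threshold, precision, recall, n_detections).
#' @seealso [predict.tuned_detector()]
#' @export
tune_threshold <- function(rec, template, truth, target = 0.95,
                           segment = NULL,
                           criterion = c("precision", "recall"),
                           min_separation = 0.02, tolerance = 0.01,
                           score_floor = 0.25) {
  criterion <- match.arg(criterion)
  if (target <= 0 || target >= 1)
    stop_cavesong("target must be in (0, 1)", "cavesong_parameter_error")
  tt <- truth$time_s
  if (!is.null(segment)) {
    i0 <- max(0L, as.integer(floor(segment[1L] * rec$sample_rate)))
    i1 <- min(length(rec$samples),
              as.integer(ceiling(segment[2L] * rec$sample_rate)))
    seg_rec <- recording(rec$samples[(i0 + 1L):i1], rec$sample_rate,
                         label = rec$label)
    offset <- i0 / rec$sample_rate
    tt <- tt[tt >= segment[1L] & tt < segment[2L]] - offset
  } else {
    seg_rec <- rec
    offset <- 0
  }
  truth_seg <- data.frame(time_s = tt)

  trace <- matched_filter(seg_rec, template)
  idx <- local_maxima_above(trace$values, score_floor)
  ptimes <- (idx - 1L) / trace$sample_rate
  pscores <- trace$values[idx]
  o <- order(ptimes)
  ptimes <- ptimes[o]; pscores <- pscores[o]

  # Suppress once at the floor: the greedy suppression decision for a peak
  # depends only on higher-scoring peaks, which survive every threshold the
  # peak itself survives, so thresholding the suppressed set is identical to
  # suppressing the thresholded set at every candidate threshold.
  keep0 <- suppress_peaks(ptimes, pscores, min_separation)
  atimes <- ptimes[keep0]
  ascores <- pscores[keep0]
  metrics_at <- function(thr) {
    sel <- ascores >= thr
    score_detections(data.frame(time_s = atimes[sel], score = ascores[sel]),
                     truth_seg, tolerance)
  }
  tts <- sort(tt)
  o2 <- order(-ascores)
  s_sorted <- ascores[o2]
  disjoint <- length(tts) < 2L || min(diff(tts)) > 2 * tolerance
  if (!length(s_sorted)) {
    cands <- numeric(0)
    prec <- rec_ <- numeric(0)
    ndet <- integer(0)
  } else if (disjoint) {
    # truth tolerance windows do not overlap, so each suppressed peak can
    # match at most one truth and one-to-one greedy matching reduces to
    # "a truth is recovered iff any in-tolerance peak is above threshold";
    # sweep all thresholds with one cumulative pass in score order
    lo <- findInterval(atimes - tolerance, tts) + 1L
    hi <- findInterval(atimes + tolerance, tts)
    near <- ifelse(hi >= lo, lo, NA_integer_)
    n_sorted <- near[o2]
    newly <- !is.na(n_sorted) & !duplicated(n_sorted)
    tp_cum <- cumsum(newly)
    runs <- rle(s_sorted)
    grp_last <- cumsum(runs$lengths)
    cands <- runs$values
    ndet <- grp_last
    tp_v <- tp_cum[grp_last]
    prec <- tp_v / ndet
    rec_ <- if (length(tts)) tp_v / length(tts) else rep(0, length(cands))
  } else {
    # overlapping truth windows: score every candidate with the full
    # one-to-one greedy matcher
    cands <- sort(unique(ascores), decreasing = TRUE)
    mets <- lapply(cands, metrics_at)
    prec <- vapply(mets, `[[`, numeric(1), "precision")
    rec_ <- vapply(mets, `[[`, numeric(1), "recall")
    ndet <- vapply(mets, function(m) m$tp + m$fp, integer(1))
  }
  sweep_df <- data.frame(threshold = cands, precision = prec,
                         recall = rec_, n_detections = as.integer(ndet))

  ok <- if (criterion == "precision") prec >= target else rec_ >= target
  if (!length(cands) || !any(ok)) {
    best <- if (length(cands)) {
      metrics_at(cands[which.max(if (criterion == "precision") prec else rec_)])
    } else score_detections(data.frame(time_s = numeric(0), score = numeric(0)),
                            truth_seg, tolerance)
    cond <- structure(
      class = c("cavesong_tuning_failure", "cavesong_error", "error",
                "condition"),
      list(message = sprintf(
        "no threshold reaches %s >= %g (best %s = %.3f)",
        criterion, target, criterion,
        if (criterion == "precision") best$precision else best$recall),
        call = sys.call(), best_metrics = best, sweep = sweep_df))
    stop(cond)
  }
  pick <- if (criterion == "precision") max(which(ok)) else min(which(ok))
  structure(list(template = template, threshold = cands[pick],
                 min_separation = min_separation, criterion = criterion,
                 target = target, tuning_metrics = metrics_at(cands[pick]),
                 matching_tolerance = tolerance, score_floor = score_floor,
                 sweep = sweep_df, segment = segment),
            class = "tuned_detector")
}

#' @export
print.tuned_detector <- function(x, ...) {
  cat(sprintf("<tuned_detector> threshold %.4f (%s >= %g)\n",
              x$threshold, x$criterion, x$target))
  print(x$tuning_metrics)
  invisible(x)
}

#' @export
summary.tuned_detector <- function(object, ...) {
  cat(sprintf(
    "Tuned matched-filter detector\n  template: %s (%d samples at %g Hz)\n",
    if (nzchar(object$template$source)) object$template$source else "(ad hoc)",
    length(object$template$waveform), object$template$sample_rate))
  cat(sprintf("  threshold: %.4f  min separation: %g s\n",
              object$threshold, object$min_separation))
  cat(sprintf("  criterion: %s >= %g on the tuning segment\n",
              object$criterion, object$target))
  print(object$tuning_metrics)
  cat(sprintf("  sweep: %d candidate thresholds in [%.3f, %.3f]\n",
              nrow(object$sweep), min(object$sweep$threshold),
              max(object$sweep$threshold)))
  invisible(object)
}

#' Run a tuned detector on a recording
#'
#' @param object a `tuned_detector` from [tune_threshold()].
#' @param rec a [recording].
#' @param ... unused.
#' @return A `detections` data frame.
#' @export
predict.tuned_detector <- function(object, rec, ...) {
  trace <- matched_filter(rec, object$template)
  detect_events(trace, object$threshold, object$min_separation)
}
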