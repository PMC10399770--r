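#' Recording objects
#'
#' A `recording` holds a uniformly sampled amplitude waveform together with
#' its sample rate, a free-text site/line label and the offset (in seconds)
#' of its first sample relative to the origin of the source file. Amplitudes
#' are dimensionless and nominally in \[-1, 1\]. All times in the package are
#' seconds from the recording start, 0-based, with half-open event windows
#' `[onset, offset)`.
#'
#' @param samples numeric vector of amplitudes.
#' @param sample_rate sampling rate in Hz (> 0).
#' @param label free-text identifier (cave or lab line).
#' @param start_offset seconds from the source-file origin.
#' @return An object of class `recording`.
#' @examples
#' rec <- recording(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 8000)), 8000)
#' duration(rec)
#' @export
recording <- function(samples, sample_rate, label = "", start_offset = 0) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L)
    stop_cavesong("recording has no samples", "cavesong_empty_input")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop_cavesong("sample_rate must be a single positive number",
                  "cavesong_parameter_error")
  structure(list(samples = samples, sample_rate = as.numeric(sample_rate),
                 label = as.character(label),
                 start_offset = as.numeric(start_offset)),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s: %.3f s at %g Hz (%d samples)\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              duration(x), x$sample_rate, length(x$samples)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a `recording`.
#' @return Duration in seconds.
#' @export
duration <- function(rec) length(rec$samples) / rec$sample_rate

## ---- WAV I/O -------------------------------------------------------------
## Minimal RIFF/WAVE codec: PCM 16/24-bit and IEEE float32, mono or
## multichannel. Unknown chunks are skipped.

#' Read a WAV file into a recording
#'
#' Supports PCM 16-bit, PCM 24-bit and IEEE float 32-bit encodings.
#' Amplitudes are rescaled to \[-1, 1\]. For multichannel files either a
#' single channel is extracted or all channels are averaged (`"mix"`, the
#' default — field recordings here are effectively single-hydrophone).
#'
#' @param path path to a WAV file.
#' @param channel integer channel index (1-based) or `"mix"` to average.
#' @param label label stored on the returned recording.
#' @return A [recording].
#' @seealso [write_wav()]
#' @export
read_wav <- function(path, channel = "mix", label = "") {
  if (!file.exists(path))
    stop_cavesong(paste0("file not found: ", path), "cavesong_io_error")
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop_cavesong("not a RIFF/WAVE file", "cavesong_format_error")
  readBin(con, "integer", 1L, 4L, endian = "little")  # chunk size, unused
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop_cavesong("not a RIFF/WAVE file", "cavesong_format_error")

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        code = readBin(body[1:2], "integer", 1L, 2L, signed = FALSE,
                       endian = "little"),
        channels = readBin(body[3:4], "integer", 1L, 2L, signed = FALSE,
                           endian = "little"),
        rate = readBin(body[5:8], "integer", 1L, 4L, endian = "little"),
        bits = readBin(body[15:16], "integer", 1L, 2L, signed = FALSE,
                       endian = "little"))
      # WAVE_FORMAT_EXTENSIBLE: true code lives in the extension
      if (fmt$code == 65534L && sz >= 40L)
        fmt$code <- readBin(body[25:26], "integer", 1L, 2L, signed = FALSE,
                            endian = "little")
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2L == 1L) readBin(con, "raw", 1L)
    } else {
      seek(con, sz + sz %% 2L, origin = "current")
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop_cavesong("missing fmt or data chunk", "cavesong_format_error")
  if (length(data_raw) == 0L)
    stop_cavesong("zero-length audio", "cavesong_empty_input")

  x <- decode_wav_samples(data_raw, fmt)
  nch <- fmt$channels
  if (nch > 1L) {
    m <- matrix(x, nrow = nch)
    if (identical(channel, "mix")) {
      x <- colMeans(m)
    } else {
      ch <- as.integer(channel)
      if (is.na(ch) || ch < 1L || ch > nch)
        stop_cavesong(sprintf("channel %s not in 1..%d", channel, nch),
                      "cavesong_parameter_error")
      x <- m[ch, ]
    }
  }
  recording(x, fmt$rate, label = label)
}

decode_wav_samples <- function(raw, fmt) {
  if (fmt$code == 1L && fmt$bits == 16L) {
    readBin(raw, "integer", length(raw) / 2L, 2L, signed = TRUE,
            endian = "little") / 32768
  } else if (fmt$code == 1L && fmt$bits == 24L) {
    n <- length(raw) / 3L
    b <- matrix(as.integer(raw), nrow = 3L)
    v <- b[1L, ] + 256 * b[2L, ] + 65536 * b[3L, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else if (fmt$code == 3L && fmt$bits == 32L) {
    readBin(raw, "double", length(raw) / 4L, 4L, endian = "little")
  } else {
    stop_cavesong(sprintf("unsupported WAV encoding (format %d, %d bit)",
                          fmt$code, fmt$bits), "cavesong_format_error")
  }
}

#' Write a recording to a WAV file
#'
#' @param rec a [recording] (or bare numeric vector with `sample_rate`).
#' @param path output path.
#' @param bit_depth 16 (PCM) or 32 (IEEE float).
#' @param sample_rate required when `rec` is a bare numeric vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, bit_depth = 16, sample_rate = NULL) {
  if (is.numeric(rec)) rec <- recording(rec, sample_rate)
  x <- rec$samples
  rate <- as.integer(round(rec$sample_rate))
  con <- file(path, "wb")
  on.exit(close(con))
  if (bit_depth == 16) {
    code <- 1L; bytes <- 2L
    pcm <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
  } else if (bit_depth == 32) {
    code <- 3L; bytes <- 4L
  } else {
    stop_cavesong("bit_depth must be 16 or 32", "cavesong_parameter_error")
  }
  nbytes <- length(x) * bytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nbytes), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(code, con, 2L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")                # channels
  writeBin(rate, con, 4L, endian = "little")
  writeBin(as.integer(rate * bytes), con, 4L, endian = "little")
  writeBin(bytes, con, 2L, endian = "little")             # block align
  writeBin(as.integer(bit_depth), con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(nbytes), con, 4L, endian = "little")
  if (bit_depth == 16) writeBin(pcm, con, 2L, endian = "little")
  else writeBin(x, con, 4L, endian = "little")
  invisible(path)
}

## ---- resampling ----------------------------------------------------------

#' Resample a recording
#'
#' Band-limited polyphase resampling (via [signal::resample()]) at the best
#' rational approximation of `target_rate / sample_rate`. Duration is
#' preserved to within one sample period; content below the target Nyquist
#' is preserved without aliasing.
#'
#' @param rec a [recording].
#' @param target_rate target sampling rate in Hz (> 0).
#' @return A resampled [recording].
#' @export
resample <- function(rec, target_rate) {
  if (!is.numeric(target_rate) || length(target_rate) != 1L ||
      target_rate <= 0)
    stop_cavesong("target_rate must be a single positive number",
                  "cavesong_parameter_error")
  if (isTRUE(all.equal(target_rate, rec$sample_rate))) return(rec)
  pq <- rational_approx(target_rate / rec$sample_rate)
  y <- signal::resample(rec$samples, pq[["p"]], pq[["q"]])
  n_expect <- round(length(rec$samples) * target_rate / rec$sample_rate)
  if (length(y) > n_expect) y <- y[seq_len(n_expect)]
  if (length(y) < n_expect) y <- c(y, numeric(n_expect - length(y)))
  recording(y, target_rate, label = rec$label,
            start_offset = rec$start_offset)
}

## ---- annotations ----------------------------------------------------------

#' Ground-truth annotation sets
#'
#' An `annotations` object is a data frame of known sound events for one
#' recording, with columns `time_s` (event onset, seconds), `event_type`
#' (`"single"` or `"serial"`) and `pulse_count` (integer, `NA` for singles).
#' Entries are kept sorted by time.
#'
#' @param time_s numeric onset times in seconds.
#' @param event_type character vector, `"single"` or `"serial"`.
#' @param pulse_count integer pulse counts (optional).
#' @param recording_id identifier of the annotated recording.
#' @return A data frame of class `annotations`.
#' @export
annotations <- function(time_s = numeric(0),
                        event_type = character(0),
                        pulse_count = NULL,
                        recording_id = "") {
  if (is.null(pulse_count)) pulse_count <- rep(NA_integer_, length(time_s))
  bad <- !event_type %in% c("single", "serial")
  if (any(bad))
    stop_cavesong(paste0("unknown event_type: ",
                         paste(unique(event_type[bad]), collapse = ", ")),
                  "cavesong_parse_error")
  df <- data.frame(time_s = as.numeric(time_s),
                   event_type = as.character(event_type),
                   pulse_count = as.integer(pulse_count),
                   stringsAsFactors = FALSE)
  df <- df[order(df$time_s), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, recording_id = as.character(recording_id),
            class = c("annotations", "data.frame"))
}

#' Read event annotations from CSV
#'
#' Expects a UTF-8 CSV with a header row and columns `time_s`, `event_type`
#' and optionally `pulse_count`. Rows are returned sorted by time; an
#' unparseable row raises an error naming its line.
#'
#' @param path CSV path.
#' @param recording_id identifier stored on the result.
#' @return An [annotations] data frame.
#' @export
read_annotations <- function(path, recording_id = "") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "event_type")
  if (!all(need %in% names(df)))
    stop_cavesong("annotation CSV must have columns time_s, event_type",
                  "cavesong_parse_error")
  times <- suppressWarnings(as.numeric(df$time_s))
  if (anyNA(times)) {
    line <- which(is.na(times))[1L] + 1L  # +1 for header
    stop_cavesong(sprintf("unparseable time_s at line %d of %s", line, path),
                  "cavesong_parse_error")
  }
  bad <- !df$event_type %in% c("single", "serial")
  if (any(bad)) {
    line <- which(bad)[1L] + 1L
    stop_cavesong(sprintf("unknown event_type at line %d of %s", line, path),
                  "cavesong_parse_error")
  }
  pc <- if ("pulse_count" %in% names(df))
    suppressWarnings(as.integer(df$pulse_count)) else NULL
  annotations(times, df$event_type, pc, recording_id = recording_id)
}

#' Write event annotations to CSV
#'
#' @param ann an [annotations] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  utils::write.csv(as.data.frame(ann)[, c("time_s", "event_type",
                                          "pulse_count")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
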