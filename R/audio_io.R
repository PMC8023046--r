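# Reading, writing and validity screening of auscultation recordings.
#
# Recordings are mono amplitude vectors in [-1, 1] with a sample rate and
# clinical metadata (age in months, sex, chest location 1-6: locations 1-4
# posterior, 5-6 anterior). Time coordinates are seconds from recording start;
# events elsewhere in the package use half-open intervals [onset, onset+dur).

#' Construct a recording object
#'
#' @param samples numeric vector of amplitudes; rescaled to lie in `[-1, 1]`
#'   if any exceed full scale.
#' @param sample_rate sampling rate in Hz (positive integer).
#' @param recording_id opaque identifier string.
#' @param age_months patient age in months (`NA` if unknown).
#' @param sex one of `"male"`, `"female"`, `"unknown"`.
#' @param chest_location auscultation point 1-6 (1-4 posterior, 5-6 anterior),
#'   or `NA` when not applicable (e.g. synthetic audio).
#' @return an object of class `recording`.
#' @export
recording <- function(samples, sample_rate, recording_id = "rec",
                      age_months = NA_real_, sex = "unknown",
                      chest_location = NA_integer_) {
  if (!is.numeric(samples) || length(samples) == 0)
    stop("samples must be a non-empty numeric vector")
  if (!all(is.finite(samples)))
    stop("samples must all be finite")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    stop("sample_rate must be a positive number")
  sex <- match.arg(sex, c("male", "female", "unknown"))
  if (!is.na(chest_location)) {
    chest_location <- as.integer(chest_location)
    if (!chest_location %in% 1:6)
      stop("chest_location must be in 1..6")
  }
  if (!is.na(age_months) && age_months < 0)
    stop("age_months must be non-negative")
  peak <- max(abs(samples))
  if (peak > 1) samples <- samples / peak
  structure(
    list(recording_id = as.character(recording_id),
         samples = as.numeric(samples),
         sample_rate = as.integer(round(sample_rate)),
         age_months = as.numeric(age_months),
         sex = sex,
         chest_location = if (is.na(chest_location)) NA_integer_ else chest_location),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording %s: %.2f s @ %d Hz, location %s, age %s mo, %s>\n",
              x$recording_id, duration_seconds(x), x$sample_rate,
              ifelse(is.na(x$chest_location), "?", x$chest_location),
              ifelse(is.na(x$age_months), "?", format(x$age_months)), x$sex))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a `recording`.
#' @return duration in seconds.
#' @export
duration_seconds <- function(rec) length(rec$samples) / rec$sample_rate

# ---------------------------------------------------------------------------
# WAV codec. Minimal RIFF reader/writer supporting PCM 16-bit and IEEE
# float32, the two encodings used by electronic stethoscope exports. Chunks
# other than fmt/data (LIST, fact, ...) are skipped.

#' Read a WAV file as a recording
#'
#' Multi-channel audio is averaged to mono; samples are rescaled only if the
#' decoded amplitudes exceed full scale, so the encoding's quantization levels
#' are preserved. The file's sample rate is kept (see [resample_recording()]
#' for rate conversion).
#'
#' @param path path to a RIFF WAV file (PCM 16-bit or IEEE float32).
#' @param recording_id identifier to attach; default is the file name.
#' @param age_months,sex,chest_location metadata passed to [recording()].
#' @return a `recording`.
#' @export
read_wav <- function(path, recording_id = NULL, age_months = NA_real_,
                     sex = "unknown", chest_location = NA_integer_) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(sz) == 0) break
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      if (sz %% 2 == 1) readBin(con, "raw", 1)
      u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
      u32 <- function(off) sum(as.numeric(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
      fmt <- list(format = u16(0), channels = u16(2), rate = u32(4),
                  bits = u16(14))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      if (fmt$format == 1 && fmt$bits == 16) {
        samples <- readBin(con, "integer", n = sz / 2, size = 2,
                           signed = TRUE, endian = "little") / 32768
      } else if (fmt$format == 3 && fmt$bits == 32) {
        samples <- readBin(con, "numeric", n = sz / 4, size = 4,
                           endian = "little")
      } else {
        stop(sprintf("unsupported WAV encoding (format %d, %d-bit)",
                     fmt$format, fmt$bits))
      }
      if (sz %% 2 == 1) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", sz + (sz %% 2))  # skip unknown chunk
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples) || length(samples) == 0)
    stop("WAV file contains no audio samples: ", path)
  if (fmt$channels > 1) {
    n <- floor(length(samples) / fmt$channels)
    samples <- rowMeans(matrix(samples[seq_len(n * fmt$channels)],
                               ncol = fmt$channels, byrow = TRUE))
  }
  if (is.null(recording_id))
    recording_id <- sub("\\.wav$", "", basename(path), ignore.case = TRUE)
  recording(samples, fmt$rate, recording_id, age_months, sex, chest_location)
}

#' Write a recording to a WAV file
#'
#' @param rec a `recording` (or numeric vector with `sample_rate` given).
#' @param path output path.
#' @param encoding `"pcm16"` (default) or `"float32"`.
#' @param sample_rate required when `rec` is a bare numeric vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, encoding = c("pcm16", "float32"),
                      sample_rate = NULL) {
  encoding <- match.arg(encoding)
  if (is.numeric(rec)) {
    if (is.null(sample_rate)) stop("sample_rate required for a bare vector")
    rec <- recording(rec, sample_rate)
  }
  x <- pmax(pmin(rec$samples, 1), -1)
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- if (encoding == "pcm16") 2L else 4L
  data_sz <- length(x) * nbytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_sz), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(as.integer(if (encoding == "pcm16") 1 else 3), con, size = 2,
           endian = "little")
  writeBin(1L, con, size = 2, endian = "little")  # mono
  writeBin(as.integer(rec$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(rec$sample_rate * nbytes), con, size = 4, endian = "little")
  writeBin(as.integer(nbytes), con, size = 2, endian = "little")
  writeBin(as.integer(8 * nbytes), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, size = 4, endian = "little")
  if (encoding == "pcm16") {
    q <- as.integer(pmax(pmin(round(x * 32768), 32767), -32768))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Resample a recording
#'
#' Polyphase resampling (via [signal::resample()]) to a target rate. The
#' package's canonical analysis rate is 8000 Hz: lung-sound energy lies well
#' below 4 kHz, so recordings at other device rates are converted on load by
#' the pipeline.
#'
#' @param rec a `recording`.
#' @param rate target sample rate in Hz (default 8000).
#' @return a `recording` at `rate`.
#' @export
resample_recording <- function(rec, rate = 8000) {
  if (rec$sample_rate == rate) return(rec)
  g <- gcd_int(as.integer(rate), rec$sample_rate)
  y <- signal::resample(rec$samples, as.integer(rate) / g, rec$sample_rate / g)
  recording(y, rate, rec$recording_id, rec$age_months, rec$sex,
            rec$chest_location)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

# ---------------------------------------------------------------------------
# Validity screening

#' Screen a recording for acceptability
#'
#' A recording is rejected as `too_short` when its duration is below
#' `min_duration` (default 9 s, the length needed to capture at least two
#' breathing cycles), or as `low_quality` when more than `clip_fraction_max`
#' of its samples sit at full scale (clipping) or when the signal is
#' essentially dead (RMS below 1e-5).
#'
#' @param rec a `recording`.
#' @param min_duration minimum duration in seconds (default 9).
#' @param clip_fraction_max maximum tolerated fraction of clipped samples
#'   (default 0.01).
#' @return a list with elements `accepted` (logical) and `reason`
#'   (`"ok"`, `"too_short"` or `"low_quality"`), class `validation_result`.
#' @export
validate_recording <- function(rec, min_duration = 9.0,
                               clip_fraction_max = 0.01) {
  stopifnot(inherits(rec, "recording"))
  reason <- "ok"
  if (duration_seconds(rec) < min_duration) {
    reason <- "too_short"
  } else {
    clipped <- mean(abs(rec$samples) >= 0.999)
    rms <- sqrt(mean(rec$samples^2))
    if (clipped > clip_fraction_max || rms < 1e-5) reason <- "low_quality"
  }
  structure(list(accepted = reason == "ok", reason = reason),
            class = "validation_result")
}

# ---------------------------------------------------------------------------
# Metadata manifests: CSV with header
# recording_id,age_months,sex,chest_location,path

#' Read a recording manifest
#'
#' @param path CSV file with columns
#'   `recording_id,age_months,sex,chest_location,path`. Unknown age/sex are
#'   permitted (empty or NA); `chest_location` must be 1-6 or NA.
#' @return a data.frame.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("recording_id", "age_months", "sex", "chest_location", "path")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols))
    stop("manifest missing columns: ", paste(missing_cols, collapse = ", "))
  bad <- !is.na(m$chest_location) & !m$chest_location %in% 1:6
  if (any(bad))
    stop("invalid chest_location for: ",
         paste(m$recording_id[bad], collapse = ", "))
  m
}

#' Write a recording manifest
#' @param manifest data.frame as in [read_manifest()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
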