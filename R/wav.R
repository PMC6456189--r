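#' Read a PCM WAV file
#'
#' Reads an uncompressed RIFF/WAVE file (PCM, 16- or 24-bit) and returns an
#' \code{audio_recording}: one column of normalized samples per channel.
#' Lapel-microphone interview sessions are stored as 2-channel files, one
#' channel per speaker; the caller maps channel index to speaker role.
#'
#' @param path Path to a PCM WAV file.
#' @param require_stereo If \code{TRUE} (default), error unless the file has
#'   exactly 2 channels, as the dyadic pipeline requires.
#' @return An object of class \code{audio_recording}: a list with
#'   \code{samples} (numeric matrix, one column per channel, values in
#'   \[-1, 1\]), \code{sample_rate} (Hz), \code{n_channels} and
#'   \code{duration} (seconds).
#' @export
read_wav <- function(path, require_stereo = TRUE) {
  if (!file.exists(path)) {
    stop("WAV file not found: ", path)
  }
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = .le_uint(body[1:2]),
        n_channels   = .le_uint(body[3:4]),
        sample_rate  = .le_uint(body[5:8]),
        bits         = .le_uint(body[15:16])
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2L == 1L) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV (missing fmt or data chunk): ", path)
  if (fmt$audio_format != 1L) stop("only PCM WAV is supported (format tag ", fmt$audio_format, ")")
  if (!fmt$bits %in% c(16L, 24L)) stop("only 16/24-bit PCM supported, got ", fmt$bits, "-bit")

  nch <- fmt$n_channels
  if (require_stereo && nch != 2L) {
    stop("expected a 2-channel recording (one channel per speaker), got ",
         nch, " channel", if (nch != 1L) "s")
  }

  bytes_per <- fmt$bits %/% 8L
  n_total <- length(data_raw) %/% bytes_per
  if (fmt$bits == 16L) {
    vals <- readBin(data_raw, "integer", n_total, size = 2, signed = TRUE,
                    endian = "little")
    x <- vals / 32767
  } else {
    m <- matrix(as.integer(data_raw[seq_len(n_total * 3L)]), nrow = 3L)
    vals <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    vals <- ifelse(vals >= 8388608, vals - 16777216, vals)
    x <- vals / 8388607
  }
  samples <- matrix(x, ncol = nch, byrow = TRUE)
  audio_recording(samples, fmt$sample_rate)
}

.le_uint <- function(bytes) {
  sum(as.integer(bytes) * 256^(seq_along(bytes) - 1L))
}

#' Construct an audio recording object
#'
#' @param samples Numeric vector (mono) or matrix with one column per channel,
#'   amplitudes in \[-1, 1\].
#' @param sample_rate Sampling rate in Hz (>= 8000 for pipeline use).
#' @return An \code{audio_recording} list.
#' @export
audio_recording <- function(samples, sample_rate) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  stopifnot(is.matrix(samples), is.numeric(samples), sample_rate > 0)
  structure(
    list(
      samples = samples,
      sample_rate = as.numeric(sample_rate),
      n_channels = ncol(samples),
      duration = nrow(samples) / sample_rate
    ),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording> %d channel(s), %.0f Hz, %.2f s (%d samples/channel)\n",
              x$n_channels, x$sample_rate, x$duration, nrow(x$samples)))
  invisible(x)
}

#' Write a PCM WAV file
#'
#' Writes 16-bit little-endian PCM. Amplitudes are clipped to \[-1, 1\] and
#' quantized as \code{round(x * 32767)}; reading the file back with
#' \code{\link{read_wav}} recovers the quantized samples exactly.
#'
#' @param recording An \code{audio_recording} (or numeric matrix/vector).
#' @param path Output file path.
#' @param sample_rate Required when \code{recording} is a bare matrix/vector.
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(recording, path, sample_rate = NULL) {
  if (inherits(recording, "audio_recording")) {
    samples <- recording$samples
    sample_rate <- recording$sample_rate
  } else {
    if (is.null(sample_rate)) stop("sample_rate required for raw samples")
    samples <- if (is.matrix(recording)) recording else matrix(recording, ncol = 1)
  }
  nch <- ncol(samples)
  x <- pmin(1, pmax(-1, t(samples)))        # interleave channels
  vals <- as.integer(round(as.vector(x) * 32767))
  n_bytes <- length(vals) * 2L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")               # PCM
  writeBin(as.integer(nch), con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * nch * 2L), con, size = 4, endian = "little")
  writeBin(as.integer(nch * 2L), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(vals, con, size = 2, endian = "little")
  invisible(path)
}
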