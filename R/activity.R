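#' Framing configuration
#'
#' Frame-level descriptors are computed from short overlapping analysis
#' windows: 30 ms segments taken at a fixed 10 ms interval by default. Frame
#' \code{i} (0-based) covers the half-open interval
#' \code{[i * hop, i * hop + window)} seconds.
#'
#' @param window Analysis window length in seconds (default 0.030).
#' @param hop Hop between consecutive frames in seconds (default 0.010).
#' @return A \code{frame_config} list.
#' @export
frame_config <- function(window = 0.030, hop = 0.010) {
  if (!(hop > 0 && hop <= window)) stop("need 0 < hop <= window")
  structure(list(window = window, hop = hop), class = "frame_config")
}

#' Number of analysis frames in a signal
#'
#' \code{floor((n_samples - window_samples) / hop_samples) + 1}, i.e. every
#' frame must fit entirely inside the signal.
#'
#' @param n_samples Signal length in samples.
#' @param config A \code{\link{frame_config}}.
#' @param sample_rate Sampling rate in Hz.
#' @return Integer frame count.
#' @export
frame_count <- function(n_samples, config = frame_config(), sample_rate) {
  w <- round(config$window * sample_rate)
  h <- round(config$hop * sample_rate)
  if (n_samples < w) stop("signal shorter than one analysis window")
  as.integer(floor((n_samples - w) / h) + 1L)
}

#' Per-frame RMS level in dBFS
#'
#' @param channel Numeric amplitude vector in \[-1, 1\].
#' @param sample_rate Sampling rate in Hz.
#' @param config A \code{\link{frame_config}}.
#' @param floor_db Level assigned to all-zero frames (default -120).
#' @return Numeric vector, one dBFS value per frame.
#' @export
frame_rms_db <- function(channel, sample_rate, config = frame_config(),
                         floor_db = -120) {
  w <- round(config$window * sample_rate)
  h <- round(config$hop * sample_rate)
  n <- frame_count(length(channel), config, sample_rate)
  cs <- c(0, cumsum(channel^2))
  starts <- (seq_len(n) - 1L) * h
  energy <- cs[starts + w + 1L] - cs[starts + 1L]
  rms <- sqrt(energy / w)
  db <- rep(floor_db, n)
  pos <- rms > 0
  db[pos] <- pmax(floor_db, 20 * log10(rms[pos]))
  db
}

#' Energy-threshold voice activity detection for one channel
#'
#' A frame is provisionally active when its RMS level exceeds
#' \code{threshold_db} (dB re full scale). The provisional stream is then
#' smoothed: first, inactive gaps shorter than \code{min_pause} lying between
#' active runs are filled; second, active runs shorter than
#' \code{min_speech} are deleted. Filling before deleting prevents a
#' fragmented utterance from being discarded piecemeal.
#'
#' @param channel Numeric amplitude vector.
#' @param sample_rate Sampling rate in Hz.
#' @param config A \code{\link{frame_config}}.
#' @param threshold_db Activity threshold in dBFS (default -40).
#' @param min_speech Minimum retained speech-run duration, seconds (default 0.1).
#' @param min_pause Maximum filled gap duration, seconds (default 0.2).
#' @return Logical vector, one activity flag per frame.
#' @export
detect_activity <- function(channel, sample_rate, config = frame_config(),
                            threshold_db = -40, min_speech = 0.1,
                            min_pause = 0.2) {
  raw <- frame_rms_db(channel, sample_rate, config) > threshold_db
  smooth_activity(raw, config$hop, min_speech = min_speech,
                  min_pause = min_pause)
}

#' Fill-then-delete smoothing of a binary activity stream
#'
#' @param active Logical per-frame stream.
#' @param hop Frame hop in seconds.
#' @param min_speech,min_pause Durations in seconds; see
#'   \code{\link{detect_activity}}.
#' @return Smoothed logical vector of the same length.
#' @export
smooth_activity <- function(active, hop, min_speech = 0.1, min_pause = 0.2) {
  n <- length(active)
  if (n == 0L) return(logical(0))
  # fill interior inactive gaps shorter than min_pause
  r <- rle(active)
  if (length(r$lengths) > 2L) {
    interior <- seq(2L, length(r$lengths) - 1L)
    fill <- interior[!r$values[interior] &
                       r$lengths[interior] * hop < min_pause]
    r$values[fill] <- TRUE
  }
  filled <- inverse.rle(r)
  # delete active runs shorter than min_speech
  r <- rle(filled)
  short <- r$values & (r$lengths * hop < min_speech)
  r$values[short] <- FALSE
  inverse.rle(r)
}

#' Paired per-frame activity streams for a dyad
#'
#' @param active_a,active_b Logical per-frame streams of equal length.
#' @param hop Frame hop in seconds.
#' @param window Frame window in seconds (metadata; default 0.030).
#' @return A \code{dyad_activity} list with fields \code{active_a},
#'   \code{active_b}, \code{frame_hop}, \code{frame_window}, \code{n_frames}.
#' @export
dyad_activity <- function(active_a, active_b, hop = 0.010, window = 0.030) {
  stopifnot(is.logical(active_a), is.logical(active_b))
  if (length(active_a) != length(active_b)) {
    stop("activity streams must share the frame grid")
  }
  if (length(active_a) < 1L) stop("need at least one frame")
  structure(
    list(active_a = active_a, active_b = active_b,
         frame_hop = hop, frame_window = window,
         n_frames = length(active_a)),
    class = "dyad_activity"
  )
}

#' @export
print.dyad_activity <- function(x, ...) {
  cat(sprintf(
    "<dyad_activity> %d frames @ %.0f ms hop (%.1f s); A active %.1f%%, B active %.1f%%\n",
    x$n_frames, x$frame_hop * 1000, x$n_frames * x$frame_hop,
    100 * mean(x$active_a), 100 * mean(x$active_b)))
  invisible(x)
}

#' Voice activity detection on both channels of a recording
#'
#' @param recording A 2-channel \code{\link{audio_recording}}.
#' @param config A \code{\link{frame_config}}.
#' @param threshold_db,min_speech,min_pause VAD parameters; see
#'   \code{\link{detect_activity}}.
#' @return A \code{\link{dyad_activity}} on the shared frame grid; channel 1
#'   becomes speaker A, channel 2 speaker B.
#' @export
build_dyad_activity <- function(recording, config = frame_config(),
                                threshold_db = -40, min_speech = 0.1,
                                min_pause = 0.2) {
  if (recording$n_channels != 2L) {
    stop("expected a 2-channel recording (one channel per speaker), got ",
         recording$n_channels)
  }
  a <- detect_activity(recording$samples[, 1], recording$sample_rate, config,
                       threshold_db, min_speech, min_pause)
  b <- detect_activity(recording$samples[, 2], recording$sample_rate, config,
                       threshold_db, min_speech, min_pause)
  dyad_activity(a, b, hop = config$hop, window = config$window)
}

#' Activity stream as a data frame
#'
#' @param activity A \code{\link{dyad_activity}}.
#' @return Data frame with \code{frame_index} (0-based), \code{t_start_s},
#'   \code{active_a}, \code{active_b}; suitable for \code{write.csv}.
#' @export
activity_as_data_frame <- function(activity) {
  idx <- seq_len(activity$n_frames) - 1L
  data.frame(frame_index = idx,
             t_start_s = idx * activity$frame_hop,
             active_a = activity$active_a,
             active_b = activity$active_b)
}
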