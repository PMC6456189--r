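#' Frame-level prosodic descriptors
#'
#' Computes, per analysis frame (30 ms window / 10 ms hop by default),
#' restricted to frames where \code{mask} is true:
#' \itemize{
#'   \item \code{volume_db}: frame RMS level in dBFS;
#'   \item \code{f0_hz}: fundamental frequency by the normalized
#'     autocorrelation method, searched in \code{f0_range}; a frame is voiced
#'     when the autocorrelation peak ratio exceeds \code{voicing_threshold}.
#'     F0 is reported at the integer-lag peak, keeping the track exactly
#'     constant on stationary signals;
#'   \item \code{f1_hz, f2_hz, f3_hz}: the three lowest formants from LPC
#'     root angles (order \code{2 + sample_rate/1000}), voiced frames only;
#'   \item \code{mfcc}: 13 mel-frequency cepstral coefficients from a 26-band
#'     mel filterbank.
#' }
#' Frames outside the mask carry \code{NA} (and all-\code{NA} rows when the
#' mask is entirely false).
#'
#' @param recording An \code{\link{audio_recording}}.
#' @param channel Channel index (1-based).
#' @param config A \code{\link{frame_config}}.
#' @param mask Logical per-frame mask (the speaker's own activity stream);
#'   \code{NULL} means all frames.
#' @param f0_range F0 search band in Hz (default c(70, 400)).
#' @param voicing_threshold Autocorrelation peak ratio above which a frame is
#'   voiced (default 0.45).
#' @return A \code{frame_descriptors} list: vectors \code{volume_db},
#'   \code{f0_hz}, \code{f1_hz}, \code{f2_hz}, \code{f3_hz}, a matrix
#'   \code{mfcc} (frames x 13), and \code{n_frames}.
#' @export
extract_descriptors <- function(recording, channel = 1L,
                                config = frame_config(), mask = NULL,
                                f0_range = c(70, 400),
                                voicing_threshold = 0.45) {
  x <- recording$samples[, channel]
  sr <- recording$sample_rate
  w <- round(config$window * sr)
  h <- round(config$hop * sr)
  n <- frame_count(length(x), config, sr)
  if (is.null(mask)) mask <- rep(TRUE, n)
  nf <- min(n, length(mask))

  lag_min <- max(2L, floor(sr / f0_range[2]))
  lag_max <- min(w - 1L, ceiling(sr / f0_range[1]))
  lpc_order <- as.integer(2 + round(sr / 1000))
  mel_fb <- .mel_filterbank(n_filters = 26L, n_fft = .next_pow2(w), sr = sr)
  ham <- 0.54 - 0.46 * cos(2 * pi * (0:(w - 1)) / (w - 1))

  volume_db <- rep(NA_real_, nf)
  f0 <- rep(NA_real_, nf)
  fmts <- matrix(NA_real_, nf, 3)
  mfcc <- matrix(NA_real_, nf, 13)

  for (i in seq_len(nf)) {
    if (!mask[i]) next
    seg <- x[((i - 1L) * h + 1L):((i - 1L) * h + w)]
    rms <- sqrt(mean(seg^2))
    volume_db[i] <- if (rms > 0) max(-120, 20 * log10(rms)) else -120

    segc <- seg - mean(seg)
    r0 <- sum(segc^2)
    if (r0 > 0) {
      ac <- .autocorr(segc, lag_max)
      band <- ac[(lag_min + 1L):(lag_max + 1L)] / r0
      k <- which.max(band)
      if (band[k] > voicing_threshold) {
        f0[i] <- sr / (lag_min + k - 1L)
        fmts[i, ] <- .lpc_formants(seg, sr, lpc_order)
      }
    }
    mfcc[i, ] <- .mfcc_frame(seg * ham, mel_fb)
  }

  structure(
    list(volume_db = volume_db, f0_hz = f0,
         f1_hz = fmts[, 1], f2_hz = fmts[, 2], f3_hz = fmts[, 3],
         mfcc = mfcc, n_frames = nf),
    class = "frame_descriptors"
  )
}

.next_pow2 <- function(n) 2^ceiling(log2(n))

# autocorrelation up to max_lag via FFT
.autocorr <- function(x, max_lag) {
  n <- length(x)
  nfft <- .next_pow2(2L * n)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  ac <- Re(stats::fft(X * Conj(X), inverse = TRUE)) / nfft
  ac[seq_len(max_lag + 1L)]
}

# LPC by the autocorrelation method; formants from pole angles.
.lpc_formants <- function(seg, sr, order, max_bandwidth = 600) {
  seg <- seg - mean(seg)
  seg <- c(seg[1], seg[-1] - 0.97 * seg[-length(seg)])  # pre-emphasis
  w <- length(seg)
  seg <- seg * (0.54 - 0.46 * cos(2 * pi * (0:(w - 1)) / (w - 1)))
  r <- .autocorr(seg, order)
  if (r[1] <= 0) return(c(NA_real_, NA_real_, NA_real_))
  a <- tryCatch(
    solve(stats::toeplitz(r[seq_len(order)]), -r[2:(order + 1L)]),
    error = function(e) NULL
  )
  if (is.null(a)) return(c(NA_real_, NA_real_, NA_real_))
  roots <- polyroot(c(1, a))
  ang <- Arg(roots)
  freq <- ang * sr / (2 * pi)
  bw <- -sr / pi * log(pmin(Mod(roots), 0.9999))
  keep <- ang > 0 & freq > 90 & freq < sr / 2 - 50 & bw < max_bandwidth
  fr <- sort(freq[keep])
  c(fr[1], fr[2], fr[3])  # NA-padded automatically when fewer than 3
}

.mel <- function(f) 2595 * log10(1 + f / 700)
.mel_inv <- function(m) 700 * (10^(m / 2595) - 1)

.mel_filterbank <- function(n_filters, n_fft, sr) {
  n_bins <- n_fft %/% 2L + 1L
  edges <- .mel_inv(seq(.mel(0), .mel(sr / 2), length.out = n_filters + 2L))
  bin_freq <- (0:(n_bins - 1L)) * sr / n_fft
  fb <- matrix(0, n_filters, n_bins)
  for (m in seq_len(n_filters)) {
    lo <- edges[m]; ce <- edges[m + 1L]; hi <- edges[m + 2L]
    up <- (bin_freq - lo) / (ce - lo)
    down <- (hi - bin_freq) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

.mfcc_frame <- function(seg, mel_fb) {
  n_fft <- 2L * (ncol(mel_fb) - 1L)
  spec <- stats::fft(c(seg, rep(0, n_fft - length(seg))))
  power <- Mod(spec[seq_len(ncol(mel_fb))])^2
  loge <- log(pmax(mel_fb %*% power, 1e-12))
  n_filters <- nrow(mel_fb)
  # DCT-II of the log filterbank energies, first 13 coefficients
  k <- 0:12
  dct <- cos(pi / n_filters * outer(k, (seq_len(n_filters) - 0.5)))
  as.numeric(dct %*% loge)
}

#' Shannon entropy of a histogram over equal-width bins
#'
#' Bins span \code{[min(values), max(values)]}; entropy is in bits (log base
#' 2). A constant sequence occupies a single bin and has entropy 0. Missing
#' values are dropped.
#'
#' @param values Numeric vector with at least 2 finite values.
#' @param n_bins Number of bins (default 50).
#' @return Entropy in bits.
#' @export
track_entropy <- function(values, n_bins = 50L) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  v <- values[is.finite(values)]
  if (length(v) < 2L) stop("need at least 2 finite values")
  rng <- range(v)
  if (rng[1] == rng[2]) return(0)
  idx <- pmin(n_bins, floor((v - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L)
  p <- tabulate(idx, n_bins) / length(v)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Session-level prosodic functionals
#'
#' Summarizes frame descriptors over a session: volume minimum / maximum /
#' mean and entropy, histogram entropies of the F0 and formant tracks
#' (voiced frames only), and per-coefficient MFCC means. Tracks with fewer
#' than 2 finite frames yield \code{NA} functionals.
#'
#' @param descriptors A \code{\link{extract_descriptors}} result.
#' @param n_bins Histogram bins for entropy functionals (default 50).
#' @return Named numeric vector: \code{vol_mean}, \code{vol_max},
#'   \code{vol_min}, \code{ent_vol}, \code{ent_freq}, \code{ent_f1},
#'   \code{ent_f2}, \code{ent_f3}, \code{mfcc_mean_1} .. \code{mfcc_mean_13}.
#' @export
summarize_prosody <- function(descriptors, n_bins = 50L) {
  ent_or_na <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2L) NA_real_ else track_entropy(v, n_bins)
  }
  vol <- descriptors$volume_db[is.finite(descriptors$volume_db)]
  out <- c(
    vol_mean = .mean_or_na(vol),
    vol_max = if (length(vol)) max(vol) else NA_real_,
    vol_min = if (length(vol)) min(vol) else NA_real_,
    ent_vol = ent_or_na(descriptors$volume_db),
    ent_freq = ent_or_na(descriptors$f0_hz),
    ent_f1 = ent_or_na(descriptors$f1_hz),
    ent_f2 = ent_or_na(descriptors$f2_hz),
    ent_f3 = ent_or_na(descriptors$f3_hz)
  )
  mf <- colMeans(descriptors$mfcc, na.rm = TRUE)
  mf[is.nan(mf)] <- NA_real_
  names(mf) <- paste0("mfcc_mean_", seq_len(13))
  c(out, mf)
}
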