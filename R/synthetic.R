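#' Synthetic speaker profile
#'
#' Parameterizes a simulated interview participant by a latent negative
#' symptom severity in \[0, 1\]. The severity couplings reproduce the
#' qualitative direction of the clinical contrasts: with increasing severity,
#' turns shorten (restricted speech), response latencies grow (prolonged
#' time to respond), back-channels and interruptions become rarer, and the
#' rendered voice becomes more monotonous (lower F0 and volume variability)
#' and slower. Magnitudes are package choices, not clinical estimates.
#'
#' @param severity Latent severity in \[0, 1\] (0 = healthy-like).
#' @param turn_meanlog,turn_sdlog Lognormal turn-length parameters (log
#'   seconds); default mean length ~12 s at severity 0 shrinking to ~3.6 s at
#'   severity 1.
#' @param rt_shape Gamma shape of response times (default 2).
#' @param rt_scale Gamma scale (seconds); default gives mean latency 0.5 s at
#'   severity 0 and 3 s at severity 1.
#' @param p_interruption,p_interjection Per-exchange probabilities of an
#'   overlapping takeover / an embedded back-channel.
#' @param f0_base,f0_sd Voice fundamental (Hz) and its between-segment SD.
#' @param vol_sd Between-segment volume SD in dB.
#' @param speaking_rate_target Syllable rate in syllables/second.
#' @return A \code{subject_profile} list.
#' @export
subject_profile <- function(severity,
                            turn_meanlog = log(12) - 1.2 * severity,
                            turn_sdlog = 0.6,
                            rt_shape = 2,
                            rt_scale = (0.25 + 1.25 * severity),
                            p_interruption = 0.02 + 0.15 * (1 - severity),
                            p_interjection = 0.02 + 0.25 * (1 - severity),
                            f0_base = 120,
                            f0_sd = 3 + 22 * (1 - severity),
                            vol_sd = 1 + 5 * (1 - severity),
                            speaking_rate_target = 4.5 - 2 * severity) {
  if (severity < 0 || severity > 1) stop("severity must lie in [0, 1]")
  if (rt_shape <= 0 || rt_scale <= 0 || turn_sdlog <= 0) {
    stop("distribution parameters must be positive")
  }
  structure(
    list(severity = severity, turn_meanlog = turn_meanlog,
         turn_sdlog = turn_sdlog, rt_shape = rt_shape, rt_scale = rt_scale,
         p_interruption = p_interruption, p_interjection = p_interjection,
         f0_base = f0_base, f0_sd = f0_sd, vol_sd = vol_sd,
         speaking_rate_target = speaking_rate_target),
    class = "subject_profile"
  )
}

#' Default interviewer profile
#'
#' A single fixed interviewer is used across subjects (as with one trained
#' rater conducting all sessions): moderate question length, short latencies,
#' few interruptions of the subject.
#'
#' @return A \code{subject_profile}.
#' @export
interviewer_profile <- function() {
  subject_profile(severity = 0,
                  turn_meanlog = log(6), turn_sdlog = 0.5,
                  rt_scale = 0.3, p_interruption = 0.05,
                  p_interjection = 0.15, f0_base = 110, f0_sd = 20,
                  vol_sd = 4, speaking_rate_target = 4.5)
}

#' Simulate a dyadic interview activity schedule
#'
#' A semi-Markov alternating-speaker process: the interviewer asks a question
#' (own lognormal turn-length draw), the subject responds after a gamma
#' response-time draw, and the floor alternates until \code{duration} is
#' reached. With probability \code{p_interruption} the next speaker starts
#' before the current turn ends (an overlapping takeover); with
#' \code{p_interjection} a short (< 1 s) back-channel is embedded inside the
#' other speaker's turn. Speaker A is the subject, speaker B the interviewer.
#'
#' @param profile \code{\link{subject_profile}} of the subject.
#' @param interviewer \code{\link{subject_profile}} of the interviewer.
#' @param duration Session length in seconds (>= 60).
#' @param seed Integer seed; identical seeds give identical schedules.
#' @param hop Frame hop for the discretized activity stream (default 10 ms).
#' @return A \code{\link{dyad_activity}} with attribute \code{"schedule"}
#'   (data frame speaker/start/end of the generating utterances).
#' @export
simulate_dyad <- function(profile, interviewer = interviewer_profile(),
                          duration = 300, seed = 1L, hop = 0.010) {
  if (duration < 60) stop("duration must be at least 60 s")
  set.seed(seed)
  draw_turn <- function(p) stats::rlnorm(1, p$turn_meanlog, p$turn_sdlog)
  draw_rt <- function(p) stats::rgamma(1, shape = p$rt_shape, scale = p$rt_scale)

  segs <- list()
  add <- function(sp, s, e) {
    if (e > s) segs[[length(segs) + 1L]] <<- data.frame(
      speaker = sp, start = s, end = e)
  }

  t <- draw_rt(interviewer)          # settling-in before the first question
  current <- "B"                     # interviewer opens
  prev_end <- t
  while (t < duration) {
    p_cur <- if (current == "A") profile else interviewer
    p_next <- if (current == "A") interviewer else profile
    len <- draw_turn(p_cur)
    s <- t; e <- min(t + len, duration)
    add(current, s, e)

    # embedded back-channel by the listener
    if (e - s > 2 && stats::runif(1) < p_next$p_interjection) {
      ij_len <- stats::runif(1, 0.2, 0.8)
      ij_start <- stats::runif(1, s + 0.5, e - ij_len - 0.5)
      add(setdiff(c("A", "B"), current), ij_start, ij_start + ij_len)
    }

    if (e >= duration) break
    if (e - s > 1.5 && stats::runif(1) < p_next$p_interruption) {
      # overlapping takeover: next speaker starts before the turn ends
      t_next <- max(s + 0.2, e - stats::runif(1, 0.3, 1.0))
    } else {
      t_next <- e + draw_rt(p_next)
    }
    current <- setdiff(c("A", "B"), current)
    t <- t_next
    prev_end <- e
  }

  schedule <- do.call(rbind, segs)
  schedule <- schedule[order(schedule$start), , drop = FALSE]
  rownames(schedule) <- NULL

  n_frames <- max(1L, as.integer(round(duration / hop)))
  act <- function(sp) {
    v <- logical(n_frames)
    rows <- schedule[schedule$speaker == sp, , drop = FALSE]
    for (r in seq_len(nrow(rows))) {
      i0 <- max(1L, floor(rows$start[r] / hop) + 1L)
      i1 <- min(n_frames, ceiling(rows$end[r] / hop))
      if (i1 >= i0) v[i0:i1] <- TRUE
    }
    v
  }
  out <- dyad_activity(act("A"), act("B"), hop = hop)
  attr(out, "schedule") <- schedule
  out
}

#' Generate an NSA-16 rating record from a latent severity
#'
#' Each item is \code{clamp(round(1 + 5 * severity + noise), 1, 6)} with
#' item-specific Gaussian noise; the global rating is generated the same way,
#' and the total and five domain sums are computed from the items (never
#' drawn independently), so the rating-record arithmetic identities always
#' hold.
#'
#' @param severity Latent severity in \[0, 1\].
#' @param noise_sd Item noise standard deviation (default 0.5).
#' @param seed Integer seed.
#' @param subject_id Optional subject identifier.
#' @param group Optional group label.
#' @return One-row data frame with \code{subject_id}, \code{group} and the
#'   \code{\link{nsa_columns}}.
#' @export
ratings_from_severity <- function(severity, noise_sd = 0.5, seed = 1L,
                                  subject_id = "s1", group = NA_character_) {
  if (severity < 0 || severity > 1) stop("severity must lie in [0, 1]")
  set.seed(seed)
  items <- pmin(6, pmax(1, round(1 + 5 * severity + stats::rnorm(16, 0, noise_sd))))
  glob <- pmin(6, pmax(1, round(1 + 5 * severity + stats::rnorm(1, 0, noise_sd))))
  rec <- data.frame(subject_id = subject_id, group = group)
  for (i in 1:16) rec[[paste0("nsa_", i)]] <- items[i]
  rec$nsa_global <- glob
  rec$nsa_total <- sum(items)
  rec$communication <- sum(items[1:4])
  rec$emotion_affect <- sum(items[5:7])
  rec$social_involvement <- sum(items[8:10])
  rec$motivation <- sum(items[11:14])
  rec$retardation <- sum(items[15:16])
  rec
}

#' Render a dyad activity schedule to 2-channel audio
#'
#' Each active region becomes a harmonic pulse train whose fundamental is
#' redrawn every 200 ms from \code{Normal(f0_base, f0_sd)} (clamped to
#' 75-390 Hz), with segment amplitudes drawn around -20 dBFS with SD
#' \code{vol_sd}, and a syllabic amplitude modulation at the profile's
#' speaking rate. Channels are rendered independently (channel 1 = speaker A).
#'
#' @param activity A \code{\link{dyad_activity}}.
#' @param profile_a,profile_b \code{\link{subject_profile}}s for the two
#'   channels.
#' @param sample_rate Output rate in Hz (default 16000).
#' @param seed Integer seed.
#' @return A 2-channel \code{\link{audio_recording}}.
#' @export
render_audio <- function(activity, profile_a, profile_b,
                         sample_rate = 16000, seed = 1L) {
  set.seed(seed)
  n <- round(activity$n_frames * activity$frame_hop * sample_rate)
  render_channel <- function(active, prof) {
    x <- numeric(n)
    r <- rle(active)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths
    for (k in which(r$values)) {
      s0 <- round(starts[k] * activity$frame_hop * sample_rate) + 1L
      s1 <- min(n, round(ends[k] * activity$frame_hop * sample_rate))
      if (s1 <= s0) next
      len <- s1 - s0 + 1L
      seg_len <- round(0.2 * sample_rate)
      n_segs <- ceiling(len / seg_len)
      f0s <- pmin(390, pmax(75, stats::rnorm(n_segs, prof$f0_base, prof$f0_sd)))
      amps_db <- stats::rnorm(n_segs, -20, prof$vol_sd)
      tt <- seq_len(len) / sample_rate
      seg_idx <- pmin(n_segs, (seq_len(len) - 1L) %/% seg_len + 1L)
      # phase-continuous harmonic pulse train (5 harmonics, 1/h rolloff)
      phase <- cumsum(2 * pi * f0s[seg_idx] / sample_rate)
      wave <- numeric(len)
      for (hmc in 1:5) wave <- wave + sin(hmc * phase) / hmc
      am <- 0.15 + 0.85 * (0.5 * (1 + sin(2 * pi * prof$speaking_rate_target * tt - pi / 2)))
      x[s0:s1] <- wave / 5 * am * 10^(amps_db[seg_idx] / 20) * 4
    }
    pmin(1, pmax(-1, x))
  }
  samples <- cbind(render_channel(activity$active_a, profile_a),
                   render_channel(activity$active_b, profile_b))
  audio_recording(samples, sample_rate)
}

#' Simulate a synthetic interview cohort
#'
#' Draws control severities from Uniform(0, 0.2) and patient severities from
#' Uniform(0.2, 1.0), simulates one dyadic interview per subject against a
#' fixed interviewer, and generates coupled NSA ratings. Per-subject seeds
#' are derived deterministically from \code{master_seed}, so a fixed master
#' seed reproduces the cohort exactly.
#'
#' @param n_patients,n_controls Group sizes (each >= 2); the study-scale
#'   default is 54 patients / 26 controls.
#' @param duration Interview length in seconds (default 300).
#' @param master_seed Integer master seed.
#' @param audio If TRUE, also render 2-channel audio per subject.
#' @param sample_rate Audio rate when rendering (default 16000).
#' @param noise_sd Rating noise SD (default 0.5).
#' @return A \code{synthetic_cohort}: list of subjects (id, group, severity,
#'   seed, activity, optional audio and profile) plus a \code{ratings} data
#'   frame and the generation parameters.
#' @export
simulate_cohort <- function(n_patients = 54, n_controls = 26, duration = 300,
                            master_seed = 1L, audio = FALSE,
                            sample_rate = 16000, noise_sd = 0.5) {
  if (n_patients < 2 || n_controls < 2) stop("each group needs >= 2 subjects")
  n <- n_patients + n_controls
  set.seed(master_seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, 3L * n)
  sev_controls <- stats::runif(n_controls, 0, 0.2)
  sev_patients <- stats::runif(n_patients, 0.2, 1.0)

  groups <- c(rep("patient", n_patients), rep("control", n_controls))
  severities <- c(sev_patients, sev_controls)
  interviewer <- interviewer_profile()

  subjects <- vector("list", n)
  ratings <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("S%03d", i)
    prof <- subject_profile(severities[i])
    act <- simulate_dyad(prof, interviewer, duration = duration,
                         seed = subject_seeds[3L * i - 2L])
    rec <- ratings_from_severity(severities[i], noise_sd = noise_sd,
                                 seed = subject_seeds[3L * i - 1L],
                                 subject_id = id, group = groups[i])
    aud <- if (audio) {
      render_audio(act, prof, interviewer, sample_rate = sample_rate,
                   seed = subject_seeds[3L * i])
    }
    subjects[[i]] <- list(id = id, group = groups[i],
                          severity = severities[i],
                          seed = subject_seeds[3L * i - 2L],
                          profile = prof, activity = act, audio = aud)
    ratings[[i]] <- rec
  }
  structure(
    list(subjects = subjects,
         ratings = do.call(rbind, ratings),
         n_patients = n_patients, n_controls = n_controls,
         duration = duration, master_seed = master_seed, audio = audio),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d patients + %d controls, %.0f s interviews%s (master seed %d)\n",
    x$n_patients, x$n_controls, x$duration,
    if (x$audio) " with audio" else "", x$master_seed))
  invisible(x)
}
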