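#' Segment per-speaker utterances from a dyad activity stream
#'
#' Maximal runs of active frames become utterances. Frame \code{i} (0-based)
#' is mapped to the time slice \code{[i * hop, (i + 1) * hop)}, so an
#' utterance spanning frames \code{[j, k)} covers
#' \code{[j * hop, k * hop)} seconds.
#'
#' @param activity A \code{\link{dyad_activity}}.
#' @return Data frame with columns \code{speaker} ("A"/"B"), \code{start},
#'   \code{end} (seconds), ordered by \code{start} then speaker.
#' @export
segment_utterances <- function(activity) {
  runs_for <- function(active, speaker) {
    r <- rle(active)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (!any(keep)) {
      return(data.frame(speaker = character(0), start = numeric(0),
                        end = numeric(0)))
    }
    data.frame(speaker = speaker,
               start = starts[keep] * activity$frame_hop,
               end = ends[keep] * activity$frame_hop)
  }
  utt <- rbind(runs_for(activity$active_a, "A"),
               runs_for(activity$active_b, "B"))
  utt[order(utt$start, utt$speaker), , drop = FALSE]
}

#' Classify utterances into conversational events
#'
#' Each utterance \code{u} of speaker X is assigned exactly one category by
#' applying these rules in order against the other speaker Y's utterances:
#' \enumerate{
#'   \item \emph{speaking interjection}: \code{u} is shorter than
#'     \code{interjection_max} and lies entirely within an utterance of Y
#'     (a back-channel such as "okay", "hmm" produced while Y holds the floor);
#'   \item \emph{natural interjection}: \code{u} is shorter than
#'     \code{interjection_max}, overlaps no utterance of Y, and both the
#'     nearest preceding and nearest following utterances belong to Y;
#'   \item \emph{interruption} (successful): \code{u} starts while an
#'     utterance \code{v} of Y is ongoing and outlasts it; \code{u} becomes a
#'     turn and X is credited one interruption;
#'   \item \emph{failed interruption}: \code{u} starts while \code{v} is
#'     ongoing but ends no later than \code{v}; not a turn;
#'   \item \emph{natural turn}: otherwise (\code{u} starts with Y silent).
#' }
#'
#' Response times are latencies over clean floor exchanges: a turn of Y
#' ending at \code{t_e} followed, with no intervening turn, by a turn of X
#' starting at \code{t_s >= t_e} yields \code{t_s - t_e}; exchanges taken by
#' interruption are excluded, so response times are non-negative. Speech gaps
#' are the pauses between one speaker's own consecutive turns.
#'
#' @param utterances Data frame from \code{\link{segment_utterances}}.
#' @param interjection_max Maximum interjection duration in seconds
#'   (default 1.0).
#' @return A \code{conversation_events} list of data frames: \code{turns}
#'   (speaker, start, end, type), \code{interruptions},
#'   \code{failed_interruptions}, \code{speaking_interjections},
#'   \code{natural_interjections} (speaker, time), \code{response_times}
#'   (speaker, gap), \code{speech_gaps} (speaker, gap).
#' @export
classify_events <- function(utterances, interjection_max = 1.0) {
  if (interjection_max <= 0) stop("interjection_max must be positive")
  n <- nrow(utterances)
  category <- character(n)

  for (i in seq_len(n)) {
    u <- utterances[i, ]
    dur <- u$end - u$start
    other <- utterances[utterances$speaker != u$speaker, , drop = FALSE]

    contained <- any(other$start <= u$start & u$end <= other$end)
    if (dur < interjection_max && contained) {
      category[i] <- "speaking_interjection"
      next
    }

    overlaps_other <- any(other$start < u$end & u$start < other$end)
    if (dur < interjection_max && !overlaps_other) {
      # nearest neighbours among all utterances; ties resolved in Y's favour
      own <- utterances[utterances$speaker == u$speaker, , drop = FALSE]
      own <- own[!(own$start == u$start & own$end == u$end), , drop = FALSE]
      prev_y <- suppressWarnings(max(other$end[other$end <= u$start]))
      prev_x <- suppressWarnings(max(own$end[own$end <= u$start]))
      next_y <- suppressWarnings(min(other$start[other$start >= u$end]))
      next_x <- suppressWarnings(min(own$start[own$start >= u$end]))
      if (is.finite(prev_y) && is.finite(next_y) &&
          prev_y >= prev_x && next_y <= next_x) {
        category[i] <- "natural_interjection"
        next
      }
    }

    # at most one utterance of Y is ongoing when u starts
    ongoing <- which(other$start < u$start & u$start < other$end)
    if (length(ongoing) > 0L) {
      v <- other[ongoing[1L], ]
      category[i] <- if (u$end > v$end) "interruption" else "failed_interruption"
    } else {
      category[i] <- "natural_turn"
    }
  }

  is_turn <- category %in% c("natural_turn", "interruption")
  turns <- utterances[is_turn, , drop = FALSE]
  turns$type <- ifelse(category[is_turn] == "interruption",
                       "interruption", "natural")
  turns <- turns[order(turns$start, turns$speaker), , drop = FALSE]
  rownames(turns) <- NULL

  point_events <- function(cat) {
    sel <- category == cat
    data.frame(speaker = utterances$speaker[sel],
               time = utterances$start[sel])
  }

  # floor exchanges -> response times
  rt_speaker <- character(0)
  rt_gap <- numeric(0)
  nt <- nrow(turns)
  if (nt >= 2L) {
    for (i in seq_len(nt)) {
      v <- turns[i, ]
      after <- which(turns$start >= v$end)
      after <- after[after != i]
      if (length(after) == 0L) next
      j <- after[which.min(turns$start[after])]
      u <- turns[j, ]
      if (u$speaker != v$speaker && u$type != "interruption") {
        rt_speaker <- c(rt_speaker, u$speaker)
        rt_gap <- c(rt_gap, u$start - v$end)
      }
    }
  }

  gaps <- do.call(rbind, lapply(c("A", "B"), function(sp) {
    tx <- turns[turns$speaker == sp, , drop = FALSE]
    if (nrow(tx) < 2L) {
      return(data.frame(speaker = character(0), gap = numeric(0)))
    }
    data.frame(speaker = sp,
               gap = tx$start[-1L] - tx$end[-nrow(tx)])
  }))

  structure(
    list(turns = turns,
         interruptions = point_events("interruption"),
         failed_interruptions = point_events("failed_interruption"),
         speaking_interjections = point_events("speaking_interjection"),
         natural_interjections = point_events("natural_interjection"),
         response_times = data.frame(speaker = rt_speaker, gap = rt_gap),
         speech_gaps = gaps,
         interjection_max = interjection_max),
    class = "conversation_events"
  )
}

#' @export
print.conversation_events <- function(x, ...) {
  cat(sprintf(
    "<conversation_events> %d turns (%d by interruption), %d failed interruptions, %d speaking + %d natural interjections\n",
    nrow(x$turns), sum(x$turns$type == "interruption"),
    nrow(x$failed_interruptions), nrow(x$speaking_interjections),
    nrow(x$natural_interjections)))
  invisible(x)
}

.mean_or_na <- function(x) if (length(x) == 0L) NA_real_ else mean(x)

#' Conversational cue values for one speaker
#'
#' Computes the per-speaker and dyad-level non-verbal conversational cues:
#' speaking percentages (fractions of recording frames), event counts
#' normalized per minute of recording, and mean durations/latencies in
#' seconds. Means over empty event sets are reported as \code{NA}, never 0.
#' Percentages satisfy \code{speaking_A + speaking_B - overlap +
#' mutual_silence = 100} exactly on the frame grid.
#'
#' @param events A \code{\link{classify_events}} result.
#' @param activity The \code{\link{dyad_activity}} the events came from.
#' @param speaker "A" or "B".
#' @return Named numeric vector: \code{natural_turns},
#'   \code{difference_turns}, \code{interjections},
#'   \code{speaking_interjections}, \code{interruptions},
#'   \code{failed_interruptions} (all per minute), \code{overlap_pct},
#'   \code{speaking_pct}, \code{difference_speaking_pct},
#'   \code{mutual_silence_pct} (percent), \code{turn_duration},
#'   \code{speech_gap}, \code{response_time} (seconds).
#' @export
conversational_features <- function(events, activity, speaker = "A") {
  stopifnot(speaker %in% c("A", "B"))
  n <- activity$n_frames
  minutes <- n * activity$frame_hop / 60
  a <- activity$active_a
  b <- activity$active_b
  own <- if (speaker == "A") a else b

  count_rate <- function(df, sp) sum(df$speaker == sp) / minutes
  nat_turns <- events$turns[events$turns$type == "natural", , drop = FALSE]

  own_turns <- events$turns[events$turns$speaker == speaker, , drop = FALSE]
  c(
    natural_turns = count_rate(nat_turns, speaker),
    difference_turns = abs(count_rate(nat_turns, "A") - count_rate(nat_turns, "B")),
    interjections = count_rate(events$natural_interjections, speaker),
    speaking_interjections = count_rate(events$speaking_interjections, speaker),
    interruptions = count_rate(events$interruptions, speaker),
    failed_interruptions = count_rate(events$failed_interruptions, speaker),
    overlap_pct = 100 * sum(a & b) / n,
    speaking_pct = 100 * sum(own) / n,
    difference_speaking_pct = 100 * abs(sum(a) - sum(b)) / n,
    mutual_silence_pct = 100 * sum(!a & !b) / n,
    turn_duration = .mean_or_na(own_turns$end - own_turns$start),
    speech_gap = .mean_or_na(
      events$speech_gaps$gap[events$speech_gaps$speaker == speaker]),
    response_time = .mean_or_na(
      events$response_times$gap[events$response_times$speaker == speaker])
  )
}

#' Syllable-nucleus speaking rate
#'
#' Estimates syllable nuclei from the smoothed wide-band energy envelope
#' inside the speaker's active regions and divides by the speaker's total
#' speaking time. Within each active run, a nucleus is registered on each
#' upward crossing of \code{high_frac} of the run's envelope peak, re-armed
#' only after the envelope dips below \code{low_frac} of that peak (a
#' prominence requirement that ignores the small phase ripple of steady
#' voicing), with successive nuclei at least \code{min_peak_distance} apart.
#'
#' @param recording A 2-channel \code{\link{audio_recording}}.
#' @param activity The matching \code{\link{dyad_activity}}.
#' @param speaker "A" (channel 1) or "B" (channel 2).
#' @param config A \code{\link{frame_config}} matching the activity grid.
#' @param min_peak_distance Minimum nucleus spacing, seconds (default 0.150).
#' @param high_frac,low_frac Hysteresis thresholds as fractions of the
#'   active-run envelope peak (defaults 0.5 / 0.25).
#' @return Syllables per second, or \code{NA} if the speaker never speaks.
#' @export
speaking_rate <- function(recording, activity, speaker = "A",
                          config = frame_config(),
                          min_peak_distance = 0.150,
                          high_frac = 0.5, low_frac = 0.25) {
  stopifnot(speaker %in% c("A", "B"))
  active <- if (speaker == "A") activity$active_a else activity$active_b
  if (!any(active)) return(NA_real_)
  ch <- if (speaker == "A") 1L else 2L
  db <- frame_rms_db(recording$samples[, ch], recording$sample_rate, config)
  env <- 10^(db / 20)
  nf <- min(length(env), length(active))
  env <- env[seq_len(nf)]

  # light smoothing (~50 ms)
  k <- 5L
  env_s <- as.numeric(stats::filter(env, rep(1 / k, k), sides = 2))
  env_s[is.na(env_s)] <- env[is.na(env_s)]

  min_dist <- round(min_peak_distance / config$hop)
  r <- rle(active[seq_len(nf)])
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  nuclei <- 0L
  for (run in which(r$values)) {
    e <- env_s[starts[run]:ends[run]]
    peak <- max(e)
    if (peak <= 0) next
    armed <- TRUE
    last <- -Inf
    for (i in seq_along(e)) {
      if (armed && e[i] >= high_frac * peak && i - last >= min_dist) {
        nuclei <- nuclei + 1L
        last <- i
        armed <- FALSE
      } else if (!armed && e[i] < low_frac * peak) {
        armed <- TRUE
      }
    }
  }
  speaking_time <- sum(active) * activity$frame_hop
  nuclei / speaking_time
}
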