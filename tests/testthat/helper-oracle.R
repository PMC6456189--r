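# Independent brute-force reference for the conversational cues: naive
# frame/interval scanning, written separately from the package internals so
# the two can disagree.

oracle_utterances <- function(active, hop) {
  segs <- list()
  in_run <- FALSE
  start <- 0L
  for (i in seq_along(active)) {
    if (active[i] && !in_run) {
      in_run <- TRUE
      start <- i
    }
    if (in_run && (!active[i] || i == length(active))) {
      last <- if (active[i]) i else i - 1L
      segs[[length(segs) + 1L]] <- c(start - 1L, last)
      in_run <- FALSE
    }
  }
  if (length(segs) == 0L) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  m <- do.call(rbind, segs)
  # m[, 1] is the 0-based first active frame, m[, 2] the 1-based last one
  data.frame(start = m[, 1] * hop, end = m[, 2] * hop)
}

oracle_classify <- function(utt_a, utt_b, imax) {
  all_utt <- rbind(
    if (nrow(utt_a)) cbind(utt_a, speaker = "A") else NULL,
    if (nrow(utt_b)) cbind(utt_b, speaker = "B") else NULL
  )
  cats <- character(if (is.null(all_utt)) 0L else nrow(all_utt))
  for (i in seq_along(cats)) {
    u <- all_utt[i, ]
    dur <- u$end - u$start
    ys <- all_utt[all_utt$speaker != u$speaker, , drop = FALSE]
    xs <- all_utt[all_utt$speaker == u$speaker, , drop = FALSE]
    xs <- xs[xs$start != u$start, , drop = FALSE]

    inside <- FALSE
    for (j in seq_len(nrow(ys))) {
      if (ys$start[j] <= u$start && u$end <= ys$end[j]) inside <- TRUE
    }
    if (dur < imax && inside) {
      cats[i] <- "speaking_interjection"
      next
    }
    overlap <- FALSE
    for (j in seq_len(nrow(ys))) {
      if (ys$start[j] < u$end && u$start < ys$end[j]) overlap <- TRUE
    }
    if (dur < imax && !overlap) {
      prev_y <- -Inf; next_y <- Inf
      for (j in seq_len(nrow(ys))) {
        if (ys$end[j] <= u$start) prev_y <- max(prev_y, ys$end[j])
        if (ys$start[j] >= u$end) next_y <- min(next_y, ys$start[j])
      }
      prev_x <- -Inf; next_x <- Inf
      for (j in seq_len(nrow(xs))) {
        if (xs$end[j] <= u$start) prev_x <- max(prev_x, xs$end[j])
        if (xs$start[j] >= u$end) next_x <- min(next_x, xs$start[j])
      }
      if (is.finite(prev_y) && is.finite(next_y) &&
          prev_y >= prev_x && next_y <= next_x) {
        cats[i] <- "natural_interjection"
        next
      }
    }
    v <- NULL
    for (j in seq_len(nrow(ys))) {
      if (ys$start[j] < u$start && u$start < ys$end[j]) v <- ys[j, ]
    }
    if (!is.null(v)) {
      cats[i] <- if (u$end > v$end) "interruption" else "failed_interruption"
    } else {
      cats[i] <- "natural_turn"
    }
  }
  list(utt = all_utt, cats = cats)
}

oracle_features <- function(active_a, active_b, hop, speaker,
                            imax = 1.0) {
  n <- length(active_a)
  minutes <- n * hop / 60
  cl <- oracle_classify(oracle_utterances(active_a, hop),
                        oracle_utterances(active_b, hop), imax)
  utt <- cl$utt; cats <- cl$cats

  is_turn <- cats %in% c("natural_turn", "interruption")
  turns <- utt[is_turn, , drop = FALSE]
  turns$type <- cats[is_turn]
  ord <- order(turns$start, turns$speaker)
  turns <- turns[ord, , drop = FALSE]

  # floor exchanges
  rt <- list()
  for (i in seq_len(nrow(turns))) {
    v <- turns[i, ]
    best <- NULL
    for (j in seq_len(nrow(turns))) {
      if (j == i) next
      if (turns$start[j] >= v$end) {
        if (is.null(best) ||
            turns$start[j] < turns$start[best] ||
            (turns$start[j] == turns$start[best] &&
             turns$speaker[j] < turns$speaker[best])) {
          best <- j
        }
      }
    }
    if (!is.null(best) && turns$speaker[best] != v$speaker &&
        turns$type[best] != "interruption") {
      rt[[length(rt) + 1L]] <- c(turns$speaker[best],
                                 turns$start[best] - v$end)
    }
  }
  rt_sp <- vapply(rt, `[`, character(1), 1)
  rt_gap <- as.numeric(vapply(rt, `[`, character(1), 2))

  gaps_for <- function(sp) {
    tx <- turns[turns$speaker == sp, , drop = FALSE]
    if (nrow(tx) < 2L) return(numeric(0))
    out <- numeric(0)
    for (i in 2:nrow(tx)) out <- c(out, tx$start[i] - tx$end[i - 1L])
    out
  }

  cnt <- function(cat, sp) sum(cats == cat & utt$speaker == sp)
  own <- if (speaker == "A") active_a else active_b
  own_turns <- turns[turns$speaker == speaker, , drop = FALSE]
  m_or_na <- function(x) if (length(x)) mean(x) else NA_real_

  c(
    natural_turns = cnt("natural_turn", speaker) / minutes,
    difference_turns = abs(cnt("natural_turn", "A") -
                             cnt("natural_turn", "B")) / minutes,
    interjections = cnt("natural_interjection", speaker) / minutes,
    speaking_interjections = cnt("speaking_interjection", speaker) / minutes,
    interruptions = cnt("interruption", speaker) / minutes,
    failed_interruptions = cnt("failed_interruption", speaker) / minutes,
    overlap_pct = 100 * sum(active_a & active_b) / n,
    speaking_pct = 100 * sum(own) / n,
    difference_speaking_pct = 100 * abs(sum(active_a) - sum(active_b)) / n,
    mutual_silence_pct = 100 * sum(!active_a & !active_b) / n,
    turn_duration = m_or_na(own_turns$end - own_turns$start),
    speech_gap = m_or_na(gaps_for(speaker)),
    response_time = m_or_na(rt_gap[rt_sp == speaker])
  )
}

# random activity stream with persistent on/off runs
random_activity_stream <- function(n, p_stay = 0.9) {
  x <- logical(n)
  x[1] <- stats::runif(1) < 0.5
  for (i in seq_len(n - 1L)) {
    x[i + 1L] <- if (stats::runif(1) < p_stay) x[i] else !x[i]
  }
  x
}

package_features <- function(active_a, active_b, speaker, hop = 0.010,
                             imax = 1.0) {
  act <- dyad_activity(active_a, active_b, hop = hop)
  ev <- classify_events(segment_utterances(act), interjection_max = imax)
  conversational_features(ev, act, speaker = speaker)
}

# synthesized fixtures for prosodic tests
make_tone <- function(freq, dur = 2, sr = 16000, amp = 0.5) {
  t <- seq_len(round(dur * sr)) / sr
  amp * sin(2 * pi * freq * t)
}

# voiced two-resonance vowel: pulse train through two second-order poles
make_vowel <- function(f_poles = c(700, 1200), bw = 80, f0 = 100,
                       dur = 2, sr = 16000) {
  pole_coef <- function(f) {
    r <- exp(-pi * bw / sr)
    c(-2 * r * cos(2 * pi * f / sr), r^2)
  }
  a <- c(1, pole_coef(f_poles[1]))
  b <- c(1, pole_coef(f_poles[2]))
  den <- convolve(a, rev(b), type = "open")
  exc <- numeric(round(dur * sr))
  exc[seq(1, length(exc), by = round(sr / f0))] <- 1
  x <- as.numeric(stats::filter(exc, -den[-1], method = "recursive"))
  0.5 * x / max(abs(x))
}
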