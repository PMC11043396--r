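#' Annotation container
#'
#' Time-ordered annotation events for one recording: one letter per detected
#' syllable plus `/` markers for silent gaps, together with song-bout
#' boundaries.
#'
#' @param events Data frame with `symbol`, `t_start`, `t_end`, `confidence`
#'   (`NA` for `/`), `emit_latency` (`NA` offline).
#' @param bouts Data frame with `bout_start`, `bout_end`, `n_syllables`.
#' @param source_id,model_id Provenance identifiers.
#' @return An object of class `annotation`.
#' @export
annotation <- function(events, bouts, source_id = NA_character_,
                       model_id = NA_character_) {
  stopifnot(is.data.frame(events))
  if (nrow(events) > 1L && is.unsorted(events$t_start)) {
    stop("annotation events must be time-ordered")
  }
  structure(list(events = events, bouts = bouts, source_id = source_id,
                 model_id = model_id),
            class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("<annotation> %s: %d events, %d bouts\n", x$source_id,
              nrow(x$events), nrow(x$bouts)))
  if (nrow(x$events) > 0L) cat(" ", annotation_to_text(x), "\n")
  invisible(x)
}

#' Extract the symbol sequence of an annotation
#'
#' @param ann An [annotation()].
#' @param exclude Symbols to drop (e.g. `"/"` or introductory-note letters).
#' @return Character vector of symbols in time order.
#' @export
annotation_symbols <- function(ann, exclude = character()) {
  s <- ann$events$symbol
  s[!s %in% exclude]
}

empty_events <- function() {
  data.frame(symbol = character(), t_start = numeric(), t_end = numeric(),
             confidence = numeric(), emit_latency = numeric())
}

# Silent-gap markers inside a frame gap [anchor, gap_end): one "/" for every
# full `gap_frames` run since the previous event, as long as the marker frame
# ends within `tail_lim` frames of the last syllable end.
gap_marker_frames <- function(anchor, gap_end, last_end_f, gap_frames, tail_lim) {
  out <- integer()
  while (anchor + gap_frames <= gap_end &&
         anchor + gap_frames <= last_end_f + tail_lim) {
    anchor <- anchor + gap_frames
    out <- c(out, anchor)
  }
  out
}

#' Decode a recording offline
#'
#' Runs the segmentation front end with the model's own configuration,
#' classifies every detected syllable, inserts `/` markers for silent gaps
#' of at least `gap_frames` frames (290 ms at defaults; the counter resets
#' after each event, so a 120-frame gap yields two markers, and it stops
#' once the bout tail window after the last syllable has elapsed), and
#' groups syllables into bouts. The whole pipeline is deterministic: the
#' same file and model always yield the identical annotation.
#'
#' @param audio An [audio_clip()].
#' @param model A trained `decoder_model` carrying a [seg_config()].
#' @return An [annotation()].
#' @export
decode_offline <- function(audio, model) {
  stopifnot(inherits(model, "decoder_model"))
  cfg <- model$config
  if (is.null(cfg)) stop("model carries no segmentation config")
  if (feature_length(cfg) != model$input_dim) {
    stop("model input dim ", model$input_dim,
         " does not match config feature length ", feature_length(cfg))
  }
  seg <- segment_audio(audio, cfg)
  fd <- seg$spectrogram$frame_duration
  n_frames <- nrow(seg$spectrogram$magnitudes)
  tail_lim <- as.integer(floor(cfg$bout_tail_s / fd + 1e-9))

  segs <- seg$segments
  events <- empty_events()
  if (nrow(segs) > 0L) {
    pred <- model_predict(model, seg$features)
    rows <- list()
    anchor <- NA_integer_
    last_end_f <- NA_integer_
    add_markers <- function(gap_end) {
      if (is.na(anchor)) return(invisible())
      ms <- gap_marker_frames(anchor, gap_end, last_end_f,
                              cfg$gap_frames, tail_lim)
      for (m in ms) {
        rows[[length(rows) + 1L]] <<- data.frame(
          symbol = "/", t_start = (m - cfg$gap_frames) * fd, t_end = m * fd,
          confidence = NA_real_, emit_latency = NA_real_)
      }
      if (length(ms)) anchor <<- ms[length(ms)]
    }
    for (i in seq_len(nrow(segs))) {
      add_markers(segs$frame_start[i])
      rows[[length(rows) + 1L]] <- data.frame(
        symbol = pred$letter[i], t_start = segs$t_start[i],
        t_end = segs$t_end[i], confidence = pred$confidence[i],
        emit_latency = NA_real_)
      anchor <- segs$frame_end[i]
      last_end_f <- segs$frame_end[i]
    }
    add_markers(n_frames)
    events <- do.call(rbind, rows)
  }
  annotation(events, seg$bouts, source_id =
               if (inherits(audio, "audio_clip")) audio$source_id else NA,
             model_id = paste(model$letters, collapse = ""))
}

# Online mirror of detect_song_bouts: fed one syllable end time at a time,
# closed by wall clock.
new_bout_tracker <- function(rise, decay, cutoff, tail_s) {
  acc <- 0; run_start_t <- NA_real_; in_bout <- FALSE
  bout_start_t <- NA_real_; last_t <- NA_real_; prev_t <- NA_real_
  n_syll <- 0L; run_count <- 0L; bouts <- list()
  close_bout <- function() {
    bouts[[length(bouts) + 1L]] <<- data.frame(
      bout_start = bout_start_t, bout_end = last_t + tail_s,
      n_syllables = n_syll)
    in_bout <<- FALSE; acc <<- 0; run_start_t <<- NA_real_; run_count <<- 0L
  }
  list(
    syllable = function(t) {
      if (in_bout && t - last_t > tail_s) close_bout()
      if (!is.na(prev_t)) acc <<- max(0, acc - decay * (t - prev_t))
      if (acc == 0) { run_start_t <<- t; run_count <<- 0L }
      acc <<- acc + rise
      run_count <<- run_count + 1L
      if (!in_bout && acc >= cutoff) {
        in_bout <<- TRUE
        bout_start_t <<- run_start_t
        n_syll <<- run_count - 1L # syllables that built the bout up
      }
      if (in_bout) { last_t <<- t; n_syll <<- n_syll + 1L }
      prev_t <<- t
    },
    tick = function(now) {
      if (in_bout && now - last_t > tail_s) close_bout()
    },
    finish = function() {
      if (in_bout) close_bout()
      if (length(bouts)) do.call(rbind, bouts)
      else data.frame(bout_start = numeric(), bout_end = numeric(),
                      n_syllables = integer())
    })
}

#' Decode an audio stream
#'
#' Consumes contiguous audio chunks of arbitrary size, reassembles exact
#' analysis frames internally, and emits each annotation event as soon as it
#' is decidable: a letter once its syllable's trailing edge plus one
#' syllable-free frame have been seen, a `/` once the silent-gap counter
#' fills, and a bout boundary once the tail silence elapses. With
#' frame-aligned chunking the emitted symbol sequence is identical to
#' [decode_offline()] on the concatenated audio. Each letter event records
#' `emit_latency`: the stream time at emission minus the syllable end time
#' (a small constant on simulated streams; on real hardware this is
#' dominated by device I/O and is logged, never asserted).
#'
#' @param chunks List of numeric sample vectors, in order. May also be a
#'   single [audio_clip()] plus `chunk_samples` to split it.
#' @param model A trained `decoder_model`.
#' @param chunk_samples Chunk size used when `chunks` is an `audio_clip`.
#' @param sample_rate Stream sample rate; taken from the clip when `chunks`
#'   is an `audio_clip`.
#' @param callback Optional `function(event)` invoked at each emission with
#'   a one-row data frame.
#' @return An [annotation()] whose events carry `emit_latency`.
#' @export
decode_stream <- function(chunks, model, chunk_samples = 882L,
                          sample_rate = 44100, callback = NULL) {
  stopifnot(inherits(model, "decoder_model"))
  cfg <- model$config
  if (is.null(cfg)) stop("model carries no segmentation config")
  if (inherits(chunks, "audio_clip")) {
    sample_rate <- chunks$sample_rate
    chunks <- split(chunks$samples,
                    ceiling(seq_along(chunks$samples) / chunk_samples))
  }
  if (!is.list(chunks)) stop("chunks must be a list of sample vectors")

  window <- cfg$window_samples
  hop <- cfg$hop_samples
  nb <- cfg$band_hi - cfg$band_lo
  fd <- window / sample_rate
  w <- hamming_window(window)
  wsum2 <- sum(w) / 2
  tail_lim <- as.integer(floor(cfg$bout_tail_s / fd + 1e-9))
  gapf <- cfg$gap_frames

  mags <- list()          # magnitude columns, 1-based frame index
  consumed <- 0L          # frames whose edge indicator has been consumed
  run_start <- NA_integer_; run_len <- 0L
  anchor <- NA_integer_; last_end_f <- NA_integer_
  rows <- list()
  tracker <- new_bout_tracker(cfg$bout_rise, cfg$bout_decay,
                              cfg$bout_cutoff, cfg$bout_tail_s)

  emit <- function(row) {
    rows[[length(rows) + 1L]] <<- row
    if (!is.null(callback)) callback(row)
  }

  edge_indicator <- function(t) { # 0-based frame, needs frames t-1..t+1
    a <- mags[[t]]; b <- mags[[t + 1L]]; c <- mags[[t + 2L]]
    if (nb < 3L) return(FALSE)
    j <- 2:(nb - 1L)
    ac3 <- (c - a)
    gt <- ac3[j - 1L] + ac3[j] + ac3[j + 1L]
    s3 <- a + b + c
    gb <- s3[j + 1L] - s3[j - 1L]
    any(pmax(abs(gt), abs(gb)) > cfg$threshold)
  }

  classify_run <- function(fs, fe) {
    take <- min(fe - fs, cfg$feature_frames)
    win <- matrix(0, nrow = cfg$feature_frames, ncol = nb)
    for (r in seq_len(take)) win[r, ] <- mags[[fs + r]]
    model_predict(model, as.vector(t(win)))
  }

  consume <- function(t, ind, now) { # t 0-based
    if (ind) {
      if (run_len == 0L) run_start <<- t
      run_len <<- run_len + 1L
    } else {
      if (run_len >= cfg$min_frames) {
        pred <- classify_run(run_start, t)
        emit(data.frame(symbol = pred$letter, t_start = run_start * fd,
                        t_end = t * fd, confidence = pred$confidence,
                        emit_latency = now - t * fd))
        anchor <<- t
        last_end_f <<- t
        tracker$syllable(t * fd)
      }
      run_len <<- 0L
      while (!is.na(anchor) && (t + 1L) - anchor >= gapf &&
             anchor + gapf <= last_end_f + tail_lim) {
        m <- anchor + gapf
        emit(data.frame(symbol = "/", t_start = (m - gapf) * fd,
                        t_end = m * fd, confidence = NA_real_,
                        emit_latency = now - m * fd))
        anchor <<- m
      }
    }
    tracker$tick(now)
  }

  buf <- numeric(0)
  for (chunk in chunks) {
    if (!is.numeric(chunk)) stop("chunks must be numeric sample vectors")
    buf <- c(buf, as.numeric(chunk))
    while (length(buf) >= window) {
      col <- Mod(stats::fft(buf[seq_len(window)] * w)) / wsum2
      mags[[length(mags) + 1L]] <- col[(cfg$band_lo + 1L):cfg$band_hi]
      buf <- buf[-seq_len(hop)]
      n <- length(mags)
      now <- n * fd
      # consume every frame whose indicator is decidable: frame 0 is border
      # (false); frame t needs t+1 ingested
      while (consumed < n - 1L) {
        t <- consumed # 0-based
        ind <- if (t == 0L) FALSE else edge_indicator(t)
        consume(t, ind, now)
        consumed <- consumed + 1L
      }
    }
  }
  # flush: final frame is a border frame (no trailing context), never an edge
  n <- length(mags)
  if (consumed < n) {
    consume(n - 1L, FALSE, n * fd)
    consumed <- n
  }
  tracker$tick(Inf)

  events <- if (length(rows)) do.call(rbind, rows) else empty_events()
  annotation(events, tracker$finish(),
             source_id = "stream",
             model_id = paste(model$letters, collapse = ""))
}

#' Sensitivity of decoding to the analysis reading frame
#'
#' Decodes the same clip at randomized sample offsets within one analysis
#' window and reports the sequence identity of each decoding against the
#' zero-offset reference, mimicking the variability a live stream sees when
#' its reading frame is arbitrary. Gap markers are excluded from the
#' identity computation.
#'
#' @param audio An [audio_clip()].
#' @param model A trained `decoder_model`.
#' @param n_offsets Number of random offsets (>= 2 unless `offsets` given).
#' @param seed RNG seed for offset sampling.
#' @param offsets Optional explicit offsets in samples (overrides sampling).
#' @return List: `offsets`, `identities` (percent, one per offset), `mean`,
#'   `sd`.
#' @export
jitter_robustness <- function(audio, model, n_offsets = 20L, seed = 1L,
                              offsets = NULL) {
  cfg <- model$config
  if (is.null(offsets)) {
    if (n_offsets < 2L) stop("n_offsets must be >= 2")
    set.seed(seed)
    offsets <- sample.int(cfg$window_samples - 1L,
                          min(n_offsets, cfg$window_samples - 1L))
  }
  ref <- annotation_symbols(decode_offline(audio, model), exclude = "/")
  ids <- vapply(offsets, function(off) {
    x <- if (off == 0L) audio$samples else audio$samples[-seq_len(off)]
    clip <- audio_clip(x, audio$sample_rate, source_id = audio$source_id)
    hyp <- annotation_symbols(decode_offline(clip, model), exclude = "/")
    sequence_identity(align_sequences(ref, hyp))
  }, numeric(1))
  list(offsets = offsets, identities = ids,
       mean = mean(ids), sd = stats::sd(ids))
}

#' Render an annotation as text
#'
#' One line per bout, events concatenated in time order; events outside all
#' bouts form a trailing line. Lossless for symbol order;
#' [parse_annotation_text()] is its inverse on the symbol sequence.
#'
#' @param ann An [annotation()].
#' @return A single string (possibly multi-line).
#' @export
annotation_to_text <- function(ann) {
  ev <- ann$events
  if (nrow(ev) == 0L) return("")
  bouts <- ann$bouts
  assigned <- rep(FALSE, nrow(ev))
  lines <- character()
  eps <- 1e-9
  if (!is.null(bouts) && nrow(bouts) > 0L) {
    for (b in seq_len(nrow(bouts))) {
      # bouts are delimited by detection (end) times, so membership is
      # judged on each event's end time
      in_b <- !assigned & ev$t_end >= bouts$bout_start[b] - eps &
        ev$t_end <= bouts$bout_end[b] + eps
      if (any(in_b)) {
        lines <- c(lines, paste(ev$symbol[in_b], collapse = ""))
        assigned <- assigned | in_b
      }
    }
  }
  if (any(!assigned)) {
    lines <- c(lines, paste(ev$symbol[!assigned], collapse = ""))
  }
  paste(lines, collapse = "\n")
}

#' Parse annotation text back into symbol sequences
#'
#' @param text String as produced by [annotation_to_text()] (one bout per
#'   line, one character per symbol).
#' @return List of character vectors, one per bout.
#' @export
parse_annotation_text <- function(text) {
  if (identical(text, "")) return(list())
  lapply(strsplit(text, "\n", fixed = TRUE)[[1L]],
         function(l) strsplit(l, "", fixed = TRUE)[[1L]])
}
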