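SHAPES <- c("tone", "harmonic_stack", "up_chirp", "down_chirp", "noise_burst")

#' Specification of one synthetic syllable type
#'
#' Describes the spectro-temporal shape of a syllable type: a pure tone, a
#' three-partial harmonic stack, a rising or falling chirp, or a
#' band-limited noise burst. Types with distinct shapes and fundamentals
#' are spectrally separable on the band-pruned spectrogram the decoder
#' sees.
#'
#' @param letter Ground-truth letter of the type.
#' @param shape One of `tone`, `harmonic_stack`, `up_chirp`, `down_chirp`,
#'   `noise_burst`.
#' @param f0 Fundamental / center frequency in Hz; must lie inside the
#'   retained band range of the default spectrogram (about 1.4-15.2 kHz).
#' @param bandwidth Sweep width (chirps) or noise band width in Hz.
#' @param duration Seconds; at least 0.03 s so the syllable spans the
#'   5-frame minimum.
#' @param amplitude Peak amplitude relative to full scale.
#' @return A `syllable_spec`.
#' @export
syllable_spec <- function(letter, shape, f0, bandwidth = 500,
                          duration = 0.06, amplitude = 0.6) {
  shape <- match.arg(shape, SHAPES)
  if (duration < 0.03) stop("syllable duration must be at least 0.03 s")
  if (f0 < 1400 || f0 > 15200) {
    stop("f0 must lie within the retained band range (~1400-15200 Hz)")
  }
  stopifnot(bandwidth > 0, amplitude >= 0, amplitude <= 1)
  structure(list(letter = letter, shape = shape, f0 = f0,
                 bandwidth = bandwidth, duration = duration,
                 amplitude = amplitude),
            class = "syllable_spec")
}

#' Render one syllable to a waveform
#'
#' Deterministic given the seed (only the noise burst consumes random
#' numbers). A 4 ms raised-cosine ramp at both ends avoids clicks.
#'
#' @param spec A [syllable_spec()].
#' @param sample_rate Samples per second.
#' @param seed RNG seed.
#' @return Numeric waveform of length `duration * sample_rate`.
#' @export
make_syllable <- function(spec, sample_rate = 44100, seed = 1L) {
  stopifnot(inherits(spec, "syllable_spec"))
  n <- round(spec$duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  x <- switch(
    spec$shape,
    tone = sin(2 * pi * spec$f0 * t),
    harmonic_stack = {
      h <- sin(2 * pi * spec$f0 * t) +
        0.5 * sin(2 * pi * 2 * spec$f0 * t) +
        0.25 * sin(2 * pi * 3 * spec$f0 * t)
      h / max(abs(h))
    },
    up_chirp = {
      f_start <- spec$f0 - spec$bandwidth / 2
      rate <- spec$bandwidth / spec$duration
      sin(2 * pi * (f_start * t + rate * t^2 / 2))
    },
    down_chirp = {
      f_start <- spec$f0 + spec$bandwidth / 2
      rate <- -spec$bandwidth / spec$duration
      sin(2 * pi * (f_start * t + rate * t^2 / 2))
    },
    noise_burst = {
      set.seed(seed)
      wn <- stats::rnorm(n)
      ny <- sample_rate / 2
      band <- c(max(spec$f0 - spec$bandwidth / 2, 50) / ny,
                min(spec$f0 + spec$bandwidth / 2, ny - 50) / ny)
      bf <- signal::butter(4, band, type = "pass")
      y <- signal::filtfilt(bf, wn)
      y / max(abs(y))
    })
  ramp_n <- min(round(0.004 * sample_rate), n %/% 2)
  if (ramp_n > 0L) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
    x[seq_len(ramp_n)] <- x[seq_len(ramp_n)] * ramp
    x[(n - ramp_n + 1L):n] <- x[(n - ramp_n + 1L):n] * rev(ramp)
  }
  spec$amplitude * x
}

#' Define a song grammar
#'
#' The generative model behind the synthetic corpus: a bout starts with
#' introductory notes, then emits syllables from a first-order transition
#' table -- except that runs of the target syllable are drawn from an
#' explicit run-length law (shifted geometric or fixed). The explicit law
#' makes repetition deliberately non-Markovian, so conditioning
#' simulations can shift it directly, and mirrors real song where
#' repetition counts do not follow a first-order chain.
#'
#' @param syllables Named list of [syllable_spec()]s (names = letters).
#' @param intro_letter Letter of the introductory note (`NA` for none).
#' @param n_intro_range Integer range of introductory-note counts.
#' @param transitions Row-stochastic matrix over the non-intro letters.
#' @param target Target (repeated) letter.
#' @param run_law List: `type` (`"geometric"` or `"fixed"`) plus `mean` or
#'   `k`; run lengths of the target are drawn from it (support >= 1).
#' @param gap_range Inter-syllable silent gap range in seconds (kept below
#'   the 290 ms silent-marker threshold within a bout).
#' @param length_range Number of main (non-intro) symbols per bout, before
#'   target-run expansion.
#' @param tail_silence_s Bout-terminating silence appended to each song
#'   (> 2 s so the bout closes).
#' @param jitter Per-instance rendition variability, as relative
#'   half-widths of uniform multiplicative jitter on `f0`, `duration` and
#'   `amplitude`. Real syllables vary slightly from rendition to rendition;
#'   the defaults (2 % pitch, 8 % duration, 10 % amplitude) keep each type
#'   a single connected cloud in feature space while leaving types far
#'   apart.
#' @return A `song_grammar`.
#' @export
song_grammar <- function(syllables, intro_letter = "i",
                         n_intro_range = c(1L, 3L), transitions,
                         target, run_law = list(type = "geometric", mean = 3),
                         gap_range = c(0.03, 0.08),
                         length_range = c(10L, 16L),
                         tail_silence_s = 2.5,
                         jitter = list(f0 = 0.02, duration = 0.08,
                                       amplitude = 0.1)) {
  letters_main <- rownames(transitions)
  stopifnot(!is.null(letters_main),
            identical(rownames(transitions), colnames(transitions)),
            all(abs(rowSums(transitions) - 1) < 1e-9),
            target %in% letters_main,
            all(letters_main %in% names(syllables)))
  if (!is.na(intro_letter)) stopifnot(intro_letter %in% names(syllables))
  stopifnot(run_law$type %in% c("geometric", "fixed"),
            tail_silence_s > 2)
  structure(list(syllables = syllables, intro_letter = intro_letter,
                 n_intro_range = as.integer(n_intro_range),
                 transitions = transitions, target = target,
                 run_law = run_law, gap_range = gap_range,
                 length_range = as.integer(length_range),
                 tail_silence_s = tail_silence_s, jitter = jitter),
            class = "song_grammar")
}

draw_law <- function(law) {
  switch(law$type,
         fixed = as.integer(law$k),
         geometric = {
           if (law$mean <= 1) 1L
           else 1L + stats::rgeom(1L, prob = 1 / law$mean)
         })
}

#' Draw one bout's symbol sequence from a grammar
#'
#' Symbol-level generation only (no audio): introductory notes, then a walk
#' on the transition table with target visits expanded into runs drawn
#' from the grammar's run-length law.
#'
#' @param grammar A [song_grammar()].
#' @param seed Optional RNG seed (omit to use the current RNG state).
#' @return Character vector of symbols.
#' @export
draw_song_sequence <- function(grammar, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- grammar
  out <- character(0)
  if (!is.na(g$intro_letter)) {
    n_intro <- sample(g$n_intro_range[1]:g$n_intro_range[2], 1L)
    out <- rep(g$intro_letter, n_intro)
  }
  mains <- rownames(g$transitions)
  n_main <- sample(g$length_range[1]:g$length_range[2], 1L)
  cur <- sample(mains, 1L)
  emitted <- 0L
  while (emitted < n_main) {
    if (cur == g$target) {
      run <- draw_law(g$run_law)
      out <- c(out, rep(cur, run))
    } else {
      out <- c(out, cur)
    }
    emitted <- emitted + 1L
    if (emitted < n_main) {
      p <- g$transitions[cur, ]
      if (cur == g$target && sum(p[mains != g$target]) > 0) {
        # the run law owns consecutive-target counts: never re-enter the
        # target straight after a run, or adjacent runs would concatenate
        p[g$target] <- 0
      }
      cur <- sample(mains, 1L, prob = p)
    }
  }
  out
}

#' Render one song with exact ground truth
#'
#' Draws a symbol sequence from the grammar and renders it: a short lead-in
#' silence, syllables separated by gaps drawn from the grammar's gap range,
#' and a bout-terminating tail silence (> 2 s). Returns the audio and a
#' ground-truth annotation giving each syllable's letter and exact
#' `[t_start, t_end]`.
#'
#' @param grammar A [song_grammar()].
#' @param seed RNG seed; the same seed reproduces the identical song.
#' @param sample_rate Samples per second.
#' @param source_id Identifier stored on the clip and annotation.
#' @return List: `audio` ([audio_clip()]), `truth` ([annotation()] without
#'   bout rows), `sequence` (string).
#' @export
make_song <- function(grammar, seed = 1L, sample_rate = 44100,
                      source_id = paste0("synthetic_", seed)) {
  set.seed(seed)
  symbols <- draw_song_sequence(grammar)
  n_syll <- length(symbols)
  gaps <- stats::runif(n_syll, grammar$gap_range[1], grammar$gap_range[2])
  lead <- 0.1
  waves <- vector("list", n_syll)
  t_start <- numeric(n_syll)
  t_end <- numeric(n_syll)
  t <- lead
  jit <- grammar$jitter
  jdraw <- function(half) stats::runif(1L, 1 - half, 1 + half)
  for (i in seq_len(n_syll)) {
    sp <- grammar$syllables[[symbols[i]]]
    if (!is.null(jit)) { # per-rendition variability
      sp$f0 <- sp$f0 * jdraw(jit$f0)
      sp$duration <- max(0.03, sp$duration * jdraw(jit$duration))
      sp$amplitude <- min(1, sp$amplitude * jdraw(jit$amplitude))
    }
    waves[[i]] <- make_syllable(sp, sample_rate,
                                seed = (seed %% 2147483L) * 1000L + i)
    t_start[i] <- t
    t_end[i] <- t + length(waves[[i]]) / sample_rate
    t <- t_end[i] + gaps[i]
  }
  total_s <- t_end[n_syll] + grammar$tail_silence_s
  x <- numeric(round(total_s * sample_rate))
  for (i in seq_len(n_syll)) {
    s0 <- round(t_start[i] * sample_rate)
    x[s0 + seq_along(waves[[i]])] <- waves[[i]]
  }
  truth_events <- data.frame(symbol = symbols, t_start = t_start,
                             t_end = t_end, confidence = NA_real_,
                             emit_latency = NA_real_)
  truth <- annotation(truth_events,
                      data.frame(bout_start = t_start[1],
                                 bout_end = t_end[n_syll] + 2.0,
                                 n_syllables = n_syll),
                      source_id = source_id, model_id = "truth")
  list(audio = audio_clip(x, sample_rate, source_id = source_id),
       truth = truth, sequence = paste(symbols, collapse = ""))
}

#' Default synthetic song grammar
#'
#' Twelve spectrally distinct syllable types (within the typical 10-20
#' range): one introductory note plus eleven song syllables spread over
#' 1.6-9 kHz with alternating shapes, target `"c"` with a shifted-geometric
#' run law of mean 3. Transitions over the non-target structure are a
#' random row-stochastic table drawn once from a fixed seed, with all
#' entries positive so every bigram has support.
#'
#' @param run_mean Mean of the target run-length law.
#' @return A [song_grammar()].
#' @export
default_song_grammar <- function(run_mean = 3) {
  shapes <- c("harmonic_stack", "tone", "down_chirp", "up_chirp", "tone",
              "harmonic_stack", "noise_burst", "tone", "up_chirp",
              "down_chirp", "tone")
  f0s <- c(1800, 2600, 3300, 4100, 5000, 2200, 6500, 7400, 5800, 8600, 9400)
  durs <- c(0.07, 0.05, 0.06, 0.08, 0.04, 0.09, 0.06, 0.05, 0.07, 0.05, 0.06)
  lets <- c("a", "b", "c", "d", "e", "f", "g", "h", "j", "k", "l") # "i" is the intro
  specs <- stats::setNames(lapply(seq_along(lets), function(i) {
    syllable_spec(lets[i], shapes[i], f0s[i], bandwidth = 600,
                  duration = durs[i], amplitude = 0.6)
  }), lets)
  # introductory note: short, soft and broadband-noisy, spectrally far from
  # every tonal type
  specs$i <- syllable_spec("i", "noise_burst", 1500, bandwidth = 700,
                           duration = 0.035, amplitude = 0.45)
  # deterministic all-positive row-stochastic table (no RNG involved)
  tm <- outer(1:11, 1:11, function(i, j) 0.25 + ((i * 7 + j * 3) %% 11) / 11)
  dimnames(tm) <- list(lets, lets)
  tm <- tm / rowSums(tm)
  song_grammar(specs, intro_letter = "i", transitions = tm, target = "c",
               run_law = list(type = "geometric", mean = run_mean))
}

#' Generate a synthetic corpus on disk
#'
#' Writes `n_songs` WAV files with additive white noise at the stated
#' signal-to-noise ratio, a ground-truth annotation text file (one bout
#' sequence per line) and a JSON index with per-song truths. Byte-identical
#' across runs with the same seed.
#'
#' @param grammar A [song_grammar()].
#' @param n_songs Number of songs (>= 1).
#' @param noise_db Signal-to-noise ratio in dB, measured against the rms of
#'   the active (syllable) samples; `Inf` disables noise.
#' @param seed Master RNG seed.
#' @param out_dir Output directory (created if missing).
#' @param sample_rate Samples per second.
#' @return A `corpus_index`: `dir`, `files`, `sequences`, `truths` (list of
#'   per-song truth data frames), `seed`, `noise_db`.
#' @export
make_corpus <- function(grammar, n_songs, noise_db = 20, seed = 1L,
                        out_dir = tempfile("corpus"), sample_rate = 44100) {
  stopifnot(n_songs >= 1)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory ", out_dir)
  }
  set.seed(seed)
  song_seeds <- sample.int(.Machine$integer.max - 1L, n_songs)
  files <- sprintf("song_%04d.wav", seq_len(n_songs))
  sequences <- character(n_songs)
  truths <- vector("list", n_songs)
  for (i in seq_len(n_songs)) {
    song <- make_song(grammar, seed = song_seeds[i],
                      sample_rate = sample_rate, source_id = files[i])
    x <- song$audio$samples
    if (is.finite(noise_db)) {
      active <- x != 0
      rms <- sqrt(mean(x[active]^2))
      set.seed(song_seeds[i] + 1L)
      x <- x + stats::rnorm(length(x), sd = rms / 10^(noise_db / 20))
    }
    write_wav(x, file.path(out_dir, files[i]), sample_rate)
    sequences[i] <- song$sequence
    truths[[i]] <- song$truth$events[, c("symbol", "t_start", "t_end")]
  }
  writeLines(sequences, file.path(out_dir, "truth.txt"))
  index <- list(files = files, sequences = sequences, seed = seed,
                noise_db = noise_db, n_songs = n_songs,
                sample_rate = sample_rate)
  jsonlite::write_json(c(index, list(truths = truths)),
                       file.path(out_dir, "index.json"),
                       digits = NA, auto_unbox = TRUE)
  structure(c(index, list(dir = out_dir, truths = truths)),
            class = "corpus_index")
}

#' Load a corpus index written by [make_corpus()]
#'
#' @param dir Corpus directory containing `index.json`.
#' @return A `corpus_index`.
#' @export
read_corpus_index <- function(dir) {
  p <- jsonlite::read_json(file.path(dir, "index.json"),
                           simplifyVector = TRUE)
  structure(list(files = p$files, sequences = p$sequences, seed = p$seed,
                 noise_db = p$noise_db, n_songs = p$n_songs,
                 sample_rate = p$sample_rate, dir = dir,
                 truths = p$truths),
            class = "corpus_index")
}

#' @export
print.corpus_index <- function(x, ...) {
  cat(sprintf("<corpus_index> %d songs in %s (SNR %g dB, seed %d)\n",
              x$n_songs, x$dir, x$noise_db, x$seed))
  invisible(x)
}
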