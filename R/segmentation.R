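#' Segmentation configuration
#'
#' Bundles every parameter the segmentation front end needs so that a trained
#' decoder can carry the exact settings it was built with.
#'
#' @param threshold Prewitt edge-response cutoff. Magnitudes are normalized to
#'   full scale (a full-scale sine gives a band magnitude of ~1), so the
#'   threshold is a fraction of full scale. The useful value depends on the
#'   vocalization amplitude and the noise floor of the recording; tune it per
#'   corpus.
#' @param window_samples FFT window length in samples (power of two).
#' @param hop_samples Hop between consecutive frames; frames are
#'   non-overlapping at the default hop = window.
#' @param band_lo,band_hi Retained frequency-band range (0-based, half-open)
#'   out of `window_samples / 2` total bands. The defaults drop the lowest 8
#'   and highest 40 of 128 bands, keeping 80.
#' @param min_frames Minimum syllable duration in frames; edge runs shorter
#'   than this are rejected (5 frames = "more than 4").
#' @param feature_frames Frames per syllable feature window (40 by default,
#'   giving 40 x 80 = 3200 feature dimensions).
#' @param gap_frames Consecutive syllable-free frames after which a silent-gap
#'   marker `/` is emitted (50 frames = 290 ms at defaults).
#' @param bout_rise,bout_decay,bout_cutoff Song-bout accumulator parameters:
#'   the accumulator gains `bout_rise` per detected syllable and decays
#'   linearly at `bout_decay` per second of silence; a bout starts when it
#'   reaches `bout_cutoff`. Defaults make four syllables within a second open
#'   a bout.
#' @param bout_tail_s Seconds of silence after the last syllable that close a
#'   bout (2 s).
#' @return A list of class `seg_config`.
#' @export
seg_config <- function(threshold = 0.1,
                       window_samples = 256L, hop_samples = 256L,
                       band_lo = 8L, band_hi = 88L,
                       min_frames = 5L, feature_frames = 40L,
                       gap_frames = 50L,
                       bout_rise = 1.0, bout_decay = 0.5, bout_cutoff = 3.0,
                       bout_tail_s = 2.0) {
  stopifnot(threshold > 0, window_samples > 0, hop_samples > 0,
            band_lo >= 0, band_hi > band_lo,
            band_hi <= window_samples / 2,
            min_frames >= 1, feature_frames >= 1, gap_frames >= 1,
            bout_rise > 0, bout_decay >= 0, bout_cutoff > 0, bout_tail_s >= 0)
  structure(
    list(threshold = threshold,
         window_samples = as.integer(window_samples),
         hop_samples = as.integer(hop_samples),
         band_lo = as.integer(band_lo), band_hi = as.integer(band_hi),
         min_frames = as.integer(min_frames),
         feature_frames = as.integer(feature_frames),
         gap_frames = as.integer(gap_frames),
         bout_rise = bout_rise, bout_decay = bout_decay,
         bout_cutoff = bout_cutoff, bout_tail_s = bout_tail_s),
    class = "seg_config"
  )
}

#' Number of retained frequency bands of a configuration
#' @param config A [seg_config()].
#' @return Integer band count (80 under defaults).
#' @export
retained_bands <- function(config) config$band_hi - config$band_lo

#' Feature-vector length of a configuration
#' @param config A [seg_config()].
#' @return `feature_frames * retained_bands` (3200 under defaults).
#' @export
feature_length <- function(config) config$feature_frames * retained_bands(config)

#' Compute a band-pruned magnitude spectrogram
#'
#' Frames the signal with non-overlapping windows (default 256 samples,
#' 5.8 ms at 44.1 kHz), applies a Hamming window, takes the FFT magnitude of
#' the lower half-spectrum (128 bands at defaults), and drops the noise-prone
#' lowest and highest bands, keeping bands `[band_lo, band_hi)`. Magnitudes
#' are normalized to full scale (divided by half the window sum), so a
#' full-scale sine has a magnitude near 1 in its band. The normalization is
#' causal and clip-independent, which keeps streaming and offline processing
#' identical and makes the edge threshold comparable across recordings.
#'
#' @param audio An [audio_clip()] or numeric sample vector.
#' @param window_samples FFT window size (power of two).
#' @param hop_samples Hop between frames; equal to the window by default.
#' @param band_lo,band_hi Retained band range, 0-based half-open.
#' @param sample_rate Used when `audio` is a bare numeric vector.
#' @return An object of class `spectrogram`: `magnitudes` (frames x retained
#'   bands), `frame_duration` (s), `band_lo`, `band_hi`, `n_fft_bands`,
#'   `sample_rate`, `window_samples`, `hop_samples`, `source_id`. Audio
#'   shorter than one window yields a 0-frame spectrogram flagged with
#'   attribute `empty = TRUE`.
#' @export
compute_spectrogram <- function(audio, window_samples = 256L,
                                hop_samples = window_samples,
                                band_lo = 8L, band_hi = 88L,
                                sample_rate = 44100) {
  if (inherits(audio, "audio_clip")) {
    x <- audio$samples
    sample_rate <- audio$sample_rate
    source_id <- audio$source_id
  } else {
    x <- as.numeric(audio)
    source_id <- NA_character_
  }
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be positive")
  }
  window_samples <- as.integer(window_samples)
  if (bitwAnd(window_samples, window_samples - 1L) != 0L) {
    stop("window_samples must be a power of two")
  }
  n_bands <- window_samples %/% 2L
  stopifnot(band_lo >= 0, band_hi > band_lo, band_hi <= n_bands)
  fd <- window_samples / sample_rate

  n <- length(x)
  if (n < window_samples) {
    mag <- matrix(0, nrow = 0L, ncol = band_hi - band_lo)
    out <- spectrogram_obj(mag, fd, band_lo, band_hi, n_bands, sample_rate,
                           window_samples, hop_samples, source_id)
    attr(out, "empty") <- TRUE
    return(out)
  }
  n_frames <- (n - window_samples) %/% hop_samples + 1L
  w <- hamming_window(window_samples)
  starts <- (seq_len(n_frames) - 1L) * hop_samples
  idx <- outer(seq_len(window_samples), starts, `+`)
  frames <- matrix(x[idx], nrow = window_samples) * w
  spec <- Mod(stats::mvfft(frames)) / (sum(w) / 2)
  mag <- t(spec[(band_lo + 1L):band_hi, , drop = FALSE])
  spectrogram_obj(mag, fd, band_lo, band_hi, n_bands, sample_rate,
                  window_samples, hop_samples, source_id)
}

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

spectrogram_obj <- function(mag, fd, band_lo, band_hi, n_bands, sample_rate,
                            window_samples, hop_samples, source_id) {
  structure(
    list(magnitudes = mag, frame_duration = fd,
         band_lo = as.integer(band_lo), band_hi = as.integer(band_hi),
         n_fft_bands = as.integer(n_bands), sample_rate = sample_rate,
         window_samples = as.integer(window_samples),
         hop_samples = as.integer(hop_samples), source_id = source_id),
    class = "spectrogram"
  )
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf(
    "<spectrogram> %d frames x %d bands (of %d), frame %.4g ms, bands [%d,%d)\n",
    nrow(x$magnitudes), ncol(x$magnitudes), x$n_fft_bands,
    1000 * x$frame_duration, x$band_lo, x$band_hi))
  invisible(x)
}

# Prewitt responses on the interior of a matrix; border cells are left at 0.
# Returns max(|time gradient|, |band gradient|) at every cell.
prewitt_response <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  resp <- matrix(0, nr, nc)
  if (nr < 3L || nc < 3L) return(resp)
  # band-summed (3 adjacent columns) and frame-summed (3 adjacent rows) grids
  bs <- m[, 1:(nc - 2), drop = FALSE] + m[, 2:(nc - 1), drop = FALSE] +
    m[, 3:nc, drop = FALSE]                       # nr x (nc-2)
  fs <- m[1:(nr - 2), , drop = FALSE] + m[2:(nr - 1), , drop = FALSE] +
    m[3:nr, , drop = FALSE]                       # (nr-2) x nc
  gt <- bs[3:nr, , drop = FALSE] - bs[1:(nr - 2), , drop = FALSE] # time grad
  gb <- fs[, 3:nc, drop = FALSE] - fs[, 1:(nc - 2), drop = FALSE] # band grad
  resp[2:(nr - 1), 2:(nc - 1)] <- pmax(abs(gt), abs(gb))
  resp
}

#' Detect spectrogram edges with a Prewitt filter
#'
#' Applies the two 3x3 Prewitt kernels (time-gradient and frequency-gradient)
#' to the retained-band magnitude grid and marks cells whose larger absolute
#' response exceeds `threshold`. Narrowband sounds produce frequency-gradient
#' edges on every frame of their duration, so a syllable appears as an
#' uninterrupted run of edge-bearing frames. Border frames and bands, where
#' the kernel does not fit, are always unmarked.
#'
#' @param spec A [compute_spectrogram()] result.
#' @param threshold Positive response cutoff; on the full-scale magnitude
#'   normalization used here, values well above the noise-floor response and
#'   below ~3x the syllable amplitude are sensible.
#' @return An `edge_mask`: logical `mask` (frames x bands), `threshold`, and
#'   the source `frame_duration`. Grids smaller than 3x3 yield an all-false
#'   mask.
#' @export
detect_edges <- function(spec, threshold) {
  stopifnot(inherits(spec, "spectrogram"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("threshold must be a single positive number")
  }
  resp <- prewitt_response(spec$magnitudes)
  structure(
    list(mask = resp > threshold, threshold = threshold,
         frame_duration = spec$frame_duration),
    class = "edge_mask"
  )
}

#' Extract syllable segments from an edge mask
#'
#' A syllable is a maximal run of consecutive frames that each carry at least
#' one edge cell. Runs shorter than `min_frames` frames (default 5, i.e.
#' "more than 4") are rejected as noise transients.
#'
#' @param mask An `edge_mask` from [detect_edges()].
#' @param min_frames Minimum run length in frames.
#' @return A data frame with one row per segment: `frame_start`, `frame_end`
#'   (0-based, half-open), `t_start`, `t_end` (seconds). Sorted by time,
#'   non-overlapping.
#' @export
extract_syllables <- function(mask, min_frames = 5L) {
  stopifnot(inherits(mask, "edge_mask"), min_frames >= 1)
  has_edge <- rowSums(mask$mask) > 0
  empty <- data.frame(frame_start = integer(), frame_end = integer(),
                      t_start = numeric(), t_end = numeric())
  if (length(has_edge) == 0L) return(empty)
  r <- rle(has_edge)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_frames
  if (!any(keep)) return(empty)
  fs <- starts[keep] - 1L  # to 0-based
  fe <- ends[keep]         # half-open
  fd <- mask$frame_duration
  data.frame(frame_start = fs, frame_end = fe,
             t_start = fs * fd, t_end = fe * fd)
}

#' Group syllables into song bouts with a rise/decay accumulator
#'
#' An accumulator gains `rise` per detected syllable and decays linearly at
#' `decay` per second of silence (floored at zero). A bout opens when the
#' accumulator first reaches `cutoff`; the bout start is backdated to the
#' first syllable of the current activity run (the first syllable since the
#' accumulator was last at zero), so the syllables that built the bout up
#' belong to it. A bout closes `tail_s` seconds after its last syllable, and
#' the accumulator resets. This keeps isolated noise-driven detections (cage
#' sounds, wing flaps) from opening bouts while dense singing does.
#'
#' @param syllable_times Sorted numeric vector of syllable detection times in
#'   seconds (use syllable end times: detection happens at the trailing
#'   edge).
#' @param rise Accumulator increment per syllable (> 0).
#' @param decay Linear decay per second of silence (>= 0).
#' @param cutoff Accumulator level that opens a bout (> 0).
#' @param tail_s Silence after the last syllable that closes the bout.
#' @return A data frame with `bout_start`, `bout_end`, `n_syllables`, plus an
#'   attribute `cutoff_trace` (accumulator value after each syllable) and
#'   `syllable_bout` (bout index per syllable, `NA` if unassigned).
#' @export
detect_song_bouts <- function(syllable_times, rise = 1.0, decay = 0.5,
                              cutoff = 3.0, tail_s = 2.0) {
  if (rise <= 0) stop("rise must be > 0")
  if (decay < 0) stop("decay must be >= 0")
  stopifnot(cutoff > 0, tail_s >= 0)
  n <- length(syllable_times)
  empty <- data.frame(bout_start = numeric(), bout_end = numeric(),
                      n_syllables = integer())
  if (n == 0L) {
    attr(empty, "cutoff_trace") <- numeric()
    attr(empty, "syllable_bout") <- integer()
    return(empty)
  }
  if (is.unsorted(syllable_times)) stop("syllable_times must be sorted")

  acc <- 0; run_start_i <- NA_integer_; in_bout <- FALSE
  bout_start_i <- NA_integer_; last_i <- NA_integer_
  trace <- numeric(n)
  assignment <- rep(NA_integer_, n)
  bouts <- list()

  close_bout <- function() {
    bouts[[length(bouts) + 1L]] <<- c(
      start = syllable_times[bout_start_i],
      end = syllable_times[last_i] + tail_s,
      from = bout_start_i, to = last_i)
  }

  prev_t <- syllable_times[1L]
  for (i in seq_len(n)) {
    t <- syllable_times[i]
    if (in_bout && t - syllable_times[last_i] > tail_s) {
      close_bout()
      in_bout <- FALSE
      acc <- 0
      run_start_i <- NA_integer_
    }
    acc <- max(0, acc - decay * (t - prev_t))
    if (acc == 0) run_start_i <- i
    acc <- acc + rise
    if (!in_bout && acc >= cutoff) {
      in_bout <- TRUE
      bout_start_i <- run_start_i
    }
    if (in_bout) last_i <- i
    trace[i] <- acc
    prev_t <- t
  }
  if (in_bout) close_bout()

  if (length(bouts) == 0L) {
    res <- empty
  } else {
    b <- do.call(rbind, bouts)
    res <- data.frame(bout_start = b[, "start"], bout_end = b[, "end"],
                      n_syllables = as.integer(b[, "to"] - b[, "from"] + 1L))
    for (k in seq_along(bouts)) {
      assignment[bouts[[k]]["from"]:bouts[[k]]["to"]] <- k
    }
  }
  attr(res, "cutoff_trace") <- trace
  attr(res, "syllable_bout") <- assignment
  res
}

#' Fixed-size feature vector for one syllable
#'
#' Takes an `n_frames`-frame window of the retained-band spectrogram anchored
#' at the syllable onset and flattens it frame by frame. Segments shorter
#' than the window are zero-padded at the tail (the window never leaks
#' magnitudes past the segment end); longer segments are truncated. Under the
#' defaults this yields 40 x 80 = 3200 dimensions.
#'
#' @param spec The source [compute_spectrogram()] result.
#' @param seg One-row segment (a row of [extract_syllables()] output) or a
#'   list with `frame_start`, `frame_end`.
#' @param n_frames Window length in frames.
#' @return Numeric feature vector of length `n_frames * retained bands`,
#'   ordered frame 0 bands, frame 1 bands, ...
#' @export
syllable_feature_vector <- function(spec, seg, n_frames = 40L) {
  stopifnot(inherits(spec, "spectrogram"))
  fs <- as.integer(seg$frame_start)
  fe <- as.integer(seg$frame_end)
  nf <- nrow(spec$magnitudes)
  if (is.na(fs) || is.na(fe) || fs < 0L || fe > nf || fe <= fs) {
    stop("segment [", fs, ",", fe, ") outside spectrogram with ", nf, " frames")
  }
  nb <- ncol(spec$magnitudes)
  win <- matrix(0, nrow = n_frames, ncol = nb)
  take <- min(fe, fs + n_frames) - fs
  win[seq_len(take), ] <- spec$magnitudes[(fs + 1L):(fs + take), , drop = FALSE]
  as.vector(t(win))
}

#' Run the full segmentation front end on one clip
#'
#' Spectrogram, edge detection, syllable extraction, feature vectors and bout
#' grouping in one call, using a single [seg_config()].
#'
#' @param audio An [audio_clip()].
#' @param config A [seg_config()].
#' @return A list: `spectrogram`, `segments` (data frame as in
#'   [extract_syllables()]), `features` (matrix, one row per segment),
#'   `bouts` (data frame from [detect_song_bouts()], on syllable end times).
#' @export
segment_audio <- function(audio, config = seg_config()) {
  spec <- compute_spectrogram(audio,
                              window_samples = config$window_samples,
                              hop_samples = config$hop_samples,
                              band_lo = config$band_lo,
                              band_hi = config$band_hi)
  mask <- detect_edges(spec, config$threshold)
  segs <- extract_syllables(mask, min_frames = config$min_frames)
  feats <- matrix(numeric(), nrow = 0L, ncol = feature_length(config))
  if (nrow(segs) > 0L) {
    feats <- t(vapply(seq_len(nrow(segs)), function(i) {
      syllable_feature_vector(spec, segs[i, ], n_frames = config$feature_frames)
    }, numeric(feature_length(config))))
  }
  bouts <- detect_song_bouts(segs$t_end,
                             rise = config$bout_rise,
                             decay = config$bout_decay,
                             cutoff = config$bout_cutoff,
                             tail_s = config$bout_tail_s)
  list(spectrogram = spec, segments = segs, features = feats, bouts = bouts)
}
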