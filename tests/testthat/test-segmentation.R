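test_that("spectrogram configuration yields the documented analysis geometry", {
  cfg <- seg_config()
  fd <- cfg$window_samples / 44100
  expect_equal(round(fd * 1000, 1), 5.8)        # frame duration in ms
  expect_equal(retained_bands(cfg), 80L)        # 128 - 8 - 40
  expect_equal(feature_length(cfg), 3200L)      # 40 frames x 80 bands
  expect_equal(round(cfg$gap_frames * fd * 1000), 290) # silent-gap span
})

test_that("compute_spectrogram handles degenerate inputs", {
  expect_true(all(compute_spectrogram(numeric(44100))$magnitudes == 0))
  short <- compute_spectrogram(numeric(100))
  expect_equal(nrow(short$magnitudes), 0L)
  expect_true(isTRUE(attr(short, "empty")))
  expect_error(compute_spectrogram(numeric(500), sample_rate = 0), "positive")
  expect_error(compute_spectrogram(numeric(500), window_samples = 200),
               "power of two")
})

test_that("a pure tone concentrates energy in the band a direct DFT predicts", {
  sr <- 44100
  x <- sin(2 * pi * 4000 * (0:(sr / 2 - 1)) / sr)
  spec <- compute_spectrogram(x)
  # oracle: windowed DFT of one frame computed from the definition
  w <- 0.54 - 0.46 * cos(2 * pi * (0:255) / 255)
  frame <- x[257:512] * w
  dft <- vapply(0:127, function(k) {
    Mod(sum(frame * exp(-2i * pi * k * (0:255) / 256)))
  }, numeric(1))
  oracle_band <- which.max(dft[9:88]) # within retained range, 1-based
  peaks <- apply(spec$magnitudes, 1L, which.max)
  expect_true(all(peaks == oracle_band))
  # constant across frames, and magnitude near full scale for amplitude 1
  expect_lt(diff(range(spec$magnitudes[, oracle_band])) , 0.05)
  expect_gt(mean(spec$magnitudes[, oracle_band]), 0.5)
})

fake_spec <- function(m) {
  structure(list(magnitudes = m, frame_duration = 256 / 44100,
                 band_lo = 8L, band_hi = 8L + ncol(m), n_fft_bands = 128L,
                 sample_rate = 44100, window_samples = 256L,
                 hop_samples = 256L, source_id = "fake"),
            class = "spectrogram")
}

prewitt_oracle <- function(m, thr) {
  # direct 3x3 convolution from the kernel definition
  kt <- matrix(c(-1, -1, -1, 0, 0, 0, 1, 1, 1), 3, 3) # d/d(frame)
  kb <- t(kt)                                         # d/d(band)
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (i in 2:(nrow(m) - 1)) {
    for (j in 2:(ncol(m) - 1)) {
      win <- m[(i - 1):(i + 1), (j - 1):(j + 1)]
      out[i, j] <- max(abs(sum(win * kt)), abs(sum(win * kb))) > thr
    }
  }
  out
}

test_that("Prewitt edge detection matches a direct convolution oracle", {
  set.seed(42)
  m <- matrix(runif(20 * 12), 20, 12)
  mask <- detect_edges(fake_spec(m), threshold = 0.4)
  expect_identical(mask$mask, prewitt_oracle(m, 0.4))
  # constant grid: no gradient anywhere
  flat <- detect_edges(fake_spec(matrix(0.7, 10, 10)), threshold = 1e-6)
  expect_false(any(flat$mask))
  # a step in time of height >> threshold marks the step columns
  step <- matrix(0, 20, 10)
  step[11:20, ] <- 1
  sm <- detect_edges(fake_spec(step), threshold = 0.5)
  expect_true(all(sm$mask[11, 2:9]))
  expect_identical(sm$mask, prewitt_oracle(step, 0.5))
  # kernel does not fit
  tiny <- detect_edges(fake_spec(matrix(runif(4), 2, 2)), threshold = 0.1)
  expect_false(any(tiny$mask))
  expect_error(detect_edges(fake_spec(m), threshold = 0), "positive")
})

fake_mask <- function(frame_has_edge) {
  structure(list(mask = matrix(frame_has_edge, ncol = 1L), threshold = 0.1,
                 frame_duration = 256 / 44100),
            class = "edge_mask")
}

test_that("syllable extraction applies the minimum-duration rule", {
  # 3-frame run rejected, 5-frame run kept
  m3 <- fake_mask(c(rep(FALSE, 5), rep(TRUE, 3), rep(FALSE, 5)))
  expect_equal(nrow(extract_syllables(m3)), 0L)
  m5 <- fake_mask(c(rep(FALSE, 5), rep(TRUE, 5), rep(FALSE, 5)))
  s5 <- extract_syllables(m5)
  expect_equal(nrow(s5), 1L)
  expect_equal(s5$frame_start, 5L)
  expect_equal(s5$frame_end, 10L)
  expect_equal(s5$t_start, 5 * 256 / 44100)
})

test_that("syllable extraction equals a run-length oracle on random masks", {
  set.seed(7)
  for (rep in 1:25) {
    v <- runif(80) < 0.4
    segs <- extract_syllables(fake_mask(v), min_frames = 5L)
    r <- rle(v)
    ends <- cumsum(r$lengths)
    keep <- r$values & r$lengths >= 5L
    expect_equal(segs$frame_start, (ends - r$lengths)[keep],
                 ignore_attr = TRUE)
    expect_equal(segs$frame_end, ends[keep], ignore_attr = TRUE)
    # segment/mask consistency: every kept run appears exactly once
    expect_equal(nrow(segs), sum(keep))
  }
})

bout_oracle <- function(times, rise, decay, cutoff, tail_s) {
  # independent step-by-step accumulator simulation
  acc <- 0; bouts <- list(); in_bout <- FALSE
  run_start <- NA; last <- NA; prev <- if (length(times)) times[1] else NA
  for (t in times) {
    if (in_bout && t - last > tail_s) {
      bouts[[length(bouts) + 1]] <- c(run_start_b, last + tail_s)
      in_bout <- FALSE; acc <- 0; run_start <- NA
    }
    acc <- max(0, acc - decay * (t - prev))
    if (acc == 0) run_start <- t
    acc <- acc + rise
    if (!in_bout && acc >= cutoff) { in_bout <- TRUE; run_start_b <- run_start }
    if (in_bout) last <- t
    prev <- t
  }
  if (in_bout) bouts[[length(bouts) + 1]] <- c(run_start_b, last + tail_s)
  bouts
}

test_that("bout detection closes 2 s after the final syllable", {
  expect_equal(nrow(detect_song_bouts(numeric())), 0L)
  times <- seq(0, by = 0.1, length.out = 20)
  b <- detect_song_bouts(times, rise = 1, decay = 0.5, cutoff = 3)
  expect_equal(nrow(b), 1L)
  expect_equal(b$bout_end, times[20] + 2.0)
  expect_equal(b$n_syllables, 20L)
  # two dense clusters 10 s apart become two bouts
  b2 <- detect_song_bouts(c(times, 10 + times), rise = 1, decay = 0.5,
                          cutoff = 3)
  expect_equal(nrow(b2), 2L)
  expect_equal(b2$bout_end, c(times[20] + 2, 10 + times[20] + 2))
  expect_error(detect_song_bouts(times, rise = 0), "rise")
  expect_error(detect_song_bouts(times, decay = -1), "decay")
})

test_that("bout detection matches the accumulator oracle on random trains", {
  set.seed(11)
  for (rep in 1:20) {
    times <- sort(cumsum(rexp(40, rate = 2)) * sample(c(0.5, 1, 3), 1))
    b <- detect_song_bouts(times, rise = 1, decay = 0.5, cutoff = 3)
    o <- bout_oracle(times, 1, 0.5, 3, 2.0)
    expect_equal(nrow(b), length(o))
    if (length(o)) {
      om <- do.call(rbind, o)
      expect_equal(b$bout_start, om[, 1])
      expect_equal(b$bout_end, om[, 2])
    }
    # tail invariant holds for every bout
    asg <- attr(b, "syllable_bout")
    for (k in seq_len(nrow(b))) {
      expect_equal(b$bout_end[k] - max(times[which(asg == k)]), 2.0)
    }
  }
})

test_that("feature vectors are onset-anchored, padded and truncated correctly", {
  set.seed(3)
  m <- matrix(runif(100 * 80), 100, 80)
  spec <- fake_spec(m)
  seg10 <- list(frame_start = 20L, frame_end = 30L)
  v <- syllable_feature_vector(spec, seg10)
  expect_length(v, 3200L)
  w <- matrix(v, nrow = 40, byrow = TRUE)
  expect_equal(w[1:10, ], m[21:30, ], ignore_attr = TRUE)
  expect_true(all(w[11:40, ] == 0))           # zero-padded tail
  seg60 <- list(frame_start = 10L, frame_end = 70L)
  v60 <- syllable_feature_vector(spec, seg60)
  expect_equal(matrix(v60, nrow = 40, byrow = TRUE), m[11:50, ],
               ignore_attr = TRUE)            # truncation slice oracle
  expect_error(syllable_feature_vector(spec, list(frame_start = 90L,
                                                  frame_end = 141L)),
               "outside")
})

test_that("the segmentation front end is deterministic", {
  song <- make_song(tiny_grammar(), seed = 5)
  a <- segment_audio(song$audio)
  b <- segment_audio(song$audio)
  expect_identical(a$spectrogram$magnitudes, b$spectrogram$magnitudes)
  expect_identical(a$segments, b$segments)
  expect_identical(a$features, b$features)
})
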