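# Shared fixtures, built once per test session and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Three spectrally distant syllable types, target "c"; no introductory note.
tiny_grammar <- function(run_mean = 2.5) {
  specs <- list(
    a = syllable_spec("a", "tone", 2000, duration = 0.06),
    b = syllable_spec("b", "harmonic_stack", 3000, duration = 0.08),
    c = syllable_spec("c", "down_chirp", 5000, duration = 0.05))
  tm <- matrix(1 / 3, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  song_grammar(specs, intro_letter = NA, transitions = tm, target = "c",
               run_law = list(type = "geometric", mean = run_mean),
               length_range = c(8L, 12L))
}

tiny_corpus <- function() {
  cached("tiny_corpus", function() {
    make_corpus(tiny_grammar(), n_songs = 24, noise_db = Inf, seed = 301,
                out_dir = file.path(tempdir(), "songloop-tiny-corpus"))
  })
}

# Small trained decoder over the tiny grammar (clean audio, fast settings).
tiny_model <- function() {
  cached("tiny_model", function() {
    suppressWarnings(
      train_decoder(tiny_corpus(), seed = 301, n_songs = 24,
                    tsne_iter = 300, min_pts = 20,
                    hidden_candidates = c(4L, 6L), max_epochs = 200L))
  })
}

# Study-scale fixture: the synthetic corpus at the conditions the whole
# pipeline is meant to handle (12 syllable types, 200 songs, 20 dB SNR) and
# a decoder trained on it with default pipeline settings.
study_fixture <- function() {
  cached("study", function() {
    grammar <- default_song_grammar()
    idx <- make_corpus(grammar, n_songs = 200, noise_db = 20, seed = 101,
                       out_dir = file.path(tempdir(), "songloop-study-corpus"))
    model <- suppressWarnings(
      train_decoder(idx, seed = 101, n_songs = 200))
    list(grammar = grammar, idx = idx, model = model)
  })
}

truth_annotation <- function(idx, i) {
  tr <- idx$truths[[i]]
  annotation(data.frame(symbol = tr$symbol, t_start = tr$t_start,
                        t_end = tr$t_end, confidence = NA_real_,
                        emit_latency = NA_real_),
             NULL, source_id = idx$files[i], model_id = "truth")
}

# Decode song i of a corpus, relabel decoded letters onto truth letters by
# temporal overlap, and return the identity versus the ground truth.
decode_identity_vs_truth <- function(idx, model, i) {
  clip <- read_wav(file.path(idx$dir, idx$files[i]))
  ann <- decode_offline(clip, model)
  truth <- truth_annotation(idx, i)
  ann <- relabel_annotation(ann, map_labels_by_overlap(truth, ann))
  aln <- align_sequences(annotation_symbols(truth, exclude = "/"),
                         annotation_symbols(ann, exclude = "/"))
  sequence_identity(aln)
}
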