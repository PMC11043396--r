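Package: songloop
Title: Birdsong Syllable Decoding and Closed-Loop Operant Conditioning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quasi-real-time decoding of birdsong syllable sequences and a
    closed-loop operant-conditioning engine built on top of it. Audio is
    converted to a band-pruned spectrogram, syllables are detected by Prewitt
    edge filtering and grouped into song bouts, and syllable classes are
    discovered without manual labels by t-SNE embedding followed by DBSCAN
    density clustering. A single-hidden-layer softmax network, selected by
    AIC over candidate hidden sizes with validation-based early stopping,
    maps each syllable to a letter so whole songs become text. Decoding runs
    offline or over a simulated audio stream with identical output. Companion
    modules score agreement between annotations by global sequence alignment
    (identity, substitution/insertion/deletion error typing, per-syllable
    match rates), evaluate reward rules on per-bout repetition counts with
    scheduled context cues and delayed feedback, estimate pruned n-gram
    transition matrices of song syntax, and generate synthetic song corpora
    with exact ground-truth annotations for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    nnet,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
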