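# A single string is split into one-character symbols (so "" is the empty
# sequence); anything else is taken as an already-split symbol vector.
as_symbols <- function(x) {
  if (length(x) == 1L && is.character(x) && !is.na(x)) {
    strsplit(x, "", fixed = TRUE)[[1L]]
  } else {
    as.character(x)
  }
}

#' Globally align two symbol sequences
#'
#' Global alignment minimizing unit edit cost (match 0, substitution /
#' insertion / deletion 1), i.e. the Levenshtein distance, with a
#' deterministic tie break: on equal cost the traceback prefers
#' match > substitution > deletion > insertion. Symbols in `exclude` (gap
#' markers, introductory notes) are removed from both sequences before
#' aligning.
#'
#' @param ref,hyp Reference and hypothesis sequences: character vectors of
#'   symbols, or single strings split into characters.
#' @param exclude Symbols filtered out of both sequences first.
#' @return An object of class `seq_alignment`: data frame `columns` with
#'   `ref`, `hyp` (`NA` at gaps) and `op`
#'   (match/substitution/insertion/deletion), plus `cost`, `ref_len`,
#'   `hyp_len`.
#' @export
align_sequences <- function(ref, hyp, exclude = character()) {
  r <- as_symbols(ref)
  h <- as_symbols(hyp)
  r <- r[!r %in% exclude]
  h <- h[!h %in% exclude]
  n <- length(r)
  m <- length(h)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n
  d[1L, ] <- 0:m
  if (n > 0L && m > 0L) {
    for (i in seq_len(n)) {
      sub_cost <- as.integer(r[i] != h)
      for (j in seq_len(m)) {
        d[i + 1L, j + 1L] <- min(d[i, j] + sub_cost[j],
                                 d[i, j + 1L] + 1L,
                                 d[i + 1L, j] + 1L)
      }
    }
  }
  # traceback, preferring match > substitution > deletion > insertion
  ops <- character(0)
  ra <- character(0)
  ha <- character(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    here <- d[i + 1L, j + 1L]
    if (i > 0L && j > 0L && here == d[i, j] + (r[i] != h[j])) {
      ops <- c(if (r[i] == h[j]) "match" else "substitution", ops)
      ra <- c(r[i], ra); ha <- c(h[j], ha)
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && here == d[i, j + 1L] + 1L) {
      ops <- c("deletion", ops)
      ra <- c(r[i], ra); ha <- c(NA_character_, ha)
      i <- i - 1L
    } else {
      ops <- c("insertion", ops)
      ra <- c(NA_character_, ra); ha <- c(h[j], ha)
      j <- j - 1L
    }
  }
  structure(
    list(columns = data.frame(ref = ra, hyp = ha, op = ops),
         cost = d[n + 1L, m + 1L], ref_len = n, hyp_len = m),
    class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("<seq_alignment> cost %d over %d columns (ref %d, hyp %d)\n",
              x$cost, nrow(x$columns), x$ref_len, x$hyp_len))
  rs <- ifelse(is.na(x$columns$ref), "-", x$columns$ref)
  hs <- ifelse(is.na(x$columns$hyp), "-", x$columns$hyp)
  cat(" ref:", paste(rs, collapse = ""), "\n hyp:",
      paste(hs, collapse = ""), "\n")
  invisible(x)
}

#' Sequence identity rate of an alignment
#'
#' Identity = 100 x matched columns / reference length. The denominator is
#' the reference sequence length, so the measure is asymmetric: swapping
#' `ref` and `hyp` keeps the match count but changes the normalization. An
#' empty reference scores 100 against an empty hypothesis and 0 otherwise.
#'
#' @param aln A `seq_alignment`.
#' @return Identity in percent.
#' @export
sequence_identity <- function(aln) {
  stopifnot(inherits(aln, "seq_alignment"))
  if (aln$ref_len == 0L) return(if (aln$hyp_len == 0L) 100 else 0)
  100 * sum(aln$columns$op == "match") / aln$ref_len
}

#' Count alignment errors by type
#'
#' @param aln A `seq_alignment`.
#' @return Named integer vector: `substitution`, `insertion`, `deletion`
#'   (and `match`). The counts satisfy
#'   `match + substitution + deletion = ref_len` and
#'   `match + substitution + insertion = hyp_len`.
#' @export
classify_errors <- function(aln) {
  stopifnot(inherits(aln, "seq_alignment"))
  ops <- factor(aln$columns$op,
                levels = c("match", "substitution", "insertion", "deletion"))
  table_out <- table(ops)
  stats::setNames(as.integer(table_out), names(table_out))
}

#' Per-syllable match rate
#'
#' For each letter, the percentage of its reference occurrences that were
#' matched exactly: 100 x (match columns with that reference letter) /
#' (reference occurrences). Letters absent from the reference are reported
#' as `NA` (undefined), never 0. Rates for letters with few occurrences are
#' statistically weak; occurrence counts are returned alongside.
#'
#' @param alignments A `seq_alignment` or list of them (pooled).
#' @param letters Letters to report; default: every letter seen in the
#'   references.
#' @return Data frame: `letter`, `occurrences`, `matched`, `rate` (percent,
#'   `NA` when the letter never occurs).
#' @export
per_syllable_match_rate <- function(alignments, letters = NULL) {
  if (inherits(alignments, "seq_alignment")) alignments <- list(alignments)
  cols <- do.call(rbind, lapply(alignments, `[[`, "columns"))
  refs <- cols$ref[!is.na(cols$ref)]
  if (is.null(letters)) letters <- sort(unique(refs))
  occ <- vapply(letters, function(l) sum(refs == l), integer(1))
  mat <- vapply(letters, function(l) {
    sum(cols$op == "match" & !is.na(cols$ref) & cols$ref == l)
  }, integer(1))
  data.frame(letter = letters, occurrences = occ, matched = mat,
             rate = ifelse(occ > 0L, 100 * mat / occ, NA_real_))
}

#' Coefficient of variation of identity rates
#'
#' `CV = 100 x sd / mean`, the reproducibility summary for repeated
#' annotation runs.
#'
#' @param identity_rates Numeric vector of identity percentages (>= 2).
#' @return CV in percent.
#' @export
reproducibility_cv <- function(identity_rates) {
  if (length(identity_rates) < 2L) {
    stop("need at least two identity rates to compute a CV")
  }
  m <- mean(identity_rates)
  if (m == 0) stop("mean identity is zero; CV undefined")
  100 * stats::sd(identity_rates) / m
}

#' Test equality of two Pearson correlations (Fisher Z)
#'
#' Fisher-transforms both coefficients (`z = atanh(r)`) and compares them
#' with `z = (z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))` against a standard
#' normal, two-sided.
#'
#' @param r1,r2 Correlation coefficients, `|r| < 1`.
#' @param n1,n2 Sample sizes, both > 3.
#' @return List: `z` (statistic), `p` (two-sided).
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Letter correspondence between two annotations by temporal overlap
#'
#' Two annotations of the same recording generally use different letter
#' alphabets (cluster letters are assigned by size). This maps each
#' hypothesis letter to the reference letter whose syllables it overlaps
#' most, by majority vote over events with positive temporal overlap.
#'
#' @param ref,hyp [annotation()] objects over the same audio.
#' @return Named character vector: hypothesis letter -> reference letter.
#' @export
map_labels_by_overlap <- function(ref, hyp) {
  re <- ref$events[ref$events$symbol != "/", , drop = FALSE]
  he <- hyp$events[hyp$events$symbol != "/", , drop = FALSE]
  if (nrow(re) == 0L || nrow(he) == 0L) return(character())
  votes <- list()
  for (i in seq_len(nrow(he))) {
    ov <- pmin(he$t_end[i], re$t_end) - pmax(he$t_start[i], re$t_start)
    j <- which.max(ov)
    if (length(j) == 1L && ov[j] > 0) {
      key <- he$symbol[i]
      votes[[key]] <- c(votes[[key]], re$symbol[j])
    }
  }
  vapply(votes, function(v) names(which.max(table(v))), character(1))
}

#' Relabel annotation symbols through a letter map
#'
#' @param ann An [annotation()].
#' @param map Named character vector (old letter -> new letter), e.g. from
#'   [map_labels_by_overlap()]. Unmapped symbols are kept.
#' @return The relabelled [annotation()].
#' @export
relabel_annotation <- function(ann, map) {
  s <- ann$events$symbol
  hit <- s %in% names(map)
  s[hit] <- unname(map[s[hit]])
  ann$events$symbol <- s
  ann
}
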