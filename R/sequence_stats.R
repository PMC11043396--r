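#' Estimate an n-gram transition matrix from bout sequences
#'
#' Counts every length-`n` window inside each bout (windows never cross
#' bout boundaries and no start/end padding symbols are added), with rows
#' indexed by the (n-1)-gram context and columns by the next symbol, and
#' normalizes each row by its total. `n = 3` gives the tri-gram matrix used
#' for song-syntax comparisons.
#'
#' @param sequences Character vector of bout sequences (or list of symbol
#'   vectors).
#' @param n N-gram order (>= 2).
#' @return A `transition_matrix`: `counts` (contexts x symbols),
#'   `probs` (row-stochastic where the row total is nonzero), `n`,
#'   `total_transitions`.
#' @export
transition_matrix <- function(sequences, n = 3L) {
  stopifnot(n >= 2L, length(sequences) > 0L)
  sym <- lapply(sequences, as_symbols)
  ctx <- character(0)
  nxt <- character(0)
  for (s in sym) {
    L <- length(s)
    if (L < n) next
    starts <- seq_len(L - n + 1L)
    ctx <- c(ctx, vapply(starts, function(i) {
      paste(s[i:(i + n - 2L)], collapse = "")
    }, character(1)))
    nxt <- c(nxt, s[starts + n - 1L])
  }
  if (length(ctx) == 0L) stop("all sequences are shorter than n = ", n)
  counts <- table(factor(ctx), factor(nxt))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs == 0, 1, rs)
  structure(list(counts = counts, probs = probs, n = as.integer(n),
                 total_transitions = sum(counts)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> order %d: %d contexts x %d symbols, %d transitions\n",
              x$n, nrow(x$counts), ncol(x$counts), x$total_transitions))
  invisible(x)
}

#' Prune rare transitions for display
#'
#' Marks as hidden every entry whose share is below `floor` in **both** its
#' row and its column (shares are count shares: entry count over row /
#' column total). Pruning is purely presentational: the counts are kept and
#' [unprune_matrix()] restores the original exactly.
#'
#' @param m A [transition_matrix()].
#' @param floor Share threshold in `[0, 1)`; 0.01 hides transitions under
#'   1 percent.
#' @return The matrix with an added logical `pruned` mask and a `display`
#'   copy of `probs` with hidden entries set to `NA`.
#' @export
prune_matrix <- function(m, floor = 0.01) {
  stopifnot(inherits(m, "transition_matrix"), floor >= 0, floor < 1)
  rs <- rowSums(m$counts)
  cs <- colSums(m$counts)
  row_share <- m$counts / ifelse(rs == 0, 1, rs)
  col_share <- sweep(m$counts, 2L, ifelse(cs == 0, 1, cs), `/`)
  pruned <- row_share < floor & col_share < floor
  display <- m$probs
  display[pruned] <- NA_real_
  m$pruned <- pruned
  m$display <- display
  m
}

#' Undo presentational pruning
#'
#' @param m A pruned [transition_matrix()].
#' @return The matrix without `pruned`/`display`, identical to the
#'   original.
#' @export
unprune_matrix <- function(m) {
  m$pruned <- NULL
  m$display <- NULL
  m
}

#' Correlation between two transition matrices
#'
#' Vectorizes both matrices over the union of their context and symbol
#' labels (absent entries count as probability 0) and computes the
#' correlation of the transition probabilities, optionally restricted to
#' the `top_k` transitions ranked by the first matrix (ties broken
#' lexicographically by "context>symbol" label). Pearson is the default;
#' Spearman is available via `method`.
#'
#' @param m1,m2 [transition_matrix()] objects of the same order.
#' @param top_k Number of top transitions of `m1` to use; `NULL` for all.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Correlation coefficient.
#' @export
matrix_correlation <- function(m1, m2, top_k = NULL,
                               method = c("pearson", "spearman")) {
  stopifnot(inherits(m1, "transition_matrix"),
            inherits(m2, "transition_matrix"), m1$n == m2$n)
  method <- match.arg(method)
  ctxs <- sort(union(rownames(m1$probs), rownames(m2$probs)))
  syms <- sort(union(colnames(m1$probs), colnames(m2$probs)))
  expand <- function(m) {
    out <- matrix(0, length(ctxs), length(syms),
                  dimnames = list(ctxs, syms))
    out[rownames(m$probs), colnames(m$probs)] <- m$probs
    out
  }
  v1 <- as.vector(expand(m1))
  v2 <- as.vector(expand(m2))
  labels <- as.vector(outer(ctxs, syms, function(a, b) paste0(a, ">", b)))
  if (!is.null(top_k)) {
    ord <- order(-v1, labels)
    keep <- ord[seq_len(min(top_k, length(v1)))]
    v1 <- v1[keep]
    v2 <- v2[keep]
  }
  if (length(v1) < 2L || stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop("correlation undefined for constant probability vectors")
  }
  stats::cor(v1, v2, method = method)
}

#' Write a transition matrix as labelled CSV
#'
#' Emits the row-stochastic probabilities with context labels as row names
#' and next-symbol labels as column names. With `what = "counts"` the raw
#' counts are written instead; pruned entries (see [prune_matrix()]) are
#' written as empty cells when `what = "display"`.
#'
#' @param m A [transition_matrix()].
#' @param path Output CSV path.
#' @param what `"probs"` (default), `"counts"` or `"display"`.
#' @return `path`, invisibly.
#' @export
write_transition_matrix <- function(m, path,
                                    what = c("probs", "counts", "display")) {
  stopifnot(inherits(m, "transition_matrix"))
  what <- match.arg(what)
  if (what == "display" && is.null(m$display)) {
    stop("matrix has no display layer; call prune_matrix() first")
  }
  utils::write.csv(m[[what]], path, row.names = TRUE, na = "")
  invisible(path)
}

max_run_locus <- function(sequence, target) {
  loci <- repetition_loci(sequence, target)
  if (nrow(loci) == 0L) return(NA_integer_)
  loci$locus[which.max(loci$length)] # earliest locus on ties
}

#' Shift of the maximum-repetition locus between two corpora
#'
#' For each bout, finds the ordinal locus (1st run, 2nd run, ...) at which
#' the maximum repetition of the target occurs (earliest on ties), and
#' compares the per-locus percentages of bouts before vs after a
#' manipulation. Bouts without the target are excluded from the
#' percentages.
#'
#' @param before_sequences,after_sequences Character vectors of bout
#'   sequences.
#' @param target Target letter.
#' @return Data frame: `locus`, `before_pct`, `after_pct`, `change_pct`
#'   (after minus before; the changes sum to zero).
#' @export
repetition_locus_shift <- function(before_sequences, after_sequences, target) {
  stopifnot(length(before_sequences) > 0L, length(after_sequences) > 0L)
  lb <- vapply(before_sequences, max_run_locus, integer(1), target = target,
               USE.NAMES = FALSE)
  la <- vapply(after_sequences, max_run_locus, integer(1), target = target,
               USE.NAMES = FALSE)
  lb <- lb[!is.na(lb)]
  la <- la[!is.na(la)]
  if (length(lb) == 0L && length(la) == 0L) {
    stop("target '", target, "' absent from both corpora")
  }
  loci <- seq_len(max(c(lb, la, 1L)))
  pct <- function(l) 100 * vapply(loci, function(k) mean(l == k), numeric(1))
  before_pct <- if (length(lb)) pct(lb) else rep(0, length(loci))
  after_pct <- if (length(la)) pct(la) else rep(0, length(loci))
  data.frame(locus = loci, before_pct = before_pct, after_pct = after_pct,
             change_pct = after_pct - before_pct)
}

#' Motif segmentation container
#'
#' A per-bout list of motifs (symbol chunks) produced by an external
#' segmentation tool or by hand; this package consumes motif segmentations,
#' it does not produce them. When the underlying bout sequences are given,
#' the constructor checks that each bout's motifs concatenate back to its
#' sequence.
#'
#' @param motifs List of character vectors, one vector of motif strings per
#'   bout.
#' @param provenance Free-text origin tag.
#' @param sequences Optional bout sequences for the concatenation check.
#' @return A `motif_segmentation`.
#' @export
motif_segmentation <- function(motifs, provenance = "external",
                               sequences = NULL) {
  stopifnot(is.list(motifs))
  if (!is.null(sequences)) {
    stopifnot(length(sequences) == length(motifs))
    for (i in seq_along(motifs)) {
      if (paste(motifs[[i]], collapse = "") != sequences[[i]]) {
        stop("bout ", i, ": motifs do not concatenate to the bout sequence")
      }
    }
  }
  structure(list(motifs = motifs, provenance = provenance),
            class = "motif_segmentation")
}

#' Read a motif segmentation from text
#'
#' One bout per line, motifs whitespace-delimited.
#'
#' @param path File path.
#' @param provenance Origin tag.
#' @return A `motif_segmentation`.
#' @export
read_motif_segmentation <- function(path, provenance = "external") {
  lines <- readLines(path, warn = FALSE)
  motif_segmentation(strsplit(trimws(lines), "\\s+"), provenance = provenance)
}

count_motif <- function(seg, motif) {
  sum(vapply(seg$motifs, function(b) sum(b == motif), integer(1)))
}

#' Change in relative usage of one motif over another
#'
#' Computes the occurrence ratio `a / (a + b)` of two motifs in a baseline
#' and a follow-up segmentation and reports the percent change of the
#' ratio, normalized to the baseline (0 percent = unchanged, -100 percent =
#' motif `a` vanished).
#'
#' @param seg_before,seg_after [motif_segmentation()]s.
#' @param motif_a,motif_b Motif strings; both must occur in the baseline.
#' @return List: `ratio_before`, `ratio_after`, `pct_change`, plus raw
#'   counts.
#' @export
motif_usage_change <- function(seg_before, seg_after, motif_a, motif_b) {
  a0 <- count_motif(seg_before, motif_a)
  b0 <- count_motif(seg_before, motif_b)
  if (a0 == 0L || b0 == 0L) {
    stop("both motifs must occur in the baseline segmentation")
  }
  a1 <- count_motif(seg_after, motif_a)
  b1 <- count_motif(seg_after, motif_b)
  if (a1 + b1 == 0L) stop("neither motif occurs after; ratio undefined")
  r0 <- a0 / (a0 + b0)
  r1 <- a1 / (a1 + b1)
  list(ratio_before = r0, ratio_after = r1,
       pct_change = 100 * (r1 / r0 - 1),
       counts = c(a_before = a0, b_before = b0, a_after = a1, b_after = b1))
}

substr_positions <- function(s, pat) {
  # all (possibly overlapping) start positions of pat in s
  L <- nchar(s)
  k <- nchar(pat)
  if (k == 0L || k > L) return(integer())
  which(vapply(seq_len(L - k + 1L),
               function(p) substr(s, p, p + k - 1L) == pat, logical(1)))
}

#' Occurrences of a syllable outside a motif context
#'
#' Counts occurrences of a syllable (or short symbol chunk) per bout,
#' excluding those lying inside an occurrence of the stated motif -- e.g.
#' the frequency of "f" excluding the ones used as part of "fbca". With no
#' exclusion context this is a plain occurrence count.
#'
#' @param sequences Character vector of bout sequences.
#' @param syllable Symbol (or chunk) to count.
#' @param excluded_motif_context Optional motif string whose occurrences
#'   mask the count.
#' @return List: `total`, `per_bout` (integer vector).
#' @export
syllable_occurrence_excluding_motif <- function(sequences, syllable,
                                                excluded_motif_context = NULL) {
  per_bout <- vapply(sequences, function(s) {
    pos <- substr_positions(s, syllable)
    if (length(pos) == 0L) return(0L)
    if (!is.null(excluded_motif_context)) {
      mpos <- substr_positions(s, excluded_motif_context)
      k <- nchar(syllable)
      mk <- nchar(excluded_motif_context)
      inside <- vapply(pos, function(p) {
        any(mpos <= p & p + k - 1L <= mpos + mk - 1L)
      }, logical(1))
      pos <- pos[!inside]
    }
    length(pos)
  }, integer(1), USE.NAMES = FALSE)
  list(total = sum(per_bout), per_bout = per_bout)
}
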