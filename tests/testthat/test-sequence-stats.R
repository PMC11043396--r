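test_that("transition matrices match window-count oracles", {
  m <- transition_matrix("ababab", n = 2)
  expect_equal(m$probs["a", "b"], 1)
  expect_equal(m$probs["b", "a"], 1)
  m3 <- transition_matrix("aaaa", n = 3)
  expect_equal(m3$probs["aa", "a"], 1)
  expect_error(transition_matrix(c("ab", "ba"), n = 3), "shorter")
  # every nonzero row sums to one, and counts conserve the window total
  set.seed(3)
  seqs <- replicate(20, paste(sample(c("a", "b", "c"), sample(5:15, 1), TRUE),
                              collapse = ""))
  for (n in 2:3) {
    tm <- transition_matrix(seqs, n = n)
    rs <- rowSums(tm$probs)
    expect_true(all(abs(rs[rowSums(tm$counts) > 0] - 1) < 1e-9))
    expect_equal(tm$total_transitions,
                 sum(pmax(nchar(seqs) - n + 1, 0)))
    # spot-check individual entries against direct substring counting
    ctx <- rownames(tm$counts)[1]
    for (sym in colnames(tm$counts)) {
      pat <- paste0(ctx, sym)
      direct <- sum(vapply(seqs, function(s) {
        if (nchar(s) < nchar(pat)) return(0L)
        sum(vapply(seq_len(nchar(s) - nchar(pat) + 1L), function(p) {
          substr(s, p, p + nchar(pat) - 1L) == pat
        }, logical(1)))
      }, integer(1)))
      expect_equal(tm$counts[ctx, sym], direct)
    }
  }
})

test_that("pruning uses the AND rule and is purely presentational", {
  # craft a corpus where one transition is rare in its row but not its column
  seqs <- c(strrep("ab", 60), "azb", rep("zb", 3))
  m <- transition_matrix(seqs, n = 2)
  p <- prune_matrix(m, floor = 0.01)
  # a->z: 1/61 in row a (<1%)... but column z gets 1 of 1+? compute shares
  row_share <- m$counts / rowSums(m$counts)
  col_share <- sweep(m$counts, 2, colSums(m$counts), "/")
  expect_identical(p$pruned, row_share < 0.01 & col_share < 0.01)
  # kept when rare in only one dimension
  kept <- which(row_share < 0.01 & col_share >= 0.01, arr.ind = TRUE)
  if (nrow(kept)) expect_false(any(p$pruned[kept]))
  # floor = 0 prunes nothing with positive counts hidden
  p0 <- prune_matrix(m, floor = 0)
  expect_false(any(p0$pruned))
  # unpruning restores the exact original
  expect_identical(unprune_matrix(p), m)
  expect_identical(p$counts, m$counts)
})

test_that("matrix correlation equals the direct Pearson formula", {
  set.seed(6)
  seqs1 <- replicate(40, paste(sample(letters[1:4], 12, TRUE), collapse = ""))
  seqs2 <- replicate(40, paste(sample(letters[1:4], 12, TRUE), collapse = ""))
  m1 <- transition_matrix(seqs1, 3)
  m2 <- transition_matrix(seqs2, 3)
  expect_equal(matrix_correlation(m1, m1), 1)
  # oracle: vectorize over the union label space by hand
  ctxs <- sort(union(rownames(m1$probs), rownames(m2$probs)))
  syms <- sort(union(colnames(m1$probs), colnames(m2$probs)))
  v1 <- v2 <- numeric(0)
  for (cc in ctxs) for (ss in syms) {
    g <- function(m) {
      if (cc %in% rownames(m$probs) && ss %in% colnames(m$probs))
        m$probs[cc, ss] else 0
    }
    v1 <- c(v1, g(m1)); v2 <- c(v2, g(m2))
  }
  expect_equal(matrix_correlation(m1, m2), stats::cor(v1, v2))
  # top_k larger than the label space behaves like all
  expect_equal(matrix_correlation(m1, m2, top_k = 1e6),
               matrix_correlation(m1, m2))
  expect_equal(matrix_correlation(m1, m2, method = "spearman"),
               stats::cor(v1, v2, method = "spearman"))
  # a single-cell matrix is constant: undefined
  m_const <- transition_matrix("aaa", 3)
  expect_error(matrix_correlation(m_const, m_const), "constant")
})

test_that("top-k restriction ranks by the first matrix's probabilities", {
  m1 <- transition_matrix(c("abab", "acac", "abab"), 2)
  m2 <- transition_matrix(c("abab", "abab", "acac"), 2)
  # oracle: rank the union-space entries by m1's probabilities, ties by
  # "context>symbol" label, take the top 3, and correlate directly
  ctxs <- sort(union(rownames(m1$probs), rownames(m2$probs)))
  syms <- sort(union(colnames(m1$probs), colnames(m2$probs)))
  g <- function(m, cc, ss) {
    if (cc %in% rownames(m$probs) && ss %in% colnames(m$probs))
      m$probs[cc, ss] else 0
  }
  grid <- expand.grid(ctx = ctxs, sym = syms, stringsAsFactors = FALSE)
  grid$v1 <- mapply(g, cc = grid$ctx, ss = grid$sym, MoreArgs = list(m = m1))
  grid$v2 <- mapply(g, cc = grid$ctx, ss = grid$sym, MoreArgs = list(m = m2))
  grid$label <- paste0(grid$ctx, ">", grid$sym)
  top <- grid[order(-grid$v1, grid$label), ][1:3, ]
  expect_equal(matrix_correlation(m1, m2, top_k = 3),
               stats::cor(top$v1, top$v2))
})

test_that("repetition-locus shifts are conservative and detect movement", {
  before <- c("ccab", "ccab", "accc") # max locus 1,1,1 (single run each)
  same <- repetition_locus_shift(before, before, "c")
  expect_true(all(same$change_pct == 0))
  # all maxima move from locus 1 to locus 2
  b2 <- rep("cccacc", 10)  # runs 3,2 -> max at locus 1
  a2 <- rep("ccaccc", 10)  # runs 2,3 -> max at locus 2
  shift <- repetition_locus_shift(b2, a2, "c")
  expect_equal(shift$change_pct[shift$locus == 1], -100)
  expect_equal(shift$change_pct[shift$locus == 2], 100)
  # ties resolve to the earliest locus
  tie <- repetition_locus_shift(rep("ccacc", 5), rep("ccacc", 5), "c")
  expect_equal(tie$before_pct[tie$locus == 1], 100)
  # conservation on mixed random corpora
  set.seed(9)
  mk <- function() replicate(30, paste(sample(c("a", "c"), 12, TRUE),
                                       collapse = ""))
  sh <- repetition_locus_shift(mk(), mk(), "c")
  expect_equal(sum(sh$change_pct), 0)
  expect_error(repetition_locus_shift("ab", "ba", "c"), "absent")
})

test_that("motif usage change normalizes to the baseline ratio", {
  seg_b <- motif_segmentation(list(c("fbca", "da"), c("dabca", "fbca")))
  same <- motif_usage_change(seg_b, seg_b, "fbca", "dabca")
  expect_equal(same$pct_change, 0)
  # a doubles while b halves: hand computation
  seg_b2 <- motif_segmentation(list(rep("A", 2), rep("B", 4)))
  seg_a2 <- motif_segmentation(list(rep("A", 4), rep("B", 2)))
  out <- motif_usage_change(seg_b2, seg_a2, "A", "B")
  expect_equal(out$ratio_before, 2 / 6)
  expect_equal(out$ratio_after, 4 / 6)
  expect_equal(out$pct_change, 100 * ((4 / 6) / (2 / 6) - 1))
  # motif absent after: ratio 0, change -100%
  seg_a3 <- motif_segmentation(list(rep("B", 3)))
  out3 <- motif_usage_change(seg_b2, seg_a3, "A", "B")
  expect_equal(out3$ratio_after, 0)
  expect_equal(out3$pct_change, -100)
  expect_error(motif_usage_change(seg_a3, seg_b2, "A", "B"), "baseline")
})

test_that("motif segmentations validate the concatenation invariant", {
  expect_silent(motif_segmentation(list(c("ab", "c")), sequences = "abc"))
  expect_error(motif_segmentation(list(c("ab", "x")), sequences = "abc"),
               "concatenate")
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("ab c", "abc"), path)
  seg <- read_motif_segmentation(path)
  expect_equal(seg$motifs, list(c("ab", "c"), "abc"))
})

test_that("syllable counts exclude occurrences embedded in a motif", {
  out <- syllable_occurrence_excluding_motif(c("fbca", "fx"), "f", "fbca")
  expect_equal(out$total, 1L)
  expect_equal(out$per_bout, c(0L, 1L))
  # no exclusion context: plain occurrence count
  plain <- syllable_occurrence_excluding_motif(c("ffa", "af"), "f")
  expect_equal(plain$total, 3L)
  # bigram counting with exclusion
  big <- syllable_occurrence_excluding_motif(c("dabcada"), "da", "dabca")
  expect_equal(big$total, 1L)
  expect_equal(syllable_occurrence_excluding_motif(character(), "f")$total, 0L)
})

test_that("transition matrices round-trip through labelled CSV", {
  m <- transition_matrix(c("ababc", "abcab"), 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_transition_matrix(m, path)
  back <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  expect_equal(back, m$probs, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rownames(back), rownames(m$probs))
  expect_equal(colnames(back), colnames(m$probs))
  expect_error(write_transition_matrix(m, path, what = "display"), "prune")
  write_transition_matrix(prune_matrix(m, 0.01), path, what = "display")
  expect_true(file.exists(path))
})

test_that("the estimator converges on sequences from a known Markov chain", {
  # 5-state chain with a fixed transition kernel; bigram estimate at 10,000
  # transitions stays within 0.05 of the truth everywhere
  states <- letters[1:5]
  set.seed(14)
  P <- matrix(rgamma(25, 2), 5, 5, dimnames = list(states, states))
  P <- P / rowSums(P)
  gen_chain <- function(len, seed) {
    set.seed(seed)
    s <- character(len)
    s[1] <- sample(states, 1)
    for (i in 2:len) s[i] <- sample(states, 1, prob = P[s[i - 1], ])
    paste(s, collapse = "")
  }
  seqs <- vapply(1:10, function(k) gen_chain(1001, 500 + k), character(1))
  est <- transition_matrix(seqs, n = 2)
  expect_equal(est$total_transitions, 10000L)
  err <- abs(est$probs[states, states] - P)
  expect_lt(max(err), 0.05)
  expect_true(all(abs(rowSums(est$probs) - 1) < 1e-9))
})
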