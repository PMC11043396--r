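# Exact t-SNE (Student-t SNE, quadratic in n). The inner loops live in
# src/tsne.cpp; this file holds preprocessing and orchestration. Sized for
# the corpora this package embeds in practice (a few thousand syllables);
# much larger inputs would need a tree-approximated implementation.

pairwise_sq_dists <- function(x) {
  s <- rowSums(x * x)
  d2 <- outer(s, s, `+`) - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  d2
}

# PCA scores to at most k components; uses the Gram-matrix route when the
# feature dimension exceeds the sample count.
pca_scores <- function(x, k) {
  k <- min(k, ncol(x), nrow(x) - 1L)
  xc <- sweep(x, 2L, colMeans(x))
  if (ncol(xc) > nrow(xc)) {
    e <- eigen(tcrossprod(xc), symmetric = TRUE)
    vals <- pmax(e$values[seq_len(k)], 0)
    sc <- e$vectors[, seq_len(k), drop = FALSE] *
      rep(sqrt(vals), each = nrow(xc))
    return(sc)
  }
  p <- stats::prcomp(xc, center = FALSE, scale. = FALSE, rank. = k)
  p$x
}

#' Exact t-SNE embedding to two dimensions
#'
#' Standard t-SNE: input similarities from a per-point Gaussian kernel whose
#' bandwidth is tuned to a fixed perplexity, Student-t similarities in the
#' output space, gradient descent with early exaggeration, momentum and
#' adaptive per-parameter gains. Features are first reduced to
#' `initial_dims` principal components, which removes the spectrogram's
#' redundant dimensions before the quadratic part of the algorithm.
#'
#' @param x Numeric matrix, one row per point.
#' @param perplexity Effective neighbour count (default 30). Capped at
#'   `(n - 1) / 3` with a warning when the input is too small.
#' @param seed RNG seed for the initial layout.
#' @param n_iter Gradient iterations.
#' @param initial_dims PCA components kept before t-SNE.
#' @param learning_rate,exaggeration Gradient step size and early
#'   exaggeration factor (applied for the first quarter of the iterations).
#' @return n x 2 matrix of embedded coordinates.
#' @export
tsne_embed <- function(x, perplexity = 30, seed = 1L, n_iter = 500L,
                       initial_dims = 50L, learning_rate = 200,
                       exaggeration = 12) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 5L) stop("t-SNE embedding needs at least 5 points")
  max_perp <- (n - 1) / 3
  if (perplexity > max_perp) {
    warning("perplexity reduced to ", signif(max_perp, 3),
            " for n = ", n, " points")
    perplexity <- max_perp
  }
  if (ncol(x) > initial_dims) x <- pca_scores(x, initial_dims)

  p <- tsne_cond_probs(pairwise_sq_dists(x), perplexity)
  p <- (p + t(p)) / (2 * n)
  p <- pmax(p, 1e-12)

  set.seed(seed)
  y0 <- matrix(stats::rnorm(n * 2, sd = 1e-4), ncol = 2)
  exag_iters <- max(50L, n_iter %/% 4L)
  tsne_descent(p, y0, as.integer(n_iter), as.integer(exag_iters),
               learning_rate, exaggeration)
}
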