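# Classic DBSCAN on Euclidean distances. Neighbourhoods are computed in
# blocks so memory stays linear in n times the block size; fine for the
# embedding sizes used here.

eps_neighbours <- function(x, eps, block = 512L) {
  n <- nrow(x)
  s <- rowSums(x * x)
  eps2 <- eps * eps
  out <- vector("list", n)
  for (from in seq(1L, n, by = block)) {
    to <- min(from + block - 1L, n)
    d2 <- outer(s[from:to], s, `+`) - 2 * tcrossprod(x[from:to, , drop = FALSE], x)
    for (i in from:to) {
      out[[i]] <- which(d2[i - from + 1L, ] <= eps2) # includes the point itself
    }
  }
  out
}

#' DBSCAN density clustering
#'
#' Density-based spatial clustering of applications with noise: a point with
#' at least `min_pts` neighbours within `eps` (itself included) is a core
#' point; clusters are the connected components of core points under the
#' eps-neighbourhood relation, plus the border points density-reachable from
#' them. Points reachable from no core point are labelled noise (cluster 0).
#' Deterministic given the row order of `x`: clusters are numbered in order
#' of discovery, and a border point in reach of two clusters joins the one
#' discovered first.
#'
#' @param x Numeric matrix of coordinates (one row per point).
#' @param eps Neighbourhood radius (> 0).
#' @param min_pts Minimum neighbourhood size for a core point (>= 1).
#' @return Integer vector of cluster labels, 0 = noise.
#' @export
dbscan_cluster <- function(x, eps, min_pts) {
  x <- as.matrix(x)
  stopifnot(eps > 0, min_pts >= 1)
  n <- nrow(x)
  if (n == 0L) return(integer())
  nb <- eps_neighbours(x, eps)
  core <- vapply(nb, length, integer(1)) >= min_pts
  labels <- rep(0L, n)
  visited <- rep(FALSE, n)
  cluster <- 0L
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    cluster <- cluster + 1L
    queue <- i
    visited[i] <- TRUE
    labels[i] <- cluster
    while (length(queue) > 0L) {
      j <- queue[[1L]]
      queue <- queue[-1L]
      for (k in nb[[j]]) {
        if (labels[k] == 0L) labels[k] <- cluster
        if (core[k] && !visited[k]) {
          visited[k] <- TRUE
          queue <- c(queue, k)
        }
      }
    }
  }
  labels
}
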