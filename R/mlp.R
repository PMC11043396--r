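# Single-hidden-layer softmax network trained by full-batch Adam, with
# validation-based early stopping: training halts once validation
# cross-entropy has risen for `patience` consecutive epochs past the best
# epoch, and the best-epoch weights are restored.

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_forward <- function(w, x) {
  h <- tanh(sweep(x %*% w$w1, 2L, w$b1, `+`))
  list(h = h, p = softmax_rows(sweep(h %*% w$w2, 2L, w$b2, `+`)))
}

mlp_cross_entropy <- function(p, y_idx) {
  -mean(log(pmax(p[cbind(seq_along(y_idx), y_idx)], 1e-12)))
}

mlp_init <- function(d, hidden, k, seed) {
  set.seed(seed)
  lim1 <- sqrt(6 / (d + hidden))
  lim2 <- sqrt(6 / (hidden + k))
  list(w1 = matrix(stats::runif(d * hidden, -lim1, lim1), d, hidden),
       b1 = rep(0, hidden),
       w2 = matrix(stats::runif(hidden * k, -lim2, lim2), hidden, k),
       b2 = rep(0, k))
}

mlp_n_params <- function(d, hidden, k) d * hidden + hidden + hidden * k + k

#' Fit a single-hidden-layer softmax classifier with early stopping
#'
#' @param x_train,y_train Training features (matrix) and integer class
#'   indices in `1..k`.
#' @param x_val,y_val Held-out validation set used only for early stopping.
#' @param hidden Hidden-layer width.
#' @param k Number of classes.
#' @param seed RNG seed for weight initialization.
#' @param max_epochs Upper bound on epochs.
#' @param patience Consecutive validation-error increases that stop training
#'   (6: the run is abandoned once validation cross-entropy has gone up six
#'   epochs in a row, and the best epoch is restored).
#' @param learning_rate Adam step size.
#' @return List: `weights`, `hidden`, `k`, `n_params`, `log_lik` (training
#'   log-likelihood at the restored epoch), `best_epoch`, `epochs_run`,
#'   `val_trace` (validation cross-entropy per epoch).
#' @keywords internal
mlp_fit <- function(x_train, y_train, x_val, y_val, hidden, k, seed = 1L,
                    max_epochs = 300L, patience = 6L, learning_rate = 5e-3) {
  d <- ncol(x_train)
  w <- mlp_init(d, hidden, k, seed)
  m <- lapply(w, function(z) z * 0)
  v <- lapply(w, function(z) z * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  n <- nrow(x_train)
  best <- list(val = Inf, weights = w, epoch = 0L, log_lik = -Inf)
  consec_up <- 0L
  prev_val <- Inf
  val_trace <- numeric(0)

  for (epoch in seq_len(max_epochs)) {
    fw <- mlp_forward(w, x_train)
    delta2 <- fw$p
    delta2[cbind(seq_len(n), y_train)] <-
      delta2[cbind(seq_len(n), y_train)] - 1
    delta2 <- delta2 / n
    grad <- list(
      w1 = NULL, b1 = NULL,
      w2 = crossprod(fw$h, delta2), b2 = colSums(delta2))
    delta1 <- (delta2 %*% t(w$w2)) * (1 - fw$h^2)
    grad$w1 <- crossprod(x_train, delta1)
    grad$b1 <- colSums(delta1)

    for (nm in names(w)) {
      m[[nm]] <- b1 * m[[nm]] + (1 - b1) * grad[[nm]]
      v[[nm]] <- b2 * v[[nm]] + (1 - b2) * grad[[nm]]^2
      mhat <- m[[nm]] / (1 - b1^epoch)
      vhat <- v[[nm]] / (1 - b2^epoch)
      w[[nm]] <- w[[nm]] - learning_rate * mhat / (sqrt(vhat) + eps)
    }

    val_ce <- mlp_cross_entropy(mlp_forward(w, x_val)$p, y_val)
    val_trace[epoch] <- val_ce
    if (val_ce < best$val) {
      train_ce <- mlp_cross_entropy(mlp_forward(w, x_train)$p, y_train)
      best <- list(val = val_ce, weights = w, epoch = epoch,
                   log_lik = -train_ce * n)
    }
    consec_up <- if (val_ce > prev_val) consec_up + 1L else 0L
    prev_val <- val_ce
    if (consec_up >= patience) break
  }
  list(weights = best$weights, hidden = hidden, k = k,
       n_params = mlp_n_params(d, hidden, k),
       log_lik = best$log_lik, best_epoch = best$epoch,
       epochs_run = length(val_trace), val_trace = val_trace)
}

mlp_predict_probs <- function(weights, x) {
  mlp_forward(weights, as.matrix(x))$p
}
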