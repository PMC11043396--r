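#' Sample a training set of syllable feature vectors from a corpus
#'
#' Randomly selects up to `n_songs` recordings from a corpus index, runs the
#' segmentation front end on each, and pools the syllable feature vectors,
#' retaining at most `max_syllables` by uniform subsampling without
#' replacement. The defaults mirror a two-week recording campaign: up to
#' 2000 songs and up to 20,000 syllables.
#'
#' @param corpus A corpus index from [make_corpus()]/[read_corpus_index()],
#'   or a character vector of WAV paths.
#' @param n_songs Maximum number of songs to draw; fewer available songs are
#'   all used, with a warning.
#' @param max_syllables Cap on pooled syllables.
#' @param seed RNG seed; the same seed reproduces the same sample.
#' @param config [seg_config()] used for segmentation.
#' @return A list of class `training_corpus`: `features` (matrix, one row
#'   per syllable), `song_id` (per syllable), `seed`, `config`.
#' @export
sample_training_set <- function(corpus, n_songs = 2000L,
                                max_syllables = 20000L, seed = 1L,
                                config = seg_config()) {
  paths <- corpus_wav_paths(corpus)
  if (length(paths) == 0L) stop("corpus is empty")
  set.seed(seed)
  if (length(paths) < n_songs) {
    warning("only ", length(paths), " songs available; using all of them")
    chosen <- paths
  } else {
    chosen <- paths[sort(sample.int(length(paths), n_songs))]
  }
  feats <- vector("list", length(chosen))
  ids <- vector("list", length(chosen))
  for (i in seq_along(chosen)) {
    seg <- segment_audio(read_wav(chosen[i]), config)
    feats[[i]] <- seg$features
    ids[[i]] <- rep(basename(chosen[i]), nrow(seg$features))
  }
  features <- do.call(rbind, feats)
  song_id <- unlist(ids, use.names = FALSE)
  if (nrow(features) > max_syllables) {
    keep <- sort(sample.int(nrow(features), max_syllables))
    features <- features[keep, , drop = FALSE]
    song_id <- song_id[keep]
  }
  structure(list(features = features, song_id = song_id, seed = seed,
                 config = config),
            class = "training_corpus")
}

corpus_wav_paths <- function(corpus) {
  if (inherits(corpus, "corpus_index")) {
    return(file.path(corpus$dir, corpus$files))
  }
  as.character(corpus)
}

#' Embed syllable features in two dimensions with t-SNE
#'
#' Wrapper around [tsne_embed()] with the perplexity the pipeline uses (30).
#' The layout is standardized to a fixed per-axis spread (`scale_sd`),
#' because the raw t-SNE canvas grows with the number of points while the
#' DBSCAN radius that follows is an absolute distance; standardizing makes
#' one eps setting transferable across corpus sizes.
#'
#' @param features Matrix of syllable feature vectors (rows) or a
#'   `training_corpus`.
#' @param perplexity t-SNE perplexity.
#' @param seed RNG seed; identical seeds give identical layouts.
#' @param scale_sd Target per-axis standard deviation of the returned
#'   layout; `NULL` returns raw t-SNE coordinates.
#' @param ... Passed to [tsne_embed()] (e.g. `n_iter`).
#' @return n x 2 coordinate matrix.
#' @export
embed_2d <- function(features, perplexity = 30, seed = 1L, scale_sd = 10,
                     ...) {
  if (inherits(features, "training_corpus")) features <- features$features
  y <- tsne_embed(as.matrix(features), perplexity = perplexity, seed = seed,
                  ...)
  if (!is.null(scale_sd)) {
    y <- y / sqrt(mean(apply(y, 2L, stats::var))) * scale_sd
  }
  y
}

#' Cluster an embedding with DBSCAN
#'
#' Clusters the 2-D embedding into syllable classes plus a noise label. The
#' defaults (`eps = 2.25`, `min_pts = 27`) are the midpoints of the ranges
#' that give 10-20 well-separated clusters on corpora of this kind; both are
#' meant to be adjusted per corpus until the clustered spectrograms look
#' distinct (the package exposes the parameters but no auto-tuner).
#'
#' @param embedding n x 2 coordinate matrix from [embed_2d()].
#' @param eps DBSCAN neighbourhood radius.
#' @param min_pts DBSCAN core-point threshold.
#' @return A list of class `cluster_result`: `embedding`, `labels` (integer,
#'   0 = noise), `eps`, `min_pts`, `sizes` (named non-noise cluster sizes).
#' @export
cluster_density <- function(embedding, eps = 2.25, min_pts = 27L) {
  embedding <- as.matrix(embedding)
  labels <- dbscan_cluster(embedding, eps = eps, min_pts = min_pts)
  nz <- labels[labels > 0L]
  sizes <- if (length(nz)) table(nz) else table(integer())
  structure(list(embedding = embedding, labels = labels, eps = eps,
                 min_pts = min_pts, sizes = sizes),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d points, %d clusters, %d noise (eps=%g, min_pts=%d)\n",
              length(x$labels), length(x$sizes), sum(x$labels == 0L),
              x$eps, x$min_pts))
  invisible(x)
}

#' Assign letters to clusters
#'
#' Letters are assigned in descending order of cluster size, `"a"` for the
#' largest; ties break by cluster index ascending. The symbol `/` is
#' reserved for silent gaps and is never assigned. Noise points receive no
#' letter.
#'
#' @param clusters A `cluster_result`.
#' @return Named character vector mapping cluster index (name) to letter.
#' @export
assign_letters <- function(clusters) {
  stopifnot(inherits(clusters, "cluster_result"))
  sizes <- clusters$sizes
  if (length(sizes) == 0L) {
    stop("no non-noise clusters found; adjust eps/min_pts and re-cluster")
  }
  if (length(sizes) > 26L) {
    stop("more than 26 clusters; the letter alphabet is exhausted")
  }
  ids <- as.integer(names(sizes))
  ord <- order(-as.integer(sizes), ids)
  map <- stats::setNames(character(length(ids)), ids)
  map[as.character(ids[ord])] <- letters[seq_along(ord)]
  map
}

#' Train the syllable classifier with AIC model selection
#'
#' For each candidate hidden-layer size, fits a single-hidden-layer softmax
#' network on the labelled syllables (stratified 90/10 train/validation
#' split; training stops once validation cross-entropy has increased for six
#' consecutive epochs and the best epoch is restored) and records
#' `AIC = 2k - 2 log L` with `k` the total weight-and-bias count and `log L`
#' the training-set multinomial log-likelihood. The AIC-minimizing size is
#' selected. Candidates default to 10 up to the number of classes.
#'
#' @param corpus A `training_corpus` or feature matrix.
#' @param labels Letter per syllable (character; `NA` or noise-cluster
#'   entries are dropped before training).
#' @param hidden_candidates Integer vector of hidden sizes; `NULL` for the
#'   default range.
#' @param seed RNG seed (split and weight init).
#' @param max_epochs,learning_rate Optimizer settings passed to the fitter.
#' @param val_frac Validation fraction for the stratified split.
#' @param config Segmentation configuration stored on the model; defaults to
#'   the corpus' own.
#' @return A `decoder_model`: classifier weights, `letters`, `input_dim`,
#'   `hidden`, `aic_trace` (data frame: hidden, n_params, log_lik, aic,
#'   best_epoch, epochs_run), `seed`, `config`.
#' @export
train_classifier <- function(corpus, labels, hidden_candidates = NULL,
                             seed = 1L, max_epochs = 300L,
                             learning_rate = 5e-3, val_frac = 0.1,
                             config = NULL) {
  if (inherits(corpus, "training_corpus")) {
    if (is.null(config)) config <- corpus$config
    features <- corpus$features
  } else {
    features <- as.matrix(corpus)
  }
  labels <- as.character(labels)
  keep <- !is.na(labels) & labels != ""
  features <- features[keep, , drop = FALSE]
  labels <- labels[keep]
  letter_set <- sort(unique(labels))
  k <- length(letter_set)
  if (k < 2L) stop("need at least two syllable classes to train a classifier")
  y <- match(labels, letter_set)
  n <- length(y)

  if (is.null(hidden_candidates)) {
    hidden_candidates <- if (k >= 10L) seq(10L, k) else seq(k, 10L)
  }
  hidden_candidates <- sort(unique(as.integer(hidden_candidates)))

  # stratified validation split
  set.seed(seed)
  val_idx <- unlist(lapply(split(seq_len(n), y), function(ix) {
    nv <- max(1L, round(length(ix) * val_frac))
    sample(ix, nv)
  }), use.names = FALSE)
  tr_idx <- setdiff(seq_len(n), val_idx)
  x_tr <- features[tr_idx, , drop = FALSE]
  y_tr <- y[tr_idx]
  x_va <- features[val_idx, , drop = FALSE]
  y_va <- y[val_idx]

  fits <- vector("list", length(hidden_candidates))
  for (i in seq_along(hidden_candidates)) {
    fits[[i]] <- mlp_fit(x_tr, y_tr, x_va, y_va,
                         hidden = hidden_candidates[i], k = k,
                         seed = seed + i, max_epochs = max_epochs,
                         learning_rate = learning_rate)
  }
  aic_trace <- data.frame(
    hidden = hidden_candidates,
    n_params = vapply(fits, `[[`, numeric(1), "n_params"),
    log_lik = vapply(fits, `[[`, numeric(1), "log_lik"),
    best_epoch = vapply(fits, function(f) as.numeric(f$best_epoch), numeric(1)),
    epochs_run = vapply(fits, function(f) as.numeric(f$epochs_run), numeric(1)))
  aic_trace$aic <- 2 * aic_trace$n_params - 2 * aic_trace$log_lik
  sel <- which.min(aic_trace$aic)
  structure(
    list(weights = fits[[sel]]$weights,
         letters = letter_set,
         input_dim = ncol(features),
         hidden = hidden_candidates[sel],
         aic_trace = aic_trace,
         seed = seed,
         config = config),
    class = "decoder_model"
  )
}

#' @export
print.decoder_model <- function(x, ...) {
  cat(sprintf("<decoder_model> %d letters (%s), input dim %d, hidden %d\n",
              length(x$letters), paste(x$letters, collapse = ""),
              x$input_dim, x$hidden))
  invisible(x)
}

#' Classify syllable feature vectors with a trained model
#'
#' @param model A `decoder_model`.
#' @param features Feature matrix (rows) or single vector.
#' @return A list: `letter` (character), `confidence` (posterior of the
#'   chosen letter), `posterior` (matrix).
#' @export
model_predict <- function(model, features) {
  stopifnot(inherits(model, "decoder_model"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  if (ncol(features) != model$input_dim) {
    stop("feature length ", ncol(features), " does not match model input dim ",
         model$input_dim)
  }
  p <- mlp_predict_probs(model$weights, features)
  idx <- max.col(p, ties.method = "first")
  list(letter = model$letters[idx],
       confidence = p[cbind(seq_len(nrow(p)), idx)],
       posterior = p)
}

#' Discover syllable classes and train a decoder in one call
#'
#' The full offline training phase: sample syllables, embed with t-SNE,
#' cluster with DBSCAN, letter the clusters by size, and fit the classifier
#' with AIC selection. Noise-labelled syllables are excluded from classifier
#' training; at decode time every detected syllable receives its argmax
#' letter (there is no reject class).
#'
#' @param corpus Corpus index or WAV paths (see [sample_training_set()]).
#' @param config [seg_config()].
#' @param seed Master RNG seed for sampling, embedding and training.
#' @param n_songs,max_syllables Sampling caps.
#' @param perplexity,tsne_iter t-SNE settings.
#' @param eps,min_pts DBSCAN settings.
#' @param hidden_candidates Classifier capacity candidates (`NULL` =
#'   default range).
#' @param max_epochs Classifier epoch cap.
#' @return A `decoder_model` with the extra fields `cluster_result` and
#'   `label_map`.
#' @export
train_decoder <- function(corpus, config = seg_config(), seed = 1L,
                          n_songs = 2000L, max_syllables = 20000L,
                          perplexity = 30, tsne_iter = 500L,
                          eps = 2.25, min_pts = 27L,
                          hidden_candidates = NULL, max_epochs = 300L) {
  ts <- sample_training_set(corpus, n_songs = n_songs,
                            max_syllables = max_syllables, seed = seed,
                            config = config)
  emb <- embed_2d(ts, perplexity = perplexity, seed = seed, n_iter = tsne_iter)
  cl <- cluster_density(emb, eps = eps, min_pts = min_pts)
  map <- assign_letters(cl)
  lab <- rep(NA_character_, length(cl$labels))
  nz <- cl$labels > 0L
  lab[nz] <- map[as.character(cl$labels[nz])]
  model <- train_classifier(ts, lab, hidden_candidates = hidden_candidates,
                            seed = seed, max_epochs = max_epochs,
                            config = ts$config)
  model$cluster_result <- cl
  model$label_map <- map
  model
}

#' Serialize a decoder model to JSON
#'
#' Writes weights, letter set, AIC trace and the segmentation configuration
#' to a single JSON archive that [load_decoder_model()] restores exactly.
#' The (possibly large) `cluster_result` is not serialized.
#'
#' @param model A `decoder_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_decoder_model <- function(model, path) {
  stopifnot(inherits(model, "decoder_model"))
  payload <- list(
    letters = model$letters,
    input_dim = model$input_dim,
    hidden = model$hidden,
    seed = model$seed,
    aic_trace = model$aic_trace,
    label_map = as.list(model$label_map),
    config = unclass(model$config),
    weights = lapply(model$weights, function(w) {
      if (is.matrix(w)) list(dim = dim(w), data = as.vector(w))
      else list(data = as.vector(w))
    }))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a decoder model saved by [save_decoder_model()]
#'
#' @param path JSON archive path.
#' @return A `decoder_model`.
#' @export
load_decoder_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- lapply(p$weights, function(w) {
    if (length(w$dim) == 2L) {
      matrix(unlist(w$data), w$dim[[1L]], w$dim[[2L]])
    } else {
      as.numeric(unlist(w$data))
    }
  })
  cfg <- NULL
  if (!is.null(p$config)) cfg <- do.call(seg_config, as.list(p$config))
  structure(
    list(weights = weights, letters = p$letters, input_dim = p$input_dim,
         hidden = p$hidden, aic_trace = p$aic_trace, seed = p$seed,
         config = cfg,
         label_map = if (!is.null(p$label_map)) unlist(p$label_map) else NULL),
    class = "decoder_model")
}
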