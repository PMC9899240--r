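#' Configuration of the graph embedding model
#'
#' Hyperparameters of the adjacency-masked Transformer encoder with a
#' recurrent master node and its contrastive training.
#'
#' @param d_m Model width (must be divisible by `n_heads`).
#' @param n_heads Attention heads (default 4).
#' @param n_layers Encoder layers (default 3).
#' @param window_l Temporal recurrence length `l`: the master state is rolled
#'   over `l` consecutive snapshots (default 3).
#' @param d Output embedding dimension (2 for visualisation, 32 for
#'   comparison runs).
#' @param tau InfoNCE temperature (default 1).
#' @param batch_size Anchors per gradient step (default 64).
#' @param epochs Training epochs (default 200).
#' @param steps_per_epoch Gradient steps per epoch (default 5).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param use_positional_encoding Add sinusoidal node positional encodings to
#'   the input features. Required when states differ only in *where* edges
#'   are removed, not in the topology itself.
#' @param feature_mode Raw node features: `"constant"` (a shared scalar, so
#'   the encoder sees topology only), `"one_hot"` (node identity), or
#'   `"degree"` (normalised snapshot degree).
#' @param d_ff Feed-forward hidden width (default `2 * d_m`).
#' @param d_head Projection-head hidden width (default `d_m`).
#' @param normalize_embeddings Batch-normalise the embedding batch (per
#'   dimension, centred, total variance one) inside the contrastive loss and
#'   standardise the embedding sequence the same way at inference. With raw
#'   dot-product similarity the InfoNCE objective is scale-sensitive: norm
#'   growth saturates the softmax towards instance discrimination, while a
#'   collapsed embedding is a stationary point. Normalisation removes the
#'   scale degree of freedom, keeping \eqn{\tau = 1} in the soft regime
#'   where slowly varying (metastable) structure dominates (default `TRUE`).
#' @param embed_l2 Coefficient of an optional ridge penalty on raw embedding
#'   magnitudes in the training loss (default 0; an alternative to
#'   `normalize_embeddings`). The penalty enters as `embed_l2 / tau`, in the
#'   same temperature-adjusted units as the similarities: with similarities
#'   \eqn{\hat g_i \cdot \hat g_j / \tau} and penalty
#'   \eqn{(\lambda/\tau)\|\hat g\|^2} the objective is invariant under
#'   \eqn{\tau}-rescaling of the embedding scale, which is what makes the
#'   clustering performance insensitive to the temperature.
#' @param grad_clip Global gradient-norm clipping threshold for Adam updates
#'   (default 1; `Inf` disables).
#' @param train_frac Leading fraction of snapshots used for training
#'   (default 0.8; the remainder is the test split).
#' @param seed Integer seed controlling initialisation and batch sampling.
#' @return An object of class `model_config`.
#' @export
model_config <- function(d_m = 32L, n_heads = 4L, n_layers = 3L,
                         window_l = 3L, d = 32L, tau = 1,
                         batch_size = 64L, epochs = 200L,
                         steps_per_epoch = 5L, learning_rate = 1e-3,
                         use_positional_encoding = FALSE,
                         feature_mode = c("constant", "one_hot", "degree"),
                         d_ff = NULL, d_head = NULL,
                         normalize_embeddings = TRUE,
                         embed_l2 = 0, grad_clip = 1,
                         train_frac = 0.8, seed = 1L) {
  feature_mode <- match.arg(feature_mode)
  stopifnot(d_m %% n_heads == 0, window_l >= 1, tau > 0, batch_size >= 2,
            epochs >= 1, steps_per_epoch >= 1, learning_rate > 0,
            embed_l2 >= 0, grad_clip > 0,
            train_frac > 0, train_frac < 1)
  structure(list(
    d_m = as.integer(d_m), n_heads = as.integer(n_heads),
    n_layers = as.integer(n_layers), window_l = as.integer(window_l),
    d = as.integer(d), tau = tau, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), steps_per_epoch = as.integer(steps_per_epoch),
    learning_rate = learning_rate,
    use_positional_encoding = isTRUE(use_positional_encoding),
    feature_mode = feature_mode,
    d_ff = as.integer(d_ff %||% (2L * d_m)),
    d_head = as.integer(d_head %||% d_m),
    normalize_embeddings = isTRUE(normalize_embeddings),
    embed_l2 = embed_l2, grad_clip = grad_clip,
    train_frac = train_frac, seed = as.integer(seed)),
    class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(paste0(
    "model_config: d_m = %d, %d heads, %d layers, l = %d, d = %d, tau = %g\n",
    "  batch %d, %d epochs x %d steps, lr %g, PE %s, features '%s'\n"),
    x$d_m, x$n_heads, x$n_layers, x$window_l, x$d, x$tau,
    x$batch_size, x$epochs, x$steps_per_epoch, x$learning_rate,
    if (x$use_positional_encoding) "on" else "off", x$feature_mode))
  invisible(x)
}

feature_dim <- function(cfg, n) {
  switch(cfg$feature_mode, constant = 1L, one_hot = n, degree = 1L)
}

# Raw (unprojected) node features for snapshot t. For "constant" and
# "one_hot" the features are the same for every snapshot. Degree features
# are z-scored within the snapshot: the informative quantity is which nodes
# deviate from the typical degree, and standardisation keeps that signal at
# unit scale regardless of graph density.
raw_features <- function(g, t, cfg) {
  switch(cfg$feature_mode,
         constant = matrix(1, g$n, 1),
         one_hot = diag(g$n),
         degree = {
           deg <- rowSums(g$snapshots[[t]])
           s <- stats::sd(deg)
           matrix((deg - mean(deg)) / if (s > 0) s else 1, g$n, 1)
         })
}

raw_feature_list <- function(g, cfg) {
  if (cfg$feature_mode == "degree")
    lapply(seq_len(n_snapshots(g)), function(t) raw_features(g, t, cfg))
  else
    list(raw_features(g, 1L, cfg))
}

# Glorot-initialised parameter set for a graph with n nodes.
init_params <- function(cfg, n, seed = cfg$seed) {
  glorot <- function(nr, nc)
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
  withr::with_seed(seed, {
    layers <- lapply(seq_len(cfg$n_layers), function(i) list(
      Wq = glorot(cfg$d_m, cfg$d_m), Wk = glorot(cfg$d_m, cfg$d_m),
      Wv = glorot(cfg$d_m, cfg$d_m), Wo = glorot(cfg$d_m, cfg$d_m),
      ln1g = rep(1, cfg$d_m), ln1b = rep(0, cfg$d_m),
      W1 = glorot(cfg$d_m, cfg$d_ff), b1 = rep(0, cfg$d_ff),
      W2 = glorot(cfg$d_ff, cfg$d_m), b2 = rep(0, cfg$d_m),
      ln2g = rep(1, cfg$d_m), ln2b = rep(0, cfg$d_m)))
    list(z0 = stats::rnorm(cfg$d_m, sd = 0.1),
         Wf = glorot(feature_dim(cfg, n), cfg$d_m),
         bf = rep(0, cfg$d_m),
         layers = layers,
         Wh1 = glorot(cfg$d_m, cfg$d_head), bh1 = rep(0, cfg$d_head),
         Wh2 = glorot(cfg$d_head, cfg$d_head), bh2 = rep(0, cfg$d_head),
         Wh3 = glorot(cfg$d_head, cfg$d), bh3 = rep(0, cfg$d))
  })
}

par_flatten <- function(p) unlist(p, use.names = FALSE)

par_unflatten <- function(flat, skeleton) {
  utils::relist(flat, skeleton)
}

# Adam update in flat parameter space; state holds m, v, step counter.
adam_step <- function(flat, grad_flat, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad_flat
  state$v <- beta2 * state$v + (1 - beta2) * grad_flat^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(flat = flat - lr * mhat / (sqrt(vhat) + eps), state = state)
}
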