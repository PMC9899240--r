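#' Sinusoidal positional encoding of node positions
#'
#' Row `pos` (0-based node position) holds
#' \eqn{p_{pos,2i} = \sin(pos / 10000^{2i/d_m})} in its even entries and
#' \eqn{p_{pos,2i+1} = \cos(pos / 10000^{2i/d_m})} in its odd entries
#' (0-based entry indices). Deterministic; all entries lie in `[-1, 1]`.
#'
#' @param n_nodes Number of node positions (rows).
#' @param d_m Encoding width (must be even).
#' @return An `n_nodes x d_m` matrix.
#' @export
positional_encoding <- function(n_nodes, d_m) {
  stopifnot(d_m %% 2 == 0)
  pos <- seq_len(n_nodes) - 1
  i <- seq_len(d_m / 2) - 1
  angle <- outer(pos, 1 / 10000^(2 * i / d_m))
  pe <- matrix(NA_real_, n_nodes, d_m)
  pe[, 2 * i + 1] <- sin(angle)
  pe[, 2 * i + 2] <- cos(angle)
  pe
}

#' Attention mask of a snapshot with the master node prepended
#'
#' Row/column 1 (the master node) is all ones — the master attends to and is
#' attended by every node — and the remaining block is the adjacency matrix
#' plus self-connections on the diagonal (without them an isolated node's
#' attention row would be empty). During encoding, zero entries of this mask
#' receive `-Inf` attention logits, so the corresponding attention weights
#' are exactly 0.
#'
#' @param A_t Symmetric `n x n` adjacency matrix with zero diagonal.
#' @return An `(n+1) x (n+1)` binary mask.
#' @export
attention_mask <- function(A_t) {
  if (!isTRUE(all.equal(A_t, t(A_t))))
    stop("adjacency matrix must be symmetric")
  n <- nrow(A_t)
  M <- matrix(0, n + 1, n + 1)
  M[1, ] <- 1
  M[, 1] <- 1
  M[-1, -1] <- A_t
  diag(M) <- 1
  M
}

#' InfoNCE contrastive loss
#'
#' \eqn{-\log\big(\exp(\hat g_t \cdot \hat g_{t+1}/\tau) / \sum_{i=1}^B
#' \exp(\hat g_t \cdot \hat g_i/\tau)\big)} — the similarity is the raw dot
#' product and the denominator runs over the batch embeddings (which include
#' the positive).
#'
#' @param g_hat_t Query embedding (length-`d` vector).
#' @param g_hat_pos Positive embedding (must be one row of `g_hat_batch`).
#' @param g_hat_batch `B x d` matrix of batch embeddings, `B >= 2`.
#' @param tau Temperature (> 0).
#' @return The scalar loss.
#' @export
info_nce_loss <- function(g_hat_t, g_hat_pos, g_hat_batch, tau = 1) {
  if (tau <= 0) stop("tau must be positive")
  g_hat_batch <- as.matrix(g_hat_batch)
  stopifnot(nrow(g_hat_batch) >= 2)
  sims <- as.numeric(g_hat_batch %*% g_hat_t) / tau
  pos_sim <- sum(g_hat_t * g_hat_pos) / tau
  m <- max(sims)
  -(pos_sim - m - log(sum(exp(sims - m))))
}

#' Build the encoder input for one snapshot
#'
#' Projects the raw node features of snapshot `t` to `d_m` dimensions with
#' the learned linear map, adds positional encodings when enabled, and
#' prepends the current master state as row 1.
#'
#' @param g A [tevograph()].
#' @param t Snapshot index.
#' @param cfg A [model_config()].
#' @param params Model parameter list (e.g. `model$params`).
#' @param master_state Current master state (`d_m` vector); defaults to the
#'   learnable initial vector `params$z0`.
#' @return An `(n+1) x d_m` input matrix.
#' @export
build_node_features <- function(g, t, cfg, params,
                                master_state = params$z0) {
  raw <- raw_features(g, t, cfg)
  X <- raw %*% params$Wf
  X <- sweep(X, 2, params$bf, "+")
  if (cfg$use_positional_encoding)
    X <- X + positional_encoding(g$n, cfg$d_m)
  rbind(matrix(master_state, 1), X)
}

pe_matrix <- function(g, cfg) {
  if (cfg$use_positional_encoding) positional_encoding(g$n, cfg$d_m)
  else matrix(0, 0, 0)
}

mask_list <- function(g) lapply(g$snapshots, attention_mask)

#' Encode one snapshot, updating the master state
#'
#' Runs the masked multi-head encoder on snapshot `t` with the given master
#' state in row 0 and returns the master node's output — the snapshot's
#' `d_m`-dimensional graph representation — together with the projected
#' embedding and, optionally, the per-layer attention matrices.
#'
#' @param model A trained `graph_embedder` (or a list with `params` and
#'   `cfg`).
#' @param g A [tevograph()].
#' @param t Snapshot index.
#' @param z_prev Master state carried from the previous snapshot; defaults to
#'   the learnable initial vector.
#' @param return_attention Also return the attention matrices
#'   (`n_layers` cubes of dimension `(n+1) x (n+1) x n_heads`).
#' @return A list with `z` (new master state), `g_hat` (projected `d`-vector)
#'   and optionally `attention`.
#' @export
encode_snapshot <- function(model, g, t, z_prev = NULL,
                            return_attention = FALSE) {
  cfg <- model$cfg
  if (t < 1 || t > n_snapshots(g)) stop("snapshot index t = ", t,
                                        " out of range")
  if (is.null(z_prev)) z_prev <- model$params$z0
  xraw <- raw_feature_list_at(g, t, cfg)
  out <- cpp_encode_snapshot(model$params, z_prev, xraw,
                             attention_mask(g$snapshots[[t]]),
                             pe_matrix(g, cfg), 1L, cfg$n_heads, numeric(0))
  res <- list(z = as.numeric(out$z), g_hat = as.numeric(out$g))
  if (return_attention) res$attention <- out$attention
  res
}

# single-snapshot raw feature list (index 1 inside C++)
raw_feature_list_at <- function(g, t, cfg) list(raw_features(g, t, cfg))

#' Project a master state to the embedding space
#'
#' The projection head: two ReLU hidden layers followed by a linear map to
#' `d` dimensions.
#'
#' @param model A `graph_embedder`.
#' @param z Master state (`d_m` vector).
#' @return The `d`-dimensional embedding \eqn{\hat g}.
#' @export
project_embedding <- function(model, z) {
  p <- model$params
  a1 <- pmax(as.numeric(crossprod(p$Wh1, z)) + p$bh1, 0)
  a2 <- pmax(as.numeric(crossprod(p$Wh2, a1)) + p$bh2, 0)
  as.numeric(crossprod(p$Wh3, a2)) + p$bh3
}

#' Train the contrastive graph embedding model
#'
#' Trains the adjacency-masked Transformer encoder with recurrent master
#' node on the leading `train_frac` of the snapshot sequence. Each gradient
#' step samples `batch_size` anchor time points; for each anchor `t` the
#' master state is rolled over the window `[t - l + 1, t]` (starting from
#' the learnable initial vector), the embeddings \eqn{\hat g_t} and
#' \eqn{\hat g_{t+1}} are computed, and the batch InfoNCE loss couples every
#' anchor with the batch of positives. Parameters are optimised with Adam.
#'
#' @param g A [tevograph()].
#' @param cfg A [model_config()].
#' @param verbose Print the loss every 10 epochs.
#' @return An object of class `graph_embedder`: `params`, `cfg`, `n`,
#'   `loss_curve` (per epoch), `split` (the temporal train/test split), and
#'   `embeddings` (the full `T x d` embedding sequence, see [embed_all()]).
#' @export
train_graph_embedder <- function(g, cfg, verbose = FALSE) {
  stopifnot(inherits(g, "tevograph"), inherits(cfg, "model_config"))
  T_ <- n_snapshots(g)
  if (T_ <= cfg$window_l + 1)
    stop("need more than window_l + 1 = ", cfg$window_l + 1, " snapshots")
  split <- temporal_split(T_, cfg$train_frac)
  n_train <- length(split$train)
  anchor_pool <- seq(cfg$window_l, n_train - 1L)
  if (length(anchor_pool) < 2)
    stop("training split too short for window_l = ", cfg$window_l)
  batch <- min(cfg$batch_size, length(anchor_pool))
  if (cfg$batch_size > length(anchor_pool))
    warning("batch_size ", cfg$batch_size, " exceeds the ",
            length(anchor_pool), " available anchors; using ", batch)

  masks <- mask_list(g)
  xraw <- raw_feature_list(g, cfg)
  pe <- pe_matrix(g, cfg)
  params <- init_params(cfg, g$n)
  flat <- par_flatten(params)
  adam <- list(m = numeric(length(flat)), v = numeric(length(flat)), t = 0L)
  loss_curve <- numeric(cfg$epochs)

  withr::with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ep_loss <- 0
      for (st in seq_len(cfg$steps_per_epoch)) {
        anchors <- sample(anchor_pool, batch,
                          replace = length(anchor_pool) < batch)
        step <- cpp_train_step(params, xraw, masks, pe, as.integer(anchors),
                               cfg$window_l, cfg$n_heads, cfg$tau,
                               cfg$embed_l2 / cfg$tau,
                               cfg$normalize_embeddings)
        ep_loss <- ep_loss + step$loss
        gf <- par_flatten(step$grads)
        gn <- sqrt(sum(gf^2))
        if (is.finite(cfg$grad_clip) && gn > cfg$grad_clip)
          gf <- gf * cfg$grad_clip / gn
        upd <- adam_step(flat, gf, adam, cfg$learning_rate)
        flat <- upd$flat
        adam <- upd$state
        params <- par_unflatten(flat, params)
      }
      loss_curve[ep] <- ep_loss / cfg$steps_per_epoch
      if (verbose && (ep %% 10 == 0 || ep == 1))
        message(sprintf("epoch %d/%d  loss %.4f", ep, cfg$epochs,
                        loss_curve[ep]))
    }
  })
  model <- structure(list(params = params, cfg = cfg, n = g$n,
                          loss_curve = loss_curve, split = split),
                     class = "graph_embedder")
  model$embeddings <- embed_all(model, g)
  model
}

#' @export
print.graph_embedder <- function(x, ...) {
  cat(sprintf(
    "graph_embedder: n = %d nodes, d = %d, loss %.4f -> %.4f over %d epochs\n",
    x$n, x$cfg$d, x$loss_curve[1], x$loss_curve[length(x$loss_curve)],
    length(x$loss_curve)))
  invisible(x)
}

#' Embed every snapshot of a time-evolving graph
#'
#' Deterministic inference pass with sliding windows: the embedding of
#' snapshot `t` is obtained by rolling the master state from the learnable
#' initial vector over the window `[t - l + 1, t]` (truncated at the start
#' of the sequence) — the same window depth seen by anchors in training —
#' and projecting the master output with the head.
#'
#' @param model A trained `graph_embedder`.
#' @param g A [tevograph()] over the same node count the model was trained
#'   on.
#' @return A `T x d` matrix of embeddings \eqn{\hat g_t}, with the master
#'   states attached as attribute `"master_states"` (`T x d_m`).
#' @export
embed_all <- function(model, g) {
  stopifnot(inherits(model, "graph_embedder") || is.list(model))
  if (g$n != model$n) stop("graph has ", g$n, " nodes, model expects ",
                           model$n)
  cfg <- model$cfg
  out <- cpp_embed_sequence(model$params, raw_feature_list(g, cfg),
                            mask_list(g), pe_matrix(g, cfg),
                            cfg$window_l, cfg$n_heads)
  emb <- out$G
  if (isTRUE(cfg$normalize_embeddings)) {
    # same standardisation as the training loss, with sequence statistics
    mu <- colMeans(emb)
    sd_ <- sqrt(apply(emb, 2, function(x) mean((x - mean(x))^2)) + 1e-8)
    emb <- sweep(sweep(emb, 2, mu), 2, sd_ * sqrt(ncol(emb)), "/")
  }
  attr(emb, "master_states") <- out$Z
  emb
}

#' Write embeddings as CSV
#'
#' Columns `t`, `g_1` ... `g_d`.
#'
#' @param embeddings `T x d` matrix from [embed_all()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(embeddings, path) {
  df <- data.frame(t = seq_len(nrow(embeddings)), embeddings)
  names(df) <- c("t", paste0("g_", seq_len(ncol(embeddings))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Save / load a trained model as a JSON parameter archive
#'
#' Parameters are stored flattened alongside the full configuration, so the
#' archive is a portable text file.
#'
#' @param model A `graph_embedder`.
#' @param path Output path (JSON).
#' @return `save_model` returns `path` invisibly; `load_model` the restored
#'   `graph_embedder` (without cached embeddings).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "graph_embedder"))
  obj <- list(config = unclass(model$cfg), n = model$n,
              loss_curve = model$loss_curve, split = model$split,
              flat_params = par_flatten(model$params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, obj$config[setdiff(names(obj$config), NULL)])
  skeleton <- init_params(cfg, obj$n)
  structure(list(params = par_unflatten(obj$flat_params, skeleton),
                 cfg = cfg, n = obj$n, loss_curve = obj$loss_curve,
                 split = lapply(obj$split, as.integer)),
            class = "graph_embedder")
}
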