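#' Per-node relevance of one snapshot by attention rollout
#'
#' Relevance propagation through the masked encoder, adapted to the
#' similarity model: relevance is seeded at the snapshot embedding
#' \eqn{\hat g_t} (uniformly over its components by default — no class
#' logit exists in a contrastive model), backpropagated through the
#' projection head to the master output, and rolled out through the encoder
#' layers. Each layer contributes a matrix
#' \eqn{\bar A = \mathrm{norm}(I + C)} and the contributions are multiplied
#' from the last layer to the first; the master-node row of the product,
#' restricted to the real nodes, is the per-node relevance.
#'
#' Two choices of the layer contribution `C` are provided:
#' \describe{
#' \item{`"grad_attention"`}{the head-summed elementwise product of each
#'   attention matrix with its gradient, negatives clamped to zero
#'   (the attention-gradient rule of transformer relevance propagation).}
#' \item{`"attention"`}{the head-averaged attention matrix itself. In an
#'   adjacency-masked encoder the attention support *is* the data: weights
#'   are exactly zero on absent edges, so the rollout measures how much
#'   attention mass the master can route through each node. For planted
#'   structural patterns this is markedly less noisy than gradient
#'   weighting, whose sign depends on the arbitrary seed direction (see the
#'   methods vignette).}
#' }
#'
#' @param model A trained `graph_embedder`.
#' @param g A [tevograph()].
#' @param t Snapshot index.
#' @param z_prev Master state entering snapshot `t`; by default the states
#'   are rolled with the same window tiling as [embed_all()].
#' @param weighting `"grad_attention"` (default) or `"attention"`, see
#'   above.
#' @param seed_direction Optional length-`d` vector seeding the relevance at
#'   \eqn{\hat g_t} (default: uniform positive).
#' @return A non-negative numeric vector of length `n` summing to at most 1
#'   (the rollout is row-stochastic).
#' @export
snapshot_relevance <- function(model, g, t, z_prev = NULL,
                               weighting = c("grad_attention", "attention"),
                               seed_direction = NULL) {
  stopifnot(inherits(model, "graph_embedder"))
  weighting <- match.arg(weighting)
  cfg <- model$cfg
  if (t < 1 || t > n_snapshots(g)) stop("snapshot index t = ", t,
                                        " out of range")
  if (is.null(z_prev)) z_prev <- rolled_master_state(model, g, t)
  if (is.null(seed_direction)) seed_direction <- rep(1 / cfg$d, cfg$d)
  need_grad <- weighting == "grad_attention"
  out <- cpp_encode_snapshot(model$params, z_prev,
                             raw_feature_list_at(g, t, cfg),
                             attention_mask(g$snapshots[[t]]),
                             pe_matrix(g, cfg), 1L, cfg$n_heads,
                             if (need_grad) seed_direction else numeric(0))
  n1 <- g$n + 1L
  roll <- diag(n1)
  for (li in seq_len(cfg$n_layers)) {
    A <- out$attention[[li]]        # (n+1) x (n+1) x heads
    if (need_grad) {
      Abar <- apply(A * out$attention_grad[[li]], c(1, 2), sum)
      Abar[Abar < 0] <- 0
    } else {
      Abar <- apply(A, c(1, 2), mean)
    }
    Abar <- Abar + diag(n1)
    Abar <- Abar / rowSums(Abar)
    roll <- Abar %*% roll
  }
  rel <- roll[1, -1]
  rel[rel < 0] <- 0
  unname(rel)
}

# master state entering snapshot t under the sliding windowing of embed_all
rolled_master_state <- function(model, g, t) {
  cfg <- model$cfg
  start <- max(1L, t - cfg$window_l + 1L)
  z <- model$params$z0
  if (start < t) {
    for (u in start:(t - 1))
      z <- encode_snapshot(model, g, u, z_prev = z)$z
  }
  z
}

#' Relevance maps for every snapshot of a sequence
#'
#' @param model A trained `graph_embedder`.
#' @param g A [tevograph()].
#' @param indices Snapshot indices to explain (default: all).
#' @param ... Passed on to [snapshot_relevance()] (e.g. `weighting`).
#' @return A `length(indices) x n` matrix of non-negative relevances.
#' @export
relevance_map <- function(model, g, indices = seq_len(n_snapshots(g)), ...) {
  t(vapply(indices, function(t) snapshot_relevance(model, g, t, ...),
           numeric(g$n)))
}

#' Aggregate snapshot relevances by metastable state
#'
#' Sums per-snapshot relevance rows within each cluster label (labels come
#' from clustering the embeddings, not from ground truth) and optionally
#' rescales each state's row to maximum 1.
#'
#' @param per_snapshot `T x n` matrix of per-snapshot relevances.
#' @param cluster_labels Integer labels of length `T` (0-based).
#' @param normalization `"max_one"` (default) divides each state row by its
#'   maximum; `"none"` returns raw sums.
#' @return An `s x n` matrix, one row per state (rownames are the labels).
#' @export
state_relevance <- function(per_snapshot, cluster_labels,
                            normalization = c("max_one", "none")) {
  normalization <- match.arg(normalization)
  per_snapshot <- as.matrix(per_snapshot)
  if (nrow(per_snapshot) != length(cluster_labels))
    stop("labels (", length(cluster_labels), ") and relevance rows (",
         nrow(per_snapshot), ") differ in count")
  labs <- sort(unique(cluster_labels))
  out <- t(vapply(labs, function(k)
    colSums(per_snapshot[cluster_labels == k, , drop = FALSE]),
    numeric(ncol(per_snapshot))))
  if (normalization == "max_one") {
    mx <- apply(out, 1, max)
    out <- out / ifelse(mx == 0, 1, mx)
  }
  rownames(out) <- labs
  out
}

#' Cross-state relevance contrast of each node
#'
#' Compares each node's mean relevance between states: entry `(k, j)` is the
#' log-ratio of node `j`'s mean relevance in state `k` against its mean
#' relevance in the remaining states. Because the per-node relevance level
#' varies with a node's overall attention load, the *change* across states —
#' not the within-state ranking — is what identifies state-discriminating
#' nodes; this mirrors how co-occurrence relevance maps are read on real
#' data, where a node whose colour differs strongly between state figures is
#' called discriminative. Nodes whose planted edges are removed in state `k`
#' lose attention mass there, so they appear with strongly negative contrast
#' in `k` and positive contrast in the complementary states.
#'
#' @inheritParams state_relevance
#' @param eps Small constant stabilising the log-ratio (default `1e-12`).
#' @return An `s x n` matrix of log-ratio contrasts (rownames are the
#'   labels).
#' @export
state_relevance_contrast <- function(per_snapshot, cluster_labels,
                                     eps = 1e-12) {
  per_snapshot <- as.matrix(per_snapshot)
  if (nrow(per_snapshot) != length(cluster_labels))
    stop("labels (", length(cluster_labels), ") and relevance rows (",
         nrow(per_snapshot), ") differ in count")
  labs <- sort(unique(cluster_labels))
  if (length(labs) < 2) stop("need at least 2 states for a contrast")
  means <- t(vapply(labs, function(k)
    colMeans(per_snapshot[cluster_labels == k, , drop = FALSE]),
    numeric(ncol(per_snapshot))))
  out <- t(vapply(seq_along(labs), function(i) {
    other <- colMeans(means[-i, , drop = FALSE])
    log(means[i, ] + eps) - log(other + eps)
  }, numeric(ncol(per_snapshot))))
  rownames(out) <- labs
  out
}

#' Recover a planted node set from per-state relevance maps
#'
#' Ranks nodes by how much attention-relevance they lose in the state that
#' removes their internal edges (the most negative [state_relevance_contrast()]
#' entries of that state) and returns the top `q` nodes.
#'
#' @param per_snapshot `T x n` relevance matrix (use
#'   `weighting = "attention"` for planted structural patterns).
#' @param cluster_labels Cluster labels of length `T`.
#' @param state Label of the state in which the sought nodes lose their
#'   edges.
#' @param q Number of nodes to return.
#' @return Integer vector of `q` node indices (1-based).
#' @export
top_state_nodes <- function(per_snapshot, cluster_labels, state, q) {
  ctr <- state_relevance_contrast(per_snapshot, cluster_labels)
  row <- ctr[as.character(state), ]
  order(row)[seq_len(q)]
}

#' Write relevance scores as CSV
#'
#' Long format with columns `node_id`, `state`, `relevance`,
#' `normalized_relevance`.
#'
#' @param per_state Raw (unnormalised) `s x n` matrix from
#'   [state_relevance()] with `normalization = "none"`.
#' @param path Output path.
#' @param node_ids Optional node identifiers (default `v0...`).
#' @return `path`, invisibly.
#' @export
write_relevance <- function(per_state, path, node_ids = NULL) {
  n <- ncol(per_state)
  if (is.null(node_ids)) node_ids <- paste0("v", seq_len(n) - 1L)
  mx <- apply(per_state, 1, max)
  norm <- per_state / ifelse(mx == 0, 1, mx)
  df <- do.call(rbind, lapply(seq_len(nrow(per_state)), function(i)
    data.frame(node_id = node_ids,
               state = rownames(per_state)[i] %||% (i - 1L),
               relevance = per_state[i, ],
               normalized_relevance = norm[i, ])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
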