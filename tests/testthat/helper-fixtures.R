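# Small deterministic fixtures shared across test files.

# random symmetric 0/1 snapshot sequence
rand_snapshots <- function(n, T_, p = 0.5, seed = 1) {
  withr::with_seed(seed, lapply(seq_len(T_), function(t) {
    A <- matrix(0L, n, n)
    idx <- which(upper.tri(A), arr.ind = TRUE)
    sel <- idx[stats::runif(nrow(idx)) < p, , drop = FALSE]
    A[sel] <- 1L
    A[sel[, 2:1, drop = FALSE]] <- 1L
    A
  }))
}

rand_tevograph <- function(n = 8, T_ = 12, p = 0.5, seed = 1, states = NULL) {
  tevograph(rand_snapshots(n, T_, p, seed), states = states)
}

# tiny model configuration that trains in seconds; any argument of
# model_config() may be overridden
tiny_model_config <- function(...) {
  defaults <- list(d_m = 8L, n_heads = 2L, n_layers = 2L, window_l = 2L,
                   d = 4L, batch_size = 8L, epochs = 3L,
                   steps_per_epoch = 2L, d_ff = 12L, d_head = 8L, seed = 7L)
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(model_config, defaults)
}

complete_graph <- function(n) {
  A <- matrix(1L, n, n); diag(A) <- 0L; A
}

path_graph <- function(n) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) { A[i, i + 1] <- 1L; A[i + 1, i] <- 1L }
  A
}

# independent pair-counting ARI used as a brute-force oracle
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  pairs <- utils::combn(n, 2)
  sa <- a[pairs[1, ]] == a[pairs[2, ]]
  sb <- b[pairs[1, ]] == b[pairs[2, ]]
  n11 <- sum(sa & sb); n00 <- sum(!sa & !sb)
  n10 <- sum(sa & !sb); n01 <- sum(!sa & sb)
  denom <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (denom == 0) return(0)
  2 * (n11 * n00 - n10 * n01) / denom
}

# all set partitions of 1..n as label vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, k) {
    i <- length(labels) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- labels; return(invisible()) }
    for (v in 0:k) rec(c(labels, v), max(k, v + 1L))
  }
  rec(integer(0), 0L)
  out
}
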