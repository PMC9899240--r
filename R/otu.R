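#' Construct an OTU count table
#'
#' A `T x p` non-negative integer matrix of per-sample taxon counts with
#' ordered sample times, the input of the co-occurrence graph construction.
#'
#' @param counts `T x p` matrix of non-negative counts (samples in rows,
#'   taxa in columns).
#' @param sample_times Optional vector of `T` ordered sample labels; defaults
#'   to `1:T`.
#' @param taxon_ids Optional character vector of `p` taxon identifiers;
#'   defaults to column names or `"otu1" ... "otup"`.
#' @return An object of class `otu_table_te`.
#' @export
otu_table_te <- function(counts, sample_times = NULL, taxon_ids = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("OTU counts must be non-negative")
  if (is.null(sample_times)) sample_times <- seq_len(nrow(counts))
  if (is.null(taxon_ids))
    taxon_ids <- colnames(counts) %||% paste0("otu", seq_len(ncol(counts)))
  stopifnot(length(sample_times) == nrow(counts),
            length(taxon_ids) == ncol(counts))
  colnames(counts) <- taxon_ids
  structure(list(counts = counts, sample_times = sample_times,
                 taxon_ids = taxon_ids),
            class = "otu_table_te")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.otu_table_te <- function(x, ...) {
  cat(sprintf("otu_table_te: %d samples x %d taxa, %.1f%% zeros\n",
              nrow(x$counts), ncol(x$counts),
              100 * mean(x$counts == 0)))
  invisible(x)
}

#' Read a flat OTU table
#'
#' Classic QIIME-style flat orientation: tab-separated, first column the
#' sample id, remaining columns taxon counts, header row of taxon ids.
#'
#' @param path Path to the tab-separated table.
#' @return An [otu_table_te()].
#' @export
read_otu_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  otu_table_te(as.matrix(df[, -1, drop = FALSE]),
               sample_times = df[[1]],
               taxon_ids = colnames(df)[-1])
}

#' Build the co-occurrence base graph from taxon correlations
#'
#' Computes the Pearson correlation between every pair of taxon count
#' columns and places an edge where `|r| >= corr_threshold`. Taxa with zero
#' count variance get no edges (their correlation is treated as 0) with a
#' warning. Absolute-value thresholding means strong co-exclusion
#' (negative correlation) also yields an edge; set `absolute = FALSE` to use
#' only positive correlations.
#'
#' @param table An [otu_table_te()].
#' @param corr_threshold Threshold on `|r|` (default 0.3).
#' @param absolute Use `|r|` (default) rather than signed `r`.
#' @return A `p x p` symmetric 0/1 adjacency matrix over taxa.
#' @export
correlation_base_graph <- function(table, corr_threshold = 0.3,
                                   absolute = TRUE) {
  stopifnot(inherits(table, "otu_table_te"))
  p <- ncol(table$counts)
  if (p < 2) stop("need at least 2 taxa")
  sds <- apply(table$counts, 2, stats::sd)
  if (any(sds == 0))
    warning(sum(sds == 0),
            " zero-variance taxon column(s); treated as uncorrelated")
  C <- suppressWarnings(stats::cor(table$counts))
  C[!is.finite(C)] <- 0
  score <- if (absolute) abs(C) else C
  A <- (score >= corr_threshold) * 1L
  diag(A) <- 0L
  storage.mode(A) <- "integer"
  dimnames(A) <- list(table$taxon_ids, table$taxon_ids)
  A
}

#' Mask the base graph by per-sample zero counts
#'
#' Snapshot `t` is the base co-occurrence graph with every edge incident to
#' a taxon whose count at sample `t` is zero removed. Never adds edges, so
#' each snapshot is a subgraph of the base graph; snapshot `t` depends only
#' on row `t` of the table.
#'
#' @param base `p x p` adjacency from [correlation_base_graph()].
#' @param table The [otu_table_te()] (same `p` taxa).
#' @return A [tevograph()] with `T` snapshots and no state labels.
#' @export
zero_mask_snapshots <- function(base, table) {
  stopifnot(inherits(table, "otu_table_te"))
  p <- ncol(table$counts)
  if (nrow(base) != p || ncol(base) != p)
    stop("base graph has ", nrow(base), " nodes but the table has ",
         p, " taxa")
  snaps <- lapply(seq_len(nrow(table$counts)), function(t) {
    A <- base
    zero <- table$counts[t, ] == 0
    if (any(zero)) {
      A[zero, ] <- 0L
      A[, zero] <- 0L
    }
    A
  })
  tevograph(snaps, node_ids = table$taxon_ids)
}

#' Generate a synthetic OTU table with metastable regimes
#'
#' Stands in for real longitudinal microbiome studies (which are not
#' bundled): columns fall into correlated blocks driven by shared latent
#' log-abundance signals, and a hidden Markov chain over `n_states` regimes
#' silences a distinct taxon block per regime (its counts are zeroed with
#' probability `zero_rate` while the regime is active), so that
#' [zero_mask_snapshots()] yields a metastable time-evolving graph. The
#' hidden labels are returned for evaluation. Synthetic data; it emulates
#' overdispersed, zero-inflated counts but not compositionality or
#' sequencing-depth variation.
#'
#' @param T_ Number of samples (time points).
#' @param p Number of taxa.
#' @param n_states Number of latent regimes.
#' @param zero_rate Probability that an active regime's silenced-block count
#'   is zeroed at a given time point.
#' @param stay_prob Self-transition probability of the hidden regime chain.
#' @param seed Integer seed.
#' @return A list with `table` (an [otu_table_te()]), `states` (integer
#'   labels, 0-based), and `silenced_blocks` (list of taxon index vectors).
#' @export
synth_otu_fixture <- function(T_ = 200L, p = 30L, n_states = 2L,
                              zero_rate = 0.9, stay_prob = 0.97,
                              seed = 1L) {
  stopifnot(T_ >= 2, p >= 2 * n_states, n_states >= 1,
            zero_rate >= 0, zero_rate <= 1,
            stay_prob > 0, stay_prob < 1 || n_states == 1)
  withr::with_seed(seed, {
    states <- integer(T_)
    states[1] <- sample.int(n_states, 1) - 1L
    for (t in 2:T_) {
      states[t] <- if (stats::runif(1) < stay_prob || n_states == 1)
        states[t - 1] else
        sample(setdiff(0:(n_states - 1), states[t - 1]), 1)
    }
    blocks <- split(seq_len(p), cut(seq_len(p), n_states, labels = FALSE))
    # correlated blocks: shared latent signal per block + taxon noise
    base_mean <- matrix(NA_real_, T_, p)
    for (b in seq_along(blocks)) {
      latent <- stats::rnorm(T_, sd = 1)
      for (j in blocks[[b]])
        base_mean[, j] <- 2.5 + latent + stats::rnorm(T_, sd = 0.3)
    }
    counts <- matrix(stats::rpois(T_ * p, lambda = exp(base_mean)), T_, p)
    for (k in seq_len(n_states)) {
      rows <- which(states == k - 1L)
      cols <- blocks[[k]]
      if (length(rows) && zero_rate > 0) {
        z <- matrix(stats::runif(length(rows) * length(cols)) < zero_rate,
                    length(rows), length(cols))
        counts[rows, cols][z] <- 0L
      }
    }
  })
  list(table = otu_table_te(counts),
       states = states,
       silenced_blocks = unname(lapply(seq_len(n_states),
                                       function(k) blocks_of(p, n_states, k))))
}

blocks_of <- function(p, n_states, k) {
  split(seq_len(p), cut(seq_len(p), n_states, labels = FALSE))[[k]]
}

#' Write an OTU table in flat orientation
#'
#' @param table An [otu_table_te()].
#' @param path Output path (tab-separated; see [read_otu_table()]).
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "otu_table_te"))
  df <- data.frame(sample_id = table$sample_times, table$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
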