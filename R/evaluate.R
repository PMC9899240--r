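#' Cluster embedding points with seeded k-means++
#'
#' k-means++ seeding followed by Lloyd iterations
#' (`stats::kmeans(algorithm = "Lloyd")`, tolerance driven by
#' `iter.max = 300`), taking the best of `n_restarts` seeded restarts by
#' within-cluster sum of squares.
#'
#' @param points `T x d` numeric matrix.
#' @param k Number of clusters (`1 <= k <= T`).
#' @param seed Integer seed; restarts derive their seeds from it.
#' @param n_restarts Number of restarts (default 10).
#' @return Integer vector of `T` labels in `0:(k-1)`.
#' @export
kmeans_cluster <- function(points, k, seed = 1L, n_restarts = 10L) {
  points <- as.matrix(points)
  T_ <- nrow(points)
  if (k > T_) stop("k = ", k, " exceeds the number of points ", T_)
  if (k == 1) return(rep(0L, T_))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- withr::with_seed(seed + 1000L * r,
                                kmeanspp_centers(points, k))
    fit <- suppressWarnings(
      stats::kmeans(points, centers = centers, iter.max = 300,
                    algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  as.integer(best$cluster) - 1L
}

# k-means++ seeding: first centre uniform, subsequent centres sampled with
# probability proportional to squared distance to the nearest chosen centre.
kmeanspp_centers <- function(points, k) {
  T_ <- nrow(points)
  centers <- matrix(NA_real_, k, ncol(points))
  centers[1, ] <- points[sample.int(T_, 1), ]
  d2 <- rowSums(sweep(points, 2, centers[1, ])^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      idx <- sample.int(T_, 1)
    } else {
      idx <- sample.int(T_, 1, prob = d2)
    }
    centers[j + 1, ] <- points[idx, ]
    d2 <- pmin(d2, rowSums(sweep(points, 2, centers[j + 1, ])^2))
  }
  # duplicate centres break stats::kmeans; jitter exact duplicates
  dup <- duplicated(centers)
  if (any(dup))
    centers[dup, ] <- centers[dup, , drop = FALSE] +
      stats::rnorm(sum(dup) * ncol(points), sd = 1e-8)
  centers
}

#' Adjusted Rand Index between two labelings
#'
#' Chance-corrected agreement of two partitions from the contingency table:
#' \eqn{(\sum_{ij} \binom{n_{ij}}{2} - E) / (\tfrac12(\sum_i \binom{a_i}{2} +
#' \sum_j \binom{b_j}{2}) - E)} with \eqn{E} the permutation-model
#' expectation. Returns 1 for identical partitions and values near 0 for
#' unrelated ones; by convention 0 when both numerator and denominator vanish
#' (e.g. one partition trivial).
#'
#' @param labels_a,labels_b Vectors of equal length (>= 2).
#' @return The ARI, a number in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("labelings differ in length")
  n <- length(labels_a)
  stopifnot(n >= 2)
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

#' PCA baseline embedding of a time-evolving graph
#'
#' Flattens each snapshot's full adjacency matrix into an `n^2` vector,
#' mean-centres the `T x n^2` matrix, and projects onto the top `d`
#' principal components.
#'
#' @param g A [tevograph()].
#' @param d Embedding dimension.
#' @return A `T x d` matrix of embeddings.
#' @export
pca_baseline <- function(g, d) {
  stopifnot(inherits(g, "tevograph"))
  T_ <- n_snapshots(g)
  if (T_ < 2) stop("need at least 2 snapshots")
  X <- t(vapply(g$snapshots, function(A) as.numeric(A),
                numeric(g$n * g$n)))
  if (d > min(T_, ncol(X)))
    stop("d = ", d, " exceeds min(T, n^2) = ", min(T_, ncol(X)))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = d)
  emb <- pc$x
  if (ncol(emb) < d)  # zero-variance input yields fewer components
    emb <- cbind(emb, matrix(0, T_, d - ncol(emb)))
  unname(emb[, seq_len(d), drop = FALSE])
}

#' Empirical transition matrix and stay-probability of a label sequence
#'
#' Metastability diagnostic: the row-normalised count matrix of consecutive
#' label transitions, whose diagonal is close to 1 for a metastable sequence,
#' and the mean diagonal element (stay-probability).
#'
#' @param labels Integer state labels in time order (length >= 2).
#' @param s Number of states; defaults to `max(labels) + 1` for 0-based
#'   labels.
#' @return A list with `transition_matrix` (`s x s`), `stay_probability`
#'   (mean of diagonal entries over visited states), and
#'   `consecutive_agreement` (fraction of consecutive pairs with equal
#'   labels).
#' @export
metastability_diagnostics <- function(labels, s = NULL) {
  if (length(labels) < 2) stop("need at least 2 time points")
  labels <- as.integer(labels)
  if (is.null(s)) s <- max(labels) + 1L
  counts <- matrix(0, s, s)
  from <- labels[-length(labels)] + 1L
  to <- labels[-1] + 1L
  for (i in seq_along(from)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
  rs <- rowSums(counts)
  P <- counts / ifelse(rs == 0, 1, rs)
  visited <- rs > 0
  list(transition_matrix = P,
       stay_probability = mean(diag(P)[visited]),
       consecutive_agreement = mean(from == to))
}

#' Contiguous temporal train/test split
#'
#' @param T_ Number of time points.
#' @param train_frac Fraction assigned to the leading train block
#'   (default 0.8).
#' @return A list with integer index vectors `train` and `test`.
#' @export
temporal_split <- function(T_, train_frac = 0.8) {
  stopifnot(T_ >= 2, train_frac > 0, train_frac < 1)
  n_train <- max(1L, min(T_ - 1L, floor(T_ * train_frac)))
  list(train = seq_len(n_train), test = (n_train + 1L):T_)
}

#' Clustering evaluation of an embedding sequence against ground truth
#'
#' Applies seeded k-means to the full embedding sequence and reports the
#' adjusted Rand index against the ground-truth states on the held-out test
#' indices (clustering the test block alone would degenerate whenever it is
#' dominated by a single metastable state), together with metastability
#' diagnostics of the predicted label sequence.
#'
#' @param embeddings `T x d` matrix of per-snapshot embeddings.
#' @param states Ground-truth labels of length `T`.
#' @param k Number of clusters; defaults to the number of distinct states.
#' @param seed Integer seed for k-means.
#' @param split A [temporal_split()]; the ARI is computed on `split$test`.
#'   `NULL` scores all points.
#' @return A list with `labels` (all `T` cluster labels), `k`, `ari` (on the
#'   test indices), `stay_probability` (of the full label sequence), and the
#'   scored `indices`.
#' @export
evaluate_embedding <- function(embeddings, states, k = NULL, seed = 1L,
                               split = temporal_split(nrow(embeddings))) {
  stopifnot(nrow(embeddings) == length(states))
  idx <- if (is.null(split)) seq_along(states) else split$test
  if (is.null(k)) k <- length(unique(states))
  labels <- kmeans_cluster(embeddings, k, seed = seed)
  list(labels = labels, k = k,
       ari = adjusted_rand_index(labels[idx], states[idx]),
       stay_probability =
         metastability_diagnostics(labels, s = k)$stay_probability,
       indices = idx)
}
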