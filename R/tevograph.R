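#' Construct a time-evolving graph
#'
#' An ordered sequence of symmetric, zero-diagonal binary adjacency snapshots
#' over a fixed node set, with optional node coordinates and per-snapshot
#' ground-truth state labels.
#'
#' @param snapshots List of `n x n` symmetric 0/1 matrices with zero diagonal.
#' @param coords Optional `n x 2` matrix of node coordinates `(a_j, b_j)`.
#' @param states Optional integer vector of state labels, one per snapshot.
#' @param node_ids Optional character vector of stable node identifiers;
#'   defaults to `"v0" ... "v(n-1)"`.
#' @return An object of class `tevograph`.
#' @export
tevograph <- function(snapshots, coords = NULL, states = NULL,
                      node_ids = NULL) {
  stopifnot(is.list(snapshots), length(snapshots) >= 1)
  n <- nrow(snapshots[[1]])
  for (t in seq_along(snapshots)) {
    A <- snapshots[[t]]
    if (!is.matrix(A) || nrow(A) != n || ncol(A) != n)
      stop("snapshot ", t, " is not an ", n, "x", n, " matrix")
    if (!isTRUE(all.equal(A, t(A))))
      stop("snapshot ", t, " is not symmetric")
    if (any(diag(A) != 0))
      stop("snapshot ", t, " has a nonzero diagonal")
  }
  if (!is.null(states) && length(states) != length(snapshots))
    stop("states must have one label per snapshot")
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    stopifnot(nrow(coords) == n, ncol(coords) == 2)
  }
  if (is.null(node_ids)) node_ids <- paste0("v", seq_len(n) - 1L)
  stopifnot(length(node_ids) == n)
  structure(list(n = n, snapshots = snapshots, coords = coords,
                 states = if (!is.null(states)) as.integer(states),
                 node_ids = node_ids),
            class = "tevograph")
}

#' @export
print.tevograph <- function(x, ...) {
  ec <- vapply(x$snapshots, function(A) sum(A) / 2, numeric(1))
  cat(sprintf("tevograph: n = %d nodes, T = %d snapshots, mean edges %.1f%s%s\n",
              x$n, length(x$snapshots), mean(ec),
              if (!is.null(x$states))
                sprintf(", %d states", length(unique(x$states))) else "",
              if (!is.null(x$coords)) ", with coordinates" else ""))
  invisible(x)
}

#' Number of snapshots of a time-evolving graph
#' @param g A `tevograph`.
#' @return Integer `T`.
#' @export
n_snapshots <- function(g) length(g$snapshots)

#' Per-snapshot and per-state edge-count summary
#'
#' @param g A `tevograph`.
#' @return A list with `per_snapshot` (integer edge counts), `mean`, `min`,
#'   `max`, and — when state labels are present — `per_state`, a data frame
#'   of mean/min/max edge counts by state.
#' @export
snapshot_edge_stats <- function(g) {
  stopifnot(inherits(g, "tevograph"))
  ec <- vapply(g$snapshots, function(A) as.integer(sum(A) / 2), integer(1))
  out <- list(per_snapshot = ec, mean = mean(ec), min = min(ec), max = max(ec))
  if (!is.null(g$states)) {
    agg <- lapply(split(ec, g$states), function(v)
      c(mean = mean(v), min = min(v), max = max(v)))
    out$per_state <- data.frame(state = as.integer(names(agg)),
                                t(vapply(agg, identity, numeric(3))),
                                row.names = NULL)
  }
  out
}

#' Write / read a time-evolving graph as per-snapshot edge lists
#'
#' Each snapshot `t` is written to `snapshot_<t>.tsv` (tab-separated, columns
#' `u`, `v` with `u < v`, 0-based node indices, header line) inside `dir`,
#' together with a JSON `manifest.json` recording `n`, `T`, node ids, and —
#' when present — states, coordinates, and the generating configuration.
#'
#' @param g A `tevograph`.
#' @param dir Output directory (created if missing).
#' @param config Optional list stored verbatim in the manifest.
#' @return `write_tevograph` returns `dir` invisibly; `read_tevograph`
#'   returns the reconstructed `tevograph`.
#' @export
write_tevograph <- function(g, dir, config = NULL) {
  stopifnot(inherits(g, "tevograph"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in seq_along(g$snapshots)) {
    idx <- which(upper.tri(g$snapshots[[t]]) & g$snapshots[[t]] != 0,
                 arr.ind = TRUE)
    df <- data.frame(u = idx[, 1] - 1L, v = idx[, 2] - 1L)
    df <- df[order(df$u, df$v), , drop = FALSE]
    utils::write.table(df, file.path(dir, sprintf("snapshot_%d.tsv", t)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(n = g$n, T = length(g$snapshots), node_ids = g$node_ids,
                   states = g$states,
                   coords = if (!is.null(g$coords))
                     unname(apply(g$coords, 1, as.numeric, simplify = FALSE)),
                   config = config)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_tevograph
#' @export
read_tevograph <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  n <- manifest$n
  snaps <- lapply(seq_len(manifest$T), function(t) {
    df <- utils::read.table(file.path(dir, sprintf("snapshot_%d.tsv", t)),
                            header = TRUE, sep = "\t")
    A <- matrix(0L, n, n)
    if (nrow(df) > 0) {
      A[cbind(df$u + 1L, df$v + 1L)] <- 1L
      A[cbind(df$v + 1L, df$u + 1L)] <- 1L
    }
    A
  })
  coords <- manifest$coords
  if (!is.null(coords) && length(coords)) {
    if (is.list(coords)) coords <- do.call(rbind, lapply(coords, as.numeric))
    coords <- matrix(as.numeric(coords), ncol = 2)
  } else {
    coords <- NULL
  }
  tevograph(snaps, coords = coords, states = manifest$states,
            node_ids = manifest$node_ids)
}
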