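#' Configuration for synthetic time-evolving graph generation
#'
#' Controls how a metastable trajectory is turned into a time-evolving graph
#' with planted state-discriminating topology. Every snapshot starts from the
#' complete graph on `n` nodes with fixed random coordinates; edges are then
#' removed according to the instantaneous trajectory point and state.
#'
#' @param n Number of nodes.
#' @param radius Radius `r` of the moving circle centred at the trajectory
#'   point.
#' @param inside_removal_prob Probability of removing an eligible edge whose
#'   both endpoints lie inside the circle (positional s-well) or inside the
#'   active half-plane (positional double-well).
#' @param noise_removal_prob Probability of removing any other edge
#'   (i.i.d. per edge and per snapshot).
#' @param per_state_degree Named list or vector mapping state label (as
#'   character, e.g. `"0"`) to the target within-circle neighbour count used
#'   by the non-positional generator.
#' @param coord_seed,edge_seed Integer seeds for node coordinates and edge
#'   removal; generation is bit-reproducible for fixed seeds.
#' @param coord_box Bounding box `c(xmin, xmax, ymin, ymax)` for uniform node
#'   coordinates. The default encloses the unit ring of the s-well potential
#'   so the moving circle covers nodes.
#' @return An object of class `graphgen_config`.
#' @export
graphgen_config <- function(n = 150L, radius = 0.75,
                            inside_removal_prob = 0.7,
                            noise_removal_prob = 0.005,
                            per_state_degree = list(`0` = 2L, `1` = 8L),
                            coord_seed = 11L, edge_seed = 12L,
                            coord_box = c(-1.5, 1.5, -1.5, 1.5)) {
  stopifnot(n >= 2, radius >= 0,
            inside_removal_prob >= 0, inside_removal_prob <= 1,
            noise_removal_prob >= 0, noise_removal_prob <= 1,
            length(coord_box) == 4)
  psd <- lapply(per_state_degree, as.integer)
  if (any(unlist(psd) >= n))
    stop("per_state_degree targets must be < n")
  structure(list(n = as.integer(n), radius = radius,
                 inside_removal_prob = inside_removal_prob,
                 noise_removal_prob = noise_removal_prob,
                 per_state_degree = psd,
                 coord_seed = as.integer(coord_seed),
                 edge_seed = as.integer(edge_seed),
                 coord_box = as.numeric(coord_box)),
            class = "graphgen_config")
}

# Stratified (jittered-grid) random coordinates: one node per grid cell,
# uniformly jittered within it. Keeps the local node density nearly uniform,
# so the number of nodes covered by the moving circle is stable across
# draws — with fully uniform draws at small n, density fluctuations near
# the wells would swamp the planted per-state signal.
draw_coords <- function(cfg) {
  withr::with_seed(cfg$coord_seed, {
    b <- cfg$coord_box
    w <- b[2] - b[1]; h <- b[4] - b[3]
    gx <- max(1L, round(sqrt(cfg$n * w / h)))
    gy <- ceiling(cfg$n / gx)
    cells <- expand.grid(ix = seq_len(gx) - 1L, iy = seq_len(gy) - 1L)
    cells <- cells[sample.int(nrow(cells), cfg$n), ]
    cbind(b[1] + (cells$ix + stats::runif(cfg$n)) * w / gx,
          b[3] + (cells$iy + stats::runif(cfg$n)) * h / gy)
  })
}

complete_adj <- function(n) {
  A <- matrix(1L, n, n)
  diag(A) <- 0L
  A
}

# Remove each currently-present edge in the index set `pairs` (2-column
# matrix, i < j) independently with probability p. Mutates and returns A.
remove_edges_bernoulli <- function(A, pairs, p) {
  if (p <= 0 || nrow(pairs) == 0) return(A)
  drop <- stats::runif(nrow(pairs)) < p
  if (any(drop)) {
    ij <- pairs[drop, , drop = FALSE]
    A[ij] <- 0L
    A[ij[, 2:1, drop = FALSE]] <- 0L
  }
  A
}

upper_pairs <- function(idx) {
  if (length(idx) < 2) return(matrix(integer(0), 0, 2))
  t(utils::combn(idx, 2))
}

# Pairs of K_n split by membership of `inside`: list(inside, rest)
split_pairs <- function(n, inside) {
  all_pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  both_in <- all_pairs[, 1] %in% inside & all_pairs[, 2] %in% inside
  list(inside = all_pairs[both_in, , drop = FALSE],
       rest = all_pairs[!both_in, , drop = FALSE])
}

#' Generate a positional s-well time-evolving graph
#'
#' Each snapshot starts from the complete graph; edges whose two endpoints
#' both lie inside the circle of radius `cfg$radius` centred at the
#' trajectory point are removed with probability `inside_removal_prob`, and
#' all other edges with probability `noise_removal_prob` (noise).
#'
#' @param traj A two-dimensional `trajectory` from [simulate_trajectory()].
#' @param cfg A [graphgen_config()].
#' @return A [tevograph()] with coordinates and state labels.
#' @export
gen_positional_swell <- function(traj, cfg) {
  stopifnot(inherits(traj, "trajectory"), inherits(cfg, "graphgen_config"))
  if (ncol(traj$points) != 2)
    stop("gen_positional_swell needs a 2-dimensional trajectory")
  coords <- draw_coords(cfg)
  T_ <- nrow(traj$points)
  snaps <- vector("list", T_)
  withr::with_seed(cfg$edge_seed, {
    for (t in seq_len(T_)) {
      c_t <- traj$points[t, ]
      inside <- which((coords[, 1] - c_t[1])^2 +
                      (coords[, 2] - c_t[2])^2 <= cfg$radius^2)
      sp <- split_pairs(cfg$n, inside)
      A <- complete_adj(cfg$n)
      A <- remove_edges_bernoulli(A, sp$inside, cfg$inside_removal_prob)
      A <- remove_edges_bernoulli(A, sp$rest, cfg$noise_removal_prob)
      snaps[[t]] <- A
    }
  })
  tevograph(snaps, coords = coords, states = traj$states)
}

#' Generate a positional double-well time-evolving graph
#'
#' The threshold `m` is the trajectory mean of `x1`. In snapshots of state 1,
#' edges between nodes with coordinate `b_j > m` ("upper" nodes) are removed
#' with probability `inside_removal_prob`; in state-0 snapshots, edges among
#' the complementary "lower" nodes are removed instead. All other edges are
#' subject to noise removal. The planted pattern (which half-plane loses its
#' internal edges) is what discriminates the two metastable states, and it is
#' tied to node positions, not to topology alone.
#'
#' @param traj A one-dimensional double-well `trajectory`.
#' @param cfg A [graphgen_config()].
#' @return A [tevograph()] with coordinates and state labels.
#' @export
gen_positional_doublewell <- function(traj, cfg) {
  stopifnot(inherits(traj, "trajectory"), inherits(cfg, "graphgen_config"))
  if (ncol(traj$points) != 1)
    stop("gen_positional_doublewell needs a 1-dimensional trajectory")
  coords <- draw_coords(cfg)
  m <- mean(traj$points[, 1])
  upper <- which(coords[, 2] > m)
  lower <- setdiff(seq_len(cfg$n), upper)
  sp_upper <- split_pairs(cfg$n, upper)
  sp_lower <- split_pairs(cfg$n, lower)
  T_ <- nrow(traj$points)
  snaps <- vector("list", T_)
  withr::with_seed(cfg$edge_seed, {
    for (t in seq_len(T_)) {
      sp <- if (traj$states[t] == 1L) sp_upper else sp_lower
      A <- complete_adj(cfg$n)
      A <- remove_edges_bernoulli(A, sp$inside, cfg$inside_removal_prob)
      A <- remove_edges_bernoulli(A, sp$rest, cfg$noise_removal_prob)
      snaps[[t]] <- A
    }
  })
  g <- tevograph(snaps, coords = coords, states = traj$states)
  attr(g, "doublewell_threshold") <- m
  attr(g, "upper_nodes") <- upper
  g
}

#' Generate a non-positional time-evolving graph
#'
#' States are discriminated purely topologically: within the moving circle,
#' edges are pruned (uniformly at random, seeded) until every inside node has
#' at most `per_state_degree[[state]]` neighbours among inside nodes, so the
#' within-circle degree differs between states. Edges with an endpoint
#' outside the circle are untouched except for noise removal. A
#' one-dimensional trajectory is lifted to the plane as `(x_t, 0)`.
#'
#' @param traj A `trajectory` (1- or 2-dimensional).
#' @param cfg A [graphgen_config()]; `per_state_degree` must cover every
#'   state occurring in `traj`.
#' @return A [tevograph()] with coordinates and state labels.
#' @export
gen_nonpositional <- function(traj, cfg) {
  stopifnot(inherits(traj, "trajectory"), inherits(cfg, "graphgen_config"))
  pts <- traj$points
  if (ncol(pts) == 1) pts <- cbind(pts[, 1], 0)
  missing_states <- setdiff(as.character(unique(traj$states)),
                            names(cfg$per_state_degree))
  if (length(missing_states))
    stop("per_state_degree lacks entries for state(s): ",
         paste(missing_states, collapse = ", "))
  coords <- draw_coords(cfg)
  T_ <- nrow(pts)
  snaps <- vector("list", T_)
  withr::with_seed(cfg$edge_seed, {
    for (t in seq_len(T_)) {
      c_t <- pts[t, ]
      inside <- which((coords[, 1] - c_t[1])^2 +
                      (coords[, 2] - c_t[2])^2 <= cfg$radius^2)
      A <- complete_adj(cfg$n)
      k <- cfg$per_state_degree[[as.character(traj$states[t])]]
      A <- prune_to_degree(A, inside, k)
      sp <- split_pairs(cfg$n, inside)
      A <- remove_edges_bernoulli(A, sp$rest, cfg$noise_removal_prob)
      snaps[[t]] <- A
    }
  })
  tevograph(snaps, coords = coords, states = traj$states)
}

# Prune edges of the induced subgraph on `inside` until every inside node has
# at most k neighbours among inside nodes. Random edge removal among
# over-degree nodes, seeded by the caller's RNG state.
prune_to_degree <- function(A, inside, k) {
  if (length(inside) < 2) return(A)
  sub_deg <- function() rowSums(A[inside, inside, drop = FALSE])
  repeat {
    deg <- sub_deg()
    over <- inside[deg > k]
    if (!length(over)) break
    v <- if (length(over) == 1) over else sample(over, 1)
    nb <- inside[A[v, inside] == 1L & inside != v]
    # prefer removing an edge to another over-degree node to avoid
    # starving compliant nodes below k
    nb_over <- intersect(nb, over)
    pool <- if (length(nb_over)) nb_over else nb
    u <- if (length(pool) == 1) pool else sample(pool, 1)
    A[v, u] <- A[u, v] <- 0L
  }
  A
}
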