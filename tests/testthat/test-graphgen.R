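# a short deterministic double-well trajectory object for generator tests
toy_traj <- function(x, states = NULL, kind = "double_well") {
  pts <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  spec <- potential_spec(kind, s = if (kind == "s_well") 3L else 2L,
                         n_steps = nrow(pts))
  if (is.null(states))
    states <- vapply(seq_len(nrow(pts)), function(i)
      assign_state(pts[i, ], spec), integer(1))
  structure(list(points = pts, states = as.integer(states), spec = spec),
            class = "trajectory")
}

test_that("zero removal probabilities reproduce the complete-graph sequence", {
  traj <- toy_traj(matrix(c(1, -1, 1, 0, 0, 0), ncol = 2), kind = "s_well")
  cfg <- graphgen_config(n = 6, inside_removal_prob = 0, noise_removal_prob = 0,
                         per_state_degree = list(`0` = 5L, `1` = 5L, `2` = 5L))
  for (gen in list(gen_positional_swell, gen_nonpositional)) {
    g <- gen(traj, cfg)
    for (A in g$snapshots) expect_equal(sum(A) / 2, 15)  # 6*5/2 edges
  }
  g <- gen_positional_doublewell(toy_traj(c(1, -1, 1)), cfg)
  for (A in g$snapshots) expect_equal(sum(A) / 2, 15)
})

test_that("radius zero disables inside-circle removal", {
  traj <- toy_traj(matrix(c(0, 0), ncol = 2), kind = "s_well")
  cfg <- graphgen_config(n = 8, radius = 0, inside_removal_prob = 1,
                         noise_removal_prob = 0,
                         per_state_degree = list(`0` = 2L, `1` = 5L))
  g <- gen_positional_swell(traj, cfg)
  expect_equal(sum(g$snapshots[[1]]) / 2, 28)
})

test_that("inside-circle removal hits exactly the covered pair", {
  cfg <- graphgen_config(n = 5, inside_removal_prob = 1, noise_removal_prob = 0,
                         coord_seed = 2,
                         per_state_degree = list(`0` = 1L, `1` = 3L))
  coords <- tegem:::draw_coords(cfg)
  # circle centred between two specific nodes, radius covering exactly them
  centre <- colMeans(coords[c(1, 2), ])
  d_all <- sqrt(colSums((t(coords) - centre)^2))
  r <- (sort(d_all)[2] + sort(d_all)[3]) / 2
  covered <- order(d_all)[1:2]
  cfg$radius <- r
  traj <- toy_traj(matrix(centre, ncol = 2), kind = "s_well")
  g <- gen_positional_swell(traj, cfg)
  A <- g$snapshots[[1]]
  expect_equal(A[covered[1], covered[2]], 0L)
  expect_equal(sum(A) / 2, 9)        # the other 9 edges of K5 remain
})

test_that("double-well removal prunes the state's half-plane block", {
  cfg <- graphgen_config(n = 4, inside_removal_prob = 1, noise_removal_prob = 0,
                         coord_seed = 5,
                         per_state_degree = list(`0` = 1L, `1` = 2L))
  coords <- tegem:::draw_coords(cfg)
  m <- stats::median(coords[, 2])    # craft trajectory mean = m
  traj <- toy_traj(c(m - 1, m + 1, m + 1, m - 1), states = c(0L, 1L, 1L, 0L))
  traj$points[] <- c(m - 1, m + 1, m + 1, m - 1)  # mean(x1) == m
  expect_equal(mean(traj$points[, 1]), m)
  g <- gen_positional_doublewell(traj, cfg)
  upper <- attr(g, "upper_nodes")
  expect_length(upper, 2)            # median splits 4 nodes two and two
  lower <- setdiff(1:4, upper)
  # state 1: single upper-upper edge removed, 5 edges of K4 remain
  A1 <- g$snapshots[[2]]
  expect_equal(A1[upper[1], upper[2]], 0L)
  expect_equal(sum(A1) / 2, 5)
  # state 0: the lower-lower edge removed instead
  A0 <- g$snapshots[[1]]
  expect_equal(A0[lower[1], lower[2]], 0L)
  expect_equal(sum(A0) / 2, 5)
})

test_that("planted half-plane pattern decodes the state perfectly", {
  traj <- simulate_trajectory(
    potential_spec("double_well", beta = 8, dt = 0.02, n_steps = 150,
                   thin = 10, seed = 13))
  cfg <- graphgen_config(n = 12, inside_removal_prob = 1, noise_removal_prob = 0,
                         coord_seed = 3, edge_seed = 4)
  g <- gen_positional_doublewell(traj, cfg)
  upper <- attr(g, "upper_nodes")
  stopifnot(length(upper) >= 2)
  pairs <- t(utils::combn(upper, 2))
  decoded <- vapply(g$snapshots, function(A) {
    missing_upper <- sum(A[pairs] == 0)
    if (missing_upper > 0) 1L else 0L
  }, integer(1))
  expect_identical(decoded, g$states)
})

test_that("non-positional pruning respects the per-state degree cap", {
  traj <- toy_traj(c(-1, 1, -1, 1))
  cfg <- graphgen_config(n = 14, radius = 1.0, inside_removal_prob = 0,
                         noise_removal_prob = 0,
                         per_state_degree = list(`0` = 2L, `1` = 8L),
                         coord_seed = 8, edge_seed = 9,
                         coord_box = c(-2, 2, -1.5, 1.5))
  g <- gen_nonpositional(traj, cfg)
  coords <- g$coords
  for (t in seq_along(g$snapshots)) {
    c_t <- c(traj$points[t, 1], 0)
    inside <- which((coords[, 1] - c_t[1])^2 + (coords[, 2] - c_t[2])^2 <= 1)
    if (length(inside) < 2) next
    sub <- g$snapshots[[t]][inside, inside]
    cap <- if (g$states[t] == 1L) 8L else 2L
    expect_lte(max(rowSums(sub)), cap)
  }
  # mean inside-circle degree differs between states when caps differ
  ec <- vapply(g$snapshots, sum, numeric(1))
  expect_gt(mean(ec[g$states == 1]), mean(ec[g$states == 0]))
  # unknown state label is rejected
  cfg_bad <- graphgen_config(n = 14, per_state_degree = list(`0` = 2L))
  expect_error(gen_nonpositional(traj, cfg_bad), "state")
})

test_that("snapshots are symmetric, zero-diagonal, and reproducible", {
  traj <- simulate_trajectory(
    potential_spec("s_well", s = 3, beta = 2, n_steps = 30, seed = 17))
  cfg <- graphgen_config(n = 10, coord_seed = 1, edge_seed = 2,
                         per_state_degree = list(`0` = 3L, `1` = 5L, `2` = 7L))
  g1 <- gen_positional_swell(traj, cfg)
  g2 <- gen_positional_swell(traj, cfg)
  expect_identical(g1$snapshots, g2$snapshots)
  for (A in g1$snapshots[1:5]) {
    expect_identical(A, t(A))
    expect_true(all(diag(A) == 0))
  }
  g3 <- gen_nonpositional(traj, cfg)
  expect_identical(g3$snapshots, gen_nonpositional(traj, cfg)$snapshots)
})

test_that("edge statistics summarise complete and empty sequences", {
  n <- 150
  g <- tevograph(list(complete_graph(n), complete_graph(n)))
  st <- snapshot_edge_stats(g)
  expect_equal(st$mean, n * (n - 1) / 2)   # 11175
  g0 <- tevograph(list(matrix(0L, 4, 4)))
  expect_equal(snapshot_edge_stats(g0)$mean, 0)
  # per-state summary present when states exist
  gs <- tevograph(list(complete_graph(4), matrix(0L, 4, 4)), states = c(0, 1))
  st2 <- snapshot_edge_stats(gs)
  expect_equal(st2$per_state$mean, c(6, 0))
})

test_that("edge-list serialization round-trips including the manifest", {
  g <- rand_tevograph(n = 7, T_ = 5, seed = 3, states = c(0, 0, 1, 1, 0))
  g$coords <- matrix(stats::runif(14), 7, 2)
  dir <- withr::local_tempdir()
  write_tevograph(g, dir, config = list(note = "fixture"))
  back <- read_tevograph(dir)
  expect_identical(lapply(back$snapshots, unname),
                   lapply(g$snapshots, unname))
  expect_identical(back$states, g$states)
  expect_equal(back$coords, g$coords, tolerance = 1e-12)
  # byte-identical manifests across rewrites (idempotence)
  dir2 <- withr::local_tempdir()
  write_tevograph(g, dir2, config = list(note = "fixture"))
  expect_identical(readLines(file.path(dir, "manifest.json")),
                   readLines(file.path(dir2, "manifest.json")))
})

test_that("invalid snapshots are rejected", {
  A <- matrix(0L, 3, 3); A[1, 2] <- 1L           # asymmetric
  expect_error(tevograph(list(A)), "symmetric")
  B <- complete_graph(3); diag(B) <- 1L
  expect_error(tevograph(list(B)), "diagonal")
  expect_error(tevograph(list(complete_graph(3)), states = c(0, 1)), "label")
})
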