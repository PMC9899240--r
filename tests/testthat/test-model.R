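test_that("sinusoidal positional encodings match their closed form", {
  pe <- positional_encoding(6, 8)
  expect_equal(dim(pe), c(6, 8))
  expect_equal(pe[1, ], rep(c(0, 1), 4))          # pos = 0: sin 0, cos 0
  expect_equal(pe[2, 1], sin(1))                  # pos = 1, i = 0
  expect_equal(pe[2, 2], cos(1))
  expect_equal(pe[3, 3], sin(2 / 10000^(2 / 8)))
  expect_true(all(pe >= -1 & pe <= 1))
  expect_error(positional_encoding(4, 7), "%%")
})

test_that("the attention mask adds the master node and self-connections", {
  n <- 3
  m_empty <- attention_mask(matrix(0, n, n))
  expect_equal(dim(m_empty), c(4, 4))
  expect_true(all(m_empty[1, ] == 1) && all(m_empty[, 1] == 1))
  expect_equal(m_empty[-1, -1], diag(n))

  m_full <- attention_mask(complete_graph(n))
  expect_true(all(m_full == 1))

  m_path <- attention_mask(path_graph(3))
  expect_equal(sum(m_path[-1, -1]), 7)            # 3 self + 2 symmetric edges

  A_bad <- matrix(0, 3, 3); A_bad[1, 2] <- 1
  expect_error(attention_mask(A_bad), "symmetric")
})

test_that("InfoNCE closed forms hold exactly", {
  # identical embeddings: numerator is one of B equal denominator terms
  B <- 7
  gh <- rep(0.3, 4)
  batch <- matrix(rep(gh, each = B), B)
  expect_equal(info_nce_loss(gh, gh, batch, tau = 1), log(B), tolerance = 1e-8)
  expect_equal(info_nce_loss(gh, gh, batch, tau = 0.05), log(B),
               tolerance = 1e-8)

  # B = 2 hand-computed case
  loss <- info_nce_loss(c(1, 0), c(1, 0), rbind(c(1, 0), c(-1, 0)), tau = 1)
  expect_equal(loss, -log(exp(1) / (exp(1) + exp(-1))), tolerance = 1e-8)
  expect_equal(loss, 0.126928, tolerance = 1e-5)

  # loss strictly decreases as the positive similarity grows
  batch2 <- rbind(c(2, 0), c(0.5, 0.1), c(-0.3, 0.4))
  l1 <- info_nce_loss(c(1, 0), batch2[1, ], batch2)
  batch3 <- batch2; batch3[1, ] <- c(3, 0)
  l2 <- info_nce_loss(c(1, 0), batch3[1, ], batch3)
  expect_lt(l2, l1)
  expect_error(info_nce_loss(c(1, 0), c(1, 0), batch2, tau = 0), "positive")
})

test_that("attention weights are exactly zero on masked pairs", {
  g <- tevograph(list(path_graph(5)))
  cfg <- tiny_model_config()
  model <- structure(list(params = tegem:::init_params(cfg, 5), cfg = cfg,
                          n = 5), class = "graph_embedder")
  out <- encode_snapshot(model, g, 1, return_attention = TRUE)
  mask <- attention_mask(g$snapshots[[1]])
  for (A in out$attention) {                       # one cube per layer
    for (h in seq_len(dim(A)[3])) {
      expect_identical(max(abs(A[, , h][mask == 0])), 0)
      expect_equal(rowSums(A[, , h]), rep(1, 6), tolerance = 1e-12)
    }
  }
})

test_that("constant-feature embeddings are invariant to node relabelling", {
  snaps <- rand_snapshots(7, 6, seed = 21)
  g <- tevograph(snaps)
  cfg <- tiny_model_config(feature_mode = "constant",
                           use_positional_encoding = FALSE)
  model <- structure(list(params = tegem:::init_params(cfg, 7), cfg = cfg,
                          n = 7), class = "graph_embedder")
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  g_perm <- tevograph(lapply(snaps, function(A) A[perm, perm]))
  e1 <- embed_all(model, g)
  e2 <- embed_all(model, g_perm)
  expect_equal(unname(e1), unname(e2), tolerance = 1e-5)
})

test_that("window gradients agree with finite differences", {
  set.seed(42)
  n <- 6
  cfg <- tiny_model_config()
  g <- rand_tevograph(n = n, T_ = 5, seed = 5)
  params <- tegem:::init_params(cfg, n)
  masks <- tegem:::mask_list(g)
  xraw <- tegem:::raw_feature_list(g, cfg)
  pe <- tegem:::pe_matrix(g, cfg)
  ts <- 1:4
  dz <- lapply(1:4, function(i) stats::rnorm(cfg$d_m, sd = 0.3))
  out <- tegem:::cpp_window_grads(params, xraw, masks, pe, as.integer(ts),
                                  cfg$n_heads, dz)
  scalar_at <- function(flat) {
    p <- tegem:::par_unflatten(flat, params)
    o <- tegem:::cpp_window_grads(p, xraw, masks, pe, as.integer(ts),
                                  cfg$n_heads, dz)
    sum(vapply(1:4, function(i) sum(o$Z[i, ] * dz[[i]]), numeric(1)))
  }
  flat <- tegem:::par_flatten(params)
  gflat <- tegem:::par_flatten(out$grads)
  idx <- sort(sample(length(flat), 40))
  eps <- 1e-5
  num <- vapply(idx, function(j) {
    f1 <- flat; f1[j] <- f1[j] + eps
    f2 <- flat; f2[j] <- f2[j] - eps
    (scalar_at(f1) - scalar_at(f2)) / (2 * eps)
  }, numeric(1))
  expect_equal(gflat[idx], num, tolerance = 1e-4)
})

test_that("training reduces the contrastive loss on easy data", {
  traj <- simulate_trajectory(
    potential_spec("double_well", beta = 8, dt = 0.02, n_steps = 120,
                   thin = 10, seed = 31))
  cfg_g <- graphgen_config(n = 10, radius = 1.2, noise_removal_prob = 0,
                           per_state_degree = list(`0` = 1L, `1` = 7L),
                           coord_seed = 1, edge_seed = 2,
                           coord_box = c(-2.3, 2.3, -1.5, 1.5))
  g <- gen_nonpositional(traj, cfg_g)
  cfg <- tiny_model_config(feature_mode = "degree", epochs = 10L,
                           steps_per_epoch = 4L, learning_rate = 3e-3,
                           embed_l2 = 0.5, normalize_embeddings = FALSE)
  model <- train_graph_embedder(g, cfg)
  expect_lt(tail(model$loss_curve, 1), model$loss_curve[1])
  emb <- model$embeddings
  expect_equal(dim(emb), c(120, cfg$d))
  # deterministic retraining yields the identical loss curve
  model2 <- train_graph_embedder(g, cfg)
  expect_identical(model$loss_curve, model2$loss_curve)
  expect_identical(unname(model$embeddings), unname(model2$embeddings))
})

test_that("projection head output matches the C++ forward pass", {
  cfg <- tiny_model_config()
  g <- rand_tevograph(n = 5, T_ = 3, seed = 11)
  model <- structure(list(params = tegem:::init_params(cfg, 5), cfg = cfg,
                          n = 5), class = "graph_embedder")
  enc <- encode_snapshot(model, g, 2)
  expect_length(enc$g_hat, cfg$d)
  expect_equal(project_embedding(model, enc$z), enc$g_hat, tolerance = 1e-12)
})

test_that("models round-trip through the JSON archive", {
  g <- rand_tevograph(n = 6, T_ = 20, seed = 2)
  cfg <- tiny_model_config(epochs = 2L)
  model <- train_graph_embedder(g, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  expect_equal(tegem:::par_flatten(back$params),
               tegem:::par_flatten(model$params), tolerance = 1e-12)
  e1 <- embed_all(model, g)
  e2 <- embed_all(back, g)
  expect_equal(unname(e1), unname(e2), tolerance = 1e-10)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_embeddings(e1, csv)
  df <- utils::read.csv(csv)
  expect_equal(ncol(df), cfg$d + 1)
  expect_equal(df$g_1, unname(e1[, 1]), tolerance = 1e-6)
})

test_that("training rejects too-short sequences and tiny anchor pools", {
  g <- rand_tevograph(n = 5, T_ = 4, seed = 3)
  cfg <- tiny_model_config(window_l = 3L)
  expect_error(train_graph_embedder(g, cfg), "snapshots")
  g2 <- rand_tevograph(n = 5, T_ = 30, seed = 3)
  cfg2 <- tiny_model_config(batch_size = 64L, epochs = 1L)
  expect_warning(train_graph_embedder(g2, cfg2), "anchors")
})
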