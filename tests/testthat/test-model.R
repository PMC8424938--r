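test_that("block layer counts are 12/10/14 for any filter width", {
  for (f in c(8L, 32L)) {
    cb <- build_block("convolution", c(12L, 16L), filters = f, stride = 2L)
    expect_equal(attr(cb, "n_block_layers"), 12L)
    ib <- build_block("identity", c(9L, f), filters = f)
    expect_equal(attr(ib, "n_block_layers"), 10L)
    ub <- build_block("upsampling", c(9L, 16L), filters = f)
    expect_equal(attr(ub, "n_block_layers"), 14L)
  }
  expect_error(build_block("identity", c(9L, 8L), filters = 16L),
    class = "pocketgrid_domain_error")
})

test_that("block shapes: identity preserves, stride halves, upsample doubles", {
  ib <- build_block("identity", c(9L, 64L), filters = 64L)
  out <- ib$layers[[ib$output]]
  expect_equal(c(out$side_out, out$channels_out), c(9L, 64L))
  cb <- build_block("convolution", c(36L, 18L), filters = 32L, stride = 2L)
  outc <- cb$layers[[cb$output]]
  expect_equal(c(outc$side_out, outc$channels_out), c(18L, 32L))
  ub <- build_block("upsampling", c(9L, 32L), filters = 16L)
  outu <- ub$layers[[ub$output]]
  expect_equal(c(outu$side_out, outu$channels_out), c(18L, 16L))
})

test_that("a zero-weight identity block passes its input through", {
  ib <- build_block("identity", c(5L, 3L), filters = 3L)
  params <- init_parameters(ib, seed = 1)
  for (lid in names(params)) {
    if (!is.null(params[[lid]]$W)) {
      params[[lid]]$W[] <- 0
      params[[lid]]$b[] <- 0
    }
    if (!is.null(params[[lid]]$gamma)) {
      params[[lid]]$beta[] <- 0
    }
  }
  X <- matrix(abs(rnorm(125 * 3)), 125, 3)  # non-negative input
  fw <- pocketgrid:::nn_forward(ib, params, X, training = TRUE)
  expect_equal(fw$output, X, tolerance = 1e-12)
})

test_that("block census is (5, 13, 4) for any schedule", {
  for (sched in list(default_schedule(), reduced_schedule())) {
    g <- build_puresnet(sched)
    expect_equal(
      unname(block_census(g)[c("convolution", "identity", "upsampling")]),
      c(5L, 13L, 4L)
    )
    expect_equal(count_parameters(g)$layers, 252L)
    out <- g$layers[[g$output]]
    expect_equal(c(out$side_out, out$channels_out), c(36L, 1L))
  }
})

test_that("parameter counting matches closed forms on single layers", {
  env <- pocketgrid:::nn_graph_env()
  inp <- pocketgrid:::add_layer(env, "in", "input", character(), 9L, 9L,
    18L, 18L)
  cv <- pocketgrid:::add_layer(env, "cv", "conv", inp, 9L, 9L, 18L, 32L,
    k = 3L, stride = 1L)
  g1 <- pocketgrid:::finalize_graph(env, inp, cv)
  expect_equal(count_parameters(g1)$trainable, 27 * 18 * 32 + 32) # 15,584
  env2 <- pocketgrid:::nn_graph_env()
  inp2 <- pocketgrid:::add_layer(env2, "in", "input", character(), 9L, 9L,
    32L, 32L)
  bn <- pocketgrid:::add_layer(env2, "bn", "bn", inp2, 9L, 9L, 32L, 32L)
  g2 <- pocketgrid:::finalize_graph(env2, inp2, bn)
  cp <- count_parameters(g2)
  expect_equal(cp$trainable, 64)
  expect_equal(cp$non_trainable, 64)
})

test_that("dice loss follows its closed form", {
  m <- c(rep(1, 100), rep(0, 100))
  expect_lte(dice_loss(m, m), 1 / (2 * 100))  # smooth-term tolerance
  p <- c(rep(0, 100), rep(1, 100))
  expect_equal(dice_loss(p, m), 1 - 1 / 201)
  # half coverage of a 2k mask, k = 50
  k <- 50
  mask <- rep(c(1, 0), c(2 * k, 50))
  pred <- rep(c(1, 0), c(k, k + 50))
  expect_equal(dice_loss(pred, mask), 1 - (2 * k + 1) / (3 * k + 1))
  expect_error(dice_loss(1:5, 1:4), class = "pocketgrid_domain_error")
  # monotone in overlap at fixed sizes
  losses <- vapply(0:5, function(ov) {
    pr <- rep(0, 60)
    pr[1:10] <- c(rep(1, ov), rep(0, 10 - ov))
    pr[11:(21 - ov)] <- 1
    dice_loss(pr[1:60], rep(c(1, 0), c(10, 50)))
  }, 1.0)
  expect_true(all(diff(losses) < 0))
})

test_that("training is deterministic and frozen at zero learning rate", {
  set.seed(1)
  X <- matrix(runif(6^3 * 18), 6^3, 18)
  mask <- as.numeric(runif(6^3) < 0.1)
  env <- pocketgrid:::nn_graph_env()
  inp <- pocketgrid:::add_layer(env, "in", "input", character(), 6L, 6L,
    18L, 18L)
  cv <- pocketgrid:::add_layer(env, "cv", "conv", inp, 6L, 6L, 18L, 4L,
    k = 3L, stride = 1L)
  bn <- pocketgrid:::add_layer(env, "bn", "bn", cv, 6L, 6L, 4L, 4L)
  rl <- pocketgrid:::add_layer(env, "rl", "relu", bn, 6L, 6L, 4L, 4L)
  hd <- pocketgrid:::add_layer(env, "hd", "conv", rl, 6L, 6L, 4L, 1L,
    k = 1L, stride = 1L, activation = "sigmoid")
  g <- pocketgrid:::finalize_graph(env, inp, hd)
  ds <- list(list(grid = X, mask = mask))
  cfg <- train_config(learning_rate = 0.01, steps = 10, batch_size = 1,
    seed = 7)
  f1 <- train_scaled(g, ds, cfg)
  f2 <- train_scaled(g, ds, cfg)
  expect_identical(f1$trace, f2$trace)
  f0 <- train_scaled(g, ds, train_config(learning_rate = 1e-12, steps = 5,
    batch_size = 1, seed = 7))
  expect_lt(diff(range(f0$trace$loss)), 1e-6)
  expect_error(train_scaled(g, list(), cfg),
    class = "pocketgrid_domain_error")
})

test_that("prediction is reproducible and strictly inside (0, 1)", {
  g <- build_puresnet(reduced_schedule(), input_side = 12L)
  params <- init_parameters(g, seed = 3)
  fit <- structure(
    list(graph = g, params = params,
      trace = tibble::tibble(step = integer(), loss = numeric()),
      config = train_config()),
    class = "puresnet_fit"
  )
  X <- matrix(0, 12^3, 18)
  p1 <- predict(fit, X)
  p2 <- predict(fit, X)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_equal(dim(p1), rep(12, 3))
})

test_that("grouped K-fold keeps families together", {
  set.seed(2)
  fams <- sample(paste0("fam", 1:12), 80, replace = TRUE)
  folds <- grouped_kfold(fams, k = 4, seed = 5)
  expect_true(all(folds %in% 1:4))
  per_fam <- tapply(folds, fams, function(x) length(unique(x)))
  expect_true(all(per_fam == 1))
  # folds reasonably balanced
  expect_lt(max(table(folds)) - min(table(folds)), 30)
})

test_that("graph tidiers expose the layer table and totals", {
  g <- build_puresnet(reduced_schedule())
  td <- tidy(g)
  expect_equal(nrow(td), 252)
  gl <- glance(g)
  expect_equal(gl$layers, 252)
  expect_equal(sum(td$trainable), gl$trainable)
  expect_equal(sum(td$non_trainable), gl$non_trainable)
})

test_that("plot methods return ggplot objects", {
  pg <- make_probability_grid(
    tibble::tibble(cx = 18, cy = 18, cz = 18, radius = 3),
    noise_level = 0.1, seed = 1
  )
  mask <- pocketgrid:::new_site_mask(pg$prob > 0.5, grid_spec())
  expect_s3_class(ggplot2::autoplot(mask), "ggplot")
  recs <- tibble::tibble(structure_id = c("a", "b"), class = c("TP", "FN"),
    dcc = c(2, NA))
  expect_s3_class(plot_eval_records(recs), "ggplot")
})
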