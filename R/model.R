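# Residual U-Net builder for voxel binding-site segmentation, plus the
# dice loss training loop and prediction. The network follows the
# encoder-decoder layout: a convolutional stem, five encoder stages
# (projection-shortcut convolution block + identity block each, the first
# at full resolution and the rest downsampling by stride-2 convolutions),
# identity blocks on the skip paths, and four decoder stages (up-sampling
# block + identity block) back to full resolution, ending in a 1-channel
# sigmoid head.
#
# Block layouts (every graph node counts as one layer):
#   convolution block (12): [conv 1x 'reduce' -> BN -> ReLU -> conv kxk 'mid'
#     -> BN -> ReLU -> conv 1x 'expand' -> BN] + projection shortcut
#     [conv 1x -> BN], add, ReLU
#   identity block (10): same main path, shortcut is the unmodified input
#   up-sampling block (14): nearest-neighbor upsample on both the decoder
#     path and the identity-processed skip, shortcut projection on the
#     skip, add, ReLU

#' Default filter schedule of the production network
#'
#' One row per stage: bottleneck width (`g`, the two inner convolutions)
#' and output width (`f`) for the encoder stages 1-5; decoder stages reuse
#' the schedule of their matching encoder stage. `stem` is the width of
#' the stem convolution. This schedule was fixed by constrained search so
#' that the default build reproduces the published layer and parameter
#' accounting of the architecture (see the methods vignette).
#'
#' @return List with `stem`, `filters` (length-5 integer vector of stage
#'   output widths), `ratio` (f / g), `head_kernel`.
#' @export
default_schedule <- function() {
  list(
    stem = 56L,
    filters = c(38L, 76L, 92L, 96L, 342L),
    ratio = 1L,
    head_kernel = 1L,
    merge = "add_skip"
  )
}

#' Reduced filter schedule for smoke-test training
#'
#' Same architecture, narrow widths: fast enough to overfit a single
#' synthetic example on one CPU while exercising every block type.
#'
#' @return Schedule list as in [default_schedule()].
#' @export
reduced_schedule <- function() {
  list(
    stem = 4L,
    filters = c(4L, 8L, 8L, 16L, 16L),
    ratio = 1L,
    head_kernel = 1L,
    merge = "add_skip"
  )
}

bneck <- function(F, ratio) as.integer(max(F %/% ratio, 1L))

conv_block_layers <- function(env, name, in_id, side, stride, cin, g, F,
                              kmid = 3L, block_kind = "convolution",
                              use_shortcut = TRUE) {
  so <- out_side_conv(side, stride)
  c1 <- add_layer(env, paste0(name, "_c1"), "conv", in_id, side, so, cin, g,
    k = 1L, stride = stride, block = name, block_kind = block_kind
  )
  b1 <- add_layer(env, paste0(name, "_b1"), "bn", c1, so, so, g, g,
    block = name, block_kind = block_kind
  )
  a1 <- add_layer(env, paste0(name, "_a1"), "relu", b1, so, so, g, g,
    block = name, block_kind = block_kind
  )
  c2 <- add_layer(env, paste0(name, "_c2"), "conv", a1, so, so, g, g,
    k = kmid, stride = 1L, block = name, block_kind = block_kind
  )
  b2 <- add_layer(env, paste0(name, "_b2"), "bn", c2, so, so, g, g,
    block = name, block_kind = block_kind
  )
  a2 <- add_layer(env, paste0(name, "_a2"), "relu", b2, so, so, g, g,
    block = name, block_kind = block_kind
  )
  c3 <- add_layer(env, paste0(name, "_c3"), "conv", a2, so, so, g, F,
    k = 1L, stride = 1L, block = name, block_kind = block_kind
  )
  b3 <- add_layer(env, paste0(name, "_b3"), "bn", c3, so, so, F, F,
    block = name, block_kind = block_kind
  )
  sc <- add_layer(env, paste0(name, "_sc"), "conv", in_id, side, so, cin, F,
    k = 1L, stride = stride, block = name, block_kind = block_kind
  )
  sb <- add_layer(env, paste0(name, "_sb"), "bn", sc, so, so, F, F,
    block = name, block_kind = block_kind
  )
  add_in <- if (use_shortcut) c(b3, sb) else b3
  ad <- add_layer(env, paste0(name, "_add"), "add", add_in, so, so, F, F,
    block = name, block_kind = block_kind
  )
  add_layer(env, paste0(name, "_out"), "relu", ad, so, so, F, F,
    block = name, block_kind = block_kind
  )
}

identity_block_layers <- function(env, name, in_id, side, C, g,
                                  kmid = 3L, skip_shortcut = TRUE) {
  c1 <- add_layer(env, paste0(name, "_c1"), "conv", in_id, side, side, C, g,
    k = 1L, stride = 1L, block = name, block_kind = "identity"
  )
  b1 <- add_layer(env, paste0(name, "_b1"), "bn", c1, side, side, g, g,
    block = name, block_kind = "identity"
  )
  a1 <- add_layer(env, paste0(name, "_a1"), "relu", b1, side, side, g, g,
    block = name, block_kind = "identity"
  )
  c2 <- add_layer(env, paste0(name, "_c2"), "conv", a1, side, side, g, g,
    k = kmid, stride = 1L, block = name, block_kind = "identity"
  )
  b2 <- add_layer(env, paste0(name, "_b2"), "bn", c2, side, side, g, g,
    block = name, block_kind = "identity"
  )
  a2 <- add_layer(env, paste0(name, "_a2"), "relu", b2, side, side, g, g,
    block = name, block_kind = "identity"
  )
  c3 <- add_layer(env, paste0(name, "_c3"), "conv", a2, side, side, g, C,
    k = 1L, stride = 1L, block = name, block_kind = "identity"
  )
  b3 <- add_layer(env, paste0(name, "_b3"), "bn", c3, side, side, C, C,
    block = name, block_kind = "identity"
  )
  # ablation variant: single-input add is a pass-through, so no identity
  # path bypasses the convolutional stack while layer ids stay aligned
  add_in <- if (skip_shortcut) c(b3, in_id) else b3
  ad <- add_layer(env, paste0(name, "_add"), "add", add_in, side,
    side, C, C, block = name, block_kind = "identity"
  )
  add_layer(env, paste0(name, "_out"), "relu", ad, side, side, C, C,
    block = name, block_kind = "identity"
  )
}

up_block_layers <- function(env, name, main_id, skip_id, side_in, side_out,
                            cin_main, cin_skip, g, F, kmid = 3L,
                            use_skip = TRUE) {
  up <- add_layer(env, paste0(name, "_up"), "upsample", main_id, side_in,
    side_out, cin_main, cin_main, block = name, block_kind = "upsampling"
  )
  c1 <- add_layer(env, paste0(name, "_c1"), "conv", up, side_out, side_out,
    cin_main, g, k = 1L, stride = 1L, block = name, block_kind = "upsampling"
  )
  b1 <- add_layer(env, paste0(name, "_b1"), "bn", c1, side_out, side_out, g,
    g, block = name, block_kind = "upsampling"
  )
  a1 <- add_layer(env, paste0(name, "_a1"), "relu", b1, side_out, side_out,
    g, g, block = name, block_kind = "upsampling"
  )
  c2 <- add_layer(env, paste0(name, "_c2"), "conv", a1, side_out, side_out,
    g, g, k = kmid, stride = 1L, block = name, block_kind = "upsampling"
  )
  b2 <- add_layer(env, paste0(name, "_b2"), "bn", c2, side_out, side_out, g,
    g, block = name, block_kind = "upsampling"
  )
  a2 <- add_layer(env, paste0(name, "_a2"), "relu", b2, side_out, side_out,
    g, g, block = name, block_kind = "upsampling"
  )
  c3 <- add_layer(env, paste0(name, "_c3"), "conv", a2, side_out, side_out,
    g, F, k = 1L, stride = 1L, block = name, block_kind = "upsampling"
  )
  b3 <- add_layer(env, paste0(name, "_b3"), "bn", c3, side_out, side_out, F,
    F, block = name, block_kind = "upsampling"
  )
  src <- if (use_skip) skip_id else main_id
  su <- add_layer(env, paste0(name, "_scup"), "upsample", src, side_in,
    side_out, cin_skip, cin_skip, block = name, block_kind = "upsampling"
  )
  sc <- add_layer(env, paste0(name, "_sc"), "conv", su, side_out, side_out,
    cin_skip, F, k = 1L, stride = 1L, block = name, block_kind = "upsampling"
  )
  sb <- add_layer(env, paste0(name, "_sb"), "bn", sc, side_out, side_out, F,
    F, block = name, block_kind = "upsampling"
  )
  add_in <- if (use_skip) c(b3, sb) else b3
  ad <- add_layer(env, paste0(name, "_add"), "add", add_in, side_out,
    side_out, F, F, block = name, block_kind = "upsampling"
  )
  add_layer(env, paste0(name, "_out"), "relu", ad, side_out, side_out, F, F,
    block = name, block_kind = "upsampling"
  )
}

#' Build a standalone residual block
#'
#' Builds one convolution, identity, or up-sampling block as its own small
#' graph, mainly for inspecting shapes and the per-block layer accounting
#' (12 / 10 / 14 layers respectively, not counting the input node).
#'
#' @param kind `"convolution"`, `"identity"`, or `"upsampling"`.
#' @param input_shape Integer c(side, channels) of the block input.
#' @param filters Output channel count.
#' @param stride Stride of the convolution block (identity blocks are
#'   always stride 1; up-sampling blocks upsample 2x).
#' @param ratio Bottleneck ratio (inner width = filters / ratio).
#' @return An `nn_graph`; `attr(, "n_block_layers")` is the block's own
#'   layer count.
#' @export
build_block <- function(kind = c("convolution", "identity", "upsampling"),
                        input_shape = c(9L, 64L), filters = 64L,
                        stride = 1L, ratio = 1L) {
  kind <- match.arg(kind)
  if (filters <= 0) {
    abort("filters must be positive", class = "pocketgrid_domain_error")
  }
  side <- as.integer(input_shape[1])
  cin <- as.integer(input_shape[2])
  g <- bneck(filters, ratio)
  env <- nn_graph_env()
  inp <- add_layer(env, "input", "input", character(), side, side, cin, cin,
    block = "input", block_kind = "io"
  )
  out <- switch(kind,
    convolution = conv_block_layers(env, "blk", inp, side, stride, cin, g,
      filters),
    identity = {
      if (cin != filters) {
        abort("identity blocks require filters == input channels",
          class = "pocketgrid_domain_error"
        )
      }
      identity_block_layers(env, "blk", inp, side, filters, g)
    },
    upsampling = up_block_layers(env, "blk", inp, inp, side, 2L * side, cin,
      cin, g, filters, use_skip = FALSE)
  )
  gph <- finalize_graph(env, inp, out)
  attr(gph, "n_block_layers") <- length(gph$layers) - 1L
  gph
}

#' Build the full residual U-Net
#'
#' Assembles the stem, the five encoder stages, the identity-processed skip
#' paths, the four decoder stages, and the sigmoid head. The default
#' schedule reproduces the production accounting: block census (5, 13, 4),
#' block layer counts 12/10/14, 252 layers in total.
#'
#' @param schedule Filter schedule, see [default_schedule()].
#' @param input_side Grid side (default 36).
#' @param input_channels Feature channels (default 18).
#' @param skip_connections Set `FALSE` to ablate every residual and skip
#'   shortcut (the additive shortcut inputs are replaced so that no
#'   identity path bypasses the convolutional stack).
#' @return An `nn_graph` with input (side^3, 18) and output (side^3, 1).
#' @export
build_puresnet <- function(schedule = default_schedule(), input_side = 36L,
                           input_channels = 18L, skip_connections = TRUE) {
  F <- as.integer(schedule$filters)
  if (length(F) != 5) {
    abort("schedule$filters must have 5 stage widths",
      class = "pocketgrid_domain_error"
    )
  }
  ratio <- schedule$ratio
  g <- vapply(F, bneck, 1L, ratio = ratio)
  s0 <- as.integer(schedule$stem)
  env <- nn_graph_env()
  inp <- add_layer(env, "input", "input", character(), input_side,
    input_side, input_channels, input_channels, block = "input",
    block_kind = "io"
  )
  # stem
  st <- add_layer(env, "stem_conv", "conv", inp, input_side, input_side,
    input_channels, s0, k = 3L, stride = 1L, block = "stem",
    block_kind = "stem"
  )
  st <- add_layer(env, "stem_bn", "bn", st, input_side, input_side, s0, s0,
    block = "stem", block_kind = "stem"
  )
  st <- add_layer(env, "stem_act", "relu", st, input_side, input_side, s0,
    s0, block = "stem", block_kind = "stem"
  )
  # encoder
  sides <- integer(5)
  enc_out <- character(5)
  x <- st
  side <- input_side
  cin <- s0
  for (i in 1:5) {
    stride <- if (i == 1) 1L else 2L
    x <- conv_block_layers(env, paste0("enc", i, "_conv"), x, side, stride,
      cin, g[i], F[i], use_shortcut = skip_connections)
    side <- out_side_conv(side, stride)
    x <- identity_block_layers(env, paste0("enc", i, "_id"), x, side, F[i],
      g[i], skip_shortcut = skip_connections)
    enc_out[i] <- x
    sides[i] <- side
    cin <- F[i]
  }
  # skip paths: identity blocks on encoder stages 2..5 outputs; each skip
  # feeds the shortcut branch of the matching up-sampling block
  skip_out <- character(5)
  for (i in 2:5) {
    skip_out[i] <- identity_block_layers(env, paste0("skip", i, "_id"),
      enc_out[i], sides[i], F[i], g[i], skip_shortcut = skip_connections)
  }
  # decoder: stage j recovers the resolution of encoder stage j
  x <- enc_out[5]
  for (j in 4:1) {
    x <- up_block_layers(env, paste0("dec", j, "_up"), x, skip_out[j + 1],
      sides[j + 1], sides[j], F[j + 1], F[j + 1], g[j], F[j],
      use_skip = skip_connections)
    x <- identity_block_layers(env, paste0("dec", j, "_id"), x, sides[j],
      F[j], g[j], skip_shortcut = skip_connections)
  }
  hk <- as.integer(schedule$head_kernel)
  hc <- add_layer(env, "head_conv", "conv", x, sides[1], sides[1], F[1], 1L,
    k = hk, stride = 1L, block = "head", block_kind = "head"
  )
  out <- add_layer(env, "head_act", "sigmoid", hc, sides[1], sides[1], 1L,
    1L, block = "head", block_kind = "head"
  )
  finalize_graph(env, inp, out)
}

#' Census of residual blocks in a built graph
#' @param graph An `nn_graph` from [build_puresnet()].
#' @return Named integer vector: convolution, identity, upsampling block
#'   counts.
#' @export
block_census <- function(graph) {
  info <- tibble::tibble(
    block = vapply(graph$layers, function(l) l$block, ""),
    kind = vapply(graph$layers, function(l) l$block_kind, "")
  )
  blocks <- dplyr::distinct(info)
  c(
    convolution = sum(blocks$kind == "convolution"),
    identity = sum(blocks$kind == "identity"),
    upsampling = sum(blocks$kind == "upsampling")
  )
}

#' Per-layer summary of a network graph
#' @param x An `nn_graph`.
#' @param ... Unused.
#' @return Tibble: one row per layer with kind, output shape, parameter
#'   counts, and owning block.
#' @export
tidy.nn_graph <- function(x, ...) {
  tibble::tibble(
    layer = vapply(x$layers, function(l) l$id, ""),
    kind = vapply(x$layers, function(l) l$kind, ""),
    side = vapply(x$layers, function(l) l$side_out, 1L),
    channels = vapply(x$layers, function(l) l$channels_out, 1L),
    trainable = vapply(x$layers, function(l) {
      if (l$kind == "conv") {
        l$k^3 * l$channels_in * l$channels_out + l$channels_out
      } else if (l$kind == "bn") 2 * l$channels_out else 0
    }, 1),
    non_trainable = vapply(x$layers, function(l) {
      if (l$kind == "bn") 2 * l$channels_out else 0
    }, 1),
    block = vapply(x$layers, function(l) l$block, ""),
    block_kind = vapply(x$layers, function(l) l$block_kind, "")
  )
}

#' One-row accounting summary of a network graph
#' @param x An `nn_graph`.
#' @param ... Unused.
#' @return Tibble: layers, trainable, non_trainable, block census columns.
#' @export
glance.nn_graph <- function(x, ...) {
  cp <- count_parameters(x)
  bc <- block_census(x)
  tibble::tibble(
    layers = cp$layers, trainable = cp$trainable,
    non_trainable = cp$non_trainable,
    conv_blocks = bc[["convolution"]], identity_blocks = bc[["identity"]],
    upsampling_blocks = bc[["upsampling"]]
  )
}

# ---- training --------------------------------------------------------------

# After the final gradient step the exponential running moments still lag
# the fitted weights, so inference would disagree with the just-trained
# network. Re-estimate batch-norm statistics with one training-mode pass
# over the training inputs (mean of per-sample batch moments), the
# standard recalibration for short runs.
reestimate_bn_stats <- function(graph, params, xs) {
  bn_ids <- names(Filter(function(l) l$kind == "bn", graph$layers))
  acc <- list()
  for (x in xs) {
    fw <- nn_forward(graph, params, x, training = TRUE,
      update_running = FALSE)
    for (id in bn_ids) {
      ce <- fw$cache[[id]]
      if (is.null(acc[[id]])) {
        acc[[id]] <- list(mu = ce$mu, var = ce$var)
      } else {
        acc[[id]]$mu <- acc[[id]]$mu + ce$mu
        acc[[id]]$var <- acc[[id]]$var + ce$var
      }
    }
  }
  for (id in bn_ids) {
    params[[id]]$rmean <- as.numeric(acc[[id]]$mu) / length(xs)
    params[[id]]$rvar <- as.numeric(acc[[id]]$var) / length(xs)
  }
  params
}

#' Training configuration
#'
#' Defaults follow the production optimization settings: Adam at learning
#' rate 1e-4 with L2 kernel regularization 1e-4, batch size 5, dice loss,
#' 4 folds for cross-validation splitting.
#'
#' @param learning_rate Adam learning rate.
#' @param l2 L2 kernel regularization weight.
#' @param batch_size Examples per gradient step.
#' @param folds Number of cross-validation folds.
#' @param loss `"dice"` or `"bce"`.
#' @param steps Gradient steps to run.
#' @param seed RNG seed for initialization.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, l2 = 1e-4, batch_size = 5L,
                         folds = 4L, loss = c("dice", "bce"), steps = 200L,
                         seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(learning_rate > 0, l2 >= 0, batch_size >= 1, folds >= 2,
    steps >= 0)
  structure(
    list(
      learning_rate = learning_rate, l2 = l2,
      batch_size = as.integer(batch_size), folds = as.integer(folds),
      loss = loss, steps = as.integer(steps), seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

as_grid_matrix <- function(grid, channels = 18L) {
  if (inherits(grid, "feature_grid")) grid <- grid$tensor
  side3 <- length(grid) / channels
  matrix(as.numeric(grid), nrow = side3, ncol = channels)
}

as_mask_vector <- function(mask) {
  if (inherits(mask, "site_mask")) mask <- mask$tensor
  as.numeric(mask)
}

loss_and_grad <- function(pred, mask, loss) {
  if (loss == "dice") {
    list(loss = dice_loss(pred, mask), grad = dice_loss_grad(pred, mask))
  } else {
    p <- pmin(pmax(as.numeric(pred), 1e-7), 1 - 1e-7)
    m <- as.numeric(mask)
    n <- length(p)
    list(
      loss = -mean(m * log(p) + (1 - m) * log(1 - p)),
      grad = (-m / p + (1 - m) / (1 - p)) / n
    )
  }
}

#' Train a network on (feature grid, site mask) pairs
#'
#' Scaled-down training loop: full-batch or mini-batch Adam with L2 weight
#' decay on the dice (or binary cross-entropy) loss. Deterministic given
#' `config$seed`. Intended for fixture-scale experiments — overfitting one
#' synthetic example, loss-function comparisons, ablations — not for
#' production-scale training.
#'
#' @param graph An `nn_graph`.
#' @param dataset List of `list(grid = , mask = )` pairs.
#' @param config A [train_config()].
#' @return A `puresnet_fit`: graph, trained params, loss trace tibble,
#'   config.
#' @export
train_scaled <- function(graph, dataset, config = train_config()) {
  if (length(dataset) == 0) {
    abort("dataset is empty", class = "pocketgrid_domain_error")
  }
  params <- init_parameters(graph, seed = config$seed)
  state <- adam_state()
  xs <- lapply(dataset, function(d) as_grid_matrix(d$grid))
  ys <- lapply(dataset, function(d) as_mask_vector(d$mask))
  static_envs <- lapply(dataset, function(d) new.env(parent = emptyenv()))
  trace <- numeric(config$steps)
  idx <- 0L
  for (step in seq_len(config$steps)) {
    agg <- NULL
    total_loss <- 0
    nb <- min(config$batch_size, length(dataset))
    for (bi in seq_len(nb)) {
      idx <- (idx %% length(dataset)) + 1L
      fw <- nn_forward(graph, params, xs[[idx]], training = TRUE,
        static_cols = static_envs[[idx]])
      params <- fw$params
      lg <- loss_and_grad(fw$output, ys[[idx]], config$loss)
      total_loss <- total_loss + lg$loss
      gr <- nn_backward(graph, params, fw$cache,
        matrix(lg$grad, ncol = 1) / nb)
      if (is.null(agg)) {
        agg <- gr
      } else {
        for (lid in names(gr)) {
          for (pn in names(gr[[lid]])) {
            agg[[lid]][[pn]] <- agg[[lid]][[pn]] + gr[[lid]][[pn]]
          }
        }
      }
    }
    loss <- total_loss / nb
    if (!is.finite(loss)) {
      abort(
        paste0("training diverged (non-finite loss) at step ", step),
        class = "pocketgrid_divergence_error",
        trace = trace[seq_len(step - 1)]
      )
    }
    params <- adam_step(params, agg, state, config$learning_rate, config$l2)
    trace[step] <- loss
  }
  params <- reestimate_bn_stats(graph, params, xs)
  structure(
    list(
      graph = graph, params = params,
      trace = tibble::tibble(step = seq_len(config$steps), loss = trace),
      config = config
    ),
    class = "puresnet_fit"
  )
}

#' Predict the voxel probability grid for one feature grid
#'
#' Runs the network in inference mode (batch-norm running statistics) and
#' returns the per-voxel site probability.
#'
#' @param object A `puresnet_fit` from [train_scaled()].
#' @param grid A `feature_grid` (or side^3 x 18 matrix).
#' @param use_batch_stats Use the per-call batch statistics instead of the
#'   running moments (matches training-time behavior; useful when the fit
#'   has seen few updates).
#' @param ... Unused.
#' @return Numeric array side^3 of probabilities in (0, 1).
#' @export
predict.puresnet_fit <- function(object, grid, use_batch_stats = FALSE,
                                 ...) {
  X <- as_grid_matrix(grid)
  fw <- nn_forward(object$graph, object$params, X,
    training = use_batch_stats, update_running = FALSE)
  side <- round(nrow(X)^(1 / 3))
  array(fw$output, dim = c(side, side, side))
}

#' @export
print.puresnet_fit <- function(x, ...) {
  cat(sprintf(
    "<puresnet_fit> %d steps, final %s loss %.4f\n",
    nrow(x$trace), x$config$loss, utils::tail(x$trace$loss, 1)
  ))
  invisible(x)
}

#' Loss trace of a fit
#' @param x A `puresnet_fit`.
#' @param ... Unused.
#' @return Tibble with step and loss.
#' @export
tidy.puresnet_fit <- function(x, ...) x$trace

#' One-row summary of a fit
#' @param x A `puresnet_fit`.
#' @param ... Unused.
#' @return Tibble: steps, final loss, loss kind, learning rate.
#' @export
glance.puresnet_fit <- function(x, ...) {
  tibble::tibble(
    steps = nrow(x$trace),
    final_loss = utils::tail(x$trace$loss, 1),
    loss = x$config$loss,
    learning_rate = x$config$learning_rate
  )
}

#' Group-aware K-fold assignment
#'
#' Assigns groups (for example protein families) to folds so that all
#' members of one group land in the same fold — the split that avoids
#' leaking near-identical structures between training and validation.
#' Groups are dealt to folds in random order, always to the currently
#' smallest fold.
#'
#' @param groups Character/factor vector, one entry per observation.
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return Integer fold id (1..k) per observation.
#' @export
grouped_kfold <- function(groups, k = 4L, seed = 1L) {
  stopifnot(k >= 2)
  set.seed(seed)
  tab <- sort(table(groups), decreasing = TRUE)
  ids <- names(tab)
  ids <- ids[order(-as.integer(tab), stats::runif(length(tab)))]
  fold_of <- setNames(integer(length(ids)), ids)
  sizes <- integer(k)
  for (g in ids) {
    f <- which.min(sizes)
    fold_of[g] <- f
    sizes[f] <- sizes[f] + tab[[g]]
  }
  unname(fold_of[as.character(groups)])
}
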