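# Minimal deterministic deep-learning engine for volumetric segmentation:
# layer graph, forward/backward passes, and an Adam optimizer with L2
# weight decay. Activations are (side^3) x C matrices (voxel index
# column-major, x fastest), convolutions run through Rcpp/Armadillo.
#
# The graph is a DAG of named layers; each layer lists its input layer ids.
# Supported kinds: input, conv (kernel k, stride, optional baked
# activation), bn (spatial batch normalization), relu, add, upsample
# (nearest-neighbor to a target side), concat (channel-wise).

new_layer <- function(id, kind, inputs, side_in, side_out, channels_in,
                      channels_out, k = NA_integer_, stride = 1L,
                      activation = NA_character_, block = NA_character_,
                      block_kind = NA_character_) {
  list(
    id = id, kind = kind, inputs = inputs, side_in = side_in,
    side_out = side_out, channels_in = channels_in,
    channels_out = channels_out, k = k, stride = stride,
    activation = activation, block = block, block_kind = block_kind
  )
}

out_side_conv <- function(side, stride) as.integer(ceiling(side / stride))

# ---- graph assembly helper -------------------------------------------------

nn_graph_env <- function() {
  env <- new.env(parent = emptyenv())
  env$layers <- list()
  env
}

add_layer <- function(env, ...) {
  ly <- new_layer(...)
  if (ly$id %in% names(env$layers)) {
    abort(paste0("duplicate layer id: ", ly$id))
  }
  env$layers[[ly$id]] <- ly
  ly$id
}

finalize_graph <- function(env, input_id, output_id) {
  structure(
    list(layers = env$layers, input = input_id, output = output_id),
    class = "nn_graph"
  )
}

#' @export
print.nn_graph <- function(x, ...) {
  cp <- count_parameters(x)
  cat(sprintf(
    "<nn_graph> %d layers, %s trainable / %s non-trainable parameters\n",
    cp$layers, format(cp$trainable, big.mark = ","),
    format(cp$non_trainable, big.mark = ",")
  ))
  invisible(x)
}

# ---- parameter initialization ---------------------------------------------

glorot_uniform <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  runif(n, -lim, lim)
}

#' Initialize the trainable parameters of a network graph
#'
#' Convolution kernels use Glorot (variance-scaling) uniform initialization;
#' biases start at zero; batch-norm scale/shift at 1/0 with running moments
#' 0/1. Deterministic given the seed.
#'
#' @param graph An `nn_graph`.
#' @param seed Integer RNG seed.
#' @return Named list of per-layer parameter lists.
#' @export
init_parameters <- function(graph, seed = 1L) {
  set.seed(seed)
  params <- list()
  for (ly in graph$layers) {
    if (ly$kind == "conv") {
      nk <- ly$k^3 * ly$channels_in
      W <- matrix(
        glorot_uniform(nk, ly$k^3 * ly$channels_out, nk * ly$channels_out),
        nrow = nk, ncol = ly$channels_out
      )
      params[[ly$id]] <- list(W = W, b = numeric(ly$channels_out))
    } else if (ly$kind == "bn") {
      C <- ly$channels_out
      params[[ly$id]] <- list(
        gamma = rep(1, C), beta = numeric(C),
        rmean = numeric(C), rvar = rep(1, C)
      )
    }
  }
  params
}

#' Count trainable and non-trainable parameters and layers of a graph
#'
#' Every node in the graph (input, convolution, normalization, activation,
#' add, concatenate, up-sampling) counts as one layer. Convolutions carry
#' k^3 * c_in * c_out weights plus c_out biases; batch normalization
#' carries 2C trainable (scale, shift) and 2C non-trainable (running
#' moments) parameters.
#'
#' @param graph An `nn_graph`.
#' @return List with `trainable`, `non_trainable`, `layers`.
#' @export
count_parameters <- function(graph) {
  tr <- 0
  nt <- 0
  for (ly in graph$layers) {
    if (ly$kind == "conv") {
      tr <- tr + ly$k^3 * ly$channels_in * ly$channels_out + ly$channels_out
    } else if (ly$kind == "bn") {
      tr <- tr + 2 * ly$channels_out
      nt <- nt + 2 * ly$channels_out
    }
  }
  list(trainable = tr, non_trainable = nt, layers = length(graph$layers))
}

# ---- forward / backward ----------------------------------------------------

.nn_memo <- new.env(parent = emptyenv())

upsample_map <- function(side_in, side_out) {
  key <- paste0("um_", side_in, "_", side_out)
  if (!is.null(.nn_memo[[key]])) return(.nn_memo[[key]])
  m1 <- floor((0:(side_out - 1)) * side_in / side_out) + 1L
  grid <- expand.grid(x = m1, y = m1, z = m1)
  v <- as.integer(
    grid$x + (grid$y - 1L) * side_in + (grid$z - 1L) * side_in^2
  )
  .nn_memo[[key]] <- v
  v
}

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.9

# flat 1-based input indices sampled by a strided 1x1x1 convolution
stride_sel <- function(side, stride) {
  os <- out_side_conv(side, stride)
  o <- (0:(os - 1)) * stride
  grid <- expand.grid(x = o, y = o, z = o)
  as.integer(grid$x + grid$y * side + grid$z * side^2 + 1L)
}

nn_forward <- function(graph, params, X, training = FALSE,
                       update_running = training, static_cols = NULL) {
  cache <- new.env(parent = emptyenv())
  for (ly in graph$layers) {
    conv_cols <- NULL
    out <- switch(ly$kind,
      input = X,
      conv = {
        xin <- cache[[ly$inputs[1]]]$y
        p <- params[[ly$id]]
        if (ly$k == 1L) {
          if (ly$stride > 1L) {
            xin <- xin[stride_sel(ly$side_in, ly$stride), , drop = FALSE]
          }
          Z <- conv3d_fw_cols(xin, p$W, p$b)
        } else if (training) {
          from_input <- graph$layers[[ly$inputs[1]]]$kind == "input"
          if (from_input && !is.null(static_cols)) {
            if (is.null(static_cols[[ly$id]])) {
              static_cols[[ly$id]] <- im2col3d_r(xin, ly$side_in, ly$k,
                ly$stride)
            }
            conv_cols <- static_cols[[ly$id]]
          } else {
            conv_cols <- im2col3d_r(xin, ly$side_in, ly$k, ly$stride)
          }
          Z <- conv3d_fw_cols(conv_cols, p$W, p$b)
        } else {
          Z <- conv3d_fw(xin, ly$side_in, ly$k, ly$stride, p$W, p$b)
        }
        if (!is.na(ly$activation) && ly$activation == "sigmoid") {
          Z <- 1 / (1 + exp(-Z))
        }
        Z
      },
      bn = {
        x <- cache[[ly$inputs[1]]]$y
        p <- params[[ly$id]]
        if (training) {
          bnres <- bn_fw(x, p$gamma, p$beta, BN_EPS)
          bnres$y
        } else {
          invstd <- 1 / sqrt(p$rvar + BN_EPS)
          xhat <- sweep(sweep(x, 2, p$rmean), 2, invstd, "*")
          sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
        }
      },
      relu = pmax(cache[[ly$inputs[1]]]$y, 0),
      sigmoid = 1 / (1 + exp(-cache[[ly$inputs[1]]]$y)),
      add = if (length(ly$inputs) == 2) {
        cache[[ly$inputs[1]]]$y + cache[[ly$inputs[2]]]$y
      } else {
        cache[[ly$inputs[1]]]$y  # ablated shortcut: pass-through
      },
      concat = cbind(cache[[ly$inputs[1]]]$y, cache[[ly$inputs[2]]]$y),
      upsample = {
        m <- upsample_map(ly$side_in, ly$side_out)
        cache[[ly$inputs[1]]]$y[m, , drop = FALSE]
      },
      abort(paste0("unknown layer kind: ", ly$kind))
    )
    entry <- list(y = out)
    if (!is.null(conv_cols)) entry$cols <- conv_cols
    if (ly$kind == "bn" && training) {
      entry$mu <- bnres$mu
      entry$var <- bnres$var
      entry$xhat <- bnres$xhat
      if (update_running) {
        p <- params[[ly$id]]
        p$rmean <- BN_MOMENTUM * p$rmean + (1 - BN_MOMENTUM) * bnres$mu
        p$rvar <- BN_MOMENTUM * p$rvar + (1 - BN_MOMENTUM) * bnres$var
        params[[ly$id]] <- p
      }
    }
    cache[[ly$id]] <- entry
  }
  list(output = cache[[graph$output]]$y, cache = cache, params = params)
}

nn_backward <- function(graph, params, cache, d_out) {
  grads <- list()
  dx <- new.env(parent = emptyenv())
  dx[[graph$output]] <- d_out
  for (ly in rev(graph$layers)) {
    dy <- dx[[ly$id]]
    if (is.null(dy)) next
    if (ly$kind == "input") next
    ins <- ly$inputs
    if (ly$kind == "conv") {
      if (!is.na(ly$activation) && ly$activation == "sigmoid") {
        y <- cache[[ly$id]]$y
        dy <- dy * y * (1 - y)
      }
      p <- params[[ly$id]]
      if (ly$k == 1L) {
        xin <- cache[[ins[1]]]$y
        if (ly$stride > 1L) {
          sel <- stride_sel(ly$side_in, ly$stride)
          xs <- xin[sel, , drop = FALSE]
          grads[[ly$id]] <- list(
            W = crossprod(xs, dy), b = colSums(dy)
          )
          dprev <- matrix(0, nrow = nrow(xin), ncol = ncol(xin))
          dprev[sel, ] <- dy %*% t(p$W)
        } else {
          grads[[ly$id]] <- list(
            W = crossprod(xin, dy), b = colSums(dy)
          )
          dprev <- dy %*% t(p$W)
        }
      } else {
        ce <- cache[[ly$id]]
        from_input <- graph$layers[[ins[1]]]$kind == "input"
        if (!is.null(ce$cols)) {
          if (from_input) {
            # no gradient flows into the data tensor
            grads[[ly$id]] <- list(
              W = crossprod(ce$cols, dy), b = colSums(dy)
            )
            dprev <- NULL
          } else {
            bw <- conv3d_bw_cols(ce$cols, ly$side_in, ly$k, ly$stride,
              p$W, dy, ly$channels_in)
            grads[[ly$id]] <- list(W = bw$dW, b = as.numeric(bw$db))
            dprev <- bw$dX
          }
        } else {
          bw <- conv3d_bw(cache[[ins[1]]]$y, ly$side_in, ly$k, ly$stride,
            p$W, dy)
          grads[[ly$id]] <- list(W = bw$dW, b = as.numeric(bw$db))
          dprev <- bw$dX
        }
      }
    } else if (ly$kind == "bn") {
      p <- params[[ly$id]]
      ce <- cache[[ly$id]]
      bw <- bn_bw(ce$xhat, ce$var, p$gamma, dy, BN_EPS)
      grads[[ly$id]] <- list(
        gamma = as.numeric(bw$dgamma), beta = as.numeric(bw$dbeta)
      )
      dprev <- bw$dX
    } else if (ly$kind == "relu") {
      dprev <- dy * (cache[[ly$id]]$y > 0)
    } else if (ly$kind == "sigmoid") {
      y <- cache[[ly$id]]$y
      dprev <- dy * y * (1 - y)
    } else if (ly$kind == "add") {
      dprev <- dy
    } else if (ly$kind == "concat") {
      c1 <- ncol(cache[[ins[1]]]$y)
      d1 <- dy[, seq_len(c1), drop = FALSE]
      d2 <- dy[, -seq_len(c1), drop = FALSE]
      acc_grad(dx, ins[1], d1)
      acc_grad(dx, ins[2], d2)
      dprev <- NULL
    } else if (ly$kind == "upsample") {
      m <- upsample_map(ly$side_in, ly$side_out)
      dprev <- matrix(0, nrow = ly$side_in^3, ncol = ncol(dy))
      for (ch in seq_len(ncol(dy))) {
        s <- rowsum(dy[, ch], group = m)
        dprev[as.integer(rownames(s)), ch] <- s[, 1]
      }
    } else {
      abort(paste0("no backward rule for layer kind: ", ly$kind))
    }
    if (ly$kind == "add") {
      acc_grad(dx, ins[1], dy)
      if (length(ins) == 2) acc_grad(dx, ins[2], dy)
    } else if (!is.null(dprev)) {
      acc_grad(dx, ins[1], dprev)
    }
    rm(list = ly$id, envir = dx)
  }
  grads
}

acc_grad <- function(env, id, g) {
  if (is.null(env[[id]])) env[[id]] <- g else env[[id]] <- env[[id]] + g
}

# ---- loss ------------------------------------------------------------------

#' Soft dice loss for binary volumetric segmentation
#'
#' `1 - (2 * sum(pred * mask) + smooth) / (sum(pred) + sum(mask) + smooth)`.
#' With heavily imbalanced voxel labels (occupied binding-site voxels are
#' ~0.1% of the grid) this loss weighs the positive class by overlap rather
#' than by voxel count, which is why it is preferred over plain binary
#' cross-entropy here.
#'
#' @param pred Numeric array/vector of probabilities in \[0, 1\].
#' @param mask Binary array/vector of the same length (or a `site_mask`).
#' @param smooth Smoothing constant (default 1).
#' @return Loss value in \[0, 1 + smooth-term epsilon).
#' @export
dice_loss <- function(pred, mask, smooth = 1) {
  if (inherits(mask, "site_mask")) mask <- mask$tensor
  if (length(pred) != length(mask)) {
    abort("pred and mask shapes differ", class = "pocketgrid_domain_error")
  }
  p <- as.numeric(pred)
  m <- as.numeric(mask)
  1 - (2 * sum(p * m) + smooth) / (sum(p) + sum(m) + smooth)
}

dice_loss_grad <- function(pred, mask, smooth = 1) {
  p <- as.numeric(pred)
  m <- as.numeric(mask)
  num <- 2 * sum(p * m) + smooth
  den <- sum(p) + sum(m) + smooth
  (num / den^2) - (2 * m / den)
}

# ---- optimizer -------------------------------------------------------------

adam_state <- function() new.env(parent = emptyenv())

adam_step <- function(params, grads, state, lr, l2 = 0, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  if (is.null(state$t)) state$t <- 0
  state$t <- state$t + 1
  t <- state$t
  for (lid in names(grads)) {
    for (pname in names(grads[[lid]])) {
      key <- paste0(lid, ".", pname)
      g <- grads[[lid]][[pname]]
      w <- params[[lid]][[pname]]
      if (l2 > 0 && pname == "W") g <- g + 2 * l2 * w
      if (is.null(state[[key]])) {
        state[[key]] <- list(m = g * 0, v = g * 0)
      }
      s <- state[[key]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      state[[key]] <- s
      mhat <- s$m / (1 - beta1^t)
      vhat <- s$v / (1 - beta2^t)
      params[[lid]][[pname]] <- w - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  params
}
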