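#' Configuration of the learned reconstructor
#'
#' A residual-in-residual channel-attention network (RCAN-style) that maps
#' the nine raw SIM frames directly to a super-resolved image on the doubled
#' grid, with no knowledge of the pattern parameters.  `desk_preset()` is a
#' compact variant trainable on a CPU in minutes; `paper_preset()` builds the
#' full-scale variant (~100 convolutional layers, reported by
#' [conv_layer_count()]) for completeness.
#'
#' @param n_groups Number of residual groups.
#' @param n_blocks_per_group Residual channel-attention blocks per group.
#' @param n_features Feature channels.
#' @param attention_reduction Squeeze factor of the channel attention.
#' @return Object of class `network_config`.
#' @export
network_config <- function(n_groups = 2, n_blocks_per_group = 2,
                           n_features = 16, attention_reduction = 4) {
  stopifnot(n_groups >= 1, n_blocks_per_group >= 1, n_features >= 1,
            attention_reduction >= 1, n_features %% attention_reduction == 0)
  structure(list(n_groups = as.integer(n_groups),
                 n_blocks_per_group = as.integer(n_blocks_per_group),
                 n_features = as.integer(n_features),
                 attention_reduction = as.integer(attention_reduction),
                 input_frames = 9L, output_scale = 2L),
            class = "network_config")
}

#' @rdname network_config
#' @export
desk_preset <- function() network_config(2, 2, 16, 4)

#' @rdname network_config
#' @export
paper_preset <- function() network_config(7, 3, 64, 16)

#' Number of convolutional layers of a configuration
#'
#' Counts the 3x3 convolutions plus the two 1x1 (dense-over-channels)
#' convolutions inside each channel-attention unit:
#' `3 + n_groups * (4 * n_blocks_per_group + 1)`.
#' @param config A [network_config()].
#' @export
conv_layer_count <- function(config) {
  3L + config$n_groups * (4L * config$n_blocks_per_group + 1L)
}

he_init <- function(dims, fan_in) array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)

#' Build an untrained network
#'
#' @param config A [network_config()].
#' @param seed Seed for the weight initialization.
#' @return Object of class `ml_model`: `params` (named list of arrays),
#'   `config`, `norm` (normalization spec filled in by [train_network()]).
#' @export
build_network <- function(config, seed = 1) {
  stopifnot(inherits(config, "network_config"))
  FF <- config$n_features
  Cr <- FF %/% config$attention_reduction
  params <- with_seed(seed, {
    p <- list()
    p[["head.W"]] <- he_init(c(3, 3, 9, FF), 9 * 9)
    p[["head.b"]] <- numeric(FF)
    for (g in seq_len(config$n_groups)) {
      for (b in seq_len(config$n_blocks_per_group)) {
        nb <- sprintf("g%d.b%d", g, b)
        p[[paste0(nb, ".c1.W")]] <- he_init(c(3, 3, FF, FF), 9 * FF)
        p[[paste0(nb, ".c1.b")]] <- numeric(FF)
        p[[paste0(nb, ".c2.W")]] <- he_init(c(3, 3, FF, FF), 9 * FF) * 0.1
        p[[paste0(nb, ".c2.b")]] <- numeric(FF)
        p[[paste0(nb, ".ca.W1")]] <- he_init(c(Cr, FF), FF)
        p[[paste0(nb, ".ca.b1")]] <- numeric(Cr)
        p[[paste0(nb, ".ca.W2")]] <- he_init(c(FF, Cr), Cr)
        p[[paste0(nb, ".ca.b2")]] <- numeric(FF)
      }
      p[[sprintf("g%d.tail.W", g)]] <- he_init(c(3, 3, FF, FF), 9 * FF) * 0.1
      p[[sprintf("g%d.tail.b", g)]] <- numeric(FF)
    }
    p[["body.W"]] <- he_init(c(3, 3, FF, FF), 9 * FF) * 0.1
    p[["body.b"]] <- numeric(FF)
    p[["up.W"]] <- he_init(c(3, 3, FF, 4), 9 * FF)
    p[["up.b"]] <- numeric(4)
    p
  })
  structure(list(params = params, config = config, norm = NULL),
            class = "ml_model")
}

#' @export
print.ml_model <- function(x, ...) {
  cat(sprintf("ml_model: %d groups x %d blocks x %d features (%d conv layers)%s\n",
              x$config$n_groups, x$config$n_blocks_per_group,
              x$config$n_features, conv_layer_count(x$config),
              if (is.null(x$norm)) ", untrained" else ""))
  invisible(x)
}

forward_net <- function(params, config, x) {
  cache <- list()
  h <- conv_fwd(x, params[["head.W"]], params[["head.b"]])
  cache$head <- h
  a <- h$y
  for (g in seq_len(config$n_groups)) {
    gin <- a
    for (b in seq_len(config$n_blocks_per_group)) {
      nb <- sprintf("g%d.b%d", g, b)
      bin <- a
      c1 <- conv_fwd(a, params[[paste0(nb, ".c1.W")]], params[[paste0(nb, ".c1.b")]])
      r1 <- relu_fwd(c1$y)
      c2 <- conv_fwd(r1$y, params[[paste0(nb, ".c2.W")]], params[[paste0(nb, ".c2.b")]])
      ca <- ca_fwd(c2$y, params[[paste0(nb, ".ca.W1")]], params[[paste0(nb, ".ca.b1")]],
                   params[[paste0(nb, ".ca.W2")]], params[[paste0(nb, ".ca.b2")]])
      a <- bin + ca$y
      cache[[nb]] <- list(c1 = c1, r1 = r1, c2 = c2, ca = ca)
    }
    gt <- conv_fwd(a, params[[sprintf("g%d.tail.W", g)]], params[[sprintf("g%d.tail.b", g)]])
    cache[[sprintf("g%d.tail", g)]] <- gt
    a <- gin + gt$y
  }
  bt <- conv_fwd(a, params[["body.W"]], params[["body.b"]])
  cache$body <- bt
  body_out <- h$y + bt$y
  up <- conv_fwd(body_out, params[["up.W"]], params[["up.b"]])
  cache$up <- up
  y <- shuffle_fwd(up$y)
  # fixed residual skip: bilinearly upsampled mean of the nine input frames
  d <- dim(x)
  for (bb in seq_len(d[4])) {
    wf <- matrix(0, d[1], d[2])
    for (cc in seq_len(d[3])) wf <- wf + x[, , cc, bb]
    y[, , 1, bb] <- y[, , 1, bb] + bilinear2x(wf / d[3])
  }
  list(y = y, cache = cache)
}

backward_net <- function(params, config, cache, dy) {
  grads <- list()
  dup <- shuffle_bwd(dy)
  gb <- conv_bwd(dup, cache$up, params[["up.W"]])
  grads[["up.W"]] <- gb$dW; grads[["up.b"]] <- gb$db
  dbody_out <- gb$dx
  dhead_skip <- dbody_out                       # global residual to head output
  gb <- conv_bwd(dbody_out, cache$body, params[["body.W"]])
  grads[["body.W"]] <- gb$dW; grads[["body.b"]] <- gb$db
  da <- gb$dx
  for (g in rev(seq_len(config$n_groups))) {
    dgin <- da                                  # group residual
    gt <- cache[[sprintf("g%d.tail", g)]]
    gb <- conv_bwd(da, gt, params[[sprintf("g%d.tail.W", g)]])
    grads[[sprintf("g%d.tail.W", g)]] <- gb$dW
    grads[[sprintf("g%d.tail.b", g)]] <- gb$db
    da <- gb$dx
    for (b in rev(seq_len(config$n_blocks_per_group))) {
      nb <- sprintf("g%d.b%d", g, b)
      cc <- cache[[nb]]
      dbin <- da                                # block residual
      cb <- ca_bwd(da, cc$ca, params[[paste0(nb, ".ca.W1")]], params[[paste0(nb, ".ca.W2")]])
      grads[[paste0(nb, ".ca.W1")]] <- cb$dW1; grads[[paste0(nb, ".ca.b1")]] <- cb$db1
      grads[[paste0(nb, ".ca.W2")]] <- cb$dW2; grads[[paste0(nb, ".ca.b2")]] <- cb$db2
      gb <- conv_bwd(cb$dx, cc$c2, params[[paste0(nb, ".c2.W")]])
      grads[[paste0(nb, ".c2.W")]] <- gb$dW; grads[[paste0(nb, ".c2.b")]] <- gb$db
      dr <- relu_bwd(gb$dx, cc$r1)
      gb <- conv_bwd(dr, cc$c1, params[[paste0(nb, ".c1.W")]])
      grads[[paste0(nb, ".c1.W")]] <- gb$dW; grads[[paste0(nb, ".c1.b")]] <- gb$db
      da <- dbin + gb$dx
    }
    da <- da + dgin
  }
  da <- da + dhead_skip
  gb <- conv_bwd(da, cache$head, params[["head.W"]])
  grads[["head.W"]] <- gb$dW; grads[["head.b"]] <- gb$db
  grads
}

#' Per-stack percentile normalization of a 9-frame array
#' @param frames `N x N x 9` array.
#' @param lo,hi Percentiles.
#' @return Normalized array with attributes `lo`, `hi`.
#' @export
normalize_stack <- function(frames, lo = 0.01, hi = 0.999) {
  q <- stats::quantile(frames, c(lo, hi), names = FALSE)
  if (q[2] <= q[1]) q[2] <- q[1] + 1
  out <- pmax((frames - q[1]) / (q[2] - q[1]), 0)
  attr(out, "lo") <- q[1]; attr(out, "hi") <- q[2]
  out
}

#' Train the network on simulated examples
#'
#' Minimizes pixel mean-squared error between the network output and the
#' (peak-normalized) ground truth with Adam.  Inputs are per-stack
#' percentile-normalized; both normalizations are recorded in the returned
#' model.  Deterministic given `seed`.
#'
#' @param model An untrained or previously trained [build_network()] model.
#' @param examples List from [generate_training_set()].
#' @param steps Optimizer steps.
#' @param batch_size Examples per step.
#' @param lr Learning rate.
#' @param patch_px Camera-grid patch side; `NULL` uses the full frames.
#' @param seed RNG seed for batching and cropping.
#' @return Object of class `train_state`: `model` (with updated params and
#'   norm spec), `loss` (per-step history), `steps`, `seed`.
#' @export
train_network <- function(model, examples, steps = 200, batch_size = 4,
                          lr = 2e-3, patch_px = NULL, seed = 1) {
  stopifnot(inherits(model, "ml_model"), length(examples) >= 1)
  xs <- lapply(examples, function(e) normalize_stack(e$stack$frames[[1]]))
  # targets are affine-aligned to the normalized input intensity scale (via
  # the upsampled mean frame), so the network learns structure, not a
  # per-stack intensity regression
  ts <- lapply(seq_along(examples), function(i) {
    t <- unclass(examples[[i]]$truth)
    wf <- apply(xs[[i]], c(1, 2), mean)
    # flux matching: blurring preserves the mean, so the scale between truth
    # units and normalized input units is the ratio of the means
    a <- if (mean(t) > 0) mean(wf) / mean(t) else 1
    a * t
  })
  n_full <- dim(xs[[1]])[1]
  hp <- if (is.null(patch_px)) n_full else min(patch_px, n_full)
  params <- model$params
  state <- adam_init(params)
  loss_hist <- numeric(steps)
  diverged <- 0L
  with_seed(seed, {
    for (s in seq_len(steps)) {
      idx <- sample.int(length(xs), batch_size, replace = TRUE)
      xb <- array(0, c(hp, hp, 9, batch_size))
      tb <- array(0, c(2 * hp, 2 * hp, 1, batch_size))
      for (j in seq_along(idx)) {
        i0 <- if (hp < n_full) sample.int(n_full - hp + 1, 1) else 1L
        j0 <- if (hp < n_full) sample.int(n_full - hp + 1, 1) else 1L
        xj <- xs[[idx[j]]][i0:(i0 + hp - 1), j0:(j0 + hp - 1), ]
        tj <- ts[[idx[j]]][(2 * i0 - 1):(2 * (i0 + hp - 1)),
                           (2 * j0 - 1):(2 * (j0 + hp - 1))]
        # flip/transpose augmentation (a flipped SIM stack is a valid stack
        # with mirrored pattern orientations)
        if (stats::runif(1) < 0.5) { xj <- xj[hp:1, , ]; tj <- tj[nrow(tj):1, ] }
        if (stats::runif(1) < 0.5) { xj <- xj[, hp:1, ]; tj <- tj[, ncol(tj):1] }
        if (stats::runif(1) < 0.5) {
          xj <- aperm(xj, c(2, 1, 3)); tj <- t(tj)
        }
        xb[, , , j] <- xj
        tb[, , 1, j] <- tj
      }
      fw <- forward_net(params, model$config, xb)
      resid <- fw$y - tb
      # per-item standardization: equalizes the gradient contribution of
      # bright and dim examples
      for (j in seq_along(idx)) {
        sc <- stats::sd(tb[, , 1, j]) + 0.02
        resid[, , 1, j] <- resid[, , 1, j] / sc
      }
      loss_hist[s] <- mean(resid^2)
      if (s > 1 && is.finite(loss_hist[1]) && loss_hist[s] > 10 * loss_hist[1]) {
        diverged <- diverged + 1L
        if (diverged >= 100L)
          stop(sprintf("training diverged: loss %.3g vs initial %.3g at step %d",
                       loss_hist[s], loss_hist[1], s))
      } else diverged <- 0L
      grads <- backward_net(params, model$config, fw$cache,
                            2 * resid / length(resid))
      lr_s <- if (s > 0.6 * steps) lr / 2 else lr   # step decay
      upd <- adam_step(params, grads, state, lr_s)
      params <- upd$params
      state <- upd$state
    }
  })
  model$params <- params
  model$norm <- list(input = "per-stack quantile [0.01, 0.999]",
                     target = "peak-normalized")
  structure(list(model = model, loss = loss_hist, steps = steps, seed = seed),
            class = "train_state")
}

#' @export
print.train_state <- function(x, ...) {
  n <- length(x$loss)
  cat(sprintf("train_state: %d steps, loss %.4g -> %.4g (last-20 mean %.4g)\n",
              n, x$loss[1], x$loss[n], mean(utils::tail(x$loss, 20))))
  invisible(x)
}

#' Parameter-free reconstruction with the trained network
#'
#' @param model A trained `ml_model`.
#' @param stack A `sim_stack` (9 frames per channel).
#' @param channel Channel index.
#' @return A `sim_recon` (image on the doubled grid, clamped non-negative).
#' @export
infer_ml <- function(model, stack, channel = 1) {
  fr <- stack$frames[[channel]]
  if (length(dim(fr)) != 3 || dim(fr)[3] != 9)
    stop(sprintf("expected 9 frames, got %d", dim(fr)[3]))
  x <- array(normalize_stack(fr), c(dim(fr)[1], dim(fr)[2], 9, 1))
  y <- forward_net(model$params, model$config, x)$y
  img <- pmax(y[, , 1, 1], 0)
  structure(list(image = img, support = NULL,
                 pixel_nm = stack$config$pixel_nm / 2,
                 params = list(method = "ml")),
            class = "sim_recon")
}
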