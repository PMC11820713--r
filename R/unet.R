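# 1D U-net segmentation of the integrated spectrum into systole (0) and
# diastole (1), built on the package's own conv-net engine (nn.R).

#' U-net configuration
#'
#' Defaults reproduce the reference architecture: 1024-point single-channel
#' input, three encoder blocks of two `Conv1D(k=3, same)` + batch
#' normalisation + ReLU layers with filters (32, 64, 128) and 2x max
#' pooling, a 256-filter bottom block, a mirrored decoder with skip
#' concatenations, and a final 1-filter `Conv1D(k=1)` with sigmoid output.
#' Training uses Adam with MAE loss.
#'
#' @param input_length input points per segment; must be divisible by
#'   `pool_size^length(encoder_filters)`.
#' @param channels_in input channels.
#' @param encoder_filters filters per encoder block (decoder mirrors them).
#' @param bottom_filters filters in the bottom block.
#' @param kernel_size convolution kernel (fixed at 3).
#' @param pool_size pooling factor (fixed at 2).
#' @param convs_per_block convolutions per block (fixed at 2).
#' @param final_filters output channels.
#' @param learning_rate Adam learning rate.
#' @param batch_size,epochs training schedule.
#' @param seed integer seed for initialisation and batch shuffling.
#' @return an object of class `unet_config`.
#' @export
unet_config <- function(input_length = 1024L, channels_in = 1L,
                        encoder_filters = c(32L, 64L, 128L),
                        bottom_filters = 256L, kernel_size = 3L,
                        pool_size = 2L, convs_per_block = 2L,
                        final_filters = 1L, learning_rate = 0.001,
                        batch_size = 256L, epochs = 100L, seed = 1L) {
  depth <- length(encoder_filters)
  if (input_length %% (pool_size^depth) != 0L)
    stop("input_length must be divisible by pool_size^depth", call. = FALSE)
  if (kernel_size != 3L || pool_size != 2L || convs_per_block != 2L)
    stop("this engine implements kernel 3, pool 2, two convs per block",
         call. = FALSE)
  structure(list(input_length = as.integer(input_length),
                 channels_in = as.integer(channels_in),
                 encoder_filters = as.integer(encoder_filters),
                 bottom_filters = as.integer(bottom_filters),
                 kernel_size = 3L, pool_size = 2L, convs_per_block = 2L,
                 final_filters = as.integer(final_filters),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 seed = as.integer(seed)), class = "unet_config")
}

#' Scaled-down U-net configuration for cohort-sized experiments
#'
#' Quarter-width filters (8, 16, 32; bottom 64), 15 epochs, batch 8. The
#' architecture is otherwise identical to [unet_config()]; the reduced width
#' keeps multi-seed cohort experiments tractable on one CPU while leaving
#' ample capacity for the segmentation task.
#'
#' @param ... overrides passed to [unet_config()].
#' @return a `unet_config`.
#' @export
unet_config_scaled <- function(...) {
  args <- list(encoder_filters = c(8L, 16L, 32L), bottom_filters = 64L,
               epochs = 15L, batch_size = 8L)
  override <- list(...)
  args[names(override)] <- override
  do.call(unet_config, args)
}

# One conv3 + BN unit.
.unit_init <- function(cin, cout) {
  list(conv = nn_conv3_init(cin, cout), bn = nn_bn_init(cout))
}

#' Build an untrained U-net
#'
#' @param cfg a [unet_config()].
#' @return an object of class `radar_unet` (untrained; see [unet_fit()]).
#' @export
build_model <- function(cfg = unet_config()) {
  f <- cfg$encoder_filters
  depth <- length(f)
  params <- with_seed(cfg$seed, {
    enc <- list(); cin <- cfg$channels_in
    for (i in seq_len(depth)) {
      enc[[i]] <- list(.unit_init(cin, f[i]), .unit_init(f[i], f[i]))
      cin <- f[i]
    }
    bottom <- list(.unit_init(cin, cfg$bottom_filters),
                   .unit_init(cfg$bottom_filters, cfg$bottom_filters))
    dec <- list(); cin <- cfg$bottom_filters
    for (i in rev(seq_len(depth))) {
      dec[[depth - i + 1L]] <- list(.unit_init(cin + f[i], f[i]),
                                    .unit_init(f[i], f[i]))
      cin <- f[i]
    }
    final <- nn_conv1_init(cin, cfg$final_filters)
    list(enc = enc, bottom = bottom, dec = dec, final = final)
  })
  structure(list(cfg = cfg, params = params, trained = FALSE,
                 history = NULL), class = "radar_unet")
}

.unit_fwd <- function(X, unit, n, l, training) {
  cv <- nn_conv3_fwd(X, unit$conv, n, l)
  bn <- nn_bn_fwd(cv$out, unit$bn, training)
  rl <- nn_relu_fwd(bn$out)
  list(out = rl$out, unit = list(conv = unit$conv, bn = bn$par),
       cache = list(conv = cv$cache, bn = bn$cache, relu = rl$cache))
}

.unit_bwd <- function(dY, unit, cache) {
  d <- nn_relu_bwd(dY, cache$relu)
  bn <- nn_bn_bwd(d, unit$bn, cache$bn)
  cv <- nn_conv3_bwd(bn$dX, unit$conv, cache$conv)
  list(dX = cv$dX, grads = list(conv = cv$grads, bn = bn$grads))
}

# Full forward pass. x_batch: (N x input_length). Returns predictions
# (N x input_length), caches for backprop, possibly-updated params (BN
# running stats), and the per-block output shapes (length, channels).
.unet_forward <- function(params, cfg, x_batch, training) {
  n <- nrow(x_batch); L0 <- ncol(x_batch)
  depth <- length(cfg$encoder_filters)
  X <- matrix(as.vector(t(x_batch)), ncol = 1L)
  l <- L0
  caches <- list(enc = list(), bottom = NULL, dec = list())
  shapes <- list()
  skips <- list()
  for (i in seq_len(depth)) {
    cc <- list()
    for (u in 1:2) {
      r <- .unit_fwd(X, params$enc[[i]][[u]], n, l, training)
      X <- r$out; params$enc[[i]][[u]] <- r$unit; cc[[u]] <- r$cache
    }
    skips[[i]] <- X
    mp <- nn_maxpool2_fwd(X)
    X <- mp$out; l <- l %/% 2L
    cc$pool <- mp$cache
    caches$enc[[i]] <- cc
    shapes[[length(shapes) + 1L]] <- c(l, ncol(X))
  }
  cc <- list()
  for (u in 1:2) {
    r <- .unit_fwd(X, params$bottom[[u]], n, l, training)
    X <- r$out; params$bottom[[u]] <- r$unit; cc[[u]] <- r$cache
  }
  caches$bottom <- cc
  shapes[[length(shapes) + 1L]] <- c(l, ncol(X))
  for (k in seq_len(depth)) {
    i <- depth - k + 1L                    # matching encoder block
    X <- nn_upsample2_fwd(X); l <- l * 2L
    skip_ch <- ncol(skips[[i]])
    X <- cbind(X, skips[[i]])
    cc <- list()
    for (u in 1:2) {
      r <- .unit_fwd(X, params$dec[[k]][[u]], n, l, training)
      X <- r$out; params$dec[[k]][[u]] <- r$unit; cc[[u]] <- r$cache
    }
    cc$skip_ch <- skip_ch
    caches$dec[[k]] <- cc
    shapes[[length(shapes) + 1L]] <- c(l, ncol(X))
  }
  fc <- nn_conv1_fwd(X, params$final)
  sg <- nn_sigmoid_fwd(fc$out)
  caches$final <- fc$cache
  caches$sigmoid <- sg$cache
  shapes[[length(shapes) + 1L]] <- c(l, ncol(sg$out))
  pred <- matrix(sg$out, nrow = n, byrow = TRUE)
  list(pred = pred, caches = caches, params = params, shapes = shapes)
}

.unet_backward <- function(params, cfg, caches, d_pred) {
  depth <- length(cfg$encoder_filters)
  dY <- matrix(as.vector(t(d_pred)), ncol = 1L)
  dY <- nn_sigmoid_bwd(dY, caches$sigmoid)
  fc <- nn_conv1_bwd(dY, params$final, caches$final)
  grads <- list(enc = vector("list", depth), bottom = NULL,
                dec = vector("list", depth), final = fc$grads)
  dX <- fc$dX
  for (k in rev(seq_len(depth))) {
    cc <- caches$dec[[k]]
    g <- list()
    for (u in 2:1) {
      r <- .unit_bwd(dX, params$dec[[k]][[u]], cc[[u]])
      dX <- r$dX; g[[u]] <- r$grads
    }
    grads$dec[[k]] <- g
    skip_ch <- cc$skip_ch
    main_ch <- ncol(dX) - skip_ch
    d_skip <- dX[, (main_ch + 1L):ncol(dX), drop = FALSE]
    dX <- nn_upsample2_bwd(dX[, seq_len(main_ch), drop = FALSE])
    # stash the skip gradient for the matching encoder block
    assign(paste0("dskip", depth - k + 1L), d_skip)
  }
  g <- list()
  for (u in 2:1) {
    r <- .unit_bwd(dX, params$bottom[[u]], caches$bottom[[u]])
    dX <- r$dX; g[[u]] <- r$grads
  }
  grads$bottom <- g
  for (i in rev(seq_len(depth))) {
    dX <- nn_maxpool2_bwd(dX, caches$enc[[i]]$pool)
    dX <- dX + get(paste0("dskip", i))
    g <- list()
    for (u in 2:1) {
      r <- .unit_bwd(dX, params$enc[[i]][[u]], caches$enc[[i]][[u]])
      dX <- r$dX; g[[u]] <- r$grads
    }
    grads$enc[[i]] <- g
  }
  grads
}

#' Per-block output shapes of a built U-net
#'
#' Runs a forward pass on a dummy input and reports the realised
#' `(length, channels)` of every encoder block (after pooling), the bottom
#' block, every decoder block and the final layer.
#'
#' @param model a `radar_unet`.
#' @return list of integer pairs `(length, channels)`.
#' @export
unet_shapes <- function(model) {
  x <- matrix(0, 1L, model$cfg$input_length)
  .unet_forward(model$params, model$cfg, x, training = FALSE)$shapes
}

#' Train a U-net on integrated-spectrum segments
#'
#' Adam optimisation of the mean-absolute-error loss between the sigmoid
#' output and the binary systole/diastole labels. Deterministic under the
#' config seed (initialisation and batch shuffling).
#'
#' @param x numeric matrix (segments x input_length) of normalised
#'   integrated-spectrum inputs.
#' @param y numeric matrix of matching binary label masks.
#' @param cfg a [unet_config()]; `cfg$epochs`, `cfg$batch_size` and
#'   `cfg$learning_rate` define the schedule.
#' @param model optionally, a pre-built `radar_unet` to continue training.
#' @param verbose print per-epoch loss.
#' @return a trained `radar_unet` with `history` (per-epoch MAE and MSE).
#' @export
unet_fit <- function(x, y, cfg = unet_config(), model = NULL,
                     verbose = FALSE) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (!is.matrix(y)) y <- matrix(y, nrow = 1L)
  if (!all(dim(x) == dim(y)) || ncol(x) != cfg$input_length)
    stop("inputs and masks must both be (segments x input_length)",
         call. = FALSE)
  if (is.null(model)) model <- build_model(cfg)
  params <- model$params
  mstate <- adam_init(params); vstate <- adam_init(params)
  n <- nrow(x)
  history <- data.frame(epoch = integer(0), mae = numeric(0), mse = numeric(0))
  step <- 0L
  with_seed(child_seed(cfg$seed, 3L), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_abs <- 0; ep_sq <- 0; ep_n <- 0
      for (b0 in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[b0:min(n, b0 + cfg$batch_size - 1L)]
        xb <- x[idx, , drop = FALSE]; yb <- y[idx, , drop = FALSE]
        fw <- .unet_forward(params, cfg, xb, training = TRUE)
        params <- fw$params
        err <- fw$pred - yb
        ep_abs <- ep_abs + sum(abs(err)); ep_sq <- ep_sq + sum(err^2)
        ep_n <- ep_n + length(err)
        d_pred <- sign(err) / length(err)
        grads <- .unet_backward(params, cfg, fw$caches, d_pred)
        step <- step + 1L
        upd <- adam_step(params, grads, mstate, vstate,
                         lr = cfg$learning_rate, t = step)
        params <- upd$p; mstate <- upd$m; vstate <- upd$v
      }
      history <- rbind(history, data.frame(epoch = ep, mae = ep_abs / ep_n,
                                           mse = ep_sq / ep_n))
      if (verbose)
        message(sprintf("epoch %d/%d  MAE %.4f", ep, cfg$epochs, ep_abs / ep_n))
    }
  })
  structure(list(cfg = cfg, params = params, trained = TRUE,
                 history = history), class = "radar_unet")
}

#' @export
print.radar_unet <- function(x, ...) {
  cat(sprintf("<radar_unet> depth %d, filters (%s; bottom %d), input %d%s\n",
              length(x$cfg$encoder_filters),
              paste(x$cfg$encoder_filters, collapse = ", "),
              x$cfg$bottom_filters, x$cfg$input_length,
              if (x$trained) sprintf(", trained %d epochs (final MAE %.4f)",
                                     nrow(x$history),
                                     x$history$mae[nrow(x$history)])
              else ", untrained"))
  invisible(x)
}

#' Predict segmentation masks
#'
#' @param object a trained `radar_unet`.
#' @param x input vector of length `input_length`, or a matrix of rows.
#' @param threshold binarisation threshold.
#' @param ... unused.
#' @return for a single input, a `segmentation_mask` (list with `values`,
#'   `binary`); for a matrix, a list of them.
#' @export
predict.radar_unet <- function(object, x, threshold = 0.5, ...) {
  single <- !is.matrix(x)
  if (single) x <- matrix(x, nrow = 1L)
  if (ncol(x) != object$cfg$input_length)
    stop("input length must equal cfg$input_length", call. = FALSE)
  preds <- matrix(NA_real_, nrow(x), ncol(x))
  for (b0 in seq(1L, nrow(x), by = 64L)) {   # bounded memory
    idx <- b0:min(nrow(x), b0 + 63L)
    preds[idx, ] <- .unet_forward(object$params, object$cfg,
                                  x[idx, , drop = FALSE],
                                  training = FALSE)$pred
  }
  preds[] <- pmin(1, pmax(0, as.vector(preds)))
  masks <- lapply(seq_len(nrow(preds)), function(i)
    structure(list(values = preds[i, ],
                   binary = as.integer(preds[i, ] >= threshold)),
              class = "segmentation_mask"))
  if (single) masks[[1L]] else masks
}

#' Binary systole/diastole labels for a window
#'
#' Label 0 inside `[r_peak, t_end)` (systole) and 1 from the T-wave end to
#' the next R peak (diastole); times before the first R peak inherit the
#' in-progress diastole.
#'
#' @param truth a `ground_truth`.
#' @param times_s label timestamps (seconds).
#' @return integer 0/1 vector, one label per timestamp.
#' @export
make_labels <- function(truth, times_s) {
  pb <- truth$per_beat
  if (nrow(pb) == 0L) stop("no beats in ground truth", call. = FALSE)
  bounds <- as.vector(rbind(pb$r_peak_s, pb$t_end_s))
  vals <- rep(c(0L, 1L), nrow(pb))
  idx <- findInterval(times_s, bounds)
  out <- ifelse(idx == 0L, 1L, vals[pmax(idx, 1L)])
  as.integer(out)
}

# Merge interior runs shorter than their phase-specific floor into their
# neighbours (physiological despeckling); the most-deficient run goes first,
# edge runs are exempt (censored anyway).
.despeckle <- function(binary, min0, min1) {
  repeat {
    r <- rle(binary)
    if (length(r$lengths) <= 1L) return(binary)
    need <- ifelse(r$values == 0L, min0, min1)
    bad <- setdiff(which(r$lengths < need), c(1L, length(r$lengths)))
    if (!length(bad)) return(binary)
    k <- bad[which.min(r$lengths[bad] / need[bad])]
    r$values[k] <- 1L - r$values[k]
    binary <- inverse.rle(r)
  }
}

#' Convert a segmentation mask to beat annotations
#'
#' Each maximal interior 0-run is a systolic interval and the following
#' 1-run the matching diastolic interval; edge-censored runs are dropped.
#' Interior runs shorter than the resting-physiology floors (`min_sys_s` for
#' systole, `min_dia_s` for diastole) are merged into their neighbours first
#' — no resting systole is shorter than ~0.12 s and no diastole shorter than
#' ~0.2 s, so shorter runs are prediction speckle, the mask-domain analogue
#' of the HSMM's minimum dwell times.
#'
#' @param mask a `segmentation_mask`, or a numeric vector of mask values.
#' @param frame_rate_hz frames per second of the mask grid.
#' @param times_s optional timestamps (override `frame_rate_hz`).
#' @param threshold binarisation threshold for numeric input.
#' @param min_sys_s,min_dia_s phase-specific despeckling floors in seconds.
#' @return beat-annotation data.frame with `source = "unet"`.
#' @export
mask_to_beats <- function(mask, frame_rate_hz = NULL, times_s = NULL,
                          threshold = 0.5, min_sys_s = 0.12,
                          min_dia_s = 0.2) {
  binary <- if (inherits(mask, "segmentation_mask")) mask$binary
            else as.integer(mask >= threshold)
  if (is.null(times_s))
    times_s <- (seq_along(binary) - 1L) / frame_rate_hz
  if (length(unique(binary)) == 1L) {
    warning("constant mask: no beats")
    return(empty_beats("unet"))
  }
  rate <- 1 / stats::median(diff(times_s))
  binary <- .despeckle(binary, max(1L, round(min_sys_s * rate)),
                       max(1L, round(min_dia_s * rate)))
  r <- rle(binary)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  m <- length(r$lengths)
  beats <- empty_beats("unet")
  for (j in seq_len(m)) {
    if (r$values[j] != 0L || j <= 1L || j + 2L > m) next
    if (r$values[j + 1L] != 1L) next
    t0 <- times_s[starts[j]]
    t1 <- times_s[starts[j + 1L]]
    t2 <- times_s[starts[j + 2L]]
    beats <- rbind(beats, data.frame(
      beat = nrow(beats) + 1L, sys_onset_s = t0, dia_onset_s = t1,
      next_sys_onset_s = t2, systolic_s = t1 - t0, diastolic_s = t2 - t1,
      ibi_s = t2 - t0, source = "unet"))
  }
  beats
}
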