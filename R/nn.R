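# Minimal 1D convolutional network engine on BLAS matrix products.
# Activations are stored as (N*L) x C matrices, rows ordered sample-major
# (sample 1 positions 1..L, then sample 2, ...). All layers provide a
# forward returning (output, cache) and a backward returning input/parameter
# gradients; optimisation is Adam.

# Row indices of the first / last position of every sample.
.edge_rows <- function(n, l) {
  list(first = seq(1L, n * l, by = l), last = seq(l, n * l, by = l))
}

.rep_row <- function(v, m) matrix(v, m, length(v), byrow = TRUE)

# -- convolution, kernel 3, "same" padding ---------------------------------

nn_conv3_init <- function(cin, cout) {
  list(W = matrix(stats::rnorm(3 * cin * cout, sd = sqrt(2 / (3 * cin))),
                  3 * cin, cout),
       b = numeric(cout))
}

nn_conv3_fwd <- function(X, par, n, l) {
  e <- .edge_rows(n, l)
  nl <- nrow(X)
  Xm <- rbind(0, X[-nl, , drop = FALSE]); Xm[e$first, ] <- 0
  Xp <- rbind(X[-1L, , drop = FALSE], 0); Xp[e$last, ] <- 0
  Xc <- cbind(Xm, X, Xp)
  Y <- Xc %*% par$W
  Y <- Y + .rep_row(par$b, nl)
  list(out = Y, cache = list(Xc = Xc, n = n, l = l))
}

nn_conv3_bwd <- function(dY, par, cache) {
  cin <- ncol(cache$Xc) / 3L
  dW <- crossprod(cache$Xc, dY)
  db <- colSums(dY)
  dXc <- dY %*% t(par$W)
  e <- .edge_rows(cache$n, cache$l)
  nl <- nrow(dY)
  dXm <- dXc[, 1:cin, drop = FALSE]; dXm[e$first, ] <- 0
  dXp <- dXc[, (2L * cin + 1L):(3L * cin), drop = FALSE]; dXp[e$last, ] <- 0
  dX <- dXc[, (cin + 1L):(2L * cin), drop = FALSE] +
    rbind(dXm[-1L, , drop = FALSE], 0) +
    rbind(0, dXp[-nl, , drop = FALSE])
  list(dX = dX, grads = list(W = dW, b = db))
}

# -- convolution, kernel 1 --------------------------------------------------

nn_conv1_init <- function(cin, cout) {
  list(W = matrix(stats::rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout),
       b = numeric(cout))
}

nn_conv1_fwd <- function(X, par) {
  Y <- X %*% par$W + .rep_row(par$b, nrow(X))
  list(out = Y, cache = list(X = X))
}

nn_conv1_bwd <- function(dY, par, cache) {
  list(dX = dY %*% t(par$W),
       grads = list(W = crossprod(cache$X, dY), b = colSums(dY)))
}

# -- batch normalisation ----------------------------------------------------

nn_bn_init <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c))
}

nn_bn_fwd <- function(X, par, training, momentum = 0.1, eps = 1e-5) {
  m <- nrow(X)
  if (training) {
    mu <- colMeans(X)
    v <- pmax(0, colMeans(X^2) - mu^2)
    par$run_mean <- (1 - momentum) * par$run_mean + momentum * mu
    par$run_var <- (1 - momentum) * par$run_var + momentum * v
  } else {
    mu <- par$run_mean; v <- par$run_var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (X - .rep_row(mu, m)) * .rep_row(invstd, m)
  Y <- xhat * .rep_row(par$gamma, m) + .rep_row(par$beta, m)
  list(out = Y, cache = list(xhat = xhat, invstd = invstd), par = par)
}

nn_bn_bwd <- function(dY, par, cache) {
  m <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dX <- (dY - .rep_row(dbeta / m, m) - cache$xhat * .rep_row(dgamma / m, m)) *
    .rep_row(par$gamma * cache$invstd, m)
  # gradient tree mirrors the parameter tree exactly (the optimiser walks
  # both positionally); running stats carry zero gradient
  list(dX = dX, grads = list(gamma = dgamma, beta = dbeta,
                             run_mean = numeric(length(dbeta)),
                             run_var = numeric(length(dbeta))))
}

# -- activations, pooling, upsampling --------------------------------------

nn_relu_fwd <- function(X) {
  mask <- X > 0
  list(out = X * mask, cache = mask)
}
nn_relu_bwd <- function(dY, mask) dY * mask

nn_sigmoid_fwd <- function(X) {
  Y <- 1 / (1 + exp(-X))
  list(out = Y, cache = Y)
}
nn_sigmoid_bwd <- function(dY, Y) dY * Y * (1 - Y)

nn_maxpool2_fwd <- function(X) {
  nl <- nrow(X)
  odd <- seq(1L, nl, by = 2L)
  A <- X[odd, , drop = FALSE]
  B <- X[odd + 1L, , drop = FALSE]
  mask <- A >= B
  list(out = pmax(A, B), cache = mask)
}

nn_maxpool2_bwd <- function(dY, mask) {
  nl2 <- nrow(dY)
  dX <- matrix(0, 2L * nl2, ncol(dY))
  odd <- seq(1L, 2L * nl2, by = 2L)
  dX[odd, ] <- dY * mask
  dX[odd + 1L, ] <- dY * (!mask)
  dX
}

nn_upsample2_fwd <- function(X) {
  X[rep(seq_len(nrow(X)), each = 2L), , drop = FALSE]
}

nn_upsample2_bwd <- function(dY) {
  odd <- seq(1L, nrow(dY), by = 2L)
  dY[odd, , drop = FALSE] + dY[odd + 1L, , drop = FALSE]
}

# -- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  rapply(params, function(p) p * 0, how = "replace")
}

# params/grads/m/v share one nested structure; returns updated (params, m, v).
adam_step <- function(params, grads, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  walk <- function(p, g, mm, vv) {
    if (is.list(p)) {
      out <- Map(walk, p, g, mm, vv)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    mm <- beta1 * mm + (1 - beta1) * g
    vv <- beta2 * vv + (1 - beta2) * g^2
    mhat <- mm / (1 - beta1^t)
    vhat <- vv / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = mm, v = vv)
  }
  walk(params, grads, m, v)
}
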