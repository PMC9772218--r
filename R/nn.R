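# Minimal neural-network primitives used by the learned reconstructor.
# Tensors are arrays with dim (H, W, C, B).  Convolutions are 3x3,
# same-padding, implemented as im2col + one BLAS matrix multiply; the
# backward passes are exact (verified by a finite-difference test).

# im2col: padded input -> matrix with rows (i, j, b) and columns ordered
# di-fastest, then dj, then input channel, matching matrix(W, 9*Cin, Cout).
im2col3 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  P <- array(0, c(H + 2, W + 2, C, B))
  P[2:(H + 1), 2:(W + 1), , ] <- x
  X <- matrix(0, H * W * B, 9 * C)
  for (c in seq_len(C)) for (dj in 1:3) for (di in 1:3) {
    X[, (c - 1) * 9 + (dj - 1) * 3 + di] <-
      as.vector(P[di:(di + H - 1), dj:(dj + W - 1), c, ])
  }
  X
}

conv_fwd <- function(x, W, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; B <- d[4]
  Cout <- dim(W)[4]
  X <- im2col3(x)
  Y <- X %*% matrix(W, ncol = Cout)
  Y <- Y + matrix(b, nrow(Y), Cout, byrow = TRUE)
  y <- aperm(array(Y, c(H, Wd, B, Cout)), c(1, 2, 4, 3))
  list(y = y, X = X, dims = d)
}

conv_bwd <- function(dy, cache, W) {
  d <- cache$dims; H <- d[1]; Wd <- d[2]; C <- d[3]; B <- d[4]
  Cout <- dim(W)[4]
  dYmat <- matrix(aperm(dy, c(1, 2, 4, 3)), H * Wd * B, Cout)
  dWmat <- crossprod(cache$X, dYmat)
  db <- colSums(dYmat)
  dXmat <- tcrossprod(dYmat, matrix(W, ncol = Cout))
  dP <- array(0, c(H + 2, Wd + 2, C, B))
  for (c in seq_len(C)) for (dj in 1:3) for (di in 1:3) {
    dP[di:(di + H - 1), dj:(dj + Wd - 1), c, ] <-
      dP[di:(di + H - 1), dj:(dj + Wd - 1), c, ] +
      array(dXmat[, (c - 1) * 9 + (dj - 1) * 3 + di], c(H, Wd, B))
  }
  list(dx = dP[2:(H + 1), 2:(Wd + 1), , , drop = FALSE],
       dW = array(dWmat, dim(W)), db = db)
}

relu_fwd <- function(x) list(y = pmax(x, 0), mask = x > 0)
relu_bwd <- function(dy, cache) dy * cache$mask

sigmoid <- function(x) 1 / (1 + exp(-x))

# squeeze-and-excitation style channel attention
ca_fwd <- function(x, W1, b1, W2, b2) {
  d <- dim(x); HW <- d[1] * d[2]
  z <- matrix(colMeans(matrix(x, HW, d[3] * d[4])), d[3], d[4])
  d1 <- W1 %*% z + b1
  r1 <- pmax(d1, 0)
  d2 <- W2 %*% r1 + b2
  s <- sigmoid(d2)
  sf <- array(rep(s, each = HW), d)
  list(y = x * sf, x = x, z = z, d1 = d1, r1 = r1, s = s, sf = sf)
}

ca_bwd <- function(dy, cache, W1, W2) {
  d <- dim(cache$x); HW <- d[1] * d[2]
  ds <- matrix(colSums(matrix(dy * cache$x, HW, d[3] * d[4])), d[3], d[4])
  dx <- dy * cache$sf
  dd2 <- ds * cache$s * (1 - cache$s)
  dW2 <- tcrossprod(dd2, cache$r1)
  db2 <- rowSums(dd2)
  dr1 <- crossprod(W2, dd2)
  dd1 <- dr1 * (cache$d1 > 0)
  dW1 <- tcrossprod(dd1, cache$z)
  db1 <- rowSums(dd1)
  dz <- crossprod(W1, dd1)
  dx <- dx + array(rep(dz / HW, each = HW), d)
  list(dx = dx, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

# (H, W, 4, B) -> (2H, 2W, 1, B); channel c = 1 + dy + 2*dx
shuffle_fwd <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; B <- d[4]
  y <- array(0, c(2 * H, 2 * W, 1, B))
  o1 <- seq(1, 2 * H, 2); o2 <- seq(2, 2 * H, 2)
  e1 <- seq(1, 2 * W, 2); e2 <- seq(2, 2 * W, 2)
  y[o1, e1, 1, ] <- x[, , 1, ]
  y[o2, e1, 1, ] <- x[, , 2, ]
  y[o1, e2, 1, ] <- x[, , 3, ]
  y[o2, e2, 1, ] <- x[, , 4, ]
  y
}

shuffle_bwd <- function(dy) {
  d <- dim(dy); H <- d[1] %/% 2; W <- d[2] %/% 2; B <- d[4]
  dx <- array(0, c(H, W, 4, B))
  o1 <- seq(1, 2 * H, 2); o2 <- seq(2, 2 * H, 2)
  e1 <- seq(1, 2 * W, 2); e2 <- seq(2, 2 * W, 2)
  dx[, , 1, ] <- dy[o1, e1, 1, ]
  dx[, , 2, ] <- dy[o2, e1, 1, ]
  dx[, , 3, ] <- dy[o1, e2, 1, ]
  dx[, , 4, ] <- dy[o2, e2, 1, ]
  dx
}

# fixed bilinear 2x upsampling of the frame-averaged input, used as a
# residual skip so the network only has to learn the correction to the
# upsampled widefield image
bilinear2x <- function(x) {
  H <- nrow(x); W <- ncol(x)
  xr <- x[pmin(seq_len(H) + 1, H), , drop = FALSE]
  xc <- x[, pmin(seq_len(W) + 1, W), drop = FALSE]
  xrc <- x[pmin(seq_len(H) + 1, H), pmin(seq_len(W) + 1, W), drop = FALSE]
  y <- matrix(0, 2 * H, 2 * W)
  o1 <- seq(1, 2 * H, 2); o2 <- seq(2, 2 * H, 2)
  e1 <- seq(1, 2 * W, 2); e2 <- seq(2, 2 * W, 2)
  y[o1, e1] <- x
  y[o2, e1] <- 0.5 * (x + xr)
  y[o1, e2] <- 0.5 * (x + xc)
  y[o2, e2] <- 0.25 * (x + xr + xc + xrc)
  y
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}
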