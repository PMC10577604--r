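# Minimal convolutional network engine: 3x3 same-padding convolutions via
# im2col + base matrix products, ReLU, 2x2 max-pooling, dense layers, Adam.
# Activations are arrays [H, W, C, N]. Deliberately small and deterministic
# (single-threaded base BLAS calls, seeded initialization) so that detector
# and classifier training is CPU-feasible and bit-reproducible.

im2col_idx <- function(H, W, C) {
  Hp <- H + 2L; Wp <- W + 2L
  # output pixels in column-major order (i fastest), patch order (ki, kj, c)
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, 9L * C)
  k <- 0L
  for (c in seq_len(C)) for (kj in 0:2) for (ki in 0:2) {
    k <- k + 1L
    idx[, k] <- (i + ki) + Hp * (j + kj - 1L) + Hp * Wp * (c - 1L)
  }
  idx
}

pad1 <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1L] + 2L, d[2L] + 2L, d[3L], d[4L]))
  out[2:(d[1L] + 1L), 2:(d[2L] + 1L), , ] <- x
  out
}

im2col <- function(x, idx) {
  d <- dim(x)
  xp <- pad1(x)
  per <- prod(dim(xp)[1:3])
  cols <- matrix(0, d[1L] * d[2L] * d[4L], ncol(idx))
  HW <- d[1L] * d[2L]
  for (n in seq_len(d[4L]))
    cols[((n - 1L) * HW + 1L):(n * HW), ] <- xp[c(idx) + (n - 1L) * per]
  cols
}

conv_fwd <- function(x, Wt, b, idx = NULL) {
  d <- dim(x)  # H W Cin N
  Cout <- dim(Wt)[4L]
  if (is.null(idx)) idx <- im2col_idx(d[1L], d[2L], d[3L])
  cols <- im2col(x, idx)
  Wm <- matrix(Wt, ncol = Cout)
  y <- sweep(cols %*% Wm, 2L, b, `+`)
  y <- array(y, c(d[1L], d[2L], d[4L], Cout))  # (pix, n) rows -> H W N Cout
  list(y = aperm(y, c(1L, 2L, 4L, 3L)), cols = cols)
}

conv_bwd <- function(dy, x, cols, Wt) {
  d <- dim(x); Cout <- dim(Wt)[4L]
  dym <- matrix(aperm(dy, c(1L, 2L, 4L, 3L)), ncol = Cout)
  dW <- array(crossprod(cols, dym), dim(Wt))
  db <- colSums(dym)
  # gradient to input = convolution of dy with spatially flipped, transposed kernels
  Wr <- array(0, c(3L, 3L, Cout, d[3L]))
  for (ci in seq_len(d[3L])) for (co in seq_len(Cout))
    Wr[, , co, ci] <- Wt[3:1, 3:1, ci, co]
  dx <- conv_fwd(dy, Wr, numeric(d[3L]))$y
  list(dx = dx, dW = dW, db = db)
}

relu_fwd <- function(x) { x[x < 0] <- 0; x }
relu_bwd <- function(dy, y) { dy[y <= 0] <- 0; dy }

maxpool_fwd <- function(x) {
  d <- dim(x)
  stopifnot(d[1L] %% 2L == 0L, d[2L] %% 2L == 0L)
  io <- seq(1L, d[1L], 2L); jo <- seq(1L, d[2L], 2L)
  s1 <- x[io, jo, , , drop = FALSE];      s2 <- x[io + 1L, jo, , , drop = FALSE]
  s3 <- x[io, jo + 1L, , , drop = FALSE]; s4 <- x[io + 1L, jo + 1L, , , drop = FALSE]
  y <- pmax(s1, s2, s3, s4)
  list(y = y, subs = list(s1, s2, s3, s4))
}

maxpool_bwd <- function(dy, pool, din_dim) {
  dx <- array(0, din_dim)
  io <- seq(1L, din_dim[1L], 2L); jo <- seq(1L, din_dim[2L], 2L)
  y <- pmax(pool$subs[[1L]], pool$subs[[2L]], pool$subs[[3L]], pool$subs[[4L]])
  taken <- array(FALSE, dim(y))
  off <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (k in 1:4) {
    m <- (pool$subs[[k]] == y) & !taken
    taken <- taken | m
    dk <- dy; dk[!m] <- 0
    dx[io + off[[k]][1L], jo + off[[k]][2L], , ] <- dk
  }
  dx
}

glorot <- function(dims, fan_in, fan_out) {
  array(stats::runif(prod(dims), -1, 1) * sqrt(6 / (fan_in + fan_out)), dims)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in seq_along(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    upd <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
    dim(upd) <- dim(params[[k]])  # keep vectors as vectors
    params[[k]] <- upd
  }
  list(params = params, state = state)
}

# subtract the per-sample, per-channel mean: removes the background DC
# level, which otherwise dominates early optimization
center_input <- function(x) {
  d <- dim(x)
  m <- colMeans(matrix(x, d[1L] * d[2L], d[3L] * d[4L]))
  sweep(x, 3:4, array(m, c(d[3L], d[4L])), `-`)
}
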