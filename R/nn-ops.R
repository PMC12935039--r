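# Dense-array neural primitives with hand-derived backward passes.
# All matmuls go through BLAS; shapes follow the comments. These are internal
# building blocks of the pairing-matrix network; gradient correctness is
# checked against finite differences in the test suite.

nn_relu <- function(x) {
  x[x < 0] <- 0
  x
}

nn_relu_bwd <- function(y, dy) {
  dy[y <= 0] <- 0
  dy
}

nn_sigmoid <- function(x) 1 / (1 + exp(-x))

# layer norm over the last (feature) dimension of a matrix (rows = positions)
ln_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = sweep(xhat, 2L, g, `*`) + rep(b, each = nrow(x)),
       xhat = xhat, inv = inv)
}

ln_bwd <- function(cache, g, dy) {
  xhat <- cache$xhat
  inv <- cache$inv
  n <- ncol(xhat)
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2L, g, `*`)
  # dx = inv * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = dg, db = db)
}

lin_fwd <- function(x, W, b) x %*% W + rep(b, each = nrow(x))

lin_bwd <- function(x, W, dy) {
  list(dx = dy %*% t(W), dW = crossprod(x, dy), db = colSums(dy))
}

row_softmax <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

softmax_bwd <- function(A, dA) {
  A * (dA - rowSums(A * dA))
}

# depthwise 1D convolution, symmetric zero padding, kernel k x C on x (L x C)
dwconv_fwd <- function(x, K, b) {
  L <- nrow(x); k <- nrow(K); pad <- (k - 1L) %/% 2L
  y <- matrix(0, L, ncol(x))
  for (o in seq_len(k)) {
    shift <- o - 1L - pad  # source row = l + shift
    src <- seq_len(L) + shift
    ok <- src >= 1L & src <= L
    y[ok, ] <- y[ok, ] + x[src[ok], , drop = FALSE] *
      rep(K[o, ], each = sum(ok))
  }
  y + rep(b, each = L)
}

dwconv_bwd <- function(x, K, dy) {
  L <- nrow(x); k <- nrow(K); pad <- (k - 1L) %/% 2L
  dx <- matrix(0, L, ncol(x))
  dK <- matrix(0, k, ncol(x))
  for (o in seq_len(k)) {
    shift <- o - 1L - pad
    src <- seq_len(L) + shift
    ok <- src >= 1L & src <= L
    dx[src[ok], ] <- dx[src[ok], ] + dy[ok, , drop = FALSE] *
      rep(K[o, ], each = sum(ok))
    dK[o, ] <- colSums(x[src[ok], , drop = FALSE] * dy[ok, , drop = FALSE])
  }
  list(dx = dx, dK = dK, db = colSums(dy))
}

# im2col for 3x3 dilated 2D convolution with same zero padding.
# P: array (L, L, C) -> matrix (L*L, 9*C); column blocks ordered by
# (dj, di) over {-dil, 0, dil} x {-dil, 0, dil}, row-major in (i, j).
# Compiled scatter/gather; the adjoint pair is gradient-checked in tests.
im2col3 <- function(P, dil = 1L) {
  d <- dim(P)
  .im2col3_cpp(P, d[1L], d[3L], as.integer(dil))
}

col2im3 <- function(dX, L, C, dil = 1L) {
  .col2im3_cpp(dX, as.integer(L), as.integer(C), as.integer(dil))
}

# 3x3 dilated conv as im2col matmul; P (L,L,Cin), K ((9*Cin) x Cout)
conv2d_fwd <- function(P, K, b, dil = 1L) {
  L <- dim(P)[1L]
  X <- im2col3(P, dil)
  list(y = array(X %*% K + rep(b, each = L * L),
                 c(L, L, length(b))),
       X = X)
}

conv2d_bwd <- function(cache, K, dY, dil = 1L) {
  L <- dim(dY)[1L]; Cout <- dim(dY)[3L]
  dYf <- matrix(dY, L * L, Cout)
  dK <- crossprod(cache$X, dYf)
  db <- colSums(dYf)
  dX <- dYf %*% t(K)
  Cin <- ncol(cache$X) %/% 9L
  dP <- col2im3(dX, L, Cin, dil)
  list(dP = dP, dK = dK, db = db)
}

# clipped relative-offset index matrix: entry (i, j) indexes offset j - i
# clipped to [-K, K], mapped to 1..(2K+1)
relpos_index <- function(L, K) {
  off <- outer(seq_len(L), seq_len(L), function(i, j) pmax(pmin(j - i, K), -K))
  off + K + 1L
}
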