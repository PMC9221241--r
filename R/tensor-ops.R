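# Low-level tensor operations for the segmentation network.
#
# Canonical tensor layout: a rank-4 numeric array (H, W, C, N) -- height,
# width, channels, batch. All spatial operators are stride-1 with
# size-preserving ("same") zero padding; only maxpool2/upsample2 change
# resolution. Convolutions are evaluated as im2col gathers followed by a
# single BLAS GEMM, which is what makes CPU training viable in plain R.

# ---- layout helpers ---------------------------------------------------------

#' Tensor (H,W,C,N) -> matrix (H*W*N, C), rows ordered h-fastest, then w, n.
#' @noRd
t2m <- function(x) {
  d <- dim(x)
  y <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(y) <- c(d[1L] * d[2L] * d[4L], d[3L])
  y
}

#' Inverse of t2m.
#' @noRd
m2t <- function(m, H, W, N) {
  C <- ncol(m)
  dim(m) <- c(H, W, N, C)
  aperm(m, c(1L, 2L, 4L, 3L))
}

#' @noRd
pad_spatial <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1L] + 2L * p, d[2L] + 2L * p, d[3L], d[4L]))
  xp[(p + 1L):(p + d[1L]), (p + 1L):(p + d[2L]), , ] <- x
  xp
}

# ---- im2col -----------------------------------------------------------------

.im2col_cache <- new.env(parent = emptyenv())

#' Integer gather-index matrix for im2col, cached per shape.
#' @noRd
im2col_index <- function(H, W, C, N, k, dilation) {
  key <- paste(H, W, C, N, k, dilation, sep = "x")
  idx <- .im2col_cache[[key]]
  if (!is.null(idx)) return(idx)
  p <- dilation * (k - 1L) %/% 2L
  Hp <- H + 2L * p; Wp <- W + 2L * p
  M <- H * W * N
  hh <- rep.int(seq_len(H), W)
  ww <- rep(seq_len(W), each = H)
  base_hw <- hh + Hp * (ww - 1L)
  base <- rep(base_hw, times = N) +
    rep((seq_len(N) - 1L) * (Hp * Wp * C), each = H * W)
  offs <- integer(k * k * C)
  col <- 0L
  for (cc in seq_len(C)) {
    off_c <- Hp * Wp * (cc - 1L)
    for (b in seq_len(k)) {
      off_b <- Hp * (b - 1L) * dilation + off_c
      for (a in seq_len(k)) {
        col <- col + 1L
        offs[col] <- (a - 1L) * dilation + off_b
      }
    }
  }
  idx <- matrix(0L, M, k * k * C)
  for (j in seq_along(offs)) idx[, j] <- base + offs[j]
  .im2col_cache[[key]] <- idx
  idx
}

#' Patch matrix for a k x k (dilated) convolution with "same" padding.
#'
#' Returns an (H*W*N) x (k*k*C) matrix. Rows are output pixels ordered
#' (h, w, n) with h fastest; columns are kernel taps ordered (a, b, c) with
#' the row offset a fastest -- the same ordering as `matrix(W, k*k*C, C_out)`
#' on a kernel array of dim (k, k, C, C_out).
#' @noRd
im2col <- function(x, k, dilation = 1L) {
  d <- dim(x)
  p <- dilation * (k - 1L) %/% 2L
  xp <- pad_spatial(x, p)
  idx <- im2col_index(d[1L], d[2L], d[3L], d[4L], k, dilation)
  P <- xp[idx]
  dim(P) <- dim(idx)
  P
}

#' Spatially flip a (k,k,Cin,Cout) kernel and swap its channel axes, giving
#' the kernel of the adjoint (gradient) convolution.
#' @noRd
flip_kernel <- function(W) {
  k <- dim(W)[1L]
  aperm(W[k:1, k:1, , , drop = FALSE], c(1L, 2L, 4L, 3L))
}

# ---- full convolution -------------------------------------------------------

#' @noRd
conv2d_fwd <- function(x, W, bias = NULL, dilation = 1L,
                       return_patches = FALSE) {
  d <- dim(x); k <- dim(W)[1L]; Cout <- dim(W)[4L]
  P <- if (k == 1L) t2m(x) else im2col(x, k, dilation)
  Y <- P %*% matrix(W, ncol = Cout)
  if (!is.null(bias)) Y <- Y + rep(bias, each = nrow(Y))
  y <- m2t(Y, d[1L], d[2L], d[4L])
  if (return_patches) list(y = y, P = P) else y
}

#' @noRd
conv2d_bwd <- function(x, W, dY, bias = FALSE, dilation = 1L, P = NULL) {
  d <- dim(x); k <- dim(W)[1L]; Cout <- dim(W)[4L]
  dYm <- t2m(dY)
  if (is.null(P)) P <- if (k == 1L) t2m(x) else im2col(x, k, dilation)
  dW <- crossprod(P, dYm)
  dim(dW) <- dim(W)
  db <- if (bias) colSums(dYm) else NULL
  dX <- conv2d_fwd(dY, flip_kernel(W), dilation = dilation)
  list(dX = dX, dW = dW, db = db)
}

# ---- depthwise convolution --------------------------------------------------

#' Depthwise k x k convolution; kernel Wd has dim (k, k, C).
#' @noRd
dwconv_fwd <- function(x, Wd, return_patches = FALSE) {
  d <- dim(x); k <- dim(Wd)[1L]; C <- d[3L]
  k2 <- k * k
  P <- im2col(x, k)
  M <- nrow(P)
  Wm <- matrix(Wd, k2, C)
  Y <- matrix(0, M, C)
  cidx <- k2 * (seq_len(C) - 1L)
  for (j in seq_len(k2)) {
    Y <- Y + P[, j + cidx, drop = FALSE] * rep(Wm[j, ], each = M)
  }
  y <- m2t(Y, d[1L], d[2L], d[4L])
  if (return_patches) list(y = y, P = P) else y
}

#' @noRd
dwconv_bwd <- function(x, Wd, dY, P = NULL) {
  d <- dim(x); k <- dim(Wd)[1L]; C <- d[3L]
  k2 <- k * k
  if (is.null(P)) P <- im2col(x, k)
  M <- nrow(P)
  dYm <- t2m(dY)
  dW <- matrix(0, k2, C)
  cidx <- k2 * (seq_len(C) - 1L)
  for (j in seq_len(k2)) {
    dW[j, ] <- colSums(P[, j + cidx, drop = FALSE] * dYm)
  }
  dim(dW) <- dim(Wd)
  Wf <- array(Wd[k:1, k:1, , drop = FALSE], dim(Wd))
  dX <- dwconv_fwd(dY, Wf)
  list(dX = dX, dW = dW)
}

# ---- batch normalization ----------------------------------------------------

#' Per-channel batch normalization over (H, W, N).
#' @noRd
bn_fwd <- function(x, gamma, beta, rmean, rvar, eps = 1e-3, momentum = 0.1,
                   train = TRUE) {
  d <- dim(x)
  xm <- t2m(x)
  M <- nrow(xm)
  if (train) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = M)
    v <- colMeans(xc * xc)
    inv <- 1 / sqrt(v + eps)
    xhat <- xc * rep(inv, each = M)
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * v
  } else {
    inv <- 1 / sqrt(rvar + eps)
    xhat <- (xm - rep(rmean, each = M)) * rep(inv, each = M)
  }
  y <- xhat * rep(gamma, each = M) + rep(beta, each = M)
  list(y = m2t(y, d[1L], d[2L], d[4L]),
       cache = list(xhat = xhat, inv = inv, dims = d),
       rmean = rmean, rvar = rvar)
}

#' @noRd
bn_bwd <- function(cache, gamma, dY) {
  d <- cache$dims
  dYm <- t2m(dY)
  M <- nrow(dYm)
  xhat <- cache$xhat
  dgamma <- colSums(dYm * xhat)
  dbeta <- colSums(dYm)
  dxhat <- dYm * rep(gamma, each = M)
  dx <- rep(cache$inv, each = M) *
    (dxhat - rep(colMeans(dxhat), each = M) -
       xhat * rep(colMeans(dxhat * xhat), each = M))
  list(dX = m2t(dx, d[1L], d[2L], d[4L]), dgamma = dgamma, dbeta = dbeta)
}

# ---- pointwise nonlinearities ----------------------------------------------

#' @noRd
relu_fwd <- function(x) {
  x[x < 0] <- 0
  x
}

#' @noRd
relu_bwd <- function(x, dY) dY * (x > 0)

#' @noRd
sigmoid_fwd <- function(x) 1 / (1 + exp(-x))

#' @noRd
sigmoid_bwd <- function(y, dY) dY * y * (1 - y)

# ---- 2x2 max pooling --------------------------------------------------------

#' @noRd
maxpool2_fwd <- function(x) {
  d <- dim(x)
  io <- seq.int(1L, d[1L], by = 2L); ie <- io + 1L
  jo <- seq.int(1L, d[2L], by = 2L); je <- jo + 1L
  x11 <- x[io, jo, , , drop = FALSE]
  x21 <- x[ie, jo, , , drop = FALSE]
  x12 <- x[io, je, , , drop = FALSE]
  x22 <- x[ie, je, , , drop = FALSE]
  y <- pmax(x11, x21, x12, x22)
  a1 <- x11 == y
  a2 <- (x21 == y) & !a1
  a3 <- (x12 == y) & !a1 & !a2
  a4 <- !(a1 | a2 | a3)
  list(y = y, cache = list(a1 = a1, a2 = a2, a3 = a3, a4 = a4, dims = d))
}

#' @noRd
maxpool2_bwd <- function(cache, dY) {
  d <- cache$dims
  dX <- array(0, d)
  io <- seq.int(1L, d[1L], by = 2L); ie <- io + 1L
  jo <- seq.int(1L, d[2L], by = 2L); je <- jo + 1L
  dX[io, jo, , ] <- dY * cache$a1
  dX[ie, jo, , ] <- dX[ie, jo, , , drop = FALSE] + dY * cache$a2
  dX[io, je, , ] <- dX[io, je, , , drop = FALSE] + dY * cache$a3
  dX[ie, je, , ] <- dX[ie, je, , , drop = FALSE] + dY * cache$a4
  dX
}

# ---- bilinear 2x upsampling -------------------------------------------------

.us_cache <- new.env(parent = emptyenv())

#' Interpolation matrix mapping H input rows to 2H output rows
#' (half-pixel-centre convention, edges replicated).
#' @noRd
us_mat <- function(H) {
  key <- as.character(H)
  if (!is.null(.us_cache[[key]])) return(.us_cache[[key]])
  i <- seq_len(2L * H)
  src <- (i - 0.5) / 2 + 0.5
  f <- floor(src)
  wgt <- src - f
  f0 <- pmin(pmax(f, 1L), H)
  f1 <- pmin(f + 1L, H)
  U <- matrix(0, 2L * H, H)
  U[cbind(i, f0)] <- U[cbind(i, f0)] + (1 - wgt)
  U[cbind(i, f1)] <- U[cbind(i, f1)] + wgt
  .us_cache[[key]] <- U
  U
}

#' Apply a row-resampling matrix along dim 1.
#' @noRd
resample_dim1 <- function(x, U) {
  d <- dim(x)
  y <- U %*% matrix(x, d[1L], prod(d[-1L]))
  dim(y) <- c(nrow(U), d[-1L])
  y
}

#' @noRd
upsample2_fwd <- function(x) {
  d <- dim(x)
  y <- resample_dim1(x, us_mat(d[1L]))
  y <- aperm(y, c(2L, 1L, 3L, 4L))
  y <- resample_dim1(y, us_mat(d[2L]))
  aperm(y, c(2L, 1L, 3L, 4L))
}

#' @noRd
upsample2_bwd <- function(dY, H, W) {
  dX <- resample_dim1(dY, t(us_mat(H)))
  dX <- aperm(dX, c(2L, 1L, 3L, 4L))
  dX <- resample_dim1(dX, t(us_mat(W)))
  aperm(dX, c(2L, 1L, 3L, 4L))
}

# ---- squeeze-and-excitation -------------------------------------------------

#' Per-channel global average pooling: (H,W,C,N) -> (N, C).
#' @noRd
se_squeeze <- function(x) {
  d <- dim(x)
  z <- colMeans(matrix(x, d[1L] * d[2L], d[3L] * d[4L]))
  t(matrix(z, d[3L], d[4L]))
}

#' @noRd
se_fwd <- function(x, W1, b1, W2, b2, force_identity = FALSE) {
  d <- dim(x)
  if (force_identity) {
    return(list(y = x, cache = list(identity = TRUE, dims = d)))
  }
  z <- se_squeeze(x)                               # N x C
  h <- z %*% W1 + rep(b1, each = nrow(z))
  h <- relu_fwd(h)
  g <- sigmoid_fwd(h %*% W2 + rep(b2, each = nrow(h)))  # N x C, gates in (0,1)
  gexp <- rep(as.vector(t(g)), each = d[1L] * d[2L])    # per (c, n) block
  y <- x * array(gexp, d)
  list(y = y, cache = list(x = x, z = z, h = h, g = g, dims = d))
}

#' @noRd
se_bwd <- function(cache, W1, W2, dY) {
  if (isTRUE(cache$identity)) {
    return(list(dX = dY, dW1 = NULL, db1 = NULL, dW2 = NULL, db2 = NULL))
  }
  d <- cache$dims
  HW <- d[1L] * d[2L]
  g <- cache$g; h <- cache$h; z <- cache$z; x <- cache$x
  gexp <- array(rep(as.vector(t(g)), each = HW), d)
  dX1 <- dY * gexp
  # gradient w.r.t. gates: sum over pixels of dY * x
  dg <- t(matrix(colSums(matrix(dY * x, HW, d[3L] * d[4L])), d[3L], d[4L]))
  da2 <- dg * g * (1 - g)
  dW2 <- crossprod(h, da2)
  db2 <- colSums(da2)
  dh <- (da2 %*% t(W2)) * (h > 0)
  dW1 <- crossprod(z, dh)
  db1 <- colSums(dh)
  dz <- dh %*% t(W1)                               # N x C
  dzexp <- array(rep(as.vector(t(dz)), each = HW), d) / HW
  list(dX = dX1 + dzexp, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

# ---- fused conv + batch norm + ReLU ----------------------------------------
#
# The workhorse layers are fused so normalization and activation run on the
# (H*W*N, C) GEMM output directly, avoiding per-layer array reshapes.

#' @noRd
bn_relu_mat <- function(Z, gamma, beta, rmean, rvar, eps, momentum, train) {
  M <- nrow(Z)
  if (train) {
    mu <- colMeans(Z)
    Zc <- Z - rep(mu, each = M)
    v <- colMeans(Zc * Zc)
    inv <- 1 / sqrt(v + eps)
    xhat <- Zc * rep(inv, each = M)
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * v
  } else {
    inv <- 1 / sqrt(rvar + eps)
    xhat <- (Z - rep(rmean, each = M)) * rep(inv, each = M)
  }
  A <- xhat * rep(gamma, each = M) + rep(beta, each = M)
  A[A < 0] <- 0
  list(A = A, xhat = xhat, inv = inv, rmean = rmean, rvar = rvar)
}

#' Backward of bn_relu_mat; returns gradient at Z plus parameter grads.
#' @noRd
bn_relu_mat_bwd <- function(dYm, cache, gamma) {
  M <- nrow(dYm)
  dA <- dYm * (cache$A > 0)
  xhat <- cache$xhat
  dgamma <- colSums(dA * xhat)
  dbeta <- colSums(dA)
  dxhat <- dA * rep(gamma, each = M)
  dZ <- rep(cache$inv, each = M) *
    (dxhat - rep(colMeans(dxhat), each = M) -
       xhat * rep(colMeans(dxhat * xhat), each = M))
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

#' Fused conv(+dilation) -> batch norm -> ReLU.
#' @noRd
cbr_fwd <- function(x, W, gamma, beta, rmean, rvar, eps = 1e-3,
                    momentum = 0.1, train = TRUE, dilation = 1L,
                    keep = FALSE) {
  d <- dim(x); k <- dim(W)[1L]; Cout <- dim(W)[4L]
  P <- if (k == 1L) t2m(x) else im2col(x, k, dilation)
  Z <- P %*% matrix(W, ncol = Cout)
  r <- bn_relu_mat(Z, gamma, beta, rmean, rvar, eps, momentum, train)
  y <- m2t(r$A, d[1L], d[2L], d[4L])
  list(y = y, rmean = r$rmean, rvar = r$rvar,
       cache = if (keep) list(P = P, A = r$A, xhat = r$xhat, inv = r$inv,
                              dims = d))
}

#' @noRd
cbr_bwd <- function(cache, W, gamma, dY, dilation = 1L) {
  d <- cache$dims
  dYm <- t2m(dY)
  b <- bn_relu_mat_bwd(dYm, cache, gamma)
  dW <- crossprod(cache$P, b$dZ)
  dim(dW) <- dim(W)
  dZt <- m2t(b$dZ, d[1L], d[2L], d[4L])
  dX <- conv2d_fwd(dZt, flip_kernel(W), dilation = dilation)
  list(dX = dX, dW = dW, dgamma = b$dgamma, dbeta = b$dbeta)
}

#' Fused depthwise conv -> batch norm -> ReLU.
#' @noRd
dbr_fwd <- function(x, Wd, gamma, beta, rmean, rvar, eps = 1e-3,
                    momentum = 0.1, train = TRUE, keep = FALSE) {
  d <- dim(x); k <- dim(Wd)[1L]; C <- d[3L]
  k2 <- k * k
  P <- im2col(x, k)
  M <- nrow(P)
  Wm <- matrix(Wd, k2, C)
  Z <- matrix(0, M, C)
  cidx <- k2 * (seq_len(C) - 1L)
  for (j in seq_len(k2)) {
    Z <- Z + P[, j + cidx, drop = FALSE] * rep(Wm[j, ], each = M)
  }
  r <- bn_relu_mat(Z, gamma, beta, rmean, rvar, eps, momentum, train)
  y <- m2t(r$A, d[1L], d[2L], d[4L])
  list(y = y, rmean = r$rmean, rvar = r$rvar,
       cache = if (keep) list(P = P, A = r$A, xhat = r$xhat, inv = r$inv,
                              dims = d))
}

#' @noRd
dbr_bwd <- function(cache, Wd, gamma, dY) {
  d <- cache$dims
  k <- dim(Wd)[1L]; C <- d[3L]
  k2 <- k * k
  dYm <- t2m(dY)
  b <- bn_relu_mat_bwd(dYm, cache, gamma)
  P <- cache$P
  dW <- matrix(0, k2, C)
  cidx <- k2 * (seq_len(C) - 1L)
  for (j in seq_len(k2)) {
    dW[j, ] <- colSums(P[, j + cidx, drop = FALSE] * b$dZ)
  }
  dim(dW) <- dim(Wd)
  Wf <- array(Wd[k:1, k:1, , drop = FALSE], dim(Wd))
  dX <- dwconv_fwd(m2t(b$dZ, d[1L], d[2L], d[4L]), Wf)
  list(dX = dX, dW = dW, dgamma = b$dgamma, dbeta = b$dbeta)
}

# ---- channel concatenation --------------------------------------------------

#' @noRd
concat_channels <- function(xs) {
  d1 <- dim(xs[[1L]])
  Cs <- vapply(xs, function(x) dim(x)[3L], integer(1))
  y <- array(0, c(d1[1L], d1[2L], sum(Cs), d1[4L]))
  at <- 0L
  for (x in xs) {
    C <- dim(x)[3L]
    y[, , at + seq_len(C), ] <- x
    at <- at + C
  }
  y
}

#' @noRd
split_channels <- function(dY, Cs) {
  out <- vector("list", length(Cs))
  at <- 0L
  for (i in seq_along(Cs)) {
    out[[i]] <- dY[, , at + seq_len(Cs[i]), , drop = FALSE]
    at <- at + Cs[i]
  }
  out
}
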