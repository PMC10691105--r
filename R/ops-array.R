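# Low-level differentiable array operations.
#
# Feature maps are numeric arrays with dim (h, w, c) for one image and
# (h, w, c, n) for a batch of n images. Convolution weights are stored as a
# (9 * c_in) x c_out matrix whose rows are ordered channel-major then
# column-major over the 3x3 window (di fastest), so the forward pass is a
# single BLAS matrix product on the im2col matrix.

.op_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (is.null(.op_cache[[key]])) .op_cache[[key]] <- build()
  .op_cache[[key]]
}

# Gather-index matrix for 3x3, stride-1, pad-1 convolution over a batch.
# Returns an (h*w*n) x (9*c) integer matrix of linear indices into the
# zero-padded batch array of dim (h+2, w+2, c, n).
im2col_indices <- function(h, w, c, n) {
  key <- paste("i2c", h, w, c, n, sep = "_")
  cache_get(key, function() {
    hp <- h + 2L
    wp <- w + 2L
    oi <- rep.int(seq_len(h), w)
    oj <- rep(seq_len(w), each = h)
    di <- rep.int(rep.int(1:3, 3L), c)
    dj <- rep.int(rep(1:3, each = 3L), c)
    ch <- rep(seq_len(c), each = 9L)
    base <- outer(oi, di, `+`) - 1L +
      (outer(oj, dj, `+`) - 2L) * hp +
      matrix((ch - 1L) * hp * wp, nrow = h * w, ncol = 9L * c, byrow = TRUE)
    if (n == 1L) return(base)
    off <- rep((0:(n - 1L)) * hp * wp * c, each = h * w)
    base[rep.int(seq_len(h * w), n), , drop = FALSE] + off
  })
}

pad_batch <- function(x) {
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
  xp[2:(d[1] + 1L), 2:(d[2] + 1L), , ] <- x
  xp
}

# raw = TRUE returns the GEMM result as an (h*w*n) x cout matrix (rows
# ordered i fastest, then j, then image) without rearranging into the
# (h, w, cout, n) array — the layout consumed by matrix-space batch norm.
#' @noRd
conv3x3_forward <- function(x, W, b, keep_cache = FALSE, raw = FALSE) {
  d <- dim(x)
  h <- d[1]; w <- d[2]; cin <- d[3]; n <- d[4]
  cout <- ncol(W)
  idx <- im2col_indices(h, w, cin, n)
  cols <- pad_batch(x)
  dim(cols) <- NULL
  cols <- matrix(cols[idx], nrow = h * w * n)
  ym <- cols %*% W
  if (any(b != 0)) ym <- ym + rep(b, each = h * w * n)
  out <- if (keep_cache) list(cols = cols, dims = d) else list(dims = d)
  if (raw) {
    out$ym <- ym
  } else {
    out$y <- aperm(array(ym, c(h, w, n, cout)), c(1L, 2L, 4L, 3L))
  }
  out
}

# Row-permutation that turns W ((9*cin) x cout) into the kernel of the
# transposed convolution (spatial 180-degree rotation, channels swapped).
flip_perm <- function(cin) {
  key <- paste("flip", cin, sep = "_")
  cache_get(key, function() {
    di <- rep.int(rep.int(1:3, 3L), cin)
    dj <- rep.int(rep(1:3, each = 3L), cin)
    ch <- rep(seq_len(cin), each = 9L)
    (ch - 1L) * 9L + (3L - dj) * 3L + (4L - di)
  })
}

#' @noRd
conv3x3_backward <- function(dy, W, cache, want_dx = TRUE) {
  d <- cache$dims
  h <- d[1]; w <- d[2]; cin <- d[3]; n <- d[4]
  cout <- ncol(W)
  dym <- aperm(dy, c(1L, 2L, 4L, 3L))
  dim(dym) <- c(h * w * n, cout)
  dW <- crossprod(cache$cols, dym)
  db <- colSums(dym)
  if (!want_dx) return(list(dx = NULL, dW = dW, db = db))
  list(dx = conv_transpose_dx(dy, W, cin), dW = dW, db = db)
}

# Input gradient of the stride-1 pad-1 convolution: correlate dy with the
# spatially rotated kernel, input/output channels swapped. Column ci of Wt
# holds the flipped 9 x cout slab of W for input channel ci, so Wt's rows
# are cout-channel-major over dy's channels, matching im2col's ordering.
#' @noRd
conv_transpose_dx <- function(dy, W, cin) {
  cout <- ncol(W)
  Wt <- matrix(0, 9L * cout, cin)
  fp <- flip_perm(1L)
  for (ci in seq_len(cin)) {
    rows <- ((ci - 1L) * 9L + 1L):(ci * 9L)
    Wt[, ci] <- as.vector(W[rows, , drop = FALSE][fp, , drop = FALSE])
  }
  conv3x3_forward(dy, Wt, numeric(cin))$y
}

#' @noRd
relu_forward <- function(x) {
  x[x < 0] <- 0
  x
}

#' @noRd
relu_backward <- function(dy, y) {
  dy[y <= 0] <- 0
  dy
}

#' @noRd
avgpool2_forward <- function(x) {
  d <- dim(x)
  a <- x[seq.int(1L, d[1], 2L), , , , drop = FALSE] +
    x[seq.int(2L, d[1], 2L), , , , drop = FALSE]
  (a[, seq.int(1L, d[2], 2L), , , drop = FALSE] +
      a[, seq.int(2L, d[2], 2L), , , drop = FALSE]) / 4
}

#' @noRd
avgpool2_backward <- function(dy) {
  d <- dim(dy)
  dy[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
     drop = FALSE] / 4
}

# Global average pooling: (h, w, c, n) -> d x n matrix (d = c).
#' @noRd
gap_forward <- function(x) {
  d <- dim(x)
  m <- x
  dim(m) <- c(d[1] * d[2], d[3] * d[4])
  matrix(colMeans(m), d[3], d[4])
}

#' @noRd
gap_backward <- function(demb, h, w) {
  d <- dim(demb) # c x n
  g <- array(rep(demb, each = h * w), c(h, w, d[1], d[2]))
  g / (h * w)
}

#' @noRd
sigmoid <- function(x) 1 / (1 + exp(-x))

# Numerically stable row softmax of a matrix.
#' @noRd
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Backward through row softmax: s = softmax(z), ds upstream.
#' @noRd
softmax_rows_backward <- function(ds, s) {
  s * (ds - rowSums(ds * s))
}

# 1-D linear interpolation matrix mapping a crop [a, a + m) of an n_in-long
# axis (0-based half-open) onto n_out output positions. Corner-anchored so
# that a full-axis crop with n_out == n_in is the identity.
interp_matrix <- function(n_out, a, m, n_in) {
  key <- paste("interp", n_out, a, m, n_in, sep = "_")
  cache_get(key, function() {
    t <- if (m == 1L) {
      rep(a, n_out)
    } else if (n_out == 1L) {
      a + (m - 1) / 2
    } else {
      a + (0:(n_out - 1)) * (m - 1) / (n_out - 1)
    }
    M <- matrix(0, n_out, n_in)
    i0 <- pmin(floor(t), n_in - 1L)
    fr <- t - i0
    for (k in seq_len(n_out)) {
      M[k, i0[k] + 1L] <- M[k, i0[k] + 1L] + (1 - fr[k])
      if (fr[k] > 0) M[k, i0[k] + 2L] <- M[k, i0[k] + 2L] + fr[k]
    }
    M
  })
}

# Crop a (h, w, c) block to a 0-based half-open box and bilinearly resize
# back to (h, w). Returns the result; the operation is linear, so the
# backward pass is the adjoint with the transposed interpolation matrices.
#' @noRd
crop_resize_block <- function(x, box) {
  d <- dim(x)
  h <- d[1]; w <- d[2]; c <- d[3]
  mr <- box$row_stop - box$row_start
  mc <- box$col_stop - box$col_start
  R <- interp_matrix(h, box$row_start, mr, h)[, (box$row_start + 1L):(box$row_stop), drop = FALSE] # nolint
  # R built against full axis then restricted: equivalent to crop-then-resize
  R <- R - 0 # keep dense
  Cm <- interp_matrix(w, box$col_start, mc, w)[, (box$col_start + 1L):(box$col_stop), drop = FALSE]
  xc <- x[(box$row_start + 1L):box$row_stop, (box$col_start + 1L):box$col_stop, ,
          drop = FALSE]
  y1 <- R %*% matrix(xc, mr, mc * c)            # h x (mc*c)
  y1 <- aperm(array(y1, c(h, mc, c)), c(2L, 1L, 3L))
  y2 <- Cm %*% matrix(y1, mc, h * c)            # w x (h*c)
  aperm(array(y2, c(w, h, c)), c(2L, 1L, 3L))
}

#' @noRd
crop_resize_backward <- function(dy, box, h, w) {
  c <- dim(dy)[3]
  mr <- box$row_stop - box$row_start
  mc <- box$col_stop - box$col_start
  R <- interp_matrix(h, box$row_start, mr, h)[, (box$row_start + 1L):(box$row_stop), drop = FALSE]
  Cm <- interp_matrix(w, box$col_start, mc, w)[, (box$col_start + 1L):(box$col_stop), drop = FALSE]
  g1 <- t(Cm) %*% matrix(aperm(dy, c(2L, 1L, 3L)), w, h * c)  # mc x (h*c)
  g1 <- aperm(array(g1, c(mc, h, c)), c(2L, 1L, 3L))          # h x mc x c
  g2 <- t(R) %*% matrix(g1, h, mc * c)                        # mr x (mc*c)
  dx <- array(0, c(h, w, c))
  dx[(box$row_start + 1L):box$row_stop, (box$col_start + 1L):box$col_stop, ] <-
    array(g2, c(mr, mc, c))
  dx
}

# Batch normalization over the rows of an n x d matrix (one feature per
# column). Population variance; eps 1e-5; running-statistics momentum 0.1.
#' @noRd
bn_forward <- function(X, bn, training) {
  eps <- 1e-5
  n <- nrow(X)
  if (training && n >= 2L) {
    mu <- colMeans(X)
    v <- colMeans(X^2) - mu^2
    v[v < 0] <- 0
    bn$running_mean <- 0.9 * bn$running_mean + 0.1 * mu
    bn$running_var <- 0.9 * bn$running_var + 0.1 * v * n / max(n - 1L, 1L)
  } else {
    mu <- bn$running_mean
    v <- bn$running_var
  }
  inv <- 1 / sqrt(v + eps)
  a <- inv * bn$gamma
  xhat <- (X - rep(mu, each = n)) * rep(inv, each = n)
  y <- X * rep(a, each = n) + rep(bn$beta - mu * a, each = n)
  list(y = y, xhat = xhat, inv = inv, mu = mu, used_batch = training && n >= 2L,
       bn = bn)
}

#' @noRd
bn_backward <- function(dy, fwd, bn) {
  n <- nrow(dy)
  dgamma <- colSums(dy * fwd$xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * rep(bn$gamma, each = n)
  if (fwd$used_batch) {
    dX <- (dxhat - rep(colMeans(dxhat), each = n) -
             fwd$xhat * rep(colMeans(dxhat * fwd$xhat), each = n)) *
      rep(fwd$inv, each = n)
  } else {
    dX <- dxhat * rep(fwd$inv, each = n)
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# Deterministic sub-seed derivation, kept below 2^31.
#' @noRd
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  acc <- 0
  for (p in parts) acc <- (acc * 69069 + as.numeric(p) %% 2147483647) %% 2147483647
  as.integer(acc)
}
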