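# Independent brute-force oracles. These deliberately use scalar loops and
# textbook formulas, never the package's vectorized code paths.

# Channel aggregation, mean-relative thresholding, intersection and
# bounding box, all via explicit loops.
naive_eflm <- function(blocks, lam, num_blocks = length(blocks)) {
  use <- blocks[(length(blocks) - num_blocks + 1L):length(blocks)]
  h <- dim(use[[1]])[1]
  w <- dim(use[[1]])[2]
  masks <- lapply(use, function(b) {
    A <- matrix(0, h, w)
    for (i in seq_len(h)) for (j in seq_len(w)) A[i, j] <- sum(b[i, j, ])
    abar <- sum(A) / (h * w)
    M <- matrix(0, h, w)
    for (i in seq_len(h)) for (j in seq_len(w)) {
      if (A[i, j] > lam * abar) M[i, j] <- 1
    }
    M
  })
  mf <- matrix(1, h, w)
  for (M in masks) {
    for (i in seq_len(h)) for (j in seq_len(w)) {
      if (M[i, j] == 0) mf[i, j] <- 0
    }
  }
  if (sum(mf) == 0) {
    box <- list(row_start = 0L, row_stop = h, col_start = 0L, col_stop = w)
  } else {
    rs <- cs <- integer(0)
    for (i in seq_len(h)) for (j in seq_len(w)) {
      if (mf[i, j] == 1) {
        rs <- c(rs, i)
        cs <- c(cs, j)
      }
    }
    box <- list(row_start = min(rs) - 1L, row_stop = max(rs),
                col_start = min(cs) - 1L, col_stop = max(cs))
  }
  list(masks = masks, mask_f = mf, box = box)
}

naive_row_softmax <- function(Z) {
  S <- Z
  for (a in seq_len(nrow(Z))) {
    e <- exp(Z[a, ] - max(Z[a, ]))
    S[a, ] <- e / sum(e)
  }
  S
}

# Textbook multi-head self-attention + inference-mode batch normalization
# + residual, in loops.
naive_mhsa <- function(X, params) {
  n <- nrow(X)
  d <- params$d
  heads <- params$heads
  dh <- d %/% heads
  H <- matrix(0, n, d)
  for (i in seq_len(heads)) {
    Q <- X %*% params$head[[i]]$WQ
    K <- X %*% params$head[[i]]$WK
    V <- X %*% params$head[[i]]$WV
    S <- naive_row_softmax(Q %*% t(K) / sqrt(params$d_k))
    H[, ((i - 1L) * dh + 1L):(i * dh)] <- S %*% V
  }
  Y <- H
  for (k in seq_len(d)) {
    xhat <- (H[, k] - params$bn$running_mean[k]) /
      sqrt(params$bn$running_var[k] + 1e-5)
    Y[, k] <- params$bn$gamma[k] * xhat + params$bn$beta[k]
  }
  Y + X
}

rand_stack <- function(h = 8L, w = 8L, c = 4L, blocks = 3L) {
  feature_stack(lapply(seq_len(blocks), function(b) {
    array(abs(stats::rnorm(h * w * c)), c(h, w, c))
  }))
}

# Support-weighted F1 via an independent metrics library.
caret_weighted_f1 <- function(pred, truth, m) {
  lev <- as.character(0:(m - 1L))
  cm <- caret::confusionMatrix(factor(pred, levels = lev),
                               factor(truth, levels = lev))
  by <- as.data.frame(cm$byClass)
  f1 <- by$F1
  f1[is.na(f1)] <- 0
  support <- as.integer(table(factor(truth, levels = lev)))
  keep <- support > 0
  sum(f1[keep] * support[keep]) / sum(support[keep])
}

# Tiny manifest + image tree for pipeline tests; returns the dataset dir.
micro_dataset <- function(dir, n_classes = 2L, images_per_class = 8L,
                          side = 64L, seed = 5L, ...) {
  spec <- synthetic_spec(n_classes = n_classes,
                         images_per_class = images_per_class,
                         image_side = side, label_error_rate = 0,
                         no_target_rate = 0, blur_rate = 0, seed = seed, ...)
  generate_dataset(spec, dir)
  dir
}
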