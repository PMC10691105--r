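#' Initialize gated attention-fusion parameters
#'
#' The fusion block is a single multi-head self-attention layer over the
#' group's embedding rows, with sigmoid gate masks modulating each head's
#' query and key, a hard selection mask on the post-softmax scores, batch
#' normalization over the concatenated heads, and a residual connection.
#' Gate parameters are shared across heads.
#'
#' @param d Embedding dimension; must be divisible by `heads`.
#' @param heads Number of attention heads (default 4).
#' @param seed Integer seed for initialization.
#' @return An `affm_params` list.
#' @export
affm_init <- function(d, heads = 4L, seed = 1L) {
  if (d %% heads != 0L) stop("d must be divisible by heads", call. = FALSE)
  dh <- d %/% heads
  set.seed(derive_seed(seed, 23L))
  xa <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(1 / nr)), nr, nc)
  structure(list(
    d = as.integer(d), heads = as.integer(heads), d_k = as.integer(d),
    head = lapply(seq_len(heads), function(i) {
      list(WQ = xa(d, dh), WK = xa(d, dh), WV = xa(d, dh))
    }),
    gate = list(
      WGQ = xa(dh, dh), WGK = xa(dh, dh),
      bGQ = numeric(dh), bGK = numeric(dh),
      WMQ = xa(2L * dh, dh), WMK = xa(2L * dh, dh),
      bMQ = numeric(dh), bMK = numeric(dh)
    ),
    bn = list(gamma = rep(1, d), beta = numeric(d),
              running_mean = numeric(d), running_var = rep(1, d))
  ), class = "affm_params")
}

#' Per-head query/key/value projection
#'
#' @param X n x d embedding matrix.
#' @param params An [affm_init()] parameter set.
#' @param head Head index (1-based).
#' @return List of `Q`, `K`, `V`, each n x d/h.
#' @export
project_qkv <- function(X, params, head) {
  hp <- params$head[[head]]
  if (ncol(X) != nrow(hp$WQ)) stop("embedding dimension mismatch", call. = FALSE)
  list(Q = X %*% hp$WQ, K = X %*% hp$WK, V = X %*% hp$WV)
}

#' Joint gate-input matrix
#'
#' Maps the head's query and key into a joint space and concatenates them
#' along the feature axis.
#'
#' @param Q,K n x d/h matrices.
#' @param params Gate parameter list (`$gate` of [affm_init()]).
#' @return n x 2(d/h) matrix.
#' @export
gate_fusion <- function(Q, K, params) {
  if (!identical(dim(Q), dim(K))) stop("Q/K shape mismatch", call. = FALSE)
  cbind(sweep(Q %*% params$WGQ, 2L, params$bGQ, `+`),
        sweep(K %*% params$WGK, 2L, params$bGK, `+`))
}

#' Sigmoid gate masks for query and key
#'
#' @param G n x 2(d/h) joint matrix from [gate_fusion()].
#' @param params Gate parameter list.
#' @return List of `MQ`, `MK`, each n x d/h with entries strictly in (0, 1).
#' @export
gate_masks <- function(G, params) {
  list(MQ = sigmoid(sweep(G %*% params$WMQ, 2L, params$bMQ, `+`)),
       MK = sigmoid(sweep(G %*% params$WMK, 2L, params$bMK, `+`)))
}

#' Gated scaled-dot-product attention scores
#'
#' Row softmax of `((MQ * Q) (MK * K)^T) / sqrt(d_k)`.
#'
#' @param Q,K n x d/h matrices.
#' @param masks List with `MQ`, `MK` (or NULL for ungated attention).
#' @param d_k Scaling dimension (the paper sets it to the full embedding
#'   dimension d).
#' @return n x n row-stochastic score matrix.
#' @export
attention_scores <- function(Q, K, masks = NULL, d_k = ncol(Q)) {
  if (!is.null(masks)) {
    Q <- masks$MQ * Q
    K <- masks$MK * K
  }
  softmax_rows(Q %*% t(K) / sqrt(d_k))
}

#' Hard selection mask on attention scores
#'
#' Entries whose post-softmax score falls below the probability threshold
#' `p` are force-discarded (set to 0); all others pass (1). The default
#' threshold is half the uniform score, `p = 1 / (2 n)`.
#'
#' @param S n x n row-stochastic score matrix.
#' @param p Threshold probability in `[0, 1]`.
#' @return Binary n x n matrix.
#' @export
selection_mask <- function(S, p = 1 / (2 * nrow(S))) {
  stopifnot(p >= 0, p <= 1)
  (S >= p) + 0
}

#' Masked attention head output
#'
#' `h = (mask * S) V`, with no renormalization of masked rows.
#'
#' @param S n x n score matrix.
#' @param mask Binary n x n selection mask.
#' @param V n x d/h value matrix.
#' @return n x d/h matrix.
#' @export
head_output <- function(S, mask, V) {
  (mask * S) %*% V
}

#' Gated multi-head attention fusion of a group's embeddings
#'
#' Full forward pass: per-head gated attention with selection masking,
#' concatenation of heads, batch normalization over the group rows, and a
#' residual connection to the (pre-dropout) input. With gates pinned to 1
#' and `p = 0` this reduces to textbook multi-head self-attention
#' (+ BN + residual).
#'
#' @param X n x d embedding matrix (rows are group members).
#' @param params An [affm_init()] parameter set.
#' @param p Selection-mask threshold; default `1 / (2 n)`. Ignored when
#'   `v_mask` is FALSE.
#' @param training Logical; batch statistics and dropout are used only in
#'   training (running statistics when `n == 1`).
#' @param dropout_rate Dropout applied to the attention path's input
#'   (residual bypasses it).
#' @param qk_mask Enable the learned sigmoid query/key gate masks.
#' @param v_mask Enable the hard selection mask.
#' @param pin_gates Test hook: force gate masks to exactly 1.
#' @param keep_cache Keep intermediates for the backward pass.
#' @return List with `out` (n x d), `bn` (updated running statistics) and,
#'   when requested, `cache` (which also stores the per-head masked scores
#'   under `Sm` for attention diagnostics).
#' @export
affm_forward <- function(X, params, p = NULL, training = FALSE,
                         dropout_rate = 0, qk_mask = TRUE, v_mask = TRUE,
                         pin_gates = FALSE, keep_cache = FALSE) {
  at <- affm_attend(X, params, p, training, dropout_rate, qk_mask, v_mask,
                    pin_gates)
  bnf <- bn_forward(at$concat, params$bn, training && nrow(X) >= 2L)
  out <- bnf$y + X
  res <- list(out = out, bn = bnf$bn)
  if (keep_cache) {
    res$cache <- c(at$cache, list(bnf = bnf))
  }
  res
}

# Attention stage of the fusion block: dropout on the attention path's
# input, per-head gated attention with selection masking, concatenation of
# heads. Batch normalization and the residual are applied by the caller,
# which lets the training loop normalize over all groups of an optimizer
# batch at once.
affm_attend <- function(X, params, p = NULL, training = FALSE,
                        dropout_rate = 0, qk_mask = TRUE, v_mask = TRUE,
                        pin_gates = FALSE) {
  n <- nrow(X)
  d <- params$d
  heads <- params$heads
  if (is.null(p)) p <- 1 / (2 * n)
  use_gates <- qk_mask && !pin_gates
  if (training && dropout_rate > 0) {
    keep <- matrix(stats::runif(length(X)) >= dropout_rate, n, d)
    Xd <- X * keep / (1 - dropout_rate)
  } else {
    keep <- NULL
    Xd <- X
  }
  hc <- vector("list", heads)
  concat <- matrix(0, n, d)
  dh <- d %/% heads
  for (i in seq_len(heads)) {
    qkv <- project_qkv(Xd, params, i)
    if (use_gates) {
      G <- gate_fusion(qkv$Q, qkv$K, params$gate)
      gm <- gate_masks(G, params$gate)
    } else {
      G <- NULL
      gm <- list(MQ = matrix(1, n, dh), MK = matrix(1, n, dh))
    }
    S <- attention_scores(qkv$Q, qkv$K, gm, params$d_k)
    Mv <- if (v_mask) selection_mask(S, p) else matrix(1, n, n)
    Sm <- Mv * S
    h_i <- Sm %*% qkv$V
    concat[, ((i - 1L) * dh + 1L):(i * dh)] <- h_i
    hc[[i]] <- list(qkv = qkv, G = G, gm = gm, S = S, Mv = Mv, Sm = Sm)
  }
  list(concat = concat,
       cache = list(X = X, Xd = Xd, keep = keep, dropout_rate = dropout_rate,
                    heads = hc, use_gates = use_gates,
                    Sm = lapply(hc, `[[`, "Sm")))
}

# Backward pass through affm_forward. d_out is n x d. Returns dX and
# gradients mirroring the parameter structure.
affm_backward <- function(d_out, cache, params) {
  bnb <- bn_backward(d_out, cache$bnf, params$bn)
  at <- affm_attend_backward(bnb$dX, cache, params)
  list(dX = d_out + at$dX,
       grads = c(at$grads, list(bn = list(gamma = bnb$dgamma,
                                          beta = bnb$dbeta))))
}

# Backward through the attention stage only: d_concat is the gradient
# w.r.t. the concatenated head outputs; the returned dX covers the
# attention path (through dropout), not the residual.
affm_attend_backward <- function(d_concat, cache, params) {
  n <- nrow(d_concat)
  d <- params$d
  heads <- params$heads
  dh <- d %/% heads
  s <- sqrt(params$d_k)
  dXd <- matrix(0, n, d)
  ghead <- vector("list", heads)
  ggate <- list(WGQ = 0, WGK = 0, bGQ = 0, bGK = 0,
                WMQ = 0, WMK = 0, bMQ = 0, bMK = 0)
  for (i in seq_len(heads)) {
    hc <- cache$heads[[i]]
    hp <- params$head[[i]]
    dh_i <- d_concat[, ((i - 1L) * dh + 1L):(i * dh), drop = FALSE]
    dV <- crossprod(hc$Sm, dh_i)
    dSm <- dh_i %*% t(hc$qkv$V)
    dS <- hc$Mv * dSm
    dZ <- softmax_rows_backward(dS, hc$S)
    Qg <- hc$gm$MQ * hc$qkv$Q
    Kg <- hc$gm$MK * hc$qkv$K
    dQg <- dZ %*% Kg / s
    dKg <- crossprod(dZ, Qg) / s
    if (cache$use_gates) {
      dQ <- hc$gm$MQ * dQg
      dK <- hc$gm$MK * dKg
      dMQ <- hc$qkv$Q * dQg
      dMK <- hc$qkv$K * dKg
      dAq <- hc$gm$MQ * (1 - hc$gm$MQ) * dMQ
      dAk <- hc$gm$MK * (1 - hc$gm$MK) * dMK
      ggate$WMQ <- ggate$WMQ + crossprod(hc$G, dAq)
      ggate$WMK <- ggate$WMK + crossprod(hc$G, dAk)
      ggate$bMQ <- ggate$bMQ + colSums(dAq)
      ggate$bMK <- ggate$bMK + colSums(dAk)
      dG <- dAq %*% t(params$gate$WMQ) + dAk %*% t(params$gate$WMK)
      dG1 <- dG[, 1:dh, drop = FALSE]
      dG2 <- dG[, (dh + 1L):(2L * dh), drop = FALSE]
      ggate$WGQ <- ggate$WGQ + crossprod(hc$qkv$Q, dG1)
      ggate$WGK <- ggate$WGK + crossprod(hc$qkv$K, dG2)
      ggate$bGQ <- ggate$bGQ + colSums(dG1)
      ggate$bGK <- ggate$bGK + colSums(dG2)
      dQ <- dQ + dG1 %*% t(params$gate$WGQ)
      dK <- dK + dG2 %*% t(params$gate$WGK)
    } else {
      dQ <- dQg
      dK <- dKg
    }
    ghead[[i]] <- list(WQ = crossprod(cache$Xd, dQ),
                       WK = crossprod(cache$Xd, dK),
                       WV = crossprod(cache$Xd, dV))
    dXd <- dXd + dQ %*% t(hp$WQ) + dK %*% t(hp$WK) + dV %*% t(hp$WV)
  }
  if (!is.null(cache$keep)) {
    dXd <- dXd * cache$keep / (1 - cache$dropout_rate)
  }
  list(dX = dXd, grads = list(head = ghead, gate = ggate))
}
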