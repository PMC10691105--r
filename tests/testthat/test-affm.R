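make_params <- function(d = 8L, heads = 2L, seed = 1L) {
  affm_init(d, heads, seed = seed)
}

test_that("query/key/value projections are plain matrix products", {
  p <- make_params()
  X0 <- matrix(0, 3, 8)
  qkv <- project_qkv(X0, p, 1L)
  expect_equal(qkv$Q, matrix(0, 3, 4))
  expect_equal(qkv$V, matrix(0, 3, 4))
  set.seed(2)
  X <- matrix(rnorm(3 * 8), 3, 8)
  qkv <- project_qkv(X, p, 2L)
  # naive triple loop
  ref <- matrix(0, 3, 4)
  for (a in 1:3) for (b in 1:4) for (k in 1:8) {
    ref[a, b] <- ref[a, b] + X[a, k] * p$head[[2]]$WQ[k, b]
  }
  expect_equal(qkv$Q, ref, tolerance = 1e-12)
  expect_error(project_qkv(matrix(0, 3, 5), p, 1L), "dimension")
})

test_that("gate fusion concatenates the mapped query and key", {
  p <- make_params()
  g0 <- p$gate
  g0$WGQ[] <- 0; g0$WGK[] <- 0; g0$bGQ[] <- 0; g0$bGK[] <- 0
  Q <- matrix(rnorm(12), 3, 4)
  K <- matrix(rnorm(12), 3, 4)
  expect_equal(gate_fusion(Q, K, g0), matrix(0, 3, 8))
  gid <- g0
  gid$WGQ <- diag(4); gid$WGK <- diag(4)
  expect_equal(gate_fusion(Q, K, gid), cbind(Q, K))
  set.seed(3)
  ref <- cbind(sweep(Q %*% p$gate$WGQ, 2, p$gate$bGQ, `+`),
               sweep(K %*% p$gate$WGK, 2, p$gate$bGK, `+`))
  expect_equal(gate_fusion(Q, K, p$gate), ref)
  expect_error(gate_fusion(Q, K[1:2, ], p$gate), "mismatch")
})

test_that("gate masks are sigmoids of an affine map, strictly in (0,1)", {
  p <- make_params()
  gz <- p$gate
  gz$WMQ[] <- 0; gz$WMK[] <- 0; gz$bMQ[] <- 0; gz$bMK[] <- 0
  G <- matrix(rnorm(24), 3, 8)
  gm <- gate_masks(G, gz)
  expect_equal(gm$MQ, matrix(0.5, 3, 4))
  gsat <- gz
  gsat$bMQ[] <- 20
  expect_equal(gate_masks(G, gsat)$MQ, matrix(1, 3, 4), tolerance = 1e-8)
  gm2 <- gate_masks(G, p$gate)
  ref <- G %*% p$gate$WMK
  for (a in 1:3) for (b in 1:4) {
    ref[a, b] <- 1 / (1 + exp(-(ref[a, b] + p$gate$bMK[b])))
  }
  expect_equal(gm2$MK, ref, tolerance = 1e-12)
  expect_true(all(gm2$MQ > 0 & gm2$MQ < 1))
  expect_true(all(gm2$MK > 0 & gm2$MK < 1))
})

test_that("attention scores are a row softmax of the gated products", {
  Q0 <- matrix(0, 3, 4)
  K <- matrix(rnorm(12), 3, 4)
  expect_equal(attention_scores(Q0, K, d_k = 8), matrix(1 / 3, 3, 3))
  expect_equal(attention_scores(matrix(1, 1, 4), matrix(1, 1, 4), d_k = 8),
               matrix(1, 1, 1))
  set.seed(5)
  Q <- matrix(rnorm(16), 4, 4)
  K <- matrix(rnorm(16), 4, 4)
  masks <- list(MQ = matrix(runif(16), 4, 4), MK = matrix(runif(16), 4, 4))
  S <- attention_scores(Q, K, masks, d_k = 8)
  ref <- naive_row_softmax((masks$MQ * Q) %*% t(masks$MK * K) / sqrt(8))
  expect_equal(S, ref, tolerance = 1e-10)
  expect_equal(rowSums(S), rep(1, 4))
})

test_that("selection mask discards scores below the probability threshold", {
  S <- matrix(1 / 5, 5, 5)
  expect_equal(selection_mask(S, 1 / (2 * 5)), matrix(1, 5, 5))
  expect_equal(selection_mask(S, 0), matrix(1, 5, 5))
  S2 <- rbind(c(0.05, 0.95), c(0.5, 0.5))
  expect_equal(selection_mask(S2, 0.1), rbind(c(0, 1), c(1, 1)))
  # default threshold is half the uniform score
  expect_equal(selection_mask(S), matrix(1, 5, 5))
})

test_that("head output composes the mask with the scores, no renormalization", {
  set.seed(6)
  S <- naive_row_softmax(matrix(rnorm(16), 4, 4))
  V <- matrix(rnorm(12), 4, 3)
  expect_equal(head_output(S, matrix(1, 4, 4), V), S %*% V)
  expect_equal(head_output(S, matrix(0, 4, 4), V), matrix(0, 4, 3))
  mask <- matrix(rbinom(16, 1, 0.6), 4, 4)
  ref <- matrix(0, 4, 3)
  for (a in 1:4) for (f in 1:3) for (b in 1:4) {
    ref[a, f] <- ref[a, f] + mask[a, b] * S[a, b] * V[b, f]
  }
  expect_equal(head_output(S, mask, V), ref, tolerance = 1e-12)
  # masked row sums stay in [0, 1]
  rs <- rowSums(mask * S)
  expect_true(all(rs >= 0 & rs <= 1 + 1e-12))
})

test_that("with pinned gates and p = 0 the fusion equals textbook attention", {
  set.seed(7)
  for (r in 1:6) {
    n <- sample(c(2L, 5L), 1)
    d <- sample(c(8L, 16L), 1)
    h <- sample(c(1L, 2L, 4L), 1)
    p <- affm_init(d, h, seed = r)
    X <- matrix(rnorm(n * d), n, d)
    out <- affm_forward(X, p, p = 0, pin_gates = TRUE)$out
    expect_lt(max(abs(out - naive_mhsa(X, p))), 1e-5)
  }
})

test_that("zero value projections reduce the fusion to the residual", {
  p <- make_params(d = 8L, heads = 2L)
  for (i in 1:2) p$head[[i]]$WV[] <- 0
  set.seed(8)
  X <- matrix(rnorm(4 * 8), 4, 8)
  out <- affm_forward(X, p)$out
  expect_equal(out, X)   # fresh BN: shift of an all-zero head output is 0
})

test_that("the fusion is permutation-equivariant over group members", {
  p <- make_params(d = 8L, heads = 4L, seed = 12L)
  set.seed(9)
  X <- matrix(rnorm(5 * 8), 5, 8)
  perm <- c(3L, 5L, 1L, 2L, 4L)
  out <- affm_forward(X, p)$out
  outp <- affm_forward(X[perm, ], p)$out
  expect_equal(outp, out[perm, ], tolerance = 1e-10)
})

test_that("a single-member group passes through without batch statistics", {
  p <- make_params()
  X <- matrix(rnorm(8), 1, 8)
  out <- affm_forward(X, p, training = TRUE)$out
  expect_identical(dim(out), c(1L, 8L))
  expect_true(all(is.finite(out)))
})
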