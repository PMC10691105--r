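#' Construct a backbone by name
#'
#' A backbone is any CNN classifier trunk that can expose the feature maps of
#' every block of its last convolutional stage. Adapters implement two
#' generics: [list_stage_blocks()] (the ordered block identifiers) and
#' [forward_with_hooks()] (a forward pass that captures those blocks'
#' outputs). The shipped reference backbone is a small three-stage CNN whose
#' last stage has exactly three blocks, so multi-block mask intersection is
#' exercised without any pretrained weights.
#'
#' @param name Backbone identifier. `"tiny"` is the reference implementation.
#' @param image_size Square input side in pixels (default 224; synthetic
#'   desk-scale runs use 64).
#' @param channels Integer vector of length 3: channels of stage 1, stage 2,
#'   and of every block of the last stage. The embedding dimension equals
#'   `channels[3]`.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `pestfuse_backbone`.
#' @export
new_backbone <- function(name = "tiny", image_size = 224L,
                         channels = c(8L, 16L, 16L), seed = 1L) {
  if (!identical(name, "tiny")) {
    stop("backbone '", name, "' has no multi-block last-stage adapter; ",
         "an adapter must implement hook points list_stage_blocks() and ",
         "forward_with_hooks() exposing every block of the last ",
         "convolutional stage", call. = FALSE)
  }
  if (image_size %% 8L != 0L || image_size < 8L) {
    stop("image_size must be a positive multiple of 8", call. = FALSE)
  }
  set.seed(derive_seed(seed, 11L))
  he <- function(cin, cout) {
    matrix(stats::rnorm(9L * cin * cout, sd = sqrt(2 / (9L * cin))),
           9L * cin, cout)
  }
  # each layer: 3x3 conv (bias-free; the normalization shift plays that
  # role) + spatial batch norm with fresh running statistics
  layer <- function(cin, cout) {
    list(W = he(cin, cout),
         bn = list(gamma = rep(1, cout), beta = numeric(cout),
                   running_mean = numeric(cout), running_var = rep(1, cout)))
  }
  bb <- list(
    name = "tiny",
    image_size = as.integer(image_size),
    channels = as.integer(channels),
    stride = 8L,
    d = as.integer(channels[3]),
    params = list(
      s1 = layer(3L, channels[1]),
      s2 = layer(channels[1], channels[2]),
      b1 = layer(channels[2], channels[3]),
      b2 = layer(channels[3], channels[3]),
      b3 = layer(channels[3], channels[3])
    )
  )
  structure(bb, class = c("tiny_backbone", "pestfuse_backbone"))
}

#' Ordered identifiers of the last-stage blocks
#'
#' @param backbone A `pestfuse_backbone`.
#' @return Character vector of block identifiers, network-depth order.
#' @export
list_stage_blocks <- function(backbone) UseMethod("list_stage_blocks")

#' @export
list_stage_blocks.tiny_backbone <- function(backbone) c("b1", "b2", "b3")

#' Forward pass capturing every last-stage block output
#'
#' @param backbone A `pestfuse_backbone`.
#' @param images Numeric array `(side, side, 3, n)`, already resized and
#'   normalized.
#' @param keep_cache Keep intermediate activations for the backward pass.
#' @param training Use batch statistics and update running statistics in
#'   the normalization layers.
#' @return List with `blocks` (list of `(h, w, c, n)` arrays, one per
#'   last-stage block, depth order), `bn` (per-layer updated running
#'   statistics) and, when `keep_cache`, a `cache`.
#' @export
forward_with_hooks <- function(backbone, images, keep_cache = FALSE,
                               training = FALSE) {
  UseMethod("forward_with_hooks")
}

#' @export
forward_with_hooks.tiny_backbone <- function(backbone, images,
                                             keep_cache = FALSE,
                                             training = FALSE) {
  p <- backbone$params
  # conv + batch norm + ReLU, fused in the GEMM's (h*w*n) x cout matrix
  # layout; a single rearrangement to (h, w, cout, n) at the end
  cbr <- function(x, lay) {
    f <- conv3x3_forward(x, lay$W, numeric(ncol(lay$W)), keep_cache,
                         raw = TRUE)
    bnf <- bn_forward(f$ym, lay$bn, training)
    am <- relu_forward(bnf$y)
    d <- f$dims
    a <- aperm(array(am, c(d[1], d[2], d[4], ncol(lay$W))), c(1L, 2L, 4L, 3L))
    if (keep_cache) list(a = a, f = f, bnf = bnf, am = am)
    else list(a = a, bnf = bnf)
  }
  l1 <- cbr(images, p$s1)
  p1 <- avgpool2_forward(l1$a)
  l2 <- cbr(p1, p$s2)
  p2 <- avgpool2_forward(avgpool2_forward(l2$a))
  l3 <- cbr(p2, p$b1)
  l4 <- cbr(l3$a, p$b2)
  l5 <- cbr(l4$a, p$b3)
  out <- list(blocks = list(b1 = l3$a, b2 = l4$a, b3 = l5$a),
              bn = list(s1 = l1$bnf$bn, s2 = l2$bnf$bn, b1 = l3$bnf$bn,
                        b2 = l4$bnf$bn, b3 = l5$bnf$bn))
  if (keep_cache) {
    out$cache <- list(l1 = l1, l2 = l2, l3 = l3, l4 = l4, l5 = l5)
  }
  out
}

# Backward through the tiny backbone given the gradient w.r.t. the last
# block's activations. Returns parameter gradients (same shape as params).
backbone_backward <- function(backbone, d_o3, cache) {
  p <- backbone$params
  back_cbr <- function(da, l, lay, want_dx = TRUE) {
    d <- l$f$dims
    cout <- ncol(lay$W)
    dam <- aperm(da, c(1L, 2L, 4L, 3L))
    dim(dam) <- c(d[1] * d[2] * d[4], cout)
    dam[l$am <= 0] <- 0
    bnb <- bn_backward(dam, l$bnf, lay$bn)
    dW <- crossprod(l$f$cols, bnb$dX)
    dx <- NULL
    if (want_dx) {
      dy4 <- aperm(array(bnb$dX, c(d[1], d[2], d[4], cout)),
                   c(1L, 2L, 4L, 3L))
      dx <- conv_transpose_dx(dy4, lay$W, d[3])
    }
    list(dx = dx,
         g = list(W = dW,
                  bn = list(gamma = bnb$dgamma, beta = bnb$dbeta)))
  }
  k5 <- back_cbr(d_o3, cache$l5, p$b3)
  k4 <- back_cbr(k5$dx, cache$l4, p$b2)
  k3 <- back_cbr(k4$dx, cache$l3, p$b1)
  dp2 <- avgpool2_backward(avgpool2_backward(k3$dx))
  k2 <- back_cbr(dp2, cache$l2, p$s2)
  dp1 <- avgpool2_backward(k2$dx)
  # the input image needs no gradient: skip the first layer's dx
  k1 <- back_cbr(dp1, cache$l1, p$s1, want_dx = FALSE)
  list(s1 = k1$g, s2 = k2$g, b1 = k3$g, b2 = k4$g, b3 = k5$g)
}

#' Create a feature stack
#'
#' A feature stack is the ordered list of one image's last-stage block
#' feature maps; all blocks share the same spatial size.
#'
#' @param blocks List of numeric `(h, w, c)` arrays in network depth order.
#' @return An object of class `feature_stack`.
#' @export
feature_stack <- function(blocks) {
  stopifnot(length(blocks) >= 1L)
  dims <- vapply(blocks, function(b) dim(b)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all blocks of a feature stack must share (h, w)", call. = FALSE)
  }
  for (b in blocks) {
    if (!all(is.finite(b))) stop("feature values must be finite", call. = FALSE)
  }
  structure(list(blocks = blocks), class = "feature_stack")
}

#' Extract per-image feature stacks from the last convolutional stage
#'
#' @param backbone A `pestfuse_backbone`.
#' @param images Numeric array `(side, side, 3, n)` (or `(side, side, 3)` for
#'   a single image), resized and normalized.
#' @return A list of [feature_stack()] objects, one per image.
#' @export
extract_last_stage <- function(backbone, images) {
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  out <- forward_with_hooks(backbone, images)
  n <- dim(images)[4]
  lapply(seq_len(n), function(i) {
    feature_stack(lapply(out$blocks, function(b) {
      array(b[, , , i], dim(b)[1:3])
    }))
  })
}

#' Pool a feature block into an embedding
#'
#' Global average pooling: entry `k` of the embedding is the spatial mean of
#' channel `k`.
#'
#' @param block Numeric `(h, w, c)` array.
#' @return Numeric vector of length `c`.
#' @export
pool_embedding <- function(block) {
  d <- dim(block)
  dim(block) <- c(d[1] * d[2], d[3])
  colMeans(block)
}

#' Inverted dropout on an embedding
#'
#' During training each coordinate is zeroed independently with probability
#' `rate` and survivors are rescaled by `1/(1 - rate)`; at inference the
#' input is returned unchanged.
#'
#' @param e Numeric vector or matrix.
#' @param rate Drop probability in `[0, 1)`.
#' @param training Logical; dropout is applied only when `TRUE`.
#' @param seed Optional integer seed (restores the caller's RNG state).
#' @return Same shape as `e`.
#' @export
apply_embedding_dropout <- function(e, rate = 0.5, training = TRUE,
                                    seed = NULL) {
  if (rate < 0 || rate >= 1) stop("dropout rate must be in [0, 1)", call. = FALSE)
  if (!training || rate == 0) return(e)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  keep <- stats::runif(length(e)) >= rate
  out <- e * keep / (1 - rate)
  attr(out, "keep_mask") <- keep
  out
}
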