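#' Channel aggregation of a feature block
#'
#' Sums the feature maps over the channel dimension to obtain the activation
#' map `A`, and caches its spatial mean, which is the localization threshold
#' base.
#'
#' @param block Numeric `(h, w, c)` array.
#' @return An `activation_map`: list with `values` (h x w matrix) and
#'   `mean_value`.
#' @export
aggregate_channels <- function(block) {
  d <- dim(block)
  dim(block) <- c(d[1] * d[2], d[3])
  v <- matrix(rowSums(block), d[1], d[2])
  structure(list(values = v, mean_value = mean(v)), class = "activation_map")
}

#' Threshold-multiplier schedule for gradual localization
#'
#' During training (and validation) the multiplier on the activation-map mean
#' rises linearly from 0 to 1 over the run, so the localized region tightens
#' as the features become trustworthy; at test time the multiplier is fixed
#' at its median, 0.5.
#'
#' @param epochs Total number of training epochs (positive).
#' @param test_value Multiplier used in the testing phase (default 0.5).
#' @return A `lambda_schedule` object.
#' @export
lambda_schedule <- function(epochs, test_value = 0.5) {
  epochs <- as.integer(epochs)
  stopifnot(epochs >= 1L)
  structure(list(epochs = epochs, test_value = test_value),
            class = "lambda_schedule")
}

#' Threshold multiplier at a given epoch
#'
#' @param schedule A [lambda_schedule()].
#' @param epoch 0-based epoch index, `0 <= epoch < epochs`.
#' @param phase `"train"`, `"validation"` or `"test"`.
#' @return The multiplier in `[0, 1]`: `epoch / (epochs - 1)` while training
#'   or validating (1 when `epochs == 1`), `test_value` at test time.
#' @export
lambda_at <- function(schedule, epoch = 0L, phase = c("train", "validation", "test")) {
  phase <- match.arg(phase)
  if (phase == "test") return(schedule$test_value)
  if (epoch < 0L || epoch >= schedule$epochs) {
    stop("epoch must satisfy 0 <= epoch < epochs", call. = FALSE)
  }
  if (schedule$epochs == 1L) return(1)
  epoch / (schedule$epochs - 1L)
}

#' Binary mask of above-threshold activations
#'
#' Position `(i, j)` is retained iff `A(i, j) > lam * mean(A)` — strictly;
#' ties drop to 0, so a constant map yields an empty mask for any positive
#' multiplier.
#'
#' @param A An `activation_map` (or plain h x w matrix).
#' @param lam Threshold multiplier in `[0, 1]`.
#' @return Binary h x w matrix.
#' @export
threshold_mask <- function(A, lam) {
  stopifnot(lam >= 0, lam <= 1)
  if (inherits(A, "activation_map")) {
    v <- A$values
    m <- A$mean_value
  } else {
    v <- A
    m <- mean(A)
  }
  (v > lam * m) + 0
}

#' Elementwise intersection of binary masks
#'
#' A position survives only if every per-block mask retains it.
#'
#' @param masks List of binary matrices of identical shape (length >= 1).
#' @return Binary matrix.
#' @export
intersect_masks <- function(masks) {
  stopifnot(length(masks) >= 1L)
  d <- dim(masks[[1]])
  out <- masks[[1]]
  for (m in masks[-1]) {
    if (!identical(dim(m), d)) stop("mask shape mismatch", call. = FALSE)
    out <- out * m
  }
  out
}

#' Minimal bounding box of a mask
#'
#' Coordinates are 0-based, half-open `[start, stop)`. An all-zero mask falls
#' back to the box of the whole map.
#'
#' @param mf Binary h x w matrix.
#' @return A `bbox`: list with `row_start`, `row_stop`, `col_start`,
#'   `col_stop`.
#' @export
mask_to_bbox <- function(mf) {
  h <- nrow(mf)
  w <- ncol(mf)
  pos <- which(mf != 0, arr.ind = TRUE)
  if (nrow(pos) == 0L) {
    box <- list(row_start = 0L, row_stop = h, col_start = 0L, col_stop = w)
  } else {
    box <- list(row_start = min(pos[, 1]) - 1L, row_stop = max(pos[, 1]),
                col_start = min(pos[, 2]) - 1L, col_stop = max(pos[, 2]))
  }
  structure(lapply(box, as.integer), class = "bbox")
}

#' Crop a feature stack to a box and upsample back to full size
#'
#' Each block's spatial slice is bilinearly resized back to `(h, w)` with
#' corner-anchored sampling, so a full-map box is the identity.
#'
#' @param stack A [feature_stack()].
#' @param box A `bbox` from [mask_to_bbox()].
#' @return A [feature_stack()] of the same shapes.
#' @export
crop_and_upsample <- function(stack, box) {
  feature_stack(lapply(stack$blocks, crop_resize_block, box = box))
}

# Box from a list of (h, w, c) block arrays; intersects the masks of the
# last `num_blocks` blocks at multiplier lam.
localize_box <- function(blocks, lam, num_blocks = length(blocks)) {
  num_blocks <- min(num_blocks, length(blocks))
  use <- blocks[(length(blocks) - num_blocks + 1L):length(blocks)]
  masks <- lapply(use, function(b) threshold_mask(aggregate_channels(b), lam))
  mask_to_bbox(intersect_masks(masks))
}

#' Locate the target region of a feature stack
#'
#' Runs the full localization chain: channel aggregation per block,
#' mean-relative thresholding at multiplier `lam`, intersection of the
#' per-block masks, bounding-box extraction (whole-map fallback when the
#' intersection is empty), and crop + bilinear upsample of every block.
#'
#' @param stack A [feature_stack()].
#' @param lam Threshold multiplier in `[0, 1]`.
#' @param num_blocks Number of deepest blocks whose masks are intersected
#'   (default: all).
#' @return List with `stack` (the localized [feature_stack()]) and `box`.
#' @export
localize <- function(stack, lam, num_blocks = length(stack$blocks)) {
  box <- localize_box(stack$blocks, lam, num_blocks)
  list(stack = crop_and_upsample(stack, box), box = box)
}

#' Tidy a set of bounding boxes
#'
#' @param boxes List of `bbox` objects (optionally named by image id).
#' @param lambda The threshold multiplier they were computed at.
#' @param stride Backbone stride; set it to back-project feature-map
#'   coordinates to image pixels.
#' @return A tibble with one row per box.
#' @export
bbox_tibble <- function(boxes, lambda = NA_real_, stride = 1L) {
  ids <- names(boxes)
  if (is.null(ids)) ids <- as.character(seq_along(boxes))
  field <- function(k) {
    unname(vapply(boxes, function(b) b[[k]], integer(1))) * stride
  }
  tibble::tibble(
    image_id = ids,
    row_start = field("row_start"), row_stop = field("row_stop"),
    col_start = field("col_start"), col_stop = field("col_stop"),
    lambda = lambda
  )
}
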