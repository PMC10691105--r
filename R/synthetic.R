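# Synthetic desk-scale datasets that emulate the failure modes of field pest
# photos: a localized textured target on a cluttered background, a fraction
# of wrongly labelled images, a fraction with no target at all, and variable
# blur. Classes differ by blob shape, texture frequency and hue so a tiny
# CNN can separate them quickly.

#' Specification of a synthetic dataset
#'
#' @param n_classes Number of classes.
#' @param images_per_class Images generated per class.
#' @param image_side Square image side in pixels.
#' @param clutter_density Expected distractor blobs per image scale, in
#'   `[0, 1]` (0 = clean background).
#' @param label_error_rate Probability an image's assigned label is swapped
#'   to a different class.
#' @param no_target_rate Probability an image contains no target blob.
#' @param blur_rate Probability an image is Gaussian-blurred.
#' @param seed Integer seed; generation is fully reproducible from the spec.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_classes = 5L, images_per_class = 57L,
                           image_side = 64L, clutter_density = 0.5,
                           label_error_rate = 0.1, no_target_rate = 0.1,
                           blur_rate = 0.2, seed = 1L) {
  rates <- c(clutter_density, label_error_rate, no_target_rate, blur_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  structure(list(
    n_classes = as.integer(n_classes),
    images_per_class = as.integer(images_per_class),
    image_side = as.integer(image_side),
    clutter_density = clutter_density,
    label_error_rate = label_error_rate,
    no_target_rate = no_target_rate,
    blur_rate = blur_rate,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# Distinct per-class blob appearance: shape cycles through five silhouettes,
# texture frequency and hue are evenly spaced.
class_blob_params <- function(k, n_classes) {
  shapes <- c("ellipse", "rect", "cross", "ring", "triangle")
  hue <- (k - 1) / n_classes
  list(shape = shapes[(k - 1L) %% length(shapes) + 1L],
       freq = 2 + 1.5 * (k - 1L),
       hue = hue)
}

hsv_rgb <- function(h, s, v) {
  rgb <- grDevices::col2rgb(grDevices::hsv(h %% 1, s, v)) / 255
  as.numeric(rgb)
}

shape_mask <- function(shape, size) {
  u <- (seq_len(size) - (size + 1) / 2) / (size / 2)
  X <- matrix(u, size, size)
  Y <- t(X)
  switch(shape,
    ellipse = (X / 0.95)^2 + (Y / 0.7)^2 <= 1,
    rect = abs(X) <= 0.85 & abs(Y) <= 0.6,
    cross = (abs(X) <= 0.3 & abs(Y) <= 0.95) | (abs(Y) <= 0.3 & abs(X) <= 0.95),
    ring = {
      r2 <- X^2 + Y^2
      r2 <= 1 & r2 >= 0.35
    },
    triangle = Y >= -0.8 & abs(X) <= (0.9 - Y) / 1.8
  )
}

# Striped texture in [0,1] at the class frequency/orientation.
blob_texture <- function(size, freq, theta = pi / 5) {
  u <- seq_len(size) / size
  X <- matrix(u, size, size)
  Y <- t(X)
  0.55 + 0.45 * sin(2 * pi * freq * (X * cos(theta) + Y * sin(theta)))
}

gauss_kernel_matrix <- function(n, sigma) {
  K <- outer(seq_len(n), seq_len(n), function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
  sweep(K, 1L, rowSums(K), `/`)
}

draw_clutter <- function(side, density) {
  img <- array(0.35, c(side, side, 3))
  n_blobs <- round(density * 10)
  u <- seq_len(side)
  for (b in seq_len(n_blobs)) {
    cx <- stats::runif(1, 1, side)
    cy <- stats::runif(1, 1, side)
    r <- stats::runif(1, side / 16, side / 5)
    col <- hsv_rgb(stats::runif(1), stats::runif(1, 0.05, 0.25),
                   stats::runif(1, 0.3, 0.6))
    w <- exp(-(outer((u - cy)^2, (u - cx)^2, `+`)) / (2 * r^2))
    for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - w) + col[ch] * w
  }
  img + array(stats::rnorm(side * side * 3, sd = 0.04), c(side, side, 3))
}

#' Generate a synthetic pest-image dataset
#'
#' Writes PNG images, a `manifest.csv` (`path,label,split`), a
#' `ground_truth.csv`
#' (`path,true_label,assigned_label,target_present,box_r0,box_r1,box_c0,box_c1`)
#' and the spec as `spec.yaml` under `out_dir`. Each class is split 70/30
#' into train/test. Target boxes are 0-based half-open pixel coordinates;
#' they are empty (NA) when the target is absent.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory (created if missing).
#' @return A tibble with one row per image: manifest columns plus ground
#'   truth and corruption flags.
#' @export
generate_dataset <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  set.seed(derive_seed(spec$seed, 71L))
  side <- spec$image_side
  rows <- vector("list", spec$n_classes * spec$images_per_class)
  idx <- 0L
  for (k in seq_len(spec$n_classes)) {
    cls_dir <- file.path(out_dir, sprintf("class_%02d", k - 1L))
    dir.create(cls_dir, showWarnings = FALSE)
    bp <- class_blob_params(k, spec$n_classes)
    n_train <- round(0.7 * spec$images_per_class)
    for (i in seq_len(spec$images_per_class)) {
      idx <- idx + 1L
      img <- draw_clutter(side, spec$clutter_density)
      has_target <- stats::runif(1) >= spec$no_target_rate
      box <- rep(NA_integer_, 4)
      if (has_target) {
        size <- round(stats::runif(1, 0.18, 0.30) * side)
        r0 <- sample.int(side - size, 1L) - 1L
        c0 <- sample.int(side - size, 1L) - 1L
        mask <- shape_mask(bp$shape, size)
        tex <- blob_texture(size, bp$freq, theta = stats::runif(1, 0, pi))
        col <- hsv_rgb(bp$hue, 0.85, 0.95)
        for (ch in 1:3) {
          patch <- img[(r0 + 1):(r0 + size), (c0 + 1):(c0 + size), ch]
          patch[mask] <- (col[ch] * tex)[mask]
          img[(r0 + 1):(r0 + size), (c0 + 1):(c0 + size), ch] <- patch
        }
        box <- c(r0, r0 + size, c0, c0 + size)
      }
      if (stats::runif(1) < spec$blur_rate) {
        B <- gauss_kernel_matrix(side, stats::runif(1, 0.8, 2))
        for (ch in 1:3) img[, , ch] <- B %*% img[, , ch] %*% t(B)
      }
      corrupted <- stats::runif(1) < spec$label_error_rate
      assigned <- if (corrupted && spec$n_classes > 1L) {
        sample(setdiff(seq_len(spec$n_classes), k), 1L) - 1L
      } else {
        k - 1L
      }
      img[img < 0] <- 0
      img[img > 1] <- 1
      path <- file.path(cls_dir, sprintf("img_%03d.png", i))
      png::writePNG(img, path)
      rows[[idx]] <- tibble::tibble(
        path = path, label = as.integer(assigned),
        split = if (i <= n_train) "train" else "test",
        true_label = k - 1L, assigned_label = as.integer(assigned),
        target_present = has_target,
        box_r0 = box[1], box_r1 = box[2], box_c0 = box[3], box_c1 = box[4]
      )
    }
  }
  gt <- dplyr::bind_rows(rows)
  utils::write.csv(gt[, c("path", "label", "split")],
                   file.path(out_dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(
    gt[, c("path", "true_label", "assigned_label", "target_present",
           "box_r0", "box_r1", "box_c0", "box_c1")],
    file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  yaml::write_yaml(unclass(spec), file.path(out_dir, "spec.yaml"))
  gt
}

#' Feature-stack fixture with a planted hot region
#'
#' Builds a multi-block feature stack whose planted box has value
#' `hot_value` (plus optional Gaussian noise) on a `background_value`
#' background, together with the analytically expected threshold mask and
#' bounding box at a given threshold multiplier — direct localization test
#' vectors that bypass any CNN.
#'
#' @param h,w Spatial size of every block.
#' @param blocks Number of blocks.
#' @param blob_box List with `row_start`, `row_stop`, `col_start`,
#'   `col_stop` (0-based half-open) inside `(h, w)`.
#' @param hot_value,background_value Plateau values, `hot_value >
#'   background_value >= 0`.
#' @param channels Channels per block.
#' @param noise_sd Gaussian noise standard deviation (0 = exact plateau).
#' @param lambda Multiplier at which the expected mask is evaluated.
#' @param seed Integer seed for the noise.
#' @return List with `stack` ([feature_stack()]), `expected_mask`
#'   (noise-free analytic mask at `lambda`) and `expected_box`.
#' @export
generate_feature_stack_fixture <- function(h, w, blocks = 3L, blob_box,
                                           hot_value = 10,
                                           background_value = 0.1,
                                           channels = 4L, noise_sd = 0,
                                           lambda = 0.5, seed = 1L) {
  stopifnot(hot_value > background_value, background_value >= 0)
  if (blob_box$row_start < 0 || blob_box$row_stop > h ||
      blob_box$col_start < 0 || blob_box$col_stop > w ||
      blob_box$row_start >= blob_box$row_stop ||
      blob_box$col_start >= blob_box$col_stop) {
    stop("blob_box outside the (h, w) grid", call. = FALSE)
  }
  set.seed(derive_seed(seed, 131L))
  base <- matrix(background_value, h, w)
  base[(blob_box$row_start + 1):blob_box$row_stop,
       (blob_box$col_start + 1):blob_box$col_stop] <- hot_value
  blks <- lapply(seq_len(blocks), function(b) {
    arr <- array(rep(base, channels), c(h, w, channels))
    if (noise_sd > 0) arr <- arr + array(stats::rnorm(length(arr), sd = noise_sd), dim(arr))
    arr[arr < 0] <- 0
    arr
  })
  # Analytic mask: channel sum is channels * value; positions pass iff
  # value > lambda * mean(value surface).
  area <- (blob_box$row_stop - blob_box$row_start) *
    (blob_box$col_stop - blob_box$col_start)
  abar <- (hot_value * area + background_value * (h * w - area)) / (h * w)
  expected_mask <- (base > lambda * abar) + 0
  structure(list(
    stack = feature_stack(blks),
    expected_mask = expected_mask,
    expected_box = mask_to_bbox(expected_mask)
  ), class = "stack_fixture")
}

#' Intersection-over-union of two boxes
#'
#' @param a,b Boxes (`bbox` or lists with the four half-open fields).
#' @return IoU in `[0, 1]`.
#' @export
bbox_iou <- function(a, b) {
  ri <- max(0, min(a$row_stop, b$row_stop) - max(a$row_start, b$row_start))
  ci <- max(0, min(a$col_stop, b$col_stop) - max(a$col_start, b$col_start))
  inter <- ri * ci
  area <- function(x) (x$row_stop - x$row_start) * (x$col_stop - x$col_start)
  un <- area(a) + area(b) - inter
  if (un <= 0) return(0)
  inter / un
}
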