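#' Fused prediction for one group of images
#'
#' All supplied images are treated as one group of the same (unknown)
#' class: they pass through localization, attention fusion and the shared
#' classifier, and soft voting integrates the per-image probabilities into
#' a single decision. No labels are required.
#'
#' @param object A `pestfuse_model`, `pestfuse_fit` or checkpoint path.
#' @param image_paths One or more image paths.
#' @param top Number of top classes to report (default 5).
#' @return A `pestfuse_prediction`: list with `predicted_label`, `top`
#'   (tibble of the top classes and soft-vote probabilities) and `boxes`
#'   (per-image localization boxes in image pixels).
#' @export
predict_group <- function(object, image_paths, top = 5L) {
  model <- as_model(object)
  if (length(image_paths) < 1L) stop("at least one image required", call. = FALSE)
  imgs <- load_images(image_paths, model$config$backbone$image_size)
  fw <- forward_group(model, imgs, "test")
  sv <- soft_vote(fw$improving)
  ord <- order(sv$probabilities, decreasing = TRUE)[seq_len(min(top, model$m))]
  names(fw$boxes) <- image_paths
  structure(list(
    predicted_label = sv$class,
    top = tibble::tibble(label = ord - 1L, probability = sv$probabilities[ord]),
    boxes = bbox_tibble(fw$boxes, lambda = fw$lambda,
                        stride = model$backbone$stride)
  ), class = "pestfuse_prediction")
}

#' @export
print.pestfuse_prediction <- function(x, ...) {
  cat("predicted label:", x$predicted_label, "\n")
  print(x$top)
  invisible(x)
}
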