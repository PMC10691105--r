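#' Shared softmax classifier
#'
#' Row-softmax of `X W + b`. Both the general and the improving branch call
#' this with the same parameters — the classifier is shared.
#'
#' @param X n x d embedding matrix (rows are images).
#' @param fc List with `W` (d x m) and `b` (length m).
#' @return n x m probability matrix; rows sum to 1.
#' @export
classify <- function(X, fc) {
  if (ncol(X) != nrow(fc$W)) stop("classifier dimension mismatch", call. = FALSE)
  softmax_rows(sweep(X %*% fc$W, 2L, fc$b, `+`))
}

#' Soft voting over a group's probability rows
#'
#' Averages the per-image class probabilities and takes the class with the
#' highest mean (lowest index on ties).
#'
#' @param P n x m probability matrix.
#' @return List with `class` (0-based index) and `probabilities` (the mean
#'   vector).
#' @export
soft_vote <- function(P) {
  pr <- colMeans(P)
  list(class = which.max(pr) - 1L, probabilities = pr)
}

#' Hard voting over per-image predicted labels
#'
#' Takes the modal label; ties are broken by soft voting over the same
#' group's probability rows when supplied, otherwise by the lowest label.
#'
#' @param labels Nonempty vector of 0-based class indices.
#' @param P Optional n x m probability matrix for tie-breaking.
#' @return 0-based class index.
#' @export
hard_vote <- function(labels, P = NULL) {
  if (length(labels) == 0L) stop("empty label list", call. = FALSE)
  tab <- table(labels)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1L && !is.null(P)) {
    cand <- as.integer(top)
    sv <- soft_vote(P)$probabilities
    return(cand[which.max(sv[cand + 1L])])
  }
  as.integer(top[1L])
}

#' Mean cross-entropy of a branch
#'
#' Mean over rows of `-log` probability at the true class; identical for
#' both branches. Zero probabilities are clamped at 1e-12 with a warning.
#'
#' @param P n x m probability matrix.
#' @param t Vector of 0-based true labels (length n, values in `[0, m)`).
#' @return Nonnegative scalar loss.
#' @export
branch_loss <- function(P, t) {
  m <- ncol(P)
  if (any(t < 0L | t >= m)) stop("labels out of range", call. = FALSE)
  pt <- P[cbind(seq_len(nrow(P)), t + 1L)]
  if (any(pt <= 0)) {
    warning("zero probability at true class clamped to 1e-12")
    pt <- pmax(pt, 1e-12)
  }
  mean(-log(pt))
}

#' Combine the two branch losses
#'
#' The overall training loss is the plain sum of the general-branch and
#' improving-branch cross-entropies; a disabled improving branch
#' contributes 0.
#'
#' @param l_general,l_improving Nonnegative branch losses.
#' @return List with `l_general`, `l_improving`, `l_total`.
#' @export
total_loss <- function(l_general, l_improving = 0) {
  list(l_general = l_general, l_improving = l_improving,
       l_total = l_general + l_improving)
}

#' Multiclass accuracy and weighted F1
#'
#' Accuracy is the fraction of correct predictions; precision, recall and
#' F1 are computed one-vs-rest per class, and the weighted F1 is the
#' support-weighted mean of per-class F1 (classes absent from the truth are
#' excluded from the weighting).
#'
#' @param predictions,truths Equal-length vectors of 0-based labels.
#' @param m Number of classes.
#' @return A `pestfuse_metrics` object: list with `accuracy`,
#'   `weighted_f1`, `per_class` (tibble) and `confusion` (m x m count
#'   matrix, truth in rows).
#' @export
compute_metrics <- function(predictions, truths, m) {
  if (length(predictions) == 0L || length(predictions) != length(truths)) {
    stop("predictions and truths must be nonempty and equal length",
         call. = FALSE)
  }
  lev <- 0:(m - 1L)
  conf <- table(factor(truths, levels = lev), factor(predictions, levels = lev))
  conf <- matrix(as.integer(conf), m, m,
                 dimnames = list(truth = lev, prediction = lev))
  tp <- unname(diag(conf))
  support <- unname(rowSums(conf))
  predicted <- unname(colSums(conf))
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  keep <- support > 0
  per_class <- tibble::tibble(
    label = lev, precision = precision, recall = recall, f1 = f1,
    support = as.integer(support)
  )
  structure(list(
    accuracy = sum(tp) / length(truths),
    weighted_f1 = sum(f1[keep] * support[keep]) / sum(support[keep]),
    per_class = per_class,
    confusion = conf
  ), class = "pestfuse_metrics")
}

#' @export
print.pestfuse_metrics <- function(x, ...) {
  cat(sprintf("pestfuse metrics: accuracy %.4f, weighted F1 %.4f over %d labels\n",
              x$accuracy, x$weighted_f1, sum(x$per_class$support)))
  print(x$per_class)
  invisible(x)
}

#' Write a metrics report to JSON (and optionally the confusion matrix CSV)
#'
#' @param metrics A `pestfuse_metrics` object.
#' @param json_path Output JSON path.
#' @param confusion_csv Optional CSV path for the confusion matrix.
#' @return `json_path`, invisibly.
#' @export
write_metrics <- function(metrics, json_path, confusion_csv = NULL) {
  jsonlite::write_json(list(
    accuracy = metrics$accuracy,
    weighted_f1 = metrics$weighted_f1,
    per_class = metrics$per_class
  ), json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(confusion_csv)) {
    utils::write.csv(as.data.frame.matrix(metrics$confusion), confusion_csv)
  }
  invisible(json_path)
}
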