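# Two-branch training pipeline: group-batch sampling, the shared-classifier
# forward pass (general branch per image; improving branch through
# localization, gated attention fusion and soft voting), jointly optimized
# cross-entropy losses, and the evaluation loops.

#' Load images into a normalized batch array
#'
#' Reads PNG files, converts to RGB, bilinearly resizes to a square side and
#' normalizes to roughly unit scale (`(x - 0.5) / 0.25`).
#'
#' @param paths Character vector of image paths.
#' @param side Target square side.
#' @param normalize Apply the normalization (default TRUE).
#' @return Array `(side, side, 3, n)`.
#' @export
load_images <- function(paths, side, normalize = TRUE) {
  out <- array(0, c(side, side, 3L, length(paths)))
  full <- list(row_start = 0L, row_stop = NA_integer_,
               col_start = 0L, col_stop = NA_integer_)
  for (i in seq_along(paths)) {
    if (!file.exists(paths[i])) stop("unreadable image: ", paths[i], call. = FALSE)
    img <- png::readPNG(paths[i])
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
    if (dim(img)[1] != side || dim(img)[2] != side) {
      box <- list(row_start = 0L, row_stop = dim(img)[1],
                  col_start = 0L, col_stop = dim(img)[2])
      R <- interp_matrix(side, 0L, dim(img)[1], dim(img)[1])
      Cm <- interp_matrix(side, 0L, dim(img)[2], dim(img)[2])
      img <- vapply(1:3, function(ch) R %*% img[, , ch] %*% t(Cm),
                    matrix(0, side, side))
    }
    out[, , , i] <- img
  }
  if (normalize) out <- (out - 0.5) / 0.25
  out
}

#' Initialize a two-branch recognition model
#'
#' @param config A configuration from [load_config()] / [default_config()].
#' @param m Number of classes.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A `pestfuse_model`: backbone, attention-fusion parameters, the
#'   shared classifier, and the threshold schedule.
#' @export
init_model <- function(config = default_config(), m, seed = config$seed) {
  backbone <- new_backbone(config$backbone$name, config$backbone$image_size,
                           config$backbone$channels, seed = seed)
  d <- backbone$d
  affm <- affm_init(d, config$affm$heads, seed = seed)
  set.seed(derive_seed(seed, 37L))
  fc <- list(W = matrix(stats::rnorm(d * m, sd = sqrt(1 / d)), d, m),
             b = numeric(m))
  structure(list(
    backbone = backbone, affm = affm, fc = fc,
    schedule = lambda_schedule(config$optim$epochs, config$eflm$test_lambda),
    config = config, m = as.integer(m), d = d
  ), class = "pestfuse_model")
}

as_manifest <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- tibble::as_tibble(utils::read.csv(manifest,
                                                  stringsAsFactors = FALSE))
  }
  manifest <- tibble::as_tibble(manifest)
  need <- c("path", "label", "split")
  if (!all(need %in% names(manifest))) {
    stop("manifest needs columns path, label, split", call. = FALSE)
  }
  if (nrow(manifest) == 0L) stop("empty manifest", call. = FALSE)
  manifest
}

#' Sample same-class training groups around anchor images
#'
#' Every training image serves as one anchor per epoch (in a seeded random
#' order); each anchor draws `n_t - 1` additional images of its own class —
#' without replacement when the class is large enough, with replacement
#' otherwise. Anchors are chunked into batches for the optimizer.
#'
#' @param manifest Manifest tibble (or CSV path); only `split == "train"`
#'   rows are used when a split column is present.
#' @param batch_anchors Anchors per optimizer batch (default 16).
#' @param n_t Group size (default 5).
#' @param seed,epoch Together determine the sampling; the same pair
#'   reproduces the same group sequence.
#' @return List with `groups` (list of row-index vectors into the train
#'   manifest), `batches` (list of group-index vectors) and `manifest` (the
#'   train rows).
#' @export
build_group_batches <- function(manifest, batch_anchors = 16L, n_t = 5L,
                                seed = 1L, epoch = 0L) {
  manifest <- as_manifest(manifest)
  train <- manifest[manifest$split == "train", ]
  if (nrow(train) == 0L) stop("no training rows in manifest", call. = FALSE)
  set.seed(derive_seed(seed, 211L, epoch))
  anchors <- sample.int(nrow(train))
  by_class <- split(seq_len(nrow(train)), train$label)
  groups <- lapply(anchors, function(a) {
    cls <- by_class[[as.character(train$label[a])]]
    if (n_t == 1L) return(a)
    if (length(cls) >= n_t) {
      others <- setdiff(cls, a)
      c(a, sample(others, n_t - 1L))
    } else {
      c(a, sample(cls, n_t - 1L, replace = TRUE))
    }
  })
  n_b <- ceiling(length(groups) / batch_anchors)
  batches <- split(seq_along(groups),
                   rep(seq_len(n_b), each = batch_anchors)[seq_along(groups)])
  list(groups = groups, batches = unname(batches), manifest = train)
}

# Current-epoch threshold multiplier under the configured schedule.
model_lambda <- function(model, epoch, phase) {
  cfg <- model$config$eflm
  if (phase == "test") return(cfg$test_lambda)
  if (!cfg$gradual) return(1)
  lambda_at(model$schedule, epoch, phase)
}

#' Two-branch forward pass over one group
#'
#' General branch: backbone, global average pooling, dropout (training
#' only), shared classifier. Improving branch: localization at the
#' scheduled threshold multiplier, pooling of the last localized block,
#' gated attention fusion, the same shared classifier.
#'
#' @param model A `pestfuse_model`.
#' @param images Array `(side, side, 3, n)` — one same-class group.
#' @param phase `"train"`, `"validation"` or `"test"`.
#' @param epoch 0-based epoch (ignored at test time).
#' @param keep_cache Keep every intermediate for the backward pass.
#' @return List with `general` and `improving` probability matrices
#'   (n x m), `boxes` (per-image `bbox`), `lambda`, and internals when
#'   `keep_cache`.
#' @export
forward_group <- function(model, images, phase = "test", epoch = 0L,
                          keep_cache = FALSE) {
  cfg <- model$config
  training <- phase == "train"
  n <- dim(images)[4]
  bb <- forward_with_hooks(model$backbone, images, keep_cache,
                           training = training)
  b3 <- bb$blocks[[length(bb$blocks)]]
  hw <- dim(b3)[1:2]
  lam <- model_lambda(model, epoch, phase)

  Eg <- gap_forward(b3)                    # d x n
  Xg <- t(Eg)
  if (training && cfg$backbone$dropout_rate > 0) {
    keep <- matrix(stats::runif(length(Xg)) >= cfg$backbone$dropout_rate,
                   n, model$d)
    Xgd <- Xg * keep / (1 - cfg$backbone$dropout_rate)
  } else {
    keep <- NULL
    Xgd <- Xg
  }
  Pg <- classify(Xgd, model$fc)

  full_box <- structure(list(row_start = 0L, row_stop = hw[1],
                             col_start = 0L, col_stop = hw[2]),
                        class = "bbox")
  if (cfg$eflm$enabled) {
    boxes <- lapply(seq_len(n), function(i) {
      localize_box(lapply(bb$blocks, function(b) array(b[, , , i], dim(b)[1:3])),
                   lam, cfg$eflm$num_blocks)
    })
    Xl <- t(vapply(seq_len(n), function(i) {
      pool_embedding(crop_resize_block(array(b3[, , , i], dim(b3)[1:3]),
                                       boxes[[i]]))
    }, numeric(model$d)))
  } else {
    boxes <- rep(list(full_box), n)
    Xl <- Xg
  }

  af <- NULL
  if (cfg$affm$enabled) {
    af <- affm_forward(Xl, model$affm, p = cfg$affm$p, training = training,
                       dropout_rate = cfg$backbone$dropout_rate,
                       qk_mask = cfg$affm$qk_mask, v_mask = cfg$affm$v_mask,
                       keep_cache = keep_cache)
    Xi <- af$out
  } else {
    Xi <- Xl
  }
  Pi <- classify(Xi, model$fc)

  out <- list(general = Pg, improving = Pi, boxes = boxes, lambda = lam,
              bn = if (!is.null(af)) af$bn else model$affm$bn,
              bn_backbone = bb$bn)
  if (keep_cache) {
    out$cache <- list(bb = bb, b3 = b3, hw = hw, Eg = Eg, Xg = Xg, Xgd = Xgd,
                      keep = keep, Xl = Xl, Xi = Xi, af = af, n = n)
  }
  out
}

# One optimizer batch: all groups' images pass through the backbone (and
# the fusion block's batch normalization) together, so normalization
# statistics mix classes exactly as the anchor-batch protocol implies;
# attention itself stays within each group. Returns mean per-image losses,
# parameter gradients, and updated running statistics.
train_batch_step <- function(model, images, labels, groups) {
  cfg <- model$config
  N <- dim(images)[4]
  m <- model$m
  d <- model$d
  bb <- forward_with_hooks(model$backbone, images, keep_cache = TRUE,
                           training = TRUE)
  b3 <- bb$blocks[[length(bb$blocks)]]
  hw <- dim(b3)[1:2]
  lam <- model_lambda(model, attr(groups, "epoch"), "train")

  Eg <- gap_forward(b3)
  Xg <- t(Eg)
  if (cfg$backbone$dropout_rate > 0) {
    keep <- matrix(stats::runif(length(Xg)) >= cfg$backbone$dropout_rate,
                   N, d)
    Xgd <- Xg * keep / (1 - cfg$backbone$dropout_rate)
  } else {
    keep <- NULL
    Xgd <- Xg
  }
  Pg <- classify(Xgd, model$fc)
  l_g <- branch_loss(Pg, labels)

  if (cfg$eflm$enabled) {
    boxes <- lapply(seq_len(N), function(i) {
      localize_box(lapply(bb$blocks,
                          function(b) array(b[, , , i], dim(b)[1:3])),
                   lam, cfg$eflm$num_blocks)
    })
    Xl <- t(vapply(seq_len(N), function(i) {
      pool_embedding(crop_resize_block(array(b3[, , , i], dim(b3)[1:3]),
                                       boxes[[i]]))
    }, numeric(d)))
  } else {
    boxes <- NULL
    Xl <- Xg
  }

  at_caches <- NULL
  bnf <- NULL
  if (cfg$affm$enabled) {
    C_all <- matrix(0, N, d)
    at_caches <- vector("list", length(groups))
    for (g in seq_along(groups)) {
      rows <- groups[[g]]
      at <- affm_attend(Xl[rows, , drop = FALSE], model$affm,
                        p = cfg$affm$p, training = TRUE,
                        dropout_rate = cfg$backbone$dropout_rate,
                        qk_mask = cfg$affm$qk_mask,
                        v_mask = cfg$affm$v_mask)
      C_all[rows, ] <- at$concat
      at_caches[[g]] <- at$cache
    }
    bnf <- bn_forward(C_all, model$affm$bn, training = TRUE)
    Xi <- bnf$y + Xl
  } else {
    Xi <- Xl
  }
  Pi <- classify(Xi, model$fc)
  l_i <- branch_loss(Pi, labels)

  Y <- matrix(0, N, m)
  Y[cbind(seq_len(N), labels + 1L)] <- 1
  Gg <- (Pg - Y) / N
  Gi <- (Pi - Y) / N
  g_fc <- list(W = crossprod(Xgd, Gg) + crossprod(Xi, Gi),
               b = colSums(Gg) + colSums(Gi))

  dXgd <- Gg %*% t(model$fc$W)
  dXg <- if (is.null(keep)) dXgd else {
    dXgd * keep / (1 - cfg$backbone$dropout_rate)
  }
  d_b3 <- gap_backward(t(dXg), hw[1], hw[2])

  dXi <- Gi %*% t(model$fc$W)
  g_affm <- NULL
  if (cfg$affm$enabled) {
    bnb <- bn_backward(dXi, bnf, model$affm$bn)
    dXl <- dXi
    for (g in seq_along(groups)) {
      rows <- groups[[g]]
      ab <- affm_attend_backward(bnb$dX[rows, , drop = FALSE],
                                 at_caches[[g]], model$affm)
      dXl[rows, ] <- dXl[rows, ] + ab$dX
      g_affm <- if (is.null(g_affm)) ab$grads else rec_add(g_affm, ab$grads)
    }
    g_affm$bn <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
  } else {
    dXl <- dXi
  }
  if (cfg$eflm$enabled) {
    scale <- 1 / (hw[1] * hw[2])
    for (i in seq_len(N)) {
      dloc <- array(rep(dXl[i, ], each = hw[1] * hw[2]),
                    c(hw[1], hw[2], d)) * scale
      d_b3[, , , i] <- d_b3[, , , i] +
        crop_resize_backward(dloc, boxes[[i]], hw[1], hw[2])
    }
  } else {
    d_b3 <- d_b3 + gap_backward(t(dXl), hw[1], hw[2])
  }
  g_bb <- backbone_backward(model$backbone, d_b3, bb$cache)
  list(l_general = l_g, l_improving = l_i,
       grads = list(backbone = g_bb, affm = g_affm, fc = g_fc),
       bn = if (!is.null(bnf)) bnf$bn else model$affm$bn,
       bn_backbone = bb$bn)
}

# --- recursive helpers over nested numeric-leaf parameter lists ----------

rec_zero <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.list(x)) lapply(x, rec_zero) else x * 0
}

rec_add <- function(a, b, w = 1) {
  if (is.null(b)) return(a)
  if (is.null(a)) a <- rec_zero(b)
  if (is.list(a)) {
    for (k in seq_along(a)) a[[k]] <- rec_add(a[[k]], b[[k]], w)
    a
  } else a + w * b
}

wd_leaf <- c("W", "WQ", "WK", "WV", "WGQ", "WGK", "WMQ", "WMK")

rec_sgd <- function(p, g, v, lr, momentum, wd, name = "") {
  if (is.null(g)) return(list(p = p, v = v))
  if (is.list(p)) {
    for (k in seq_along(p)) {
      r <- rec_sgd(p[[k]], g[[k]], v[[k]], lr, momentum, wd,
                   if (!is.null(names(p))) names(p)[k] else "")
      p[[k]] <- r$p
      v[[k]] <- r$v
    }
    return(list(p = p, v = v))
  }
  decay <- if (name %in% wd_leaf) wd else 0
  v <- momentum * v - lr * (g + decay * p)
  list(p = p + v, v = v)
}

get_trainables <- function(model) {
  list(backbone = lapply(model$backbone$params, function(l) {
    list(W = l$W, bn = list(gamma = l$bn$gamma, beta = l$bn$beta))
  }),
       affm = list(head = model$affm$head, gate = model$affm$gate,
                   bn = list(gamma = model$affm$bn$gamma,
                             beta = model$affm$bn$beta)),
       fc = model$fc)
}

set_trainables <- function(model, tr) {
  for (ly in names(tr$backbone)) {
    model$backbone$params[[ly]]$W <- tr$backbone[[ly]]$W
    model$backbone$params[[ly]]$bn$gamma <- tr$backbone[[ly]]$bn$gamma
    model$backbone$params[[ly]]$bn$beta <- tr$backbone[[ly]]$bn$beta
  }
  model$affm$head <- tr$affm$head
  model$affm$gate <- tr$affm$gate
  model$affm$bn$gamma <- tr$affm$bn$gamma
  model$affm$bn$beta <- tr$affm$bn$beta
  model$fc <- tr$fc
  model
}

#' Train the two-branch model
#'
#' SGD with momentum and weight decay over seeded same-class group batches;
#' the general and improving branch cross-entropies are summed and jointly
#' optimized through the shared trunk and classifier. The learning rate is
#' multiplied once by `lr_decay_factor` after `lr_decay_at_epoch` epochs.
#'
#' @param manifest Manifest tibble or CSV path (`path,label,split`).
#' @param config Configuration list from [load_config()].
#' @param quiet Suppress per-epoch progress messages.
#' @return A `pestfuse_fit`: the trained model, a per-epoch `log` tibble
#'   (epoch, lambda, lr, losses, validation accuracies) and the ablation
#'   header.
#' @export
fit <- function(manifest, config = default_config(), quiet = FALSE) {
  manifest <- as_manifest(manifest)
  m <- max(manifest$label) + 1L
  model <- init_model(config, m)
  opt <- config$optim
  train_rows <- manifest[manifest$split == "train", ]
  val_rows <- manifest[manifest$split != "train", ]
  side <- config$backbone$image_size
  imgs <- load_images(train_rows$path, side)
  val_imgs <- if (nrow(val_rows)) {
    load_images(val_rows$path[seq_len(min(60L, nrow(val_rows)))], side)
  } else NULL
  val_lab <- if (nrow(val_rows)) val_rows$label[seq_len(min(60L, nrow(val_rows)))]

  vel <- rec_zero(get_trainables(model))
  log_rows <- vector("list", opt$epochs)
  for (epoch in seq_len(opt$epochs)) {
    lr <- opt$lr * if (epoch > opt$lr_decay_at_epoch) opt$lr_decay_factor else 1
    gb <- build_group_batches(train_rows, opt$batch_anchors, opt$n_t,
                              config$seed, epoch - 1L)
    set.seed(derive_seed(config$seed, 307L, epoch))
    e_lg <- e_li <- 0
    e_n <- 0L
    for (bi in seq_along(gb$batches)) {
      gidx <- gb$batches[[bi]]
      rows_all <- unlist(gb$groups[gidx])
      offs <- c(0L, cumsum(lengths(gb$groups[gidx])))
      rel_groups <- lapply(seq_along(gidx), function(g) {
        (offs[g] + 1L):offs[g + 1L]
      })
      attr(rel_groups, "epoch") <- epoch - 1L
      st <- train_batch_step(model, imgs[, , , rows_all, drop = FALSE],
                             train_rows$label[rows_all], rel_groups)
      if (!is.finite(st$l_general + st$l_improving)) {
        stop("non-finite loss at epoch ", epoch, ", batch ", bi,
             " (l_general=", st$l_general, ", l_improving=",
             st$l_improving, ")", call. = FALSE)
      }
      model$affm$bn <- st$bn
      for (ly in names(st$bn_backbone)) {
        model$backbone$params[[ly]]$bn$running_mean <-
          st$bn_backbone[[ly]]$running_mean
        model$backbone$params[[ly]]$bn$running_var <-
          st$bn_backbone[[ly]]$running_var
      }
      upd <- rec_sgd(get_trainables(model), st$grads, vel, lr, opt$momentum,
                     opt$weight_decay)
      model <- set_trainables(model, upd$p)
      vel <- upd$v
      nb <- length(rows_all)
      e_lg <- e_lg + st$l_general * nb
      e_li <- e_li + st$l_improving * nb
      e_n <- e_n + nb
    }
    e_lg <- e_lg / e_n * length(gb$groups)
    e_li <- e_li / e_n * length(gb$groups)
    n_groups <- length(gb$groups)
    val_acc_g <- val_acc_i <- NA_real_
    if (!is.null(val_imgs)) {
      qa <- quick_val(model, val_imgs, val_lab, epoch - 1L, opt$n_t)
      val_acc_g <- qa$general
      val_acc_i <- qa$improving
    }
    log_rows[[epoch]] <- tibble::tibble(
      epoch = epoch, lambda = model_lambda(model, epoch - 1L, "train"),
      lr = lr, l_general = e_lg / n_groups, l_improving = e_li / n_groups,
      l_total = (e_lg + e_li) / n_groups,
      val_acc_general = val_acc_g, val_acc_improving = val_acc_i
    )
    if (!quiet) {
      message(sprintf(
        "epoch %d/%d  lambda %.2f  L_total %.4f  val acc g/i %.3f/%.3f",
        epoch, opt$epochs, log_rows[[epoch]]$lambda,
        log_rows[[epoch]]$l_total, val_acc_g, val_acc_i))
    }
  }
  structure(list(model = model, log = dplyr::bind_rows(log_rows),
                 config = config, m = m, seed = config$seed,
                 ablation = ablation_flags(config)),
            class = "pestfuse_fit")
}

ablation_flags <- function(config) {
  list(eflm = config$eflm$enabled, affm = config$affm$enabled,
       soft_vote = config$head$soft_vote, qk_mask = config$affm$qk_mask,
       v_mask = config$affm$v_mask, gradual_lambda = config$eflm$gradual,
       num_blocks = as.integer(config$eflm$num_blocks))
}

# Cheap per-epoch validation: general accuracy per image, improving
# accuracy over label-grouped soft-vote decisions, both at the current
# epoch's (validation-phase) threshold multiplier.
quick_val <- function(model, imgs, labels, epoch, n_t) {
  n <- length(labels)
  preds <- integer(n)
  for (start in seq(1L, n, by = 32L)) {
    sel <- start:min(start + 31L, n)
    bb <- forward_with_hooks(model$backbone, imgs[, , , sel, drop = FALSE])
    P <- classify(t(gap_forward(bb$blocks[[length(bb$blocks)]])), model$fc)
    preds[sel] <- max.col(P, ties.method = "first") - 1L
  }
  grp_pred <- integer(0)
  grp_true <- integer(0)
  for (cl in unique(labels)) {
    rows <- which(labels == cl)
    take <- rows[seq_len(min(n_t, length(rows)))]
    fw <- forward_group(model, imgs[, , , take, drop = FALSE],
                        "validation", epoch)
    grp_pred <- c(grp_pred, soft_vote(fw$improving)$class)
    grp_true <- c(grp_true, cl)
  }
  list(general = mean(preds == labels), improving = mean(grp_pred == grp_true))
}

#' Evaluate a trained model
#'
#' General mode scores one prediction per test image. Improving mode groups
#' test images by their manifest label (the oracle-grouping evaluation
#' protocol) — or by caller-supplied group ids — draws `n_test` images per
#' group, and scores one fused soft-vote decision per group at the
#' test-time threshold multiplier.
#'
#' @param manifest Manifest tibble or CSV path; rows with `split == "test"`
#'   are used (all rows if no test split exists).
#' @param object A `pestfuse_fit`, `pestfuse_model`, or checkpoint path.
#' @param mode `"general"` or `"improving"`.
#' @param n_test Images fused per decision in improving mode.
#' @param seed Seed for the grouping.
#' @param voting `"soft"` (default), `"hard"`, or `"none"` (score each
#'   image of the fused group separately — the no-voting ablation).
#' @param group_ids Optional vector (one entry per evaluated test row)
#'   assigning images to fusion groups, replacing the label-based
#'   grouping; each group's truth is its modal label.
#' @return A `pestfuse_metrics` object with a `details` attribute
#'   (per-decision tibble).
#' @export
evaluate <- function(manifest, object, mode = c("general", "improving"),
                     n_test = 5L, seed = 1L, voting = NULL,
                     group_ids = NULL) {
  mode <- match.arg(mode)
  model <- as_model(object)
  if (is.null(voting)) {
    voting <- if (isTRUE(model$config$head$soft_vote)) "soft" else "none"
  }
  if (n_test < 1L) stop("n_test must be >= 1", call. = FALSE)
  manifest <- as_manifest(manifest)
  test <- manifest[manifest$split == "test", ]
  if (nrow(test) == 0L) test <- manifest
  side <- model$config$backbone$image_size
  if (mode == "general") {
    imgs <- load_images(test$path, side)
    preds <- integer(nrow(test))
    for (start in seq(1L, nrow(test), by = 32L)) {
      sel <- start:min(start + 31L, nrow(test))
      bb <- forward_with_hooks(model$backbone, imgs[, , , sel, drop = FALSE])
      P <- classify(t(gap_forward(bb$blocks[[length(bb$blocks)]])), model$fc)
      preds[sel] <- max.col(P, ties.method = "first") - 1L
    }
    met <- compute_metrics(preds, test$label, model$m)
    attr(met, "details") <- tibble::tibble(path = test$path,
                                           truth = test$label,
                                           prediction = preds)
    met$mode <- "general"
    return(met)
  }
  set.seed(derive_seed(seed, 401L))
  det <- list()
  preds <- integer(0)
  truths <- integer(0)
  if (!is.null(group_ids)) {
    if (length(group_ids) != nrow(test)) {
      stop("group_ids must have one entry per evaluated test row",
           call. = FALSE)
    }
    plan <- lapply(split(seq_len(nrow(test)), group_ids), function(rows) {
      tab <- table(test$label[rows])
      list(truth = as.integer(names(tab)[which.max(tab)]), chunks = list(rows))
    })
  } else {
    plan <- lapply(sort(unique(test$label)), function(cl) {
      rows <- which(test$label == cl)
      if (length(rows) < n_test) {
        warning("class ", cl, " has fewer than n_test test images; ",
                "sampling with replacement")
        rows <- sample(rows, n_test, replace = TRUE)
      } else {
        rows <- sample(rows)
      }
      n_full <- floor(length(rows) / n_test)
      list(truth = cl, chunks = lapply(seq_len(max(n_full, 1L)), function(j) {
        rows[((j - 1L) * n_test + 1L):(j * n_test)]
      }))
    })
  }
  for (pl in plan) {
    cl <- pl$truth
    for (ch in pl$chunks) {
      imgs <- load_images(test$path[ch], side)
      fw <- forward_group(model, imgs, "test")
      dec <- switch(voting,
        soft = soft_vote(fw$improving)$class,
        hard = hard_vote(max.col(fw$improving, ties.method = "first") - 1L,
                         fw$improving),
        none = max.col(fw$improving, ties.method = "first") - 1L
      )
      k <- length(dec)
      preds <- c(preds, dec)
      truths <- c(truths, rep(cl, k))
      det[[length(det) + 1L]] <- tibble::tibble(
        truth = rep(cl, k), prediction = dec,
        paths = rep(paste(test$path[ch], collapse = ";"), k))
    }
  }
  met <- compute_metrics(preds, truths, model$m)
  attr(met, "details") <- dplyr::bind_rows(det)
  met$mode <- "improving"
  met$n_test <- n_test
  met$voting <- voting
  met
}

as_model <- function(object) {
  if (inherits(object, "pestfuse_model")) return(object)
  if (inherits(object, "pestfuse_fit")) return(object$model)
  if (is.character(object)) return(load_checkpoint(object)$model)
  stop("expected a pestfuse_model, pestfuse_fit or checkpoint path",
       call. = FALSE)
}

#' Save a training checkpoint
#'
#' Writes the fit as a single RDS archive plus a sidecar `meta.json`
#' holding the configuration hash, epoch count and final log row.
#'
#' @param fitted A `pestfuse_fit`.
#' @param path Checkpoint file path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(fitted, path) {
  saveRDS(fitted, path)
  last <- fitted$log[nrow(fitted$log), ]
  jsonlite::write_json(list(
    config_hash = config_hash(fitted$config),
    epochs = nrow(fitted$log),
    ablation = as.list(fitted$ablation),
    final = as.list(last)
  ), paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a training checkpoint
#'
#' @param path Path written by [save_checkpoint()].
#' @return The `pestfuse_fit`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path, call. = FALSE)
  readRDS(path)
}

#' Mean attention mass received by each group member
#'
#' Runs the improving branch on one group and reports, per member, the mean
#' over heads and queries of the selection-masked post-softmax attention
#' score directed at that member. Corrupted or target-absent members should
#' receive less mass than clean ones after training.
#'
#' @param model A `pestfuse_model` (or fit / checkpoint path).
#' @param images Array `(side, side, 3, n)` or character paths.
#' @return Numeric vector of length n.
#' @export
attention_received <- function(model, images) {
  model <- as_model(model)
  if (is.character(images)) {
    images <- load_images(images, model$config$backbone$image_size)
  }
  fw <- forward_group(model, images, "test", keep_cache = TRUE)
  if (is.null(fw$cache$af)) stop("attention fusion is disabled", call. = FALSE)
  Sm <- fw$cache$af$cache$Sm
  Reduce(`+`, lapply(Sm, colMeans)) / length(Sm)
}

#' @export
print.pestfuse_fit <- function(x, ...) {
  flags <- paste(names(x$ablation), unlist(x$ablation), sep = "=",
                 collapse = " ")
  cat("pestfuse fit:", nrow(x$log), "epochs |", flags, "\n")
  print(x$log)
  invisible(x)
}

#' Write the training log as JSON lines
#'
#' The first line is a header with the configuration hash and ablation
#' switches; each subsequent line is one epoch's log row.
#'
#' @param fitted A `pestfuse_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_log <- function(fitted, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(list(
    type = "header", config_hash = config_hash(fitted$config),
    seed = fitted$seed, ablation = as.list(fitted$ablation)
  ), auto_unbox = TRUE, digits = NA), con)
  for (i in seq_len(nrow(fitted$log))) {
    writeLines(jsonlite::toJSON(as.list(fitted$log[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  }
  invisible(path)
}
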