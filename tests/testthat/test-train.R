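test_that("group sampling never mixes labels and honors class sizes", {
  man <- tibble::tibble(
    path = sprintf("img%02d.png", 1:14),
    label = c(rep(0L, 5L), rep(1L, 2L), rep(2L, 7L)),
    split = "train"
  )
  gb <- build_group_batches(man, batch_anchors = 4L, n_t = 5L, seed = 3L,
                            epoch = 1L)
  expect_length(gb$groups, 14L)
  for (g in gb$groups) {
    expect_length(g, 5L)
    expect_length(unique(man$label[g]), 1L)
  }
  # class with exactly n_t members: every group over it is a permutation
  cls0 <- which(man$label == 0L)
  for (g in gb$groups) {
    if (man$label[g[1]] == 0L) expect_setequal(g, cls0)
  }
  # class smaller than n_t: sampled with replacement (repeats appear)
  small_groups <- Filter(function(g) man$label[g[1]] == 1L, gb$groups)
  expect_true(all(vapply(small_groups,
                         function(g) any(duplicated(g)), logical(1))))
  # deterministic given (seed, epoch)
  gb2 <- build_group_batches(man, batch_anchors = 4L, n_t = 5L, seed = 3L,
                             epoch = 1L)
  expect_identical(gb$groups, gb2$groups)
  gb3 <- build_group_batches(man, batch_anchors = 4L, n_t = 5L, seed = 3L,
                             epoch = 2L)
  expect_false(identical(gb$groups, gb3$groups))
  expect_error(build_group_batches(man[0, ], 4L, 5L, 1L, 0L), "empty")
})

test_that("with both modules disabled the branches coincide at inference", {
  cfg <- default_config()
  cfg$eflm$enabled <- FALSE
  cfg$affm$enabled <- FALSE
  model <- init_model(cfg, m = 3L, seed = 4L)
  set.seed(30)
  imgs <- array(rnorm(64 * 64 * 3 * 4), c(64, 64, 3, 4))
  fw <- forward_group(model, imgs, "test")
  expect_equal(fw$improving, fw$general, tolerance = 1e-12)
  # and every box is the whole feature map
  for (b in fw$boxes) {
    expect_equal(b$row_start, 0L)
    expect_equal(b$row_stop, 8L)
  }
})

test_that("a single-image group runs the full improving branch", {
  model <- init_model(default_config(), m = 3L, seed = 6L)
  set.seed(31)
  img <- array(rnorm(64 * 64 * 3 * 1), c(64, 64, 3, 1))
  fw <- forward_group(model, img, "test")
  expect_identical(dim(fw$improving), c(1L, 3L))
  expect_true(all(is.finite(fw$improving)))
  # deterministic at inference
  fw2 <- forward_group(model, img, "test")
  expect_identical(fw$improving, fw2$improving)
})

test_that("one optimization step sends gradient into every parameter block", {
  cfg <- default_config()
  model <- init_model(cfg, m = 3L, seed = 8L)
  set.seed(32)
  imgs <- array(rnorm(64 * 64 * 3 * 6), c(64, 64, 3, 6))
  groups <- list(1:3, 4:6)
  attr(groups, "epoch") <- 1L
  st <- pestfuse:::train_batch_step(model, imgs, c(0L, 0L, 0L, 1L, 1L, 1L),
                                    groups)
  walk <- function(g, path = "") {
    if (is.list(g)) {
      for (k in seq_along(g)) {
        walk(g[[k]], paste(path, names(g)[k] %||% k, sep = "/"))
      }
    } else {
      expect_true(any(g != 0), label = paste("gradient at", path))
    }
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  walk(st$grads)
  expect_true(is.finite(st$l_general))
  expect_true(is.finite(st$l_improving))
})

test_that("training loss, schedule and checkpoints behave end to end", {
  dir <- withr::local_tempdir()
  micro_dataset(dir, n_classes = 2L, images_per_class = 6L, seed = 5L)
  cfg <- desk_config(seed = 2L, epochs = 2L)
  cfg$optim$n_t <- 3L
  cfg$optim$batch_anchors <- 4L
  fitted <- fit(file.path(dir, "manifest.csv"), cfg, quiet = TRUE)
  expect_s3_class(fitted$log, "tbl_df")
  expect_equal(nrow(fitted$log), 2L)
  expect_true(all(is.finite(fitted$log$l_total)))
  expect_equal(fitted$log$l_total,
               fitted$log$l_general + fitted$log$l_improving)
  expect_equal(fitted$log$lambda, c(0, 1))
  # checkpoint round trip: bitwise-identical forward pass on a probe batch
  ck <- file.path(dir, "ck.rds")
  save_checkpoint(fitted, ck)
  expect_true(file.exists(paste0(ck, ".meta.json")))
  reloaded <- load_checkpoint(ck)
  probe <- load_images(generate_dataset(
    synthetic_spec(2L, 2L, 64L, seed = 99L),
    file.path(dir, "probe"))$path[1:2], 64L)
  f1 <- forward_group(fitted$model, probe, "test")
  f2 <- forward_group(reloaded$model, probe, "test")
  expect_identical(f1$improving, f2$improving)
  expect_identical(f1$general, f2$general)
  # broom-style accessors
  expect_identical(tidy(fitted), fitted$log)
  expect_equal(glance(fitted)$epochs, 2L)
  expect_s3_class(autoplot(fitted), "ggplot")
})

test_that("the learning rate decays once after the configured epoch", {
  dir <- withr::local_tempdir()
  micro_dataset(dir, n_classes = 2L, images_per_class = 4L, seed = 6L)
  cfg <- default_config()
  cfg$optim$epochs <- 12L
  cfg$optim$n_t <- 2L
  cfg$optim$batch_anchors <- 6L
  cfg$seed <- 3L
  fitted <- fit(file.path(dir, "manifest.csv"), cfg, quiet = TRUE)
  expect_equal(fitted$log$lr[1:10], rep(1e-3, 10))
  expect_equal(fitted$log$lr[11:12], rep(1e-4, 2))
})

test_that("evaluation is seeded, grouped by label, and warns on small classes", {
  dir <- withr::local_tempdir()
  micro_dataset(dir, n_classes = 2L, images_per_class = 10L, seed = 7L)
  cfg <- desk_config(seed = 4L, epochs = 1L)
  cfg$optim$n_t <- 3L
  fitted <- fit(file.path(dir, "manifest.csv"), cfg, quiet = TRUE)
  man <- file.path(dir, "manifest.csv")
  m1 <- evaluate(man, fitted, mode = "improving", n_test = 3L, seed = 11L)
  m2 <- evaluate(man, fitted, mode = "improving", n_test = 3L, seed = 11L)
  expect_identical(m1$accuracy, m2$accuracy)
  expect_identical(attr(m1, "details"), attr(m2, "details"))
  mg <- evaluate(man, fitted, mode = "general")
  expect_equal(sum(mg$per_class$support), 6L)  # 3 test images per class
  w <- testthat::capture_warnings(
    evaluate(man, fitted, mode = "improving", n_test = 5L))
  expect_true(all(grepl("replacement", w)))
  expect_length(w, 2L)  # one per undersized class
  # n_test = 1: soft voting is the identity; per-image decisions
  m3 <- evaluate(man, fitted, mode = "improving", n_test = 1L, seed = 2L)
  expect_equal(sum(m3$per_class$support), 6L)
  expect_error(evaluate(man, fitted, n_test = 0L), "n_test")
  expect_s3_class(tidy(m1), "tbl_df")
  expect_s3_class(autoplot(m1), "ggplot")
  # caller-supplied grouping replaces the label-based protocol
  m4 <- evaluate(man, fitted, mode = "improving",
                 group_ids = c(1L, 1L, 2L, 2L, 3L, 3L))
  expect_equal(sum(m4$per_class$support), 3L)  # one decision per group
  expect_error(evaluate(man, fitted, mode = "improving",
                        group_ids = c(1L, 2L)), "one entry per")
})

test_that("attention diagnostics report per-member received mass", {
  model <- init_model(default_config(), m = 2L, seed = 10L)
  set.seed(33)
  imgs <- array(rnorm(64 * 64 * 3 * 4), c(64, 64, 3, 4))
  am <- attention_received(model, imgs)
  expect_length(am, 4L)
  expect_true(all(am >= 0))
  m2 <- model
  m2$config$affm$enabled <- FALSE
  expect_error(attention_received(m2, imgs), "disabled")
})
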