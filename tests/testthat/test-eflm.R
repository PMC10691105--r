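test_that("channel aggregation sums channels and caches the mean", {
  blk <- array(c(1, 0, 0, 1,   # channel 1: [[1,0],[0,1]]
                 1, 3, 2, 0),  # channel 2: [[1,2],[3,0]]
               c(2, 2, 2))
  A <- aggregate_channels(blk)
  expect_equal(A$values, rbind(c(2, 2), c(3, 1)))
  expect_equal(A$mean_value, 2)
  one <- array(stats::rnorm(12), c(3, 4, 1))
  expect_equal(aggregate_channels(one)$values, one[, , 1])
  z <- aggregate_channels(array(0, c(2, 2, 3)))
  expect_equal(z$values, matrix(0, 2, 2))
  expect_equal(z$mean_value, 0)
})

test_that("threshold multiplier schedule is linear with fixed test value", {
  sch <- lambda_schedule(20L)
  expect_identical(lambda_at(sch, 0L, "train"), 0)
  expect_identical(lambda_at(sch, 19L, "train"), 1)
  expect_equal(lambda_at(sch, 5L, "train"), 5 / 19)
  expect_identical(lambda_at(sch, 3L, "test"), 0.5)
  expect_error(lambda_at(sch, 20L, "train"), "epoch")
  expect_error(lambda_at(sch, -1L, "validation"), "epoch")
  expect_identical(lambda_at(lambda_schedule(1L), 0L, "train"), 1)
  # nondecreasing over the run
  lams <- vapply(0:19, lambda_at, numeric(1), schedule = sch, phase = "train")
  expect_true(all(diff(lams) >= 0))
})

test_that("mask thresholding is strict and mean-relative", {
  A <- aggregate_channels(array(c(1, 5, 3, 7), c(2, 2, 1)))  # [[1,3],[5,7]]
  expect_equal(threshold_mask(A, 0.5), rbind(c(0, 1), c(1, 1)))
  # ties drop to zero: at the full multiplier a constant map is empty, and
  # an all-zero map is empty at every multiplier
  expect_equal(threshold_mask(matrix(3, 4, 4), 1), matrix(0, 4, 4))
  expect_equal(threshold_mask(matrix(0, 4, 4), 0.5), matrix(0, 4, 4))
  expect_equal(threshold_mask(matrix(0, 4, 4), 0), matrix(0, 4, 4))
  expect_equal(threshold_mask(matrix(runif(12) + 1, 3, 4), 0),
               matrix(1, 3, 4))
})

test_that("mask intersection is an elementwise AND", {
  eye <- diag(3)
  expect_equal(intersect_masks(list(matrix(1, 3, 3), eye, matrix(1, 3, 3))),
               eye)
  m1 <- rbind(c(1, 1), c(0, 1))
  m2 <- rbind(c(1, 0), c(0, 1))
  expect_equal(intersect_masks(list(m1, m2)), rbind(c(1, 0), c(0, 1)))
  expect_equal(intersect_masks(list(m1)), m1)
  expect_error(intersect_masks(list(m1, matrix(1, 3, 3))), "mismatch")
  # subset property on random masks
  set.seed(4)
  for (r in 1:10) {
    ms <- lapply(1:3, function(i) matrix(rbinom(30, 1, 0.6), 5, 6))
    mf <- intersect_masks(ms)
    for (m in ms) expect_true(all(mf <= m))
  }
})

test_that("bounding boxes are minimal with whole-map fallback", {
  mf <- matrix(0, 4, 5)
  mf[2, 2] <- 1  # (1,1) 0-based
  mf[3, 4] <- 1  # (2,3) 0-based
  box <- mask_to_bbox(mf)
  expect_equal(unclass(box)[c("row_start", "row_stop", "col_start", "col_stop")],
               list(row_start = 1L, row_stop = 3L, col_start = 1L,
                    col_stop = 4L))
  full <- mask_to_bbox(matrix(0, 4, 5))
  expect_equal(full$row_stop, 4L)
  expect_equal(full$col_stop, 5L)
  expect_equal(full$row_start, 0L)
  allone <- mask_to_bbox(matrix(1, 4, 5))
  expect_equal(allone, full)
  # covers every positive entry, and no smaller box does
  set.seed(11)
  for (r in 1:20) {
    m <- matrix(rbinom(42, 1, 0.2), 6, 7)
    b <- mask_to_bbox(m)
    pos <- which(m == 1, arr.ind = TRUE)
    if (nrow(pos)) {
      expect_true(all(pos[, 1] > b$row_start & pos[, 1] <= b$row_stop))
      expect_true(all(pos[, 2] > b$col_start & pos[, 2] <= b$col_stop))
      expect_true(any(pos[, 1] == b$row_start + 1L))
      expect_true(any(pos[, 1] == b$row_stop))
      expect_true(any(pos[, 2] == b$col_start + 1L))
      expect_true(any(pos[, 2] == b$col_stop))
    }
  }
})

test_that("crop + upsample is identity on full boxes and preserves constants", {
  set.seed(21)
  st <- rand_stack(8, 8, 4)
  full <- mask_to_bbox(matrix(0, 8, 8))
  out <- crop_and_upsample(st, full)
  for (k in 1:3) {
    expect_lt(max(abs(out$blocks[[k]] - st$blocks[[k]])), 1e-6)
  }
  cst <- feature_stack(list(array(5, c(8, 8, 2))))
  box <- structure(list(row_start = 2L, row_stop = 6L, col_start = 1L,
                        col_stop = 7L), class = "bbox")
  expect_equal(crop_and_upsample(cst, box)$blocks[[1]], array(5, c(8, 8, 2)))
  tiny <- structure(list(row_start = 3L, row_stop = 4L, col_start = 2L,
                         col_stop = 3L), class = "bbox")
  out1 <- crop_and_upsample(st, tiny)$blocks[[2]]
  for (ch in 1:4) {
    expect_equal(out1[, , ch], matrix(st$blocks[[2]][4, 3, ch], 8, 8))
  }
})

test_that("localization recovers a planted hot region", {
  bg <- array(0.1, c(8, 8, 4))
  blocks <- lapply(1:3, function(b) {
    a <- bg
    a[3:5, 4:6, ] <- 10
    a
  })
  st <- feature_stack(blocks)
  res <- localize(st, 0.5)
  expect_equal(res$box$row_start, 2L)
  expect_equal(res$box$row_stop, 5L)
  expect_equal(res$box$col_start, 3L)
  expect_equal(res$box$col_stop, 6L)
  # lam = 0 on strictly positive stacks keeps everything
  set.seed(31)
  stp <- rand_stack()
  r0 <- localize(stp, 0)
  expect_equal(r0$box, mask_to_bbox(matrix(0, 8, 8)))
  for (k in 1:3) {
    expect_lt(max(abs(r0$stack$blocks[[k]] - stp$blocks[[k]])), 1e-6)
  }
  # disjoint per-block activations intersect to nothing: whole-map fallback
  dj <- lapply(1:3, function(b) {
    a <- array(0.01, c(8, 8, 2))
    rows <- list(1:2, 4:5, 7:8)[[b]]
    a[rows, , ] <- 50
    a
  })
  rdj <- localize(feature_stack(dj), 0.5)
  expect_equal(rdj$box$row_start, 0L)
  expect_equal(rdj$box$row_stop, 8L)
})

test_that("retained positions shrink as the threshold multiplier grows", {
  set.seed(41)
  for (r in 1:10) {
    st <- rand_stack()
    lams <- sort(runif(4))
    prev <- NULL
    for (lam in lams) {
      masks <- lapply(st$blocks, function(b) {
        threshold_mask(aggregate_channels(b), lam)
      })
      cur <- intersect_masks(masks)
      if (!is.null(prev)) expect_true(all(cur <= prev))
      prev <- cur
    }
  }
})

test_that("box export back-projects to pixels by the backbone stride", {
  boxes <- list(img1 = structure(list(row_start = 1L, row_stop = 3L,
                                      col_start = 2L, col_stop = 6L),
                                 class = "bbox"))
  tb <- bbox_tibble(boxes, lambda = 0.5, stride = 8L)
  expect_equal(tb$row_start, 8L)
  expect_equal(tb$col_stop, 48L)
  expect_equal(tb$image_id, "img1")
})
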