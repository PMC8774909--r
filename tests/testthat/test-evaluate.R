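mk_mask <- function(h, w, rows, cols) {
  m <- matrix(FALSE, h, w); m[rows, cols] <- TRUE; m
}

test_that("mask IoU equals brute-force pixel counting", {
  a <- mk_mask(6, 6, 2:3, 2:3)
  expect_equal(mask_iou(a, a), 1)
  expect_equal(mask_iou(a, mk_mask(6, 6, 5:6, 5:6)), 0)
  # 2x2 square against itself shifted one column: 2 / 6
  b <- mk_mask(6, 6, 2:3, 3:4)
  expect_equal(mask_iou(a, b), 2 / 6)
  expect_equal(mask_iou(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3)), 0)
  expect_error(mask_iou(a, matrix(FALSE, 3, 3)), class = "deepwise_validation_error")

  set.seed(14)
  for (i in 1:50) {
    x <- random_blob_mask(8, 8, runif(1, 0.2, 0.8))
    y <- random_blob_mask(8, 8, runif(1, 0.2, 0.8))
    inter <- 0L; uni <- 0L
    for (r in 1:8) for (c in 1:8) {        # scalar-loop oracle
      if (x[r, c] && y[r, c]) inter <- inter + 1L
      if (x[r, c] || y[r, c]) uni <- uni + 1L
    }
    expected <- if (uni == 0L) 0 else inter / uni
    expect_equal(mask_iou(x, y), expected)
    expect_equal(mask_iou(x, y), mask_iou(y, x))
  }
})

test_that("greedy matching claims the highest-IoU ground truth one-to-one", {
  gt1 <- mk_mask(10, 10, 1:5, 1:5)
  gt2 <- mk_mask(10, 10, 7:9, 7:9)
  gts <- instance_set(list(gt1, gt2))

  # identical predictions: all matched at IoU 1
  m <- match_instances(instance_set(list(gt1, gt2), scores = c(1, 1)), gts)
  expect_equal(nrow(m$pairs), 2L)
  expect_equal(m$pairs$iou, c(1, 1))
  expect_length(m$unmatched_preds, 0L)
  expect_length(m$unmatched_gts, 0L)

  # one prediction overlapping two gts takes the higher-IoU one
  gt_a <- mk_mask(10, 10, 1:4, 1:10)          # 40 px
  gt_b <- mk_mask(10, 10, 6:9, 1:10)          # 40 px
  pred <- mk_mask(10, 10, 1:7, 1:10)          # 70 px, overlaps both gts
  iou_a <- mask_iou(pred, gt_a); iou_b <- mask_iou(pred, gt_b)
  expect_gt(iou_a, iou_b)
  m2 <- match_instances(instance_set(list(pred)), instance_set(list(gt_b, gt_a)),
                        iou_threshold = 0.1)
  expect_equal(m2$pairs$gt, 2L)               # the higher-IoU gt
  expect_equal(m2$unmatched_gts, 1L)

  # every reported pair respects the threshold and one-to-one constraints
  expect_true(all(m2$pairs$iou >= 0.1))
})

test_that("greedy matching is compared against the exhaustive assignment oracle", {
  set.seed(27)
  n_cases <- 40
  n_agree <- 0L
  for (case in seq_len(n_cases)) {
    np <- sample(0:5, 1); ng <- sample(1:5, 1)
    preds <- replicate(np, random_blob_mask(7, 7, runif(1, 0.2, 0.7)),
                       simplify = FALSE)
    gts <- replicate(ng, random_blob_mask(7, 7, runif(1, 0.2, 0.7)),
                     simplify = FALSE)
    th <- 0.3
    ps <- instance_set(preds)
    gs <- instance_set(gts)
    m <- match_instances(ps, gs, th)
    iou <- matrix(0, np, ng)
    if (np > 0) for (i in 1:np) for (j in 1:ng)
      iou[i, j] <- mask_iou(preds[[i]], gts[[j]])
    opt <- exhaustive_match_oracle(iou, th)
    # greedy can never beat the exhaustive optimum
    expect_lte(nrow(m$pairs), opt$count)
    expect_lte(sum(m$pairs$iou), opt$total + 1e-9)
    # validity: one-to-one, above threshold
    expect_equal(anyDuplicated(m$pairs$pred), 0L)
    expect_equal(anyDuplicated(m$pairs$gt), 0L)
    expect_true(all(m$pairs$iou >= th))
    if (nrow(m$pairs) == opt$count) n_agree <- n_agree + 1L
  }
  # greedy attains the optimal matched count in the overwhelming majority of
  # small random scenes; disagreements are counted, not hidden
  expect_gte(n_agree, round(0.9 * n_cases))
})

test_that("segmentation metrics follow the TP/FP/FN definitions", {
  gt1 <- mk_mask(12, 12, 1:4, 1:4)
  gt2 <- mk_mask(12, 12, 7:9, 7:10)
  gts <- instance_set(list(gt1, gt2))

  # identity
  m <- segmentation_metrics(instance_set(list(gt1, gt2), c(1, 1)), gts)
  expect_equal(c(m$precision, m$recall, m$mean_iou), c(1, 1, 1))

  # 3 preds vs 2 gts, matches at IoU 0.8 and 0.6: precision 2/3, recall 1,
  # mean IoU 0.7 (hand-evaluated: 16/20 and 12/20)
  p1 <- mk_mask(12, 12, 1:4, 1:4); p1[5, 1:4] <- TRUE
  p2 <- mk_mask(12, 12, 7:9, 7:10); p2[10:11, 7:10] <- TRUE
  expect_equal(mask_iou(p1, gt1), 0.8)
  expect_equal(mask_iou(p2, gt2), 0.6)
  p3 <- mk_mask(12, 12, 1:2, 9:10)                          # matches nothing
  mm <- segmentation_metrics(instance_set(list(p1, p2, p3), c(0.9, 0.8, 0.7)),
                             gts, iou_threshold = 0.5)
  expect_equal(mm$precision, 2 / 3)
  expect_equal(mm$recall, 1)
  expect_equal(mm$mean_iou, 0.7)

  # zero predictions against 2 gts
  z <- segmentation_metrics(instance_set(list()), gts)
  expect_equal(c(z$precision, z$recall, z$mean_iou), c(0, 0, 0))
})

test_that("raising the IoU threshold never increases the matched count", {
  set.seed(31)
  preds <- replicate(4, random_blob_mask(9, 9, 0.5), simplify = FALSE)
  gts <- replicate(4, random_blob_mask(9, 9, 0.5), simplify = FALSE)
  tps <- vapply(seq(0.1, 0.9, by = 0.1), function(th)
    nrow(match_instances(instance_set(preds), instance_set(gts), th)$pairs), 0L)
  expect_true(all(diff(tps) <= 0L))
})

test_that("metrics are invariant to instance order", {
  set.seed(55)
  preds <- replicate(4, random_blob_mask(8, 8, 0.4), simplify = FALSE)
  gts <- replicate(3, random_blob_mask(8, 8, 0.4), simplify = FALSE)
  sc <- runif(4)
  m1 <- segmentation_metrics(instance_set(preds, sc), instance_set(gts), 0.3)
  perm_p <- sample(4); perm_g <- sample(3)
  m2 <- segmentation_metrics(instance_set(preds[perm_p], sc[perm_p]),
                             instance_set(gts[perm_g]), 0.3)
  expect_equal(c(m1$precision, m1$recall, m1$mean_iou),
               c(m2$precision, m2$recall, m2$mean_iou))
})

test_that("dataset aggregation: macro averages images, micro pools counts", {
  gt1 <- mk_mask(10, 10, 1:4, 1:4)
  s1 <- segmentation_metrics(instance_set(list(gt1), 1), instance_set(list(gt1)))
  expect_equal(unname(dataset_metrics(list(s1))$macro),
               c(s1$precision, s1$recall, s1$mean_iou))

  # image A: 1 TP of 1 pred / 1 gt; image B: 1 TP + 1 FP of 2 preds / 1 gt
  gtB <- mk_mask(10, 10, 2:5, 2:5)
  fpB <- mk_mask(10, 10, 8:9, 8:9)
  sB <- segmentation_metrics(instance_set(list(gtB, fpB), c(0.9, 0.8)),
                             instance_set(list(gtB)))
  expect_equal(sB$precision, 0.5)
  dm <- dataset_metrics(list(s1, sB))
  expect_equal(unname(dm$macro["mean_precision"]), mean(c(1, 0.5)))   # 0.75
  # micro: TP 2, FP 1, FN 0 -> precision 2/3 (differs from macro)
  expect_equal(unname(dm$micro["mean_precision"]), 2 / 3)
  expect_equal(unname(dm$micro["mean_recall"]), 1)
  expect_equal(unname(dm$micro["mean_iou"]), mean(c(1, 1)))

  expect_error(dataset_metrics(list()), class = "deepwise_validation_error")
})
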