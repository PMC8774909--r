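#' Instance set
#'
#' A collection of binary instance masks over one image frame, optionally
#' with per-instance confidence scores (predictions only).
#'
#' @param masks List of H x W logical matrices sharing one shape.
#' @param scores Optional numeric vector of confidences in \[0, 1\], aligned
#'   1:1 with `masks`.
#' @return An object of class `instance_set`.
#' @export
instance_set <- function(masks, scores = NULL) {
  if (!is.list(masks))
    abort_dw("`masks` must be a list of logical matrices", "deepwise_validation_error")
  if (length(masks) > 0L) {
    shape <- dim(masks[[1]])
    for (i in seq_along(masks))
      assert_mask(masks[[i]], sprintf("masks[[%d]]", i), shape = shape)
  }
  if (!is.null(scores)) {
    if (length(scores) != length(masks) || any(scores < 0 | scores > 1))
      abort_dw("`scores` must align with `masks` and lie in [0, 1]",
               "deepwise_validation_error")
    scores <- as.numeric(scores)
  }
  structure(list(masks = masks, scores = scores), class = "instance_set")
}

#' @export
print.instance_set <- function(x, ...) {
  cat(sprintf("<instance_set> %d mask(s)%s\n", length(x$masks),
              if (is.null(x$scores)) "" else " with scores"))
  invisible(x)
}

#' Intersection over union of two binary masks
#'
#' `|a & b| / |a | b|`; defined as 0 when both masks are empty.
#'
#' @param a,b H x W logical matrices of equal shape.
#' @return IoU in \[0, 1\].
#' @export
mask_iou <- function(a, b) {
  assert_mask(a, "a"); assert_mask(b, "b", shape = dim(a))
  uni <- sum(a | b)
  if (uni == 0L) return(0)
  sum(a & b) / uni
}

#' Greedy one-to-one instance matching
#'
#' Predictions are visited in descending score order (ties and missing
#' scores: descending best-IoU against any ground truth, then index) and
#' each claims its highest-IoU unclaimed ground-truth instance provided that
#' IoU reaches the threshold.
#'
#' @param preds,gts [instance_set] objects over the same image frame.
#' @param iou_threshold Minimum IoU for a valid match, default 0.5.
#' @return An object of class `match_result`: data frame `pairs` with
#'   columns `pred`, `gt`, `iou`, plus integer vectors `unmatched_preds` and
#'   `unmatched_gts`.
#' @export
match_instances <- function(preds, gts, iou_threshold = 0.5) {
  if (!inherits(preds, "instance_set") || !inherits(gts, "instance_set"))
    abort_dw("`preds` and `gts` must be instance_set objects",
             "deepwise_validation_error")
  np <- length(preds$masks); ng <- length(gts$masks)
  if (np > 0L && ng > 0L &&
      !identical(dim(preds$masks[[1]]), dim(gts$masks[[1]])))
    abort_dw("prediction and ground-truth masks are on different image frames",
             "deepwise_validation_error")
  iou <- matrix(0, np, ng)
  for (i in seq_len(np)) for (j in seq_len(ng))
    iou[i, j] <- mask_iou(preds$masks[[i]], gts$masks[[j]])
  best <- if (ng > 0L && np > 0L) apply(iou, 1L, max) else rep(0, np)
  score_key <- if (!is.null(preds$scores)) preds$scores else best
  visit <- order(-score_key, -best, seq_len(np))
  claimed <- logical(ng)
  pairs <- list()
  for (i in visit) {
    if (ng == 0L) break
    cand <- which(!claimed & iou[i, ] >= iou_threshold)
    if (length(cand) == 0L) next
    j <- cand[which.max(iou[i, cand])]
    claimed[j] <- TRUE
    pairs[[length(pairs) + 1L]] <- c(i, j, iou[i, j])
  }
  pairs_df <- if (length(pairs) > 0L) {
    m <- do.call(rbind, pairs)
    data.frame(pred = as.integer(m[, 1]), gt = as.integer(m[, 2]), iou = m[, 3])
  } else data.frame(pred = integer(0), gt = integer(0), iou = numeric(0))
  structure(list(pairs = pairs_df,
                 unmatched_preds = setdiff(seq_len(np), pairs_df$pred),
                 unmatched_gts = setdiff(seq_len(ng), pairs_df$gt)),
            class = "match_result")
}

#' Instance-segmentation metrics for one image
#'
#' Matches predictions to ground truth with [match_instances()] and reports
#' precision = TP / (TP + FP), recall = TP / (TP + FN) and the mean IoU over
#' matched pairs. Conventions for empty inputs: with zero predictions,
#' precision is 1 if there are also zero ground truths and 0 otherwise
#' (symmetrically for recall); mean IoU is 0 whenever nothing matched.
#'
#' @inheritParams match_instances
#' @return An object of class `seg_metrics`: `precision`, `recall`,
#'   `mean_iou`, plus the counts `tp`, `fp`, `fn` and the vector
#'   `matched_ious` used for pooled aggregation.
#' @export
segmentation_metrics <- function(preds, gts, iou_threshold = 0.5) {
  m <- match_instances(preds, gts, iou_threshold)
  tp <- nrow(m$pairs)
  fp <- length(m$unmatched_preds)
  fn <- length(m$unmatched_gts)
  precision <- if (tp + fp == 0L) as.numeric(fn == 0L) else tp / (tp + fp)
  recall <- if (tp + fn == 0L) as.numeric(fp == 0L) else tp / (tp + fn)
  mean_iou <- if (tp > 0L) mean(m$pairs$iou) else 0
  structure(list(precision = precision, recall = recall, mean_iou = mean_iou,
                 tp = tp, fp = fp, fn = fn, matched_ious = m$pairs$iou,
                 match = m),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("precision %.4f  recall %.4f  mean IoU %.4f  (TP %d, FP %d, FN %d)\n",
              x$precision, x$recall, x$mean_iou, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Aggregate per-image metrics over a dataset
#'
#' Macro aggregation (the default report) averages the per-image precision,
#' recall and mean IoU with equal image weight; micro aggregation pools
#' TP/FP/FN counts and matched IoUs across images before computing the three
#' numbers. Both are returned.
#'
#' @param per_image List of `seg_metrics` objects, one per image.
#' @param aggregation Which aggregate to treat as primary: `"macro"`
#'   (default) or `"micro"`.
#' @return An object of class `dataset_metrics` with elements `macro`,
#'   `micro` (each a named vector: mean_precision, mean_recall, mean_iou),
#'   `aggregation` and `n_images`.
#' @export
dataset_metrics <- function(per_image, aggregation = c("macro", "micro")) {
  aggregation <- match.arg(aggregation)
  if (!is.list(per_image) || length(per_image) == 0L ||
      !all(vapply(per_image, inherits, TRUE, "seg_metrics")))
    abort_dw("`per_image` must be a non-empty list of seg_metrics objects",
             "deepwise_validation_error")
  take <- function(f) vapply(per_image, `[[`, 0, f)
  macro <- c(mean_precision = mean(take("precision")),
             mean_recall = mean(take("recall")),
             mean_iou = mean(take("mean_iou")))
  tp <- sum(take("tp")); fp <- sum(take("fp")); fn <- sum(take("fn"))
  ious <- unlist(lapply(per_image, `[[`, "matched_ious"))
  micro <- c(
    mean_precision = if (tp + fp == 0L) as.numeric(fn == 0L) else tp / (tp + fp),
    mean_recall = if (tp + fn == 0L) as.numeric(fp == 0L) else tp / (tp + fn),
    mean_iou = if (tp > 0L) mean(ious) else 0
  )
  structure(list(macro = macro, micro = micro, aggregation = aggregation,
                 n_images = length(per_image)),
            class = "dataset_metrics")
}

#' @export
print.dataset_metrics <- function(x, ...) {
  cat(sprintf("<dataset_metrics> %d image(s), primary aggregation: %s\n",
              x$n_images, x$aggregation))
  for (nm in c("macro", "micro"))
    cat(sprintf("  %-5s precision %.4f  recall %.4f  mean IoU %.4f\n", nm,
                x[[nm]]["mean_precision"], x[[nm]]["mean_recall"],
                x[[nm]]["mean_iou"]))
  invisible(x)
}

#' Rasterize an annotated image's polygons to an instance set
#'
#' @param annotated An [annotated_image], or a list of annotations plus
#'   explicit `height`/`width`.
#' @param height,width Frame size; taken from the image when omitted.
#' @return An [instance_set] with one mask per annotation.
#' @export
annotations_to_instance_set <- function(annotated, height = NULL, width = NULL) {
  if (inherits(annotated, "annotated_image")) {
    height <- dim(annotated$image)[1]; width <- dim(annotated$image)[2]
    anns <- annotated$annotations
  } else anns <- annotated
  if (is.null(height) || is.null(width))
    abort_dw("`height` and `width` are required for a bare annotation list",
             "deepwise_validation_error")
  instance_set(lapply(anns, rasterize_polygon, height = height, width = width))
}
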