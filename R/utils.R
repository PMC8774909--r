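#' @keywords internal
"_PACKAGE"

## Conventions used throughout:
##  - images are H x W x 3 numeric arrays with integer values in [0, 255]
##  - masks are H x W logical matrices
##  - pixel coordinates are 0-based; pixel (r, c) spans [c, c+1) x [r, r+1)
##    in continuous (x, y) coordinates with origin at the top-left, x along
##    columns and y along rows; its center is (c + 0.5, r + 0.5)

# base round() already rounds half to even (IEEE); named for intent
round_half_even <- function(x) round(x)

clip255 <- function(x) pmin(pmax(x, 0), 255)

abort_dw <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "deepwise_error")))
}

warn_dw <- function(msg, class = "deepwise_warning") {
  warning(warningCondition(paste0(msg, "\n"), class = c(class, "deepwise_warning")))
}

assert_image <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    abort_dw(sprintf("`%s` must be an H x W x 3 array", arg), "deepwise_validation_error")
  if (dim(image)[1] < 1L || dim(image)[2] < 1L)
    abort_dw(sprintf("`%s` is empty", arg), "deepwise_validation_error")
  rng <- range(image)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    abort_dw(sprintf("`%s` must have channel values in [0, 255]", arg),
             "deepwise_validation_error")
  invisible(image)
}

assert_mask <- function(mask, arg = "mask", shape = NULL) {
  if (!is.matrix(mask) || !is.logical(mask))
    abort_dw(sprintf("`%s` must be a logical matrix", arg), "deepwise_validation_error")
  if (!is.null(shape) && !identical(dim(mask), as.integer(shape[1:2])))
    abort_dw(sprintf("`%s` shape (%d x %d) does not match expected (%d x %d)",
                     arg, nrow(mask), ncol(mask), shape[1], shape[2]),
             "deepwise_validation_error")
  invisible(mask)
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's
# RNG state afterwards so library code does not disturb user simulations.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## ---- mask shifts and morphology ------------------------------------------

# Shift a logical matrix by (dr, dc), filling vacated cells with `fill`.
shift_mask <- function(m, dr, dc, fill = FALSE) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- seq_len(h) - dr; cs <- seq_len(w) - dc
  keep_r <- rs >= 1L & rs <= h
  keep_c <- cs >= 1L & cs <= w
  out[keep_r, keep_c] <- m[rs[keep_r], cs[keep_c]]
  out
}

# One erosion step with the unit-radius disk (4-neighbour cross).
# Pixels beyond the image border count as background.
erode1 <- function(m) {
  m & shift_mask(m, 1L, 0L) & shift_mask(m, -1L, 0L) &
    shift_mask(m, 0L, 1L) & shift_mask(m, 0L, -1L)
}

dilate1 <- function(m) {
  m | shift_mask(m, 1L, 0L) | shift_mask(m, -1L, 0L) |
    shift_mask(m, 0L, 1L) | shift_mask(m, 0L, -1L)
}

dilate1_8 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    out <- out | shift_mask(m, dr, dc)
  }
  out
}

erode_disk <- function(m, k) {
  k <- as.integer(k)
  while (k > 0L) { m <- erode1(m); k <- k - 1L }
  m
}

dilate_disk <- function(m, k) {
  k <- as.integer(k)
  while (k > 0L) { m <- dilate1(m); k <- k - 1L }
  m
}

# Morphological opening by a radius-r iterated unit disk.
open_disk <- function(m, r) dilate_disk(erode_disk(m, r), r)

## ---- connected components -------------------------------------------------

# Label connected components of a logical mask by breadth-first search over
# linear pixel indices (vectorised per frontier). Returns an integer matrix,
# 0 = background.
label_components <- function(mask, connectivity = 8L) {
  assert_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  offs <- if (connectivity == 8L)
    expand.grid(dr = -1:1, dc = -1:1)[-5, ] else
    data.frame(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  labels <- matrix(0L, h, w)
  remaining <- mask
  lab <- 0L
  todo <- which(remaining)
  while (length(todo) > 0L) {
    lab <- lab + 1L
    frontier <- todo[1]
    remaining[frontier] <- FALSE
    labels[frontier] <- lab
    while (length(frontier) > 0L) {
      r <- ((frontier - 1L) %% h) + 1L
      c <- ((frontier - 1L) %/% h) + 1L
      nbs <- integer(0)
      for (k in seq_len(nrow(offs))) {
        dr <- offs$dr[k]; dc <- offs$dc[k]
        ok <- r + dr >= 1L & r + dr <= h & c + dc >= 1L & c + dc <= w
        nbs <- c(nbs, frontier[ok] + dr + dc * h)
      }
      nbs <- unique(nbs[remaining[nbs]])
      remaining[nbs] <- FALSE
      labels[nbs] <- lab
      frontier <- nbs
    }
    todo <- todo[remaining[todo]]
  }
  labels
}

# Drop connected components smaller than min_px (8-connectivity).
filter_small_components <- function(mask, min_px) {
  if (min_px <= 0L || !any(mask)) return(mask)
  labels <- label_components(mask, 8L)
  sizes <- tabulate(labels[labels > 0L])
  keep <- which(sizes >= min_px)
  matrix(labels %in% keep & mask, nrow(mask), ncol(mask))
}
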