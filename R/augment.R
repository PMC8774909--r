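#' Cell patch
#'
#' One extracted cell: the bounding-box crop of its source image plus the
#' binary mask isolating the cell inside the crop. True-mask pixels carry
#' the source colours verbatim; crop pixels outside the mask are retained as
#' blending guidance only.
#'
#' @param patch h x w x 3 array cropped to the cell's bounding box.
#' @param mask h x w logical matrix, nonempty.
#' @param source_id Identifier of the originating image.
#' @param label Annotation label carried along.
#' @param transform_log Character vector of transforms applied so far.
#' @return An object of class `cell_patch`.
#' @export
cell_patch <- function(patch, mask, source_id = "unknown", label = "myeloma",
                       transform_log = character(0)) {
  assert_image(patch, "patch")
  assert_mask(mask, "mask", shape = dim(patch))
  if (!any(mask))
    abort_dw("cell_patch mask must be nonempty", "deepwise_validation_error")
  storage.mode(patch) <- "integer"
  structure(list(patch = patch, mask = mask, source_id = source_id,
                 label = label, transform_log = transform_log),
            class = "cell_patch")
}

#' @export
print.cell_patch <- function(x, ...) {
  cat(sprintf("<cell_patch> %d x %d px crop, %d cell pixel(s), from \"%s\"%s\n",
              dim(x$patch)[1], dim(x$patch)[2], sum(x$mask), x$source_id,
              if (length(x$transform_log))
                paste0(" [", paste(x$transform_log, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Edge-blending parameters
#'
#' @param band_halfwidth Half-width k of the blended edge band in pixels
#'   (the band spans from the k-eroded to the k-dilated cell outline),
#'   default 3.
#' @param solver_tol Maximum admissible relative residual of the band
#'   Poisson solve, default 1e-8.
#' @param max_iter Iteration cap reserved for iterative solvers; the
#'   default sparse direct factorization ignores it.
#' @return An object of class `blend_spec`. Connectivity is fixed at 4.
#' @export
blend_spec <- function(band_halfwidth = 3L, solver_tol = 1e-8,
                       max_iter = 10000L) {
  if (band_halfwidth < 1L || solver_tol <= 0)
    abort_dw("need band_halfwidth >= 1 and solver_tol > 0",
             "deepwise_validation_error")
  structure(list(band_halfwidth = as.integer(band_halfwidth),
                 connectivity = 4L, solver_tol = solver_tol,
                 max_iter = as.integer(max_iter)),
            class = "blend_spec")
}

#' Cell-placement policy
#'
#' Constraints for pasting transformed cells onto a background image.
#' Pasted cells may overlap each other up to a small IoU (emulating the
#' clustered growth pattern of plasma cells) but may cover only a bounded
#' fraction of any pre-existing annotated cell, so the original ground
#' truth stays honest.
#'
#' @param n_cells_per_image Integer range `c(lo, hi)` of cells pasted per
#'   output image, default `c(2, 5)`.
#' @param max_overlap_existing Maximum fraction of an existing annotated
#'   cell's area that pasted cells may cover, default 0.1.
#' @param max_overlap_pasted Maximum IoU between any two pasted cells,
#'   default 0.1.
#' @param max_attempts Rejection-sampling attempts per cell, default 25.
#' @param seed Integer RNG seed driving all placement randomness.
#' @return An object of class `placement_policy`.
#' @export
placement_policy <- function(n_cells_per_image = c(2L, 5L),
                             max_overlap_existing = 0.1,
                             max_overlap_pasted = 0.1,
                             max_attempts = 25L, seed = 0L) {
  n_cells_per_image <- as.integer(rep(n_cells_per_image, length.out = 2L))
  if (n_cells_per_image[1] > n_cells_per_image[2] || n_cells_per_image[1] < 0L)
    abort_dw("`n_cells_per_image` must be a non-decreasing non-negative range",
             "deepwise_validation_error")
  if (max_overlap_existing < 0 || max_overlap_existing > 1 ||
      max_overlap_pasted < 0 || max_overlap_pasted > 1 || max_attempts < 1L)
    abort_dw("overlap fractions must be in [0, 1] and max_attempts >= 1",
             "deepwise_validation_error")
  structure(list(n_cells_per_image = n_cells_per_image,
                 max_overlap_existing = max_overlap_existing,
                 max_overlap_pasted = max_overlap_pasted,
                 max_attempts = as.integer(max_attempts),
                 seed = as.integer(seed)),
            class = "placement_policy")
}

#' Extract annotated cells as patches
#'
#' Rasterizes each polygon annotation, crops the image to the annotation's
#' bounding box and returns one [cell_patch] per annotation. Annotations
#' rasterizing to an empty mask are skipped with a warning.
#'
#' @param annotated An [annotated_image] with at least the image set.
#' @return List of [cell_patch] objects (possibly empty).
#' @export
extract_cells <- function(annotated) {
  if (!inherits(annotated, "annotated_image"))
    abort_dw("`annotated` must be an annotated_image", "deepwise_validation_error")
  h <- dim(annotated$image)[1]; w <- dim(annotated$image)[2]
  out <- list()
  for (i in seq_along(annotated$annotations)) {
    ann <- annotated$annotations[[i]]
    mask <- withCallingHandlers(
      rasterize_polygon(ann, h, w),
      deepwise_degenerate_polygon = function(w_) invokeRestart("muffleWarning"))
    if (!any(mask)) {
      warn_dw(sprintf("annotation %d of \"%s\" rasterizes to an empty mask; skipped",
                      i, annotated$identifier), "deepwise_empty_annotation")
      next
    }
    rows <- range(which(rowSums(mask) > 0L))
    cols <- range(which(colSums(mask) > 0L))
    out[[length(out) + 1L]] <- cell_patch(
      patch = annotated$image[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE],
      mask = mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE],
      source_id = annotated$identifier, label = ann$label)
  }
  out
}

rot_cw_mat <- function(m) t(m[nrow(m):1, , drop = FALSE])

apply_mat_op <- function(m, op) {
  switch(op,
    flip_h = m[, ncol(m):1, drop = FALSE],
    flip_v = m[nrow(m):1, , drop = FALSE],
    rot90  = rot_cw_mat(m),
    rot180 = m[nrow(m):1, ncol(m):1, drop = FALSE],
    rot270 = rot_cw_mat(rot_cw_mat(rot_cw_mat(m))),
    abort_dw(sprintf("unknown transform \"%s\"", op), "deepwise_validation_error"))
}

#' Transform a cell patch
#'
#' Flips and 90-degree rotations are exact pixel permutations, so the cell's
#' colour values and mask pixel count are conserved verbatim (`rot90` turns
#' the patch 90 degrees clockwise on screen). `rot_free` rotates by an
#' arbitrary angle (degrees, clockwise on screen) with bilinear resampling
#' for colour and nearest-neighbour for the mask, on a canvas expanded to
#' the rotated extent and then cropped back to the mask's bounding box.
#'
#' @param patch A [cell_patch].
#' @param op One of `"flip_h"`, `"flip_v"`, `"rot90"`, `"rot180"`,
#'   `"rot270"`, `"rot_free"`.
#' @param angle Rotation angle in degrees for `op = "rot_free"`.
#' @return The transformed [cell_patch] with `transform_log` appended.
#' @export
transform_patch <- function(patch, op, angle = NULL) {
  if (!inherits(patch, "cell_patch"))
    abort_dw("`patch` must be a cell_patch", "deepwise_validation_error")
  if (op == "rot_free") {
    if (is.null(angle))
      abort_dw("rot_free requires `angle`", "deepwise_validation_error")
    return(rotate_patch_free(patch, angle))
  }
  img <- array(0L, if (op %in% c("rot90", "rot270"))
    dim(patch$patch)[c(2, 1, 3)] else dim(patch$patch))
  for (ch in 1:3) img[, , ch] <- apply_mat_op(patch$patch[, , ch], op)
  cell_patch(img, apply_mat_op(patch$mask, op), patch$source_id, patch$label,
             c(patch$transform_log, op))
}

rotate_patch_free <- function(patch, angle) {
  h <- dim(patch$patch)[1]; w <- dim(patch$patch)[2]
  th <- angle * pi / 180
  ct <- cos(th); st <- sin(th)
  cx <- w / 2; cy <- h / 2
  corners_x <- c(0, w, w, 0) - cx; corners_y <- c(0, 0, h, h) - cy
  rx <- ct * corners_x - st * corners_y
  ry <- st * corners_x + ct * corners_y
  w2 <- ceiling(max(rx) - min(rx)); h2 <- ceiling(max(ry) - min(ry))
  cx2 <- w2 / 2; cy2 <- h2 / 2
  # inverse-map every target pixel center into the source frame
  tx <- rep(seq_len(w2) - 0.5, each = h2) - cx2
  ty <- rep(seq_len(h2) - 0.5, times = w2) - cy2
  sx <- ct * tx + st * ty + cx
  sy <- -st * tx + ct * ty + cy
  u <- sx - 0.5; v <- sy - 0.5                # 0-based fractional pixel coords
  ui <- round(u); vi <- round(v)              # nearest neighbour for the mask
  in_src <- ui >= 0 & ui <= w - 1 & vi >= 0 & vi <= h - 1
  mask2 <- matrix(FALSE, h2, w2)
  mask2[in_src] <- patch$mask[cbind(vi[in_src] + 1L, ui[in_src] + 1L)]
  if (!any(mask2))
    abort_dw("degenerate transform: rotation left an empty mask",
             "deepwise_validation_error")
  uc <- pmin(pmax(u, 0), w - 1); vc <- pmin(pmax(v, 0), h - 1)
  u0 <- floor(uc); v0 <- floor(vc)
  u1 <- pmin(u0 + 1, w - 1); v1 <- pmin(v0 + 1, h - 1)
  fu <- uc - u0; fv <- vc - v0
  img2 <- array(0L, c(h2, w2, 3L))
  for (ch in 1:3) {
    pl <- patch$patch[, , ch]
    val <- (1 - fu) * (1 - fv) * pl[cbind(v0 + 1, u0 + 1)] +
           fu * (1 - fv) * pl[cbind(v0 + 1, u1 + 1)] +
           (1 - fu) * fv * pl[cbind(v1 + 1, u0 + 1)] +
           fu * fv * pl[cbind(v1 + 1, u1 + 1)]
    img2[, , ch] <- matrix(as.integer(round_half_even(clip255(val))), h2, w2)
  }
  rows <- range(which(rowSums(mask2) > 0L))
  cols <- range(which(colSums(mask2) > 0L))
  cell_patch(img2[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE],
             mask2[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE],
             patch$source_id, patch$label,
             c(patch$transform_log, sprintf("rot_free(%g)", angle)))
}

#' Split a mask into interior, edge band and exterior boundary
#'
#' The interior is the mask eroded k times with the unit-radius disk, the
#' band is the k-fold dilation minus the interior, and the exterior boundary
#' is the first ring outside the dilated mask. The three sets are disjoint
#' and interior plus band cover the mask. If erosion empties the interior
#' the band is the whole dilated mask (with a message).
#'
#' @param mask H x W logical matrix, nonempty.
#' @param k Band half-width in pixels (>= 1).
#' @return List of logical matrices `interior`, `band`, `exterior_boundary`.
#' @export
edge_band <- function(mask, k = 3L) {
  assert_mask(mask)
  if (!any(mask))
    abort_dw("`mask` must be nonempty", "deepwise_validation_error")
  if (k < 1L) abort_dw("`k` must be >= 1", "deepwise_validation_error")
  interior <- erode_disk(mask, k)
  dilated <- dilate_disk(mask, k)
  if (!any(interior))
    message("edge_band: erosion emptied the interior; band is the whole dilated mask")
  band <- dilated & !interior
  exterior <- dilate1(dilated) & !dilated
  list(interior = interior, band = band, exterior_boundary = exterior)
}

#' Gradient-domain blending restricted to an edge band
#'
#' Solves, per colour channel, the discrete Poisson equation on the edge
#' band of `mask`: the blended values reproduce the Laplacian (4-neighbour)
#' of the guidance field — the composite inside the mask, the background
#' outside — subject to Dirichlet boundary values from the fixed interior
#' (composite) and exterior (background) pixels. Interior pixels stay
#' bit-identical to the composite, pixels outside the k-dilated mask stay
#' bit-identical to the background, and band pixels on the image border are
#' fixed to the background. The sparse symmetric positive-definite system is
#' solved by direct factorization and checked against `spec$solver_tol`.
#'
#' @param composite Background image with the patch pixels copied in over
#'   `mask`.
#' @param background The untouched background image.
#' @param mask Pasted-cell mask in the full image frame.
#' @param spec A [blend_spec].
#' @return The blended image.
#' @export
blend_edge <- function(composite, background, mask, spec = blend_spec()) {
  assert_image(composite, "composite"); assert_image(background, "background")
  if (!identical(dim(composite), dim(background)))
    abort_dw("composite and background shapes differ", "deepwise_validation_error")
  assert_mask(mask, "mask", shape = dim(composite))
  if (!any(mask))
    abort_dw("`mask` must be nonempty", "deepwise_validation_error")
  sol <- solve_edge_band(composite, background, mask, spec)
  out <- background
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[sol$interior] <- composite[, , ch][sol$interior]
    if (length(sol$unknown_idx) > 0L)
      plane[sol$unknown_idx] <- round_half_even(clip255(sol$values[, ch]))
    out[, , ch] <- plane
  }
  storage.mode(out) <- "integer"
  out
}

# Assemble and solve the band Poisson system. Returns the linear indices of
# the unknown band pixels, the continuous (pre-quantization) per-channel
# solution, and the band decomposition. Band pixels on the image border are
# Dirichlet-fixed to the background and are not unknowns.
solve_edge_band <- function(composite, background, mask, spec = blend_spec()) {
  h <- dim(composite)[1]; w <- dim(composite)[2]
  bands <- edge_band(mask, spec$band_halfwidth)
  interior <- bands$interior
  border <- matrix(FALSE, h, w)
  border[c(1L, h), ] <- TRUE; border[, c(1L, w)] <- TRUE
  unknown <- bands$band & !border
  un_idx <- which(unknown)
  nu <- length(un_idx)
  if (nu == 0L)
    return(list(unknown_idx = integer(0), values = matrix(0, 0, 3),
                interior = interior, bands = bands))
  map <- integer(h * w); map[un_idx] <- seq_len(nu)
  rr <- ((un_idx - 1L) %% h) + 1L
  cc <- ((un_idx - 1L) %/% h) + 1L
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  deg <- integer(nu)
  ai <- list(); aj <- list()
  fixed_nbrs <- vector("list", length(offs))   # fixed neighbour linear indices
  fixed_of <- vector("list", length(offs))     # which unknown each belongs to
  guid_nbrs <- vector("list", length(offs))
  guid_of <- vector("list", length(offs))
  for (d in seq_along(offs)) {
    dr <- offs[[d]][1]; dc <- offs[[d]][2]
    ok <- rr + dr >= 1L & rr + dr <= h & cc + dc >= 1L & cc + dc <= w
    nb <- un_idx[ok] + dr + dc * h
    deg <- deg + as.integer(ok)
    is_un <- map[nb] > 0L
    ai[[d]] <- which(ok)[is_un]; aj[[d]] <- map[nb[is_un]]
    fixed_nbrs[[d]] <- nb[!is_un]; fixed_of[[d]] <- which(ok)[!is_un]
    guid_nbrs[[d]] <- nb; guid_of[[d]] <- which(ok)
  }
  A <- Matrix::sparseMatrix(
    i = c(seq_len(nu), unlist(ai)), j = c(seq_len(nu), unlist(aj)),
    x = c(as.numeric(deg), rep(-1, length(unlist(ai)))), dims = c(nu, nu))

  B <- matrix(0, nu, 3L)
  for (ch in 1:3) {
    g <- ifelse(mask, composite[, , ch], background[, , ch])
    fixed_plane <- ifelse(interior, composite[, , ch], background[, , ch])
    b <- deg * g[un_idx]
    for (d in seq_along(offs)) {
      b[guid_of[[d]]] <- b[guid_of[[d]]] - g[guid_nbrs[[d]]]
      b[fixed_of[[d]]] <- b[fixed_of[[d]]] + fixed_plane[fixed_nbrs[[d]]]
    }
    B[, ch] <- b
  }
  X <- as.matrix(Matrix::solve(A, B))
  res <- sqrt(sum(as.matrix(A %*% X - B)^2))
  rel <- res / max(sqrt(sum(B^2)), .Machine$double.eps)
  if (rel > spec$solver_tol)
    abort_dw(sprintf("band Poisson solve did not reach tolerance: relative residual %.3g",
                     rel), "deepwise_solver_error")
  list(unknown_idx = un_idx, values = X, interior = interior, bands = bands)
}
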