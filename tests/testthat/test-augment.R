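test_that("cell extraction yields one masked bounding-box crop per annotation", {
  gen <- generate_image(synth_config(width = 96, height = 96,
                                     n_stained = c(5L, 5L), seed = 17))
  expect_length(gen$image$annotations, 5L)
  patches <- extract_cells(gen$image)
  expect_length(patches, 5L)
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    full <- rasterize_polygon(gen$image$annotations[[i]], 96, 96)
    expect_equal(sum(p$mask), sum(full))
    # mask pixels carry the source colours verbatim
    rows <- range(which(rowSums(full) > 0)); cols <- range(which(colSums(full) > 0))
    crop <- gen$image$image[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE]
    expect_identical(p$patch, crop)
  }

  # rectangular 12-pixel annotation: mask has exactly 12 true pixels
  img <- flat_image(10, 10, c(50, 60, 70))
  ann <- polygon_annotation(rbind(c(2, 3), c(6, 3), c(6, 6), c(2, 6)))
  p <- extract_cells(annotated_image(img, list(ann)))[[1]]
  expect_equal(sum(p$mask), 12L)
  expect_equal(dim(p$mask), c(3L, 4L))

  expect_length(extract_cells(annotated_image(img)), 0L)
})

test_that("flips and quarter rotations permute pixels exactly", {
  gen <- generate_image(synth_config(width = 96, height = 96, seed = 23))
  p <- extract_cells(gen$image)[[1]]
  n_mask <- sum(p$mask)
  colours <- sort(as.vector(p$patch[, , 2][p$mask]))
  for (op in c("flip_h", "flip_v", "rot90", "rot180", "rot270")) {
    tp <- transform_patch(p, op)
    expect_equal(sum(tp$mask), n_mask, label = op)
    expect_equal(sort(as.vector(tp$patch[, , 2][tp$mask])), colours, label = op)
    expect_equal(tp$transform_log, op)
  }
  # involutions and compositions
  expect_equal(transform_patch(transform_patch(p, "flip_h"), "flip_h")$patch, p$patch)
  expect_equal(transform_patch(transform_patch(p, "flip_v"), "flip_v")$mask, p$mask)
  r4 <- Reduce(function(q, .) transform_patch(q, "rot90"), 1:4, p)
  expect_equal(r4$patch, p$patch)
  expect_equal(transform_patch(p, "rot180")$patch,
               transform_patch(transform_patch(p, "flip_h"), "flip_v")$patch)
})

test_that("free rotation approximately conserves a disk mask's area", {
  img <- flat_image(24, 24, c(120, 80, 160))
  disk <- polygon_annotation(deepwise:::ellipse_ring(12, 12, 10, 10, 0, 24, 24))
  p <- extract_cells(annotated_image(img, list(disk)))[[1]]
  a0 <- sum(p$mask)
  for (ang in c(30, 137, 245)) {
    tp <- transform_patch(p, "rot_free", angle = ang)
    expect_lt(abs(sum(tp$mask) - a0) / a0, 0.05)
    expect_match(tp$transform_log, "rot_free")
  }
})

test_that("edge band splits a mask into disjoint interior/band/exterior", {
  # single pixel, k = 1: interior empty, band = clipped 3x3... cross-dilated
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  expect_message(b <- edge_band(m, 1), "emptied")
  expect_false(any(b$interior))
  expect_identical(b$band, dilate_oracle(m, 1))

  # 10x10 square, k = 1: interior is the 8x8 core
  m2 <- matrix(FALSE, 14, 14); m2[3:12, 3:12] <- TRUE
  b2 <- edge_band(m2, 1)
  expect_equal(sum(b2$interior), 64L)
  expect_identical(b2$interior, erode_oracle(m2, 1))
  expect_identical(b2$interior | b2$band, dilate_oracle(m2, 1))

  # random masks at several k: oracle equality and set algebra
  set.seed(12)
  for (i in 1:6) {
    m3 <- random_blob_mask(12, 12, 0.6)
    if (!any(m3)) next
    k <- sample(1:3, 1)
    b3 <- suppressMessages(edge_band(m3, k))
    expect_identical(b3$interior, erode_oracle(m3, k))
    expect_identical(b3$interior | b3$band, dilate_oracle(m3, k))
    expect_false(any(b3$interior & b3$band))
    expect_false(any(b3$band & b3$exterior_boundary))
    expect_false(any(b3$interior & b3$exterior_boundary))
    expect_true(all((b3$interior | b3$band)[m3])) # interior+band covers mask
  }
})

test_that("edge blending solves the band Poisson system against a dense oracle", {
  spec <- blend_spec(band_halfwidth = 2)
  set.seed(33)
  for (rep in 1:5) {
    sc <- random_blend_scene(16, 16)
    if (sum(sc$mask) < 4) next
    res <- dense_band_oracle(sc$composite, sc$background, sc$mask, spec)
    nu <- length(res$unknown_idx)
    expect_lte(nu, 500L)
    if (nu == 0) next
    expect_lt(max(abs(res$dense - res$sol$values[, 1])), 1e-6)
  }
})

test_that("blending preserves interiors and exteriors bit-exactly", {
  set.seed(44)
  h <- 20; w <- 20
  background <- array(sample(0:255, h * w * 3, TRUE), c(h, w, 3))
  storage.mode(background) <- "integer"
  mask <- matrix(FALSE, h, w); mask[6:14, 6:14] <- TRUE
  composite <- background
  for (ch in 1:3) {
    plane <- composite[, , ch]; plane[mask] <- c(30L, 200L, 90L)[ch]
    composite[, , ch] <- plane
  }
  spec <- blend_spec(band_halfwidth = 2)
  out <- blend_edge(composite, background, mask, spec)
  b <- edge_band(mask, 2)
  dil <- b$interior | b$band
  for (ch in 1:3) {
    expect_identical(out[, , ch][b$interior], composite[, , ch][b$interior])
    expect_identical(out[, , ch][!dil], background[, , ch][!dil])
  }

  # fixed point: composite equal to background returns the background
  expect_identical(blend_edge(background, background, mask, spec), background)
})

test_that("a single band pixel with zero guidance takes its boundary mean", {
  # one unknown (the center of a 3x3 frame) surrounded by Dirichlet values
  # 10 and 30; the composite's center value of 20 makes the guidance
  # Laplacian exactly zero, so the solve reduces to 4f = 10+30+10+30
  h <- 3; w <- 3
  background <- flat_image(h, w, c(20, 20, 20))
  background[2, 1, ] <- 10L; background[2, 3, ] <- 30L
  background[1, 2, ] <- 10L; background[3, 2, ] <- 30L
  mask <- matrix(FALSE, h, w); mask[2, 2] <- TRUE
  composite <- background
  composite[2, 2, ] <- 20L
  sol <- suppressMessages(deepwise:::solve_edge_band(
    composite, background, mask, blend_spec(band_halfwidth = 1)))
  expect_length(sol$unknown_idx, 1L)
  expect_equal(unname(sol$values[1, ]), c(20, 20, 20), tolerance = 1e-12)
})

test_that("with zero guidance band values obey the discrete maximum principle", {
  # discrete harmonic saddle x^2 - y^2 has an exactly zero 5-point Laplacian
  h <- 21; w <- 21
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), times = w), h, w)
  saddle <- (xs^2 - ys^2 - min(xs^2 - ys^2)) / 4
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- saddle
  mask <- matrix(FALSE, h, w); mask[8:14, 8:14] <- TRUE
  spec <- blend_spec(band_halfwidth = 2)
  sol <- deepwise:::solve_edge_band(img, img, mask, spec)
  b <- sol$bands
  fixed_vals <- c(saddle[b$interior], saddle[b$exterior_boundary])
  expect_gte(min(sol$values[, 1]), min(fixed_vals) - 1e-9)
  expect_lte(max(sol$values[, 1]), max(fixed_vals) + 1e-9)
  # and the harmonic field is its own solution
  expect_lt(max(abs(sol$values[, 1] - saddle[sol$unknown_idx])), 1e-8)
})

test_that("placement honours overlap policy and keeps the bookkeeping additive", {
  gen <- generate_image(synth_config(width = 128, height = 128,
                                     n_stained = c(4L, 4L), seed = 51))
  bg <- gen$image
  patches <- extract_cells(bg)[1:3]
  pol <- placement_policy(max_overlap_existing = 0.1, max_overlap_pasted = 0.1,
                          max_attempts = 60, seed = 9)
  out <- place_cells(bg, patches, pol, blend_spec())
  n_placed <- nrow(attr(out, "placements"))
  expect_gte(n_placed, 1L)
  expect_length(out$annotations, length(bg$annotations) + n_placed)
  # originals are intact and first in the list
  for (i in seq_along(bg$annotations))
    expect_identical(out$annotations[[i]], bg$annotations[[i]])

  h <- 128; w <- 128
  orig_masks <- lapply(bg$annotations, rasterize_polygon, height = h, width = w)
  new_masks <- lapply(out$annotations[-seq_along(bg$annotations)],
                      rasterize_polygon, height = h, width = w)
  pasted_union <- Reduce(`|`, new_masks, matrix(FALSE, h, w))
  for (om in orig_masks)
    expect_lte(sum(pasted_union & om) / sum(om), 0.1 + 1e-12)
  if (n_placed > 1) {
    for (i in 1:(n_placed - 1)) for (j in (i + 1):n_placed)
      expect_lte(mask_iou(new_masks[[i]], new_masks[[j]]), 0.1 + 1e-12)
  }

  # pixel accounting: pasting only converts non-cell pixels into cell pixels
  union_before <- Reduce(`|`, orig_masks, matrix(FALSE, h, w))
  union_after <- union_before | pasted_union
  expect_lte(sum(!union_after), sum(!union_before))

  expect_error(place_cells(bg, list(), pol), class = "deepwise_validation_error")
})

test_that("dataset augmentation is seed-deterministic and minority-class only", {
  train <- small_train_pair(61, 128)
  pol <- placement_policy(n_cells_per_image = c(2L, 3L), seed = 13)
  a1 <- suppressWarnings(augment_dataset(train, 3, pol))
  a2 <- suppressWarnings(augment_dataset(train, 3, pol))
  expect_identical(lapply(a1, `[[`, "image"), lapply(a2, `[[`, "image"))
  expect_equal(attr(a1, "manifest"), attr(a2, "manifest"))
  expect_gte(length(a1), 1L)

  for (res in a1) {
    src <- train[[match(attr(a1, "manifest")$background_id[
      match(res$identifier, attr(a1, "manifest")$image_id)],
      vapply(train, `[[`, "", "identifier"))]]
    h <- dim(src$image)[1]; w <- dim(src$image)[2]
    noncell <- function(ai) {
      u <- matrix(FALSE, h, w)
      for (a in ai$annotations) u <- u | rasterize_polygon(a, h, w)
      sum(!u)
    }
    expect_lte(noncell(res), noncell(src))
  }

  # n_out = 0: empty result but a valid (empty) annotation file
  dir0 <- withr::local_tempdir()
  res0 <- augment_dataset(train, 0, pol, out_dir = dir0)
  expect_length(res0, 0L)
  expect_length(read_via_json(file.path(dir0, "annotations.json")), 0L)

  expect_error(augment_dataset(list(annotated_image(flat_image(40, 40))), 1, pol),
               class = "deepwise_validation_error")
})
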