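## Pasting transformed cell patches onto background images and driving the
## whole minority-class augmentation of a training set.

sample_range <- function(lo, hi) {
  if (hi <= lo) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
}

# Embed a patch mask at 0-based offset (r0, c0) in an h x w frame.
embed_mask <- function(mask, h, w, r0, c0) {
  full <- matrix(FALSE, h, w)
  full[r0 + seq_len(nrow(mask)), c0 + seq_len(ncol(mask))] <- mask
  full
}

#' Paste cell patches onto a background image
#'
#' For each patch a position is rejection-sampled (seeded from the policy)
#' such that the pasted cells cover at most `max_overlap_existing` of any
#' original annotated cell's area (cumulatively over all pasted cells) and
#' any two pasted cells have IoU at most `max_overlap_pasted`. In addition a
#' candidate's k-dilated mask may never touch the k-eroded interior of an
#' already pasted cell: blending only ever rewrites edge-band pixels, so
#' every pasted cell's interior stays bit-exact no matter how many cells
#' follow it. Each accepted
#' patch is composited over the image and blended with [blend_edge()], and
#' its mask is traced back to a polygon annotation. Original annotations are
#' never removed. Patches that cannot be placed within `max_attempts` are
#' skipped with a warning; if no patch can be placed at all an error is
#' raised.
#'
#' @param background An [annotated_image] used as canvas.
#' @param patches List of [cell_patch] objects.
#' @param policy A [placement_policy].
#' @param spec A [blend_spec].
#' @return An [annotated_image] whose annotations are the originals plus one
#'   traced polygon per pasted cell, with attribute `"placements"`: a data
#'   frame of (source_id, transforms, row0, col0) per pasted cell.
#' @export
place_cells <- function(background, patches, policy = placement_policy(),
                        spec = blend_spec()) {
  if (!inherits(background, "annotated_image"))
    abort_dw("`background` must be an annotated_image", "deepwise_validation_error")
  if (length(patches) == 0L)
    abort_dw("`patches` must be nonempty", "deepwise_validation_error")
  h <- dim(background$image)[1]; w <- dim(background$image)[2]
  orig_masks <- lapply(background$annotations, rasterize_polygon,
                       height = h, width = w)
  orig_areas <- vapply(orig_masks, sum, 0L)
  img <- background$image
  pasted_masks <- list()
  placements <- list()
  new_anns <- list()
  covered <- matrix(FALSE, h, w)
  interiors <- matrix(FALSE, h, w)   # union of k-eroded pasted interiors
  with_seed(policy$seed, {
    for (pi in seq_along(patches)) {
      patch <- patches[[pi]]
      ph <- nrow(patch$mask); pw <- ncol(patch$mask)
      if (ph > h || pw > w) {
        warn_dw(sprintf("patch %d (%d x %d) exceeds the background frame; skipped",
                        pi, ph, pw), "deepwise_placement_failure")
        next
      }
      placed <- FALSE
      for (attempt in seq_len(policy$max_attempts)) {
        r0 <- sample.int(h - ph + 1L, 1L) - 1L
        c0 <- sample.int(w - pw + 1L, 1L) - 1L
        full <- embed_mask(patch$mask, h, w, r0, c0)
        cand_cover <- covered | full
        ok <- TRUE
        for (oi in seq_along(orig_masks)) {
          if (orig_areas[oi] == 0L) next
          if (sum(cand_cover & orig_masks[[oi]]) / orig_areas[oi] >
              policy$max_overlap_existing) { ok <- FALSE; break }
        }
        if (ok) for (pm in pasted_masks) {
          if (mask_iou(full, pm) > policy$max_overlap_pasted) { ok <- FALSE; break }
        }
        # never let this paste's blended region reach an earlier interior
        if (ok && length(pasted_masks) > 0L &&
            any(dilate_disk(full, spec$band_halfwidth) & interiors))
          ok <- FALSE
        if (!ok) next
        composite <- img
        for (ch in 1:3) {
          plane <- composite[, , ch]
          plane[full] <- patch$patch[, , ch][patch$mask]
          composite[, , ch] <- plane
        }
        img <- blend_edge(composite, img, full, spec)
        pasted_masks[[length(pasted_masks) + 1L]] <- full
        interiors <- interiors | erode_disk(full, spec$band_halfwidth)
        covered <- cand_cover
        polys <- mask_to_polygon(full, label = patch$label)
        if (length(polys) > 1L) {
          areas <- vapply(polys, function(p) abs(polygon_area(p$vertices)), 0)
          polys <- polys[which.max(areas)]
        }
        new_anns[[length(new_anns) + 1L]] <- polys[[1]]
        placements[[length(placements) + 1L]] <- data.frame(
          patch_index = pi, source_id = patch$source_id,
          transforms = paste(patch$transform_log, collapse = "+"),
          row0 = r0, col0 = c0, stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed)
        warn_dw(sprintf("patch %d could not be placed after %d attempts; skipped",
                        pi, policy$max_attempts), "deepwise_placement_failure")
    }
  })
  if (length(pasted_masks) == 0L)
    abort_dw("augmentation produced no new cells", "deepwise_placement_error")
  out <- annotated_image(img, c(background$annotations, new_anns),
                         identifier = background$identifier)
  attr(out, "placements") <- do.call(rbind, placements)
  out
}

#' Deep-wise augmentation of a training set
#'
#' Builds the global pool of cell patches from every annotated training
#' image, then generates `n_out` augmented images: for each one a background
#' is drawn uniformly from the training set, a seeded number of patches and
#' transforms is sampled, and the patches are pasted and edge-blended with
#' [place_cells()]. Only the minority cell class grows; non-cell pixels can
#' only be converted into cell pixels, never the other way around. The whole
#' procedure is a deterministic function of `policy$seed`.
#'
#' @param train List of [annotated_image] with at least one annotation
#'   overall.
#' @param n_out Number of augmented images to generate.
#' @param policy A [placement_policy]; its `n_cells_per_image` range and
#'   seed drive the sampling.
#' @param spec A [blend_spec].
#' @param transforms Allowed transform set; a subset of `"flip_h"`,
#'   `"flip_v"`, `"rot90"`, `"rot180"`, `"rot270"`, `"rot_free"` (the latter
#'   draws a uniform angle in \[0, 360)).
#' @param out_dir Optional directory: when given, augmented images are
#'   written as PNG plus one VIA JSON (`annotations.json`) and a tabular
#'   manifest (`manifest.csv`).
#' @return List of augmented [annotated_image] objects, invisibly when
#'   `out_dir` is given; the manifest data frame is attached as attribute
#'   `"manifest"`.
#' @export
augment_dataset <- function(train, n_out, policy = placement_policy(),
                            spec = blend_spec(),
                            transforms = c("flip_h", "flip_v", "rot90",
                                           "rot180", "rot270"),
                            out_dir = NULL) {
  if (!is.list(train) || length(train) == 0L ||
      !all(vapply(train, inherits, TRUE, "annotated_image")))
    abort_dw("`train` must be a non-empty list of annotated_image objects",
             "deepwise_validation_error")
  pool <- list()
  for (ai in train) pool <- c(pool, extract_cells(ai))
  if (length(pool) == 0L)
    abort_dw("training set has no usable cell annotations",
             "deepwise_validation_error")
  results <- list()
  manifest <- list()
  with_seed(policy$seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, max(n_out, 1L))
    for (j in seq_len(n_out)) {
      bg <- train[[sample.int(length(train), 1L)]]
      n_cells <- sample_range(policy$n_cells_per_image[1],
                              policy$n_cells_per_image[2])
      n_cells <- max(1L, n_cells)
      sel <- sample.int(length(pool), n_cells, replace = TRUE)
      ops <- if (length(transforms) == 1L) rep(transforms, n_cells)
             else sample(transforms, n_cells, replace = TRUE)
      angles <- stats::runif(n_cells, 0, 360)
      patches <- lapply(seq_len(n_cells), function(i)
        transform_patch(pool[[sel[i]]], ops[i],
                        angle = if (ops[i] == "rot_free") angles[i]))
      pol_j <- policy
      pol_j$seed <- sub_seeds[j]
      res <- tryCatch(place_cells(bg, patches, pol_j, spec),
                      deepwise_placement_error = function(e) NULL)
      if (is.null(res)) {
        warn_dw(sprintf("augmented image %d: no cell could be placed; skipped", j),
                "deepwise_placement_failure")
        next
      }
      res$identifier <- sprintf("aug_%04d_%s", j, bg$identifier)
      pl <- attr(res, "placements")
      pl$image_id <- res$identifier
      pl$background_id <- bg$identifier
      manifest[[length(manifest) + 1L]] <- pl
      results[[length(results) + 1L]] <- res
    }
  })
  manifest_df <- if (length(manifest) > 0L) do.call(rbind, manifest)
    else data.frame(patch_index = integer(0), source_id = character(0),
                    transforms = character(0),
                    row0 = integer(0), col0 = integer(0),
                    image_id = character(0), background_id = character(0))
  attr(results, "manifest") <- manifest_df
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    anns <- list()
    for (res in results) {
      fname <- paste0(res$identifier, ".png")
      write_image(res$image, file.path(out_dir, fname))
      anns[[fname]] <- res$annotations
    }
    write_via_json(anns, file.path(out_dir, "annotations.json"))
    utils::write.csv(manifest_df, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    return(invisible(results))
  }
  results
}
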