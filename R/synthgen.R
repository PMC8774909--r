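#' Synthetic blood-smear image configuration
#'
#' Parameterizes the seeded generator of microscopy-like test images:
#' a pinkish-white background, stained plasma cells drawn as ellipse pairs
#' (dark blue/purple nucleus inside a lighter blue cytoplasm), pinkish
#' unstained cells (possibly underneath stained cells), and touching cell
#' clusters. The colour model is chosen for clear class separability rather
#' than photorealism: it emulates the property of stain-normalized smears
#' that percentile stretching drives unstained material into green-channel
#' dominance while background and stained cells stay out of it.
#'
#' @param width,height Canvas size in pixels, default 512 x 512 (full-scale
#'   2560 x 1920 is accepted).
#' @param n_stained Integer range `c(lo, hi)` of stained cells, default
#'   `c(4, 8)`.
#' @param n_unstained Integer range of unstained cells, default `c(5, 8)`
#'   (unstained red blood cells outnumber plasma cells on real smears, and
#'   they must occupy enough area to anchor the upper green-channel
#'   percentile of the stretch).
#' @param unstained_axis_scale Unstained cells are drawn this much larger
#'   than stained ones, default 1.3.
#' @param cluster_prob Probability that a stained cell is seeded adjacent to
#'   an existing one with touching cytoplasm, default 0.35.
#' @param colors Named list of `mean` (length-3 RGB) and `sd` per class:
#'   `background`, `nucleus`, `cytoplasm`, `unstained`.
#' @param axis_range Cytoplasm semi-axis range in pixels, default `c(14, 26)`
#'   at 512 x 512 (scaled linearly with canvas width when you pass larger
#'   canvases yourself).
#' @param nucleus_fraction Nucleus-to-cell linear scale fraction, default 0.55
#'   (roughly 30 percent of the cell area).
#' @param texture_noise_sd Per-pixel Gaussian intensity noise, default 4.
#' @param seed Integer seed; the image and truth are fully determined by it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(width = 512L, height = 512L,
                         n_stained = c(4L, 8L), n_unstained = c(5L, 8L),
                         cluster_prob = 0.35,
                         colors = list(
                           background = list(mean = c(240, 185, 230), sd = 3),
                           nucleus    = list(mean = c(80, 60, 150), sd = 6),
                           cytoplasm  = list(mean = c(150, 140, 200), sd = 6),
                           unstained  = list(mean = c(210, 205, 150), sd = 3)),
                         axis_range = c(14, 26), unstained_axis_scale = 1.3,
                         nucleus_fraction = 0.55,
                         texture_noise_sd = 3, seed = 0L) {
  n_stained <- as.integer(rep(n_stained, length.out = 2L))
  n_unstained <- as.integer(rep(n_unstained, length.out = 2L))
  if (width < 32L || height < 32L)
    abort_dw("canvas must be at least 32 x 32", "deepwise_validation_error")
  if (n_stained[1] > n_stained[2] || n_unstained[1] > n_unstained[2] ||
      any(c(n_stained, n_unstained) < 0L))
    abort_dw("cell count ranges must be non-decreasing and non-negative",
             "deepwise_validation_error")
  if (cluster_prob < 0 || cluster_prob > 1 ||
      nucleus_fraction < 0 || nucleus_fraction > 1)
    abort_dw("fractions must lie in [0, 1]", "deepwise_validation_error")
  for (cls in c("background", "nucleus", "cytoplasm", "unstained")) {
    cm <- colors[[cls]]
    if (is.null(cm) || length(cm$mean) != 3L || any(cm$mean < 0 | cm$mean > 255))
      abort_dw(sprintf("colour model for \"%s\" needs a length-3 mean in [0, 255]",
                       cls), "deepwise_validation_error")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_stained = n_stained, n_unstained = n_unstained,
                 cluster_prob = cluster_prob, colors = colors,
                 axis_range = axis_range,
                 unstained_axis_scale = unstained_axis_scale,
                 nucleus_fraction = nucleus_fraction,
                 texture_noise_sd = texture_noise_sd, seed = as.integer(seed)),
            class = "synth_config")
}

# Polygon ring approximating an ellipse, 32 vertices, clipped to the frame.
ellipse_ring <- function(cx, cy, a, b, theta, width, height, n = 32L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x <- cx + a * cos(t) * cos(theta) - b * sin(t) * sin(theta)
  y <- cy + a * cos(t) * sin(theta) + b * sin(t) * cos(theta)
  cbind(x = pmin(pmax(x, 0), width), y = pmin(pmax(y, 0), height))
}

paint_region <- function(image, mask, mean_rgb, sd_rgb, noise_sd) {
  n <- sum(mask)
  if (n == 0L) return(image)
  total_sd <- sqrt(sd_rgb^2 + noise_sd^2)
  for (ch in 1:3) {
    plane <- image[, , ch]
    plane[mask] <- round_half_even(clip255(
      stats::rnorm(n, mean_rgb[ch], total_sd)))
    image[, , ch] <- plane
  }
  image
}

#' Generate one synthetic annotated smear image
#'
#' Draws the background, unstained cells and stained cells (cytoplasm plus
#' interior nucleus ellipses; with probability `cluster_prob` a cell is
#' seeded adjacent to an earlier one so cytoplasm touches or slightly
#' overlaps). Unstained cells may end up underneath stained cells; the
#' returned unstained-truth mask contains only their visible pixels.
#'
#' @param config A [synth_config].
#' @return List with `image` (an [annotated_image] whose annotations are the
#'   stained-cell cytoplasm polygons) and `truth` (class `synth_truth`:
#'   `unstained_mask`, per-cell metadata data frame `cells` with center,
#'   axes, rotation and cluster id, and `nucleus_masks`).
#' @export
generate_image <- function(config = synth_config()) {
  w <- config$width; h <- config$height
  scale <- w / 512
  ax_rng <- config$axis_range * scale
  with_seed(config$seed, {
    img <- array(0L, c(h, w, 3L))
    bgc <- config$colors$background
    img <- paint_region(img, matrix(TRUE, h, w), bgc$mean, bgc$sd,
                        config$texture_noise_sd)

    n_un <- sample_range(config$n_unstained[1], config$n_unstained[2])
    n_st <- sample_range(config$n_stained[1], config$n_stained[2])

    unstained_mask <- matrix(FALSE, h, w)
    for (i in seq_len(n_un)) {
      a <- stats::runif(1, ax_rng[1], ax_rng[2]) * config$unstained_axis_scale
      b <- stats::runif(1, 0.7, 1) * a
      th <- stats::runif(1, 0, pi)
      cx <- stats::runif(1, a, w - a); cy <- stats::runif(1, a, h - a)
      ring <- ellipse_ring(cx, cy, a, b, th, w, h)
      m <- rasterize_polygon(polygon_annotation(ring, "unstained"), h, w)
      unstained_mask <- unstained_mask | m
      uc <- config$colors$unstained
      img <- paint_region(img, m, uc$mean, uc$sd, config$texture_noise_sd)
    }

    anns <- list()
    nucleus_masks <- list()
    cells <- list()
    centers <- matrix(numeric(0), 0, 2)
    stained_union <- matrix(FALSE, h, w)
    attempts_cap <- 40L
    for (i in seq_len(n_st)) {
      a <- stats::runif(1, ax_rng[1], ax_rng[2])
      b <- stats::runif(1, 0.75, 1) * a
      th <- stats::runif(1, 0, pi)
      clustered <- nrow(centers) > 0L && stats::runif(1) < config$cluster_prob
      cluster_id <- NA_integer_
      placed <- FALSE
      for (att in seq_len(attempts_cap)) {
        if (clustered) {
          j <- sample.int(nrow(centers), 1L)
          dir <- stats::runif(1, 0, 2 * pi)
          # minor-axis sum guarantees touching/slight overlap in any direction
          dist <- (cells[[j]]$b + b) * stats::runif(1, 0.85, 0.98)
          cx <- centers[j, 1] + dist * cos(dir)
          cy <- centers[j, 2] + dist * sin(dir)
          cluster_id <- cells[[j]]$cluster_id
        } else {
          cx <- stats::runif(1, a, w - a); cy <- stats::runif(1, a, h - a)
        }
        if (cx < a / 2 || cx > w - a / 2 || cy < a / 2 || cy > h - a / 2) next
        if (nrow(centers) > 0L && !clustered) {
          d <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
          if (any(d < (vapply(cells, function(cl) cl$a, 0) + a) * 1.05)) next
        }
        placed <- TRUE
        break
      }
      if (!placed)
        abort_dw(sprintf("could not fit stained cell %d after %d attempts",
                         i, attempts_cap), "deepwise_generation_error")
      if (is.na(cluster_id)) cluster_id <- i
      ring <- ellipse_ring(cx, cy, a, b, th, w, h)
      ann <- polygon_annotation(ring, "myeloma")
      cyto <- rasterize_polygon(ann, h, w)
      cyc <- config$colors$cytoplasm
      img <- paint_region(img, cyto, cyc$mean, cyc$sd, config$texture_noise_sd)
      nf <- config$nucleus_fraction
      nring <- ellipse_ring(cx, cy, a * nf, b * nf, th, w, h)
      nuc <- rasterize_polygon(polygon_annotation(nring, "nucleus"), h, w)
      nuc <- nuc & cyto
      ncc <- config$colors$nucleus
      img <- paint_region(img, nuc, ncc$mean, ncc$sd, config$texture_noise_sd)
      stained_union <- stained_union | cyto
      anns[[length(anns) + 1L]] <- ann
      nucleus_masks[[length(nucleus_masks) + 1L]] <- nuc
      centers <- rbind(centers, c(cx, cy))
      cells[[length(cells) + 1L]] <- list(cx = cx, cy = cy, a = a, b = b,
                                          theta = th, cluster_id = cluster_id)
    }
    unstained_mask <- unstained_mask & !stained_union   # visible pixels only

    cells_df <- if (length(cells) > 0L)
      do.call(rbind, lapply(seq_along(cells), function(i)
        data.frame(cell = i, cx = cells[[i]]$cx, cy = cells[[i]]$cy,
                   a = cells[[i]]$a, b = cells[[i]]$b,
                   theta = cells[[i]]$theta,
                   cluster_id = cells[[i]]$cluster_id)))
    else data.frame(cell = integer(0), cx = numeric(0), cy = numeric(0),
                    a = numeric(0), b = numeric(0), theta = numeric(0),
                    cluster_id = integer(0))
    list(
      image = annotated_image(img, anns,
                              identifier = sprintf("synth_%06d", config$seed)),
      truth = structure(list(unstained_mask = unstained_mask,
                             cells = cells_df,
                             nucleus_masks = nucleus_masks),
                        class = "synth_truth"))
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_images` PNG images with per-image seeds derived from the master
#' seed in `config`, one VIA JSON annotation file (`annotations.json`) and
#' one JSON truth sidecar per image (unstained pixel mask as COCO-style RLE
#' plus the per-cell metadata). Regenerating with the same master seed
#' reproduces the dataset byte for byte.
#'
#' @param config A [synth_config]; its `seed` is the master seed.
#' @param n_images Number of images to generate (>= 1).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a character vector of the image file names.
#' @export
generate_dataset <- function(config = synth_config(), n_images, out_dir) {
  if (n_images < 1L)
    abort_dw("`n_images` must be >= 1", "deepwise_validation_error")
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, 2L) != 0L)
    abort_dw(sprintf("cannot write to directory %s", out_dir),
             "deepwise_io_error")
  seeds <- with_seed(config$seed,
                     sample.int(.Machine$integer.max - 1L, n_images))
  anns <- list()
  files <- character(n_images)
  for (i in seq_len(n_images)) {
    cfg_i <- config
    cfg_i$seed <- seeds[i]
    gen <- generate_image(cfg_i)
    fname <- sprintf("synth_%03d.png", i)
    write_image(gen$image$image, file.path(out_dir, fname))
    anns[[fname]] <- gen$image$annotations
    truth <- list(
      unstained_rle = coco_rle_encode(gen$truth$unstained_mask),
      cells = gen$truth$cells
    )
    jsonlite::write_json(truth, file.path(out_dir,
                                          sprintf("synth_%03d_truth.json", i)),
                         auto_unbox = TRUE, digits = NA)
    files[i] <- fname
  }
  write_via_json(anns, file.path(out_dir, "annotations.json"))
  invisible(files)
}
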