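#' Contrast-stretch parameters
#'
#' Configuration for percentile contrast stretching: intensities between the
#' low and high percentile of each channel are mapped linearly onto the full
#' 8-bit dynamic range.
#'
#' @param low_percentile Lower percentile in \[0, 50), default 2.
#' @param high_percentile Upper percentile in (50, 100\], default 98.
#' @param per_channel Stretch each channel with its own percentiles (default)
#'   or use joint percentiles over all channels.
#' @return An object of class `stretch_params`.
#' @export
stretch_params <- function(low_percentile = 2, high_percentile = 98,
                           per_channel = TRUE) {
  if (low_percentile < 0 || low_percentile >= 50 ||
      high_percentile <= 50 || high_percentile > 100 ||
      low_percentile >= high_percentile)
    abort_dw("need 0 <= low_percentile < 50 < high_percentile <= 100",
             "deepwise_validation_error")
  structure(list(low_percentile = low_percentile,
                 high_percentile = high_percentile,
                 per_channel = isTRUE(per_channel)),
            class = "stretch_params")
}

#' Percentile contrast stretching
#'
#' Maps each channel value v to
#' `clip((v - p_lo) * 255 / (p_hi - p_lo), 0, 255)`, rounded half-to-even,
#' where `p_lo`/`p_hi` are the configured percentiles of that channel (or of
#' all channels jointly). On stain-normalized marrow smears this drives the
#' pinkish unstained material towards green, which is what the downstream
#' unstained-cell detector keys on. Channels whose two percentiles coincide
#' are returned unchanged with a message.
#'
#' @param image H x W x 3 array, values in \[0, 255\].
#' @param params A [stretch_params] object.
#' @return Stretched image, same shape, integer values in \[0, 255\].
#' @export
contrast_stretch <- function(image, params = stretch_params()) {
  assert_image(image)
  probs <- c(params$low_percentile, params$high_percentile) / 100
  out <- image
  stretch_one <- function(v) {
    p <- stats::quantile(v, probs, names = FALSE)
    if (p[2] == p[1]) {
      message("contrast_stretch: degenerate percentile range; channel left unchanged")
      return(v)
    }
    round_half_even(clip255((v - p[1]) * 255 / (p[2] - p[1])))
  }
  if (params$per_channel) {
    for (ch in 1:3) out[, , ch] <- stretch_one(image[, , ch])
  } else {
    out[] <- stretch_one(as.numeric(image))
  }
  storage.mode(out) <- "integer"
  out
}

#' Hue channel of an RGB image
#'
#' Standard RGB -> HSV hue rescaled from \[0, 360) degrees to \[0, 255\];
#' achromatic pixels get hue 0. Provided for inspecting stained/unstained
#' separability in the hue plane; the removal pipeline itself operates on the
#' contrast-stretched RGB image.
#'
#' @param image H x W x 3 array.
#' @return H x W numeric matrix with values in \[0, 255\].
#' @export
hue_channel <- function(image) {
  assert_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  hsv <- grDevices::rgb2hsv(r = as.numeric(image[, , 1]),
                            g = as.numeric(image[, , 2]),
                            b = as.numeric(image[, , 3]),
                            maxColorValue = 255)
  matrix(round_half_even(hsv["h", ] * 255), h, w)
}

#' Unstained-cell detection rule
#'
#' Operationalizes "greenish after stretching" as green-channel dominance:
#' a pixel is flagged when `G - max(R, B) >= green_margin`. The raw flag map
#' is cleaned by a morphological opening and a minimum component size.
#' Cleanup defaults are stated at the native 2560 x 1920 scale of typical
#' scanner output and scale linearly with image area via
#' `scale_unstained_rule()`.
#'
#' @param green_margin Dominance threshold in intensity units, default 10.
#' @param min_component_px Minimum connected-component size kept, default 50.
#' @param opening_radius Radius of the morphological opening, default 2.
#' @return An object of class `unstained_rule`.
#' @export
unstained_rule <- function(green_margin = 10, min_component_px = 50,
                           opening_radius = 2) {
  if (green_margin < 0 || min_component_px < 0 || opening_radius < 0)
    abort_dw("unstained_rule parameters must be non-negative",
             "deepwise_validation_error")
  structure(list(green_margin = green_margin,
                 min_component_px = as.integer(min_component_px),
                 opening_radius = as.integer(opening_radius)),
            class = "unstained_rule")
}

#' Rescale an unstained-cell rule to a different image size
#'
#' `min_component_px` scales with image area relative to the 2560 x 1920
#' reference; `opening_radius` scales with its square root (a length).
#'
#' @param rule An [unstained_rule].
#' @param height,width Target image size in pixels.
#' @return A rescaled [unstained_rule].
#' @export
scale_unstained_rule <- function(rule, height, width) {
  area_ratio <- (height * width) / (2560 * 1920)
  unstained_rule(
    green_margin = rule$green_margin,
    min_component_px = max(1L, as.integer(round(rule$min_component_px * area_ratio))),
    opening_radius = max(0L, as.integer(round(rule$opening_radius * sqrt(area_ratio))))
  )
}

#' Detect unstained-cell pixels in a contrast-stretched image
#'
#' Flags pixels whose green channel dominates (`G - max(R, B) >= margin`),
#' then applies a morphological opening and removes small connected
#' components. Expects an image that has already been contrast-stretched;
#' on raw images the greenish signature of unstained cells is absent.
#'
#' @param stretched_image Contrast-stretched H x W x 3 array.
#' @param rule An [unstained_rule].
#' @return H x W logical mask of unstained pixels.
#' @export
detect_unstained <- function(stretched_image, rule = unstained_rule()) {
  assert_image(stretched_image, "stretched_image")
  g <- stretched_image[, , 2]
  rb_max <- pmax(stretched_image[, , 1], stretched_image[, , 3])
  flag <- matrix(g - rb_max >= rule$green_margin,
                 dim(stretched_image)[1], dim(stretched_image)[2])
  if (rule$opening_radius > 0L) flag <- open_disk(flag, rule$opening_radius)
  if (rule$min_component_px > 0L) flag <- filter_small_components(flag, rule$min_component_px)
  flag
}

#' Estimate a background colour model
#'
#' Per-channel median and robust spread (scaled median absolute deviation)
#' of the pixels outside an exclusion mask. The exclusion mask should be the
#' union of annotated cells and detected unstained pixels so that only true
#' background contributes.
#'
#' @param image H x W x 3 array.
#' @param exclusion H x W logical mask of pixels to ignore.
#' @return An object of class `background_model` with numeric length-3
#'   elements `median` and `spread`.
#' @export
estimate_background <- function(image, exclusion = NULL) {
  assert_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (is.null(exclusion)) exclusion <- matrix(FALSE, h, w)
  assert_mask(exclusion, "exclusion", shape = dim(image))
  keep <- !exclusion
  if (!any(keep))
    abort_dw("no background pixels available: exclusion mask covers the whole image",
             "deepwise_validation_error")
  med <- numeric(3); spread <- numeric(3)
  for (ch in 1:3) {
    v <- image[, , ch][keep]
    med[ch] <- stats::median(v)
    spread[ch] <- stats::mad(v)          # 1.4826 * MAD: robust sd estimate
  }
  structure(list(median = med, spread = spread, n_pixels = sum(keep)),
            class = "background_model")
}

#' Replace unstained pixels with background fill
#'
#' Pixels inside the unstained mask are replaced by the background median
#' colour plus zero-mean Gaussian noise with the model's per-channel spread
#' (seeded, clipped to \[0, 255\], rounded half-to-even). Pixels outside the
#' mask are left bit-exact. With zero spread the fill is exactly the median
#' colour. Replacing rather than zeroing keeps the slide free of artificial
#' regions a segmenter could latch onto.
#'
#' @param image H x W x 3 array.
#' @param unstained H x W logical mask of pixels to replace.
#' @param background A `background_model` from [estimate_background()].
#' @param noise_seed Integer seed for the fill noise.
#' @return Image with unstained pixels replaced.
#' @export
remove_unstained <- function(image, unstained, background, noise_seed = 0L) {
  assert_image(image)
  assert_mask(unstained, "unstained", shape = dim(image))
  if (!inherits(background, "background_model"))
    abort_dw("`background` must come from estimate_background()",
             "deepwise_validation_error")
  n <- sum(unstained)
  if (n == 0L) return(image)
  out <- image
  with_seed(noise_seed, {
    for (ch in 1:3) {
      fill <- background$median[ch] +
        (if (background$spread[ch] > 0) stats::rnorm(n, 0, background$spread[ch]) else 0)
      plane <- out[, , ch]
      plane[unstained] <- round_half_even(clip255(fill))
      out[, , ch] <- plane
    }
  })
  storage.mode(out) <- "integer"
  out
}

#' Full stained-cell preprocessing of one annotated image
#'
#' Convenience pipeline: contrast stretching, unstained-pixel detection,
#' background estimation (excluding annotated cells and detected pixels) and
#' replacement. Returns both the contrast-enhanced and the stained-cell
#' image so a downstream trainer can use either representation.
#'
#' @param annotated An [annotated_image].
#' @param params A [stretch_params].
#' @param rule An [unstained_rule]; by default rescaled to the image size
#'   with [scale_unstained_rule()].
#' @param noise_seed Seed for the background fill noise.
#' @param rescale_rule Rescale `rule` to the image area (default TRUE).
#' @return List with elements `contrast` (stretched image), `stained`
#'   (unstained cells removed), `unstained_mask` and `background` model.
#' @export
preprocess_image <- function(annotated, params = stretch_params(),
                             rule = unstained_rule(), noise_seed = 0L,
                             rescale_rule = TRUE) {
  if (!inherits(annotated, "annotated_image"))
    abort_dw("`annotated` must be an annotated_image", "deepwise_validation_error")
  h <- dim(annotated$image)[1]; w <- dim(annotated$image)[2]
  if (rescale_rule) rule <- scale_unstained_rule(rule, h, w)
  stretched <- contrast_stretch(annotated$image, params)
  unstained <- detect_unstained(stretched, rule)
  cells <- matrix(FALSE, h, w)
  for (ann in annotated$annotations)
    cells <- cells | rasterize_polygon(ann, h, w)
  bg <- estimate_background(stretched, cells | unstained)
  stained <- remove_unstained(stretched, unstained, bg, noise_seed)
  list(contrast = stretched, stained = stained,
       unstained_mask = unstained, background = bg)
}
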