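#' Polygon cell annotation
#'
#' A single annotated cell: an ordered ring of vertices in continuous image
#' coordinates (x = column axis, y = row axis, origin top-left, pixel units)
#' plus a free-text label. The polygon is implicitly closed.
#'
#' @param vertices Numeric n x 2 matrix (or coercible) of (x, y) vertices,
#'   n >= 3.
#' @param label Category string; defaults to `"myeloma"`.
#' @return An object of class `polygon_annotation`.
#' @export
polygon_annotation <- function(vertices, label = "myeloma") {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2L)
    abort_dw("`vertices` must be an n x 2 numeric matrix of (x, y) points",
             "deepwise_validation_error")
  if (nrow(vertices) < 3L)
    abort_dw("a polygon annotation needs at least 3 vertices",
             "deepwise_validation_error")
  dimnames(vertices) <- list(NULL, c("x", "y"))
  structure(list(vertices = vertices, label = as.character(label)[1]),
            class = "polygon_annotation")
}

#' @export
print.polygon_annotation <- function(x, ...) {
  cat(sprintf("<polygon_annotation> %d vertices, label \"%s\", area %.1f px^2\n",
              nrow(x$vertices), x$label, abs(polygon_area(x$vertices))))
  invisible(x)
}

# Signed shoelace area; positive when vertices wind counter-clockwise in the
# y-down image frame convention used here.
polygon_area <- function(vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

assert_annotation <- function(ann, width = NULL, height = NULL, arg = "annotation") {
  if (!inherits(ann, "polygon_annotation"))
    abort_dw(sprintf("`%s` must be a polygon_annotation", arg),
             "deepwise_validation_error")
  v <- ann$vertices
  if (!is.null(width) &&
      (any(v[, 1] < 0) || any(v[, 1] > width) ||
       any(v[, 2] < 0) || any(v[, 2] > height)))
    abort_dw(sprintf("`%s` has vertices outside [0, %s] x [0, %s]",
                     arg, width, height), "deepwise_validation_error")
  invisible(ann)
}

#' Annotated image
#'
#' An RGB raster together with its polygon cell annotations; the ground-truth
#' carrier used throughout the preprocessing, augmentation and evaluation
#' steps.
#'
#' @param image H x W x 3 array, 8-bit channel values.
#' @param annotations List of [polygon_annotation] objects (may be empty).
#' @param identifier Image identifier string (e.g. file name).
#' @return An object of class `annotated_image`.
#' @export
annotated_image <- function(image, annotations = list(), identifier = "image") {
  assert_image(image)
  storage.mode(image) <- "integer"
  h <- dim(image)[1]; w <- dim(image)[2]
  for (i in seq_along(annotations))
    assert_annotation(annotations[[i]], width = w, height = h,
                      arg = sprintf("annotations[[%d]]", i))
  structure(list(image = image, annotations = annotations,
                 identifier = as.character(identifier)[1]),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  cat(sprintf("<annotated_image> \"%s\": %d x %d px, %d annotation(s)\n",
              x$identifier, dim(x$image)[1], dim(x$image)[2],
              length(x$annotations)))
  invisible(x)
}

## ---- VIA 2.x project JSON --------------------------------------------------

#' Read VIA 2.x polygon annotations
#'
#' Parses a VGG Image Annotator (VIA) 2.x project JSON file and returns the
#' polygon regions per image. Non-polygon region shapes (rect, circle, ...)
#' are skipped with a warning. A region attribute named `label` (or the first
#' region attribute present) becomes the annotation label; missing attributes
#' default to `"myeloma"`.
#'
#' @param path Path to a VIA 2.x project JSON file.
#' @return Named list: image identifier -> list of [polygon_annotation].
#' @export
read_via_json <- function(path) {
  if (!file.exists(path))
    abort_dw(sprintf("VIA file not found: %s", path), "deepwise_io_error")
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    abort_dw(sprintf("malformed JSON in %s: %s", path,
                                     conditionMessage(e)), "deepwise_parse_error"))
  metadata <- doc[["_via_img_metadata"]]
  if (is.null(metadata)) {
    # Plain export flavour: top level is the metadata map itself
    looks_meta <- length(doc) > 0L &&
      all(vapply(doc, function(e) is.list(e) && !is.null(e[["regions"]]), TRUE))
    if (!looks_meta)
      abort_dw(sprintf("%s: missing key \"_via_img_metadata\" (need VIA 2.x project JSON)",
                       path), "deepwise_parse_error")
    metadata <- doc
  }
  out <- list()
  for (key in names(metadata)) {
    entry <- metadata[[key]]
    id <- if (!is.null(entry$filename)) entry$filename else key
    anns <- list()
    regions <- entry$regions
    for (ri in seq_along(regions)) {
      reg <- regions[[ri]]
      sa <- reg$shape_attributes
      if (is.null(sa$name) || sa$name != "polygon") {
        warn_dw(sprintf("image \"%s\" region %d: shape \"%s\" is not a polygon; skipped",
                        id, ri, if (is.null(sa$name)) "?" else sa$name),
                "deepwise_skipped_region")
        next
      }
      xs <- unlist(sa$all_points_x); ys <- unlist(sa$all_points_y)
      if (length(xs) != length(ys))
        abort_dw(sprintf("image \"%s\" region %d: all_points_x/all_points_y lengths differ",
                         id, ri), "deepwise_parse_error")
      if (length(xs) < 3L)
        abort_dw(sprintf("image \"%s\" region %d: polygon has fewer than 3 points",
                         id, ri), "deepwise_validation_error")
      ra <- reg$region_attributes
      label <- if (length(ra) == 0L) "myeloma"
               else as.character(if (!is.null(ra$label)) ra$label else ra[[1]])[1]
      anns[[length(anns) + 1L]] <- polygon_annotation(cbind(xs, ys), label)
    }
    out[[id]] <- anns
  }
  out
}

#' Write VIA 2.x polygon annotations
#'
#' Serializes annotations into a VIA 2.x project JSON readable by
#' [read_via_json()]. Coordinates are written at full double precision so
#' that a write/read round trip is lossless.
#'
#' @param annotations Named list: image identifier -> list of
#'   [polygon_annotation].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_via_json <- function(annotations, path) {
  metadata <- list()
  for (id in names(annotations)) {
    regions <- lapply(annotations[[id]], function(ann) {
      assert_annotation(ann)
      list(
        shape_attributes = list(
          name = "polygon",
          all_points_x = as.numeric(ann$vertices[, 1]),
          all_points_y = as.numeric(ann$vertices[, 2])
        ),
        region_attributes = list(label = ann$label)
      )
    })
    metadata[[paste0(id, "-1")]] <- list(filename = id, size = -1L,
                                         regions = regions,
                                         file_attributes = c())
  }
  doc <- list(
    `_via_settings` = list(project = list(name = "deepwise")),
    `_via_img_metadata` = metadata,
    `_via_attributes` = list(
      region = list(label = list(type = "text", default_value = "myeloma")),
      file = c()
    )
  )
  ok <- tryCatch({
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "list")
    TRUE
  }, error = function(e) FALSE)
  if (!ok)
    abort_dw(sprintf("cannot write VIA JSON to %s", path), "deepwise_io_error")
  invisible(path)
}
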