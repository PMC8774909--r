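#' Rasterize a polygon annotation to a binary mask
#'
#' A pixel (r, c) is set iff its center (c + 0.5, r + 0.5) lies inside the
#' polygon under the even-odd rule. Boundary cases resolve by the same
#' crossing-parity test on the center point, so the result is deterministic
#' for vertices lying on pixel-center lines.
#'
#' @param polygon A [polygon_annotation].
#' @param height,width Dimensions of the owning image in pixels.
#' @return H x W logical matrix.
#' @export
rasterize_polygon <- function(polygon, height, width) {
  assert_annotation(polygon, width = width, height = height, arg = "polygon")
  v <- polygon$vertices
  mask <- matrix(FALSE, height, width)
  x1 <- v[, 1]; y1 <- v[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  keep <- y1 != y2                      # horizontal edges never cross a scanline
  if (!any(keep)) {
    warn_dw("polygon encloses zero area; rasterized to an empty mask",
            "deepwise_degenerate_polygon")
    return(mask)
  }
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  centers <- seq_len(width) - 0.5
  any_set <- FALSE
  for (r in seq_len(height)) {
    y <- r - 0.5
    # half-open span [min(y1,y2), max(y1,y2)) makes shared vertices count once
    cross <- (y1 <= y & y < y2) | (y2 <= y & y < y1)
    if (!any(cross)) next
    xs <- sort(x1[cross] + (y - y1[cross]) * (x2[cross] - x1[cross]) /
                 (y2[cross] - y1[cross]))
    # parity of strict crossings left of the pixel center decides insideness
    inside <- (findInterval(centers, xs, left.open = TRUE) %% 2L) == 1L
    mask[r, ] <- inside
    any_set <- any_set || any(inside)
  }
  if (!any_set)
    warn_dw("polygon encloses zero area; rasterized to an empty mask",
            "deepwise_degenerate_polygon")
  mask
}

#' Trace binary mask components back to polygons
#'
#' Each 8-connected component of the mask becomes one polygon traced along
#' the outer boundary of its pixel squares (vertices at pixel-grid corners).
#' Holes are filled: re-rasterizing the polygon with [rasterize_polygon()]
#' reproduces the component's pixel set exactly for hole-free components and
#' the filled component otherwise.
#'
#' @param mask H x W logical matrix with at least one foreground pixel.
#' @param label Label given to the traced polygons.
#' @return List of [polygon_annotation], one per component, in label order.
#' @export
mask_to_polygon <- function(mask, label = "myeloma") {
  assert_mask(mask)
  if (!any(mask))
    abort_dw("no foreground: cannot trace polygons from an empty mask",
             "deepwise_validation_error")
  labels <- label_components(mask, 8L)
  lapply(seq_len(max(labels)), function(lab) {
    ring <- trace_outer_ring(labels == lab)
    polygon_annotation(ring, label)
  })
}

# Trace the outer boundary ring of one connected pixel set. Boundary edges
# are directed so the component lies on a consistent side; at pinch corners
# (two diagonal pixels meeting at a vertex) the continuation that crosses to
# the diagonal neighbour is taken, keeping an 8-connected component on a
# single ring. Returns an n x 2 matrix of (x, y) grid-corner vertices.
trace_outer_ring <- function(fg) {
  h <- nrow(fg); w <- ncol(fg)
  idx <- which(fg, arr.ind = TRUE)
  r0 <- idx[, 1] - 1L; c0 <- idx[, 2] - 1L     # 0-based pixel coords
  # shift_mask(fg, 1, 0)[r, c] == fg[r - 1, c]: the neighbour above; the
  # FALSE fill makes pixels beyond the border count as background
  bg_n <- !shift_mask(fg,  1L, 0L, fill = FALSE)[idx]
  bg_s <- !shift_mask(fg, -1L, 0L, fill = FALSE)[idx]
  bg_w <- !shift_mask(fg, 0L,  1L, fill = FALSE)[idx]
  bg_e <- !shift_mask(fg, 0L, -1L, fill = FALSE)[idx]
  # directed boundary edges (sx, sy) -> (ex, ey)
  sx <- c(c0[bg_n],      c0[bg_e] + 1L, c0[bg_s] + 1L, c0[bg_w])
  sy <- c(r0[bg_n],      r0[bg_e],      r0[bg_s] + 1L, r0[bg_w] + 1L)
  ex <- c(c0[bg_n] + 1L, c0[bg_e] + 1L, c0[bg_s],      c0[bg_w])
  ey <- c(r0[bg_n],      r0[bg_e] + 1L, r0[bg_s] + 1L, r0[bg_w])
  n_edge <- length(sx)
  key <- function(x, y) y * (w + 1L) + x + 1L
  # bucket outgoing edges by start vertex (at most 2 per vertex)
  start_key <- key(sx, sy)
  ord <- order(start_key)
  first_at <- integer((h + 1L) * (w + 1L))
  count_at <- integer((h + 1L) * (w + 1L))
  for (i in rev(seq_len(n_edge))) {
    k <- start_key[ord[i]]
    first_at[k] <- i
    count_at[k] <- count_at[k] + 1L
  }
  used <- logical(n_edge)
  rings <- list()
  for (e0 in seq_len(n_edge)) {
    if (used[e0]) next
    ring_x <- integer(0); ring_y <- integer(0)
    e <- e0
    repeat {
      used[e] <- TRUE
      ring_x <- c(ring_x, sx[e]); ring_y <- c(ring_y, sy[e])
      k <- key(ex[e], ey[e])
      cand <- ord[seq.int(first_at[k], length.out = count_at[k])]
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) break                      # ring closed
      if (length(cand) > 1L) {
        # pinch corner: continue with the left-rotated direction, which
        # crosses onto the diagonal pixel and keeps the ring connected
        dx <- ex[e] - sx[e]; dy <- ey[e] - sy[e]
        px <- dy; py <- -dx
        hit <- cand[(ex[cand] - sx[cand]) == px & (ey[cand] - sy[cand]) == py]
        e <- if (length(hit) >= 1L) hit[1] else cand[1]
      } else e <- cand
    }
    rings[[length(rings) + 1L]] <- cbind(x = ring_x, y = ring_y)
  }
  # outer ring has the largest absolute area; inner (hole) rings are dropped
  areas <- vapply(rings, function(rg) abs(polygon_area(rg)), 0)
  simplify_ring(rings[[which.max(areas)]])
}

# Merge consecutive collinear grid steps into single segments.
simplify_ring <- function(ring) {
  n <- nrow(ring)
  if (n <= 3L) return(ring)
  prev <- ring[c(n, seq_len(n - 1L)), ]
  nxt <- ring[c(seq.int(2L, n), 1L), ]
  turn <- (ring[, 1] - prev[, 1]) * (nxt[, 2] - ring[, 2]) !=
          (ring[, 2] - prev[, 2]) * (nxt[, 1] - ring[, 1])
  if (!any(turn)) return(ring)
  ring[turn, , drop = FALSE]
}
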