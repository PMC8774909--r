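# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately written differently from the package
# implementation (scalar loops, ray casting, dense algebra).

# Even-odd point-in-polygon by counting crossings of a ray to +infinity,
# one point at a time.
pip_oracle <- function(px, py, vertices) {
  n <- nrow(vertices)
  crossings <- 0L
  for (i in seq_len(n)) {
    x1 <- vertices[i, 1]; y1 <- vertices[i, 2]
    j <- if (i == n) 1L else i + 1L
    x2 <- vertices[j, 1]; y2 <- vertices[j, 2]
    if ((y1 <= py && py < y2) || (y2 <= py && py < y1)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      if (xint > px) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

# Rasterize by testing every pixel center with the ray-casting oracle.
rasterize_oracle <- function(vertices, height, width) {
  out <- matrix(FALSE, height, width)
  for (r in seq_len(height)) for (c in seq_len(width))
    out[r, c] <- pip_oracle(c - 0.5, r - 0.5, vertices)
  out
}

# Brute-force erosion with the unit disk (4-neighbourhood), k iterations,
# checking each pixel's neighbourhood explicitly.
erode_oracle <- function(mask, k) {
  h <- nrow(mask); w <- ncol(mask)
  for (step in seq_len(k)) {
    out <- matrix(FALSE, h, w)
    for (r in seq_len(h)) for (c in seq_len(w)) {
      if (!mask[r, c]) next
      ok <- TRUE
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr < 1 || rr > h || cc < 1 || cc > w || !mask[rr, cc]) { ok <- FALSE; break }
      }
      out[r, c] <- ok
    }
    mask <- out
  }
  mask
}

dilate_oracle <- function(mask, k) {
  h <- nrow(mask); w <- ncol(mask)
  for (step in seq_len(k)) {
    out <- mask
    for (r in seq_len(h)) for (c in seq_len(w)) {
      if (mask[r, c]) next
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w && mask[rr, cc]) {
          out[r, c] <- TRUE; break
        }
      }
    }
    mask <- out
  }
  mask
}

# Is the mask free of holes, i.e. is its complement 4-connected to the
# image border? (Filled tracing is only exact for hole-free components.)
is_hole_free <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  bg <- !mask
  reach <- matrix(FALSE, h, w)
  frontier <- which(bg & (row(bg) %in% c(1, h) | col(bg) %in% c(1, w)))
  reach[frontier] <- TRUE
  while (length(frontier) > 0) {
    r <- ((frontier - 1) %% h) + 1; c <- ((frontier - 1) %/% h) + 1
    nbs <- integer(0)
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ok <- r + d[1] >= 1 & r + d[1] <= h & c + d[2] >= 1 & c + d[2] <= w
      nbs <- c(nbs, frontier[ok] + d[1] + d[2] * h)
    }
    nbs <- unique(nbs[bg[nbs] & !reach[nbs]])
    reach[nbs] <- TRUE
    frontier <- nbs
  }
  all(reach[bg])
}

# Exhaustive one-to-one assignment oracle: maximise matched count, then
# total IoU, over all injective pred -> gt maps with IoU >= threshold.
exhaustive_match_oracle <- function(iou, threshold) {
  np <- nrow(iou); ng <- ncol(iou)
  best <- list(count = 0L, total = 0)
  recurse <- function(p, used, count, total) {
    if (count > best$count ||
        (count == best$count && total > best$total + 1e-12))
      best <<- list(count = count, total = total)
    if (p > np) return()
    recurse(p + 1L, used, count, total)          # leave pred p unmatched
    for (g in seq_len(ng)) {
      if (!used[g] && iou[p, g] >= threshold)
        recurse(p + 1L, replace(used, g, TRUE), count + 1L, total + iou[p, g])
    }
  }
  if (np > 0L && ng > 0L) recurse(1L, logical(ng), 0L, 0)
  best
}

# Dense reassembly of the edge-band Poisson system for one channel, solved
# with base::solve; the independent check for the package's sparse solver.
dense_band_oracle <- function(composite, background, mask, spec, channel = 1L) {
  h <- dim(composite)[1]; w <- dim(composite)[2]
  sol <- deepwise:::solve_edge_band(composite, background, mask, spec)
  nu <- length(sol$unknown_idx)
  if (nu == 0L) return(list(unknown_idx = integer(0), dense = numeric(0), sol = sol))
  interior <- sol$interior
  g <- ifelse(mask, composite[, , channel], background[, , channel])
  f <- ifelse(interior, composite[, , channel], background[, , channel])
  A <- matrix(0, nu, nu); b <- numeric(nu)
  pos <- match(seq_len(h * w), sol$unknown_idx)
  for (ii in seq_len(nu)) {
    idx <- sol$unknown_idx[ii]
    r <- (idx - 1) %% h + 1; c <- (idx - 1) %/% h + 1
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr < 1 || rr > h || cc < 1 || cc > w) next
      nb <- (cc - 1) * h + rr
      A[ii, ii] <- A[ii, ii] + 1
      b[ii] <- b[ii] + g[idx] - g[nb]
      if (!is.na(pos[nb])) A[ii, pos[nb]] <- A[ii, pos[nb]] - 1
      else b[ii] <- b[ii] + f[nb]
    }
  }
  list(unknown_idx = sol$unknown_idx, dense = solve(A, b), sol = sol)
}

# Random blend scene on an h x w canvas: a random polygon mask pasted with a
# flat foreign colour over a noisy background.
random_blend_scene <- function(h = 16, w = 16) {
  background <- array(sample(0:255, h * w * 3, TRUE), c(h, w, 3))
  storage.mode(background) <- "integer"
  mask <- suppressWarnings(rasterize_polygon(random_polygon(w, h, 7), h, w))
  composite <- background
  patchcol <- sample(0:255, 3)
  for (ch in 1:3) {
    plane <- composite[, , ch]; plane[mask] <- patchcol[ch]
    composite[, , ch] <- plane
  }
  list(composite = composite, background = background, mask = mask)
}

# Small random fixtures -------------------------------------------------

random_polygon <- function(w = 40, h = 40, n = 8L) {
  cx <- runif(1, w * 0.3, w * 0.7); cy <- runif(1, h * 0.3, h * 0.7)
  ang <- sort(runif(n, 0, 2 * pi))
  rad <- runif(n, w * 0.08, w * 0.25)
  polygon_annotation(cbind(
    pmin(pmax(cx + rad * cos(ang), 0), w),
    pmin(pmax(cy + rad * sin(ang), 0), h)))
}

random_blob_mask <- function(h = 20, w = 20, p = 0.5) {
  matrix(runif(h * w) < p, h, w)
}

flat_image <- function(h, w, rgb = c(128, 128, 128)) {
  img <- array(0L, c(h, w, 3L))
  for (ch in 1:3) img[, , ch] <- as.integer(rgb[ch])
  img
}

small_train_pair <- function(seed = 11L, wd = 128L) {
  list(
    generate_image(synth_config(width = wd, height = wd, seed = seed))$image,
    generate_image(synth_config(width = wd, height = wd, seed = seed + 1L))$image
  )
}
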