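#' Read an 8-bit RGB image
#'
#' Reads PNG, TIFF or uncompressed 24-bit BMP into the package's raster
#' convention: an H x W x 3 integer array with values in \[0, 255\],
#' rows top to bottom.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff` or `.bmp` file.
#' @return An H x W x 3 integer array.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    abort_dw(sprintf("image file not found: %s", path), "deepwise_io_error")
  ext <- tolower(tools::file_ext(path))
  raw01 <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    bmp  = return(read_bmp24(path)),
    abort_dw(sprintf("unsupported image format: .%s (use png, tiff or bmp)", ext),
             "deepwise_io_error")
  )
  if (length(dim(raw01)) == 2L)               # greyscale -> replicate channels
    raw01 <- array(raw01, c(dim(raw01), 3L))
  if (dim(raw01)[3] > 3L) raw01 <- raw01[, , 1:3, drop = FALSE]  # drop alpha
  img <- round_half_even(raw01 * 255)
  storage.mode(img) <- "integer"
  assert_image(img)
}

#' Write an 8-bit RGB image
#'
#' @param image H x W x 3 array with values in \[0, 255\].
#' @param path Output path; format chosen by extension (png, tif/tiff, bmp).
#' @return Invisibly, `path`.
#' @export
write_image <- function(image, path) {
  assert_image(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(image / 255, path),
    tif  = ,
    tiff = tiff::writeTIFF(image / 255, path, bits.per.sample = 8L,
                           compression = "none"),
    bmp  = write_bmp24(image, path),
    abort_dw(sprintf("unsupported image format: .%s (use png, tiff or bmp)", ext),
             "deepwise_io_error")
  )
  invisible(path)
}

## ---- minimal 24-bit BI_RGB bitmap support ---------------------------------
## The source microscopy datasets ship as 24-bit .bmp; no installed R package
## reads BMP, so the uncompressed flavour is handled here directly.

read_bmp24 <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 2L)
  if (!identical(rawToChar(magic), "BM"))
    abort_dw(sprintf("not a BMP file: %s", path), "deepwise_io_error")
  invisible(readBin(con, "integer", 2L, size = 4L))          # file size, reserved
  data_offset <- readBin(con, "integer", 1L, size = 4L)
  header_size <- readBin(con, "integer", 1L, size = 4L)
  if (header_size < 40L)
    abort_dw("unsupported BMP header (need BITMAPINFOHEADER)", "deepwise_io_error")
  w <- readBin(con, "integer", 1L, size = 4L)
  h <- readBin(con, "integer", 1L, size = 4L)
  invisible(readBin(con, "integer", 1L, size = 2L))          # planes
  bpp <- readBin(con, "integer", 1L, size = 2L)
  compression <- readBin(con, "integer", 1L, size = 4L)
  if (bpp != 24L || compression != 0L)
    abort_dw("only uncompressed 24-bit BMP is supported", "deepwise_io_error")
  top_down <- h < 0L
  h <- abs(h)
  seek(con, data_offset)
  stride <- (3L * w + 3L) %/% 4L * 4L
  bytes <- readBin(con, "raw", stride * h)
  px <- array(0L, c(h, w, 3L))
  for (row in seq_len(h)) {
    line <- as.integer(bytes[((row - 1L) * stride + 1L):((row - 1L) * stride + 3L * w)])
    r_out <- if (top_down) row else h - row + 1L             # BMP rows are bottom-up
    px[r_out, , 1L] <- line[seq(3L, by = 3L, length.out = w)]  # stored B, G, R
    px[r_out, , 2L] <- line[seq(2L, by = 3L, length.out = w)]
    px[r_out, , 3L] <- line[seq(1L, by = 3L, length.out = w)]
  }
  px
}

write_bmp24 <- function(image, path) {
  h <- dim(image)[1]; w <- dim(image)[2]
  stride <- (3L * w + 3L) %/% 4L * 4L
  data_size <- stride * h
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  writeBin(c(54L + data_size, 0L, 54L), con, size = 4L)      # file size, reserved, offset
  writeBin(40L, con, size = 4L)                              # BITMAPINFOHEADER
  writeBin(c(w, h), con, size = 4L)
  writeBin(c(1L, 24L), con, size = 2L)                       # planes, bpp
  writeBin(c(0L, data_size, 2835L, 2835L, 0L, 0L), con, size = 4L)
  img <- round_half_even(image)
  buf <- raw(data_size)
  for (row in seq_len(h)) {
    src <- h - row + 1L                                      # bottom-up
    line <- integer(3L * w)
    line[seq(1L, by = 3L, length.out = w)] <- img[src, , 3L]
    line[seq(2L, by = 3L, length.out = w)] <- img[src, , 2L]
    line[seq(3L, by = 3L, length.out = w)] <- img[src, , 1L]
    buf[((row - 1L) * stride + 1L):((row - 1L) * stride + 3L * w)] <- as.raw(line)
  }
  writeBin(buf, con)
  invisible(path)
}
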