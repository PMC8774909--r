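#' Encode a binary mask as COCO-style run-length counts
#'
#' Uses the COCO `counts` convention: the mask is flattened in column-major
#' order and runs alternate background/foreground starting with the number
#' of leading background pixels (possibly 0).
#'
#' @param mask H x W logical matrix.
#' @return List with `size = c(H, W)` and integer vector `counts`.
#' @export
coco_rle_encode <- function(mask) {
  assert_mask(mask)
  flat <- as.logical(mask)                 # column-major by R storage
  r <- rle(flat)
  counts <- r$lengths
  if (length(r$values) > 0L && r$values[1])
    counts <- c(0L, counts)                # first count is always background
  list(size = c(nrow(mask), ncol(mask)), counts = as.integer(counts))
}

#' Decode COCO-style run-length counts to a binary mask
#'
#' @param rle List with `size` and `counts` as produced by [coco_rle_encode()].
#' @return H x W logical matrix.
#' @export
coco_rle_decode <- function(rle) {
  size <- as.integer(rle$size); counts <- as.integer(rle$counts)
  if (length(size) != 2L || any(size < 1L))
    abort_dw("`rle$size` must be two positive integers", "deepwise_validation_error")
  if (sum(counts) != prod(size))
    abort_dw("RLE counts do not sum to the mask size", "deepwise_validation_error")
  values <- rep(c(FALSE, TRUE), length.out = length(counts))
  matrix(rep(values, counts), nrow = size[1], ncol = size[2])
}
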