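#' Image and mask containers
#'
#' Images are plain numeric arrays: a color image is `H x W x 3` with
#' intensities in `[0, 1]`, a segmentation mask is an `H x W` matrix in
#' `[0, 1]` (binarized by thresholding at 1/2). These helpers validate and
#' coerce; all heavy operations work on the raw arrays.
#'
#' @param x numeric array.
#' @param strict if `TRUE`, error when values fall outside `[0, 1]`.
#' @return the validated array (invisibly unchanged).
#' @export
as_color_image <- function(x, strict = TRUE) {
  if (is.matrix(x)) stop("a color image needs three channels (H x W x 3)")
  d <- dim(x)
  if (length(d) != 3L || d[3] != 3L)
    stop("a color image must be an H x W x 3 array, got dim ",
         paste(d, collapse = "x"))
  if (strict && (anyNA(x) || min(x) < 0 || max(x) > 1))
    stop("color image intensities must lie in [0, 1]")
  x
}

#' @rdname as_color_image
#' @export
as_seg_mask <- function(x, strict = TRUE) {
  if (length(dim(x)) == 3L && dim(x)[3] == 1L) x <- x[, , 1L]
  if (!is.matrix(x)) stop("a segmentation mask must be an H x W matrix")
  if (strict && (anyNA(x) || min(x) < 0 || max(x) > 1))
    stop("mask values must lie in [0, 1]")
  x
}

#' Clip values to the unit interval
#'
#' The pointwise projection onto the admissible image set `[0,1]^(HxWx3)`
#' and mask set `[0,1]^(HxW)` used by every step of the unrolled scheme.
#'
#' @param x numeric array.
#' @return `x` with every entry clipped to `[0, 1]`.
#' @export
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Binarize a soft segmentation mask
#'
#' @param m numeric mask in `[0, 1]`.
#' @param threshold threshold, default 1/2.
#' @return logical matrix, `TRUE` where `m >= threshold`.
#' @export
binarize_mask <- function(m, threshold = 0.5) m >= threshold

# internal: H x W matrix -> H x W x 1 array
.as_plane <- function(m) array(m, dim = c(dim(m)[1], dim(m)[2], 1L))
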