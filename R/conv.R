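#' Multichannel 2D convolution and its adjoint
#'
#' `conv_forward()` applies a bank of spatially-2D, full-depth kernels to a
#' multichannel image with zero-padded, same-size boundary handling (one
#' output channel per kernel). `conv_adjoint()` is its exact adjoint, i.e.
#' `sum(conv_forward(K, x) * y) == sum(x * conv_adjoint(K, y))` holds to
#' machine precision for all `x`, `y`. The adjoint is the transposed operator
#' that appears throughout the chain-rule gradients of the coupled energy.
#'
#' @param kernels 4-d numeric array `kh x kw x cin x cout` (odd `kh`, `kw`).
#' @param input numeric array `H x W x cin` (a matrix is treated as
#'   single-channel).
#' @param features numeric array `H x W x cout`, one channel per kernel.
#' @return `conv_forward()`: feature array `H x W x cout`;
#'   `conv_adjoint()`: image array `H x W x cin`.
#' @export
conv_forward <- function(kernels, input) {
  if (is.matrix(input)) input <- .as_plane(input)
  dk <- dim(kernels)
  if (length(dk) != 4L) stop("kernels must be a kh x kw x cin x cout array")
  if (dk[1] %% 2L == 0L || dk[2] %% 2L == 0L)
    stop("kernel spatial sizes must be odd")
  if (dim(input)[3] != dk[3])
    stop("kernel channel depth (", dk[3], ") must equal input channel count (",
         dim(input)[3], ")")
  .cpp_conv_forward(input, kernels)
}

#' @rdname conv_forward
#' @export
conv_adjoint <- function(kernels, features) {
  if (is.matrix(features)) features <- .as_plane(features)
  dk <- dim(kernels)
  if (length(dk) != 4L) stop("kernels must be a kh x kw x cin x cout array")
  if (dim(features)[3] != dk[4])
    stop("feature channel count (", dim(features)[3],
         ") must equal the number of kernels (", dk[4], ")")
  .cpp_conv_adjoint(features, kernels)
}

# internal: kernel cotangent of conv_forward given input and output cotangent
.conv_kernel_grad <- function(input, outgrad, kh, kw) {
  if (is.matrix(input)) input <- .as_plane(input)
  if (is.matrix(outgrad)) outgrad <- .as_plane(outgrad)
  .cpp_conv_kernel_grad(input, outgrad, as.integer(kh), as.integer(kw))
}
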