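#' Gaussian radial-basis-function nonlinearities
#'
#' Each learned pointwise nonlinearity is a weighted sum of `n_bases`
#' Gaussian bumps with equally spaced means on `[mu_min, mu_max]` and a
#' shared width. One weight row per feature channel. Two flavors exist:
#'
#' * function-parameterized (`derivative_parameterized = FALSE`): the weights
#'   parameterize the function itself; its derivative is obtained by
#'   differentiating the Gaussian bases. Used for the image and mask feature
#'   nonlinearities, which the energy gradients need both as values and as
#'   derivatives.
#' * derivative-parameterized (`derivative_parameterized = TRUE`): the
#'   weights parameterize the derivative directly (the coupling
#'   nonlinearity); only the derivative ever enters the scheme, so the
#'   function value is never represented.
#'
#' The default width equals the spacing between consecutive means (0.08 for
#' the default 31 bases on `[-1.2, 1.2]`). Inputs outside the mean range are
#' not clipped; the Gaussian bases decay naturally.
#'
#' @param weights numeric matrix, `n_channels x n_bases`.
#' @param mu_min,mu_max range of the equally spaced means.
#' @param width Gaussian standard deviation shared by all bases; default the
#'   mean spacing.
#' @param derivative_parameterized see above.
#' @return an object of class `vn_rbf`.
#' @export
rbf_nonlinearity <- function(weights, mu_min = -1.2, mu_max = 1.2,
                             width = NULL,
                             derivative_parameterized = FALSE) {
  weights <- as.matrix(weights)
  n_bases <- ncol(weights)
  if (n_bases < 2L) stop("an RBF nonlinearity needs at least 2 bases")
  if (mu_max <= mu_min) stop("mu_max must exceed mu_min")
  means <- seq(mu_min, mu_max, length.out = n_bases)
  spacing <- means[2] - means[1]
  if (is.null(width)) width <- spacing
  if (width <= 0) stop("width must be positive")
  structure(
    list(weights = weights, means = means, width = width,
         derivative_parameterized = isTRUE(derivative_parameterized)),
    class = "vn_rbf")
}

#' @export
print.vn_rbf <- function(x, ...) {
  cat(sprintf("<vn_rbf> %d channels, %d bases on [%g, %g], width %g%s\n",
              nrow(x$weights), ncol(x$weights), min(x$means), max(x$means),
              x$width,
              if (x$derivative_parameterized) " (parameterizes derivative)"
              else ""))
  invisible(x)
}

# internal: coerce H x W x F (or n x F) input to an n x F matrix + restorer
.rbf_shape <- function(x, n_channels) {
  d <- dim(x)
  if (is.null(d)) x <- matrix(x, ncol = 1L)
  else if (length(d) == 3L) x <- matrix(x, nrow = d[1] * d[2], ncol = d[3])
  else x <- as.matrix(x)
  if (ncol(x) != n_channels)
    stop("input has ", ncol(x), " channels but the nonlinearity has ",
         n_channels, " weight rows")
  list(mat = x, dim = d)
}

.rbf_unshape <- function(m, d) {
  if (is.null(d) || length(d) < 3L) {
    if (is.null(d)) return(as.numeric(m))
    dim(m) <- d
    return(m)
  }
  array(m, dim = d)
}

#' Evaluate an RBF nonlinearity
#'
#' `rbf_eval()` returns the Gaussian mixture
#' `phi_f(x) = sum_j w[f, j] * exp(-(x - mu_j)^2 / (2 width^2))` per channel.
#' `rbf_deriv()` returns the derivative of the function the object
#' represents: the analytic mixture derivative for function-parameterized
#' nonlinearities, and the mixture itself for derivative-parameterized ones
#' (whose weights already are the derivative).
#'
#' @param nonlin a [rbf_nonlinearity()] object.
#' @param x numeric array `H x W x F`, matrix `n x F`, or vector (then `F`
#'   must be 1); channel `f` is transformed by weight row `f`.
#' @return array of the same shape as `x`.
#' @export
rbf_eval <- function(nonlin, x) {
  s <- .rbf_shape(x, nrow(nonlin$weights))
  .rbf_unshape(.cpp_rbf_mix(s$mat, nonlin$weights, nonlin$means,
                            nonlin$width, 0L), s$dim)
}

#' @rdname rbf_eval
#' @export
rbf_deriv <- function(nonlin, x) {
  s <- .rbf_shape(x, nrow(nonlin$weights))
  order <- if (nonlin$derivative_parameterized) 0L else 1L
  .rbf_unshape(.cpp_rbf_mix(s$mat, nonlin$weights, nonlin$means,
                            nonlin$width, order), s$dim)
}

# internal: derivative of whatever rbf_deriv() returns (needed when
# differentiating through the unrolled scheme)
.rbf_deriv2 <- function(nonlin, x) {
  s <- .rbf_shape(x, nrow(nonlin$weights))
  order <- if (nonlin$derivative_parameterized) 1L else 2L
  .rbf_unshape(.cpp_rbf_mix(s$mat, nonlin$weights, nonlin$means,
                            nonlin$width, order), s$dim)
}
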