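#' Random velocity field
#'
#' Strictly positive speed field for the fast-marching operations:
#' Gaussian white noise, spatially smoothed (circular FFT convolution with a
#' Gaussian kernel), standardized and exponentiated. The exponential
#' guarantees positivity; `blur_sd` sets the spatial coherence scale and
#' `gain` the log-amplitude of the speed variation. Draws from the current
#' RNG stream.
#'
#' @param dim image size `c(H, W)`.
#' @param blur_sd standard deviation (pixels) of the smoothing kernel.
#' @param gain log-scale amplitude of the field.
#' @return `H x W` matrix of positive speeds.
#' @export
velocity_field <- function(dim, blur_sd = 8, gain = 0.5) {
  H <- dim[1]; W <- dim[2]
  z <- matrix(rnorm(H * W), H, W)
  if (blur_sd > 0) {
    gi <- stats::dnorm(pmin(0:(H - 1), H - (0:(H - 1))), sd = blur_sd)
    gj <- stats::dnorm(pmin(0:(W - 1), W - (0:(W - 1))), sd = blur_sd)
    ker <- outer(gi, gj)
    ker <- ker / sum(ker)
    z <- Re(stats::fft(stats::fft(z) * stats::fft(ker), inverse = TRUE)) /
      (H * W)
  }
  s <- stats::sd(z)
  if (s > 0) z <- z / s
  exp(gain * z)
}

#' Weighted arrival times by front propagation
#'
#' Propagates a front from the seed set over the 4-connected pixel grid;
#' entering pixel `v` costs `1/speed[v]`, seeds start at time 0. Arrival
#' ties are broken by row-major pixel order. This is the discrete fast
#' marching primitive behind region decomposition, cell growth and the
#' connective-tissue distance maps.
#'
#' @param speed `H x W` matrix of strictly positive speeds.
#' @param seeds logical seed mask, or an integer matrix of seed labels
#'   (0 = not a seed).
#' @return list with `time` (`H x W` arrival times), `label` (`H x W`
#'   integer, seed component that arrived first) and `order` (1-based
#'   linear indices of non-seed pixels in acceptance order).
#' @export
fast_march <- function(speed, seeds) {
  stopifnot(is.matrix(speed), all(speed > 0))
  if (is.logical(seeds)) seeds <- matrix(as.integer(seeds), nrow(seeds))
  storage.mode(seeds) <- "integer"
  stopifnot(identical(dim(speed), dim(seeds)))
  if (!any(seeds > 0L)) stop("seed set must be nonempty")
  .cpp_fast_march(speed, seeds)
}

#' Random region decomposition
#'
#' Partitions the canvas into `n_regions` labeled regions from uniformly
#' drawn control points: either the Euclidean Voronoi tessellation of the
#' sites, or the fast-marching decomposition (each pixel labeled by the
#' seed of minimal weighted travel time under a random velocity field).
#'
#' @param mode `"voronoi"` or `"fast_march"`.
#' @param n_regions number of regions.
#' @param dim canvas size `c(H, W)`.
#' @param blur_sd,gain velocity-field parameters (fast-march mode).
#' @return list with `labels` (`H x W` integer matrix in `1..n_regions`),
#'   `sites` (matrix of `(row, col)` control points) and `mode`.
#' @export
region_decomposition <- function(mode = c("voronoi", "fast_march"),
                                 n_regions, dim, blur_sd = 8, gain = 0.5) {
  mode <- match.arg(mode)
  H <- dim[1]; W <- dim[2]
  if (n_regions < 1L) stop("n_regions must be at least 1")
  if (n_regions > H * W) stop("more regions than pixels")
  idx <- sample.int(H * W, n_regions)
  sites <- cbind(row = (idx - 1L) %% H + 1L, col = (idx - 1L) %/% H + 1L)
  if (mode == "voronoi") {
    rows <- rep(seq_len(H), times = W)
    cols <- rep(seq_len(W), each = H)
    D <- matrix(0, H * W, n_regions)
    for (s in seq_len(n_regions))
      D[, s] <- (rows - sites[s, 1])^2 + (cols - sites[s, 2])^2
    labels <- matrix(max.col(-D, ties.method = "first"), H, W)
  } else {
    speed <- velocity_field(dim, blur_sd, gain)
    seedm <- matrix(0L, H, W)
    seedm[idx] <- seq_len(n_regions)
    labels <- fast_march(speed, seedm)$label
  }
  list(labels = labels, sites = sites, mode = mode)
}

#' Grow a region by fast marching
#'
#' Front propagation from `initial_mask` under `field`, accepting exactly
#' `n_iterations` additional pixels in order of increasing arrival time
#' (row-major tie-break). The result always contains the initial mask and
#' grows monotonically in `n_iterations`.
#'
#' @param initial_mask nonempty logical `H x W` mask.
#' @param field positive `H x W` velocity field.
#' @param n_iterations number of pixels to accept beyond the mask.
#' @return logical `H x W` mask.
#' @export
grow_region_fast_march <- function(initial_mask, field, n_iterations) {
  stopifnot(is.matrix(initial_mask), n_iterations >= 0)
  if (!any(initial_mask)) stop("initial mask must be nonempty")
  grown <- initial_mask
  if (n_iterations == 0) return(grown)
  fm <- fast_march(field, initial_mask)
  take <- utils::head(fm$order, n_iterations)
  grown[take] <- TRUE
  grown
}

#' Ribbon-type connective tissue
#'
#' Models connective tissue hugging the border of a region as the
#' intersection, over several random velocity fields, of the preimages of
#' an arrival-time interval, where the front starts from the complement of
#' the region. Wider intervals give thicker ribbons; a degenerate interval
#' (`a >= b`) yields an empty ribbon.
#'
#' @param region logical `H x W` mask, a proper subset of the canvas.
#' @param n_fields number of independent velocity fields to intersect.
#' @param interval arrival-time interval `c(a, b)`.
#' @param blur_sd,gain velocity-field parameters.
#' @return logical `H x W` ribbon mask, subset of `region`.
#' @export
connective_tissue <- function(region, n_fields = 3L, interval,
                              blur_sd = 8, gain = 0.5) {
  stopifnot(is.matrix(region), is.logical(region), n_fields >= 1L,
            length(interval) == 2L)
  if (all(region)) stop("region must be a proper subset of the image")
  if (interval[1] >= interval[2])
    return(matrix(FALSE, nrow(region), ncol(region)))
  ribbon <- region
  for (i in seq_len(n_fields)) {
    field <- velocity_field(dim(region), blur_sd, gain)
    tm <- fast_march(field, !region)$time
    ribbon <- ribbon & (tm >= interval[1]) & (tm <= interval[2])
  }
  ribbon
}
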