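# Reinhard color transfer: match per-channel mean and standard deviation in
# the decorrelated log-LMS (l-alpha-beta) color space of a reference image.
# Applied to H&E images before inference or statistics extraction to
# enforce comparable staining.

# RGB -> LMS matrix and the l-alpha-beta construction of the color-transfer
# literature; the inverses are computed numerically.
.M_rgb2lms <- matrix(c(0.3811, 0.5783, 0.0402,
                       0.1967, 0.7244, 0.0782,
                       0.0241, 0.1288, 0.8444), 3L, 3L, byrow = TRUE)
.M_lab <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*%
  matrix(c(1, 1, 1,
           1, 1, -2,
           1, -1, 0), 3L, 3L, byrow = TRUE)
.LOG_EPS <- 1 / 255   # clamp away from zero before the log transform

#' Convert between RGB and the decorrelated lab color space
#'
#' `rgb_to_lab()` maps RGB to the log-LMS-based l-alpha-beta space
#' (clamping intensities at 1/255 before the base-10 log); `lab_to_rgb()`
#' inverts the map and clips to `[0, 1]`.
#'
#' @param img `H x W x 3` array (RGB in `[0, 1]`, or lab values).
#' @return array of the same shape.
#' @export
rgb_to_lab <- function(img) {
  d <- dim(img)
  m <- matrix(img, ncol = 3L)
  lms <- pmax(m %*% t(.M_rgb2lms), .LOG_EPS)
  lab <- log10(lms) %*% t(.M_lab)
  array(lab, dim = d)
}

#' @rdname rgb_to_lab
#' @export
lab_to_rgb <- function(img) {
  d <- dim(img)
  m <- matrix(img, ncol = 3L)
  loglms <- m %*% t(solve(.M_lab))
  rgb <- (10^loglms) %*% t(solve(.M_rgb2lms))
  array(clip01(rgb), dim = d)
}

#' Color statistics in the decorrelated lab space
#'
#' Per-channel mean and standard deviation of an image in l-alpha-beta
#' space; the statistics of a chosen reference image drive
#' [reinhard_normalize()].
#'
#' @param img RGB image `H x W x 3` in `[0, 1]`.
#' @return object of class `vn_colorstats` with `mean` and `sd` (length 3).
#' @export
lab_stats <- function(img) {
  lab <- matrix(rgb_to_lab(img), ncol = 3L)
  structure(list(mean = colMeans(lab), sd = apply(lab, 2L, stats::sd)),
            class = "vn_colorstats")
}

#' Reinhard stain normalization
#'
#' Color transfer of a fixed reference to the image: per channel in the
#' decorrelated lab space, the source mean is subtracted, values are
#' rescaled by (reference sd / source sd) and the reference mean is added;
#' the result is mapped back to RGB and clipped. A channel with zero source
#' spread is shifted only (with a warning). Normalizing an already
#' normalized image with the same reference is a fixed point.
#'
#' @param image RGB image `H x W x 3` in `[0, 1]`.
#' @param reference_stats a [lab_stats()] object (or a reference image,
#'   whose stats are computed on the fly).
#' @return normalized RGB image.
#' @export
reinhard_normalize <- function(image, reference_stats) {
  if (!inherits(reference_stats, "vn_colorstats"))
    reference_stats <- lab_stats(reference_stats)
  if (any(reference_stats$sd <= 0))
    stop("reference standard deviations must be positive")
  d <- dim(image)
  lab <- matrix(rgb_to_lab(image), ncol = 3L)
  mu <- colMeans(lab)
  sd <- apply(lab, 2L, stats::sd)
  for (ch in 1:3) {
    if (sd[ch] > 0) {
      lab[, ch] <- (lab[, ch] - mu[ch]) *
        (reference_stats$sd[ch] / sd[ch]) + reference_stats$mean[ch]
    } else {
      warning("zero spread in lab channel ", ch, "; shifting only")
      lab[, ch] <- lab[, ch] - mu[ch] + reference_stats$mean[ch]
    }
  }
  lab_to_rgb(array(lab, dim = d))
}

#' Store or load reference color statistics
#'
#' Small text (YAML) files carrying the lab-space mean and standard
#' deviation of a reference image.
#'
#' @param stats a `vn_colorstats` object.
#' @param path file path.
#' @return `read_color_stats()` returns the `vn_colorstats`.
#' @export
write_color_stats <- function(stats, path) {
  stopifnot(inherits(stats, "vn_colorstats"))
  yaml::write_yaml(list(lab_mean = as.numeric(stats$mean),
                        lab_sd = as.numeric(stats$sd)), path,
                   precision = 15L)
  invisible(path)
}

#' @rdname write_color_stats
#' @export
read_color_stats <- function(path) {
  x <- yaml::read_yaml(path)
  structure(list(mean = as.numeric(unlist(x$lab_mean)),
                 sd = as.numeric(unlist(x$lab_sd))),
            class = "vn_colorstats")
}
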