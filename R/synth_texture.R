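#' Multivariate-normal color texture
#'
#' Per-pixel independent draws from a trivariate normal with the given mean
#' color and channel covariance (the covariance models the correlated RGB
#' noise of a stain category; in practice it is estimated from small
#' patches of real, stain-normalized images). Draws are clipped to
#' `[0, 1]`.
#'
#' @param mean_color RGB mean, length 3.
#' @param cov 3x3 symmetric positive semidefinite covariance.
#' @param n number of pixels to draw.
#' @return `n x 3` matrix of clipped RGB values.
#' @export
gaussian_texture <- function(mean_color, cov, n) {
  stopifnot(length(mean_color) == 3L, identical(dim(cov), c(3L, 3L)))
  if (max(abs(cov - t(cov))) > 1e-8) stop("covariance must be symmetric")
  ev <- eigen(cov, symmetric = TRUE)
  if (min(ev$values) < -1e-10)
    stop("covariance must be positive semidefinite")
  lam <- pmax(ev$values, 0)
  A <- ev$vectors %*% diag(sqrt(lam), 3L)
  x <- matrix(rnorm(3L * n), n, 3L) %*% t(A)
  x <- sweep(x, 2L, mean_color, "+")
  clip01(x)
}

#' Build a texture patch library
#'
#' Patch libraries drive the mosaic textures of the patch-based cell
#' categories. Patches are always grouped into three cohorts by mean color,
#' and a single cohort is used per simulated cell to avoid heterogeneity
#' artifacts.
#'
#' In `"procedural"` mode the patches are synthesized around three distinct
#' cohort mean colors (a stand-in for extraction from real images): each
#' patch is a smoothly shaded elliptical blob with correlated color noise.
#' In `"images"` mode, fixed-size patches are cut from the supplied images
#' at annotated foreground positions and assigned to cohorts by a 3-means
#' clustering of their mean colors.
#'
#' @param source `"procedural"`, or a list of RGB images (`H x W x 3`).
#' @param patch_size side length of the square patches, pixels.
#' @param patches_per_cohort number of patches in each of the 3 cohorts.
#' @param cohort_means list of 3 RGB means (procedural mode).
#' @param annotations list of logical masks marking foreground (images
#'   mode); patch centers are sampled where the mask is `TRUE`.
#' @param noise_sd per-pixel color noise of procedural patches.
#' @return an object of class `vn_patch_library`: `cohorts` (list of 3
#'   lists of patches, each with `rgb` and `alpha`), `centroids` (3x3
#'   matrix of cohort mean colors) and `patch_size`.
#' @export
build_patch_library <- function(source = "procedural", patch_size = 12L,
                                patches_per_cohort = 55L,
                                cohort_means = NULL, annotations = NULL,
                                noise_sd = 0.03) {
  stopifnot(patches_per_cohort >= 1L, patch_size >= 3L)
  p <- as.integer(patch_size)
  if (identical(source, "procedural")) {
    if (is.null(cohort_means))
      cohort_means <- list(c(0.55, 0.38, 0.62), c(0.66, 0.48, 0.72),
                           c(0.45, 0.30, 0.52))
    stopifnot(length(cohort_means) == 3L)
    cohorts <- lapply(cohort_means, function(mc) {
      lapply(seq_len(patches_per_cohort), function(i)
        .procedural_patch(p, mc, noise_sd))
    })
  } else {
    images <- source
    stopifnot(is.list(images), length(images) >= 1L)
    patches <- .extract_patches(images, annotations, p,
                                3L * patches_per_cohort)
    if (length(patches) < 3L)
      stop("too few patches for the requested cohort sizes")
    means <- t(vapply(patches, function(pt)
      apply(pt$rgb, 3L, mean), numeric(3)))
    km <- stats::kmeans(means, centers = 3L, nstart = 5L)
    cohorts <- lapply(1:3, function(k) patches[km$cluster == k])
    if (any(vapply(cohorts, length, integer(1)) == 0L))
      stop("too few patches for the requested cohort sizes")
  }
  centroids <- t(vapply(cohorts, function(co) {
    rowMeans(vapply(co, function(pt) apply(pt$rgb, 3L, mean), numeric(3)))
  }, numeric(3)))
  structure(list(cohorts = cohorts, centroids = centroids, patch_size = p),
            class = "vn_patch_library")
}

# internal: one synthetic nucleus-like patch -- elliptical blob, darker
# core, correlated color noise
.procedural_patch <- function(p, mean_color, noise_sd) {
  ctr <- (p + 1) / 2
  a <- runif(1, 0.32, 0.46) * p
  b <- runif(1, 0.32, 0.46) * p
  phi <- runif(1, 0, pi)
  rr <- matrix(seq_len(p) - ctr, p, p)
  cc <- t(rr)
  x <- rr * cos(phi) + cc * sin(phi)
  y <- -rr * sin(phi) + cc * cos(phi)
  rad2 <- (x / a)^2 + (y / b)^2
  alpha <- rad2 <= 1
  shade <- 1 - 0.35 * pmax(1 - rad2, 0)   # darker toward the core
  rgb <- array(0, dim = c(p, p, 3L))
  noise <- gaussian_texture(c(0, 0, 0),
                            diag(noise_sd^2, 3L) +
                              noise_sd^2 / 2 * (1 - diag(3L)), p * p)
  for (ch in 1:3)
    rgb[, , ch] <- clip01(mean_color[ch] * shade + matrix(noise[, ch], p, p))
  list(rgb = rgb, alpha = alpha)
}

# internal: cut patches from images at annotated positions
.extract_patches <- function(images, annotations, p, n_total) {
  half <- (p - 1L) %/% 2L
  out <- list()
  per_img <- ceiling(n_total / length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]
    H <- dim(img)[1]; W <- dim(img)[2]
    ann <- if (is.null(annotations)) matrix(TRUE, H, W) else annotations[[i]]
    ok <- which(ann)
    ri <- (ok - 1L) %% H + 1L
    ci <- (ok - 1L) %/% H + 1L
    keep <- ri > half & ri <= H - half & ci > half & ci <= W - half
    ok <- ok[keep]
    if (length(ok) == 0L) next
    pick <- ok[sample.int(length(ok), min(per_img, length(ok)))]
    for (idx in pick) {
      r <- (idx - 1L) %% H + 1L
      cl <- (idx - 1L) %/% H + 1L
      rgb <- img[(r - half):(r - half + p - 1L),
                 (cl - half):(cl - half + p - 1L), , drop = FALSE]
      al <- ann[(r - half):(r - half + p - 1L),
                (cl - half):(cl - half + p - 1L)]
      out[[length(out) + 1L]] <- list(rgb = rgb, alpha = al)
    }
  }
  out
}

#' Mosaic texture from a patch cohort
#'
#' Fills a region with randomly chosen square patches of one cohort on a
#' lattice whose stride is smaller than the patch size, so adjacent patches
#' overlap moderately; overlaps are blended with separable triangular
#' weights normalized to a partition of unity (every output pixel is a
#' convex combination of the contributing patch values). A region smaller
#' than one patch receives the crop of a single patch.
#'
#' @param library a [build_patch_library()] object.
#' @param cohort cohort index in 1..3.
#' @param region nonempty logical `H x W` mask to fill.
#' @param stride lattice stride in pixels; default `patch_size - 4`.
#' @return `H x W x 3` array with the mosaic over `region` (zero outside).
#' @export
mosaic_texture <- function(library, cohort, region, stride = NULL) {
  stopifnot(inherits(library, "vn_patch_library"),
            cohort %in% 1:3, is.matrix(region))
  if (!any(region)) stop("region must be nonempty")
  p <- library$patch_size
  if (is.null(stride)) stride <- max(1L, p - 4L)
  stopifnot(stride >= 1L, stride < p)
  H <- nrow(region); W <- ncol(region)
  idx <- which(region)
  rr <- range((idx - 1L) %% H + 1L)
  cr <- range((idx - 1L) %/% H + 1L)
  patches <- library$cohorts[[cohort]]
  out <- array(0, dim = c(H, W, 3L))
  if (diff(rr) + 1L <= p && diff(cr) + 1L <= p) {
    pt <- patches[[sample.int(length(patches), 1L)]]
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[idx] <- pt$rgb[cbind((idx - 1L) %% H + 1L - rr[1] + 1L,
                                 (idx - 1L) %/% H + 1L - cr[1] + 1L, ch)]
      out[, , ch] <- plane
    }
    return(out)
  }
  tri <- pmin(seq_len(p), rev(seq_len(p)))
  wgt <- outer(tri, tri)
  acc <- array(0, dim = c(H, W, 3L))
  wsum <- matrix(0, H, W)
  r_starts <- seq(rr[1] - sample.int(stride, 1L) + 1L, rr[2], by = stride)
  c_starts <- seq(cr[1] - sample.int(stride, 1L) + 1L, cr[2], by = stride)
  for (r0 in r_starts) for (c0 in c_starts) {
    pt <- patches[[sample.int(length(patches), 1L)]]
    rs <- r0:(r0 + p - 1L)
    cs <- c0:(c0 + p - 1L)
    ok_r <- rs >= 1L & rs <= H
    ok_c <- cs >= 1L & cs <= W
    if (!any(ok_r) || !any(ok_c)) next
    ri <- rs[ok_r]; ci <- cs[ok_c]
    wblk <- wgt[ok_r, ok_c, drop = FALSE]
    wsum[ri, ci] <- wsum[ri, ci] + wblk
    for (ch in 1:3)
      acc[ri, ci, ch] <- acc[ri, ci, ch] +
        wblk * pt$rgb[ok_r, ok_c, ch]
  }
  wsum[wsum == 0] <- 1
  for (ch in 1:3) {
    plane <- acc[, , ch] / wsum
    plane[!region] <- 0
    out[, , ch] <- plane
  }
  out
}
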