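# Layered scene synthesis: each object category renders into an RGBA layer
# (binary alpha, exactly 1 on object pixels), layers are merged top-wins,
# and the ground-truth mask is derived from the shape registry alone.

#' Merge RGBA layers
#'
#' Merges layers given bottom to top: at every pixel the topmost layer with
#' alpha 1 wins, and the merged alpha is 1 iff any layer's alpha is 1.
#'
#' @param layers list of layers, each a list with `rgb` (`H x W x 3`) and
#'   `alpha` (logical or 0/1 matrix), ordered bottom to top.
#' @return list with merged `rgb` and logical `alpha`.
#' @export
compose_layers <- function(layers) {
  stopifnot(length(layers) >= 1L)
  d <- dim(layers[[1]]$rgb)
  rgb <- array(0, dim = d)
  alpha <- matrix(FALSE, d[1], d[2])
  for (ly in layers) {
    if (!identical(dim(ly$rgb), d)) stop("layer size mismatch")
    a <- if (is.logical(ly$alpha)) ly$alpha else ly$alpha >= 0.5
    idx <- which(a)
    if (length(idx)) {
      n <- d[1] * d[2]
      for (ch in 1:3) rgb[idx + (ch - 1L) * n] <- ly$rgb[idx + (ch - 1L) * n]
      alpha[idx] <- TRUE
    }
  }
  list(rgb = rgb, alpha = alpha)
}

#' Classify cells by neighborhood concentration
#'
#' Implements the interaction-based ground-truth rule: a cell is classified
#' iff the concentration of the target category -- the area fraction of the
#' disk of radius `radius` centered at the cell centroid covered by
#' `target_mask` -- strictly exceeds `threshold`. The returned ground-truth
#' mask is 1 exactly on the pixels of classified cells.
#'
#' @param cells list of shapes (each with `center` and `pixels`), e.g. a
#'   registry subset from [generate_sample()].
#' @param target_mask logical `H x W` mask of the target category.
#' @param radius neighborhood radius in pixels.
#' @param threshold concentration threshold in `[0, 1]` (strict).
#' @return list with `classified` (logical per cell), `concentration`
#'   (numeric per cell) and `mask` (`H x W` 0/1 matrix).
#' @export
classify_by_neighborhood <- function(cells, target_mask, radius, threshold) {
  stopifnot(radius > 0, threshold >= 0, threshold <= 1)
  dimHW <- dim(target_mask)
  conc <- vapply(cells, function(cl) {
    dp <- disk_pixels(cl$center, radius, dimHW)
    if (length(dp) == 0L) 0 else mean(target_mask[dp])
  }, numeric(1))
  classified <- conc > threshold
  mask <- matrix(0, dimHW[1], dimHW[2])
  for (i in which(classified)) mask[cells[[i]]$pixels] <- 1
  list(classified = classified, concentration = conc, mask = mask)
}

#' Empirical flip point of the classification rule
#'
#' Diagnostic for the neighborhood rule: places one cell at the canvas
#' center, covers a growing share of its radius-`radius` disk with target
#' pixels (in row-major order), and bisects on the covered pixel count
#' until the classification decision flips. The returned fraction is the
#' smallest concentration at which the cell is classified; by the strict
#' rule it exceeds `threshold` by at most one pixel-area quantum.
#'
#' @param radius neighborhood radius in pixels.
#' @param threshold concentration threshold.
#' @param dim canvas size `c(H, W)`.
#' @return the flip fraction (in `(threshold, threshold + 1/disk area]`).
#' @export
classification_flip_point <- function(radius = 40, threshold,
                                      dim = c(300L, 300L)) {
  center <- (dim + 1) / 2
  disk <- disk_pixels(center, radius, dim)
  n <- length(disk)
  cell <- list(center = center, pixels = disk)
  lo <- 0L; hi <- n
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    mask <- matrix(FALSE, dim[1], dim[2])
    mask[disk[seq_len(mid)]] <- TRUE
    if (classify_by_neighborhood(list(cell), mask, radius,
                                 threshold)$classified) hi <- mid
    else lo <- mid
  }
  hi / n
}

# ---- internal rendering helpers -------------------------------------------

.empty_layer <- function(name, dimHW) {
  list(name = name, clean = array(0, dim = c(dimHW, 3L)),
       noisy = array(0, dim = c(dimHW, 3L)),
       alpha = matrix(FALSE, dimHW[1], dimHW[2]))
}

# paint pixels with a constant clean color and multivariate-normal noise
.paint <- function(layer, pixels, mean_color, cov) {
  if (length(pixels) == 0L) return(layer)
  n <- prod(dim(layer$alpha))
  draws <- gaussian_texture(mean_color, cov, length(pixels))
  for (ch in 1:3) {
    layer$clean[pixels + (ch - 1L) * n] <- mean_color[ch]
    layer$noisy[pixels + (ch - 1L) * n] <- draws[, ch]
  }
  layer$alpha[pixels] <- TRUE
  layer
}

# paint pixels carrying their own colors (patch/mosaic categories); the
# noisy rendering adds iid correlated color noise on top
.paint_colored <- function(layer, pixels, colors, cov) {
  if (length(pixels) == 0L) return(layer)
  n <- prod(dim(layer$alpha))
  noise <- gaussian_texture(c(0, 0, 0), cov, length(pixels))
  for (ch in 1:3) {
    layer$clean[pixels + (ch - 1L) * n] <- colors[, ch]
    layer$noisy[pixels + (ch - 1L) * n] <- clip01(colors[, ch] + noise[, ch])
  }
  layer$alpha[pixels] <- TRUE
  layer
}

# rotate a library patch by `angle` around its center; returns relative
# (dr, dc) offsets and per-pixel colors via nearest-neighbor lookup
.rotate_patch <- function(patch, angle) {
  p <- dim(patch$rgb)[1]
  ctr <- (p + 1) / 2
  ext <- ceiling(p / sqrt(2)) + 1L
  off <- -ext:ext
  dr <- matrix(off, length(off), length(off))
  dc <- t(dr)
  sr <- dr * cos(angle) + dc * sin(angle) + ctr
  sc <- -dr * sin(angle) + dc * cos(angle) + ctr
  ri <- round(sr); ci <- round(sc)
  ok <- ri >= 1 & ri <= p & ci >= 1 & ci <= p
  ok[ok] <- patch$alpha[cbind(ri[ok], ci[ok])]
  keep <- which(ok)
  cols <- vapply(1:3, function(ch)
    patch$rgb[cbind(ri[keep], ci[keep], ch)], numeric(length(keep)))
  list(dr = dr[keep], dc = dc[keep],
       colors = matrix(cols, ncol = 3L))
}

# place rotated patches in the given regions, no pixel overlap within the
# layer; returns shapes (with pixels and per-pixel colors) + occupancy
.place_patches <- function(library, regions_idx, labels, attempts_per_region,
                           dimHW) {
  H <- dimHW[1]
  occupancy <- matrix(FALSE, dimHW[1], dimHW[2])
  shapes <- list()
  for (reg in regions_idx) {
    allowed <- which(labels == reg)
    if (length(allowed) == 0L) next
    for (att in seq_len(attempts_per_region)) {
      idx <- allowed[sample.int(length(allowed), 1L)]
      center <- c((idx - 1L) %% H + 1L, (idx - 1L) %/% H + 1L)
      cohort <- sample.int(3L, 1L)
      pidx <- sample.int(length(library$cohorts[[cohort]]), 1L)
      angle <- runif(1, 0, 2 * pi)
      rp <- .rotate_patch(library$cohorts[[cohort]][[pidx]], angle)
      rr <- center[1] + rp$dr
      cc <- center[2] + rp$dc
      ok <- rr >= 1 & rr <= dimHW[1] & cc >= 1 & cc <= dimHW[2]
      if (mean(ok) < 0.8) next      # mostly outside the canvas
      px <- rr[ok] + H * (cc[ok] - 1L)
      if (any(occupancy[px])) next  # no overlapping
      occupancy[px] <- TRUE
      shapes[[length(shapes) + 1L]] <-
        list(category = "patch", center = center, rotation = angle,
             cohort = cohort, patch = pidx, pixels = px,
             colors = rp$colors[ok, , drop = FALSE], region = reg)
    }
  }
  list(shapes = shapes, occupancy = occupancy)
}

# 4-neighbor boundary pixels of a mask (cell contours)
.mask_boundary <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  interior <- mask
  interior[2:H, ] <- interior[2:H, ] & mask[1:(H - 1), ]
  interior[1:(H - 1), ] <- interior[1:(H - 1), ] & mask[2:H, ]
  interior[, 2:W] <- interior[, 2:W] & mask[, 1:(W - 1)]
  interior[, 1:(W - 1)] <- interior[, 1:(W - 1)] & mask[, 2:W]
  mask & !interior
}
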