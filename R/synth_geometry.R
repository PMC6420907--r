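# Rasterized geometric primitives of the scene generator. Pixel centers sit
# at integer coordinates (row, col), 1-based as everywhere in R.

#' Pixels of an ellipse or disk
#'
#' `ellipse_pixels()` returns the 1-based linear (column-major) indices of
#' all pixels whose centers lie inside the ellipse with the given center,
#' semi-axes and inclination. `disk_pixels()` is the circular special case
#' used by the neighborhood classification rule.
#'
#' @param center `(row, col)` center.
#' @param a,b semi-axis lengths in pixels.
#' @param phi inclination in radians.
#' @param radius disk radius in pixels.
#' @param dim canvas size `c(H, W)`.
#' @return integer vector of linear pixel indices (clipped to the canvas).
#' @export
ellipse_pixels <- function(center, a, b, phi, dim) {
  H <- dim[1]; W <- dim[2]
  ext <- ceiling(max(a, b))
  r0 <- max(1L, floor(center[1] - ext)); r1 <- min(H, ceiling(center[1] + ext))
  c0 <- max(1L, floor(center[2] - ext)); c1 <- min(W, ceiling(center[2] + ext))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rr <- seq(r0, r1); cc <- seq(c0, c1)
  dr <- outer(rr - center[1], rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - center[2])
  x <- dr * cos(phi) + dc * sin(phi)
  y <- -dr * sin(phi) + dc * cos(phi)
  inside <- (x / a)^2 + (y / b)^2 <= 1
  idx <- which(inside)
  ri <- rr[(idx - 1L) %% length(rr) + 1L]
  ci <- cc[(idx - 1L) %/% length(rr) + 1L]
  as.integer(ri + H * (ci - 1L))
}

#' @rdname ellipse_pixels
#' @export
disk_pixels <- function(center, radius, dim) {
  ellipse_pixels(center, radius, radius, 0, dim)
}

#' Place ellipses on a layer
#'
#' Draws ellipse centers uniformly over the allowed region, semi-axes
#' uniformly from `semi_axes` and inclinations uniformly from `[0, pi)`,
#' enforcing the overlap policy by rejection against the layer occupancy:
#' `"forbidden"` rejects any pixel overlap with previously placed
#' same-layer shapes, `"moderate"` tolerates up to half of the new shape's
#' pixels, `"free"` never rejects. Placement failures after `max_attempts`
#' rejections per shape leave a partial placement (reported in the
#' `failures` count).
#'
#' @param n number of ellipses to place.
#' @param semi_axes range `c(min, max)` of the semi-axis lengths, pixels.
#' @param dim canvas size `c(H, W)`.
#' @param allowed_region logical mask of admissible centers (`NULL` = whole
#'   canvas); must be nonempty.
#' @param occupancy logical layer-occupancy mask to respect and update
#'   (`NULL` starts empty).
#' @param overlap overlap policy.
#' @param category category name stored with each shape.
#' @param max_attempts rejection budget per ellipse.
#' @return list with `shapes` (each: `category`, `center`, `a`, `b`, `phi`,
#'   `pixels`), the updated `occupancy` and the `failures` count.
#' @export
place_ellipses <- function(n, semi_axes, dim, allowed_region = NULL,
                           occupancy = NULL,
                           overlap = c("free", "forbidden", "moderate"),
                           category = "cell", max_attempts = 100L) {
  overlap <- match.arg(overlap)
  stopifnot(length(semi_axes) == 2L, semi_axes[1] > 0,
            semi_axes[2] >= semi_axes[1])
  H <- dim[1]; W <- dim[2]
  if (is.null(occupancy)) occupancy <- matrix(FALSE, H, W)
  allowed_idx <- if (is.null(allowed_region)) NULL else which(allowed_region)
  if (!is.null(allowed_idx) && length(allowed_idx) == 0L)
    stop("allowed region is empty")
  shapes <- list()
  failures <- 0L
  for (k in seq_len(n)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      idx <- if (is.null(allowed_idx)) sample.int(H * W, 1L)
             else allowed_idx[sample.int(length(allowed_idx), 1L)]
      center <- c((idx - 1L) %% H + 1L, (idx - 1L) %/% H + 1L)
      a <- runif(1, semi_axes[1], semi_axes[2])
      b <- runif(1, semi_axes[1], semi_axes[2])
      phi <- runif(1, 0, pi)
      px <- ellipse_pixels(center, a, b, phi, c(H, W))
      if (length(px) == 0L) next
      ov <- sum(occupancy[px])
      ok <- switch(overlap,
                   free = TRUE,
                   forbidden = ov == 0L,
                   moderate = ov <= 0.5 * length(px))
      if (ok) {
        occupancy[px] <- TRUE
        shapes[[length(shapes) + 1L]] <-
          list(category = category, center = center, a = a, b = b,
               phi = phi, pixels = px)
        placed <- TRUE
        break
      }
    }
    if (!placed) failures <- failures + 1L
  }
  if (failures > 0L)
    warning(failures, " of ", n, " ", category,
            " placements failed after ", max_attempts, " attempts")
  list(shapes = shapes, occupancy = occupancy, failures = failures)
}

# internal: one nucleus per parent cell, concentric up to a small jitter,
# semi-axes drawn from `semi_axes` but capped at 90% of the parent's
.place_nuclei <- function(parents, semi_axes, dim, category) {
  lapply(parents, function(p) {
    a <- min(runif(1, semi_axes[1], semi_axes[2]), 0.9 * p$a)
    b <- min(runif(1, semi_axes[1], semi_axes[2]), 0.9 * p$b)
    jr <- 0.25 * max(min(p$a, p$b) - max(a, b), 0)
    ang <- runif(1, 0, 2 * pi)
    rad <- jr * sqrt(runif(1))
    center <- p$center + rad * c(cos(ang), sin(ang))
    phi <- p$phi
    list(category = category, center = center, a = a, b = b, phi = phi,
         pixels = ellipse_pixels(center, a, b, phi, dim),
         parent_center = p$center)
  })
}

# internal: exact-count uniform visibility subset (round(fraction * n))
.apply_visibility <- function(shapes, fraction) {
  n <- length(shapes)
  n_vis <- round(fraction * n)
  vis <- rep(FALSE, n)
  if (n_vis > 0L) vis[sample.int(n, n_vis)] <- TRUE
  for (i in seq_len(n)) shapes[[i]]$visible <- vis[i]
  shapes
}
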