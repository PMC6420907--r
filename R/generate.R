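# Sample synthesis: geometry pass (in dependency order), rendering pass
# (in layer order), composition, and rule-based ground truth.

# geometry must visit a fast-march-grown category after its source, even
# though it sits below the source in the layer stack
.geometry_order <- function(categories) {
  nms <- names(categories)
  ord <- seq_along(categories)
  for (i in ord) {
    src <- categories[[i]]$source
    if (!is.null(src)) {
      j <- match(src, nms)
      if (j > i) ord <- append(ord[ord != i], i, after = which(ord == j))
    }
  }
  ord
}

#' Generate one training sample
#'
#' Runs the full stochastic synthesis for the configured scenario: domain
#' decomposition, per-category geometry (ellipses, rotated patches,
#' fast-marching-grown cells), clean and noisy texture rendering into RGBA
#' layers, top-wins composition, and the rule-derived ground-truth mask.
#' The clean composition is the reconstruction target `g_u` (mean colors
#' and blended mosaics, no sampled noise); the noisy composition is the
#' network input `u0`; `m0` is the empty mask.
#'
#' @param config a `vn_scenario` (see [scenario_config()],
#'   [parse_scene_script()]).
#' @param sample_seed integer seed of this sample's draw.
#' @param keep_layers if `TRUE`, the rendered layers are attached.
#' @return an object of class `vn_sample`: `u0`, `m0`, `g_u`, `g_m`, the
#'   shape `registry` (with per-shape category, center, geometry, pixel
#'   set, visibility and region), the `regions` decomposition (or `NULL`)
#'   and the seed.
#' @export
generate_sample <- function(config, sample_seed = 0L, keep_layers = FALSE) {
  stopifnot(inherits(config, "vn_scenario"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sample_seed)
  dimHW <- config$size
  H <- dimHW[1]; W <- dimHW[2]

  regions <- NULL
  avail <- integer(0)
  if (!is.null(config$regions)) {
    regions <- region_decomposition(config$regions$mode,
                                    config$regions$count, dimHW,
                                    config$regions$blur_sd,
                                    config$regions$gain)
    avail <- seq_len(config$regions$count)
  }
  libs <- lapply(config$libraries, function(ls)
    build_patch_library("procedural", ls$patch_size, ls$patches_per_cohort,
                        ls$cohort_means, noise_sd = ls$noise_sd))

  # ---- geometry pass ----
  shapes_by_cat <- list()
  regions_by_cat <- list()
  cell_labels <- list()   # per fast-march category: label info for textures
  for (ci in .geometry_order(config$categories)) {
    cs <- config$categories[[ci]]
    if (cs$shape == "ellipse" && is.null(cs$parent)) {
      if (!is.null(cs$region_fill)) {
        regs <- avail[sample.int(length(avail), cs$region_fill)]
        avail <- setdiff(avail, regs)
        regions_by_cat[[cs$name]] <- regs
        occ <- matrix(FALSE, H, W)
        shapes <- list()
        for (reg in regs) {
          pl <- suppressWarnings(
            place_ellipses(cs$fill_attempts, cs$semi_axes, dimHW,
                           allowed_region = regions$labels == reg,
                           occupancy = occ, overlap = cs$overlap,
                           category = cs$name, max_attempts = 1L))
          occ <- pl$occupancy
          for (sh in pl$shapes) { sh$region <- reg
            shapes[[length(shapes) + 1L]] <- sh }
        }
      } else {
        pl <- place_ellipses(cs$count, cs$semi_axes, dimHW,
                             overlap = cs$overlap, category = cs$name,
                             max_attempts = cs$max_attempts)
        shapes <- pl$shapes
      }
      if (!is.null(cs$library))                  # patch-mosaic textured cells
        for (i in seq_along(shapes)) shapes[[i]]$cohort <- sample.int(3L, 1L)
      shapes <- .apply_visibility(shapes, cs$visible_fraction %||% 1)
    } else if (cs$shape == "ellipse") {          # nuclei: one per parent
      shapes <- .place_nuclei(shapes_by_cat[[cs$parent]], cs$semi_axes,
                              dimHW, cs$name)
      for (i in seq_along(shapes))
        shapes[[i]]$region <- shapes_by_cat[[cs$parent]][[i]]$region
      shapes <- .apply_visibility(shapes, cs$visible_fraction %||% 1)
    } else if (cs$shape == "region_noise") {
      regs <- avail[sample.int(length(avail), cs$region_fill)]
      avail <- setdiff(avail, regs)
      regions_by_cat[[cs$name]] <- regs
      px <- which(matrix(regions$labels %in% regs, H, W))
      shapes <- list(list(category = cs$name, center = c(NA, NA),
                          pixels = px, region = regs[1], visible = TRUE))
    } else if (cs$shape == "patch") {
      regs <- avail[sample.int(length(avail), cs$region_fill)]
      avail <- setdiff(avail, regs)
      regions_by_cat[[cs$name]] <- regs
      pp <- .place_patches(libs[[cs$library]], regs, regions$labels,
                           cs$attempts_per_region, dimHW)
      shapes <- lapply(pp$shapes, function(sh) {
        sh$category <- cs$name; sh$visible <- TRUE; sh })
    } else if (cs$shape == "fast_march_grown") {
      src <- shapes_by_cat[[cs$source]]
      if (length(src) == 0L) stop("source category '", cs$source,
                                  "' placed no shapes")
      seedm <- matrix(0L, H, W)
      for (i in seq_along(src)) seedm[src[[i]]$pixels] <- i
      field <- velocity_field(dimHW, blur_sd = 6, gain = 0.5)
      fm <- fast_march(field, seedm)
      grown <- seedm > 0L
      grown[utils::head(fm$order, cs$growth_per_nucleus * length(src))] <- TRUE
      shapes <- lapply(seq_along(src), function(i) {
        list(category = cs$name, center = src[[i]]$center,
             pixels = which(grown & fm$label == i),
             cohort = sample.int(3L, 1L),
             region = src[[i]]$region, visible = TRUE)
      })
      cell_labels[[cs$name]] <- list(grown = grown, label = fm$label)
    }
    shapes_by_cat[[cs$name]] <- shapes
  }

  # ---- rendering pass ----
  bg <- .empty_layer("background", dimHW)
  bg <- .paint(bg, seq_len(H * W), config$background$mean_color,
               config$background$color_cov)
  layers <- list(bg)

  add_connective_after <- NULL
  if (!is.null(config$connective)) {
    bc <- config$connective$border_category
    basis_regs <- regions_by_cat[[bc]]
    region_mask <- matrix(regions$labels %in% basis_regs, H, W)
    ribbon <- connective_tissue(region_mask, config$connective$n_fields,
                                config$connective$interval,
                                config$connective$blur_sd,
                                config$connective$gain)
    ct <- .empty_layer("connective_tissue", dimHW)
    ct <- .paint(ct, which(ribbon), config$connective$mean_color,
                 config$connective$color_cov)
    # sits directly above the bordered region's own layer if that category
    # renders as region noise (blood vessels), else right above background
    add_connective_after <-
      if (!is.null(config$categories[[bc]]) &&
          config$categories[[bc]]$shape == "region_noise") bc
      else "background"
    if (identical(add_connective_after, "background"))
      layers[[length(layers) + 1L]] <- ct
  }

  for (cs in config$categories) {
    shapes <- shapes_by_cat[[cs$name]]
    ly <- .empty_layer(cs$name, dimHW)
    vis <- Filter(function(sh) isTRUE(sh$visible), shapes)
    if (cs$shape %in% c("ellipse", "region_noise") && is.null(cs$library)) {
      col <- cs$mean_color
      if (cs$blend_to_background > 0)
        col <- (1 - cs$blend_to_background) * col +
          cs$blend_to_background * config$background$mean_color
      px <- unlist(lapply(vis, `[[`, "pixels"))
      ly <- .paint(ly, px, col, cs$color_cov)
    } else if (cs$shape == "patch") {
      for (sh in vis)
        ly <- .paint_colored(ly, sh$pixels, sh$colors, cs$color_cov)
    } else {   # mosaic-textured cells (fast-march-grown or ellipse+library)
      colors <- array(0, dim = c(H, W, 3L))
      for (co in 1:3) {
        cells_co <- Filter(function(sh) sh$cohort == co, vis)
        if (length(cells_co) == 0L) next
        mask_co <- matrix(FALSE, H, W)
        mask_co[unlist(lapply(cells_co, `[[`, "pixels"))] <- TRUE
        mz <- mosaic_texture(libs[[cs$library]], co, mask_co)
        idx <- which(mask_co)
        for (ch in 1:3)
          colors[idx + (ch - 1L) * H * W] <- mz[idx + (ch - 1L) * H * W]
      }
      if (cs$shape == "fast_march_grown") {
        for (sh in vis) {         # cell contours
          mcell <- matrix(FALSE, H, W)
          mcell[sh$pixels] <- TRUE
          bidx <- which(.mask_boundary(mcell))
          for (ch in 1:3)
            colors[bidx + (ch - 1L) * H * W] <-
              cs$contour_darken * colors[bidx + (ch - 1L) * H * W]
        }
      }
      px <- unlist(lapply(vis, `[[`, "pixels"))
      cmat <- vapply(1:3, function(ch) colors[px + (ch - 1L) * H * W],
                     numeric(length(px)))
      ly <- .paint_colored(ly, px, matrix(cmat, ncol = 3L), cs$color_cov)
    }
    layers[[length(layers) + 1L]] <- ly
    if (identical(add_connective_after, cs$name))
      layers[[length(layers) + 1L]] <- ct
  }

  clean <- compose_layers(lapply(layers, function(l)
    list(rgb = l$clean, alpha = l$alpha)))
  noisy <- compose_layers(lapply(layers, function(l)
    list(rgb = l$noisy, alpha = l$alpha)))

  registry <- unlist(shapes_by_cat, recursive = FALSE, use.names = FALSE)
  g_m <- recompute_ground_truth(registry, config, dimHW)
  out <- list(u0 = noisy$rgb, m0 = matrix(0, H, W), g_u = clean$rgb,
              g_m = g_m, registry = registry, regions = regions,
              scenario = config$scenario, seed = sample_seed)
  if (keep_layers) out$layers <- layers
  structure(out, class = "vn_sample")
}

#' Recompute the ground-truth mask from a shape registry
#'
#' Applies the scenario's rule to the geometry alone (no texture):
#' neighborhood rules classify the rule's cell category against the pixel
#' union of the target category and mark all pixels of classified cells;
#' the visibility rule marks the pixels of the rule category not covered by
#' any occluder category.
#'
#' @param registry flat shape registry (see [generate_sample()]).
#' @param config the `vn_scenario`.
#' @param dim canvas size `c(H, W)`.
#' @return `H x W` 0/1 matrix.
#' @export
recompute_ground_truth <- function(registry, config, dim) {
  rule <- config$rule
  cats <- vapply(registry, `[[`, character(1), "category")
  vis <- vapply(registry, function(sh) isTRUE(sh$visible), logical(1))
  if (rule$type == "neighborhood") {
    target <- matrix(FALSE, dim[1], dim[2])
    target[unlist(lapply(registry[cats == rule$target_category],
                         `[[`, "pixels"))] <- TRUE
    cells <- registry[cats == rule$cell_category & vis]
    classify_by_neighborhood(cells, target, rule$radius, rule$threshold)$mask
  } else {
    mask <- matrix(0, dim[1], dim[2])
    mask[unlist(lapply(registry[cats == rule$category & vis],
                       `[[`, "pixels"))] <- 1
    occl <- unlist(lapply(registry[cats %in% rule$occluders & vis],
                          `[[`, "pixels"))
    if (length(occl)) mask[occl] <- 0
    mask
  }
}

#' Generate a training dataset
#'
#' Draws `n` independent samples with per-sample seeds derived
#' deterministically from `master_seed` (see [derive_seed()]); the same
#' master seed reproduces the dataset bit-exactly.
#'
#' @param config a `vn_scenario`.
#' @param n number of samples.
#' @param master_seed integer master seed.
#' @return list of `vn_sample` objects.
#' @export
generate_dataset <- function(config, n, master_seed = 0L) {
  stopifnot(n >= 0)
  lapply(seq_len(n), function(i)
    generate_sample(config, derive_seed(master_seed, i)))
}

#' @export
print.vn_sample <- function(x, ...) {
  cats <- table(vapply(x$registry, `[[`, character(1), "category"))
  cat(sprintf("<vn_sample> scenario %d, %dx%d, seed %d\n  shapes: %s\n",
              x$scenario, nrow(x$m0), ncol(x$m0), x$seed,
              paste(names(cats), as.integer(cats), sep = "=",
                    collapse = ", ")))
  invisible(x)
}
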