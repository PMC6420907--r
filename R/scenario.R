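# Scene scripts: declarative per-scenario configuration of the stochastic
# generator. The shipped scripts encode the three study scenarios
# (immunofluorescence tumor/immune imagery; immune-rich H&E regions; H&E
# tumor nuclei); user scripts follow the same schema.

`%||%` <- function(a, b) if (is.null(a)) b else a

.known_keys <- list(
  top = c("scenario", "size", "rules", "background", "regions",
          "connective", "libraries", "categories"),
  rules = c("type", "cell_category", "target_category",
            "neighborhood_radius", "concentration_threshold",
            "category", "occluders"),
  background = c("mean_color", "color_cov", "color_sd", "color_corr"),
  regions = c("mode", "count", "blur_sd", "gain"),
  connective = c("n_fields", "interval", "blur_sd", "gain", "mean_color",
                 "color_cov", "color_sd", "color_corr", "border_category"),
  library = c("patch_size", "patches_per_cohort", "cohort_means",
              "noise_sd"),
  category = c("name", "shape", "mean_color", "color_cov", "color_sd",
               "color_corr", "semi_axes", "count", "region_fill",
               "fill_attempts", "attempts_per_region", "parent",
               "visible_fraction", "overlap", "blend_to_background",
               "library", "source", "growth_per_nucleus", "contour_darken",
               "max_attempts"))

.check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "))
}

# resolve a covariance: explicit 3x3 `color_cov`, or compact
# `color_sd`/`color_corr` (equicorrelated)
.cov_from <- function(x, default_sd = 0.05, default_corr = 0.5) {
  if (!is.null(x$color_cov)) {
    cv <- matrix(unlist(x$color_cov), 3L, 3L, byrow = TRUE)
  } else {
    s <- x$color_sd %||% default_sd
    r <- x$color_corr %||% default_corr
    cv <- s^2 * ((1 - r) * diag(3L) + r * matrix(1, 3L, 3L))
  }
  if (max(abs(cv - t(cv))) > 1e-8) stop("color_cov must be symmetric")
  if (min(eigen(cv, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("color_cov must be positive semidefinite")
  cv
}

#' Parse a scene script
#'
#' Reads and validates a declarative scenario configuration (YAML). The
#' script controls the shape, placement and coloring of every object
#' category, the domain decomposition, the patch libraries and the
#' ground-truth rule parameters. Unknown keys and out-of-range values are
#' rejected with the offending key named.
#'
#' @param path path to a scene script.
#' @return an object of class `vn_scenario`.
#' @seealso [scenario_config()] for the shipped default scripts,
#'   [write_scene_script()] for the inverse.
#' @export
parse_scene_script <- function(path) {
  if (!file.exists(path)) stop("scene script not found: ", path)
  raw <- yaml::read_yaml(path)
  .validate_scenario(raw)
}

#' @rdname parse_scene_script
#' @param config a `vn_scenario` object.
#' @export
write_scene_script <- function(config, path) {
  stopifnot(inherits(config, "vn_scenario"))
  yaml::write_yaml(attr(config, "raw"), path)
  invisible(path)
}

#' Shipped default scenario configuration
#'
#' The full-size scripts synthesize 300x300 scenes; the `"small"` variant
#' (Scenario 1 only) is the same scene at 100x100 with all lengths scaled
#' by 1/3, used for fast end-to-end training checks.
#'
#' @param scenario scenario id (1, 2 or 3).
#' @param size `"full"` (300x300) or `"small"` (100x100, Scenario 1 only).
#' @return the parsed `vn_scenario`.
#' @export
scenario_config <- function(scenario, size = c("full", "small")) {
  stopifnot(scenario %in% 1:3)
  size <- match.arg(size)
  fname <- if (size == "small") {
    if (scenario != 1L) stop("the small variant ships for Scenario 1 only")
    "scenario1_small.yaml"
  } else sprintf("scenario%d.yaml", scenario)
  parse_scene_script(system.file("extdata", fname, package = "vnseg",
                                 mustWork = TRUE))
}

.validate_scenario <- function(raw) {
  .check_keys(raw, .known_keys$top, "scene script")
  if (is.null(raw$scenario) || !(raw$scenario %in% 1:3))
    stop("key 'scenario' must be 1, 2 or 3")
  size <- as.integer(unlist(raw$size %||% c(300L, 300L)))
  if (length(size) != 2L || any(size < 16L)) stop("key 'size' invalid")

  ru <- raw$rules
  .check_keys(ru, .known_keys$rules, "rules")
  rule_type <- ru$type %||% "neighborhood"
  if (rule_type == "neighborhood") {
    radius <- ru$neighborhood_radius %||% 40
    thr <- ru$concentration_threshold
    if (is.null(thr) || thr < 0 || thr > 1)
      stop("key 'concentration_threshold' must lie in [0, 1]")
    if (radius <= 0) stop("key 'neighborhood_radius' must be positive")
    rule <- list(type = "neighborhood",
                 cell_category = ru$cell_category,
                 target_category = ru$target_category,
                 radius = radius, threshold = thr)
  } else if (rule_type == "visible") {
    rule <- list(type = "visible", category = ru$category,
                 occluders = as.character(ru$occluders %||% character(0)))
  } else stop("key 'rules/type' must be 'neighborhood' or 'visible'")

  .check_keys(raw$background, .known_keys$background, "background")
  background <- list(mean_color = as.numeric(unlist(raw$background$mean_color)),
                     color_cov = .cov_from(raw$background))
  if (length(background$mean_color) != 3L)
    stop("key 'background/mean_color' must have 3 entries")

  regions <- NULL
  if (!is.null(raw$regions)) {
    .check_keys(raw$regions, .known_keys$regions, "regions")
    regions <- list(mode = match.arg(raw$regions$mode,
                                     c("voronoi", "fast_march")),
                    count = as.integer(raw$regions$count),
                    blur_sd = raw$regions$blur_sd %||% 12,
                    gain = raw$regions$gain %||% 0.5)
    if (regions$count < 1L) stop("key 'regions/count' must be >= 1")
  }

  connective <- NULL
  if (!is.null(raw$connective)) {
    .check_keys(raw$connective, .known_keys$connective, "connective")
    iv <- as.numeric(unlist(raw$connective$interval))
    if (length(iv) != 2L) stop("key 'connective/interval' must have 2 entries")
    connective <- list(n_fields = as.integer(raw$connective$n_fields %||% 3L),
                       interval = iv,
                       blur_sd = raw$connective$blur_sd %||% 10,
                       gain = raw$connective$gain %||% 0.6,
                       mean_color = as.numeric(unlist(raw$connective$mean_color)),
                       color_cov = .cov_from(raw$connective),
                       border_category = raw$connective$border_category)
  }

  libraries <- lapply(raw$libraries %||% list(), function(ls) {
    .check_keys(ls, .known_keys$library, "libraries")
    list(patch_size = as.integer(ls$patch_size %||% 12L),
         patches_per_cohort = as.integer(ls$patches_per_cohort),
         cohort_means = lapply(ls$cohort_means, function(m) as.numeric(unlist(m))),
         noise_sd = ls$noise_sd %||% 0.03)
  })

  if (is.null(raw$categories) || length(raw$categories) == 0L)
    stop("key 'categories' must list at least one category")
  cat_names <- vapply(raw$categories, function(cs) cs$name %||% "",
                      character(1))
  if (any(cat_names == "") || anyDuplicated(cat_names))
    stop("every category needs a unique 'name'")
  categories <- lapply(raw$categories, function(cs) {
    .check_keys(cs, .known_keys$category, paste0("category '", cs$name, "'"))
    shape <- match.arg(cs$shape,
                       c("ellipse", "patch", "fast_march_grown",
                         "region_noise"))
    sa <- if (!is.null(cs$semi_axes)) as.numeric(unlist(cs$semi_axes))
    if (!is.null(sa) && (length(sa) != 2L || sa[1] <= 0 || sa[2] < sa[1]))
      stop("category '", cs$name, "': semi_axes must be 0 < min <= max")
    vf <- cs$visible_fraction
    if (!is.null(vf) && (vf < 0 || vf > 1))
      stop("category '", cs$name, "': visible_fraction must lie in [0, 1]")
    if (!is.null(cs$region_fill)) {
      if (is.null(regions))
        stop("category '", cs$name, "': region_fill without a 'regions' block")
      if (cs$region_fill > regions$count)
        stop("category '", cs$name,
             "': region_fill exceeds the region count")
    }
    list(name = cs$name, shape = shape,
         mean_color = if (!is.null(cs$mean_color))
           as.numeric(unlist(cs$mean_color)),
         color_cov = .cov_from(cs, default_sd = 0.04),
         semi_axes = sa,
         count = if (!is.null(cs$count)) as.integer(cs$count),
         region_fill = if (!is.null(cs$region_fill))
           as.integer(cs$region_fill),
         fill_attempts = as.integer(cs$fill_attempts %||% 60L),
         attempts_per_region = as.integer(cs$attempts_per_region %||% 8L),
         parent = cs$parent,
         visible_fraction = vf,
         overlap = match.arg(cs$overlap %||% "free",
                             c("free", "forbidden", "moderate")),
         blend_to_background = cs$blend_to_background %||% 0,
         library = cs$library,
         source = cs$source,
         growth_per_nucleus = as.integer(cs$growth_per_nucleus %||% 400L),
         contour_darken = cs$contour_darken %||% 0.65,
         max_attempts = as.integer(cs$max_attempts %||% 100L))
  })
  names(categories) <- cat_names

  for (cs in categories) {
    if (!is.null(cs$parent) && !(cs$parent %in% cat_names))
      stop("category '", cs$name, "': unknown parent '", cs$parent, "'")
    if (cs$shape == "fast_march_grown" &&
        (is.null(cs$source) || !(cs$source %in% cat_names)))
      stop("category '", cs$name,
           "': fast_march_grown needs a valid 'source' category")
    if (cs$shape %in% c("patch", "fast_march_grown") &&
        (is.null(cs$library) || !(cs$library %in% names(libraries))))
      stop("category '", cs$name, "': unknown library '",
           cs$library %||% "<missing>", "'")
  }
  if (rule$type == "neighborhood") {
    for (k in c("cell_category", "target_category"))
      if (is.null(rule[[k]]) || !(rule[[k]] %in% cat_names))
        stop("rules/", k, " must name a category")
  } else {
    if (!(rule$category %in% cat_names))
      stop("rules/category must name a category")
  }

  structure(list(scenario = as.integer(raw$scenario), size = size,
                 rule = rule, background = background, regions = regions,
                 connective = connective, libraries = libraries,
                 categories = categories),
            class = "vn_scenario", raw = raw)
}

#' @export
print.vn_scenario <- function(x, ...) {
  cat(sprintf("<vn_scenario> scenario %d, %dx%d, %d categories\n",
              x$scenario, x$size[1], x$size[2], length(x$categories)))
  invisible(x)
}
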