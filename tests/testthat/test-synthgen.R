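test_that("ellipse placement respects ranges and overlap policies", {
  set.seed(90)
  pl <- place_ellipses(12L, c(4, 9), c(80L, 80L), overlap = "forbidden",
                       category = "cell")
  expect_length(pl$shapes, 12L)
  for (sh in pl$shapes) {
    expect_gte(sh$a, 4); expect_lte(sh$a, 9)
    expect_gte(sh$b, 4); expect_lte(sh$b, 9)
    expect_gte(sh$phi, 0); expect_lt(sh$phi, pi)
  }
  # pairwise-empty pixel intersections under the forbidden policy
  for (i in seq_along(pl$shapes)) for (j in seq_len(i - 1))
    expect_length(intersect(pl$shapes[[i]]$pixels, pl$shapes[[j]]$pixels),
                  0L)
  # count 0: empty list
  expect_length(place_ellipses(0L, c(4, 9), c(80L, 80L))$shapes, 0L)
  # impossible packing leaves a partial placement with a warning
  expect_warning(pl2 <- place_ellipses(50L, c(20, 30), c(60L, 60L),
                                       overlap = "forbidden",
                                       max_attempts = 5L),
                 "failed")
  expect_lt(length(pl2$shapes), 50L)
})

test_that("ellipse rasterization is consistent with the inside test", {
  px <- ellipse_pixels(c(10, 15), 4, 6, 0.7, c(30L, 30L))
  H <- 30
  ri <- (px - 1) %% H + 1; ci <- (px - 1) %/% H + 1
  x <- (ri - 10) * cos(0.7) + (ci - 15) * sin(0.7)
  y <- -(ri - 10) * sin(0.7) + (ci - 15) * cos(0.7)
  expect_true(all((x / 4)^2 + (y / 6)^2 <= 1))
  # disk area close to pi r^2
  dp <- disk_pixels(c(150, 150), 40, c(300L, 300L))
  expect_lt(abs(length(dp) - pi * 40^2) / (pi * 40^2), 0.01)
})

test_that("gaussian textures reproduce the requested color statistics", {
  set.seed(91)
  mu <- c(0.5, 0.4, 0.6)
  cv <- 0.03^2 * ((1 - 0.5) * diag(3) + 0.5)
  x <- gaussian_texture(mu, cv, 1e5)
  expect_true(all(x >= 0 & x <= 1))
  se_mean <- sqrt(diag(cv) / 1e5)
  expect_true(all(abs(colMeans(x) - mu) < 3 * se_mean))
  emp_cv <- stats::cov(x)
  expect_lt(max(abs(emp_cv - cv)), 3 * 0.03^2 / sqrt(1e5) * 10)
  # zero covariance: constant mean color
  x0 <- gaussian_texture(mu, matrix(0, 3, 3), 50)
  expect_true(all(abs(sweep(x0, 2, mu)) == 0))
  expect_error(gaussian_texture(mu, -diag(3), 10), "semidefinite")
})

test_that("patch libraries have three separated cohorts", {
  set.seed(92)
  lib <- build_patch_library("procedural", patch_size = 10L,
                             patches_per_cohort = 12L)
  expect_s3_class(lib, "vn_patch_library")
  expect_length(lib$cohorts, 3L)
  expect_true(all(vapply(lib$cohorts, length, integer(1)) == 12L))
  # each patch is nearest (in mean color) to its own cohort centroid
  for (k in 1:3) for (pt in lib$cohorts[[k]]) {
    pm <- apply(pt$rgb, 3, mean)
    d <- sqrt(colSums((t(lib$centroids) - pm)^2))
    expect_identical(which.min(d), k)
  }
  # between-cohort centroid distances exceed within-cohort spread
  within <- max(vapply(1:3, function(k) {
    ms <- t(vapply(lib$cohorts[[k]], function(pt) apply(pt$rgb, 3, mean),
                   numeric(3)))
    mean(sqrt(rowSums(sweep(ms, 2, lib$centroids[k, ])^2)))
  }, numeric(1)))
  between <- min(dist(lib$centroids))
  expect_gt(between, within)
})

test_that("mosaic textures blend overlapping patches convexly", {
  set.seed(93)
  lib <- build_patch_library("procedural", patch_size = 8L,
                             patches_per_cohort = 6L)
  region <- matrix(FALSE, 40L, 40L)
  region[8:35, 6:32] <- TRUE
  mz <- mosaic_texture(lib, 2L, region)
  idx <- which(region)
  vals <- cbind(mz[, , 1][idx], mz[, , 2][idx], mz[, , 3][idx])
  # every region pixel is covered and a convex combination of patch values
  lo <- min(vapply(lib$cohorts[[2]], function(pt) min(pt$rgb), numeric(1)))
  hi <- max(vapply(lib$cohorts[[2]], function(pt) max(pt$rgb), numeric(1)))
  expect_true(all(vals >= lo - 1e-12 & vals <= hi + 1e-12))
  expect_true(all(mz[, , 1][!region] == 0))
  # a region smaller than one patch gets the crop of a single patch
  small <- matrix(FALSE, 40L, 40L)
  small[3:7, 3:6] <- TRUE
  mzs <- mosaic_texture(lib, 1L, small)
  got <- matrix(c(mzs[, , 1][which(small)], mzs[, , 2][which(small)],
                  mzs[, , 3][which(small)]), ncol = 3)
  match_one <- any(vapply(lib$cohorts[[1]], function(pt) {
    ref <- matrix(c(pt$rgb[1:5, 1:4, 1], pt$rgb[1:5, 1:4, 2],
                    pt$rgb[1:5, 1:4, 3]), ncol = 3)
    isTRUE(all.equal(got, ref, tolerance = 1e-12))
  }, logical(1)))
  expect_true(match_one)
  expect_error(mosaic_texture(lib, 2L, matrix(FALSE, 4, 4)), "nonempty")
})

test_that("neighborhood classification is the disk area fraction rule", {
  dimHW <- c(120L, 120L)
  cell <- list(center = c(60, 60), pixels = integer(0))
  full <- matrix(TRUE, 120, 120)
  empty <- matrix(FALSE, 120, 120)
  expect_true(classify_by_neighborhood(list(cell), full, 20,
                                       0.99)$classified)
  expect_false(classify_by_neighborhood(list(cell), empty, 20,
                                        0)$classified)
  # half-plane target: concentration matches the pixel-count oracle
  half <- matrix(FALSE, 120, 120)
  half[, 1:60] <- TRUE
  res <- classify_by_neighborhood(list(cell), half, 20, 0.3)
  dp <- disk_pixels(c(60, 60), 20, dimHW)
  expect_equal(res$concentration, mean(half[dp]))
  expect_equal(res$concentration, 0.5, tolerance = 0.05)
  expect_true(res$classified)                       # 0.5 > 0.3
  expect_true(classify_by_neighborhood(list(cell), half, 20,
                                       0.2)$classified)
  # the ground-truth mask marks exactly the classified cell's pixels
  cell2 <- list(center = c(60, 60),
                pixels = ellipse_pixels(c(60, 60), 5, 4, 0, dimHW))
  res2 <- classify_by_neighborhood(list(cell2), half, 20, 0.3)
  expect_identical(which(res2$mask == 1), cell2$pixels[order(cell2$pixels)])
})

test_that("layer composition is top-wins with union alpha", {
  d <- c(5L, 6L)
  l1 <- list(rgb = array(0.2, c(d, 3)), alpha = matrix(TRUE, d[1], d[2]))
  a2 <- matrix(FALSE, d[1], d[2]); a2[2, 3] <- TRUE
  l2 <- list(rgb = array(0.9, c(d, 3)), alpha = a2)
  out <- compose_layers(list(l1, l2))
  expect_equal(out$rgb[2, 3, ], rep(0.9, 3))
  expect_equal(out$rgb[1, 1, ], rep(0.2, 3))
  expect_true(all(out$alpha))
  # single layer composes to itself (on its own alpha support)
  single <- compose_layers(list(l2))
  expected <- array(0, c(d, 3))
  for (ch in 1:3) expected[, , ch][a2] <- 0.9
  expect_identical(single$rgb, expected)
  expect_identical(single$alpha, a2)
  # merged alpha is the pixelwise union
  a3 <- matrix(FALSE, d[1], d[2]); a3[5, 1] <- TRUE
  l3 <- list(rgb = array(0.4, c(d, 3)), alpha = a3)
  out3 <- compose_layers(list(l2, l3))
  expect_identical(out3$alpha, a2 | a3)
  expect_error(compose_layers(list(l1, list(rgb = array(0, c(4, 4, 3)),
                                            alpha = matrix(TRUE, 4, 4)))),
               "size")
})

test_that("scenario 1 samples satisfy the scene contracts", {
  cfg <- scenario_config(1)
  s <- generate_sample(cfg, 2)
  expect_identical(dim(s$u0), c(300L, 300L, 3L))
  expect_identical(dim(s$g_u), c(300L, 300L, 3L))
  expect_true(all(s$u0 >= 0 & s$u0 <= 1))
  expect_true(all(s$g_u >= 0 & s$g_u <= 1))
  expect_true(all(s$m0 == 0))
  expect_true(all(s$g_m %in% c(0, 1)))
  cats <- vapply(s$registry, `[[`, character(1), "category")
  expect_identical(sum(cats == "tumor_cell"), 25L)
  expect_identical(sum(cats == "immune_cell"), 20L)
  expect_identical(sum(cats == "stroma"), 20L)
  # exact-count visibility: round(0.6 * 25) = 15 and round(0.6 * 20) = 12
  vis <- vapply(s$registry, function(x) isTRUE(x$visible), logical(1))
  expect_identical(sum(vis & cats == "tumor_nucleus"), 15L)
  expect_identical(sum(vis & cats == "immune_nucleus"), 12L)
  # semi-axes within the printed ranges
  for (sh in s$registry[cats == "tumor_cell"]) {
    expect_gte(sh$a, 20); expect_lte(sh$a, 35)
  }
  for (sh in s$registry[cats == "immune_cell"]) {
    expect_gte(sh$a, 8); expect_lte(sh$a, 20)
  }
  # ground truth reproducible from geometry alone, bit-exactly
  expect_identical(recompute_ground_truth(s$registry, cfg, c(300L, 300L)),
                   s$g_m)
})

test_that("scenario 2 fills disjoint Voronoi regions per category", {
  cfg <- scenario_config(2)
  s <- generate_sample(cfg, 3)
  cats <- vapply(s$registry, `[[`, character(1), "category")
  regs_t <- unique(vapply(s$registry[cats == "tumor_cell"], `[[`,
                          numeric(1), "region"))
  regs_i <- unique(vapply(s$registry[cats == "immune_cell"], `[[`,
                          numeric(1), "region"))
  expect_length(regs_t, 5L)
  expect_length(regs_i, 2L)
  expect_length(intersect(regs_t, regs_i), 0L)
  expect_identical(sort(unique(as.vector(s$regions$labels))), 1:7)
  # every cell center lies in its recorded region
  for (sh in s$registry[cats %in% c("tumor_cell", "immune_cell")])
    expect_identical(s$regions$labels[sh$center[1], sh$center[2]],
                     as.integer(sh$region))
  expect_identical(recompute_ground_truth(s$registry, cfg, c(300L, 300L)),
                   s$g_m)
})

test_that("scenario 3 masks the visible tumor nuclei only", {
  cfg <- scenario_config(3)
  s <- generate_sample(cfg, 4)
  cats <- vapply(s$registry, `[[`, character(1), "category")
  regs_n <- unique(vapply(s$registry[cats == "tumor_nucleus"], `[[`,
                          numeric(1), "region"))
  expect_length(regs_n, 10L)
  expect_length(unique(vapply(s$registry[cats == "blood_vessel"], `[[`,
                              numeric(1), "region")), 1L)
  # no nucleus pixel under an immune cell is labeled
  immune_px <- unlist(lapply(s$registry[cats == "immune_cell"], `[[`,
                             "pixels"))
  expect_true(all(s$g_m[immune_px] == 0))
  # every labeled pixel belongs to some tumor nucleus
  nuc_px <- unlist(lapply(s$registry[cats == "tumor_nucleus"], `[[`,
                          "pixels"))
  expect_true(all(which(s$g_m == 1) %in% nuc_px))
  # each tumor cell contains its source nucleus
  nucs <- s$registry[cats == "tumor_nucleus"]
  cells <- s$registry[cats == "tumor_cell"]
  expect_identical(length(cells), length(nucs))
  for (i in seq_along(nucs))
    expect_true(all(nucs[[i]]$pixels %in% cells[[i]]$pixels))
  expect_identical(recompute_ground_truth(s$registry, cfg, c(300L, 300L)),
                   s$g_m)
})

test_that("datasets are reproducible from the master seed", {
  cfg <- scenario_config(1, "small")
  d1 <- generate_dataset(cfg, 2, 123)
  d2 <- generate_dataset(cfg, 2, 123)
  expect_identical(d1[[1]]$u0, d2[[1]]$u0)
  expect_identical(d1[[2]]$g_m, d2[[2]]$g_m)
  d3 <- generate_dataset(cfg, 2, 124)
  expect_false(identical(d1[[1]]$u0, d3[[1]]$u0))
  expect_false(identical(d1[[1]]$u0, d1[[2]]$u0))   # samples differ
  expect_length(generate_dataset(cfg, 0, 1), 0L)
})
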