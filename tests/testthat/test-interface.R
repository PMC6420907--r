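test_that("shipped scene scripts parse and round-trip", {
  for (sc in 1:3) {
    cfg <- scenario_config(sc)
    expect_s3_class(cfg, "vn_scenario")
    expect_identical(cfg$scenario, sc)
    path <- tempfile(fileext = ".yaml")
    write_scene_script(cfg, path)
    cfg2 <- parse_scene_script(path)
    expect_equal(cfg2, cfg, ignore_attr = TRUE)
    unlink(path)
  }
  # the script controls shape, placement and coloring of every category
  cfg1 <- scenario_config(1)
  for (cs in cfg1$categories) {
    expect_true(cs$shape %in% c("ellipse", "patch", "fast_march_grown",
                                "region_noise"))
    expect_true(!is.null(cs$count) || !is.null(cs$parent) ||
                  !is.null(cs$region_fill))
    expect_identical(dim(cs$color_cov), c(3L, 3L))
  }
})

test_that("invalid scene scripts are rejected with the offending key", {
  cfg <- scenario_config(1)
  raw <- attr(cfg, "raw")
  bad <- raw
  bad$rules$concentration_threshold <- 1.5
  p <- tempfile(fileext = ".yaml"); yaml::write_yaml(bad, p)
  expect_error(parse_scene_script(p), "concentration_threshold")
  bad2 <- raw
  bad2$categories[[2]]$semi_axes <- c(5, 2)
  yaml::write_yaml(bad2, p)
  expect_error(parse_scene_script(p), "semi_axes")
  bad3 <- raw
  bad3$no_such_key <- 1
  yaml::write_yaml(bad3, p)
  expect_error(parse_scene_script(p), "no_such_key")
  unlink(p)
  expect_error(parse_scene_script(tempfile()), "not found")
})

test_that("images quantize to at most 1/255 per pixel on a round trip", {
  set.seed(110)
  img <- array(runif(20 * 15 * 3), c(20, 15, 3))
  for (ext in c(".png", ".tiff")) {
    p <- tempfile(fileext = ext)
    write_image(img, p, "rgb")
    back <- read_image(p, "rgb")
    expect_lte(max(abs(back - img)), 1 / 255)
    unlink(p)
  }
  # masks come back in [0, 1]
  m <- matrix(runif(100), 10, 10)
  p <- tempfile(fileext = ".png")
  write_image(m, p, "mask")
  back <- read_image(p, "mask")
  expect_true(all(back >= 0 & back <= 1))
  expect_lte(max(abs(back - m)), 1 / 255)
  # binary RGBA alpha survives exactly
  rgba <- array(runif(10 * 10 * 4), c(10, 10, 4))
  rgba[, , 4] <- matrix(rbinom(100, 1, 0.5), 10, 10)
  write_image(rgba, p, "rgba")
  back4 <- read_image(p, "rgba")
  expect_identical(back4[, , 4], rgba[, , 4])
  unlink(p)
  expect_error(read_image(tempfile(fileext = ".png")), "cannot read")
  expect_error(write_image(img, tempfile(fileext = ".bmp")), "format")
})

test_that("the generate command writes a dataset directory with manifest", {
  out <- file.path(tempdir(), "vnseg-cli-test")
  on.exit(unlink(out, recursive = TRUE), add = TRUE)
  suppressMessages(
    vnseg_cli(c("generate", "--scenario", "1", "--config",
                system.file("extdata", "scenario1_small.yaml",
                            package = "vnseg"),
                "--n", "2", "--seed", "7", "--out", out)))
  expect_true(file.exists(file.path(out, "manifest.yaml")))
  expect_true(file.exists(file.path(out, "index.tsv")))
  for (i in 1:2) for (sfx in c("u0", "gu", "m0", "gm"))
    expect_true(file.exists(file.path(out,
                                      sprintf("sample_%04d_%s.png", i, sfx))))
  mf <- read_manifest(file.path(out, "manifest.yaml"))
  expect_identical(mf$command, "generate")
  expect_identical(mf$seed, 7L)
  # reproducibility from the manifest: same seed, same pixels
  out2 <- file.path(tempdir(), "vnseg-cli-test2")
  on.exit(unlink(out2, recursive = TRUE), add = TRUE)
  suppressMessages(
    vnseg_cli(c("generate", "--scenario", "1", "--config",
                system.file("extdata", "scenario1_small.yaml",
                            package = "vnseg"),
                "--n", "2", "--seed", "7", "--out", out2)))
  expect_identical(read_image(file.path(out, "sample_0001_u0.png"), "rgb"),
                   read_image(file.path(out2, "sample_0001_u0.png"), "rgb"))
})

test_that("the CLI rejects invalid invocations", {
  expect_error(vnseg_cli(character(0)), "usage")
  expect_error(vnseg_cli("frobnicate"), "unknown subcommand")
  expect_error(suppressMessages(
    vnseg_cli(c("predict", "--checkpoint", tempfile(),
                "--input", "x.png", "--out", "y"))),
    "checkpoint not found")
  expect_error(vnseg_cli(c("generate", "--scenario", "1")),
               "--out")
})

test_that("predict runs a checkpoint end to end on a written image", {
  arch <- tiny_arch(1L)
  p <- vn_init_params(arch, seed = 12)
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(p, ck)
  img <- tempfile(fileext = ".png")
  set.seed(111)
  write_image(array(runif(16 * 16 * 3), c(16, 16, 3)), img, "rgb")
  pre <- tempfile()
  suppressMessages(
    vnseg_cli(c("predict", "--checkpoint", ck, "--input", img,
                "--out", pre)))
  expect_true(file.exists(paste0(pre, "_uT.png")))
  expect_true(file.exists(paste0(pre, "_mT.png")))
  # matches an in-process forward pass up to 8-bit quantization
  res <- vn_forward(p, read_image(img, "rgb"))
  expect_lte(max(abs(read_image(paste0(pre, "_uT.png"), "rgb") - res$u)),
             1 / 255)
  unlink(c(ck, img, paste0(pre, c("_uT.png", "_mT.png", ".manifest.yaml"))))
})
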