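#' Read and write images
#'
#' PNG or TIFF (by extension), 8-bit quantized on write, so a write/read
#' round trip changes no value by more than 1/255. Masks are written as
#' single-channel images and read back into `[0, 1]`; RGBA alpha channels
#' round-trip exactly when binary.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param kind `"rgb"` (`H x W x 3`), `"rgba"` (`H x W x 4`) or `"mask"`
#'   (`H x W`).
#' @param img array matching `kind`, values in `[0, 1]`.
#' @return `read_image()` returns the array.
#' @export
read_image <- function(path, kind = c("rgb", "rgba", "mask")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext))
  nc <- if (length(dim(img)) == 3L) dim(img)[3] else 1L
  if (kind == "mask") {
    if (nc > 1L) stop(path, ": expected a single-channel mask, got ", nc,
                      " channels")
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    return(img)
  }
  want <- if (kind == "rgb") 3L else 4L
  if (nc < want) stop(path, ": expected ", want, " channels, got ", nc)
  img[, , seq_len(want), drop = FALSE]
}

#' @rdname read_image
#' @export
write_image <- function(img, path, kind = c("rgb", "rgba", "mask")) {
  kind <- match.arg(kind)
  if (kind == "mask") img <- as_seg_mask(img, strict = FALSE)
  img <- clip01(img)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(img, path),
         tif = ,
         tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
         stop("unsupported image format: .", ext))
  invisible(path)
}

#' Write a run manifest
#'
#' Every artifact-producing command records the information needed to
#' reproduce it exactly: the command, scenario, seeds, configuration and
#' output paths, and the package version.
#'
#' @param path manifest path (YAML).
#' @param command command name.
#' @param ... further fields (scenario, seed, paths, ...).
#' @return `read_manifest()` returns the manifest list.
#' @export
write_manifest <- function(path, command, ...) {
  yaml::write_yaml(c(list(command = command),
                     list(...),
                     list(package = "vnseg",
                          version = as.character(utils::packageVersion("vnseg")))),
                   path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) yaml::read_yaml(path)
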