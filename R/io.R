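#' Read and write binary masks as PNG
#'
#' Masks are stored as single-channel 8-bit PNG with foreground 255 and
#' background 0; reading binarizes at half intensity.
#'
#' @param mask binary matrix.
#' @param path PNG file path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(as_mask_matrix(mask), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  (x >= 0.5) * 1
}

#' Read and write grayscale images as PNG
#'
#' Images are stored as single-channel 8-bit PNG in `[0, 1]`. PNG carries no
#' physical scale, so the spacing must be supplied on read.
#'
#' @param image `us_image` or matrix in `[0, 1]`.
#' @param path PNG file path.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(as_pixel_matrix(image), path, dpi = NULL)
  invisible(path)
}

#' @rdname write_image_png
#' @param row_spacing_mm,col_spacing_mm physical spacing of the stored image.
#' @param ... passed to [us_image()].
#' @export
read_image_png <- function(path, row_spacing_mm, col_spacing_mm = row_spacing_mm,
                           ...) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  us_image(x, row_spacing_mm, col_spacing_mm, ...)
}

#' Read and write probability maps as 32-bit float TIFF
#'
#' @param probs probability map in `[0, 1]` (also used for weight fields,
#'   which may exceed 1; values are stored as IEEE floats unchanged).
#' @param path TIFF file path.
#' @export
write_float_tiff <- function(probs, path) {
  tiff::writeTIFF(as_pixel_matrix(probs), path, bits.per.sample = 32)
  invisible(path)
}

#' @rdname write_float_tiff
#' @export
read_float_tiff <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x
}

#' Write a phantom dataset to disk
#'
#' Emits `<image_id>.png` (image), `<image_id>_mask.png` (mask) and
#' `manifest.csv` (`image_id`, `patient_id`, `split`, `margin_mm`, `domain`,
#' `row_spacing_mm`, `col_spacing_mm`) into `dir`.
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in dataset$samples) {
    write_image_png(s$image, file.path(dir, paste0(s$image$image_id, ".png")))
    write_mask_png(s$mask, file.path(dir, paste0(s$image$image_id, "_mask.png")))
  }
  manifest <- dataset$manifest
  manifest$row_spacing_mm <- dataset$spec$row_spacing_mm
  manifest$col_spacing_mm <- dataset$spec$col_spacing_mm
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Load a phantom dataset written by [write_dataset()]
#'
#' @param dir directory holding `manifest.csv` and the paired PNGs.
#' @return object of class `phantom_dataset` (without the generating spec).
#' @export
load_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  samples <- list()
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    img <- read_image_png(file.path(dir, paste0(r$image_id, ".png")),
                          r$row_spacing_mm, r$col_spacing_mm,
                          patient_id = r$patient_id, image_id = r$image_id)
    msk <- read_mask_png(file.path(dir, paste0(r$image_id, "_mask.png")))
    samples[[r$image_id]] <- structure(
      list(image = img, mask = msk,
           meta = list(margin_mm = r$margin_mm, domain = r$domain),
           split = r$split), class = "phantom")
  }
  structure(list(samples = samples, manifest = manifest, spec = NULL),
            class = "phantom_dataset")
}

#' Read a YAML run configuration
#'
#' Convenience wrapper turning a YAML file with `phantom`, `train`, and
#' `evaluate` sections into the corresponding argument lists.
#'
#' @param path YAML file.
#' @return named list of configuration sections.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)
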