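#' Ultrasound image container
#'
#' A 2-D grayscale B-mode-like image with physical pixel spacing. Row index
#' increases with depth: row 1 is the transducer (specimen) surface, which is
#' the surgically relevant side of the image.
#'
#' @param pixels numeric matrix with values in `[0, 1]` (rows = depth).
#' @param row_spacing_mm,col_spacing_mm physical size of one pixel (mm).
#' @param patient_id,image_id provenance labels.
#' @return An object of class `us_image`: a list with elements `pixels`,
#'   `row_spacing_mm`, `col_spacing_mm`, `patient_id`, `image_id`.
#' @export
us_image <- function(pixels, row_spacing_mm, col_spacing_mm = row_spacing_mm,
                     patient_id = NA_character_, image_id = NA_character_) {
  pixels <- as_pixel_matrix(pixels)
  if (!is.numeric(row_spacing_mm) || row_spacing_mm <= 0 ||
      !is.numeric(col_spacing_mm) || col_spacing_mm <= 0)
    stop("pixel spacing must be positive (mm/px)")
  if (min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9)
    stop("us_image pixels must lie in [0, 1]")
  structure(
    list(pixels = pixels,
         row_spacing_mm = as.numeric(row_spacing_mm),
         col_spacing_mm = as.numeric(col_spacing_mm),
         patient_id = patient_id, image_id = image_id),
    class = "us_image")
}

#' @export
print.us_image <- function(x, ...) {
  cat(sprintf("<us_image %d x %d px, %.4f x %.4f mm/px, patient=%s, image=%s>\n",
              nrow(x$pixels), ncol(x$pixels),
              x$row_spacing_mm, x$col_spacing_mm,
              x$patient_id, x$image_id))
  invisible(x)
}

#' @export
dim.us_image <- function(x) dim(x$pixels)

# Coerce input to a plain numeric matrix of pixels.
as_pixel_matrix <- function(x) {
  if (inherits(x, "us_image")) return(x$pixels)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) stop("expected a numeric matrix of pixels")
  x
}

# Coerce and validate a binary mask; returns a 0/1 numeric matrix.
as_mask_matrix <- function(x, arg = "mask") {
  if (is.logical(x)) x <- x * 1
  x <- as_pixel_matrix(x)
  if (!all(x %in% c(0, 1)))
    stop(sprintf("%s must be binary (values 0/1)", arg))
  x
}

as_prob_matrix <- function(x, arg = "probs") {
  x <- as_pixel_matrix(x)
  if (min(x) < -1e-9 || max(x) > 1 + 1e-9)
    stop(sprintf("%s must lie in [0, 1]", arg))
  pmin(pmax(x, 0), 1)
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("shape mismatch: %s vs %s",
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  invisible(TRUE)
}

#' Two-channel view of a binary tumor mask
#'
#' Ground-truth masks enter the losses as a two-channel image: channel 1 is
#' background, channel 2 is foreground (tumor), with channel 1 = 1 - channel 2
#' at every pixel.
#'
#' @param mask binary matrix (1 = tumor).
#' @return list with matrices `bg` (k = 1) and `fg` (k = 2).
#' @export
mask_channels <- function(mask) {
  fg <- as_mask_matrix(mask)
  list(bg = 1 - fg, fg = fg)
}

# Run code with a locally-seeded RNG, restoring global state afterwards.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
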