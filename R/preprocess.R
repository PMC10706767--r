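#' Default physical row spacing
#'
#' The acquisition geometry images 3 cm of depth over 344 rows
#' (~0.0872 mm/px). After cropping to the top half (15 mm of depth) and
#' resizing to `rows` rows, one row spans `15 / rows` mm. All mm-valued
#' outputs are computed from an explicit spacing; this helper only supplies
#' the documented default.
#'
#' @param rows image height in pixels after preprocessing.
#' @param cropped whether the 30 mm field was cropped to its top half.
#' @return row spacing in mm/px.
#' @export
default_row_spacing_mm <- function(rows = 128, cropped = TRUE) {
  depth_mm <- if (cropped) 15 else 30
  depth_mm / rows
}

#' Crop image and mask to the top half
#'
#' Keeps rows 1..floor(nrow/2), i.e. the tissue nearest the transducer /
#' resection surface. Pixel spacing is unchanged.
#'
#' @param image `us_image` or numeric matrix.
#' @param mask paired binary mask.
#' @return list with cropped `image` and `mask` (inputs' types preserved).
#' @export
crop_top_half <- function(image, mask) {
  px <- as_pixel_matrix(image)
  m <- as_mask_matrix(mask)
  check_same_shape(px, m)
  if (nrow(px) < 2) stop("need at least 2 rows to crop")
  keep <- seq_len(nrow(px) %/% 2)
  out_px <- px[keep, , drop = FALSE]
  out_m <- m[keep, , drop = FALSE]
  list(image = rewrap_image(image, out_px), mask = out_m)
}

# Preserve us_image metadata when pixel content changes.
rewrap_image <- function(orig, pixels, row_scale = 1, col_scale = 1) {
  if (inherits(orig, "us_image")) {
    us_image(pixels,
             row_spacing_mm = orig$row_spacing_mm * row_scale,
             col_spacing_mm = orig$col_spacing_mm * col_scale,
             patient_id = orig$patient_id, image_id = orig$image_id)
  } else pixels
}

#' Resize to the network input size and normalize intensities
#'
#' Bilinear resize for the image, nearest-neighbor for the mask (so it stays
#' binary), followed by per-image min-max normalization to `[0, 1]`. Pixel
#' spacing is rescaled by the old/new size ratio so physical geometry is
#' preserved. A constant image cannot be min-max scaled and becomes all zeros
#' with a warning.
#'
#' @param image `us_image` or numeric matrix.
#' @param mask paired binary mask.
#' @param target `c(rows, cols)` output size.
#' @return list with resized `image` and `mask`.
#' @export
resize_and_normalize <- function(image, mask, target = c(128, 128)) {
  px <- as_pixel_matrix(image)
  m <- as_mask_matrix(mask)
  check_same_shape(px, m)
  if (any(target < 1)) stop("degenerate target size")
  if (!identical(dim(px), as.integer(target))) {
    out_px <- as.matrix(EBImage::resize(px, w = target[1], h = target[2],
                                        filter = "bilinear"))
    out_m <- as.matrix(EBImage::resize(m, w = target[1], h = target[2],
                                       filter = "none"))
    out_m <- (out_m >= 0.5) * 1
  } else {
    out_px <- px; out_m <- m
  }
  rng <- range(out_px)
  if (diff(rng) == 0) {
    warning("constant image; normalized to all zeros")
    out_px[] <- 0
  } else {
    out_px <- (out_px - rng[1]) / diff(rng)
  }
  list(image = rewrap_image(image, out_px,
                            row_scale = nrow(px) / target[1],
                            col_scale = ncol(px) / target[2]),
       mask = out_m)
}

#' Training-time augmentation
#'
#' Independently samples a left-right mirror (probability 1/2), a rotation
#' angle uniform in `angle_range` degrees (bilinear for the image,
#' nearest-neighbor + re-binarization for the mask, exposed corners filled
#' with 0), and a gamma correction `P_out = P_in^gamma` with gamma uniform in
#' `gamma_range`, applied to the image only. Mirroring is about the vertical
#' axis: flipping top-to-bottom would move the resection surface away from
#' row 1 and break the depth semantics the margin metric and the
#' gradient-weighted loss rely on.
#'
#' @param image normalized `us_image` or matrix in `[0, 1]`.
#' @param mask paired binary mask.
#' @param seed optional integer; a fixed seed makes the draw reproducible.
#' @param flip_prob probability of the left-right mirror.
#' @param angle_range rotation range in degrees.
#' @param gamma_range gamma range (`> 0`).
#' @return list with augmented `image`, `mask`, and the sampled `params`.
#' @export
augment <- function(image, mask, seed = NULL, flip_prob = 0.5,
                    angle_range = c(-5, 5), gamma_range = c(0.8, 1.2)) {
  px <- as_pixel_matrix(image)
  m <- as_mask_matrix(mask)
  check_same_shape(px, m)
  params <- with_local_seed(seed, list(
    flip = stats::runif(1) < flip_prob,
    angle = stats::runif(1, angle_range[1], angle_range[2]),
    gamma = stats::runif(1, gamma_range[1], gamma_range[2])
  ))
  if (params$flip) {
    px <- px[, rev(seq_len(ncol(px))), drop = FALSE]
    m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  }
  if (params$angle != 0) {
    px <- as.matrix(EBImage::rotate(px, params$angle, filter = "bilinear",
                                    output.dim = dim(px), bg.col = 0))
    px <- pmin(pmax(px, 0), 1)
    m <- as.matrix(EBImage::rotate(m, params$angle, filter = "none",
                                   output.dim = dim(m), bg.col = 0))
    m <- (m >= 0.5) * 1
  }
  px <- px^params$gamma
  list(image = rewrap_image(image, px), mask = m, params = params)
}
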