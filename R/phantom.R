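# Analytic mean/sd of a normal truncated to [a, b].
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  Z <- stats::pnorm(be) - stats::pnorm(al)
  da <- stats::dnorm(al); db <- stats::dnorm(be)
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (al * da - be * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Solve for the (mu, sigma) of the *untruncated* kernel such that after
# truncation to [a, b] the distribution has the requested mean and sd. The
# cohort statistics are quoted for tumors that need not fit the phantom's
# field of view, so matching the realized (truncated) moments keeps the
# generated margins faithful to them.
truncnorm_match <- function(target_mean, target_sd, a, b) {
  # a window can at most support the sd of its tilted-uniform limit; the
  # kernel scale is softly bounded so the solve stays well-conditioned and
  # the fit degrades gracefully when the target sd is unattainable
  obj <- function(par) {
    mo <- truncnorm_moments(par[1], exp(par[2]), a, b)
    (mo[1] - target_mean)^2 + (mo[2] - target_sd)^2 +
      100 * max(0, par[2] - log(5 * (b - a)))^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Exact truncated-normal draw by inverse-CDF (no rejection).
rtruncnorm1 <- function(mu, sigma, a, b) {
  pa <- stats::pnorm(a, mu, sigma); pb <- stats::pnorm(b, mu, sigma)
  if (pb - pa < 1e-12) stop("lesion geometry kernel is degenerate")
  stats::qnorm(pa + stats::runif(1) * (pb - pa), mu, sigma)
}

# Texture statistics per domain. The source domain stands in for the large
# related dataset used for pre-training (smoother speckle, darker lesions);
# the target domain for the study tissue (stronger, finer speckle, lower
# lesion contrast, rougher boundaries), giving transfer learning a real
# appearance gap to bridge.
domain_params <- function(domain = c("target", "source")) {
  domain <- match.arg(domain)
  if (domain == "source")
    list(contrast = 0.35, speckle_strength = 0.55, speckle_blur = 1.2,
         roughness = 0.04)
  else
    list(contrast = 0.50, speckle_strength = 1.00, speckle_blur = 0.6,
         roughness = 0.10)
}

#' Phantom generator specification
#'
#' Describes the population of synthetic B-mode-like phantoms: cohort
#' geometry (top-margin depth 6.4 +/- 3.7 mm, tumor diameter 41 +/- 19 mm,
#' truncated/capped to the field of view), per-patient image counts (1-3
#' cross-sections sharing geometry up to a small re-scan jitter), image size
#' and physical spacing, and domain-dependent texture (speckle, attenuation,
#' lesion contrast).
#'
#' The margin sampling kernel is moment-matched: its parameters are solved so
#' that the distribution *after* truncation to the visible depth reproduces
#' the quoted cohort mean/sd.
#'
#' @param n_patients number of synthetic patients.
#' @param images_per_patient inclusive range of cross-sections per patient.
#' @param size image size `c(rows, cols)`; the default 128 x 128 matches the
#'   post-preprocessing network input. Use `raw = TRUE` for 344 x 430
#'   acquisition-scale phantoms to exercise the crop/resize path.
#' @param raw emit acquisition-scale phantoms (30 mm depth, 344 x 430 px).
#' @param margin_mean_mm,margin_sd_mm cohort top-margin distribution (mm).
#' @param margin_jitter_sd_mm within-patient re-scan variation of the margin.
#' @param diam_mean_mm,diam_sd_mm cohort tumor diameter distribution (mm).
#' @param aspect_range vertical/horizontal lesion semi-axis ratio range.
#' @param attenuation_per_mm residual depth attenuation after gain control.
#' @param domain `"target"` or `"source"` texture statistics.
#' @param split_fractions image-count proportions for train/validation/test.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_patients = 74, images_per_patient = c(1, 3),
                         size = c(128, 128), raw = FALSE,
                         margin_mean_mm = 6.4, margin_sd_mm = 3.7,
                         margin_jitter_sd_mm = 0.5,
                         diam_mean_mm = 41, diam_sd_mm = 19,
                         aspect_range = c(0.35, 0.75),
                         attenuation_per_mm = 0.02,
                         domain = c("target", "source"),
                         split_fractions = c(train = 121, val = 28, test = 30) / 179) {
  domain <- match.arg(domain)
  if (raw) size <- c(344, 430)
  depth_mm <- if (raw) 30 else 15
  width_mm <- depth_mm * 430 / 344  # square pixels at acquisition scale
  row_sp <- depth_mm / size[1]
  col_sp <- width_mm / size[2]
  stopifnot(n_patients >= 1, images_per_patient[1] >= 1,
            images_per_patient[2] >= images_per_patient[1],
            margin_sd_mm > 0, diam_sd_mm > 0,
            abs(sum(split_fractions) - 1) < 1e-6)
  margin_lo <- 0.3
  margin_hi <- depth_mm - 6 * row_sp  # keep several tumor rows visible
  kern <- truncnorm_match(margin_mean_mm, margin_sd_mm, margin_lo, margin_hi)
  structure(list(
    n_patients = n_patients, images_per_patient = images_per_patient,
    size = size, raw = raw, depth_mm = depth_mm,
    row_spacing_mm = row_sp, col_spacing_mm = col_sp,
    margin_mean_mm = margin_mean_mm, margin_sd_mm = margin_sd_mm,
    margin_kernel = kern, margin_bounds = c(margin_lo, margin_hi),
    margin_jitter_sd_mm = margin_jitter_sd_mm,
    diam_mean_mm = diam_mean_mm, diam_sd_mm = diam_sd_mm,
    aspect_range = aspect_range,
    attenuation_per_mm = attenuation_per_mm,
    domain = domain, texture = domain_params(domain),
    split_fractions = split_fractions), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec: %d patients x %d-%d images, %dx%d px ",
                     "(%.4f mm/px), margin %.1f+/-%.1f mm, domain %s>\n"),
              x$n_patients, x$images_per_patient[1], x$images_per_patient[2],
              x$size[1], x$size[2], x$row_spacing_mm,
              x$margin_mean_mm, x$margin_sd_mm, x$domain))
  invisible(x)
}

# Patient-level lesion geometry draw.
sample_geometry <- function(spec) {
  k <- spec$margin_kernel
  margin <- rtruncnorm1(k$mu, k$sigma, spec$margin_bounds[1], spec$margin_bounds[2])
  diam <- stats::rnorm(1, spec$diam_mean_mm, spec$diam_sd_mm)
  # diameters beyond the field of view appear truncated, as in real imaging:
  # cap rather than reject, with a floor well above the speckle grain
  width_mm <- spec$col_spacing_mm * spec$size[2]
  diam <- min(max(diam, 8), 2 * width_mm)
  amps <- stats::rnorm(4, 0, spec$texture$roughness / (1:4))
  list(margin_mm = margin, diam_mm = diam,
       aspect = stats::runif(1, spec$aspect_range[1], spec$aspect_range[2]),
       cx_frac = stats::runif(1, 0.40, 0.60),
       amps = amps, phases = stats::runif(4, 0, 2 * pi))
}

# Re-scan jitter applied to a shared patient geometry.
jitter_geometry <- function(geom, spec) {
  g <- geom
  g$margin_mm <- min(max(geom$margin_mm +
                           stats::rnorm(1, 0, spec$margin_jitter_sd_mm),
                         spec$margin_bounds[1]), spec$margin_bounds[2])
  g$cx_frac <- min(max(geom$cx_frac + stats::rnorm(1, 0, 0.02), 0.35), 0.65)
  g$phases <- geom$phases + stats::rnorm(4, 0, 0.15)
  g
}

# Gaussian blur with zero padding: EBImage's gblur convolves circularly via
# FFT, which would wrap a deep lesion's halo onto the transducer surface.
blur_zero_pad <- function(x, sigma, edge = c("zero", "replicate")) {
  edge <- match.arg(edge)
  r <- ceiling(3 * sigma)
  ri <- r + seq_len(nrow(x)); ci <- r + seq_len(ncol(x))
  pad <- matrix(0, nrow(x) + 2 * r, ncol(x) + 2 * r)
  pad[ri, ci] <- x
  if (edge == "replicate") {
    pad[1:r, ci] <- matrix(x[1, ], r, ncol(x), byrow = TRUE)
    pad[r + nrow(x) + 1:r, ci] <- matrix(x[nrow(x), ], r, ncol(x), byrow = TRUE)
    pad[, 1:r] <- pad[, r + 1]
    pad[, r + ncol(x) + 1:r] <- pad[, r + ncol(x)]
  }
  out <- as.matrix(EBImage::gblur(pad, sigma = sigma))
  out[ri, ci, drop = FALSE]
}

# Smooth unit-variance random field (low-frequency gain inhomogeneity).
smooth_field <- function(nr, nc, sigma) {
  f <- as.matrix(EBImage::gblur(matrix(stats::rnorm(nr * nc), nr, nc),
                                sigma = sigma))
  (f - mean(f)) / stats::sd(f)
}

# Rasterize a radially-perturbed ellipse lesion; returns binary mask whose
# topmost row is exactly `top_row` (the mask is shifted to honor the sampled
# margin after boundary perturbation).
rasterize_lesion <- function(geom, spec, top_row) {
  H <- spec$size[1]; W <- spec$size[2]
  a_px <- (geom$diam_mm / 2) / spec$col_spacing_mm
  b_px <- (geom$diam_mm / 2) * geom$aspect / spec$row_spacing_mm
  cx <- geom$cx_frac * W
  cy <- top_row + b_px
  dy <- (matrix(seq_len(H), H, W) - cy) / b_px
  dx <- (matrix(seq_len(W), H, W, byrow = TRUE) - cx) / a_px
  rho <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  r <- 1
  for (h in seq_along(geom$amps))
    r <- r + geom$amps[h] * cos((h + 1) * theta + geom$phases[h])
  m <- (rho <= r) * 1
  if (sum(m) == 0) return(m)
  shift <- top_row - top_tumor_row(m)
  if (shift != 0) {
    shifted <- matrix(0, H, W)
    src <- seq_len(H) - shift
    ok <- src >= 1 & src <= H
    shifted[which(ok), ] <- m[src[ok], ]
    m <- shifted
  }
  m
}

#' Generate one synthetic ultrasound phantom
#'
#' Produces a B-mode-like image and its exact tumor mask: a layered
#' soft-tissue background with slow gain inhomogeneity and residual depth
#' attenuation, a hypoechoic lesion (radially perturbed ellipse) whose top
#' sits at the sampled margin depth, and correlated multiplicative
#' Rayleigh speckle. Deterministic given `seed`.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed for this phantom.
#' @param geometry optional pre-sampled patient geometry (used internally to
#'   share geometry across a patient's images).
#' @param patient_id,image_id provenance labels.
#' @return list of class `phantom`: `image` ([us_image()]), `mask` (binary
#'   matrix), `meta` (sampled margin/diameter, domain).
#' @export
generate_phantom <- function(spec, seed = NULL, geometry = NULL,
                             patient_id = "p1", image_id = "p1_i1") {
  with_local_seed(seed, {
    geom <- if (is.null(geometry)) sample_geometry(spec)
            else jitter_geometry(geometry, spec)
    H <- spec$size[1]; W <- spec$size[2]
    tx <- spec$texture
    mask <- NULL
    for (try in 1:25) {
      top_row <- round(geom$margin_mm / spec$row_spacing_mm) + 1
      top_row <- min(max(top_row, 1), H - 4)
      m <- rasterize_lesion(geom, spec, top_row)
      if (sum(m) >= 4) { mask <- m; break }
      geom <- if (is.null(geometry)) sample_geometry(spec)
              else jitter_geometry(geometry, spec)
    }
    if (is.null(mask)) stop("lesion repeatedly sampled outside the field of view")
    depth_mm <- (seq_len(H) - 0.5) * spec$row_spacing_mm
    gain <- 1 + 0.12 * smooth_field(H, W, sigma = max(4, H / 16))
    echo <- 0.60 * gain * exp(-spec$attenuation_per_mm * depth_mm)  # recycles by row
    echo <- echo * (1 - (1 - tx$contrast) * mask)
    echo <- blur_zero_pad(echo, 0.8, edge = "replicate")  # soft lesion boundary
    ray <- sqrt(2 / pi) * sqrt(-2 * log(stats::runif(H * W)))
    ray <- matrix(ray, H, W)
    ray <- as.matrix(EBImage::gblur(ray, sigma = tx$speckle_blur))
    ray <- ray / mean(ray)
    img <- pmax(echo * (1 + tx$speckle_strength * (ray - 1)), 0)
    img <- img / stats::quantile(img, 0.999)
    img <- pmin(img, 1)
    structure(list(
      image = us_image(img, spec$row_spacing_mm, spec$col_spacing_mm,
                       patient_id = patient_id, image_id = image_id),
      mask = mask,
      meta = list(margin_mm = geom$margin_mm, diam_mm = geom$diam_mm,
                  top_row = top_tumor_row(mask), domain = spec$domain,
                  seed = seed)), class = "phantom")
  })
}

#' Generate a patient-wise split phantom dataset
#'
#' Draws `spec$n_patients` patients, 1-3 cross-sections each (shared lesion
#' geometry with re-scan jitter), and assigns whole patients to
#' train/validation/test so that image counts approximate
#' `spec$split_fractions` and no patient spans splits.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed for the whole dataset.
#' @return object of class `phantom_dataset`: list with `samples` (list of
#'   `phantom` objects each carrying `split`) and `manifest` (data.frame with
#'   `image_id`, `patient_id`, `split`, `margin_mm`, `domain`).
#' @export
generate_dataset <- function(spec, seed = 1) {
  if (spec$n_patients < 3)
    stop("too few patients to fill train/validation/test splits")
  with_local_seed(seed, {
    counts <- sample(seq(spec$images_per_patient[1], spec$images_per_patient[2]),
                     spec$n_patients, replace = TRUE)
    # patient-wise greedy assignment toward the target image proportions
    total <- sum(counts)
    target <- spec$split_fractions * total
    got <- c(train = 0, val = 0, test = 0)
    ord <- sample(spec$n_patients)
    split_of <- character(spec$n_patients)
    for (p in ord) {
      deficit <- target - got
      s <- names(which.max(deficit))
      split_of[p] <- s
      got[s] <- got[s] + counts[p]
    }
    # every split must hold at least one patient
    for (s in c("train", "val", "test")) {
      if (!any(split_of == s)) {
        donor_split <- names(which.max(table(split_of)))
        donor <- which(split_of == donor_split)
        split_of[donor[length(donor)]] <- s
      }
    }
    samples <- list()
    rows <- list()
    for (p in seq_len(spec$n_patients)) {
      pid <- sprintf("p%03d", p)
      geom <- sample_geometry(spec)
      for (i in seq_len(counts[p])) {
        iid <- sprintf("%s_i%d", pid, i)
        ph <- generate_phantom(spec, seed = NULL, geometry = geom,
                               patient_id = pid, image_id = iid)
        ph$split <- split_of[p]
        samples[[iid]] <- ph
        rows[[iid]] <- data.frame(image_id = iid, patient_id = pid,
                                  split = split_of[p],
                                  margin_mm = ph$meta$margin_mm,
                                  domain = spec$domain)
      }
    }
    structure(list(samples = samples,
                   manifest = do.call(rbind, c(rows, make.row.names = FALSE)),
                   spec = spec, seed = seed),
              class = "phantom_dataset")
  })
}

#' @export
print.phantom_dataset <- function(x, ...) {
  tab <- table(x$manifest$split)
  cat(sprintf("<phantom_dataset: %d images / %d patients (%s), domain %s>\n",
              nrow(x$manifest), length(unique(x$manifest$patient_id)),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              x$spec$domain))
  invisible(x)
}

# Subset of samples belonging to one split.
split_samples <- function(dataset, split) {
  Filter(function(s) identical(s$split, split), dataset$samples)
}

# 1-D Gaussian convolution matrix with zero-padding semantics.
gauss_conv_matrix <- function(n, sigma) {
  d <- outer(seq_len(n), seq_len(n), `-`)
  k <- exp(-d^2 / (2 * sigma^2))
  k / sum(exp(-(seq(-n, n))^2 / (2 * sigma^2)))
}

#' Construct a Dice/margin trade-off fixture
#'
#' Builds phantom masks paired with deliberately biased probability maps:
#' each map is the ground truth shifted *down* by a few rows (the simulated
#' model under-segments the shallow margin) and smeared anisotropically —
#' mildly in depth, strongly sideways. Only a low threshold reaches through
#' the faint vertical halo back up to the true top margin, but at such
#' thresholds the wide horizontal spill over-segments and the Dice drops;
#' the Dice-optimal threshold sits higher and still misses the top rows.
#' The Dice-optimal and margin-optimal thresholds therefore differ, which is
#' the operating-point trade-off the threshold sweep exposes.
#'
#' @param n number of images.
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @param shift_rows downward displacement of the simulated prediction (px).
#' @param blur_sigma_v,blur_sigma_h vertical / horizontal smear (px).
#' @return list with `truths` and `probs` lists.
#' @export
tradeoff_fixture <- function(n = 6, spec = phantom_spec(size = c(64, 64)),
                             seed = 1, shift_rows = 4, blur_sigma_v = 3,
                             blur_sigma_h = 10) {
  with_local_seed(seed, {
    truths <- list(); probs <- list()
    for (i in seq_len(n)) {
      ph <- generate_phantom(spec, seed = NULL)
      m <- ph$mask
      H <- nrow(m); W <- ncol(m)
      shifted <- matrix(0, H, W)
      src <- seq_len(H) - shift_rows
      ok <- src >= 1
      shifted[which(ok), ] <- m[src[ok], ]
      p <- gauss_conv_matrix(H, blur_sigma_v) %*% shifted %*%
        t(gauss_conv_matrix(W, blur_sigma_h))
      p <- p / max(p)
      truths[[i]] <- m
      probs[[i]] <- pmin(pmax(p, 0), 1)
    }
    list(truths = truths, probs = probs)
  })
}
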