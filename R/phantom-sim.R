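#' Tube-phantom geometry and attenuation calibration
#'
#' Describes a silicone tube immersed in water and filled with an iodine
#' dilution. Attenuation is linear in iodine concentration at the working
#' virtual monoenergetic level; the default calibration (silicone 500 HU,
#' 52 HU per mg I/mL) places the 9.25 mg I/mL dilution (481 HU) nearly
#' iso-attenuating with the tube wall, so that the wall-lumen transition
#' carries almost no contrast.
#'
#' @param inner_diameter_mm Inner (lumen) diameter in mm; the measured set is
#'   1-5 mm.
#' @param iodine_mg_ml Iodine concentration of the lumen filling in mg I/mL;
#'   the dilution series is 37.0, 18.5, 9.25, 4.63, 0.
#' @param wall_mm Wall thickness in mm (default 1).
#' @param hu_water Background water attenuation in HU (default 0).
#' @param hu_silicone Tube-wall attenuation in HU (calibrated default 500).
#' @param hu_per_mg_iodine Iodine attenuation slope in HU per mg I/mL at
#'   55 keV (calibrated default 52).
#' @param center_mm Tube centre `(x, y)` in mm relative to the image centre.
#' @return An object of class `phantom_spec`.
#' @export
#' @examples
#' phantom_spec(3, 37)
phantom_spec <- function(inner_diameter_mm, iodine_mg_ml, wall_mm = 1,
                         hu_water = 0, hu_silicone = 500,
                         hu_per_mg_iodine = 52, center_mm = c(0, 0)) {
  if (inner_diameter_mm <= 0) rlang::abort("inner_diameter_mm must be positive")
  if (wall_mm <= 0) rlang::abort("wall_mm must be positive")
  if (iodine_mg_ml < 0) rlang::abort("iodine_mg_ml must be non-negative")
  structure(
    list(inner_diameter_mm = inner_diameter_mm, wall_mm = wall_mm,
         iodine_mg_ml = iodine_mg_ml, hu_water = hu_water,
         hu_silicone = hu_silicone, hu_per_mg_iodine = hu_per_mg_iodine,
         center_mm = center_mm),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> tube d=%g mm, wall %g mm, %g mg I/mL (lumen %g HU, wall %g HU)\n",
    x$inner_diameter_mm, x$wall_mm, x$iodine_mg_ml,
    x$hu_water + x$iodine_mg_ml * x$hu_per_mg_iodine, x$hu_silicone))
  invisible(x)
}

#' Construct a CT slice object
#'
#' A `ct_slice` is a square matrix of attenuation values (HU) with an
#' isotropic pixel spacing and a provenance record.
#'
#' @param values Square numeric matrix, HU.
#' @param spacing_mm Pixel spacing in mm.
#' @param provenance Named list recording how the slice was made.
#' @return A `ct_slice` object.
#' @export
ct_slice <- function(values, spacing_mm = 0.4, provenance = list()) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) rlang::abort("slice must be square")
  if (spacing_mm <= 0) rlang::abort("spacing_mm must be positive")
  if (!all(is.finite(values))) rlang::abort("slice values must be finite")
  structure(list(values = values, spacing_mm = spacing_mm,
                 provenance = provenance),
            class = "ct_slice")
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice> %dx%d px, %.2f mm spacing, HU range [%.0f, %.0f]\n",
              nrow(x$values), ncol(x$values), x$spacing_mm,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.ct_slice <- function(x) dim(x$values)

# Pixel-centre coordinates (mm) along one axis for an n-pixel grid centred
# on the origin: for even n the centre falls between the two middle pixels.
.grid_coords <- function(n, spacing_mm) {
  (seq_len(n) - (n + 1) / 2) * spacing_mm
}

#' Render a noise-free tube-phantom slice
#'
#' Rasterises the concentric lumen/wall/water geometry onto a square pixel
#' grid. Pixels cut by a material boundary are area-weighted by supersampling
#' (`supersample^2` subsamples per pixel); pixels away from the boundaries
#' take their material value exactly, so the far field equals `hu_water`
#' bit-for-bit.
#'
#' @param phantom A [phantom_spec()].
#' @param n Grid size in pixels (default 512).
#' @param spacing_mm Pixel spacing in mm (default 0.4; the default
#'   field of view is 204.8 mm).
#' @param supersample Subsamples per pixel edge on boundary pixels
#'   (default 8).
#' @return A [ct_slice()].
#' @export
#' @examples
#' img <- rasterize_phantom(phantom_spec(3, 37), n = 64)
rasterize_phantom <- function(phantom, n = 512, spacing_mm = 0.4,
                              supersample = 8) {
  stopifnot(inherits(phantom, "phantom_spec"))
  r_in <- phantom$inner_diameter_mm / 2
  r_out <- r_in + phantom$wall_mm
  half_fov <- n * spacing_mm / 2
  if (r_out + max(abs(phantom$center_mm)) >= half_fov) {
    rlang::abort("tube does not fit inside the field of view")
  }
  hu_lumen <- phantom$hu_water + phantom$iodine_mg_ml * phantom$hu_per_mg_iodine
  co <- .grid_coords(n, spacing_mm)
  x <- outer(rep(1, n), co - phantom$center_mm[1])
  y <- outer(co - phantom$center_mm[2], rep(1, n))
  r <- sqrt(x^2 + y^2)

  vals <- matrix(phantom$hu_water, n, n)
  half_diag <- spacing_mm * sqrt(2) / 2
  vals[r < r_in - half_diag] <- hu_lumen
  vals[r >= r_in - half_diag & r < r_out - half_diag] <- phantom$hu_silicone

  # supersample the two boundary bands
  band <- which(abs(r - r_in) <= half_diag | abs(r - r_out) <= half_diag)
  if (length(band) > 0) {
    s <- supersample
    off <- ((seq_len(s) - 0.5) / s - 0.5) * spacing_mm
    sub <- expand.grid(dx = off, dy = off)
    bx <- x[band]
    by <- y[band]
    acc <- numeric(length(band))
    for (k in seq_len(nrow(sub))) {
      rr <- sqrt((bx + sub$dx[k])^2 + (by + sub$dy[k])^2)
      acc <- acc + ifelse(rr < r_in, hu_lumen,
                          ifelse(rr < r_out, phantom$hu_silicone,
                                 phantom$hu_water))
    }
    vals[band] <- acc / nrow(sub)
  }
  ct_slice(vals, spacing_mm,
           provenance = list(phantom = phantom, step = "rasterized"))
}

# Radial spatial-frequency grid (Lp/cm) for an n x n image with the given
# pixel spacing.
.freq_grid <- function(n, spacing_mm) {
  f <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1)) / (n * spacing_mm / 10)
  fx <- outer(rep(1, n), f)
  fy <- outer(f, rep(1, n))
  sqrt(fx^2 + fy^2)
}

#' Blur a slice with a reconstruction kernel's MTF
#'
#' Multiplies the image spectrum by the radially symmetric MTF. The zero-
#' frequency gain is exactly 1, so uniform images and the image mean are
#' preserved.
#'
#' @param image A [ct_slice()].
#' @param mtf An `mtf_curve` from [fit_mtf()].
#' @return A blurred [ct_slice()].
#' @export
apply_kernel <- function(image, mtf) {
  stopifnot(inherits(image, "ct_slice"), inherits(mtf, "mtf_curve"))
  n <- nrow(image$values)
  rho <- .freq_grid(n, image$spacing_mm)
  h <- mtf_eval(mtf, rho)
  out <- Re(stats::fft(stats::fft(image$values) * h, inverse = TRUE)) / n^2
  prov <- image$provenance
  prov$kernel <- mtf$kernel
  prov$step <- "blurred"
  ct_slice(out, image$spacing_mm, prov)
}

#' Add dose- and QIR-scaled reconstruction noise
#'
#' Adds a zero-mean stationary Gaussian field whose power spectrum follows
#' the ramp-filtered reconstruction-noise model
#' \eqn{P(\rho) \propto \rho \cdot MTF(\rho)^2}, rescaled so the field's
#' standard deviation equals the [noise_sd_model()] target for the kernel,
#' QIR level and dose. The same seed reproduces the same field bit for bit;
#' the global RNG state is left untouched.
#'
#' @param image A [ct_slice()] (typically the blurred phantom).
#' @param mtf `mtf_curve` shaping the noise spectrum.
#' @param acq An [acquisition_spec()].
#' @param seed Integer seed for the noise field.
#' @return A noisy [ct_slice()].
#' @export
add_noise <- function(image, mtf, acq, seed) {
  stopifnot(inherits(image, "ct_slice"), inherits(mtf, "mtf_curve"),
            inherits(acq, "acquisition_spec"))
  target_sd <- as.numeric(noise_sd_model(mtf$kernel, acq))
  stopifnot(target_sd > 0)
  n <- nrow(image$values)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  white <- matrix(stats::rnorm(n * n), n, n)
  rho <- .freq_grid(n, image$spacing_mm)
  amp <- sqrt(rho) * mtf_eval(mtf, rho)
  amp[1, 1] <- 0  # zero-mean field
  field <- Re(stats::fft(stats::fft(white) * amp, inverse = TRUE)) / n^2
  field <- field * (target_sd / stats::sd(as.vector(field)))
  prov <- image$provenance
  prov$acquisition <- acq
  prov$seed <- seed
  prov$target_noise_sd <- target_sd
  prov$step <- "noisy"
  ct_slice(image$values + field, image$spacing_mm, prov)
}

#' Simulate a complete phantom acquisition
#'
#' Composes [rasterize_phantom()], [apply_kernel()] and [add_noise()] into a
#' single seeded slice, recording full provenance. With `ctdi = Inf` the
#' noise step is skipped and the result is the noise-free blurred phantom.
#'
#' @param phantom A [phantom_spec()].
#' @param kernel A [kernel_spec()].
#' @param acq An [acquisition_spec()]; `acq$ctdi = Inf` means noise-free.
#' @param seed Integer seed (ignored when noise-free).
#' @param n Grid size in pixels (default 512).
#' @return A [ct_slice()].
#' @export
#' @examples
#' img <- simulate_slice(phantom_spec(3, 37), kernel_spec("Qr60"),
#'                       acquisition_spec(30, qir_level = 4), seed = 1)
simulate_slice <- function(phantom, kernel, acq, seed = 1L, n = 512) {
  stopifnot(inherits(acq, "acquisition_spec"))
  mtf <- fit_mtf(kernel)
  img <- rasterize_phantom(phantom, n = n, spacing_mm = acq$voxel_mm)
  img <- apply_kernel(img, mtf)
  if (is.finite(acq$ctdi)) {
    img <- add_noise(img, mtf, acq, seed)
  } else {
    img$provenance$acquisition <- acq
    img$provenance$step <- "noise-free"
  }
  img
}

#' Write a slice as 32-bit TIFF with a provenance manifest row
#'
#' @param image A [ct_slice()].
#' @param path Output TIFF path.
#' @param manifest Optional CSV path; a one-row provenance record (phantom,
#'   kernel, acquisition, seed) is appended there.
#' @return `path`, invisibly.
#' @export
write_slice_tiff <- function(image, path, manifest = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    rlang::abort("the 'tiff' package is required for TIFF export")
  }
  # 32-bit float TIFF keeps HU values intact
  tiff::writeTIFF(image$values, path, bits.per.sample = 32L)
  if (!is.null(manifest)) {
    p <- image$provenance
    row <- tibble::tibble(
      file = path,
      spacing_mm = image$spacing_mm,
      inner_diameter_mm = p$phantom$inner_diameter_mm %||% NA_real_,
      iodine_mg_ml = p$phantom$iodine_mg_ml %||% NA_real_,
      kernel = p$kernel$name %||% NA_character_,
      qir_level = p$acquisition$qir_level %||% NA_integer_,
      ctdi_mgy = p$acquisition$ctdi %||% NA_real_,
      seed = p$seed %||% NA_integer_
    )
    utils::write.table(row, manifest, sep = ",", row.names = FALSE,
                       col.names = !file.exists(manifest), append = file.exists(manifest))
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
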