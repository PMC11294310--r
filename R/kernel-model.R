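#' Reconstruction kernel characteristics
#'
#' Returns the table of quantitative reconstruction kernels (sharpness levels
#' 36-76) with their MTF anchor frequencies and the measured maximum edge
#' slopes for the reference condition (5 mm tube, 37 mg I/mL, 3 mGy, QIR-4).
#' `rho50` and `rho10` are the spatial frequencies (Lp/cm) at which the
#' modulation transfer function falls to 50% and 10% of its zero-frequency
#' value.
#'
#' @return A tibble with columns `name`, `sharpness`, `rho50_lp_per_cm`,
#'   `rho10_lp_per_cm`, `max_slope_hu_per_mm`, `rel_diff_pct`.
#' @export
#' @examples
#' kernel_table()
kernel_table <- function() {
  path <- system.file("extdata", "kernel_table.csv", package = "ctiq",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Define a reconstruction kernel by its MTF anchors
#'
#' A kernel is characterised by the two spatial frequencies at which its MTF
#' drops to 50% (`rho50`) and 10% (`rho10`). Named kernels from
#' [kernel_table()] can be looked up by label.
#'
#' @param name Kernel label, e.g. `"Qr60"`. If it matches a row of
#'   [kernel_table()] and `rho50`/`rho10` are missing, the anchors are taken
#'   from the table.
#' @param rho50,rho10 MTF anchor frequencies in Lp/cm; `rho10 > rho50 > 0`.
#' @param sharpness Integer sharpness level (36-76 for the calibrated set).
#'   Parsed from `name` when it follows the `Qr<level>` convention.
#' @return An object of class `kernel_spec`.
#' @export
#' @examples
#' kernel_spec("Qr60")
#' kernel_spec("custom", rho50 = 5, rho10 = 10, sharpness = 50)
kernel_spec <- function(name, rho50 = NULL, rho10 = NULL, sharpness = NULL) {
  if (is.null(rho50) || is.null(rho10)) {
    tab <- kernel_table()
    row <- tab[tab$name == name, ]
    if (nrow(row) != 1L) {
      rlang::abort(paste0("unknown kernel '", name,
                          "'; supply rho50 and rho10 explicitly"))
    }
    rho50 <- row$rho50_lp_per_cm
    rho10 <- row$rho10_lp_per_cm
    if (is.null(sharpness)) sharpness <- row$sharpness
  }
  if (is.null(sharpness)) {
    parsed <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", name)))
    sharpness <- if (is.na(parsed)) NA_integer_ else parsed
  }
  if (!is.numeric(rho50) || !is.numeric(rho10) || rho50 <= 0 ||
      rho10 <= rho50) {
    rlang::abort("invalid kernel: need rho10 > rho50 > 0")
  }
  structure(
    list(name = name, sharpness = as.integer(sharpness),
         rho50 = as.numeric(rho50), rho10 = as.numeric(rho10)),
    class = "kernel_spec"
  )
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec> %s (sharpness %s): rho50 = %.1f, rho10 = %.1f Lp/cm\n",
              x$name, x$sharpness, x$rho50, x$rho10))
  invisible(x)
}

#' Fit a continuous MTF through the two anchor frequencies
#'
#' Fits the two-parameter generalised-Gaussian family
#' \deqn{MTF(\rho) = \exp\{-(\rho/a)^b\}}
#' through the anchors \eqn{MTF(\rho_{50}) = 0.5} and
#' \eqn{MTF(\rho_{10}) = 0.1}. The solution is closed-form:
#' \eqn{b = \log(\log 10 / \log 2) / \log(\rho_{10}/\rho_{50})} and
#' \eqn{a = \rho_{50} / (\log 2)^{1/b}}. The family is strictly decreasing
#' for \eqn{\rho > 0} and normalised to 1 at zero frequency.
#'
#' @param kernel A [kernel_spec()].
#' @return An object of class `mtf_curve`: a list with parameters `a` (Lp/cm)
#'   and `b` (dimensionless), the source kernel, and callable via
#'   [mtf_eval()].
#' @export
#' @examples
#' m <- fit_mtf(kernel_spec("Qr60"))
#' mtf_eval(m, c(0, 8.8, 11.2))
fit_mtf <- function(kernel) {
  stopifnot(inherits(kernel, "kernel_spec"))
  b <- log(log(10) / log(2)) / log(kernel$rho10 / kernel$rho50)
  a <- kernel$rho50 / (log(2))^(1 / b)
  structure(list(a = a, b = b, kernel = kernel), class = "mtf_curve")
}

#' Evaluate an MTF curve
#'
#' @param mtf An `mtf_curve` from [fit_mtf()].
#' @param rho Spatial frequencies in Lp/cm (vectorised, `rho >= 0`).
#' @return MTF values in (0, 1]; `mtf_eval(mtf, 0)` is exactly 1.
#' @export
mtf_eval <- function(mtf, rho) {
  stopifnot(inherits(mtf, "mtf_curve"))
  exp(-(rho / mtf$a)^mtf$b)
}

#' @export
print.mtf_curve <- function(x, ...) {
  cat(sprintf("<mtf_curve> %s: exp(-(rho/%.4f)^%.4f)\n",
              x$kernel$name, x$a, x$b))
  invisible(x)
}

#' Nyquist frequency of an isotropic reconstruction grid
#'
#' The voxel edge length fixes the maximum spatial frequency representable in
#' the reconstruction: \eqn{\rho_{max} = 1 / (2 \Delta x)} with \eqn{\Delta x}
#' in cm. At the default 0.4 mm voxel this is 12.5 Lp/cm.
#'
#' @param voxel_mm Voxel edge length in mm (> 0).
#' @return Nyquist frequency in Lp/cm.
#' @export
#' @examples
#' nyquist_frequency(0.4)  # 12.5
nyquist_frequency <- function(voxel_mm) {
  if (!is.numeric(voxel_mm) || any(voxel_mm <= 0)) {
    rlang::abort("voxel_mm must be positive")
  }
  1 / (2 * voxel_mm / 10)
}

#' Acquisition settings for a simulated scan
#'
#' @param ctdi CT dose index in mGy (> 0). `Inf` is accepted and means a
#'   noise-free acquisition.
#' @param qir_level Iterative-reconstruction strength, one of 2, 3, 4.
#' @param voxel_mm Isotropic voxel edge length in mm (default 0.4).
#' @param kev_label Virtual monoenergetic level in keV; metadata only.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(ctdi, qir_level = 3, voxel_mm = 0.4,
                             kev_label = 55) {
  if (!is.numeric(ctdi) || length(ctdi) != 1L || ctdi <= 0) {
    rlang::abort("ctdi must be a single positive number (mGy)")
  }
  if (!qir_level %in% c(2L, 3L, 4L)) {
    rlang::abort("qir_level must be 2, 3 or 4")
  }
  if (voxel_mm <= 0) rlang::abort("voxel_mm must be positive")
  structure(
    list(ctdi = as.numeric(ctdi), qir_level = as.integer(qir_level),
         voxel_mm = as.numeric(voxel_mm), kev_label = kev_label),
    class = "acquisition_spec"
  )
}

# Background-noise calibration anchors: measured SD (HU) at QIR-3 and 3 mGy
# for three kernels; other sharpness levels by log-linear interpolation.
.noise_anchors <- function() {
  tibble::tibble(sharpness = c(44L, 60L, 72L), sd_hu = c(16, 38, 77))
}

# QIR strength rescales noise by the measured Qr60 ratios (QIR-3 = 1).
.qir_factor <- function(qir_level) {
  c(`2` = 51 / 38, `3` = 1, `4` = 25 / 38)[[as.character(qir_level)]]
}

#' Predicted background noise for a kernel/dose/QIR combination
#'
#' Noise SD is anchored at measured values for three kernels (Qr44 = 16 HU,
#' Qr60 = 38 HU, Qr72 = 77 HU at QIR-3 and 3 mGy), interpolated log-linearly
#' in sharpness level between the anchors, multiplied by the QIR strength
#' ratio measured at Qr60 (51/38, 1, 25/38 for QIR-2/3/4) and scaled with
#' dose by the quantum-noise law \eqn{\sqrt{3\,\mathrm{mGy}/\mathrm{CTDI}}}.
#'
#' @param kernel A [kernel_spec()] with a sharpness level.
#' @param acq An [acquisition_spec()].
#' @return Noise SD in HU, with attribute `extrapolated = TRUE` when the
#'   sharpness level lies outside the calibrated 36-76 range.
#' @export
#' @examples
#' noise_sd_model(kernel_spec("Qr60"), acquisition_spec(3, qir_level = 3))  # 38
noise_sd_model <- function(kernel, acq) {
  stopifnot(inherits(kernel, "kernel_spec"), inherits(acq, "acquisition_spec"))
  s <- kernel$sharpness
  if (is.na(s)) rlang::abort("kernel has no sharpness level; cannot calibrate noise")
  anchors <- .noise_anchors()
  log_sd <- stats::approx(anchors$sharpness, log(anchors$sd_hu), xout = s,
                          rule = 2)$y
  # linear extension of the nearest segment outside the anchor span
  if (s < min(anchors$sharpness) || s > max(anchors$sharpness)) {
    fit_pts <- if (s < min(anchors$sharpness)) 1:2 else 2:3
    slope <- diff(log(anchors$sd_hu[fit_pts])) / diff(anchors$sharpness[fit_pts])
    ref <- if (s < min(anchors$sharpness)) 1L else 3L
    log_sd <- log(anchors$sd_hu[ref]) + slope * (s - anchors$sharpness[ref])
  }
  sd <- exp(log_sd) * .qir_factor(acq$qir_level) * sqrt(3 / acq$ctdi)
  if (s < 36L || s > 76L) {
    attr(sd, "extrapolated") <- TRUE
  }
  sd
}

#' Relative difference of an edge slope to a reference slope
#'
#' @param slope_value Slope in HU/mm.
#' @param reference_slope Reference slope in HU/mm (> 0).
#' @param round_pct Round to integer percent (half away from zero), as used
#'   for reporting. Default `TRUE`.
#' @return Percent difference `100 * (slope - reference) / reference`.
#' @export
#' @examples
#' relative_slope_difference(900, 1690)  # -47
relative_slope_difference <- function(slope_value, reference_slope,
                                      round_pct = TRUE) {
  if (any(reference_slope <= 0)) {
    rlang::abort("reference_slope must be positive")
  }
  pct <- 100 * (slope_value - reference_slope) / reference_slope
  if (round_pct) sign(pct) * floor(abs(pct) + 0.5) else pct
}
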