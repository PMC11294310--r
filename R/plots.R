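#' Plot fitted MTF curves
#'
#' Draws the fitted MTF of one or more kernels over 0 to `rho_max` Lp/cm,
#' with the anchor points and the grid Nyquist frequency marked.
#'
#' @param kernels Character vector of kernel names or list of
#'   [kernel_spec()] objects.
#' @param rho_max Upper frequency limit, Lp/cm (default 20).
#' @param voxel_mm Voxel size whose Nyquist frequency is drawn (default 0.4).
#' @return A ggplot object.
#' @export
plot_mtf <- function(kernels = c("Qr36", "Qr44", "Qr60", "Qr76"),
                     rho_max = 20, voxel_mm = 0.4) {
  specs <- purrr::map(kernels, function(k) {
    if (inherits(k, "kernel_spec")) k else kernel_spec(k)
  })
  rho <- seq(0, rho_max, length.out = 400)
  curves <- purrr::map_dfr(specs, function(k) {
    tibble::tibble(kernel = k$name, rho = rho,
                   mtf = mtf_eval(fit_mtf(k), rho))
  })
  anchors <- purrr::map_dfr(specs, function(k) {
    tibble::tibble(kernel = k$name, rho = c(k$rho50, k$rho10),
                   mtf = c(0.5, 0.1))
  })
  ggplot2::ggplot(curves, ggplot2::aes(.data$rho, .data$mtf,
                                       colour = .data$kernel)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = anchors) +
    ggplot2::geom_vline(xintercept = nyquist_frequency(voxel_mm),
                        linetype = "dashed") +
    ggplot2::labs(x = "Spatial frequency (Lp/cm)", y = "MTF",
                  colour = "Kernel") +
    ggplot2::theme_minimal()
}

#' Plot the edge profiles and slope curves of a slope analysis
#'
#' Upper panel: horizontal and vertical attenuation profiles. Lower panel:
#' their three-point slope curves with the detected transition maxima marked
#' (filled when visible).
#'
#' @param object A `slope_analysis` from [analyze_image()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.slope_analysis <- function(object, ...) {
  prof <- dplyr::mutate(object$profiles, panel = "profile (HU)")
  slopes <- object$slopes |>
    dplyr::mutate(panel = "slope (HU/mm)") |>
    dplyr::rename(hu = "slope_hu_mm")
  marks <- object$transitions |>
    dplyr::filter(!is.na(.data$position_mm)) |>
    dplyr::mutate(panel = "slope (HU/mm)")
  ggplot2::ggplot(dplyr::bind_rows(prof, slopes),
                  ggplot2::aes(.data$position_mm, .data$hu)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = marks,
                        ggplot2::aes(y = .data$slope_hu_mm,
                                     shape = .data$visible),
                        size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::facet_grid(panel ~ direction, scales = "free_y") +
    ggplot2::labs(x = "Position (mm)", y = NULL, shape = "Visible") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot noise across a sweep
#'
#' Median background noise versus kernel sharpness, coloured by QIR level
#' and faceted by dose — the standard view of how kernel sharpness, the
#' iterative-reconstruction strength and dose drive image noise.
#'
#' @param result A [run_sweep()] tibble.
#' @return A ggplot object.
#' @export
plot_noise_sweep <- function(result) {
  tab <- kernel_table()[, c("name", "sharpness")]
  d <- result |>
    dplyr::left_join(tab, by = c(kernel = "name")) |>
    dplyr::group_by(.data$sharpness, .data$qir_level, .data$ctdi_mgy) |>
    dplyr::summarise(noise_sd = stats::median(.data$noise_sd, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$sharpness, .data$noise_sd,
                                  colour = factor(.data$qir_level))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~ .data$ctdi_mgy, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Kernel sharpness level", y = "Noise SD (HU)",
                  colour = "QIR level") +
    ggplot2::theme_minimal()
}

#' Display a simulated slice
#'
#' @param x A [ct_slice()].
#' @param window HU display window `c(level, width)` (default angiography
#'   window, level 300 width 1100).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ct_slice <- function(x, window = c(300, 1100), ...) {
  n <- nrow(x$values)
  co <- .grid_coords(n, x$spacing_mm)
  d <- tidyr::expand_grid(y = co, x_mm = co)
  d$hu <- as.vector(t(x$values))
  lo <- window[1] - window[2] / 2
  hi <- window[1] + window[2] / 2
  ggplot2::ggplot(d, ggplot2::aes(.data$x_mm, .data$y, fill = .data$hu)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(lo, hi), oob = scales_squish) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "mm", y = "mm", fill = "HU") +
    ggplot2::theme_minimal()
}

# minimal squish so we do not depend on the scales package directly
scales_squish <- function(x, range = c(0, 1), only.finite = TRUE) {
  pmin(pmax(x, range[1]), range[2])
}
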