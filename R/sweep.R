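#' Configure a factorial simulation sweep
#'
#' Builds the factorial design over kernels, QIR levels, doses, tube
#' diameters, iodine concentrations and seeds. The default configuration is
#' a desk-scale subsample of the full measured grid (10 kernels x 3 QIR x 6
#' doses x 5 diameters x 5 concentrations); pass `full_grid = TRUE` for the
#' complete design.
#'
#' @param kernels Character vector of kernel names from [kernel_table()].
#' @param qir_levels Subset of `c(2, 3, 4)`.
#' @param ctdis Dose levels, mGy.
#' @param diameters_mm Tube inner diameters, mm.
#' @param concentrations_mg_ml Iodine concentrations, mg I/mL.
#' @param seeds Distinct integer seeds; each design cell is simulated once
#'   per seed.
#' @param full_grid Use the complete measured factorial instead of the
#'   defaults.
#' @param cache_dir Optional directory; per-cell results are stored as CSV
#'   keyed by the cell signature and reused on rerun.
#' @return A `sweep_config` list.
#' @export
sweep_config <- function(kernels = c("Qr44", "Qr60", "Qr72"),
                         qir_levels = c(2, 3, 4),
                         ctdis = c(3, 30),
                         diameters_mm = c(2, 5),
                         concentrations_mg_ml = c(0, 9.25, 37),
                         seeds = 1:5,
                         full_grid = FALSE,
                         cache_dir = NULL) {
  if (full_grid) {
    kernels <- kernel_table()$name
    qir_levels <- c(2, 3, 4)
    ctdis <- c(1, 2, 3, 4, 10, 30)
    diameters_mm <- 1:5
    concentrations_mg_ml <- c(0, 4.63, 9.25, 18.5, 37)
  }
  stopifnot(length(kernels) > 0, length(qir_levels) > 0, length(ctdis) > 0,
            length(diameters_mm) > 0, length(concentrations_mg_ml) > 0,
            length(seeds) > 0, !anyDuplicated(seeds))
  structure(
    list(kernels = kernels, qir_levels = qir_levels, ctdis = ctdis,
         diameters_mm = diameters_mm,
         concentrations_mg_ml = concentrations_mg_ml,
         seeds = as.integer(seeds), cache_dir = cache_dir),
    class = "sweep_config"
  )
}

.cell_key <- function(kernel, qir, ctdi, diameter, concentration, seed) {
  sprintf("%s_q%d_d%gmGy_%gmm_%gmg_s%d", kernel, qir, ctdi, diameter,
          concentration, seed)
}

#' Run a factorial simulation sweep
#'
#' Simulates and analyses one slice per design cell and seed, returning a
#' long-format tibble (one row per cell x seed) with the four per-image
#' metrics. Deterministic given the seeds. When the config has a
#' `cache_dir`, finished cells are written there as one-row CSVs and skipped
#' on rerun; per-cell failures are recorded in the `error` column rather
#' than aborting the sweep.
#'
#' @param config A [sweep_config()].
#' @param n Grid size in pixels passed to [simulate_slice()] (default 512).
#' @return A tibble with columns `kernel`, `qir_level`, `ctdi_mgy`,
#'   `diameter_mm`, `concentration_mg_ml`, `seed`, `noise_sd`, `amplitude`,
#'   `mean_slope_maximum`, `slope_score`, `error`.
#' @export
#' @examples
#' cfg <- sweep_config(kernels = "Qr60", qir_levels = 3, ctdis = 3,
#'                     diameters_mm = 3, concentrations_mg_ml = 37,
#'                     seeds = 1)
#' run_sweep(cfg, n = 256)
run_sweep <- function(config, n = 512) {
  stopifnot(inherits(config, "sweep_config"))
  design <- tidyr::expand_grid(
    kernel = config$kernels, qir_level = config$qir_levels,
    ctdi_mgy = config$ctdis, diameter_mm = config$diameters_mm,
    concentration_mg_ml = config$concentrations_mg_ml, seed = config$seeds
  )
  run_cell <- function(kernel, qir_level, ctdi_mgy, diameter_mm,
                       concentration_mg_ml, seed) {
    key <- .cell_key(kernel, qir_level, ctdi_mgy, diameter_mm,
                     concentration_mg_ml, seed)
    cache_file <- if (!is.null(config$cache_dir))
      file.path(config$cache_dir, paste0(key, ".csv")) else NULL
    if (!is.null(cache_file) && file.exists(cache_file)) {
      return(tibble::as_tibble(utils::read.csv(
        cache_file,
        colClasses = c(slope_score = "integer", error = "character"))))
    }
    out <- tryCatch({
      ph <- phantom_spec(diameter_mm, concentration_mg_ml)
      img <- simulate_slice(ph, kernel_spec(kernel),
                            acquisition_spec(ctdi_mgy, qir_level = qir_level),
                            seed = seed, n = n)
      g <- glance(analyze_image(img, ph))
      dplyr::mutate(g, error = NA_character_)
    }, error = function(e) {
      tibble::tibble(noise_sd = NA_real_, amplitude = NA_real_,
                     mean_slope_maximum = NA_real_, slope_score = NA_integer_,
                     error = conditionMessage(e))
    })
    if (!is.null(cache_file)) {
      dir.create(dirname(cache_file), showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(out, cache_file, row.names = FALSE)
    }
    out
  }
  metrics <- purrr::pmap(design, run_cell)
  dplyr::bind_cols(design, dplyr::bind_rows(metrics))
}

#' Kernel plateau summary of maximum slopes
#'
#' Summarises per-kernel mean slope maxima, their relative difference to a
#' reference kernel, and which kernels lie within a threshold of the
#' reference — the "sharpness plateau" (kernels at sharpness 60 and above
#' differ from the sharpest kernel by less than 10% in the reference
#' measurement).
#'
#' @param data Tibble with columns `kernel` and a slope column (default
#'   `mean_slope_maximum`), e.g. a [run_sweep()] result or [kernel_table()]
#'   renamed.
#' @param reference_kernel Reference kernel label (must be present).
#' @param threshold_pct Plateau threshold in percent (default 10).
#' @param slope_col Name of the slope column.
#' @return A list with `per_kernel` (tibble: kernel, mean slope, relative
#'   difference in percent) and `plateau_kernels` (labels within
#'   `threshold_pct` of the reference).
#' @export
#' @examples
#' tab <- dplyr::rename(kernel_table(), kernel = name,
#'                      mean_slope_maximum = max_slope_hu_per_mm)
#' plateau_summary(tab, "Qr76")
plateau_summary <- function(data, reference_kernel, threshold_pct = 10,
                            slope_col = "mean_slope_maximum") {
  if (!reference_kernel %in% data$kernel) {
    rlang::abort(paste0("reference kernel '", reference_kernel,
                        "' not present in data"))
  }
  per_kernel <- data |>
    dplyr::group_by(.data$kernel) |>
    dplyr::summarise(mean_slope = mean(.data[[slope_col]], na.rm = TRUE),
                     .groups = "drop")
  ref <- per_kernel$mean_slope[per_kernel$kernel == reference_kernel]
  per_kernel <- per_kernel |>
    dplyr::mutate(
      rel_diff_pct = relative_slope_difference(.data$mean_slope, ref,
                                               round_pct = FALSE)
    )
  list(
    per_kernel = per_kernel,
    reference_kernel = reference_kernel,
    plateau_kernels =
      per_kernel$kernel[abs(per_kernel$rel_diff_pct) < threshold_pct]
  )
}

#' Slope-score grids by dose
#'
#' Pivots a sweep result into per-dose score matrices: for each CTDI, a grid
#' of median slope score (across seeds) by reconstruction (kernel x QIR
#' level) and phantom cell (diameter x concentration).
#'
#' @param result A [run_sweep()] tibble.
#' @param out_dir Optional directory; one CSV per dose is written there.
#' @return A named list of tibbles, one per CTDI, in wide format with a
#'   `kernel`/`qir_level` row key and one column per
#'   diameter-concentration combination.
#' @export
score_grid <- function(result, out_dir = NULL) {
  grids <- result |>
    dplyr::group_by(.data$ctdi_mgy, .data$kernel, .data$qir_level,
                    .data$diameter_mm, .data$concentration_mg_ml) |>
    dplyr::summarise(score = stats::median(.data$slope_score, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(cell = paste0("d", .data$diameter_mm, "_c",
                                .data$concentration_mg_ml)) |>
    dplyr::select(-"diameter_mm", -"concentration_mg_ml") |>
    tidyr::pivot_wider(names_from = "cell", values_from = "score") |>
    dplyr::group_split(.data$ctdi_mgy)
  names(grids) <- purrr::map_chr(grids, ~ paste0("ctdi_", .x$ctdi_mgy[1]))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    purrr::iwalk(grids, function(g, nm) {
      utils::write.csv(g, file.path(out_dir, paste0("score_grid_", nm, ".csv")),
                       row.names = FALSE)
    })
  }
  grids
}
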