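#' Centered crop of a slice
#'
#' Returns the centered `size` x `size` sub-grid. The image size and crop
#' size must have the same parity so the crop shares the image centre; a
#' parity mismatch would silently shift the grid by half a pixel and is
#' rejected.
#'
#' @param image A [ct_slice()].
#' @param size Crop edge length in pixels.
#' @return A [ct_slice()] of the requested size.
#' @export
#' @examples
#' img <- rasterize_phantom(phantom_spec(3, 37), n = 512)
#' crop_center(img, 128)
crop_center <- function(image, size) {
  stopifnot(inherits(image, "ct_slice"))
  n <- nrow(image$values)
  if (size > n) rlang::abort("crop size exceeds image size")
  if ((n - size) %% 2L != 0L) {
    rlang::abort("crop size parity does not match image size; refuse off-center crop")
  }
  off <- (n - size) / 2
  idx <- seq.int(off + 1L, off + size)
  ct_slice(image$values[idx, idx, drop = FALSE], image$spacing_mm,
           image$provenance)
}

#' Background noise from corner water ROIs
#'
#' On the 128 x 128 centered crop, the noise level is the sample standard
#' deviation (n - 1 denominator) of the water attenuation in the two 44 x 44
#' regions in the bottom-left and bottom-right corners, combined as the
#' arithmetic mean of the two SDs.
#'
#' @param image128 A [ct_slice()], conventionally the 128 x 128 crop.
#' @param roi_size ROI edge length in pixels (default 44).
#' @return Noise SD in HU.
#' @export
estimate_noise <- function(image128, roi_size = 44) {
  stopifnot(inherits(image128, "ct_slice"))
  v <- image128$values
  n <- nrow(v)
  if (roi_size > n) rlang::abort("ROI larger than image")
  rows <- seq.int(n - roi_size + 1L, n)
  sd_left <- stats::sd(v[rows, seq_len(roi_size)])
  sd_right <- stats::sd(v[rows, seq.int(n - roi_size + 1L, n)])
  (sd_left + sd_right) / 2
}

#' Horizontal and vertical edge profiles
#'
#' On the 64 x 64 crop centered on the tube, the horizontal profile is the
#' mean of the four central rows and the vertical profile the mean of the
#' four central columns (a 4-pixel averaging band perpendicular to the
#' profile direction; with an even grid the band straddles the midline).
#' Positions are in mm relative to the image centre.
#'
#' @param image64 A [ct_slice()], conventionally the 64 x 64 crop.
#' @param band_width Averaging band width in pixels (default 4).
#' @return A tibble with columns `direction` (`"horizontal"`/`"vertical"`),
#'   `position_mm` and `hu`.
#' @export
extract_profiles <- function(image64, band_width = 4) {
  stopifnot(inherits(image64, "ct_slice"))
  v <- image64$values
  n <- nrow(v)
  mid <- n / 2
  band <- seq.int(mid - band_width / 2 + 1L, mid + band_width / 2)
  pos <- .grid_coords(n, image64$spacing_mm)
  dplyr::bind_rows(
    tibble::tibble(direction = "horizontal", position_mm = pos,
                   hu = colMeans(v[band, , drop = FALSE])),
    tibble::tibble(direction = "vertical", position_mm = pos,
                   hu = rowMeans(v[, band, drop = FALSE]))
  )
}

#' Profile amplitude above the water background
#'
#' The amplitude is the mean over the two profiles of the profile maximum
#' minus the local water background, the background being estimated from the
#' outer `edge_points` positions at each end of the profile.
#'
#' @param profiles Tibble from [extract_profiles()].
#' @param edge_points Background points per profile end (default 8).
#' @return Amplitude in HU.
#' @export
profile_amplitude <- function(profiles, edge_points = 8) {
  per_dir <- profiles |>
    dplyr::group_by(.data$direction) |>
    dplyr::summarise(
      amp = max(.data$hu) -
        mean(c(utils::head(.data$hu, edge_points),
               utils::tail(.data$hu, edge_points))),
      .groups = "drop"
    )
  mean(per_dir$amp)
}

#' Three-point regression slope along a profile
#'
#' The slope at each interior point is the least-squares slope of the three
#' neighbouring points, which for uniformly spaced samples reduces to the
#' central difference `(y[i+1] - y[i-1]) / (2h)`. Endpoints have no slope, so
#' the curve is two points shorter than the profile.
#'
#' @param position_mm Uniformly spaced positions, mm.
#' @param hu Attenuation values, HU.
#' @return A tibble with `position_mm` (interior points) and `slope_hu_mm`.
#' @export
#' @examples
#' slope_curve(c(0, 0.4, 0.8), c(0, 0, 6))  # 7.5 HU/mm at the middle point
slope_curve <- function(position_mm, hu) {
  k <- length(hu)
  if (k < 3L) rlang::abort("profile must have at least 3 points")
  h <- diff(position_mm)
  if (max(abs(h - h[1])) > 1e-9 * abs(h[1])) {
    rlang::abort("positions must be uniformly spaced")
  }
  i <- seq.int(2L, k - 1L)
  tibble::tibble(
    position_mm = position_mm[i],
    slope_hu_mm = (hu[i + 1L] - hu[i - 1L]) / (2 * h[1])
  )
}

# Indices of local maxima of x (plateaus count once, at their first index).
.local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer())
  idx <- integer()
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j <= n - 1L && x[j + 1L] < x[j]) idx <- c(idx, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  idx
}

# Noise SD propagated from pixel noise to the slope curve under a white-noise
# assumption: band averaging of w pixels divides SD by sqrt(w); the central
# difference of two such independent samples spaced 2h apart gives
# sd * sqrt(2) / (sqrt(w) * 2h) = sd / (2h * sqrt(w / 2)). Used as fallback
# when the slope noise cannot be measured; CT noise is spatially correlated,
# so prefer estimate_slope_noise().
.slope_noise_sd <- function(noise_sd, spacing_mm, band_width = 4) {
  noise_sd / (2 * spacing_mm * sqrt(band_width / 2))
}

#' Noise level of the slope curve, measured in the background ROIs
#'
#' Reconstruction noise is spatially correlated, so the noise on the slope
#' curve cannot be obtained from the pixel SD by white-noise error
#' propagation. Instead, the exact measurement chain (4-pixel band
#' averaging followed by the three-point slope) is applied to the water
#' background in the same two bottom-corner ROIs used by [estimate_noise()],
#' and the SD of the resulting slope samples is returned. On white noise
#' this agrees with the closed-form propagation
#' `noise_sd / (2h * sqrt(band_width / 2))`.
#'
#' @param image128 A [ct_slice()], conventionally the 128 x 128 crop.
#' @param roi_size Corner ROI edge length in pixels (default 44).
#' @param band_width Averaging band width in pixels (default 4).
#' @return SD of the background slope samples, HU/mm.
#' @export
estimate_slope_noise <- function(image128, roi_size = 44, band_width = 4) {
  stopifnot(inherits(image128, "ct_slice"))
  v <- image128$values
  n <- nrow(v)
  h <- image128$spacing_mm
  rows <- seq.int(n - roi_size + 1L, n)
  samples <- unlist(lapply(list(seq_len(roi_size), seq.int(n - roi_size + 1L, n)),
                           function(cols) {
    roi <- v[rows, cols, drop = FALSE]
    n_bands <- floor(roi_size / band_width)
    unlist(lapply(seq_len(n_bands), function(b) {
      band <- roi[seq.int((b - 1L) * band_width + 1L, b * band_width), ,
                  drop = FALSE]
      prof <- colMeans(band)
      (prof[3:roi_size] - prof[1:(roi_size - 2L)]) / (2 * h)
    }))
  }))
  stats::sd(samples)
}

#' Locate and grade the tube-edge slope maxima
#'
#' For each profile the tube cross-section offers four attenuation
#' transitions: water-to-wall (outer) and wall-to-lumen (inner) on both
#' sides. Each transition is assigned the strongest local maximum of
#' `|slope|` lying within `window_mm` of its nominal boundary radius, with
#' each local maximum claimable by only its nearest nominal boundary (so a
#' single merged peak cannot be counted twice). A transition is *visible*
#' when it owns a distinct local maximum whose `|slope|` exceeds
#' `c_vis * sigma_slope`, where `sigma_slope` propagates the background
#' pixel noise through the band averaging and the central-difference
#' operator. The per-transition slope magnitude (for the mean slope maximum)
#' falls back to the largest `|slope|` in the window when no distinct local
#' maximum exists there.
#'
#' @param slopes Tibble from [slope_curve()] for one profile.
#' @param phantom A [phantom_spec()] giving the nominal boundary radii.
#' @param noise_sd Background noise SD in HU (from [estimate_noise()]).
#' @param spacing_mm Pixel spacing, mm.
#' @param window_mm Half-width of the search window around each nominal
#'   boundary (default 0.8 mm, i.e. two pixels).
#' @param c_vis Visibility threshold in units of `sigma_slope` (default 2).
#' @param band_width Averaging band width used for the profile (default 4).
#' @param slope_noise_sd Measured noise SD of the slope curve in HU/mm (from
#'   [estimate_slope_noise()]); when `NULL`, falls back to white-noise
#'   propagation of `noise_sd`.
#' @return A tibble with one row per transition: `side` (`left`/`right`),
#'   `boundary` (`outer`/`inner`), `nominal_mm`, `slope_hu_mm`,
#'   `position_mm`, `visible`.
#' @export
find_transition_maxima <- function(slopes, phantom, noise_sd, spacing_mm,
                                   window_mm = 0.8, c_vis = 2,
                                   band_width = 4, slope_noise_sd = NULL) {
  stopifnot(inherits(phantom, "phantom_spec"))
  r_in <- phantom$inner_diameter_mm / 2
  r_out <- r_in + phantom$wall_mm
  nominal <- tibble::tibble(
    side = c("left", "left", "right", "right"),
    boundary = c("outer", "inner", "inner", "outer"),
    nominal_mm = c(-r_out, -r_in, r_in, r_out)
  )
  sigma_slope <- slope_noise_sd %||%
    .slope_noise_sd(noise_sd, spacing_mm, band_width)
  thr <- c_vis * sigma_slope
  pos <- slopes$position_mm
  mag <- abs(slopes$slope_hu_mm)
  lm_idx <- .local_maxima(mag)
  # each local maximum may only serve its nearest nominal boundary
  owner <- if (length(lm_idx)) {
    vapply(pos[lm_idx], function(p) which.min(abs(nominal$nominal_mm - p)),
           integer(1))
  } else integer()

  res <- purrr::pmap(nominal, function(side, boundary, nominal_mm) {
    t_idx <- which(nominal$side == side & nominal$boundary == boundary)
    in_win <- which(abs(pos - nominal_mm) <= window_mm + 1e-9)
    cand <- lm_idx[owner == t_idx & lm_idx %in% in_win]
    if (length(cand) > 0) {
      best <- cand[order(-mag[cand], abs(pos[cand] - nominal_mm))][1]
      tibble::tibble(side = side, boundary = boundary,
                     nominal_mm = nominal_mm,
                     slope_hu_mm = mag[best], position_mm = pos[best],
                     visible = mag[best] > thr)
    } else if (length(in_win) > 0) {
      best <- in_win[which.max(mag[in_win])]
      tibble::tibble(side = side, boundary = boundary,
                     nominal_mm = nominal_mm,
                     slope_hu_mm = mag[best], position_mm = pos[best],
                     visible = FALSE)
    } else {
      tibble::tibble(side = side, boundary = boundary,
                     nominal_mm = nominal_mm, slope_hu_mm = NA_real_,
                     position_mm = NA_real_, visible = FALSE)
    }
  })
  dplyr::bind_rows(res)
}

#' Count the visible transitions (slope score)
#'
#' The slope score is the number of tube-edge transitions that appear as
#' distinct local slope maxima above the noise level, out of a maximum of
#' eight (four transitions in each of the two profiles).
#'
#' @param transitions Tibble of transition records from
#'   [find_transition_maxima()] (both profiles bound together).
#' @return Integer score 0-8.
#' @export
slope_score <- function(transitions) {
  sum(transitions$visible)
}

#' Full edge-profile analysis of a slice
#'
#' Runs the complete measurement chain on a (512 x 512 or pre-cropped)
#' slice: centered crop to 128 x 128, background-noise estimation in the two
#' bottom corner ROIs, second crop to 64 x 64, horizontal/vertical profile
#' extraction with 4-pixel band averaging, profile amplitude, three-point
#' slope curves, transition slope maxima and the 0-8 slope score.
#'
#' @param image A [ct_slice()].
#' @param phantom The [phantom_spec()] that the slice shows (for nominal
#'   boundary radii).
#' @param window_mm,c_vis Passed to [find_transition_maxima()].
#' @return An object of class `slope_analysis`: a list with `noise_sd`,
#'   `slope_noise_sd`, `amplitude`, `profiles`, `slopes`, `transitions`,
#'   `mean_slope_maximum`, `slope_score`, `params` and `provenance`.
#'   Use [tidy()][generics::tidy] / `glance()` for tabular views.
#' @export
#' @examples
#' img <- simulate_slice(phantom_spec(3, 37), kernel_spec("Qr60"),
#'                       acquisition_spec(30, qir_level = 4), seed = 1)
#' analyze_image(img, phantom_spec(3, 37))
analyze_image <- function(image, phantom, window_mm = 0.8, c_vis = 2) {
  stopifnot(inherits(image, "ct_slice"))
  n <- nrow(image$values)
  img128 <- if (n > 128) crop_center(image, 128) else image
  noise_sd <- estimate_noise(img128)
  slope_noise_sd <- estimate_slope_noise(img128)
  img64 <- if (nrow(img128$values) > 64) crop_center(img128, 64) else img128
  profiles <- extract_profiles(img64)
  amplitude <- profile_amplitude(profiles)
  per_dir <- profiles |>
    dplyr::group_by(.data$direction) |>
    dplyr::group_map(function(df, key) {
      sl <- slope_curve(df$position_mm, df$hu)
      tr <- find_transition_maxima(sl, phantom, noise_sd, image$spacing_mm,
                                   window_mm = window_mm, c_vis = c_vis,
                                   slope_noise_sd = slope_noise_sd)
      list(direction = key$direction,
           slopes = dplyr::mutate(sl, direction = key$direction,
                                  .before = 1),
           transitions = dplyr::mutate(tr, direction = key$direction,
                                       .before = 1))
    })
  slopes <- dplyr::bind_rows(purrr::map(per_dir, "slopes"))
  transitions <- dplyr::bind_rows(purrr::map(per_dir, "transitions"))
  mean_max <- transitions |>
    dplyr::group_by(.data$direction) |>
    dplyr::summarise(m = mean(.data$slope_hu_mm, na.rm = TRUE),
                     .groups = "drop")
  structure(
    list(noise_sd = noise_sd, slope_noise_sd = slope_noise_sd,
         amplitude = amplitude, profiles = profiles,
         slopes = slopes, transitions = transitions,
         mean_slope_maximum = mean(mean_max$m),
         slope_score = slope_score(transitions),
         params = list(window_mm = window_mm, c_vis = c_vis, band_width = 4),
         provenance = image$provenance),
    class = "slope_analysis"
  )
}

#' @export
print.slope_analysis <- function(x, ...) {
  cat(sprintf(
    "<slope_analysis> noise %.1f HU, amplitude %.0f HU, mean slope max %.0f HU/mm, score %d/8\n",
    x$noise_sd, x$amplitude, x$mean_slope_maximum, x$slope_score))
  invisible(x)
}

#' Tidy the transition table of a slope analysis
#'
#' @param x A `slope_analysis`.
#' @param ... Unused.
#' @return Tibble of per-transition records (direction, side, boundary,
#'   nominal and found positions, slope magnitude, visibility).
#' @export
tidy.slope_analysis <- function(x, ...) {
  x$transitions
}

#' One-row summary of a slope analysis
#'
#' @param x A `slope_analysis`.
#' @param ... Unused.
#' @return One-row tibble with `noise_sd`, `amplitude`,
#'   `mean_slope_maximum`, `slope_score`.
#' @export
glance.slope_analysis <- function(x, ...) {
  tibble::tibble(noise_sd = x$noise_sd, slope_noise_sd = x$slope_noise_sd,
                 amplitude = x$amplitude,
                 mean_slope_maximum = x$mean_slope_maximum,
                 slope_score = x$slope_score)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
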