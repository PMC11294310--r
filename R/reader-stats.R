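# Exact two-sided signed-rank p-value for differences d (zeros already
# discarded), valid with tied |d| (average ranks): dynamic programming over
# the 2^n equiprobable sign assignments. Doubled ranks keep sums integral.
.exact_signed_rank_p <- function(d) {
  rk <- rank(abs(d))
  s <- as.integer(round(2 * rk))
  v2 <- sum(s[d > 0])
  total <- sum(s)
  f <- numeric(total + 1)
  f[1] <- 1
  for (si in s) {
    g <- f
    g[(si + 1):(total + 1)] <- g[(si + 1):(total + 1)] + f[1:(total + 1 - si)]
    f <- g
  }
  f <- f / 2^length(d)
  p_low <- sum(f[seq_len(v2 + 1)])
  p_high <- sum(f[seq.int(v2 + 1, total + 1)])
  min(1, 2 * min(p_low, p_high))
}

#' Paired Wilcoxon signed-rank tests with Bonferroni correction
#'
#' Runs the two-sided paired Wilcoxon signed-rank test on each pair of score
#' vectors and applies the Bonferroni correction for the size of the
#' comparison family. Zero differences are discarded (the classical
#' convention). For n <= 25 non-zero pairs the exact signed-rank
#' distribution is used (computed over all 2^n sign assignments, which with
#' ordinal data must accommodate tied ranks, so it is evaluated by dynamic
#' programming rather than the tie-free closed form); larger samples use
#' the normal approximation with tie correction.
#'
#' @param x,y Equal-length numeric vectors of paired scores, or `x` a
#'   two-column data frame / list of such pairs for a whole family.
#' @param m_comparisons Size of the comparison family for the Bonferroni
#'   correction (default: the number of pairs supplied).
#' @return A tibble with one row per comparison: `comparison`, `n_pairs`,
#'   `n_nonzero`, `statistic`, `p_value`, `p_adjusted`, `degenerate`
#'   (all differences zero).
#' @export
#' @examples
#' wilcoxon_paired(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
wilcoxon_paired <- function(x, y = NULL, m_comparisons = NULL) {
  pairs <- if (!is.null(y)) {
    list(list(x = x, y = y, name = "1"))
  } else if (is.data.frame(x)) {
    list(list(x = x[[1]], y = x[[2]], name = "1"))
  } else {
    purrr::imap(x, function(p, nm) list(x = p[[1]], y = p[[2]],
                                        name = as.character(nm)))
  }
  m <- m_comparisons %||% length(pairs)
  if (m < 1) rlang::abort("m_comparisons must be >= 1")
  rows <- purrr::map(pairs, function(p) {
    if (length(p$x) != length(p$y)) {
      rlang::abort("paired vectors must have equal length")
    }
    d <- p$x - p$y
    nz <- sum(d != 0)
    if (nz == 0) {
      return(tibble::tibble(comparison = p$name, n_pairs = length(d),
                            n_nonzero = 0L, statistic = NA_real_,
                            p_value = 1, degenerate = TRUE))
    }
    dn <- d[d != 0]
    v_stat <- sum(rank(abs(dn))[dn > 0])
    p_val <- if (nz <= 25) {
      .exact_signed_rank_p(dn)
    } else {
      suppressWarnings(
        stats::wilcox.test(p$x, p$y, paired = TRUE, exact = FALSE,
                           correct = FALSE)$p.value
      )
    }
    tibble::tibble(comparison = p$name, n_pairs = length(d),
                   n_nonzero = as.integer(nz),
                   statistic = v_stat,
                   p_value = p_val, degenerate = FALSE)
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(p_adjusted = pmin(1, m * .data$p_value),
                  .after = "p_value")
}

#' Krippendorff's alpha for ordinal ratings
#'
#' Chance-corrected inter-rater agreement via the coincidence matrix:
#' \eqn{\alpha = 1 - D_o / D_e}, with observed and expected disagreement
#' weighted by the ordinal distance metric
#' \eqn{\delta^2_{ck} = \big(\sum_{g=c}^{k} n_g - (n_c + n_k)/2\big)^2}
#' on the marginal coincidence counts \eqn{n_g}. Handles any number of
#' raters and missing ratings; units with fewer than two ratings are
#' ignored.
#'
#' @param ratings Matrix or data frame, units in rows and raters in columns;
#'   values are ordinal category scores (e.g. Likert 1-5), `NA` for missing.
#' @param level_set Optional full ordered set of categories (so that unused
#'   scale points keep their place); defaults to the observed values.
#' @return An `agreement_result` list: `alpha`, `band` (see
#'   [interpret_alpha()]), `n_units`, `n_raters`, `d_observed`,
#'   `d_expected`. `alpha` is `NA` with band `"undefined"` when the data
#'   show no variation (expected disagreement zero).
#' @export
#' @examples
#' r <- cbind(reader1 = c(1, 2, 3, 3, 2), reader2 = c(1, 2, 3, 4, 2))
#' krippendorff_alpha(r)
krippendorff_alpha <- function(ratings, level_set = NULL) {
  ratings <- as.matrix(ratings)
  if (ncol(ratings) < 2) rlang::abort("need at least 2 raters")
  keep <- rowSums(!is.na(ratings)) >= 2
  if (!any(keep)) rlang::abort("no unit carries two or more ratings")
  ratings <- ratings[keep, , drop = FALSE]
  levs <- if (is.null(level_set)) sort(unique(stats::na.omit(as.vector(ratings))))
          else sort(level_set)
  k <- length(levs)
  # coincidence matrix: within each unit every ordered pair of ratings
  # contributes 1/(m_u - 1)
  co <- matrix(0, k, k, dimnames = list(levs, levs))
  for (u in seq_len(nrow(ratings))) {
    vals <- stats::na.omit(ratings[u, ])
    m_u <- length(vals)
    idx <- match(vals, levs)
    for (i in seq_len(m_u)) {
      for (j in seq_len(m_u)) {
        if (i != j) co[idx[i], idx[j]] <- co[idx[i], idx[j]] + 1 / (m_u - 1)
      }
    }
  }
  n_g <- rowSums(co)
  n_tot <- sum(n_g)
  # ordinal distance: squared count of coincidences between the two
  # categories' midpoints
  delta2 <- matrix(0, k, k)
  for (c_i in seq_len(k)) {
    for (k_i in seq_len(k)) {
      lo <- min(c_i, k_i); hi <- max(c_i, k_i)
      delta2[c_i, k_i] <- (sum(n_g[lo:hi]) - (n_g[c_i] + n_g[k_i]) / 2)^2
    }
  }
  d_obs <- sum(co * delta2) / n_tot
  # expected disagreement: random pairing of all coincidence-marginal values
  # (delta2 has a zero diagonal, so the c == k terms drop out on their own)
  d_exp <- sum(outer(n_g, n_g) * delta2) / (n_tot * (n_tot - 1))
  if (d_exp <= 0) {
    return(structure(list(alpha = NA_real_, band = "undefined",
                          n_units = nrow(ratings), n_raters = ncol(ratings),
                          d_observed = d_obs, d_expected = d_exp),
                     class = "agreement_result"))
  }
  alpha <- 1 - d_obs / d_exp
  structure(list(alpha = alpha, band = interpret_alpha(alpha),
                 n_units = nrow(ratings), n_raters = ncol(ratings),
                 d_observed = d_obs, d_expected = d_exp),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> alpha = %.3f (%s), %d units x %d raters\n",
              x$alpha, x$band, x$n_units, x$n_raters))
  invisible(x)
}

#' @export
glance.agreement_result <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, band = x$band, n_units = x$n_units,
                 n_raters = x$n_raters)
}

#' Interpretation band for an agreement coefficient
#'
#' Maps alpha to the conventional labels: poor (0.0-0.2], fair (0.2-0.4],
#' moderate (0.4-0.6], substantial (0.6-0.8] and excellent (0.8-1.0], with
#' each interval open at its lower end. Values at or below 0.2 (including
#' negative alpha) are "poor".
#'
#' @param alpha Finite agreement coefficient in \[-1, 1\].
#' @return Band label.
#' @export
#' @examples
#' interpret_alpha(0.71)  # "substantial"
interpret_alpha <- function(alpha) {
  if (!is.finite(alpha)) rlang::abort("alpha must be finite")
  cuts <- c(0.2, 0.4, 0.6, 0.8)
  labels <- c("poor", "fair", "moderate", "substantial", "excellent")
  labels[findInterval(alpha, cuts, left.open = TRUE) + 1]
}

#' Reference profile for the synthetic Likert generator
#'
#' Per-cell target medians and interquartile ranges for the reader study
#' layout: 9 reconstructions (3 kernels x 3 QIR levels) x 3 criteria (image
#' noise, delineation of plaques and vessel walls, overall quality) x 2
#' anatomic levels (popliteal, below-the-knee).
#'
#' @return Tibble with columns `kernel`, `qir`, `criterion`, `level`,
#'   `median`, `q1`, `q3`.
#' @export
likert_profile <- function() {
  path <- system.file("extdata", "likert_profile.csv", package = "ctiq",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Generate a synthetic reader-study Likert dataset
#'
#' Latent-Gaussian ordinal model: for each cell of the study layout the
#' latent score is the cell's target median plus a per-reader additive bias
#' plus Gaussian residual noise, then rounded to the nearest integer and
#' clipped to the 1-5 scale. The residual SD per cell grows with the cell's
#' target interquartile width (`sd = residual_sd + iqr_sd_slope * (q3 -
#' q1)`). With zero noise and zero bias every rating equals its cell's
#' target median.
#'
#' @param profile Target tibble as from [likert_profile()].
#' @param n_readers Number of readers (default 3).
#' @param n_patients Number of patients (default 20).
#' @param reader_bias_sd SD of the per-reader additive bias (default 0.2).
#' @param residual_sd Baseline residual SD (default 0.3).
#' @param iqr_sd_slope Extra residual SD per unit of target IQR width
#'   (default 0.5).
#' @param seed Integer seed.
#' @return A tibble in long format: `reader`, `patient`, `kernel`, `qir`,
#'   `criterion`, `level`, `score` (integer 1-5), with the generator
#'   parameters in attribute `provenance`.
#' @export
#' @examples
#' d <- synth_likert(seed = 1)
#' dplyr::count(d, score)
synth_likert <- function(profile = likert_profile(), n_readers = 3,
                         n_patients = 20, reader_bias_sd = 0.2,
                         residual_sd = 0.3, iqr_sd_slope = 0.5, seed = 1L) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  biases <- stats::rnorm(n_readers, 0, reader_bias_sd)
  grid <- tidyr::expand_grid(
    reader = seq_len(n_readers), patient = seq_len(n_patients),
    profile
  )
  latent <- grid$median + biases[grid$reader] +
    stats::rnorm(nrow(grid), 0,
                 residual_sd + iqr_sd_slope * (grid$q3 - grid$q1))
  out <- grid |>
    dplyr::mutate(score = as.integer(pmin(5, pmax(1, round(latent))))) |>
    dplyr::select("reader", "patient", "kernel", "qir", "criterion",
                  "level", "score")
  attr(out, "provenance") <- list(
    n_readers = n_readers, n_patients = n_patients,
    reader_bias_sd = reader_bias_sd, residual_sd = residual_sd,
    iqr_sd_slope = iqr_sd_slope, seed = seed
  )
  out
}

#' Ratings table (units x raters) from a long Likert dataset
#'
#' Each combination of patient, reconstruction, criterion and level becomes
#' one unit; readers become columns — the layout [krippendorff_alpha()]
#' expects.
#'
#' @param data Long tibble as from [synth_likert()].
#' @return Numeric matrix, units x readers.
#' @export
likert_ratings_matrix <- function(data) {
  wide <- data |>
    tidyr::pivot_wider(names_from = "reader", values_from = "score",
                       names_prefix = "reader")
  as.matrix(dplyr::select(wide, dplyr::starts_with("reader")))
}
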