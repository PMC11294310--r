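test_that("paired Wilcoxon matches exact sign-assignment enumeration", {
  set.seed(5)
  for (n in c(4, 5, 6, 8)) {
    for (rep in 1:5) {
      x <- round(rnorm(n, 3, 1), 3)
      y <- x + round(rnorm(n, 0.3, 0.7), 3)  # continuous: tie-free
      got <- wilcoxon_paired(x, y)$p_value
      want <- enum_signed_rank_p(x - y)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("Wilcoxon handles the classic small-sample and degenerate cases", {
  # n = 5, all differences one-signed: two-sided exact p = 2/32
  r <- wilcoxon_paired(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  expect_equal(r$p_value, 0.0625)
  # identical vectors: degenerate, p = 1
  r0 <- wilcoxon_paired(c(3, 3, 4), c(3, 3, 4))
  expect_true(r0$degenerate)
  expect_equal(r0$p_adjusted, 1)
  # Bonferroni arithmetic
  r3 <- wilcoxon_paired(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6),
                        m_comparisons = 3)
  expect_equal(r3$p_adjusted, min(1, 3 * r3$p_value))
  # a whole family of comparisons at once
  fam <- wilcoxon_paired(list(a = list(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6)),
                              b = list(c(1, 2, 3), c(1, 2, 3))))
  expect_equal(nrow(fam), 2)
  expect_equal(fam$p_adjusted, pmin(1, 2 * fam$p_value))
})

test_that("ordinal alpha matches the brute-force pair-enumeration oracle", {
  # hand-checkable case: two raters, units (1,2) and (2,1) on a 1-2 scale
  r <- rbind(c(1, 2), c(2, 1))
  a <- krippendorff_alpha(r)
  expect_equal(a$alpha, brute_alpha(r), tolerance = 1e-9)
  # 50 random small ordinal tables, including missing entries
  set.seed(7)
  for (i in 1:50) {
    nu <- sample(4:10, 1)
    nr <- sample(2:4, 1)
    m <- matrix(sample(1:5, nu * nr, replace = TRUE), nu, nr)
    if (i %% 3 == 0) m[sample(length(m), 2)] <- NA
    if (length(unique(stats::na.omit(as.vector(m)))) < 2) next
    got <- krippendorff_alpha(m)$alpha
    want <- brute_alpha(m)
    if (is.na(want)) {
      expect_true(is.na(got))
    } else {
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("alpha is 1 under perfect agreement and invariant to rater relabeling", {
  m <- cbind(a = c(1, 2, 3, 4, 5, 2), b = c(1, 2, 3, 4, 5, 2),
             c = c(1, 2, 3, 4, 5, 2))
  expect_equal(krippendorff_alpha(m)$alpha, 1)
  set.seed(13)
  for (i in 1:10) {
    m <- matrix(sample(1:5, 24, replace = TRUE), 8, 3)
    a1 <- krippendorff_alpha(m)$alpha
    a2 <- krippendorff_alpha(m[, c(3, 1, 2)])$alpha
    expect_equal(a1, a2, tolerance = 1e-12)
    expect_gte(a1, -1); expect_lte(a1, 1)
  }
})

test_that("single-category ratings give an undefined alpha", {
  m <- matrix(3, 5, 3)
  a <- krippendorff_alpha(m)
  expect_true(is.na(a$alpha))
  expect_equal(a$band, "undefined")
  expect_error(krippendorff_alpha(matrix(1:5, 5, 1)), "2 raters")
  expect_error(krippendorff_alpha(cbind(1:3, NA)), "two or more")
})

test_that("interpretation bands follow the half-open cut points", {
  expect_equal(interpret_alpha(0.71), "substantial")
  expect_equal(interpret_alpha(0.86), "excellent")
  expect_equal(interpret_alpha(0.20), "poor")
  expect_equal(interpret_alpha(-0.4), "poor")
  expect_equal(interpret_alpha(0.4), "fair")
  expect_equal(interpret_alpha(0.6), "moderate")
  expect_equal(interpret_alpha(0.8), "substantial")
  expect_equal(interpret_alpha(1.0), "excellent")
  # total and non-overlapping over the range
  grid <- seq(-1, 1, by = 0.01)
  bands <- vapply(grid, interpret_alpha, character(1))
  expect_true(all(bands %in% c("poor", "fair", "moderate", "substantial",
                               "excellent")))
  expect_error(interpret_alpha(NA_real_), "finite")
})

test_that("noiseless synthetic ratings equal the target medians cell by cell", {
  d <- synth_likert(reader_bias_sd = 0, residual_sd = 0, iqr_sd_slope = 0,
                    seed = 1)
  expect_equal(nrow(d), 3 * 20 * 9 * 3 * 2)
  expect_true(all(d$score %in% 1:5))
  per_cell <- d |>
    dplyr::group_by(kernel, qir, criterion, level) |>
    dplyr::summarise(med = median(score), .groups = "drop") |>
    dplyr::left_join(likert_profile(),
                     by = c("kernel", "qir", "criterion", "level"))
  expect_equal(per_cell$med, as.numeric(per_cell$median))
})

test_that("synthetic ratings are seed-deterministic", {
  d1 <- synth_likert(seed = 42)
  d2 <- synth_likert(seed = 42)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  d3 <- synth_likert(seed = 43)
  expect_false(identical(d1$score, d3$score))
})

test_that("agreement rises to 1 as the residual noise vanishes", {
  alphas <- vapply(c(1.2, 0.6, 0.2, 0), function(s) {
    d <- synth_likert(reader_bias_sd = 0, residual_sd = s, iqr_sd_slope = 0,
                      n_patients = 6, seed = 9)
    krippendorff_alpha(likert_ratings_matrix(d))$alpha
  }, numeric(1))
  expect_true(all(diff(alphas) > -1e-12))
  expect_equal(alphas[4], 1)
})

test_that("synthetic reader study lands in plausible agreement bands", {
  d <- synth_likert(seed = 2)
  m <- likert_ratings_matrix(d)
  a <- krippendorff_alpha(m)
  expect_gt(a$alpha, 0.4)   # defaults emulate substantial-range agreement
  expect_lte(a$alpha, 1)
  g <- glance(a)
  expect_named(g, c("alpha", "band", "n_units", "n_raters"))
  expect_equal(g$n_raters, 3)
})
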