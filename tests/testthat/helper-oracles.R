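# Independent oracles used across the suite. Each is deliberately written
# with a different algorithm than the package implementation it checks.

# Generic least-squares slope of (x, y) via the normal equations -- checks
# the three-point-regression/central-difference identity.
ols_slope <- function(x, y) {
  xm <- mean(x); ym <- mean(y)
  sum((x - xm) * (y - ym)) / sum((x - xm)^2)
}

# Brute-force ordinal Krippendorff's alpha by explicit pair enumeration
# (no coincidence matrix). ratings: units x raters, NA for missing.
brute_alpha <- function(ratings) {
  ratings <- as.matrix(ratings)
  keep <- rowSums(!is.na(ratings)) >= 2
  ratings <- ratings[keep, , drop = FALSE]
  levs <- sort(unique(stats::na.omit(as.vector(ratings))))
  # pairable-value marginals: every rating in a unit with >= 2 ratings
  vals <- unlist(apply(ratings, 1, function(r) stats::na.omit(r),
                       simplify = FALSE))
  n_g <- vapply(levs, function(g) sum(vals == g), numeric(1))
  names(n_g) <- levs
  d2 <- function(a, b) {
    ia <- which(levs == a); ib <- which(levs == b)
    lo <- min(ia, ib); hi <- max(ia, ib)
    (sum(n_g[lo:hi]) - (n_g[ia] + n_g[ib]) / 2)^2
  }
  n_tot <- length(vals)
  # observed: ordered pairs within units, weighted 1/(m_u - 1)
  d_obs <- 0
  for (u in seq_len(nrow(ratings))) {
    r <- stats::na.omit(ratings[u, ])
    m <- length(r)
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i != j) d_obs <- d_obs + d2(r[i], r[j]) / (m - 1)
    }
  }
  d_obs <- d_obs / n_tot
  # expected: all ordered pairs of pairable values
  d_exp <- 0
  for (i in seq_len(n_tot)) for (j in seq_len(n_tot)) {
    if (i != j) d_exp <- d_exp + d2(vals[i], vals[j])
  }
  d_exp <- d_exp / (n_tot * (n_tot - 1))
  if (d_exp <= 0) return(NA_real_)
  unname(1 - d_obs / d_exp)
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign
# assignments of the nonzero differences (tie-free data assumed).
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% rk)
  p_low <- mean(v_all <= v_obs)
  p_high <- mean(v_all >= v_obs)
  min(1, 2 * min(p_low, p_high))
}

# Small noise-free simulated slice (cheap default grid) for edge-metric
# tests; n = 512 only where the full chain geometry matters.
sim_noise_free <- function(diameter, conc, kernel, n = 512) {
  ph <- phantom_spec(diameter, conc)
  img <- rasterize_phantom(ph, n = n)
  apply_kernel(img, fit_mtf(kernel_spec(kernel)))
}

# Rotate a square matrix by 90 degrees counter-clockwise.
rot90 <- function(m) t(m)[rev(seq_len(ncol(m))), ]
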