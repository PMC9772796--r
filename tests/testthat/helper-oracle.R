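# Independent brute-force implementations of every per-cell metric, used
# only to cross-check the package. They deliberately take different routes:
# stats::quantile(type = 1) for the ordinal-rank percentile, e1071 for the
# standardized moments, lm() for the plane fit, and explicit loops for the
# counting metrics.

oracle_percentile <- function(z, p) {
  stats::quantile(z, p / 100, names = FALSE, type = 1)
}

oracle_band <- function(z, lo, hi) {
  hits <- 0L
  for (v in z) if (v >= lo && v < hi) hits <- hits + 1L
  hits / length(z)
}

oracle_entropy <- function(z, w = 0.5) {
  cnt <- as.vector(table(floor(z / w)))
  p <- cnt / sum(cnt)
  -sum(p * log(p)) / log(2)
}

oracle_density_above_mean <- function(z) 100 * mean(z > mean(z))

oracle_moments <- function(z) {
  n <- length(z)
  c(Hstd = stats::sd(z),
    Hvar = stats::var(z),
    Coeff_var_z = stats::sd(z) / mean(z),
    Hskew = if (n >= 2) e1071::skewness(z, type = 1) else NA_real_,
    Hkurt = if (n >= 2) e1071::kurtosis(z, type = 1) + 3 else NA_real_)
}

oracle_sigma_z <- function(x, y, z) {
  if (length(z) < 3) return(NA_real_)
  fit <- stats::lm(z ~ x + y)
  if (anyNA(stats::coef(fit))) return(NA_real_)
  stats::sd(stats::resid(fit))
}

oracle_cell_metrics <- function(veg_z, veg_x, veg_y, n_ground, n_all,
                                cell_area = 100) {
  out <- setNames(rep(NA_real_, 26L), als_metric_names())
  out["point_density"] <- n_all / cell_area
  if (n_ground + length(veg_z) >= 1)
    out["PPR"] <- n_ground / (n_ground + length(veg_z))
  n <- length(veg_z)
  if (n >= 1) {
    out["Hmax"] <- max(veg_z)
    out["Hmean"] <- mean(veg_z)
    for (p in c(25, 50, 75, 95))
      out[paste0("Hp", p)] <- oracle_percentile(veg_z, p)
    out["Hmedian"] <- out[["Hp50"]]
    out["Density_above_mean_z"] <- oracle_density_above_mean(veg_z)
    out["BR_below_1"] <- oracle_band(veg_z, -Inf, 1)
    out["BR_1_2"] <- oracle_band(veg_z, 1, 2)
    out["BR_2_3"] <- oracle_band(veg_z, 2, 3)
    out["BR_above_3"] <- oracle_band(veg_z, 3, Inf)
    out["BR_3_4"] <- oracle_band(veg_z, 3, 4)
    out["BR_4_5"] <- oracle_band(veg_z, 4, 5)
    out["BR_below_5"] <- oracle_band(veg_z, -Inf, 5)
    out["BR_5_20"] <- oracle_band(veg_z, 5, 20)
    out["BR_above_20"] <- oracle_band(veg_z, 20, Inf)
    out["Entropy_z"] <- oracle_entropy(veg_z)
    mo <- oracle_moments(veg_z)
    sig <- if (n >= 2) sqrt(sum((veg_z - mean(veg_z))^2) / n) else 0
    if (sig == 0) mo[c("Hskew", "Hkurt")] <- NA_real_
    if (n >= 2 && mean(veg_z) == 0) mo["Coeff_var_z"] <- NA_real_
    out[names(mo)] <- mo
    out["Sigma_z"] <- oracle_sigma_z(veg_x, veg_y, veg_z)
  }
  out
}

# Random cell: heights from a mixture of uniform strata (continuous, so no
# ties and no zero-variance degeneracies), positions uniform in a 10 m cell.
random_cell <- function(n = NULL) {
  if (is.null(n)) n <- sample(1:500, 1)
  k <- sample(1:3, 1)
  lo <- sort(runif(k, 0, 25))
  hi <- lo + runif(k, 0.5, 8)
  comp <- sample.int(k, n, replace = TRUE)
  list(
    veg_z = lo[comp] + runif(n) * (hi[comp] - lo[comp]),
    veg_x = runif(n, 0, 10), veg_y = runif(n, 0, 10),
    n_ground = rpois(1, n / 2), n_extra = rpois(1, 5)
  )
}

# Compare metric vectors: NA must match NA; finite values to a hybrid
# relative tolerance (absolute below magnitude 1).
expect_metrics_equal <- function(got, want, tol = 1e-9, sigma_tol = 1e-6) {
  expect_identical(names(got), names(want))
  for (m in names(got)) {
    t <- if (m == "Sigma_z") sigma_tol else tol
    if (is.na(want[[m]])) {
      expect_true(is.na(got[[m]]),
                  label = paste(m, "expected nodata, got", got[[m]]))
    } else {
      expect_true(abs(got[[m]] - want[[m]]) <= t * max(1, abs(want[[m]])),
                  label = sprintf("%s: %.15g vs oracle %.15g", m,
                                  got[[m]], want[[m]]))
    }
  }
}

# A small normalized cloud wrapped around given per-cell vegetation points.
cloud_from_cells <- function(cells, cell_size = 10) {
  parts <- lapply(seq_along(cells), function(k) {
    cl <- cells[[k]]
    ox <- ((k - 1) %% 100) * cell_size
    oy <- ((k - 1) %/% 100) * cell_size
    n <- length(cl$veg_z)
    data.table::data.table(
      x = c(ox + cl$veg_x, ox + runif(cl$n_ground, 0, cell_size)),
      y = c(oy + cl$veg_y, oy + runif(cl$n_ground, 0, cell_size)),
      z = c(cl$veg_z, rep(0, cl$n_ground)),
      nz = c(cl$veg_z, rep(0, cl$n_ground)),
      classification = c(rep(1L, n), rep(2L, cl$n_ground))
    )
  })
  as_als_cloud(data.table::rbindlist(parts))
}
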