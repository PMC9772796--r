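# The 25 per-cell ecosystem-structure metrics plus point density.
#
# All vegetation metrics consume the multiset of normalized heights z_i of
# the class-1 ("unclassified", predominantly vegetation) points in a grid
# cell; the pulse penetration ratio additionally uses the class-2 ground
# count, and point density counts every class. Metrics are grouped in three
# dimensions: ecosystem height (Hmax, Hmean, Hmedian, Hp25-Hp95), cover
# (PPR, canopy density above the mean, nine vertical band ratios) and
# structural complexity (variability moments, foliage-height entropy,
# plane-fit roughness).

#' Metric identifiers
#'
#' The 25 structure metrics plus `point_density`, in canonical order.
#'
#' @return character vector of length 26.
#' @export
als_metric_names <- function() {
  c("Hmax", "Hmean", "Hmedian", "Hp25", "Hp50", "Hp75", "Hp95",
    "PPR", "Density_above_mean_z",
    "BR_below_1", "BR_1_2", "BR_2_3", "BR_above_3", "BR_3_4", "BR_4_5",
    "BR_below_5", "BR_5_20", "BR_above_20",
    "Coeff_var_z", "Entropy_z", "Hkurt", "Sigma_z", "Hskew", "Hstd", "Hvar",
    "point_density")
}

#' Nearest-rank height percentile
#'
#' The ordinal-rank definition: sort the `N` heights ascending and return
#' the value at rank `ceiling((p/100) * N)` (clamped to `[1, N]`). With
#' `interpolate = TRUE` the linearly interpolated sample quantile
#' ([stats::quantile()] type 7) is returned instead.
#'
#' @param z numeric vector of normalized heights (metres).
#' @param p percentile in (0, 100].
#' @param interpolate use linear interpolation between ranks.
#' @return height in metres; `NA` when `z` is empty.
#' @export
#' @examples
#' height_percentile(c(2, 4, 6, 8), 50)  # 4
#' height_percentile(c(2, 4, 6, 8), 95)  # 8
height_percentile <- function(z, p, interpolate = FALSE) {
  n <- length(z)
  if (n == 0) return(NA_real_)
  if (interpolate)
    return(stats::quantile(z, p / 100, names = FALSE, type = 7))
  sort(z, method = "quick")[min(n, max(1L, as.integer(ceiling(p / 100 * n))))]
}

#' Pulse penetration ratio
#'
#' Ground points divided by total (ground + vegetation) points in the cell;
#' a measure of canopy openness. Building and water returns are excluded
#' from the total so that built cover is not conflated with openness.
#'
#' @param n_ground number of ground-class points.
#' @param n_veg number of vegetation-class points.
#' @return ratio in `[0, 1]`; `NA` when the cell has neither.
#' @export
pulse_penetration_ratio <- function(n_ground, n_veg) {
  tot <- n_ground + n_veg
  ifelse(tot >= 1, n_ground / tot, NA_real_)
}

#' Canopy density above the mean height
#'
#' Percentage of vegetation returns strictly above the cell's mean
#' normalized height.
#'
#' @param z numeric vector of normalized heights (metres).
#' @return percentage in `[0, 100]`; `NA` for an empty cell.
#' @export
density_above_mean <- function(z) {
  if (length(z) == 0) return(NA_real_)
  100 * sum(z > mean(z)) / length(z)
}

#' Vertical band ratio
#'
#' Fraction of vegetation returns with normalized height in `[low, high)`.
#' Half-open bands make the standard stacks partition: the four bands
#' `<1, 1-2, 2-3, >3` sum to 1, as do `<5, 5-20, >20`.
#'
#' @param z numeric vector of normalized heights (metres).
#' @param low,high band bounds in metres (`-Inf`/`Inf` for open ends).
#' @return ratio in `[0, 1]`; `NA` for an empty cell.
#' @export
#' @examples
#' band_ratio(c(0.5, 1.5, 2.5, 3.5), 1, 2)  # 0.25
band_ratio <- function(z, low = -Inf, high = Inf) {
  if (length(z) == 0) return(NA_real_)
  sum(z >= low & z < high) / length(z)
}

#' Foliage-height entropy (Shannon index of height layers)
#'
#' Bins normalized heights into `bin_width` layers anchored at height 0
#' (half-open `[k*w, (k+1)*w)`) and returns the Shannon entropy (base 2) of
#' the layer proportions. Empty layers contribute nothing (0*log(0) = 0).
#'
#' @param z numeric vector of normalized heights (metres).
#' @param bin_width layer thickness in metres (default 0.5).
#' @return entropy in bits, `>= 0`; `NA` for an empty cell.
#' @export
#' @examples
#' entropy_z(c(0.1, 0.2, 0.6, 0.7))  # 1 bit
entropy_z <- function(z, bin_width = 0.5) {
  n <- length(z)
  if (n == 0) return(NA_real_)
  b <- floor(z / bin_width)
  cnt <- tabulate(match(b, unique(b)))
  p <- cnt / n
  -sum(p * log2(p))
}

#' Height-distribution moments
#'
#' Sample variance and standard deviation use the `N - 1` divisor;
#' the coefficient of variation is their ratio to the mean. Skewness and
#' kurtosis are standardized central moments with the population standard
#' deviation (divisor `N`) in the denominator, and kurtosis is raw (a
#' normal sample gives about 3), matching the published formulas exactly —
#' the mixed divisor convention is deliberate.
#'
#' @param z numeric vector of normalized heights (metres).
#' @return named numeric vector `Hstd`, `Hvar`, `Coeff_var_z`, `Hskew`,
#'   `Hkurt`; entries are `NA` where their precondition fails
#'   (`N >= 2`; additionally `sigma > 0` for skew/kurtosis and a nonzero
#'   mean for the coefficient of variation).
#' @export
#' @examples
#' moment_metrics(c(1, 2, 3))  # Hvar 1, Hstd 1, CV 0.5, skew 0
moment_metrics <- function(z) {
  out <- c(Hstd = NA_real_, Hvar = NA_real_, Coeff_var_z = NA_real_,
           Hskew = NA_real_, Hkurt = NA_real_)
  n <- length(z)
  if (n < 2) return(out)
  m <- mean(z)
  d <- z - m
  ss <- sum(d^2)
  out["Hvar"] <- ss / (n - 1)
  out["Hstd"] <- sqrt(out[["Hvar"]])
  if (m != 0) out["Coeff_var_z"] <- out[["Hstd"]] / m
  sig <- sqrt(ss / n)
  if (sig > 0) {
    out["Hskew"] <- sum(d^3) / (n * sig^3)
    out["Hkurt"] <- sum(d^4) / (n * sig^4)
  }
  out
}

#' Plane-fit roughness
#'
#' Fits `z = a*x + b*y + c` to the cell's vegetation points by least
#' squares and returns the standard deviation (divisor `N - 1`) of the
#' residuals: small-scale surface roughness after removing the local slope.
#'
#' @param x,y point coordinates in metres.
#' @param z normalized heights in metres.
#' @return roughness in metres; `NA` with fewer than 3 points or when the
#'   `(x, y)` positions are (numerically) collinear.
#' @export
sigma_z <- function(x, y, z) {
  n <- length(z)
  if (n < 3) return(NA_real_)
  cx <- x - mean(x); cy <- y - mean(y); cz <- z - mean(z)
  sxx <- sum(cx^2); syy <- sum(cy^2); sxy <- sum(cx * cy)
  det <- sxx * syy - sxy^2
  if (det <= 1e-10 * max(sxx * syy, .Machine$double.eps)) return(NA_real_)
  a <- (syy * sum(cx * cz) - sxy * sum(cy * cz)) / det
  b <- (sxx * sum(cy * cz) - sxy * sum(cx * cz)) / det
  r <- cz - a * cx - b * cy
  sqrt(sum((r - mean(r))^2) / (n - 1))
}

#' Point density
#'
#' Points per square metre over all classes in the cell.
#'
#' @param n_points total point count (all classes).
#' @param cell_area cell area in square metres (default 100 for 10 m cells).
#' @return density in points per square metre.
#' @export
point_density <- function(n_points, cell_area = 100) {
  stopifnot(cell_area > 0)
  n_points / cell_area
}

#' All 26 metrics for one grid cell
#'
#' Evaluates every metric from the cell's vegetation heights plus the
#' ground and all-class counts. Metrics whose preconditions fail are `NA`
#' (the table/raster nodata).
#'
#' @param veg_z normalized heights of the cell's class-1 points (metres).
#' @param veg_x,veg_y their coordinates (needed only for `Sigma_z`; may be
#'   `NULL` to skip the plane fit).
#' @param n_ground number of class-2 points in the cell.
#' @param n_all number of points of all classes in the cell.
#' @param cell_area cell area in square metres.
#' @param interpolate passed to [height_percentile()].
#' @return named numeric vector over [als_metric_names()].
#' @export
cell_metrics <- function(veg_z, veg_x = NULL, veg_y = NULL, n_ground = 0L,
                         n_all = length(veg_z) + n_ground, cell_area = 100,
                         interpolate = FALSE) {
  out <- stats::setNames(rep(NA_real_, 26L), als_metric_names())
  out["point_density"] <- point_density(n_all, cell_area)
  out["PPR"] <- pulse_penetration_ratio(n_ground, length(veg_z))
  n <- length(veg_z)
  if (n >= 1) {
    zs <- sort(veg_z, method = "quick")
    out["Hmax"] <- zs[n]
    out["Hmean"] <- mean(veg_z)
    pr <- function(p) if (interpolate) stats::quantile(zs, p / 100, names = FALSE, type = 7)
                      else zs[min(n, max(1L, as.integer(ceiling(p / 100 * n))))]
    out["Hp25"] <- pr(25); out["Hp50"] <- pr(50)
    out["Hp75"] <- pr(75); out["Hp95"] <- pr(95)
    out["Hmedian"] <- out[["Hp50"]]
    out["Density_above_mean_z"] <- 100 * sum(veg_z > out[["Hmean"]]) / n
    out["BR_below_1"] <- sum(zs < 1) / n
    out["BR_1_2"] <- sum(zs >= 1 & zs < 2) / n
    out["BR_2_3"] <- sum(zs >= 2 & zs < 3) / n
    out["BR_above_3"] <- sum(zs >= 3) / n
    out["BR_3_4"] <- sum(zs >= 3 & zs < 4) / n
    out["BR_4_5"] <- sum(zs >= 4 & zs < 5) / n
    out["BR_below_5"] <- sum(zs < 5) / n
    out["BR_5_20"] <- sum(zs >= 5 & zs < 20) / n
    out["BR_above_20"] <- sum(zs >= 20) / n
    out["Entropy_z"] <- entropy_z(veg_z)
    out[c("Hstd", "Hvar", "Coeff_var_z", "Hskew", "Hkurt")] <-
      moment_metrics(veg_z)
    if (!is.null(veg_x)) out["Sigma_z"] <- sigma_z(veg_x, veg_y, veg_z)
  }
  out
}

#' Per-cell feature extraction over a grid
#'
#' Assigns every point of a normalized cloud to a half-open `cell_size`
#' feature cell anchored at `origin` and computes all 26 metrics per
#' occupied cell. Vegetation metrics use class-1 points only; the pulse
#' penetration ratio adds class-2 ground counts; point density counts all
#' classes.
#'
#' @param cloud an `als_cloud` with an `nz` column (see
#'   [normalize_height()]).
#' @param cell_size feature cell side in metres (default 10).
#' @param origin numeric `c(x, y)` grid anchor; use the tile-grid anchor so
#'   cells nest inside tiles.
#' @param interpolate passed to [height_percentile()].
#' @param copy work on a copy of the point table (default). `copy = FALSE`
#'   adds the transient cell-index columns to `cloud` by reference (they
#'   are removed again), halving peak memory on country-scale tiles.
#' @return a `data.table` with one row per occupied cell: zero-based cell
#'   indices `cell_i`, `cell_j`, centroid coordinates `cell_x`, `cell_y`,
#'   and one column per metric (`NA` = nodata). Sorted by `(cell_i, cell_j)`.
#' @export
extract_features <- function(cloud, cell_size = 10, origin = c(0, 0),
                             interpolate = FALSE, copy = TRUE) {
  stopifnot(cell_size > 0)
  if (!"nz" %in% names(cloud))
    stop("cloud has no normalized heights; run normalize_height() first")
  if (nrow(cloud) == 0)
    return(data.table::data.table(cell_i = integer(), cell_j = integer(),
                                  cell_x = numeric(), cell_y = numeric()))
  area <- cell_size^2
  dt <- if (copy) cloud[, .(x, y, nz, classification)] else cloud
  dt[, `:=`(cell_i = as.integer(floor((x - origin[1]) / cell_size)),
            cell_j = as.integer(floor((y - origin[2]) / cell_size)))]
  if (nrow(dt) > 2^24) invisible(gc(FALSE))
  res <- dt[, {
    veg <- classification == 1L
    as.list(cell_metrics(nz[veg], x[veg], y[veg],
                         n_ground = sum(classification == 2L),
                         n_all = .N, cell_area = area,
                         interpolate = interpolate))
  }, by = .(cell_i, cell_j)]
  dt[, c("cell_i", "cell_j") := NULL]
  data.table::setorder(res, cell_i, cell_j)
  res[, `:=`(cell_x = origin[1] + (cell_i + 0.5) * cell_size,
             cell_y = origin[2] + (cell_j + 0.5) * cell_size)]
  data.table::setcolorder(res, c("cell_i", "cell_j", "cell_x", "cell_y"))
  data.table::setattr(res, "cell_size", cell_size)
  data.table::setattr(res, "origin", as.numeric(origin))
  data.table::setattr(res, "crs", cloud_crs(cloud))
  res[]
}

#' Write a per-cell feature table as ASCII PLY
#'
#' One vertex per cell centroid with a double property per metric
#' (the per-tile intermediate product of the pipeline); `NA` is written as
#' `NaN`. Use [data.table::fwrite()] on the table itself for CSV export.
#'
#' @param features a table from [extract_features()].
#' @param path output `.ply` path.
#' @return `path`, invisibly.
#' @export
write_features_ply <- function(features, path) {
  cols <- c("cell_x", "cell_y", intersect(als_metric_names(), names(features)))
  hdr <- c("ply", "format ascii 1.0",
           paste("comment crs", attr(features, "crs") %||% "EPSG:28992"),
           paste("comment cell_size", attr(features, "cell_size") %||% 10),
           paste("comment origin",
                 paste((attr(features, "origin") %||% c(0, 0)), collapse = " ")),
           paste("element vertex", nrow(features)),
           paste("property double", cols),
           "end_header")
  writeLines(hdr, path)
  if (nrow(features) > 0)
    data.table::fwrite(features[, ..cols], path, append = TRUE, sep = " ",
                       col.names = FALSE, na = "NaN", scipen = 50)
  invisible(path)
}

#' Read a per-cell feature table written by [write_features_ply()]
#'
#' @param path `.ply` path.
#' @return a feature `data.table` (cell indices reconstructed from the
#'   centroids and the stored cell size).
#' @export
read_features_ply <- function(path) {
  head_lines <- readLines(path, n = 64L, warn = FALSE)
  end <- match("end_header", head_lines)
  if (is.na(end)) stop("not a feature PLY: ", path)
  hdr <- head_lines[seq_len(end)]
  nv <- as.integer(sub("^element vertex ", "", grep("^element vertex ", hdr, value = TRUE)[1]))
  props <- sub("^property \\S+ ", "", grep("^property ", hdr, value = TRUE))
  cs_line <- grep("^comment cell_size ", hdr, value = TRUE)
  cs <- if (length(cs_line)) as.numeric(sub("^comment cell_size ", "", cs_line[1])) else 10
  org_line <- grep("^comment origin ", hdr, value = TRUE)
  org <- if (length(org_line))
    as.numeric(strsplit(sub("^comment origin ", "", org_line[1]), " ")[[1]])
  else c(0, 0)
  crs_line <- grep("^comment crs ", hdr, value = TRUE)
  if (nv == 0) {
    res <- data.table::as.data.table(stats::setNames(
      rep(list(numeric()), length(props)), props))
  } else {
    res <- data.table::fread(path, skip = end, nrows = nv, header = FALSE,
                             col.names = props, sep = " ")
  }
  res[, `:=`(cell_i = as.integer(round((cell_x - org[1]) / cs - 0.5)),
             cell_j = as.integer(round((cell_y - org[2]) / cs - 0.5)))]
  data.table::setcolorder(res, c("cell_i", "cell_j", "cell_x", "cell_y"))
  data.table::setattr(res, "cell_size", cs)
  data.table::setattr(res, "origin", org)
  if (length(crs_line))
    data.table::setattr(res, "crs", sub("^comment crs ", "", crs_line[1]))
  res[]
}
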