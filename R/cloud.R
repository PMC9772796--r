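#' Construct a classified point cloud
#'
#' A point cloud is a `data.table` with one row per return and columns
#' `x`, `y` (projected coordinates in metres), `z` (elevation in metres) and
#' `classification` (integer ASPRS class code). Optional columns carry
#' `nz` (height normalized against the local 1 m minimum, see
#' [normalize_height()]) and `label` (hand label, one of `"vegetation"`,
#' `"ground"`, `"other"`). The projected CRS identifier travels along as an
#' attribute; the Dutch national system EPSG:28992 (Amersfoort / RD New) is
#' the default.
#'
#' Points with non-finite coordinates are dropped with a message: every
#' downstream formula assumes finite heights. Class codes outside the
#' expected national-survey set \{0, 1, 2, 6, 9, 26\} are accepted but
#' reported.
#'
#' @param x,y,z numeric coordinate vectors (metres).
#' @param classification integer ASPRS class codes (1 = unclassified /
#'   vegetation, 2 = ground, 6 = building, 9 = water).
#' @param crs projected CRS identifier string.
#' @param label optional character vector of hand labels.
#' @param nz optional numeric vector of normalized heights.
#' @return an `als_cloud` (a `data.table`).
#' @export
#' @examples
#' pc <- point_cloud(c(0, 1), c(0, 1), c(10, 12), c(2L, 1L))
#' cloud_bounds(pc)
point_cloud <- function(x, y, z, classification = rep(1L, length(x)),
                        crs = "EPSG:28992", label = NULL, nz = NULL) {
  stopifnot(length(x) == length(y), length(x) == length(z),
            length(x) == length(classification))
  dt <- data.table::data.table(
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    classification = as.integer(classification)
  )
  if (!is.null(nz)) dt[, nz := as.numeric(nz)]
  if (!is.null(label)) dt[, label := as.character(label)]
  as_als_cloud(dt, crs = crs)
}

#' Coerce a data.frame to an als_cloud, dropping non-finite coordinates
#'
#' A `data.frame` input is converted to a fresh `data.table`; a
#' `data.table` input is taken over by reference (only its class and crs
#' attributes are set), so country-scale tables are never duplicated.
#'
#' @param dt data.frame/data.table with columns x, y, z, classification.
#' @param crs projected CRS identifier string.
#' @return an `als_cloud`.
#' @export
as_als_cloud <- function(dt, crs = "EPSG:28992") {
  if (!data.table::is.data.table(dt)) dt <- data.table::as.data.table(dt)
  req <- c("x", "y", "z", "classification")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("point cloud is missing column(s): ",
                         paste(miss, collapse = ", "))
  # min/max give an O(1)-memory finiteness screen (range() would copy);
  # the full mask is only materialized when something non-finite is present
  clean <- nrow(dt) == 0 ||
    all(is.finite(c(min(dt$x), max(dt$x), min(dt$y), max(dt$y),
                    min(dt$z), max(dt$z))))
  if (!clean) {
    ok <- is.finite(dt$x) & is.finite(dt$y) & is.finite(dt$z)
    message(sum(!ok), " point(s) with non-finite coordinates dropped")
    dt <- dt[ok]
  }
  known <- c(0L, 1L, 2L, 6L, 9L, 26L)
  odd <- integer(0)
  if (nrow(dt) > 0) {
    # tabulate over the observed code range: O(1) extra memory per point
    lo <- min(dt$classification)
    cnt <- tabulate(dt$classification - (lo - 1L),
                    max(dt$classification) - lo + 1L)
    codes <- which(cnt > 0L) + (lo - 1L)
    odd <- setdiff(codes, known)
  }
  if (length(odd)) message("unexpected class code(s) present: ",
                           paste(sort(odd), collapse = ", "))
  .gc_big(nrow(dt))
  data.table::setattr(dt, "crs", crs)
  data.table::setattr(dt, "class", c("als_cloud", class(data.table::data.table())))
  dt[]
}

#' @export
print.als_cloud <- function(x, ...) {
  b <- cloud_bounds(x)
  cat(sprintf("<als_cloud> %d points, CRS %s\n", nrow(x), cloud_crs(x)))
  if (nrow(x) > 0)
    cat(sprintf("  extent x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f]\n",
                b["xmin"], b["xmax"], b["ymin"], b["ymax"], b["zmin"], b["zmax"]))
  tab <- table(x$classification)
  cat("  classes:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' CRS identifier of a point cloud
#' @param cloud an `als_cloud`.
#' @return CRS string.
#' @export
cloud_crs <- function(cloud) attr(cloud, "crs") %||% "EPSG:28992"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coordinate extrema of a point cloud
#'
#' @param cloud an `als_cloud`.
#' @return named numeric vector `xmin, xmax, ymin, ymax, zmin, zmax`;
#'   all `NA` for an empty cloud (the empty-bounds sentinel).
#' @export
cloud_bounds <- function(cloud) {
  if (nrow(cloud) == 0)
    return(c(xmin = NA_real_, xmax = NA_real_, ymin = NA_real_,
             ymax = NA_real_, zmin = NA_real_, zmax = NA_real_))
  c(xmin = min(cloud$x), xmax = max(cloud$x),
    ymin = min(cloud$y), ymax = max(cloud$y),
    zmin = min(cloud$z), zmax = max(cloud$z))
}

#' Clip an axis-aligned rectangular plot from a point cloud
#'
#' Membership is half-open, `[xmin, xmax) x [ymin, ymax)`, so a partition of
#' the plane into adjacent plots never double-counts boundary points.
#'
#' @param cloud an `als_cloud`.
#' @param footprint numeric `c(xmin, xmax, ymin, ymax)` in metres.
#' @return an `als_cloud` with the points inside the footprint (possibly
#'   zero rows); all columns and the CRS are preserved.
#' @export
#' @examples
#' pc <- point_cloud(c(0.5, 10.5), c(0.5, 0.5), c(1, 1), c(1L, 1L))
#' nrow(clip_plot(pc, c(0, 10, 0, 10)))  # 1
clip_plot <- function(cloud, footprint) {
  stopifnot(length(footprint) == 4)
  footprint <- as.numeric(footprint)
  if (footprint[2] <= footprint[1] || footprint[4] <= footprint[3])
    stop("footprint must have positive side lengths")
  keep <- cloud$x >= footprint[1] & cloud$x < footprint[2] &
    cloud$y >= footprint[3] & cloud$y < footprint[4]
  out <- cloud[keep]
  data.table::setattr(out, "crs", cloud_crs(cloud))
  data.table::setattr(out, "class", class(cloud))
  out[]
}
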