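#' Normalize point heights against the lowest point in a local cell
#'
#' Converts absolute elevations to vegetation heights: each point's
#' normalized height is its elevation minus the lowest elevation among all
#' points (any class) falling in the same `cell_size` x `cell_size` cell.
#' With the default 1 m cells this approximates height above the terrain
#' surface without any ground-model interpolation. The lowest point of every
#' occupied cell gets normalized height exactly 0.
#'
#' Cells are anchored at `origin` (half-open membership), which should be
#' the same anchor as the tile grid so that cell membership is reproducible
#' across tiled and untiled runs.
#'
#' Cells containing no ground-class (class 2) point normalize against their
#' own lowest return; their count is reported with a message and attached as
#' attribute `n_ground_free_cells`.
#'
#' @param cloud an `als_cloud` with at least one point.
#' @param cell_size normalization cell side in metres (default 1).
#' @param origin numeric `c(x, y)` grid anchor in metres.
#' @param copy work on a copy of the cloud (default). `copy = FALSE` adds
#'   the `nz` column to `cloud` itself by reference, halving peak memory on
#'   country-scale tiles; use only on clouds the caller owns.
#' @return the cloud with an added/replaced `nz` column (normalized height,
#'   metres, `>= 0`); class codes and point order unchanged.
#' @export
#' @examples
#' pc <- point_cloud(rep(0.5, 3), rep(0.5, 3), c(5.2, 6.0, 7.3), c(2L, 1L, 1L))
#' normalize_height(pc)$nz  # 0.0 0.8 2.1
normalize_height <- function(cloud, cell_size = 1, origin = c(0, 0),
                             copy = TRUE) {
  stopifnot(nrow(cloud) > 0, cell_size > 0)
  ci <- as.integer(floor((cloud$x - origin[1]) / cell_size))
  cj <- as.integer(floor((cloud$y - origin[2]) / cell_size))
  out <- if (copy) data.table::copy(cloud) else cloud
  big <- nrow(out) > 2^24
  out[, `:=`(.ci = ci, .cj = cj)]
  rm(ci, cj)
  if (big) invisible(gc(FALSE))
  out[, nz := z - min(z), by = .(.ci, .cj)]
  if (big) invisible(gc(FALSE))
  gf <- out[, .(gf = !any(classification == 2L)), by = .(.ci, .cj)][, sum(gf)]
  if (gf > 0) message(gf, " normalization cell(s) contain no ground-class point")
  out[, c(".ci", ".cj") := NULL]
  data.table::setattr(out, "crs", cloud_crs(cloud))
  data.table::setattr(out, "class", class(cloud))
  data.table::setattr(out, "n_ground_free_cells", gf)
  out[]
}
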