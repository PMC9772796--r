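# Retiling onto a regular kilometre grid: the first pipeline stage. Tiles,
# feature cells and normalization cells all share one origin so that the
# finer grids nest inside tiles and tiled and untiled runs agree.

#' Define a regular square tile grid
#'
#' Tile `(i, j)` (zero-based) covers the half-open square
#' `[origin_x + i*s, origin_x + (i+1)*s) x [origin_y + j*s, origin_y + (j+1)*s)`.
#'
#' @param origin_x,origin_y lower-left anchor of the grid in metres.
#' @param tile_size tile side length in metres (default 1000, the 1 km
#'   national processing grid).
#' @param n_tiles_x,n_tiles_y grid extent in tiles (default 512 x 512,
#'   enough to span the Netherlands at 1 km).
#' @return a `tile_grid` list.
#' @export
tile_grid <- function(origin_x = 0, origin_y = 0, tile_size = 1000,
                      n_tiles_x = 512L, n_tiles_y = 512L) {
  stopifnot(tile_size > 0, n_tiles_x >= 1, n_tiles_y >= 1)
  structure(list(origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
                 tile_size = as.numeric(tile_size),
                 n_tiles_x = as.integer(n_tiles_x), n_tiles_y = as.integer(n_tiles_y)),
            class = "tile_grid")
}

#' Snap a grid origin down to a tile multiple of a cloud's bounding box
#'
#' Default anchor rule when no national grid origin is configured: the
#' lower-left corner of the input bounding box, rounded down to a multiple
#' of the tile size.
#'
#' @param clouds a list of `als_cloud`s (or a single cloud).
#' @param tile_size tile side length in metres.
#' @return numeric `c(origin_x, origin_y)`.
#' @export
default_grid_origin <- function(clouds, tile_size = 1000) {
  if (inherits(clouds, "als_cloud")) clouds <- list(clouds)
  xmin <- min(vapply(clouds, function(cl) cloud_bounds(cl)[["xmin"]], 0))
  ymin <- min(vapply(clouds, function(cl) cloud_bounds(cl)[["ymin"]], 0))
  c(floor(xmin / tile_size) * tile_size, floor(ymin / tile_size) * tile_size)
}

#' Map coordinates to tile indices
#'
#' @param grid a `tile_grid`.
#' @param x,y coordinate vectors in metres.
#' @return integer matrix with columns `i`, `j` (zero-based tile indices);
#'   rows are `NA` for points outside the grid (the outside sentinel).
#' @export
#' @examples
#' g <- tile_grid(0, 0, 1000)
#' tile_index(g, c(1500, 1000), c(2500, 0))  # (1,2) and (1,0)
tile_index <- function(grid, x, y) {
  big <- length(x) > 2^24
  i <- as.integer(floor((x - grid$origin_x) / grid$tile_size))
  if (big) invisible(gc(FALSE))
  j <- as.integer(floor((y - grid$origin_y) / grid$tile_size))
  if (big) invisible(gc(FALSE))
  out <- i < 0L | i >= grid$n_tiles_x | j < 0L | j >= grid$n_tiles_y
  i[out] <- NA_integer_
  j[out] <- NA_integer_
  if (big) invisible(gc(FALSE))
  cbind(i = i, j = j)
}

#' Split point clouds into tiles on a regular grid
#'
#' Every in-grid point lands in exactly one tile file (half-open tile
#' membership); points from different input clouds that share a tile are
#' merged into one file. Points outside the grid are dropped with a
#' message. Empty tiles produce no file.
#'
#' @param clouds a list of `als_cloud`s, a single cloud, or a character
#'   vector of point-cloud file paths.
#' @param grid a `tile_grid`, or `NULL` to anchor a default grid at the
#'   snapped-down input bounding box.
#' @param out_dir output directory for tile files.
#' @param format tile file format, `"las"` (default) or `"ply"`.
#' @return the manifest: a `data.table` with columns `i`, `j`, `path`,
#'   `n_points`, sorted by `(i, j)`; also written to
#'   `file.path(out_dir, "tiles.json")`. The total dropped-point count is
#'   attached as attribute `n_dropped`.
#' @export
retile <- function(clouds, grid = NULL, out_dir, format = "las") {
  if (is.character(clouds)) clouds <- lapply(clouds, read_point_cloud)
  if (inherits(clouds, "als_cloud")) clouds <- list(clouds)
  stopifnot(length(clouds) >= 1)
  crs <- cloud_crs(clouds[[1]])
  if (is.null(grid)) {
    org <- default_grid_origin(clouds)
    grid <- tile_grid(org[1], org[2])
  }
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)

  # avoid materializing a concatenated copy of the inputs: tiles are cut
  # with a per-point row-index table instead (large archives stay single)
  all <- if (length(clouds) == 1L) clouds[[1]]
         else data.table::rbindlist(clouds, fill = TRUE)
  ij <- tile_index(grid, all$x, all$y)
  grp <- data.table::data.table(ti = ij[, "i"], tj = ij[, "j"],
                                row = seq_len(nrow(all)))
  rm(ij)
  if (nrow(all) > 2^24) invisible(gc(FALSE))
  n_drop <- sum(is.na(grp$ti))
  if (n_drop > 0) message(n_drop, " point(s) outside the tile grid dropped")
  grp <- grp[!is.na(ti)]
  data.table::setkey(grp, ti, tj)
  if (nrow(all) > 2^24) invisible(gc(FALSE))
  idx <- unique(grp, by = c("ti", "tj"))[, .(ti, tj)]
  rows <- vector("list", nrow(idx))
  for (k in seq_len(nrow(idx))) {
    i <- idx$ti[k]; j <- idx$tj[k]
    rws <- grp[.(i, j), row]
    path <- file.path(out_dir, sprintf("tile_%d_%d.%s", i, j, format))
    if (format == "las") {
      # stream the tile subset straight to disk, never materializing it
      write_las(all, path, rows = rws)
    } else {
      tc <- as_als_cloud(all[rws], crs = crs)
      write_point_cloud(tc, path, format = format)
      rm(tc)
    }
    rows[[k]] <- data.table::data.table(i = i, j = j, path = path,
                                        n_points = length(rws))
    rm(rws)
    if (nrow(all) > 2^24) invisible(gc(FALSE))
  }
  manifest <- data.table::rbindlist(rows)
  data.table::setorder(manifest, i, j)
  jsonlite::write_json(
    list(origin = c(grid$origin_x, grid$origin_y), tile_size = grid$tile_size,
         crs = crs, tiles = manifest),
    file.path(out_dir, "tiles.json"), auto_unbox = TRUE, digits = NA)
  data.table::setattr(manifest, "n_dropped", n_drop)
  data.table::setattr(manifest, "grid", grid)
  manifest[]
}
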