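# End-to-end orchestration: retile -> normalize -> extract features ->
# rasterize (-> mask). Feature cells and normalization cells are forced to
# share the tile grid's anchor and to divide the tile size, so a tiled run
# and an untiled run of the same scene produce identical rasters.

#' Run the full raster-production pipeline
#'
#' Executes the four processing stages in order on one or more input
#' clouds and writes one single-band GeoTIFF per metric, plus a JSON
#' manifest with MD5 checksums and per-stage counts. Re-running with the
#' same inputs and configuration reproduces identical rasters.
#'
#' @param inputs character vector of point-cloud files, a single
#'   `als_cloud`, or a list of them.
#' @param out_dir output directory.
#' @param grid_origin numeric `c(x, y)` tile-grid anchor, or `NULL` to
#'   snap the input bounding box down to a tile multiple.
#' @param tile_size tile side in metres (default 1000).
#' @param cell_size feature cell side in metres (default 10); must divide
#'   `tile_size`.
#' @param norm_cell normalization cell side in metres (default 1); must
#'   divide `tile_size`.
#' @param metrics metric identifiers to rasterize (default all 26).
#' @param nodata raster nodata sentinel.
#' @param mask optional mask `als_raster`, or a list of polygons (see
#'   [build_mask()]) rasterized onto the output grid; masked variants are
#'   written next to each metric raster.
#' @param interpolate use interpolated percentiles.
#' @param tile_format format for intermediate tile files.
#' @param keep_tiles keep the intermediate tile and feature files.
#' @return the manifest (named list), invisibly; also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(inputs, out_dir, grid_origin = NULL, tile_size = 1000,
                         cell_size = 10, norm_cell = 1,
                         metrics = als_metric_names(), nodata = -9999,
                         mask = NULL, interpolate = FALSE,
                         tile_format = "las", keep_tiles = FALSE) {
  if (tile_size %% cell_size != 0 || tile_size %% norm_cell != 0)
    stop("cell sizes must divide the tile size so grids nest inside tiles")
  bad <- setdiff(metrics, als_metric_names())
  if (length(bad)) stop("unknown metric(s): ", paste(bad, collapse = ", "))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  if (is.character(inputs)) inputs <- lapply(inputs, read_point_cloud)
  if (inherits(inputs, "als_cloud")) inputs <- list(inputs)
  crs <- cloud_crs(inputs[[1]])
  if (is.null(grid_origin))
    grid_origin <- default_grid_origin(inputs, tile_size)
  grid <- tile_grid(grid_origin[1], grid_origin[2], tile_size)

  tile_dir <- file.path(out_dir, "tiles")
  manifest_tiles <- retile(inputs, grid, tile_dir, format = tile_format)
  n_in <- sum(vapply(inputs, nrow, 0L))
  big <- n_in > 2^24
  rm(inputs)
  if (big) invisible(gc(FALSE))

  feats <- vector("list", nrow(manifest_tiles))
  n_ground_free <- 0L
  for (k in seq_len(nrow(manifest_tiles))) {
    tc <- read_point_cloud(manifest_tiles$path[k], crs = crs)
    npc <- withCallingHandlers(
      normalize_height(tc, cell_size = norm_cell, origin = grid_origin,
                       copy = FALSE),
      message = function(m) invokeRestart("muffleMessage"))
    rm(tc)
    n_ground_free <- n_ground_free + (attr(npc, "n_ground_free_cells") %||% 0L)
    feats[[k]] <- extract_features(npc, cell_size = cell_size,
                                   origin = grid_origin,
                                   interpolate = interpolate, copy = FALSE)
    rm(npc)
    if (big) invisible(gc(FALSE))
    if (keep_tiles)
      write_features_ply(feats[[k]],
                         sub(paste0("\\.", tile_format, "$"), "_features.ply",
                             manifest_tiles$path[k]))
  }

  rasters <- character(0)
  mask_layer <- NULL
  for (m in metrics) {
    lay <- rasterize_features(feats, m, cell_size = cell_size,
                              origin = grid_origin, crs = crs, nodata = nodata)
    path <- file.path(out_dir, paste0(m, ".tif"))
    write_geotiff(lay, path)
    rasters <- c(rasters, path)
    if (!is.null(mask)) {
      if (is.null(mask_layer))
        mask_layer <- if (inherits(mask, "als_raster")) mask
                      else build_mask(mask, template = lay)
      mpath <- file.path(out_dir, paste0(m, "_masked.tif"))
      write_geotiff(apply_mask(lay, mask_layer), mpath)
      rasters <- c(rasters, mpath)
    }
  }
  if (!is.null(mask_layer)) {
    mask_path <- file.path(out_dir, "mask.tif")
    write_geotiff(mask_layer, mask_path)
    rasters <- c(rasters, mask_path)
  }
  if (!keep_tiles) unlink(tile_dir, recursive = TRUE)

  manifest <- list(
    crs = crs, grid_origin = grid_origin, tile_size = tile_size,
    cell_size = cell_size, norm_cell = norm_cell,
    counts = list(points_in = n_in,
                  points_tiled = sum(manifest_tiles$n_points),
                  points_dropped = attr(manifest_tiles, "n_dropped") %||% 0L,
                  tiles = nrow(manifest_tiles),
                  ground_free_norm_cells = n_ground_free,
                  cells = sum(vapply(feats, nrow, 0L))),
    rasters = lapply(stats::setNames(rasters, basename(rasters)), function(p)
      list(path = p, md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
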