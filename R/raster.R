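# Single-band georeferenced raster layers: the pipeline's end product.
# Values are held as a matrix with rows running north -> south and columns
# west -> east; nodata cells are NA in memory and a sentinel on disk.

#' Construct a single-band raster layer
#'
#' @param values numeric matrix; row 1 is the northernmost row, column 1
#'   the westernmost column. `NA` entries are nodata.
#' @param origin numeric `c(x, y)` of the grid's top-left corner in metres.
#' @param cell_size cell side in metres.
#' @param crs projected CRS identifier.
#' @param nodata sentinel written to the GeoTIFF nodata tag.
#' @return an `als_raster`.
#' @export
raster_layer <- function(values, origin, cell_size = 10, crs = "EPSG:28992",
                         nodata = -9999) {
  stopifnot(is.matrix(values), length(origin) == 2, cell_size > 0)
  structure(list(values = values, origin = as.numeric(origin),
                 cell_size = as.numeric(cell_size), crs = crs,
                 nodata = as.numeric(nodata)),
            class = "als_raster")
}

#' @export
print.als_raster <- function(x, ...) {
  cat(sprintf("<als_raster> %d x %d cells of %g m, CRS %s, nodata %g\n",
              nrow(x$values), ncol(x$values), x$cell_size, x$crs, x$nodata))
  cat(sprintf("  top-left (%.1f, %.1f); %d valid cell(s)\n",
              x$origin[1], x$origin[2], sum(!is.na(x$values))))
  invisible(x)
}

#' Cell-centre coordinates of a raster layer
#'
#' @param layer an `als_raster`.
#' @return list with numeric vectors `x` (per column) and `y` (per row).
#' @export
raster_cell_centres <- function(layer) {
  list(x = layer$origin[1] + (seq_len(ncol(layer$values)) - 0.5) * layer$cell_size,
       y = layer$origin[2] - (seq_len(nrow(layer$values)) - 0.5) * layer$cell_size)
}

#' Merge per-tile feature tables into a metric raster
#'
#' Each cell centroid maps to exactly one raster cell; the raster covers
#' the union bounding box of all tables, with nodata where no table
#' supplies a value. Two tables supplying the same cell must agree (exact
#' equality, both-`NA` counts as agreement) or an error names the cell;
#' agreeing duplicates are merged. The result does not depend on table
#' order.
#'
#' @param tables a feature `data.table` from [extract_features()] or a list
#'   of them (one per tile).
#' @param metric metric identifier, one of [als_metric_names()].
#' @param cell_size feature cell side in metres.
#' @param origin numeric `c(x, y)` anchor shared by the feature grids.
#' @param crs,nodata passed to [raster_layer()].
#' @return an `als_raster`.
#' @export
rasterize_features <- function(tables, metric, cell_size = 10, origin = c(0, 0),
                               crs = "EPSG:28992", nodata = -9999) {
  if (data.table::is.data.table(tables)) tables <- list(tables)
  stopifnot(length(tables) >= 1)
  if (!metric %in% als_metric_names())
    stop("unknown metric: ", metric)
  cells <- data.table::rbindlist(lapply(tables, function(tb)
    tb[, .(cell_i, cell_j, value = tb[[metric]])]))
  if (nrow(cells) == 0) stop("no cells to rasterize")
  dup <- cells[, .(n_distinct = data.table::uniqueN(value, na.rm = FALSE),
                   .N), by = .(cell_i, cell_j)]
  bad <- dup[n_distinct > 1]
  if (nrow(bad) > 0)
    stop(sprintf("conflicting values for cell (%d, %d) across tiles",
                 bad$cell_i[1], bad$cell_j[1]))
  cells <- unique(cells, by = c("cell_i", "cell_j"))

  imin <- min(cells$cell_i); imax <- max(cells$cell_i)
  jmin <- min(cells$cell_j); jmax <- max(cells$cell_j)
  nc <- imax - imin + 1L; nr <- jmax - jmin + 1L
  vals <- matrix(NA_real_, nrow = nr, ncol = nc)
  r <- jmax - cells$cell_j + 1L      # north -> south
  c_ <- cells$cell_i - imin + 1L     # west -> east
  vals[cbind(r, c_)] <- cells$value
  raster_layer(vals,
               origin = c(origin[1] + imin * cell_size,
                          origin[2] + (jmax + 1) * cell_size),
               cell_size = cell_size, crs = crs, nodata = nodata)
}

#' Rasterize polygons into a binary mask
#'
#' A cell gets value 1 when, under the default `"centre"` rule, its centre
#' point lies inside the union of the polygons (matching the cell-centroid
#' semantics of the metric grids); the `"any"` rule instead marks cells
#' whose 3x3 interior sample grid hits any polygon. Intended for
#' aggregated water/building/road cadastre polygons (1 = water, building,
#' road; 0 = other).
#'
#' @param polygons a list of polygons, each a list of rings, each ring a
#'   two-column matrix of x, y vertices (first ring outer, later rings
#'   holes; even-odd rule within a polygon, union across polygons). The
#'   output of [read_polygons_geojson()].
#' @param template an `als_raster` defining the grid, or `NULL` to build
#'   one from `extent`.
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` when no template is
#'   given.
#' @param cell_size,crs grid parameters when no template is given.
#' @param rule `"centre"` (default) or `"any"`.
#' @return an `als_raster` with values in \{0, 1\} (a mask layer).
#' @export
build_mask <- function(polygons, template = NULL, extent = NULL,
                       cell_size = 10, crs = "EPSG:28992", rule = c("centre", "any")) {
  rule <- match.arg(rule)
  if (is.null(template)) {
    stopifnot(!is.null(extent), length(extent) == 4)
    nc <- as.integer(ceiling((extent[2] - extent[1]) / cell_size))
    nr <- as.integer(ceiling((extent[4] - extent[3]) / cell_size))
    template <- raster_layer(matrix(NA_real_, nr, nc),
                             origin = c(extent[1], extent[3] + nr * cell_size),
                             cell_size = cell_size, crs = crs)
  }
  ctr <- raster_cell_centres(template)
  nr <- nrow(template$values); nc <- ncol(template$values)
  ncell <- nr * nc
  base <- cbind(rep(ctr$x, each = nr), rep(ctr$y, times = nc))  # cell centres
  if (rule == "centre") {
    pts <- base
  } else {
    offs <- expand.grid(dx = c(-1, 0, 1), dy = c(-1, 0, 1)) * template$cell_size / 3
    pts <- do.call(rbind, lapply(seq_len(9), function(k)
      cbind(base[, 1] + offs$dx[k], base[, 2] + offs$dy[k])))
  }
  inside <- rep(FALSE, nrow(pts))
  if (length(polygons) == 0) {
    message("empty polygon set: mask is all zero")
  } else {
    for (pg in polygons) {
      bnd <- do.call(rbind, lapply(pg, function(r) rbind(r, c(NA, NA))))
      bnd <- bnd[-nrow(bnd), , drop = FALSE]
      inside <- inside | mgcv::in.out(bnd, pts)
    }
  }
  hit <- if (rule == "centre") inside
         else rowSums(matrix(inside, nrow = ncell, ncol = 9)) > 0
  mask <- matrix(as.numeric(hit), nrow = nr, ncol = nc)
  raster_layer(mask, origin = template$origin, cell_size = template$cell_size,
               crs = template$crs, nodata = template$nodata)
}

#' Apply a binary mask to a metric raster
#'
#' Cells where the mask is 1 (water/building/road) become nodata; all other
#' cells pass through bit-exact. Applying the same mask twice equals
#' applying it once.
#'
#' @param layer an `als_raster`.
#' @param mask a mask `als_raster` on the identical grid.
#' @return the masked `als_raster`.
#' @export
apply_mask <- function(layer, mask) {
  if (!identical(dim(layer$values), dim(mask$values)) ||
      !isTRUE(all.equal(layer$origin, mask$origin)) ||
      layer$cell_size != mask$cell_size)
    stop("mask grid does not align with the raster grid")
  out <- layer
  out$values[!is.na(mask$values) & mask$values == 1] <- NA_real_
  out
}

#' Read tagged polygons from a GeoJSON file
#'
#' Supports FeatureCollection / Feature / bare geometry documents with
#' Polygon and MultiPolygon geometries. Feature properties are scanned for
#' a surface-type tag (property `type`, `class` or `category`) so water /
#' building / road polygon sets can be filtered before masking.
#'
#' @param path GeoJSON file path.
#' @param types optional character vector: keep only polygons whose tag is
#'   in this set (e.g. `c("water", "building", "road")`).
#' @return list of polygons (each a list of ring matrices) with a `tag`
#'   attribute per polygon.
#' @export
read_polygons_geojson <- function(path, types = NULL) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- switch(doc$type %||% "",
    FeatureCollection = doc$features,
    Feature = list(doc),
    Polygon = ,
    MultiPolygon = list(list(geometry = doc, properties = NULL)),
    stop("unsupported GeoJSON document: ", path))
  ring_mat <- function(r) {
    m <- do.call(rbind, lapply(r, function(p) c(p[[1]], p[[2]])))
    storage.mode(m) <- "double"
    m
  }
  out <- list()
  for (f in feats) {
    g <- f$geometry
    props <- f$properties
    tag <- props$type %||% props$class %||% props$category %||% NA_character_
    polys <- switch(g$type,
      Polygon = list(g$coordinates),
      MultiPolygon = g$coordinates,
      stop("unsupported geometry type: ", g$type))
    for (pg in polys) {
      poly <- lapply(pg, ring_mat)
      attr(poly, "tag") <- tag
      out[[length(out) + 1L]] <- poly
    }
  }
  if (!is.null(types))
    out <- Filter(function(p) isTRUE(attr(p, "tag") %in% types), out)
  out
}
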