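# Synthetic classified scenes with known ground truth. The generator
# emulates the statistical structure of leaf-off national ALS data: a
# terrain surface sampled by ground returns (class 2), vegetation returns
# in the "unclassified" class 1 distributed over vertical strata, and
# class-1 clutter objects (boats, fences, cars) that are *not* vegetation,
# carried with per-point truth labels. Positions are uniform in the plane
# and uniform within each stratum's height range — the simplest
# distributions that keep every metric analytically checkable.

#' Configure a synthetic scene
#'
#' @param extent numeric `c(width, height)` of the scene in metres,
#'   anchored at `origin`.
#' @param density target point density in points per square metre
#'   (default 12, within the 10-20 range typical of the national
#'   leaf-off surveys this emulates); realized counts are Poisson.
#' @param terrain either `list(type = "constant", z0 = <m>)` or
#'   `list(type = "gradient", z0 = <m>, slope_x = , slope_y = )` giving the
#'   ground elevation field.
#' @param layers list of vegetation strata, each
#'   `list(zmin = , zmax = , fraction = )` with heights in metres above the
#'   terrain and fractions (of vegetation points) summing to at most 1;
#'   fractions are renormalized to 1 when they sum below 1.
#' @param ground_fraction fraction of (non-clutter) points that are ground
#'   returns (class 2).
#' @param clutter list of clutter objects, each
#'   `list(x = , y = , w = , h = , zmin = , zmax = , n = )`: an axis-aligned
#'   box footprint with `n` uniform class-1 points at heights
#'   `[zmin, zmax]` above the terrain, truth-labelled `"other"`.
#' @param origin numeric `c(x, y)` lower-left corner.
#' @param ensure_ground_coverage when `TRUE`, add one ground return at a
#'   random position inside every 1 m cell (about +1 point/m^2) so that
#'   height normalization always has terrain support, as in dense leaf-off
#'   surveys. Makes metric truths on noise-free scenes exact.
#' @param seed integer random seed; identical config + seed reproduces the
#'   scene exactly.
#' @param crs CRS identifier.
#' @return a `scene_config` list.
#' @export
scene_config <- function(extent = c(100, 100), density = 12,
                         terrain = list(type = "constant", z0 = 0),
                         layers = list(list(zmin = 0, zmax = 2, fraction = 1)),
                         ground_fraction = 0.3, clutter = list(),
                         origin = c(0, 0), ensure_ground_coverage = FALSE,
                         seed = 1L, crs = "EPSG:28992") {
  stopifnot(all(extent > 0), density > 0,
            ground_fraction >= 0, ground_fraction <= 1)
  fr <- vapply(layers, `[[`, 0, "fraction")
  if (any(fr < 0) || sum(fr) > 1 + 1e-9)
    stop("layer fractions must be in [0,1] and sum to at most 1")
  structure(list(extent = as.numeric(extent), density = density,
                 terrain = terrain, layers = layers,
                 ground_fraction = ground_fraction, clutter = clutter,
                 origin = as.numeric(origin),
                 ensure_ground_coverage = isTRUE(ensure_ground_coverage),
                 seed = as.integer(seed), crs = crs),
            class = "scene_config")
}

.terrain_z <- function(terrain, x, y) {
  switch(terrain$type,
    constant = rep(terrain$z0, length(x)),
    gradient = terrain$z0 + terrain$slope_x * x + terrain$slope_y * y,
    stop("unknown terrain type: ", terrain$type))
}

#' Generate a classified point cloud from a scene configuration
#'
#' Draws `Poisson(density * area)` points uniformly in the plane, splits
#' them into ground (class 2, on the terrain surface) and vegetation
#' (class 1, height uniform within a stratum chosen by the layer
#' fractions), then adds the configured clutter boxes as class-1 points
#' with truth label `"other"`. The `label` column carries the truth for
#' every point, so the cloud doubles as a hand-labelled input for the
#' validation module.
#'
#' @param config a `scene_config`.
#' @return an `als_cloud` with columns `x`, `y`, `z`, `classification` and
#'   truth `label`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  area <- prod(config$extent)
  n <- stats::rpois(1, config$density * area)
  x <- config$origin[1] + stats::runif(n, 0, config$extent[1])
  y <- config$origin[2] + stats::runif(n, 0, config$extent[2])

  # work with index subsets and free temporaries promptly: country-scale
  # scenes reach tens of millions of points
  is_ground <- stats::runif(n) < config$ground_fraction
  .gc_big(n)
  cls <- rep(1L, n); cls[is_ground] <- 2L
  lab <- rep("vegetation", n); lab[is_ground] <- "ground"
  z <- numeric(n)
  ig <- which(is_ground)
  z[ig] <- .terrain_z(config$terrain, x[ig], y[ig])
  iv <- which(!is_ground)
  rm(is_ground, ig)
  .gc_big(n)
  nveg <- length(iv)
  if (nveg > 0 && length(config$layers) > 0) {
    fr <- vapply(config$layers, `[[`, 0, "fraction")
    stratum <- sample.int(length(fr), nveg, replace = TRUE, prob = fr / sum(fr))
    zmin <- vapply(config$layers, `[[`, 0, "zmin")[stratum]
    zmax <- vapply(config$layers, `[[`, 0, "zmax")[stratum]
    rm(stratum)
    hts <- zmin + stats::runif(nveg) * (zmax - zmin)
    rm(zmin, zmax)
    .gc_big(n)
    z[iv] <- .terrain_z(config$terrain, x[iv], y[iv]) + hts
    rm(hts)
  }
  rm(iv)
  .gc_big(n)

  if (isTRUE(config$ensure_ground_coverage)) {
    gg <- expand.grid(i = seq_len(ceiling(config$extent[1])) - 1L,
                      j = seq_len(ceiling(config$extent[2])) - 1L)
    gx <- config$origin[1] + gg$i + stats::runif(nrow(gg))
    gy <- config$origin[2] + gg$j + stats::runif(nrow(gg))
    x <- c(x, gx); y <- c(y, gy)
    z <- c(z, .terrain_z(config$terrain, gx, gy))
    cls <- c(cls, rep(2L, nrow(gg)))
    lab <- c(lab, rep("ground", nrow(gg)))
  }

  for (ob in config$clutter) {
    cx <- ob$x + stats::runif(ob$n, 0, ob$w)
    cy <- ob$y + stats::runif(ob$n, 0, ob$h)
    czt <- .terrain_z(config$terrain, cx, cy)
    x <- c(x, cx); y <- c(y, cy)
    z <- c(z, czt + ob$zmin + stats::runif(ob$n) * (ob$zmax - ob$zmin))
    cls <- c(cls, rep(1L, ob$n))
    lab <- c(lab, rep("other", ob$n))
  }
  # setDT avoids copying the (possibly very large) column vectors
  dt <- data.table::setDT(list(x = x, y = y, z = z,
                               classification = cls, label = lab))
  as_als_cloud(dt, crs = config$crs)
}

#' Truth metric raster computed from ground-truth labels
#'
#' Re-runs the production feature extraction with the truth labels playing
#' the role of the classification (vegetation -> class 1, ground ->
#' class 2, other -> class 0), giving the raster a perfect classifier
#' would produce. On clutter-free scenes it equals the pipeline raster
#' exactly.
#'
#' @param scene a labelled `als_cloud` from [generate_scene()].
#' @param metric metric identifier.
#' @param cell_size feature cell side in metres.
#' @param origin grid anchor.
#' @param norm_cell normalization cell side in metres.
#' @return an `als_raster`.
#' @export
scene_truth_raster <- function(scene, metric, cell_size = 10, origin = c(0, 0),
                               norm_cell = 1) {
  stopifnot("label" %in% names(scene))
  truth <- data.table::copy(scene)
  truth[, classification := c(vegetation = 1L, ground = 2L, other = 0L)[label]]
  truth <- as_als_cloud(truth, crs = cloud_crs(scene))
  npc <- suppressMessages(normalize_height(truth, cell_size = norm_cell,
                                           origin = origin))
  feats <- extract_features(npc, cell_size = cell_size, origin = origin)
  rasterize_features(feats, metric, cell_size = cell_size, origin = origin,
                     crs = cloud_crs(scene))
}

#' Generate hand-labelled 10 m validation plots with planted clutter
#'
#' Each plot is a 10 m x 10 m labelled cloud: ground returns on a flat
#' terrain, low-vegetation returns, and a planted block of class-1 clutter
#' (a boat/car-sized box) sized so that the plot's class-1 misclassified
#' fraction *exactly* equals the recorded planted fraction (counts are
#' integers, so the requested fraction is rounded to the nearest
#' achievable one).
#'
#' @param n_plots number of plots.
#' @param clutter_fraction requested misclassified fraction(s) of class-1
#'   points, recycled over plots.
#' @param seed integer random seed.
#' @param density point density in points per square metre.
#' @param plot_size plot side in metres.
#' @param veg_height vegetation stratum upper bound in metres.
#' @param clutter_height clutter box height range `c(zmin, zmax)` metres.
#' @return list of labelled plots (`als_cloud`s with a `footprint`
#'   attribute); the achieved per-plot fractions are attached as attribute
#'   `planted_fraction`.
#' @export
make_validation_plots <- function(n_plots = 100, clutter_fraction = 0,
                                  seed = 1L, density = 15, plot_size = 10,
                                  veg_height = 1.5,
                                  clutter_height = c(0.5, 3)) {
  stopifnot(n_plots >= 1, all(clutter_fraction >= 0), all(clutter_fraction < 1))
  frac <- rep_len(clutter_fraction, n_plots)
  set.seed(seed)
  plots <- vector("list", n_plots)
  planted <- numeric(n_plots)
  area <- plot_size^2
  for (k in seq_len(n_plots)) {
    n <- stats::rpois(1, density * area)
    n_ground <- stats::rbinom(1, n, 0.3)
    n_c1 <- max(1L, n - n_ground)
    n_clut <- as.integer(round(frac[k] * n_c1))
    n_veg <- n_c1 - n_clut
    planted[k] <- n_clut / n_c1

    gx <- stats::runif(n_ground, 0, plot_size)
    gy <- stats::runif(n_ground, 0, plot_size)
    vx <- stats::runif(n_veg, 0, plot_size)
    vy <- stats::runif(n_veg, 0, plot_size)
    vz <- stats::runif(n_veg, 0, veg_height)
    # clutter box: 3 x 3 m, random corner fully inside the plot
    bx <- stats::runif(1, 0, plot_size - 3)
    by <- stats::runif(1, 0, plot_size - 3)
    cx <- bx + stats::runif(n_clut, 0, 3)
    cy <- by + stats::runif(n_clut, 0, 3)
    cz <- stats::runif(n_clut, clutter_height[1], clutter_height[2])

    pl <- point_cloud(
      x = c(gx, vx, cx), y = c(gy, vy, cy), z = c(rep(0, n_ground), vz, cz),
      classification = c(rep(2L, n_ground), rep(1L, n_veg + n_clut)),
      label = c(rep("ground", n_ground), rep("vegetation", n_veg),
                rep("other", n_clut))
    )
    data.table::setattr(pl, "footprint", c(0, 0))
    plots[[k]] <- pl
  }
  attr(plots, "planted_fraction") <- planted
  plots
}
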