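# Minimal single-band GeoTIFF codec: baseline little-endian TIFF with
# 32-bit IEEE float samples plus the georeferencing tags GIS software
# expects (ModelPixelScale, ModelTiepoint, GeoKeyDirectory with a projected
# EPSG code) and the conventional GDAL_NODATA ASCII tag. One strip,
# uncompressed, north-up. The reader accepts both byte orders and
# multi-strip layouts, and float32 or float64 samples.

TIFF_TYPE_SIZE <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)  # by type id

.u16le <- function(v) writeBin(as.integer(v), raw(), size = 2, endian = "little")
.u32le <- function(v) writeBin(as.integer(v), raw(), size = 4, endian = "little")
.f64le <- function(v) writeBin(as.numeric(v), raw(), size = 8, endian = "little")

#' Write a raster layer as a single-band GeoTIFF
#'
#' Samples are 32-bit floats (values survive a round trip to the precision
#' of that type); nodata cells are written as the layer's sentinel, which
#' is recorded in the GDAL_NODATA tag. The CRS is stored as a projected
#' EPSG code in the GeoTIFF key directory (EPSG:28992 by default).
#'
#' @param layer an `als_raster`.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_geotiff <- function(layer, path) {
  vals <- layer$values
  h <- nrow(vals); w <- ncol(vals)
  stopifnot(h >= 1, w >= 1)
  pix <- as.vector(t(vals))                   # row-major, top row first
  pix[is.na(pix)] <- layer$nodata
  epsg <- as.integer(sub("^EPSG:", "", layer$crs))
  if (is.na(epsg)) epsg <- 32767L             # user-defined
  nodata_str <- c(charToRaw(format(layer$nodata, scientific = FALSE)), as.raw(0))

  data_len <- w * h * 4L
  ext <- list(
    pixel_scale = .f64le(c(layer$cell_size, layer$cell_size, 0)),
    tiepoint = .f64le(c(0, 0, 0, layer$origin[1], layer$origin[2], 0)),
    geokeys = .u16le(c(1L, 1L, 0L, 3L,
                       1024L, 0L, 1L, 1L,    # model type: projected
                       1025L, 0L, 1L, 1L,    # raster type: pixel is area
                       3072L, 0L, 1L, epsg)),
    nodata = nodata_str
  )
  ext_off <- 8L + data_len
  offs <- ext_off + cumsum(c(0L, vapply(ext, length, 1L)))[seq_along(ext)]
  names(offs) <- names(ext)
  ifd_off <- ext_off + sum(vapply(ext, length, 1L))

  entry <- function(tag, type, count, value, inline = TRUE) {
    val <- if (inline) {
      r <- if (type %in% c(3L)) .u16le(value) else .u32le(value)
      c(r, raw(4L - length(r)))
    } else .u32le(value)
    c(.u16le(tag), .u16le(type), .u32le(count), val)
  }
  entries <- list(
    entry(256L, 4L, 1L, w),
    entry(257L, 4L, 1L, h),
    entry(258L, 3L, 1L, 32L),
    entry(259L, 3L, 1L, 1L),
    entry(262L, 3L, 1L, 1L),
    entry(273L, 4L, 1L, 8L),                 # strip starts after header
    entry(277L, 3L, 1L, 1L),
    entry(278L, 4L, 1L, h),
    entry(279L, 4L, 1L, data_len),
    entry(284L, 3L, 1L, 1L),
    entry(339L, 3L, 1L, 3L),                 # IEEE float
    entry(33550L, 12L, 3L, offs[["pixel_scale"]], inline = FALSE),
    entry(33922L, 12L, 6L, offs[["tiepoint"]], inline = FALSE),
    entry(34735L, 3L, 16L, offs[["geokeys"]], inline = FALSE),
    entry(42113L, 2L, length(nodata_str), offs[["nodata"]], inline = FALSE)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_off, con, size = 4, endian = "little")
  writeBin(pix, con, size = 4, endian = "little")
  for (e in ext) writeBin(e, con)
  writeBin(length(entries), con, size = 2, endian = "little")
  for (e in entries) writeBin(e, con)
  writeBin(0L, con, size = 4, endian = "little")
  invisible(path)
}

#' Read a single-band GeoTIFF into a raster layer
#'
#' Understands the uncompressed single-band float GeoTIFFs produced by
#' [write_geotiff()] (either byte order, one or more strips, 32- or 64-bit
#' float samples). Cells equal to the GDAL_NODATA sentinel become `NA`.
#'
#' @param path `.tif` path.
#' @return an `als_raster`.
#' @export
read_geotiff <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw_all <- readBin(path, raw(), file.info(path)$size)
  order_tag <- rawToChar(raw_all[1:2])
  en <- switch(order_tag, II = "little", MM = "big",
               stop("not a TIFF file: ", path))
  rd_int <- function(bytes, size, signed = TRUE)
    readBin(bytes, integer(), n = length(bytes) / size, size = size,
            signed = signed, endian = en)
  magic <- rd_int(raw_all[3:4], 2)
  if (magic != 42L) stop("not a TIFF file: ", path)
  ifd_off <- rd_int(raw_all[5:8], 4)
  n_ent <- rd_int(raw_all[ifd_off + (1:2)], 2, signed = FALSE)
  tags <- list()
  for (k in seq_len(n_ent)) {
    e <- raw_all[ifd_off + 2L + (k - 1L) * 12L + (1:12)]
    tag <- rd_int(e[1:2], 2, signed = FALSE)
    type <- rd_int(e[3:4], 2, signed = FALSE)
    if (type < 1L || type > 12L) next
    count <- rd_int(e[5:8], 4)
    nbytes <- TIFF_TYPE_SIZE[type] * count
    src <- if (nbytes <= 4) e[9:12][seq_len(nbytes)]
           else raw_all[rd_int(e[9:12], 4) + seq_len(nbytes)]
    value <- switch(as.character(type),
      `2` = rawToChar(src[src != as.raw(0)]),
      `3` = rd_int(src, 2, signed = FALSE),
      `4` = rd_int(src, 4),
      `12` = readBin(src, numeric(), count, size = 8, endian = en),
      src)
    tags[[as.character(tag)]] <- value
  }
  need <- function(tag) tags[[as.character(tag)]] %||%
    stop("TIFF tag ", tag, " missing in ", path)
  w <- need(256L); h <- need(257L)
  bits <- tags[["258"]] %||% 32L
  if ((tags[["259"]] %||% 1L) != 1L) stop("compressed TIFF not supported: ", path)
  if ((tags[["339"]] %||% 3L) != 3L || !bits %in% c(32L, 64L))
    stop("only IEEE float samples supported: ", path)
  strip_off <- need(273L)
  strip_cnt <- need(279L)
  pix_raw <- unlist(lapply(seq_along(strip_off), function(k)
    raw_all[strip_off[k] + seq_len(strip_cnt[k])]))
  pix <- readBin(pix_raw, numeric(), w * h, size = bits / 8L, endian = en)
  vals <- matrix(pix, nrow = h, ncol = w, byrow = TRUE)

  scale <- tags[["33550"]] %||% c(1, 1, 0)
  tie <- tags[["33922"]] %||% rep(0, 6)
  origin <- c(tie[4] - tie[1] * scale[1], tie[5] + tie[2] * scale[2])
  crs <- "EPSG:28992"
  gk <- tags[["34735"]]
  if (!is.null(gk) && length(gk) >= 4) {
    keys <- matrix(gk[-(1:4)], ncol = 4, byrow = TRUE)
    pcs <- keys[keys[, 1] == 3072L, 4]
    if (length(pcs) == 1 && pcs != 32767L) crs <- paste0("EPSG:", pcs)
  }
  nodata <- suppressWarnings(as.numeric(tags[["42113"]] %||% NA))
  if (!is.na(nodata)) {
    # compare against the sentinel as stored at the file's precision
    sent <- readBin(writeBin(nodata, raw(), size = bits / 8L), numeric(),
                    1, size = bits / 8L)
    vals[vals == sent] <- NA_real_
  }
  raster_layer(vals, origin = origin, cell_size = scale[1], crs = crs,
               nodata = if (is.na(nodata)) -9999 else nodata)
}
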