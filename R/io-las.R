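# LAS 1.2 reader/writer, point data record format 0 (x, y, z, classification).
# Coordinates are stored as int32 counts of a scale step from an offset; the
# writer picks a 0.001 m step so round-trip error stays below 0.5 mm.

LAS_HEADER_SIZE <- 227L
LAS_POINT_SIZE <- 20L
LAS_IO_CHUNK <- 4194304L  # points per readBin/writeBin block

# keep multi-gigabyte IO loops from accumulating dead chunk buffers
.gc_big <- function(n) if (n > 2^24) invisible(gc(FALSE))

#' Write a point cloud as a LAS 1.2 file
#'
#' Point data record format 0. Coordinates are quantized with the given
#' scale (default 1 mm); the offset is the floor of the coordinate minima.
#' With `rows`, only that subset of points is written — streamed in chunks
#' without materializing the subset table, which is how the retiler cuts
#' tiles out of country-scale inputs.
#'
#' @param cloud an `als_cloud`.
#' @param path output file path (conventionally `.las`).
#' @param scale coordinate quantization step in metres.
#' @param rows optional integer vector of row indices to write.
#' @return `path`, invisibly.
#' @export
write_las <- function(cloud, path, scale = 0.001, rows = NULL) {
  n <- if (is.null(rows)) nrow(cloud) else length(rows)
  # first pass: bounds, offsets and class-code check, chunkwise
  lo <- c(Inf, Inf, Inf); hi <- c(-Inf, -Inf, -Inf); crange <- c(0L, 0L)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + LAS_IO_CHUNK - 1L)
    idx <- if (is.null(rows)) i:j else rows[i:j]
    lo <- pmin(lo, c(min(cloud$x[idx]), min(cloud$y[idx]), min(cloud$z[idx])))
    hi <- pmax(hi, c(max(cloud$x[idx]), max(cloud$y[idx]), max(cloud$z[idx])))
    crange <- c(min(crange[1], min(cloud$classification[idx])),
                max(crange[2], max(cloud$classification[idx])))
    i <- j + 1L
  }
  if (n > 0 && (crange[1] < 0L || crange[2] > 31L))
    stop("LAS point format 0 stores class codes 0-31 only")
  off <- if (n > 0) floor(lo) else c(0, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))

  writeChar("LASF", con, 4, eos = NULL)
  writeBin(rep(0L, 2), con, size = 2, endian = "little")      # source id, encoding
  writeBin(raw(16), con)                                       # GUID
  writeBin(c(1L, 2L), con, size = 1)                           # version 1.2
  writeChar(formatC("alsmetrics", width = 32, flag = "-"), con, 32, eos = NULL)
  writeChar(formatC("alsmetrics", width = 32, flag = "-"), con, 32, eos = NULL)
  writeBin(c(1L, 2000L), con, size = 2, endian = "little")     # day, year
  writeBin(LAS_HEADER_SIZE, con, size = 2, endian = "little")
  writeBin(LAS_HEADER_SIZE, con, size = 4, endian = "little")  # offset to points
  writeBin(0L, con, size = 4, endian = "little")               # n VLRs
  writeBin(0L, con, size = 1)                                  # point format 0
  writeBin(LAS_POINT_SIZE, con, size = 2, endian = "little")
  writeBin(n, con, size = 4, endian = "little")
  writeBin(c(n, 0L, 0L, 0L, 0L), con, size = 4, endian = "little")
  writeBin(rep(scale, 3), con, size = 8, endian = "little")
  writeBin(off, con, size = 8, endian = "little")
  b <- if (n == 0) rep(0, 6) else c(hi[1], lo[1], hi[2], lo[2], hi[3], lo[3])
  writeBin(as.numeric(b), con, size = 8, endian = "little")

  .gc_big(n)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + LAS_IO_CHUNK - 1L)
    m <- j - i + 1L
    idx <- if (is.null(rows)) i:j else rows[i:j]
    rec <- matrix(as.raw(0), nrow = LAS_POINT_SIZE, ncol = m)
    rec[1:4, ] <- writeBin(as.integer(round((cloud$x[idx] - off[1]) / scale)),
                           raw(), size = 4, endian = "little")
    rec[5:8, ] <- writeBin(as.integer(round((cloud$y[idx] - off[2]) / scale)),
                           raw(), size = 4, endian = "little")
    rec[9:12, ] <- writeBin(as.integer(round((cloud$z[idx] - off[3]) / scale)),
                            raw(), size = 4, endian = "little")
    rec[15, ] <- as.raw(9L)  # return 1 of 1
    rec[16, ] <- as.raw(cloud$classification[idx])
    writeBin(as.vector(rec), con)
    i <- j + 1L
    rm(rec, idx); .gc_big(n)
  }
  invisible(path)
}

#' Read a LAS file into a point cloud
#'
#' Supports uncompressed LAS (any 1.x minor version) with point data record
#' formats 0-3; only x, y, z and the classification code are retained.
#' Compressed LAZ input is rejected with a pointer to decompress first.
#'
#' @param path LAS file path.
#' @param crs CRS identifier to attach (LAS 1.2 headers do not carry one).
#' @return an `als_cloud`.
#' @export
read_las <- function(path, crs = "EPSG:28992") {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readChar(con, 4, useBytes = TRUE)
  if (!identical(sig, "LASF")) stop("not a LAS file (bad signature): ", path)
  seek(con, 24)
  ver <- readBin(con, integer(), 2, size = 1, signed = FALSE)
  if (ver[1] != 1L) stop("unsupported LAS version ", ver[1], ".", ver[2])
  seek(con, 96)
  pt_offset <- readBin(con, integer(), 1, size = 4, endian = "little")
  seek(con, 100); n_vlr <- readBin(con, integer(), 1, size = 4, endian = "little")
  fmt <- readBin(con, integer(), 1, size = 1, signed = FALSE)
  if (bitwAnd(fmt, 128L) != 0L)
    stop("compressed LAZ data is not supported; decompress to LAS first: ", path)
  if (fmt > 3L) stop("unsupported LAS point format ", fmt)
  rec_len <- readBin(con, integer(), 1, size = 2, signed = FALSE, endian = "little")
  n <- readBin(con, integer(), 1, size = 4, endian = "little")
  seek(con, 131)
  scl <- readBin(con, numeric(), 3, size = 8, endian = "little")
  off <- readBin(con, numeric(), 3, size = 8, endian = "little")

  seek(con, pt_offset)
  xs <- vector("list", 0); ys <- vector("list", 0)
  zs <- vector("list", 0); cl <- vector("list", 0)
  got <- 0L; k <- 0L
  while (got < n) {
    m <- min(LAS_IO_CHUNK, n - got)
    blk <- readBin(con, raw(), m * rec_len)
    if (length(blk) < m * rec_len) stop("truncated LAS point data: ", path)
    rec <- matrix(blk, nrow = rec_len)
    k <- k + 1L
    xs[[k]] <- readBin(as.vector(rec[1:4, ]), integer(), m, size = 4, endian = "little")
    ys[[k]] <- readBin(as.vector(rec[5:8, ]), integer(), m, size = 4, endian = "little")
    zs[[k]] <- readBin(as.vector(rec[9:12, ]), integer(), m, size = 4, endian = "little")
    # low 5 bits of the classification byte; high bits are synthetic/key/withheld flags
    cl[[k]] <- bitwAnd(as.integer(rec[16, ]), 31L)
    got <- got + m
    rm(blk, rec); .gc_big(n)
  }
  cols <- list(x = NULL, y = NULL, z = NULL, classification = NULL)
  cols$x <- unlist(xs) * scl[1] + off[1]; xs <- NULL
  cols$y <- unlist(ys) * scl[2] + off[2]; ys <- NULL
  cols$z <- unlist(zs) * scl[3] + off[3]; zs <- NULL
  cols$classification <- unlist(cl); cl <- NULL
  .gc_big(n)
  dt <- data.table::setDT(cols)
  if (n == 0) dt <- data.table::data.table(x = numeric(), y = numeric(),
                                           z = numeric(), classification = integer())
  as_als_cloud(dt, crs = crs)
}
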