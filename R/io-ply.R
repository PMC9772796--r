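# ASCII PLY reader/writer. PLY carries small fixtures, normalized clouds
# (extra vertex property normalized_z) and hand-labelled plots (property
# hand_label: 1 = vegetation, 2 = ground, 3 = other).

PLY_LABELS <- c("vegetation", "ground", "other")

#' Write a point cloud as ASCII PLY
#'
#' Vertex properties `x`, `y`, `z` (double) and `classification` (uchar);
#' a `nz` column is written as property `normalized_z` and a `label` column
#' as property `hand_label` (uchar; 1 = vegetation, 2 = ground, 3 = other).
#'
#' @param cloud an `als_cloud`.
#' @param path output file path (conventionally `.ply`).
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path) {
  has_nz <- "nz" %in% names(cloud)
  has_lab <- "label" %in% names(cloud)
  hdr <- c("ply", "format ascii 1.0",
           paste("comment crs", cloud_crs(cloud)),
           if (has_lab) "comment hand_label codes: 1=vegetation 2=ground 3=other",
           paste("element vertex", nrow(cloud)),
           "property double x", "property double y", "property double z",
           "property uchar classification",
           if (has_nz) "property double normalized_z",
           if (has_lab) "property uchar hand_label",
           "end_header")
  writeLines(hdr, path)
  cols <- c("x", "y", "z", "classification",
            if (has_nz) "nz", if (has_lab) "label")
  body <- cloud[, ..cols]
  if (has_lab) {
    code <- match(body$label, PLY_LABELS)
    if (anyNA(code)) stop("hand labels must be one of: ",
                          paste(PLY_LABELS, collapse = ", "))
    body[, label := code]
  }
  if (nrow(body) > 0)
    data.table::fwrite(body, path, append = TRUE, sep = " ",
                       col.names = FALSE, scipen = 50)
  invisible(path)
}

#' Read an ASCII PLY point cloud
#'
#' @param path PLY file path.
#' @param crs fallback CRS identifier when the file has no crs comment.
#' @return an `als_cloud`; `normalized_z` and `hand_label` vertex properties
#'   become the `nz` and `label` columns.
#' @export
read_ply <- function(path, crs = "EPSG:28992") {
  if (!file.exists(path)) stop("no such file: ", path)
  head_lines <- readLines(path, n = 64L, warn = FALSE)
  if (length(head_lines) == 0 || head_lines[1] != "ply")
    stop("not a PLY file: ", path)
  end <- match("end_header", head_lines)
  if (is.na(end)) stop("PLY header too long or missing end_header: ", path)
  hdr <- head_lines[seq_len(end)]
  if (!any(grepl("^format ascii", hdr)))
    stop("only ASCII PLY is supported: ", path)
  nv <- as.integer(sub("^element vertex ", "", grep("^element vertex ", hdr, value = TRUE)[1]))
  props <- sub("^property \\S+ ", "", grep("^property ", hdr, value = TRUE))
  crs_line <- grep("^comment crs ", hdr, value = TRUE)
  if (length(crs_line)) crs <- sub("^comment crs ", "", crs_line[1])
  req <- c("x", "y", "z", "classification")
  if (!all(req %in% props)) stop("PLY lacks required vertex properties: ", path)

  if (is.na(nv) || nv == 0) {
    dt <- data.table::data.table(x = numeric(), y = numeric(), z = numeric(),
                                 classification = integer())
    return(as_als_cloud(dt, crs = crs))
  }
  dt <- data.table::fread(path, skip = end, nrows = nv, header = FALSE,
                          col.names = props, sep = " ")
  out <- dt[, .(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                classification = as.integer(classification))]
  if ("normalized_z" %in% props) out[, nz := dt$normalized_z]
  if ("hand_label" %in% props) out[, label := PLY_LABELS[dt$hand_label]]
  as_als_cloud(out, crs = crs)
}

#' Read a point cloud, dispatching on the file format
#'
#' @param path input file (`.las`, `.ply`; `.laz` is recognized but
#'   unsupported and raises an informative error).
#' @param format override the extension-based format guess
#'   (`"las"` or `"ply"`).
#' @param crs CRS identifier to attach.
#' @return an `als_cloud`.
#' @export
read_point_cloud <- function(path, format = NULL, crs = "EPSG:28992") {
  fmt <- tolower(format %||% tools::file_ext(path))
  switch(fmt,
    las = read_las(path, crs = crs),
    ply = read_ply(path, crs = crs),
    laz = stop("LAZ decompression is not available; convert to LAS first: ", path),
    stop("unknown point cloud format '", fmt, "' for: ", path)
  )
}

#' Write a point cloud, dispatching on the file format
#'
#' @param cloud an `als_cloud`.
#' @param path output file (`.las` or `.ply`).
#' @param format override the extension-based format guess.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path, format = NULL) {
  fmt <- tolower(format %||% tools::file_ext(path))
  switch(fmt,
    las = write_las(cloud, path),
    ply = write_ply(cloud, path),
    stop("unknown point cloud format '", fmt, "' for: ", path)
  )
}
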