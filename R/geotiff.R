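# Minimal GeoTIFF I/O: uncompressed little-endian band-per-page TIFFs with
# ModelPixelScale/ModelTiepoint geo tags, float32 or int32 samples, and a
# GDAL-style nodata tag. Deliberately small: enough for the gridded
# weather and model-output rasters this package exchanges, written with a
# fully deterministic byte layout so identical runs yield identical files.

.TIFF_TYPES <- c(ASCII = 2L, SHORT = 3L, LONG = 4L, DOUBLE = 12L)
.TYPE_SIZE <- c(`2` = 1L, `3` = 2L, `4` = 4L, `12` = 8L)

#' Grid geometry descriptor
#'
#' North-up raster geometry: the coordinate of the outer upper-left corner,
#' the cell size, and a CRS label. Cell centers sit half a cell inside the
#' corner. Row 1 of all grid matrices is the northernmost row.
#'
#' @param xmin X coordinate of the left edge of the grid.
#' @param ymax Y coordinate of the top edge of the grid.
#' @param xres,yres Cell width and height (positive).
#' @param crs CRS label; `"EPSG:4326"` (geographic WGS 84) is the default
#'   and the only CRS written into GeoTIFF keys; other labels are carried
#'   through the JSON run manifest.
#' @return A `grid_geometry` list.
#' @export
grid_geometry <- function(xmin = 0, ymax = 0, xres = 1, yres = 1,
                          crs = "EPSG:4326") {
  stopifnot(xres > 0, yres > 0)
  structure(list(xmin = xmin, ymax = ymax, xres = xres, yres = yres,
                 crs = crs),
            class = "grid_geometry")
}

#' Write a multi-band GeoTIFF
#'
#' Writes a matrix or 3-d array (rows x cols x bands) as an uncompressed
#' little-endian GeoTIFF, one band per TIFF page, with geo-referencing
#' tags (pixel scale, tiepoint, WGS 84 geo keys), per-band descriptions,
#' and a nodata tag. `NA` values are stored as the nodata code. The byte
#' layout is deterministic: identical inputs produce identical files.
#'
#' @param data Numeric matrix or 3-d array. Row 1 = north.
#' @param path Output file path.
#' @param geo A [grid_geometry()].
#' @param band_names Optional character vector of band descriptions
#'   (e.g. dates).
#' @param datatype `"float32"` or `"int32"`.
#' @param nodata Numeric nodata code stored in place of `NA`.
#' @return `path`, invisibly.
#' @export
write_geotiff <- function(data, path, geo = grid_geometry(),
                          band_names = NULL,
                          datatype = c("float32", "int32"),
                          nodata = -9999) {
  datatype <- match.arg(datatype)
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  stopifnot(length(dim(data)) == 3L)
  nr <- dim(data)[1L]; nc <- dim(data)[2L]; nb <- dim(data)[3L]
  if (is.null(band_names)) band_names <- paste0("band_", seq_len(nb))
  stopifnot(length(band_names) == nb)

  strip_bytes <- nr * nc * 4L
  sample_format <- if (datatype == "float32") 3L else 2L

  # shared external payloads
  scale_vals <- c(geo$xres, geo$yres, 0)
  tie_vals <- c(0, 0, 0, geo$xmin, geo$ymax, 0)
  geokeys <- as.integer(c(1, 1, 0, 3,
                          1024, 0, 1, 2,     # model type: geographic
                          1025, 0, 1, 1,     # raster type: pixel-is-area
                          2048, 0, 1, 4326)) # geographic CRS: WGS 84
  geoascii <- "WGS 84|"
  nodata_str <- format(nodata, scientific = FALSE, trim = TRUE)

  # tag list per band (values resolved to offsets later)
  mk_tags <- function(b, strip_off, off) {
    # off: named offsets of external payloads
    list(
      list(id = 256L, type = "LONG", values = nc),
      list(id = 257L, type = "LONG", values = nr),
      list(id = 258L, type = "SHORT", values = 32L),
      list(id = 259L, type = "SHORT", values = 1L),
      list(id = 262L, type = "SHORT", values = 1L),
      list(id = 270L, type = "ASCII", values = band_names[b],
           offset = off[["desc"]][b]),
      list(id = 273L, type = "LONG", values = strip_off),
      list(id = 277L, type = "SHORT", values = 1L),
      list(id = 278L, type = "LONG", values = nr),
      list(id = 279L, type = "LONG", values = strip_bytes),
      list(id = 284L, type = "SHORT", values = 1L),
      list(id = 339L, type = "SHORT", values = sample_format),
      list(id = 33550L, type = "DOUBLE", values = scale_vals,
           offset = off[["scale"]]),
      list(id = 33922L, type = "DOUBLE", values = tie_vals,
           offset = off[["tie"]]),
      list(id = 34735L, type = "SHORT", values = geokeys,
           offset = off[["gk"]]),
      list(id = 34737L, type = "ASCII", values = geoascii,
           offset = off[["ga"]]),
      list(id = 42113L, type = "ASCII", values = nodata_str,
           offset = off[["nd"]])
    )
  }

  ascii_len <- function(s) nchar(s, type = "bytes") + 1L  # trailing NUL
  n_tags <- 17L
  ifd_size <- 2L + n_tags * 12L + 4L

  # layout: header | band strips | external payloads | IFD chain
  pos <- 8L
  strip_off <- integer(nb)
  for (b in seq_len(nb)) { strip_off[b] <- pos; pos <- pos + strip_bytes }
  off <- list()
  off$scale <- pos; pos <- pos + 24L
  off$tie <- pos; pos <- pos + 48L
  off$gk <- pos; pos <- pos + 2L * length(geokeys)
  off$ga <- pos; pos <- pos + ascii_len(geoascii)
  off$nd <- pos; pos <- pos + ascii_len(nodata_str)
  off$desc <- integer(nb)
  for (b in seq_len(nb)) {
    # short descriptions are inlined in the tag, no payload needed
    if (ascii_len(band_names[b]) > 4L) {
      off$desc[b] <- pos
      pos <- pos + ascii_len(band_names[b])
    }
  }
  ifd_off <- integer(nb)
  for (b in seq_len(nb)) { ifd_off[b] <- pos; pos <- pos + ifd_size }

  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")

  # header
  writeBin(charToRaw("II"), con)
  wb(42L, 2L)
  wb(ifd_off[1L], 4L)

  # strips (row-major within band)
  for (b in seq_len(nb)) {
    v <- as.numeric(t(data[, , b]))
    v[is.na(v)] <- nodata
    if (datatype == "float32") wb(v, 4L) else wb(as.integer(round(v)), 4L)
  }

  # external payloads
  wb(scale_vals, 8L)
  wb(tie_vals, 8L)
  wb(geokeys, 2L)
  writeBin(c(charToRaw(geoascii), as.raw(0L)), con)
  writeBin(c(charToRaw(nodata_str), as.raw(0L)), con)
  for (b in seq_len(nb)) {
    if (off$desc[b] > 0L)
      writeBin(c(charToRaw(band_names[b]), as.raw(0L)), con)
  }

  # IFD chain
  for (b in seq_len(nb)) {
    tags <- mk_tags(b, strip_off[b], off)
    wb(n_tags, 2L)
    for (tg in tags) .write_tag(con, tg)
    wb(if (b < nb) ifd_off[b + 1L] else 0L, 4L)
  }
  invisible(path)
}

.write_tag <- function(con, tg) {
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  type <- .TIFF_TYPES[[tg$type]]
  count <- if (tg$type == "ASCII")
    nchar(tg$values, type = "bytes") + 1L else length(tg$values)
  wb(tg$id, 2L)
  wb(type, 2L)
  wb(as.integer(count), 4L)
  nbytes <- count * .TYPE_SIZE[[as.character(type)]]
  if (nbytes <= 4L) {
    # value fits inline; pad to 4 bytes
    if (tg$type == "ASCII") {
      raw4 <- c(charToRaw(tg$values), as.raw(0L))
      writeBin(c(raw4, rep(as.raw(0L), 4L - length(raw4))), con)
    } else if (tg$type == "SHORT") {
      v <- c(as.integer(tg$values), 0L)[1:2]
      wb(v, 2L)
    } else {
      wb(as.integer(tg$values), 4L)
    }
  } else {
    wb(as.integer(tg$offset), 4L)
  }
}

#' Read a GeoTIFF written by this package (or a compatible plain TIFF)
#'
#' Parses uncompressed little-endian striped TIFFs with one sample per
#' pixel and 32-bit float or integer samples, returning the bands, the
#' grid geometry, and band names. Nodata values become `NA`.
#'
#' @param path Path to the file.
#' @return List with `data` (rows x cols x bands array), `geo`
#'   ([grid_geometry()]), `band_names`, and `nodata`.
#' @export
read_geotiff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rb <- function(n, size, what = "integer", signed = TRUE)
    readBin(con, what, n = n, size = size, endian = "little",
            signed = signed)
  hdr <- readBin(con, "raw", 2L)
  if (!identical(rawToChar(hdr), "II"))
    stop("only little-endian TIFFs are supported: ", path, call. = FALSE)
  if (rb(1L, 2L) != 42L) stop("not a TIFF file: ", path, call. = FALSE)
  next_ifd <- rb(1L, 4L)

  bands <- list()
  band_names <- character()
  geo <- grid_geometry()
  nodata <- NA_real_

  while (next_ifd != 0L) {
    seek(con, next_ifd)
    n_tags <- rb(1L, 2L, signed = FALSE)
    tags <- vector("list", n_tags)
    for (i in seq_len(n_tags)) {
      id <- rb(1L, 2L, signed = FALSE)
      type <- rb(1L, 2L, signed = FALSE)
      count <- rb(1L, 4L)
      valraw <- readBin(con, "raw", 4L)
      tags[[i]] <- list(id = id, type = type, count = count, raw = valraw)
    }
    next_ifd <- rb(1L, 4L)

    get_tag <- function(id) {
      for (tg in tags) if (tg$id == id) return(.tag_values(con, tg))
      NULL
    }
    nc <- get_tag(256L); nr <- get_tag(257L)
    comp <- get_tag(259L)
    if (!is.null(comp) && comp != 1L)
      stop("compressed TIFFs are not supported: ", path, call. = FALSE)
    bits <- get_tag(258L)
    if (bits != 32L) stop("only 32-bit samples are supported", call. = FALSE)
    fmt <- get_tag(339L); if (is.null(fmt)) fmt <- 1L
    offs <- get_tag(273L)
    counts <- get_tag(279L)
    desc <- get_tag(270L)
    scale <- get_tag(33550L)
    tie <- get_tag(33922L)
    nd <- get_tag(42113L)
    if (!is.null(nd)) nodata <- as.numeric(nd)
    if (!is.null(scale) && !is.null(tie))
      geo <- grid_geometry(xmin = tie[4L], ymax = tie[5L],
                           xres = scale[1L], yres = scale[2L],
                           crs = geo$crs)

    vals <- numeric(0)
    for (i in seq_along(offs)) {
      seek(con, offs[i])
      n <- counts[i] %/% 4L
      vals <- c(vals, if (fmt == 3L)
        readBin(con, "numeric", n = n, size = 4L, endian = "little")
      else rb(n, 4L))
    }
    m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
    if (!is.na(nodata)) m[abs(m - nodata) < 1e-6 * max(1, abs(nodata))] <- NA
    bands[[length(bands) + 1L]] <- m
    band_names <- c(band_names,
                    if (is.null(desc)) paste0("band_", length(bands))
                    else desc)
  }
  arr <- array(unlist(bands), c(dim(bands[[1L]]), length(bands)))
  list(data = arr, geo = geo, band_names = band_names, nodata = nodata)
}

.tag_values <- function(con, tg) {
  size <- .TYPE_SIZE[[as.character(tg$type)]]
  nbytes <- tg$count * size
  read_from <- function(raw_or_con) {
    if (tg$type == .TIFF_TYPES[["ASCII"]]) {
      s <- readBin(raw_or_con, "character", n = 1L)
      return(s)
    }
    what <- if (tg$type == .TIFF_TYPES[["DOUBLE"]]) "numeric" else "integer"
    readBin(raw_or_con, what, n = tg$count, size = size, endian = "little",
            signed = TRUE)
  }
  if (nbytes <= 4L) {
    read_from(tg$raw)
  } else {
    off <- readBin(tg$raw, "integer", size = 4L, endian = "little")
    old <- seek(con, off)
    on.exit(seek(con, old))
    read_from(con)
  }
}
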