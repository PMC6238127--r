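# File formats. ESRI ASCII grid is plain text. GeoTIFF support is a minimal
# self-contained codec: baseline little-endian TIFF, one image, one strip,
# uncompressed, single band (float32 for continuous, int16 for categorical),
# georeferenced with ModelPixelScale + ModelTiepoint and a GDAL_NODATA tag.
# That subset round-trips exactly and is readable by GDAL-based tools; it is
# not a general TIFF reader (no compression, tiles or multi-band).

#' Read a raster file
#'
#' @param path File path.
#' @param format `"ascii_grid"` (ESRI `.asc`) or `"geotiff"`. Guessed from
#'   the file extension when omitted.
#' @param categorical If `TRUE`, return a [categorical_map] (values must be
#'   whole numbers); otherwise a [grid_raster].
#' @return A [grid_raster] or [categorical_map] with nodata cells as `NA`.
#' @export
read_raster <- function(path, format = c("auto", "ascii_grid", "geotiff"),
                        categorical = FALSE) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("file not found: ", path)
  r <- switch(format,
              ascii_grid = read_ascii_grid(path),
              geotiff = read_geotiff(path))
  if (categorical) {
    r <- categorical_map(r$values, r$x_origin, r$y_origin, r$cell_size,
                         r$crs_label)
  }
  r
}

#' Write a raster file
#'
#' Continuous rasters are stored as float32 in GeoTIFF (full double precision
#' in ASCII grids); categorical maps as int16. Round-trip read reproduces
#' values (to float32 for continuous GeoTIFF), shape, origin, cell size and
#' the nodata mask exactly.
#'
#' @param r A [grid_raster] or [categorical_map].
#' @param path Output path.
#' @param format `"ascii_grid"` or `"geotiff"` (guessed from extension).
#' @param nodata_value Sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_raster <- function(r, path, format = c("auto", "ascii_grid", "geotiff"),
                         nodata_value = NULL) {
  stopifnot(inherits(r, "grid_raster"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  categorical <- inherits(r, "categorical_map")
  if (is.null(nodata_value))
    nodata_value <- if (categorical) -9999L else -9999
  if (any(!is.na(r$values) & r$values == nodata_value))
    stop("nodata_value ", nodata_value, " collides with a data value")
  switch(format,
         ascii_grid = write_ascii_grid(r, path, nodata_value),
         geotiff = write_geotiff(r, path, nodata_value, categorical))
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("asc", "agr", "grd")) return("ascii_grid")
  if (ext %in% c("tif", "tiff")) return("geotiff")
  stop("cannot guess raster format from extension '.", ext,
       "'; pass format explicitly")
}

## ---- ESRI ASCII grid ----

read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4) stop("not an ESRI ASCII grid (too short): ", path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^\\s*[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2) stop("malformed header line: ", lines[i])
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header missing: ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  if (!any(c("xllcorner", "xllcenter") %in% names(hdr)))
    stop("ASCII grid header missing x origin")
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  if (cs <= 0) stop("cellsize must be positive")
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cs / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cs / 2
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("ASCII grid body has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  grid_raster(m, x_origin = xll, y_origin = yll + nr * cs, cell_size = cs)
}

write_ascii_grid <- function(r, path, nodata_value) {
  v <- r$values
  nr <- nrow(v); nc <- ncol(v)
  v[is.na(v)] <- nodata_value
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", nc),
    paste("nrows", nr),
    paste("xllcorner", format(r$x_origin, digits = 15)),
    paste("yllcorner", format(r$y_origin - nr * r$cell_size, digits = 15)),
    paste("cellsize", format(r$cell_size, digits = 15)),
    paste("NODATA_value", format(nodata_value, digits = 15))), con)
  body <- apply(v, 1, function(row)
    paste(format(row, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = " "))
  writeLines(body, con)
}

## ---- minimal GeoTIFF ----

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, spp = 277L,
               rows_per_strip = 278L, strip_bytes = 279L,
               sample_format = 339L, pixel_scale = 33550L,
               tiepoint = 33922L, gdal_nodata = 42113L)

write_geotiff <- function(r, path, nodata_value, categorical) {
  v <- r$values
  nr <- nrow(v); nc <- ncol(v)
  v[is.na(v)] <- nodata_value
  pix <- as.vector(t(v))                      # TIFF is row-major, top row first
  if (categorical) {
    if (any(pix < -32768 | pix > 32767))
      stop("categorical codes out of int16 range")
    bytes_per <- 2L; bits <- 16L; fmt <- 2L   # signed int
  } else {
    bytes_per <- 4L; bits <- 32L; fmt <- 3L   # IEEE float
  }
  strip_len <- nr * nc * bytes_per
  nodata_str <- c(charToRaw(format(nodata_value, digits = 15)), as.raw(0))
  if (length(nodata_str) %% 2L) nodata_str <- c(nodata_str, as.raw(0))

  n_tags <- length(TIFF_TAGS)
  ifd_offset <- 8L + strip_len
  ifd_size <- 2L + n_tags * 12L + 4L
  ext_offset <- ifd_offset + ifd_size        # external values live after IFD
  off_scale <- ext_offset
  off_tie <- off_scale + 3L * 8L
  off_nodata <- off_tie + 6L * 8L

  entry <- function(tag, type, count, value_raw4) {
    c(writeBin(as.integer(tag), raw(), size = 2, endian = "little"),
      writeBin(as.integer(type), raw(), size = 2, endian = "little"),
      writeBin(as.integer(count), raw(), size = 4, endian = "little"),
      value_raw4)
  }
  long4 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
  short4 <- function(x) c(writeBin(as.integer(x), raw(), size = 2,
                                   endian = "little"), raw(2))

  ifd <- c(
    writeBin(n_tags, raw(), size = 2, endian = "little"),
    entry(256, 4, 1, long4(nc)),
    entry(257, 4, 1, long4(nr)),
    entry(258, 3, 1, short4(bits)),
    entry(259, 3, 1, short4(1)),             # no compression
    entry(262, 3, 1, short4(1)),             # BlackIsZero
    entry(273, 4, 1, long4(8)),              # single strip right after header
    entry(277, 3, 1, short4(1)),
    entry(278, 4, 1, long4(nr)),
    entry(279, 4, 1, long4(strip_len)),
    entry(339, 3, 1, short4(fmt)),
    entry(33550, 12, 3, long4(off_scale)),
    entry(33922, 12, 6, long4(off_tie)),
    entry(42113, 2, length(nodata_str), long4(off_nodata)),
    long4(0))                                # no next IFD

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), writeBin(42L, raw(), size = 2, endian = "little"),
             long4(ifd_offset)), con)
  if (categorical)
    writeBin(as.integer(pix), con, size = 2, endian = "little")
  else
    writeBin(as.double(pix), con, size = 4, endian = "little")
  writeBin(ifd, con)
  writeBin(c(r$cell_size, r$cell_size, 0), con, size = 8, endian = "little")
  writeBin(c(0, 0, 0, r$x_origin, r$y_origin, 0), con, size = 8,
           endian = "little")
  writeBin(nodata_str, con)
}

read_geotiff <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 8) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(raw_all[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big"
            else stop("not a TIFF file: ", path)
  rd <- function(off, what, n, size, signed = TRUE)
    readBin(raw_all[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = signed)
  magic <- rd(2, "integer", 1, 2)
  if (magic != 42) stop("not a TIFF file (bad magic): ", path)
  ifd_off <- rd(4, "integer", 1, 4)
  n_tags <- rd(ifd_off, "integer", 1, 2, signed = FALSE)
  tags <- list()
  for (k in seq_len(n_tags)) {
    e <- ifd_off + 2 + (k - 1) * 12
    tag <- rd(e, "integer", 1, 2, signed = FALSE)   # ids exceed 32767
    type <- rd(e + 2, "integer", 1, 2, signed = FALSE)
    count <- rd(e + 4, "integer", 1, 4)
    type_size <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)[type]
    total <- type_size * count
    voff <- if (total > 4) rd(e + 8, "integer", 1, 4) else e + 8
    val <- switch(as.character(type),
      `2` = rawToChar(raw_all[(voff + 1):(voff + count)]),   # ASCII
      `3` = rd(voff, "integer", count, 2, signed = FALSE),   # SHORT
      `4` = rd(voff, "integer", count, 4),                   # LONG
      `12` = rd(voff, "double", count, 8),                   # DOUBLE
      NULL)
    tags[[as.character(tag)]] <- val
  }
  g <- function(id, default = NULL) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) default else v
  }
  nc <- g(256); nr <- g(257)
  if (is.null(nc) || is.null(nr)) stop("TIFF lacks image dimensions")
  if (g(259, 1L) != 1L) stop("compressed TIFF not supported")
  if (g(277, 1L) != 1L) stop("multi-band TIFF not supported")
  bits <- g(258, 32L)
  fmt <- g(339, if (bits >= 32) 3L else 1L)
  offs <- g(273); byte_counts <- g(279, nr * nc * bits / 8)
  if (is.null(offs)) stop("TIFF lacks strip offsets")
  pix_raw <- unlist(lapply(seq_along(offs), function(i)
    raw_all[(offs[i] + 1):(offs[i] + byte_counts[min(i, length(byte_counts))])]))
  n_pix <- nr * nc
  pix <- if (fmt == 3L)
    readBin(pix_raw, "double", n = n_pix, size = bits / 8, endian = endian)
  else
    readBin(pix_raw, "integer", n = n_pix, size = bits / 8, endian = endian,
            signed = (fmt == 2L || bits > 8))
  scale <- g(33550)
  tie <- g(33922)
  if (is.null(scale) || is.null(tie))
    stop("TIFF lacks georeference (ModelPixelScale/ModelTiepoint): ", path)
  if (abs(scale[1] - scale[2]) > 1e-9 * max(abs(scale[1:2])))
    stop(sprintf("non-square cells: %g x %g", scale[1], scale[2]))
  # tiepoint maps raster (i, j) to model (x, y); we only write (0, 0)
  x_origin <- tie[4] - tie[1] * scale[1]
  y_origin <- tie[5] + tie[2] * scale[2]
  m <- matrix(pix, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- g(42113)
  if (!is.null(nodata)) {
    nd <- suppressWarnings(as.numeric(trimws(nodata)))
    if (!is.na(nd)) m[m == nd] <- NA
  }
  grid_raster(m, x_origin = x_origin, y_origin = y_origin,
              cell_size = scale[1])
}

## ---- points ----

#' Read occurrence points from CSV
#'
#' Expects columns `id`, `x`, `y`, `label` (extra columns are ignored).
#' Labels are normalized to `"presence"`/`"absence"`; exact duplicate
#' (x, y, label) rows are dropped with a message.
#'
#' @param path CSV file path.
#' @return An [occurrence_set].
#' @export
read_points <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x", "y", "label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("points CSV missing column(s): ", paste(miss, collapse = ", "))
  x <- suppressWarnings(as.numeric(df$x))
  y <- suppressWarnings(as.numeric(df$y))
  bad <- which(is.na(x) | is.na(y))
  if (length(bad))
    stop("unparseable coordinates on row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  occurrence_set(x, y, df$label, id = df$id)
}

#' Write occurrence points to CSV
#' @param pts An [occurrence_set].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_points <- function(pts, path) {
  utils::write.csv(as.data.frame(pts)[c("id", "x", "y", "label")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract predictor values at points
#'
#' Looks up each point's cell (half-open cell membership) in every layer of
#' an aligned stack. Out-of-extent points and points falling in nodata cells
#' are flagged and excluded from the modelling view.
#'
#' @param stack An [env_stack].
#' @param pts An [occurrence_set].
#' @param layers Optional character vector restricting/ordering the layers.
#' @return A data.frame with `id`, `label`, `row`, `col`, logical `in_extent`
#'   and `valid`, plus one numeric column per layer. Attribute `"n_dropped"`
#'   counts flagged rows. Rows with `valid == FALSE` carry `NA` predictors.
#' @export
extract_values <- function(stack, pts, layers = NULL) {
  if (is.null(layers)) layers <- names(stack$layers)
  template <- stack$layers[[1]]
  loc <- cell_from_xy(template, pts$x, pts$y)
  out <- data.frame(id = pts$id, label = pts$label,
                    row = loc$row, col = loc$col, in_extent = loc$inside,
                    stringsAsFactors = FALSE)
  vm <- stack_values(stack, layers)
  idx <- ifelse(loc$inside, (loc$col - 1L) * nrow(template$values) + loc$row,
                NA_integer_)
  for (nm in layers) out[[nm]] <- vm[idx, nm]
  out$valid <- out$in_extent & !apply(
    is.na(out[, layers, drop = FALSE]), 1, any)
  if (!any(out$valid))
    stop("no points fall on valid cells of the stack")
  n_dropped <- sum(!out$valid)
  if (n_dropped)
    message(n_dropped, " point(s) out of extent or on nodata cells; ",
            "excluded from modelling")
  attr(out, "n_dropped") <- n_dropped
  out
}
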