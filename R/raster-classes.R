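# Grid data model: georeferenced matrices with a north-up, square-cell
# convention. Row 1 is the northernmost row; cell (r, c) has its center at
#   x = x_origin + (c - 0.5) * cell_size
#   y = y_origin - (r - 0.5) * cell_size
# where (x_origin, y_origin) is the TOP-LEFT corner of the grid.
# Nodata is represented internally as NA in the values matrix.

#' Create a gridded raster of continuous values
#'
#' A `grid_raster` is a plain numeric matrix plus georeference: top-left
#' corner, square cell size and a free-text CRS label. Coordinates are planar
#' map units; geographic data must be projected before use. Nodata cells are
#' `NA` in `values`.
#'
#' @param values Numeric matrix; row 1 is the northernmost row.
#' @param x_origin,y_origin Map coordinates of the top-left corner.
#' @param cell_size Cell edge length in map units (cells are square).
#' @param crs_label Free-text coordinate-system tag (not interpreted).
#' @return An object of class `grid_raster`.
#' @examples
#' r <- grid_raster(matrix(runif(12), 3, 4), x_origin = 0, y_origin = 3)
#' cell_center(r, 1, 1)
#' @export
grid_raster <- function(values, x_origin = 0, y_origin = nrow(values),
                        cell_size = 1, crs_label = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  structure(
    list(values = values, x_origin = as.numeric(x_origin),
         y_origin = as.numeric(y_origin), cell_size = as.numeric(cell_size),
         crs_label = as.character(crs_label)),
    class = "grid_raster")
}

#' Create a categorical (integer-coded) map
#'
#' Same georeference as [grid_raster()] but values are small integer category
#' codes drawn from an explicit code set. Binary presence/absence maps use
#' exactly codes 0 (absent) and 1 (present).
#'
#' @inheritParams grid_raster
#' @param values Integer matrix of category codes (`NA` = nodata).
#' @param categories Integer vector of permitted codes. Defaults to the codes
#'   observed in `values`.
#' @return An object of class `categorical_map` (also `grid_raster`).
#' @export
categorical_map <- function(values, x_origin = 0, y_origin = nrow(values),
                            cell_size = 1, crs_label = "",
                            categories = NULL) {
  values <- as.matrix(values)
  if (any(!is.na(values) & values != round(values)))
    stop("categorical_map values must be whole numbers")
  storage.mode(values) <- "integer"
  if (is.null(categories))
    categories <- sort(unique(values[!is.na(values)]))
  categories <- as.integer(categories)
  bad <- !is.na(values) & !(values %in% categories)
  if (any(bad))
    stop(sum(bad), " cell(s) carry codes outside the declared category set")
  r <- grid_raster(values, x_origin, y_origin, cell_size, crs_label)
  storage.mode(r$values) <- "integer"
  r$categories <- categories
  class(r) <- c("categorical_map", "grid_raster")
  r
}

#' @export
print.grid_raster <- function(x, ...) {
  kind <- if (inherits(x, "categorical_map")) "categorical_map" else "grid_raster"
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<%s> %d x %d, cell %g, origin (%g, %g)\n", kind,
              nrow(x$values), ncol(x$values), x$cell_size,
              x$x_origin, x$y_origin))
  if (length(v))
    cat(sprintf("  %d valid cells, range [%g, %g]\n", length(v),
                min(v), max(v)))
  else cat("  no valid cells\n")
  invisible(x)
}

#' @rdname grid_raster
#' @param r A `grid_raster`.
#' @param row,col Cell indices (1-based).
#' @return `cell_center()`: a two-column matrix of x, y center coordinates.
#' @export
cell_center <- function(r, row, col) {
  cbind(x = r$x_origin + (col - 0.5) * r$cell_size,
        y = r$y_origin - (row - 0.5) * r$cell_size)
}

#' Locate points in a grid
#'
#' Cells are half-open: a point belongs to cell (r, c) iff
#' `x_left <= x < x_right` and `y_bottom < y <= y_top`, so every in-extent
#' point maps to exactly one cell.
#'
#' @param r A `grid_raster`.
#' @param x,y Point coordinates in map units.
#' @return A data.frame with columns `row`, `col` and logical `inside`;
#'   `row`/`col` are `NA` for out-of-extent points.
#' @export
cell_from_xy <- function(r, x, y) {
  col <- floor((x - r$x_origin) / r$cell_size) + 1
  row <- floor((r$y_origin - y) / r$cell_size) + 1
  # top edge (y == y_origin) belongs to row 1; left edge to col 1
  row[r$y_origin - y == 0] <- 1
  inside <- col >= 1 & col <= ncol(r$values) & row >= 1 & row <= nrow(r$values)
  row[!inside] <- NA_integer_
  col[!inside] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col), inside = inside)
}

raster_extent <- function(r) {
  c(xmin = r$x_origin,
    xmax = r$x_origin + ncol(r$values) * r$cell_size,
    ymin = r$y_origin - nrow(r$values) * r$cell_size,
    ymax = r$y_origin)
}

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$x_origin - b$x_origin) < tol &&
    abs(a$y_origin - b$y_origin) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

geometry_mismatch_message <- function(a, b) {
  sprintf(paste0("grids are not aligned: shape (%d x %d) vs (%d x %d), ",
                 "origin offset (%g, %g), cell sizes %g vs %g"),
          nrow(a$values), ncol(a$values), nrow(b$values), ncol(b$values),
          b$x_origin - a$x_origin, b$y_origin - a$y_origin,
          a$cell_size, b$cell_size)
}

#' Stack aligned predictor layers
#'
#' An `env_stack` is a named, ordered collection of [grid_raster] layers that
#' share shape, origin, cell size and nodata mask. Construction fails loudly
#' on any mismatch so downstream per-cell arithmetic is always well defined.
#'
#' @param layers Named list of `grid_raster` objects.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(layers) {
  if (!length(layers)) stop("env_stack needs at least one layer")
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    names(layers) <- paste0("env", seq_along(layers))
  ref <- layers[[1]]
  for (i in seq_along(layers)) {
    li <- layers[[i]]
    if (!inherits(li, "grid_raster")) stop("all layers must be grid_raster")
    if (!same_geometry(ref, li))
      stop("layer '", names(layers)[i], "': ", geometry_mismatch_message(ref, li))
    if (!identical(is.na(ref$values), is.na(li$values)))
      stop("layer '", names(layers)[i], "' has a different nodata mask")
  }
  structure(list(layers = layers), class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d layer(s): %s\n", length(x$layers),
              paste(names(x$layers), collapse = ", ")))
  print(x$layers[[1]])
  invisible(x)
}

#' @export
names.env_stack <- function(x) names(x$layers)

# matrix (n_valid_or_all cells x n_layers) view of a stack, cells in
# column-major matrix order
stack_values <- function(stack, layers = NULL) {
  if (is.null(layers)) layers <- names(stack$layers)
  miss <- setdiff(layers, names(stack$layers))
  if (length(miss)) stop("unknown layer(s): ", paste(miss, collapse = ", "))
  n_cell <- length(stack$layers[[1]]$values)
  out <- vapply(layers, function(nm) as.vector(stack$layers[[nm]]$values),
                numeric(n_cell))
  if (!is.matrix(out))                  # single-cell grids collapse in vapply
    out <- matrix(out, nrow = 1, dimnames = list(NULL, layers))
  out
}

#' Build an occurrence table
#'
#' Point records with planar coordinates and a presence/absence label.
#' Exact duplicate (x, y, label) triples are dropped with a message.
#'
#' @param x,y Planar coordinates in map units.
#' @param label Character vector, each `"presence"` or `"absence"` (or
#'   anything [normalize_labels()] understands).
#' @param id Optional record identifiers; generated when missing.
#' @return A data.frame of class `occurrence_set` with columns
#'   `id`, `x`, `y`, `label`.
#' @export
occurrence_set <- function(x, y, label, id = NULL) {
  label <- normalize_labels(label)
  if (is.null(id)) id <- sprintf("pt%04d", seq_along(x))
  df <- data.frame(id = as.character(id), x = as.numeric(x),
                   y = as.numeric(y), label = label,
                   stringsAsFactors = FALSE)
  dup <- duplicated(df[c("x", "y", "label")])
  if (any(dup)) {
    message(sum(dup), " duplicate record(s) dropped")
    df <- df[!dup, , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("occurrence_set", "data.frame")
  df
}

#' @rdname occurrence_set
#' @param labels Vector of raw labels: 1/0, "p"/"a", "presence"/"absence",
#'   TRUE/FALSE (case-insensitive, partial words allowed).
#' @export
normalize_labels <- function(labels) {
  raw <- tolower(trimws(as.character(labels)))
  out <- rep(NA_character_, length(raw))
  out[raw %in% c("1", "p", "pres", "presence", "true", "t")] <- "presence"
  out[raw %in% c("0", "a", "abs", "absence", "false", "f")] <- "absence"
  if (anyNA(out))
    stop("unrecognized occurrence label(s): ",
         paste(unique(raw[is.na(out)]), collapse = ", "))
  out
}

presences <- function(pts) pts[pts$label == "presence", , drop = FALSE]
absences  <- function(pts) pts[pts$label == "absence", , drop = FALSE]

# run code under a temporary RNG state seeded with `seed`; global stream
# untouched
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
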