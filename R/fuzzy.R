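# Fuzzy global matching (FGM) between two categorical maps. A cell may
# partially match a nearby cell's category: the membership of category c at
# cell i in the fuzzified map is the maximum, over cells j of category c
# within the neighborhood radius, of 2^(-d(i, j) / halving_distance), where d
# is Euclidean center-to-center distance in cell units. A cell's two-map
# similarity is the minimum of the two directed memberships (each map's crisp
# category looked up in the other map's fuzzified field), and FGM is the mean
# cell similarity over jointly valid cells. With radius 0 this reduces
# exactly to the crisp proportion of agreeing cells.

#' Configure fuzzy map comparison
#'
#' Defaults follow the documented fuzziness-of-location settings of the
#' standard map-comparison toolkit: exponential distance decay with a
#' halving distance of 2 cells inside a 4-cell neighborhood.
#'
#' @param neighborhood_radius Neighborhood radius in cells (integer >= 0);
#'   radius 0 degenerates to crisp cell-by-cell agreement.
#' @param halving_distance Distance in cells at which membership halves
#'   (> 0).
#' @return An object of class `fuzzy_config`.
#' @export
fuzzy_config <- function(neighborhood_radius = 4, halving_distance = 2) {
  if (neighborhood_radius < 0 || neighborhood_radius != round(neighborhood_radius))
    stop("neighborhood_radius must be a non-negative integer")
  if (halving_distance <= 0) stop("halving_distance must be > 0")
  structure(list(neighborhood_radius = as.integer(neighborhood_radius),
                 halving_distance = halving_distance),
            class = "fuzzy_config")
}

# neighborhood offsets (dr, dc, weight) within the radius, strongest first
fuzzy_offsets <- function(cfg) {
  r <- cfg$neighborhood_radius
  grid <- expand.grid(dr = -r:r, dc = -r:r)
  d <- sqrt(grid$dr^2 + grid$dc^2)
  keep <- d <= r | d == 0
  grid <- grid[keep, , drop = FALSE]
  grid$w <- 2^(-d[keep] / cfg$halving_distance)
  grid[order(-grid$w), , drop = FALSE]
}

#' Fuzzify a categorical map
#'
#' @param m A [categorical_map].
#' @param cfg A [fuzzy_config].
#' @param categories Category codes to build membership fields for; defaults
#'   to the map's own set.
#' @return Named list of membership matrices (one per category, names are the
#'   codes); nodata cells hold `NA` and contribute no membership anywhere.
#' @export
fuzzify <- function(m, cfg = fuzzy_config(), categories = NULL) {
  stopifnot(inherits(m, "categorical_map"))
  if (is.null(categories)) categories <- m$categories
  v <- m$values
  nr <- nrow(v); nc <- ncol(v)
  offs <- fuzzy_offsets(cfg)
  out <- lapply(categories, function(cat) {
    ind <- !is.na(v) & v == cat
    acc <- matrix(0, nr, nc)
    for (k in seq_len(nrow(offs))) {
      dr <- offs$dr[k]; dc <- offs$dc[k]; w <- offs$w[k]
      if (abs(dr) >= nr || abs(dc) >= nc) next   # shift leaves the map
      dst_r <- max(1, 1 + dr):min(nr, nr + dr)
      dst_c <- max(1, 1 + dc):min(nc, nc + dc)
      src_r <- dst_r - dr
      src_c <- dst_c - dc
      acc[dst_r, dst_c] <- pmax(acc[dst_r, dst_c], w * ind[src_r, src_c])
    }
    acc[is.na(v)] <- NA
    acc
  })
  names(out) <- as.character(categories)
  out
}

#' Fuzzy global matching of two categorical maps
#'
#' @param a,b Aligned [categorical_map]s sharing at least one category.
#' @param cfg A [fuzzy_config].
#' @return The FGM similarity in `[0, 1]`; attribute `similarity` holds the
#'   per-cell two-way similarity [grid_raster].
#' @export
fgm <- function(a, b, cfg = fuzzy_config()) {
  if (!same_geometry(a, b)) stop(geometry_mismatch_message(a, b))
  cats <- union(a$categories, b$categories)
  if (!length(intersect(a$categories, b$categories)))
    stop("maps share no categories; comparison is undefined")
  fa <- fuzzify(a, cfg, cats)
  fb <- fuzzify(b, cfg, cats)
  ok <- !is.na(a$values) & !is.na(b$values)
  lookup <- function(fields, crisp) {
    out <- matrix(NA_real_, nrow(crisp), ncol(crisp))
    for (cat in cats) {
      sel <- ok & crisp == cat
      out[sel] <- fields[[as.character(cat)]][sel]
    }
    out
  }
  s_ab <- lookup(fa, b$values)      # b's crisp category in fuzzified a
  s_ba <- lookup(fb, a$values)
  sim <- pmin(s_ab, s_ba)
  value <- mean(sim[ok])
  sim_raster <- grid_raster(sim, a$x_origin, a$y_origin, a$cell_size,
                            a$crs_label)
  structure(value, similarity = sim_raster)
}
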