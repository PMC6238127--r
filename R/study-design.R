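# Data-preparation rules: delimiting an empirical distribution (ED) from
# peripheral presences with distance buffers, minimum-distance thinning of
# occurrence records, random subsetting, and greedy collinearity-based
# predictor selection under a Spearman-rho bound.

#' Configure ED buffers
#'
#' The ED is drawn around presence points with a wide buffer in
#' environmentally homogeneous terrain and a narrow one where conditions
#' change abruptly (e.g. across a mountain front), marked by `abrupt_mask`.
#'
#' @param buffer_default Buffer radius in map units (e.g. 30 km).
#' @param buffer_abrupt Buffer radius where `abrupt_mask` is 1 (e.g. 5 km);
#'   must not exceed `buffer_default`.
#' @param abrupt_mask Optional [categorical_map] (codes 0/1) marking abrupt
#'   zones; `NULL` means the default buffer applies everywhere.
#' @return An object of class `ed_config`.
#' @export
ed_config <- function(buffer_default = 30, buffer_abrupt = 5,
                      abrupt_mask = NULL) {
  if (buffer_default < 0 || buffer_abrupt < 0) stop("buffers must be >= 0")
  if (buffer_abrupt > buffer_default)
    stop("buffer_abrupt must not exceed buffer_default")
  structure(list(buffer_default = buffer_default,
                 buffer_abrupt = buffer_abrupt, abrupt_mask = abrupt_mask),
            class = "ed_config")
}

#' Build an empirical-distribution map from presence points
#'
#' A cell belongs to the ED iff its center lies within the applicable buffer
#' (the abrupt buffer where `abrupt_mask = 1`, the default elsewhere) of any
#' presence point. Distances are planar Euclidean in map units; the operation
#' is raster-native (no polygon geometry).
#'
#' @param pts An [occurrence_set]; only its presence records are used.
#' @param grid A [grid_raster] template supplying geometry and nodata mask.
#' @param cfg An [ed_config].
#' @return A binary [categorical_map] (1 = ED, 0 = outside).
#' @export
build_ed <- function(pts, grid, cfg = ed_config()) {
  pr <- presences(pts)
  if (!nrow(pr)) stop("build_ed needs at least one presence point")
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cx <- grid$x_origin + (seq_len(nc) - 0.5) * grid$cell_size
  cy <- grid$y_origin - (seq_len(nr) - 0.5) * grid$cell_size
  d2 <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(pr))) {
    di <- outer((cy - pr$y[i])^2, (cx - pr$x[i])^2, `+`)
    d2 <- pmin(d2, di)
  }
  buf <- matrix(cfg$buffer_default, nr, nc)
  if (!is.null(cfg$abrupt_mask)) {
    if (!same_geometry(grid, cfg$abrupt_mask))
      stop("abrupt_mask: ", geometry_mismatch_message(grid, cfg$abrupt_mask))
    buf[!is.na(cfg$abrupt_mask$values) & cfg$abrupt_mask$values == 1L] <-
      cfg$buffer_abrupt
  }
  ed <- ifelse(d2 <= buf^2, 1L, 0L)
  ed[is.na(grid$values)] <- NA_integer_
  categorical_map(ed, grid$x_origin, grid$y_origin, grid$cell_size,
                  categories = c(0L, 1L))
}

#' Thin points to a minimum pairwise distance
#'
#' Greedy filter over a seeded random permutation: visit points in random
#' order and accept one iff it lies at least `min_dist` from every point
#' already accepted. The result depends on the permutation (hence the seed)
#' but always satisfies the pairwise-distance guarantee and is maximal with
#' respect to its own visiting order.
#'
#' @param pts An [occurrence_set].
#' @param min_dist Minimum allowed pairwise distance in map units.
#' @param seed RNG seed for the permutation.
#' @return A thinned [occurrence_set].
#' @export
thin_points <- function(pts, min_dist, seed = 1) {
  if (min_dist < 0) stop("min_dist must be >= 0")
  n <- nrow(pts)
  if (n == 0 || min_dist == 0) return(pts)
  ord <- with_seed(seed, sample.int(n))
  keep <- integer(0)
  for (i in ord) {
    if (!length(keep) ||
        all((pts$x[keep] - pts$x[i])^2 + (pts$y[keep] - pts$y[i])^2 >=
            min_dist^2))
      keep <- c(keep, i)
  }
  out <- pts[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Draw a uniform random subset of points
#'
#' @param pts An [occurrence_set].
#' @param n Subset size (`n <= nrow(pts)`).
#' @param seed RNG seed.
#' @return An [occurrence_set] of `n` records (original ordering preserved).
#' @export
subsample_points <- function(pts, n, seed = 1) {
  if (n > nrow(pts))
    stop("cannot draw ", n, " from ", nrow(pts), " points")
  if (n == nrow(pts)) return(pts)
  keep <- with_seed(seed, sample.int(nrow(pts), n))
  out <- pts[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select low-collinearity predictors by greedy Spearman scan
#'
#' Scans layers in `priority` order and keeps a layer iff its absolute
#' Spearman rank correlation (midranks for ties) with every already-kept
#' layer is below `threshold`. The priority order is where expert judgement
#' enters: put the variables you trust most first.
#'
#' @param table Data.frame or matrix of per-point predictor values (as from
#'   [extract_values()]; non-layer bookkeeping columns are ignored).
#' @param threshold Correlation bound (keep iff `|rho| < threshold`).
#' @param priority Character vector giving the scan order; defaults to
#'   column order.
#' @return List with `kept` (character), `dropped` (character) and `rho`
#'   (the full pairwise Spearman matrix).
#' @export
select_predictors <- function(table, threshold = 0.7, priority = NULL) {
  tab <- as.data.frame(table)
  meta <- c("id", "label", "row", "col", "in_extent", "valid")
  tab <- tab[, setdiff(names(tab), meta), drop = FALSE]
  tab <- tab[stats::complete.cases(tab), , drop = FALSE]
  if (nrow(tab) < 2) stop("need at least 2 complete rows")
  constant <- vapply(tab, function(v) stats::sd(v) == 0, logical(1))
  if (any(constant)) {
    warning("constant layer(s) excluded (Spearman rho undefined): ",
            paste(names(tab)[constant], collapse = ", "))
    tab <- tab[, !constant, drop = FALSE]
  }
  if (is.null(priority)) priority <- names(tab)
  if (!all(priority %in% names(tab)))
    stop("priority names not in table: ",
         paste(setdiff(priority, names(tab)), collapse = ", "))
  rho <- stats::cor(tab, method = "spearman")
  kept <- character(0)
  for (nm in priority) {
    if (!length(kept) || all(abs(rho[nm, kept]) < threshold))
      kept <- c(kept, nm)
  }
  list(kept = kept, dropped = setdiff(priority, kept), rho = rho)
}
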