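# Virtual-species worlds: spatially autocorrelated predictors, a logistic
# true-suitability surface, a known true range (optionally with disjunct
# satellite patches), and seeded presence/true-absence samplers. Everything
# downstream of the samplers can then be validated against exact ground truth.

#' Configure a synthetic world
#'
#' @param n_rows,n_cols Grid shape (at least 8 cells a side).
#' @param cell_size Map units per cell.
#' @param n_predictors Number of base predictor layers (>= 2).
#' @param autocorr_length Gaussian smoothing scale in cells; 0 gives
#'   unsmoothed white noise.
#' @param seed RNG seed; identical config + seed gives a bit-identical world.
#' @param collinearity_spec Optional list of `list(source =, weight =,
#'   noise_sd =)` entries; each appends a layer `weight * source + noise` so
#'   pairwise correlation is controllable (emulating the strong collinearity
#'   of bioclimatic variable sets).
#' @return An object of class `world_config`.
#' @export
world_config <- function(n_rows = 100, n_cols = 100, cell_size = 1,
                         n_predictors = 5, autocorr_length = 5, seed = 1,
                         collinearity_spec = NULL) {
  if (n_rows < 8 || n_cols < 8)
    stop("degenerate grid: need at least 8 cells a side")
  if (n_predictors < 2) stop("need n_predictors >= 2")
  if (autocorr_length < 0) stop("autocorr_length must be >= 0")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = cell_size, n_predictors = as.integer(n_predictors),
                 autocorr_length = autocorr_length, seed = as.integer(seed),
                 collinearity_spec = collinearity_spec),
            class = "world_config")
}

# separable truncated-Gaussian blur (sd = scale, radius 3*scale), edge
# renormalized so the kernel always sums to 1 over in-grid cells
gaussian_smooth <- function(m, scale) {
  if (scale <= 0) return(m)
  radius <- max(1L, ceiling(3 * scale))
  w <- stats::dnorm(-radius:radius, sd = scale)
  smooth_1d <- function(mat) {                 # along columns
    n <- nrow(mat)
    acc <- matrix(0, n, ncol(mat))
    norm <- matrix(0, n, ncol(mat))
    for (k in -radius:radius) {
      src <- seq_len(n) + k
      ok <- src >= 1 & src <= n
      acc[ok, ] <- acc[ok, ] + w[k + radius + 1] * mat[src[ok], ]
      norm[ok, ] <- norm[ok, ] + w[k + radius + 1]
    }
    acc / norm
  }
  t(smooth_1d(t(smooth_1d(m))))
}

#' Generate spatially autocorrelated predictor layers
#'
#' Each base layer is white noise smoothed with a truncated Gaussian kernel of
#' scale `autocorr_length` cells, then standardized to mean 0, sd 1 over valid
#' cells. Collinear layers are then appended per `collinearity_spec` and
#' standardized the same way (standardization preserves their correlation
#' with the source layer).
#'
#' @param cfg A [world_config].
#' @return An [env_stack] with layers `env1 ... envK` (collinear layers
#'   continue the numbering).
#' @export
generate_predictors <- function(cfg) {
  stopifnot(inherits(cfg, "world_config"))
  with_seed(cfg$seed, {
    nr <- cfg$n_rows; nc <- cfg$n_cols
    base <- lapply(seq_len(cfg$n_predictors), function(i) {
      m <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                           cfg$autocorr_length)
      (m - mean(m)) / stats::sd(m)
    })
    names(base) <- paste0("env", seq_along(base))
    for (spec in cfg$collinearity_spec) {
      src <- spec$source
      if (is.numeric(src)) src <- names(base)[src]
      if (!src %in% names(base)) stop("unknown collinearity source: ", src)
      m <- spec$weight * base[[src]] +
        matrix(stats::rnorm(nr * nc, sd = spec$noise_sd), nr, nc)
      m <- (m - mean(m)) / stats::sd(m)
      base[[paste0("env", length(base) + 1L)]] <- m
    }
    env_stack(lapply(base, grid_raster, x_origin = 0,
                     y_origin = nr * cfg$cell_size, cell_size = cfg$cell_size))
  })
}

#' Define a virtual species on a predictor stack
#'
#' True suitability is `plogis(beta[1] + sum(beta[k+1] * env_k))` per cell;
#' the true range is every valid cell with suitability at or above `cutoff`,
#' plus any satellite patches. Satellites are circular patches force-added to
#' the range irrespective of climate — a controllable stand-in for disjunct
#' relict populations that envelope models typically miss.
#'
#' @param stack An [env_stack].
#' @param beta Numeric vector: intercept followed by one slope per layer.
#' @param cutoff Suitability threshold in (0, 1) defining the range.
#' @param satellite_spec Optional list of `list(row =, col =, radius =)`
#'   patches (cell units; a cell joins the patch if its center is within
#'   `radius` cells of the patch center).
#' @return An object of class `virtual_species` with elements
#'   `true_suitability` ([grid_raster]), `true_range` ([categorical_map]),
#'   `beta`, `cutoff`, `prevalence` (share of valid cells in range).
#' @export
define_species <- function(stack, beta, cutoff = 0.5, satellite_spec = NULL) {
  stopifnot(inherits(stack, "env_stack"))
  k <- length(stack$layers)
  if (length(beta) != k + 1)
    stop("beta must have length n_layers + 1 (intercept first); got ",
         length(beta), " for ", k, " layer(s)")
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be inside (0, 1)")
  template <- stack$layers[[1]]
  vm <- stack_values(stack)
  eta <- beta[1] + as.vector(vm %*% beta[-1])
  suit <- matrix(stats::plogis(eta), nrow(template$values))
  suit[is.na(template$values)] <- NA
  range01 <- ifelse(is.na(suit), NA_integer_,
                    as.integer(suit >= cutoff))
  for (sat in satellite_spec) {
    rows <- matrix(seq_len(nrow(range01)), nrow(range01), ncol(range01))
    cols <- matrix(seq_len(ncol(range01)), nrow(range01), ncol(range01),
                   byrow = TRUE)
    inpatch <- (rows - sat$row)^2 + (cols - sat$col)^2 <= sat$radius^2
    range01[inpatch & !is.na(range01)] <- 1L
  }
  if (sum(range01 == 1L, na.rm = TRUE) == 0)
    stop("empty true range: max suitability ",
         format(max(suit, na.rm = TRUE), digits = 4), " < cutoff ", cutoff,
         " and no satellite patches")
  structure(list(
    true_suitability = grid_raster(suit, template$x_origin,
                                   template$y_origin, template$cell_size),
    true_range = categorical_map(range01, template$x_origin,
                                 template$y_origin, template$cell_size,
                                 categories = c(0L, 1L)),
    beta = beta, cutoff = cutoff,
    prevalence = mean(range01 == 1L, na.rm = TRUE)),
    class = "virtual_species")
}

#' @export
print.virtual_species <- function(x, ...) {
  cat(sprintf("<virtual_species> prevalence %.3f, cutoff %.2f, %d coefficients\n",
              x$prevalence, x$cutoff, length(x$beta)))
  invisible(x)
}

#' Sample presence points from the true range
#'
#' Draws `n` distinct range cells without replacement, with inclusion weight
#' proportional to true suitability, and returns points at the cell centers.
#' One point per cell mirrors minimum-distance thinning of field records.
#'
#' @param vs A [virtual_species].
#' @param n Number of presences.
#' @param seed RNG seed (sampling is deterministic per seed).
#' @return An [occurrence_set] of `n` presence records.
#' @export
sample_presences <- function(vs, n, seed = 1) {
  rng <- vs$true_range$values
  idx <- which(!is.na(rng) & rng == 1L)
  if (n > length(idx))
    stop("n = ", n, " exceeds the ", length(idx), " true-range cells")
  wt <- vs$true_suitability$values[idx]
  wt[is.na(wt) | wt <= 0] <- min(wt[wt > 0], 1e-12)  # satellite cells may sit
                                                     # below the cutoff
  pick <- with_seed(seed, sample(idx, n, replace = FALSE, prob = wt))
  rc <- arrayInd(pick, dim(rng))
  xy <- cell_center(vs$true_range, rc[, 1], rc[, 2])
  occurrence_set(xy[, "x"], xy[, "y"], rep("presence", n),
                 id = sprintf("pres%04d", seq_len(n)))
}

# cells within `radius` (Euclidean, cell units, center-to-center) of any TRUE
# cell; offset-based binary dilation
dilate_cells <- function(mask, radius) {
  if (radius <= 0) return(mask & TRUE)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  r <- floor(radius)
  for (dr in -r:r) for (dc in -r:r) {
    if (dr * dr + dc * dc > radius^2) next
    src_r <- seq_len(nr) - dr
    src_c <- seq_len(nc) - dc
    ok_r <- src_r >= 1 & src_r <= nr
    ok_c <- src_c >= 1 & src_c <= nc
    out[ok_r, ok_c] <- out[ok_r, ok_c] | mask[src_r[ok_r], src_c[ok_c]]
  }
  out
}

#' Sample true absences outside the range
#'
#' Draws `n` distinct valid cells whose center-to-center distance to the
#' nearest true-range cell exceeds `buffer_cells`, uniformly at random, and
#' returns points at the cell centers. This emulates reliable absence records
#' taken well outside the species' distribution.
#'
#' @param vs A [virtual_species].
#' @param n Number of absences.
#' @param buffer_cells Exclusion distance around the range, in cells.
#' @param seed RNG seed.
#' @return An [occurrence_set] of `n` absence records.
#' @export
sample_true_absences <- function(vs, n, buffer_cells = 0, seed = 1) {
  rng <- vs$true_range$values
  inrange <- !is.na(rng) & rng == 1L
  blocked <- dilate_cells(inrange, buffer_cells)
  idx <- which(!is.na(rng) & !blocked)
  if (n > length(idx))
    stop("n = ", n, " exceeds the ", length(idx),
         " eligible cells outside the buffered range")
  pick <- with_seed(seed, sample(idx, n, replace = FALSE))
  rc <- arrayInd(pick, dim(rng))
  xy <- cell_center(vs$true_range, rc[, 1], rc[, 2])
  occurrence_set(xy[, "x"], xy[, "y"], rep("absence", n),
                 id = sprintf("abs%04d", seq_len(n)))
}
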