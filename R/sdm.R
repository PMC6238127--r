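# From-scratch presence-only and presence/absence models.
#
# BIOCLIM: per-variable climate envelope with a tail-percentile score.
# For a cell value v on layer k, F is the midrank empirical CDF position of v
# among the training presences and the layer score is t_k = 2 * min(F, 1 - F)
# (1 at the training median, falling towards the envelope edges, hard 0
# strictly outside the min/max envelope). The cell score is min_k t_k.
#
# DOMAIN: Gower distance d(a, b) = mean_k |a_k - b_k| / range_k with ranges
# taken over the training presences; a cell's suitability is the similarity
# 1 - d to its single most similar training record, clamped to [0, 1].
#
# GLM: binomial logit fit by iteratively reweighted least squares, linear
# terms only, with explicit separation detection.

#' Fit a BIOCLIM climate envelope
#'
#' @param train Data.frame or matrix of predictor values at training
#'   presences, one column per layer (bookkeeping columns from
#'   [extract_values()] are ignored). No missing values.
#' @return An object of class `bioclim_model`.
#' @export
fit_bioclim <- function(train) {
  tab <- model_table(train)
  if (nrow(tab) < 5) stop("BIOCLIM needs at least 5 presence points")
  sorted <- lapply(tab, sort)
  structure(list(sorted = sorted,
                 envelope = lapply(sorted, range),
                 layers = names(tab)),
            class = "bioclim_model")
}

#' Predict BIOCLIM suitability over a stack
#'
#' @param m A `bioclim_model`.
#' @param stack An [env_stack] carrying at least the model's layers.
#' @return A [grid_raster] of suitability scores in `[0, 1]`.
#' @export
predict_bioclim <- function(m, stack) {
  vm <- stack_values(stack, check_layers(m$layers, stack))
  score <- rep(1, nrow(vm))
  for (nm in m$layers) {
    st <- m$sorted[[nm]]
    n <- length(st)
    v <- vm[, nm]
    le <- findInterval(v, st)                       # count(train <= v)
    lt <- findInterval(v, st, left.open = TRUE)     # count(train <  v)
    f <- (lt + 0.5 * (le - lt)) / n                 # midrank CDF position
    t_k <- 2 * pmin(f, 1 - f)
    t_k[v < st[1] | v > st[n]] <- 0                 # hard envelope
    score <- pmin(score, t_k)
  }
  raster_like(stack, score)
}

#' Fit a DOMAIN (Gower similarity) model
#'
#' @inheritParams fit_bioclim
#' @return An object of class `domain_model`.
#' @export
fit_domain <- function(train) {
  tab <- model_table(train)
  rng <- vapply(tab, function(v) diff(range(v)), numeric(1))
  if (any(rng == 0))
    stop("zero training range on layer(s): ",
         paste(names(tab)[rng == 0], collapse = ", "))
  structure(list(train = as.matrix(tab), ranges = rng, layers = names(tab)),
            class = "domain_model")
}

#' Predict DOMAIN similarity over a stack
#'
#' @param m A `domain_model`.
#' @inheritParams predict_bioclim
#' @return A [grid_raster] of similarities in `[0, 1]`.
#' @export
predict_domain <- function(m, stack) {
  vm <- stack_values(stack, check_layers(m$layers, stack))
  p <- length(m$layers)
  best <- rep(-Inf, nrow(vm))
  for (i in seq_len(nrow(m$train))) {
    d <- rowSums(abs(vm - rep(m$train[i, ], each = nrow(vm))) /
                   rep(m$ranges, each = nrow(vm))) / p
    best <- pmax(best, 1 - d)
  }
  raster_like(stack, pmin(pmax(best, 0), 1))
}

#' Fit a binomial GLM (logit link) by IRLS
#'
#' Linear terms only. Convergence is declared when the relative deviance
#' change drops below `tol`; after `max_iter` iterations without convergence
#' the fit is returned as-is. Complete separation (fitted probabilities
#' escaping to 0/1 with diverging coefficients) sets `separation = TRUE` with
#' a warning — the returned coefficients are then the iteration-cap values
#' and should be treated as a ranking, not estimates.
#'
#' @param train Data.frame with a `label` column (`presence`/`absence`) plus
#'   one column per predictor, as from [extract_values()]; or a plain
#'   predictor table combined with `y`.
#' @param y Optional 0/1 response overriding the `label` column.
#' @param tol Relative deviance-change tolerance (default 1e-8).
#' @param max_iter Iteration cap (default 100).
#' @return An object of class `glm_model` with `coefficients` (intercept
#'   first), `deviance`, `iterations`, `converged`, `separation`,
#'   `std_errors`.
#' @export
fit_glm_sdm <- function(train, y = NULL, tol = 1e-8, max_iter = 100L) {
  if (is.null(y)) {
    if (!"label" %in% names(as.data.frame(train)))
      stop("no response: supply y or a label column")
    y <- as.integer(as.data.frame(train)$label == "presence")
  }
  tab <- model_table(train)
  if (length(unique(y)) < 2)
    stop("GLM needs both presences and absences")
  X <- cbind(`(Intercept)` = 1, as.matrix(tab))
  n <- nrow(X); p <- ncol(X)
  beta <- numeric(p)
  dev_old <- Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    fit <- stats::lm.wfit(X, z, w)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    mu <- stats::plogis(as.vector(X %*% beta))
    dev <- -2 * sum(y * log(pmax(mu, 1e-300)) +
                      (1 - y) * log(pmax(1 - mu, 1e-300)))
    if (is.finite(dev_old) &&
        abs(dev - dev_old) / (abs(dev_old) + 0.1) < tol) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  eta <- as.vector(X %*% beta)
  # a (near-)zero deviance means fitted probabilities have reached the 0/1
  # corners -- only possible under complete separation; diverging
  # coefficients at the iteration cap are the same pathology caught earlier
  separation <- dev < 1e-6 || (!converged && max(abs(beta)) > 1e3)
  if (separation)
    warning("complete separation detected; coefficients are a ranking, ",
            "not estimates")
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  xtwx <- crossprod(X * sqrt(w))
  se <- tryCatch(sqrt(diag(solve(xtwx))), error = function(e)
    rep(NA_real_, p))
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 layers = names(tab), deviance = dev, iterations = iter,
                 converged = converged, separation = separation,
                 std_errors = stats::setNames(se, colnames(X))),
            class = "glm_model")
}

#' Predict GLM suitability over a stack
#'
#' @param m A `glm_model`.
#' @inheritParams predict_bioclim
#' @return A [grid_raster] of probabilities in `(0, 1)`.
#' @export
predict_glm_sdm <- function(m, stack) {
  vm <- stack_values(stack, check_layers(m$layers, stack))
  eta <- m$coefficients[1] + as.vector(vm %*% m$coefficients[-1])
  raster_like(stack, stats::plogis(eta))
}

#' Import an externally produced suitability raster
#'
#' Ingests predictions from algorithms not implemented here (e.g. MaxEnt,
#' GARP, Random Forest outputs) for evaluation on the analysis grid.
#'
#' @param path Raster file (ASCII grid or GeoTIFF), or a [grid_raster].
#' @param template A [grid_raster] the prediction must align with.
#' @param rescale If `TRUE`, min-max rescale values to `[0, 1]`.
#' @return A [grid_raster] of suitability values.
#' @export
import_prediction <- function(path, template, rescale = FALSE) {
  r <- if (inherits(path, "grid_raster")) path else read_raster(path)
  if (!same_geometry(template, r))
    stop("imported prediction misaligned: ", geometry_mismatch_message(template, r))
  v <- r$values
  if (rescale) {
    rng <- range(v, na.rm = TRUE)
    if (diff(rng) == 0)
      stop("cannot rescale a constant raster (zero range)")
    v <- (v - rng[1]) / diff(rng)
  }
  grid_raster(v, r$x_origin, r$y_origin, r$cell_size, r$crs_label)
}

## ---- internals ----

# strip bookkeeping columns and keep complete numeric predictor rows
model_table <- function(train) {
  tab <- as.data.frame(train)
  meta <- c("id", "label", "row", "col", "in_extent", "valid")
  tab <- tab[, setdiff(names(tab), meta), drop = FALSE]
  if (!ncol(tab)) stop("no predictor columns")
  if (anyNA(tab)) stop("missing values in training table")
  tab
}

check_layers <- function(layers, stack) {
  miss <- setdiff(layers, names(stack$layers))
  if (length(miss))
    stop("stack lacks model layer(s): ", paste(miss, collapse = ", "))
  layers
}

# wrap a per-cell vector (column-major, NA respected via the stack mask) back
# into a raster with the stack's geometry
raster_like <- function(stack, values_vec) {
  template <- stack$layers[[1]]
  m <- matrix(values_vec, nrow(template$values))
  m[is.na(template$values)] <- NA
  grid_raster(m, template$x_origin, template$y_origin, template$cell_size,
              template$crs_label)
}
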