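# Orchestration: run a model x predictor-subset ensemble on one world, score
# every variant against the reference range, and correlate the fuzzy global
# matching column with the accuracy indices -- the full study design on
# simulated ground truth.

#' Define one ensemble variant
#'
#' @param id Short label (e.g. `"B5"`, `"GLM20"`).
#' @param algo `"bioclim"`, `"domain"`, `"glm"`, `"oracle"` (the reference
#'   range fed back as a perfect prediction) or `"import"`.
#' @param layers Predictor subset for the fitted algorithms (`NULL` = all).
#' @param threshold `"auto"` (maximise sensitivity + specificity on the
#'   training points) or a fixed numeric threshold.
#' @param suitability A [grid_raster] with the external prediction
#'   (`algo = "import"` only).
#' @return An object of class `sdm_variant`.
#' @export
sdm_variant <- function(id, algo = c("bioclim", "domain", "glm", "oracle",
                                     "import"),
                        layers = NULL, threshold = "auto",
                        suitability = NULL) {
  algo <- match.arg(algo)
  if (algo == "import" && !inherits(suitability, "grid_raster"))
    stop("variant '", id, "': import needs a suitability grid_raster")
  if (!identical(threshold, "auto") && !is.numeric(threshold))
    stop("threshold must be \"auto\" or numeric")
  structure(list(id = id, algo = algo, layers = layers,
                 threshold = threshold, suitability = suitability),
            class = "sdm_variant")
}

#' Define an ensemble run
#'
#' @param variants List of [sdm_variant]s (at least 3 are needed for the
#'   correlation stage downstream).
#' @param n_presences,n_absences Training sample sizes (defaults 100 and
#'   1000, the classic small-presence/large-absence design).
#' @param absence_buffer Exclusion distance (cells) between absences and the
#'   true range.
#' @param fuzzy A [fuzzy_config] for the FGM stage.
#' @param upr_convention Passed to [compute_metrics()].
#' @param seed Master seed; presence/absence draws derive from it.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(variants, n_presences = 100, n_absences = 1000,
                          absence_buffer = 5, fuzzy = fuzzy_config(),
                          upr_convention = "barbosa", seed = 1) {
  if (!length(variants)) stop("need at least one variant")
  ids <- vapply(variants, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("variant ids must be unique")
  structure(list(variants = variants, n_presences = n_presences,
                 n_absences = n_absences, absence_buffer = absence_buffer,
                 fuzzy = fuzzy, upr_convention = upr_convention,
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

score_at_points <- function(suit, pts) {
  loc <- cell_from_xy(suit, pts$x, pts$y)
  out <- rep(NA_real_, nrow(pts))
  ok <- loc$inside
  out[ok] <- suit$values[cbind(loc$row[ok], loc$col[ok])]
  out
}

#' Run a model ensemble against a reference range
#'
#' Samples one shared training set (presences inside the range weighted by
#' true suitability; true absences outside a buffered range), then for each
#' variant: fit (or import), score, select the binarization threshold,
#' binarize, overlay on the reference map, and compute the full index suite
#' plus FGM. A failing variant is logged and skipped; the others proceed.
#'
#' @param stack The predictor [env_stack].
#' @param species A [virtual_species] providing ground truth and samples.
#' @param spec An [ensemble_spec].
#' @param reference Binary [categorical_map] to evaluate against; defaults to
#'   the species' true range (an expert-drawn ED raster can substitute).
#' @return List of class `ensemble_result`: `metrics` (one row per variant),
#'   `details` (per-variant suitability, binary map, comparison map,
#'   similarity raster), `train` (the shared occurrence set), `spec`.
#' @export
run_ensemble <- function(stack, species, spec, reference = NULL) {
  stopifnot(inherits(spec, "ensemble_spec"))
  if (is.null(reference)) reference <- species$true_range
  pres <- sample_presences(species, spec$n_presences, seed = spec$seed)
  abs_ <- sample_true_absences(species, spec$n_absences,
                               buffer_cells = spec$absence_buffer,
                               seed = spec$seed + 1L)
  train <- rbind(pres, abs_)
  class(train) <- c("occurrence_set", "data.frame")
  rows <- list()
  details <- list()
  for (v in spec$variants) {
    res <- tryCatch(
      run_variant(v, stack, species, reference, pres, abs_, spec),
      error = function(e) {
        message("variant '", v$id, "' failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) next
    rows[[v$id]] <- res$row
    details[[v$id]] <- res$detail
  }
  if (!length(rows)) stop("every ensemble variant failed")
  metrics <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(metrics) <- NULL
  structure(list(metrics = metrics, details = details, train = train,
                 spec = spec),
            class = "ensemble_result")
}

run_variant <- function(v, stack, species, reference, pres, abs_, spec) {
  suit <- switch(v$algo,
    bioclim = predict_bioclim(
      fit_bioclim(training_table(stack, pres, v$layers)), stack),
    domain = predict_domain(
      fit_domain(training_table(stack, pres, v$layers)), stack),
    glm = {
      tabs <- training_table(stack, rbind(pres, abs_), v$layers,
                             keep_label = TRUE)
      predict_glm_sdm(fit_glm_sdm(tabs), stack)
    },
    oracle = grid_raster(species$true_range$values + 0,
                         reference$x_origin, reference$y_origin,
                         reference$cell_size),
    import = import_prediction(v$suitability, stack$layers[[1]]))
  ps <- score_at_points(suit, pres)
  as <- score_at_points(suit, abs_)
  ok_p <- !is.na(ps); ok_a <- !is.na(as)
  thr <- if (identical(v$threshold, "auto"))
    as.numeric(select_threshold(ps[ok_p], as[ok_a])) else v$threshold
  binmap <- binarize(suit, thr)
  cc <- confusion_from_maps(binmap, reference)
  met <- compute_metrics(cc, spec$upr_convention)
  pct <- percentage_indices(cc, spec$upr_convention)
  auc <- compute_auc(ps[ok_p], as[ok_a])
  cmp <- compare_per_category(binmap, reference)
  f <- fgm(binmap, reference, spec$fuzzy)
  row <- c(list(model_id = v$id, algo = v$algo, threshold = thr), met[
    c("sensitivity", "specificity", "tss", "opr", "upr")],
    list(auc = auc, fgm = as.numeric(f)), as.list(pct),
    list(tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn))
  list(row = row,
       detail = list(suitability = suit, binary = binmap, comparison = cmp,
                     similarity = attr(f, "similarity")))
}

training_table <- function(stack, pts, layers, keep_label = FALSE) {
  tab <- extract_values(stack, pts, layers)
  tab <- tab[tab$valid, , drop = FALSE]
  keep <- c(if (keep_label) "label",
            if (is.null(layers)) names(stack$layers) else layers)
  tab[, keep, drop = FALSE]
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Midrank Spearman rho. The two-sided p-value uses the exact permutation
#' distribution (all `n!` rank orderings) for `n <= 9` and the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` otherwise.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`.
#' @return List with `rho`, `p_value`, `n`, `method`. Zero variance in
#'   either vector gives `rho = NA` with a warning.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; Spearman rho undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "undefined"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    perms <- permutations_of(n)
    ry_perm <- matrix(ry[perms], nrow(perms), n)
    s <- as.vector(ry_perm %*% rx)
    mx <- mean(rx); my <- mean(ry)
    denom <- (n - 1) * stats::sd(rx) * stats::sd(ry)
    rho_perm <- (s - n * mx * my) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    t_stat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-15))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

# all permutations of 1..n as an (n! x n) integer matrix
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rowsel <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rowsel, 1] <- i
    rest <- seq_len(n)[-i]
    out[rowsel, -1] <- matrix(rest[sub], nrow(sub))
  }
  out
}

#' Correlate FGM with the accuracy indices across an ensemble
#'
#' One [spearman_cor()] row per metric against the FGM column — the test of
#' whether fuzzy map similarity can stand in for discrimination indices.
#'
#' @param metrics Metrics data.frame from [run_ensemble()] (>= 3 rows).
#' @param columns Metric columns to correlate with `fgm`.
#' @return Data.frame of class `fgm_correlations`: `metric`, `rho`,
#'   `p_value`, `n`, `method`.
#' @export
correlate_fgm <- function(metrics,
                          columns = c("sensitivity", "specificity", "upr",
                                      "opr", "auc", "tss")) {
  if (inherits(metrics, "ensemble_result")) metrics <- metrics$metrics
  if (nrow(metrics) < 3)
    stop("need at least 3 ensemble variants for rank correlation")
  if (stats::sd(metrics$fgm) == 0)
    warning("constant FGM column; all correlations undefined")
  out <- do.call(rbind, lapply(columns, function(cl) {
    ok <- stats::complete.cases(metrics$fgm, metrics[[cl]])
    sc <- if (sum(ok) < 3)
      list(rho = NA_real_, p_value = NA_real_, n = sum(ok),
           method = "undefined")
    else withCallingHandlers(
      spearman_cor(metrics$fgm[ok], metrics[[cl]][ok]),
      warning = function(w) invokeRestart("muffleWarning"))
    data.frame(metric = cl, rho = sc$rho, p_value = sc$p_value, n = sc$n,
               method = sc$method, stringsAsFactors = FALSE)
  }))
  class(out) <- c("fgm_correlations", "data.frame")
  out
}

#' Write ensemble reports
#'
#' Emits `metrics.csv` (one row per variant), `correlations.csv` (skipped
#' with a notice below 3 variants), per-variant comparison and similarity
#' rasters, and a `manifest.json` echoing the configuration and seed so a
#' re-run reproduces the CSVs byte-identically.
#'
#' @param result An `ensemble_result` from [run_ensemble()].
#' @param out_dir Output directory (created if missing).
#' @param write_rasters Also write per-variant GeoTIFFs (default `TRUE`).
#' @return Character vector of files written, invisibly.
#' @export
report_ensemble <- function(result, out_dir, write_rasters = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  metrics_path <- file.path(out_dir, "metrics.csv")
  utils::write.csv(format(result$metrics, digits = 12), metrics_path,
                   row.names = FALSE, quote = FALSE)
  files <- c(files, metrics_path)
  if (nrow(result$metrics) >= 3) {
    cors <- correlate_fgm(result$metrics)
    cor_path <- file.path(out_dir, "correlations.csv")
    utils::write.csv(format(cors, digits = 12), cor_path,
                     row.names = FALSE, quote = FALSE)
    files <- c(files, cor_path)
  } else {
    message("fewer than 3 variants; correlation stage skipped")
  }
  if (write_rasters) {
    for (id in names(result$details)) {
      d <- result$details[[id]]
      for (what in c("comparison", "similarity")) {
        p <- file.path(out_dir, paste0(id, "_", what, ".tif"))
        write_raster(d[[what]], p, "geotiff")
        files <- c(files, p)
      }
    }
  }
  manifest <- list(
    package = "sdmeval",
    version = as.character(utils::packageVersion("sdmeval")),
    seed = result$spec$seed,
    n_presences = result$spec$n_presences,
    n_absences = result$spec$n_absences,
    absence_buffer = result$spec$absence_buffer,
    upr_convention = result$spec$upr_convention,
    fuzzy = result$spec$fuzzy[c("neighborhood_radius", "halving_distance")],
    variants = lapply(result$spec$variants, function(v)
      list(id = v$id, algo = v$algo,
           layers = if (is.null(v$layers)) "all" else v$layers,
           threshold = v$threshold)))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(files, manifest_path))
}
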