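# Binarization and accuracy indices. All indices derive from the confusion
# matrix (TP, FP, FN, TN), counted either over evaluation points or cell by
# cell between two binary maps. Undefined quantities (zero denominator)
# propagate as NA, never as 0.

#' Confusion-matrix counts
#'
#' @param tp,fp,fn,tn Non-negative integer counts (true positive, false
#'   positive, false negative, true negative).
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  if (sum(v) == 0) stop("empty confusion matrix")
  storage.mode(v) <- "integer"
  structure(as.list(v), class = "confusion_counts")
}

#' Select the sensitivity+specificity-optimal threshold
#'
#' Scans every unique observed score as a candidate threshold under the rule
#' `score >= t => presence` and returns the candidate maximising Youden's J
#' (sensitivity + specificity - 1). Ties are broken towards the smallest
#' qualifying threshold. This gives presences and absences equal weight even
#' when the classes are unbalanced.
#'
#' @param pres_scores,abs_scores Suitability scores at presence and absence
#'   points; both non-empty.
#' @return The selected threshold, with attributes `youden_j`,
#'   `sensitivity`, `specificity`.
#' @export
select_threshold <- function(pres_scores, abs_scores) {
  if (!length(pres_scores) || !length(abs_scores))
    stop("both score sets must be non-empty")
  cand <- sort(unique(c(pres_scores, abs_scores)))
  if (length(cand) == 1) {
    warning("all scores identical; threshold degenerate")
    return(structure(cand, youden_j = 0, sensitivity = 1, specificity = 0))
  }
  sens <- vapply(cand, function(t) mean(pres_scores >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(abs_scores < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1]            # candidates are sorted ascending
  if (max(j) <= 0)
    warning("scores are inverted or uninformative: best Youden's J = ",
            format(max(j), digits = 3))
  structure(cand[best], youden_j = j[best], sensitivity = sens[best],
            specificity = spec[best])
}

#' Binarize a suitability raster
#'
#' @param s A [grid_raster] of scores.
#' @param t Threshold; cells with `score >= t` become 1 (presence).
#' @return A binary [categorical_map]; nodata preserved.
#' @export
binarize <- function(s, t) {
  stopifnot(inherits(s, "grid_raster"))
  v <- ifelse(is.na(s$values), NA_integer_, as.integer(s$values >= t))
  categorical_map(v, s$x_origin, s$y_origin, s$cell_size, s$crs_label,
                  categories = c(0L, 1L))
}

#' Confusion counts from evaluation points
#'
#' Looks up each point's predicted class in a binary map: TP are presences on
#' predicted-presence cells, and so on. Points outside the extent or on
#' nodata cells are ignored.
#'
#' @param pred A binary [categorical_map].
#' @param pts An [occurrence_set].
#' @return A [confusion_counts].
#' @export
confusion_from_points <- function(pred, pts) {
  loc <- cell_from_xy(pred, pts$x, pts$y)
  pv <- rep(NA_integer_, nrow(pts))
  ok <- loc$inside
  pv[ok] <- pred$values[cbind(loc$row[ok], loc$col[ok])]
  use <- !is.na(pv)
  obs <- pts$label == "presence"
  confusion_counts(tp = sum(use & obs & pv == 1L),
                   fp = sum(use & !obs & pv == 1L),
                   fn = sum(use & obs & pv == 0L),
                   tn = sum(use & !obs & pv == 0L))
}

#' Confusion counts from a cell-by-cell map overlay
#'
#' @param pred A binary [categorical_map] (the prediction).
#' @param ref A binary [categorical_map] (the reference distribution).
#' @return A [confusion_counts] over jointly valid cells.
#' @export
confusion_from_maps <- function(pred, ref) {
  if (!same_geometry(pred, ref))
    stop(geometry_mismatch_message(pred, ref))
  p <- pred$values; r <- ref$values
  ok <- !is.na(p) & !is.na(r)
  confusion_counts(tp = sum(ok & p == 1L & r == 1L),
                   fp = sum(ok & p == 1L & r == 0L),
                   fn = sum(ok & p == 0L & r == 1L),
                   tn = sum(ok & p == 0L & r == 0L))
}

#' Accuracy indices from a confusion matrix
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), TSS = sensitivity +
#' specificity - 1. The over-prediction rate is OPR = FP/(TP+FP) under both
#' conventions. Two published under-prediction-rate conventions exist:
#' \describe{
#'   \item{`barbosa`}{UPR = FN/(FN+TN) — observed presences as a share of the
#'     predicted-absence area (the default).}
#'   \item{`complement`}{UPR = FN/(TP+FN) = 1 - sensitivity — omission as a
#'     share of observed presences.}
#' }
#'
#' @param cc A [confusion_counts].
#' @param convention `"barbosa"` or `"complement"` (UPR denominator).
#' @return Named list: `sensitivity`, `specificity`, `tss`, `opr`, `upr`,
#'   `convention`. Zero-denominator fields are `NA`.
#' @export
compute_metrics <- function(cc, convention = c("barbosa", "complement")) {
  convention <- match.arg(convention)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- rate(cc$tp, cc$tp + cc$fn)
  spec <- rate(cc$tn, cc$tn + cc$fp)
  upr <- switch(convention,
                barbosa = rate(cc$fn, cc$fn + cc$tn),
                complement = rate(cc$fn, cc$tp + cc$fn))
  list(sensitivity = sens, specificity = spec, tss = sens + spec - 1,
       opr = rate(cc$fp, cc$tp + cc$fp), upr = upr,
       convention = convention)
}

#' Rank-based AUC
#'
#' Mann-Whitney formulation with midranks for ties: the probability that a
#' random presence scores above a random absence (ties count 1/2).
#'
#' @inheritParams select_threshold
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(pres_scores, abs_scores) {
  np <- length(pres_scores); na <- length(abs_scores)
  if (!np || !na) stop("both score sets must be non-empty")
  r <- rank(c(pres_scores, abs_scores))        # midranks for ties
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * na)
}

#' Cell-by-cell comparison map
#'
#' Overlays a binary prediction on a binary reference and codes each jointly
#' valid cell: 0 = both absent, 1 = agreement on presence, 2 = omission
#' (reference presence missed), 3 = commission (predicted presence where the
#' reference is absent).
#'
#' @inheritParams confusion_from_maps
#' @return A [categorical_map] with codes 0-3; attribute `counts` holds the
#'   per-code cell counts.
#' @export
compare_per_category <- function(pred, ref) {
  if (!same_geometry(pred, ref))
    stop(geometry_mismatch_message(pred, ref))
  p <- pred$values; r <- ref$values
  out <- matrix(NA_integer_, nrow(p), ncol(p))
  ok <- !is.na(p) & !is.na(r)
  out[ok & r == 0L & p == 0L] <- 0L
  out[ok & r == 1L & p == 1L] <- 1L
  out[ok & r == 1L & p == 0L] <- 2L
  out[ok & r == 0L & p == 1L] <- 3L
  m <- categorical_map(out, pred$x_origin, pred$y_origin, pred$cell_size,
                       categories = 0:3)
  counts <- vapply(0:3, function(code) sum(out == code, na.rm = TRUE),
                   integer(1))
  attr(m, "counts") <- stats::setNames(counts, c("both_absent", "agreement",
                                                 "omission", "commission"))
  m
}

#' Percentage-index table row
#'
#' The [compute_metrics()] quantities expressed as percentages, plus the
#' overall cell agreement `100 * (TP + TN) / N`. The published "total cells
#' detected" column has no stated definition; overall agreement is reported
#' here as a clearly labelled substitute, not a replica.
#'
#' @inheritParams compute_metrics
#' @return Named numeric vector: `sensitivity_pct`, `specificity_pct`,
#'   `opr_pct`, `upr_pct`, `agreement_pct`.
#' @export
percentage_indices <- function(cc, convention = c("barbosa", "complement")) {
  m <- compute_metrics(cc, convention)
  n <- cc$tp + cc$fp + cc$fn + cc$tn
  c(sensitivity_pct = 100 * m$sensitivity,
    specificity_pct = 100 * m$specificity,
    opr_pct = 100 * m$opr,
    upr_pct = 100 * m$upr,
    agreement_pct = 100 * (cc$tp + cc$tn) / n)
}
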