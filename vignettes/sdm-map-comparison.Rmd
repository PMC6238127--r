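---
title: "Evaluating SDM predictions against a known range: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating SDM predictions against a known range: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdmeval)
```

## The problem

Discrimination statistics computed on point samples (AUC, sensitivity,
specificity) can rate a species distribution model highly even when its
mapped prediction badly over- or under-shoots the species' actual range.
When a trustworthy reference range exists — an expert-delimited empirical
distribution built from dense, unbiased survey data, or a simulated species
whose range is known by construction — the prediction can instead be
compared with the range itself, cell by cell and with fuzzy map similarity.
`sdmeval` implements that full pipeline and, because real expert maps are
rare, ships a virtual-species world generator so every stage is testable
with exact ground truth.

## Models

**BIOCLIM.** The envelope model stores, per predictor, the sorted training
presence values. For a candidate cell value $v$ on layer $k$, let $F_k$ be
the midrank empirical CDF position of $v$ among the $n$ training values,
$F_k = (\#\{t < v\} + 0.5\,\#\{t = v\})/n$. The layer score is the tail
percentile $t_k = 2\min(F_k, 1-F_k)$ — 1 at the training median, falling
towards the envelope edges — hard-zeroed strictly outside the min–max
envelope, and the cell score is $\min_k t_k$. The historical
desktop-GIS implementations advertise "default settings" without defining
them; this formulation is the standard envelope/percentile reading of the
algorithm, documented here rather than claimed as a replica.

**DOMAIN.** Gower distance between a cell $a$ and a training record $b$ is
$d(a,b) = \frac{1}{p}\sum_k |a_k - b_k| / r_k$ with $r_k$ the training range
of layer $k$ (a zero range is an error naming the layer). The cell's
suitability is the similarity $1 - d$ to its single most similar training
record (nearest-record aggregation, not mean-of-$k$, matching the
point-to-point description of the method), clamped to $[0, 1]$.

**GLM.** Binomial logit with linear terms only, fitted by iteratively
reweighted least squares; convergence when the relative deviance change
drops below $10^{-8}$, capped at 100 iterations. Complete separation is
flagged explicitly: a deviance collapsing to zero (fitted probabilities at
the 0/1 corners) or diverging coefficients at the cap set `separation =
TRUE` with a warning, and the coefficients should then be read as a ranking,
not estimates. No polynomial or interaction terms are offered: nothing in
the linear-combination formulation of the method calls for them, and the
evaluation machinery is the point of the package.

MaxEnt-, GARP- or Random-Forest-style algorithms are deliberately not
reimplemented; their rasters enter through `import_prediction()`, which
enforces grid alignment and optionally min–max rescales to $[0, 1]$.

## Thresholding and indices

Continuous suitability is binarized at the threshold maximising sensitivity
+ specificity over the observed scores, with `score >= t` mapped to presence
(the published procedure leaves the boundary side ambiguous; closing it at
the threshold is this package's documented choice, ties broken towards the
smallest qualifying candidate). From a confusion matrix over cells or
points:

* sensitivity $= TP/(TP+FN)$, specificity $= TN/(TN+FP)$,
  $TSS = \text{sens} + \text{spec} - 1$;
* $OPR = FP/(TP+FP)$;
* UPR carries **two published conventions**, both implemented behind a flag:
  the prose definition "observed presences in the predicted absence area"
  gives $UPR = FN/(FN+TN)$ (`"barbosa"`, the default); published tables
  instead often satisfy sensitivity + UPR = 100%, i.e.
  $UPR = FN/(TP+FN)$ (`"complement"`). Defaulting to the prose reading and
  exposing both is the honest resolution of that conflict.
* AUC is the Mann–Whitney rank statistic with midranks for ties.
* Zero-denominator indices propagate as `NA`, never silently as 0 — a map
  that predicts presence everywhere genuinely has no under-prediction rate
  under the barbosa convention.

The per-category overlay codes each jointly valid cell 0 (both absent), 1
(agreement), 2 (omission), 3 (commission); the percentage table reports the
same quantities ×100 plus overall agreement $100(TP+TN)/N$. A published
"total cells detected" column exists whose definition is not stated and is
not reconstructible from its siblings; overall agreement is reported as a
clearly-labelled substitute, not as that column.

## Fuzzy global matching

Membership of category $c$ at cell $i$ in the fuzzified map is
$\max_j 2^{-d(i,j)/h}$ over cells $j$ of category $c$ within radius $R$
($d$ Euclidean center-to-center in cell units; the cell itself contributes
1 for its own category; map edges truncate the neighborhood — no padding).
Each map's crisp category is looked up in the other map's fuzzified field;
the cell similarity is the minimum of the two directed values, and FGM is
the mean over jointly valid cells. Defaults $R = 4$, $h = 2$ follow the
documented fuzziness-of-location defaults of the standard map-comparison
toolkit; the source study names that tool without stating its settings, so
both are exposed in `fuzzy_config()` and exact numeric replication of its
published FGM values is explicitly out of reach. Useful exact properties,
all tested against an independent direct-loop oracle: symmetry,
self-similarity 1, range $[0,1]$, monotonicity in $R$ and $h$, and the
radius-0 collapse to crisp agreement $(TP+TN)/N$.

## The synthetic world

`generate_predictors()` smooths white noise with a truncated Gaussian
kernel (sd = `autocorr_length` cells, radius 3 sd, edge-renormalized) and
standardizes each layer; collinear layers are manufactured as
`weight * source + noise` so pairwise correlation is controllable. True
suitability is $\mathrm{logistic}(\beta_0 + \sum_k \beta_k e_k)$; the true
range is suitability ≥ cutoff plus optional circular satellite patches
force-added irrespective of climate — a controllable stand-in for disjunct
relict populations, the hardest real-world pattern for envelope methods.
Presences are drawn without replacement at cell centers with probability
proportional to suitability (one point per cell, mirroring the intent of
minimum-distance thinning); true absences are uniform draws from cells
farther than a buffer from the range.

Defaults (the package's *stated world*, chosen once): 100 × 100 unit cells,
five predictors at autocorrelation scale 5 plus one collinear layer
(weight 1, noise sd 0.5); $\beta = (0, 3, -2, 1.5, 0, 0, 0)$, cutoff 0.6,
one satellite patch of radius 4 at (82, 88); 100 presences, 1,000 absences,
absence buffer 5 cells. Sample sizes follow the classic small-presence /
large-absence design; the coefficient scale is set so that climate strongly
controls the range (prevalence ≈ 0.4–0.5), which is what the recovery
criteria assume. Two honest consequences of this world, documented rather
than tuned away: buffered absences make the GLM training classes perfectly
separable (the separation flag fires; predictions remain a valid ranking),
and DOMAIN's automatic threshold degenerates to 1.0 because presences sit
exactly at cell centers where training similarity is exactly 1 — the
permissive-DOMAIN behaviour is therefore represented by a fixed
low-threshold variant (`D5perm`, t = 0.5) in the default ensemble.

What the generator does **not** emulate: geographic sampling bias,
observation error in labels, non-stationary covariance, realistic climate
physics, temporal dynamics. A green test here establishes algorithmic
correctness and directional behaviour, not field performance.

## The default ensemble and what its numbers mean

Seven variants span restrictive to permissive: BIOCLIM and DOMAIN
(automatic thresholds), permissive DOMAIN, the full GLM, two degraded GLMs
(one informative layer; noise layers only) and the oracle (the true range
itself — the row every other variant must not beat). Across that spread the
FGM column correlates positively with TSS and negatively with the error
rates, reproducing the direction pattern that motivates FGM as a
stand-alone comparison index; only directions are asserted, since the
published magnitudes summarize an unpublished 12-model real-data table.
Rank-correlation p-values use the exact permutation distribution up to
$n = 9$ and the t-approximation above.

## Numerical choices and degenerate inputs

* Cells are half-open ($[x_l, x_r) \times (y_b, y_t]$): every point maps to
  exactly one cell; all geometry is planar Euclidean (project first — the
  buffer distances are map units).
* GeoTIFFs are written as uncompressed single-band float32 (continuous) or
  int16 (categorical); round-trips are exact up to float32 for continuous
  data. The codec is a minimal self-contained implementation (no R raster
  stack is required) and was validated against an independent GDAL-style
  reader.
* Thinning is a greedy pass over a seeded permutation — the result is
  permutation-dependent by design (the cited GIS tool is random too), but
  always satisfies, and is maximal for, the pairwise-distance guarantee.
* Predictor selection is a greedy scan in a user-supplied priority order;
  that order is where expert knowledge enters, made explicit and
  reproducible. Spearman uses average ranks for ties; constant layers are
  excluded with a warning.
* All samplers take explicit seeds and restore the global RNG state;
  identical config + seed ⇒ bit-identical output, including CSV reports.

## Known limitations

No reprojection or resampling; no polygon geometry (the ED is raster-native
by design); no fuzzy-kappa expectation correction or multi-resolution
comparison; no spatial cross-validation. The minimal GeoTIFF codec reads
only the subset it writes (uncompressed, single strip/band). Exact
replication of published real-data tables is out of scope: those numbers
depend on a private occurrence database and on undocumented tool settings.
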