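# The default synthetic experiment: one fixed virtual-species world and one
# fixed ensemble, spanning restrictive (climate envelope) through permissive
# (low-threshold similarity) variants plus deliberately weakened GLMs and a
# ground-truth oracle. These defaults are the package's stated test world;
# they are chosen once, on scientific grounds, and are not tuning knobs.

#' Default world configuration
#'
#' A 100 x 100 unit-cell grid with five smooth (autocorrelation scale 5
#' cells) standardized predictors plus a sixth layer manufactured to be
#' strongly collinear with the first — mimicking the heavy collinearity of
#' bioclimatic variable sets.
#'
#' @param seed World RNG seed.
#' @return A [world_config].
#' @export
default_world_config <- function(seed = 1) {
  world_config(n_rows = 100, n_cols = 100, cell_size = 1, n_predictors = 5,
               autocorr_length = 5, seed = seed,
               collinearity_spec = list(
                 list(source = "env1", weight = 1, noise_sd = 0.5)))
}

#' Default virtual species
#'
#' Suitability is driven strongly by three of the six layers
#' (`beta = (0, 3, -2, 1.5, 0, 0, 0)`); the range is suitability >= 0.6 plus
#' one forced satellite patch (radius 4 cells) standing in for a disjunct
#' relict population that climate alone does not explain.
#'
#' @param stack The [env_stack] from [default_world_config()] predictors.
#' @return A [virtual_species].
#' @export
default_species <- function(stack) {
  define_species(stack, beta = c(0, 3, -2, 1.5, 0, 0, 0), cutoff = 0.6,
                 satellite_spec = list(list(row = 82, col = 88, radius = 4)))
}

#' Default ensemble specification
#'
#' Seven variants: BIOCLIM and DOMAIN on the five base predictors (automatic
#' thresholds), a permissive DOMAIN binarized at a fixed low threshold of
#' 0.5, the full GLM, two degraded GLMs (one informative layer; noise layers
#' only), and the true range fed back as an oracle. The spread from
#' restrictive to permissive is what gives the FGM-vs-index correlations
#' something to rank.
#'
#' @param seed Sampling seed (presences/absences derive from it).
#' @return An [ensemble_spec] with the classic 100-presence / 1000-absence
#'   training design and a 5-cell absence buffer.
#' @export
default_ensemble <- function(seed = 1) {
  base5 <- paste0("env", 1:5)
  ensemble_spec(
    variants = list(
      sdm_variant("B5", "bioclim", layers = base5),
      sdm_variant("D5", "domain", layers = base5),
      sdm_variant("D5perm", "domain", layers = base5, threshold = 0.5),
      sdm_variant("GLM5", "glm", layers = base5),
      sdm_variant("GLM1", "glm", layers = "env1"),
      sdm_variant("GLMnoise", "glm", layers = c("env4", "env5")),
      sdm_variant("ORACLE", "oracle")),
    n_presences = 100, n_absences = 1000, absence_buffer = 5,
    fuzzy = fuzzy_config(), upr_convention = "barbosa", seed = seed)
}

#' Run the default synthetic experiment end to end
#'
#' Generates the default world and species, runs the default ensemble and
#' the FGM-vs-index correlation stage.
#'
#' @param seed Master seed for world and sampling.
#' @return List: `stack`, `species`, `result` (an `ensemble_result`),
#'   `correlations` (an `fgm_correlations` table).
#' @export
run_default_experiment <- function(seed = 1) {
  stack <- generate_predictors(default_world_config(seed))
  species <- default_species(stack)
  result <- run_ensemble(stack, species, default_ensemble(seed))
  list(stack = stack, species = species, result = result,
       correlations = correlate_fgm(result$metrics))
}
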