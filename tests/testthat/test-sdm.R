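# BIOCLIM, DOMAIN, GLM and the prediction importer.

test_that("BIOCLIM envelope and tail-percentile scoring", {
  train <- data.frame(a = as.numeric(1:100))
  m <- fit_bioclim(train)
  expect_equal(m$envelope$a, c(1, 100))
  expect_identical(m, fit_bioclim(train))          # deterministic refit

  m2 <- fit_bioclim(data.frame(a = 1:10, b = 101:110))
  expect_equal(m2$envelope$a, c(1, 10))
  expect_equal(m2$envelope$b, c(101, 110))
  expect_error(fit_bioclim(data.frame(a = 1:4)), "at least 5")

  # per-layer scores: median -> 1; outside envelope -> 0; F = 0.9 -> 0.2
  train2 <- data.frame(a = as.numeric(1:100), b = as.numeric(1:100))
  mb <- fit_bioclim(train2)
  cells <- list(a = matrix(c(50.5, 0.5, 90.5), 1), # median, below-min, F=0.9
                b = matrix(c(50.5, 50.5, 50.5), 1))
  stack <- make_stack(cells)
  s <- predict_bioclim(mb, stack)$values
  expect_equal(s[1, 1], 1.0)                        # both layers at median
  expect_equal(s[1, 2], 0)                          # envelope rule
  expect_equal(s[1, 3], 0.2)                        # min(2*0.1, 1)
})

test_that("DOMAIN Gower similarity: training hit, hand case, clamping", {
  train <- data.frame(a = c(2, 7, 12), b = c(1, 3, 5))
  m <- fit_domain(train)                            # ranges (10, 4)
  expect_equal(unname(m$ranges), c(10, 4))
  cells <- list(a = matrix(c(7, 2, 1000), 1), b = matrix(c(3, 1, -1000), 1))
  s <- predict_domain(m, make_stack(cells))$values
  expect_equal(s[1, 1], 1.0)                        # equals a training point
  # cell (2,1): nearest is (2,1) itself -> 1; hand case below uses (2,1) vs (7,3)
  d <- (abs(2 - 7) / 10 + abs(1 - 3) / 4) / 2
  expect_equal(d, 0.5)                              # the worked Gower value
  expect_equal(s[1, 3], 0)                          # clamped far cell
  expect_error(fit_domain(data.frame(a = c(1, 1), b = 1:2)),
               "zero training range.*a")
})

test_that("DOMAIN worked example: similarity 0.5 one range away on average", {
  train <- data.frame(a = c(7, 17), b = c(3, 7))    # ranges (10, 4)
  m <- fit_domain(train)
  s <- predict_domain(m, make_stack(list(a = matrix(2), b = matrix(1))))
  expect_equal(s$values[1, 1], 0.5)                 # d = (0.5 + 0.5)/2
})

test_that("BIOCLIM/DOMAIN agree with brute-force oracles on random worlds", {
  set.seed(77)
  for (trial in 1:5) {
    mats <- list(env1 = matrix(rnorm(400), 20), env2 = matrix(rnorm(400), 20))
    stack <- make_stack(mats)
    train <- data.frame(env1 = rnorm(30), env2 = rnorm(30))
    mb <- fit_bioclim(train)
    md <- fit_domain(train)
    sb <- predict_bioclim(mb, stack)$values
    sd_ <- predict_domain(md, stack)$values
    idx <- cbind(sample(20, 25, TRUE), sample(20, 25, TRUE))
    for (k in seq_len(nrow(idx))) {
      cv <- c(mats$env1[idx[k, 1], idx[k, 2]], mats$env2[idx[k, 1], idx[k, 2]])
      expect_equal(sb[idx[k, , drop = FALSE]],
                   bioclim_oracle_cell(train, cv), tolerance = 1e-12)
      expect_equal(sd_[idx[k, , drop = FALSE]],
                   domain_oracle_cell(as.matrix(train), unname(md$ranges), cv),
                   tolerance = 1e-12)
    }
    expect_true(all(sb >= 0 & sb <= 1))
    expect_true(all(sd_ >= 0 & sd_ <= 1))
  }
})

test_that("GLM: intercept-only closed form, null slopes, separation flag", {
  # logit of prevalence 0.25
  y <- rep(c(1, 0), c(50, 150))
  # constant-zero predictor is aliased away, leaving an intercept-only fit
  m <- fit_glm_sdm(data.frame(v = rep(0, 200)), y = y)
  expect_equal(unname(m$coefficients[1]), log(0.25 / 0.75), tolerance = 1e-6)

  # under the null (zero true slope) fitted slopes are within 3 SE of 0
  set.seed(12)
  xs <- matrix(rnorm(4000), ncol = 2)
  y0 <- rbinom(2000, 1, 0.4)
  m0 <- fit_glm_sdm(data.frame(a = xs[, 1], b = xs[, 2]), y = y0)
  expect_true(all(abs(m0$coefficients[-1]) < 3 * m0$std_errors[-1]))
  expect_true(m0$converged)
  expect_false(m0$separation)

  # perfectly separated toy data
  expect_warning(
    msep <- fit_glm_sdm(data.frame(v = c(-2, -1, 1, 2)), y = c(0, 0, 1, 1)),
    "separation")
  expect_true(msep$separation)
  expect_error(fit_glm_sdm(data.frame(v = 1:4), y = rep(1, 4)),
               "both presences and absences")
})

test_that("GLM predictions follow the logistic surface", {
  stack <- make_stack(list(a = matrix(c(0, 2, 5), 1),
                           b = matrix(c(0, 2, 1), 1)))
  m <- structure(list(coefficients = c(`(Intercept)` = 0, a = 1, b = -1),
                      layers = c("a", "b")), class = "glm_model")
  p <- predict_glm_sdm(m, stack)$values
  expect_equal(p[1, 1], 0.5)                        # logistic(0)
  expect_equal(p[1, 2], 0.5)                        # beta=(0,1,-1), env=(2,2)
  expect_equal(p[1, 3], stats::plogis(4))
  # monotone in a positive-slope layer
  expect_true(all(diff(stats::plogis(0:5)) > 0))
  m0 <- structure(list(coefficients = c(`(Intercept)` = 0, a = 0, b = 0),
                       layers = c("a", "b")), class = "glm_model")
  expect_true(all(predict_glm_sdm(m0, stack)$values == 0.5))
})

test_that("GLM recovers simulated coefficients against glm() and truth", {
  set.seed(91)
  X <- matrix(rnorm(4000), ncol = 2)
  beta <- c(-0.5, 1.2, -0.8)
  y <- rbinom(2000, 1, stats::plogis(beta[1] + X %*% beta[-1]))
  tab <- data.frame(a = X[, 1], b = X[, 2])
  m <- fit_glm_sdm(tab, y = y)
  ref <- stats::glm(y ~ a + b, data = tab, family = stats::binomial())
  expect_equal(unname(m$coefficients), unname(stats::coef(ref)),
               tolerance = 1e-6)
  expect_true(all(abs(m$coefficients - beta) < 3 * m$std_errors))
})

test_that("import_prediction aligns, rescales and rejects mismatches", {
  template <- grid_raster(matrix(0, 4, 4))
  ok <- grid_raster(matrix(runif(16), 4, 4))
  expect_equal(import_prediction(ok, template)$values, ok$values)
  scaled <- import_prediction(
    grid_raster(matrix(seq(0, 255, length.out = 16), 4, 4)), template,
    rescale = TRUE)
  expect_equal(range(scaled$values), c(0, 1))
  expect_error(import_prediction(grid_raster(matrix(1, 4, 4)), template,
                                 rescale = TRUE), "zero range")
  off <- grid_raster(matrix(0, 4, 4), x_origin = 2)
  expect_error(import_prediction(off, template), "misaligned")
  f <- withr::local_tempfile(fileext = ".asc")
  write_raster(ok, f)
  expect_equal(import_prediction(f, template)$values, ok$values,
               tolerance = 1e-12)
})

test_that("restrictive-vs-permissive pattern: BIOCLIM omits, DOMAIN commits", {
  # shared world; DOMAIN binarized at a low threshold must show the higher
  # commission rate and BIOCLIM the higher omission rate
  stack <- generate_predictors(world_config(n_rows = 60, n_cols = 60,
                                            n_predictors = 3,
                                            autocorr_length = 4, seed = 19))
  vs <- define_species(stack, beta = c(0, 2.5, -2, 1), cutoff = 0.6)
  pres <- sample_presences(vs, 100, seed = 1)
  tab <- extract_values(stack, pres)[, names(stack$layers)]
  sb <- predict_bioclim(fit_bioclim(tab), stack)
  sd_ <- predict_domain(fit_domain(tab), stack)
  abs_ <- sample_true_absences(vs, 500, buffer_cells = 2, seed = 2)
  thr_b <- select_threshold(
    sb$values[cbind(cell_from_xy(sb, pres$x, pres$y)$row,
                    cell_from_xy(sb, pres$x, pres$y)$col)],
    sb$values[cbind(cell_from_xy(sb, abs_$x, abs_$y)$row,
                    cell_from_xy(sb, abs_$x, abs_$y)$col)])
  cb <- compute_metrics(confusion_from_maps(binarize(sb, as.numeric(thr_b)),
                                            vs$true_range), "complement")
  cd <- compute_metrics(confusion_from_maps(binarize(sd_, 0.5),
                                            vs$true_range), "complement")
  expect_gt(cd$opr, cb$opr)   # DOMAIN-like commission exceeds BIOCLIM's
  expect_gt(cb$upr, cd$upr)   # BIOCLIM omission exceeds DOMAIN's
})
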