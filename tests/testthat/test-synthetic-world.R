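# Virtual-species generator.

lag1_autocor <- function(m) {
  stats::cor(as.vector(m[-1, ]), as.vector(m[-nrow(m), ]))
}

test_that("worlds are bit-identical under identical config and seed", {
  cfg <- world_config(n_rows = 30, n_cols = 30, n_predictors = 3,
                      autocorr_length = 2, seed = 7)
  s1 <- generate_predictors(cfg)
  s2 <- generate_predictors(cfg)
  expect_identical(s1, s2)
  s3 <- generate_predictors(world_config(n_rows = 30, n_cols = 30,
                                         n_predictors = 3,
                                         autocorr_length = 2, seed = 8))
  expect_false(identical(s1, s3))
})

test_that("autocorrelation and standardization behave as configured", {
  cfg0 <- world_config(n_rows = 100, n_cols = 100, n_predictors = 2,
                       autocorr_length = 0, seed = 3)
  s0 <- generate_predictors(cfg0)
  expect_lt(abs(lag1_autocor(s0$layers[[1]]$values)), 0.05)  # white noise
  cfg5 <- world_config(n_rows = 100, n_cols = 100, n_predictors = 2,
                       autocorr_length = 5, seed = 3)
  s5 <- generate_predictors(cfg5)
  expect_gt(lag1_autocor(s5$layers[[1]]$values), 0.8)        # smooth field
  for (l in s5$layers) {
    expect_equal(mean(l$values), 0, tolerance = 1e-12)
    expect_equal(stats::sd(l$values), 1, tolerance = 1e-12)
  }
})

test_that("collinearity_spec manufactures correlated layers", {
  cfg <- world_config(n_rows = 100, n_cols = 100, n_predictors = 2,
                      autocorr_length = 3, seed = 11,
                      collinearity_spec = list(
                        list(source = "env1", weight = 1, noise_sd = 0.1)))
  s <- generate_predictors(cfg)
  expect_equal(names(s$layers), c("env1", "env2", "env3"))
  r <- stats::cor(as.vector(s$layers$env1$values),
                  as.vector(s$layers$env3$values))
  expect_gt(r, 0.99)
})

test_that("define_species honors the range invariants", {
  s <- generate_predictors(world_config(n_rows = 40, n_cols = 40,
                                        n_predictors = 2,
                                        autocorr_length = 3, seed = 5))
  # all-zero coefficients: suitability exactly 0.5 everywhere
  vs0 <- define_species(s, beta = c(0, 0, 0), cutoff = 0.4)
  expect_true(all(vs0$true_suitability$values == 0.5))
  expect_equal(vs0$prevalence, 1)

  vs <- define_species(s, beta = c(0, 2, -2), cutoff = 0.99)
  expect_lt(vs$prevalence, 0.5)
  expect_true(all(vs$true_suitability$values >= 0 &
                    vs$true_suitability$values <= 1))
  agree <- (vs$true_suitability$values >= 0.99) ==
    (vs$true_range$values == 1L)
  expect_true(all(agree))

  expect_error(define_species(s, beta = c(0, 1), cutoff = 0.5), "length")
  expect_error(define_species(s, beta = c(0, 1, 1), cutoff = 1.2),
               "inside \\(0, 1\\)")
  expect_error(define_species(s, beta = c(-50, 0, 0), cutoff = 0.9),
               "empty true range")
})

test_that("satellite patches add a disjoint range component", {
  s <- generate_predictors(world_config(n_rows = 40, n_cols = 40,
                                        n_predictors = 2,
                                        autocorr_length = 4, seed = 13))
  vs <- define_species(s, beta = c(-1, 3, 0), cutoff = 0.7)
  # place the patch in a far corner outside the climatic range
  stopifnot(all(vs$true_range$values[33:39, 33:39] == 0))
  vs_sat <- define_species(s, beta = c(-1, 3, 0), cutoff = 0.7,
                           satellite_spec = list(
                             list(row = 36, col = 36, radius = 2)))
  n_comp <- function(rng) {
    lab <- matrix(0L, nrow(rng), ncol(rng))
    nxt <- 0L
    for (i in which(rng == 1L)) {
      if (lab[i] > 0L) next
      nxt <- nxt + 1L
      queue <- i
      while (length(queue)) {
        j <- queue[[1]]; queue <- queue[-1]
        if (lab[j] > 0L) next
        lab[j] <- nxt
        r <- (j - 1L) %% nrow(rng) + 1L; c <- (j - 1L) %/% nrow(rng) + 1L
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          rr <- r + d[1]; cc <- c + d[2]
          if (rr >= 1 && rr <= nrow(rng) && cc >= 1 && cc <= ncol(rng) &&
              rng[rr, cc] == 1L && lab[rr, cc] == 0L)
            queue <- c(queue, (cc - 1L) * nrow(rng) + rr)
        }
      }
    }
    nxt
  }
  expect_equal(n_comp(vs_sat$true_range$values),
               n_comp(vs$true_range$values) + 1L)
  expect_true(all(vs_sat$true_range$values[35:37, 35:37] == 1L))
})

test_that("presence sampling stays in range, is seeded and exhausts", {
  s <- generate_predictors(world_config(n_rows = 30, n_cols = 30,
                                        n_predictors = 2,
                                        autocorr_length = 3, seed = 21))
  vs <- define_species(s, beta = c(0, 2, 1), cutoff = 0.6)
  pts <- sample_presences(vs, 100, seed = 4)
  expect_identical(pts, sample_presences(vs, 100, seed = 4))
  loc <- cell_from_xy(vs$true_range, pts$x, pts$y)
  expect_true(all(vs$true_range$values[cbind(loc$row, loc$col)] == 1L))
  n_range <- sum(vs$true_range$values == 1L)
  all_pts <- sample_presences(vs, n_range, seed = 4)
  loc_all <- cell_from_xy(vs$true_range, all_pts$x, all_pts$y)
  expect_equal(nrow(unique(loc_all[1:2])), n_range)  # every cell once
  expect_error(sample_presences(vs, n_range + 1), "exceeds")
})

test_that("under uniform suitability, aggregated draws are uniform", {
  # without-replacement draws of 20 cells, aggregated over 150 seeds, should
  # hit a 10 x 20 all-range world's 200 cells uniformly
  m <- matrix(0, 10, 20)
  s <- make_stack(list(env1 = m, env2 = m))
  vs <- define_species(s, beta = c(0, 0, 0), cutoff = 0.4)
  counts <- matrix(0, 10, 20)
  for (seed in 1:150) {
    p <- sample_presences(vs, 20, seed = seed)
    loc <- cell_from_xy(vs$true_range, p$x, p$y)
    counts[cbind(loc$row, loc$col)] <- counts[cbind(loc$row, loc$col)] + 1
  }
  p_val <- stats::chisq.test(as.vector(counts))$p.value
  expect_gt(p_val, 0.001)
})

test_that("true absences respect the buffer and are distinct cells", {
  s <- generate_predictors(world_config(n_rows = 60, n_cols = 60,
                                        n_predictors = 2,
                                        autocorr_length = 4, seed = 17))
  vs <- define_species(s, beta = c(-0.7, 2.5, -1), cutoff = 0.6)
  ab0 <- sample_true_absences(vs, 200, buffer_cells = 0, seed = 2)
  loc0 <- cell_from_xy(vs$true_range, ab0$x, ab0$y)
  expect_true(all(vs$true_range$values[cbind(loc0$row, loc0$col)] == 0L))

  ab5 <- sample_true_absences(vs, 200, buffer_cells = 5, seed = 2)
  loc5 <- cell_from_xy(vs$true_range, ab5$x, ab5$y)
  expect_equal(nrow(unique(loc5[1:2])), 200)
  rng_cells <- which(vs$true_range$values == 1L, arr.ind = TRUE)
  min_d <- vapply(seq_len(nrow(loc5)), function(i)
    sqrt(min((rng_cells[, 1] - loc5$row[i])^2 +
               (rng_cells[, 2] - loc5$col[i])^2)), numeric(1))
  expect_true(all(min_d > 5))
  expect_error(sample_true_absences(vs, 1e6, buffer_cells = 0), "eligible")
})
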