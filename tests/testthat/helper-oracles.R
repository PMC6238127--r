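# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (direct loops, no shared code with the package
# internals) so they can arbitrate the production implementations.

make_stack <- function(mats, cell_size = 1, x_origin = 0) {
  layers <- lapply(mats, sdmeval::grid_raster, x_origin = x_origin,
                   y_origin = nrow(mats[[1]]) * cell_size,
                   cell_size = cell_size)
  sdmeval::env_stack(layers)
}

rand_binary_map <- function(nr = 8, nc = 8, p = 0.5) {
  sdmeval::categorical_map(matrix(as.integer(stats::runif(nr * nc) < p),
                                  nr, nc),
                           categories = c(0L, 1L))
}

# direct-loop fuzzy global matching: for each cell of each map, scan every
# cell of the other map inside the radius
fgm_oracle <- function(a, b, cfg) {
  av <- a$values; bv <- b$values
  nr <- nrow(av); nc <- ncol(av)
  membership <- function(v, cat, r0, c0) {
    best <- 0
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (is.na(v[r, c]) || v[r, c] != cat) next
      d <- sqrt((r - r0)^2 + (c - c0)^2)
      if (d > cfg$neighborhood_radius && d > 0) next
      best <- max(best, 2^(-d / cfg$halving_distance))
    }
    best
  }
  sims <- c()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(av[r, c]) || is.na(bv[r, c])) next
    s_ab <- membership(av, bv[r, c], r, c)
    s_ba <- membership(bv, av[r, c], r, c)
    sims <- c(sims, min(s_ab, s_ba))
  }
  mean(sims)
}

# brute-force pairwise-concordance AUC (ties count 1/2)
auc_oracle <- function(pres, abs_) {
  tot <- 0
  for (p in pres) for (a in abs_)
    tot <- tot + (p > a) + 0.5 * (p == a)
  tot / (length(pres) * length(abs_))
}

# exhaustive-scan Youden-optimal threshold (score >= t => presence),
# smallest qualifying threshold on ties
threshold_oracle <- function(pres, abs_) {
  cand <- sort(unique(c(pres, abs_)))
  j <- sapply(cand, function(t)
    mean(pres >= t) + mean(abs_ < t) - 1)
  cand[which(j == max(j))[1]]
}

# naive per-cell BIOCLIM score via explicit counting over training values
bioclim_oracle_cell <- function(train_tab, cell_vals) {
  scores <- sapply(seq_along(cell_vals), function(k) {
    tr <- train_tab[[k]]
    v <- cell_vals[k]
    if (v < min(tr) || v > max(tr)) return(0)
    f <- (sum(tr < v) + 0.5 * sum(tr == v)) / length(tr)
    2 * min(f, 1 - f)
  })
  min(scores)
}

# naive per-cell DOMAIN similarity via explicit loops over training points
domain_oracle_cell <- function(train_mat, ranges, cell_vals) {
  best <- -Inf
  for (i in seq_len(nrow(train_mat))) {
    d <- mean(abs(cell_vals - train_mat[i, ]) / ranges)
    best <- max(best, 1 - d)
  }
  min(max(best, 0), 1)
}

expect_raster_equal <- function(a, b, tolerance = 0) {
  testthat::expect_equal(dim(a$values), dim(b$values))
  testthat::expect_equal(a$x_origin, b$x_origin)
  testthat::expect_equal(a$y_origin, b$y_origin)
  testthat::expect_equal(a$cell_size, b$cell_size)
  testthat::expect_identical(is.na(a$values), is.na(b$values))
  if (tolerance > 0)
    testthat::expect_equal(a$values, b$values, tolerance = tolerance)
  else testthat::expect_equal(a$values, b$values)
}
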