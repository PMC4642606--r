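test_that("toy configurations have their defining geometry", {
  g <- toy_configuration("grid5")
  expect_equal(dim(g), c(25L, 2L))

  p6 <- toy_configuration("prologue6")
  subs <- toy_subsets("prologue6")
  expect_true(is_square_oracle(p6[subs$small, ]))
  expect_true(is_square_oracle(p6[subs$large, ]))
  side <- function(pts) sqrt(min(dist(pts)^2))
  expect_equal(side(p6[subs$large, ]) / side(p6[subs$small, ]), sqrt(2),
               tolerance = 1e-12)

  gz <- toy_configuration("giza")
  gs <- toy_subsets("giza")
  expect_equal(dim(gz), c(9L, 3L))
  # both pentahedra are the same shape at scale ratio 4
  expect_equal(centroid_size(gz[gs$large, ]) / centroid_size(gz[gs$small, ]),
               4, tolerance = 1e-12)
  expect_equal(as.vector(dist(gz[gs$large, ])),
               4 * as.vector(dist(gz[gs$small, ])), tolerance = 1e-12)

  expect_error(toy_configuration("nonesuch"))
})

test_that("the isotropic generator is seeded, centered, and shrinks with sigma", {
  m <- toy_configuration("quincunx")
  s1 <- isotropic_sample(m, 0.05, 50, seed = 81)
  s2 <- isotropic_sample(m, 0.05, 50, seed = 81)
  expect_identical(s1$coords, s2$coords)

  tiny <- isotropic_sample(m, 1e-12, 5, seed = 82)
  expect_lt(max(abs(tiny$coords - array(rep(m, 5), c(5, 2, 5)))), 1e-10)

  big <- isotropic_sample(m, 0.1, 2000, seed = 83)
  emp_mean <- apply(big$coords, c(1, 2), mean)
  expect_lt(max(abs(emp_mean - m)), 3 * 0.1 / sqrt(2000) * 4)
})

test_that("per-landmark raw scatter of the isotropic generator is circular", {
  s <- isotropic_sample(toy_configuration("grid5"), 0.15, 1000, seed = 84)
  ratios <- vapply(1:25, function(i) {
    ev <- eigen(stats::cov(t(s$coords[i, , ])), symmetric = TRUE)$values
    ev[1] / ev[2]
  }, numeric(1))
  expect_lt(mean(ratios), 1.1)
  expect_lt(max(ratios), 1.35)                  # 25 simultaneous F-ratios
})

test_that("square enumeration is exact against the brute-force oracle", {
  g22 <- unname(as.matrix(expand.grid(0:1, 0:1)))
  expect_equal(length(enumerate_grid_squares(g22)), 1L)
  g33 <- unname(as.matrix(expand.grid(0:2, 0:2)))
  expect_equal(length(enumerate_grid_squares(g33)), brute_squares(g33))
  expect_equal(length(enumerate_grid_squares(g33)), 6L)
  g55 <- toy_configuration("grid5")
  expect_equal(length(enumerate_grid_squares(g55)), 50L)
  # every returned 4-tuple is a genuine square in cyclic vertex order
  sq <- enumerate_grid_squares(g55)
  for (idx in sq[c(1, 25, 50)]) {
    expect_true(is_square_oracle(g55[idx, ]))
    e <- diff(rbind(g55[idx, ], g55[idx[1], , drop = FALSE]))
    expect_equal(unname(rowSums(e^2)), rep(sum(e[1, ]^2), 4))  # equal edges
  }
  expect_error(enumerate_grid_squares(g55 + 0.5), "lattice")
})

test_that("subset nonaffine variance follows the inverse-area law, undeflated", {
  s <- isotropic_sample(toy_configuration("prologue6"), 0.05, 1000, seed = 85)
  subs <- toy_subsets("prologue6")
  v_small <- subconfig_nonaffine_variance(s, subs$small)
  v_large <- subconfig_nonaffine_variance(s, subs$large)
  expect_lt(abs(v_large / v_small - 0.5), 0.1 * 0.5)

  ident <- shape_sample(array(rep(toy_configuration("prologue6"), 4),
                              c(6, 2, 4)))
  expect_equal(subconfig_nonaffine_variance(ident, 1:4), 0, tolerance = 1e-20)

  # grid5: unit square vs the full-span square, ratio = area ratio = 16
  g <- toy_configuration("grid5")
  sg <- shape_sample(grid5_fit()$aligned)
  unit_sq <- c(1L, 2L, 7L, 6L)                  # row-major indexing
  big_sq <- c(1L, 5L, 25L, 21L)
  r <- subconfig_nonaffine_variance(sg, unit_sq) /
    subconfig_nonaffine_variance(sg, big_sq)
  expect_lt(abs(r / 16 - 1), 0.2)

  # across all 50 squares the undeflated variance is inverse to area
  sq <- enumerate_grid_squares(g)
  areas <- vapply(sq, function(idx) {
    e <- g[idx[2], ] - g[idx[1], ]
    sum(e^2)
  }, numeric(1))
  vars <- vapply(sq, function(idx) subconfig_nonaffine_variance(sg, idx),
                 numeric(1))
  fit <- stats::lm(log(vars) ~ log(areas))
  expect_gt(summary(fit)$r.squared, 0.95)
  expect_lt(abs(unname(stats::coef(fit)[2]) + 1), 0.15)
})

test_that("deflated samples equalize subset variances across scales", {
  defl <- self_similar_sample(toy_configuration("prologue6"), 0.05, 1000,
                              seed = 86)
  subs <- toy_subsets("prologue6")
  v_small <- subconfig_nonaffine_variance(defl, subs$small)
  v_large <- subconfig_nonaffine_variance(defl, subs$large)
  expect_lt(abs(v_large / v_small - 1), 0.1)
})

test_that("3D deflation equalizes the giza pentahedron amplitudes", {
  gz <- toy_configuration("giza")
  gs <- toy_subsets("giza")
  s <- isotropic_sample(gz, 0.02, 500, seed = 87)
  amp_pre <- sqrt(subconfig_nonaffine_variance(s, gs$small) /
                    subconfig_nonaffine_variance(s, gs$large))
  expect_lt(abs(amp_pre / 4 - 1), 0.15)
  defl <- self_similar_sample(gz, 0.02, 500, seed = 87)
  amp_post <- sqrt(subconfig_nonaffine_variance(defl, gs$small) /
                     subconfig_nonaffine_variance(defl, gs$large))
  expect_lt(abs(amp_post - 1), 0.15)
})

test_that("the parcellation generator respects its construction", {
  tmpl <- warpscaling:::parcellation_template(3)
  expect_equal(nrow(tmpl$points), 13L)
  expect_equal(as.vector(table(tmpl$level)), c(4L, 1L, 4L, 4L))

  flat <- parcellation_sample(3, base_sd = 0, n = 3, seed = 88)
  for (s in 1:3) expect_equal(flat$coords[, , s], tmpl$points)

  p <- parcellation_sample(3, base_sd = 0.05, decay = 0.5, n = 1000,
                           seed = 89)
  # center residual from its corner-imputed location has variance
  # about decay x the corner variance
  resid <- matrix(0, 1000, 2)
  for (s in 1:1000) {
    map <- tps_map(tmpl$points[1:4, ], p$coords[1:4, , s])
    resid[s, ] <- p$coords[5, , s] -
      evaluate_map(map, tmpl$points[5, , drop = FALSE])
  }
  corner_var <- mean(apply(p$coords[1, , ], 1, stats::var) +
                       apply(p$coords[2, , ], 1, stats::var)) / 2
  ratio <- mean(apply(resid, 2, stats::var)) / corner_var
  expect_lt(abs(ratio / 0.5 - 1), 0.15)

  expect_error(parcellation_sample(4, 0.05, 0.5, 10, 1), "levels")
})

test_that("parcellation output scales near self-similarity", {
  p <- parcellation_sample(3, base_sd = 0.05, decay = 0.5, n = 1000,
                           seed = 90)
  fit <- gpa(p)
  spec <- bending_spectrum(fit$mean)
  pw <- partial_warp_scores(fit, spec)
  sl <- scaling_regression(pw$variances, spec$energies)$slope
  expect_lt(abs(sl + 1), 0.3)
})

test_that("parcellation displacements are spatially autocorrelated", {
  tmpl <- warpscaling:::parcellation_template(3)
  neighbor_cos <- function(sample) {
    co <- sample$coords
    n <- dim(co)[3]
    # displacement field relative to the sample mean configuration
    mn <- apply(co, c(1, 2), mean)
    pairs <- which(as.matrix(dist(tmpl$points)) < 0.6 &
                     upper.tri(matrix(0, 13, 13)), arr.ind = TRUE)
    cosv <- numeric(0)
    for (s in seq_len(n)) {
      dv <- co[, , s] - mn
      for (r in seq_len(nrow(pairs))) {
        a <- dv[pairs[r, 1], ]; b <- dv[pairs[r, 2], ]
        na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
        if (na > 0 && nb > 0) cosv <- c(cosv, sum(a * b) / (na * nb))
      }
    }
    mean(cosv)
  }
  p <- parcellation_sample(3, base_sd = 0.05, decay = 0.5, n = 150, seed = 91)
  iso <- isotropic_sample(tmpl$points, 0.05, 150, seed = 92)
  expect_gt(neighbor_cos(p), 0.1)
  expect_lt(abs(neighbor_cos(iso)), 0.05)
})
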