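test_that("standardize_mean enforces the centering and moment conventions", {
  set.seed(41)
  for (d in 2:3) {
    X <- matrix(rnorm(8 * d, sd = 2), 8, d) + 5
    P <- standardize_mean(X)
    expect_equal(colSums(P), rep(0, d), tolerance = 1e-12)
    expect_equal(sum(P^2), 1, tolerance = 1e-12)
    mom <- crossprod(P)
    expect_lt(max(abs(mom[upper.tri(mom)])), 1e-12)   # principal axes
    expect_true(all(diff(diag(mom)) <= 1e-12))        # non-increasing moments
  }
})

test_that("gpa is exact on similarity-equivalent inputs and idempotent", {
  sq <- toy_configuration("prologue6")
  # identical configurations: aligned coordinates all equal the mean
  same <- shape_sample(array(rep(sq, 4), c(6, 2, 4)))
  fit <- gpa(same)
  for (s in 1:4) expect_equal(fit$aligned[, , s], fit$mean, tolerance = 1e-10)
  expect_equal(total_var <- sum(apply(fit$aligned, c(1, 2), var)), 0,
               tolerance = 1e-20)

  # two triangles differing by a similarity transform only
  tri <- matrix(c(0, 3, 1, 0, 0, 2), 3, 2)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  tri2 <- 2.5 * tri %*% R + 7
  ft <- gpa(shape_sample(list(tri, tri2)))
  expect_lt(sqrt(sum((ft$aligned[, , 1] - ft$aligned[, , 2])^2)), 1e-12)

  # invariance: transforming every input similarity-style leaves the fit alone
  sim <- isotropic_sample(sq, 0.05, 20, seed = 9)
  f1 <- gpa(sim)
  moved <- sim$coords
  for (s in 1:20) moved[, , s] <- 0.3 * moved[, , s] %*% R - 11
  f2 <- gpa(shape_sample(moved))
  expect_equal(f2$aligned, f1$aligned, tolerance = 1e-9)
  expect_equal(f2$mean, f1$mean, tolerance = 1e-9)

  # idempotence on its own output
  f3 <- gpa(shape_sample(f1$aligned))
  expect_equal(f3$aligned, f1$aligned, tolerance = 1e-9)
})

test_that("full Procrustes distance matches a grid-search minimization", {
  set.seed(10)
  tri <- matrix(c(0, 2, 0.5, 0, 0.2, 1.5), 3, 2)
  for (rep in 1:3) {
    X <- tri + matrix(rnorm(6, sd = 0.05), 3, 2)
    M <- tri + matrix(rnorm(6, sd = 0.05), 3, 2)
    fit <- gpa(shape_sample(list(X, M)))
    # full Procrustes distance of specimen 1 to the standardized mean:
    # minimizing over scale as well as rotation gives sqrt(1 - cos^2) for
    # unit-size optimally rotated configurations
    dot <- sum(fit$aligned[, , 1] * fit$mean)
    dpkg <- sqrt(1 - dot^2)
    dor <- brute_procrustes_distance(X, fit$mean)
    expect_equal(dpkg, unname(dor), tolerance = 1e-6)
  }
})

test_that("isotropic aligned scatter is circular landmark by landmark", {
  fit <- prologue6_fit()
  ratios <- vapply(1:6, function(i) {
    ev <- eigen(stats::cov(t(fit$aligned[i, , ])), symmetric = TRUE)$values
    ev[1] / ev[2]
  }, numeric(1))
  # each ratio is F-distributed noise around 1 (relative se about 6% at
  # n = 1000); demand closeness on average and no gross anisotropy anywhere
  expect_lt(mean(ratios), 1.1)
  expect_lt(max(ratios), 1.25)
})

test_that("uniform basis spans the affine variation and is warp-orthogonal", {
  fit <- gpa(isotropic_sample(toy_configuration("prologue6"), 0.05, 50,
                              seed = 2))
  ub <- uniform_basis(fit$mean)
  expect_equal(dim(ub$vectors), c(2L, 12L))
  expect_equal(qr(ub$vectors)$rank, 2L)
  expect_lt(abs(sum(ub$vectors[1, ] * ub$vectors[2, ])), 1e-12)

  spec <- bending_spectrum(fit$mean)
  # warps act on one Cartesian axis at a time in the interleaved order
  for (l in seq_along(spec$energies)) for (a in 1:2) {
    wvec <- rep(0, 12)
    wvec[seq(a, 12, by = 2)] <- spec$warps[, l]
    expect_lt(abs(sum(ub$vectors[1, ] * wvec)), 1e-10)
    expect_lt(abs(sum(ub$vectors[2, ] * wvec)), 1e-10)
  }

  # displacements built from the uniform rows carry no nonaffine variance
  M <- fit$mean
  n <- 40
  co <- array(0, c(6, 2, n))
  set.seed(4)
  for (s in 1:n) {
    eps <- rnorm(2, sd = 1e-3)
    dv <- eps[1] * ub$vectors[1, ] + eps[2] * ub$vectors[2, ]
    co[, , s] <- M + matrix(dv, 6, 2, byrow = TRUE)
  }
  dev <- t(matrix(aperm(co, c(2, 1, 3)), 12, n))
  dev <- sweep(dev, 2, as.vector(t(M)))
  Un <- ub$vectors / sqrt(rowSums(ub$vectors^2))
  residual <- dev - (dev %*% t(Un)) %*% Un
  expect_lt(sum(residual^2) / sum(dev^2), 1e-10)
})

test_that("quincunx uniform basis has rank 2", {
  m <- standardize_mean(toy_configuration("quincunx"))
  expect_equal(qr(uniform_basis(m)$vectors)$rank, 2L)
})

test_that("nonaffine projection kills affine perturbations and is idempotent", {
  M <- standardize_mean(toy_configuration("prologue6"))
  n <- 25
  co <- array(0, c(6, 2, n))
  set.seed(6)
  for (s in 1:n) {
    A <- diag(2) + matrix(rnorm(4, sd = 1e-4), 2, 2)   # small affine maps
    co[, , s] <- M %*% A
  }
  fit <- gpa(shape_sample(co))
  na <- project_nonaffine(fit)
  for (s in 1:n)
    expect_lt(sqrt(sum((na$coords[, , s] - fit$mean)^2)), 1e-10)

  # idempotence (about the same mean) and variance conservation
  fit2 <- gpa(isotropic_sample(M, 0.04, 200, seed = 12))
  na2 <- project_nonaffine(fit2)
  refit <- fit2
  refit$aligned <- na2$coords
  na3 <- project_nonaffine(refit)
  expect_equal(na3$coords, na2$coords, tolerance = 1e-12)

  dev <- t(matrix(aperm(fit2$aligned, c(2, 1, 3)), 12, 200))
  dev <- sweep(dev, 2, as.vector(t(fit2$mean)))
  # full affine subspace: (1, x, y) patterns on each axis, orthonormalized
  Z <- affine_block_basis(fit2$mean)
  removed <- total_coordinate_variance(fit2$aligned) -
    total_coordinate_variance(na2$coords)
  captured <- sum(apply(dev %*% t(Z), 2, stats::var))
  expect_equal(removed, captured, tolerance = 1e-12)
})

test_that("3D affine removal agrees with the 2D closed-form route", {
  # shared 2D case embedded: compare projector-based removal with explicit
  # per-specimen regression on (1, x, y) of the mean
  fit <- gpa(isotropic_sample(toy_configuration("prologue6"), 0.05, 30,
                              seed = 14))
  na <- project_nonaffine(fit)
  Z <- cbind(1, fit$mean)
  for (s in c(1, 17, 30)) {
    dv <- fit$aligned[, , s] - fit$mean
    resid <- dv - Z %*% solve(crossprod(Z), crossprod(Z, dv))
    expect_equal(na$coords[, , s], fit$mean + resid, tolerance = 1e-10)
  }
  # genuine 3D case: projection leaves nothing in the affine span
  fit3 <- gpa(isotropic_sample(toy_configuration("giza"), 0.02, 20, seed = 15))
  na3 <- project_nonaffine(fit3)
  Z3 <- cbind(1, fit3$mean)
  for (s in 1:20) {
    dv <- na3$coords[, , s] - fit3$mean
    expect_lt(max(abs(crossprod(Z3, dv))), 1e-10)
  }
})
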