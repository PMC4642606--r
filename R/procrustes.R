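#' Centroid size of a configuration
#'
#' The square root of the summed squared distances of the landmarks from
#' their centroid; the size measure used for Procrustes scaling.
#'
#' @param config a k x d coordinate matrix.
#' @return a positive scalar.
#' @export
centroid_size <- function(config) {
  X <- as_configuration(config)
  ctr <- sweep(X, 2, colMeans(X))
  sqrt(sum(ctr^2))
}

# optimal proper rotation R minimizing ||X R - M||_F (Kabsch)
optimal_rotation <- function(X, M) {
  S <- crossprod(X, M)
  if (ncol(X) == 2L) {
    theta <- atan2(S[2, 1] - S[1, 2], S[1, 1] + S[2, 2])
    c_ <- cos(theta); s_ <- sin(theta)
    matrix(c(c_, s_, -s_, c_), 2, 2)
  } else {
    sv <- svd(S)
    d <- sign(det(sv$u) * det(sv$v))
    sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  }
}

#' Standardize a mean configuration
#'
#' Centers the configuration, scales it to unit centroid size, and rotates
#' it to principal axes: in 2D the standardized mean satisfies
#' sum(x) = sum(y) = sum(x*y) = 0, sum(x^2 + y^2) = 1 and
#' sum(x^2) >= sum(y^2); in 3D the second-moment matrix of the coordinates
#' is diagonal with non-increasing entries. The residual rotation ambiguity
#' (proper-axis flips) is resolved deterministically: the landmark of
#' largest radius gets a positive first coordinate, remaining ties broken
#' by positive subsequent coordinates. All reported statistics are
#' invariant to this convention.
#'
#' @param config a k x d coordinate matrix.
#' @return a k x d standardized configuration.
#' @export
standardize_mean <- function(config) {
  X <- as_configuration(config)
  d <- ncol(X)
  X <- sweep(X, 2, colMeans(X))
  cs <- sqrt(sum(X^2))
  if (cs == 0) stop("degenerate configuration: all landmarks coincide")
  X <- X / cs
  eg <- eigen(crossprod(X), symmetric = TRUE)
  R <- eg$vectors                       # columns ordered by decreasing moment
  if (det(R) < 0) R[, d] <- -R[, d]     # keep a proper rotation
  P <- X %*% R
  # flip convention among the proper axis-sign candidates: the landmark of
  # largest radius gets positive coordinates, axis by axis; the last axis
  # absorbs the det = +1 constraint
  radii <- sqrt(rowSums(P^2))
  i1 <- which.max(radii)
  if (d == 2L) {
    # only two proper candidates: identity and the half-turn
    if (P[i1, 1] < 0 || (abs(P[i1, 1]) < 1e-12 && P[i1, 2] < 0)) P <- -P
  } else {
    s <- c(if (P[i1, 1] < 0) -1 else 1, if (P[i1, 2] < 0) -1 else 1, 1)
    s[3] <- s[1] * s[2]
    P <- sweep(P, 2, s, `*`)
  }
  dimnames(P) <- dimnames(config)
  P
}

#' Generalized Procrustes superposition
#'
#' Full (scaled) generalized Procrustes analysis: each specimen is
#' centered, scaled to unit centroid size, and iteratively rotated to the
#' evolving mean until the mean stabilizes; the converged mean is then
#' standardized by [standardize_mean()] and all specimens are re-rotated
#' into that frame. Variances of the resulting shape coordinates are "in
#' Procrustes units".
#'
#' @param sample a [shape_sample()] (validated and nondegenerate).
#' @param tol convergence tolerance on the root-mean-square change of the
#'   mean between iterations.
#' @param max_iter maximum number of mean-update iterations.
#' @return an object of class `"procrustes_fit"`: a list with `aligned`
#'   (k x d x n array of Procrustes shape coordinates), `mean`
#'   (standardized k x d mean), `centroid_sizes`, `alpha` and `gamma`
#'   (2D only: the principal moments of the mean), and `iterations`.
#' @export
gpa <- function(sample, tol = 1e-10, max_iter = 200L) {
  stopifnot(inherits(sample, "shape_sample"))
  assert_valid(sample, require_nonaffine = FALSE)
  co <- sample$coords
  k <- dim(co)[1L]; d <- dim(co)[2L]; n <- dim(co)[3L]
  sizes <- numeric(n)
  X <- co
  for (s in seq_len(n)) {
    cfg <- sweep(co[, , s], 2, colMeans(co[, , s]))
    sizes[s] <- sqrt(sum(cfg^2))
    X[, , s] <- cfg / sizes[s]
  }
  mean_shape <- X[, , 1L]
  mean_shape <- mean_shape / sqrt(sum(mean_shape^2))
  iter <- 0L; delta <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    for (s in seq_len(n))
      X[, , s] <- X[, , s] %*% optimal_rotation(X[, , s], mean_shape)
    new_mean <- apply(X, c(1, 2), mean)
    new_mean <- sweep(new_mean, 2, colMeans(new_mean))
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    delta <- sqrt(mean((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) break
  }
  if (delta >= tol)
    stop(sprintf(paste0("GPA did not converge after %d iterations ",
                        "(last mean change %.3e > tol %.3e)"),
                 max_iter, delta, tol))
  mean_std <- standardize_mean(mean_shape)
  for (s in seq_len(n))
    X[, , s] <- X[, , s] %*% optimal_rotation(X[, , s], mean_std)
  alpha <- gamma <- NULL
  if (d == 2L) {
    alpha <- sum(mean_std[, 1]^2)
    gamma <- sum(mean_std[, 2]^2)
  }
  structure(list(aligned = X, mean = mean_std, centroid_sizes = sizes,
                 alpha = alpha, gamma = gamma,
                 iterations = iter, tol = tol,
                 ids = sample$ids, labels = sample$labels),
            class = "procrustes_fit")
}

#' @export
print.procrustes_fit <- function(x, ...) {
  dm <- dim(x$aligned)
  cat(sprintf("procrustes_fit: %d specimens, %d landmarks in %dD (%d iterations)\n",
              dm[3L], dm[1L], dm[2L], x$iterations))
  if (!is.null(x$alpha))
    cat(sprintf("  mean moments: alpha = %.6f, gamma = %.6f\n",
                x$alpha, x$gamma))
  invisible(x)
}

#' Uniform (affine) basis of a standardized 2D mean
#'
#' The two row vectors spanning the uniform subspace of shape variation
#' about a standardized 2D mean, in the vectorized coordinate order
#' (x1, y1, x2, y2, ..., xk, yk):
#' \deqn{(\alpha y_1, \gamma x_1, \alpha y_2, \gamma x_2, \ldots)}
#' \deqn{(-\gamma x_1, \alpha y_1, -\gamma x_2, \alpha y_2, \ldots)}
#' where \eqn{\alpha = \sum x_i^2} and \eqn{\gamma = \sum y_i^2} are the
#' principal moments of the mean. Both rows are orthogonal to every
#' principal warp direction.
#'
#' @param mean a standardized k x 2 mean configuration (see
#'   [standardize_mean()]).
#' @return an object of class `"uniform_basis"`: list with `vectors`
#'   (2 x 2k matrix), `alpha`, `gamma`, and the `mean` used.
#' @export
uniform_basis <- function(mean) {
  M <- as_configuration(mean)
  if (ncol(M) != 2L)
    stop("the closed-form uniform basis is available in 2D only")
  if (abs(sum(M[, 1] * M[, 2])) > 1e-8 || abs(sum(M^2) - 1) > 1e-8)
    stop("'mean' must be standardized (principal axes, unit centroid size)")
  alpha <- sum(M[, 1]^2); gamma <- sum(M[, 2]^2)
  k <- nrow(M)
  v1 <- as.vector(rbind(alpha * M[, 2], gamma * M[, 1]))
  v2 <- as.vector(rbind(-gamma * M[, 1], alpha * M[, 2]))
  structure(list(vectors = rbind(v1, v2), alpha = alpha, gamma = gamma,
                 mean = M),
            class = "uniform_basis")
}

# k x (d+1) affine regressors (1, coordinates) of a mean configuration
affine_design <- function(mean) cbind(1, as_configuration(mean))

# projector onto the orthogonal complement of span(1, x, y[, z]) in R^k
nonaffine_projector <- function(mean) {
  Z <- affine_design(mean)
  diag(nrow(Z)) - Z %*% solve(crossprod(Z), t(Z))
}

#' Project out the affine component of a Procrustes fit
#'
#' Removes the uniform (affine) part of every specimen's deviation from
#' the mean, leaving only the nonaffine (bent) variation: per specimen and
#' Cartesian axis, the deviation is replaced by its residual from ordinary
#' least-squares regression on (1, x, y[, z]) of the mean, and added back
#' to the mean. The result is exactly the projection onto the span of the
#' principal warps; it is idempotent, and purely affine perturbations map
#' to the mean itself.
#'
#' @param fit a `"procrustes_fit"` from [gpa()].
#' @return a [shape_sample()] of nonaffine shape coordinates.
#' @export
project_nonaffine <- function(fit) {
  stopifnot(inherits(fit, "procrustes_fit"))
  Pk <- nonaffine_projector(fit$mean)
  co <- fit$aligned
  n <- dim(co)[3L]
  out <- co
  for (s in seq_len(n))
    out[, , s] <- fit$mean + Pk %*% (co[, , s] - fit$mean)
  shape_sample(out, labels = fit$labels, ids = fit$ids,
               metadata = list(projection = "nonaffine"))
}

#' Total coordinate variance of a sample array
#'
#' The trace of the coordinate covariance matrix: the sum of the
#' per-coordinate variances over all k x d shape coordinates.
#'
#' @param coords a k x d x n array (e.g. `fit$aligned` or a
#'   `shape_sample`'s `$coords`).
#' @return a nonnegative scalar.
#' @export
total_coordinate_variance <- function(coords) {
  dm <- dim(coords)
  flat <- t(matrix(coords, dm[1L] * dm[2L], dm[3L]))
  sum(apply(flat, 2, stats::var))
}
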