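#' Relative intrinsic warps
#'
#' Principal components of the deflated shape coordinates. Because
#' deflation rescales the warp basis by the inverse (root) relative
#' bending energy, this ordinary PCA is equivalent to a relative
#' eigenanalysis of the nonaffine shape covariance with respect to the
#' bending-energy quadratic form: the components are ordered by variance
#' *per unit bending energy* rather than per unit Procrustes distance,
#' which is what makes them suitable for describing integration across
#' spatial scales.
#'
#' Loadings are reported both in the deflated coordinate system (unit
#' norm there) and "reinflated" back to Procrustes units (each warp
#' component multiplied by the inverse prefactor and the result
#' re-normalized), the latter showing any local modules with less
#' attenuation.
#'
#' @param deflated a `"deflated_sample"` from [deflate()].
#' @param zero_tol components with eigenvalue below
#'   `zero_tol * largest` are dropped. No automatic retention rule is
#'   applied beyond this rank cut; which components are interpretable is
#'   the user's judgment.
#' @return an object of class `"riw_result"`: list with `eigenvalues`
#'   (descending), `var_explained`, `scores` (n x c), `loadings_deflated`
#'   and `loadings_reinflated` (k x d x c arrays), `loadings_warp_basis`
#'   (m x d x c array of deflated-basis warp coefficients), `mean`,
#'   `spectrum`, `prefactors`.
#' @export
relative_intrinsic_warps <- function(deflated, zero_tol = 1e-10) {
  stopifnot(inherits(deflated, "deflated_sample"))
  co <- deflated$coords
  k <- dim(co)[1L]; d <- dim(co)[2L]; n <- dim(co)[3L]
  if (n < 3L) stop("need at least 3 specimens for relative intrinsic warps")
  flat <- t(matrix(co, k * d, n))               # n x kd, coordinate-major
  cv <- stats::cov(flat)
  eg <- eigen(cv, symmetric = TRUE)
  total <- sum(pmax(eg$values, 0))
  keep <- which(eg$values > zero_tol * eg$values[1L])
  vals <- eg$values[keep]
  vecs <- eg$vectors[, keep, drop = FALSE]
  for (cidx in seq_along(keep)) {               # deterministic sign
    i <- which.max(abs(vecs[, cidx]))
    if (vecs[i, cidx] < 0) vecs[, cidx] <- -vecs[, cidx]
  }
  ctr <- sweep(flat, 2, colMeans(flat))
  scores <- ctr %*% vecs
  W <- deflated$spectrum$warps; m <- ncol(W)
  pref <- deflated$prefactors
  nc <- length(keep)
  load_defl <- array(vecs, c(k, d, nc))
  load_warp <- array(0, c(m, d, nc))
  load_reinf <- array(0, c(k, d, nc))
  for (cidx in seq_len(nc)) {
    for (a in seq_len(d)) {
      wcoef <- drop(crossprod(W, load_defl[, a, cidx]))
      load_warp[, a, cidx] <- wcoef
      load_reinf[, a, cidx] <- W %*% (wcoef / pref)
    }
    nrm <- sqrt(sum(load_reinf[, , cidx]^2))
    if (nrm > 0) load_reinf[, , cidx] <- load_reinf[, , cidx] / nrm
  }
  structure(list(eigenvalues = vals, var_explained = vals / total,
                 scores = scores, loadings_deflated = load_defl,
                 loadings_reinflated = load_reinf,
                 loadings_warp_basis = load_warp,
                 mean = deflated$mean, spectrum = deflated$spectrum,
                 prefactors = pref),
            class = "riw_result")
}

#' @export
print.riw_result <- function(x, ...) {
  cat(sprintf("riw_result: %d components over %d specimens\n",
              length(x$eigenvalues), nrow(x$scores)))
  cat("  var explained:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$var_explained, 5)),
            collapse = ", "),
      if (length(x$var_explained) > 5) "...", "\n")
  invisible(x)
}

#' Deformation grid for a relative intrinsic warp
#'
#' Thin-plate map from the mean to the mean displaced by
#' `amplitude` times the chosen component's loading, in either the
#' deflated or the reinflated rendering.
#'
#' @param result a `"riw_result"`.
#' @param index component index.
#' @param amplitude displacement amplitude in Procrustes units.
#' @param type `"deflated"` or `"reinflated"` loading.
#' @return a `"spline_map"` (see [tps_map()], [evaluate_grid()]).
#' @export
riw_grid <- function(result, index = 1L, amplitude = 0.1,
                     type = c("deflated", "reinflated")) {
  stopifnot(inherits(result, "riw_result"))
  type <- match.arg(type)
  nc <- length(result$eigenvalues)
  if (index < 1L || index > nc)
    stop("component index out of range (1..", nc, ")")
  L <- if (type == "deflated") result$loadings_deflated[, , index]
  else result$loadings_reinflated[, , index]
  tps_map(result$mean, result$mean + amplitude * L)
}

#' Quadratic growth-gradient analysis
#'
#' Principal components of just the quadratic trend in a 2D Procrustes
#' sample: the six regressors x^2, xy, y^2 per output axis, built from
#' the mean's coordinates, orthonormalized against the linear terms
#' (1, x, y) per axis (which also makes them orthogonal to the uniform
#' rows), projected onto each specimen's deviation, followed by a PCA of
#' the six scores. A dominant first component is the signature of a
#' single large-scale growth gradient.
#'
#' @param fit a 2D `"procrustes_fit"` with at least 6 landmarks.
#' @return an object of class `"quadratic_gradient"`: list with `basis`
#'   (6 x 2k orthonormal rows, coordinate order x1,y1,...),
#'   `scores` (n x 6), `pc_eigenvalues`, `pc_loadings`, `pc_scores`,
#'   `var_explained`.
#' @export
quadratic_gradient <- function(fit) {
  stopifnot(inherits(fit, "procrustes_fit"))
  M <- fit$mean
  if (ncol(M) != 2L) stop("quadratic gradient analysis is 2D only")
  k <- nrow(M)
  if (k < 6L) stop("need at least 6 landmarks for a full-rank quadratic basis")
  x <- M[, 1]; y <- M[, 2]
  lin <- cbind(1, x, y)
  quad <- cbind(x^2, x * y, y^2)
  # residualize against the linear terms, then orthonormalize
  resid <- quad - lin %*% solve(crossprod(lin), crossprod(lin, quad))
  U <- qr.Q(qr(resid))                          # k x 3 orthonormal
  # fix signs for reproducibility
  for (j in 1:3) if (U[which.max(abs(U[, j])), j] < 0) U[, j] <- -U[, j]
  basis <- matrix(0, 6L, 2L * k)
  for (j in 1:3) {
    basis[j, seq(1L, 2L * k, by = 2L)] <- U[, j]          # x-axis output
    basis[j + 3L, seq(2L, 2L * k, by = 2L)] <- U[, j]     # y-axis output
  }
  co <- fit$aligned
  n <- dim(co)[3L]
  # n x 2k deviations in coordinate order (x1, y1, x2, y2, ...)
  dev <- t(matrix(aperm(co, c(2, 1, 3)), 2L * k, n))
  dev <- sweep(dev, 2, as.vector(t(M)))
  scores <- dev %*% t(basis)                    # n x 6
  eg <- eigen(stats::cov(scores), symmetric = TRUE)
  pc_scores <- sweep(scores, 2, colMeans(scores)) %*% eg$vectors
  structure(list(basis = basis, scores = scores,
                 pc_eigenvalues = eg$values, pc_loadings = eg$vectors,
                 pc_scores = pc_scores,
                 var_explained = eg$values / sum(eg$values),
                 mean = M),
            class = "quadratic_gradient")
}
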