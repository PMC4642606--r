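#' Principal warps of a bending-energy matrix
#'
#' Eigenvectors of the bending-energy matrix with nonzero eigenvalue,
#' sorted by increasing eigenvalue (increasing specific bending energy,
#' i.e. from largest to smallest geometric scale). There are k - 3 of them
#' in 2D and k - 4 in 3D; the zero eigenvalues correspond to exact planes
#' (the span of 1, x, y[, z]). Eigenvector signs are fixed by requiring
#' the entry of largest magnitude to be positive.
#'
#' @param B a bending-energy matrix from [bending_energy_matrix()].
#' @param mean the configuration `B` was computed from.
#' @param zero_tol relative tolerance: eigenvalues below
#'   `zero_tol * max(abs(eigenvalues))` count as zero.
#' @return an object of class `"bending_spectrum"`: list with `energies`
#'   (ascending nonzero eigenvalues), `warps` (k x m matrix of unit-norm
#'   eigenvectors), `mean`, `dim`, `zero_tol`.
#' @export
principal_warps <- function(B, mean, zero_tol = 1e-9) {
  M <- as_configuration(mean)
  stopifnot(nrow(B) == nrow(M))
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  keep <- eg$values > zero_tol * max(abs(eg$values))
  if (!any(keep))
    stop("no nonzero bending eigenvalues: configuration has no nonaffine space")
  E <- rev(eg$values[keep])                     # ascending
  W <- eg$vectors[, rev(which(keep)), drop = FALSE]
  for (l in seq_len(ncol(W))) {
    i <- which.max(abs(W[, l]))
    if (W[i, l] < 0) W[, l] <- -W[, l]
  }
  structure(list(energies = E, warps = W, mean = M, dim = ncol(M),
                 zero_tol = zero_tol),
            class = "bending_spectrum")
}

#' Bending spectrum of a mean configuration
#'
#' Convenience wrapper: [bending_energy_matrix()] followed by
#' [principal_warps()].
#'
#' @inheritParams principal_warps
#' @param mean a nondegenerate k x d configuration.
#' @return a `"bending_spectrum"`.
#' @export
bending_spectrum <- function(mean, zero_tol = 1e-9) {
  principal_warps(bending_energy_matrix(mean), mean, zero_tol = zero_tol)
}

#' @export
print.bending_spectrum <- function(x, ...) {
  cat(sprintf("bending_spectrum: %d principal warps (%dD, %d landmarks)\n",
              length(x$energies), x$dim, nrow(x$mean)))
  cat("  specific bending energies:",
      paste(signif(x$energies, 4), collapse = ", "), "\n")
  invisible(x)
}

check_same_mean <- function(a, b) {
  if (max(abs(a - b)) > 1e-8)
    stop("fit and spectrum were computed from different mean configurations")
}

#' Partial warp scores of a Procrustes fit
#'
#' The projection of each specimen's deviation from the mean onto each
#' principal warp, one component per Cartesian axis:
#' score(j, l, a) = W_l . (aligned_j - mean)[, a]. Because the warps are
#' orthogonal to the uniform basis, the scores are the same whether or not
#' the uniform term has been projected out.
#'
#' @param fit a `"procrustes_fit"` from [gpa()].
#' @param spectrum a `"bending_spectrum"` computed from the same mean.
#' @return an object of class `"pw_scores"`: list with `scores`
#'   (n x m x d array), `variances` (length-m vector, variance of each
#'   warp's score summed over its d components), `energies`.
#' @export
partial_warp_scores <- function(fit, spectrum) {
  stopifnot(inherits(fit, "procrustes_fit"),
            inherits(spectrum, "bending_spectrum"))
  check_same_mean(fit$mean, spectrum$mean)
  W <- spectrum$warps
  co <- fit$aligned
  k <- dim(co)[1L]; d <- dim(co)[2L]; n <- dim(co)[3L]
  m <- ncol(W)
  scores <- array(0, c(n, m, d))
  for (a in seq_len(d)) {
    dev <- matrix(co[, a, ], k, n) - fit$mean[, a]
    scores[, , a] <- t(crossprod(W, dev))       # n x m
  }
  variances <- vapply(seq_len(m), function(l)
    sum(apply(scores[, l, , drop = FALSE], 3, stats::var)), numeric(1L))
  structure(list(scores = scores, variances = variances,
                 energies = spectrum$energies),
            class = "pw_scores")
}

#' Bending-energy deflation of a Procrustes shape distribution
#'
#' Replaces each specimen's nonaffine deviation from the mean by its
#' partial-warp expansion with warp l rescaled by (E_1/E_l)^exponent:
#' by default the inverse square root of relative specific bending energy
#' in 2D (exponent 1/2) and the inverse ratio itself in 3D (exponent 1),
#' which turns the isotropic Procrustes model into a spatially
#' self-similar one. The largest-scale warp (l = 1) is left unchanged;
#' the uniform component and any residual outside the warp span are
#' dropped. Non-default exponents generate synthetic integrated
#' (exponent > default) or disintegrated samples.
#'
#' @param fit a `"procrustes_fit"` from [gpa()].
#' @param spectrum a `"bending_spectrum"` from the same mean; computed
#'   from `fit$mean` if omitted.
#' @param exponent the deflation exponent p in the prefactor
#'   (E_1/E_l)^p; default 1/2 in 2D, 1 in 3D.
#' @param mean optional override of the deflation center for
#'   fixed-template workflows; default is the fit's Procrustes mean.
#' @return an object of class `"deflated_sample"`: list with `coords`
#'   (k x d x n deflated shape coordinates), `prefactors`
#'   (length-m, equal to 1 at index 1 and decreasing), `spectrum`,
#'   `scores` (the undeflated n x m x d partial warp scores),
#'   `scores_deflated`, `mean`, `exponent`.
#' @export
deflate <- function(fit, spectrum = NULL, exponent = NULL, mean = NULL) {
  stopifnot(inherits(fit, "procrustes_fit"))
  if (is.null(spectrum)) spectrum <- bending_spectrum(fit$mean)
  stopifnot(inherits(spectrum, "bending_spectrum"))
  center <- if (is.null(mean)) fit$mean else as_configuration(mean)
  check_same_mean(spectrum$mean, center)
  d <- spectrum$dim
  if (is.null(exponent)) exponent <- if (d == 2L) 0.5 else 1
  E <- spectrum$energies
  pref <- (E[1L] / E)^exponent
  W <- spectrum$warps
  co <- fit$aligned
  k <- dim(co)[1L]; n <- dim(co)[3L]; m <- ncol(W)
  scores <- array(0, c(n, m, d))
  out <- co
  for (a in seq_len(d)) {
    dev <- matrix(co[, a, ], k, n) - center[, a]
    S <- crossprod(W, dev)                      # m x n
    scores[, , a] <- t(S)
    out[, a, ] <- center[, a] + W %*% (pref * S)
  }
  scores_deflated <- scores
  for (a in seq_len(d)) scores_deflated[, , a] <-
      sweep(scores[, , a, drop = FALSE][, , 1L], 2, pref, `*`)
  structure(list(coords = out, prefactors = pref, spectrum = spectrum,
                 scores = scores, scores_deflated = scores_deflated,
                 mean = center, exponent = exponent,
                 ids = fit$ids, labels = fit$labels),
            class = "deflated_sample")
}

#' @export
print.deflated_sample <- function(x, ...) {
  dm <- dim(x$coords)
  cat(sprintf("deflated_sample: %d specimens, %d landmarks in %dD (exponent %g)\n",
              dm[3L], dm[1L], dm[2L], x$exponent))
  invisible(x)
}

#' Per-warp variances of a deflated sample
#'
#' @param deflated a `"deflated_sample"`.
#' @param deflated_scores if `TRUE` (default) use the deflated scores,
#'   otherwise the undeflated partial warp scores.
#' @return a length-m vector of per-warp variances (summed over axes).
#' @export
warp_variances <- function(deflated, deflated_scores = TRUE) {
  stopifnot(inherits(deflated, "deflated_sample"))
  S <- if (deflated_scores) deflated$scores_deflated else deflated$scores
  m <- dim(S)[2L]
  vapply(seq_len(m), function(l)
    sum(apply(S[, l, , drop = FALSE], 3, stats::var)), numeric(1L))
}

#' Undo a deflation
#'
#' Multiplies each warp component by the inverse prefactor, recovering
#' the nonaffine part of the original sample (the projection of the
#' Procrustes fit onto the span of the principal warps).
#'
#' @param deflated a `"deflated_sample"` from [deflate()].
#' @return a [shape_sample()].
#' @export
reinflate <- function(deflated) {
  stopifnot(inherits(deflated, "deflated_sample"))
  W <- deflated$spectrum$warps
  center <- deflated$mean
  d <- deflated$spectrum$dim
  n <- dim(deflated$coords)[3L]
  out <- deflated$coords
  for (a in seq_len(d)) {
    S <- t(deflated$scores[, , a])              # m x n (undeflated)
    out[, a, ] <- center[, a] + W %*% S
  }
  shape_sample(out, labels = deflated$labels, ids = deflated$ids,
               metadata = list(projection = "nonaffine (reinflated)"))
}
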