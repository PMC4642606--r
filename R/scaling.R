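#' Log-log regression of partial warp variance on bending energy
#'
#' Ordinary (unweighted) least squares of log variance on log specific
#' bending energy over a chosen subset of warps. The fitted slope is the
#' scaling dimension of the shape distribution: -1 under spatial
#' self-similarity, below -1 for integrated variation, above -1 (towards
#' 0, the isotropic Procrustes expectation) for disintegrated variation.
#' A positive slope is permitted (anti-correlated, "caricature"
#' variation).
#'
#' @param variances length-m positive per-warp variances (summed over
#'   Cartesian components; see [partial_warp_scores()]).
#' @param energies length-m positive specific bending energies, ascending.
#' @param subset 1-based warp indices to use (default all). Warp
#'   subsetting is a scientific judgment, never automatic; studentized
#'   residuals above 3 in magnitude are flagged in the result but not
#'   acted on.
#' @return an object of class `"scaling_fit"`: list with `slope`,
#'   `intercept`, `nugget` (NA here; see [scaling_regression_nugget()]),
#'   `subset`, `sse` (residual sum of squares on the log scale),
#'   `n_warps`, `variances`, `energies`, `outliers` (flagged warp
#'   indices).
#' @export
scaling_regression <- function(variances, energies, subset = NULL) {
  stopifnot(length(variances) == length(energies))
  m <- length(variances)
  if (is.null(subset)) subset <- seq_len(m)
  subset <- sort(unique(as.integer(subset)))
  if (length(subset) < 2L) stop("need at least 2 warps for a regression")
  if (any(subset < 1L | subset > m)) stop("subset indices out of range")
  v <- variances[subset]; e <- energies[subset]
  if (any(v <= 0)) stop("nonpositive variance in regression subset")
  if (any(e <= 0)) stop("nonpositive energy in regression subset")
  fit <- stats::lm(log(v) ~ log(e))
  cf <- stats::coef(fit)
  outl <- integer(0)
  if (length(subset) > 3L) {
    rs <- stats::rstudent(fit)
    outl <- subset[which(abs(rs) > 3)]
  }
  structure(list(slope = unname(cf[2L]), intercept = unname(cf[1L]),
                 nugget = NA_real_, subset = subset,
                 sse = sum(stats::resid(fit)^2), n_warps = m,
                 variances = variances, energies = energies,
                 outliers = outl, bootstrap_ci = NULL, regime = NULL),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("scaling_fit: slope = %.4f, intercept = %.4f over %d of %d warps\n",
              x$slope, x$intercept, length(x$subset), x$n_warps))
  if (!is.na(x$nugget))
    cat(sprintf("  nugget variance = %.6g\n", x$nugget))
  if (!is.null(x$regime))
    cat(sprintf("  regime: %s (95%% slope CI %.3f .. %.3f)\n", x$regime,
                x$bootstrap_ci[1L], x$bootstrap_ci[2L]))
  invisible(x)
}

# SSE of the log-log OLS after subtracting a candidate nugget
nugget_sse <- function(nu, v, e) {
  y <- log(v - nu)
  x <- log(e)
  r <- stats::resid(stats::lm(y ~ x))
  sum(r^2)
}

#' Scaling regression with a nugget term
#'
#' Adds an additive, scale-free variance term nu for irreducible
#' landmark-specific digitizing noise: the fit minimizes the residual sum
#' of squares of the OLS regression of log(variance - nu) on log(energy)
#' over nu in [0, just under the smallest variance in the subset]. The
#' search is a 64-point grid followed by golden-section refinement.
#'
#' @inheritParams scaling_regression
#' @return a `"scaling_fit"` with `nugget` set; `boundary` is `TRUE` when
#'   the optimum sits at the upper search boundary.
#' @export
scaling_regression_nugget <- function(variances, energies, subset = NULL) {
  m <- length(variances)
  if (is.null(subset)) subset <- seq_len(m)
  subset <- sort(unique(as.integer(subset)))
  if (length(subset) < 3L)
    stop("nugget fitting needs at least 3 warps in the subset")
  v <- variances[subset]; e <- energies[subset]
  if (any(v <= 0)) stop("nonpositive variance in regression subset")
  hi <- 0.999 * min(v)
  grid <- seq(0, hi, length.out = 64L)
  sse <- vapply(grid, nugget_sse, numeric(1L), v = v, e = e)
  i0 <- which.min(sse)
  lo_b <- grid[max(i0 - 1L, 1L)]; hi_b <- grid[min(i0 + 1L, 64L)]
  opt <- stats::optimize(nugget_sse, c(lo_b, hi_b), v = v, e = e,
                         tol = 1e-12 * max(hi, 1e-300))
  nu <- opt$minimum
  if (nugget_sse(0, v, e) <= opt$objective) nu <- 0   # degenerate nugget
  out <- scaling_regression(variances - nu, energies, subset)
  out$variances <- variances
  out$nugget <- nu
  out$sse <- nugget_sse(nu, v, e)
  out$boundary <- nu >= (1 - 1e-6) * hi
  if (out$boundary)
    warning("nugget optimum at the search boundary (", signif(nu, 6), ")")
  out
}

#' Classify the scaling regime by a specimen bootstrap
#'
#' Resamples specimens with replacement, recomputes per-warp variances
#' and the scaling fit (with nugget if the supplied fit used one), and
#' forms a percentile confidence interval for the slope. The sample is
#' labelled `self-similar` if the interval contains -1, `integrated` if
#' it lies entirely below -1, and `disintegrated` if entirely above.
#'
#' @param fit a fitted `"scaling_fit"`.
#' @param scores a `"pw_scores"` object (specimen-level scores for the
#'   resampling), or an n x m x d score array. For deflated samples pass
#'   the deflated scores.
#' @param reps bootstrap replicates.
#' @param conf confidence level.
#' @param seed integer seed for the resampling.
#' @return the `"scaling_fit"` with `regime` and `bootstrap_ci` filled
#'   in; fewer than 10 specimens gives regime `"indeterminate"` with no
#'   interval.
#' @export
classify_regime <- function(fit, scores, reps = 1000L, conf = 0.95,
                            seed = NULL) {
  stopifnot(inherits(fit, "scaling_fit"))
  S <- if (inherits(scores, "pw_scores")) scores$scores else scores
  stopifnot(length(dim(S)) == 3L)
  n <- dim(S)[1L]; m <- dim(S)[2L]; d <- dim(S)[3L]
  stopifnot(m == fit$n_warps)
  if (n < 10L) {
    fit$regime <- "indeterminate"
    return(fit)
  }
  if (!is.null(seed)) set.seed(seed)
  use_nugget <- !is.na(fit$nugget)
  slopes <- rep(NA_real_, reps)
  for (b in seq_len(reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    v <- vapply(seq_len(m), function(l)
      sum(apply(S[idx, l, , drop = FALSE], 3, stats::var)), numeric(1L))
    sl <- tryCatch({
      f <- if (use_nugget)
        suppressWarnings(scaling_regression_nugget(v, fit$energies, fit$subset))
      else scaling_regression(v, fit$energies, fit$subset)
      f$slope
    }, error = function(e) NA_real_)
    slopes[b] <- sl
  }
  slopes <- slopes[is.finite(slopes)]
  a <- (1 - conf) / 2
  ci <- unname(stats::quantile(slopes, c(a, 1 - a)))
  fit$bootstrap_ci <- ci
  fit$regime <- if (ci[1L] <= -1 && ci[2L] >= -1) "self-similar"
  else if (ci[2L] < -1) "integrated"
  else "disintegrated"
  fit
}

#' Fictive abscissa for the uniform term ("partial warp 0")
#'
#' The uniform (affine) term has zero bending energy, so it has no
#' natural abscissa on the log-energy axis. This heuristic places it at
#' the fictive energy where the fitted regression line reaches the
#' uniform term's log variance: displaced from warp 1's log energy by
#' log(uniform_variance / variance_1) / slope (to the left for steeper-
#' than--1 fits when the uniform variance exceeds warp 1's). The exact
#' abscissa is indeterminate; treat the output as a plotting heuristic.
#'
#' @param fit a fitted `"scaling_fit"` with nonzero slope.
#' @param uniform_variance the Procrustes variance captured on the
#'   uniform basis.
#' @return a list with `abscissa` (fictive log energy), `ordinate`
#'   (log uniform variance), `displacement` (signed shift from warp 1's
#'   log energy), and `heuristic = TRUE`.
#' @export
uniform_point <- function(fit, uniform_variance) {
  stopifnot(inherits(fit, "scaling_fit"), uniform_variance > 0)
  if (fit$slope == 0)
    stop("the uniform-point abscissa is undefined for zero slope")
  v1 <- fit$variances[1L]
  e1 <- fit$energies[1L]
  displacement <- log(uniform_variance / v1) / fit$slope
  list(abscissa = log(e1) + displacement,
       ordinate = log(uniform_variance),
       displacement = displacement, heuristic = TRUE)
}
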