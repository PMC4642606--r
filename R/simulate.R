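#' Canonical toy mean configurations
#'
#' Named reference configurations used throughout the package's examples
#' and tests:
#' \describe{
#'   \item{`quincunx`}{the five-spot of a die: four corners at unit
#'     offsets (+-1, +-1), numbered consecutively around the outline,
#'     plus the center as landmark 5. Its bending-energy matrix has
#'     exactly two nonzero eigenvalues in ratio 3:5.}
#'   \item{`grid5`}{a 5 x 5 square grid of 25 landmarks at integer
#'     positions 0..4 x 0..4 (row-major). 22 principal warps; its lattice
#'     contains exactly 50 squares.}
#'   \item{`prologue6`}{six landmarks from a square grid: the unit square
#'     as landmarks 1-4, numbered so that 2 and 3 are diagonally
#'     opposite, plus landmarks 5, 6 completing the sqrt(2)-scale square
#'     erected outward on the diagonal 2-3. The layout is a
#'     reconstruction: no canonical coordinates exist, and the inferred
#'     layout is checked by its bending eigenvalue ratios
#'     (about 1 : 1.07 : 2.15).}
#'   \item{`giza`}{two square-pyramid pentahedra sharing their apex
#'     (3D): base edges 4 and 1, apex height half the base edge, both
#'     bases square to the common axis — nine landmarks, scale ratio 4.}
#' }
#'
#' @param name one of `"prologue6"`, `"quincunx"`, `"grid5"`, `"giza"`.
#' @return a k x d coordinate matrix.
#' @export
toy_configuration <- function(name = c("prologue6", "quincunx", "grid5",
                                       "giza")) {
  name <- match.arg(name)
  switch(name,
    quincunx = rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1), c(0, 0)),
    grid5 = unname(as.matrix(expand.grid(x = 0:4, y = 0:4))),
    prologue6 = rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1),
                      c(0, -1), c(-1, 0)),
    giza = {
      base <- function(edge, z)
        cbind(edge / 2 * rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1)), z)
      # apex at height 2 = half the large base edge; small base edge 1 at
      # height 1.5 so that its own apex height is 0.5 = half its edge
      rbind(base(4, 0), base(1, 1.5), c(0, 0, 2))
    })
}

#' Landmark subsets of the toy configurations
#'
#' Index sets for the sub-configurations discussed alongside the toys:
#' the two squares of `prologue6` (the unit square 1-4 and the
#' sqrt(2)-scale square 2,3,5,6) and the two pentahedra of `giza`
#' (large base + apex, small base + apex).
#'
#' @param name `"prologue6"` or `"giza"`.
#' @return a named list of index vectors.
#' @export
toy_subsets <- function(name = c("prologue6", "giza")) {
  name <- match.arg(name)
  switch(name,
    prologue6 = list(small = c(1L, 2L, 3L, 4L), large = c(2L, 3L, 5L, 6L)),
    giza = list(large = c(1L, 2L, 3L, 4L, 9L), small = c(5L, 6L, 7L, 8L, 9L)))
}

#' Isotropic offset Gaussian (Mardia-Dryden) sample
#'
#' Draws n specimens by perturbing every coordinate of the mean with
#' independent Gaussian noise of standard deviation `sigma` (in the units
#' of the mean's coordinates): the textbook isotropic shape distribution,
#' whose partial warp variances after Procrustes fitting are equal across
#' warps (log-log slope about 0).
#'
#' @param mean a k x d mean configuration.
#' @param sigma per-coordinate standard deviation, same units as `mean`.
#' @param n number of specimens (>= 2).
#' @param seed integer seed; identical arguments give identical samples.
#' @return a [shape_sample()].
#' @export
isotropic_sample <- function(mean, sigma, n, seed = NULL) {
  M <- as_configuration(mean)
  stopifnot(sigma > 0, n >= 2)
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(M); d <- ncol(M)
  noise <- array(stats::rnorm(k * d * n, sd = sigma), c(k, d, n))
  co <- array(rep(M, n), c(k, d, n)) + noise
  shape_sample(co, metadata = list(model = "isotropic", sigma = sigma,
                                   seed = seed))
}

#' Bending-deflated self-similar sample
#'
#' The self-similar null: an isotropic sample around the mean, Procrustes
#' superimposed, then bending-deflated. The per-warp variances of the
#' result fall off as the inverse of specific bending energy (log-log
#' slope -1), and the nonaffine variation of any sub-configuration is
#' independent of its geometric scale.
#'
#' @inheritParams isotropic_sample
#' @param exponent deflation exponent passed to [deflate()]; the default
#'   (1/2 in 2D, 1 in 3D) produces the self-similar null, larger values
#'   synthetic integrated samples.
#' @param tol,max_iter passed to [gpa()].
#' @return a `"deflated_sample"`, with the underlying `"procrustes_fit"`
#'   attached as `$fit`.
#' @export
self_similar_sample <- function(mean, sigma, n, seed = NULL,
                                exponent = NULL, tol = 1e-10,
                                max_iter = 200L) {
  sample <- isotropic_sample(mean, sigma, n, seed)
  fit <- gpa(sample, tol = tol, max_iter = max_iter)
  out <- deflate(fit, exponent = exponent)
  out$fit <- fit
  out
}

# template for the hierarchical parcellation process: unit square,
# landmark counts 4, 5, 9, 13 at levels 0..3
parcellation_template <- function(levels = 3L) {
  stopifnot(levels >= 0L, levels <= 3L)
  pts <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  lv <- rep(0L, 4L)
  if (levels >= 1L) { pts <- rbind(pts, c(0.5, 0.5)); lv <- c(lv, 1L) }
  if (levels >= 2L) {
    pts <- rbind(pts, c(0.5, 0), c(1, 0.5), c(0.5, 1), c(0, 0.5))
    lv <- c(lv, rep(2L, 4L))
  }
  if (levels >= 3L) {
    pts <- rbind(pts, c(0.25, 0.25), c(0.75, 0.25), c(0.75, 0.75),
                 c(0.25, 0.75))
    lv <- c(lv, rep(3L, 4L))
  }
  list(points = pts, level = lv)
}

#' Hierarchical parcellation sample
#'
#' A generative caricature of (near) self-similar variation: a 13-landmark
#' square template is parcellated into successively smaller compartments,
#' each contributing one new landmark perturbed with circular symmetry
#' around the location *imputed* to it by the thin-plate deformation of
#' all previously placed landmarks, with variance shrinking by `decay`
#' per level. Level 0 is the four outer corners (variance `base_sd^2`);
#' level 1 the center (variance `decay * base_sd^2`); level 2 the four
#' edge midpoints (`decay^2 ...`); level 3 the four quarter-cell centers
#' (`decay^3 ...`). Unlike the isotropic model, neighbouring landmarks'
#' displacements are positively correlated.
#'
#' @param levels template depth, 0 to 3 (landmark counts 4, 5, 9, 13).
#' @param base_sd standard deviation of the corner perturbations, in
#'   units of the unit-square template edge.
#' @param decay per-level variance ratio in (0, 1]; the default 1/2
#'   halves the variance at each level.
#' @param n number of specimens.
#' @param seed integer seed.
#' @return a [shape_sample()] with the template stored in `metadata`.
#' @export
parcellation_sample <- function(levels = 3L, base_sd = 0.05, decay = 0.5,
                                n = 100L, seed = NULL) {
  stopifnot(base_sd >= 0, decay > 0, decay <= 1, n >= 2)
  tmpl <- parcellation_template(levels)
  P <- tmpl$points; lv <- tmpl$level
  k <- nrow(P)
  if (!is.null(seed)) set.seed(seed)
  co <- array(0, c(k, 2L, n))
  for (s in seq_len(n)) {
    X <- matrix(NA_real_, k, 2L)
    placed <- which(lv == 0L)
    X[placed, ] <- P[placed, ] +
      matrix(stats::rnorm(2L * length(placed), sd = base_sd),
             length(placed), 2L)
    if (max(lv) >= 1L) for (L in 1L:max(lv)) {
      new_i <- which(lv == L)
      map <- tps_map(P[placed, , drop = FALSE], X[placed, , drop = FALSE])
      imputed <- evaluate_map(map, P[new_i, , drop = FALSE])
      sd_L <- base_sd * sqrt(decay^L)
      X[new_i, ] <- imputed +
        matrix(stats::rnorm(2L * length(new_i), sd = sd_L),
               length(new_i), 2L)
      placed <- c(placed, new_i)
    }
    co[, , s] <- X
  }
  shape_sample(co, metadata = list(model = "parcellation",
                                   template = P, level = lv,
                                   base_sd = base_sd, decay = decay,
                                   seed = seed))
}

# exact 90-degree rotation of an integer lattice vector
rot90_int <- function(v) c(-v[2L], v[1L])

#' Enumerate the squares of an integer lattice configuration
#'
#' Every 4-subset of the landmarks forming a square of any size,
#' position, or orientation (including "knight's-move" tilted squares),
#' detected by exact integer arithmetic on the lattice vectors. Each
#' square is listed once, vertices in cyclic order starting from the
#' smallest index.
#'
#' @param grid a k x 2 configuration with integer coordinates.
#' @return a list of integer 4-vectors of landmark indices. The 5 x 5
#'   grid yields exactly 50 squares.
#' @export
enumerate_grid_squares <- function(grid) {
  P <- as_configuration(grid)
  if (ncol(P) != 2L) stop("square enumeration is for 2D lattices")
  if (max(abs(P - round(P))) > 0)
    stop("non-lattice input: coordinates must be exact integers")
  P <- round(P)
  key <- paste(P[, 1L], P[, 2L])
  lookup <- stats::setNames(seq_len(nrow(P)), key)
  seen <- new.env(hash = TRUE)
  out <- list()
  k <- nrow(P)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    v <- P[j, ] - P[i, ]
    w <- rot90_int(v)
    r <- P[j, ] + w; s <- P[i, ] + w
    ri <- lookup[paste(r[1L], r[2L])]
    si <- lookup[paste(s[1L], s[2L])]
    if (is.na(ri) || is.na(si)) next
    idx <- c(i, j, ri, si)                      # cyclic order i -> j -> r -> s
    id <- paste(sort(idx), collapse = ",")
    if (!is.null(seen[[id]])) next
    seen[[id]] <- TRUE
    # rotate the cycle to start at the smallest index, preserving order
    start <- which.min(idx)
    out[[length(out) + 1L]] <-
      unname(idx[((seq_len(4L) + start - 2L) %% 4L) + 1L])
  }
  out
}

#' Nonaffine shape variance of a landmark subset
#'
#' Extracts the chosen landmarks from every specimen, runs a *fresh* full
#' Procrustes superposition of the subset sample (re-centering,
#' re-scaling, re-rotating), projects out its affine subspace, and
#' returns the trace of the coordinate variances divided by (d x subset
#' size): a per-coordinate nonaffine variance in the Procrustes units of
#' the subset. Under the isotropic model this scales as the inverse
#' squared size of the subset; after bending deflation it is independent
#' of the subset's scale.
#'
#' @param x a [shape_sample()], `"procrustes_fit"`, `"deflated_sample"`,
#'   or k x d x n array.
#' @param indices landmark subset, at least d + 2 of them.
#' @param tol,max_iter passed to [gpa()].
#' @return a nonnegative scalar.
#' @export
subconfig_nonaffine_variance <- function(x, indices, tol = 1e-10,
                                         max_iter = 200L) {
  co <- if (inherits(x, "shape_sample")) x$coords
  else if (inherits(x, "procrustes_fit")) x$aligned
  else if (inherits(x, "deflated_sample")) x$coords
  else x
  stopifnot(is.array(co), length(dim(co)) == 3L)
  d <- dim(co)[2L]
  indices <- as.integer(indices)
  if (length(indices) < d + 2L)
    stop("subset needs at least d + 2 landmarks")
  sub <- shape_sample(co[indices, , , drop = FALSE])
  fit <- gpa(sub, tol = tol, max_iter = max_iter)
  nonaff <- project_nonaffine(fit)
  total_coordinate_variance(nonaff$coords) / (d * length(indices))
}
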