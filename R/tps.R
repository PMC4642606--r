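#' Thin-plate spline kernel
#'
#' U(r) = r^2 log r in 2D (with U(0) = 0, the continuous extension) and
#' U(r) = |r| in 3D.
#'
#' @param r nonnegative distances.
#' @param dim 2 or 3.
#' @return kernel values, same shape as `r`.
#' @keywords internal
tps_kernel <- function(r, dim) {
  if (dim == 2L) ifelse(r > 0, r^2 * log(r), 0) else r
}

# the bordered spline matrix L = [K Q; Q^t O] for a source configuration
spline_L <- function(source) {
  P <- as_configuration(source)
  k <- nrow(P); d <- ncol(P)
  K <- tps_kernel(as.matrix(stats::dist(P)), d)
  Q <- cbind(1, P)
  unname(rbind(cbind(K, Q), cbind(t(Q), matrix(0, d + 1L, d + 1L))))
}

#' Build and solve a thin-plate spline system
#'
#' Assembles the bordered matrix L = (K Q; Q' O) for the source landmarks,
#' with kernel entries U_ij, and solves L V = H for the height vector
#' H = (h_1 ... h_k, 0, ..., 0). The solution V = (v_1 ... v_k, a_0, a_x,
#' a_y[, a_z]) defines the interpolating spline of [tps_map()].
#'
#' @param source a nondegenerate k x d configuration.
#' @param heights a length-k vector of heights (values) at the landmarks.
#' @return an object of class `"spline_system"`: list with `K`, `Q`, `L`,
#'   `H`, `V`, `source`, `dim`.
#' @export
build_spline_system <- function(source, heights) {
  P <- as_configuration(source)
  k <- nrow(P); d <- ncol(P)
  stopifnot(length(heights) == k)
  L <- spline_L(P)
  lu <- tryCatch(solve(L), error = function(e)
    stop("degenerate source configuration: spline system is singular (",
         conditionMessage(e), ")"))
  H <- unname(c(heights, rep(0, d + 1L)))
  V <- unname(drop(lu %*% H))
  structure(list(K = L[1:k, 1:k], Q = L[1:k, (k + 1L):(k + d + 1L)],
                 L = L, Linv = lu, H = H, V = V, source = P, dim = d),
            class = "spline_system")
}

#' Bending energy of a solved spline system
#'
#' The minimized integral of summed squared second derivatives of the
#' interpolant, computed in closed form. The three equivalent expressions
#' (1/8\eqn{\pi}) V'KV = (1/8\eqn{\pi}) V'H = (1/8\eqn{\pi}) H_k' B H_k
#' agree to high relative accuracy; the first is returned. In 3D the value
#' is sign-normalized to be nonnegative (see [bending_energy_matrix()]).
#'
#' @param system a `"spline_system"` from [build_spline_system()].
#' @return a nonnegative scalar.
#' @export
bending_energy <- function(system) {
  stopifnot(inherits(system, "spline_system"))
  k <- nrow(system$source)
  v <- system$V[1:k]
  be <- sum(v * (system$K %*% v)) / (8 * pi)
  if (system$dim == 3L) be <- -be
  max(be, 0)
}

#' Thin-plate spline map between two configurations
#'
#' One spline per Cartesian coordinate of the target: the heights of the
#' d systems are the target's x-, y- (and z-) coordinates. Evaluating the
#' map at the source landmarks reproduces the target landmarks exactly;
#' affine source-target pairs have zero bending energy.
#'
#' @param source,target k x d configurations with the same k and d.
#' @return an object of class `"spline_map"`: list with `source`,
#'   `target`, `systems` (one solved [build_spline_system()] per axis,
#'   sharing a single factorization of L), and `bending` (total bending
#'   energy, the sum over axes).
#' @export
tps_map <- function(source, target) {
  P <- as_configuration(source); Tg <- as_configuration(target)
  if (!all(dim(P) == dim(Tg)))
    stop("source and target must have the same landmark count and dimension")
  k <- nrow(P); d <- ncol(P)
  L <- spline_L(P)
  Linv <- tryCatch(solve(L), error = function(e)
    stop("degenerate source configuration: spline system is singular"))
  systems <- vector("list", d)
  for (a in seq_len(d)) {
    H <- unname(c(Tg[, a], rep(0, d + 1L)))
    V <- unname(drop(Linv %*% H))
    systems[[a]] <- structure(
      list(K = L[1:k, 1:k], Q = L[1:k, (k + 1L):(k + d + 1L)],
           L = L, Linv = Linv, H = H, V = V, source = P, dim = d),
      class = "spline_system")
  }
  structure(list(source = P, target = Tg, systems = systems,
                 bending = sum(vapply(systems, bending_energy, numeric(1L))),
                 dim = d),
            class = "spline_map")
}

#' Evaluate a thin-plate spline map at arbitrary points
#'
#' @param map a `"spline_map"` from [tps_map()].
#' @param points an m x d matrix of points in the source frame.
#' @return an m x d matrix of mapped points.
#' @export
evaluate_map <- function(map, points) {
  stopifnot(inherits(map, "spline_map"))
  pts <- as.matrix(points)
  if (ncol(pts) != map$dim) stop("points must be m x ", map$dim)
  P <- map$source; k <- nrow(P); d <- map$dim
  # kernel distances from each evaluation point to each source landmark
  D <- sqrt(outer(rowSums(pts^2), rep(1, k)) +
              outer(rep(1, nrow(pts)), rowSums(P^2)) -
              2 * pts %*% t(P))
  D[D < 0 | is.nan(D)] <- 0
  Uk <- tps_kernel(D, d)
  out <- matrix(0, nrow(pts), d)
  for (a in seq_len(d)) {
    V <- map$systems[[a]]$V
    out[, a] <- Uk %*% V[1:k] + V[k + 1L] + pts %*% V[(k + 2L):(k + d + 1L)]
  }
  out
}

#' Deformed grid through a spline map
#'
#' Maps a regular rectangular grid of source points through the spline,
#' for deformation-grid displays.
#'
#' @param map a 2D `"spline_map"`.
#' @param bounds optional list with `xlim`, `ylim`; default is the source
#'   bounding box expanded by `expand` on each side.
#' @param resolution number of grid lines per axis.
#' @param expand fractional margin around the source bounding box.
#' @return a list with `source_grid` and `mapped_grid` (each m x 2, in
#'   row-major order), and `resolution`.
#' @export
evaluate_grid <- function(map, bounds = NULL, resolution = 21L,
                          expand = 0.1) {
  stopifnot(inherits(map, "spline_map"))
  if (map$dim != 2L) stop("grid evaluation is for 2D maps")
  if (is.null(bounds)) {
    rx <- range(map$source[, 1]); ry <- range(map$source[, 2])
    mx <- expand * diff(rx); my <- expand * diff(ry)
    bounds <- list(xlim = rx + c(-mx, mx), ylim = ry + c(-my, my))
  }
  gx <- seq(bounds$xlim[1], bounds$xlim[2], length.out = resolution)
  gy <- seq(bounds$ylim[1], bounds$ylim[2], length.out = resolution)
  grid <- unname(as.matrix(expand.grid(gx, gy)))
  list(source_grid = grid, mapped_grid = evaluate_map(map, grid),
       resolution = resolution)
}

#' Bending-energy matrix of a mean configuration
#'
#' The k x k upper-left block of the inverse of the bordered spline matrix
#' L. In 2D it is positive semidefinite of rank k - 3 (its kernel is
#' spanned by 1, x, y: exact planes bend nothing); in 3D the block itself
#' is negative semidefinite of rank k - 4, and the returned matrix is
#' sign-normalized to positive semidefinite so that 2D and 3D share one
#' downstream code path.
#'
#' @param mean a nondegenerate k x d configuration.
#' @return a symmetric positive semidefinite k x k matrix.
#' @export
bending_energy_matrix <- function(mean) {
  P <- as_configuration(mean)
  k <- nrow(P); d <- ncol(P)
  if (k < d + 2L)
    stop("need at least d + 2 landmarks for a nontrivial bending-energy matrix")
  Linv <- tryCatch(solve(spline_L(P)), error = function(e)
    stop("degenerate configuration: spline system is singular"))
  B <- unname(Linv[1:k, 1:k])
  B <- (B + t(B)) / 2
  if (d == 3L) B <- -B
  B
}
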