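#' Landmark configurations and shape samples
#'
#' A *configuration* is one specimen's set of k homologous landmarks in
#' d = 2 or 3 Cartesian dimensions, stored as a plain k x d numeric matrix
#' (optionally with landmark names as rownames). A *shape sample* collects
#' n configurations that share k, d and landmark order.
#'
#' @param coords a k x d x n numeric array of landmark coordinates, or a
#'   list of k x d matrices with identical dimensions.
#' @param labels optional character vector of k landmark names.
#' @param ids optional character vector of n specimen identifiers.
#' @param metadata optional named list of free-form metadata.
#' @return an object of class `"shape_sample"`: a list with elements
#'   `coords` (k x d x n array), `labels`, `ids` and `metadata`.
#' @seealso [read_landmarks()], [validate_sample()]
#' @export
shape_sample <- function(coords, labels = NULL, ids = NULL, metadata = list()) {
  if (is.list(coords) && !is.array(coords)) {
    dims <- unique(lapply(coords, dim))
    if (length(dims) != 1L)
      stop("homology error: configurations differ in landmark count or dimension")
    coords <- array(unlist(coords), dim = c(dims[[1L]], length(coords)))
  }
  if (!is.array(coords) || length(dim(coords)) != 3L)
    stop("'coords' must be a k x d x n array or a list of k x d matrices")
  storage.mode(coords) <- "double"
  k <- dim(coords)[1L]; d <- dim(coords)[2L]; n <- dim(coords)[3L]
  if (!d %in% c(2L, 3L)) stop("landmark dimension must be 2 or 3, got ", d)
  if (n < 1L) stop("a shape sample needs at least one specimen")
  if (!is.null(labels)) {
    stopifnot(length(labels) == k)
    dimnames(coords)[[1L]] <- labels
  }
  if (!is.null(ids)) {
    stopifnot(length(ids) == n)
    dimnames(coords)[[3L]] <- ids
  }
  structure(list(coords = coords, labels = labels, ids = ids,
                 metadata = metadata),
            class = "shape_sample")
}

#' @export
print.shape_sample <- function(x, ...) {
  dm <- dim(x$coords)
  cat(sprintf("shape_sample: %d specimens, %d landmarks in %dD\n",
              dm[3L], dm[1L], dm[2L]))
  invisible(x)
}

#' @export
dim.shape_sample <- function(x) dim(x$coords)

n_specimens <- function(sample) dim(sample$coords)[3L]
n_landmarks <- function(sample) dim(sample$coords)[1L]
landmark_dim <- function(x) {
  if (inherits(x, "shape_sample")) dim(x$coords)[2L] else ncol(x)
}

# coerce a k x d matrix or a shape_sample's array slice to a configuration
as_configuration <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!ncol(x) %in% c(2L, 3L)) stop("a configuration must be k x 2 or k x 3")
  x
}

#' Read landmark data from a TPS or CSV file
#'
#' The TPS dialect accepted is the Rohlf-style one: each specimen is a block
#' beginning `LM=k` (or `LM3=k` for 3D) followed by k coordinate lines;
#' optional `ID=` and `SCALE=` keys are honoured (`SCALE=` multiplies the
#' block's coordinates), `IMAGE=` and `CURVES=`/outline blocks are ignored.
#' The CSV convention is one specimen per row with columns
#' x1,y1[,z1],x2,y2[,z2],...; a header row is detected automatically.
#'
#' @param path path to an existing file.
#' @param format `"tps"` or `"csv"`; default guesses from the extension.
#' @param dim for CSV input, the coordinate dimension (2 or 3) used to fold
#'   the row into a k x d configuration. Ignored for TPS.
#' @return a validated [shape_sample()].
#' @export
read_landmarks <- function(path, format = c("auto", "tps", "csv"), dim = 2L) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tps$", path, ignore.case = TRUE)) "tps" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tps") read_tps(path) else read_landmark_csv(path, dim = dim)
}

read_tps <- function(path) {
  lines <- readLines(path, warn = FALSE)
  configs <- list(); ids <- character(0)
  i <- 1L; n_lines <- length(lines)
  while (i <= n_lines) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    m <- regmatches(ln, regexec("^LM(3?)\\s*=\\s*([0-9]+)\\s*$", ln,
                                ignore.case = TRUE))[[1L]]
    if (length(m) == 0L)
      stop(sprintf("parse error at line %d: expected an LM= block, got '%s'",
                   i, ln))
    d <- if (m[2L] == "3") 3L else 2L
    k <- as.integer(m[3L])
    if (i + k > n_lines)
      stop(sprintf("parse error: LM block at line %d is truncated", i))
    coord <- matrix(NA_real_, k, d)
    for (j in seq_len(k)) {
      toks <- strsplit(trimws(lines[i + j]), "[ \t,]+")[[1L]]
      vals <- suppressWarnings(as.numeric(toks))
      if (length(vals) < d || anyNA(vals[seq_len(d)]))
        stop(sprintf("parse error at line %d: non-numeric coordinate '%s'",
                     i + j, lines[i + j]))
      coord[j, ] <- vals[seq_len(d)]
    }
    i <- i + k + 1L
    id <- NA_character_; scale <- NA_real_
    # trailing keys for this block
    while (i <= n_lines) {
      ln <- trimws(lines[i])
      if (ln == "") { i <- i + 1L; next }
      if (grepl("^ID\\s*=", ln, ignore.case = TRUE)) {
        id <- sub("^ID\\s*=\\s*", "", ln, ignore.case = TRUE)
      } else if (grepl("^SCALE\\s*=", ln, ignore.case = TRUE)) {
        scale <- as.numeric(sub("^SCALE\\s*=\\s*", "", ln, ignore.case = TRUE))
        if (is.na(scale))
          stop(sprintf("parse error at line %d: non-numeric SCALE", i))
      } else if (grepl("^(IMAGE|CURVES|POINTS|OUTLINES)\\s*=", ln,
                       ignore.case = TRUE)) {
        # ignored keys
      } else if (grepl("^LM3?\\s*=", ln, ignore.case = TRUE)) {
        break
      } else if (grepl("^[A-Za-z]+\\s*=", ln)) {
        # unknown key: ignore
      } else {
        # outline coordinate lines following CURVES= etc.: skip silently
      }
      i <- i + 1L
    }
    if (!is.na(scale)) coord <- coord * scale
    configs[[length(configs) + 1L]] <- coord
    ids <- c(ids, if (is.na(id)) sprintf("specimen_%d", length(configs)) else id)
  }
  if (length(configs) == 0L) stop("no LM blocks found in ", path)
  dims <- unique(lapply(configs, base::dim))
  if (length(dims) != 1L)
    stop("homology error: specimens differ in landmark count or dimension")
  shape_sample(configs, ids = ids)
}

read_landmark_csv <- function(path, dim = 2L) {
  dim <- as.integer(dim)
  first <- strsplit(readLines(path, n = 1L), ",")[[1L]]
  header <- anyNA(suppressWarnings(as.numeric(first)))
  tab <- utils::read.csv(path, header = header, check.names = FALSE)
  mat <- as.matrix(tab)
  if (!is.numeric(mat)) {
    bad <- which(!apply(tab, 2, function(col)
      all(!is.na(suppressWarnings(as.numeric(col))))))[1L]
    stop("parse error: non-numeric token in column ", bad, " of ", path)
  }
  if (ncol(mat) %% dim != 0L)
    stop("CSV has ", ncol(mat), " coordinate columns, not a multiple of dim = ",
         dim)
  k <- ncol(mat) %/% dim
  coords <- array(0, c(k, dim, nrow(mat)))
  for (s in seq_len(nrow(mat)))
    coords[, , s] <- matrix(mat[s, ], k, dim, byrow = TRUE)
  ids <- if (!is.null(rownames(tab)) &&
             !identical(rownames(tab), as.character(seq_len(nrow(tab)))))
    rownames(tab) else sprintf("specimen_%d", seq_len(nrow(mat)))
  shape_sample(coords, ids = ids)
}

#' Write landmark data to a TPS or CSV file
#'
#' Coordinates are printed with 15 significant digits so that a
#' write/read round trip preserves them to at least 12 significant digits.
#'
#' @param sample a [shape_sample()].
#' @param path output file path.
#' @param format `"tps"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(sample, path, format = c("auto", "tps", "csv")) {
  stopifnot(inherits(sample, "shape_sample"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tps$", path, ignore.case = TRUE)) "tps" else "csv"
  co <- sample$coords
  k <- dim(co)[1L]; d <- dim(co)[2L]; n <- dim(co)[3L]
  fmt <- function(x) formatC(x, digits = 15, format = "g")
  if (format == "tps") {
    lines <- character(0)
    key <- if (d == 3L) "LM3" else "LM"
    ids <- sample$ids %||% sprintf("specimen_%d", seq_len(n))
    for (s in seq_len(n)) {
      lines <- c(lines, sprintf("%s=%d", key, k),
                 apply(co[, , s, drop = FALSE], 1,
                       function(r) paste(fmt(r), collapse = " ")),
                 sprintf("ID=%s", ids[s]))
    }
    writeLines(lines, path)
  } else {
    rows <- vapply(seq_len(n), function(s)
      paste(fmt(as.vector(t(co[, , s]))), collapse = ","), character(1L))
    writeLines(rows, path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a shape sample
#'
#' Reports (without erroring) the defects that make downstream spline and
#' Procrustes computations ill-posed: non-finite coordinates, coincident
#' landmarks within a specimen, too few landmarks (k < d + 2 leaves no
#' nonaffine variation), and an exactly collinear (2D) or coplanar (3D)
#' mean configuration, which makes the spline system singular.
#'
#' @param sample a [shape_sample()].
#' @param tol relative tolerance for coincidence/degeneracy checks.
#' @return a data frame with columns `specimen`, `type`, `detail`;
#'   zero rows for a clean sample.
#' @export
validate_sample <- function(sample, tol = 1e-12) {
  stopifnot(inherits(sample, "shape_sample"))
  co <- sample$coords
  k <- dim(co)[1L]; d <- dim(co)[2L]; n <- dim(co)[3L]
  out <- list()
  add <- function(specimen, type, detail)
    out[[length(out) + 1L]] <<- data.frame(specimen = specimen, type = type,
                                           detail = detail)
  if (k < d + 2L)
    add(NA_integer_, "too_few_landmarks",
        sprintf("k = %d < d + 2 = %d: no nonaffine variation exists", k, d + 2L))
  for (s in seq_len(n)) {
    X <- co[, , s]
    if (!all(is.finite(X))) {
      add(s, "non_finite", "configuration contains NA/NaN/Inf coordinates")
      next
    }
    span <- max(dist(X))
    dd <- as.matrix(dist(X)); diag(dd) <- Inf
    dup <- which(dd <= tol * max(span, 1), arr.ind = TRUE)
    if (nrow(dup)) {
      pair <- sort(dup[1L, ])
      add(s, "duplicate_landmark",
          sprintf("landmarks %d and %d coincide", pair[1L], pair[2L]))
    }
  }
  if (all(is.finite(co))) {
    mean_cfg <- apply(co, c(1, 2), mean)
    ctr <- scale(mean_cfg, scale = FALSE)
    if (qr(ctr)$rank < d)
      add(NA_integer_, "degenerate_mean",
          if (d == 2L) "mean configuration is exactly collinear"
          else "mean configuration is exactly coplanar")
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(specimen = integer(0), type = character(0),
                  detail = character(0))
}

# error if a sample fails validation. Superposition itself only needs
# nondegenerate configurations, so gpa passes require_nonaffine = FALSE:
# k < d + 2 merely means there is no nonaffine variation for the spline
# machinery downstream, which performs its own landmark-count checks.
assert_valid <- function(sample, require_nonaffine = TRUE) {
  rep <- validate_sample(sample)
  if (!require_nonaffine)
    rep <- rep[rep$type != "too_few_landmarks", , drop = FALSE]
  if (nrow(rep))
    stop("invalid shape sample: ", paste(rep$detail, collapse = "; "))
  invisible(sample)
}
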