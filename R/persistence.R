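#' Compute a persistence diagram
#'
#' Builds the Vietoris-Rips or Cech filtration of a point cloud (or, for
#' Rips, a precomputed distance matrix) and returns its persistence diagram.
#' All filtration values are radii: an edge enters at half the pairwise
#' distance under both filtrations, a Cech simplex at the radius of the
#' smallest ball enclosing its vertices, so that Cech and Rips diagrams of
#' the same cloud are directly comparable.
#'
#' Backends: `"alpha2d"` computes the Cech diagram of a planar cloud through
#' the alpha complex on the Delaunay triangulation (identical persistence,
#' linear-size complex; the default for `filtration = "cech"` in the plane);
#' `"flag"` enumerates simplices up to the threshold explicitly and works
#' for any dimension and both filtrations. The raw diagram retains
#' zero-persistence pairs and degree-0 features born at 0; use
#' [selectNoiseCandidates()] to extract the features the universal-null
#' machinery tests.
#'
#' @param x a [PointCloud-class], a numeric coordinate matrix, a `dist`
#'   object, or (with `input = "distance"`) a square symmetric matrix.
#' @param filtration "cech" or "rips".
#' @param maxDegree largest homology degree computed (simplices one
#'   dimension higher are enumerated).
#' @param threshold filtration radius to truncate at; `Inf` for the full
#'   filtration. The explicit backend refuses `threshold = Inf` beyond
#'   `fullCap` points because the full flag complex grows cubically.
#' @param backend "auto", "alpha2d" or "flag".
#' @param input "auto", "points" or "distance".
#' @param fullCap largest n for which the explicit backend will build the
#'   untruncated filtration (default 300).
#' @return a [PersistenceDiagram-class].
#' @examples
#' sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
#' features(computeDiagram(sq, "cech", maxDegree = 1))
#' @export
computeDiagram <- function(x, filtration = c("cech", "rips"), maxDegree = 1L,
                           threshold = Inf, backend = c("auto", "alpha2d", "flag"),
                           input = c("auto", "points", "distance"),
                           fullCap = 300L) {
  filtration <- match.arg(filtration)
  backend <- match.arg(backend)
  input <- match.arg(input)
  isDist <- FALSE
  if (is(x, "PointCloud")) {
    m <- coords(x)
  } else if (inherits(x, "dist")) {
    m <- as.matrix(x)
    isDist <- TRUE
  } else if (is.matrix(x)) {
    m <- x
    if (input == "distance") {
      .checkDistanceMatrix(m)
      isDist <- TRUE
    }
  } else stop("x must be a PointCloud, a coordinate matrix or a dist object")
  if (!all(is.finite(m))) stop("non-finite values in the input")
  if (isDist && filtration == "cech")
    stop("the Cech filtration needs point coordinates, not a distance matrix")
  stopifnot(maxDegree >= 0, threshold > 0)

  n <- nrow(m)
  if (backend == "auto")
    backend <- if (filtration == "cech" && !isDist && ncol(m) == 2) "alpha2d" else "flag"

  if (backend == "alpha2d") {
    if (filtration != "cech" || isDist || ncol(m) != 2)
      stop("the alpha2d backend computes Cech persistence of planar coordinates")
    feats <- .alpha2dDiagram(m)
    feats <- feats[feats$degree <= maxDegree, , drop = FALSE]
    dgm <- new("PersistenceDiagram", features = feats, filtration = "cech",
               scale = "radius", threshold = Inf, nPoints = as.integer(n))
    if (is.finite(threshold)) dgm <- thresholdDiagram(dgm, threshold)
    return(dgm)
  }

  if (!is.finite(threshold) && n > fullCap)
    stop(sprintf(paste0("the full flag filtration on %d points is too large; ",
                        "pass a finite threshold (or raise fullCap)"), n))
  res <- cpp_flag_persistence(m, isDist, filtration, as.integer(maxDegree),
                              threshold)
  feats <- data.frame(degree = as.integer(res[, 1]), birth = res[, 2],
                      death = res[, 3])
  feats <- feats[order(feats$degree, feats$birth, feats$death), , drop = FALSE]
  rownames(feats) <- NULL
  new("PersistenceDiagram", features = feats, filtration = filtration,
      scale = "radius", threshold = threshold, nPoints = as.integer(n))
}

.checkDistanceMatrix <- function(m) {
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (any(abs(m - t(m)) > 1e-12)) stop("distance matrix must be symmetric")
  if (any(abs(diag(m)) > 1e-12)) stop("distance matrix must have a zero diagonal")
  if (any(m < 0)) stop("distances must be nonnegative")
  invisible(TRUE)
}

.alpha2dDiagram <- function(m) {
  if (nrow(m) < 3) stop("alpha complex needs at least 3 points")
  tm <- interp::tri.mesh(m[, 1], m[, 2])
  tri <- interp::triangles(tm)[, 1:3, drop = FALSE]
  res <- cpp_alpha2d_persistence(m, tri)
  feats <- data.frame(degree = as.integer(res[, 1]), birth = res[, 2],
                      death = res[, 3])
  feats <- feats[order(feats$degree, feats$birth, feats$death), , drop = FALSE]
  rownames(feats) <- NULL
  feats
}

#' Truncate a persistence diagram at a filtration threshold
#'
#' Features born after `tau` are dropped; features dying after `tau` become
#' infinite. Truncating a full diagram this way reproduces what a direct
#' computation capped at `tau` would report.
#'
#' @param dgm a [PersistenceDiagram-class].
#' @param tau new threshold; must not exceed the diagram's own.
#' @return a [PersistenceDiagram-class] with threshold `tau`.
#' @export
thresholdDiagram <- function(dgm, tau) {
  stopifnot(is(dgm, "PersistenceDiagram"), tau > 0)
  if (tau > dgm@threshold)
    stop("cannot raise a diagram's threshold; recompute instead")
  f <- features(dgm)
  f <- f[f$birth <= tau, , drop = FALSE]
  f$death[f$death > tau] <- Inf
  rownames(f) <- NULL
  new("PersistenceDiagram", features = f, filtration = dgm@filtration,
      scale = "radius", threshold = tau, nPoints = dgm@nPoints)
}

#' Split a diagram into testable finite features and infinite features
#'
#' Returns the degree-k features the hypothesis-testing machinery can use:
#' finite features with positive birth and strictly positive persistence
#' (zero-persistence pairs and anything born at 0 are noise artefacts of the
#' complex, not cycles), and the infinite features of the same degree.
#'
#' @param dgm a [PersistenceDiagram-class].
#' @param k homology degree, k >= 1 (the death/birth ratio is undefined for
#'   the degree-0 class born at 0).
#' @return list with data.frames `finite` and `infinite`.
#' @export
selectNoiseCandidates <- function(dgm, k = 1L) {
  stopifnot(is(dgm, "PersistenceDiagram"))
  if (k < 1) stop("k must be >= 1: degree-0 features are born at 0 where the ratio statistic is undefined")
  f <- features(dgm)
  f <- f[f$degree == k, , drop = FALSE]
  fin <- f[is.finite(f$death) & f$birth > 0 & f$death > f$birth, , drop = FALSE]
  inf <- f[!is.finite(f$death), , drop = FALSE]
  rownames(fin) <- rownames(inf) <- NULL
  list(finite = fin, infinite = inf)
}

#' Count filtration edges at a radius
#'
#' Number of point pairs within distance `2 * radius`, i.e. the number of
#' edges present in either filtration at that radius; used to audit the
#' complex-size savings of the infinite-cycle threshold search.
#'
#' @param pc a [PointCloud-class] or coordinate matrix.
#' @param radius filtration radius.
#' @return edge count (double, to avoid integer overflow).
#' @export
edgeCount <- function(pc, radius) {
  m <- if (is(pc, "PointCloud")) coords(pc) else pc
  cpp_edge_count(m, radius)
}
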