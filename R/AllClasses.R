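#' PointCloud: an n x d coordinate matrix with provenance
#'
#' Container for a finite point cloud together with the sampling model that
#' produced it, its parameters and the RNG seed, so that every sample is
#' reproducible from its metadata alone.
#'
#' @slot points numeric matrix, one point per row.
#' @slot model name of the generating model ("external" for loaded data).
#' @slot params named list of model parameters.
#' @slot seed integer seed used for generation (NA for external data).
#' @export
setClass("PointCloud",
  representation(points = "matrix", model = "character",
                 params = "list", seed = "integer"),
  prototype(model = "external", params = list(), seed = NA_integer_))

setValidity("PointCloud", function(object) {
  p <- object@points
  if (!is.numeric(p)) return("points must be a numeric matrix")
  if (nrow(p) < 1L || ncol(p) < 1L) return("need n >= 1 points in d >= 1 dimensions")
  if (!all(is.finite(p))) return("all coordinates must be finite")
  TRUE
})

#' PersistenceDiagram: a multiset of (degree, birth, death) features
#'
#' Features are stored as a data frame; `death` may be `Inf` for cycles still
#' alive at the computation threshold. All scales are radii.
#'
#' @slot features data.frame with columns degree, birth, death.
#' @slot filtration "cech" or "rips".
#' @slot scale scale convention, always "radius".
#' @slot threshold filtration radius the computation was truncated at (Inf
#'   for the full filtration).
#' @slot nPoints number of points in the source cloud (NA if unknown).
#' @export
setClass("PersistenceDiagram",
  representation(features = "data.frame", filtration = "character",
                 scale = "character", threshold = "numeric",
                 nPoints = "integer"),
  prototype(scale = "radius", threshold = Inf, nPoints = NA_integer_))

setValidity("PersistenceDiagram", function(object) {
  f <- object@features
  need <- c("degree", "birth", "death")
  if (!all(need %in% names(f))) return("features needs degree, birth, death columns")
  if (nrow(f)) {
    if (any(f$birth < 0)) return("negative birth")
    if (any(f$death < f$birth)) return("death before birth")
    tau <- object@threshold
    if (is.finite(tau) && any(f$birth > tau + 1e-9))
      return("birth beyond the computation threshold")
  }
  if (!object@filtration %in% c("cech", "rips")) return("unknown filtration")
  if (!identical(object@scale, "radius")) return("scale convention must be 'radius'")
  TRUE
})

#' TransformParams: constants of the log-log normalization
#'
#' Holds the slope A (1 for Rips, 1/2 for Cech), the diagram mean `Lbar` of
#' log log pi, and the intercept B = -lambda - A * Lbar that centres the
#' transformed values at minus the Euler-Mascheroni constant.
#'
#' @slot A slope (1 or 1/2).
#' @slot B intercept.
#' @slot Lbar mean of log log pi over the diagram the transform was fit on.
#' @slot filtration "cech" or "rips".
#' @export
setClass("TransformParams",
  representation(A = "numeric", B = "numeric", Lbar = "numeric",
                 filtration = "character"))

setValidity("TransformParams", function(object) {
  if (!object@A %in% c(1, 0.5)) return("A must be 1 (rips) or 1/2 (cech)")
  if (!is.finite(object@B)) return("B must be finite")
  TRUE
})

#' SignificanceReport: per-feature verdicts of the universal-null test
#'
#' @slot alpha family-wise significance level.
#' @slot degree homology degree tested.
#' @slot filtration "cech" or "rips".
#' @slot decisions data.frame with one row per tested feature: birth, death,
#'   pi, ell, p_value, threshold (the Bonferroni level alpha/m), significant,
#'   bound_only (TRUE when p_value is the upper bound for an infinite cycle).
#' @slot params the fitted [TransformParams-class].
#' @slot nTested the Bonferroni denominator m (all degree-k features tested,
#'   finite and infinite).
#' @export
setClass("SignificanceReport",
  representation(alpha = "numeric", degree = "integer", filtration = "character",
                 decisions = "data.frame", params = "TransformParams",
                 nTested = "integer"))

#' InfiniteSearchTrace: the iterative threshold search for infinite cycles
#'
#' One row of `iterations` per pass: the threshold tau, the diagram size |D|,
#' the number of infinite cycles, the number still undecided, and pi_min at
#' the Bonferroni level of that pass.
#'
#' @slot iterations data.frame (iter, tau, size, n_infinite, n_undecided, pi_min).
#' @slot tauFinal the final threshold of the loop.
#' @slot converged FALSE when the tau cap was hit with cycles undecided.
#' @slot verdicts data.frame, one row per infinite cycle encountered during
#'   the search: birth, tau_certified (the per-cycle threshold at which its
#'   p-value bound cleared the Bonferroni level while the cycle was still
#'   infinite; NA if never), p_bound (at certification, else at the final
#'   threshold), significant.
#' @slot finalDiagram the diagram computed at the final threshold.
#' @slot alpha,degree,filtration run parameters.
#' @export
setClass("InfiniteSearchTrace",
  representation(iterations = "data.frame", tauFinal = "numeric",
                 converged = "logical", verdicts = "data.frame",
                 finalDiagram = "PersistenceDiagram",
                 alpha = "numeric", degree = "integer", filtration = "character"))
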