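#' @name accessors
#' @title Accessors for tdanull objects
#' @param object,x an object of the respective class
#' @param ... unused
NULL

#' @describeIn accessors coordinate matrix of a PointCloud
#' @export
setGeneric("coords", function(object, ...) standardGeneric("coords"))
#' @export
setMethod("coords", "PointCloud", function(object, ...) object@points)

#' @describeIn accessors number of points
#' @export
setGeneric("nPoints", function(object, ...) standardGeneric("nPoints"))
#' @export
setMethod("nPoints", "PointCloud", function(object, ...) nrow(object@points))
#' @export
setMethod("nPoints", "PersistenceDiagram", function(object, ...) object@nPoints)

#' @describeIn accessors generating model name
#' @export
setGeneric("modelName", function(object, ...) standardGeneric("modelName"))
#' @export
setMethod("modelName", "PointCloud", function(object, ...) object@model)

#' @describeIn accessors model parameters
#' @export
setGeneric("modelParams", function(object, ...) standardGeneric("modelParams"))
#' @export
setMethod("modelParams", "PointCloud", function(object, ...) object@params)

#' @describeIn accessors feature table of a diagram
#' @export
setGeneric("features", function(object, ...) standardGeneric("features"))
#' @export
setMethod("features", "PersistenceDiagram", function(object, ...) object@features)

#' @describeIn accessors filtration type ("cech" or "rips")
#' @export
setGeneric("filtrationType", function(object, ...) standardGeneric("filtrationType"))
#' @export
setMethod("filtrationType", "PersistenceDiagram", function(object, ...) object@filtration)
#' @export
setMethod("filtrationType", "TransformParams", function(object, ...) object@filtration)
#' @export
setMethod("filtrationType", "SignificanceReport", function(object, ...) object@filtration)

#' @describeIn accessors computation threshold of a diagram
#' @export
setGeneric("diagramThreshold", function(object, ...) standardGeneric("diagramThreshold"))
#' @export
setMethod("diagramThreshold", "PersistenceDiagram", function(object, ...) object@threshold)

#' @describeIn accessors decision table of a SignificanceReport
#' @export
setGeneric("decisions", function(object, ...) standardGeneric("decisions"))
#' @export
setMethod("decisions", "SignificanceReport", function(object, ...) object@decisions)

#' @describeIn accessors iteration table of an InfiniteSearchTrace
#' @export
setGeneric("iterations", function(object, ...) standardGeneric("iterations"))
#' @export
setMethod("iterations", "InfiniteSearchTrace", function(object, ...) object@iterations)

#' @describeIn accessors fitted transform parameters
#' @export
setGeneric("transformParams", function(object, ...) standardGeneric("transformParams"))
#' @export
setMethod("transformParams", "SignificanceReport", function(object, ...) object@params)

setMethod("show", "PointCloud", function(object) {
  cat(sprintf("PointCloud: %d points in R^%d (model: %s, seed: %s)\n",
              nrow(object@points), ncol(object@points), object@model,
              ifelse(is.na(object@seed), "none", object@seed)))
})

setMethod("show", "PersistenceDiagram", function(object) {
  f <- object@features
  cat(sprintf("PersistenceDiagram (%s, radius scale, threshold %s): %d features\n",
              object@filtration,
              ifelse(is.finite(object@threshold),
                     format(object@threshold), "Inf"),
              nrow(f)))
  if (nrow(f)) {
    tb <- table(factor(f$degree, levels = sort(unique(f$degree))))
    cat("  per degree:", paste(sprintf("H%s=%d", names(tb), tb), collapse = ", "), "\n")
    cat(sprintf("  infinite features: %d\n", sum(!is.finite(f$death))))
  }
})

setMethod("show", "TransformParams", function(object) {
  cat(sprintf("TransformParams: A=%g (%s), B=%.6f, mean loglog pi=%.6f\n",
              object@A, object@filtration, object@B, object@Lbar))
})

setMethod("show", "SignificanceReport", function(object) {
  d <- object@decisions
  cat(sprintf("SignificanceReport: H%d, %s filtration, alpha=%g, m=%d tested\n",
              object@degree, object@filtration, object@alpha, object@nTested))
  cat(sprintf("  significant: %d of %d (Bonferroni level %.3g)\n",
              sum(d$significant), nrow(d), object@alpha / max(1L, object@nTested)))
})

setMethod("show", "InfiniteSearchTrace", function(object) {
  cat(sprintf("InfiniteSearchTrace: H%d, %s, alpha=%g; %d iterations, tau*=%g%s\n",
              object@degree, object@filtration, object@alpha,
              nrow(object@iterations), object@tauFinal,
              if (object@converged) "" else " (truncated)"))
  if (nrow(object@verdicts))
    cat(sprintf("  infinite cycles at tau*: %d, significant: %d\n",
                nrow(object@verdicts), sum(object@verdicts$significant)))
})
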