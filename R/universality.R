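#' Persistence ratio and lifetime statistics
#'
#' `piValues` returns the death/birth ratio pi = d/b of each finite feature,
#' the scale-invariant persistence statistic the universal null law is
#' phrased in; `lifetimes` returns the additive lifetimes d - b.
#'
#' @param features data.frame with `birth` and `death` columns (e.g. the
#'   `finite` part of [selectNoiseCandidates()]), or a numeric matrix with
#'   two columns.
#' @return numeric vector, in input order.
#' @examples
#' piValues(data.frame(birth = c(0.2, 0.4, 2), death = c(0.675, 1.35, 4)))
#' @export
piValues <- function(features) {
  bd <- .birthDeath(features)
  if (any(bd$birth <= 0)) stop("pi is undefined at birth 0; pre-filter with selectNoiseCandidates()")
  if (any(!is.finite(bd$death))) stop("pi is undefined for infinite features; pre-filter with selectNoiseCandidates()")
  bd$death / bd$birth
}

#' @rdname piValues
#' @export
lifetimes <- function(features) {
  bd <- .birthDeath(features)
  if (any(!is.finite(bd$death))) stop("lifetime is undefined for infinite features")
  bd$death - bd$birth
}

.birthDeath <- function(features) {
  if (is.data.frame(features)) {
    stopifnot(all(c("birth", "death") %in% names(features)))
    list(birth = features$birth, death = features$death)
  } else if (is.matrix(features) && ncol(features) == 2) {
    list(birth = features[, 1], death = features[, 2])
  } else stop("features must be a data.frame with birth/death or a 2-column matrix")
}

#' The log-log transform of persistence ratios
#'
#' Maps pi-values to ell = A log log pi + B with A = 1 (Rips) or 1/2 (Cech)
#' and B = -lambda - A * mean(log log pi), lambda the Euler-Mascheroni
#' constant. The centring makes mean(ell) = -lambda exactly, and makes the
#' ell-values invariant to raising pi to any fixed positive power — hence to
#' the radius-vs-diameter and radius-vs-squared-radius scale conventions of
#' persistence backends. Under the universality null the ell-values follow
#' the left-skewed Gumbel law.
#'
#' Values numerically at or below 1 carry no log-log information and are
#' dropped with a warning; `B` may instead be fixed in advance (simulation
#' studies) via `B`.
#'
#' @param pi numeric vector of persistence ratios, all > 1.
#' @param filtration "cech" or "rips" (sets A).
#' @param B optional known intercept; by default estimated from `pi`.
#' @return list with `ell` (numeric vector, same order as the kept `pi`),
#'   `params` (a [TransformParams-class]) and `kept` (logical vector marking
#'   which inputs were used).
#' @export
ellTransform <- function(pi, filtration = c("cech", "rips"), B = NULL) {
  filtration <- match.arg(filtration)
  if (!length(pi)) stop("ellTransform needs at least one pi-value")
  keep <- pi > 1 + 1e-12
  if (!all(keep)) {
    warning(sum(!keep), " pi-value(s) <= 1 dropped (zero-persistence artefacts)")
    pi <- pi[keep]
  }
  if (!length(pi)) stop("no pi-values above 1 remain")
  A <- if (filtration == "rips") 1 else 0.5
  ll <- log(log(pi))
  Lbar <- mean(ll)
  if (is.null(B)) B <- -.lambda - A * Lbar
  params <- new("TransformParams", A = A, B = B, Lbar = Lbar,
                filtration = filtration)
  list(ell = A * ll + B, params = params, kept = keep)
}

#' Invert the log-log transform
#'
#' Returns the pi-value whose ell-value is `y`: exp(exp((y - B) / A)).
#'
#' @param y numeric ell-scale value(s).
#' @param params a [TransformParams-class].
#' @return pi-value(s), always > 1.
#' @export
ellInverse <- function(y, params) {
  stopifnot(is(params, "TransformParams"))
  z <- (y - params@B) / params@A
  if (any(z > 709)) stop("ellInverse overflows for this argument")
  out <- exp(exp(z))
  if (any(!is.finite(out))) stop("ellInverse overflows for this argument")
  out
}

#' The left-skewed Gumbel null law
#'
#' The parameter-free law conjectured to govern ell-values of noise cycles:
#' CDF F(x) = 1 - exp(-exp(x)), PDF f(x) = exp(x - exp(x)). This is the
#' mirror image of the classical (right-skewed) Gumbel law, so its mean is
#' minus the Euler-Mascheroni constant, -lambda = -0.5772156649...; the
#' centring of [ellTransform()] places ell-values at exactly this mean.
#' `lgumbelMean()` evaluates the mean by adaptive quadrature of x f(x) as an
#' independent check on the closed form.
#'
#' @param x,q quantile vector.
#' @param p probability vector in (0,1).
#' @param n number of random deviates.
#' @return `dlgumbel`/`plgumbel`: densities/probabilities; `qlgumbel`:
#'   quantiles; `rlgumbel`: random deviates; `lgumbelMean`: the mean by
#'   quadrature.
#' @examples
#' plgumbel(0)            # 1 - exp(-1)
#' qlgumbel(plgumbel(1.3))
#' @export
plgumbel <- function(q) -expm1(-exp(q))

#' @rdname plgumbel
#' @export
dlgumbel <- function(x) exp(x - exp(x))

#' @rdname plgumbel
#' @export
qlgumbel <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("quantile argument must lie strictly in (0,1)")
  log(-log1p(-p))
}

#' @rdname plgumbel
#' @export
rlgumbel <- function(n) qlgumbel(runif(n))

#' @rdname plgumbel
#' @export
lgumbelMean <- function() {
  integrate(function(x) x * dlgumbel(x), -Inf, Inf,
            rel.tol = 1e-12, abs.tol = 1e-12)$value
}

#' Kolmogorov-Smirnov goodness of fit against the null law
#'
#' One-sample KS test of ell-values against the left-skewed Gumbel CDF,
#' with the p-value from the asymptotic Kolmogorov distribution. Because the
#' intercept B is estimated from the same diagram, the test is mildly
#' conservative.
#'
#' @param ell numeric vector of ell-values (at least 5).
#' @return list with `statistic` (the sup-distance D) and `p.value`.
#' @export
ksGof <- function(ell) {
  if (length(ell) < 5) stop("ksGof needs at least 5 values")
  kt <- suppressWarnings(ks.test(ell, plgumbel, exact = FALSE))
  list(statistic = unname(kt$statistic), p.value = unname(kt$p.value))
}

#' ECDF and QQ tables against the null law
#'
#' Plain tabular diagnostics ready for any plotting layer: QQ pairs at
#' plotting positions (i - 1/2)/m and the empirical CDF step function.
#'
#' @param values numeric vector (at least 1 value).
#' @return list with `qq` (data.frame: prob, empirical, theoretical) and
#'   `ecdf` (data.frame: x, F_empirical, F_null).
#' @export
ecdfQq <- function(values) {
  if (!length(values)) stop("no values")
  m <- length(values)
  s <- sort(values)
  p <- (seq_len(m) - 0.5) / m
  list(qq = data.frame(prob = p, empirical = s, theoretical = qlgumbel(p)),
       ecdf = data.frame(x = s, F_empirical = seq_len(m) / m,
                         F_null = plgumbel(s)))
}
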