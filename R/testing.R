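#' Per-cycle p-value under the universal null
#'
#' The probability, under the left-skewed Gumbel null, of an ell-value at
#' least as large as the observed one: exp(-exp(ell)) — the complement of
#' the null CDF. Strictly decreasing in ell (hence in pi).
#'
#' @param ell numeric ell-value(s).
#' @return p-value(s) in (0,1), saturating gracefully at the extremes.
#' @examples
#' pValue(log(log(20)))   # exactly 0.05
#' @export
pValue <- function(ell) exp(-exp(ell))

#' Smallest persistence ratio that reaches a target p-value
#'
#' pi_min(x) is the minimum death/birth ratio whose p-value under the
#' universal null falls below x: the inverse ell-map evaluated at
#' log log (1/x). It drives the threshold updates of the infinite-cycle
#' search.
#'
#' @param x target p-value in (0,1).
#' @param params a [TransformParams-class].
#' @return pi_min(x) > 1, strictly decreasing in x.
#' @export
piMin <- function(x, params) {
  if (any(x <= 0 | x >= 1)) stop("x must lie strictly in (0,1)")
  ellInverse(log(log(1 / x)), params)
}

#' Upper bound on the p-value of an infinite cycle
#'
#' A cycle born at b and still alive at the computation threshold tau has
#' pi > tau/b, so its p-value is below the value obtained by pushing the
#' ratio tau/b through the ell-map: exp(-exp(A log log(tau/b) + B)).
#' Decreasing in tau, increasing in b.
#'
#' @param b birth radius (0 < b, tau/b > 1).
#' @param tau computation threshold.
#' @param params a [TransformParams-class].
#' @return upper bound(s) on the p-value.
#' @export
infinitePBound <- function(b, tau, params) {
  stopifnot(is(params, "TransformParams"))
  ratio <- tau / b
  if (any(ratio <= 1)) stop("infinite-cycle bound needs tau/b > 1")
  pValue(params@A * log(log(ratio)) + params@B)
}

#' Extract the significant (signal) features of a diagram
#'
#' Computes ell-values of the finite degree-k features (B estimated from
#' this diagram), their p-values, and applies the Bonferroni correction at
#' family-wise level alpha: a feature is signal when its p-value is below
#' alpha / m, where m counts every tested degree-k feature of the diagram —
#' finite and infinite alike.
#'
#' Infinite features (present when the diagram was truncated) are included
#' in the decision table with their p-value upper bound and
#' `bound_only = TRUE`; a bound below alpha/m already certifies
#' significance, while a bound above it leaves the feature undecided (use
#' [findInfiniteThreshold()] to resolve it).
#'
#' @param dgm a [PersistenceDiagram-class].
#' @param k homology degree (>= 1).
#' @param alpha family-wise significance level in (0,1), default 0.05.
#' @return a [SignificanceReport-class].
#' @export
signalFeatures <- function(dgm, k = 1L, alpha = 0.05) {
  stopifnot(is(dgm, "PersistenceDiagram"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)")
  cand <- selectNoiseCandidates(dgm, k)
  fin <- cand$finite; infin <- cand$infinite
  if (!nrow(fin)) stop("no finite degree-", k, " candidates to estimate the transform from")
  tr <- ellTransform(piValues(fin), filtrationType(dgm))
  fin <- fin[tr$kept, , drop = FALSE]
  m <- nrow(fin) + nrow(infin)
  bon <- alpha / m
  p <- pValue(tr$ell)
  dec <- data.frame(degree = k, birth = fin$birth, death = fin$death,
                    pi = piValues(fin), ell = tr$ell, p_value = p,
                    threshold = bon, significant = p < bon,
                    bound_only = FALSE)
  if (nrow(infin)) {
    tau <- diagramThreshold(dgm)
    pb <- infinitePBound(infin$birth, tau, tr$params)
    dec <- rbind(dec, data.frame(degree = k, birth = infin$birth, death = Inf,
                                 pi = NA_real_, ell = NA_real_, p_value = pb,
                                 threshold = bon, significant = pb < bon,
                                 bound_only = TRUE))
  }
  dec <- dec[order(dec$p_value), , drop = FALSE]
  rownames(dec) <- NULL
  new("SignificanceReport", alpha = alpha, degree = as.integer(k),
      filtration = filtrationType(dgm), decisions = dec, params = tr$params,
      nTested = as.integer(m))
}

#' Iterative threshold search for infinite cycles
#'
#' Decides the significance of cycles still alive at the computation
#' threshold without ever computing the full filtration. Starting from
#' tau0, each pass computes the degree-k diagram at the current tau,
#' collects the undecided infinite births I = \{b : tau/b < pi_min(alpha/|D|)\},
#' and raises the threshold to min(I) * pi_min(alpha/|D|) (or max(I) with
#' `pick = "max"`: fewer passes, larger complexes) until no cycle is
#' undecided. An infinite cycle of the final diagram is significant when
#' its bound tau*/b reaches pi_min; cycles that became finite along the way
#' are tested by [signalFeatures()] on the final diagram.
#'
#' The tau sequence is strictly increasing (b * pi_min > tau for undecided
#' b). A cap `tauMax` (default: half the cloud diameter, beyond which a Rips
#' complex is a cone and carries no cycles) guarantees termination; hitting
#' it with cycles still undecided is reported as `converged = FALSE`.
#'
#' @param pc a [PointCloud-class] or coordinate matrix.
#' @param k homology degree (>= 1).
#' @param filtration "cech" or "rips".
#' @param alpha family-wise level, default 0.05.
#' @param tau0 initial threshold radius.
#' @param tauMax cap on tau (default half the point-cloud diameter).
#' @param pick "min" (earliest-born undecided cycle, smallest thresholds)
#'   or "max" (fewest iterations).
#' @param maxIter iteration cap, default 50.
#' @param ... passed to [computeDiagram()] (e.g. `backend`).
#' @return an [InfiniteSearchTrace-class].
#' @export
findInfiniteThreshold <- function(pc, k = 1L, filtration = c("cech", "rips"),
                                  alpha = 0.05, tau0, tauMax = NULL,
                                  pick = c("min", "max"), maxIter = 50L, ...) {
  filtration <- match.arg(filtration)
  pick <- match.arg(pick)
  m <- if (is(pc, "PointCloud")) coords(pc) else pc
  stopifnot(tau0 > 0)
  if (is.null(tauMax)) {
    # half the diameter: at this radius every pair is joined and the flag
    # complex is a cone, so no k-cycle survives
    tauMax <- sqrt(cpp_sq_diameter(m)) / 2
  }
  if (tauMax < tau0) stop("tauMax must be at least tau0")
  tau <- tau0
  rows <- list()
  converged <- FALSE
  dgm <- NULL
  pm <- NA_real_
  # per-cycle certification records, keyed by the (stable) birth value
  certB <- numeric(0); certTau <- numeric(0); certP <- numeric(0)
  for (it in seq_len(maxIter)) {
    dgm <- computeDiagram(m, filtration, maxDegree = k, threshold = tau, ...)
    cand <- selectNoiseCandidates(dgm, k)
    if (!nrow(cand$finite))
      stop("no finite degree-", k, " features at tau0; increase tau0")
    tr <- ellTransform(piValues(cand$finite), filtration)
    sizeD <- sum(tr$kept) + nrow(cand$infinite)
    pm <- piMin(alpha / sizeD, tr$params)
    bInf <- cand$infinite$birth
    # cycles whose bound clears the Bonferroni level while still infinite:
    # certified significant at this threshold (the per-cycle tau*)
    newCert <- bInf[tau / bInf >= pm &
                    !vapply(bInf, function(b)
                      any(abs(certB - b) < 1e-9), logical(1))]
    if (length(newCert)) {
      certB <- c(certB, newCert)
      certTau <- c(certTau, rep(tau, length(newCert)))
      certP <- c(certP, infinitePBound(newCert, tau, tr$params))
    }
    I <- bInf[tau / bInf < pm]
    rows[[it]] <- data.frame(iter = it, tau = tau, size = sizeD,
                             n_infinite = length(bInf),
                             n_undecided = length(I), pi_min = pm)
    if (!length(I)) { converged <- TRUE; break }
    tauNext <- if (pick == "min") min(I) * pm else max(I) * pm
    if (tauNext >= tauMax) {
      if (tau >= tauMax) break
      tauNext <- tauMax
    }
    tau <- tauNext
  }
  trace <- do.call(rbind, rows)
  finParams <- ellTransform(piValues(selectNoiseCandidates(dgm, k)$finite),
                            filtration)$params
  infinB <- selectNoiseCandidates(dgm, k)$infinite$birth
  undecB <- infinB[!vapply(infinB, function(b)
    any(abs(certB - b) < 1e-9), logical(1))]
  verdicts <- rbind(
    if (length(certB)) data.frame(birth = certB, tau_certified = certTau,
                                  p_bound = certP, significant = TRUE),
    if (length(undecB)) data.frame(birth = undecB, tau_certified = NA_real_,
                                   p_bound = infinitePBound(undecB, tau,
                                                            finParams),
                                   significant = FALSE))
  if (is.null(verdicts))
    verdicts <- data.frame(birth = numeric(), tau_certified = numeric(),
                           p_bound = numeric(), significant = logical())
  verdicts <- verdicts[order(verdicts$birth), , drop = FALSE]
  rownames(verdicts) <- NULL
  new("InfiniteSearchTrace", iterations = trace, tauFinal = tau,
      converged = converged, verdicts = verdicts, finalDiagram = dgm,
      alpha = alpha, degree = as.integer(k), filtration = filtration)
}

#' End-to-end significance report for a point cloud
#'
#' Convenience orchestration: compute the diagram at threshold `tau`, test
#' the finite degree-k features, and, when infinite cycles are present and
#' undecided, run the iterative threshold search to resolve them.
#'
#' @inheritParams findInfiniteThreshold
#' @param tau computation threshold (Inf for the full filtration where
#'   feasible).
#' @return list with `report` (a [SignificanceReport-class]) and `trace`
#'   (an [InfiniteSearchTrace-class], or NULL when no search was needed).
#' @export
fullReport <- function(pc, k = 1L, filtration = c("cech", "rips"),
                       alpha = 0.05, tau = Inf, ...) {
  filtration <- match.arg(filtration)
  dgm <- computeDiagram(pc, filtration, maxDegree = k, threshold = tau, ...)
  cand <- selectNoiseCandidates(dgm, k)
  if (!nrow(cand$finite) && !nrow(cand$infinite)) {
    dec <- data.frame(degree = integer(), birth = numeric(), death = numeric(),
                      pi = numeric(), ell = numeric(), p_value = numeric(),
                      threshold = numeric(), significant = logical(),
                      bound_only = logical())
    rep <- new("SignificanceReport", alpha = alpha, degree = as.integer(k),
               filtration = filtration, decisions = dec,
               params = new("TransformParams", A = if (filtration == "rips") 1 else 0.5,
                            B = 0, Lbar = 0, filtration = filtration),
               nTested = 0L)
    return(list(report = rep, trace = NULL))
  }
  report <- signalFeatures(dgm, k, alpha)
  trace <- NULL
  dec <- decisions(report)
  undecided <- dec$bound_only & !dec$significant
  if (any(undecided) && is.finite(tau)) {
    trace <- findInfiniteThreshold(pc, k, filtration, alpha, tau0 = tau, ...)
    report <- signalFeatures(trace@finalDiagram, k, alpha)
  }
  list(report = report, trace = trace)
}
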