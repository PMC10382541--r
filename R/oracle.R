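#' Reference Rips persistence by full boundary-matrix reduction
#'
#' A deliberately simple, self-contained correctness oracle: it enumerates
#' every simplex up to dimension `maxDegree + 1` of the full Rips filtration
#' (no neighbourhood pruning), orders them by (filtration value, dimension,
#' lexicographic vertex order) and runs the textbook left-to-right column
#' reduction of the global boundary matrix over GF(2). It shares no code
#' with the production engine and is capped at small inputs.
#'
#' @param dm square symmetric distance matrix (or `dist` object).
#' @param maxDegree largest homology degree (default 1).
#' @param threshold truncate the filtration at this radius (default Inf).
#' @param cap refuse matrices larger than this (default 64 points).
#' @return a [PersistenceDiagram-class] (filtration "rips", radius scale).
#' @export
naiveRipsPersistence <- function(dm, maxDegree = 1L, threshold = Inf,
                                 cap = 64L) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  .checkDistanceMatrix(dm)
  n <- nrow(dm)
  if (n > cap) stop("the reduction oracle is capped at ", cap, " points")

  # enumerate simplices: list of vertex vectors + value (radius = half the
  # largest pairwise distance), dimension
  simplices <- list()
  values <- numeric(0)
  dims <- integer(0)
  for (v in seq_len(n)) {
    simplices[[length(simplices) + 1L]] <- v
    values <- c(values, 0)
    dims <- c(dims, 0L)
  }
  for (d in seq_len(maxDegree + 1L)) {
    if (d + 1L > n) break
    combs <- combn(n, d + 1L)
    for (ci in seq_len(ncol(combs))) {
      vs <- combs[, ci]
      val <- max(dm[vs, vs]) / 2
      if (val <= threshold) {
        simplices[[length(simplices) + 1L]] <- vs
        values <- c(values, val)
        dims <- c(dims, d)
      }
    }
  }
  ord <- order(values, dims, vapply(simplices, function(v)
    sum(v * n^(rev(seq_along(v)) - 1)), numeric(1)))
  simplices <- simplices[ord]
  values <- values[ord]
  dims <- dims[ord]
  m <- length(simplices)
  key <- vapply(simplices, paste, "", collapse = ",")
  pos <- seq_len(m)
  names(pos) <- key

  # global boundary matrix, columns as sorted row-index vectors
  cols <- vector("list", m)
  for (j in seq_len(m)) {
    vs <- simplices[[j]]
    if (length(vs) == 1L) { cols[[j]] <- integer(0); next }
    faces <- vapply(seq_along(vs), function(i)
      paste(vs[-i], collapse = ","), "")
    cols[[j]] <- sort(unname(pos[faces]))
  }

  low <- rep(NA_integer_, m)   # pivot row of column j after reduction
  owner <- rep(NA_integer_, m) # column owning pivot row i
  for (j in seq_len(m)) {
    cur <- cols[[j]]
    while (length(cur)) {
      piv <- cur[length(cur)]
      if (is.na(owner[piv])) {
        owner[piv] <- j
        low[j] <- piv
        break
      }
      other <- cols[[owner[piv]]]
      cur <- sort(c(setdiff(cur, other), setdiff(other, cur)))
    }
    cols[[j]] <- cur
  }

  paired <- !is.na(low)
  isPivotRow <- logical(m)
  isPivotRow[low[paired]] <- TRUE
  deg <- integer(0); birth <- numeric(0); death <- numeric(0)
  for (j in seq_len(m)) {
    if (paired[j]) {
      i <- low[j]
      deg <- c(deg, dims[i])
      birth <- c(birth, values[i])
      death <- c(death, values[j])
    } else if (!isPivotRow[j] && dims[j] <= maxDegree) {
      deg <- c(deg, dims[j])
      birth <- c(birth, values[j])
      death <- c(death, Inf)
    }
  }
  feats <- data.frame(degree = deg, birth = birth, death = death)
  feats <- feats[order(feats$degree, feats$birth, feats$death), , drop = FALSE]
  rownames(feats) <- NULL
  new("PersistenceDiagram", features = feats, filtration = "rips",
      scale = "radius", threshold = threshold, nPoints = as.integer(n))
}
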