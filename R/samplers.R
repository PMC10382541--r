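#' Run code under a local, restorable RNG seed
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.null(seed) && !is.na(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

.modelNames <- c("box", "ball", "annulus", "sphere", "beta", "normal",
                 "cauchy", "torus", "klein", "projective", "linkage",
                 "henneberg", "stratified", "brownian", "lorenz")

.rejectionCap <- 10000L  # batches; a rejection model failing this is mis-set

#' Sample a synthetic point cloud
#'
#' Seedable generators for the point-cloud models used throughout the
#' package. Uniform models on manifolds (`sphere`, `torus`, `klein`,
#' `projective`, `henneberg`) draw their parametrisation angles uniformly;
#' `box`, `ball`, `annulus` are uniform on the solid region (rejection
#' sampling for the latter two); `beta`, `normal`, `cauchy` are coordinatewise
#' iid draws; `linkage` samples the configuration space of closed unit
#' pentagonal linkages; `stratified` mixes a plane into a cube; `brownian`
#' returns the partial-sum path of iid standard normal increments; `lorenz`
#' returns one trajectory of the Lorenz system sampled every `dt` time units.
#'
#' @param model one of `r paste0('"', paste(tdanull:::.modelNames, collapse='", "'), '"')`.
#' @param n number of points (>= 1).
#' @param seed integer seed; identical (model, params, n, seed) gives
#'   identical output.
#' @param d intrinsic/ambient dimension for the models that take one
#'   (box, ball, annulus, normal, cauchy, beta, brownian: ambient dimension,
#'   default 2; sphere: sphere dimension, embedded in R^(d+1), default 2).
#'   Fixed-dimension models ignore it.
#' @param params named list of model parameters overriding the defaults:
#'   `beta_a`, `beta_b` (2, 2); torus `R1`, `R2` (2, 1); annulus `r_in`,
#'   `r_out` (1/2, 1); stratified mixture probability `p` (1/2); lorenz
#'   `sigma` (45), `rho` (54), `beta` (10), `dt` (0.1), `method`
#'   ("lsoda", "rk4" or "euler"), `substeps` (internal steps per dt for the
#'   fixed-step methods, 100).
#' @return a [PointCloud-class].
#' @examples
#' pc <- samplePointCloud("torus", 100, seed = 1)
#' range(sqrt((sqrt(rowSums(coords(pc)[, 1:2]^2)) - 2)^2 + coords(pc)[, 3]^2))
#' @export
samplePointCloud <- function(model, n, seed = NULL, d = NULL, params = list()) {
  model <- match.arg(model, .modelNames)
  stopifnot(n >= 1)
  pts <- withSeed(seed, .sampleModel(model, n, d, params))
  new("PointCloud", points = pts$points, model = model,
      params = pts$params, seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

.sampleModel <- function(model, n, d, params) {
  pget <- function(name, default) if (!is.null(params[[name]])) params[[name]] else default
  switch(model,
    box = {
      d <- if (is.null(d)) 2L else as.integer(d)
      list(points = matrix(runif(n * d), n, d), params = list(d = d))
    },
    ball = {
      d <- if (is.null(d)) 2L else as.integer(d)
      list(points = .rejection(n, d, bound = 1,
                               keep = function(x) rowSums(x^2) <= 1),
           params = list(d = d))
    },
    annulus = {
      d <- if (is.null(d)) 2L else as.integer(d)
      rIn <- pget("r_in", 0.5); rOut <- pget("r_out", 1)
      if (!(rIn > 0 && rOut > rIn)) stop("annulus requires 0 < r_in < r_out")
      keep <- function(x) { r2 <- rowSums(x^2); r2 >= rIn^2 & r2 <= rOut^2 }
      list(points = .rejection(n, d, bound = rOut, keep = keep),
           params = list(d = d, r_in = rIn, r_out = rOut))
    },
    sphere = {
      d <- if (is.null(d)) 2L else as.integer(d)
      g <- matrix(rnorm(n * (d + 1)), n, d + 1)
      list(points = g / sqrt(rowSums(g^2)), params = list(d = d))
    },
    beta = {
      d <- if (is.null(d)) 2L else as.integer(d)
      a <- pget("beta_a", 2); b <- pget("beta_b", 2)
      list(points = matrix(rbeta(n * d, a, b), n, d),
           params = list(d = d, beta_a = a, beta_b = b))
    },
    normal = {
      d <- if (is.null(d)) 2L else as.integer(d)
      list(points = matrix(rnorm(n * d), n, d), params = list(d = d))
    },
    cauchy = {
      d <- if (is.null(d)) 2L else as.integer(d)
      list(points = matrix(rcauchy(n * d), n, d), params = list(d = d))
    },
    torus = {
      R1 <- pget("R1", 2); R2 <- pget("R2", 1)
      if (!(R1 > R2 && R2 > 0)) stop("torus requires R1 > R2 > 0")
      list(points = .torusPoint(runif(n, 0, 2 * pi), runif(n, 0, 2 * pi), R1, R2),
           params = list(R1 = R1, R2 = R2))
    },
    klein = {
      list(points = .kleinPoint(runif(n, 0, 2 * pi), runif(n, 0, 2 * pi)),
           params = list())
    },
    projective = {
      g <- matrix(rnorm(n * 3), n, 3)
      g <- g / sqrt(rowSums(g^2))
      list(points = .projectivePoint(g[, 1], g[, 2], g[, 3]), params = list())
    },
    linkage = .sampleLinkage(n),
    henneberg = {
      list(points = .hennebergPoint(runif(n, 0, 2 * pi), runif(n, 0, 2 * pi)),
           params = list())
    },
    stratified = {
      p <- pget("p", 0.5)
      onPlane <- runif(n) < p
      pts <- matrix(runif(n * 3, -1, 1), n, 3)
      pts[onPlane, 3] <- 0
      list(points = pts, params = list(p = p))
    },
    brownian = {
      d <- if (is.null(d)) 2L else as.integer(d)
      z <- matrix(rnorm(n * d), n, d)
      pts <- if (n == 1L) z else apply(z, 2, cumsum)
      list(points = matrix(pts, n, d), params = list(d = d))
    },
    lorenz = .sampleLorenz(n, params)
  )
}

.rejection <- function(n, d, bound, keep) {
  out <- matrix(0, 0, d)
  for (it in seq_len(.rejectionCap)) {
    cand <- matrix(runif(2 * n * d, -bound, bound), ncol = d)
    cand <- cand[keep(cand), , drop = FALSE]
    out <- rbind(out, cand)
    if (nrow(out) >= n) return(out[seq_len(n), , drop = FALSE])
  }
  stop("rejection sampler failed to accept enough points; model mis-parameterised?")
}

# parametrisations, vectorised over the angle arguments
.torusPoint <- function(phi, theta, R1 = 2, R2 = 1) {
  cbind((R1 + R2 * cos(phi)) * cos(theta),
        (R1 + R2 * cos(phi)) * sin(theta),
        R2 * sin(phi))
}

.kleinPoint <- function(phi, theta) {
  cbind((1 + cos(theta)) * cos(phi),
        (1 + cos(theta)) * sin(phi),
        sin(theta) * cos(phi / 2),
        sin(theta) * sin(phi / 2))
}

.projectivePoint <- function(U, V, W) {
  cbind(U * V, U * W, V^2 - W^2, 2 * V * W)
}

.hennebergPoint <- function(phi, theta) {
  cbind(2 * cos(theta) * sinh(phi) - (2 / 3) * cos(3 * theta) * sinh(3 * phi),
        2 * sin(theta) * sinh(phi) + (2 / 3) * sin(3 * theta) * sinh(3 * phi),
        2 * cos(2 * theta) * cosh(2 * phi))
}

# one linkage configuration from its two angles and branch sign
.linkageConfig <- function(phi, theta, S) {
  p5 <- c(cos(phi), sin(phi))
  p3 <- c(1 + cos(theta), sin(theta))
  gap <- sqrt(sum((p3 - p5)^2))
  if (gap > 2) return(NULL)
  q <- (p3 + p5) / 2
  half <- gap / 2
  h <- sqrt(max(0, 1 - half^2)) / half
  v <- c(q[2] - p5[2], p5[1] - q[1])
  p4 <- q + S * h * v
  c(p3, p4, p5)
}

# configuration space of closed pentagonal linkages with unit edges;
# p1=(0,0), p2=(1,0) fixed, the sampled configuration is (p3, p4, p5)
.sampleLinkage <- function(n) {
  out <- matrix(NA_real_, n, 6)
  got <- 0L
  for (it in seq_len(.rejectionCap)) {
    m <- 2L * (n - got)
    phi <- runif(m, 0, 2 * pi); theta <- runif(m, 0, 2 * pi)
    p5 <- cbind(cos(phi), sin(phi))
    p3 <- cbind(1 + cos(theta), sin(theta))
    gap <- sqrt(rowSums((p3 - p5)^2))
    okRows <- which(gap <= 2 & gap > 1e-12)
    if (!length(okRows)) next
    S <- ifelse(runif(length(okRows)) < 0.5, 1, -1)
    q <- (p3[okRows, , drop = FALSE] + p5[okRows, , drop = FALSE]) / 2
    half <- gap[okRows] / 2
    h <- sqrt(pmax(0, 1 - half^2)) / half
    # unit-perpendicular to p3-p5 through the midpoint; orientation fixed so
    # that S=+1 at (phi,theta)=(pi/2,pi/2) drops p4 below the chord
    v <- cbind(q[, 2] - p5[okRows, 2], p5[okRows, 1] - q[, 1])
    p4 <- q + S * h * v
    take <- seq_len(min(length(okRows), n - got))
    rows <- got + take
    out[rows, ] <- cbind(p3[okRows[take], , drop = FALSE],
                         p4[take, , drop = FALSE],
                         p5[okRows[take], , drop = FALSE])
    got <- got + length(take)
    if (got >= n) {
      return(list(points = out,
                  params = list(p1 = c(0, 0), p2 = c(1, 0),
                                layout = c("p3", "p4", "p5"))))
    }
  }
  stop("linkage rejection sampler exceeded its iteration cap")
}

.sampleLorenz <- function(n, params) {
  pget <- function(name, default) if (!is.null(params[[name]])) params[[name]] else default
  sigma <- pget("sigma", 45); rho <- pget("rho", 54); beta <- pget("beta", 10)
  dt <- pget("dt", 0.1)
  method <- pget("method", "lsoda")
  substeps <- pget("substeps", 100L)
  y0 <- runif(3)
  deriv <- function(t, y, p) {
    list(c(p["sigma"] * (y[2] - y[1]),
           y[1] * (p["rho"] - y[3]) - y[2],
           y[1] * y[2] - p["beta"] * y[3]))
  }
  times <- dt * (seq_len(n) - 1)
  p <- c(sigma = sigma, rho = rho, beta = beta)
  sol <- if (method == "lsoda") {
    deSolve::ode(y0, times, deriv, p, method = "lsoda")
  } else {
    # fixed-step integration with `substeps` internal steps per output step
    deSolve::ode(y0, times, deriv, p, method = deSolve::rkMethod(method),
                 hini = dt / substeps)
  }
  pts <- unname(as.matrix(sol[seq_len(n), 2:4, drop = FALSE]))
  if (!all(is.finite(pts)))
    stop("Lorenz integration diverged; use a finer step or the adaptive method")
  list(points = pts, params = list(sigma = sigma, rho = rho, beta = beta,
                                   dt = dt, method = method, y0 = y0))
}

#' Sample a noisy figure-eight (wedge of two circles)
#'
#' Points are drawn uniformly on two unit circles centred at (-1,0) and
#' (1,0), tangent at the origin. Points landing within `W/2` of the origin
#' are discarded and redrawn, opening a "neck" of width `W`, and isotropic
#' Gaussian jitter of scale `noiseSigma` is then added. Exactly `n` points
#' are returned.
#'
#' @param n number of points.
#' @param W neck width, 0 < W < 2.
#' @param noiseSigma jitter standard deviation (default 0.01, about the mean
#'   inter-point spacing at n = 1000).
#' @param seed integer seed.
#' @return a [PointCloud-class] in the plane.
#' @export
sampleEight <- function(n, W = 0.1, noiseSigma = 0.01, seed = NULL) {
  stopifnot(n >= 1, W > 0)
  if (W >= 2) stop("neck width W must be below 2")
  pts <- withSeed(seed, {
    out <- matrix(NA_real_, 0, 2)
    for (it in seq_len(.rejectionCap)) {
      m <- 2L * (n - nrow(out))
      ang <- runif(m, 0, 2 * pi)
      side <- ifelse(runif(m) < 0.5, -1, 1)
      p <- cbind(side + cos(ang), sin(ang))
      p <- p[rowSums(p^2) >= (W / 2)^2, , drop = FALSE]
      out <- rbind(out, p)
      if (nrow(out) >= n) break
    }
    if (nrow(out) < n) stop("eight-shape sampler exceeded its iteration cap")
    out <- out[seq_len(n), , drop = FALSE]
    out + matrix(rnorm(2 * n, 0, noiseSigma), n, 2)
  })
  new("PointCloud", points = pts, model = "eight",
      params = list(W = W, noise_sigma = noiseSigma),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Time-delay embedding of a scalar series
#'
#' Maps a scalar signal to a d-dimensional point cloud with row i =
#' `(V[(i-1)s+1], V[(i-1)s+1+L], ..., V[(i-1)s+1+(d-1)L])` for stride s and
#' lag L.
#'
#' @param series numeric vector of signal samples.
#' @param embedDim embedding dimension d (>= 1).
#' @param stride index stride between consecutive points (default 3).
#' @param lag index lag between consecutive coordinates (default 7).
#' @param n number of points; `NULL` takes the maximum the series allows.
#' @return a [PointCloud-class].
#' @examples
#' coords(delayEmbed(1:6, embedDim = 2, stride = 1, lag = 1, n = 3))
#' @export
delayEmbed <- function(series, embedDim, stride = 3L, lag = 7L, n = NULL) {
  stopifnot(embedDim >= 1, stride >= 1, lag >= 1)
  series <- as.numeric(series)
  if (!all(is.finite(series))) stop("series must be finite")
  len <- length(series)
  span <- (embedDim - 1L) * lag
  nMax <- (len - 1L - span) %/% stride + 1L
  if (nMax < 1L) stop("series too short for the requested embedding")
  if (is.null(n)) n <- nMax
  if (n > nMax) stop(sprintf("series supports at most %d points", nMax))
  starts <- (seq_len(n) - 1L) * stride + 1L
  pts <- vapply(0:(embedDim - 1L), function(k) series[starts + k * lag],
                numeric(n))
  pts <- matrix(pts, nrow = n)
  new("PointCloud", points = pts, model = "delay",
      params = list(embed_dim = embedDim, stride = stride, lag = lag),
      seed = NA_integer_)
}

#' Sample points uniformly from a triangulated surface
#'
#' Triangles are selected with probability proportional to their area and a
#' point is then placed uniformly inside the chosen triangle by barycentric
#' sampling, giving the uniform measure on the surface.
#'
#' @param mesh a mesh as returned by [readMesh()]: a list with `vertices`
#'   (v x 3 matrix) and `faces` (f x 3 integer matrix, 1-based).
#' @param n number of points.
#' @param seed integer seed.
#' @return a [PointCloud-class].
#' @export
sampleMesh <- function(mesh, n, seed = NULL) {
  V <- mesh$vertices; f <- mesh$faces
  stopifnot(is.matrix(V), is.matrix(f), ncol(f) == 3)
  a <- V[f[, 1], , drop = FALSE]
  b <- V[f[, 2], , drop = FALSE]
  c_ <- V[f[, 3], , drop = FALSE]
  cr <- .cross3(b - a, c_ - a)
  areas <- 0.5 * sqrt(rowSums(cr^2))
  if (all(areas <= 0)) stop("mesh has no nondegenerate triangle")
  pts <- withSeed(seed, {
    idx <- sample.int(nrow(f), n, replace = TRUE, prob = areas)
    u <- runif(n); v <- runif(n)
    flip <- u + v > 1
    u[flip] <- 1 - u[flip]; v[flip] <- 1 - v[flip]
    a[idx, , drop = FALSE] +
      u * (b[idx, , drop = FALSE] - a[idx, , drop = FALSE]) +
      v * (c_[idx, , drop = FALSE] - a[idx, , drop = FALSE])
  })
  new("PointCloud", points = pts, model = "mesh",
      params = list(n_faces = nrow(f)),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

.cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}
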