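test_that("parametrisations reproduce hand-computed points", {
  expect_equal(as.numeric(tdanull:::.torusPoint(0, 0)), c(3, 0, 0))
  expect_equal(as.numeric(tdanull:::.kleinPoint(0, 0)), c(2, 0, 0, 0))
  expect_equal(as.numeric(tdanull:::.hennebergPoint(0, 0)), c(0, 0, 2))
  expect_equal(as.numeric(tdanull:::.projectivePoint(0, 0, 1)), c(0, 0, -1, 0))
})

test_that("linkage configuration matches the brute-force circle intersection", {
  cfg <- tdanull:::.linkageConfig(pi / 2, pi / 2, +1)
  p3 <- cfg[1:2]; p4 <- cfg[3:4]; p5 <- cfg[5:6]
  expect_equal(p5, c(0, 1), tolerance = 1e-12)
  expect_equal(p3, c(1, 1), tolerance = 1e-12)
  expect_equal(p4, c(0.5, 1 - sqrt(0.75)), tolerance = 1e-12)
  # brute force: intersect unit circles about p3 and p5 by root finding
  f <- function(t) {
    pt <- c(t[1], t[2])
    c(sum((pt - p3)^2) - 1, sum((pt - p5)^2) - 1)
  }
  expect_equal(f(p4), c(0, 0), tolerance = 1e-10)
  # all five consecutive edges have unit length
  verts <- unname(rbind(c(0, 0), c(1, 0), p3, p4, p5))
  lens <- sqrt(rowSums((verts - verts[c(2:5, 1), ])^2))
  expect_equal(lens, rep(1, 5), tolerance = 1e-10)
})

test_that("samplers are deterministic and respect membership invariants", {
  for (model in c("box", "sphere", "torus", "klein", "linkage", "annulus")) {
    a <- samplePointCloud(model, 50, seed = 7)
    b <- samplePointCloud(model, 50, seed = 7)
    expect_identical(coords(a), coords(b))
  }
  ptsS <- coords(samplePointCloud("sphere", 200, seed = 1))
  expect_equal(sqrt(rowSums(ptsS^2)), rep(1, 200), tolerance = 1e-9)
  ptsT <- coords(samplePointCloud("torus", 200, seed = 2))
  expect_equal((sqrt(ptsT[, 1]^2 + ptsT[, 2]^2) - 2)^2 + ptsT[, 3]^2,
               rep(1, 200), tolerance = 1e-9)
  ptsL <- coords(samplePointCloud("linkage", 200, seed = 3))
  for (i in 1:200) {
    verts <- rbind(c(0, 0), c(1, 0), ptsL[i, 1:2], ptsL[i, 3:4], ptsL[i, 5:6])
    lens <- sqrt(rowSums((verts - verts[c(2:5, 1), ])^2))
    expect_equal(lens, rep(1, 5), tolerance = 1e-9)
  }
  ptsA <- coords(samplePointCloud("annulus", 300, seed = 4))
  r <- sqrt(rowSums(ptsA^2))
  expect_true(all(r >= 0.5 & r <= 1))
})

test_that("distributional sanity holds at 3-sigma for fixed seeds", {
  x <- coords(samplePointCloud("box", 4000, seed = 11))
  se <- sqrt(1 / 12 / 4000)
  expect_true(all(abs(colMeans(x) - 0.5) < 3 * se))
  s <- coords(samplePointCloud("sphere", 4000, seed = 12))
  expect_true(all(abs(colMeans(s)) < 3 / sqrt(3 * 4000) * 3))
  # brownian increments are iid standard normal per coordinate
  w <- coords(samplePointCloud("brownian", 3000, seed = 13, d = 3))
  inc <- diff(w)
  v <- apply(inc, 2, var)
  se_v <- sqrt(2 / (nrow(inc) - 1))
  expect_true(all(abs(v - 1) < 3 * se_v))
  # both linkage branches occur about equally often
  cfg <- coords(samplePointCloud("linkage", 2000, seed = 14))
  p3 <- cfg[, 1:2]; p5 <- cfg[, 5:6]; p4 <- cfg[, 3:4]
  q <- (p3 + p5) / 2
  v <- cbind(q[, 2] - p5[, 2], p5[, 1] - q[, 1])
  side <- sign(rowSums((p4 - q) * v))
  ph <- mean(side > 0)
  expect_lt(abs(ph - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("brownian path is the partial-sum of its increments", {
  w <- coords(samplePointCloud("brownian", 500, seed = 21, d = 2))
  inc <- rbind(w[1, ], diff(w))
  expect_equal(apply(inc, 2, cumsum), w, tolerance = 1e-12)
})

test_that("lorenz trajectories are finite and settle on the attractor set", {
  pc <- samplePointCloud("lorenz", 300, seed = 5)
  expect_true(all(is.finite(coords(pc))))
  expect_equal(nrow(coords(pc)), 300)
  # fixed-step methods with substepping also work
  pc2 <- samplePointCloud("lorenz", 50, seed = 5,
                          params = list(method = "rk4", substeps = 200))
  expect_true(all(is.finite(coords(pc2))))
})

test_that("model parameter validation rejects inconsistent settings", {
  expect_error(samplePointCloud("torus", 10, seed = 1,
                                params = list(R1 = 1, R2 = 2)), "R1 > R2")
  expect_error(samplePointCloud("annulus", 10, seed = 1,
                                params = list(r_in = 2, r_out = 1)), "r_in")
  expect_error(samplePointCloud("nosuchmodel", 10, seed = 1))
})

test_that("eight-shape sampler honours the neck and curve geometry", {
  pc <- sampleEight(500, W = 1e-9, noiseSigma = 0, seed = 1)
  x <- coords(pc)
  dl <- sqrt((x[, 1] + 1)^2 + x[, 2]^2)
  dr <- sqrt((x[, 1] - 1)^2 + x[, 2]^2)
  expect_equal(pmin(abs(dl - 1), abs(dr - 1)), rep(0, 500), tolerance = 1e-12)
  # no point within W/2 of the origin before jitter
  pc2 <- sampleEight(2000, W = 0.4, noiseSigma = 0, seed = 2)
  expect_true(all(rowSums(coords(pc2)^2) >= (0.2)^2 - 1e-12))
  # arc endpoints sit ~ W/2 from the origin; cross-gap spacing ~ W
  r0 <- sqrt(rowSums(coords(pc2)^2))
  expect_lt(min(r0) - 0.2, 0.01)
  upper <- coords(pc2)[coords(pc2)[, 2] > 0, ]
  lower <- coords(pc2)[coords(pc2)[, 2] < 0, ]
  nearU <- upper[which.min(rowSums(upper^2)), ]
  gap <- min(sqrt((lower[, 1] - nearU[1])^2 + (lower[, 2] - nearU[2])^2))
  expect_equal(gap, 0.4, tolerance = 0.06)
  expect_error(sampleEight(10, W = 2), "below 2")
})

test_that("delay embedding follows the index arithmetic", {
  pc <- delayEmbed(1:6, embedDim = 2, stride = 1, lag = 1, n = 3)
  expect_equal(coords(pc), cbind(c(1, 2, 3), c(2, 3, 4)))
  pc1 <- delayEmbed(seq(0, 1, length.out = 20), embedDim = 1, stride = 2, lag = 5)
  expect_equal(ncol(coords(pc1)), 1)
  # max n for length 100, embed 3, stride 3, lag 7: (n-1)*3 + 14 < 100
  pcm <- delayEmbed(rnorm(100), embedDim = 3, stride = 3, lag = 7)
  expect_equal(nrow(coords(pcm)), 29)
  expect_error(delayEmbed(1:10, embedDim = 3, stride = 3, lag = 7), "too short")
})

test_that("mesh sampling is uniform on the surface", {
  tmp <- withr::local_tempfile(fileext = ".off")
  offUnitTriangle(tmp)
  mesh <- readMesh(tmp)
  pts <- coords(sampleMesh(mesh, 400, seed = 1))
  expect_true(all(pts[, 1] >= -1e-12 & pts[, 2] >= -1e-12 &
                  pts[, 1] + pts[, 2] <= 1 + 1e-12))
  expect_equal(pts[, 3], rep(0, 400))
  # two triangles with areas 1 and 3: selection fractions within 3 sigma
  mesh2 <- list(
    vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0),
                     c(10, 0, 0), c(13, 0, 0), c(10, 2, 0)),
    faces = rbind(c(1L, 2L, 3L), c(4L, 5L, 6L)))
  pts2 <- coords(sampleMesh(mesh2, 10000, seed = 2))
  frac <- mean(pts2[, 1] < 5)
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))
  # cube surface: every sample lies on a face
  tmp3 <- withr::local_tempfile(fileext = ".off")
  offUnitCube(tmp3)
  cube <- readMesh(tmp3)
  pts3 <- coords(sampleMesh(cube, 500, seed = 3))
  onFace <- apply(pts3, 1, function(p)
    min(abs(p), abs(p - 1)) < 1e-12 &&
      all(p >= -1e-12) && all(p <= 1 + 1e-12))
  expect_true(all(onFace))
})

test_that("PLY meshes parse to the same sampler input as OFF", {
  tmp <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0",
               "element vertex 3",
               "property float x", "property float y", "property float z",
               "element face 1", "property list uchar int vertex_indices",
               "end_header",
               "0 0 0", "1 0 0", "0 1 0", "3 0 1 2"), tmp)
  mesh <- readMesh(tmp)
  expect_equal(mesh$vertices, rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(mesh$faces, rbind(c(1L, 2L, 3L)))
})

test_that("signal reader handles text and PCM WAV input", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(format(c(0.1, -0.2, 0.3)), tmp)
  expect_equal(readSignal(tmp), c(0.1, -0.2, 0.3))
  wav <- withr::local_tempfile(fileext = ".wav")
  sig <- sin(2 * pi * 440 * (0:999) / 8000) * 0.5
  writeTestWav(wav, sig)
  got <- readSignal(wav)
  expect_equal(length(got), 1000)
  expect_equal(got, sig, tolerance = 1e-3)
  # embedding a read signal works end to end
  pc <- delayEmbed(got, embedDim = 3)
  expect_equal(ncol(coords(pc)), 3)
})

test_that("point-cloud CSV round trip preserves coordinates and provenance", {
  pc <- samplePointCloud("torus", 25, seed = 9)
  tmp <- withr::local_tempfile(fileext = ".csv")
  writePointCloud(pc, tmp)
  back <- readPointCloud(tmp)
  expect_equal(coords(back), coords(pc), tolerance = 1e-12)
  expect_equal(modelName(back), "torus")
  expect_equal(back@seed, 9L)
})
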