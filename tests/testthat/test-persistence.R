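test_that("unit-square corners give the textbook H1 pair under both filtrations", {
  sq <- unitSquare()
  cech <- positivePart(computeDiagram(sq, "cech", maxDegree = 1))
  h1c <- cech[cech$degree == 1, ]
  expect_equal(nrow(h1c), 1)
  expect_equal(h1c$birth, 0.5, tolerance = 1e-12)
  expect_equal(h1c$death, sqrt(2) / 2, tolerance = 1e-12)
  rips <- positivePart(computeDiagram(sq, "rips", maxDegree = 1))
  h1r <- rips[rips$degree == 1, ]
  expect_equal(nrow(h1r), 1)
  expect_equal(h1r$death / h1r$birth, sqrt(2), tolerance = 1e-12)
})

test_that("equilateral triangle has no positive-persistence H1 class", {
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  f <- positivePart(computeDiagram(tri, "rips", maxDegree = 1))
  expect_equal(sum(f$degree == 1), 0)
})

test_that("H0 structure: merge radii and one essential class", {
  two <- matrix(c(0, 0, 2, 0), ncol = 2, byrow = TRUE)
  f <- features(naiveRipsPersistence(dist(two), maxDegree = 0))
  expect_same_diagram(f, data.frame(degree = 0L, birth = c(0, 0),
                                    death = c(1, Inf)))
  set.seed(42)
  x <- matrix(rnorm(20), 10, 2)
  f10 <- features(computeDiagram(x, "rips", maxDegree = 0))
  expect_equal(sum(f10$degree == 0 & is.finite(f10$death)), 9)
  expect_equal(sum(f10$degree == 0 & !is.finite(f10$death)), 1)
})

test_that("engine agrees with the reduction oracle on random clouds", {
  for (s in 1:12) {
    set.seed(s)
    n <- sample(6:22, 1); d <- sample(2:3, 1)
    x <- matrix(runif(n * d), n, d)
    expect_same_diagram(computeDiagram(x, "rips", maxDegree = 1, fullCap = 30),
                        naiveRipsPersistence(dist(x), maxDegree = 1))
  }
  # degree 2 as well
  set.seed(99)
  x <- matrix(runif(12 * 3), 12, 3)
  expect_same_diagram(computeDiagram(x, "rips", maxDegree = 2, fullCap = 30),
                      naiveRipsPersistence(dist(x), maxDegree = 2))
})

test_that("alpha complex and explicit Cech agree on positive persistence", {
  for (s in 1:8) {
    set.seed(100 + s)
    n <- sample(6:25, 1)
    x <- matrix(runif(n * 2), n, 2)
    a <- computeDiagram(x, "cech", maxDegree = 1, backend = "alpha2d")
    b <- computeDiagram(x, "cech", maxDegree = 1, backend = "flag")
    expect_same_diagram(positivePart(a), positivePart(b))
  }
})

test_that("diagrams are equivariant under rescaling", {
  set.seed(5)
  x <- matrix(runif(30), 15, 2)
  for (cc in c(0.01, 100)) {
    for (filt in c("cech", "rips")) {
      f1 <- positivePart(computeDiagram(x, filt, maxDegree = 1))
      f2 <- positivePart(computeDiagram(x * cc, filt, maxDegree = 1))
      expect_equal(f2$birth, f1$birth * cc, tolerance = 1e-9 * cc)
      expect_equal(f2$death[is.finite(f2$death)],
                   f1$death[is.finite(f1$death)] * cc, tolerance = 1e-9 * cc)
    }
  }
})

test_that("threshold truncation is consistent with direct computation", {
  set.seed(8)
  x <- matrix(runif(60), 30, 2)
  full <- computeDiagram(x, "rips", maxDegree = 1, fullCap = 40)
  tau <- 0.2
  direct <- computeDiagram(x, "rips", maxDegree = 1, threshold = tau)
  expect_same_diagram(thresholdDiagram(full, tau), direct)
  # monotonicity: features finished by tau1 persist into the tau2 diagram
  d1 <- features(computeDiagram(x, "rips", maxDegree = 1, threshold = 0.15))
  d2 <- features(computeDiagram(x, "rips", maxDegree = 1, threshold = 0.3))
  fin1 <- d1[is.finite(d1$death), ]
  key <- function(f) sprintf("%d|%.12f|%.12f", f$degree, f$birth, f$death)
  expect_true(all(key(fin1) %in% key(d2[is.finite(d2$death), ])))
})

test_that("distance-matrix input works for Rips and is rejected for Cech", {
  set.seed(3)
  x <- matrix(runif(24), 12, 2)
  viaPoints <- computeDiagram(x, "rips", maxDegree = 1, fullCap = 20)
  viaDist <- computeDiagram(dist(x), "rips", maxDegree = 1, fullCap = 20)
  expect_same_diagram(viaPoints, viaDist)
  expect_error(computeDiagram(dist(x), "cech"), "coordinates")
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(computeDiagram(bad, "rips", input = "distance"), "symmetric")
})

test_that("diagram CSV round trip and malformed-row reporting", {
  feats <- data.frame(degree = c(1L, 1L, 2L), birth = c(0.2, 0.5, 0.3),
                      death = c(0.3, Inf, 0.9))
  dgm <- new("PersistenceDiagram", features = feats, filtration = "cech",
             threshold = 1, nPoints = 10L)
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeDiagram(dgm, tmp)
  back <- readDiagram(tmp)
  expect_same_diagram(back, dgm)
  expect_equal(filtrationType(back), "cech")
  expect_equal(diagramThreshold(back), 1)
  # inf token parses; invalid rows are named
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("degree,birth,death", "1,0.5,inf"), tmp2)
  f2 <- features(readDiagram(tmp2))
  expect_equal(f2$death, Inf)
  writeLines(c("degree,birth,death", "1,2.0,1.0"), tmp2)
  expect_error(readDiagram(tmp2), "row 2")
  writeLines(c("degree,birth,death", "1,0.1,0.2", "1,-1,0.5"), tmp2)
  expect_error(readDiagram(tmp2), "row 3")
})

test_that("noise-candidate selection partitions and filters correctly", {
  feats <- data.frame(degree = c(1L, 1L, 1L, 2L, 1L),
                      birth = c(0.2, 0.4, 0.5, 0.1, 0),
                      death = c(0.3, 0.4, Inf, 0.2, 0.1))
  dgm <- new("PersistenceDiagram", features = feats, filtration = "rips",
             threshold = 1)
  out <- selectNoiseCandidates(dgm, 1)
  expect_equal(out$finite$birth, 0.2)     # zero-persistence + zero-birth dropped
  expect_equal(out$infinite$birth, 0.5)
  out2 <- selectNoiseCandidates(dgm, 2)
  expect_equal(nrow(out2$finite), 1)
  expect_error(selectNoiseCandidates(dgm, 0), "degree-0")
  empty <- new("PersistenceDiagram",
               features = data.frame(degree = integer(), birth = numeric(),
                                     death = numeric()),
               filtration = "rips")
  both <- selectNoiseCandidates(empty, 1)
  expect_equal(nrow(both$finite), 0)
  expect_equal(nrow(both$infinite), 0)
})

test_that("the full-complex guard and validity checks fire", {
  set.seed(1)
  big <- matrix(runif(800), 400, 2)
  expect_error(computeDiagram(big, "rips", threshold = Inf), "too large")
  withInf <- matrix(c(0, 0, 1, Inf), 2, 2)
  expect_error(computeDiagram(withInf, "rips"), "finite")
})
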