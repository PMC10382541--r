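lambda <- 0.57721566490153286061

test_that("p-values follow the closed form and complement the null CDF", {
  expect_equal(pValue(0), exp(-1), tolerance = 1e-15)
  expect_equal(pValue(log(log(20))), 0.05, tolerance = 1e-12)
  xs <- seq(-5, 4, by = 0.25)
  expect_equal(pValue(xs) + plgumbel(xs), rep(1, length(xs)), tolerance = 1e-14)
  # saturation without error
  expect_equal(pValue(1000), 0)
  expect_equal(pValue(-1000), 1)
})

test_that("piMin is coherent with the p-value map and monotone", {
  tp <- new("TransformParams", A = 1, B = 0, Lbar = 0, filtration = "rips")
  for (x in c(0.001, 0.01, 0.2))
    expect_equal(piMin(x, tp), 1 / x, tolerance = 1e-9)
  tr <- ellTransform(c(1.5, 2.5, 4, 8), "cech")
  for (x in c(0.01, 0.1)) {
    pm <- piMin(x, tr$params)
    ell <- tr$params@A * log(log(pm)) + tr$params@B
    expect_equal(pValue(ell), x, tolerance = 1e-9)
  }
  xs <- c(0.01, 0.05, 0.2, 0.5)
  expect_true(all(diff(piMin(xs, tr$params)) < 0))
  expect_error(piMin(1.2, tr$params), "0,1")
})

test_that("infinite-cycle bound matches its defining identities", {
  tp <- new("TransformParams", A = 1, B = 0, Lbar = 0, filtration = "rips")
  # tau/b = piMin(x) gives bound exactly x
  for (x in c(0.001, 0.05)) {
    pm <- piMin(x, tp)
    expect_equal(infinitePBound(b = 1, tau = pm, tp), x, tolerance = 1e-12)
  }
  expect_equal(infinitePBound(b = 1, tau = exp(1), tp), exp(-1),
               tolerance = 1e-12)
  b1 <- infinitePBound(b = 0.3, tau = 1, tp)
  b2 <- infinitePBound(b = 0.3, tau = 2, tp)
  expect_lt(b2, b1)
  expect_error(infinitePBound(b = 1, tau = 0.5, tp), "tau/b")
})

test_that("a single tested feature is never significant", {
  # one finite feature: ell = -lambda, p = exp(-exp(-lambda)) ~ 0.5704
  feats <- data.frame(degree = 1L, birth = 0.1, death = 0.9)
  dgm <- new("PersistenceDiagram", features = feats, filtration = "cech",
             threshold = Inf)
  rep <- signalFeatures(dgm, 1, alpha = 0.05)
  expect_equal(decisions(rep)$p_value, exp(-exp(-lambda)), tolerance = 1e-9)
  expect_false(any(decisions(rep)$significant))
})

test_that("report structure: Bonferroni count includes infinite features", {
  feats <- data.frame(degree = 1L, birth = c(0.1, 0.12, 0.2, 0.05),
                      death = c(0.4, 0.3, Inf, Inf))
  dgm <- new("PersistenceDiagram", features = feats, filtration = "rips",
             threshold = 0.5)
  rep <- signalFeatures(dgm, 1, alpha = 0.05)
  expect_equal(rep@nTested, 4L)
  dec <- decisions(rep)
  expect_equal(sum(dec$bound_only), 2)
  expect_equal(unique(dec$threshold), 0.05 / 4)
  expect_true(all(dec$significant == (dec$p_value < 0.05 / 4)))
  expect_error(signalFeatures(dgm, 1, alpha = 1.2), "alpha")
})

test_that("verdicts survive rescaling of the input cloud", {
  pc <- sampleEight(400, W = 0.3, seed = 5)
  d1 <- computeDiagram(pc, "cech", maxDegree = 1)
  d2 <- computeDiagram(coords(pc) * 50, "cech", maxDegree = 1)
  r1 <- signalFeatures(d1, 1)
  r2 <- signalFeatures(d2, 1)
  expect_equal(decisions(r1)$significant, decisions(r2)$significant)
  expect_equal(decisions(r1)$p_value, decisions(r2)$p_value, tolerance = 1e-9)
})

test_that("threshold search converges on an annulus and matches the full verdict", {
  pc <- samplePointCloud("annulus", 400, seed = 1)
  # reference: a diagram computed past every death (no infinite features)
  ref <- computeDiagram(pc, "rips", maxDegree = 1, threshold = 0.55)
  expect_equal(nrow(selectNoiseCandidates(ref, 1)$infinite), 0)
  full <- signalFeatures(ref, 1, 0.05)
  nSigFull <- sum(decisions(full)$significant)
  tr <- findInfiniteThreshold(pc, 1, "rips", 0.05, tau0 = 0.08)
  expect_true(tr@converged)
  taus <- iterations(tr)$tau
  expect_true(all(diff(taus) > 0))
  expect_equal(sum(tr@verdicts$significant), nSigFull)
})

test_that("trivial search cases terminate in one pass", {
  pc <- samplePointCloud("annulus", 300, seed = 2)
  # tau0 beyond every death: no infinite cycles at all
  tr <- findInfiniteThreshold(pc, 1, "rips", 0.05, tau0 = 0.6)
  expect_equal(nrow(iterations(tr)), 1)
  expect_equal(tr@tauFinal, 0.6)
  expect_equal(nrow(tr@verdicts), 0)
})

test_that("fullReport flags the hole of a noisy circle and stays quiet on noise", {
  hits <- 0L
  for (s in 1:5) {
    pc <- samplePointCloud("annulus", 300, seed = 300 + s,
                           params = list(r_in = 0.8, r_out = 1))
    out <- fullReport(pc, 1, "rips", alpha = 0.05, tau = 0.85)
    hits <- hits + (sum(decisions(out$report)$significant) == 1L)
  }
  expect_gte(hits, 3)
  # pure noise: no significant features for these seeds
  for (s in 1:3) {
    pc <- samplePointCloud("box", 500, seed = 400 + s)
    out <- fullReport(pc, 1, "cech", alpha = 0.05)
    expect_equal(sum(decisions(out$report)$significant), 0)
  }
})
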