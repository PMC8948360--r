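test_that("probability gradients close the normalization and vanish where forced", {
  set.seed(21)
  for (k in 1:10) {
    sc <- refScenario(order = sample(c(1, 1.5, 2, 3), 1), SBR = 4,
                       emitter = runif(2, -45, 45))
    G <- probabilityGradients(sc)
    expect_equal(colSums(G), c(d_dx = 0, d_dy = 0), tolerance = 1e-15)
  }
  # center exposure at the origin: quadratic zero flattens the gradient
  G0 <- probabilityGradients(refScenario(order = 1, SBR = 4))
  expect_equal(G0[4, ], c(d_dx = 0, d_dy = 0), tolerance = 1e-15)
})

test_that("analytic gradients match central finite differences to 1e-6 relative", {
  h <- 0.01
  set.seed(31)
  for (method in c("minflux", "rastmin")) {
    for (c in c(1, 1.5, 2, 3)) {
      rE <- runif(2, -40, 40)
      sc <- refScenario(order = c, method = method, SBR = 4, emitter = rE)
      G <- probabilityGradients(sc)
      mk <- function(r) exposureProbabilities(
        refScenario(order = c, method = method, SBR = 4, emitter = r))
      fd <- cbind((mk(rE + c(h, 0)) - mk(rE - c(h, 0))) / (2 * h),
                  (mk(rE + c(0, h)) - mk(rE - c(0, h))) / (2 * h))
      expect_lt(max(abs(G - fd)) / max(abs(fd)), 1e-6)
    }
  }
})

test_that("Fisher information is linear in N, symmetric, and isotropic at the center", {
  sc <- refScenario(order = 2, SBR = 4, emitter = c(17, -9))
  F1 <- fisherInformation(sc)
  sc2 <- sc; sc2@N <- 1000
  expect_equal(fisherInformation(sc2), 2 * F1, tolerance = 1e-12)
  expect_equal(F1[1, 2], F1[2, 1])
  ev <- eigen(F1, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  F0 <- fisherInformation(refScenario(order = 1, SBR = 4))
  expect_equal(F0[1, 1], F0[2, 2], tolerance = 1e-12)
  expect_equal(F0[1, 2], 0, tolerance = 1e-15 * F0[1, 1])
})

test_that("analytic Fisher information matches the score-sampling estimate", {
  # empirical information = covariance of the score over multinomial draws
  sc <- refScenario(order = 1, SBR = 4, emitter = c(15, 10))
  Fa <- fisherInformation(sc)
  p <- exposureProbabilities(sc)
  G <- probabilityGradients(sc)          # score of one photon: sum n_i d log p_i
  dlogp <- G / p
  set.seed(77)
  n <- stats::rmultinom(1e5, 500, p)     # 1e5 seeded draws
  scores <- t(n) %*% dlogp
  Fhat <- crossprod(scores) / ncol(n)    # score has zero mean
  expect_equal(Fhat[1, 1] / Fa[1, 1], 1, tolerance = 0.02)
  expect_equal(Fhat[2, 2] / Fa[2, 2], 1, tolerance = 0.02)
  expect_lt(abs(Fhat[1, 2] - Fa[1, 2]), 0.02 * sqrt(Fa[1, 1] * Fa[2, 2]))
})

test_that("sigma_CRB obeys the exact 1/sqrt(N) law and is positive", {
  set.seed(41)
  for (c in c(1, 2, 3)) {
    for (k in 1:5) {
      rE <- runif(2, -45, 45)
      sc <- refScenario(order = c, SBR = 4, emitter = rE)
      s1 <- crbSigma(sc)
      sc4 <- sc; sc4@N <- 2000
      expect_gt(s1, 0)
      expect_equal(crbSigma(sc4), s1 / 2, tolerance = 1e-12)
    }
  }
})

test_that("sigma_CRB is non-increasing in SBR at fixed position", {
  for (rE in list(c(0, 0), c(20, 10), c(-30, 35))) {
    s <- sapply(c(0.5, 1, 2, 4, 10, 100, 1e4),
                function(b) crbSigma(refScenario(order = 2, SBR = b,
                                                  emitter = rE)))
    expect_true(all(diff(s) <= 1e-12))
  }
})

test_that("probability concentrated on one exposure raises a singular-model error", {
  # extreme order without background: one exposure absorbs (numerically)
  # all probability mass, leaving a rank-deficient information matrix
  deg <- makeScenario(refBeam(), minfluxSequence(100), order = 300,
                      N = 500, SBR = Inf, emitterPosition = c(30, 17))
  expect_gt(max(exposureProbabilities(deg)), 1 - 1e-12)
  expect_error(crbSigma(deg), "singular")
})

test_that("precision maps are positive, finite, deterministic, and carry the pattern symmetry", {
  scMF <- refScenario(order = 2, SBR = 4)
  map <- precisionMap(scMF, 21)
  v <- sigmaValues(map)
  expect_true(all(is.finite(v)) && all(v > 0))
  expect_identical(sigmaValues(precisionMap(scMF, 21)), v)
  # minflux: sigma field invariant under 120-degree rotation of the probe
  set.seed(51)
  for (k in 1:10) {
    rE <- runif(2, -35, 35)
    s0 <- crbSigma(refScenario(order = 2, SBR = 4, emitter = rE))
    s1 <- crbSigma(refScenario(order = 2, SBR = 4, emitter = rotate2(rE, 120)))
    expect_equal(s1 / s0, 1, tolerance = 1e-6)
  }
  # rastmin: map matrix invariant under 90-degree grid rotation
  mapRM <- precisionMap(refScenario(order = 2, method = "rastmin", SBR = 4), 21)
  vr <- sigmaValues(mapRM)
  rot90 <- t(vr)[, rev(seq_len(ncol(vr)))]
  expect_equal(rot90, vr, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("map summary reports center, spread and dynamic range consistently", {
  map <- precisionMap(refScenario(order = 1, SBR = 4), 21)
  s <- mapSummary(map)
  expect_equal(s$center, crbSigma(refScenario(order = 1, SBR = 4)),
               tolerance = 1e-12)
  expect_lt(s$min, s$mean)
  expect_lt(s$mean, s$max)
  expect_equal(s$dynamicRange, s$max / s$center)
  expect_equal(s$cv, sd(sigmaValues(map)) / mean(sigmaValues(map)))
})

test_that("superlinear excitation widens the map's center-to-edge dynamic range", {
  # the model's expression of precision heterogeneity: the two-photon
  # minflux map spans a larger max/center range than the one-photon map,
  # and the raster scheme stays closer to homogeneous (same beam, L, N, SBR)
  dr <- function(order, method) mapSummary(precisionMap(
    refScenario(order = order, method = method, SBR = 4), 41))$dynamicRange
  expect_gt(dr(2, "minflux"), dr(1, "minflux"))
  expect_gt(dr(2, "minflux"), dr(2, "rastmin"))
})

test_that("center improvement ratio equals the order ratio without background", {
  sc <- refScenario(order = 1, SBR = 4)
  expect_identical(centerImprovementRatio(sc, 1, 1), 1)
  expect_equal(centerImprovementRatio(sc, 1, 2), 2, tolerance = 1e-3)
  # small-L limit: ratio -> c for L/R -> 0 (within 1% at L/R < 0.1)
  scSmall <- makeScenario(refBeam(), minfluxSequence(20), N = 500, SBR = 4)
  expect_equal(centerImprovementRatio(scSmall, 1, 3), 3, tolerance = 0.01)
})

test_that("photon equivalence is the inverse square of the improvement ratio", {
  sc <- refScenario(order = 1, SBR = 4)
  expect_identical(photonEquivalence(sc, 2, 2), 1)
  expect_equal(photonEquivalence(sc, 1, 2), 0.25, tolerance = 1e-3)
  scSmall <- makeScenario(refBeam(), minfluxSequence(20), N = 500, SBR = 4)
  expect_equal(photonEquivalence(scSmall, 1, 3), 1 / 9, tolerance = 0.02)
})
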