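test_that("center-emitter probabilities: symmetry at infinite SBR, mixing at SBR 4", {
  scInf <- refScenario(order = 1, SBR = Inf)
  expect_equal(exposureProbabilities(scInf), c(1/3, 1/3, 1/3, 0),
               tolerance = 1e-14)
  for (c in c(1, 2, 3))    # holds for any order by symmetry
    expect_equal(exposureProbabilities(refScenario(order = c, SBR = Inf)),
                 c(1/3, 1/3, 1/3, 0), tolerance = 1e-14)
  # direct evaluation of the mixing formula: p4 = 0 * 4/5 + 1/(4*5)
  sc4 <- refScenario(order = 1, SBR = 4)
  p <- exposureProbabilities(sc4)
  expect_equal(p[4], 0.05)
  expect_equal(p[1:3], rep(0.8 / 3 + 0.05, 3))
})

test_that("probabilities are conserved and nonnegative across random scenarios", {
  set.seed(11)
  for (k in 1:40) {
    sc <- refScenario(
      order = sample(c(1, 1.5, 2, 3), 1),
      method = sample(c("minflux", "rastmin"), 1),
      SBR = exp(runif(1, log(0.1), log(100))),
      wavelength = runif(1, 500, 1400),
      emitter = runif(2, -60, 60))
    p <- exposureProbabilities(sc)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
})

test_that("background limits: pure signal as SBR grows, uniform as SBR vanishes", {
  rE <- c(12, -7)
  scInf <- refScenario(order = 2, SBR = Inf, emitter = rE)
  pSig <- exposureProbabilities(scInf)
  scBig <- refScenario(order = 2, SBR = 1e9, emitter = rE)
  expect_equal(exposureProbabilities(scBig), pSig, tolerance = 1e-8)
  scTiny <- refScenario(order = 2, SBR = 1e-9, emitter = rE)
  expect_equal(exposureProbabilities(scTiny), rep(0.25, 4), tolerance = 1e-8)
})

test_that("higher order drains probability from the exposure nearest the emitter", {
  rE <- c(5, 45)  # close to the first triangle vertex (0, 50)
  pNear <- sapply(c(1, 1.5, 2, 2.5, 3),
                  function(c) exposureProbabilities(
                    refScenario(order = c, SBR = Inf, emitter = rE))[1])
  expect_true(all(diff(pNear) <= 1e-12))
})

test_that("expected counts scale linearly with the photon budget and sum to N", {
  sc <- refScenario(order = 1, SBR = 4, emitter = c(10, 20))
  lam <- expectedCounts(sc)
  expect_equal(sum(lam), 500)
  sc2 <- sc; sc2@N <- 1000
  expect_equal(expectedCounts(sc2), 2 * lam)
  expect_error(makeScenario(refBeam(), minfluxSequence(100), N = 0), "N")
  scc <- refScenario(order = 1, SBR = Inf)
  expect_equal(expectedCounts(scc), c(500/3, 500/3, 500/3, 0))
})

test_that("multinomial sampling: support, degenerate case, reproducibility, validation", {
  r <- sampleCounts(c(1, 0, 0, 0), 500, seed = 3)
  expect_equal(photonCounts(r), c(500, 0, 0, 0))
  p <- c(0.4, 0.3, 0.2, 0.1)
  a <- sampleCounts(p, 500, seed = 99)
  expect_equal(sum(photonCounts(a)), 500)
  expect_identical(photonCounts(sampleCounts(p, 500, seed = 99)),
                   photonCounts(a))
  expect_false(identical(photonCounts(sampleCounts(p, 500, seed = 100)),
                         photonCounts(a)))
  expect_error(sampleCounts(c(0.5, 0.4), 500, seed = 1), "sum to 1")
  expect_error(sampleCounts(p, 0, seed = 1), "N")
})

test_that("seeded sample means match the multinomial moments within 3 SE", {
  p <- exposureProbabilities(refScenario(order = 1, SBR = Inf))
  N <- 500
  draws <- 1e4
  counts <- matrix(0, draws, 4)
  for (j in seq_len(draws))
    counts[j, ] <- photonCounts(sampleCounts(p, N, seed = 5000 + j))
  se <- sqrt(N * p * (1 - p) / draws)
  dev <- abs(colMeans(counts) - N * p)
  expect_true(all(dev <= pmax(3 * se, 1e-9)))
})

test_that("fixture generation is reproducible and matches the forward model", {
  cfg <- makeRunConfig("minflux", L = 100, N = 500, SBR = 4, order = 1,
                       wavelength = 647, seed = 17)
  one <- generateFixtureDataset(cfg, c(10, -5), repeats = 1)
  expect_equal(nrow(one), 1L)
  expect_equal(sum(one[paste0("n_", 1:4)]), 500)
  expect_identical(generateFixtureDataset(cfg, c(10, -5), repeats = 1), one)

  ax <- c(-30, 0, 30)
  grid9 <- cbind(rep(ax, 3), rep(ax, each = 3))
  tab <- generateFixtureDataset(cfg, grid9, repeats = 100)
  expect_equal(nrow(tab), 900L)
  expect_equal(names(tab)[1:3], c("true_x_nm", "true_y_nm", "repeat"))
  expect_true(all(rowSums(tab[paste0("n_", 1:4)]) == 500))
  # per-position empirical means vs N p within 3 SE (Monte-Carlo check)
  for (i in seq_len(9)) {
    sub <- tab[tab$true_x_nm == grid9[i, 1] & tab$true_y_nm == grid9[i, 2], ]
    p <- exposureProbabilities(refScenario(order = 1, SBR = 4,
                                            emitter = grid9[i, ]))
    se <- sqrt(500 * p * (1 - p) / 100)
    dev <- abs(colMeans(sub[paste0("n_", 1:4)]) - 500 * p)
    expect_true(all(dev <= 3 * se))
  }
})
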