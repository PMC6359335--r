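test_that("boost threshold arithmetic matches hand-computed values", {
  # dihedral-only boost of a 19-residue peptide in water:
  # E = 210 + 3.5*19 = 276.5, alpha = 3.5*19/5 = 13.3
  p <- computeBoostParameters(a1 = 3.5, a2 = 3.5, nRes = 19,
                              vAvgDihed = 210, mode = "iamd2_dihedral")
  expect_equal(p@eDihed, 276.5)
  expect_equal(p@alphaDihed, 13.3)
  expect_true(is.na(p@eTotal))
  # dual boost adds the total-potential channel
  p3 <- computeBoostParameters(a1 = 3.5, a2 = 3.5, b1 = 0.30, b2 = 0.30,
                               nRes = 19, nAtoms = 8243,
                               vAvgDihed = 210, vAvgTotal = -25429,
                               mode = "iamd3_dual")
  expect_equal(p3@eTotal, -25429 + 0.30 * 8243)
  expect_equal(p3@alphaTotal, 0.30 * 8243)
  expect_error(computeBoostParameters(a1 = 0, a2 = 0, nRes = 19,
                                      vAvgDihed = 210,
                                      mode = "iamd2_dihedral"),
               "alpha")
})

test_that("boost energy matches the closed form on a dense grid", {
  E <- 276.5; alpha <- 13.3
  V <- seq(E - 200, E + 50, length.out = 1e4)
  # independently written reference expression
  ref <- ifelse(V >= E, 0, (E - V) * (E - V) / (alpha + (E - V)))
  expect_lt(max(abs(boostEnergy(V, E, alpha) - ref)), 1e-12)
  expect_identical(boostEnergy(E, E, alpha), 0)
  expect_equal(boostEnergy(E - alpha, E, alpha), alpha / 2)
  # non-negative everywhere, zero iff V >= E, decreasing below E
  dv <- boostEnergy(V, E, alpha)
  expect_true(all(dv >= 0))
  expect_true(all((dv == 0) == (V >= E)))
  below <- dv[V < E]
  expect_true(all(diff(below) < 0))
  expect_error(boostEnergy(0, 1, 0), "alpha")
})

test_that("weight estimators behave as specified", {
  # zero boost: every estimator yields unit weights
  for (est in c("exponential", "maclaurin", "cumulant2")) {
    w <- computeWeights(rep(0, 5), estimator = est)
    expect_identical(frameWeights(w), rep(1, 5))
  }
  # Maclaurin order 10 approximates the exponential to 1e-6 relative at
  # dV/kBT = 0.5
  dv <- 0.5 * kBT()
  wm <- frameWeights(computeWeights(dv, estimator = "maclaurin", k = 10))
  we <- frameWeights(computeWeights(dv, estimator = "exponential"))
  expect_lt(abs(wm - we) / we, 1e-6)
  # single frame at dV = kBT: exponential weight is e
  expect_equal(frameWeights(computeWeights(kBT(),
                                           estimator = "exponential")),
               exp(1))
  # monotone approach to the exponential as k grows
  dv <- c(0.3, 0.8, 1) * kBT()
  err <- vapply(1:10, function(k)
    max(abs(frameWeights(computeWeights(dv, estimator = "maclaurin",
                                        k = k)) -
            frameWeights(computeWeights(dv, estimator = "exponential")))),
    0)
  expect_true(all(diff(err) < 0))
  expect_error(computeWeights(c(0.1, -0.2)), "negative|corrupt")
  expect_error(computeWeights(1, estimator = "maclaurin", k = 0), "k")
})

test_that("reweighted histograms satisfy the PMF-grid contract", {
  # two equally populated bins under uniform weights: PMF (0, 0)
  x <- c(rep(0.25, 10), rep(0.75, 10))
  g <- reweightHistogram(x, breaks = c(0, 0.5, 1))
  expect_equal(as.numeric(pmfValues(g)), c(0, 0))
  expect_equal(sum(binProbabilities(g)[g@mask]), 1)
  # empty bins masked NA, populated minimum anchored at 0
  g2 <- reweightHistogram(c(0.1, 0.1, 0.9), breaks = c(0, 0.25, 0.5, 1))
  expect_true(is.na(pmfValues(g2)[2]))
  expect_equal(min(pmfValues(g2), na.rm = TRUE), 0)
  expect_error(
    reweightHistogram(x, new("FrameWeights", estimator = "exponential",
                             order = NA_integer_, weights = rep(0, 20),
                             dVkT = rep(0, 20))),
    "all-zero")
})

test_that("zero-boost reweighting reproduces the raw histogram bit-for-bit", {
  pot <- doubleWellPotential(depths = c(2, 1.5))
  run <- sampleBiased(pot, 2e4, seed = 13)
  xy <- cbind(phiAngles(run$series)[, 1], psiAngles(run$series)[, 1])
  for (est in c("exponential", "maclaurin", "cumulant2")) {
    w <- computeWeights(run$log, estimator = est)
    g <- reweightHistogram(xy, w, breaks = 36L, angular = TRUE)
    raw <- reweightHistogram(xy, NULL, breaks = 36L, angular = TRUE)
    expect_identical(pmfValues(g), pmfValues(raw))
  }
})

test_that("reweighting is invariant to a positive rescaling of the weights", {
  set.seed(17)
  x <- runif(500)
  w <- computeWeights(runif(500, 0, 1), estimator = "exponential")
  ws <- new("FrameWeights", estimator = "exponential",
            order = NA_integer_, weights = frameWeights(w) * 17.3,
            dVkT = w@dVkT)
  g1 <- reweightHistogram(x, w, breaks = 20)
  g2 <- reweightHistogram(x, ws, breaks = 20)
  expect_equal(pmfValues(g1), pmfValues(g2))
})

test_that("all three estimators recover the analytic PMF from a boosted run", {
  pot <- doubleWellPotential()
  run <- sampleBiased(pot, 2e5, seed = 19, boost = list(E = 0.5, alpha = 3))
  xy <- cbind(phiAngles(run$series)[, 1], psiAngles(run$series)[, 1])
  ana <- analyticPmf(pot)
  for (est in c("maclaurin", "exponential", "cumulant2")) {
    w <- computeWeights(run$log, estimator = est, k = 10)
    g <- reweightHistogram(xy, w, breaks = 72L, angular = TRUE)
    sel <- g@mask & ana < 4
    expect_lte(mean(abs(pmfValues(g)[sel] - ana[sel])), 0.3)
  }
})

test_that("effective boost follows the mode of the run", {
  log3 <- new("BoostLog", dVDihed = c(1, 2), dVTotal = c(0.5, 0.5),
              mode = "iamd3_dual")
  expect_equal(effectiveBoost(log3), c(1.5, 2.5))
  log2 <- new("BoostLog", dVDihed = c(1, 2), dVTotal = c(0.5, 0.5),
              mode = "iamd2_dihedral")
  expect_equal(effectiveBoost(log2), c(1, 2))
  log1 <- new("BoostLog", dVDihed = c(1, 2), dVTotal = c(0.5, 0.5),
              mode = "iamd1_total")
  expect_equal(effectiveBoost(log1), c(0.5, 0.5))
})
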