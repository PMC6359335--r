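test_that("sampler is deterministic given a seed", {
  pot <- doubleWellPotential(depths = c(2, 1.5))
  a <- sampleBiased(pot, 5000, seed = 42)
  b <- sampleBiased(pot, 5000, seed = 42)
  expect_identical(phiAngles(a$series), phiAngles(b$series))
  expect_identical(a$log@dVDihed, b$log@dVDihed)
  reps <- makeReplicas(pot, 2, seeds = c(7, 7), overlapMode = "same_basin",
                       nSteps = 2000)
  expect_identical(phiAngles(reps[[1]]), phiAngles(reps[[2]]))
})

test_that("single-basin sampling centers on the well", {
  pot <- gaussianBasinPotential(c(-63, -43), depths = 6, widths = 20)
  run <- sampleBiased(pot, 5e4, seed = 11)
  phi <- phiAngles(run$series)[, 1]
  psi <- psiAngles(run$series)[, 1]
  # symmetric well: mean within 2 standard errors (batch means for the
  # correlated chain)
  for (v in list(list(x = phi, c = -63), list(x = psi, c = -43))) {
    bm <- tapply(v$x, rep(1:50, each = length(v$x) / 50), mean)
    se <- sd(bm) / sqrt(50)
    expect_lt(abs(mean(v$x) - v$c), 2 * se)
  }
  expect_true(all(effectiveBoost(run$log) == 0))
})

test_that("unbiased well occupancy matches the Boltzmann quadrature oracle", {
  pot <- doubleWellPotential(depths = c(2, 1.5))
  run <- sampleBiased(pot, 5e5, seed = 1)
  phi <- phiAngles(run$series)[, 1]
  psi <- psiAngles(run$series)[, 1]
  lab <- basinLabel(phi, psi, pot@centers)
  f1 <- mean(lab == 1)
  f1star <- quadratureOccupancy(pot)[1]
  bm <- tapply(lab == 1, rep(1:100, each = length(lab) / 100), mean)
  se <- sd(bm) / sqrt(100)
  expect_lt(abs(f1 - f1star), 3 * se)
})

test_that("boost is always positive above-threshold and accelerates barrier crossing", {
  pot <- doubleWellPotential()          # depths 4, 3
  unb <- sampleBiased(pot, 2e5, seed = 3)
  boo <- sampleBiased(pot, 2e5, seed = 3, boost = list(E = 0.5, alpha = 3))
  expect_true(all(effectiveBoost(boo$log) > 0))
  crossings <- function(run) {
    lab <- basinLabel(phiAngles(run$series)[, 1],
                      psiAngles(run$series)[, 1], pot@centers)
    sum(diff(lab) != 0)
  }
  expect_gte(crossings(boo), crossings(unb))
})

test_that("empirical unbiased PMF converges to the analytic surface", {
  pot <- doubleWellPotential(depths = c(2, 1.5))
  run <- sampleBiased(pot, 1e6, seed = 7)
  g <- reweightHistogram(cbind(phiAngles(run$series)[, 1],
                               psiAngles(run$series)[, 1]),
                         NULL, breaks = 72L, angular = TRUE)
  ana <- analyticPmf(pot)
  sel <- g@mask & ana < 4
  expect_lte(mean(abs(pmfValues(g)[sel] - ana[sel])), 0.25)
})

test_that("sampler rejects invalid configurations", {
  pot <- doubleWellPotential()
  expect_error(sampleBiased(pot, 100, temperature = -1), "temperature")
  expect_error(sampleBiased(pot, 100, boost = list(E = 0, alpha = 0)),
               "alpha")
  expect_error(makeReplicas(pot, 3, seeds = c(1, 2)), "seeds")
  expect_error(makeReplicas(gaussianBasinPotential(c(0, 0), 10, 30), 2,
                            seeds = c(1, 2),
                            overlapMode = "disjoint_basins"),
               "multi-well")
})

test_that("toy chain round-trips its dihedrals to 1e-6 degrees", {
  phi <- matrix(rep(-63, 18), 1)
  psi <- matrix(rep(-43, 18), 1)
  tc <- buildToyChain(phi, psi)
  dh <- computeDihedrals(tc)
  expect_equal(phiAngles(dh)[1, -1], phi[1, -1], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(psiAngles(dh)[1, -18], psi[1, -18], tolerance = 1e-6,
               ignore_attr = TRUE)
  # general multi-frame random dihedrals
  set.seed(5)
  phi <- matrix(runif(3 * 6, -170, 170), 3, 6)
  psi <- matrix(runif(3 * 6, -170, 170), 3, 6)
  dh2 <- computeDihedrals(buildToyChain(phi, psi))
  expect_equal(phiAngles(dh2)[, -1], phi[, -1], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(psiAngles(dh2)[, -6], psi[, -6], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("chain ends have undefined angles and correct atom sets", {
  tc <- buildToyChain(-60, -40, nRes = 2)
  atoms <- atomInfo(tc)
  expect_identical(sort(atoms$elety[atoms$resid == 1]),
                   sort(c("N", "CA", "C", "O")))
  expect_identical(sort(atoms$elety[atoms$resid == 2]),
                   sort(c("N", "H", "CA", "C", "O")))
  dh <- computeDihedrals(tc)
  expect_true(is.na(phiAngles(dh)[1, 1]))
  expect_true(is.na(psiAngles(dh)[1, 2]))
  expect_false(is.na(psiAngles(dh)[1, 1]))
  expect_error(buildToyChain(-60, -40, nRes = 1), "at least 2")
})

test_that("helical chains are more compact than extended ones", {
  helix <- buildToyChain(-63, -43, nRes = 18)
  ext <- buildToyChain(-157, 161, nRes = 18)
  expect_lt(endToEnd(helix)$distances, endToEnd(ext)$distances)
})

test_that("disjoint-basin replicas stay in their own wells", {
  pot <- doubleWellPotential(depths = c(10, 10))
  reps <- makeReplicas(pot, 2, seeds = c(1, 2),
                       overlapMode = "disjoint_basins", nSteps = 1e5)
  # replica 2 started in basin 2 must never come within 30 deg of basin 1
  d <- sqrt(wrapAngle(phiAngles(reps[[2]])[, 1] - pot@centers[1, 1])^2 +
            wrapAngle(psiAngles(reps[[2]])[, 1] - pot@centers[1, 2])^2)
  expect_identical(sum(d < 30), 0L)
})
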