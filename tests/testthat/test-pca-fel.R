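test_that("dPCA matches a brute-force covariance eigendecomposition", {
  set.seed(53)
  nF <- 8; nR <- 3
  phi <- matrix(wrapAngle(rnorm(nF * nR, -63, 40)), nF, nR)
  psi <- matrix(wrapAngle(rnorm(nF * nR, -43, 40)), nF, nR)
  ds <- new("DihedralSeries", phi = phi, psi = psi,
            segments = rep(1L, nF))
  m <- dpca(ds)
  rad <- pi / 180
  X <- do.call(cbind, lapply(seq_len(nR), function(r)
    cbind(cos(phi[, r] * rad), sin(phi[, r] * rad),
          cos(psi[, r] * rad), sin(psi[, r] * rad))))
  ref <- bruteForceEigen(X)
  expect_lt(max(abs(eigenValues(m) - pmax(ref$values, 0))), 1e-8)
  # eigenpairs satisfy S v = lambda v
  S <- cov(X)
  for (j in 1:3)
    expect_lt(max(abs(S %*% m@vectors[, j] -
                      eigenValues(m)[j] * m@vectors[, j])), 1e-8)
  expect_equal(sum(varianceFractions(m)), 1)
  # covariance of projections is diagonal with the eigenvalues
  cp <- cov(projections(m))
  expect_lt(max(abs(cp - diag(eigenValues(m)))), 1e-8)
})

test_that("dPCA separates a two-state trajectory on PC1", {
  nF <- 200
  state <- rep(c(1, 2), nF / 2)
  phi <- cbind(ifelse(state == 1, -63, -157),
               ifelse(state == 1, -65, -150))
  psi <- cbind(ifelse(state == 1, -43, 161),
               ifelse(state == 1, -40, 150))
  ds <- new("DihedralSeries", phi = phi, psi = psi,
            segments = rep(1L, nF))
  m <- dpca(ds)
  # exactly two distinct frames: all variance on PC1
  expect_gt(varianceFractions(m)[1], 1 - 1e-9)
  p1 <- projections(m)[, 1]
  expect_gt(min(abs(tapply(p1, state, mean))), 0.1)
  expect_true(all(sign(p1[state == 1]) != sign(p1[state == 2])))
})

test_that("duplicated frames project identically and ordering is immaterial", {
  set.seed(59)
  nF <- 6
  phi <- matrix(wrapAngle(rnorm(nF * 2, 0, 50)), nF, 2)
  psi <- matrix(wrapAngle(rnorm(nF * 2, 0, 50)), nF, 2)
  ds <- new("DihedralSeries", phi = rbind(phi, phi), psi = rbind(psi, psi),
            segments = rep(1L, 2 * nF))
  m <- dpca(ds)
  expect_equal(projections(m)[1:nF, ], projections(m)[nF + 1:nF, ])
  expect_error(dpca(new("DihedralSeries", phi = matrix(-63, 5, 2),
                        psi = matrix(-43, 5, 2),
                        segments = rep(1L, 5))), "constant")
})

test_that("Kabsch superposition equals the quaternion oracle", {
  set.seed(61)
  for (i in 1:6) {
    P <- matrix(rnorm(15), 5, 3)
    Q <- matrix(rnorm(15), 5, 3)
    expect_lt(abs(kabschFit(P, Q)$rmsd - hornRmsd(P, Q)), 1e-9)
  }
  expect_error(kabschFit(matrix(0, 2, 3), matrix(0, 2, 3)), "3 atoms")
})

test_that("cPCA removes rigid-body motion completely", {
  set.seed(67)
  base <- buildToyChain(-63, -43, nRes = 5)
  xyz0 <- matrix(coords(base)[1, , ], ncol = 3)
  nF <- 10
  arr <- array(NA_real_, c(nF, nrow(xyz0), 3))
  for (f in seq_len(nF)) {
    th <- runif(2, 0, 2 * pi)
    Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]),
                   0, sin(th[1]), cos(th[1])), 3, byrow = TRUE)
    Rz <- matrix(c(cos(th[2]), -sin(th[2]), 0,
                   sin(th[2]), cos(th[2]), 0, 0, 0, 1), 3, byrow = TRUE)
    arr[f, , ] <- sweep(xyz0 %*% t(Rx %*% Rz), 2, runif(3, -5, 5), "+")
  }
  traj <- new("TrajectorySet", coords = arr, atoms = atomInfo(base),
              segments = rep(1L, nF))
  m <- cpca(traj)
  expect_lt(max(eigenValues(m)), 1e-10)
})

test_that("cPCA is invariant to a global rotation of every frame", {
  tc <- wobbleChain(-63, -43, nRes = 4, nF = 12, sdDeg = 10, seed = 71)
  m1 <- cpca(tc)
  th <- 0.7
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, byrow = TRUE)
  rot <- tc@coords
  for (f in seq_len(nFrames(tc)))
    rot[f, , ] <- matrix(tc@coords[f, , ], ncol = 3) %*% t(Rz) + 3
  m2 <- cpca(new("TrajectorySet", coords = rot, atoms = atomInfo(tc),
                 segments = segments(tc)))
  expect_equal(eigenValues(m1), eigenValues(m2), tolerance = 1e-8)
  expect_equal(abs(projections(m1)[, 1]), abs(projections(m2)[, 1]),
               tolerance = 1e-6)
})

test_that("cPCA captures a two-conformer split on PC1", {
  a <- buildToyChain(-63, -43, nRes = 4)
  b <- buildToyChain(-157, 161, nRes = 4)
  arr <- array(NA_real_, c(10, nrow(atomInfo(a)), 3))
  for (f in 1:10) arr[f, , ] <- if (f %% 2) coords(a)[1, , ]
                                else coords(b)[1, , ]
  traj <- new("TrajectorySet", coords = arr, atoms = atomInfo(a),
              segments = rep(1L, 10))
  m <- cpca(traj)
  # two distinct conformers: a single mode carries all variance
  expect_gt(varianceFractions(m)[1], 1 - 1e-9)
})

test_that("a Gaussian landscape gives a harmonic PMF with curvature kBT/lambda", {
  set.seed(73)
  proj <- cbind(rnorm(5e4, 0, 2), rnorm(5e4, 0, 1))
  m <- new("PCModel", kind = "cartesian", center = c(0, 0),
           vectors = diag(2), values = c(4, 1), varFrac = c(0.8, 0.2),
           projections = proj, segments = rep(1L, 5e4))
  g <- fel(m, bins = 40)
  expect_equal(min(pmfValues(g), na.rm = TRUE), 0)
  cen <- axisCenters(g)
  row0 <- which.min(abs(cen[[2]]))
  prof <- pmfValues(g)[, row0]
  sel <- is.finite(prof) & abs(cen[[1]]) < 4
  quad <- coef(lm(prof[sel] ~ I(cen[[1]][sel]^2)))[2]
  expect_equal(as.numeric(quad), kBT() / (2 * 4), tolerance = 0.1)
})

test_that("a two-basin landscape shows two minima split by kBT*log occupancy", {
  set.seed(79)
  n1 <- 30000; n2 <- 10000
  proj <- rbind(cbind(rnorm(n1, -2, 0.4), rnorm(n1, 0, 0.4)),
                cbind(rnorm(n2, 2, 0.4), rnorm(n2, 0, 0.4)))
  m <- new("PCModel", kind = "cartesian", center = c(0, 0),
           vectors = diag(2), values = c(2, 1), varFrac = c(2, 1) / 3,
           projections = proj, segments = rep(1L, n1 + n2))
  g <- fel(m, bins = 40)
  z <- pmfValues(g); cen <- axisCenters(g)
  left <- min(z[cen[[1]] < 0, ], na.rm = TRUE)
  right <- min(z[cen[[1]] > 0, ], na.rm = TRUE)
  expect_equal(abs(right - left), kBT() * log(3), tolerance = 0.1)
  # saddle between them is higher than both minima
  mid <- min(z[abs(cen[[1]]) < 0.5, ], na.rm = TRUE)
  expect_gt(mid, max(left, right))
})

test_that("density clustering recovers constructed mixtures", {
  set.seed(83)
  one <- new("PCModel", kind = "cartesian", center = c(0, 0),
             vectors = diag(2), values = c(1, 1), varFrac = c(0.5, 0.5),
             projections = cbind(rnorm(10000), rnorm(10000)),
             segments = rep(1L, 10000))
  cl1 <- densityCluster(one, nComponents = 2, bins = 12, threshold = 0.1)
  expect_identical(length(occupancies(cl1)), 1L)
  expect_gte(occupancies(cl1)[1], 0.99)
  # threshold 1.0 keeps only the densest cell: still exactly one peak
  clT <- densityCluster(one, nComponents = 2, bins = 12, threshold = 1.0)
  expect_identical(length(occupancies(clT)), 1L)
  expect_error(densityCluster(one, threshold = 0), "threshold")
  # 60/40 mixture
  n1 <- 3000; n2 <- 2000
  X <- rbind(cbind(rnorm(n1, 0, 0.5), rnorm(n1, 0, 0.5)),
             cbind(rnorm(n2, 6, 0.5), rnorm(n2, 6, 0.5)))
  mix <- new("PCModel", kind = "cartesian", center = c(0, 0),
             vectors = diag(2), values = c(2, 1), varFrac = c(2, 1) / 3,
             projections = X, segments = rep(1L, n1 + n2))
  cl2 <- densityCluster(mix, nComponents = 2, bins = 30, threshold = 0.1)
  expect_identical(length(occupancies(cl2)), 2L)
  expect_lt(abs(occupancies(cl2)[1] - 0.6), 0.03)
  expect_lt(abs(occupancies(cl2)[2] - 0.4), 0.03)
  # representative frames belong to their clusters
  expect_identical(clusterLabels(cl2)[representativeFrames(cl2)], 1:2)
})

test_that("cluster timelines count transitions exactly", {
  mk <- function(lab, k) new("ClusterAssignment",
                             labels = as.integer(lab),
                             occupancy = as.numeric(table(factor(
                               lab[lab > 0], levels = seq_len(k)))) /
                               length(lab),
                             representative = vapply(seq_len(k), function(j)
                               which(lab == j)[1], 0L),
                             peaks = matrix(0, k, 2), nComponents = 2L)
  cl <- mk(c(1, 1, 2, 2, 1), 2)
  tl <- clusterTimeline(cl)
  expect_identical(tl$transitions[1, 2], 1L)
  expect_identical(tl$transitions[2, 1], 1L)
  single <- mk(rep(1, 5), 1)
  expect_true(all(clusterTimeline(single)$transitions == 0L))
  # constructed switching series
  lab <- rep(c(1, 2, 1, 3), times = c(10, 5, 5, 10))
  tl2 <- clusterTimeline(mk(lab, 3))
  expect_identical(tl2$transitions[1, 2], 1L)
  expect_identical(tl2$transitions[2, 1], 1L)
  expect_identical(tl2$transitions[1, 3], 1L)
  expect_identical(sum(tl2$transitions), 3L)
  expect_error(clusterTimeline(cl, frameTimes = c(2, 1, 3, 4, 5)),
               "monotone")
})
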