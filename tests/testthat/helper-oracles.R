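# Shared fixtures and independent oracles, built in code at test time.

# Assign each (phi, psi) to the nearest basin center (periodic distance).
basinLabel <- function(phi, psi, centers) {
  d <- vapply(seq_len(nrow(centers)), function(j)
    sqrt(wrapAngle(phi - centers[j, 1])^2 +
         wrapAngle(psi - centers[j, 2])^2), numeric(length(phi)))
  apply(matrix(d, nrow = length(phi)), 1, which.min)
}

# Analytic Boltzmann occupancy of each basin by numerical quadrature on a
# 1-degree grid (independent of the sampler).
quadratureOccupancy <- function(potential, temperature = 300) {
  g <- seq(-179.5, 179.5, by = 1)
  V <- outer(g, g, function(a, b) evalPotential(potential, a, b))
  lab <- outer(g, g, function(a, b)
    basinLabel(a, b, potential@centers))
  w <- exp(-V / kBT(temperature))
  vapply(seq_len(nrow(potential@centers)), function(j)
    sum(w[lab == j]) / sum(w), 0)
}

# Horn quaternion superposition: independent oracle for the Kabsch fit.
hornRmsd <- function(P, Q) {
  cP <- colMeans(P); cQ <- colMeans(Q)
  Pc <- sweep(P, 2, cP); Qc <- sweep(Q, 2, cQ)
  M <- crossprod(Pc, Qc)
  N <- matrix(c(
    M[1,1]+M[2,2]+M[3,3], M[2,3]-M[3,2], M[3,1]-M[1,3], M[1,2]-M[2,1],
    M[2,3]-M[3,2], M[1,1]-M[2,2]-M[3,3], M[1,2]+M[2,1], M[3,1]+M[1,3],
    M[3,1]-M[1,3], M[1,2]+M[2,1], -M[1,1]+M[2,2]-M[3,3], M[2,3]+M[3,2],
    M[1,2]-M[2,1], M[3,1]+M[1,3], M[2,3]+M[3,2], -M[1,1]-M[2,2]+M[3,3]),
    4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1-2*(y^2+z^2), 2*(x*y-w*z), 2*(x*z+w*y),
                2*(x*y+w*z), 1-2*(x^2+z^2), 2*(y*z-w*x),
                2*(x*z-w*y), 2*(y*z+w*x), 1-2*(x^2+y^2)),
              3, 3, byrow = TRUE)
  fitted <- sweep(Pc %*% t(R), 2, cQ, "+")
  sqrt(mean(rowSums((fitted - Q)^2)))
}

# Brute-force covariance eigendecomposition (explicit loops), oracle for
# the PCA implementations.
bruteForceEigen <- function(X) {
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X)
  S <- matrix(0, p, p)
  for (i in seq_len(n)) S <- S + tcrossprod(X[i, ] - mu)
  eigen(S / (n - 1), symmetric = TRUE)
}

# A helix trajectory with small thermal wobble about a dihedral center.
wobbleChain <- function(phi0, psi0, nRes, nF, sdDeg = 8, seed = 1) {
  set.seed(seed)
  phi <- matrix(phi0 + rnorm(nF * nRes, 0, sdDeg), nF, nRes)
  psi <- matrix(psi0 + rnorm(nF * nRes, 0, sdDeg), nF, nRes)
  buildToyChain(wrapAngle(phi), wrapAngle(psi))
}

# Minimal hand-placed trajectory exposing one candidate H-bond
# (acceptor residue 1 carbonyl O -> donor residue 3 amide N-H) whose
# geometry is scripted per frame.
scriptedHbondTraj <- function(distances, angleDeg = 160) {
  nF <- length(distances)
  elety <- c("N", "CA", "C", "O",          # res 1
             "N", "H", "CA", "C", "O",     # res 2
             "N", "H", "CA", "C", "O")     # res 3
  resid <- c(rep(1L, 4), rep(2L, 5), rep(3L, 5))
  atoms <- data.frame(eleno = seq_along(elety), elety = elety,
                      resid = resid, resname = "ALA",
                      element = substr(elety, 1, 1))
  coords <- array(0, c(nF, length(elety), 3))
  for (f in seq_len(nF)) {
    xyz <- matrix(0, length(elety), 3)
    # spread the irrelevant atoms far apart so no other pair bonds
    xyz[] <- rep(seq(0, by = 50, length.out = length(elety)), 3)
    d <- distances[f]
    O <- c(0, 0, 0)
    N <- c(d, 0, 0)
    # place H (1.01 A from N) so the N-H...O angle is exactly angleDeg,
    # by solving the O-H-N triangle
    gam <- angleDeg * pi / 180
    angO <- asin(min(1, 1.01 * sin(gam) / d))
    delta <- pi - gam - angO
    H <- N + 1.01 * c(-cos(delta), sin(delta), 0)
    xyz[4, ] <- O          # res1 O
    xyz[10, ] <- N         # res3 N
    xyz[11, ] <- H         # res3 H
    coords[f, , ] <- xyz
  }
  new("TrajectorySet", coords = coords, atoms = atoms,
      segments = rep(1L, nF))
}
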