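#' @include toychain.R amd.R
NULL

.crossRows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Torsion angle of four points, vectorised over frames
#'
#' @param p1,p2,p3,p4 Matrices (frames x 3) of Cartesian coordinates.
#' @return Torsion angles in degrees, wrapped to [-180, 180). Degenerate
#'   geometries (collinear triples, zero cross products) raise an error.
#' @export
torsionAngle <- function(p1, p2, p3, p4) {
  asM <- function(p) if (is.null(dim(p))) matrix(p, ncol = 3) else p
  p1 <- asM(p1); p2 <- asM(p2); p3 <- asM(p3); p4 <- asM(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .crossRows(b1, b2)
  n2 <- .crossRows(b2, b3)
  n1n <- sqrt(rowSums(n1^2))
  n2n <- sqrt(rowSums(n2^2))
  bad <- n1n < 1e-10 | n2n < 1e-10
  if (any(bad))
    stop("degenerate dihedral geometry (collinear atoms) in frame(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  b2n <- b2 / sqrt(rowSums(b2^2))
  m <- .crossRows(n1, b2n)
  x <- rowSums(n1 * n2)
  y <- rowSums(m * n2)
  wrapAngle(atan2(-y, x) * 180 / pi)
}

.backboneIndex <- function(atoms, res, name) {
  i <- which(atoms$resid == res & atoms$elety == name)
  if (length(i) != 1L)
    stop("missing backbone atom ", name, " in residue ", res)
  i
}

#' Extract phi/psi dihedral series from a trajectory
#'
#' Computes IUPAC-convention backbone dihedrals for every residue and
#' frame: phi_i = C(i-1)-N(i)-CA(i)-C(i), psi_i = N(i)-CA(i)-C(i)-N(i+1).
#' Angles whose defining atoms do not exist (phi of the first residue, psi
#' of the last) are NA, never zero-filled.
#'
#' @param traj A \linkS4class{TrajectorySet} with backbone atoms N, CA, C
#'   present in each residue.
#' @return A \linkS4class{DihedralSeries}.
#' @export
computeDihedrals <- function(traj) {
  stopifnot(is(traj, "TrajectorySet"))
  atoms <- traj@atoms
  resIds <- sort(unique(atoms$resid))
  nR <- length(resIds)
  nF <- nFrames(traj)
  at <- function(i) traj@coords[, i, , drop = FALSE][, 1, ]
  N <- vapply(resIds, function(r) .backboneIndex(atoms, r, "N"), 0L)
  CA <- vapply(resIds, function(r) .backboneIndex(atoms, r, "CA"), 0L)
  C <- vapply(resIds, function(r) .backboneIndex(atoms, r, "C"), 0L)
  phi <- matrix(NA_real_, nF, nR)
  psi <- matrix(NA_real_, nF, nR)
  for (k in seq_len(nR)) {
    if (k > 1)
      phi[, k] <- torsionAngle(at(C[k - 1]), at(N[k]), at(CA[k]), at(C[k]))
    if (k < nR)
      psi[, k] <- torsionAngle(at(N[k]), at(CA[k]), at(C[k]), at(N[k + 1]))
  }
  new("DihedralSeries", phi = phi, psi = psi, segments = traj@segments)
}

# Ramachandran region centers (degrees): tabulated conformational classes
# with the left-handed helix as the mirror of the right-handed one. Row
# order is the tie-break order.
.ramaCenters <- data.frame(
  label = c("alpha_R", "alpha_L", "beta", "PII", "gamma", "gamma_prime",
            "zeta"),
  phi = c(-63, 63, -157.2, -65, 80, -80, -130),
  psi = c(-43, 43, 161.9, 145, -80, 80, 80),
  stringsAsFactors = FALSE)

#' Ramachandran region classification
#'
#' Assigns each (phi, psi) pair the label of the nearest tabulated
#' conformational center under periodic Euclidean distance: alpha_R
#' (-63, -43), alpha_L (+63, +43; mirror convention), beta (-157.2, 161.9),
#' PII (-65, +145), gamma (+80, -80), gamma_prime (-80, +80) and zeta
#' (-130, +80). Points nearest a helical center but whose distance to the
#' corresponding extended-strand center is within \code{bridgeBand}
#' degrees of the helical distance are labelled delta (delta_prime for the
#' left-handed mirror) -- the bridge band between helix and strand where
#' beta-turns live. The classification is total and invariant under
#' 360-degree shifts.
#'
#' @param phi,psi Angles in degrees (vectorised).
#' @param bridgeBand Width of the helix/strand bridge band, degrees.
#' @return Character vector of region labels.
#' @examples
#' classifyRegion(-63, -43)   # "alpha_R"
#' classifyRegion(-80, 80)    # "gamma_prime"
#' @export
classifyRegion <- function(phi, psi, bridgeBand = 25) {
  stopifnot(length(phi) == length(psi))
  phi <- wrapAngle(phi); psi <- wrapAngle(psi)
  cen <- .ramaCenters
  d <- vapply(seq_len(nrow(cen)), function(j) {
    sqrt(wrapAngle(phi - cen$phi[j])^2 + wrapAngle(psi - cen$psi[j])^2)
  }, numeric(length(phi)))
  d <- matrix(d, nrow = length(phi))
  nearest <- apply(d, 1, which.min)
  label <- cen$label[nearest]
  dBeta <- sqrt(wrapAngle(phi - cen$phi[cen$label == "beta"])^2 +
                wrapAngle(psi - cen$psi[cen$label == "beta"])^2)
  dBetaMirror <- sqrt(wrapAngle(phi + cen$phi[cen$label == "beta"])^2 +
                      wrapAngle(psi + cen$psi[cen$label == "beta"])^2)
  dNearest <- d[cbind(seq_along(phi), nearest)]
  label[label == "alpha_R" & dBeta - dNearest <= bridgeBand] <- "delta"
  label[label == "alpha_L" & dBetaMirror - dNearest <= bridgeBand] <-
    "delta_prime"
  label
}

#' Reweighted per-residue phi/psi PMF map
#'
#' The per-residue Ramachandran free-energy map: a 2D PMF over
#' [-180, 180)^2 built from one residue's dihedral series with
#' canonical-ensemble reweighting, the per-residue analogue of a
#' reweighted phi-psi plot.
#'
#' @param series A \linkS4class{DihedralSeries}.
#' @param weights A \linkS4class{FrameWeights} or NULL (unweighted).
#' @param residue 1-based residue index; must have both angles defined.
#' @param bins Bins per axis (default 72, i.e. 5-degree bins).
#' @param temperature Kelvin.
#' @return A \linkS4class{PMFGrid} with axes phi, psi.
#' @export
residuePmfMap <- function(series, weights = NULL, residue, bins = 72L,
                          temperature = 300) {
  stopifnot(is(series, "DihedralSeries"))
  phi <- series@phi[, residue]
  psi <- series@psi[, residue]
  if (all(is.na(phi)) || all(is.na(psi)))
    stop("residue ", residue, " lacks a defined phi or psi angle ",
         "(chain end); no map can be built")
  reweightHistogram(cbind(phi, psi), weights, breaks = bins,
                    temperature = temperature, angular = TRUE,
                    axisNames = c("phi", "psi"))
}

#' Region occupancy summary
#'
#' Weighted fraction of frames each residue spends in each Ramachandran
#' region.
#'
#' @param series A \linkS4class{DihedralSeries}.
#' @param weights A \linkS4class{FrameWeights} or NULL.
#' @param bridgeBand Passed to \code{\link{classifyRegion}}.
#' @return data.frame residue x region of weighted fractions (residues
#'   with an undefined angle get NA).
#' @export
regionOccupancy <- function(series, weights = NULL, bridgeBand = 25) {
  labs <- c(.ramaCenters$label, "delta", "delta_prime")
  nR <- nResidues(series)
  w <- if (is.null(weights)) rep(1, nFrames(series)) else weights@weights
  out <- matrix(NA_real_, nR, length(labs),
                dimnames = list(seq_len(nR), labs))
  for (r in seq_len(nR)) {
    phi <- series@phi[, r]; psi <- series@psi[, r]
    ok <- !is.na(phi) & !is.na(psi)
    if (!any(ok)) next
    cls <- classifyRegion(phi[ok], psi[ok], bridgeBand)
    ws <- w[ok] / sum(w[ok])
    out[r, ] <- vapply(labs, function(l) sum(ws[cls == l]), 0)
  }
  as.data.frame(out)
}
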