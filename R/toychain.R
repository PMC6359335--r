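#' @include potentials.R
NULL

# Ideal backbone geometry (Angstrom, degrees); standard Engh--Huber-like
# values. Only relative geometry matters downstream.
.geom <- list(
  bNCa = 1.458, bCaC = 1.525, bCN = 1.329, bCO = 1.231, bNH = 1.010,
  aNCaC = 111.2, aCaCN = 116.2, aCNCa = 121.7, aCaCO = 121.0, aCNH = 119.5,
  omega = 180)

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Natural-extension (NeRF) placement: position D bonded to c with given
# bond length, angle b-c-D and torsion a-b-c-D (degrees).
.placeAtom <- function(a, b, c, bond, angle, torsion) {
  angle <- angle * pi / 180
  torsion <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- .cross3(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d <- c(-bond * cos(angle), bond * sin(angle) * cos(torsion),
         bond * sin(angle) * sin(torsion))
  c + d[1] * bc + d[2] * m + d[3] * n
}

#' Build an ideal-geometry peptide backbone from (phi, psi) series
#'
#' Places backbone atoms (N, amide H, CA, C, carbonyl O) frame by frame
#' with ideal bond lengths and angles and a fixed trans peptide bond
#' (omega = 180 deg), using the supplied IUPAC phi/psi dihedrals
#' (phi = C(i-1)-N-CA-C, psi = N-CA-C-N(i+1)). Recomputing phi/psi from
#' the output recovers the input, which makes the builder the geometric
#' ground truth for dihedral extraction, hydrogen-bond detection and
#' end-to-end distances. Residue 1 carries no amide H (no preceding
#' carbonyl); phi of residue 1 and psi of the last residue do not affect
#' the build.
#'
#' @param phi,psi Dihedrals in degrees: matrices (frames x residues),
#'   vectors of length \code{nRes} (single frame), or scalars recycled to
#'   \code{nRes}.
#' @param nRes Number of residues (>= 2); inferred from matrix inputs.
#' @param resname Residue name stamped on all residues.
#' @param segment Segment label per frame (recycled).
#' @return A \linkS4class{TrajectorySet}.
#' @examples
#' helix <- buildToyChain(-63, -43, nRes = 6)
#' nResidues(helix)
#' @export
buildToyChain <- function(phi, psi, nRes = NULL, resname = "ALA",
                          segment = 1L) {
  if (is.matrix(phi)) {
    nRes <- ncol(phi)
  } else if (is.null(nRes)) {
    if (length(phi) > 1) nRes <- length(phi)
    else stop("nRes must be given when phi/psi are scalars")
  }
  if (nRes < 2) stop("a chain needs at least 2 residues")
  if (!is.matrix(phi)) phi <- matrix(rep_len(phi, nRes), nrow = 1,
                                     ncol = nRes, byrow = TRUE)
  if (!is.matrix(psi)) psi <- matrix(rep_len(psi, nRes), nrow = 1,
                                     ncol = nRes, byrow = TRUE)
  stopifnot(identical(dim(phi), dim(psi)))
  phi <- wrapAngle(phi)
  psi <- wrapAngle(psi)
  nF <- nrow(phi)
  g <- .geom

  atomNames <- c("N", "CA", "C", "O")
  elety <- c(atomNames, unlist(lapply(seq_len(nRes - 1) + 1, function(i)
    c("N", "H", "CA", "C", "O"))))
  resid <- c(rep(1L, 4), rep(seq_len(nRes - 1) + 1L, each = 5))
  atoms <- data.frame(
    eleno = seq_along(elety), elety = elety, resid = resid,
    resname = resname,
    element = substr(elety, 1, 1), stringsAsFactors = FALSE)
  nAtoms <- nrow(atoms)

  coords <- array(NA_real_, dim = c(nF, nAtoms, 3))
  for (f in seq_len(nF)) {
    xyz <- matrix(NA_real_, nAtoms, 3)
    idx <- function(res, name) which(atoms$resid == res & atoms$elety == name)
    # residue 1: N at origin, CA on x-axis, C in the xy-plane
    N <- c(0, 0, 0)
    CA <- c(g$bNCa, 0, 0)
    ang <- g$aNCaC * pi / 180
    C <- CA + g$bCaC * c(-cos(ang), sin(ang), 0)
    xyz[idx(1, "N"), ] <- N
    xyz[idx(1, "CA"), ] <- CA
    xyz[idx(1, "C"), ] <- C
    xyz[idx(1, "O"), ] <- .placeAtom(N, CA, C, g$bCO, g$aCaCO,
                                     psi[f, 1] - 180)
    prevN <- N; prevCA <- CA; prevC <- C
    for (i in seq_len(nRes - 1) + 1) {
      Ni <- .placeAtom(prevN, prevCA, prevC, g$bCN, g$aCaCN, psi[f, i - 1])
      CAi <- .placeAtom(prevCA, prevC, Ni, g$bNCa, g$aCNCa, g$omega)
      Hi <- .placeAtom(prevCA, prevC, Ni, g$bNH, g$aCNH, 0)
      Ci <- .placeAtom(prevC, Ni, CAi, g$bCaC, g$aNCaC, phi[f, i])
      Oi <- .placeAtom(Ni, CAi, Ci, g$bCO, g$aCaCO, psi[f, i] - 180)
      xyz[idx(i, "N"), ] <- Ni
      xyz[idx(i, "H"), ] <- Hi
      xyz[idx(i, "CA"), ] <- CAi
      xyz[idx(i, "C"), ] <- Ci
      xyz[idx(i, "O"), ] <- Oi
      prevN <- Ni; prevCA <- CAi; prevC <- Ci
    }
    stopifnot(all(is.finite(xyz)))
    coords[f, , ] <- xyz
  }
  new("TrajectorySet", coords = coords, atoms = atoms,
      segments = rep_len(as.integer(segment), nF))
}
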