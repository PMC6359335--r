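#' @include dihedrals.R
NULL

.eigenPCA <- function(X, kind, segments, constantTol = 0) {
  if (nrow(X) < 3) stop("need at least 3 frames")
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  if (max(abs(Xc)) <= constantTol)
    stop("constant series: covariance is zero, no principal components")
  S <- crossprod(Xc) / (nrow(X) - 1)
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  # sign convention: largest-magnitude loading positive, for determinism
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  new("PCModel", kind = kind, center = center, vectors = vecs,
      values = vals, varFrac = vals / sum(vals),
      projections = Xc %*% vecs, segments = segments)
}

#' Dihedral principal component analysis
#'
#' PCA on the sin/cos-transformed backbone dihedrals: the analysed
#' variables are (cos phi, sin phi, cos psi, sin psi) per residue, which
#' respects the 360-degree periodicity that raw-angle PCA would break.
#' Undefined chain-end angles are dropped from the variable set. The
#' covariance matrix of the transformed variables is eigendecomposed and
#' all frames are projected onto the eigenvectors (descending eigenvalue
#' order).
#'
#' @param series A \linkS4class{DihedralSeries} with at least 2 residues
#'   carrying defined angles and at least 3 frames.
#' @return A \linkS4class{PCModel} of kind \code{"dihedral_sincos"}.
#' @export
dpca <- function(series) {
  stopifnot(is(series, "DihedralSeries"))
  cols <- list()
  for (r in seq_len(nResidues(series))) {
    phi <- series@phi[, r]
    psi <- series@psi[, r]
    rad <- pi / 180
    if (!anyNA(phi))
      cols[[length(cols) + 1]] <- cbind(cos(phi * rad), sin(phi * rad))
    if (!anyNA(psi))
      cols[[length(cols) + 1]] <- cbind(cos(psi * rad), sin(psi * rad))
  }
  if (length(cols) < 2)
    stop("need at least 2 residues with defined angles")
  X <- do.call(cbind, cols)
  .eigenPCA(X, "dihedral_sincos", series@segments, constantTol = 1e-12)
}

#' Optimal (Kabsch) superposition of one frame onto a reference
#'
#' @param P,Q Matrices (atoms x 3): mobile and reference coordinates.
#' @return List with the rotated-and-translated \code{P} (fit onto Q) and
#'   the RMSD after fitting.
#' @export
kabschFit <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  if (nrow(P) < 3) stop("rotation underdetermined: need >= 3 atoms")
  cP <- colMeans(P); cQ <- colMeans(Q)
  Pc <- sweep(P, 2, cP); Qc <- sweep(Q, 2, cQ)
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- Pc %*% t(R)
  fitted <- sweep(fitted, 2, cQ, "+")
  list(coords = fitted, rmsd = sqrt(mean(rowSums((fitted - Q)^2))))
}

#' Cartesian principal component analysis
#'
#' Two-pass superposition then covariance eigendecomposition of the
#' selected Cartesian coordinates: every frame is RMS-fit (optimal Kabsch
#' rotation) to the first frame to remove global translation/rotation,
#' then RMS-fit again to the average structure computed from that first
#' pass, and the covariance of the fitted coordinates is diagonalised.
#'
#' @param traj A \linkS4class{TrajectorySet} (>= 3 frames).
#' @param selection Logical or integer atom selection; default backbone
#'   heavy atoms (N, CA, C, O).
#' @return A \linkS4class{PCModel} of kind \code{"cartesian"}.
#' @export
cpca <- function(traj, selection = NULL) {
  stopifnot(is(traj, "TrajectorySet"))
  if (nFrames(traj) < 3) stop("need at least 3 frames")
  if (is.null(selection))
    selection <- which(traj@atoms$elety %in% c("N", "CA", "C", "O"))
  if (is.logical(selection)) selection <- which(selection)
  if (length(selection) < 3)
    stop("rotation underdetermined: need >= 3 atoms in selection")
  nF <- nFrames(traj)
  getF <- function(f) traj@coords[f, selection, , drop = FALSE][1, , ]
  ref <- getF(1)
  pass1 <- lapply(seq_len(nF), function(f) kabschFit(getF(f), ref)$coords)
  avg <- Reduce(`+`, pass1) / nF
  pass2 <- lapply(pass1, function(P) kabschFit(P, avg)$coords)
  X <- t(vapply(pass2, function(P) as.numeric(t(P)),
                numeric(3 * length(selection))))
  .eigenPCA(X, "cartesian", traj@segments)
}

#' Reweighted free-energy landscape over principal components
#'
#' The PMF mu(q1, q2) = -kB T ln P(q1, q2) over two PC projections, with
#' canonical-ensemble reweighting of the biased frames.
#'
#' @param model A \linkS4class{PCModel}.
#' @param weights A \linkS4class{FrameWeights} or NULL.
#' @param components Length-2 integer vector of PCs (default 1:2).
#' @param bins Bins per axis.
#' @param temperature Kelvin.
#' @return A \linkS4class{PMFGrid}.
#' @export
fel <- function(model, weights = NULL, components = c(1L, 2L),
                bins = 50L, temperature = 300) {
  stopifnot(is(model, "PCModel"), length(components) == 2)
  if (max(components) > ncol(model@projections))
    stop("requested components not present in the model")
  reweightHistogram(model@projections[, components, drop = FALSE],
                    weights, breaks = bins, temperature = temperature,
                    axisNames = paste0("PC", components))
}
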