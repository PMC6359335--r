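#' @include AllClasses.R
NULL

#' Construct an analytic basin potential
#'
#' Builds a periodic model energy surface as a sum of Gaussian wells on the
#' (phi, psi) torus. The potential is finite everywhere, periodic with
#' period 360 degrees on each axis, and its exact PMF (V - min V) is
#' available through \code{\link{analyticPmf}}, which makes it a ground
#' truth for samplers and reweighting.
#'
#' @param centers Matrix (basins x 2) or length-2 vector of well centers,
#'   degrees.
#' @param depths Well depths, kcal/mol (positive).
#' @param widths Gaussian widths, degrees; recycled.
#' @param kind Potential kind tag.
#' @return A \linkS4class{ModelPotential}.
#' @examples
#' pot <- doubleWellPotential()
#' evalPotential(pot, -63, -43)
#' @export
gaussianBasinPotential <- function(centers, depths, widths = 30,
                                   kind = "gaussian_basins") {
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 2, byrow = TRUE)
  n <- nrow(centers)
  new("ModelPotential", kind = kind, centers = centers,
      depths = rep_len(depths, n), widths = rep_len(widths, n))
}

#' @rdname gaussianBasinPotential
#' @details \code{doubleWellPotential} is the canonical two-well surface
#'   with wells at the right-handed helical (-63, -43) and extended
#'   (-157, 161) regions; the default depths give a 4 kcal/mol barrier out
#'   of the deeper well, inside the 2-10 kcal/mol range typical of small
#'   peptide backbone transitions.
#' @export
doubleWellPotential <- function(depths = c(4, 3), widths = 30,
                                centers = rbind(c(-63, -43), c(-157, 161))) {
  gaussianBasinPotential(centers, depths, widths,
                         kind = "double_well_periodic")
}

#' Evaluate a model potential
#'
#' @param potential A \linkS4class{ModelPotential}.
#' @param phi,psi Angles in degrees (vectorised, equal length).
#' @return Potential energy, kcal/mol.
#' @export
evalPotential <- function(potential, phi, psi) {
  stopifnot(is(potential, "ModelPotential"), length(phi) == length(psi))
  v <- numeric(length(phi))
  for (j in seq_len(nrow(potential@centers))) {
    dp <- wrapAngle(phi - potential@centers[j, 1])
    ds <- wrapAngle(psi - potential@centers[j, 2])
    w2 <- potential@widths[j]^2
    v <- v - potential@depths[j] * exp(-(dp^2 + ds^2) / (2 * w2))
  }
  v
}

#' Analytic PMF of a model potential on a grid
#'
#' Evaluates V on the grid and anchors it so that the minimum is zero,
#' giving the exact potential of mean force the samplers should recover.
#'
#' @param potential A \linkS4class{ModelPotential}.
#' @param phiCenters,psiCenters Grid points in degrees (defaults: 5-degree
#'   bin centers over [-180, 180)).
#' @return Matrix of PMF values (phi x psi), kcal/mol, min 0.
#' @export
analyticPmf <- function(potential,
                        phiCenters = seq(-177.5, 177.5, by = 5),
                        psiCenters = phiCenters) {
  v <- .potential_grid(phiCenters, psiCenters, potential@centers,
                       potential@depths, potential@widths)
  v - min(v)
}

#' Wrap angles to [-180, 180)
#'
#' @param x Angles in degrees.
#' @return Wrapped angles.
#' @examples
#' wrapAngle(c(181, -181, 360))
#' @export
wrapAngle <- function(x) {
  ((x + 180) %% 360) - 180
}
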