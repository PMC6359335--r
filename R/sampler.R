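#' @include potentials.R
NULL

.resolveBoost <- function(boost) {
  if (is.null(boost)) return(NULL)
  if (is(boost, "AMDParameters")) {
    if (is.na(boost@eDihed))
      stop("AMDParameters has no dihedral channel; the 2D sampler boosts ",
           "the (phi, psi) potential only")
    return(list(E = boost@eDihed, alpha = boost@alphaDihed))
  }
  if (is.list(boost) && all(c("E", "alpha") %in% names(boost))) {
    if (boost$alpha <= 0) stop("boost alpha must be > 0")
    return(boost[c("E", "alpha")])
  }
  stop("boost must be NULL, an AMDParameters object or list(E=, alpha=)")
}

#' Metropolis sampling of a model potential, optionally aMD-boosted
#'
#' Samples the canonical distribution exp(-V*(phi, psi)/kBT) on the 2D
#' torus by Metropolis Monte Carlo with Gaussian angular proposals and
#' periodic wrapping, where V* = V + dV(V) and dV is the aMD boost
#' \eqn{(E - V)^2 / (\alpha + E - V)} applied whenever V < E. The boost
#' energy of every recorded frame is logged, mirroring the role of Amber's
#' amd.log, so the ensemble can be reweighted back to the canonical one.
#'
#' @param potential A \linkS4class{ModelPotential}.
#' @param nSteps Number of Monte Carlo steps (>= 1).
#' @param temperature Kelvin (> 0), default 300.
#' @param stepSize Gaussian proposal standard deviation, degrees.
#' @param seed Integer seed; fixes the full trajectory bit-for-bit.
#' @param boost \code{NULL} for unbiased sampling, otherwise
#'   \code{list(E =, alpha =)} in kcal/mol or an
#'   \linkS4class{AMDParameters} with a dihedral channel.
#' @param recordStride Record every \code{recordStride}-th step.
#' @param start Length-2 start point (degrees); defaults to the deepest
#'   basin center.
#' @param segment Segment label stored on the outputs.
#' @return List with \code{series} (a one-residue-like
#'   \linkS4class{DihedralSeries}), \code{log} (a \linkS4class{BoostLog};
#'   all-zero when unbiased) and \code{acceptance} (MC acceptance rate).
#' @examples
#' pot <- doubleWellPotential(depths = c(2, 1.5))
#' run <- sampleBiased(pot, nSteps = 2000, seed = 1)
#' nFrames(run$series)
#' @export
sampleBiased <- function(potential, nSteps, temperature = 300,
                         stepSize = 10, seed = 1, boost = NULL,
                         recordStride = 1L, start = NULL, segment = 1L) {
  stopifnot(is(potential, "ModelPotential"), nSteps >= 1)
  if (temperature <= 0) stop("temperature must be positive")
  b <- .resolveBoost(boost)
  if (is.null(start))
    start <- potential@centers[which.max(potential@depths), ]
  set.seed(as.integer(seed))
  res <- .metropolis2d(potential@centers, potential@depths,
                       potential@widths, kBT(temperature),
                       as.integer(nSteps), stepSize,
                       start[1], start[2], !is.null(b),
                       if (is.null(b)) 0 else b$E,
                       if (is.null(b)) 1 else b$alpha,
                       as.integer(recordStride))
  n <- length(res$phi)
  series <- new("DihedralSeries",
                phi = matrix(res$phi, ncol = 1),
                psi = matrix(res$psi, ncol = 1),
                segments = rep(as.integer(segment), n))
  log <- new("BoostLog", dVDihed = res$dV, dVTotal = numeric(n),
             mode = "iamd2_dihedral")
  list(series = series, log = log, acceptance = res$acceptance)
}

#' Generate replica trajectories with controlled overlap
#'
#' Produces independent Metropolis runs of the same potential, either all
#' started in the deepest well (\code{same_basin}: stationary distributions
#' agree, the converging-replica case) or started in separate wells of a
#' high-barrier surface (\code{disjoint_basins}: replicas do not mix within
#' the run, the non-converging case). Two independent runs started from
#' different configurations should eventually sample the same
#' conformations; these modes construct both the converged and the
#' unconverged limit for testing convergence diagnostics.
#'
#' @param potential A \linkS4class{ModelPotential}; \code{disjoint_basins}
#'   needs at least \code{nReplicas} wells and, to actually keep replicas
#'   apart, barriers of >= 8 kcal/mol (a warning is issued otherwise).
#' @param nReplicas Number of replicas (>= 2).
#' @param seeds Integer seeds, one per replica.
#' @param overlapMode \code{"same_basin"} or \code{"disjoint_basins"}.
#' @param nSteps,temperature,stepSize,recordStride Passed to
#'   \code{\link{sampleBiased}}.
#' @param boost Optional boost, as in \code{\link{sampleBiased}}.
#' @return List of \linkS4class{DihedralSeries}, one per replica, with
#'   segment labels 1..nReplicas.
#' @export
makeReplicas <- function(potential, nReplicas, seeds,
                         overlapMode = c("same_basin", "disjoint_basins"),
                         nSteps = 1e5, temperature = 300, stepSize = 10,
                         recordStride = 1L, boost = NULL) {
  overlapMode <- match.arg(overlapMode)
  stopifnot(nReplicas >= 2)
  if (length(seeds) < nReplicas)
    stop("need at least ", nReplicas, " seeds, got ", length(seeds))
  nb <- nrow(potential@centers)
  if (overlapMode == "disjoint_basins") {
    if (nb < 2) stop("disjoint_basins requires a multi-well potential")
    if (min(potential@depths) < 8)
      warning("disjoint_basins wells shallower than 8 kcal/mol; ",
              "replicas may mix within the run")
  }
  lapply(seq_len(nReplicas), function(r) {
    start <- if (overlapMode == "same_basin")
      potential@centers[which.max(potential@depths), ]
    else
      potential@centers[((r - 1) %% nb) + 1, ]
    sampleBiased(potential, nSteps = nSteps, temperature = temperature,
                 stepSize = stepSize, seed = seeds[r], boost = boost,
                 recordStride = recordStride, start = start,
                 segment = r)$series
  })
}
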