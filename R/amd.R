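#' @include AllClasses.R accessors.R
NULL

#' Derive aMD boost thresholds from coefficients and system size
#'
#' Computes the boost threshold energies E and acceleration factors alpha
#' for the dihedral and total-potential channels:
#' E_dihed = V_avg_dihed + a1 * N_res, alpha_dihed = a2 * N_res / 5,
#' E_total = V_avg_total + b1 * N_atoms, alpha_total = b2 * N_atoms.
#' Channels the mode does not use are left unset (NA).
#'
#' @param a1,a2 Dihedral coefficients, kcal/mol per residue (>= 0).
#' @param b1,b2 Total-potential coefficients, kcal/mol per atom (>= 0).
#' @param nRes Residue count (including any capping group counted as a
#'   residue by the MD engine).
#' @param nAtoms Total atom count of the solvated system.
#' @param vAvgDihed,vAvgTotal Average dihedral/total potential energies
#'   from a short conventional run, kcal/mol.
#' @param mode Boost mode: \code{"iamd1_total"} (whole potential),
#'   \code{"iamd2_dihedral"} (torsions only) or \code{"iamd3_dual"} (both).
#' @return An \linkS4class{AMDParameters}.
#' @examples
#' p <- computeBoostParameters(a1 = 3.5, a2 = 3.5, nRes = 19,
#'                             vAvgDihed = 210, mode = "iamd2_dihedral")
#' p  # E_dihed 276.5, alpha_dihed 13.3
#' @export
computeBoostParameters <- function(a1 = 0, a2 = a1, b1 = 0, b2 = b1,
                                   nRes, nAtoms = 1L,
                                   vAvgDihed = NA_real_,
                                   vAvgTotal = NA_real_,
                                   mode = c("iamd3_dual", "iamd2_dihedral",
                                            "iamd1_total")) {
  mode <- match.arg(mode)
  if (any(c(a1, a2, b1, b2) < 0)) stop("coefficients must be >= 0")
  if (nRes < 1 || nAtoms < 1) stop("system sizes must be positive")
  dihedralActive <- mode %in% c("iamd2_dihedral", "iamd3_dual")
  totalActive <- mode %in% c("iamd1_total", "iamd3_dual")
  if (dihedralActive && (a1 == 0 || a2 == 0))
    stop("mode ", mode, " needs positive a1/a2 (alpha_dihed would be 0)")
  if (totalActive && (b1 == 0 || b2 == 0))
    stop("mode ", mode, " needs positive b1/b2 (alpha_total would be 0)")
  if (dihedralActive && !is.finite(vAvgDihed))
    stop("vAvgDihed required for the dihedral channel")
  if (totalActive && !is.finite(vAvgTotal))
    stop("vAvgTotal required for the total channel")
  new("AMDParameters", mode = mode, a1 = a1, a2 = a2, b1 = b1, b2 = b2,
      nRes = as.integer(nRes), nAtoms = as.integer(nAtoms),
      vAvgDihed = vAvgDihed, vAvgTotal = vAvgTotal,
      eDihed = if (dihedralActive) vAvgDihed + a1 * nRes else NA_real_,
      alphaDihed = if (dihedralActive) a2 * nRes / 5 else NA_real_,
      eTotal = if (totalActive) vAvgTotal + b1 * nAtoms else NA_real_,
      alphaTotal = if (totalActive) b2 * nAtoms else NA_real_)
}

#' aMD boost energy
#'
#' The non-negative bias added to the potential when it falls below the
#' threshold E: dV(V) = (E - V)^2 / (alpha + E - V) for V < E, and 0 for
#' V >= E. Continuous at V = E and monotonically decreasing in V below E.
#'
#' @param V Potential energy, kcal/mol (vectorised).
#' @param E Boost threshold, kcal/mol.
#' @param alpha Acceleration factor, kcal/mol (> 0).
#' @return Boost energies, kcal/mol.
#' @examples
#' boostEnergy(c(-2, 0, 1), E = 0, alpha = 2)
#' @export
boostEnergy <- function(V, E, alpha) {
  if (alpha <= 0) stop("alpha must be > 0")
  d <- E - V
  ifelse(d <= 0, 0, d^2 / (alpha + d))
}

#' Per-frame reweighting factors from a boost log
#'
#' Converts the effective per-frame boost dV into canonical-ensemble
#' weights. The exponential estimator uses the exact Boltzmann factor
#' exp(dV/kBT); the Maclaurin estimator its series truncated at order k,
#' \eqn{\sum_{j=0}^{k} (dV/k_BT)^j / j!}, which trades a small bias for
#' much lower statistical noise (order 10 is the default downstream). The
#' second-order cumulant estimator is applied bin-wise inside
#' \code{\link{reweightHistogram}}; here it passes unit weights plus the
#' raw dV/kBT through.
#'
#' @param log A \linkS4class{BoostLog} (or numeric vector of effective
#'   boosts, kcal/mol).
#' @param temperature Kelvin.
#' @param estimator \code{"exponential"}, \code{"maclaurin"} or
#'   \code{"cumulant2"}.
#' @param k Maclaurin truncation order (>= 1), default 10.
#' @return A \linkS4class{FrameWeights}.
#' @examples
#' w <- computeWeights(c(0, 0.3, 0.6), estimator = "maclaurin", k = 10)
#' frameWeights(w)
#' @export
computeWeights <- function(log, temperature = 300,
                           estimator = c("maclaurin", "exponential",
                                         "cumulant2"),
                           k = 10L) {
  estimator <- match.arg(estimator)
  dV <- if (is(log, "BoostLog")) effectiveBoost(log) else as.numeric(log)
  if (any(!is.finite(dV)) || any(dV < 0))
    stop("boost log corrupt: dV must be finite and non-negative")
  x <- dV / kBT(temperature)
  w <- switch(estimator,
    exponential = exp(x),
    maclaurin = {
      if (k < 1) stop("Maclaurin order k must be >= 1")
      acc <- rep(1, length(x))
      term <- rep(1, length(x))
      for (j in seq_len(k)) {
        term <- term * x / j
        acc <- acc + term
      }
      acc
    },
    cumulant2 = rep(1, length(x)))
  new("FrameWeights", estimator = estimator,
      order = if (estimator == "maclaurin") as.integer(k) else NA_integer_,
      weights = w, dVkT = x)
}

.makeAxis <- function(x, breaks, name, units) {
  if (length(breaks) == 1L) {
    rng <- range(x)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1], rng[2] + 1e-9 * diff(rng), length.out = breaks + 1)
  } else {
    edges <- breaks
  }
  list(name = name, edges = edges,
       centers = (edges[-1] + edges[-length(edges)]) / 2, units = units)
}

.binIndex <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[i == length(edges)] <- length(edges) - 1L
  ifelse(x < edges[1] | x > edges[length(edges)], NA_integer_, i)
}

#' Reweight a histogram into a potential of mean force
#'
#' Bins a 1D or 2D coordinate series, accumulates frame weights per bin,
#' normalises over populated bins and returns the PMF
#' \eqn{\mu = -k_B T \ln p} anchored so its minimum is zero. For the
#' second-order cumulant estimator the raw bin probability p* is corrected
#' bin-wise by \eqn{\exp(\beta\langle dV\rangle + \beta^2\sigma^2/2)} using
#' the per-bin mean and variance of the boost. Empty bins are masked NA.
#'
#' @param series Numeric vector (1D) or two-column matrix (2D) of
#'   per-frame coordinates.
#' @param weights A \linkS4class{FrameWeights} (or \code{NULL} for
#'   unweighted).
#' @param breaks Bin count, or vector of edges; for 2D a list of two such.
#'   Default: 72 bins per axis on [-180, 180) for angle-like data flagged
#'   by \code{angular}, else 50 bins (1D) over the data range.
#' @param temperature Kelvin.
#' @param angular If TRUE, use fixed [-180, 180) axes.
#' @param axisNames Axis names stored on the grid.
#' @return A \linkS4class{PMFGrid}.
#' @export
reweightHistogram <- function(series, weights = NULL, breaks = NULL,
                              temperature = 300, angular = FALSE,
                              axisNames = NULL) {
  is2d <- !is.null(dim(series))
  if (is2d) stopifnot(ncol(series) == 2)
  n <- if (is2d) nrow(series) else length(series)
  if (is.null(weights))
    weights <- new("FrameWeights", estimator = "exponential",
                   order = NA_integer_, weights = rep(1, n),
                   dVkT = numeric(n))
  stopifnot(is(weights, "FrameWeights"))
  w <- weights@weights
  if (length(w) != n) stop("series length must equal weights length")
  if (all(w == 0)) stop("all-zero weights: nothing to reweight")

  if (is.null(breaks))
    breaks <- if (angular) 72L else if (is2d) list(50L, 50L) else 50L
  if (angular) {
    nb <- if (is.list(breaks)) breaks[[1]] else breaks
    breaks <- if (is2d) list(seq(-180, 180, length.out = nb + 1),
                             seq(-180, 180, length.out = nb + 1))
              else seq(-180, 180, length.out = nb + 1)
  }
  units <- if (angular) "deg" else ""
  if (is2d) {
    if (!is.list(breaks)) breaks <- list(breaks, breaks)
    if (is.null(axisNames)) axisNames <- c("q1", "q2")
    ax1 <- .makeAxis(series[, 1], breaks[[1]], axisNames[1], units)
    ax2 <- .makeAxis(series[, 2], breaks[[2]], axisNames[2], units)
    i1 <- .binIndex(series[, 1], ax1$edges)
    i2 <- .binIndex(series[, 2], ax2$edges)
    keep <- !is.na(i1) & !is.na(i2)
    dims <- c(length(ax1$centers), length(ax2$centers))
    bin <- (i2[keep] - 1L) * dims[1] + i1[keep]
    axes <- list(ax1, ax2)
  } else {
    if (is.null(axisNames)) axisNames <- "q"
    ax1 <- .makeAxis(series, breaks, axisNames[1], units)
    i1 <- .binIndex(series, ax1$edges)
    keep <- !is.na(i1)
    dims <- length(ax1$centers)
    bin <- i1[keep]
    axes <- list(ax1)
  }
  nBins <- prod(dims)
  counts <- tabulate(bin, nBins)
  agg <- rowsum(w[keep], bin)
  wsumFull <- numeric(nBins)
  wsumFull[as.integer(rownames(agg))] <- agg[, 1]
  if (weights@estimator == "cumulant2") {
    x <- weights@dVkT[keep]
    m1 <- numeric(nBins); m2 <- numeric(nBins)
    agg1 <- rowsum(x, bin)
    agg2 <- rowsum(x^2, bin)
    m1[as.integer(rownames(agg1))] <- agg1[, 1]
    m2[as.integer(rownames(agg2))] <- agg2[, 1]
    pop <- counts > 0
    mu <- ifelse(pop, m1 / pmax(counts, 1), 0)
    sig2 <- ifelse(pop, m2 / pmax(counts, 1) - mu^2, 0)
    sig2[sig2 < 0] <- 0
    p <- counts * exp(mu + sig2 / 2)
  } else {
    p <- wsumFull
  }
  mask <- counts > 0
  if (!any(mask & p > 0)) stop("no populated bins with positive weight")
  p[!mask] <- 0
  p <- p / sum(p)
  kT <- kBT(temperature)
  pmf <- rep(NA_real_, nBins)
  pos <- mask & p > 0
  pmf[pos] <- -kT * log(p[pos])
  # populated-but-zero-weight bins sit at the top of the scale, not at 0
  pmf[mask & !pos] <- Inf
  pmf <- pmf - min(pmf[mask])
  pmf[is.infinite(pmf)] <- NA_real_
  mask[mask & !pos] <- FALSE
  dim(p) <- dims; dim(pmf) <- dims; dim(mask) <- dims
  if (!is2d) { dim(p) <- nBins; dim(pmf) <- nBins; dim(mask) <- nBins }
  new("PMFGrid", axes = axes, prob = as.array(p), pmf = as.array(pmf),
      mask = as.array(mask), temperature = temperature)
}
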