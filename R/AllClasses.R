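#' @include accelMD-package.R
NULL

#' Analytic model potential on the 2D dihedral torus
#'
#' A sum of Gaussian basins, periodic with period 360 degrees on each axis.
#' Stands in for a peptide's free-energy surface so that samplers and
#' reweighting can be validated against a known ground truth.
#'
#' @slot kind Either \code{"double_well_periodic"} or
#'   \code{"gaussian_basins"}.
#' @slot centers Numeric matrix (basins x 2) of basin centers in degrees.
#' @slot depths Basin depths, kcal/mol (positive; wells are -depth deep).
#' @slot widths Gaussian widths per basin, degrees.
#' @name ModelPotential-class
#' @rdname ModelPotential-class
#' @exportClass ModelPotential
setClass("ModelPotential",
  representation(kind = "character", centers = "matrix",
                 depths = "numeric", widths = "numeric"))

setValidity("ModelPotential", function(object) {
  msg <- NULL
  if (!object@kind %in% c("double_well_periodic", "gaussian_basins"))
    msg <- c(msg, "kind must be 'double_well_periodic' or 'gaussian_basins'")
  if (ncol(object@centers) != 2L)
    msg <- c(msg, "centers must have two columns (phi, psi)")
  if (nrow(object@centers) != length(object@depths) ||
      nrow(object@centers) != length(object@widths))
    msg <- c(msg, "centers, depths and widths must agree in length")
  if (any(!is.finite(object@centers)) || any(!is.finite(object@depths)) ||
      any(!is.finite(object@widths)))
    msg <- c(msg, "potential parameters must be finite")
  if (any(object@depths <= 0) || any(object@widths <= 0))
    msg <- c(msg, "depths and widths must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Accelerated-MD boost parameters
#'
#' Holds the boost thresholds E and acceleration factors alpha for the
#' dihedral and/or total-potential channels, derived from per-residue and
#' per-atom coefficients and the average energies of a short conventional
#' run:
#' \deqn{E_{dihed} = V_{avg,dihed} + a_1 N_{res},\quad
#'       \alpha_{dihed} = a_2 N_{res} / 5}
#' \deqn{E_{total} = V_{avg,total} + b_1 N_{atoms},\quad
#'       \alpha_{total} = b_2 N_{atoms}}
#'
#' @slot mode One of \code{"iamd1_total"}, \code{"iamd2_dihedral"},
#'   \code{"iamd3_dual"}.
#' @slot a1,a2 Dihedral-channel coefficients, kcal/mol per residue.
#' @slot b1,b2 Total-potential coefficients, kcal/mol per atom.
#' @slot nRes,nAtoms System sizes.
#' @slot vAvgDihed,vAvgTotal Average dihedral/total potential energies,
#'   kcal/mol.
#' @slot eDihed,alphaDihed,eTotal,alphaTotal Derived thresholds (NA for
#'   channels the mode does not use).
#' @name AMDParameters-class
#' @rdname AMDParameters-class
#' @exportClass AMDParameters
setClass("AMDParameters",
  representation(mode = "character", a1 = "numeric", a2 = "numeric",
                 b1 = "numeric", b2 = "numeric",
                 nRes = "integer", nAtoms = "integer",
                 vAvgDihed = "numeric", vAvgTotal = "numeric",
                 eDihed = "numeric", alphaDihed = "numeric",
                 eTotal = "numeric", alphaTotal = "numeric"))

setValidity("AMDParameters", function(object) {
  msg <- NULL
  if (!object@mode %in% c("iamd1_total", "iamd2_dihedral", "iamd3_dual"))
    msg <- c(msg, "unknown mode")
  dihedralActive <- object@mode %in% c("iamd2_dihedral", "iamd3_dual")
  totalActive <- object@mode %in% c("iamd1_total", "iamd3_dual")
  if (dihedralActive && (is.na(object@alphaDihed) || object@alphaDihed <= 0))
    msg <- c(msg, "alphaDihed must be > 0 when the dihedral boost is active")
  if (totalActive && (is.na(object@alphaTotal) || object@alphaTotal <= 0))
    msg <- c(msg, "alphaTotal must be > 0 when the total boost is active")
  if (dihedralActive && object@a1 > 0 &&
      !is.na(object@eDihed) && object@eDihed < object@vAvgDihed)
    msg <- c(msg, "eDihed must be >= vAvgDihed when a1 > 0")
  if (is.null(msg)) TRUE else msg
})

#' Per-frame boost-energy log
#'
#' Mirrors the role of Amber's amd.log: the extra boost added to each
#' snapshot of a biased trajectory, split into the dihedral and
#' total-potential channels. The effective boost used for reweighting is
#' mode-dependent (see \code{\link{effectiveBoost}}).
#'
#' @slot dVDihed Dihedral-channel boost per frame, kcal/mol (>= 0).
#' @slot dVTotal Total-channel boost per frame, kcal/mol (>= 0).
#' @slot mode The boost mode the run used.
#' @name BoostLog-class
#' @rdname BoostLog-class
#' @exportClass BoostLog
setClass("BoostLog",
  representation(dVDihed = "numeric", dVTotal = "numeric", mode = "character"))

setValidity("BoostLog", function(object) {
  msg <- NULL
  if (length(object@dVDihed) != length(object@dVTotal))
    msg <- c(msg, "dVDihed and dVTotal must have equal length")
  if (any(!is.finite(object@dVDihed)) || any(!is.finite(object@dVTotal)))
    msg <- c(msg, "boost energies must be finite")
  if (any(object@dVDihed < 0) || any(object@dVTotal < 0))
    msg <- c(msg, "boost energies must be non-negative")
  if (!object@mode %in% c("iamd1_total", "iamd2_dihedral", "iamd3_dual"))
    msg <- c(msg, "unknown mode")
  if (is.null(msg)) TRUE else msg
})

#' Per-frame reweighting factors
#'
#' @slot estimator \code{"exponential"}, \code{"maclaurin"} or
#'   \code{"cumulant2"}.
#' @slot order Maclaurin truncation order (NA otherwise).
#' @slot weights Non-negative per-frame weights. For \code{cumulant2} these
#'   are all 1; the bin-wise cumulant correction is applied inside
#'   \code{\link{reweightHistogram}} using \code{dVkT}.
#' @slot dVkT The dimensionless boost dV/kBT per frame.
#' @name FrameWeights-class
#' @rdname FrameWeights-class
#' @exportClass FrameWeights
setClass("FrameWeights",
  representation(estimator = "character", order = "integer",
                 weights = "numeric", dVkT = "numeric"))

setValidity("FrameWeights", function(object) {
  msg <- NULL
  if (!object@estimator %in% c("exponential", "maclaurin", "cumulant2"))
    msg <- c(msg, "unknown estimator")
  if (any(!is.finite(object@weights)) || any(object@weights < 0))
    msg <- c(msg, "weights must be finite and non-negative")
  if (length(object@weights) != length(object@dVkT))
    msg <- c(msg, "weights and dVkT must align")
  if (is.null(msg)) TRUE else msg
})

#' Binned potential-of-mean-force surface
#'
#' One- or two-dimensional histogram-derived PMF, mu = -kB T ln P, anchored
#' so the minimum over populated bins is zero; empty bins are masked (NA),
#' never reported as zero energy.
#'
#' @slot axes List of axis definitions, each a list with \code{name},
#'   \code{edges}, \code{centers}, \code{units}.
#' @slot prob Bin probabilities (vector or matrix); populated bins sum to 1.
#' @slot pmf PMF values, kcal/mol; NA on empty bins.
#' @slot mask Logical populated-bin mask.
#' @slot temperature Kelvin.
#' @name PMFGrid-class
#' @rdname PMFGrid-class
#' @exportClass PMFGrid
setClass("PMFGrid",
  representation(axes = "list", prob = "array", pmf = "array",
                 mask = "array", temperature = "numeric"))

setValidity("PMFGrid", function(object) {
  msg <- NULL
  p <- object@prob[object@mask]
  if (length(p) && abs(sum(p) - 1) > 1e-8)
    msg <- c(msg, "probabilities over populated bins must sum to 1")
  v <- object@pmf[object@mask]
  if (length(v) && abs(min(v)) > 1e-8)
    msg <- c(msg, "minimum PMF over populated bins must be 0")
  if (any(!is.na(object@pmf[!object@mask])))
    msg <- c(msg, "empty bins must be masked NA")
  if (object@temperature <= 0) msg <- c(msg, "temperature must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Trajectory coordinates with atom metadata
#'
#' @slot coords Numeric array, frames x atoms x 3, Angstrom.
#' @slot atoms data.frame with one row per atom: \code{eleno}, \code{elety}
#'   (PDB atom name), \code{resid} (1-based residue number), \code{resname},
#'   \code{element}.
#' @slot segments Integer replica/segment label per frame.
#' @name TrajectorySet-class
#' @rdname TrajectorySet-class
#' @exportClass TrajectorySet
setClass("TrajectorySet",
  representation(coords = "array", atoms = "data.frame",
                 segments = "integer"))

setValidity("TrajectorySet", function(object) {
  msg <- NULL
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "coords must be a frames x atoms x 3 array")
  if (!is.null(d) && d[2] != nrow(object@atoms))
    msg <- c(msg, "atom metadata rows must match coords atom dimension")
  if (length(object@segments) != d[1])
    msg <- c(msg, "segments must have one label per frame")
  if (is.null(msg)) TRUE else msg
})

#' Per-residue phi/psi dihedral series
#'
#' Angles are in degrees wrapped to [-180, 180). Undefined angles (phi of
#' the first residue, psi of the last, absent atoms) are NA, never
#' zero-filled.
#'
#' @slot phi,psi Numeric matrices, frames x residues.
#' @slot segments Integer segment label per frame.
#' @name DihedralSeries-class
#' @rdname DihedralSeries-class
#' @exportClass DihedralSeries
setClass("DihedralSeries",
  representation(phi = "matrix", psi = "matrix", segments = "integer"))

setValidity("DihedralSeries", function(object) {
  msg <- NULL
  if (!identical(dim(object@phi), dim(object@psi)))
    msg <- c(msg, "phi and psi must have identical dimensions")
  rng <- range(c(object@phi, object@psi), na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < -180 || rng[2] >= 180.000001))
    msg <- c(msg, "angles must lie in [-180, 180)")
  if (length(object@segments) != nrow(object@phi))
    msg <- c(msg, "segments must have one label per frame")
  if (is.null(msg)) TRUE else msg
})

#' Principal component model of a trajectory
#'
#' @slot kind \code{"dihedral_sincos"} or \code{"cartesian"}.
#' @slot center Mean vector of the analysed variables.
#' @slot vectors Eigenvectors in columns, descending eigenvalue order.
#' @slot values Eigenvalues (non-negative, descending).
#' @slot varFrac Variance fractions (sum to 1).
#' @slot projections Frames x components scores.
#' @slot segments Integer segment label per frame.
#' @name PCModel-class
#' @rdname PCModel-class
#' @exportClass PCModel
setClass("PCModel",
  representation(kind = "character", center = "numeric",
                 vectors = "matrix", values = "numeric",
                 varFrac = "numeric", projections = "matrix",
                 segments = "integer"))

setValidity("PCModel", function(object) {
  msg <- NULL
  if (!object@kind %in% c("dihedral_sincos", "cartesian"))
    msg <- c(msg, "unknown kind")
  v <- object@values
  if (any(v < -1e-8 * max(abs(v), 1)))
    msg <- c(msg, "eigenvalues must be non-negative")
  if (is.unsorted(rev(v), strictly = FALSE))
    msg <- c(msg, "eigenvalues must be in descending order")
  if (abs(sum(object@varFrac) - 1) > 1e-9)
    msg <- c(msg, "variance fractions must sum to 1")
  if (length(object@segments) != nrow(object@projections))
    msg <- c(msg, "segments must have one label per frame")
  if (is.null(msg)) TRUE else msg
})

#' Density-peak cluster assignment in PC space
#'
#' @slot labels Integer per-frame cluster id; 0 = unassigned. Clusters are
#'   numbered 1..K in descending occupancy.
#' @slot occupancy Fraction of all frames per cluster.
#' @slot representative Frame index (1-based) nearest each density peak.
#' @slot peaks Cluster peak coordinates in PC space (clusters x components).
#' @slot nComponents Number of PCs clustered over.
#' @name ClusterAssignment-class
#' @rdname ClusterAssignment-class
#' @exportClass ClusterAssignment
setClass("ClusterAssignment",
  representation(labels = "integer", occupancy = "numeric",
                 representative = "integer", peaks = "matrix",
                 nComponents = "integer"))

setValidity("ClusterAssignment", function(object) {
  msg <- NULL
  k <- length(object@occupancy)
  if (sum(object@occupancy) > 1 + 1e-9)
    msg <- c(msg, "occupancies must sum to <= 1")
  if (any(object@labels < 0L) || any(object@labels > k))
    msg <- c(msg, "labels must lie in 0..K")
  if (k && any(object@labels[object@representative] != seq_len(k)))
    msg <- c(msg, "each representative frame must belong to its cluster")
  if (is.null(msg)) TRUE else msg
})

#' Gaussian kernel density estimate on a fixed grid
#'
#' @slot grid Evaluation points.
#' @slot density Density values normalised to sum to 1.
#' @slot bandwidth Gaussian kernel bandwidth used.
#' @slot segment Source segment/replica id.
#' @slot horizon Number of leading frames the estimate uses (prefix
#'   semantics: all data from time 0 to t).
#' @name KDEHistogram-class
#' @rdname KDEHistogram-class
#' @exportClass KDEHistogram
setClass("KDEHistogram",
  representation(grid = "numeric", density = "numeric",
                 bandwidth = "numeric", segment = "integer",
                 horizon = "integer"))

setValidity("KDEHistogram", function(object) {
  msg <- NULL
  if (length(object@grid) != length(object@density))
    msg <- c(msg, "grid and density must align")
  if (any(object@density < 0)) msg <- c(msg, "density must be non-negative")
  if (abs(sum(object@density) - 1) > 1e-9)
    msg <- c(msg, "density must sum to 1")
  if (object@bandwidth <= 0) msg <- c(msg, "bandwidth must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Time-dependent Kullback-Leibler divergence between replicas
#'
#' @slot times Evaluation horizons (fractions of trajectory length).
#' @slot kldValues Matrix, times x pairs.
#' @slot slopes Finite-difference KLD slopes, same shape (first row NA).
#' @slot pairs Character labels, e.g. "1-2".
#' @slot converged Logical per pair: KLD stays below the cutoff from some
#'   horizon through the final one.
#' @slot convergenceTime First horizon of the terminal below-cutoff run
#'   (NA when never converged).
#' @slot cutoff Convergence cutoff on the KLD value.
#' @name KLDSeries-class
#' @rdname KLDSeries-class
#' @exportClass KLDSeries
setClass("KLDSeries",
  representation(times = "numeric", kldValues = "matrix", slopes = "matrix",
                 pairs = "character", converged = "logical",
                 convergenceTime = "numeric", cutoff = "numeric"))

setValidity("KLDSeries", function(object) {
  msg <- NULL
  if (ncol(object@kldValues) != length(object@pairs))
    msg <- c(msg, "one KLD column per pair required")
  if (any(object@kldValues < -1e-12, na.rm = TRUE))
    msg <- c(msg, "KLD must be non-negative")
  if (is.null(msg)) TRUE else msg
})
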