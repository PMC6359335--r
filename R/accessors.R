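#' @include AllClasses.R
NULL

#' Accessors for accelMD classes
#'
#' Small generic accessors so user code never touches slots directly.
#'
#' @param x An accelMD object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))
#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("atomInfo", function(x) standardGeneric("atomInfo"))
#' @rdname accessors
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))
#' @rdname accessors
#' @export
setGeneric("phiAngles", function(x) standardGeneric("phiAngles"))
#' @rdname accessors
#' @export
setGeneric("psiAngles", function(x) standardGeneric("psiAngles"))
#' @rdname accessors
#' @export
setGeneric("effectiveBoost", function(x) standardGeneric("effectiveBoost"))
#' @rdname accessors
#' @export
setGeneric("frameWeights", function(x) standardGeneric("frameWeights"))
#' @rdname accessors
#' @export
setGeneric("pmfValues", function(x) standardGeneric("pmfValues"))
#' @rdname accessors
#' @export
setGeneric("binProbabilities", function(x) standardGeneric("binProbabilities"))
#' @rdname accessors
#' @export
setGeneric("axisCenters", function(x) standardGeneric("axisCenters"))
#' @rdname accessors
#' @export
setGeneric("projections", function(x) standardGeneric("projections"))
#' @rdname accessors
#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))
#' @rdname accessors
#' @export
setGeneric("varianceFractions", function(x) standardGeneric("varianceFractions"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("occupancies", function(x) standardGeneric("occupancies"))
#' @rdname accessors
#' @export
setGeneric("representativeFrames", function(x) standardGeneric("representativeFrames"))
#' @rdname accessors
#' @export
setGeneric("peakCoordinates", function(x) standardGeneric("peakCoordinates"))
#' @rdname accessors
#' @export
setGeneric("kldValues", function(x) standardGeneric("kldValues"))
#' @rdname accessors
#' @export
setGeneric("convergedPairs", function(x) standardGeneric("convergedPairs"))

#' @rdname accessors
setMethod("nFrames", "TrajectorySet", function(x) dim(x@coords)[1])
#' @rdname accessors
setMethod("nFrames", "DihedralSeries", function(x) nrow(x@phi))
#' @rdname accessors
setMethod("nFrames", "BoostLog", function(x) length(x@dVDihed))
#' @rdname accessors
setMethod("nFrames", "PCModel", function(x) nrow(x@projections))

#' @rdname accessors
setMethod("nResidues", "TrajectorySet", function(x) length(unique(x@atoms$resid)))
#' @rdname accessors
setMethod("nResidues", "DihedralSeries", function(x) ncol(x@phi))

#' @rdname accessors
setMethod("coords", "TrajectorySet", function(x) x@coords)
#' @rdname accessors
setMethod("atomInfo", "TrajectorySet", function(x) x@atoms)
#' @rdname accessors
setMethod("segments", "TrajectorySet", function(x) x@segments)
#' @rdname accessors
setMethod("segments", "DihedralSeries", function(x) x@segments)
#' @rdname accessors
setMethod("segments", "PCModel", function(x) x@segments)

#' @rdname accessors
setMethod("phiAngles", "DihedralSeries", function(x) x@phi)
#' @rdname accessors
setMethod("psiAngles", "DihedralSeries", function(x) x@psi)

#' @rdname accessors
setMethod("effectiveBoost", "BoostLog", function(x) {
  switch(x@mode,
    iamd1_total = x@dVTotal,
    iamd2_dihedral = x@dVDihed,
    iamd3_dual = x@dVDihed + x@dVTotal)
})

#' @rdname accessors
setMethod("frameWeights", "FrameWeights", function(x) x@weights)

#' @rdname accessors
setMethod("pmfValues", "PMFGrid", function(x) x@pmf)
#' @rdname accessors
setMethod("binProbabilities", "PMFGrid", function(x) x@prob)
#' @rdname accessors
setMethod("axisCenters", "PMFGrid", function(x)
  lapply(x@axes, function(a) a$centers))

#' @rdname accessors
setMethod("projections", "PCModel", function(x) x@projections)
#' @rdname accessors
setMethod("eigenValues", "PCModel", function(x) x@values)
#' @rdname accessors
setMethod("varianceFractions", "PCModel", function(x) x@varFrac)

#' @rdname accessors
setMethod("clusterLabels", "ClusterAssignment", function(x) x@labels)
#' @rdname accessors
setMethod("occupancies", "ClusterAssignment", function(x) x@occupancy)
#' @rdname accessors
setMethod("representativeFrames", "ClusterAssignment", function(x) x@representative)
#' @rdname accessors
setMethod("peakCoordinates", "ClusterAssignment", function(x) x@peaks)

#' @rdname accessors
setMethod("kldValues", "KLDSeries", function(x) x@kldValues)
#' @rdname accessors
setMethod("convergedPairs", "KLDSeries", function(x) {
  out <- x@converged
  names(out) <- x@pairs
  out
})

setMethod("show", "ModelPotential", function(object) {
  cat("ModelPotential (", object@kind, "), ", nrow(object@centers),
      " basin(s)\n", sep = "")
  for (i in seq_len(nrow(object@centers)))
    cat(sprintf("  basin %d: center (%.1f, %.1f) deg, depth %.2f kcal/mol, width %.1f deg\n",
                i, object@centers[i, 1], object@centers[i, 2],
                object@depths[i], object@widths[i]))
})

setMethod("show", "AMDParameters", function(object) {
  cat("AMDParameters, mode ", object@mode, "\n", sep = "")
  cat(sprintf("  N_res %d, N_atoms %d\n", object@nRes, object@nAtoms))
  if (!is.na(object@eDihed))
    cat(sprintf("  dihedral channel: E %.4g, alpha %.4g kcal/mol\n",
                object@eDihed, object@alphaDihed))
  if (!is.na(object@eTotal))
    cat(sprintf("  total channel:    E %.4g, alpha %.4g kcal/mol\n",
                object@eTotal, object@alphaTotal))
})

setMethod("show", "BoostLog", function(object) {
  dv <- effectiveBoost(object)
  cat(sprintf("BoostLog (%s), %d frames, effective dV mean %.3g kcal/mol (max %.3g)\n",
              object@mode, length(dv), mean(dv), max(dv)))
})

setMethod("show", "FrameWeights", function(object) {
  cat(sprintf("FrameWeights (%s%s), %d frames\n", object@estimator,
              if (object@estimator == "maclaurin")
                sprintf(" order %d", object@order) else "",
              length(object@weights)))
})

setMethod("show", "PMFGrid", function(object) {
  cat(sprintf("PMFGrid %s at %g K, %d/%d populated bins, max PMF %.3g kcal/mol\n",
              paste(vapply(object@axes, function(a)
                sprintf("%s[%d]", a$name, length(a$centers)), ""),
                collapse = " x "),
              object@temperature, sum(object@mask), length(object@mask),
              max(object@pmf, na.rm = TRUE)))
})

setMethod("show", "TrajectorySet", function(object) {
  cat(sprintf("TrajectorySet: %d frames, %d atoms, %d residues, %d segment(s)\n",
              nFrames(object), nrow(object@atoms), nResidues(object),
              length(unique(object@segments))))
})

setMethod("show", "DihedralSeries", function(object) {
  cat(sprintf("DihedralSeries: %d frames x %d residues (%d segment(s))\n",
              nFrames(object), nResidues(object),
              length(unique(object@segments))))
})

setMethod("show", "PCModel", function(object) {
  k <- min(3L, length(object@varFrac))
  cat(sprintf("PCModel (%s): %d frames, %d variables; top-%d variance %s\n",
              object@kind, nrow(object@projections), length(object@values), k,
              paste(sprintf("%.1f%%", 100 * object@varFrac[seq_len(k)]),
                    collapse = ", ")))
})

setMethod("show", "ClusterAssignment", function(object) {
  cat(sprintf("ClusterAssignment: %d cluster(s) over %d PCs, %.1f%% of frames assigned\n",
              length(object@occupancy), object@nComponents,
              100 * sum(object@occupancy)))
  if (length(object@occupancy))
    cat(paste(sprintf("  cluster %d: %.1f%% (representative frame %d)",
                      seq_along(object@occupancy), 100 * object@occupancy,
                      object@representative), collapse = "\n"), "\n")
})

setMethod("show", "KLDSeries", function(object) {
  cat(sprintf("KLDSeries: %d horizons, pairs %s; converged: %s (cutoff %g)\n",
              length(object@times), paste(object@pairs, collapse = ", "),
              paste(ifelse(object@converged, "yes", "no"), collapse = ", "),
              object@cutoff))
})

setMethod("show", "KDEHistogram", function(object) {
  cat(sprintf("KDEHistogram: %d grid points, bandwidth %.4g, horizon %d frames\n",
              length(object@grid), object@bandwidth, object@horizon))
})
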