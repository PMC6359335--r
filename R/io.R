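#' @include structure.R convergence.R
NULL

#' Write a trajectory as multi-model PDB
#'
#' One MODEL/ENDMDL block per frame, standard ATOM records (coordinates at
#' PDB's 0.001 Angstrom precision).
#'
#' @param traj A \linkS4class{TrajectorySet}.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
writeTrajectory <- function(traj, path) {
  stopifnot(is(traj, "TrajectorySet"))
  atoms <- traj@atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nFrames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- matrix(traj@coords[f, , ], ncol = 3)
    name4 <- ifelse(nchar(atoms$elety) < 4,
                    sprintf(" %-3s", atoms$elety),
                    atoms$elety)
    writeLines(sprintf(
      "ATOM  %5d %4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      atoms$eleno, name4, atoms$resname, atoms$resid,
      xyz[, 1], xyz[, 2], xyz[, 3], 1.0, 0.0, atoms$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a trajectory from multi-model PDB
#'
#' Frames are returned in file order (frame 1 = first MODEL); 1-based
#' residue numbering is retained from the source. All models must contain
#' the same atoms; a model whose atom count differs from model 1 is an
#' error naming the model.
#'
#' @param path Multi-model PDB file.
#' @param segments Optional integer segment label per frame.
#' @return A \linkS4class{TrajectorySet}.
#' @export
readTrajectory <- function(path, segments = NULL) {
  lines <- readLines(path)
  modelStarts <- grep("^MODEL", lines)
  if (length(modelStarts) > 1) {
    modelEnds <- grep("^ENDMDL", lines)
    counts <- vapply(seq_along(modelStarts), function(i)
      sum(grepl("^(ATOM|HETATM)",
                lines[modelStarts[i]:modelEnds[i]])), 0L)
    if (any(counts != counts[1]))
      stop("inconsistent atom count in model ",
           which(counts != counts[1])[1], " (expected ", counts[1],
           ", found ", counts[counts != counts[1]][1], ")")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nAtoms <- nrow(pdb$atom)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nF <- nrow(xyz)
  coords <- array(NA_real_, c(nF, nAtoms, 3))
  for (f in seq_len(nF))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  elem <- pdb$atom$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(trimws(pdb$atom$elety), 1, 1)
  atoms <- data.frame(
    eleno = pdb$atom$eleno, elety = trimws(pdb$atom$elety),
    resid = pdb$atom$resno, resname = trimws(pdb$atom$resid),
    element = trimws(elem), stringsAsFactors = FALSE)
  if (is.null(segments)) segments <- rep(1L, nF)
  new("TrajectorySet", coords = coords, atoms = atoms,
      segments = as.integer(segments))
}

#' Read / write a boost-energy log (TSV)
#'
#' Columnar dialect mirroring the role of Amber's amd.log: header
#' \code{frame dV_dihed dV_total} (kcal/mol); \code{dV_total} may be
#' absent for a dihedral-only run. Negative boost entries are rejected
#' with their line number.
#'
#' @param path TSV file.
#' @param mode Boost mode recorded on the object; a missing
#'   \code{dV_total} column is accepted for \code{"iamd2_dihedral"}.
#' @param nFramesExpected Optional frame count to check against.
#' @return A \linkS4class{BoostLog}.
#' @export
readBoostLog <- function(path, mode = "iamd2_dihedral",
                         nFramesExpected = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!"dV_dihed" %in% names(tab))
    stop("boost log must have a dV_dihed column")
  if (!"dV_total" %in% names(tab)) {
    if (mode != "iamd2_dihedral")
      stop("mode ", mode, " needs a dV_total column")
    tab$dV_total <- 0
  }
  bad <- which(tab$dV_dihed < 0 | tab$dV_total < 0)
  if (length(bad))
    stop("negative boost energy at line ", bad[1] + 1,
         " of ", path)
  if (!is.null(nFramesExpected) && nrow(tab) != nFramesExpected)
    stop("boost log has ", nrow(tab), " frames, expected ",
         nFramesExpected)
  new("BoostLog", dVDihed = tab$dV_dihed, dVTotal = tab$dV_total,
      mode = mode)
}

#' @rdname readBoostLog
#' @param log A \linkS4class{BoostLog} to write.
#' @export
writeBoostLog <- function(log, path) {
  stopifnot(is(log, "BoostLog"))
  tab <- data.frame(frame = seq_along(log@dVDihed) - 1L,
                    dV_dihed = log@dVDihed, dV_total = log@dVTotal)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a 2D dihedral series (TSV)
#'
#' Header \code{frame phi psi}, degrees; frames 0-based in the file.
#'
#' @param path TSV file.
#' @param segment Segment label for the frames read.
#' @return A one-residue \linkS4class{DihedralSeries}.
#' @export
readDihedralSeries <- function(path, segment = 1L) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("phi", "psi") %in% names(tab)))
  new("DihedralSeries",
      phi = matrix(wrapAngle(tab$phi), ncol = 1),
      psi = matrix(wrapAngle(tab$psi), ncol = 1),
      segments = rep(as.integer(segment), nrow(tab)))
}

#' @rdname readDihedralSeries
#' @param series A one-residue \linkS4class{DihedralSeries} to write.
#' @export
writeDihedralSeries <- function(series, path) {
  stopifnot(is(series, "DihedralSeries"), ncol(series@phi) == 1)
  tab <- data.frame(frame = seq_len(nFrames(series)) - 1L,
                    phi = series@phi[, 1], psi = series@psi[, 1])
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a PMF grid as TSV
#'
#' Bin centers plus PMF (kcal/mol); empty bins are written as NA.
#'
#' @param grid A \linkS4class{PMFGrid}.
#' @param path Output file.
#' @export
writePmfGrid <- function(grid, path) {
  stopifnot(is(grid, "PMFGrid"))
  cent <- axisCenters(grid)
  if (length(cent) == 2) {
    tab <- expand.grid(cent[[1]], cent[[2]])
    names(tab) <- vapply(grid@axes, `[[`, "", "name")
    tab$pmf <- as.numeric(grid@pmf)
  } else {
    tab <- data.frame(cent[[1]], pmf = as.numeric(grid@pmf))
    names(tab)[1] <- grid@axes[[1]]$name
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# documented run-configuration defaults; every pipeline knob in one place
.defaultConfig <- function() {
  list(temperature = 300, estimator = "maclaurin", order = 10L,
       bins2d = 72L, felBins = 50L, clusterComponents = 3L,
       clusterBins = 50L, clusterThreshold = 0.1, kldCutoff = 0.025,
       hbondDistCutoff = 3.0, hbondAngleCutoff = 135, seed = 1L,
       nSteps = 1e5, nReplicas = 2L, stepSize = 10)
}

#' Read / write a run configuration
#'
#' Flat key-value (YAML) file holding every pipeline parameter:
#' temperature, estimator and order, bin counts, cluster threshold, KLD
#' cutoff, H-bond cutoffs, seed, replica count. Unknown keys are
#' rejected; the round trip is lossless.
#'
#' @param path YAML file.
#' @return Named list of parameters (defaults filled in).
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  def <- .defaultConfig()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(def, cfg)
  validateRunConfig(out)
  out
}

#' @rdname readRunConfig
#' @param config Named list of parameters.
#' @export
writeRunConfig <- function(config, path) {
  validateRunConfig(config)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname readRunConfig
#' @export
validateRunConfig <- function(config) {
  def <- .defaultConfig()
  config <- utils::modifyList(def, config)
  if (config$temperature <= 0) stop("temperature must be positive")
  if (config$clusterThreshold <= 0 || config$clusterThreshold > 1)
    stop("clusterThreshold must lie in (0, 1]")
  if (config$kldCutoff <= 0) stop("kldCutoff must be positive")
  if (config$hbondDistCutoff <= 0) stop("hbondDistCutoff must be positive")
  if (config$order < 1) stop("Maclaurin order must be >= 1")
  if (!config$estimator %in% c("maclaurin", "exponential", "cumulant2"))
    stop("unknown estimator: ", config$estimator)
  invisible(config)
}
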