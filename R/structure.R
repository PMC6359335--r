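#' @include dihedrals.R
NULL

#' Backbone hydrogen-bond detection and occupancy table
#'
#' Detects backbone N-H...O=C hydrogen bonds frame by frame: a bond is
#' present when the acceptor carbonyl O to donor amide N heavy-atom
#' distance is at most \code{distCutoff} and the N-H...O angle (at the
#' hydrogen) is at least \code{angleCutoff}. Donor/acceptor pairs closer
#' than two residues along the chain are skipped, and donors lacking an
#' amide H (the first residue; proline in real chains) are skipped with a
#' notice. The table aggregates, per (acceptor, donor) pair with at least
#' one bonded frame: the fraction of frames bonded, and the mean distance
#' and angle over bonded frames only; rows are sorted by acceptor then
#' donor.
#'
#' @param traj A \linkS4class{TrajectorySet} with backbone N, H, O atoms.
#' @param distCutoff Heavy-atom O...N cutoff, Angstrom (default 3.0).
#' @param angleCutoff N-H...O angle cutoff, degrees (default 135).
#' @param verbose Emit a message when a donor is skipped for lacking H.
#' @return List with \code{records} (data.frame: acceptor, donor,
#'   fraction, avgDistance, avgAngle, turnClass) and \code{presence}
#'   (logical frames x pairs matrix named "acceptor>donor").
#' @export
detectHbonds <- function(traj, distCutoff = 3.0, angleCutoff = 135,
                         verbose = FALSE) {
  stopifnot(is(traj, "TrajectorySet"))
  atoms <- traj@atoms
  resIds <- sort(unique(atoms$resid))
  nF <- nFrames(traj)
  at <- function(i) matrix(traj@coords[, i, ], ncol = 3)
  getIdx <- function(res, name) {
    i <- which(atoms$resid == res & atoms$elety == name)
    if (length(i)) i[1] else NA_integer_
  }
  Oidx <- vapply(resIds, getIdx, 0L, name = "O")
  Nidx <- vapply(resIds, getIdx, 0L, name = "N")
  Hidx <- vapply(resIds, getIdx, 0L, name = "H")

  recs <- list()
  presence <- list()
  for (ai in seq_along(resIds)) {
    for (di in seq_along(resIds)) {
      if (abs(di - ai) < 2) next
      if (is.na(Oidx[ai]) || is.na(Nidx[di])) next
      if (is.na(Hidx[di])) {
        if (verbose)
          message("donor residue ", resIds[di],
                  " has no amide H; pair skipped")
        next
      }
      O <- at(Oidx[ai])
      N <- at(Nidx[di])
      H <- at(Hidx[di])
      dist <- sqrt(rowSums((O - N)^2))
      v1 <- N - H
      v2 <- O - H
      cosA <- rowSums(v1 * v2) /
        (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
      ang <- acos(pmin(pmax(cosA, -1), 1)) * 180 / pi
      present <- dist <= distCutoff & ang >= angleCutoff
      if (any(present)) {
        recs[[length(recs) + 1]] <- data.frame(
          acceptor = resIds[ai], donor = resIds[di],
          fraction = mean(present),
          avgDistance = mean(dist[present]),
          avgAngle = mean(ang[present]))
        presence[[length(presence) + 1]] <- present
        names(presence)[length(presence)] <-
          paste0(resIds[ai], ">", resIds[di])
      }
    }
  }
  if (!length(recs)) {
    records <- data.frame(acceptor = integer(), donor = integer(),
                          fraction = numeric(), avgDistance = numeric(),
                          avgAngle = numeric())
    presence <- matrix(FALSE, nF, 0)
  } else {
    records <- do.call(rbind, recs)
    ord <- order(records$acceptor, records$donor)
    records <- records[ord, , drop = FALSE]
    presence <- do.call(cbind, presence)[, ord, drop = FALSE]
    rownames(records) <- NULL
  }
  records <- classifyTurns(records)
  list(records = records, presence = presence)
}

#' Parse a residue label like "Gln6" or "Pol18" to its index
#'
#' The C-terminal amino-alcohol residue may be written "Pheol18" or
#' "Pol18"; both parse to 18.
#'
#' @param x Character labels or integers.
#' @return Integer residue indices.
#' @export
residueIndex <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  i <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", x)))
  if (anyNA(i)) stop("cannot parse residue label(s): ",
                     paste(x[is.na(i)], collapse = ", "))
  i
}

#' Turn-type classification of hydrogen bonds
#'
#' Classifies each backbone H-bond by the donor minus acceptor residue
#' offset: i+2 -> i bonds close a gamma turn (C7 ring), i+3 -> i a 3_10
#' helical turn, i+4 -> i an alpha-helical turn; anything else is
#' "other".
#'
#' @param records data.frame with \code{acceptor} and \code{donor} columns
#'   (integer indices or labels like "Ala3").
#' @return The records with a \code{turnClass} column added
#'   (\code{"i2_gamma"}, \code{"i3_310"}, \code{"i4_alpha"},
#'   \code{"other"}).
#' @examples
#' classifyTurns(data.frame(acceptor = "Ala3", donor = "Gln6"))
#' @export
classifyTurns <- function(records) {
  off <- residueIndex(records$donor) - residueIndex(records$acceptor)
  records$turnClass <- ifelse(off == 2, "i2_gamma",
                       ifelse(off == 3, "i3_310",
                       ifelse(off == 4, "i4_alpha", "other")))
  records
}

#' End-to-end distance profile and PMF
#'
#' Per-frame Euclidean distance between the first residue's backbone N and
#' the last residue's terminal heavy atom, with an optionally reweighted
#' 1D PMF -- the folding reaction coordinate distinguishing bent from
#' extended backbones.
#'
#' @param traj A \linkS4class{TrajectorySet}.
#' @param weights A \linkS4class{FrameWeights} or NULL.
#' @param bins Bins for the 1D PMF (default 50).
#' @param temperature Kelvin.
#' @return List with \code{distances} (per frame, Angstrom) and \code{pmf}
#'   (a \linkS4class{PMFGrid}).
#' @export
endToEnd <- function(traj, weights = NULL, bins = 50L, temperature = 300) {
  stopifnot(is(traj, "TrajectorySet"))
  atoms <- traj@atoms
  firstRes <- min(atoms$resid)
  lastRes <- max(atoms$resid)
  i1 <- which(atoms$resid == firstRes & atoms$elety == "N")
  if (!length(i1)) stop("first residue has no backbone N")
  i1 <- i1[1]
  heavy <- which(atoms$resid == lastRes & atoms$element != "H")
  if (!length(heavy)) stop("last residue has no heavy atoms")
  i2 <- heavy[length(heavy)]
  a <- matrix(traj@coords[, i1, ], nFrames(traj))
  b <- matrix(traj@coords[, i2, ], nFrames(traj))
  dist <- sqrt(rowSums((a - b)^2))
  pmf <- reweightHistogram(dist, weights, breaks = bins,
                           temperature = temperature,
                           axisNames = "end_to_end")
  list(distances = dist, pmf = pmf)
}
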