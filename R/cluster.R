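#' @include pca.R
NULL

#' Density-peak clustering in principal component space
#'
#' Histograms the top-k PC projections on a regular grid, selects all
#' cells whose density exceeds \code{threshold} times the maximum density,
#' groups contiguous above-threshold cells into clusters (each cluster's
#' peak is its densest cell) and assigns frames: frames falling in a
#' cluster's cells or within one grid cell of them join that cluster
#' (nearest peak wins on ties), remaining frames within
#' \code{leftoverRadius} cells (Euclidean, cell units) of a peak join the
#' nearest peak, everything else stays unassigned (label 0). Clusters are
#' reported in descending occupancy, occupancy being the fraction of all
#' frames.
#'
#' @param model A \linkS4class{PCModel}.
#' @param nComponents Number of leading PCs to cluster over (2-5 supported,
#'   default 3).
#' @param bins Grid bins per axis (default 50).
#' @param threshold Density threshold as a fraction of the maximum density,
#'   in (0, 1].
#' @param leftoverRadius Euclidean assignment radius for leftover frames,
#'   grid cells.
#' @return A \linkS4class{ClusterAssignment}.
#' @export
densityCluster <- function(model, nComponents = 3L, bins = 50L,
                           threshold = 0.1, leftoverRadius = 2) {
  stopifnot(is(model, "PCModel"))
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  k <- as.integer(nComponents)
  if (k < 2 || k > 5) stop("nComponents must be between 2 and 5")
  if (k > ncol(model@projections))
    stop("model has fewer than ", k, " components")
  X <- model@projections[, seq_len(k), drop = FALSE]
  n <- nrow(X)

  idx <- matrix(0L, n, k)
  for (j in seq_len(k)) {
    rng <- range(X[, j])
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1], rng[2], length.out = bins + 1)
    i <- findInterval(X[, j], edges, rightmost.closed = TRUE)
    idx[, j] <- pmin(pmax(i, 1L), bins)
  }
  key <- as.integer(idx[, 1])
  for (j in seq_len(k)[-1]) key <- key + (idx[, j] - 1L) * bins^(j - 1)
  counts <- table(key)
  cellKeys <- as.integer(names(counts))
  cellCounts <- as.integer(counts)
  maxd <- max(cellCounts)
  above <- cellKeys[cellCounts >= threshold * maxd]
  aboveCounts <- cellCounts[cellCounts >= threshold * maxd]

  decode <- function(keys) {
    m <- matrix(0L, length(keys), k)
    rem <- keys - 1L
    for (j in seq_len(k)) {
      m[, j] <- rem %% bins + 1L
      rem <- rem %/% bins
    }
    m
  }
  aboveIdx <- decode(above)

  # connected components among above-threshold cells (Chebyshev <= 1)
  nA <- length(above)
  comp <- integer(nA)
  nComp <- 0L
  for (s in order(-aboveCounts)) {
    if (comp[s] != 0L) next
    nComp <- nComp + 1L
    queue <- s
    comp[s] <- nComp
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      cheb <- apply(abs(aboveIdx - matrix(aboveIdx[cur, ], nA, k,
                                          byrow = TRUE)), 1, max)
      nb <- which(cheb <= 1 & comp == 0L)
      comp[nb] <- nComp
      queue <- c(queue, nb)
    }
  }

  peakCell <- vapply(seq_len(nComp), function(cc) {
    members <- which(comp == cc)
    members[which.max(aboveCounts[members])]
  }, 0L)
  peakIdx <- aboveIdx[peakCell, , drop = FALSE]

  # frame assignment: member cells, then a 1-cell halo, then leftovers by
  # nearest peak within leftoverRadius cells
  cellComp <- integer(0)
  cellComp[match(above, cellKeys)] <- comp
  frameCellPos <- match(key, cellKeys)
  labels <- integer(n)
  inAbove <- !is.na(match(key, above))
  labels[inAbove] <- comp[match(key[inAbove], above)]

  un <- which(labels == 0L)
  if (length(un)) {
    dPeak <- vapply(seq_len(nComp), function(cc)
      sqrt(rowSums((idx[un, , drop = FALSE] -
                    matrix(peakIdx[cc, ], length(un), k,
                           byrow = TRUE))^2)), numeric(length(un)))
    dPeak <- matrix(dPeak, nrow = length(un))
    for (ui in seq_along(un)) {
      f <- un[ui]
      delta <- aboveIdx - matrix(idx[f, ], nA, k, byrow = TRUE)
      cheb <- apply(abs(delta), 1, max)
      cand <- unique(comp[cheb <= 1])
      if (length(cand) == 1L) {
        labels[f] <- cand
      } else if (length(cand) > 1L) {
        labels[f] <- cand[which.min(dPeak[ui, cand])]
      } else {
        # leftovers: Euclidean distance (cell units) to the nearest cell
        # of each cluster's region
        dCell <- sqrt(rowSums(delta^2))
        dComp <- vapply(seq_len(nComp), function(cc)
          min(dCell[comp == cc]), 0)
        if (min(dComp) <= leftoverRadius) {
          near <- which(dComp <= min(dComp) + 1e-9)
          labels[f] <- if (length(near) == 1L) near
                       else near[which.min(dPeak[ui, near])]
        }
      }
    }
  }

  occ <- vapply(seq_len(nComp), function(cc) sum(labels == cc), 0L) / n
  ord <- order(-occ)
  relabel <- integer(nComp)
  relabel[ord] <- seq_len(nComp)
  labels <- ifelse(labels == 0L, 0L, relabel[labels])
  occ <- occ[ord]
  peakIdx <- peakIdx[ord, , drop = FALSE]

  # peak coordinates in PC units and representative frames
  peakPC <- matrix(NA_real_, nComp, k)
  for (j in seq_len(k)) {
    rng <- range(X[, j])
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    w <- diff(rng) / bins
    peakPC[, j] <- rng[1] + (peakIdx[, j] - 0.5) * w
  }
  rep <- vapply(seq_len(nComp), function(cc) {
    members <- which(labels == cc)
    d <- rowSums((X[members, , drop = FALSE] -
                  matrix(peakPC[cc, ], length(members), k, byrow = TRUE))^2)
    members[which.min(d)]
  }, 0L)

  new("ClusterAssignment", labels = as.integer(labels), occupancy = occ,
      representative = rep, peaks = peakPC, nComponents = k)
}

#' Cluster occupancy timeline and transition counts
#'
#' Returns the per-frame cluster label series along the trajectory and a
#' transition-count matrix between clusters (counted over consecutive
#' assigned frames with differing labels), supporting statements about
#' mutually exclusive or interconverting metastable states.
#'
#' @param assign A \linkS4class{ClusterAssignment}.
#' @param frameTimes Monotone non-decreasing frame times (default frame
#'   index).
#' @return List with \code{timeline} (data.frame time, cluster) and
#'   \code{transitions} (K x K matrix of counts, zero diagonal).
#' @export
clusterTimeline <- function(assign, frameTimes = NULL) {
  stopifnot(is(assign, "ClusterAssignment"))
  lab <- assign@labels
  if (is.null(frameTimes)) frameTimes <- seq_along(lab)
  if (length(frameTimes) != length(lab))
    stop("frameTimes length must match the number of frames")
  if (is.unsorted(frameTimes)) stop("frameTimes must be monotone")
  K <- length(assign@occupancy)
  trans <- matrix(0L, K, K,
                  dimnames = list(seq_len(K), seq_len(K)))
  a <- lab[-length(lab)]
  b <- lab[-1]
  ok <- a > 0L & b > 0L & a != b
  if (any(ok))
    for (i in which(ok)) trans[a[i], b[i]] <- trans[a[i], b[i]] + 1L
  list(timeline = data.frame(time = frameTimes, cluster = lab),
       transitions = trans)
}
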