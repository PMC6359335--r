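#' @include cluster.R
NULL

#' Gaussian kernel density estimate on a fixed grid
#'
#' Estimates the probability distribution of a projection series with a
#' Gaussian kernel on a shared, equally spaced grid and normalises it to
#' sum to 1. Using a KDE (rather than a raw histogram) keeps the
#' distribution smooth and lets unpopulated regions be flagged and
#' excluded from divergence sums. Prefix semantics: only the first
#' \code{horizon} samples enter the estimate, i.e. all data from time 0
#' to t.
#'
#' @param x Numeric sample (projection series).
#' @param grid Equally spaced evaluation points; default 512 points
#'   spanning the sample padded by 3 bandwidths.
#' @param bandwidth Gaussian bandwidth; default Silverman's rule on the
#'   used prefix.
#' @param horizon Number of leading samples to use (default all).
#' @param segment Segment id recorded on the result.
#' @return A \linkS4class{KDEHistogram}.
#' @export
kdeHistogram <- function(x, grid = NULL, bandwidth = NULL, horizon = NULL,
                         segment = 1L) {
  if (is.null(horizon)) horizon <- length(x)
  if (horizon < 2) stop("need at least 2 samples at the requested horizon")
  x <- x[seq_len(horizon)]
  if (is.null(bandwidth)) {
    bandwidth <- stats::bw.nrd0(x)
    if (bandwidth <= 0) bandwidth <- 1e-3 * max(abs(x), 1)
  }
  if (bandwidth <= 0) stop("bandwidth must be positive")
  if (is.null(grid))
    grid <- seq(min(x) - 3 * bandwidth, max(x) + 3 * bandwidth,
                length.out = 512)
  d <- stats::density(x, bw = bandwidth, from = grid[1],
                      to = grid[length(grid)], n = length(grid))
  y <- pmax(d$y, 0)
  if (sum(y) <= 0)
    stop("evaluation grid does not cover the sample")
  y <- y / sum(y)
  new("KDEHistogram", grid = grid, density = y, bandwidth = bandwidth,
      segment = as.integer(segment), horizon = as.integer(horizon))
}

#' Kullback-Leibler divergence between two gridded distributions
#'
#' KLD = sum_i P_i ln(P_i / Q_i) over the grid points where both
#' distributions are populated (P_i > 0 and Q_i > 0); both are
#' renormalised over that common support before summing, mirroring the
#' exclusion of bins with no population. Asymmetric in (P, Q);
#' KLD(P, P) = 0.
#'
#' @param P,Q \linkS4class{KDEHistogram}s on the same grid.
#' @return Non-negative divergence (nats).
#' @export
kld <- function(P, Q) {
  stopifnot(is(P, "KDEHistogram"), is(Q, "KDEHistogram"))
  if (length(P@grid) != length(Q@grid) ||
      max(abs(P@grid - Q@grid)) > 1e-9)
    stop("P and Q must share the same evaluation grid")
  supp <- P@density > 0 & Q@density > 0
  if (!any(supp))
    stop("disjoint supports: Kullback-Leibler divergence undefined")
  p <- P@density[supp] / sum(P@density[supp])
  q <- Q@density[supp] / sum(Q@density[supp])
  max(sum(p * log(p / q)), 0)
}

#' Time-dependent KLD between replica distributions
#'
#' For each replica pair and growing time horizon t, builds Gaussian-KDE
#' distributions of the PC projection from the first t-fraction of each
#' replica and evaluates their Kullback-Leibler divergence. A pair is
#' flagged converged at the first horizon after which the KLD stays below
#' \code{cutoff} through the final horizon; a pair whose KLD rises above
#' the cutoff again after once dipping under it is not converged until it
#' re-enters for good -- replicas that diverge late (a mid-run jump to a
#' new basin) therefore lose the flag.
#'
#' @param replicas List of numeric projection series (one per replica), or
#'   a \linkS4class{PCModel} whose segments define the replicas.
#' @param component PC index used when \code{replicas} is a PCModel.
#' @param pairs List of length-2 integer vectors; default consecutive
#'   pairs (1-2, 2-3, ...).
#' @param evalFractions Horizons as fractions of each replica's length
#'   (default every 5 percent).
#' @param cutoff Convergence cutoff on the KLD value (default 0.025).
#' @param gridPoints Shared evaluation grid size.
#' @return A \linkS4class{KLDSeries}.
#' @export
kldTimeseries <- function(replicas, component = 1L, pairs = NULL,
                          evalFractions = seq(0.05, 1, by = 0.05),
                          cutoff = 0.025, gridPoints = 512L) {
  if (is(replicas, "PCModel")) {
    segs <- sort(unique(replicas@segments))
    replicas <- lapply(segs, function(s)
      replicas@projections[replicas@segments == s, component])
  }
  if (length(replicas) < 2) stop("need at least 2 replicas")
  if (is.unsorted(evalFractions, strictly = TRUE))
    stop("evaluation times must be increasing")
  if (is.null(pairs))
    pairs <- lapply(seq_len(length(replicas) - 1), function(i) c(i, i + 1))
  pairLabels <- vapply(pairs, paste, "", collapse = "-")

  kmat <- matrix(NA_real_, length(evalFractions), length(pairs),
                 dimnames = list(NULL, pairLabels))
  for (pi in seq_along(pairs)) {
    a <- replicas[[pairs[[pi]][1]]]
    b <- replicas[[pairs[[pi]][2]]]
    bwFull <- max(stats::bw.nrd0(a), stats::bw.nrd0(b), 1e-8)
    rng <- range(c(a, b))
    grid <- seq(rng[1] - 3 * bwFull, rng[2] + 3 * bwFull,
                length.out = gridPoints)
    for (ti in seq_along(evalFractions)) {
      na <- max(2L, ceiling(evalFractions[ti] * length(a)))
      nb <- max(2L, ceiling(evalFractions[ti] * length(b)))
      P <- kdeHistogram(a, grid = grid, horizon = na,
                        segment = pairs[[pi]][1])
      Q <- kdeHistogram(b, grid = grid, horizon = nb,
                        segment = pairs[[pi]][2])
      kmat[ti, pi] <- kld(P, Q)
    }
  }
  slopes <- rbind(NA_real_, apply(kmat, 2, diff) /
                              diff(evalFractions))
  dim(slopes) <- dim(kmat)
  below <- kmat < cutoff
  convTime <- rep(NA_real_, length(pairs))
  converged <- logical(length(pairs))
  for (pi in seq_along(pairs)) {
    runEnd <- rev(cumprod(rev(below[, pi]))) == 1
    if (any(runEnd)) {
      converged[pi] <- TRUE
      convTime[pi] <- evalFractions[which(runEnd)[1]]
    }
  }
  new("KLDSeries", times = evalFractions, kldValues = kmat,
      slopes = slopes, pairs = pairLabels, converged = converged,
      convergenceTime = convTime, cutoff = cutoff)
}
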