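#' @include io.R
NULL

#' Heat-map of a 2D PMF grid
#'
#' @param grid A 2D \linkS4class{PMFGrid}.
#' @param main Plot title.
#' @param maxPmf Color-scale ceiling, kcal/mol.
#' @importFrom graphics image axis box legend lines
#' @importFrom grDevices hcl.colors
#' @export
plotPmf <- function(grid, main = "PMF", maxPmf = NULL) {
  stopifnot(is(grid, "PMFGrid"), length(grid@axes) == 2)
  z <- grid@pmf
  if (!is.null(maxPmf)) z[z > maxPmf] <- maxPmf
  cent <- axisCenters(grid)
  image(cent[[1]], cent[[2]], z, col = rev(hcl.colors(64, "Viridis")),
        xlab = grid@axes[[1]]$name, ylab = grid@axes[[2]]$name,
        main = main, useRaster = TRUE)
  box()
  invisible(NULL)
}

#' Line plot of replica KLD time series
#'
#' One line per replica pair ("KLD:1" = first pair, etc.) with the
#' convergence cutoff marked.
#'
#' @param klds A \linkS4class{KLDSeries}.
#' @param main Plot title.
#' @importFrom graphics matplot abline legend
#' @export
plotKld <- function(klds, main = "KLD vs time") {
  stopifnot(is(klds, "KLDSeries"))
  matplot(klds@times, klds@kldValues, type = "l", lty = 1,
          xlab = "trajectory fraction", ylab = "KLD", main = main)
  abline(h = klds@cutoff, lty = 2)
  legend("topright", legend = paste0("KLD:", seq_along(klds@pairs)),
         col = seq_along(klds@pairs), lty = 1, bty = "n")
  invisible(NULL)
}
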