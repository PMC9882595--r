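#' Simulate an actin stress-fiber scene with planted co-alignment
#'
#' Renders smooth periodic fibre stripes inside each focal adhesion's
#' Voronoi region (regions of the FA centroids clipped to the cell
#' boundary), at the orientation `theta_FA + offset` planted for that
#' adhesion. Stripe profiles are Gaussian across the fibre axis, with their
#' full width at half maximum tuned so the stroked area fraction matches
#' `areaFraction`. A companion adhesion-channel image with
#' Gaussian-intensity ellipses at the planted positions is also rendered.
#'
#' @param dim image dimensions `c(nrow, ncol)`.
#' @param cellPolygon two-column (x, y) polygon of the cell boundary.
#' @param faEllipses data.frame with `cx`, `cy`, `a`, `b`, `theta_fa_deg`
#'   and `offset_deg` (the planted fibre-to-adhesion angular offset).
#' @param areaFraction target stress-fibre area fraction within the cell.
#' @param period stripe period in pixels.
#' @param intensity peak fibre intensity (counts).
#' @param noiseSd Gaussian noise SD added to the actin image (0 = none).
#' @param seed integer seed.
#' @return list with `actin` (matrix), `faImage` (matrix), `cellMask`,
#'   `sfTruthMask` (stroked pixels), `regionLabel` (planted Voronoi
#'   regions) and `faTruth` (per adhesion: `label`, `centroid_x/y`,
#'   `theta_fa_deg`, `theta_sf_true_deg`, `theta_rel_deg`).
#' @export
simulateSfScene <- function(dim = c(256, 256), cellPolygon, faEllipses,
                            areaFraction = 0.15, period = 12,
                            intensity = 500, noiseSd = 0, seed = NULL) {
  cell <- polygonMask(cellPolygon, dim)
  if (!any(cell)) stop("empty cell polygon")
  n <- nrow(faEllipses)
  stopifnot(n >= 1)
  cent <- data.frame(label = seq_len(n),
                     x = faEllipses$cx, y = faEllipses$cy)
  regions <- voronoiRegions(cent, cell)
  g <- coordGrids(dim)
  width <- areaFraction * period / (2 * sqrt(2 * log(2)))  # FWHM tuning

  actin <- matrix(0, dim[1], dim[2])
  truthMask <- matrix(FALSE, dim[1], dim[2])
  faTruth <- do.call(rbind, lapply(seq_len(n), function(i) {
    e <- faEllipses[i, ]
    thetaFiber <- wrapAxialDeg(e$theta_fa_deg + e$offset_deg)
    t <- degToRad(thetaFiber)
    inRegion <- regions$label == i
    ## coordinate perpendicular to the fibre axis
    perp <- -g$x * sin(t) + g$y * cos(t)
    phase <- (perp %% period) - period / 2
    prof <- exp(-phase^2 / (2 * width^2))
    actin[inRegion] <<- intensity * prof[inRegion]
    ## stroked pixels: brightest areaFraction of the region, selected by
    ## rank (deterministic index tie-break) so grid alignment cannot bias
    ## the stroked area
    idx <- which(inRegion)
    k <- round(areaFraction * length(idx))
    truthMask[idx[order(prof[idx], decreasing = TRUE)[seq_len(k)]]] <<- TRUE
    data.frame(label = i, centroid_x = e$cx, centroid_y = e$cy,
               theta_fa_deg = wrapAxialDeg(e$theta_fa_deg),
               theta_sf_true_deg = thetaFiber,
               theta_rel_deg = axialDiffDeg(thetaFiber, e$theta_fa_deg))
  }))
  faImage <- matrix(0, dim[1], dim[2])
  for (i in seq_len(n)) {
    e <- faEllipses[i, ]
    t <- degToRad(e$theta_fa_deg)
    dx <- g$x - e$cx; dy <- g$y - e$cy
    u <- dx * cos(t) + dy * sin(t); v <- -dx * sin(t) + dy * cos(t)
    faImage <- faImage + intensity * exp(-((u / e$a)^2 + (v / e$b)^2) / 0.5)
  }
  if (noiseSd > 0)
    actin <- withSeed(seed, actin +
                        matrix(rnorm(length(actin), 0, noiseSd),
                               dim[1], dim[2]))
  actin[!cell] <- 0
  list(actin = actin, faImage = faImage, cellMask = cell,
       sfTruthMask = truthMask & cell, regionLabel = regions$label,
       faTruth = faTruth)
}
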