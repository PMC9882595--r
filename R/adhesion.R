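#' Segment focal adhesions by intensity flooding
#'
#' Smooths the image, thresholds it inside the cell boundary, splits
#' touching blobs at watershed lines of the inverted intensity surface
#' (regions grow from local maxima by descending-intensity flooding), and
#' filters by minimum area.
#'
#' @param image single-channel matrix.
#' @param boundary cell boundary: a two-column polygon (x, y; 0-based pixel
#'   centres) or a logical mask of the same dimensions.
#' @param sigma Gaussian smoothing sigma in pixels.
#' @param threshold seed threshold: if `< 1`, a quantile of the smoothed
#'   intensity within the cell; otherwise an absolute intensity.
#' @param minArea minimum blob area in pixels.
#' @param tolerance watershed flooding tolerance (minimum object depth).
#' @return integer label matrix (0 = background), labels renumbered
#'   consecutively.
#' @export
segmentFas <- function(image, boundary, sigma = 1, threshold = 0.995,
                       minArea = 10, tolerance = 0.1) {
  cell <- if (is.matrix(boundary) && is.logical(boundary)) boundary
          else polygonMask(boundary, dim(image))
  if (!any(cell)) stop("empty cell boundary")
  sm <- if (sigma > 0) ebimg(EBImage::gblur(image, sigma = sigma))
        else image
  th <- if (threshold < 1) quantile(sm[cell], threshold)
        else threshold
  fg <- sm > th & cell
  if (!any(fg)) return(matrix(0L, nrow(image), ncol(image)))
  surf <- sm - min(sm)
  surf[!fg] <- 0
  lab <- ebimg(EBImage::watershed(EBImage::as.Image(surf),
                                  tolerance = tolerance))
  ## filter small blobs and renumber
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= minArea)
  out <- matrix(0L, nrow(image), ncol(image))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  out
}

## EBImage returns Image objects; strip back to a plain matrix
ebimg <- function(x) {
  m <- as.matrix(EBImage::imageData(x))
  m
}

#' Binary central moments of a blob
#'
#' Central moments `u_ij = sum (x - xbar)^i (y - ybar)^j` over the blob's
#' pixel set with unit weight per pixel (`u00` is the area). Coordinates are
#' 0-based pixel centres, x = column, y = row.
#'
#' @param pixels two-column matrix or data.frame of (x, y) pixel coordinates,
#'   or a logical matrix (the TRUE pixels form the blob).
#' @return list with `u00`, `u20`, `u02`, `u11`, `centroid` (x, y).
#' @export
blobMoments <- function(pixels) {
  if (is.matrix(pixels) && is.logical(pixels)) {
    idx <- which(pixels, arr.ind = TRUE)
    pixels <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
  }
  pixels <- as.matrix(pixels)
  if (nrow(pixels) == 0) stop("empty pixel set")
  x <- pixels[, 1]; y <- pixels[, 2]
  xb <- mean(x); yb <- mean(y)
  list(u00 = nrow(pixels),
       u20 = sum((x - xb)^2), u02 = sum((y - yb)^2),
       u11 = sum((x - xb) * (y - yb)),
       centroid = c(x = xb, y = yb))
}

#' Equivalent-ellipse metrics from blob moments
#'
#' Forms the normalised second-moment matrix
#' `[[u20, u11], [u11, u02]] / u00`, adds the unit-pixel-square variance
#' `1/12` to the diagonal (each pixel is a unit square, so a `w x h`
#' rectangle of pixels recovers the continuous moments `w^2/12`, `h^2/12`),
#' and reports the equivalent ellipse: full axis lengths `4 sqrt(lambda)`,
#' axis ratio `major/minor`, and orientation
#' `theta = atan2(2 u11, u20 - u02) / 2` from the +x axis, reduced to
#' `[0, pi)`.
#'
#' @param m moments from [blobMoments()].
#' @param pixelCorrection logical; set FALSE for pure point moments.
#' @return list with `major`, `minor` (full lengths, px), `axisRatio`,
#'   `theta` (radians, axial; NA when the blob is isotropic), `degenerate`
#'   (TRUE when the minor eigenvalue vanishes).
#' @export
faEllipseMetrics <- function(m, pixelCorrection = TRUE) {
  if (m$u00 <= 0) stop("u00 must be positive")
  corr <- if (pixelCorrection) 1 / 12 else 0
  mxx <- m$u20 / m$u00 + corr
  myy <- m$u02 / m$u00 + corr
  mxy <- m$u11 / m$u00
  tr <- mxx + myy
  disc <- sqrt(((mxx - myy) / 2)^2 + mxy^2)
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  l2 <- max(l2, 0)
  degenerate <- l2 < 1e-12
  iso <- disc < 1e-9 * max(tr, 1e-12)
  list(major = 4 * sqrt(l1), minor = 4 * sqrt(l2),
       axisRatio = if (degenerate) Inf else sqrt(l1 / l2),
       theta = if (iso) NA_real_
               else (atan2(2 * mxy, mxx - myy) / 2) %% pi,
       degenerate = degenerate)
}

#' Per-cell focal adhesion summary
#'
#' Computes, for every labelled adhesion, its area, centroid,
#' equivalent-ellipse metrics and mean intensity in each supplied channel,
#' plus the cell-level adhesion count and the axial circular standard
#' deviation of adhesion orientations (doubled-angle method).
#'
#' @param labels integer label matrix from [segmentFas()].
#' @param intensity named list of matrices to average within each adhesion
#'   (e.g. a FRET efficiency map), or NULL.
#' @return list with `fa` (per-adhesion data.frame: `label`, `area_px`,
#'   `centroid_x`, `centroid_y`, `major_px`, `minor_px`, `axis_ratio`,
#'   `theta_fa_deg`, mean intensities) and `cell` (data.frame: `n_fa`,
#'   `orientation_sd_deg`, `mean_area_px`, `mean_axis_ratio`).
#' @export
cellFaSummary <- function(labels, intensity = NULL) {
  ids <- sort(unique(labels[labels > 0]))
  fa <- do.call(rbind, lapply(ids, function(id) {
    mask <- labels == id
    m <- blobMoments(mask)
    e <- faEllipseMetrics(m)
    row <- data.frame(label = id, area_px = m$u00,
                      centroid_x = m$centroid["x"],
                      centroid_y = m$centroid["y"],
                      major_px = e$major, minor_px = e$minor,
                      axis_ratio = e$axisRatio,
                      theta_fa_deg = radToDeg(e$theta))
    for (ch in names(intensity))
      row[[paste0("mean_", ch)]] <- mean(intensity[[ch]][mask], na.rm = TRUE)
    row
  }))
  if (is.null(fa)) fa <- data.frame(label = integer(), area_px = numeric(),
                                    centroid_x = numeric(),
                                    centroid_y = numeric())
  rownames(fa) <- NULL
  th <- fa$theta_fa_deg[is.finite(fa$theta_fa_deg)]
  cell <- data.frame(
    n_fa = nrow(fa),
    orientation_sd_deg = if (length(th) >= 2) axialSdDeg(th) else NA_real_,
    mean_area_px = if (nrow(fa)) mean(fa$area_px) else NA_real_,
    mean_axis_ratio = if (nrow(fa)) mean(fa$axis_ratio[is.finite(fa$axis_ratio)])
                      else NA_real_)
  list(fa = fa, cell = cell)
}

#' Cytosol mask: cell interior away from adhesions
#'
#' Pixels inside the cell boundary whose Euclidean distance to the nearest
#' adhesion pixel exceeds `dilationRadius` (i.e. the adhesion mask dilated
#' by that radius, then inverted within the cell).
#'
#' @param faMask logical adhesion mask (or label matrix; nonzero = adhesion).
#' @param boundary polygon or logical cell mask (see [segmentFas()]).
#' @param dilationRadius dilation radius in pixels, >= 0.
#' @return logical matrix.
#' @export
cytosolMask <- function(faMask, boundary, dilationRadius = 10) {
  if (dilationRadius < 0) stop("dilationRadius must be >= 0")
  fa <- faMask > 0
  cell <- if (is.matrix(boundary) && is.logical(boundary)) boundary
          else polygonMask(boundary, dim(fa))
  if (!any(fa)) return(cell)
  ## distance of every pixel to the nearest adhesion pixel
  d <- ebimg(EBImage::distmap(EBImage::as.Image(!fa), metric = "euclidean"))
  cell & d > dilationRadius
}
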