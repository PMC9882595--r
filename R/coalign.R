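## Scharr gradients (separable 3-10-3 smoothing x central difference),
## replicate-padded; the 3-10-3 cross-smoothing minimises the angular bias
## of plain central differences on oblique high-frequency patterns.
## x = column, y = row.
.gradients <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  dcol <- function(m) {
    p <- m[, c(1, seq_len(nc), nc)]
    (p[, 3:(nc + 2)] - p[, 1:nc]) / 2
  }
  drow <- function(m) {
    p <- m[c(1, seq_len(nr), nr), ]
    (p[3:(nr + 2), ] - p[1:nr, ]) / 2
  }
  scol <- function(m) {
    p <- m[, c(1, seq_len(nc), nc)]
    (3 * p[, 1:nc] + 10 * p[, 2:(nc + 1)] + 3 * p[, 3:(nc + 2)]) / 16
  }
  srow <- function(m) {
    p <- m[c(1, seq_len(nr), nr), ]
    (3 * p[1:nr, ] + 10 * p[2:(nr + 1), ] + 3 * p[3:(nr + 2), ]) / 16
  }
  list(Ix = srow(dcol(img)), Iy = scol(drow(img)))
}

.smooth <- function(img, sigma)
  if (sigma > 0) ebimg(EBImage::gblur(img, sigma = sigma)) else img

#' Per-pixel stress-fiber orientation via the structure tensor
#'
#' Computes Gaussian-smoothed image gradients, forms the structure tensor
#' `[[Ix^2, Ix Iy], [Ix Iy, Iy^2]]` smoothed component-wise at
#' `tensorSigma`, and eigen-decomposes it per pixel. The dominant
#' eigenvector of the structure tensor points along the intensity gradient,
#' perpendicular to a fibre; with the default `convention = "fiber"` the
#' reported orientation is that of the smaller eigenvalue's eigenvector, so
#' fibres are recovered at their drawn angle. `convention = "gradient"`
#' reports the dominant-eigenvector angle instead (90 degrees away).
#' Pixels whose dominant eigenvalue `l1` falls below
#' `validFloor x max(l1)` are flagged invalid.
#'
#' @param image single-channel matrix.
#' @param gradientSigma Gaussian sigma (px) applied before differentiation.
#' @param tensorSigma Gaussian sigma (px) smoothing the tensor components.
#' @param validFloor relative floor on `l1` for the validity mask.
#' @param convention `"fiber"` or `"gradient"`.
#' @return an [OrientationField-class].
#' @export
structureTensorField <- function(image, gradientSigma = 1, tensorSigma = 4,
                                 validFloor = 1e-3,
                                 convention = c("fiber", "gradient")) {
  convention <- match.arg(convention)
  stopifnot(gradientSigma >= 0, tensorSigma >= 0)
  gr <- .gradients(.smooth(image, gradientSigma))
  Jxx <- .smooth(gr$Ix^2, tensorSigma)
  Jyy <- .smooth(gr$Iy^2, tensorSigma)
  Jxy <- .smooth(gr$Ix * gr$Iy, tensorSigma)
  tr <- Jxx + Jyy
  disc <- sqrt(((Jxx - Jyy) / 2)^2 + Jxy^2)
  l1 <- tr / 2 + disc
  l2 <- pmax(tr / 2 - disc, 0)
  gradAngle <- atan2(2 * Jxy, Jxx - Jyy) / 2
  theta <- if (convention == "fiber") (gradAngle + pi / 2) %% pi
           else gradAngle %% pi
  top <- max(l1)
  valid <- if (top > 0) l1 > validFloor * top
           else matrix(FALSE, nrow(image), ncol(image))
  theta[!valid] <- NA_real_
  new("OrientationField", theta = theta, l1 = l1, l2 = l2,
      valid = valid, convention = convention)
}

#' Stress-fiber mask from a tensor field
#'
#' Valid pixels whose dominant eigenvalue `l1` (gradient-energy magnitude)
#' exceeds a threshold: an absolute value, a quantile of `l1` over valid
#' pixels, or Otsu's threshold.
#'
#' @param field an [OrientationField-class].
#' @param rule `"quantile"`, `"absolute"` or `"otsu"`.
#' @param value threshold value (quantile must be in (0, 1)).
#' @param within optional logical matrix restricting the quantile/Otsu
#'   computation (e.g. the cell mask).
#' @return logical matrix.
#' @export
sfMask <- function(field, rule = c("quantile", "absolute", "otsu"),
                   value = 0.9, within = NULL) {
  rule <- match.arg(rule)
  l1 <- tensorEnergy(field); valid <- validityMask(field)
  scope <- if (is.null(within)) valid else valid & within
  th <- switch(rule,
    quantile = {
      if (value <= 0 || value >= 1) stop("quantile must be in (0, 1)")
      quantile(l1[scope], value)
    },
    absolute = value,
    otsu = {
      r <- range(l1[scope])
      EBImage::otsu(EBImage::as.Image((l1 - r[1]) / diff(r)),
                    range = c(0, 1)) * diff(r) + r[1]
    })
  valid & l1 > th & (if (is.null(within)) TRUE else within)
}

#' Axial standard deviation of stress-fiber orientations
#'
#' Circular standard deviation on doubled angles, halved back to axial
#' degrees, over the masked pixels of an orientation field.
#'
#' @param field an [OrientationField-class].
#' @param mask logical matrix (e.g. from [sfMask()]).
#' @return degrees; NA (flagged undefined) with fewer than 2 masked pixels.
#' @export
sfOrientationSd <- function(field, mask) {
  th <- orientationMap(field)[mask & validityMask(field)]
  th <- th[is.finite(th)]
  if (length(th) < 2) return(NA_real_)
  axialSdDeg(radToDeg(th))
}

#' Voronoi regions of focal-adhesion centroids within a cell
#'
#' Assigns every pixel of the cell interior to its nearest adhesion
#' centroid (Euclidean distance on the pixel grid; ties break
#' deterministically to the lowest label). The regions partition the cell
#' mask exactly.
#'
#' @param centroids data.frame with `label`, `x`, `y` (0-based pixel
#'   coordinates).
#' @param cell logical cell mask or two-column boundary polygon.
#' @param dim image dimensions, required when `cell` is a polygon.
#' @return list with `label` (integer matrix, 0 outside the cell; values
#'   are `centroids$label`), `areas` (data.frame `label`, `area_px`).
#' @export
voronoiRegions <- function(centroids, cell, dim = NULL) {
  if (!is.matrix(cell) || !is.logical(cell)) {
    if (is.null(dim)) stop("dim is required when cell is a polygon")
    cell <- polygonMask(cell, dim)
  }
  stopifnot(nrow(centroids) >= 1)
  if (anyDuplicated(centroids[, c("x", "y")]))
    warning("duplicate centroids; ties broken to the lowest label")
  g <- coordGrids(dim(cell))
  px <- g$x[cell]; py <- g$y[cell]
  best <- rep(1L, length(px)); bestD <- rep(Inf, length(px))
  for (i in seq_len(nrow(centroids))) {
    d <- (px - centroids$x[i])^2 + (py - centroids$y[i])^2
    upd <- d < bestD            # strict: ties keep the earlier (lower) label
    best[upd] <- i; bestD[upd] <- d[upd]
  }
  lab <- matrix(0L, nrow(cell), ncol(cell))
  lab[cell] <- centroids$label[best]
  areas <- data.frame(label = centroids$label,
                      area_px = vapply(centroids$label,
                                       function(l) sum(lab == l), 1))
  list(label = lab, areas = areas)
}

#' Per-region stress-fiber density and FA-SF co-alignment
#'
#' For each Voronoi region: the stress-fibre density (percent of region
#' pixels in the fibre mask), the region's fibre orientation (axial mean of
#' per-pixel orientations over fibre pixels), and `theta_Rel`, the axial
#' distance between that orientation and the generating adhesion's
#' orientation, wrapped to `[0, 90]` degrees. Regions without fibre pixels
#' get density 0, an undefined orientation, and are excluded (flagged) from
#' the cell-level `theta_Rel` average.
#'
#' @param regions output of [voronoiRegions()].
#' @param mask logical stress-fibre mask (see [sfMask()]).
#' @param field an [OrientationField-class].
#' @param faTable data.frame with `label` and `theta_fa_deg` per adhesion.
#' @return data.frame (one row per region): `label`, `area_px`,
#'   `sf_density_pct`, `theta_sf_deg`, `theta_fa_deg`, `theta_rel_deg`,
#'   `has_sf`; cell-level unweighted means in attribute `"cell"`.
#' @export
regionMetrics <- function(regions, mask, field, faTable) {
  th <- orientationMap(field)
  out <- do.call(rbind, lapply(seq_len(nrow(faTable)), function(i) {
    l <- faTable$label[i]
    inR <- regions$label == l
    nR <- sum(inR)
    sfPix <- inR & mask
    nSf <- sum(sfPix)
    angles <- radToDeg(th[sfPix])
    angles <- angles[is.finite(angles)]
    thetaSf <- if (length(angles)) axialMeanDeg(angles) else NA_real_
    data.frame(label = l, area_px = nR,
               sf_density_pct = if (nR) 100 * nSf / nR else NA_real_,
               theta_sf_deg = thetaSf,
               theta_fa_deg = faTable$theta_fa_deg[i],
               theta_rel_deg = if (is.na(thetaSf)) NA_real_
                               else axialDiffDeg(thetaSf,
                                                 faTable$theta_fa_deg[i]),
               has_sf = nSf > 0)
  }))
  rownames(out) <- NULL
  attr(out, "cell") <- data.frame(
    mean_sf_density_pct = mean(out$sf_density_pct, na.rm = TRUE),
    mean_theta_rel_deg = mean(out$theta_rel_deg[out$has_sf], na.rm = TRUE),
    n_regions = nrow(out), n_regions_with_sf = sum(out$has_sf))
  out
}
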