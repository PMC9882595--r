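#' @importFrom stats median quantile rnorm runif rbinom rpois sd var approx
#'   aov TukeyHSD ptukey anova lm setNames t.test qnorm fft aggregate
#' @importFrom utils head tail combn
#' @import methods
NULL

## Evaluate expr under a local RNG state seeded with `seed`; the caller's
## .Random.seed is restored afterwards so generators are pure in (spec, seed).
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

degToRad <- function(deg) deg * pi / 180
radToDeg <- function(rad) rad * 180 / pi

#' Axial-angle utilities
#'
#' Orientations of fibres, adhesions and ellipses are axial: an angle and the
#' same angle plus 180 degrees describe the same undirected line. All summary
#' statistics therefore work on doubled angles (the standard trick mapping
#' axial data onto the circle), and results are halved back.
#'
#' `wrapAxialDeg` reduces angles to `[0, 180)`. `axialMeanDeg` is the
#' doubled-angle circular mean. `axialSdDeg` is the doubled-angle angular
#' deviation `sqrt(2 (1 - R))` (with `R` the mean resultant length of the
#' doubled angles), halved back to axial degrees; unlike the `-2 ln R`
#' form it is bounded, approaching `sqrt(2)/2` rad (about 40.5 degrees)
#' for uniformly distributed orientations. `axialDiffDeg` is the axial
#' distance between two orientations, in `[0, 90]`.
#'
#' @param theta,a,b orientations in degrees.
#' @return degrees; `axialDiffDeg` is always in `[0, 90]`.
#' @examples
#' axialDiffDeg(10, 170)   # 20: the two lines are 20 degrees apart
#' axialSdDeg(c(10, 170))  # about 10
#' @export
wrapAxialDeg <- function(theta) theta %% 180

#' @rdname wrapAxialDeg
#' @export
axialMeanDeg <- function(theta) {
  t2 <- degToRad(2 * theta)
  wrapAxialDeg(radToDeg(atan2(mean(sin(t2)), mean(cos(t2))) / 2))
}

#' @rdname wrapAxialDeg
#' @export
axialSdDeg <- function(theta) {
  if (length(theta) < 2) return(NA_real_)
  t2 <- degToRad(2 * theta)
  R <- sqrt(mean(cos(t2))^2 + mean(sin(t2))^2)
  R <- min(R, 1)
  radToDeg(sqrt(2 * (1 - R))) / 2
}

#' @rdname wrapAxialDeg
#' @export
axialDiffDeg <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Rasterise a polygon to a pixel mask
#'
#' Pixels use 0-based centre coordinates with `x` = column and `y` = row;
#' a pixel belongs to the mask when its centre falls inside the polygon.
#'
#' @param polygon two-column matrix (x, y) of vertices, open or closed.
#' @param dim image dimensions `c(nrow, ncol)` (rows are y, columns x).
#' @return logical matrix of the requested dimensions.
#' @export
polygonMask <- function(polygon, dim) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3) stop("polygon needs at least 3 vertices")
  nr <- dim[1]; nc <- dim[2]
  xs <- rep(seq_len(nc) - 1, each = nr)
  ys <- rep(seq_len(nr) - 1, times = nc)
  inside <- mgcv::in.out(rbind(polygon, polygon[1, ]), cbind(xs, ys))
  matrix(inside, nrow = nr, ncol = nc)
}

## row/column coordinate grids (0-based, x = column, y = row)
coordGrids <- function(dim) {
  list(x = matrix(rep(seq_len(dim[2]) - 1, each = dim[1]), dim[1], dim[2]),
       y = matrix(rep(seq_len(dim[1]) - 1, times = dim[2]), dim[1], dim[2]))
}
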