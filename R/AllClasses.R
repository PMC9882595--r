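#' PmfProfile: a 1-D potential of mean force
#'
#' Holds a reconstructed potential of mean force (PMF) on a reaction
#' coordinate grid, together with the WHAM convergence report. The PMF is
#' defined up to an additive constant; the constructor anchors the minimum of
#' the reliable region at zero.
#'
#' @slot xi numeric, bin centres of the reaction coordinate (Angstrom).
#' @slot pmf numeric, PMF values at `xi` (units given by `unit`).
#' @slot unit character, energy unit (`"kT"`, `"kcal/mol"` or `"kJ/mol"`).
#' @slot reliable logical, bins with sufficient sampling across windows.
#' @slot convergence list with `iterations`, `residual`, `converged`.
#'
#' @seealso [whamSolve()], [deltaG()]
#' @exportClass PmfProfile
setClass("PmfProfile",
  representation(xi = "numeric", pmf = "numeric", unit = "character",
                 reliable = "logical", convergence = "list"),
  validity = function(object) {
    msg <- NULL
    if (length(object@xi) != length(object@pmf))
      msg <- c(msg, "xi and pmf lengths differ")
    if (length(object@reliable) != length(object@xi))
      msg <- c(msg, "reliable mask length differs from grid")
    if (is.unsorted(object@xi, strictly = TRUE))
      msg <- c(msg, "xi grid must be strictly increasing")
    if (!object@unit %in% c("kT", "kcal/mol", "kJ/mol"))
      msg <- c(msg, "unit must be kT, kcal/mol or kJ/mol")
    if (is.null(msg)) TRUE else msg
  })

#' EfficiencyImage: pixelwise sensitized-emission FRET efficiency
#'
#' Result container of the three-channel FRET pipeline: the corrected FRET
#' image `Fc`, the proportionality constant `G`, the raw (unclamped)
#' efficiency, the `[0, 1]`-clamped efficiency, and the validity mask
#' (pixels where the total donor signal `Id + Fc/G` is positive).
#'
#' @slot E matrix, clamped efficiency in `[0, 1]` (NA outside mask).
#' @slot rawE matrix, pre-clamp efficiency (NA outside mask).
#' @slot Fc matrix, bleed-through-corrected FRET signal (negatives retained).
#' @slot G numeric(1), sensitized-emission proportionality constant, > 0.
#' @slot mask logical matrix, pixels with a defined efficiency.
#'
#' @seealso [efficiencyImage()], [correctedFretImage()], [estimateGFactor()]
#' @exportClass EfficiencyImage
setClass("EfficiencyImage",
  representation(E = "matrix", rawE = "matrix", Fc = "matrix",
                 G = "numeric", mask = "matrix"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@E)
    if (!identical(d, dim(object@Fc)) || !identical(d, dim(object@mask)) ||
        !identical(d, dim(object@rawE)))
      msg <- c(msg, "E, rawE, Fc and mask dimensions differ")
    if (length(object@G) != 1 || !is.finite(object@G) || object@G <= 0)
      msg <- c(msg, "G must be a single positive number")
    ev <- object@E[object@mask]
    if (length(ev) && (min(ev, na.rm = TRUE) < 0 || max(ev, na.rm = TRUE) > 1))
      msg <- c(msg, "clamped E outside [0,1]")
    if (is.null(msg)) TRUE else msg
  })

#' OrientationField: per-pixel structure-tensor orientation
#'
#' Eigen-decomposition of the smoothed structure tensor of an actin image:
#' per-pixel eigenvalues `l1 >= l2 >= 0`, the fibre orientation `theta`
#' (radians, axial in `[0, pi)`) and a validity mask (pixels whose dominant
#' eigenvalue exceeds the configured floor).
#'
#' @slot theta matrix, fibre orientation in radians, axial (NA where invalid).
#' @slot l1 matrix, dominant eigenvalue (gradient-energy magnitude).
#' @slot l2 matrix, minor eigenvalue.
#' @slot valid logical matrix.
#' @slot convention character, `"fiber"` (eigenvector of the smaller
#'   eigenvalue; fibre-parallel) or `"gradient"` (larger eigenvector).
#'
#' @seealso [structureTensorField()], [sfMask()], [sfOrientationSd()]
#' @exportClass OrientationField
setClass("OrientationField",
  representation(theta = "matrix", l1 = "matrix", l2 = "matrix",
                 valid = "matrix", convention = "character"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@theta)
    if (!identical(d, dim(object@l1)) || !identical(d, dim(object@l2)) ||
        !identical(d, dim(object@valid)))
      msg <- c(msg, "component dimensions differ")
    if (any(object@l2 > object@l1 + 1e-9, na.rm = TRUE))
      msg <- c(msg, "l2 exceeds l1")
    if (!object@convention %in% c("fiber", "gradient"))
      msg <- c(msg, "convention must be 'fiber' or 'gradient'")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "PmfProfile", function(object) {
  cat(sprintf("PmfProfile: %d bins over xi = [%.3g, %.3g] %s\n",
              length(object@xi), min(object@xi), max(object@xi), "Angstrom"))
  cat(sprintf("  unit: %s | range: %.4g | reliable bins: %d/%d\n",
              object@unit, diff(range(object@pmf[object@reliable])),
              sum(object@reliable), length(object@reliable)))
  cv <- object@convergence
  cat(sprintf("  WHAM: %d iterations, residual %.3g (%s)\n",
              cv$iterations, cv$residual,
              if (isTRUE(cv$converged)) "converged" else "NOT converged"))
})

setMethod("show", "EfficiencyImage", function(object) {
  cat(sprintf("EfficiencyImage: %d x %d px | G = %.4g\n",
              nrow(object@E), ncol(object@E), object@G))
  ev <- object@E[object@mask]
  cat(sprintf("  masked pixels: %d | mean E = %.4g\n",
              length(ev), mean(ev)))
})

setMethod("show", "OrientationField", function(object) {
  cat(sprintf("OrientationField (%s convention): %d x %d px, %d valid\n",
              object@convention, nrow(object@theta), ncol(object@theta),
              sum(object@valid)))
})
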