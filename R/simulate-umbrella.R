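#' Simulate umbrella-sampling windows from a known 1-D potential
#'
#' Draws samples from the biased Boltzmann density
#' `p_i(xi) ∝ exp(-[U(xi) + k/2 (xi - xi0_i)^2] / kT)` for each window
#' centre, by exact inverse-CDF sampling on a fine grid (no Markov chain, no
#' burn-in). This gives seedable, exactly reproducible window samples whose
#' underlying potential is known, so a WHAM estimator can be validated
#' against numerically integrated truth.
#'
#' @param potential function of `xi` returning `U(xi)` in kT units, or a
#'   two-column matrix/data.frame `(xi, U)` that is linearly interpolated.
#' @param centers numeric vector of window centres `xi0_i` (Angstrom).
#' @param springConstant harmonic constant `k` in kT per Angstrom squared,
#'   `>= 0` (0 gives unbiased sampling of `U`).
#' @param nSamples samples per window, `>= 1`.
#' @param kT energy scale (the internal unit; defaults to 1).
#' @param xiRange range of the reaction coordinate sampled.
#' @param gridSize fine-grid resolution for the inverse CDF.
#' @param seed integer seed.
#' @return list of umbrella windows, each a list with `center`, `k`,
#'   `samples` (and the common `kT`); suitable for [whamSolve()].
#' @export
simulateUmbrellaWindows <- function(potential, centers, springConstant,
                                    nSamples, kT = 1,
                                    xiRange = range(centers) + c(-3, 3),
                                    gridSize = 4096, seed = NULL) {
  if (nSamples < 1) stop("nSamples must be >= 1")
  if (springConstant < 0) stop("springConstant must be >= 0")
  U <- if (is.function(potential)) potential else {
    tab <- as.matrix(potential)
    function(x) approx(tab[, 1], tab[, 2], x, rule = 2)$y
  }
  xi <- seq(xiRange[1], xiRange[2], length.out = gridSize)
  u <- U(xi)
  if (any(!is.finite(u))) stop("potential not finite on the grid")
  withSeed(seed, {
    windows <- lapply(centers, function(x0) {
      e <- (u + springConstant / 2 * (xi - x0)^2) / kT
      w <- exp(-(e - min(e)))
      cdf <- cumsum(w)
      cdf <- cdf / cdf[length(cdf)]
      ## invert the CDF by linear interpolation (strictly increasing on
      ## the support; drop duplicated plateau values)
      keep <- c(TRUE, diff(cdf) > 0)
      s <- approx(cdf[keep], xi[keep], runif(nSamples), rule = 2)$y
      list(center = x0, k = springConstant, kT = kT, samples = s)
    })
    windows
  })
}

#' Reference double-well potential
#'
#' A smooth double-well on `[0, 20]` Angstrom used throughout the tests: a
#' bound basin, a barrier, and a flat unbound plateau, with tunable well
#' depth relative to the plateau.
#'
#' @param depth well depth in kT (plateau minus basin minimum).
#' @return function of `xi` returning energy in kT.
#' @export
doubleWellPotential <- function(depth = 3) {
  function(xi) {
    well <- -depth * exp(-(xi - 4)^2 / 2)
    barrier <- 1.5 * exp(-(xi - 8)^2 / 1.5)
    well + barrier
  }
}
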