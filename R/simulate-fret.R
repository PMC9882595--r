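## rasterise a rotated ellipse; 0-based pixel-centre coordinates
ellipseMask <- function(dim, cx, cy, a, b, thetaDeg = 0) {
  g <- coordGrids(dim)
  t <- degToRad(thetaDeg)
  dx <- g$x - cx; dy <- g$y - cy
  u <- dx * cos(t) + dy * sin(t)
  v <- -dx * sin(t) + dy * cos(t)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Simulate a three-channel sensitized-emission FRET scene
#'
#' Builds donor, FRET and acceptor channel images of elliptical focal
#' adhesions with known FRET efficiency, under the forward model that the
#' quantification pipeline inverts. Per pixel, with donor budget `D` and
#' direct acceptor signal `A` inside an adhesion:
#' donor signal `D (1 - E)`, sensitized emission `G D E`, FRET-channel
#' signal `dbt D (1 - E) + abt A + G D E`, acceptor signal `A`. Each raw
#' channel is `shading x (background + signal) + dark`, optionally with
#' Poisson shot noise on the shaded photon count and Gaussian read noise.
#'
#' @param dim image dimensions `c(nrow, ncol)` in pixels.
#' @param faEllipses data.frame with columns `cx`, `cy`, `a`, `b`,
#'   `theta_deg`, `donor_level`, `acceptor_level`, `E_true` (in `[0, 1]`).
#' @param dbt,abt true donor/acceptor bleed-through coefficients in `[0, 1)`.
#' @param G true sensitized-emission proportionality constant, > 0.
#' @param darkLevel camera dark level (counts), added unshaded.
#' @param backgroundLevel uniform background signal (counts).
#' @param shading flat-field map (matrix, mean-normalised internally) or 1.
#' @param noise NULL for a noiseless scene, or a list with `poisson`
#'   (logical) and `readSd` (Gaussian read noise SD in counts).
#' @param seed integer seed (noise only).
#' @return list with `channels` (matrices `donor`, `fret`, `acceptor`),
#'   `faMask` (logical), `faLabel` (integer matrix, 0 = background) and
#'   `truth` (all generating parameters, per-ellipse table included).
#' @export
simulateFretScene <- function(dim = c(128, 128), faEllipses,
                              dbt = 0.25, abt = 0.12, G = 2.8,
                              darkLevel = 100, backgroundLevel = 20,
                              shading = 1, noise = NULL, seed = NULL) {
  if (any(faEllipses$E_true < 0 | faEllipses$E_true > 1))
    stop("E_true must be in [0, 1]")
  if (dbt < 0 || dbt >= 1 || abt < 0 || abt >= 1)
    stop("bleed-through coefficients must be in [0, 1)")
  if (G <= 0) stop("G must be positive")
  if (is.matrix(shading) && !identical(dim(shading), as.integer(dim)))
    stop("shading dimensions do not match the image dimensions")
  sh <- if (is.matrix(shading)) shading / mean(shading)
        else matrix(1, dim[1], dim[2])
  if (any(sh <= 0)) stop("shading must be strictly positive")

  sigD <- matrix(0, dim[1], dim[2])
  sigF <- matrix(0, dim[1], dim[2])
  sigA <- matrix(0, dim[1], dim[2])
  faLabel <- matrix(0L, dim[1], dim[2])
  for (i in seq_len(nrow(faEllipses))) {
    e <- faEllipses[i, ]
    m <- ellipseMask(dim, e$cx, e$cy, e$a, e$b, e$theta_deg)
    sigD[m] <- e$donor_level * (1 - e$E_true)
    sigA[m] <- e$acceptor_level
    sigF[m] <- dbt * e$donor_level * (1 - e$E_true) +
      abt * e$acceptor_level + G * e$donor_level * e$E_true
    faLabel[m] <- i
  }
  forward <- function(sig) sh * (backgroundLevel + sig) + darkLevel
  channels <- list(donor = forward(sigD), fret = forward(sigF),
                   acceptor = forward(sigA))
  if (!is.null(noise)) {
    channels <- withSeed(seed, lapply(channels, function(ch) {
      photons <- ch - darkLevel
      if (isTRUE(noise$poisson))
        photons <- matrix(rpois(length(photons), pmax(photons, 0)),
                          nrow(ch), ncol(ch))
      readSd <- if (is.null(noise$readSd)) 0 else noise$readSd
      ch <- photons + darkLevel
      if (readSd > 0)
        ch <- ch + matrix(rnorm(length(ch), 0, readSd), nrow(ch), ncol(ch))
      ch
    }))
  }
  list(channels = channels, faMask = faLabel > 0, faLabel = faLabel,
       truth = list(faEllipses = faEllipses, dbt = dbt, abt = abt, G = G,
                    darkLevel = darkLevel,
                    backgroundLevel = backgroundLevel, shading = sh,
                    signals = list(donor = sigD, fret = sigF,
                                   acceptor = sigA)))
}

#' @importFrom stats rpois
NULL
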