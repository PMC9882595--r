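## pN exerted by 1 kcal/mol per Angstrom (4184 J/mol / N_A / 1e-10 m)
.KCALMOL_PER_ANGSTROM_IN_PN <- 69.48

#' Solve the 1-D WHAM equations for umbrella-sampling windows
#'
#' Reconstructs the unbiased probability `P(b)` on a reaction-coordinate
#' histogram and the per-window free-energy shifts `f_i` from harmonically
#' biased window samples, by Jacobi (simultaneous) iteration of the standard
#' WHAM self-consistency equations:
#' `P(b) = M(b) / sum_i N_i c_i(b) exp(f_i/kT)` and
#' `exp(-f_i/kT) = sum_b c_i(b) P(b)`, with bias factors
#' `c_i(b) = exp(-k_i (x_b - xi0_i)^2 / (2 kT))`. The potential of mean
#' force is `-kT ln P`, anchored so its minimum over reliable bins is zero.
#'
#' @param windows list of windows, each with `center`, `k` (kT per Angstrom
#'   squared) and `samples`; see [simulateUmbrellaWindows()].
#' @param nBins number of histogram bins over the sampled range.
#' @param kT energy unit scale.
#' @param tol convergence tolerance: maximum absolute change of any `f_i`
#'   (in kT) per iteration.
#' @param maxIter iteration cap; exceeding it is an error that reports the
#'   final residual.
#' @return a [PmfProfile-class]; bins never visited by any sample are
#'   flagged unreliable (`validityMask`) and carry `NA` PMF.
#' @export
whamSolve <- function(windows, nBins = 100, kT = 1, tol = 1e-7,
                      maxIter = 1e5) {
  stopifnot(length(windows) >= 1, tol > 0)
  samples <- lapply(windows, `[[`, "samples")
  if (any(vapply(samples, length, 1L) < 1)) stop("window with no samples")
  .warnOnWindowGaps(windows)
  rng <- range(unlist(samples))
  edges <- seq(rng[1], rng[2], length.out = nBins + 1)
  xb <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- vapply(samples, function(s) {
    idx <- findInterval(s, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    tabulate(idx, nBins)
  }, numeric(nBins))                      # nBins x nWindows
  M <- rowSums(counts)
  N <- colSums(counts)
  k <- vapply(windows, `[[`, 1, "k")
  x0 <- vapply(windows, `[[`, 1, "center")
  ## bias factors c_i(b), nBins x nWindows
  C <- exp(-outer(xb, seq_along(windows),
                  function(b, i) k[i] * (b - x0[i])^2) / (2 * kT))
  logz <- rep(0, length(windows))         # f_i = -kT * logz_i
  iter <- 0L; residual <- Inf
  while (iter < maxIter) {
    iter <- iter + 1L
    denom <- as.vector(C %*% (N / exp(logz)))
    P <- ifelse(denom > 0, M / denom, 0)
    P <- P / sum(P)
    logzNew <- log(as.vector(crossprod(C, P)))
    residual <- max(abs(logzNew - logz))
    logz <- logzNew
    if (residual < tol) break
  }
  if (residual >= tol)
    stop(sprintf("WHAM did not converge in %d iterations (residual %.3g kT)",
                 as.integer(maxIter), residual))
  reliable <- M > 0
  pmf <- rep(NA_real_, nBins)
  pmf[reliable] <- -kT * log(P[reliable])
  pmf <- pmf - min(pmf[reliable])
  new("PmfProfile", xi = xb, pmf = pmf, unit = "kT", reliable = reliable,
      convergence = list(iterations = iter, residual = residual,
                         converged = TRUE))
}

.warnOnWindowGaps <- function(windows) {
  if (length(windows) < 2) return(invisible())
  o <- order(vapply(windows, `[[`, 1, "center"))
  rngs <- lapply(windows[o], function(w) range(w$samples))
  for (i in seq_len(length(rngs) - 1))
    if (rngs[[i]][2] < rngs[[i + 1]][1])
      warning(sprintf(
        "umbrella windows %d and %d do not overlap along xi; bins between %.3g and %.3g are unreliable",
        i, i + 1, rngs[[i]][2], rngs[[i + 1]][1]))
  invisible()
}

#' Binding free energy from a PMF profile
#'
#' `deltaG` is the mean PMF over the unbound plateau minus the minimum PMF
#' over the bound region. Defaults: the bound region is the whole grid (the
#' global minimum) and the unbound plateau is the last 10 percent of the
#' reliable grid.
#'
#' @param pmf a [PmfProfile-class].
#' @param boundRegion,unboundRegion length-2 xi intervals (Angstrom).
#' @return list with `deltaG`, `unit`, `boundRegion`, `unboundRegion`.
#' @export
deltaG <- function(pmf, boundRegion = NULL, unboundRegion = NULL) {
  xi <- pmfGrid(pmf); v <- pmfValues(pmf); ok <- validityMask(pmf)
  xr <- range(xi[ok])
  if (is.null(boundRegion)) boundRegion <- xr
  if (is.null(unboundRegion))
    unboundRegion <- c(xr[2] - 0.1 * diff(xr), xr[2])
  inB <- ok & xi >= boundRegion[1] & xi <= boundRegion[2]
  inU <- ok & xi >= unboundRegion[1] & xi <= unboundRegion[2]
  if (!any(inB) || !any(inU)) stop("region outside the reliable grid")
  list(deltaG = mean(v[inU]) - min(v[inB]), unit = energyUnit(pmf),
       boundRegion = boundRegion, unboundRegion = unboundRegion)
}

#' Enumerate a constant-force pulling protocol grid
#'
#' Expands a force sweep into the full condition list: every combination of
#' force (from `fMin` to `fMax` inclusive at spacing `step`), pulling
#' direction and replicate. The default protocol (0-150 pN at 1 pN, three
#' directions, ten replicates) comprises 4530 pulling simulations.
#'
#' @param fMin,fMax,step force sweep in pN; `fMax >= fMin`, `step > 0`.
#' @param directions character vector of pulling directions.
#' @param replicates replicate runs per condition, >= 1.
#' @return list with `conditions` (data.frame `force_pN`, `direction`,
#'   `replicate`) and `count`.
#' @export
enumeratePullingGrid <- function(fMin = 0, fMax = 150, step = 1,
                                 directions = c("F_P", "F_B", "F_N"),
                                 replicates = 10) {
  if (fMax < fMin) stop("fMax must be >= fMin")
  if (step <= 0) stop("step must be positive")
  if (replicates < 1) stop("replicates must be >= 1")
  forces <- seq(fMin, fMax, by = step)
  conditions <- expand.grid(force_pN = forces, direction = directions,
                            replicate = seq_len(replicates),
                            KEEP.OUT.ATTRS = FALSE,
                            stringsAsFactors = FALSE)
  list(conditions = conditions, count = nrow(conditions))
}

#' Force quantum of a discretized constant-force pulling step
#'
#' A discretized step potential with energy jump `dE` (kcal/mol) at distance
#' intervals `dR` (Angstrom) exerts a constant force `f = dE/dR`, converted
#' to piconewtons with 1 kcal/mol/Angstrom = 69.48 pN.
#'
#' @param dE energy jump in kcal/mol.
#' @param dR distance interval in Angstrom, > 0.
#' @return force in pN.
#' @examples
#' forceQuantumPn(0.015, 1)  # about 1.04 pN: a 1 pN sampling quantum
#' @export
forceQuantumPn <- function(dE, dR = 1) {
  if (any(dR <= 0)) stop("dR must be positive")
  dE / dR * .KCALMOL_PER_ANGSTROM_IN_PN
}
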