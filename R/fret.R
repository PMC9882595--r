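#' Estimate a rigid translation between two images
#'
#' Cross-correlation via FFT with parabolic sub-pixel refinement of the
#' correlation peak. Suitable for the shift-dominated misalignment of a
#' single-camera filter-wheel acquisition.
#'
#' @param ref,img matrices of identical dimensions.
#' @return numeric `c(dy, dx)`: the translation that maps `img` onto `ref`.
#' @export
estimateShift <- function(ref, img) {
  stopifnot(identical(dim(ref), dim(img)))
  r <- ref - mean(ref); m <- img - mean(img)
  cc <- Re(fft(fft(r) * Conj(fft(m)), inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  nr <- nrow(cc); nc <- ncol(cc)
  sub <- function(idx, n, along) {
    ## parabolic fit through the peak and its two neighbours (circular)
    i0 <- idx; im <- (idx - 2) %% n + 1; ip <- idx %% n + 1
    y <- if (along == 1) c(cc[im, pk[2]], cc[i0, pk[2]], cc[ip, pk[2]])
         else c(cc[pk[1], im], cc[pk[1], i0], cc[pk[1], ip])
    d <- y[1] - 2 * y[2] + y[3]
    if (d == 0) 0 else 0.5 * (y[1] - y[3]) / d
  }
  shift <- c(pk[1] - 1 + sub(pk[1], nr, 1), pk[2] - 1 + sub(pk[2], nc, 2))
  ## wrap to signed shifts; sign convention: img == shiftImage(ref, shift)
  shift[1] <- ifelse(shift[1] > nr / 2, shift[1] - nr, shift[1])
  shift[2] <- ifelse(shift[2] > nc / 2, shift[2] - nc, shift[2])
  unname(-shift)
}

#' Translate an image by (dy, dx)
#'
#' Integer part by index shifting, fractional part by bilinear
#' interpolation; uncovered pixels are filled with `fill`.
#'
#' @param img matrix.
#' @param shift numeric `c(dy, dx)`.
#' @param fill value for uncovered pixels.
#' @return matrix of the same dimensions.
#' @export
shiftImage <- function(img, shift, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(fill, nr, nc)
  iy <- floor(shift[1]); ix <- floor(shift[2])
  fy <- shift[1] - iy; fx <- shift[2] - ix
  place <- function(dy, dx, w) {
    if (w == 0) return()
    sr <- max(1, 1 + dy):min(nr, nr + dy)
    sc <- max(1, 1 + dx):min(nc, nc + dx)
    out[sr, sc] <<- out[sr, sc] + w * img[sr - dy, sc - dx, drop = FALSE]
  }
  base <- matrix(0, nr, nc); out <- base
  place(iy, ix, (1 - fy) * (1 - fx))
  place(iy + 1, ix, fy * (1 - fx))
  place(iy, ix + 1, (1 - fy) * fx)
  place(iy + 1, ix + 1, fy * fx)
  out
}

#' Correct raw FRET channels for dark current, shading and background
#'
#' Per channel: subtract the dark level, divide by the mean-normalised
#' shading (flat-field) image, register the FRET and acceptor channels onto
#' the donor channel by translation, and subtract the background estimated
#' as the median over a cell-free region.
#'
#' @param raw list of matrices `donor`, `fret`, `acceptor`.
#' @param dark per-channel dark level: scalar, matrix, or named list.
#' @param shading per-channel flat-field: 1, matrix, or named list; strictly
#'   positive.
#' @param backgroundMask logical matrix marking a cell-free region, or NULL
#'   to skip background subtraction.
#' @param register logical; estimate and undo channel translations.
#' @param maxShift warn when a recovered shift exceeds this many pixels.
#' @return list with `channels` (corrected matrices), `shifts` (per-channel
#'   `c(dy, dx)`), `background` (per-channel subtracted level).
#' @export
preprocessChannels <- function(raw, dark = 0, shading = 1,
                               backgroundMask = NULL, register = TRUE,
                               maxShift = 10) {
  chan <- c("donor", "fret", "acceptor")
  stopifnot(all(chan %in% names(raw)))
  pick <- function(x, ch) if (is.list(x)) x[[ch]] else x
  corrected <- lapply(chan, function(ch) {
    sh <- pick(shading, ch)
    if (is.matrix(sh)) {
      if (any(sh <= 0)) stop("shading contains non-positive values")
      sh <- sh / mean(sh)
    }
    (raw[[ch]] - pick(dark, ch)) / sh
  })
  names(corrected) <- chan
  shifts <- list(donor = c(0, 0), fret = c(0, 0), acceptor = c(0, 0))
  if (register) {
    for (ch in c("fret", "acceptor")) {
      s <- estimateShift(corrected$donor, corrected[[ch]])
      if (max(abs(s)) > maxShift)
        warning(sprintf("%s channel shift (%.2f, %.2f) exceeds %g px",
                        ch, s[1], s[2], maxShift))
      shifts[[ch]] <- s
      if (any(abs(s) > 1e-3))
        corrected[[ch]] <- shiftImage(corrected[[ch]], -s)
    }
  }
  background <- setNames(rep(0, 3), chan)
  if (!is.null(backgroundMask)) {
    for (ch in chan) {
      background[ch] <- median(corrected[[ch]][backgroundMask])
      corrected[[ch]] <- corrected[[ch]] - background[ch]
    }
  }
  list(channels = corrected, shifts = shifts, background = background)
}

.binnedBleedthrough <- function(If, Iref, nBins, what) {
  ok <- is.finite(Iref) & is.finite(If) & Iref > 0
  if (!any(ok)) stop("all ", what, "-channel pixels are zero or invalid")
  v <- Iref[ok]; r <- If[ok] / v
  edges <- unique(quantile(v, probs = seq(0, 1, length.out = nBins + 1)))
  if (length(edges) < 2) edges <- c(edges, edges)  # constant intensity
  bin <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  nb <- length(edges) - 1
  data.frame(
    bin = seq_len(nb),
    lo = edges[-length(edges)], hi = edges[-1],
    coefficient = vapply(seq_len(nb),
                         function(b) median(r[bin == b]), 1),
    n = tabulate(bin, nb))
}

#' Calibrate spectral bleed-through coefficients
#'
#' From corrected donor-only acquisitions, the donor bleed-through
#' coefficient is `dbt = If / Id`, binned by donor-channel intensity
#' (equal-count quantile bins, per-bin robust mean = median). The acceptor
#' coefficient `abt = If / Ia` is estimated symmetrically from acceptor-only
#' acquisitions, binned by acceptor-channel intensity. Zero-intensity pixels
#' are excluded.
#'
#' @param If,Id,Ia corrected channel matrices (donor-only acquisitions for
#'   `estimateDonorBleedthrough`, acceptor-only for the acceptor case).
#' @param nBins number of quantile bins.
#' @return data.frame with `bin`, `lo`, `hi`, `coefficient`, `n`; usable as
#'   a lookup in [correctedFretImage()].
#' @export
estimateDonorBleedthrough <- function(If, Id, nBins = 16)
  .binnedBleedthrough(If, Id, nBins, "donor")

#' @rdname estimateDonorBleedthrough
#' @export
estimateAcceptorBleedthrough <- function(If, Ia, nBins = 16)
  .binnedBleedthrough(If, Ia, nBins, "acceptor")

## resolve a bleed-through model (scalar or binned table) at intensities x;
## nearest-bin extrapolation outside the calibrated range
.btLookup <- function(model, x) {
  if (is.numeric(model) && length(model) == 1)
    return(rep(model, length(x)))
  idx <- findInterval(x, c(model$lo[1], model$hi),
                      rightmost.closed = TRUE, all.inside = TRUE)
  model$coefficient[idx]
}

#' Bleed-through-corrected FRET image
#'
#' `Fc = If - dbt(Id) * Id - abt(Ia) * Ia` per pixel. Negative values are
#' retained (not clipped) so that region averages stay unbiased.
#'
#' @param If,Id,Ia corrected FRET, donor and acceptor channel matrices.
#' @param dbt,abt bleed-through models: a scalar coefficient or a binned
#'   table from [estimateDonorBleedthrough()]; intensities outside the
#'   calibrated bins use the nearest bin.
#' @return matrix `Fc`.
#' @export
correctedFretImage <- function(If, Id, Ia, dbt, abt) {
  if (!identical(dim(If), dim(Id)) || !identical(dim(If), dim(Ia)))
    stop("channel dimensions differ")
  If - .btLookup(dbt, Id) * Id - .btLookup(abt, Ia) * Ia
}

#' Estimate the sensitized-emission proportionality constant G
#'
#' From two donor-acceptor fusion constructs of constant but different FRET
#' efficiency: `G = -Delta(Fc/Ia) / Delta(Id/Ia)`, with the per-construct
#' ratios taken as medians over the masked cell pixels.
#'
#' @param high,low lists with matrices `Fc`, `Id`, `Ia` for the high- and
#'   low-efficiency constructs.
#' @param maskHigh,maskLow logical matrices of cell pixels (default: all).
#' @return scalar `G`.
#' @export
estimateGFactor <- function(high, low, maskHigh = NULL, maskLow = NULL) {
  ratios <- function(acq, mask) {
    if (is.null(mask)) mask <- acq$Ia > 0
    ok <- mask & acq$Ia > 0
    c(f = median(acq$Fc[ok] / acq$Ia[ok]),
      d = median(acq$Id[ok] / acq$Ia[ok]))
  }
  rh <- ratios(high, maskHigh); rl <- ratios(low, maskLow)
  dd <- rh["d"] - rl["d"]
  if (abs(dd) < 1e-12)
    stop("degenerate construct pair: identical Id/Ia ratios")
  G <- unname(-(rh["f"] - rl["f"]) / dd)
  if (G <= 0) warning("estimated G is not positive; check construct order")
  G
}

#' Pixelwise FRET efficiency
#'
#' `E = (Fc/G) / (Id + Fc/G)`: the fraction of donor excitations transferred
#' to the acceptor, with `Fc/G` the donor-equivalent sensitized emission.
#' Pixels where `Id + Fc/G <= 0` are masked. Both the raw and the
#' `[0, 1]`-clamped efficiency are kept.
#'
#' @param Fc corrected FRET image from [correctedFretImage()].
#' @param Id corrected donor channel.
#' @param G proportionality constant, > 0.
#' @return an [EfficiencyImage-class].
#' @export
efficiencyImage <- function(Fc, Id, G) {
  if (length(G) != 1 || !is.finite(G) || G <= 0) stop("G must be > 0")
  if (!identical(dim(Fc), dim(Id))) stop("Fc and Id dimensions differ")
  s <- Fc / G
  denom <- Id + s
  mask <- is.finite(denom) & denom > 0
  raw <- matrix(NA_real_, nrow(Fc), ncol(Fc))
  raw[mask] <- s[mask] / denom[mask]
  new("EfficiencyImage", E = clamp(raw, 0, 1), rawE = raw, Fc = Fc,
      G = G, mask = mask)
}
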