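#' Read and write channel images as TIFF
#'
#' `writeImageTiff` stores a matrix as a single-channel TIFF: 16-bit
#' integer (values scaled by `scale` and clamped to `[0, 65535]`) or 32-bit
#' float. `readImageTiff` inverts the operation.
#'
#' @param img numeric matrix.
#' @param path file path.
#' @param bits 16 (integer) or 32 (float).
#' @param scale divisor applied on write (multiplier on read) for 16-bit.
#' @return `readImageTiff` returns a numeric matrix in original units.
#' @export
writeImageTiff <- function(img, path, bits = 16, scale = 1) {
  if (bits == 16) {
    tiff::writeTIFF(clamp(img / scale, 0, 65535) / 65535, path,
                    bits.per.sample = 16)
  } else {
    tiff::writeTIFF(img, path, bits.per.sample = 32, reduce = FALSE)
  }
  invisible(path)
}

#' @rdname writeImageTiff
#' @export
readImageTiff <- function(path, bits = 16, scale = 1) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  if (bits == 16) m * 65535 * scale else m
}

#' Write umbrella windows / samples in the two-file CSV layout
#'
#' Windows go to one CSV (`window_id`, `center`, `k`, `kT`), samples to
#' another (`window_id`, `xi`); [readUmbrellaCsv()] reassembles the window
#' list for [whamSolve()].
#'
#' @param windows window list (see [simulateUmbrellaWindows()]).
#' @param windowsPath,samplesPath file paths.
#' @return `readUmbrellaCsv` returns a window list.
#' @export
writeUmbrellaCsv <- function(windows, windowsPath, samplesPath) {
  w <- data.frame(window_id = seq_along(windows),
                  center = vapply(windows, `[[`, 1, "center"),
                  k = vapply(windows, `[[`, 1, "k"),
                  kT = vapply(windows, `[[`, 1, "kT"))
  s <- do.call(rbind, lapply(seq_along(windows), function(i)
    data.frame(window_id = i, xi = windows[[i]]$samples)))
  utils::write.csv(w, windowsPath, row.names = FALSE)
  utils::write.csv(s, samplesPath, row.names = FALSE)
  invisible(NULL)
}

#' @rdname writeUmbrellaCsv
#' @export
readUmbrellaCsv <- function(windowsPath, samplesPath) {
  w <- utils::read.csv(windowsPath)
  s <- utils::read.csv(samplesPath)
  lapply(seq_len(nrow(w)), function(i)
    list(center = w$center[i], k = w$k[i], kT = w$kT[i],
         samples = s$xi[s$window_id == w$window_id[i]]))
}
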