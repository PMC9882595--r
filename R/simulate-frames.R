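#' Simulate coordinate frames with planted H-bond occupancies
#'
#' Builds a trajectory-like set of coordinate snapshots in which each
#' requested donor-hydrogen-acceptor triplet satisfies the geometric H-bond
#' criteria (donor-acceptor distance, acceptor-donor-hydrogen angle) in
#' exactly `round(occupancy/100 * nFrames)` frames; in all other frames the
#' acceptor is placed beyond the distance cutoff. The donor sits at a
#' per-triplet offset, the hydrogen 1 Angstrom away along +x, and in
#' qualifying frames the acceptor at `daDistance` Angstrom from the donor at
#' `adhAngleDeg` degrees from the donor-hydrogen axis.
#'
#' @param requests data.frame with columns `donor`, `hydrogen`, `acceptor`
#'   (atom ids), `occupancy_pct` in `[0, 100]`, and optionally `da_distance`
#'   (default 3.0) and `adh_angle_deg` (default 10).
#' @param nFrames number of frames, >= 1.
#' @param seed integer seed; which frames qualify is drawn once per triplet.
#' @return a frame set: list with `atoms` (data.frame `atom_id`,
#'   `residue_id`, `role`) and `coords` (array `nFrames x nAtoms x 3`, in
#'   Angstrom).
#' @export
simulateCoordinateFrames <- function(requests, nFrames = 500, seed = NULL) {
  stopifnot(nFrames >= 1, nrow(requests) >= 1)
  if (any(requests$occupancy_pct < 0 | requests$occupancy_pct > 100))
    stop("requested occupancy must be in [0, 100]")
  if (is.null(requests$da_distance)) requests$da_distance <- 3.0
  if (is.null(requests$adh_angle_deg)) requests$adh_angle_deg <- 10
  ids <- c(rbind(requests$donor, requests$hydrogen, requests$acceptor))
  if (anyDuplicated(ids)) stop("duplicate atom ids across triplets")

  nA <- 3 * nrow(requests)
  atoms <- data.frame(
    atom_id = ids,
    residue_id = rep(seq_len(nrow(requests)), each = 3),
    role = rep(c("donor", "hydrogen", "acceptor"), nrow(requests)))
  coords <- array(0, dim = c(nFrames, nA, 3),
                  dimnames = list(NULL, ids, c("x", "y", "z")))
  withSeed(seed, {
    for (i in seq_len(nrow(requests))) {
      r <- requests[i, ]
      base <- c(20 * (i - 1), 0, 0)           # separate triplets spatially
      k <- round(r$occupancy_pct / 100 * nFrames)
      on_frames <- if (k > 0) sample.int(nFrames, k) else integer()
      a <- degToRad(r$adh_angle_deg)
      bonded <- base + r$da_distance * c(cos(a), sin(a), 0)
      unbonded <- base + c(6, 0, 0)           # beyond any sensible cutoff
      d <- matrix(base, nFrames, 3, byrow = TRUE)
      h <- matrix(base + c(1, 0, 0), nFrames, 3, byrow = TRUE)
      acc <- matrix(unbonded, nFrames, 3, byrow = TRUE)
      if (k > 0)
        acc[on_frames, ] <- matrix(bonded, k, 3, byrow = TRUE)
      coords[, 3 * i - 2, ] <- d
      coords[, 3 * i - 1, ] <- h
      coords[, 3 * i, ] <- acc
    }
  })
  list(atoms = atoms, coords = coords)
}

#' Write / read a frame set as a multi-model PDB file
#'
#' Minimal fixed-width writer and reader for MODEL/ATOM/ENDMDL records, so
#' frame sets can be exchanged with standard structural-biology tools.
#'
#' @param frameSet a frame set from [simulateCoordinateFrames()].
#' @param path file path.
#' @return `readFrameSetPdb` returns a frame set (roles are not stored in
#'   PDB and come back as `"other"`).
#' @export
writeFrameSetPdb <- function(frameSet, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nF <- dim(frameSet$coords)[1]
  nA <- dim(frameSet$coords)[2]
  for (f in seq_len(nF)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    for (a in seq_len(nA)) {
      xyz <- frameSet$coords[f, a, ]
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        a, substr(frameSet$atoms$atom_id[a], 1, 4), "GLY",
        frameSet$atoms$residue_id[a], xyz[1], xyz[2], xyz[3]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @rdname writeFrameSetPdb
#' @export
readFrameSetPdb <- function(path) {
  lines <- readLines(path)
  at <- grepl("^ATOM", lines)
  model <- cumsum(grepl("^MODEL", lines))[at]
  xyz <- cbind(as.numeric(substr(lines[at], 31, 38)),
               as.numeric(substr(lines[at], 39, 46)),
               as.numeric(substr(lines[at], 47, 54)))
  ids <- trimws(substr(lines[at], 13, 16))
  res <- as.integer(substr(lines[at], 23, 26))
  nF <- max(model)
  first <- model == 1
  nA <- sum(first)
  coords <- array(NA_real_, dim = c(nF, nA, 3),
                  dimnames = list(NULL, ids[first], c("x", "y", "z")))
  for (f in seq_len(nF)) coords[f, , ] <- xyz[model == f, , drop = FALSE]
  list(atoms = data.frame(atom_id = ids[first], residue_id = res[first],
                          role = "other"),
       coords = coords)
}
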