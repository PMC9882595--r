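#' Geometric hydrogen-bond criteria
#'
#' An H-bond between a donor (D), its hydrogen (H) and an acceptor (A) is
#' deemed present when the donor-acceptor distance is strictly below
#' `maxDistance` and the angle at the donor between the D-A and D-H vectors
#' (the acceptor-donor-hydrogen angle) is at most `maxAngle`. The defaults
#' (3.5 Angstrom, 30 degrees) are the standard criteria for analysing
#' molecular-dynamics trajectories of the Vt:F-actin complex.
#'
#' @param maxDistance donor-acceptor cutoff in Angstrom (strict `<`).
#' @param maxAngle acceptor-donor-hydrogen cutoff in degrees (inclusive).
#' @return an object of class `"hbondCriteria"`.
#' @export
hbondCriteria <- function(maxDistance = 3.5, maxAngle = 30) {
  if (maxDistance <= 0) stop("maxDistance must be positive")
  if (maxAngle <= 0 || maxAngle > 180) stop("maxAngle must be in (0, 180]")
  structure(list(maxDistance = maxDistance, maxAngle = maxAngle),
            class = "hbondCriteria")
}

#' Detect hydrogen bonds in a single coordinate frame
#'
#' @param frame data.frame with columns `atom_id`, `x`, `y`, `z` (Angstrom),
#'   or a matrix of coordinates with atom ids as row names.
#' @param triplets data.frame with columns `donor`, `hydrogen`, `acceptor`
#'   naming atom ids present in the frame.
#' @param criteria an [hbondCriteria()] object.
#' @return logical vector, one entry per triplet: bond present or not.
#' @export
detectHbonds <- function(frame, triplets, criteria = hbondCriteria()) {
  if (is.data.frame(frame)) {
    xyz <- as.matrix(frame[, c("x", "y", "z")])
    rownames(xyz) <- frame$atom_id
  } else xyz <- frame
  need <- c(triplets$donor, triplets$hydrogen, triplets$acceptor)
  missing <- setdiff(need, rownames(xyz))
  if (length(missing))
    stop("atoms not in frame: ", paste(missing, collapse = ", "))
  D <- xyz[triplets$donor, , drop = FALSE]
  H <- xyz[triplets$hydrogen, , drop = FALSE]
  A <- xyz[triplets$acceptor, , drop = FALSE]
  da <- A - D
  dh <- H - D
  dist <- sqrt(rowSums(da^2))
  cosang <- rowSums(da * dh) / (dist * sqrt(rowSums(dh^2)))
  ang <- radToDeg(acos(clamp(cosang, -1, 1)))
  unname(dist < criteria$maxDistance & ang <= criteria$maxAngle)
}

#' Per-run H-bond occupancy of a frame set
#'
#' Occupancy is the percentage of frames in which a bond satisfies the
#' geometric criteria.
#'
#' @param frameSet a frame set (see [simulateCoordinateFrames()]).
#' @inheritParams detectHbonds
#' @return data.frame: `donor`, `hydrogen`, `acceptor`, `occupancy_pct`.
#' @export
hbondOccupancy <- function(frameSet, triplets, criteria = hbondCriteria()) {
  nF <- dim(frameSet$coords)[1]
  if (is.null(nF) || nF == 0) stop("frame set has zero frames")
  present <- matrix(FALSE, nF, nrow(triplets))
  for (f in seq_len(nF)) {
    xyz <- frameSet$coords[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3,
                                         dimnames = list(dimnames(frameSet$coords)[[2]], NULL))
    present[f, ] <- detectHbonds(xyz, triplets, criteria)
  }
  data.frame(donor = triplets$donor, hydrogen = triplets$hydrogen,
             acceptor = triplets$acceptor,
             occupancy_pct = 100 * colMeans(present))
}

#' Build an occupancy profile from per-frame or per-replicate records
#'
#' Aggregates H-bond event records into per-(bond, direction, force)
#' occupancies. Per-run occupancy is `100 x` the fraction of frames with the
#' bond present; the per-force value is the arithmetic mean over replicate
#' runs (the per-replicate values are kept in the `"replicates"` attribute
#' so confidence intervals remain computable).
#'
#' @param events data.frame with columns `bond_id`, `direction`, `force_pN`,
#'   `replicate`, and either `present` (logical, one row per frame) or
#'   `occupancy_pct` (one row per replicate run).
#' @return data.frame `bond_id`, `direction`, `force_pN`, `occupancy_pct`,
#'   `n_replicates`, with attribute `"replicates"`.
#' @export
occupancyProfile <- function(events) {
  if (nrow(events) == 0) stop("no events: zero frames")
  key <- c("bond_id", "direction", "force_pN", "replicate")
  if ("present" %in% names(events)) {
    reps <- aggregate(list(occupancy_pct = 100 * as.numeric(events$present)),
                      events[key], mean)
  } else if ("occupancy_pct" %in% names(events)) {
    reps <- events[, c(key, "occupancy_pct")]
    if (anyDuplicated(reps[key]))
      stop("conflicting duplicate (bond, direction, force, replicate) rows")
  } else stop("events need a 'present' or 'occupancy_pct' column")
  if (any(reps$occupancy_pct < 0 | reps$occupancy_pct > 100))
    stop("occupancy outside [0, 100]")
  prof <- aggregate(list(occupancy_pct = reps$occupancy_pct),
                    reps[c("bond_id", "direction", "force_pN")], mean)
  nrep <- aggregate(list(n_replicates = reps$replicate),
                    reps[c("bond_id", "direction", "force_pN")],
                    function(z) length(unique(z)))
  prof <- merge(prof, nrep, by = c("bond_id", "direction", "force_pN"))
  prof <- prof[order(prof$bond_id, prof$direction, prof$force_pN), ]
  rownames(prof) <- NULL
  attr(prof, "replicates") <- reps
  prof
}

#' Classify H-bond lifetime from occupancy
#'
#' Occupancies of at least 40 percent are long-lived, `[20, 40)` medium
#' duration, and below 20 percent short-lived.
#'
#' @param occupancyPct numeric vector of occupancies in `[0, 100]`.
#' @return factor with levels `short`, `medium`, `long`.
#' @export
classifyLifetime <- function(occupancyPct) {
  if (any(!is.finite(occupancyPct)) ||
      any(occupancyPct < 0 | occupancyPct > 100))
    stop("occupancy must be in [0, 100]")
  cut(occupancyPct, breaks = c(-Inf, 20, 40, Inf), right = FALSE,
      labels = c("short", "medium", "long"))
}

#' Classify the force response of an occupancy profile
#'
#' Labels each (bond, direction) profile as one of `absent` (occupancy zero
#' everywhere), `induced` (below `epsBaseline` unloaded but appearing in the
#' analysis window), `lost` (present unloaded, reaching zero at some force
#' and staying zero), `strengthened` (mean occupancy over the upper half of
#' the window exceeds the lower half by more than `deltaTrend`, relative) or
#' `weakened` (everything else). Rules are applied in that order.
#'
#' @param profile output of [occupancyProfile()] (or any data.frame with
#'   `bond_id`, `direction`, `force_pN`, `occupancy_pct`). The smallest force
#'   on the grid (normally 0 pN) defines the baseline.
#' @param analysisWindow force range (pN) over which trends are judged; the
#'   default 123-132 pN is the dissociation range of the Vt:F-actin complex.
#' @param epsBaseline occupancy (%) below which a bond counts as absent at
#'   baseline for the `induced` rule.
#' @param deltaTrend minimum relative increase (upper vs lower half-window)
#'   to call `strengthened`.
#' @return data.frame `bond_id`, `direction`, `baseline_pct`, `response`.
#' @export
classifyForceResponse <- function(profile, analysisWindow = c(123, 132),
                                  epsBaseline = 5, deltaTrend = 0.1) {
  grid <- sort(unique(profile$force_pN))
  if (analysisWindow[1] < min(grid) || analysisWindow[2] > max(grid))
    stop("analysis window outside the force grid")
  groups <- unique(profile[c("bond_id", "direction")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    p <- profile[profile$bond_id == g$bond_id &
                   profile$direction == g$direction, ]
    p <- p[order(p$force_pN), ]
    data.frame(bond_id = g$bond_id, direction = g$direction,
               baseline_pct = p$occupancy_pct[1],
               response = .responseFromCurve(p$occupancy_pct, p$force_pN,
                                             analysisWindow, epsBaseline,
                                             deltaTrend))
  }))
  rownames(out) <- NULL
  out
}

#' Call DAFS bonds across the three pulling directions
#'
#' A bond is a directionally asymmetric force-strengthened (DAFS)
#' interaction when, pulled toward the pointed end (`F_P`), it is induced or
#' strengthened by force and long-lived at its occupancy peak inside the
#' analysis window, while never reaching long-lived occupancy at any force
#' when pulled toward the barbed end (`F_B`) or normal to the filament
#' (`F_N`). Directions without observations are treated as absent.
#'
#' @inheritParams classifyForceResponse
#' @return list with `calls` (per bond: `is_dafs` plus per-direction
#'   response and lifetime labels) and `counts` (per direction:
#'   `n_long`, `n_medium`, `n_short`, `n_total` over observed bonds).
#' @export
callDafs <- function(profile, analysisWindow = c(123, 132),
                     epsBaseline = 5, deltaTrend = 0.1) {
  if (anyDuplicated(profile[c("bond_id", "direction", "force_pN")]))
    stop("conflicting duplicate bond ids at the same force")
  resp <- classifyForceResponse(profile, analysisWindow, epsBaseline,
                                deltaTrend)
  inWin <- profile$force_pN >= analysisWindow[1] &
    profile$force_pN <= analysisWindow[2]
  peak <- aggregate(list(peak_pct = profile$occupancy_pct[inWin]),
                    profile[inWin, c("bond_id", "direction")], max)
  anyF <- aggregate(list(max_pct = profile$occupancy_pct),
                    profile[c("bond_id", "direction")], max)
  lab <- merge(resp, peak, by = c("bond_id", "direction"))
  lab <- merge(lab, anyF, by = c("bond_id", "direction"))
  lab$lifetime <- as.character(classifyLifetime(lab$peak_pct))

  ids <- unique(profile$bond_id)
  calls <- do.call(rbind, lapply(ids, function(id) {
    get <- function(dir, col) {
      v <- lab[lab$bond_id == id & lab$direction == dir, col]
      if (length(v)) v else NA
    }
    fpResp <- get("F_P", "response"); fpLife <- get("F_P", "lifetime")
    longElsewhere <- vapply(c("F_B", "F_N"), function(dir) {
      m <- get(dir, "max_pct")
      !is.na(m) && m >= 40
    }, logical(1))
    data.frame(bond_id = id,
               is_dafs = !is.na(fpResp) &&
                 fpResp %in% c("induced", "strengthened") &&
                 identical(fpLife, "long") && !any(longElsewhere),
               response_FP = if (is.na(fpResp)) "absent" else fpResp,
               lifetime_FP = if (is.na(fpLife)) NA_character_ else fpLife,
               response_FB = {v <- get("F_B", "response")
                 if (is.na(v)) "absent" else v},
               response_FN = {v <- get("F_N", "response")
                 if (is.na(v)) "absent" else v})
  }))
  observed <- lab[lab$response != "absent", ]
  counts <- do.call(rbind, lapply(unique(observed$direction), function(dir) {
    l <- observed$lifetime[observed$direction == dir]
    data.frame(direction = dir,
               n_long = sum(l == "long"), n_medium = sum(l == "medium"),
               n_short = sum(l == "short"), n_total = length(l))
  }))
  rownames(calls) <- NULL
  list(calls = calls, counts = counts)
}
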