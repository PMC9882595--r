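#' Closed-form occupancy-versus-force curve
#'
#' The synthetic generator models each hydrogen bond's occupancy as a
#' piecewise-linear function of pulling force: constant at the baseline below
#' the response window, linear with the stated slope inside it, constant
#' above, and zero at and beyond a hard rupture force. Occupancies are
#' clamped to `[0, 100]` percent.
#'
#' @param force numeric vector of forces (pN).
#' @param baseline occupancy (%) at 0 pN.
#' @param slope occupancy change (% per pN) inside the response window.
#' @param windowLo,windowHi force window (pN) over which the slope acts.
#' @param rupture force (pN) at and beyond which occupancy is 0 (NA: never).
#' @return occupancy (%) at each force.
#' @examples
#' hbondOccupancyCurve(128, baseline = 30, slope = 2,
#'                     windowLo = 123, windowHi = 128)  # 40
#' @export
hbondOccupancyCurve <- function(force, baseline, slope,
                                windowLo, windowHi, rupture = NA) {
  occ <- baseline + slope * clamp(force - windowLo, 0, windowHi - windowLo)
  occ <- clamp(occ, 0, 100)
  if (!is.na(rupture)) occ[force >= rupture] <- 0
  occ
}

#' Simulate per-bond H-bond occupancy tables with ground truth
#'
#' Generates an occupancy table emulating what constant-force pulling
#' simulations would yield: for every (bond, direction, force, replicate) an
#' occupancy percentage drawn from the bond's closed-form curve
#' ([hbondOccupancyCurve()]), optionally with binomial sampling noise at the
#' stated number of trajectory frames. Ground-truth lifetime and
#' force-response labels (and the DAFS call per bond) are derived
#' analytically from the curve parameters and returned alongside, so that
#' downstream classifiers can be validated on a noiseless round trip.
#'
#' @param bonds data.frame with columns `bond_id`, `direction` (one of
#'   `"F_P"`, `"F_B"`, `"F_N"`), `baseline`, `slope`, `window_lo`,
#'   `window_hi`, and optionally `rupture` (NA for none). One row per
#'   (bond, direction); directions without a row are treated as absent.
#' @param forceGrid integer forces in pN; must include the baseline force 0.
#' @param nFrames frames per simulated run (binomial denominator), > 0.
#' @param nReplicates replicate runs per condition.
#' @param noise logical; FALSE gives the noiseless closed-form values.
#' @param analysisWindow,epsBaseline,deltaTrend classification parameters
#'   used for the ground-truth labels; see [classifyForceResponse()].
#' @param seed integer seed; identical inputs give identical outputs.
#' @return list with `occupancy` (long data.frame: `bond_id`, `direction`,
#'   `force_pN`, `replicate`, `occupancy_pct`), `truth` (per bond/direction:
#'   `lifetime`, `response`), and `dafs` (per bond: `is_dafs`).
#' @export
simulateHbondOccupancy <- function(bonds, forceGrid = c(0, 123:132),
                                   nFrames = 4000, nReplicates = 10,
                                   noise = TRUE,
                                   analysisWindow = c(123, 132),
                                   epsBaseline = 5, deltaTrend = 0.1,
                                   seed = NULL) {
  if (nFrames <= 0) stop("nFrames must be positive")
  if (nReplicates < 1) stop("nReplicates must be >= 1")
  forceGrid <- sort(unique(as.numeric(forceGrid)))
  empty <- data.frame(bond_id = character(), direction = character(),
                      force_pN = numeric(), replicate = integer(),
                      occupancy_pct = numeric())
  if (nrow(bonds) == 0)
    return(list(occupancy = empty,
                truth = data.frame(bond_id = character(),
                                   direction = character(),
                                   lifetime = character(),
                                   response = character()),
                dafs = data.frame(bond_id = character(),
                                  is_dafs = logical())))
  if (is.null(bonds$rupture)) bonds$rupture <- NA_real_
  if (anyDuplicated(bonds[c("bond_id", "direction")]))
    stop("duplicate (bond_id, direction) rows")

  withSeed(seed, {
    rows <- lapply(seq_len(nrow(bonds)), function(i) {
      b <- bonds[i, ]
      curve <- hbondOccupancyCurve(forceGrid, b$baseline, b$slope,
                                   b$window_lo, b$window_hi, b$rupture)
      occ <- rep(curve, each = nReplicates)
      if (noise)
        occ <- 100 * rbinom(length(occ), nFrames, occ / 100) / nFrames
      data.frame(bond_id = b$bond_id, direction = b$direction,
                 force_pN = rep(forceGrid, each = nReplicates),
                 replicate = rep(seq_len(nReplicates), length(forceGrid)),
                 occupancy_pct = occ)
    })
    occupancy <- do.call(rbind, rows)

    truth <- do.call(rbind, lapply(seq_len(nrow(bonds)), function(i) {
      b <- bonds[i, ]
      curve <- hbondOccupancyCurve(forceGrid, b$baseline, b$slope,
                                   b$window_lo, b$window_hi, b$rupture)
      data.frame(bond_id = b$bond_id, direction = b$direction,
                 lifetime = .lifetimeFromCurve(curve, forceGrid,
                                               analysisWindow),
                 response = .responseFromCurve(curve, forceGrid,
                                               analysisWindow, epsBaseline,
                                               deltaTrend))
    }))

    dafs <- .dafsFromTruth(truth, bonds, forceGrid)
    list(occupancy = occupancy, truth = truth, dafs = dafs)
  })
}

## peak occupancy inside the analysis window -> lifetime bin
.lifetimeFromCurve <- function(curve, grid, window) {
  inWin <- grid >= window[1] & grid <= window[2]
  peak <- if (any(inWin)) max(curve[inWin]) else max(curve)
  as.character(classifyLifetime(peak))
}

.responseFromCurve <- function(curve, grid, window, epsBaseline, deltaTrend) {
  baseline <- curve[which.min(grid)]
  inWin <- grid >= window[1] & grid <= window[2]
  if (all(curve == 0)) return("absent")
  if (baseline < epsBaseline && max(curve[inWin]) > epsBaseline)
    return("induced")
  pulled <- grid > min(grid)
  zero <- curve == 0 & pulled
  if (baseline > 0 && any(zero)) {
    firstZero <- min(grid[zero])
    if (all(curve[grid >= firstZero] == 0)) return("lost")
  }
  wf <- grid[inWin]; wo <- curve[inWin]
  mid <- (window[1] + window[2]) / 2
  lo <- mean(wo[wf <= mid]); up <- mean(wo[wf > mid])
  if ((lo == 0 && up > 0) || (lo > 0 && (up - lo) / lo > deltaTrend))
    return("strengthened")
  "weakened"
}

## DAFS truth: (induced|strengthened) + long-lived at peak in F_P, and never
## long-lived at any force in F_B and F_N
.dafsFromTruth <- function(truth, bonds, forceGrid) {
  ids <- unique(bonds$bond_id)
  is_dafs <- vapply(ids, function(id) {
    fp <- truth[truth$bond_id == id & truth$direction == "F_P", ]
    if (nrow(fp) == 0) return(FALSE)
    ok <- fp$response %in% c("induced", "strengthened") &&
      fp$lifetime == "long"
    if (!ok) return(FALSE)
    for (dir in c("F_B", "F_N")) {
      b <- bonds[bonds$bond_id == id & bonds$direction == dir, ]
      if (nrow(b) == 0) next
      curve <- hbondOccupancyCurve(forceGrid, b$baseline, b$slope,
                                   b$window_lo, b$window_hi, b$rupture)
      if (any(curve >= 40)) return(FALSE)
    }
    TRUE
  }, logical(1))
  data.frame(bond_id = ids, is_dafs = unname(is_dafs))
}

#' Example directional H-bond scenario
#'
#' A ready-made bond roster mirroring the composition observed for the
#' Vt:F-actin complex under directional pulling: 34 bonds toward the pointed
#' end (5 long-lived and force-strengthened or force-induced, 3 medium
#' newly-formed, 26 short-lived of which 19 rupture), 20 toward the barbed
#' end (no long-lived), and 21 normal to the filament (all short-lived, below
#' 10 percent occupancy). The five long-lived pointed-end bonds are weak or
#' absent in the other two directions, making them the planted DAFS set.
#'
#' @return data.frame suitable for [simulateHbondOccupancy()].
#' @export
exampleHbondScenario <- function() {
  bond <- function(id, dir, baseline, slope, lo = 123, hi = 128,
                   rupture = NA)
    data.frame(bond_id = id, direction = dir, baseline = baseline,
               slope = slope, window_lo = lo, window_hi = hi,
               rupture = rupture)
  fp <- rbind(
    # 3 long-lived, present unloaded, strengthened (R976/E83-like)
    bond("B01", "F_P", 30, 4), bond("B02", "F_P", 35, 3),
    bond("B03", "F_P", 28, 5),
    # 2 long-lived, induced under load (E1015/R335-like)
    bond("B04", "F_P", 0, 11), bond("B05", "F_P", 0, 9),
    # 3 medium, newly formed
    bond("B06", "F_P", 0, 5), bond("B07", "F_P", 0, 6),
    bond("B08", "F_P", 0, 4.5),
    # 7 short, weakened
    do.call(rbind, lapply(1:7, function(i)
      bond(sprintf("B%02d", 8 + i), "F_P", 12 + i %% 4, -1.5))),
    # 19 short, lost (rupture inside the grid)
    do.call(rbind, lapply(1:19, function(i)
      bond(sprintf("B%02d", 15 + i), "F_P", 8 + i %% 8, -1,
           rupture = 126 + i %% 6))))
  fb <- rbind(
    # DAFS bonds weak in F_B
    bond("B01", "F_B", 8, -0.5), bond("B02", "F_B", 6, -0.5),
    # 2 medium, weakened
    bond("B40", "F_B", 25, -1.5), bond("B41", "F_B", 0, 7.5,
                                       rupture = 131),
    # 16 short
    do.call(rbind, lapply(1:16, function(i)
      bond(sprintf("B%02d", 41 + i), "F_B", 5 + i %% 10,
           if (i <= 5) 0.5 else -1))))
  fn <- do.call(rbind, lapply(1:21, function(i)
    bond(sprintf("B%02d", 60 + i), "F_N", 2 + i %% 7, -0.5)))
  rbind(fp, fb, fn)
}
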