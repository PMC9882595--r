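mkFrame <- function(...) {
  # atoms as name = c(x, y, z)
  args <- list(...)
  data.frame(atom_id = names(args),
             x = vapply(args, `[`, 1, 1),
             y = vapply(args, `[`, 1, 2),
             z = vapply(args, `[`, 1, 3))
}
tripDHA <- data.frame(donor = "D", hydrogen = "H", acceptor = "A")

test_that("H-bond detection applies the distance and angle cutoffs", {
  at <- function(dist, angleDeg) {
    a <- angleDeg * pi / 180
    mkFrame(D = c(0, 0, 0), H = c(1, 0, 0),
            A = dist * c(cos(a), sin(a), 0))
  }
  expect_true(detectHbonds(at(3.4, 20), tripDHA))
  expect_false(detectHbonds(at(3.6, 0), tripDHA))    # distance exceeded
  expect_false(detectHbonds(at(3.5, 0), tripDHA))    # boundary: strict <
  expect_true(detectHbonds(at(3.4999, 30), tripDHA)) # angle inclusive
  expect_false(detectHbonds(at(3.0, 30.5), tripDHA))
  expect_error(detectHbonds(at(3, 0),
                            data.frame(donor = "D", hydrogen = "H",
                                       acceptor = "Z")), "Z")
})

test_that("detection agrees with a brute-force geometric oracle", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 30
    frame <- data.frame(atom_id = paste0("a", 1:n),
                        x = runif(n, 0, 8), y = runif(n, 0, 8),
                        z = runif(n, 0, 8))
    idx <- replicate(15, sample(n, 3))
    trips <- data.frame(donor = frame$atom_id[idx[1, ]],
                        hydrogen = frame$atom_id[idx[2, ]],
                        acceptor = frame$atom_id[idx[3, ]])
    got <- detectHbonds(frame, trips)
    oracle <- vapply(seq_len(nrow(trips)), function(i) {
      p <- function(id) unlist(frame[frame$atom_id == id, c("x", "y", "z")])
      D <- p(trips$donor[i]); H <- p(trips$hydrogen[i])
      A <- p(trips$acceptor[i])
      dda <- sqrt(sum((A - D)^2))
      ang <- acos(sum((A - D) * (H - D)) /
                    (dda * sqrt(sum((H - D)^2)))) * 180 / pi
      dda < 3.5 && ang <= 30
    }, logical(1))
    expect_identical(got, oracle)
  }
})

test_that("occupancy aggregates frames then averages replicates", {
  ev <- expand.grid(frame = 1:500, replicate = 1, force_pN = 0,
                    direction = "F_P", bond_id = "b")
  ev$present <- ev$frame <= 200
  prof <- occupancyProfile(ev)
  expect_equal(prof$occupancy_pct, 40)
  ev$present <- TRUE
  expect_equal(occupancyProfile(ev)$occupancy_pct, 100)
  # replicates 30% and 50% average to 40%
  reps <- data.frame(bond_id = "b", direction = "F_P", force_pN = 0,
                     replicate = 1:2, occupancy_pct = c(30, 50))
  expect_equal(occupancyProfile(reps)$occupancy_pct, 40)
  expect_error(occupancyProfile(ev[0, ]), "zero frames")
})

test_that("occupancy is invariant to frame order and criteria tightening is monotone", {
  req <- data.frame(donor = "D1", hydrogen = "H1", acceptor = "A1",
                    occupancy_pct = 30, adh_angle_deg = 25,
                    da_distance = 3.3)
  fs <- simulateCoordinateFrames(req, nFrames = 200, seed = 13)
  trip <- req[c("donor", "hydrogen", "acceptor")]
  base <- hbondOccupancy(fs, trip)$occupancy_pct
  perm <- fs
  perm$coords <- fs$coords[sample(200), , , drop = FALSE]
  expect_equal(hbondOccupancy(perm, trip)$occupancy_pct, base)
  for (crit in list(hbondCriteria(3.2, 30), hbondCriteria(3.5, 20),
                    hbondCriteria(3.0, 10)))
    expect_lte(hbondOccupancy(fs, trip, crit)$occupancy_pct, base)
})

test_that("lifetime bins use the 40/20 thresholds with stated closure", {
  expect_equal(as.character(classifyLifetime(c(40, 20, 19.9, 55, 0))),
               c("long", "medium", "short", "long", "short"))
  expect_error(classifyLifetime(101), "0, 100")
  expect_error(classifyLifetime(-1), "0, 100")
})

test_that("force-response labels match the described behaviours", {
  grid <- c(0, 123:132)
  prof <- function(occ) data.frame(bond_id = "b", direction = "F_P",
                                   force_pN = grid, occupancy_pct = occ)
  # induced: absent unloaded, present at 125-128
  induced <- hbondOccupancyCurve(grid, 0, 9, 123, 128)
  expect_equal(classifyForceResponse(prof(induced))$response, "induced")
  # strengthened: 25% rising through the window
  strong <- hbondOccupancyCurve(grid, 25, 5, 123, 132)
  expect_equal(classifyForceResponse(prof(strong))$response, "strengthened")
  # lost: present at baseline, zero from 130 pN on
  lost <- hbondOccupancyCurve(grid, 15, -0.5, 123, 132, rupture = 130)
  expect_equal(classifyForceResponse(prof(lost))$response, "lost")
  weak <- hbondOccupancyCurve(grid, 30, -1, 123, 132)
  expect_equal(classifyForceResponse(prof(weak))$response, "weakened")
  expect_equal(classifyForceResponse(prof(rep(0, length(grid))))$response,
               "absent")
  expect_error(classifyForceResponse(prof(weak),
                                     analysisWindow = c(123, 200)),
               "window")
})

test_that("noiseless generator round trip recovers all planted labels", {
  sim <- simulateHbondOccupancy(exampleHbondScenario(), noise = FALSE,
                                seed = 7)
  prof <- occupancyProfile(sim$occupancy)
  res <- callDafs(prof)
  m <- merge(sim$truth,
             res$calls[c("bond_id", "response_FP", "response_FB",
                         "response_FN")],
             by = "bond_id")
  fp <- m[m$direction == "F_P", ]
  expect_equal(fp$response_FP, fp$response)
  fb <- m[m$direction == "F_B", ]
  expect_equal(fb$response_FB, fb$response)
  td <- merge(sim$dafs, res$calls[c("bond_id", "is_dafs")], by = "bond_id")
  expect_equal(td$is_dafs.y, td$is_dafs.x)
  expect_equal(sum(td$is_dafs.y), 5)
})

test_that("DAFS calls demand pointed-end-specific strengthening", {
  grid <- c(0, 123:132)
  mk <- function(id, dir, occ) data.frame(bond_id = id, direction = dir,
                                          force_pN = grid,
                                          occupancy_pct = occ)
  induced <- hbondOccupancyCurve(grid, 0, 9, 123, 128)
  lowflat <- hbondOccupancyCurve(grid, 5, 0, 123, 132)
  highflat <- hbondOccupancyCurve(grid, 60, 1, 123, 132)
  # induced + long-lived in F_P only: DAFS
  p1 <- rbind(mk("X", "F_P", induced), mk("X", "F_B", lowflat),
              mk("X", "F_N", lowflat))
  expect_true(callDafs(p1)$calls$is_dafs)
  # long-lived in all three directions: not DAFS
  p2 <- rbind(mk("Y", "F_P", highflat), mk("Y", "F_B", highflat),
              mk("Y", "F_N", highflat))
  expect_false(callDafs(p2)$calls$is_dafs)
  # missing directions count as absent: still DAFS
  expect_true(callDafs(mk("Z", "F_P", induced))$calls$is_dafs)
  expect_error(callDafs(rbind(p1, p1[1, ])), "duplicate")
})

test_that("category counts per direction sum to the observed bonds", {
  sim <- simulateHbondOccupancy(exampleHbondScenario(), noise = FALSE)
  res <- callDafs(occupancyProfile(sim$occupancy))
  cnt <- res$counts
  expect_equal(cnt$n_long + cnt$n_medium + cnt$n_short, cnt$n_total)
  expect_equal(cnt$n_total[cnt$direction == "F_P"], 34)
  expect_equal(cnt$n_total[cnt$direction == "F_B"], 20)
  expect_equal(cnt$n_total[cnt$direction == "F_N"], 21)
  expect_equal(unlist(cnt[cnt$direction == "F_P",
                          c("n_long", "n_medium", "n_short")],
                      use.names = FALSE), c(5, 3, 26))
})
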