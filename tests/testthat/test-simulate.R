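test_that("occupancy generator follows its closed-form curve and clamps", {
  # baseline 30%, +2%/pN over 123-128 pN: 40% at the window top
  expect_equal(hbondOccupancyCurve(128, 30, 2, 123, 128), 40)
  expect_equal(hbondOccupancyCurve(0, 30, 2, 123, 128), 30)
  expect_equal(hbondOccupancyCurve(150, 30, 2, 123, 128), 40)  # flat above
  # clamping and hard rupture
  expect_equal(hbondOccupancyCurve(128, 95, 4, 123, 128), 100)
  expect_equal(hbondOccupancyCurve(c(125, 130), 20, 1, 123, 128,
                                   rupture = 130), c(22, 0))
  bonds <- data.frame(bond_id = "b", direction = "F_P", baseline = 30,
                      slope = 2, window_lo = 123, window_hi = 128)
  sim <- simulateHbondOccupancy(bonds, noise = FALSE)
  at128 <- sim$occupancy$occupancy_pct[sim$occupancy$force_pN == 128]
  expect_true(all(at128 == 40))
})

test_that("occupancy generator handles empty rosters and is deterministic", {
  empty <- simulateHbondOccupancy(data.frame())
  expect_identical(nrow(empty$occupancy), 0L)
  expect_error(simulateHbondOccupancy(exampleHbondScenario(), nFrames = -5),
               "positive")
  s1 <- simulateHbondOccupancy(exampleHbondScenario(), seed = 11)
  s2 <- simulateHbondOccupancy(exampleHbondScenario(), seed = 11)
  expect_identical(s1, s2)
  rng <- s1$occupancy$occupancy_pct
  expect_true(all(rng >= 0 & rng <= 100))
})

test_that("coordinate frames plant exact occupancies and round-trip", {
  req <- data.frame(donor = "D1", hydrogen = "H1", acceptor = "A1",
                    occupancy_pct = 40)
  fs <- simulateCoordinateFrames(req, nFrames = 500, seed = 3)
  occ <- hbondOccupancy(fs, data.frame(donor = "D1", hydrogen = "H1",
                                       acceptor = "A1"))
  expect_equal(occ$occupancy_pct, 40)   # exactly 200 of 500 frames

  # an acceptor placed at 35 degrees exceeds the 30-degree cutoff
  req35 <- data.frame(donor = "D2", hydrogen = "H2", acceptor = "A2",
                      occupancy_pct = 100, adh_angle_deg = 35)
  fs35 <- simulateCoordinateFrames(req35, nFrames = 50, seed = 1)
  occ35 <- hbondOccupancy(fs35, data.frame(donor = "D2", hydrogen = "H2",
                                           acceptor = "A2"))
  expect_equal(occ35$occupancy_pct, 0)

  expect_error(simulateCoordinateFrames(
    data.frame(donor = c("D", "D"), hydrogen = c("H", "H2"),
               acceptor = c("A", "A2"), occupancy_pct = 10)),
    "duplicate")

  # multi-triplet round trip at several requested levels
  reqs <- data.frame(donor = paste0("D", 1:4), hydrogen = paste0("H", 1:4),
                     acceptor = paste0("A", 1:4),
                     occupancy_pct = c(0, 25, 60, 100))
  fsm <- simulateCoordinateFrames(reqs, nFrames = 200, seed = 5)
  occm <- hbondOccupancy(fsm, reqs)
  expect_equal(occm$occupancy_pct, c(0, 25, 60, 100))
})

test_that("umbrella sampler reproduces the biased density", {
  # U = 0, k = 10, kT = 1: biased density is N(center, 1/10)
  w <- simulateUmbrellaWindows(function(x) 0 * x, centers = 5,
                               springConstant = 10, nSamples = 5000,
                               xiRange = c(0, 10), seed = 5)
  s <- w[[1]]$samples
  se <- sqrt(1 / 10) / sqrt(2 * 5000)    # SE of a Gaussian SD estimate
  expect_lt(abs(sd(s) - sqrt(1 / 10)), 3 * se)
  expect_lt(abs(mean(s) - 5), 3 * sqrt(1 / 10) / sqrt(5000))

  # k = 0, flat U: uniform over the grid
  wu <- simulateUmbrellaWindows(function(x) 0 * x, centers = 5,
                                springConstant = 0, nSamples = 4000,
                                xiRange = c(0, 10), seed = 7)
  ks <- suppressWarnings(ks.test(wu[[1]]$samples, "punif", 0, 10))
  expect_gt(ks$p.value, 0.01)

  # double well: samples concentrate near window centres
  pot <- doubleWellPotential(3)
  wd <- simulateUmbrellaWindows(pot, centers = c(4, 12),
                                springConstant = 5, nSamples = 3000,
                                seed = 9)
  expect_lt(abs(median(wd[[1]]$samples) - 4), 1)
  expect_lt(abs(median(wd[[2]]$samples) - 12), 1)

  expect_error(simulateUmbrellaWindows(function(x) 0 * x, 1, 1,
                                       nSamples = 0), "nSamples")
  expect_identical(simulateUmbrellaWindows(pot, 1:3, 2, 100, seed = 2),
                   simulateUmbrellaWindows(pot, 1:3, 2, 100, seed = 2))
})

test_that("FRET scene forward model is exact and seeded", {
  fa <- fretEllipses(E = 0)
  sc0 <- simulateFretScene(faEllipses = fa, dbt = 0, abt = 0,
                           darkLevel = 100, backgroundLevel = 20,
                           noise = NULL)
  # E = 0, no bleed-through: FRET channel is shading x (dark+background)
  expect_true(all(sc0$channels$fret == 120))

  sh <- 1 + 0.1 * outer(sin(seq(0, 3, length.out = 128)),
                        cos(seq(0, 3, length.out = 128)))
  sc <- simulateFretScene(faEllipses = fretEllipses(E = 0.4), dbt = 0.2,
                          abt = 0.1, G = 3, darkLevel = 50,
                          backgroundLevel = 10, shading = sh, noise = NULL)
  shn <- sh / mean(sh)
  sig <- sc$truth$signals
  expect_equal(sc$channels$donor, shn * (10 + sig$donor) + 50)
  expect_equal(sc$channels$fret, shn * (10 + sig$fret) + 50)
  inFa <- sc$faLabel == 1
  e <- fretEllipses(E = 0.4)[1, ]
  expect_equal(unique(sig$fret[inFa]),
               0.2 * e$donor_level * 0.6 + 0.1 * e$acceptor_level +
                 3 * e$donor_level * 0.4)

  expect_error(simulateFretScene(faEllipses = fretEllipses(E = 1.2)),
               "E_true")
  n1 <- simulateFretScene(faEllipses = fa,
                          noise = list(poisson = TRUE, readSd = 2),
                          seed = 8)
  n2 <- simulateFretScene(faEllipses = fa,
                          noise = list(poisson = TRUE, readSd = 2),
                          seed = 8)
  expect_identical(n1, n2)
})

test_that("stress-fibre scenes plant orientations, offsets and area", {
  run <- sfCoalignmentRun(offsets = c(0, 20, 40))
  truth <- run$scene$faTruth
  expect_equal(truth$theta_rel_deg, c(0, 20, 40))
  expect_equal(truth$theta_sf_true_deg,
               wrapAxialDeg(truth$theta_fa_deg + c(0, 20, 40)))
  frac <- sum(run$scene$sfTruthMask) / sum(run$scene$cellMask)
  expect_lt(abs(frac - 0.15), 0.02)
  expect_error(simulateSfScene(cellPolygon = cbind(c(0, 1, 0), c(0, 0, 1)) +
                                 500,
                               faEllipses = data.frame(cx = 1, cy = 1,
                                                       a = 2, b = 1,
                                                       theta_fa_deg = 0,
                                                       offset_deg = 0)),
               "empty cell polygon")
})
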