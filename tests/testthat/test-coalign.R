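test_that("structure tensor recovers stripe orientations", {
  for (a in c(0, 30, 77)) {
    f <- structureTensorField(stripeImage(a))
    th <- orientationMap(f)[validityMask(f)] * 180 / pi
    expect_lt(axialDiffDeg(axialMeanDeg(th), a), 1)
  }
  # rotating the pattern shifts the recovered angle equivariantly
  f20 <- structureTensorField(stripeImage(20))
  f50 <- structureTensorField(stripeImage(50))
  m20 <- axialMeanDeg(orientationMap(f20)[validityMask(f20)] * 180 / pi)
  m50 <- axialMeanDeg(orientationMap(f50)[validityMask(f50)] * 180 / pi)
  expect_lt(abs(axialDiffDeg(m20, m50) - 30), 2)
  # constant image: no gradient energy, empty validity mask
  fc <- structureTensorField(matrix(5, 64, 64))
  expect_true(all(tensorEnergy(fc) == 0))
  expect_false(any(validityMask(fc)))
  # the literal gradient convention is 90 degrees away
  fg <- structureTensorField(stripeImage(30), convention = "gradient")
  mg <- axialMeanDeg(orientationMap(fg)[validityMask(fg)] * 180 / pi)
  expect_lt(abs(axialDiffDeg(mg, 30) - 90), 1)
})

test_that("eigenvalues are ordered and the mask rules behave", {
  f <- structureTensorField(stripeImage(40))
  expect_true(all(tensorEnergy(f) >= f@l2 - 1e-9))
  expect_true(all(f@l2 >= 0))
  # threshold above the maximum: empty mask
  expect_false(any(sfMask(f, "absolute", max(tensorEnergy(f)) + 1)))
  # quantile rule is deterministic
  expect_identical(sfMask(f, "quantile", 0.9), sfMask(f, "quantile", 0.9))
  expect_error(sfMask(f, "quantile", 1.5), "quantile")
  # quantile-rule mask is invariant to intensity rescaling
  f2 <- structureTensorField(stripeImage(40) * 7.3)
  expect_identical(sfMask(f, "quantile", 0.9), sfMask(f2, "quantile", 0.9))
})

test_that("orientation spread uses doubled-angle axial statistics", {
  f <- structureTensorField(stripeImage(25))
  m <- sfMask(f, "quantile", 0.8)
  expect_lt(sfOrientationSd(f, m), 3)
  expect_true(is.na(sfOrientationSd(f, matrix(FALSE, 128, 128))))
  # closed forms on raw angles
  expect_equal(axialDiffDeg(10, 170), 20)
  expect_equal(axialDiffDeg(0, 90), 90)
  expect_equal(axialMeanDeg(c(10, 170)), 0, tolerance = 1e-9)
})

test_that("Voronoi regions partition the cell and match brute force", {
  cell <- matrix(TRUE, 60, 80)
  # two mirror-symmetric centroids: split at the perpendicular bisector
  # (bisector x = 39.5 falls between pixel columns)
  cent <- data.frame(label = 1:2, x = c(20, 59), y = c(30, 30))
  vr <- voronoiRegions(cent, cell)
  expect_equal(vr$areas$area_px[1], vr$areas$area_px[2])
  expect_equal(sum(vr$areas$area_px), sum(cell))
  expect_true(all(vr$label[, 1:40] == 1))
  expect_true(all(vr$label[, 41:80] == 2))

  # irregular polygon cell with several centroids vs brute force
  poly <- cbind(c(5, 70, 75, 40, 8), c(5, 10, 50, 58, 45))
  cellP <- polygonMask(poly, c(64, 84))
  set.seed(12)
  cents <- data.frame(label = 1:6, x = runif(6, 15, 60),
                      y = runif(6, 12, 40))
  vrP <- voronoiRegions(cents, cellP)
  expect_equal(sum(vrP$areas$area_px), sum(cellP))
  idx <- which(cellP, arr.ind = TRUE)
  pick <- idx[seq(1, nrow(idx), by = 7), , drop = FALSE]
  for (r in seq_len(nrow(pick))) {
    x <- pick[r, 2] - 1; y <- pick[r, 1] - 1
    d <- (cents$x - x)^2 + (cents$y - y)^2
    expect_equal(vrP$label[pick[r, 1], pick[r, 2]],
                 cents$label[which.min(d)])
  }
  expect_warning(voronoiRegions(data.frame(label = 1:2, x = c(5, 5),
                                           y = c(5, 5)),
                                matrix(TRUE, 10, 10)), "duplicate")
  expect_equal(sum(voronoiRegions(data.frame(label = 1, x = 3, y = 3),
                                  matrix(TRUE, 10, 10))$areas$area_px),
               100)
})

test_that("theta_Rel is an axial distance in [0, 90]", {
  fa <- data.frame(label = 1, theta_fa_deg = 170)
  f <- structureTensorField(stripeImage(10, dim = 64))
  vr <- voronoiRegions(data.frame(label = 1, x = 32, y = 32),
                       matrix(TRUE, 64, 64))
  tab <- regionMetrics(vr, sfMask(f, "quantile", 0.5), f, fa)
  expect_equal(tab$theta_rel_deg, 20, tolerance = 1)
  # perfect co-alignment
  fa0 <- data.frame(label = 1, theta_fa_deg = 10)
  tab0 <- regionMetrics(vr, sfMask(f, "quantile", 0.5), f, fa0)
  expect_lt(tab0$theta_rel_deg, 1)
  # a region with no fibre pixels is flagged and excluded
  tabE <- regionMetrics(vr, matrix(FALSE, 64, 64), f, fa0)
  expect_false(tabE$has_sf)
  expect_equal(tabE$sf_density_pct, 0)
  expect_true(is.na(tabE$theta_rel_deg))
})

test_that("planted per-adhesion offsets are recovered end to end", {
  run <- sfCoalignmentRun(offsets = c(0, 20, 40))
  expect_lt(max(abs(run$table$theta_rel_deg -
                      run$scene$faTruth$theta_rel_deg)), 3)
  expect_equal(sum(run$regions$areas$area_px), sum(run$scene$cellMask))
  cellStats <- attr(run$table, "cell")
  expect_equal(cellStats$n_regions_with_sf, 3)
})

test_that("co-alignment is invariant to rotating the whole scene", {
  run0 <- sfCoalignmentRun(offsets = c(15, 35, 55), seed = 6)
  poly <- cbind(c(10, 245, 245, 10), c(10, 10, 245, 245))
  # same geometry, all orientations rotated by 90 degrees
  rotFa <- data.frame(cx = c(70, 180, 128), cy = c(70, 70, 190),
                      a = 12, b = 5,
                      theta_fa_deg = c(30, 80, 140) + 90,
                      offset_deg = c(15, 35, 55))
  scR <- simulateSfScene(dim = c(256, 256), cellPolygon = poly,
                         faEllipses = rotFa, areaFraction = 0.15,
                         seed = 6)
  fR <- structureTensorField(scR$actin)
  mR <- sfMask(fR, "quantile", 0.85, within = scR$cellMask)
  vrR <- voronoiRegions(data.frame(label = scR$faTruth$label,
                                   x = scR$faTruth$centroid_x,
                                   y = scR$faTruth$centroid_y),
                        scR$cellMask)
  tabR <- regionMetrics(vrR, mR, fR, scR$faTruth)
  expect_lt(max(abs(tabR$theta_rel_deg - run0$table$theta_rel_deg)), 3)
  expect_lt(max(abs(tabR$sf_density_pct - run0$table$sf_density_pct)), 2)
})
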