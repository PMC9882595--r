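# Shared fixture builders; everything is generated in code at test time.

# sin^2 stripe image with fibres at `deg` (axial, x = column, y = row)
stripeImage <- function(deg, dim = 128, period = 10) {
  g <- expand.grid(y = 0:(dim - 1), x = 0:(dim - 1))
  t <- deg * pi / 180
  perp <- -g$x * sin(t) + g$y * cos(t)
  matrix(sin(2 * pi * perp / period)^2, dim, dim)
}

# Gaussian-intensity ellipse scene for segmentation tests
blobScene <- function(dim = c(100, 100),
                      blobs = data.frame(cx = c(30, 70), cy = c(35, 65),
                                         sx = c(40, 20), sy = c(12, 30),
                                         amp = c(1000, 800))) {
  x <- matrix(rep(0:(dim[2] - 1), each = dim[1]), dim[1])
  y <- matrix(rep(0:(dim[1] - 1), dim[2]), dim[1])
  img <- matrix(0, dim[1], dim[2])
  for (i in seq_len(nrow(blobs)))
    img <- img + blobs$amp[i] *
      exp(-((x - blobs$cx[i])^2 / blobs$sx[i] +
              (y - blobs$cy[i])^2 / blobs$sy[i]))
  list(img = img, blobs = blobs)
}

# standard two-adhesion FRET ellipse table
fretEllipses <- function(E = 0.25, donor = 900, acceptor = 800) {
  data.frame(cx = c(40, 90), cy = c(45, 85), a = c(14, 11), b = c(7, 5),
             theta_deg = c(25, 120), donor_level = donor,
             acceptor_level = acceptor, E_true = E)
}

# full calibration chain on noiseless scenes: returns dbt/abt tables and G
fretCalibration <- function(dbt = 0.25, abt = 0.12, G = 2.8) {
  fa <- fretEllipses()
  corr <- function(scene) preprocessChannels(
    scene$channels, dark = scene$truth$darkLevel,
    backgroundMask = !scene$faMask, register = FALSE)$channels
  dOnly <- simulateFretScene(faEllipses = transform(fa, acceptor_level = 0,
                                                    E_true = 0),
                             dbt = dbt, abt = abt, G = G, noise = NULL)
  aOnly <- simulateFretScene(faEllipses = transform(fa, donor_level = 0,
                                                    E_true = 0),
                             dbt = dbt, abt = abt, G = G, noise = NULL)
  dch <- corr(dOnly); ach <- corr(aOnly)
  dbtTab <- estimateDonorBleedthrough(dch$fret, dch$donor)
  abtTab <- estimateAcceptorBleedthrough(ach$fret, ach$acceptor)
  construct <- function(E) {
    s <- simulateFretScene(faEllipses = transform(fa, E_true = E),
                           dbt = dbt, abt = abt, G = G, noise = NULL)
    ch <- corr(s)
    list(Fc = correctedFretImage(ch$fret, ch$donor, ch$acceptor,
                                 dbtTab, abtTab),
         Id = ch$donor, Ia = ch$acceptor, mask = s$faMask)
  }
  hi <- construct(0.9); lo <- construct(0.1)
  list(dbt = dbtTab, abt = abtTab,
       G = estimateGFactor(hi, lo, hi$mask, lo$mask))
}

# measure the FA-masked mean efficiency of a scene through the full chain
fretRecoverE <- function(E, noise = NULL, seed = NULL, cal = NULL,
                         dbt = 0.25, abt = 0.12, G = 2.8) {
  if (is.null(cal)) cal <- fretCalibration(dbt, abt, G)
  sc <- simulateFretScene(faEllipses = fretEllipses(E = E),
                          dbt = dbt, abt = abt, G = G,
                          noise = noise, seed = seed)
  ch <- preprocessChannels(sc$channels, dark = sc$truth$darkLevel,
                           backgroundMask = !sc$faMask,
                           register = FALSE)$channels
  Fc <- correctedFretImage(ch$fret, ch$donor, ch$acceptor, cal$dbt, cal$abt)
  eff <- efficiencyImage(Fc, ch$donor, cal$G)
  mean(efficiencyMap(eff)[sc$faMask], na.rm = TRUE)
}

# planted-offset stress-fibre scene plus its analysis chain
sfCoalignmentRun <- function(offsets = c(0, 20, 40), seed = 2,
                             areaFraction = 0.15) {
  poly <- cbind(c(10, 245, 245, 10), c(10, 10, 245, 245))
  fa <- data.frame(cx = c(70, 180, 128), cy = c(70, 70, 190), a = 12, b = 5,
                   theta_fa_deg = c(30, 80, 140), offset_deg = offsets)
  sc <- simulateSfScene(dim = c(256, 256), cellPolygon = poly,
                        faEllipses = fa, areaFraction = areaFraction,
                        seed = seed)
  field <- structureTensorField(sc$actin)
  mask <- sfMask(field, "quantile", 1 - areaFraction, within = sc$cellMask)
  cent <- data.frame(label = sc$faTruth$label, x = sc$faTruth$centroid_x,
                     y = sc$faTruth$centroid_y)
  vr <- voronoiRegions(cent, sc$cellMask)
  tab <- regionMetrics(vr, mask, field, sc$faTruth)
  list(scene = sc, field = field, mask = mask, regions = vr, table = tab)
}
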