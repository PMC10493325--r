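test_that("radius profiles read half-extents off the masks", {
  m <- cleanCylinderModel()
  masks <- modelMasks(m, nFrames = 2L)
  prof <- radiusProfile(masks)
  expect_equal(max(prof$r), 2.5, tolerance = 3.126e-2 / 2.5)

  # single frame: profile equals that frame's half-extents
  p1 <- radiusProfile(masks[[1]])
  cols <- which(colSums(masks[[1]]) > 0)
  expect_equal(p1$r, colSums(masks[[1]])[cols] / 2 * 3.126e-2)

  # averaging two identical frames changes nothing
  p2 <- radiusProfile(list(masks[[1]], masks[[1]]))
  expect_equal(p2, p1)

  expect_error(radiusProfile(list()), "empty")
  expect_error(radiusProfile(matrix(FALSE, 5, 5)), "empty")
})

test_that("ear length averages corrected extents", {
  m <- cleanCylinderModel()
  masks <- modelMasks(m, nFrames = 2L)
  el <- earLength(masks)
  expect_equal(el, 15, tolerance = 2 * 3.126e-2 / 15)

  # identity correction, one mask of known extent: pure arithmetic
  mk <- matrix(FALSE, 50, 500)
  mk[10:40, 11:490] <- TRUE
  expect_equal(earLength(mk, pixelSize = 3.126e-2), 480 * 3.126e-2)

  # the mean lies between the per-frame extremes
  perFrame <- vapply(masks, function(mm) earLength(mm), 1)
  expect_gte(el, min(perFrame)); expect_lte(el, max(perFrame))

  # the chord-to-arc correction stretches the estimate
  expect_gt(earLength(mk, cameraTheta = 0.3), earLength(mk))
})

test_that("width, perimeter, surface and volume follow the profile rules", {
  cylProf <- data.frame(y = seq(0, 15, by = 0.01), r = 2.5)
  wp <- earWidthPerimeter(cylProf)
  expect_equal(wp[["EW"]], 5)
  expect_equal(wp[["EP"]], 15.70796, tolerance = 1e-6)
  expect_equal(wp[["EP"]] / wp[["EW"]], pi)

  sv <- surfaceVolume(cylProf)
  expect_equal(sv[["EV"]], pi * 2.5^2 * 15, tolerance = 0.005)
  expect_equal(sv[["ESA"]], 2 * pi * 2.5 * 15, tolerance = 0.005)

  # EP/EW = pi for arbitrary profiles
  set.seed(1)
  randProf <- data.frame(y = seq(0, 10, by = 0.05),
                         r = runif(201, 0.5, 3))
  wpr <- earWidthPerimeter(randProf)
  expect_equal(wpr[["EP"]] / wpr[["EW"]], pi)

  # hemisphere-capped cylinder vs closed-form sphere-zone + cylinder areas
  R <- 2; hcyl <- 6
  y <- seq(0, hcyl + 2 * R, by = 0.01)
  r <- ifelse(y < R, sqrt(pmax(0, R^2 - (R - y)^2)),
       ifelse(y < R + hcyl, R, sqrt(pmax(0, R^2 - (y - R - hcyl)^2))))
  svh <- surfaceVolume(data.frame(y = y, r = r))
  exactA <- 2 * pi * R * hcyl + 4 * pi * R^2  # lateral + two hemispheres
  exactV <- pi * R^2 * hcyl + 4 / 3 * pi * R^3
  expect_equal(svh[["ESA"]], exactA, tolerance = 0.005)
  expect_equal(svh[["EV"]], exactV, tolerance = 0.005)

  # refining the step by 2x changes EV by < 0.1%
  y2 <- seq(0, hcyl + 2 * R, by = 0.005)
  r2 <- ifelse(y2 < R, sqrt(pmax(0, R^2 - (R - y2)^2)),
        ifelse(y2 < R + hcyl, R, sqrt(pmax(0, R^2 - (y2 - R - hcyl)^2))))
  sv2 <- surfaceVolume(data.frame(y = y2, r = r2))
  expect_lt(abs(sv2[["EV"]] - svh[["EV"]]) / sv2[["EV"]], 0.001)

  expect_error(surfaceVolume(data.frame(y = 1, r = 1)), "at least 2")
  expect_error(earWidthPerimeter(data.frame(y = 1:3, r = 0)), "all-zero")
})

test_that("the non-sphericity index is 1 for spheres and grows with elongation", {
  R <- 3
  expect_equal(earShape(4 * pi * R^2, 4 / 3 * pi * R^3), 1)

  # cylinder with h = 4r, full surface 10 pi r^2: hand-evaluated oracle
  r <- 1.7
  esa <- 10 * pi * r^2; ev <- 4 * pi * r^3
  oracle <- esa / (pi^(1 / 3) * (6 * ev)^(2 / 3))
  expect_equal(earShape(esa, ev), oracle)
  expect_equal(oracle, 10 * pi / (pi^(1 / 3) * (24 * pi)^(2 / 3)))  # 1.2020
  expect_equal(oracle, 1.2019, tolerance = 1e-4)

  # elongating a fixed-volume spheroid increases ES monotonically
  es <- vapply(c(1, 1.5, 2.5, 4), function(q) {
    a <- (1 / q^2)^(1 / 3)  # semi-minor, fixing a^2 * c = 1 with c = q * a
    c <- q * a
    y <- seq(0, 2 * c, length.out = 4000)
    rr <- a * sqrt(pmax(0, 1 - (y / c - 1)^2))
    sv <- surfaceVolume(data.frame(y = y, r = rr))
    earShape(sv[["ESA"]], sv[["EV"]])
  }, 1)
  expect_true(all(diff(es) > 0))
  expect_true(all(es >= 1 - 1e-6))

  expect_error(earShape(10, 0), "EV")
})

test_that("barren tip measures the kernel-free tip span", {
  m <- buildEarModel(15, 2.5, "cylinder", 14L, 24L, barrenTipFraction = 0.2,
                     seed = 1L)
  rp <- renderPanorama(m)
  km <- markValid(segmentKernels(rp$panorama))
  masks <- modelMasks(m, nFrames = 2L)
  prof <- radiusProfile(masks)
  bt <- barrenTip(km, prof)
  tt <- trueTraits(m)
  expect_equal(bt[["BTL"]], tt[["BTL"]], tolerance = 2 * 3.126e-2 / tt[["BTL"]])
  expect_lte(bt[["BTA"]], surfaceVolume(prof)[["ESA"]])

  # kernels to the very tip: BTL and BTA are zero
  m0 <- cleanCylinderModel()
  rp0 <- renderPanorama(m0)
  km0 <- markValid(segmentKernels(rp0$panorama))
  prof0 <- radiusProfile(modelMasks(m0, nFrames = 2L))
  bt0 <- barrenTip(km0, prof0)
  expect_lt(bt0[["BTL"]], 2 * 3.126e-2)
})

test_that("kernel geometry traits are arithmetic on the kernel map", {
  # single square 10 x 10 px kernel at the default pixel size
  labels <- matrix(0L, 60, 60)
  labels[20:29, 20:29] <- 1L
  km <- kernelMapFromLabels(labels)
  kg <- kernelGeometry(km)
  expect_equal(kg[["AKA"]], 100 * 3.126e-2^2, tolerance = 1e-9)  # 0.0977 cm^2
  expect_equal(kg[["KW"]], 10 * 3.126e-2, tolerance = 1e-9)      # 0.3126 cm
  expect_true(is.na(kg[["KT"]]))

  # lattice with axial pitch 0.45 cm: KT within 0.02
  m <- benchmarkEarModel(2, jitterFraction = 0.05)
  rp <- renderPanorama(m)
  kmm <- markValid(segmentKernels(rp$panorama))
  kgm <- kernelGeometry(kmm)
  expect_equal(kgm[["KT"]], m@pitchAxial, tolerance = 0.02 / m@pitchAxial)

  # KT is invariant to a circumferential shift of the whole lattice
  sh <- 37L
  H <- nrow(kmm@labels)
  shifted <- kmm@labels[(seq_len(H) - 1L - sh) %% H + 1L, ]
  rgbS <- rp$panorama@rgb[(seq_len(H) - 1L - sh) %% H + 1L, , , drop = FALSE]
  panoS <- new("Panorama", rgb = rgbS, pixelSize = rp$panorama@pixelSize,
               provenance = list())
  kmS <- markValid(segmentKernels(panoS))
  kgS <- kernelGeometry(kmS)
  expect_equal(kgS[["KT"]], kgm[["KT"]], tolerance = 0.005)
})

test_that("color traits average the configured regions", {
  m <- cleanCylinderModel()
  rp <- renderPanorama(m)
  km <- markValid(segmentKernels(rp$panorama))
  ct <- colorTraits(rp$panorama, km)
  expect_equal(unname(ct[c("KR", "KG", "KB")]), c(210, 180, 60),
               tolerance = 1 / 60)
  # cob darker than kernels: ear mean below kernel mean, channelwise
  expect_lte(ct[["ER"]], ct[["KR"]] + 1e-9)
  expect_lte(ct[["EG"]], ct[["KG"]] + 1e-9)

  # channel means are invariant to rotation by a full circumference
  H <- nrow(rp$panorama@rgb)
  rolled <- rp$panorama@rgb[c((H %/% 2 + 1):H, 1:(H %/% 2)), , , drop = FALSE]
  panoR <- new("Panorama", rgb = rolled, pixelSize = 3.126e-2,
               provenance = list())
  kmR <- markValid(segmentKernels(panoR))
  ctR <- colorTraits(panoR, kmR)
  expect_equal(unname(ctR[c("ER", "EG", "EB")]),
               unname(ct[c("ER", "EG", "EB")]), tolerance = 1e-6)
})

test_that("cm-valued traits scale linearly with pixel size", {
  m <- cleanCylinderModel()
  for (px in c(3.126e-2, 6.252e-2)) {
    rp <- renderPanorama(m, pixelSize = px)
    km <- markValid(segmentKernels(rp$panorama))
    sq <- renderSequence(m, nFrames = 2L, rotationPerFrame = 180,
                         pixelSize = px, nLead = 0L, nTrail = 0L)
    ref <- list(background = m@backgroundColor, roller = m@rollerColor)
    masks <- lapply(sq@frames, function(f)
      normalizeOrientation(f, segmentEar(f, ref))$mask)
    me <- measureEar(rp$panorama, masks,
                     traits = c("EL", "EW", "KNE", "AKA", "KW"))
    tt <- trueTraits(m)
    for (tr in c("EL", "EW", "AKA", "KW"))
      expect_equal(me$traits[[tr]], tt[[tr]], tolerance = 0.03,
                   info = paste(tr, "at px", px))
    expect_equal(me$traits[["KNE"]], 420)
  }
})

test_that("trait CSV output uses the canonical header order", {
  tt <- trueTraits(cleanCylinderModel())
  f <- tempfile(fileext = ".csv")
  writeTraitCSV(list(tt), f, ids = "ear1")
  hdr <- strsplit(readLines(f, n = 1), ",")[[1]]
  expect_equal(hdr, c("ear", "BTL", "EL", "EP", "EW", "KNE", "KNR", "RNE",
                      "AKA", "BTA", "EB", "EG", "ER", "ES", "ESA", "EV",
                      "KB", "KG", "KR", "KT", "KW"))
  unlink(f)
})
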