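test_that("rasterised organ masks match analytic volumes and stay disjoint", {
  ps <- phantomSpec(c(30, 30, 30), 1, list(
    organSpec("ball", "sphere", c(15, 15, 15), 10, uptakeFraction = 0.05)),
    bodyCenter = c(15, 15, 15), bodySemiAxes = c(14, 14, 14))
  ph <- buildPhantom(ps)
  analytic <- 4 / 3 * pi * 10^3                # voxel units (1 mm voxels)
  expect_lt(abs(sum(ph@masks$ball) / analytic - 1), 0.05)

  ps2 <- phantomSpec(c(30, 20, 30), 2, list(
    organSpec("a", "ellipsoid", c(18, 20, 20), c(8, 6, 8), uptakeFraction = 0.02),
    organSpec("b", "ellipsoid", c(42, 20, 40), c(8, 6, 8), uptakeFraction = 0.02)))
  ph2 <- buildPhantom(ps2)
  expect_true(any(ph2@masks$a))
  expect_true(any(ph2@masks$b))
  expect_false(any(ph2@masks$a & ph2@masks$b))
})

test_that("invalid phantom geometries are rejected with informative errors", {
  outside <- phantomSpec(c(20, 20, 20), 2, list(
    organSpec("stray", "sphere", c(60, 20, 20), 10, uptakeFraction = 0.01)))
  expect_error(buildPhantom(outside), "stray")

  overlapping <- phantomSpec(c(30, 20, 30), 2, list(
    organSpec("a", "sphere", c(30, 20, 30), 10, uptakeFraction = 0.02),
    organSpec("b", "sphere", c(34, 20, 30), 10, uptakeFraction = 0.02)))
  expect_error(buildPhantom(overlapping), "overlap")

  strayTumour <- phantomSpec(c(30, 20, 30), 2, list(
    organSpec("host", "sphere", c(30, 20, 30), 10, uptakeFraction = 0.02),
    organSpec("lesion", "sphere", c(44, 20, 30), 6, uptakeFraction = 0.001,
              isTumour = TRUE, hostOrgan = "host")))
  expect_error(buildPhantom(strayTumour), "outside host")
})

test_that("analytic organ activity follows the effective decay constant", {
  adm <- administrationRecord(7)
  o1 <- organSpec("k", "sphere", c(50, 50, 50), 10, uptakeFraction = 0.1)
  expect_equal(organActivity(o1, adm, 0), 700)
  # one physical half-life, no biological washout
  expect_equal(organActivity(o1, adm, 159.528, physicalHalfLife = 159.528), 350)
  # equal physical and biological half-life: two half-lives combined
  o2 <- organSpec("k", "sphere", c(50, 50, 50), 10, uptakeFraction = 0.1,
                  bioHalfLife = 159.528)
  expect_equal(organActivity(o2, adm, 159.528, physicalHalfLife = 159.528), 175)
  expect_error(organActivity(o1, adm, -1), "t must be")

  ts <- seq(0, 200, by = 10)
  acts <- organActivity(o2, adm, ts)
  expect_true(all(diff(acts) < 0))
})

test_that("rendered activity volumes conserve activity with and without blur", {
  ph <- buildPhantom(isolatedOrganSpec(mu = 0))
  vol0 <- renderActivityVolume(ph, c(ball = 500), backgroundActivity = 0)
  expect_equal(sum(vol0[ph@masks$ball]), 500)
  expect_equal(sum(vol0), 500)

  volB <- renderActivityVolume(ph, c(ball = 500), psfFwhmMm = 12)
  expect_lt(abs(sum(volB) / 500 - 1), 1e-3)
  # partial-volume loss: mask-restricted sum drops below the input
  expect_lt(sum(volB[ph@masks$ball]), 500)
  expect_error(renderActivityVolume(ph, c(ball = 1), psfFwhmMm = -1), "FWHM")
})

test_that("FFT blur agrees with an independent shift-add convolution", {
  ph <- buildPhantom(isolatedOrganSpec(mu = 0))
  vol0 <- renderActivityVolume(ph, c(ball = 500))
  fft_blur <- renderActivityVolume(ph, c(ball = 500), psfFwhmMm = 10)
  oracle <- bruteBlur3d(vol0, 10, ph@spec@voxelSize)
  expect_lt(max(abs(fft_blur - oracle)), 1e-6 * max(oracle))
})

test_that("planar projection integrates activity with attenuation and noise", {
  d <- c(12, 16, 12)
  a <- array(0, d); a[6, 8, 6] <- 10
  mu0 <- array(0, d)
  img <- projectPlanar(a, mu0, c(5, 5, 5), "anterior", sensitivity = 2,
                       duration = 100)
  expect_equal(sum(img), 2 * 100 * 10)
  expect_error(projectPlanar(a, array(0, c(12, 16, 11)), c(5, 5, 5)),
               "same grid")

  # conjugate-view invariance: geometric mean independent of source depth
  mu <- array(0, d); mu[, 3:14, ] <- 0.137
  gms <- sapply(4:13, function(yj) {
    src <- array(0, d); src[6, yj, 6] <- 5
    ia <- projectPlanar(src, mu, c(5, 5, 5), "anterior", 1, 1)
    ip <- projectPlanar(src, mu, c(5, 5, 5), "posterior", 1, 1)
    geometricMean(ia, ip)[6, 6]
  })
  expect_lt(stats::sd(gms) / mean(gms), 0.005)

  n1 <- projectPlanar(a, mu0, c(5, 5, 5), "anterior", 2, 100, noise = TRUE,
                      seed = 42)
  n2 <- projectPlanar(a, mu0, c(5, 5, 5), "anterior", 2, 100, noise = TRUE,
                      seed = 42)
  n3 <- projectPlanar(a, mu0, c(5, 5, 5), "anterior", 2, 100, noise = TRUE,
                      seed = 43)
  expect_identical(n1, n2)
  expect_false(identical(n1, n3))
})

test_that("simulated studies have the requested frames and are reproducible", {
  ps <- isolatedOrganSpec(mu = 0)
  acq <- acquisitionSpec(seed = 5)
  st <- simulateStudy(ps, acq, administrationRecord(7))
  expect_length(st@anterior, 5)
  expect_length(st@posterior, 5)
  expect_length(st@spect, 5)

  acq1 <- acquisitionSpec(spectTimes = 24, seed = 5)
  st1 <- simulateStudy(ps, acq1, administrationRecord(7))
  expect_length(st1@spect, 1)
  expect_named(st1@spect, "24")

  expect_error(acquisitionSpec(spectTimes = c(24, 30)), "subset")

  acqN <- acquisitionSpec(noise = TRUE, seed = 11)
  stA <- simulateStudy(ps, acqN, administrationRecord(7))
  stB <- simulateStudy(ps, acqN, administrationRecord(7))
  expect_identical(stA@anterior, stB@anterior)
  expect_identical(stA@spect, stB@spect)
})

test_that("noise-free planar counts recover organ activity after analytic attenuation correction", {
  mu <- 0.137
  ps <- isolatedOrganSpec(mu = mu)
  st <- simulateStudy(ps, acquisitionSpec(seed = 1), administrationRecord(7))
  ph <- st@phantom
  roiMask <- projectVoi(ph@masks$ball)
  # grow the ROI so the full column contribution is captured
  roi <- perturbRoi(roiMask, "dilate", 2)
  acq <- st@acquisition
  # body is a uniform slab: GM attenuation factor is exp(-mu * D / 2)
  D_cm <- 8   # body y extent 80 mm
  for (i in c(1L, 3L)) {
    gm <- geometricMean(st@anterior[[i]], st@posterior[[i]])
    est <- sum(gm[roi]) / acq@planarDuration / acq@planarSensitivity *
      exp(mu * D_cm / 2)
    truth <- organActivity(ps@organs[[1]], st@admin, st@timesH[i])
    expect_lt(abs(est / truth - 1), 0.01)
  }
})

test_that("activity conservation holds between analytic and rendered totals", {
  st <- referenceStudyNoBlur()
  ph <- st@phantom
  spec <- ph@spec
  adminMBq <- st@admin@activityGBq * 1000
  tr <- truthRecord(st)
  t <- 48
  acts <- setNames(adminMBq * tr$f * exp(-tr$lambda_eff_per_h * t), tr$organ)
  lamBg <- log(2) / 159.528 + log(2) / spec@backgroundHalfLife
  bg <- adminMBq * spec@backgroundUptake * exp(-lamBg * t)
  vol <- st@spect[["48"]]
  expect_lt(abs(sum(vol) / (sum(acts) + bg) - 1), 1e-3)
  for (nm in tr$organ)
    expect_lt(abs(sum(vol[ph@masks[[nm]]]) / acts[[nm]] - 1), 1e-9)
})

test_that("ROI perturbation is conservative, reproducible and safe", {
  m <- array(FALSE, c(12, 12, 12)); m[5:8, 5:8, 5:8] <- TRUE
  expect_identical(perturbRoi(m, "dilate", 0), m)
  d1 <- perturbRoi(m, "dilate", 1)
  expect_true(all(d1[m]))
  expect_gt(sum(d1), sum(m))
  e1 <- perturbRoi(m, "erode", 1)
  expect_true(all(m[e1]))
  expect_lt(sum(e1), sum(m))
  expect_error(perturbRoi(m, "erode", 4), "emptied")

  sh <- perturbRoi(m, "shift", shift = c(1, 0, 0))
  expect_equal(sum(sh), sum(m))
  expect_true(all(sh[6:9, 5:8, 5:8]))

  r1 <- perturbRoi(m, "shift", magnitude = 2, seed = 9)
  r2 <- perturbRoi(m, "shift", magnitude = 2, seed = 9)
  expect_identical(r1, r2)

  m2 <- matrix(FALSE, 10, 10); m2[4:6, 4:6] <- TRUE
  expect_equal(sum(perturbRoi(m2, "shift", shift = c(2, -1))), sum(m2))
  expect_gt(sum(perturbRoi(m2, "dilate", 1)), sum(m2))
})
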