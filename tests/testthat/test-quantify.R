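test_that("geometric mean combines conjugate views pixelwise", {
  a <- matrix(100, 3, 3); p <- matrix(400, 3, 3)
  expect_equal(geometricMean(a, p, mirrorPosterior = FALSE),
               matrix(200, 3, 3))
  expect_equal(geometricMean(a, a, mirrorPosterior = FALSE), a)
  a0 <- a; a0[2, 2] <- 0
  expect_equal(geometricMean(a0, p, mirrorPosterior = FALSE)[2, 2], 0)
  expect_error(geometricMean(a, matrix(1, 2, 3)), "same shape")
  # symmetry and degree-1 homogeneity
  x <- matrix(stats::runif(9, 1, 10), 3, 3)
  y <- matrix(stats::runif(9, 1, 10), 3, 3)
  expect_equal(geometricMean(x, y, mirrorPosterior = FALSE),
               geometricMean(y, x, mirrorPosterior = FALSE))
  expect_equal(geometricMean(3 * x, 3 * y, mirrorPosterior = FALSE),
               3 * geometricMean(x, y, mirrorPosterior = FALSE))
})

test_that("posterior mirroring is required and fixed by camera geometry", {
  # off-centre point source: the rear detector sees it mirrored in x
  d <- c(11, 8, 7)
  a <- array(0, d); a[3, 4, 4] <- 10
  mu <- array(0, d)
  ia <- projectPlanar(a, mu, c(5, 5, 5), "anterior", 1, 1)
  ip <- projectPlanar(a, mu, c(5, 5, 5), "posterior", 1, 1)
  expect_gt(ia[3, 4], 0)
  expect_gt(ip[9, 4], 0)          # mirrored x index: 11 + 1 - 3
  expect_equal(ip[3, 4], 0)
  gm <- geometricMean(ia, ip)     # flip realigns the frames
  expect_gt(gm[3, 4], 0)
  expect_equal(sum(gm > 0), 1L)
})

test_that("background weighting factor follows the thickness ratio", {
  expect_equal(backgroundWeighting(4.5, 25), 0.82)
  expect_equal(backgroundWeighting(0, 20), 1)
  expect_equal(backgroundWeighting(20, 20), 0)
  expect_error(backgroundWeighting(26, 25), "<=")
  expect_error(backgroundWeighting(1, 0), "> 0")
  for (i in 1:20) {
    db <- stats::runif(1, 5, 40); do <- stats::runif(1, 0, db)
    wf <- backgroundWeighting(do, db)
    expect_true(wf >= 0 && wf <= 1)
  }
  expect_equal(backgroundCorrectionSpec(4.5, 25)@wf, 0.82)
})

test_that("weighted background subtraction floors at zero with a flag", {
  r <- correctBackground(1000, 50, 500, 50, 0.8)
  expect_equal(r$counts, 600)
  expect_false(r$floored)
  expect_equal(correctBackground(1000, 50, 500, 50, 0)$counts, 1000)
  rf <- correctBackground(100, 50, 5000, 50, 0.8)
  expect_equal(rf$counts, 0)
  expect_true(rf$floored)
})

test_that("calibration sensitivity is decay-corrected to scan time", {
  std <- calibrationStandard(196)
  expect_equal(sensitivityFromStandard(19600, 100, std, scanTimeH = 0), 1)
  expect_equal(sensitivityFromStandard(39200, 200, std, scanTimeH = 0), 1)
  # one half-life later the same rate implies doubled sensitivity
  s <- sensitivityFromStandard(19600, 100, std, scanTimeH = 159.528,
                               physicalHalfLife = 159.528)
  expect_equal(s, 2)
  expect_error(sensitivityFromStandard(0, 100, std), "standard")
})

test_that("planar quantification recovers activity in the no-attenuation limit", {
  st <- noPhysicsStudy()
  res <- runPlanar(st)
  tr <- truthRecord(st)
  for (nm in c("organ_a", "organ_b")) {
    a4 <- res@tacs[[nm]]@activitiesMBq[1]
    truth <- st@admin@activityGBq * 1000 *
      tr$f[tr$organ == nm] * exp(-tr$lambda_eff_per_h[tr$organ == nm] * 4)
    expect_lt(abs(a4 / truth - 1), 0.01)
  }
})

test_that("planar estimates of a deep organ without overlap are biased low under attenuation", {
  # attenuation with no correction: counts lost, bias sign fixed by geometry
  ps <- isolatedOrganSpec(mu = 0.137)
  st <- simulateStudy(ps, acquisitionSpec(seed = 1), administrationRecord(7))
  res <- runPlanar(st)
  truth <- truthRecord(st)
  expect_lt(res@doses$tau_h, truth$tau_h)        # underestimation, mu > 0
  # and near zero for a zero-uptake organ
  ps0 <- phantomSpec(c(24, 24, 28), 5, list(
    organSpec("cold", "sphere", c(60, 60, 70), 15, uptakeFraction = 0),
    organSpec("hot", "sphere", c(60, 60, 110), 12, uptakeFraction = 0.1,
              bioHalfLife = 80)),
    bodyCenter = c(60, 60, 80), bodySemiAxes = c(40, 40, 50),
    muSoft = 0, muLung = 0)
  st0 <- simulateStudy(ps0, acquisitionSpec(seed = 1), administrationRecord(7))
  gm <- geometricMean(st0@anterior[[1]], st0@posterior[[1]])
  ph <- st0@phantom
  roi <- new("ROI2D", organ = "cold", mask = projectVoi(ph@masks$cold),
             background = placeBackgroundRoi(projectVoi(ph@masks$cold),
               projectVoi(ph@masks$cold) | projectVoi(ph@masks$hot),
               apply(ph@body, c(1, 3), any)))
  est <- planarOrganActivity(gm, roi, 1, 10, 300)
  expect_lt(est$activityMBq, 1)   # ~0 MBq against 700 MBq in the hot organ
})

test_that("VOI activity scales with the calibration factor and respects blur", {
  ph <- buildPhantom(isolatedOrganSpec(mu = 0))
  vol <- renderActivityVolume(ph, c(ball = 400))
  expect_equal(voiActivity(vol, ph@masks$ball), 400)
  expect_equal(voiActivity(vol, ph@masks$ball, calibrationFactor = 2), 800)
  expect_error(voiActivity(vol, array(FALSE, dim(vol))), "empty")

  fwhm <- 15
  volB <- renderActivityVolume(ph, c(ball = 400), psfFwhmMm = fwhm)
  measured <- voiActivity(volB, ph@masks$ball)
  expect_lt(measured, 400)
  volMl <- sum(ph@masks$ball) * prod(ph@spec@voxelSize) / 1000
  rc <- recoveryCoefficient(recoveryModel(fwhm), volMl)
  expect_lt(abs(measured / 400 / rc - 1), 0.02)
})

test_that("VOI projection collapses the anterior-posterior axis", {
  full <- array(TRUE, c(5, 4, 6))
  expect_true(all(projectVoi(full)))
  single <- array(FALSE, c(5, 4, 6)); single[2, 3, 4] <- TRUE
  p <- projectVoi(single)
  expect_equal(sum(p), 1L)
  expect_true(p[2, 4])
  # disjoint in 3D, overlapping in projection
  a <- array(FALSE, c(6, 6, 6)); a[2:4, 1:2, 2:4] <- TRUE
  b <- array(FALSE, c(6, 6, 6)); b[3:5, 5:6, 3:5] <- TRUE
  expect_false(any(a & b))
  expect_true(any(projectVoi(a) & projectVoi(b)))
})

test_that("overlap removal with residual-volume substitution is exact for uniform organs", {
  d <- c(20, 12, 20)
  organA <- array(FALSE, d); organA[5:14, 3:5, 5:14] <- TRUE     # 10x10 footprint
  organB <- array(FALSE, d); organB[5:14, 8:10, 12:17] <- TRUE   # overlaps 3 z-rows
  sub <- removeOverlapAndSubstitute(list(a = organA, b = organB))
  # organ A: 10 of its 10 z-columns, 3 removed -> 30% of voxels in overlap
  expect_equal(sub$a$voxelsResidual / sub$a$voxelsTotal, 0.7)
  expect_equal(sub$a$factor, 1 / 0.7)
  expect_gte(sub$b$factor, 1)

  # uniform concentration: measured residual activity times the factor is exact
  vol <- array(0, d)
  vol[organA] <- 500 / sum(organA)
  surv <- sub$a$mask2d
  measured <- sum(vol[organA & aperm(array(rep(surv, d[2]),
                                           c(d[1], d[3], d[2])), c(1, 3, 2))])
  expect_equal(measured * sub$a$factor, 500, tolerance = 1e-12)

  # a hot spot inside the removed part breaks the extrapolation downward
  hot <- array(0, d)
  hot[organA] <- 1
  hot[8:11, 3:5, 13:14] <- 5                    # lesion in the removed rows
  total <- sum(hot[organA])
  measuredHot <- sum(hot[organA & aperm(array(rep(surv, d[2]),
                                              c(d[1], d[3], d[2])), c(1, 3, 2))])
  expect_lt(measuredHot * sub$a$factor, total)

  expect_equal(removeOverlapAndSubstitute(list(a = organA))$a$factor, 1)
  inner <- array(FALSE, d); inner[6:9, 11, 13:14] <- TRUE
  expect_error(removeOverlapAndSubstitute(list(a = organA, c = inner)),
               "occluded")
})

test_that("hybrid rescaling anchors the curve without changing its shape", {
  tac <- timeActivityCurve("k", c(4, 24, 48), c(10, 5, 2.5), method = "planar")
  r <- hybridRescale(tac, 10, 24)
  expect_equal(r@activitiesMBq, c(20, 10, 5))
  expect_equal(r@method, "hybrid")
  expect_equal(hybridRescale(tac, 5, 24)@activitiesMBq, tac@activitiesMBq)
  f0 <- fitMonoexp(tac)
  f1 <- fitMonoexp(hybridRescale(tac, 123.4, 24))
  expect_equal(f1@lambda, f0@lambda, tolerance = 1e-7)
  expect_error(hybridRescale(tac, 10, 30), "not a time point")
  tac0 <- timeActivityCurve("k", c(4, 24, 48), c(10, 0, 2.5))
  expect_error(hybridRescale(tac0, 10, 24), "> 0")
})

test_that("sphere recovery coefficients behave like a Gaussian-blurred sphere", {
  expect_equal(recoveryCoefficient(recoveryModel(0), 10), 1)
  expect_error(recoveryCoefficient(recoveryModel(10), -1), "> 0")
  vols <- c(0.5, 2, 8, 30, 120, 500)
  rcs <- vapply(vols, function(v) recoveryCoefficient(10, v), numeric(1))
  expect_true(all(diff(rcs) > 0))
  expect_true(all(rcs > 0 & rcs <= 1))
  expect_gt(rcs[length(rcs)], 0.85)
  expect_gt(recoveryCoefficient(10, 1e6), 0.98)   # volume -> infinity limit

  # sphere diameter equal to the FWHM, checked against brute-force 3D
  # convolution of a finely rasterised sphere
  fwhm <- 16
  R <- 8
  volMl <- 4 / 3 * pi * R^3 / 1000
  rc <- recoveryCoefficient(recoveryModel(fwhm), volMl)
  n <- 48; vox <- 1
  ball <- array(FALSE, c(n, n, n))
  cx <- (n / 2) * vox
  for (k in 1:n) {
    zk <- (k - 0.5) - cx
    sl <- outer(((1:n) - 0.5) - cx, ((1:n) - 0.5) - cx,
                function(x, y) x^2 + y^2 + zk^2) <= R^2
    ball[, , k] <- sl
  }
  vol <- array(0, dim(ball)); vol[ball] <- 1
  blurred <- bruteBlur3d(vol, fwhm, c(vox, vox, vox))
  rcOracle <- sum(blurred[ball]) / sum(vol)
  expect_lt(abs(rc / rcOracle - 1), 0.02)
})

test_that("background bands stay inside the body and clear of every ROI", {
  body <- matrix(TRUE, 30, 30)
  organ <- matrix(FALSE, 30, 30); organ[10:15, 10:20] <- TRUE
  other <- matrix(FALSE, 30, 30); other[17:20, 8:22] <- TRUE
  band <- placeBackgroundRoi(organ, organ | other, body)
  expect_true(any(band))
  expect_false(any(band & (organ | other)))
  expect_true(all(body[band]))
  expect_error(placeBackgroundRoi(organ, matrix(TRUE, 30, 30), body),
               "no valid")
})
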