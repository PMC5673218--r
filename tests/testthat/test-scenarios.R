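test_that("the three scenarios coincide in the no-physics limit", {
  res <- runAllScenarios(noPhysicsStudy())
  doses <- sapply(res, function(r) setNames(r@doses$dose_Gy, r@doses$organ))
  rel <- abs(doses - doses[, "multi_spect"]) / doses[, "multi_spect"]
  expect_lt(max(rel), 0.01)
  # and all agree with the generator truth
  tr <- truthRecord(noPhysicsStudy())
  expect_lt(max(abs(doses[tr$organ, "multi_spect"] / tr$dose_Gy - 1)), 0.01)
})

test_that("multi-SPECT-CT recovers true residence times without blur", {
  st <- referenceStudyNoBlur()
  res <- runMultiSpect(st)
  tr <- truthRecord(st)
  tau <- setNames(res@doses$tau_h, res@doses$organ)
  expect_lt(max(abs(tau[tr$organ] / tr$tau_h - 1)), 0.02)
})

test_that("scenario preconditions raise actionable errors", {
  ps <- isolatedOrganSpec(mu = 0)
  stPartial <- simulateStudy(ps, acquisitionSpec(spectTimes = 24, seed = 1),
                             administrationRecord(7))
  expect_error(runMultiSpect(stPartial), "hybrid")
  expect_error(runHybrid(stPartial, tRefH = 60), "within 2 h")
  expect_error(runHybrid(stPartial, tRefH = 48), "SPECT")
  expect_error(acquisitionSpec(timePoints = 24), "2")
  # hybrid works from the single 24 h SPECT
  expect_s4_class(runHybrid(stPartial, tRefH = 24), "ScenarioResult")
})

test_that("hybrid substitution stays exact for uniform organs under projection overlap", {
  st <- simulateStudy(overlapNoMuSpec(),
                      acquisitionSpec(spectFwhm = 0, planarFwhm = 0, seed = 2),
                      administrationRecord(7.2))
  tr <- truthRecord(st)
  hy <- runHybrid(st)
  tau <- setNames(hy@doses$tau_h, hy@doses$organ)
  expect_lt(max(abs(tau[tr$organ] / tr$tau_h - 1)), 0.02)
  # and the hybrid equals multi-SPECT-CT in this no-physics limit
  ms <- runMultiSpect(st)
  expect_equal(tau[ms@doses$organ], setNames(ms@doses$tau_h, ms@doses$organ),
               tolerance = 0.01)
})

test_that("scenario runs are deterministic for a fixed study", {
  st <- referenceStudy()
  r1 <- runAllScenarios(st)
  r2 <- runAllScenarios(st)
  for (s in names(r1)) expect_identical(r1[[s]]@doses, r2[[s]]@doses)
  stA <- simulateStudy(referencePhantomSpec(),
                       referenceAcquisitionSpec(seed = 7, noise = TRUE),
                       administrationRecord(7.2))
  stB <- simulateStudy(referencePhantomSpec(),
                       referenceAcquisitionSpec(seed = 7, noise = TRUE),
                       administrationRecord(7.2))
  expect_identical(runPlanar(stA)@doses, runPlanar(stB)@doses)
})

test_that("planar overestimates the liver-overlapped kidney while SPECT-based scenarios stay close", {
  res <- runAllScenarios(referenceStudy())
  dpa <- sapply(res, function(r)
    r@doses$dpa_Gy_per_GBq[r@doses$organ == "kidney_right"])
  expect_gt(dpa["planar"], dpa["hybrid"])
  expect_gt(dpa["hybrid"], dpa["multi_spect"])
  # without overlap the planar estimate of a deep organ falls below SPECT
  dpaL <- sapply(res, function(r)
    r@doses$dpa_Gy_per_GBq[r@doses$organ == "kidney_left"])
  expect_lt(dpaL["planar"], dpaL["multi_spect"])
})

test_that("cohort comparison reports Friedman, Wilcoxon and median ratios", {
  res <- lapply(testCohort(), runAllScenarios)
  tab <- cohortDoseTable(res)
  cmp <- compareScenarios(tab)
  expect_setequal(cmp@friedman$organ, unique(tab$organ))
  expect_true(all(cmp@friedman$p_value >= 0 & cmp@friedman$p_value <= 1))
  expect_true(all(cmp@wilcoxon$p_value >= 0 & cmp@wilcoxon$p_value <= 1))
  rt <- ratioTable(cmp)
  kid <- rt[rt$organ == "kidney_right", ]
  expect_gt(kid$planar_multi, kid$hybrid_multi)
  expect_gt(kid$hybrid_multi, 1)

  # degenerate input: identical scenarios give a zero statistic, unit ratios
  same <- tab[tab$scenario == "multi_spect", ]
  ident <- do.call(rbind, lapply(c("multi_spect", "hybrid", "planar"),
                                 function(s) transform(same, scenario = s)))
  cmp0 <- compareScenarios(ident)
  expect_true(all(cmp0@friedman$statistic == 0))
  expect_true(all(abs(ratioTable(cmp0)$hybrid_multi - 1) < 1e-12))

  bad <- tab[!(tab$study == "study01" & tab$organ == "liver"), ]
  expect_error(compareScenarios(bad), "unequal organ sets")
  expect_error(compareScenarios(tab[tab$study %in% c("study01", "study02"), ]),
               ">= 3 studies")
})

test_that("Friedman and Wilcoxon statistics match textbook oracles", {
  # hand-built table: statistic from the rank formula
  mat <- cbind(multi_spect = c(0.4, 0.5, 0.45, 0.38, 0.62),
               hybrid = c(0.5, 0.55, 0.5, 0.42, 0.6),
               planar = c(0.7, 0.82, 0.65, 0.55, 0.9))
  tab <- data.frame(study = rep(paste0("s", 1:5), 3),
                    organ = "kidneys",
                    scenario = rep(colnames(mat), each = 5),
                    dpa_Gy_per_GBq = as.vector(mat))
  cmp <- compareScenarios(tab)
  expect_equal(cmp@friedman$statistic, friedmanOracle(mat), tolerance = 1e-9)

  # Wilcoxon signed-rank against enumeration over all sign assignments
  # (distinct difference magnitudes keep the exact distribution applicable)
  x <- c(0.50, 0.55, 0.50, 0.42, 0.60, 0.75)
  y <- c(0.41, 0.47, 0.45, 0.38, 0.72, 0.62)
  orc <- wilcoxExactOracle(x - y)
  wt <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(unname(wt$statistic), orc$statistic)
  expect_equal(wt$p.value, orc$p, tolerance = 1e-12)
  w8 <- cmp@wilcoxon[cmp@wilcoxon$comparison == "planar_vs_multi_spect", ]
  orc8 <- wilcoxExactOracle(mat[, "planar"] - mat[, "multi_spect"])
  expect_equal(w8$statistic, orc8$statistic)
  expect_equal(w8$p_value, orc8$p, tolerance = 1e-12)
})

test_that("Kendall's W matches closed forms and a Spearman-based oracle", {
  expect_equal(kendallsW(rbind(1:6, 1:6, 1:6))@W, 1)
  # two observers in perfect disagreement: W = (rho + 1) / 2 = 0
  expect_equal(kendallsW(rbind(1:5, 5:1))@W, 0)
  set.seed(31)
  mat <- matrix(stats::rnorm(3 * 16), 3, 16)
  w <- kendallsW(mat)
  expect_equal(w@W, kendallWSpearmanOracle(mat), tolerance = 1e-12)
  expect_equal(w@pChisq,
               stats::pchisq(3 * 15 * w@W, df = 15, lower.tail = FALSE))
  # tie handling: a constant observer is legal
  wt <- kendallsW(rbind(c(1, 1, 1, 1), c(1, 2, 3, 4)))
  expect_true(wt@W >= 0 && wt@W <= 1)
  # permutation p reproducible under seed
  p1 <- kendallsW(mat, permutations = 99, seed = 5)@pPermutation
  p2 <- kendallsW(mat, permutations = 99, seed = 5)@pPermutation
  expect_equal(p1, p2)
  expect_error(kendallsW(matrix(1:4, 1)), "observers")
})

test_that("simulated observers agree perfectly without perturbation and degrade with it", {
  coh <- testCohort()
  obs0 <- simulateObserverStudy(coh, "kidney_right", magnitude = 0, seed = 1)
  expect_equal(obs0$threeD@W, 1)
  expect_equal(obs0$twoD@W, 1)
  obs <- simulateObserverStudy(coh, "kidney_right", magnitude = 2, seed = 42)
  obsB <- simulateObserverStudy(coh, "kidney_right", magnitude = 2, seed = 42)
  expect_equal(obs$threeD@W, obsB$threeD@W)
  expect_equal(obs$twoD@W, obsB$twoD@W)
  # CT-based 3D delineation concords at least as well as planar 2D
  # (seeded regression at the default configuration, not a theorem)
  expect_gte(obs$threeD@W, obs$twoD@W)
  expect_error(simulateObserverStudy(coh, "kidney_right", nObservers = 1),
               "observers")
})
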