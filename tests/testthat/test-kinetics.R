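test_that("mono-exponential fits recover noise-free parameters to machine precision", {
  t <- c(4, 24, 48, 72, 168)
  tac <- timeActivityCurve("k", t, 100 * exp(-0.05 * t))
  f <- fitMonoexp(tac)
  expect_lt(abs(f@A0 / 100 - 1), 1e-6)
  expect_lt(abs(f@lambda / 0.05 - 1), 1e-6)
  expect_gt(f@r2, 1 - 1e-10)

  # two points: closed-form decay constant
  tac2 <- timeActivityCurve("k", c(10, 40), c(80, 20))
  f2 <- fitMonoexp(tac2)
  expect_equal(f2@lambda, log(80 / 20) / 30, tolerance = 1e-9)
  expect_equal(f2@A0 * exp(-f2@lambda * 10), 80, tolerance = 1e-6)
})

test_that("noisy fits match a brute-force grid-search oracle", {
  t <- c(4, 24, 48, 72, 168)
  set.seed(99)
  a <- 100 * exp(-0.02 * t) * (1 + 0.05 * stats::rnorm(5))
  f <- fitMonoexp(timeActivityCurve("k", t, a))
  orc <- gridSearchFitOracle(t, a, c(80, 120), c(0.005, 0.05))
  expect_lt(abs(f@A0 - orc$A0), 2 * orc$resA0)
  expect_lt(abs(f@lambda - orc$lambda), 2 * orc$resLam)
  expect_lte(f@rss, orc$sse + 1e-9)
})

test_that("degenerate curves raise errors instead of clamped values", {
  t <- c(4, 24, 48)
  expect_error(fitMonoexp(timeActivityCurve("k", t, c(0, 0, 0))), "zero")
  growing <- timeActivityCurve("k", t, c(10, 20, 40))
  err <- tryCatch(fitMonoexp(growing), error = function(e) e)
  expect_s3_class(err, "lutadose_nondecay_error")
  expect_true(err$lambda <= 0)
  expect_gt(err$A0, 0)
})

test_that("fits are scale-equivariant and time-unit consistent", {
  t <- c(4, 24, 48, 72, 168)
  set.seed(7)
  a <- 50 * exp(-0.03 * t) * (1 + 0.03 * stats::rnorm(5))
  f1 <- fitMonoexp(timeActivityCurve("k", t, a))
  f2 <- fitMonoexp(timeActivityCurve("k", t, 10 * a))
  expect_equal(f2@A0, 10 * f1@A0, tolerance = 1e-6)
  expect_equal(f2@lambda, f1@lambda, tolerance = 1e-6)
  adm <- administrationRecord(7)
  expect_equal(residenceTime(f2, adm), 10 * residenceTime(f1, adm),
               tolerance = 1e-6)
  # fitting in days instead of hours scales tau by exactly 24
  fd <- fitMonoexp(timeActivityCurve("k", t / 24, a))
  expect_equal(residenceTime(f1, adm) / residenceTime(fd, adm), 24,
               tolerance = 1e-6)
})

test_that("residence time integrates the fitted curve over all time", {
  f <- new("FitResult", organ = "k", A0 = 700, lambda = 0.01, rss = 0,
           r2 = 1, converged = TRUE, method = "spect")
  adm <- administrationRecord(7)
  expect_equal(residenceTime(f, adm), 10)
  expect_equal(residenceTime(f, administrationRecord(14)), 5)

  # full uptake, physical decay only: tau = T_phys / ln 2
  t <- c(4, 24, 48, 72, 168)
  lam <- log(2) / 159.528
  fp <- fitMonoexp(timeActivityCurve("wb", t, 7000 * exp(-lam * t)))
  expect_equal(residenceTime(fp, adm), 159.528 / log(2), tolerance = 1e-6)
})

test_that("ground-truth residence times mirror the generator kinetics", {
  o <- organSpec("k", "sphere", c(9, 9, 9), 3, uptakeFraction = 0.069315,
                 bioHalfLife = 300)
  lam <- log(2) / 159.528 + log(2) / 300
  expect_equal(trueResidenceTime(o), 0.069315 / lam)
  o2 <- organSpec("k", "sphere", c(9, 9, 9), 3,
                  uptakeFraction = 2 * 0.069315, bioHalfLife = 300)
  expect_equal(trueResidenceTime(o2), 2 * trueResidenceTime(o))
  o0 <- organSpec("k", "sphere", c(9, 9, 9), 3, uptakeFraction = 0)
  expect_warning(tau0 <- trueResidenceTime(o0), "zero uptake")
  expect_equal(tau0, 0)
})

test_that("residence times are recovered from noisy curves across many simulations", {
  t <- c(4, 24, 48, 72, 168)
  adm <- administrationRecord(7.2)
  set.seed(2024)
  relErr <- replicate(200, {
    f0 <- stats::runif(1, 0.01, 0.2)
    lam <- log(2) / 159.528 + log(2) / stats::runif(1, 30, 300)
    a <- 7200 * f0 * exp(-lam * t) * (1 + 0.05 * stats::rnorm(5))
    a <- pmax(a, 1e-6)
    fit <- fitMonoexp(timeActivityCurve("k", t, a))
    abs(residenceTime(fit, adm) - f0 / lam) / (f0 / lam)
  })
  expect_lt(stats::median(relErr), 0.05)
})
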