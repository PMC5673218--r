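# Shared fixtures (built once per test run) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

.memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# reference abdominal study: attenuation on, PSFs on, noise off, seed 7
referenceStudy <- function() .memo("refStudy", function()
  simulateStudy(referencePhantomSpec(), referenceAcquisitionSpec(seed = 7),
                administrationRecord(7.2)))

# same phantom, ideal imaging (no blur) -- for truth-recovery checks
referenceStudyNoBlur <- function() .memo("refStudyNoBlur", function()
  simulateStudy(referencePhantomSpec(),
                acquisitionSpec(spectFwhm = 0, planarFwhm = 0, seed = 7),
                administrationRecord(7.2)))

noPhysicsStudy <- function() .memo("npStudy", function()
  simulateStudy(noPhysicsPhantomSpec(),
                acquisitionSpec(spectFwhm = 0, planarFwhm = 0, seed = 1),
                administrationRecord(7.2)))

testCohort <- function() .memo("cohort", function() simulateCohort(6, seed = 3))

# a mu = 0, blur-free phantom whose two organs overlap in projection
overlapNoMuSpec <- function() {
  organs <- list(
    organSpec("deep", "ellipsoid", c(100, 85, 100), c(24, 12, 24),
              density = 1.05, uptakeFraction = 0.04, bioHalfLife = 60),
    organSpec("shallow", "ellipsoid", c(90, 35, 110), c(30, 14, 30),
              density = 1.06, uptakeFraction = 0.1, bioHalfLife = 200))
  phantomSpec(c(40, 24, 44), 5, organs, bodyShape = "box",
              bodyCenter = c(100, 60, 115), bodySemiAxes = c(80, 50, 95),
              backgroundUptake = 0.2, backgroundHalfLife = 100,
              muSoft = 0, muLung = 0)
}

# single isolated organ in an attenuating uniform slab body (box)
isolatedOrganSpec <- function(mu = 0.137) {
  organs <- list(
    organSpec("ball", "sphere", c(60, 60, 70), 15,
              density = 1.05, uptakeFraction = 0.1, bioHalfLife = 80))
  phantomSpec(c(24, 24, 28), 5, organs, bodyShape = "box",
              bodyCenter = c(60, 60, 80), bodySemiAxes = c(40, 40, 50),
              backgroundUptake = 0, backgroundHalfLife = Inf,
              muSoft = mu, muLung = mu)
}

# --- independent oracles -------------------------------------------------

# spatial shift-add Gaussian convolution (zero-padded), independent of the
# package's FFT route
bruteBlur3d <- function(vol, fwhmMm, voxMm) {
  sig <- fwhmMm / (2 * sqrt(2 * log(2))) / voxMm
  r <- ceiling(4 * max(sig))
  off <- -r:r
  k1 <- function(s) { k <- exp(-off^2 / (2 * s^2)); k / sum(k) }
  kx <- k1(sig[1]); ky <- k1(sig[2]); kz <- k1(sig[3])
  d <- dim(vol)
  shift1 <- function(v, ax, by) {
    out <- array(0, dim(v))
    if (abs(by) >= dim(v)[ax]) return(out)
    idx <- lapply(dim(v), seq_len)
    src <- idx; dst <- idx
    n <- dim(v)[ax]
    if (by >= 0) { src[[ax]] <- seq_len(n - by); dst[[ax]] <- src[[ax]] + by }
    else { src[[ax]] <- seq(1 - by, n); dst[[ax]] <- src[[ax]] + by }
    out[dst[[1]], dst[[2]], dst[[3]]] <- v[src[[1]], src[[2]], src[[3]]]
    out
  }
  conv1 <- function(v, ax, k) {
    acc <- array(0, dim(v))
    for (i in seq_along(off)) acc <- acc + k[i] * shift1(v, ax, off[i])
    acc
  }
  conv1(conv1(conv1(vol, 1, kx), 2, ky), 3, kz)
}

# exact two-sided Wilcoxon signed-rank p by enumeration over sign
# assignments (distinct non-zero differences assumed)
wilcoxExactOracle <- function(d) {
  n <- length(d)
  rk <- rank(abs(d))
  v <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% rk
  pLe <- mean(vs <= v)
  pGe <- mean(vs >= v)
  list(statistic = v, p = min(1, 2 * min(pLe, pGe)))
}

# Friedman chi-square statistic from the textbook rank formula
friedmanOracle <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  R <- colSums(t(apply(mat, 1, rank)))
  12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
}

# Kendall's W from mean pairwise Spearman correlation (no ties)
kendallWSpearmanOracle <- function(mat) {
  m <- nrow(mat)
  cors <- c()
  for (i in seq_len(m - 1)) for (j in (i + 1):m)
    cors <- c(cors, stats::cor(mat[i, ], mat[j, ], method = "spearman"))
  ((m - 1) * mean(cors) + 1) / m
}

# brute-force (A0, lambda) grid search minimising the SSE
gridSearchFitOracle <- function(t, a, A0range, lamRange, nGrid = 201) {
  A0s <- seq(A0range[1], A0range[2], length.out = nGrid)
  lams <- seq(lamRange[1], lamRange[2], length.out = nGrid)
  best <- c(NA, NA, Inf)
  for (A0 in A0s) {
    for (lam in lams) {
      sse <- sum((a - A0 * exp(-lam * t))^2)
      if (sse < best[3]) best <- c(A0, lam, sse)
    }
  }
  list(A0 = best[1], lambda = best[2], sse = best[3],
       resA0 = diff(A0range) / (nGrid - 1), resLam = diff(lamRange) / (nGrid - 1))
}
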