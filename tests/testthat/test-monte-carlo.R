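# Shared small runs (built once per test file execution)
homog10 <- layeredMedium(Inf, mua = 0, musp = 10)
ringGeo <- detectionGeometry(3, ringHalfWidth = 0.25, tMaxRecord = 6)
allGeo <- detectionGeometry(3, acceptAllExits = TRUE, tMaxRecord = 10)
resRing <- runMC(homog10, ringGeo, 3e4, seed = 7, maxLaunch = 1e9)
resAll <- runMC(homog10, allGeo, 3e4, seed = 8)

test_that("path-length bookkeeping identity holds for every record", {
  v <- lightSpeed(1.4)
  for (res in list(resRing, resAll)) {
    expect_true(nDetected(res) > 0)
    err <- abs(rowSums(res@pathlen) - v * res@exitTime)
    expect_lt(max(err), 1e-6)
  }
})

test_that("identical seed and parameters reproduce the identical result", {
  a <- runMC(homog10, ringGeo, 2000, seed = 123, maxLaunch = 1e8)
  b <- runMC(homog10, ringGeo, 2000, seed = 123, maxLaunch = 1e8)
  expect_identical(a@exitTime, b@exitTime)
  expect_identical(a@pathlen, b@pathlen)
  expect_identical(a@nLaunched, b@nLaunched)
  c <- runMC(homog10, ringGeo, 2000, seed = 124, maxLaunch = 1e8)
  expect_false(identical(a@exitTime, c@exitTime))
})

test_that("splitting a homogeneous medium into layers is a transport no-op", {
  split2 <- layeredMedium(c(2, Inf), mua = c(0, 0), musp = c(10, 10))
  rs <- runMC(split2, allGeo, 2e4, seed = 5)
  rh <- runMC(homog10, allGeo, 2e4, seed = 6)
  # two-sample chi-square on 20 exit-time bins at the 1% level
  br <- seq(0, 5, length.out = 21)
  hs <- hist(pmin(rs@exitTime, 4.999), breaks = br, plot = FALSE)$counts
  hh <- hist(pmin(rh@exitTime, 4.999), breaks = br, plot = FALSE)$counts
  p <- suppressWarnings(stats::chisq.test(rbind(hs, hh)))$p.value
  expect_gt(p, 0.01)
})

test_that("zero absorption reweighting returns the raw count histogram", {
  ax <- timeAxis(0, 0.1, 60L)
  d <- applyAbsorption(resRing, 0, axis = ax)
  raw <- hist(resRing@exitTime[resRing@exitTime < 6],
              breaks = seq(0, 6, 0.1), plot = FALSE)$counts
  expect_equal(counts(d), as.numeric(raw))
})

test_that("photon weights obey the exponential identity w(2 mua) = w(mua)^2", {
  med2 <- layeredMedium(c(1.5, Inf), mua = c(0, 0), musp = c(7, 12))
  r2 <- runMC(med2, detectionGeometry(2, tMaxRecord = 5), 5000, seed = 3,
              maxLaunch = 1e9)
  w1 <- lungtdos:::photonWeights(r2, c(0.12, 0.3))
  w2 <- lungtdos:::photonWeights(r2, 2 * c(0.12, 0.3))
  expect_equal(w2, w1^2, tolerance = 1e-12)
  expect_error(applyAbsorption(r2, c(-0.1, 0.1)), "mua")
  expect_error(applyAbsorption(r2, 0.1), "layer count")
})

test_that("reweighted histogram matches diffusion theory at late times", {
  ax <- timeAxis(0, 0.1, 60L)
  d <- applyAbsorption(resRing, 0.1, axis = ax)
  model <- trReflectance(3, ax, opticalProperties(0.1, 10))
  sel <- which(timeCenters(ax) > 0.5 & timeCenters(ax) < 4)
  sc <- sum(counts(d)[sel]) / sum(model[sel])
  z <- (counts(d)[sel] - model[sel] * sc) / sqrt(pmax(model[sel] * sc, 1))
  # per-bin 3 sigma, allowing for the expected rate of statistical outliers
  expect_gt(mean(abs(z) < 3), 0.93)
  expect_lt(max(abs(z)), 5)
})

test_that("absorption reweighting agrees with an independent absorbing MC", {
  # oracle: plain-R transport that samples absorption events directly
  mua <- 0.2
  orc <- rTransportOracle(4e4, Inf, mus = 10, mua = mua, pathMax = 4 * lightSpeed(1.4),
                          seed = 17)
  v <- lightSpeed(1.4)
  br <- seq(0, 2.5, 0.25)
  hOrc <- hist(orc$exitPath[orc$exitPath / v < 2.5] / v, breaks = br,
               plot = FALSE)$counts
  # implementation: absorption-free kernel + Lambert-Beer reweighting
  resA <- runMC(homog10, detectionGeometry(1, acceptAllExits = TRUE,
                                           tMaxRecord = 4), 3e4, seed = 18)
  w <- lungtdos:::photonWeights(resA, mua)
  tsel <- resA@exitTime < 2.5
  hImp <- sapply(seq_len(length(br) - 1), function(i)
    sum(w[tsel & resA@exitTime >= br[i] & resA@exitTime < br[i + 1]]))
  # normalize per launched photon, compare within 3 sigma per bin
  nO <- orc$nLaunched
  nI <- resA@nLaunched
  pO <- hOrc / nO
  pI <- hImp / nI
  sig <- sqrt(hOrc / nO^2 + sapply(seq_len(length(br) - 1), function(i)
    sum(w[tsel & resA@exitTime >= br[i] & resA@exitTime < br[i + 1]]^2)) / nI^2)
  # Gaussian z-scores are only meaningful where expected counts are not in
  # the deep-Poisson regime
  ok <- hOrc >= 10 & pI * nO >= 10
  expect_gt(sum(ok), 3)
  zs <- (pO[ok] - pI[ok]) / pmax(sig[ok], 1e-12)
  expect_true(all(abs(zs) < 3.5))
})

test_that("direct-absorption kernel mode agrees with reweighting", {
  medAbs <- layeredMedium(Inf, mua = 0.2, musp = 10)
  rd <- runMC(medAbs, detectionGeometry(1, acceptAllExits = TRUE,
                                        tMaxRecord = 4), 3e4, seed = 19,
              directAbsorption = TRUE)
  resA <- runMC(homog10, detectionGeometry(1, acceptAllExits = TRUE,
                                           tMaxRecord = 4), 3e4, seed = 20)
  w <- lungtdos:::photonWeights(resA, 0.2)
  br <- seq(0, 2.5, 0.25)
  hD <- hist(rd@exitTime[rd@exitTime < 2.5], breaks = br, plot = FALSE)$counts
  hW <- sapply(seq_len(length(br) - 1), function(i)
    sum(w[resA@exitTime >= br[i] & resA@exitTime < br[i + 1]]))
  pD <- hD / rd@nLaunched
  pW <- hW / resA@nLaunched
  sig <- sqrt(hD / rd@nLaunched^2 +
                sapply(seq_len(length(br) - 1), function(i)
                  sum(w[resA@exitTime >= br[i] & resA@exitTime < br[i + 1]]^2)) /
                resA@nLaunched^2)
  ok <- hD >= 10 & pW * rd@nLaunched >= 10
  expect_gt(sum(ok), 3)
  expect_true(all(abs(pD[ok] - pW[ok]) / pmax(sig[ok], 1e-12) < 3.5))
})

test_that("correlated perturbation contrast has exact algebraic limits", {
  med2 <- layeredMedium(c(2, Inf), mua = c(0.15, 0.15), musp = c(7, 12))
  r2 <- runMC(med2, detectionGeometry(3, tMaxRecord = 6), 1e4, seed = 4,
              maxLaunch = 1e9)
  gates <- list(c(0.5, 0.5), c(2, 0.5), c(4, 0.5))
  # identical states: C = 0 exactly in every gate
  pc0 <- perturbationContrast(r2, c(0.15, 0.15), c(0.15, 0.15), gates)
  expect_true(all(pc0$contrast[pc0$defined] == 0))
  # reduced lung absorption: weights strictly increase, C > 0 everywhere
  pc1 <- perturbationContrast(r2, c(0.15, 0.15), c(0.15, 0.10), gates)
  lungVisited <- any(r2@pathlen[, 2] > 0)
  expect_true(lungVisited)
  expect_true(all(pc1$contrast[pc1$defined] > 0))
  # gate beyond the recorded range is rejected; empty gate flagged
  expect_error(perturbationContrast(r2, c(0.15, 0.15), c(0.15, 0.1),
                                    list(c(5.9, 0.5))), "recorded time range")
  tiny <- runMC(med2, detectionGeometry(3, tMaxRecord = 6), 50, seed = 9,
                maxLaunch = 1e8)
  pcEmpty <- perturbationContrast(tiny, c(0.15, 0.15), c(0.15, 0.1),
                                  list(c(5.4, 0.1)))
  if (pcEmpty$nPhotons[1] == 0) {
    expect_false(pcEmpty$defined[1])
    expect_true(is.na(pcEmpty$contrast[1]))
  }
})

test_that("mean maximum depth rises with time, falls with scattering, and is
           invariant under homogeneous absorption reweighting", {
  ax <- timeAxis(0, 0.5, 10L)
  z10 <- meanMaxDepthCurve(resAll, ax)
  ok <- z10$reliable
  expect_true(all(diff(z10$meanMaxDepth[ok]) > 0))
  # early-time limit: shallow depths toward the ballistic time
  expect_lt(z10$meanMaxDepth[which(ok)[1]], z10$meanMaxDepth[rev(which(ok))[1]])
  resHi <- runMC(layeredMedium(Inf, 0, 18), allGeo, 3e4, seed = 12)
  zHi <- meanMaxDepthCurve(resHi, ax)
  both <- z10$reliable & zHi$reliable
  expect_true(all(zHi$meanMaxDepth[both] < z10$meanMaxDepth[both]))
  # homogeneous reweighting leaves the within-bin mean unchanged up to the
  # (second-order) weight variation across a narrow bin; the earliest bins
  # are excluded because depth and arrival time are strongly correlated
  # right at the ballistic limit
  axN <- timeAxis(0, 0.05, 100L)
  zU <- meanMaxDepthCurve(resAll, axN, minRecords = 300L)
  v <- lightSpeed(1.4)
  w <- exp(-0.3 * v * resAll@exitTime)
  idx <- floor(resAll@exitTime / axN@dt) + 1
  for (b in which(zU$reliable & zU$t > 0.5)) {
    inb <- idx == b
    zW <- sum(resAll@maxDepth[inb] * w[inb]) / sum(w[inb])
    expect_equal(zW, zU$meanMaxDepth[b], tolerance = 0.01)
  }
})

test_that("depth statistics do not depend on the detection ring", {
  # compare mean max depth between two detection radii inside a narrow
  # arrival-time bin (Welch test, 1% level). The bin must be narrow:
  # pooling a wide window would mix different within-window time
  # distributions, which do depend on the radius.
  win <- c(1.9, 2.1)
  r1 <- runMC(homog10, detectionGeometry(2, tMaxRecord = 3), 2e4, seed = 31,
              maxLaunch = 1e9)
  r3 <- runMC(homog10, detectionGeometry(4, tMaxRecord = 3), 2e4, seed = 32,
              maxLaunch = 1e9)
  d1 <- r1@maxDepth[r1@exitTime >= win[1] & r1@exitTime < win[2]]
  d3 <- r3@maxDepth[r3@exitTime >= win[1] & r3@exitTime < win[2]]
  expect_gt(length(d1), 50)
  expect_gt(length(d3), 50)
  expect_gt(stats::t.test(d1, d3)$p.value, 0.01)
})

test_that("an unreachable detection target yields a flagged partial result", {
  expect_warning(
    res <- runMC(homog10, detectionGeometry(3, tMaxRecord = 6), 1e6,
                 seed = 1, maxLaunch = 2e4),
    "budget")
  expect_true(res@budgetExhausted)
  expect_lt(nDetected(res), 1e6)
  expect_error(meanMaxDepthCurve(
    runMC(homog10, ringGeo, 1, seed = 1, maxLaunch = 1e7),
    timeAxis(0, 1, 5L)), NA)
})
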