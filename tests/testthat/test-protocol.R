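# tiny synthetic series builders (pure construction, no transport)
toyAxis <- timeAxis(0, 0.5, 12L)   # centres 0.25 .. 5.75 ns
toySeries <- function(countList, protocol = breathingProtocol("custom",
                                                              phaseDuration = 2,
                                                              nRepetitions = 2L,
                                                              referencePrefix = FALSE),
                      labels = NULL, acqTime = 1) {
  n <- length(countList)
  ts <- seq(0, n - 1)
  if (is.null(labels)) labels <- protocolLabels(protocol, ts)
  protocolSeries(lapply(countList, function(cc)
    dtofCurve(toyAxis, cc, rho = 6, acqTime = acqTime)), ts, labels, protocol)
}

test_that("identical acquisitions give zero contrast everywhere", {
  cc <- rep(list(rep(100, 12)), 8)
  cs <- gatedContrast(toySeries(cc), defaultGates())
  expect_true(all(abs(cs@contrast) < 1e-12))
})

test_that("a scaled acquisition against a fixed reference shows its scale", {
  base <- rep(100, 12)
  scaled <- base * 1.1
  ser <- toySeries(list(base, scaled, base, base, base, base, base, base))
  ref <- dtofCurve(toyAxis, base, rho = 6, acqTime = 1)
  cs <- gatedContrast(ser, defaultGates(), reference = ref)
  expect_equal(cs@contrast[2, ], rep(0.1, 5), tolerance = 1e-12)
  expect_equal(cs@contrast[1, ], rep(0, 5), tolerance = 1e-12)
})

test_that("gated contrast equals the direct evaluation of the defining sums", {
  set.seed(77)
  cc <- lapply(1:8, function(i) rpois(12, 50) + 1)
  gates <- cbind(c(0.5, 2, 4), c(1, 1.5, 0.5))
  ser <- toySeries(cc)
  cs <- gatedContrast(ser, gates)
  tc <- timeCenters(toyAxis)
  M <- do.call(rbind, cc)
  for (k in 1:3) {
    inG <- tc >= gates[k, 1] & tc < gates[k, 1] + gates[k, 2]
    G <- rowSums(M[, inG, drop = FALSE])
    G0 <- mean(G)
    expect_equal(cs@contrast[, k], G / G0 - 1, tolerance = 1e-12)
  }
})

test_that("contrast is invariant under global rescaling of all acquisitions", {
  set.seed(78)
  cc <- lapply(1:8, function(i) rpois(12, 80) + 1)
  cs1 <- gatedContrast(toySeries(cc), defaultGates())
  cs2 <- gatedContrast(toySeries(lapply(cc, function(x) x * 7)), defaultGates())
  expect_equal(cs1@contrast, cs2@contrast, tolerance = 1e-12)
})

test_that("with the whole-exercise mean reference the contrast averages to
           zero per gate", {
  set.seed(79)
  cc <- lapply(1:10, function(i) rpois(12, 60) + 1)
  cs <- gatedContrast(toySeries(cc, breathingProtocol("custom",
                                                      phaseDuration = 2.5,
                                                      nRepetitions = 2L,
                                                      referencePrefix = FALSE)),
                      defaultGates())
  expect_true(all(abs(colMeans(cs@contrast)) < 1e-12))
})

test_that("REF acquisitions are excluded from the mean reference", {
  base <- rep(100, 12)
  hot <- rep(200, 12)
  prot <- breathingProtocol("custom", phaseDuration = 1, nRepetitions = 3L,
                            referencePrefix = TRUE)
  # the REF cycle has double counts: including it would bias the reference
  ser <- toySeries(c(rep(list(hot), 2), rep(list(base), 6)), prot)
  expect_identical(ser@labels[1:2], c("REF", "REF"))
  cs <- gatedContrast(ser, defaultGates())
  expect_true(all(abs(cs@contrast[3:8, ]) < 1e-12))
  csIn <- gatedContrast(ser, defaultGates(), includeReferencePrefix = TRUE)
  expect_true(all(cs@contrast[3:8, ] > csIn@contrast[3:8, ]))
})

test_that("folding average reproduces hand-computed cycles", {
  prot <- breathingProtocol("custom", phaseDuration = 2, nRepetitions = 2L,
                            referencePrefix = FALSE)
  expect_equal(foldingAverage(c(1, 2, 3, 4, 3, 4, 5, 6), prot), c(2, 3, 4, 5))
  # identical repetitions fold to any single cycle
  expect_equal(foldingAverage(c(7, 8, 9, 1, 7, 8, 9, 1), prot), c(7, 8, 9, 1))
  # single repetition is the identity
  prot1 <- breathingProtocol("custom", phaseDuration = 2, nRepetitions = 1L,
                             referencePrefix = FALSE)
  expect_equal(foldingAverage(1:4, prot1), 1:4)
  # reference prefix is dropped before folding
  protR <- breathingProtocol("custom", phaseDuration = 1, nRepetitions = 2L,
                             referencePrefix = TRUE)
  expect_equal(foldingAverage(c(9, 9, 1, 2, 3, 4), protR), c(2, 3))
  expect_error(foldingAverage(1:7, prot), "expected 8")
})

test_that("folding then contrast equals contrast then folding for a fixed
           reference", {
  set.seed(80)
  prot <- breathingProtocol("custom", phaseDuration = 2, nRepetitions = 2L,
                            referencePrefix = FALSE)
  cc <- lapply(1:8, function(i) rpois(12, 90) + 1)
  ref <- dtofCurve(toyAxis, rep(80, 12), rho = 6, acqTime = 1)
  cs <- gatedContrast(toySeries(cc, prot), defaultGates(), reference = ref)
  foldedC <- foldingAverage(cs@contrast, prot)
  # fold the raw curves first, then contrast
  M <- do.call(rbind, cc)
  Mf <- foldingAverage(M, prot)
  serF <- toySeries(lapply(seq_len(nrow(Mf)), function(i) Mf[i, ]), prot,
                    labels = protocolLabels(prot, 0:3))
  csF <- gatedContrast(serF, defaultGates(), reference = ref)
  expect_equal(csF@contrast, foldedC, tolerance = 1e-12)
})

test_that("protocol labels follow the Prot10 and Prot5 timing", {
  p10 <- breathingProtocol("prot10")
  lab10 <- protocolLabels(p10, 0:99)
  expect_equal(sum(lab10 == "IN"), 50)
  expect_equal(sum(lab10 == "OUT"), 50)
  expect_equal(lab10[1:21], c(rep("IN", 10), rep("OUT", 10), "IN"))
  p5 <- breathingProtocol("prot5")
  lab5 <- protocolLabels(p5, 0:109)
  expect_equal(sum(lab5 == "REF"), 10)
  expect_equal(lab5[11:16], c(rep("IN", 5), "OUT"))
})

test_that("plateau summary has the exact algebraic limits", {
  prot <- breathingProtocol("prot10")
  n <- 100
  ts <- 0:99
  labels <- protocolLabels(prot, ts)
  # constant contrast c
  mkCS <- function(vals) new("ContrastSeries",
                             contrast = matrix(vals, ncol = 1),
                             gateStart = 4.5, gateWidth = 0.5,
                             timestamps = ts, labels = labels,
                             reference = "test")
  s1 <- phasePlateauSummary(mkCS(rep(0.3, n)), prot)
  expect_equal(s1$meanIN, 0.3)
  expect_equal(s1$meanOUT, 0.3)
  expect_equal(s1$inMinusOut, 0)
  # alternating +c/-c plateaus with zero transient
  vals <- ifelse(labels == "IN", 0.2, -0.2)
  s2 <- phasePlateauSummary(mkCS(vals), prot, transient = 0)
  expect_equal(s2$inMinusOut, 0.4)
  expect_error(phasePlateauSummary(mkCS(vals), prot, transient = 11),
               "plateau")
})

test_that("per-acquisition fits track a stationary synthetic series", {
  irf <- testIRF()
  set.seed(88)
  acqs <- lapply(1:8, function(i)
    generateDTOF(opticalProperties(0.15, 8), 3, irf, noiseModel(1e6, 1)))
  prot <- breathingProtocol("custom", phaseDuration = 2, nRepetitions = 2L,
                            referencePrefix = FALSE)
  ser <- protocolSeries(acqs, 0:7, protocolLabels(prot, 0:7), prot)
  fits <- fitTimeseries(ser, irf, init = c(mua = 0.1, musp = 10))
  expect_true(all(fits$converged))
  expect_lt(stats::sd(fits$mua) / mean(fits$mua), 0.05)
  expect_lt(stats::sd(fits$musp) / mean(fits$musp), 0.05)
  expect_equal(mean(fits$mua), 0.15, tolerance = 0.05)
  # empty series -> empty output, no error
  empty <- protocolSeries(list(), numeric(0), character(0), prot)
  expect_equal(nrow(fitTimeseries(empty, irf)), 0)
})
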