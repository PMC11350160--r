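#' Acquisition noise model
#'
#' TCSPC-like counting statistics: the expected total count rate (the
#' instrument's operating point, about 1 Mcounts/s within the single-
#' photon regime), the acquisition time, and an optional uniform
#' background rate. Channel counts are Poisson.
#'
#' @param totalCountRate counts/s (default 1e6).
#' @param acqTime s (default 1).
#' @param backgroundRate counts/s per channel (default 0).
#' @param seed integer RNG seed.
#' @return A list with class "NoiseModel" fields.
#' @export
noiseModel <- function(totalCountRate = 1e6, acqTime = 1,
                       backgroundRate = 0, seed = 1L) {
  stopifnot(totalCountRate >= 0, acqTime > 0, backgroundRate >= 0)
  structure(list(totalCountRate = totalCountRate, acqTime = acqTime,
                 backgroundRate = backgroundRate, seed = as.integer(seed)),
            class = "NoiseModel")
}

#' Generate a synthetic instrument response function
#'
#' An asymmetric peaked curve — Gaussian rise, exponential tail — with
#' its peak in the channel containing t = 0, Poisson-sampled to the
#' requested total. Emulates the measured IRF of a TCSPC system whose
#' laser pulse is much narrower than the detector response.
#'
#' @param axis a [TimeAxis-class] (should extend below 0 to capture the
#'   rise; the default generator axes start at -1 ns).
#' @param fwhm full width at half maximum of the Gaussian core, ps
#'   (default 150).
#' @param totalCounts expected total counts (default 1e6).
#' @param seed integer RNG seed; NULL for the current RNG stream.
#' @param tailFraction fraction of the curve area in the exponential tail
#'   (default 0.2).
#' @param tailTau tail time constant, ps (default 250).
#' @param poisson Poisson-sample the curve (default TRUE; FALSE returns
#'   the noiseless expectation).
#' @return An [IRFCurve-class].
#' @export
generateIRF <- function(axis, fwhm = 150, totalCounts = 1e6, seed = NULL,
                        tailFraction = 0.2, tailTau = 250, poisson = TRUE) {
  stopifnot(is(axis, "TimeAxis"), fwhm > 0)
  fwhm_ns <- fwhm / 1000
  if (fwhm_ns >= axis@nChannels * axis@dt)
    stop("IRF width exceeds the time axis span")
  tc <- timeCenters(axis)
  sigma <- fwhm_ns / (2 * sqrt(2 * log(2)))
  core <- exp(-tc^2 / (2 * sigma^2))
  tau_ns <- tailTau / 1000
  tail <- ifelse(tc > 0, exp(-tc / tau_ns), 0)
  shape <- (1 - tailFraction) * core / sum(core)
  if (sum(tail) > 0) shape <- shape + tailFraction * tail / sum(tail)
  expected <- totalCounts * shape / sum(shape)
  cts <- if (poisson) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    stats::rpois(length(expected), expected)
  } else expected
  if (sum(cts) <= 0) cts[which.min(abs(tc))] <- 1
  irfCurve(axis, cts)
}

#' Generate a synthetic DTOF measurement
#'
#' Forward model + acquisition statistics: [trReflectance()] on the IRF's
#' axis, convolved with the IRF, scaled so the expected total equals
#' `totalCountRate * acqTime`, Poisson-sampled per channel, plus Poisson
#' background.
#'
#' @param props an [OpticalProperties-class] (ground truth).
#' @param rho source-detector distance, cm.
#' @param irf an [IRFCurve-class]; the DTOF is generated on its axis.
#' @param noise a [noiseModel()].
#' @param wavelength metadata, nm.
#' @param poisson FALSE returns the noiseless expectation.
#' @return A [DTOFCurve-class].
#' @export
generateDTOF <- function(props, rho, irf, noise = noiseModel(),
                         wavelength = 820, poisson = TRUE) {
  stopifnot(is(props, "OpticalProperties"), is(irf, "IRFCurve"))
  axis <- irf@axis
  m <- trReflectance(rho, timeCenters(axis), props)
  conv <- convolveIRF(m, irf, axis)
  total <- sum(conv)
  expected <- if (total > 0)
    conv * (noise$totalCountRate * noise$acqTime / total)
  else conv
  expected <- expected + noise$backgroundRate * noise$acqTime
  cts <- if (poisson) stats::rpois(length(expected), expected) else expected
  dtofCurve(axis, cts, rho = rho, wavelength = wavelength,
            acqTime = noise$acqTime)
}

#' Default generator time axis
#'
#' 10 ps channels from -1 to 9 ns: the negative lead-in captures the IRF
#' rise, the 10 ns span covers the latest usable gates.
#'
#' @return A [TimeAxis-class].
#' @export
defaultGeneratorAxis <- function() timeAxis(-1, 0.01, 1000L)

#' Generate a broadband spectral series with ground truth
#'
#' Emulates a broadband acquisition (default 600-1100 nm in 10 nm steps,
#' 4 s per wavelength): `mua(lambda)` synthesized from a tissue
#' composition and the chromophore basis, `musp(lambda)` from the
#' power law, one synthetic DTOF per wavelength.
#'
#' @param composition a [TissueComposition-class] (ground truth).
#' @param powerLaw a [PowerLawFit-class] (ground truth).
#' @param basis a [ChromophoreBasis-class].
#' @param wavelengths nm grid (default `seq(600, 1100, 10)`).
#' @param rho cm (default 3, the broadband probing distance).
#' @param irf an [IRFCurve-class].
#' @param noise a [noiseModel()] (default 1 Mcounts/s x 4 s).
#' @param nIn,nOut refractive indices.
#' @param seed integer seed for the per-wavelength Poisson sampling.
#' @param poisson FALSE for noiseless curves.
#' @return A list: `dtofs` (list of [DTOFCurve-class]), `truth` (a
#'   [SpectralDataset-class] of the generating mua/musp), `composition`,
#'   `powerLaw`.
#' @export
generateSpectralSeries <- function(composition, powerLaw,
                                   basis = loadChromophoreBasis(),
                                   wavelengths = seq(600, 1100, 10),
                                   rho = 3, irf = NULL,
                                   noise = noiseModel(1e6, 4),
                                   nIn = 1.4, nOut = 1.0,
                                   seed = 1L, poisson = TRUE) {
  stopifnot(is(composition, "TissueComposition"), is(powerLaw, "PowerLawFit"))
  if (is.null(irf)) irf <- generateIRF(defaultGeneratorAxis(), seed = seed)
  B <- chromophoreBasis(basis@wavelengths, basis@spectra,
                        wavelengths = wavelengths)
  mua <- as.numeric(B@spectra %*% compositionVector(composition))
  musp <- evalPowerLaw(powerLaw, wavelengths)
  truth <- spectralDataset(wavelengths, mua, musp)
  set.seed(as.integer(seed))
  dtofs <- lapply(seq_along(wavelengths), function(i) {
    props <- opticalProperties(mua[i], musp[i], nIn, nOut)
    generateDTOF(props, rho, irf, noise, wavelength = wavelengths[i],
                 poisson = poisson)
  })
  list(dtofs = dtofs, truth = truth, irf = irf,
       composition = composition, powerLaw = powerLaw)
}

#' Recover optical-property spectra from a DTOF series
#'
#' Convenience inverse of [generateSpectralSeries()]: fits every DTOF
#' with [fitHomogeneous()] and assembles the fitted spectra.
#'
#' @param dtofs list of [DTOFCurve-class].
#' @param irf the shared [IRFCurve-class].
#' @param init optional starting guess for the first wavelength; later
#'   wavelengths warm-start from the previous fit.
#' @param ... passed to [fitHomogeneous()].
#' @return A [SpectralDataset-class] of fitted values.
#' @export
fitSpectralSeries <- function(dtofs, irf, init = NULL, ...) {
  wl <- vapply(dtofs, function(d) d@wavelength, numeric(1))
  mua <- musp <- rep(NA_real_, length(dtofs))
  prev <- init
  for (i in seq_along(dtofs)) {
    fit <- fitHomogeneous(dtofs[[i]], irf, init = prev, ...)
    mua[i] <- fit@mua
    musp[i] <- fit@musp
    if (fit@converged) prev <- c(mua = fit@mua, musp = fit@musp)
  }
  spectralDataset(wl, mua, musp)
}

#' Synthetic breathing-protocol scenario
#'
#' The study conditions for the protocol generator: a two-layer
#' chest + lung medium whose lung absorption (and optionally scattering)
#' is modulated by the breathing phase. The defaults mirror the
#' simulation scenario used throughout: chest wall musp 7 1/cm over a
#' lung at musp 12 1/cm, baseline mua 0.15 1/cm in both layers, a 10%
#' reduction of lung absorption during inhalation, lung roof at 3 cm,
#' rho = 6 cm.
#'
#' @param medium baseline [LayeredMedium-class] (last layer = lung).
#' @param protocol a [BreathingProtocol-class].
#' @param muaFactorIN,muaFactorOUT multiplicative factors on the lung
#'   baseline mua during IN/OUT phases (defaults 0.9 / 1).
#' @param muspFactorIN,muspFactorOUT same for lung musp (defaults 1 / 1;
#'   non-unit values trigger one extra transport run per distinct state).
#' @param rho source-detector distance, cm.
#' @param irfWidth IRF FWHM, ps.
#' @return A list with class "SyntheticScenario".
#' @export
syntheticScenario <- function(medium = layeredMedium(c(3, Inf),
                                                     mua = c(0.15, 0.15),
                                                     musp = c(7, 12)),
                              protocol = breathingProtocol("prot10"),
                              muaFactorIN = 0.9, muaFactorOUT = 1,
                              muspFactorIN = 1, muspFactorOUT = 1,
                              rho = 6, irfWidth = 150) {
  stopifnot(is(medium, "LayeredMedium"), is(protocol, "BreathingProtocol"),
            muaFactorIN > 0, muaFactorOUT > 0,
            muspFactorIN > 0, muspFactorOUT > 0)
  structure(list(medium = medium, protocol = protocol,
                 muaFactorIN = muaFactorIN, muaFactorOUT = muaFactorOUT,
                 muspFactorIN = muspFactorIN, muspFactorOUT = muspFactorOUT,
                 rho = rho, irfWidth = irfWidth),
            class = "SyntheticScenario")
}

#' Generate a synthetic breathing-protocol series
#'
#' One absorption-free Monte Carlo transport run per distinct scattering
#' state (reused across acquisitions); per-acquisition DTOFs are obtained
#' by Lambert-Beer reweighting with the phase's lung absorption,
#' convolution with a synthetic IRF, scaling to the noise model's count
#' rate and per-channel Poisson sampling. Phase labels follow the
#' protocol timing at the given cadence.
#'
#' @param scenario a [syntheticScenario()].
#' @param noise a [noiseModel()] (acqTime is the per-acquisition time;
#'   cadence below must satisfy `acqTime <= 1/cadence`).
#' @param nDetected detected photons for the transport run(s)
#'   (default 2e4).
#' @param cadence acquisitions per second (default 1).
#' @param seed integer seed (transport + Poisson).
#' @param mcKwargs extra arguments passed to [runMC()].
#' @return A list: `series` (a [ProtocolSeries-class]), `irf`, `truth`
#'   (data.frame of per-acquisition lung mua/musp), `mc` (the transport
#'   result(s)).
#' @export
generateProtocolSeries <- function(scenario = syntheticScenario(),
                                   noise = noiseModel(), nDetected = 2e4,
                                   cadence = 1, seed = 1L,
                                   mcKwargs = list()) {
  stopifnot(inherits(scenario, "SyntheticScenario"))
  med <- scenario$medium
  L <- nLayers(med)
  prot <- scenario$protocol
  cycle <- 2 * prot@phaseDuration
  prefix <- if (prot@referencePrefix) cycle else 0
  totalTime <- prefix + cycle * prot@nRepetitions
  # Prot10: 5 cycles x 20 s at 1/s -> 100; Prot5: one 10 s reference cycle
  # + 10 cycles x 10 s -> 110
  nAcq <- as.integer(round(totalTime * cadence))
  timestamps <- (seq_len(nAcq) - 1L) / cadence
  labels <- protocolLabels(prot, timestamps, cadence)

  geometry <- detectionGeometry(scenario$rho)
  axis <- defaultGeneratorAxis()
  irf <- generateIRF(axis, fwhm = scenario$irfWidth, seed = seed)

  muspStates <- unique(c(scenario$muspFactorIN, scenario$muspFactorOUT, 1))
  mcRuns <- list()
  for (f in muspStates) {
    m <- med
    m@musp[L] <- med@musp[L] * f
    mcRuns[[as.character(f)]] <- do.call(runMC, c(
      list(medium = m, geometry = geometry,
           nDetectedTarget = as.integer(nDetected), seed = seed),
      mcKwargs))
  }
  if (any(vapply(mcRuns, function(r) r@budgetExhausted, logical(1))))
    warning("Monte Carlo launch budget exhausted for at least one state")

  histAxis <- timeAxis(0, 0.01, 1000L)
  set.seed(as.integer(seed) + 1L)
  muaLung <- muspLung <- numeric(nAcq)
  acqs <- vector("list", nAcq)
  for (i in seq_len(nAcq)) {
    fa <- switch(labels[i], IN = scenario$muaFactorIN,
                 OUT = scenario$muaFactorOUT, REF = 1)
    fs <- switch(labels[i], IN = scenario$muspFactorIN,
                 OUT = scenario$muspFactorOUT, REF = 1)
    muaVec <- med@mua
    muaVec[L] <- med@mua[L] * fa
    muaLung[i] <- muaVec[L]
    muspLung[i] <- med@musp[L] * fs
    run <- mcRuns[[as.character(fs)]]
    hist <- applyAbsorption(run, muaVec, axis = histAxis, rho = scenario$rho)
    conv <- convolveIRF(hist@counts, irf, histAxis)
    total <- sum(conv)
    expected <- if (total > 0)
      conv * (noise$totalCountRate * noise$acqTime / total) else conv
    expected <- expected + noise$backgroundRate * noise$acqTime
    cts <- stats::rpois(length(expected), expected)
    acqs[[i]] <- dtofCurve(histAxis, cts, rho = scenario$rho,
                           acqTime = noise$acqTime)
  }
  series <- protocolSeries(acqs, timestamps, labels, prot)
  list(series = series, irf = irf,
       truth = data.frame(timestamp = timestamps, label = labels,
                          muaLung = muaLung, muspLung = muspLung),
       mc = mcRuns)
}
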