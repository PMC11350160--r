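#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib lungtdos, .registration = TRUE
NULL

# ---- TimeAxis ----------------------------------------------------------

#' TimeAxis: uniform TCSPC histogram binning
#'
#' A uniform time grid of `nChannels` channels of width `dt` starting at
#' `t0`. Channel i covers `[t0 + (i-1) dt, t0 + i dt)` and its centre is
#' `t0 + (i - 1/2) dt`. All times are in nanoseconds.
#'
#' @slot t0 start time of the first channel, ns.
#' @slot dt channel width, ns.
#' @slot nChannels number of channels.
#' @export
setClass("TimeAxis",
  representation(t0 = "numeric", dt = "numeric", nChannels = "integer"),
  validity = function(object) {
    if (length(object@t0) != 1L || !is.finite(object@t0))
      return("t0 must be a single finite number")
    if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
      return("dt must be a single positive number")
    if (length(object@nChannels) != 1L || object@nChannels < 2L)
      return("nChannels must be >= 2")
    TRUE
  })

#' Construct a TimeAxis
#'
#' @param t0 start time, ns (default 0).
#' @param dt channel width, ns (default 0.01, i.e. 10 ps).
#' @param nChannels number of channels (default 1000: a 0-10 ns window at
#'   10 ps).
#' @return A [TimeAxis-class] object.
#' @examples
#' ax <- timeAxis()
#' head(timeCenters(ax))
#' @export
timeAxis <- function(t0 = 0, dt = 0.01, nChannels = 1000L) {
  new("TimeAxis", t0 = as.numeric(t0), dt = as.numeric(dt),
      nChannels = as.integer(nChannels))
}

#' Channel centres of a TimeAxis
#' @param axis a [TimeAxis-class].
#' @return Numeric vector of channel-centre times, ns.
#' @export
timeCenters <- function(axis) {
  stopifnot(is(axis, "TimeAxis"))
  axis@t0 + (seq_len(axis@nChannels) - 0.5) * axis@dt
}

#' @describeIn timeAxis channel width accessor (ns).
#' @param axis a [TimeAxis-class].
#' @export
channelWidth <- function(axis) {
  stopifnot(is(axis, "TimeAxis"))
  axis@dt
}

#' @describeIn timeAxis number of channels.
#' @export
nChannels <- function(axis) {
  stopifnot(is(axis, "TimeAxis"))
  axis@nChannels
}

setMethod("show", "TimeAxis", function(object) {
  cat(sprintf("TimeAxis: %d channels of %.4g ns from %.4g to %.4g ns\n",
              object@nChannels, object@dt, object@t0,
              object@t0 + object@nChannels * object@dt))
})

# ---- OpticalProperties -------------------------------------------------

#' OpticalProperties: absorption and reduced scattering of a medium
#'
#' @slot mua absorption coefficient, 1/cm.
#' @slot musp reduced scattering coefficient, 1/cm.
#' @slot nIn refractive index of the medium.
#' @slot nOut refractive index of the external medium.
#' @export
setClass("OpticalProperties",
  representation(mua = "numeric", musp = "numeric",
                 nIn = "numeric", nOut = "numeric"),
  validity = function(object) {
    if (object@mua < 0) return("mua must be >= 0")
    if (object@musp <= 0) return("musp must be > 0")
    if (object@nIn < 1) return("nIn must be >= 1")
    if (object@nOut < 1) return("nOut must be >= 1")
    TRUE
  })

#' Construct optical properties
#'
#' @param mua absorption coefficient, 1/cm.
#' @param musp reduced scattering coefficient, 1/cm.
#' @param nIn interior refractive index (default 1.4, standard soft tissue).
#' @param nOut exterior refractive index (default 1.0, air).
#' @return An [OpticalProperties-class] object.
#' @export
opticalProperties <- function(mua, musp, nIn = 1.4, nOut = 1.0) {
  new("OpticalProperties", mua = as.numeric(mua), musp = as.numeric(musp),
      nIn = as.numeric(nIn), nOut = as.numeric(nOut))
}

setMethod("show", "OpticalProperties", function(object) {
  cat(sprintf(
    "OpticalProperties: mua = %.4g 1/cm, musp = %.4g 1/cm, n = %.3g/%.3g\n",
    object@mua, object@musp, object@nIn, object@nOut))
})

# ---- DTOFCurve / IRFCurve ----------------------------------------------

#' DTOFCurve: a photon time-of-flight histogram
#'
#' The universal measurement record: per-channel photon counts on a
#' [TimeAxis-class], plus the acquisition metadata needed by the analyses
#' (source-detector distance, wavelength, acquisition time).
#'
#' @slot axis the [TimeAxis-class].
#' @slot counts per-channel photon counts (nonnegative).
#' @slot rho source-detector distance, cm.
#' @slot wavelength nm.
#' @slot acqTime acquisition duration, s.
#' @export
setClass("DTOFCurve",
  representation(axis = "TimeAxis", counts = "numeric", rho = "numeric",
                 wavelength = "numeric", acqTime = "numeric"),
  validity = function(object) {
    if (length(object@counts) != object@axis@nChannels)
      return("counts length must match the time axis")
    if (any(!is.finite(object@counts))) return("counts must be finite")
    if (any(object@counts < 0)) return("counts must be nonnegative")
    if (object@rho <= 0) return("rho must be > 0")
    if (object@acqTime <= 0) return("acqTime must be > 0")
    TRUE
  })

#' Construct a DTOF curve
#'
#' @param axis a [TimeAxis-class].
#' @param counts per-channel photon counts.
#' @param rho source-detector distance, cm.
#' @param wavelength nm (default 820, the deep-probing wavelength near the
#'   hemoglobin isosbestic point).
#' @param acqTime acquisition time, s.
#' @return A [DTOFCurve-class] object.
#' @export
dtofCurve <- function(axis, counts, rho, wavelength = 820, acqTime = 1) {
  new("DTOFCurve", axis = axis, counts = as.numeric(counts),
      rho = as.numeric(rho), wavelength = as.numeric(wavelength),
      acqTime = as.numeric(acqTime))
}

#' IRFCurve: instrument response function histogram
#'
#' @slot axis the [TimeAxis-class].
#' @slot counts per-channel counts; total must be positive.
#' @export
setClass("IRFCurve",
  representation(axis = "TimeAxis", counts = "numeric"),
  validity = function(object) {
    if (length(object@counts) != object@axis@nChannels)
      return("counts length must match the time axis")
    if (any(!is.finite(object@counts)) || any(object@counts < 0))
      return("counts must be finite and nonnegative")
    if (sum(object@counts) <= 0) return("total IRF counts must be > 0")
    TRUE
  })

#' Construct an IRF curve
#' @param axis a [TimeAxis-class].
#' @param counts per-channel counts.
#' @return An [IRFCurve-class] object.
#' @export
irfCurve <- function(axis, counts) {
  new("IRFCurve", axis = axis, counts = as.numeric(counts))
}

#' Counts accessor
#' @param x a [DTOFCurve-class] or [IRFCurve-class].
#' @return Numeric vector of per-channel counts.
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname counts
#' @export
setMethod("counts", "DTOFCurve", function(x) x@counts)

#' @rdname counts
#' @export
setMethod("counts", "IRFCurve", function(x) x@counts)

#' Time axis accessor
#' @param x an object carrying a [TimeAxis-class].
#' @return The [TimeAxis-class].
#' @export
setGeneric("curveAxis", function(x) standardGeneric("curveAxis"))

#' @rdname curveAxis
#' @export
setMethod("curveAxis", "DTOFCurve", function(x) x@axis)

#' @rdname curveAxis
#' @export
setMethod("curveAxis", "IRFCurve", function(x) x@axis)

setMethod("show", "DTOFCurve", function(object) {
  cat(sprintf(
    "DTOFCurve: %d channels, %.3g total counts, rho = %.3g cm, %g nm, %.3g s\n",
    object@axis@nChannels, sum(object@counts), object@rho,
    object@wavelength, object@acqTime))
})

setMethod("show", "IRFCurve", function(object) {
  pk <- which.max(object@counts)
  cat(sprintf("IRFCurve: %d channels, %.3g total counts, peak at %.3g ns\n",
              object@axis@nChannels, sum(object@counts),
              timeCenters(object@axis)[pk]))
})

# ---- LayeredMedium -----------------------------------------------------

#' LayeredMedium: ordered slabs over a semi-infinite base
#'
#' Layer 1 is at the surface; the last layer is semi-infinite (its
#' thickness is stored as `Inf`). All layers share the interior
#' refractive index, so light refracts only at the top surface.
#'
#' @slot thickness per-layer thickness, cm; last entry `Inf`.
#' @slot mua per-layer absorption, 1/cm.
#' @slot musp per-layer reduced scattering, 1/cm.
#' @slot nIn shared interior refractive index.
#' @slot nOut exterior refractive index.
#' @export
setClass("LayeredMedium",
  representation(thickness = "numeric", mua = "numeric", musp = "numeric",
                 nIn = "numeric", nOut = "numeric"),
  validity = function(object) {
    L <- length(object@thickness)
    if (L < 1L) return("at least one layer required")
    if (length(object@mua) != L || length(object@musp) != L)
      return("mua, musp and thickness must have equal length")
    if (!is.infinite(object@thickness[L]))
      return("last layer must be semi-infinite (thickness Inf)")
    if (L > 1L && any(object@thickness[-L] <= 0))
      return("finite layer thicknesses must be > 0")
    if (any(object@mua < 0)) return("mua must be >= 0")
    if (any(object@musp <= 0)) return("musp must be > 0")
    if (object@nIn < 1 || object@nOut < 1) return("refractive indices must be >= 1")
    TRUE
  })

#' Construct a layered medium
#'
#' @param thickness per-layer thicknesses, cm; the last entry may be `Inf`
#'   (it is forced to `Inf` regardless: the base layer is semi-infinite).
#' @param mua per-layer absorption coefficients, 1/cm.
#' @param musp per-layer reduced scattering coefficients, 1/cm.
#' @param nIn interior refractive index (default 1.4).
#' @param nOut exterior refractive index (default 1.0).
#' @return A [LayeredMedium-class].
#' @examples
#' # chest wall over lung, lung roof at 3 cm
#' m <- layeredMedium(c(3, Inf), mua = c(0.15, 0.15), musp = c(7, 12))
#' @export
layeredMedium <- function(thickness, mua, musp, nIn = 1.4, nOut = 1.0) {
  thickness <- as.numeric(thickness)
  thickness[length(thickness)] <- Inf
  new("LayeredMedium", thickness = thickness, mua = as.numeric(mua),
      musp = as.numeric(musp), nIn = as.numeric(nIn), nOut = as.numeric(nOut))
}

#' @describeIn layeredMedium number of layers.
#' @param medium a [LayeredMedium-class].
#' @export
nLayers <- function(medium) {
  stopifnot(is(medium, "LayeredMedium"))
  length(medium@thickness)
}

setMethod("show", "LayeredMedium", function(object) {
  cat(sprintf("LayeredMedium: %d layer(s), n = %.3g/%.3g\n",
              length(object@thickness), object@nIn, object@nOut))
  for (j in seq_along(object@thickness)) {
    cat(sprintf("  layer %d: thickness %s cm, mua %.3g, musp %.3g 1/cm\n",
                j, format(object@thickness[j]), object@mua[j], object@musp[j]))
  }
})

# ---- DetectionGeometry -------------------------------------------------

#' DetectionGeometry: how exiting photons are detected
#'
#' Photons leaving the surface at a radius within `rho +/- ringHalfWidth`
#' are recorded; with `acceptAllExits` every exiting photon is kept
#' (depth-statistics mode, where the mean maximum depth is independent of
#' the detection radius).
#'
#' @slot rho nominal source-detector distance, cm.
#' @slot ringHalfWidth half-width of the detection annulus, cm.
#' @slot tMaxRecord trajectories abandoned beyond this time, ns.
#' @slot acceptAllExits logical flag.
#' @export
setClass("DetectionGeometry",
  representation(rho = "numeric", ringHalfWidth = "numeric",
                 tMaxRecord = "numeric", acceptAllExits = "logical"),
  validity = function(object) {
    if (object@rho < 0) return("rho must be >= 0")
    if (object@ringHalfWidth <= 0) return("ringHalfWidth must be > 0")
    if (object@tMaxRecord <= 0) return("tMaxRecord must be > 0")
    TRUE
  })

#' Construct a detection geometry
#'
#' @param rho nominal source-detector distance, cm.
#' @param ringHalfWidth detection annulus half-width, cm (default 0.25).
#' @param tMaxRecord maximum recorded time, ns (default 10).
#' @param acceptAllExits detect every exiting photon (default FALSE).
#' @return A [DetectionGeometry-class].
#' @export
detectionGeometry <- function(rho, ringHalfWidth = 0.25, tMaxRecord = 10,
                              acceptAllExits = FALSE) {
  new("DetectionGeometry", rho = as.numeric(rho),
      ringHalfWidth = as.numeric(ringHalfWidth),
      tMaxRecord = as.numeric(tMaxRecord),
      acceptAllExits = as.logical(acceptAllExits))
}

# ---- MCResult ----------------------------------------------------------

#' MCResult: detected Monte Carlo trajectories
#'
#' One row per detected photon: per-layer geometric path lengths,
#' exit time, exit radius and maximum visited depth. Transport is run
#' without absorption (microscopic Lambert-Beer), so any absorption can be
#' applied afterwards by reweighting with [applyAbsorption()].
#'
#' @slot pathlen numeric matrix, detected photons x layers, cm.
#' @slot exitTime ns.
#' @slot exitRadius cm.
#' @slot maxDepth cm.
#' @slot nLaunched photons launched.
#' @slot seed RNG seed used.
#' @slot medium the [LayeredMedium-class] simulated (absorption ignored).
#' @slot geometry the [DetectionGeometry-class].
#' @slot budgetExhausted TRUE when the launch budget ran out before the
#'   target count was reached.
#' @export
setClass("MCResult",
  representation(pathlen = "matrix", exitTime = "numeric",
                 exitRadius = "numeric", maxDepth = "numeric",
                 nLaunched = "numeric", seed = "integer",
                 medium = "LayeredMedium", geometry = "DetectionGeometry",
                 budgetExhausted = "logical"),
  validity = function(object) {
    n <- nrow(object@pathlen)
    if (length(object@exitTime) != n || length(object@exitRadius) != n ||
        length(object@maxDepth) != n)
      return("per-photon vectors must match pathlen rows")
    if (n > 0 && (any(object@pathlen < 0) || any(object@maxDepth < 0)))
      return("path lengths and depths must be >= 0")
    TRUE
  })

#' @describeIn runMC number of detected photons in a result.
#' @export
nDetected <- function(result) {
  stopifnot(is(result, "MCResult"))
  nrow(result@pathlen)
}

setMethod("show", "MCResult", function(object) {
  cat(sprintf(
    "MCResult: %d detected / %.3g launched photons, %d layer(s), seed %d%s\n",
    nrow(object@pathlen), object@nLaunched, ncol(object@pathlen),
    object@seed,
    if (object@budgetExhausted) " [launch budget exhausted]" else ""))
})

# ---- FitResult ---------------------------------------------------------

#' FitResult: outcome of a homogeneous-model DTOF fit
#'
#' @slot mua fitted absorption, 1/cm.
#' @slot musp fitted reduced scattering, 1/cm.
#' @slot amplitude multiplicative scale of the convolved model.
#' @slot timeShift fitted time offset, ns.
#' @slot chi2Reduced reduced Pearson chi-square over the fit range.
#' @slot fitRange integer vector `c(iStart, iEnd)` (inclusive channels).
#' @slot converged logical.
#' @export
setClass("FitResult",
  representation(mua = "numeric", musp = "numeric", amplitude = "numeric",
                 timeShift = "numeric", chi2Reduced = "numeric",
                 fitRange = "integer", converged = "logical"),
  validity = function(object) {
    if (object@mua < 0 || object@musp <= 0)
      return("mua must be >= 0 and musp > 0")
    if (object@chi2Reduced < 0) return("chi2Reduced must be >= 0")
    TRUE
  })

setMethod("show", "FitResult", function(object) {
  cat(sprintf(
    "FitResult: mua = %.4g 1/cm, musp = %.4g 1/cm, shift = %.3g ps, chi2r = %.3g%s\n",
    object@mua, object@musp, 1000 * object@timeShift, object@chi2Reduced,
    if (object@converged) "" else " [not converged]"))
})

# ---- Spectral types ----------------------------------------------------

#' SpectralDataset: per-wavelength optical properties
#'
#' @slot wavelengths nm, strictly increasing.
#' @slot mua 1/cm per wavelength.
#' @slot musp 1/cm per wavelength.
#' @export
setClass("SpectralDataset",
  representation(wavelengths = "numeric", mua = "numeric", musp = "numeric"),
  validity = function(object) {
    n <- length(object@wavelengths)
    if (length(object@mua) != n || length(object@musp) != n)
      return("wavelengths, mua and musp must have equal length")
    if (n >= 2 && any(diff(object@wavelengths) <= 0))
      return("wavelengths must be strictly increasing")
    TRUE
  })

#' Construct a spectral dataset
#' @param wavelengths nm, strictly increasing.
#' @param mua absorption spectrum, 1/cm.
#' @param musp reduced scattering spectrum, 1/cm.
#' @return A [SpectralDataset-class].
#' @export
spectralDataset <- function(wavelengths, mua, musp) {
  new("SpectralDataset", wavelengths = as.numeric(wavelengths),
      mua = as.numeric(mua), musp = as.numeric(musp))
}

setMethod("show", "SpectralDataset", function(object) {
  cat(sprintf("SpectralDataset: %d wavelengths, %g-%g nm\n",
              length(object@wavelengths), min(object@wavelengths),
              max(object@wavelengths)))
})

#' ChromophoreBasis: specific absorption spectra of the 5 tissue absorbers
#'
#' Columns: deoxy-hemoglobin (Hb, per uM), oxy-hemoglobin (HbO2, per uM),
#' water, lipid and collagen (per g/cm^3), each in 1/cm per unit
#' concentration on a shared wavelength grid.
#'
#' @slot wavelengths nm.
#' @slot spectra numeric matrix, wavelengths x 5 named columns.
#' @export
setClass("ChromophoreBasis",
  representation(wavelengths = "numeric", spectra = "matrix"),
  validity = function(object) {
    if (nrow(object@spectra) != length(object@wavelengths))
      return("spectra rows must match wavelengths")
    need <- c("Hb", "HbO2", "water", "lipid", "collagen")
    if (!identical(colnames(object@spectra), need))
      return("spectra columns must be Hb, HbO2, water, lipid, collagen")
    if (any(object@spectra < 0)) return("specific absorptions must be >= 0")
    TRUE
  })

#' TissueComposition: concentrations of the 5 absorbers
#'
#' @slot Hb uM.
#' @slot HbO2 uM.
#' @slot water g/cm^3.
#' @slot lipid g/cm^3.
#' @slot collagen g/cm^3.
#' @slot residualNorm residual of the non-negative spectral fit (1/cm, L2).
#' @export
setClass("TissueComposition",
  representation(Hb = "numeric", HbO2 = "numeric", water = "numeric",
                 lipid = "numeric", collagen = "numeric",
                 residualNorm = "numeric"),
  validity = function(object) {
    vals <- c(object@Hb, object@HbO2, object@water, object@lipid,
              object@collagen)
    if (any(vals < 0)) return("concentrations must be >= 0")
    TRUE
  })

#' Construct a tissue composition
#' @param Hb deoxy-hemoglobin, uM.
#' @param HbO2 oxy-hemoglobin, uM.
#' @param water g/cm^3.
#' @param lipid g/cm^3.
#' @param collagen g/cm^3.
#' @param residualNorm optional fit residual, 1/cm.
#' @return A [TissueComposition-class].
#' @export
tissueComposition <- function(Hb, HbO2, water, lipid, collagen,
                              residualNorm = 0) {
  new("TissueComposition", Hb = as.numeric(Hb), HbO2 = as.numeric(HbO2),
      water = as.numeric(water), lipid = as.numeric(lipid),
      collagen = as.numeric(collagen), residualNorm = as.numeric(residualNorm))
}

#' Composition as a named vector
#' @param x a [TissueComposition-class].
#' @return Named numeric vector (Hb, HbO2, water, lipid, collagen).
#' @export
compositionVector <- function(x) {
  stopifnot(is(x, "TissueComposition"))
  c(Hb = x@Hb, HbO2 = x@HbO2, water = x@water, lipid = x@lipid,
    collagen = x@collagen)
}

setMethod("show", "TissueComposition", function(object) {
  cat(sprintf(
    "TissueComposition: Hb %.3g uM, HbO2 %.3g uM, water %.3g, lipid %.3g, collagen %.3g g/cm^3\n",
    object@Hb, object@HbO2, object@water, object@lipid, object@collagen))
})

#' PowerLawFit: empirical scattering spectrum parameters
#'
#' `musp(lambda) = a (lambda/600 nm)^(-b)`: the amplitude `a` tracks the
#' density of scattering centres, the power `b` their size.
#'
#' @slot a scattering amplitude at 600 nm, 1/cm.
#' @slot b scattering power, dimensionless.
#' @slot lambda0 reference wavelength, fixed at 600 nm.
#' @export
setClass("PowerLawFit",
  representation(a = "numeric", b = "numeric", lambda0 = "numeric"),
  validity = function(object) {
    if (object@a <= 0) return("a must be > 0")
    if (object@lambda0 != 600) return("lambda0 is fixed at 600 nm")
    TRUE
  })

#' Construct power-law scattering parameters
#' @param a amplitude at 600 nm, 1/cm.
#' @param b scattering power.
#' @return A [PowerLawFit-class].
#' @export
powerLawFit <- function(a, b) {
  new("PowerLawFit", a = as.numeric(a), b = as.numeric(b), lambda0 = 600)
}

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf("PowerLawFit: musp(lambda) = %.4g (lambda/600)^-%.4g 1/cm\n",
              object@a, object@b))
})

# ---- Protocol types ----------------------------------------------------

#' BreathingProtocol: paced breath-hold timing
#'
#' Each repetition is an IN (suspended full inspiration) phase followed by
#' an OUT (suspended full expiration) phase of equal duration. Prot10 is 5
#' repetitions of 10 s phases; Prot5 is 10 repetitions of 5 s phases with a
#' leading normal-breathing repetition serving as reference.
#'
#' @slot phaseDuration s.
#' @slot nRepetitions count.
#' @slot referencePrefix logical; TRUE when a leading normal-breathing
#'   repetition precedes the paced cycles.
#' @export
setClass("BreathingProtocol",
  representation(phaseDuration = "numeric", nRepetitions = "integer",
                 referencePrefix = "logical"),
  validity = function(object) {
    if (object@phaseDuration <= 0) return("phaseDuration must be > 0")
    if (object@nRepetitions < 1L) return("nRepetitions must be >= 1")
    TRUE
  })

#' Construct a breathing protocol
#'
#' @param name "prot10" (5 x 10 s phases), "prot5" (10 x 5 s phases with a
#'   normal-breathing reference prefix), or "custom".
#' @param phaseDuration s, for custom protocols.
#' @param nRepetitions for custom protocols.
#' @param referencePrefix for custom protocols.
#' @return A [BreathingProtocol-class].
#' @export
breathingProtocol <- function(name = c("prot10", "prot5", "custom"),
                              phaseDuration = NULL, nRepetitions = NULL,
                              referencePrefix = NULL) {
  name <- match.arg(name)
  if (name == "prot10") {
    phaseDuration <- 10; nRepetitions <- 5L; referencePrefix <- FALSE
  } else if (name == "prot5") {
    phaseDuration <- 5; nRepetitions <- 10L; referencePrefix <- TRUE
  } else {
    stopifnot(!is.null(phaseDuration), !is.null(nRepetitions),
              !is.null(referencePrefix))
  }
  new("BreathingProtocol", phaseDuration = as.numeric(phaseDuration),
      nRepetitions = as.integer(nRepetitions),
      referencePrefix = as.logical(referencePrefix))
}

setMethod("show", "BreathingProtocol", function(object) {
  cat(sprintf(
    "BreathingProtocol: %d repetitions of IN/OUT, %g s per phase%s\n",
    object@nRepetitions, object@phaseDuration,
    if (object@referencePrefix) ", with normal-breathing reference prefix"
    else ""))
})

#' ProtocolSeries: a laboratory-time sequence of DTOFs
#'
#' @slot acquisitions list of [DTOFCurve-class], time-ordered.
#' @slot timestamps laboratory time of each acquisition start, s.
#' @slot labels per-acquisition phase labels: "IN", "OUT" or "REF".
#' @slot protocol the [BreathingProtocol-class].
#' @export
setClass("ProtocolSeries",
  representation(acquisitions = "list", timestamps = "numeric",
                 labels = "character", protocol = "BreathingProtocol"),
  validity = function(object) {
    n <- length(object@acquisitions)
    if (length(object@timestamps) != n || length(object@labels) != n)
      return("timestamps and labels must match acquisitions")
    if (n >= 2 && any(diff(object@timestamps) <= 0))
      return("timestamps must be strictly increasing")
    if (n > 0 && !all(object@labels %in% c("IN", "OUT", "REF")))
      return("labels must be IN, OUT or REF")
    if (n > 0 && !all(vapply(object@acquisitions, is, logical(1), "DTOFCurve")))
      return("acquisitions must be DTOFCurve objects")
    TRUE
  })

#' Construct a protocol series
#' @param acquisitions list of [DTOFCurve-class].
#' @param timestamps laboratory times, s.
#' @param labels "IN"/"OUT"/"REF" per acquisition.
#' @param protocol a [BreathingProtocol-class].
#' @return A [ProtocolSeries-class].
#' @export
protocolSeries <- function(acquisitions, timestamps, labels, protocol) {
  new("ProtocolSeries", acquisitions = acquisitions,
      timestamps = as.numeric(timestamps), labels = as.character(labels),
      protocol = protocol)
}

setMethod("show", "ProtocolSeries", function(object) {
  cat(sprintf("ProtocolSeries: %d acquisitions (%s)\n",
              length(object@acquisitions),
              paste(sprintf("%s:%d", names(table(object@labels)),
                            as.integer(table(object@labels))),
                    collapse = ", ")))
})

#' ContrastSeries: per-acquisition, per-gate relative contrast
#'
#' @slot contrast numeric matrix, acquisitions x gates; NA where a gate is
#'   undefined (zero reference integral).
#' @slot gateStart ns per gate.
#' @slot gateWidth ns per gate.
#' @slot timestamps s, per acquisition.
#' @slot labels per acquisition.
#' @slot reference description of the reference state.
#' @export
setClass("ContrastSeries",
  representation(contrast = "matrix", gateStart = "numeric",
                 gateWidth = "numeric", timestamps = "numeric",
                 labels = "character", reference = "character"),
  validity = function(object) {
    if (ncol(object@contrast) != length(object@gateStart) ||
        length(object@gateStart) != length(object@gateWidth))
      return("gate metadata must match contrast columns")
    if (nrow(object@contrast) != length(object@timestamps) ||
        length(object@timestamps) != length(object@labels))
      return("per-acquisition metadata must match contrast rows")
    TRUE
  })

setMethod("show", "ContrastSeries", function(object) {
  cat(sprintf("ContrastSeries: %d acquisitions x %d gates (reference: %s)\n",
              nrow(object@contrast), ncol(object@contrast), object@reference))
})
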