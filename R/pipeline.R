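#' Default pipeline configuration
#'
#' All tunables of the end-to-end synthetic workflows in one validated
#' list: physical constants, fit bounds, gate family, protocol choice,
#' photon budgets and seeds. Every value is serialized into the result
#' bundle for provenance.
#'
#' @param ... named overrides of the defaults.
#' @return A named list with class "RunConfig".
#' @export
runConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    nIn = 1.4, nOut = 1.0,
    # spectroscopy stage
    wavelengths = seq(700, 1060, 60),
    composition = list(Hb = 3.0, HbO2 = 15.5, water = 0.29, lipid = 0.63,
                       collagen = 0.11),
    scatterA = 9.0, scatterB = 0.78,
    rhoSpectral = 3, spectralCountRate = 1e6, spectralAcqTime = 4,
    # protocol stage
    protocol = "prot10", rhoProtocol = 6,
    lungDepth = 3, chestMusp = 7, lungMusp = 12, baselineMua = 0.15,
    muaFactorIN = 0.9,
    gates = defaultGates(),
    nDetectedProtocol = 2e4, countRate = 1e6, cadence = 1,
    # depth statistics stage
    zmaxMusp = 9.12, zmaxTime = 3.2, nDetectedZmax = 2e4,
    irfWidth = 150
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validateConfig(structure(cfg, class = "RunConfig"))
}

validateConfig <- function(cfg) {
  stopifnot(cfg$nIn >= 1, cfg$nOut >= 1,
            all(cfg$wavelengths > 0), cfg$scatterA > 0,
            cfg$rhoSpectral > 0, cfg$rhoProtocol > 0,
            cfg$lungDepth > 0, cfg$chestMusp > 0, cfg$lungMusp > 0,
            cfg$baselineMua >= 0, cfg$muaFactorIN > 0,
            cfg$nDetectedProtocol >= 1, cfg$nDetectedZmax >= 1,
            cfg$zmaxMusp > 0, cfg$zmaxTime > 0,
            cfg$protocol %in% c("prot10", "prot5"))
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file holds named overrides of the [runConfig()] defaults; unknown
#' fields are rejected. YAML files require the `yaml` package.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return A validated "RunConfig" list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be .yaml, .yml or .json")
  if (!is.null(vals$gates)) vals$gates <- gatesAsMatrix(vals$gates)
  do.call(runConfig, vals)
}

#' Run the end-to-end synthetic analysis pipeline
#'
#' Executes the three workflows on synthetic data per the configuration:
#' (1) broadband spectroscopy — generate per-wavelength DTOFs, fit
#' (mua, musp) at each wavelength, decompose into chromophores and fit
#' the scattering power law; (2) breathing protocol — generate a
#' two-layer protocol series by Monte Carlo reweighting, compute gated
#' contrasts and the IN/OUT plateau summary; (3) depth statistics —
#' mean maximum penetration depth at the configured arrival time, plus
#' the latest usable gate (t_max) of the synthetic protocol DTOFs.
#'
#' @param config a [runConfig()].
#' @param outFile optional path: the summary is written there as JSON.
#' @return A list bundle: `config`, `spectroscopy` (fitted spectra,
#'   composition, power law), `protocol` (contrast series, plateau
#'   summary, t_max), `depth` (mean max depth), `seeds`.
#' @export
runPipeline <- function(config = runConfig(), outFile = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  cfg <- validateConfig(config)
  seed <- as.integer(cfg$seed)

  # --- broadband spectroscopy -------------------------------------
  comp <- do.call(tissueComposition, cfg$composition)
  pl <- powerLawFit(cfg$scatterA, cfg$scatterB)
  basis <- loadChromophoreBasis()
  spec <- generateSpectralSeries(comp, pl, basis,
                                 wavelengths = cfg$wavelengths,
                                 rho = cfg$rhoSpectral,
                                 noise = noiseModel(cfg$spectralCountRate,
                                                    cfg$spectralAcqTime),
                                 nIn = cfg$nIn, nOut = cfg$nOut, seed = seed)
  fitted <- fitSpectralSeries(spec$dtofs, spec$irf,
                              nIn = cfg$nIn, nOut = cfg$nOut)
  compFit <- fitComposition(fitted, basis)
  plFit <- fitPowerLaw(fitted)

  # --- breathing protocol -----------------------------------------
  med <- layeredMedium(c(cfg$lungDepth, Inf),
                       mua = c(cfg$baselineMua, cfg$baselineMua),
                       musp = c(cfg$chestMusp, cfg$lungMusp),
                       nIn = cfg$nIn, nOut = cfg$nOut)
  scen <- syntheticScenario(med, breathingProtocol(cfg$protocol),
                            muaFactorIN = cfg$muaFactorIN,
                            rho = cfg$rhoProtocol, irfWidth = cfg$irfWidth)
  gen <- generateProtocolSeries(scen, noiseModel(cfg$countRate),
                                nDetected = cfg$nDetectedProtocol,
                                cadence = cfg$cadence, seed = seed)
  contrast <- gatedContrast(gen$series, cfg$gates)
  plateau <- phasePlateauSummary(contrast, scen$protocol)
  tmax <- estimateTmax(gen$series@acquisitions[[1]])

  # --- depth statistics -------------------------------------------
  mz <- runMC(layeredMedium(Inf, 0, cfg$zmaxMusp, cfg$nIn, cfg$nOut),
              detectionGeometry(cfg$rhoProtocol, acceptAllExits = TRUE),
              cfg$nDetectedZmax, seed = seed)
  zAxis <- timeAxis(cfg$zmaxTime - 0.25, 0.5, 2L)
  zmax <- meanMaxDepthCurve(mz, zAxis, minRecords = 20L)

  bundle <- list(
    config = unclass(cfg),
    seeds = seed,
    spectroscopy = list(
      fitted = data.frame(wavelength_nm = fitted@wavelengths,
                          mua_cm = fitted@mua, musp_cm = fitted@musp),
      composition = as.list(compositionVector(compFit)),
      powerLaw = list(a = plFit@a, b = plFit@b),
      truthComposition = as.list(compositionVector(comp)),
      truthPowerLaw = list(a = pl@a, b = pl@b)),
    protocol = list(
      plateau = plateau,
      tmax_ns = tmax,
      gates = as.data.frame(cfg$gates)),
    depth = list(t_ns = cfg$zmaxTime, meanMaxDepth_cm = zmax$meanMaxDepth[1],
                 nRecords = zmax$nRecords[1]))
  if (!is.null(outFile))
    jsonlite::write_json(bundle, outFile, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", pretty = TRUE)
  bundle
}
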