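#' Load the bundled chromophore basis
#'
#' Specific absorption spectra of the five key tissue absorbers used in
#' broadband tissue spectroscopy: deoxy-hemoglobin (Hb) and
#' oxy-hemoglobin (HbO2) in 1/cm per uM, and water, lipid and collagen in
#' 1/cm per g/cm^3, tabulated from 600 to 1100 nm in 10 nm steps.
#'
#' The bundled table (`chromophore_basis_synthetic.csv`) is a *synthetic*
#' basis: smooth spectra anchored at literature-order values (hemoglobin
#' near-infrared extinctions, the 975 nm water and 930 nm lipid bands,
#' the broad rising collagen background), not a published compilation.
#' Composition results are basis-dependent; analyses in this package use
#' the same basis for generation and recovery, so they are
#' self-consistent.
#'
#' @param wavelengths optional grid (nm) onto which the basis is linearly
#'   interpolated; must lie within 600-1100 nm.
#' @return A [ChromophoreBasis-class].
#' @export
loadChromophoreBasis <- function(wavelengths = NULL) {
  path <- system.file("extdata", "chromophore_basis_synthetic.csv",
                      package = "lungtdos", mustWork = TRUE)
  tab <- utils::read.csv(path)
  chromophoreBasis(tab$wavelength_nm,
                   as.matrix(tab[c("Hb", "HbO2", "water", "lipid", "collagen")]),
                   wavelengths = wavelengths)
}

#' Construct a chromophore basis
#'
#' @param baseWavelengths nm grid of the supplied spectra.
#' @param spectra matrix (wavelengths x 5) with columns Hb, HbO2, water,
#'   lipid, collagen.
#' @param wavelengths optional target grid for linear interpolation.
#' @return A [ChromophoreBasis-class].
#' @export
chromophoreBasis <- function(baseWavelengths, spectra, wavelengths = NULL) {
  spectra <- as.matrix(spectra)
  colnames(spectra) <- c("Hb", "HbO2", "water", "lipid", "collagen")
  if (!is.null(wavelengths)) {
    wavelengths <- as.numeric(wavelengths)
    if (min(wavelengths) < min(baseWavelengths) - 1e-9 ||
        max(wavelengths) > max(baseWavelengths) + 1e-9)
      stop("requested wavelengths outside the basis range")
    spectra <- vapply(seq_len(ncol(spectra)), function(j)
      stats::approx(baseWavelengths, spectra[, j], xout = wavelengths)$y,
      numeric(length(wavelengths)))
    if (!is.matrix(spectra)) spectra <- matrix(spectra, nrow = 1L)
    colnames(spectra) <- c("Hb", "HbO2", "water", "lipid", "collagen")
    baseWavelengths <- wavelengths
  }
  new("ChromophoreBasis", wavelengths = as.numeric(baseWavelengths),
      spectra = spectra)
}

#' Absorption spectrum of a tissue composition
#'
#' Beer-Lambert synthesis: `mua(lambda) = sum_i c_i eps_i(lambda)`.
#'
#' @param composition a [TissueComposition-class].
#' @param basis a [ChromophoreBasis-class].
#' @return Numeric vector of mua (1/cm) on the basis grid.
#' @export
compositionToMua <- function(composition, basis) {
  stopifnot(is(composition, "TissueComposition"), is(basis, "ChromophoreBasis"))
  as.numeric(basis@spectra %*% compositionVector(composition))
}

#' Decompose an absorption spectrum into chromophore concentrations
#'
#' Non-negative least squares solution of
#' `mua(lambda) = sum_i c_i eps_i(lambda)` over the five absorbers
#' (Beer-Lambert decomposition). The basis is interpolated onto the
#' spectrum's grid.
#'
#' @param muaSpectrum a [SpectralDataset-class] (its `mua` slot is used)
#'   with at least 5 wavelengths.
#' @param basis a [ChromophoreBasis-class] covering the spectral range
#'   (default: the bundled basis).
#' @return A [TissueComposition-class]; its `residualNorm` slot holds the
#'   L2 norm of the fit residual (1/cm).
#' @export
fitComposition <- function(muaSpectrum, basis = loadChromophoreBasis()) {
  stopifnot(is(muaSpectrum, "SpectralDataset"), is(basis, "ChromophoreBasis"))
  wl <- muaSpectrum@wavelengths
  if (length(wl) < 5) stop("at least 5 wavelengths are required")
  B <- chromophoreBasis(basis@wavelengths, basis@spectra, wavelengths = wl)
  E <- B@spectra
  if (qr(E)$rank < ncol(E))
    stop("chromophore basis is rank-deficient on the provided wavelength grid")
  sol <- pracma::lsqnonneg(E, muaSpectrum@mua)
  x <- sol$x
  tissueComposition(x[1], x[2], x[3], x[4], x[5],
                    residualNorm = sqrt(sum(sol$resid.norm)))
}

#' Evaluate the power-law scattering spectrum
#'
#' `musp(lambda) = a (lambda / 600 nm)^(-b)`.
#'
#' @param fit a [PowerLawFit-class].
#' @param wavelength nm (> 0), vectorized.
#' @return musp in 1/cm.
#' @examples
#' evalPowerLaw(powerLawFit(11.1, 0.63), 820)  # ~ 9.12 1/cm
#' @export
evalPowerLaw <- function(fit, wavelength) {
  stopifnot(is(fit, "PowerLawFit"))
  wavelength <- as.numeric(wavelength)
  if (any(wavelength <= 0)) stop("wavelength must be > 0")
  fit@a * (wavelength / fit@lambda0)^(-fit@b)
}

#' Fit the empirical power law to a scattering spectrum
#'
#' Least squares in log-log space: linear regression of `ln musp` on
#' `ln(lambda/600)`; `a = exp(intercept)`, `b = -slope`. Exact on
#' noiseless power-law input.
#'
#' @param muspSpectrum a [SpectralDataset-class] (its `musp` slot is
#'   used) with at least 3 wavelengths, all positive.
#' @return A [PowerLawFit-class].
#' @export
fitPowerLaw <- function(muspSpectrum) {
  stopifnot(is(muspSpectrum, "SpectralDataset"))
  wl <- muspSpectrum@wavelengths
  mu <- muspSpectrum@musp
  if (length(wl) < 3) stop("at least 3 wavelengths are required")
  if (any(mu <= 0)) stop("musp values must be > 0")
  x <- log(wl / 600)
  co <- stats::coef(stats::lm(log(mu) ~ x))
  powerLawFit(exp(co[[1]]), -co[[2]])
}
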