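#' Write a DTOF (or IRF) curve to CSV + JSON sidecar
#'
#' The curve goes to a two-column CSV (`time_ns`, `counts`); the
#' acquisition metadata (`rho_cm`, `wavelength_nm`, `acq_time_s`,
#' `label`) to `<path>.json`. Integer counts round-trip exactly.
#'
#' @param curve a [DTOFCurve-class] or [IRFCurve-class].
#' @param path CSV file path; the sidecar is written at `<path>.json`.
#' @param label free-text label stored in the sidecar.
#' @return `path`, invisibly.
#' @export
writeDTOF <- function(curve, path, label = "") {
  isIRF <- is(curve, "IRFCurve")
  stopifnot(isIRF || is(curve, "DTOFCurve"))
  tab <- data.frame(time_ns = timeCenters(curve@axis), counts = curve@counts)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  meta <- if (isIRF) list(type = "IRF", label = label)
  else list(type = "DTOF", rho_cm = curve@rho,
            wavelength_nm = curve@wavelength, acq_time_s = curve@acqTime,
            label = label)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a DTOF (or IRF) curve written by [writeDTOF()]
#'
#' @param path CSV file path with `<path>.json` sidecar.
#' @return A [DTOFCurve-class] or [IRFCurve-class], per the sidecar type.
#' @export
readDTOF <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path)
  if (!all(c("time_ns", "counts") %in% names(tab)))
    stop("malformed header: expected columns time_ns, counts in ", path)
  if (any(!is.finite(tab$counts)))
    stop("non-finite counts in ", path)
  bad <- which(tab$counts < 0)
  if (length(bad))
    stop(sprintf("negative count at row %d of %s", bad[1], path))
  n <- nrow(tab)
  if (n < 2) stop("curve needs at least 2 channels: ", path)
  dt <- diff(tab$time_ns)
  if (any(abs(dt - dt[1]) > 1e-6 * abs(dt[1])))
    stop("time axis is not uniform in ", path)
  axis <- timeAxis(tab$time_ns[1] - dt[1] / 2, dt[1], n)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing metadata sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (identical(meta$type, "IRF")) return(irfCurve(axis, tab$counts))
  for (k in c("rho_cm", "acq_time_s"))
    if (is.null(meta[[k]])) stop("missing metadata field ", k, " in ", sidecar)
  dtofCurve(axis, tab$counts, rho = meta$rho_cm,
            wavelength = if (is.null(meta$wavelength_nm)) NA_real_
            else meta$wavelength_nm,
            acqTime = meta$acq_time_s)
}

#' Write/read a spectral dataset as CSV
#'
#' Columns: `wavelength_nm`, `mua_cm`, `musp_cm`.
#'
#' @param dataset a [SpectralDataset-class].
#' @param path CSV path.
#' @return `path` invisibly / the [SpectralDataset-class].
#' @export
writeSpectralDataset <- function(dataset, path) {
  stopifnot(is(dataset, "SpectralDataset"))
  utils::write.csv(data.frame(wavelength_nm = dataset@wavelengths,
                              mua_cm = dataset@mua, musp_cm = dataset@musp),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSpectralDataset
#' @export
readSpectralDataset <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("wavelength_nm", "mua_cm", "musp_cm")
  if (!all(need %in% names(tab)))
    stop("malformed header: expected ", paste(need, collapse = ", "))
  spectralDataset(tab$wavelength_nm, tab$mua_cm, tab$musp_cm)
}
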