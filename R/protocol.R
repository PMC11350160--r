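#' Default family of contrast gates
#'
#' Five gates with start times 0.5-4.5 ns and 0.5 ns width, the family
#' used for gated-intensity displays.
#'
#' @param starts gate start times, ns.
#' @param width shared gate width, ns.
#' @return A 2-column matrix (start, width), one row per gate.
#' @export
defaultGates <- function(starts = c(0.5, 1.5, 2.5, 3.5, 4.5), width = 0.5) {
  cbind(start = as.numeric(starts), width = rep(as.numeric(width), length(starts)))
}

# per-acquisition count-rate gate integrals: rows acquisitions, cols gates
gateIntegrals <- function(series, gates) {
  gm <- gatesAsMatrix(gates)
  n <- length(series@acquisitions)
  out <- matrix(0, n, nrow(gm))
  for (i in seq_len(n)) {
    d <- series@acquisitions[[i]]
    tc <- timeCenters(d@axis)
    rate <- d@counts / d@acqTime
    for (k in seq_len(nrow(gm))) {
      inGate <- tc >= gm[k, 1] & tc < gm[k, 1] + gm[k, 2]
      out[i, k] <- sum(rate[inGate])
    }
  }
  out
}

#' Gated relative contrast of a breathing-protocol series
#'
#' For each acquisition and gate, the relative contrast
#' `C = (G - G0) / G0`, where `G` is the sum of count-rate-normalized
#' channel counts whose centres fall in the gate `[t, t + dt)` and `G0`
#' the same integral of the reference curve `R0`. By default `R0` is the
#' element-wise mean count-rate curve over the whole exercise (reference
#' acquisitions labelled "REF" excluded), so `C` is the relative change of
#' the gated signal with respect to the exercise mean.
#'
#' @param series a [ProtocolSeries-class]; all acquisitions must share a
#'   time axis.
#' @param gates a 2-column matrix or list of `c(start, width)` pairs, ns
#'   (default [defaultGates()]).
#' @param reference "mean" (whole-exercise mean excluding REF), or a
#'   [DTOFCurve-class] used as a fixed external reference.
#' @param includeReferencePrefix include REF-labelled acquisitions in the
#'   mean reference (default FALSE).
#' @return A [ContrastSeries-class]; gates with zero reference integral
#'   are NA and flagged undefined, never silently zero.
#' @export
gatedContrast <- function(series, gates = defaultGates(),
                          reference = "mean",
                          includeReferencePrefix = FALSE) {
  stopifnot(is(series, "ProtocolSeries"))
  gm <- gatesAsMatrix(gates)
  n <- length(series@acquisitions)
  if (n == 0) stop("empty series")
  axes_ok <- vapply(series@acquisitions, function(d)
    isTRUE(all.equal(timeCenters(d@axis),
                     timeCenters(series@acquisitions[[1]]@axis))), logical(1))
  if (!all(axes_ok)) stop("all acquisitions must share one time axis")
  G <- gateIntegrals(series, gm)

  if (is(reference, "DTOFCurve")) {
    refSeries <- protocolSeries(list(reference), 0, "REF", series@protocol)
    G0 <- gateIntegrals(refSeries, gm)[1, ]
    refDesc <- "fixed external curve"
  } else if (identical(reference, "mean")) {
    keep <- if (includeReferencePrefix) rep(TRUE, n) else series@labels != "REF"
    if (!any(keep)) stop("no acquisitions available for the mean reference")
    G0 <- colMeans(G[keep, , drop = FALSE])
    refDesc <- "whole-exercise mean"
  } else stop("reference must be \"mean\" or a DTOFCurve")

  C <- matrix(NA_real_, n, nrow(gm))
  for (k in seq_len(nrow(gm)))
    if (G0[k] > 0) C[, k] <- G[, k] / G0[k] - 1
  new("ContrastSeries", contrast = C, gateStart = gm[, 1],
      gateWidth = gm[, 2], timestamps = series@timestamps,
      labels = series@labels, reference = refDesc)
}

#' Folding average over protocol repetitions
#'
#' Averages a per-acquisition series at matched within-cycle offsets
#' across the protocol's repetitions. A reference prefix (one leading
#' normal-breathing repetition, Prot5) is removed before folding.
#'
#' @param values numeric vector (one value per acquisition) or matrix
#'   (acquisitions x variables).
#' @param protocol a [BreathingProtocol-class].
#' @param cadence acquisitions per second (default 1).
#' @return A vector/matrix of one averaged cycle (`2 * phaseDuration *
#'   cadence` rows).
#' @examples
#' foldingAverage(c(1, 2, 3, 4, 3, 4, 5, 6),
#'                breathingProtocol("custom", phaseDuration = 2,
#'                                  nRepetitions = 2L,
#'                                  referencePrefix = FALSE))  # 2 3 4 5
#' @export
foldingAverage <- function(values, protocol, cadence = 1) {
  stopifnot(is(protocol, "BreathingProtocol"))
  mat <- if (is.matrix(values)) values else matrix(values, ncol = 1L)
  cyc <- as.integer(round(2 * protocol@phaseDuration * cadence))
  if (cyc < 1) stop("cycle shorter than one acquisition")
  nPrefix <- if (protocol@referencePrefix) cyc else 0L
  expected <- nPrefix + cyc * protocol@nRepetitions
  if (nrow(mat) != expected)
    stop(sprintf("series length %d does not match the protocol (expected %d = %s%d cycles x %d acquisitions)",
                 nrow(mat), expected,
                 if (nPrefix) "1 reference cycle + " else "",
                 protocol@nRepetitions, cyc))
  body <- mat[(nPrefix + 1L):nrow(mat), , drop = FALSE]
  folded <- matrix(0, cyc, ncol(mat))
  for (r in seq_len(protocol@nRepetitions))
    folded <- folded + body[((r - 1L) * cyc + 1L):(r * cyc), , drop = FALSE]
  folded <- folded / protocol@nRepetitions
  if (is.matrix(values)) folded else as.numeric(folded)
}

#' Phase labels implied by a protocol's timing
#'
#' @param protocol a [BreathingProtocol-class].
#' @param timestamps acquisition start times, s (laboratory time; t = 0 is
#'   the first paced inhale; a reference prefix occupies the preceding
#'   cycle).
#' @param cadence acquisitions per second (default 1).
#' @return Character vector of "IN"/"OUT"/"REF" labels.
#' @export
protocolLabels <- function(protocol, timestamps, cadence = 1) {
  stopifnot(is(protocol, "BreathingProtocol"))
  cycle <- 2 * protocol@phaseDuration
  prefix <- if (protocol@referencePrefix) cycle else 0
  vapply(timestamps, function(ts) {
    if (ts < prefix) return("REF")
    within <- (ts - prefix) %% cycle
    if (within < protocol@phaseDuration) "IN" else "OUT"
  }, character(1))
}

#' Plateau summary of IN and OUT phases
#'
#' Per gate, the mean contrast over the plateau of the inspiration (IN)
#' and expiration (OUT) breath-hold phases, and their difference. The
#' plateau excludes a transient at the start of every phase (default 2 s)
#' to drop the inhalation/exhalation transitions.
#'
#' @param contrast a [ContrastSeries-class] with IN/OUT labels.
#' @param protocol the [BreathingProtocol-class] that produced it.
#' @param transient seconds excluded at each phase start (default 2).
#' @return A data.frame with one row per gate: `tStart`, `width`,
#'   `meanIN`, `meanOUT`, `inMinusOut`.
#' @export
phasePlateauSummary <- function(contrast, protocol, transient = 2) {
  stopifnot(is(contrast, "ContrastSeries"), is(protocol, "BreathingProtocol"))
  ts <- contrast@timestamps
  lab <- contrast@labels
  cycle <- 2 * protocol@phaseDuration
  prefix <- if (protocol@referencePrefix) cycle else 0
  phaseTime <- (ts - prefix) %% protocol@phaseDuration
  plateau <- lab %in% c("IN", "OUT") & ts >= prefix & phaseTime >= transient
  if (!any(plateau & lab == "IN") || !any(plateau & lab == "OUT"))
    stop("empty plateau: transient too long for the phase duration")
  meanIN <- colMeans(contrast@contrast[plateau & lab == "IN", , drop = FALSE])
  meanOUT <- colMeans(contrast@contrast[plateau & lab == "OUT", , drop = FALSE])
  data.frame(tStart = contrast@gateStart, width = contrast@gateWidth,
             meanIN = meanIN, meanOUT = meanOUT,
             inMinusOut = meanIN - meanOUT)
}

#' Homogeneous fits over a protocol series
#'
#' Fits every acquisition independently with [fitHomogeneous()],
#' warm-starting each fit at the previous acquisition's result. Fit
#' failures are recorded per acquisition and never abort the series.
#'
#' @param series a [ProtocolSeries-class].
#' @param irf the shared [IRFCurve-class].
#' @param init optional initial guess for the first acquisition.
#' @param ... passed to [fitHomogeneous()].
#' @return A data.frame with one row per acquisition: `timestamp`,
#'   `label`, `mua`, `musp`, `chi2Reduced`, `converged`.
#' @export
fitTimeseries <- function(series, irf, init = NULL, ...) {
  stopifnot(is(series, "ProtocolSeries"))
  n <- length(series@acquisitions)
  out <- data.frame(timestamp = series@timestamps, label = series@labels,
                    mua = rep(NA_real_, n), musp = rep(NA_real_, n),
                    chi2Reduced = rep(NA_real_, n),
                    converged = rep(FALSE, n))
  prev <- init
  for (i in seq_len(n)) {
    fit <- tryCatch(fitHomogeneous(series@acquisitions[[i]], irf,
                                   init = prev, ...),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      out$mua[i] <- fit@mua
      out$musp[i] <- fit@musp
      out$chi2Reduced[i] <- fit@chi2Reduced
      out$converged[i] <- fit@converged
      if (fit@converged) prev <- c(mua = fit@mua, musp = fit@musp)
    }
  }
  out
}
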