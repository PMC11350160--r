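#' Determine the fitting range of a DTOF
#'
#' The fitted channels run from the last channel at or before the peak
#' whose counts still exceed 80% of the peak (scanning backward from the
#' peak along the leading edge) to the channel just before the first
#' downward crossing of 1% of the peak on the falling edge. Thresholds are
#' relative, so the range is invariant under count rescaling. Peak ties
#' are broken by the earliest channel.
#'
#' @param dtof a [DTOFCurve-class] (or a bare numeric count vector).
#' @return Integer vector `c(iStart, iEnd)`, inclusive channel indices.
#' @examples
#' ax <- timeAxis(0, 0.1, 9L)
#' d <- dtofCurve(ax, c(0, 50, 900, 1000, 600, 200, 50, 9, 2), rho = 3)
#' determineFitRange(d)   # channels 3 to 7 (counts 900 .. 50)
#' @export
determineFitRange <- function(dtof) {
  y <- if (is(dtof, "DTOFCurve")) dtof@counts else as.numeric(dtof)
  if (all(y <= 0)) stop("cannot determine a fit range on an all-zero curve")
  ipk <- which.max(y)              # earliest maximum on ties
  peak <- y[ipk]
  iStart <- ipk
  while (iStart > 1L && y[iStart - 1L] > 0.8 * peak) iStart <- iStart - 1L
  iEnd <- length(y)
  if (ipk < length(y)) {
    below <- which(y[(ipk + 1L):length(y)] <= 0.01 * peak)
    if (length(below)) iEnd <- ipk + below[1L] - 1L
  }
  if (iStart >= iEnd) stop("degenerate fit range (peak at the curve edge)")
  c(iStart = iStart, iEnd = iEnd)
}

# convolved, shifted, scaled homogeneous model evaluated on a DTOF's axis
convolvedModel <- function(pars, axis, irf, rho, nIn, nOut) {
  props <- opticalProperties(pars[["mua"]], pars[["musp"]], nIn, nOut)
  tc <- timeCenters(axis) - pars[["shift"]]
  m <- trReflectance(rho, tc, props)
  pars[["amp"]] * convolveIRF(m, irf, axis)
}

#' Fit the homogeneous diffusion model to a measured DTOF
#'
#' Minimizes the Pearson chi-square (variance taken from the model counts,
#' the Poisson-appropriate choice) between the measured counts and the
#' amplitude-scaled, time-shifted, IRF-convolved [trReflectance()]
#' prediction, restricted to the range of [determineFitRange()]. Free
#' parameters: `mua` (bounded to [0, 2] 1/cm), `musp` ([1, 50] 1/cm), a
#' global amplitude, and a time shift bounded to +/- 100 ps that absorbs
#' residual offset between the IRF peak and the true time origin.
#' Levenberg-Marquardt with up to 3 restarts on non-convergence; a stalled
#' optimizer returns `converged = FALSE` rather than raising.
#'
#' @param dtof a [DTOFCurve-class].
#' @param irf an [IRFCurve-class] on a compatible axis (equal dt).
#' @param init optional named list/vector with elements `mua`, `musp`
#'   (1/cm) used as the starting point (default c(0.1, 10)).
#' @param nIn,nOut refractive indices assumed for the medium (defaults
#'   1.4 / 1.0).
#' @param fitRange optional `c(iStart, iEnd)` overriding the automatic
#'   range.
#' @return A [FitResult-class].
#' @export
fitHomogeneous <- function(dtof, irf, init = NULL, nIn = 1.4, nOut = 1.0,
                           fitRange = NULL) {
  stopifnot(is(dtof, "DTOFCurve"), is(irf, "IRFCurve"))
  axis <- dtof@axis
  if (abs(irf@axis@dt - axis@dt) > 1e-12 * axis@dt)
    stop("DTOF and IRF must share the same channel width")
  if (any(!is.finite(dtof@counts))) stop("non-finite counts in DTOF")
  fr <- if (is.null(fitRange)) determineFitRange(dtof) else as.integer(fitRange)
  if (fr[1] >= fr[2] || fr[1] < 1 || fr[2] > axis@nChannels)
    stop("invalid fit range")
  sel <- seq.int(fr[1], fr[2])
  y <- dtof@counts[sel]

  start <- c(mua = 0.1, musp = 10)
  if (!is.null(init)) {
    init <- unlist(init)
    if (!is.null(init["mua"]) && is.finite(init["mua"])) start["mua"] <- init[["mua"]]
    if (!is.null(init["musp"]) && is.finite(init["musp"])) start["musp"] <- init[["musp"]]
  }

  residFun <- function(p) {
    pars <- c(mua = p[1], musp = p[2], amp = exp(p[3]), shift = p[4])
    mod <- convolvedModel(pars, axis, irf, dtof@rho, nIn, nOut)[sel]
    mod <- pmax(mod, 1e-12)
    (y - mod) / sqrt(mod)
  }

  ampInit <- function(mua, musp) {
    mod <- convolvedModel(c(mua = mua, musp = musp, amp = 1, shift = 0),
                          axis, irf, dtof@rho, nIn, nOut)[sel]
    s <- sum(mod)
    if (s <= 0) 1 else sum(y) / s
  }

  lower <- c(0, 1, -Inf, -0.1)
  upper <- c(2, 50, Inf, 0.1)
  starts <- list(start,
                 c(mua = 0.1, musp = 10),
                 c(mua = max(start[["mua"]] * 0.5, 0.02), musp = min(start[["musp"]] * 1.5, 45)),
                 c(mua = min(start[["mua"]] * 2, 1.5), musp = max(start[["musp"]] * 0.6, 2)))
  dof <- max(length(sel) - 4L, 1L)
  best <- NULL
  for (s0 in starts) {
    p0 <- c(s0[["mua"]], s0[["musp"]], log(ampInit(s0[["mua"]], s0[["musp"]])), 0)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = residFun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    # a "converged" fit stuck in a poor local minimum (reduced chi-square
    # well above 1) still triggers the remaining multi-starts
    if (fit$info %in% 1:4 && fit$deviance / dof < 2) break
  }
  if (is.null(best)) {
    return(new("FitResult", mua = start[["mua"]], musp = start[["musp"]],
               amplitude = 1, timeShift = 0, chi2Reduced = Inf,
               fitRange = as.integer(fr), converged = FALSE))
  }
  p <- best$par
  new("FitResult", mua = p[1], musp = p[2], amplitude = exp(p[3]),
      timeShift = p[4], chi2Reduced = best$deviance / dof,
      fitRange = as.integer(fr), converged = best$info %in% 1:4)
}

#' Latest usable gate start time of a DTOF
#'
#' The largest gate start `t` (on the channel grid) such that the gate
#' `[t, t + gateWidth)` still collects more than
#' `countRateThreshold * acqTime` counts. With the default threshold of
#' 10,000 counts/s a 1-s acquisition needs > 1e4 counts in the gate —
#' i.e. shot noise at the 1% level.
#'
#' @param dtof a [DTOFCurve-class] with `acqTime > 0`.
#' @param gateWidth ns (default 0.5, matching the contrast gates).
#' @param countRateThreshold counts/s (default 1e4).
#' @return Gate start time in ns, or `NA_real_` when no gate satisfies the
#'   threshold.
#' @export
estimateTmax <- function(dtof, gateWidth = 0.5, countRateThreshold = 1e4) {
  stopifnot(is(dtof, "DTOFCurve"))
  if (gateWidth <= 0) stop("gateWidth must be > 0")
  axis <- dtof@axis
  nGate <- round(gateWidth / axis@dt)
  if (nGate < 1 || nGate > axis@nChannels) stop("gateWidth outside the axis")
  need <- countRateThreshold * dtof@acqTime
  cs <- cumsum(dtof@counts)
  nStarts <- axis@nChannels - nGate + 1L
  starts <- seq_len(nStarts)
  gateSums <- cs[starts + nGate - 1L] - c(0, cs)[starts]
  ok <- which(gateSums > need)
  if (!length(ok)) return(NA_real_)
  axis@t0 + (max(ok) - 1L) * axis@dt
}
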