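#' Time-resolved diffuse reflectance of a semi-infinite medium
#'
#' Analytic solution of the time-dependent diffusion equation for a
#' homogeneous semi-infinite medium in reflectance geometry, under the
#' extrapolated boundary condition: the fluence is forced to zero on a
#' plane `z_e = 2 A D` above the surface, which a single image-source
#' (dipole) pair realises. `D = 1/(3 musp)` is the (absorption-free)
#' diffusion coefficient and `A` the boundary factor from
#' [boundaryReflectionFactor()]. Absorption factorises exactly as
#' `exp(-mua v t)`.
#'
#' The overall amplitude is arbitrary (fits carry a free scale); the shape
#' in `t` and `rho` is what matters.
#'
#' @param rho source-detector distance, cm (> 0).
#' @param t times at which to evaluate, ns — either a numeric vector or a
#'   [TimeAxis-class] (evaluated at channel centres).
#' @param props an [OpticalProperties-class].
#' @return Numeric vector: reflectance per unit area and time (arbitrary
#'   overall scale), zero for `t <= 0`.
#' @examples
#' ax <- timeAxis()
#' R <- trReflectance(3, ax, opticalProperties(0.1, 10))
#' @export
trReflectance <- function(rho, t, props) {
  stopifnot(is(props, "OpticalProperties"))
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0)
    stop("rho must be a single positive number (cm)")
  if (props@musp <= 0) stop("musp must be > 0")
  tc <- if (is(t, "TimeAxis")) timeCenters(t) else as.numeric(t)

  v <- lightSpeed(props@nIn)                  # cm/ns
  D <- 1 / (3 * props@musp)                   # cm
  A <- boundaryReflectionFactor(props@nIn / props@nOut)
  z0 <- 1 / props@musp                        # isotropic-source depth, cm
  ze <- 2 * A * D                             # extrapolation distance, cm

  out <- numeric(length(tc))
  pos <- which(tc > 0)
  if (length(pos)) {
    tp <- tc[pos]
    fourDvt <- 4 * D * v * tp
    pref <- 0.5 * (4 * pi * D * v)^(-1.5) * tp^(-2.5) *
      exp(-props@mua * v * tp - rho^2 / fourDvt)
    zp <- z0
    zm <- z0 + 2 * ze
    out[pos] <- pref *
      (zp * exp(-zp^2 / fourDvt) + zm * exp(-zm^2 / fourDvt))
  }
  out
}

#' Convolve a model reflectance curve with a measured IRF
#'
#' Discrete causal convolution on a shared channel grid, truncated to the
#' model's axis: `out[k] = dt * sum_j model[j] * irf[k - j + i0]`, where
#' `i0` is the IRF channel containing its time origin (t = 0). An IRF
#' equal to a unit count in the t = 0 channel therefore returns the model
#' times `dt`, and when the supports fit inside the window the output
#' total equals (model total) x (IRF total) x dt.
#'
#' @param model numeric vector of model values on `axis` channel centres.
#' @param irf an [IRFCurve-class]; its axis must have the same `dt` as
#'   `axis`.
#' @param axis the [TimeAxis-class] the model lives on.
#' @return Numeric vector: the convolved model on `axis`.
#' @export
convolveIRF <- function(model, irf, axis) {
  stopifnot(is(irf, "IRFCurve"), is(axis, "TimeAxis"))
  iax <- irf@axis
  if (abs(iax@dt - axis@dt) > 1e-12 * axis@dt)
    stop("model and IRF time axes must share the same channel width dt")
  n <- axis@nChannels
  if (length(model) != n) stop("model length must match the time axis")
  h <- irf@counts
  # IRF channel whose bin contains t = 0 (channel i covers
  # [t0+(i-1)dt, t0+i dt)); clamp into the axis for IRFs defined on t >= 0
  i0 <- min(max(1L, 1L + floor((0 - iax@t0) / iax@dt + 1e-9)), iax@nChannels)
  full <- convolve_full(model, h)             # length n + length(h) - 1
  out <- full[seq.int(i0, length.out = n)] * axis@dt
  out
}

# full linear convolution via FFT with a brute-force fallback for tiny inputs
convolve_full <- function(a, b) {
  na <- length(a); nb <- length(b)
  N <- na + nb - 1L
  if (N < 64L) {
    out <- numeric(N)
    for (j in seq_len(na)) out[j:(j + nb - 1L)] <- out[j:(j + nb - 1L)] + a[j] * b
    return(out)
  }
  M <- stats::nextn(N, 2)
  fa <- stats::fft(c(a, numeric(M - na)))
  fb <- stats::fft(c(b, numeric(M - nb)))
  out <- Re(stats::fft(fa * fb, inverse = TRUE)) / M
  out <- out[seq_len(N)]
  # FFT round-off can leave tiny negative values where the true result is 0
  tinyneg <- out < 0 & out > -1e-9 * max(abs(out))
  out[tinyneg] <- 0
  out
}
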