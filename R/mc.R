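#' Run layered-slab time-resolved Monte Carlo photon transport
#'
#' Photons are launched at the origin heading into the medium; free paths
#' are exponential with mean `1/mus` (with `mus = musp/(1-g)`; the default
#' `g = 0` makes scattering isotropic and `mus = musp`), deflections are
#' Henyey-Greenstein, and the top surface applies unpolarized Fresnel
#' reflection/refraction for the `nIn/nOut` mismatch. Transport is run
#' **without absorption** (microscopic Lambert-Beer): per-layer path
#' lengths and the running maximum depth are stored per detected photon,
#' so any absorption can be applied afterwards by [applyAbsorption()] and
#' perturbation contrasts computed from the very same trajectories
#' ([perturbationContrast()], correlated sampling).
#'
#' Trajectories are abandoned once they exceed `geometry@tMaxRecord`.
#' Detection is an annulus `rho +/- ringHalfWidth`, or every exiting
#' photon when `acceptAllExits` is set (depth-statistics mode).
#'
#' @param medium a [LayeredMedium-class] (its `mua` slots are ignored
#'   during transport).
#' @param geometry a [DetectionGeometry-class].
#' @param nDetectedTarget detected photons wanted (>= 1).
#' @param seed integer RNG seed; identical (seed, parameters) give an
#'   identical result.
#' @param g Henyey-Greenstein anisotropy factor (default 0).
#' @param maxLaunch launch budget; when exhausted a partial result is
#'   returned with `budgetExhausted = TRUE` and a warning.
#' @param directAbsorption when TRUE, absorption events are sampled during
#'   transport from the medium's `mua` (photons absorbed are lost). This
#'   direct-sampling mode exists as a cross-check of the reweighting
#'   scheme; the standard mode is absorption-free.
#' @return An [MCResult-class].
#' @examples
#' m <- layeredMedium(Inf, mua = 0, musp = 10)
#' res <- runMC(m, detectionGeometry(3, acceptAllExits = TRUE), 1000, seed = 1)
#' res
#' @export
runMC <- function(medium, geometry, nDetectedTarget, seed,
                  g = 0, maxLaunch = 5000 * nDetectedTarget,
                  directAbsorption = FALSE) {
  stopifnot(is(medium, "LayeredMedium"), is(geometry, "DetectionGeometry"))
  if (nDetectedTarget < 1) stop("nDetectedTarget must be >= 1")
  if (g < 0 || g >= 1) stop("g must be in [0, 1)")
  seed <- as.integer(seed)

  mus <- medium@musp / (1 - g)
  v <- lightSpeed(medium@nIn)
  pathMax <- geometry@tMaxRecord * v
  thick <- medium@thickness
  thick[length(thick)] <- 1e30  # kernel treats last layer as unbounded

  raw <- mc_transport_cpp(thick, mus, g, medium@nIn / medium@nOut,
                          geometry@rho, geometry@ringHalfWidth,
                          geometry@acceptAllExits, pathMax,
                          as.integer(nDetectedTarget), as.numeric(maxLaunch),
                          medium@mua, isTRUE(directAbsorption), seed)

  if (raw$budget_exhausted)
    warning(sprintf("launch budget exhausted: %d of %d photons detected",
                    length(raw$exit_path), nDetectedTarget))
  pl <- raw$pathlen
  if (!is.matrix(pl)) pl <- matrix(pl, ncol = nLayers(medium))
  new("MCResult",
      pathlen = pl,
      exitTime = raw$exit_path / v,
      exitRadius = raw$exit_radius,
      maxDepth = raw$max_depth,
      nLaunched = raw$n_launched,
      seed = seed,
      medium = medium,
      geometry = geometry,
      budgetExhausted = raw$budget_exhausted)
}

#' Apply absorption to stored trajectories (microscopic Lambert-Beer)
#'
#' Each detected photon contributes weight
#' `w = exp(-sum_j mua_j L_j)` to its exit-time bin, where `L_j` is its
#' geometric path length in layer j. The result is the weighted exit-time
#' histogram the medium would have produced with those absorptions.
#'
#' @param result an [MCResult-class] from an absorption-free run.
#' @param muaPerLayer absorption coefficient per layer, 1/cm (length must
#'   match the medium's layer count; all >= 0).
#' @param axis [TimeAxis-class] for the histogram (default: 10 ps channels
#'   covering the recorded time span).
#' @param rho nominal distance stored in the returned curve's metadata
#'   (default: the geometry's).
#' @return A [DTOFCurve-class] holding the weighted histogram (weights,
#'   not integer counts).
#' @export
applyAbsorption <- function(result, muaPerLayer, axis = NULL, rho = NULL) {
  w <- photonWeights(result, muaPerLayer)
  if (is.null(axis))
    axis <- timeAxis(0, 0.01, ceiling(result@geometry@tMaxRecord / 0.01))
  if (is.null(rho)) rho <- max(result@geometry@rho, 1e-6)
  counts <- weightedTimeHistogram(result@exitTime, w, axis)
  dtofCurve(axis, counts, rho = rho, acqTime = 1)
}

# per-photon Lambert-Beer weights for a per-layer absorption vector
photonWeights <- function(result, muaPerLayer) {
  stopifnot(is(result, "MCResult"))
  muaPerLayer <- as.numeric(muaPerLayer)
  if (length(muaPerLayer) != ncol(result@pathlen))
    stop("muaPerLayer length must match the medium's layer count")
  if (any(muaPerLayer < 0)) stop("mua must be >= 0")
  as.numeric(exp(-(result@pathlen %*% muaPerLayer)))
}

weightedTimeHistogram <- function(times, weights, axis) {
  idx <- floor((times - axis@t0) / axis@dt) + 1
  keep <- idx >= 1 & idx <= axis@nChannels
  counts <- numeric(axis@nChannels)
  if (any(keep)) {
    s <- tapply(weights[keep], factor(idx[keep], levels = seq_len(axis@nChannels)), sum)
    counts <- as.numeric(ifelse(is.na(s), 0, s))
  }
  counts
}

#' Correlated-sampling perturbation contrast
#'
#' Computes the gated relative contrast
#' `C = (R - R0) / R0` between a perturbed and a baseline absorption
#' state, both obtained by reweighting the **same** stored trajectories —
#' correlated sampling, whose variance for absorption-only perturbations
#' is far below that of independent runs. `R` and `R0` are the summed
#' photon weights with exit time inside each gate `[t, t + dt)`.
#'
#' @param result an [MCResult-class].
#' @param baselineMua per-layer baseline absorption, 1/cm (the reference
#'   state R0).
#' @param perturbedMua per-layer perturbed absorption, 1/cm.
#' @param gates a list of `c(start, width)` pairs in ns, or a 2-column
#'   matrix (start, width).
#' @return A data.frame with columns `tStart`, `width`, `contrast`,
#'   `nPhotons` (photons in the gate) and `defined` (FALSE where the gate
#'   holds no photons; contrast is NA there, never silently 0).
#' @export
perturbationContrast <- function(result, baselineMua, perturbedMua, gates) {
  w0 <- photonWeights(result, baselineMua)
  w1 <- photonWeights(result, perturbedMua)
  gm <- gatesAsMatrix(gates)
  tmax <- result@geometry@tMaxRecord
  if (any(gm[, 1] < 0) || any(gm[, 1] + gm[, 2] > tmax + 1e-9))
    stop("gates must lie within the recorded time range [0, tMaxRecord]")
  out <- data.frame(tStart = gm[, 1], width = gm[, 2], contrast = NA_real_,
                    nPhotons = 0L, defined = FALSE)
  for (k in seq_len(nrow(gm))) {
    inGate <- result@exitTime >= gm[k, 1] &
      result@exitTime < gm[k, 1] + gm[k, 2]
    n <- sum(inGate)
    out$nPhotons[k] <- n
    if (n > 0 && sum(w0[inGate]) > 0) {
      out$contrast[k] <- sum(w1[inGate]) / sum(w0[inGate]) - 1
      out$defined[k] <- TRUE
    }
  }
  out
}

gatesAsMatrix <- function(gates) {
  if (is.list(gates)) gates <- do.call(rbind, gates)
  gates <- as.matrix(gates)
  if (ncol(gates) != 2) stop("gates must be (start, width) pairs")
  if (any(gates[, 2] <= 0)) stop("gate widths must be > 0")
  storage.mode(gates) <- "double"
  gates
}

#' Gated contrast between two independent Monte Carlo runs
#'
#' Path reweighting is exact only for absorption changes; a scattering
#' perturbation needs a second transport run. This computes the gated
#' relative contrast `C = R/R0 - 1` between two independent (ideally
#' paired-seed) runs, normalizing each weighted gate sum by the number of
#' photons *launched* so that detection efficiency differences are
#' accounted for. Unlike correlated reweighting, the estimate carries
#' full independent-run Monte Carlo noise.
#'
#' @param perturbed,baseline [MCResult-class] objects from runs that
#'   differ in their media (e.g. lung scattering reduced).
#' @param muaPerturbed,muaBaseline per-layer absorption applied by
#'   reweighting to each run (1/cm).
#' @param gates `c(start, width)` pairs, ns.
#' @return A data.frame as in [perturbationContrast()].
#' @export
independentRunContrast <- function(perturbed, baseline,
                                   muaPerturbed, muaBaseline, gates) {
  wP <- photonWeights(perturbed, muaPerturbed)
  wB <- photonWeights(baseline, muaBaseline)
  gm <- gatesAsMatrix(gates)
  out <- data.frame(tStart = gm[, 1], width = gm[, 2], contrast = NA_real_,
                    nPhotons = 0L, defined = FALSE)
  for (k in seq_len(nrow(gm))) {
    inP <- perturbed@exitTime >= gm[k, 1] &
      perturbed@exitTime < gm[k, 1] + gm[k, 2]
    inB <- baseline@exitTime >= gm[k, 1] &
      baseline@exitTime < gm[k, 1] + gm[k, 2]
    out$nPhotons[k] <- sum(inP) + sum(inB)
    sB <- sum(wB[inB]) / baseline@nLaunched
    if (sum(inB) > 0 && sB > 0) {
      sP <- sum(wP[inP]) / perturbed@nLaunched
      out$contrast[k] <- sP / sB - 1
      out$defined[k] <- TRUE
    }
  }
  out
}

#' Mean maximum penetration depth versus arrival time
#'
#' For each time bin, the unweighted mean of the maximum depth visited by
#' the photons whose exit time falls in the bin. Run the Monte Carlo with
#' `acceptAllExits = TRUE`: for a homogeneous medium the depth statistics
#' at a given arrival time are rigorously independent of both the
#' absorption (a constant weight `exp(-mua v t)` within a bin cancels in
#' the mean) and the detection radius.
#'
#' @param result an [MCResult-class] with at least one detected photon.
#' @param axis a [TimeAxis-class] defining the arrival-time bins.
#' @param minRecords bins with fewer records are flagged (default 50).
#' @return A data.frame with columns `t` (bin centre, ns), `meanMaxDepth`
#'   (cm, NA for empty bins), `nRecords` and `reliable`
#'   (`nRecords >= minRecords`).
#' @export
meanMaxDepthCurve <- function(result, axis, minRecords = 50L) {
  stopifnot(is(result, "MCResult"), is(axis, "TimeAxis"))
  if (nDetected(result) == 0) stop("MCResult holds no detected photons")
  idx <- floor((result@exitTime - axis@t0) / axis@dt) + 1
  keep <- idx >= 1 & idx <= axis@nChannels
  f <- factor(idx[keep], levels = seq_len(axis@nChannels))
  n <- as.integer(table(f))
  s <- tapply(result@maxDepth[keep], f, sum)
  m <- ifelse(n > 0, as.numeric(s) / n, NA_real_)
  data.frame(t = timeCenters(axis), meanMaxDepth = m, nRecords = n,
             reliable = n >= minRecords)
}
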