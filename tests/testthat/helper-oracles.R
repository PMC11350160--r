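# Independent oracles used across the suite. These deliberately share no
# code with the package implementation they check.

# Brute-force O(N^2) causal convolution on a shared grid:
# out[k] = dt * sum_j model[j] * irf[k - j + i0], i0 = IRF channel of t = 0.
bruteConvolve <- function(model, irfCounts, dt, i0 = 1L) {
  n <- length(model)
  out <- numeric(n)
  for (k in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      idx <- k - j + i0
      if (idx >= 1 && idx <= length(irfCounts))
        acc <- acc + model[j] * irfCounts[idx]
    }
    out[k] <- acc * dt
  }
  out
}

# Exhaustive scan implementation of the fit-range rule.
bruteFitRange <- function(y) {
  ipk <- which.max(y)
  peak <- y[ipk]
  above80 <- which(y > 0.8 * peak)
  iStart <- min(above80[above80 <= ipk & seq_along(y)[above80] >=
                          (max(which(y[seq_len(ipk)] <= 0.8 * peak), 0) + 1)])
  # leading edge: contiguous run of >80% channels ending at the peak
  iStart <- ipk
  while (iStart > 1 && y[iStart - 1] > 0.8 * peak) iStart <- iStart - 1
  iEnd <- length(y)
  for (i in seq.int(ipk + 1L, length(y))) {
    if (ipk + 1L > length(y)) break
    if (y[i] <= 0.01 * peak) { iEnd <- i - 1L; break }
  }
  c(iStart, iEnd)
}

# Exhaustive scan for the latest gate exceeding a count-rate threshold.
bruteTmax <- function(countsVec, t0, dt, gateWidth, thresholdCounts) {
  nGate <- round(gateWidth / dt)
  best <- NA_real_
  for (i in seq_len(length(countsVec) - nGate + 1L)) {
    if (sum(countsVec[i:(i + nGate - 1L)]) > thresholdCounts)
      best <- t0 + (i - 1L) * dt
  }
  best
}

# Independent plain-R Monte Carlo photon transport in a layered slab,
# vectorized across photons (lock-step stepping). Isotropic scattering,
# unpolarized Fresnel at the top surface, optional direct absorption
# sampling. Returns per-photon exit path length, per-layer path lengths
# and maximum depth for photons that exited before pathMax.
rTransportOracle <- function(n, thickness, mus, mua = rep(0, length(mus)),
                             nRel = 1.4, pathMax = 130, seed = 1) {
  set.seed(seed)
  L <- length(mus)
  zb <- cumsum(c(0, thickness[-L]))        # layer top depths
  zlo <- zb
  zhi <- c(zb[-1], Inf)
  x <- y <- z <- numeric(n)
  ux <- uy <- numeric(n); uz <- rep(1, n)
  layer <- rep(1L, n)
  total <- numeric(n); zmax <- numeric(n)
  lp <- matrix(0, n, L)
  alive <- rep(TRUE, n); exited <- rep(FALSE, n)
  fresnel <- function(cosI) {
    sinT2 <- nRel^2 * (1 - cosI^2)
    R <- rep(1, length(cosI))
    ok <- sinT2 < 1
    cosT <- sqrt(pmax(1 - sinT2[ok], 0))
    rs <- (nRel * cosI[ok] - cosT) / (nRel * cosI[ok] + cosT)
    rp <- (cosT * nRel - cosI[ok]) / (cosT * nRel + cosI[ok])
    R[ok] <- 0.5 * (rs^2 + rp^2)
    R
  }
  mut <- mus + mua   # total interaction rate (absorption sampled directly)
  while (any(alive)) {
    a <- which(alive)
    s <- -log(runif(length(a))) / mut[layer[a]]
    dUp <- ifelse(uz[a] < 0, (zlo[layer[a]] - z[a]) / uz[a], Inf)
    dDn <- ifelse(uz[a] > 0, (zhi[layer[a]] - z[a]) / uz[a], Inf)
    dB <- pmin(dUp, dDn)
    d <- pmin(s, dB)
    x[a] <- x[a] + ux[a] * d; y[a] <- y[a] + uy[a] * d
    z[a] <- z[a] + uz[a] * d
    for (j in seq_len(L)) {
      inj <- layer[a] == j
      lp[a[inj], j] <- lp[a[inj], j] + d[inj]
    }
    total[a] <- total[a] + d
    zmax[a] <- pmax(zmax[a], z[a])
    over <- total[a] > pathMax
    alive[a[over]] <- FALSE
    a2 <- a[!over]; d2 <- d[!over]; s2 <- s[!over]; dB2 <- dB[!over]
    coll <- s2 <= dB2
    # collisions: absorb or scatter isotropically
    ac <- a2[coll]
    if (length(ac)) {
      if (any(mua > 0)) {
        pAbs <- mua[layer[ac]] / (mua[layer[ac]] + mus[layer[ac]])
        dead <- runif(length(ac)) < pAbs
        alive[ac[dead]] <- FALSE
        ac <- ac[!dead]
      }
      if (length(ac)) {
        czn <- runif(length(ac), -1, 1)
        phi <- runif(length(ac), 0, 2 * pi)
        st <- sqrt(1 - czn^2)
        ux[ac] <- st * cos(phi); uy[ac] <- st * sin(phi); uz[ac] <- czn
      }
    }
    # boundary hits
    ab <- a2[!coll]
    if (length(ab)) {
      up <- uz[ab] < 0
      toSurf <- ab[up & layer[ab] == 1L]
      if (length(toSurf)) {
        z[toSurf] <- 0
        refl <- runif(length(toSurf)) < fresnel(abs(uz[toSurf]))
        uz[toSurf[refl]] <- -uz[toSurf[refl]]
        out <- toSurf[!refl]
        exited[out] <- TRUE
        alive[out] <- FALSE
      }
      inner <- setdiff(ab, toSurf)
      if (length(inner)) {
        goingDown <- uz[inner] > 0
        layer[inner] <- layer[inner] + ifelse(goingDown, 1L, -1L)
        z[inner] <- ifelse(goingDown, zlo[layer[inner]], zhi[layer[inner]])
      }
    }
  }
  list(exitPath = total[exited], pathlen = lp[exited, , drop = FALSE],
       maxDepth = zmax[exited], exitRadius = sqrt(x[exited]^2 + y[exited]^2),
       nLaunched = n)
}

# small standard IRF + axis used by several fitting tests
testAxis <- function() timeAxis(-1, 0.01, 1000L)
testIRF <- function(seed = 99, total = 2e6) {
  set.seed(seed)
  generateIRF(testAxis(), fwhm = 150, totalCounts = total)
}
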