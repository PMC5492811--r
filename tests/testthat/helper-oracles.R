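# Independent oracles used across the suite.

# PSA solar position algorithm (Blanco-Muriel et al. 2001), coded
# independently of the package's NOAA formulation. No refraction; geometric
# accuracy ~0.01 degree for 1999-2015.
psaSolar <- function(lat, lon, timeUtc) {
  jd <- as.numeric(timeUtc) / 86400 + 2440587.5
  elapsed <- jd - 2451545
  hourUtc <- (jd - 0.5 - floor(jd - 0.5)) * 24
  omega <- 2.1429 - 0.0010394594 * elapsed
  meanLong <- 4.8950630 + 0.017202791698 * elapsed
  meanAnom <- 6.2400600 + 0.0172019699 * elapsed
  eclLong <- meanLong + 0.03341607 * sin(meanAnom) + 0.00034894 * sin(2 * meanAnom) -
    0.0001134 - 0.0000203 * sin(omega)
  obliq <- 0.4090928 - 6.2140e-9 * elapsed + 0.0000396 * cos(omega)
  ra <- atan2(cos(obliq) * sin(eclLong), cos(eclLong))
  if (ra < 0) ra <- ra + 2 * pi
  dec <- asin(sin(obliq) * sin(eclLong))
  gmst <- 6.6974243242 + 0.0657098283 * elapsed + hourUtc
  lmst <- (gmst * 15 + lon) * pi / 180
  ha <- lmst - ra
  latR <- lat * pi / 180
  zen <- acos(cos(latR) * cos(ha) * cos(dec) + sin(dec) * sin(latR))
  az <- atan2(-sin(ha), tan(dec) * cos(latR) - sin(latR) * cos(ha))
  az <- (az / pi * 180) %% 360   # PSA yields azimuth clockwise from north
  # parallax correction
  zen <- zen + (6371.01 / 149597890) * sin(zen)
  c(sza = zen * 180 / pi, saa = az)
}

# Independent re-evaluation of the parametric canopy reflectance model.
refModelOracle <- function(chl, lai, wl) {
  rMin <- 0.04 + 0.26 * exp(-0.045 * chl)
  rVis <- rMin + (0.05 + 0.10 * exp(-0.02 * chl)) * exp(-((wl - 550) / 40)^2)
  rNir <- 0.28 + 0.20 * (1 - exp(-0.6 * lai))
  s <- 1 / (1 + exp(-(wl - 720) / 12))
  rVis * (1 - s) + rNir * s
}

# Brute-force triple search over a LutSpec, coded from the definitions with
# plain loops: saturation replacement, logarithmic gap averaging, Poisson
# ring gaps and count-weighted RMS cost.
bruteInvert <- function(grids, lut, satLai = 10) {
  th <- seq(1.25, 36.25, by = 2.5)
  best <- list(cost = Inf)
  for (e in lut@effAlaGrid) {
    chiE <- chiFromAla(e)
    pSat <- exp(-gFunction(th, chiE) * satLai / cos(th * pi / 180))
    meanGap <- meanLog <- wRing <- numeric(15)
    for (i in 1:15) {
      g <- c(); w <- c()
      for (gr in grids) {
        gi <- gapFractions(gr)[i, ]; wi <- cellCounts(gr)[i, ]
        sel <- wi > 0 & !is.na(gi)
        g <- c(g, gi[sel]); w <- c(w, wi[sel])
      }
      if (!length(g)) { wRing[i] <- 0; next }
      g <- pmin(1, pmax(g, pSat[i]))
      wRing[i] <- sum(w)
      meanGap[i] <- sum(w * g) / sum(w)
      meanLog[i] <- sum(w * log(g)) / sum(w)
    }
    use <- wRing > 0
    om <- ifelse(meanLog == 0, 1, log(meanGap) / meanLog)
    om <- pmin(om, 1)
    for (a in lut@alaGrid) {
      Ga <- gFunction(th, chiFromAla(a))
      for (l in lut@laiGrid) {
        pm <- exp(-Ga * om * l / cos(th * pi / 180))
        cost <- sqrt(sum(wRing[use] * (meanGap[use] - pm[use])^2) / sum(wRing[use]))
        if (cost < best$cost - 1e-15) best <- list(cost = cost, lai = l, ala = a, eff = e)
      }
    }
  }
  best
}

# Equal-weight simple OLS via the normal equations.
olsOracle <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  c(intercept = a, slope = b)
}
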