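## Canopy structure from downward hemispherical photographs: vegetation
## segmentation, angular binning, the Poisson gap-fraction model with an
## ellipsoidal leaf inclination distribution, logarithmic gap averaging for
## clumping, and the look-up-table inversion for plant area index, average
## leaf inclination angle and the clumping profile.

#' Mean projected leaf area (G-function) of an ellipsoidal canopy
#'
#' Projection coefficient of unit foliage area on the plane perpendicular to
#' a view direction at zenith angle theta, for an ellipsoidal leaf
#' inclination distribution with shape parameter chi (ratio of vertical to
#' horizontal axes of the representative ellipsoid):
#' \deqn{G(\theta,\chi) = \frac{\cos\theta\sqrt{\chi^2+\tan^2\theta}}
#'   {\chi + 1.774(\chi+1.182)^{-0.733}}}
#' For the spherical distribution (chi = 1) G is 0.4997 at every angle.
#'
#' @param thetaDeg view zenith angle(s) in degrees, < 90.
#' @param chi ellipsoidal shape parameter, positive. Planophile canopies
#'   have chi > 1, erectophile chi < 1.
#' @return G value(s), positive.
#' @export
gFunction <- function(thetaDeg, chi) {
  if (any(chi <= 0)) stop("chi must be positive")
  if (any(thetaDeg < 0 | thetaDeg >= 90)) stop("thetaDeg must lie in [0, 90)")
  th <- thetaDeg * pi / 180
  cos(th) * sqrt(chi^2 + tan(th)^2) / (chi + 1.774 * (chi + 1.182)^(-0.733))
}

#' Convert between the ellipsoidal shape parameter and the average leaf angle
#'
#' Uses the closed-form approximation
#' \eqn{ALA \approx 9.65 (3 + \chi)^{-1.65}} (radians), inverted numerically
#' for `chiFromAla`. Valid for average leaf inclination angles between about
#' 5 and 85 degrees.
#'
#' @param chi ellipsoidal shape parameter (positive).
#' @param alaDeg average leaf inclination angle in degrees.
#' @return `alaFromChi`: ALA in degrees; `chiFromAla`: chi.
#' @export
alaFromChi <- function(chi) 180 / pi * 9.65 * (3 + chi)^(-1.65)

#' @rdname alaFromChi
#' @export
chiFromAla <- function(alaDeg) {
  vapply(alaDeg, function(a) {
    if (a <= 0 || a >= 90) stop("alaDeg must lie in (0, 90)")
    ((180 / pi * 9.65 / a)^(1 / 1.65)) - 3
  }, numeric(1))
}

#' Poisson gap-fraction model
#'
#' Probability that a view ray at zenith angle theta traverses the canopy:
#' \deqn{P(\theta) = \exp(-G(\theta,\chi)\,\Omega\,L/\cos\theta)}
#' with plant area index L, clumping index Omega and the ellipsoidal
#' G-function parameterized by the average leaf inclination angle.
#'
#' @param lai plant area index (m2/m2, >= 0).
#' @param alaDeg average leaf inclination angle (degrees).
#' @param omega clumping index in (0, 1]; scalar or one value per theta.
#' @param thetaDeg view zenith angle(s) in degrees, < 90.
#' @return Gap fraction(s) in (0, 1].
#' @export
gapModel <- function(lai, alaDeg, omega, thetaDeg) {
  if (any(thetaDeg >= 90)) stop("thetaDeg must be < 90 degrees")
  chi <- chiFromAla(alaDeg)
  exp(-gFunction(thetaDeg, chi) * omega * lai / cos(thetaDeg * pi / 180))
}

# Saturation-replaced, count-weighted per-ring statistics over all photos of
# a plot. Zero-gap (fully vegetated) cells are replaced by the saturated gap
# fraction at PAI = satLai for the given effective inclination angle, and all
# gaps are clipped to [P_sat, 1] before logs.
.ringStats <- function(grids, effAlaDeg, satLai = 10) {
  th <- ringCenters()
  pSat <- gapModel(satLai, effAlaDeg, 1, th)
  gaps <- lapply(grids, gapFractions)
  cnts <- lapply(grids, cellCounts)
  meanGap <- meanLog <- weight <- numeric(15L)
  for (i in seq_len(15L)) {
    g <- unlist(lapply(gaps, function(m) m[i, ]))
    w <- unlist(lapply(cnts, function(m) m[i, ]))
    ok <- w > 0 & !is.na(g)
    g <- g[ok]; w <- w[ok]
    if (!length(g)) { meanGap[i] <- NA; meanLog[i] <- NA; weight[i] <- 0; next }
    g <- pmin(1, pmax(g, pSat[i]))
    weight[i] <- sum(w)
    meanGap[i] <- sum(w * g) / weight[i]
    meanLog[i] <- sum(w * log(g)) / weight[i]
  }
  list(meanGap = meanGap, meanLog = meanLog, weight = weight)
}

#' Clumping index by logarithmic gap-fraction averaging
#'
#' Per zenith ring, the clumping index is the ratio of the logarithm of the
#' (count-weighted) mean cell gap fraction to the mean of the cell log gap
#' fractions, pooled over all photographs of the plot. Fully vegetated cells
#' are first replaced by the saturated gap fraction computed at a plant area
#' index of 10 m2/m2 with the supplied effective leaf inclination angle.
#' Rings whose mean gap is 1 (empty canopy) return 1.
#'
#' @param grids list of \linkS4class{GapFractionGrid} for one plot.
#' @param saturationAlaDeg effective leaf inclination angle (degrees) used
#'   for the saturated-gap replacement.
#' @param satLai saturation plant area index (default 10 m2/m2).
#' @param rings ring indices to evaluate (default all 15).
#' @return Numeric vector of clumping values in (0, 1], one per ring
#'   (NA for unpopulated rings).
#' @export
clumpingLangXiang <- function(grids, saturationAlaDeg, satLai = 10,
                              rings = seq_len(15L)) {
  if (is(grids, "GapFractionGrid")) grids <- list(grids)
  st <- .ringStats(grids, saturationAlaDeg, satLai)
  if (all(st$weight[rings] == 0)) stop("no populated cells in requested rings")
  om <- rep(NA_real_, 15L)
  for (i in rings) {
    if (st$weight[i] == 0) next
    om[i] <- if (st$meanLog[i] == 0) 1 else log(st$meanGap[i]) / st$meanLog[i]
  }
  pmin(om[rings], 1)
}

#' Ground cover from near-nadir gap fractions
#'
#' One minus the count-weighted mean raw gap fraction over the zenith rings
#' fully contained in the 0--20 degree view cone (rings 1--8).
#'
#' @param grids list of \linkS4class{GapFractionGrid} for one plot.
#' @return Ground-cover fraction in [0, 1].
#' @export
groundCover <- function(grids) {
  if (is(grids, "GapFractionGrid")) grids <- list(grids)
  g <- unlist(lapply(grids, function(x) gapFractions(x)[1:8, ]))
  w <- unlist(lapply(grids, function(x) cellCounts(x)[1:8, ]))
  ok <- w > 0 & !is.na(g)
  if (!any(ok)) stop("no populated cells within 0-20 degrees")
  1 - sum(g[ok] * w[ok]) / sum(w[ok])
}

#' Invert gap fractions for canopy structure (look-up-table search)
#'
#' Searches the full grid of (plant area index, average leaf inclination
#' angle, effective inclination angle) candidates. For each effective angle
#' the clumping profile is estimated by [clumpingLangXiang()] (that angle
#' governs the saturated-gap replacement) and ring gap fractions are
#' modelled as \eqn{\exp(-G(\theta,\chi)\Omega(\theta)L/\cos\theta)}. The
#' cost is the count-weighted root-mean-square difference between measured
#' (saturation-replaced) and modelled ring gap fractions; exact cost ties
#' are broken toward the lowest plant area index, then the lowest
#' inclination angle, then the lowest effective angle.
#'
#' @param grids list of \linkS4class{GapFractionGrid} for one plot
#'   (typically 4 photographs).
#' @param lut a \linkS4class{LutSpec} (default: the full 1001 x 36 x 36 grid).
#' @param satLai saturation plant area index for the replacement.
#' @return A \linkS4class{CanopyParams}.
#' @export
invertCanopy <- function(grids, lut = lutSpec(), satLai = 10) {
  if (is(grids, "GapFractionGrid")) grids <- list(grids)
  th <- ringCenters()
  cosTh <- cos(th * pi / 180)
  laiG <- lut@laiGrid; alaG <- lut@alaGrid; effG <- lut@effAlaGrid
  nL <- length(laiG); nA <- length(alaG)

  # G(theta, ala) for every candidate ala: nA x 15
  Gmat <- t(vapply(alaG, function(a) gFunction(th, chiFromAla(a)), numeric(15L)))

  best <- list(cost = Inf, lai = NA, ala = NA, eff = NA, omega = NULL)
  anyRing <- FALSE
  for (e in effG) {
    st <- .ringStats(grids, e, satLai)
    use <- st$weight > 0
    if (!any(use)) next
    anyRing <- TRUE
    w <- st$weight[use]; w <- w / sum(w)
    pMeas <- st$meanGap[use]
    om <- ifelse(st$meanLog == 0, 1, log(st$meanGap) / st$meanLog)
    om <- pmin(om, 1)
    # attenuation per (ala, ring): G * omega / cos(theta)
    A <- sweep(Gmat[, use, drop = FALSE], 2L, om[use] / cosTh[use], `*`)
    E <- exp(-outer(laiG, as.vector(t(A))))            # nL x (nRings*nA), ring fastest
    nR <- sum(use)
    Wsel <- matrix(0, nR * nA, nA)
    Wsel[cbind(seq_len(nR * nA), rep(seq_len(nA), each = nR))] <- rep(w, nA)
    cost2 <- E^2 %*% Wsel - 2 * (E %*% (Wsel * rep(pMeas, nA))) + sum(w * pMeas^2)
    cost2[cost2 < 0] <- 0                              # guard fp round-off
    m <- min(cost2)
    if (m < best$cost - 1e-15) {
      # exact-tie break inside this slice: lowest lai, then lowest ala
      hit <- which(cost2 <= m + 1e-15, arr.ind = TRUE)
      hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
      best <- list(cost = m, lai = laiG[hit[1, 1]], ala = alaG[hit[1, 2]],
                   eff = e, omega = om)
    }
  }
  if (!anyRing) stop("no populated rings")
  new("CanopyParams", lai = best$lai, ala = best$ala, omega = best$omega,
      omegaEffAla = best$eff, groundCover = groundCover(grids),
      cost = sqrt(best$cost))
}

#' Segment an RGB image into vegetation and background
#'
#' Computes the excess-green channel (2G - R - B) and thresholds it by
#' between-class variance maximization (Otsu). Intended for downward
#' hemispherical photographs of green canopies over soil.
#'
#' @param rgb numeric array (rows, cols, 3) with values in [0, 1].
#' @return Binary matrix: 1 = vegetation, 0 = gap/background.
#' @export
classifyVegetation <- function(rgb) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L) stop("input must be an RGB array")
  exg <- 2 * rgb[, , 2] - rgb[, , 1] - rgb[, , 3]
  rng <- range(exg, na.rm = TRUE)
  if (diff(rng) < 1e-12) {
    # uniform image: all vegetation if greenish, else all background
    return(matrix(as.integer(exg[1, 1] > 0), nrow(exg), ncol(exg)))
  }
  norm <- (exg - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  out <- matrix(0L, nrow(exg), ncol(exg))
  out[norm > thr] <- 1L
  out
}

#' Bin a binary canopy mask into a gap-fraction grid
#'
#' Maps every pixel to (zenith, azimuth) view angles and accumulates gap
#' fractions on the fixed 15 x 72 angular grid. The default projection is an
#' ideal equidistant fisheye: zenith proportional to the distance from the
#' image centre, reaching `zenithMaxDeg` at radius `min(dim)/2`; azimuth is
#' the polar angle. `NA` pixels are treated as masked and excluded.
#'
#' @param mask binary matrix (1 = vegetation, 0 = gap, NA = masked).
#' @param projection optional function mapping matrices of (row, col) pixel
#'   coordinates to a list with `zenith` and `azimuth` matrices (degrees).
#' @param zenithMaxDeg zenith angle at the default projection's image-circle
#'   edge (default 90).
#' @return A \linkS4class{GapFractionGrid}.
#' @export
binToGrid <- function(mask, projection = NULL, zenithMaxDeg = 90) {
  nr <- nrow(mask); nc <- ncol(mask)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  if (is.null(projection)) {
    cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
    rad <- min(nr, nc) / 2
    dy <- rows - cy; dx <- cols - cx
    zen <- sqrt(dx^2 + dy^2) / rad * zenithMaxDeg
    azi <- (atan2(dx, -dy) * 180 / pi) %% 360
  } else {
    prj <- projection(rows, cols)
    zen <- prj$zenith; azi <- prj$azimuth
  }
  keep <- !is.na(mask) & zen < 37.5
  ringIx <- pmin(15L, floor(zen / 2.5) + 1L)[keep]
  aziIx <- pmin(72L, floor((azi %% 360) / 5) + 1L)[keep]
  gapPix <- (mask == 0)[keep]
  idx <- (aziIx - 1L) * 15L + ringIx
  cnt <- matrix(tabulate(idx, nbins = 15L * 72L), 15, 72)
  gapSum <- matrix(0, 15, 72)
  if (length(idx)) {
    gs <- rowsum(as.numeric(gapPix), idx)
    gapSum[as.integer(rownames(gs))] <- gs
  }
  gap <- gapSum / ifelse(cnt > 0, cnt, NA)
  GapFractionGrid(gap, cnt)
}
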