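## Narrow-band vegetation index library.
##
## Index formulations follow the published narrow-band definitions; each
## index carries per-sensor nominal band centres because the two reference
## sensors place the NIR/red-edge anchor bands slightly differently
## (e.g. 780 nm on the ground radiometer vs 800 nm on the UAV grid).

# Internal registry. `bands` holds named nominal-centre vectors: `canonical`
# plus optional per-sensor overrides ("ground", "uav"). `fn` receives the
# resolved reflectance values in the order of the nominal vector, plus the
# soil-line ratio C where needed.
.osavi <- function(rn, rr) 1.16 * (rn - rr) / (rn + rr + 0.16)
.mcari <- function(r550, r670, r700) ((r700 - r670) - 0.2 * (r700 - r550)) * (r700 / r670)
.tcari <- function(r550, r670, r700) 3 * ((r700 - r670) - 0.2 * (r700 - r550) * (r700 / r670))
.mcariRe <- function(r550, r705, r750) ((r750 - r705) - 0.2 * (r750 - r550)) * (r750 / r705)
.tcariRe <- function(r550, r705, r750) 3 * ((r750 - r705) - 0.2 * (r750 - r550) * (r750 / r705))

.indexRegistry <- list(
  NDVI = list(
    bands = list(canonical = c(670, 800), ground = c(670, 780)),
    fn = function(v, C) (v[2] - v[1]) / (v[2] + v[1])),
  WDVI = list(
    bands = list(canonical = c(670, 870)), needsSoil = TRUE,
    fn = function(v, C) v[2] - C * v[1]),
  OSAVI = list(
    bands = list(canonical = c(670, 800), ground = c(670, 780)),
    fn = function(v, C) .osavi(v[2], v[1])),
  MCARI = list(
    bands = list(canonical = c(550, 670, 700)),
    fn = function(v, C) .mcari(v[1], v[2], v[3])),
  TCARI = list(
    bands = list(canonical = c(550, 670, 700)),
    fn = function(v, C) .tcari(v[1], v[2], v[3])),
  MCARI_OSAVI = list(
    bands = list(canonical = c(550, 670, 700, 800), ground = c(550, 670, 700, 780)),
    fn = function(v, C) .mcari(v[1], v[2], v[3]) / .osavi(v[4], v[2])),
  TCARI_OSAVI = list(
    bands = list(canonical = c(550, 670, 700, 800), ground = c(550, 670, 700, 780)),
    fn = function(v, C) .tcari(v[1], v[2], v[3]) / .osavi(v[4], v[2])),
  MCARI_re = list(
    bands = list(canonical = c(550, 705, 750), ground = c(550, 700, 750)),
    fn = function(v, C) .mcariRe(v[1], v[2], v[3])),
  MCARI_OSAVI_re = list(
    bands = list(canonical = c(550, 705, 750), ground = c(550, 700, 750)),
    fn = function(v, C) .mcariRe(v[1], v[2], v[3]) / .osavi(v[3], v[2])),
  TCARI_OSAVI_re = list(
    bands = list(canonical = c(550, 705, 750), ground = c(550, 700, 750)),
    fn = function(v, C) .tcariRe(v[1], v[2], v[3]) / .osavi(v[3], v[2])),
  CI_re = list(
    bands = list(canonical = c(710, 780)),
    fn = function(v, C) v[2] / v[1] - 1),
  # The formula governs the band choice: R780/R550 - 1 (green band replacing
  # the red-edge band of CI_re).
  CI_g = list(
    bands = list(canonical = c(550, 780)),
    fn = function(v, C) v[2] / v[1] - 1),
  MCARI2 = list(
    bands = list(canonical = c(550, 670, 800), ground = c(550, 670, 780)),
    fn = function(v, C) {
      num <- 1.5 * (2.5 * (v[3] - v[2]) - 1.3 * (v[3] - v[1]))
      disc <- (2 * v[3] + 1)^2 - (6 * v[3] - 5 * sqrt(v[2])) - 0.5
      ifelse(disc <= 0, NA_real_, num / sqrt(disc))
    }),
  REP = list(
    bands = list(canonical = c(670, 700, 740, 780)),
    fn = function(v, C) 700 + 40 * (((v[1] + v[4]) / 2 - v[2]) / (v[3] - v[2]))),
  MTCI = list(
    bands = list(canonical = c(681, 709, 754), ground = c(670, 710, 750),
                 uav = c(680, 710, 755)),
    fn = function(v, C) (v[3] - v[2]) / (v[2] - v[1])),
  PRI = list(
    bands = list(canonical = c(531, 570), ground = c(530, 570), uav = c(530, 570)),
    fn = function(v, C) (v[2] - v[1]) / (v[2] + v[1]))
)

#' Names of the available vegetation indices
#'
#' @return Character vector of the 16 supported index names.
#' @export
indexNames <- function() names(.indexRegistry)

#' Resolve a nominal band centre against a sensor's band set
#'
#' Returns the position of the band whose centre is nearest to the nominal
#' wavelength; ties are broken toward the shorter wavelength. It is an error
#' if no band lies within `toleranceNm` of the nominal centre.
#'
#' @param bandSet a \linkS4class{SpectralBandSet}.
#' @param nominalNm nominal band centre(s) in nm.
#' @param toleranceNm maximum allowed |centre - nominal| (default 10 nm).
#' @return Integer band position(s).
#' @export
resolveBand <- function(bandSet, nominalNm, toleranceNm = 10) {
  centers <- bandCenters(bandSet)
  vapply(nominalNm, function(nm) {
    d <- abs(centers - nm)
    i <- which.min(d)  # which.min takes the first (shortest wavelength) on ties
    if (d[i] > toleranceNm)
      stop(sprintf("no band within %g nm of nominal %g nm on sensor '%s'",
                   toleranceNm, nm, sensorLabel(bandSet)))
    i
  }, integer(1))
}

#' Soil line for the weighted difference vegetation index
#'
#' The WDVI soil correction uses the ratio `C = RSoil870 / RSoil670` of bare
#' soil reflectance in the near-infrared and red bands.
#'
#' @param soilSpectra bare-soil reflectance: a numeric vector, a matrix (rows
#'   = spectra), or a \linkS4class{PlotSpectra}.
#' @param bandSet band set of the spectra (taken from `soilSpectra` when it
#'   is a PlotSpectra).
#' @param toleranceNm band matching tolerance.
#' @return The soil-line ratio `C` (dimensionless, positive).
#' @export
estimateSoilLine <- function(soilSpectra, bandSet = NULL, toleranceNm = 10) {
  if (is(soilSpectra, "PlotSpectra")) {
    bandSet <- bandSet(soilSpectra)
    soilSpectra <- reflectance(soilSpectra)
  }
  if (is.null(dim(soilSpectra))) soilSpectra <- matrix(soilSpectra, nrow = 1L)
  if (nrow(soilSpectra) == 0L) stop("no soil spectra supplied")
  ix <- resolveBand(bandSet, c(670, 870), toleranceNm)
  r670 <- soilSpectra[, ix[1]]
  r870 <- soilSpectra[, ix[2]]
  if (any(r670 <= 0)) stop("soil reflectance at 670 nm must be positive")
  mean(r870 / r670)
}

.nominalBands <- function(entry, label) {
  b <- entry$bands[[label]]
  if (is.null(b)) entry$bands$canonical else b
}

#' Compute a vegetation index from reflectance spectra
#'
#' Evaluates one of the 16 supported narrow-band indices on reflectance
#' values, matching each nominal band centre to the sensor's nearest band
#' (see [resolveBand()]). Per-sensor nominal centres are used for the
#' built-in "ground" and "uav" sensors. Undefined values (zero denominators,
#' negative discriminants) yield `NA` rather than an error.
#'
#' @param x reflectance: numeric vector (one spectrum), matrix (rows =
#'   spectra) or a \linkS4class{PlotSpectra}.
#' @param name index name, one of [indexNames()].
#' @param bandSet the \linkS4class{SpectralBandSet} (taken from `x` when it
#'   is a PlotSpectra).
#' @param soilLine soil-line ratio `C`, required for WDVI (see
#'   [estimateSoilLine()]).
#' @param toleranceNm band matching tolerance in nm.
#' @return Numeric vector of index values, one per spectrum.
#' @examples
#' bs <- uavBandSet()
#' r <- rep(0.1, nBands(bs))
#' r[resolveBand(bs, 670)] <- 0.05
#' r[resolveBand(bs, 800)] <- 0.45
#' computeIndex(r, "NDVI", bs)  # 0.8
#' @export
computeIndex <- function(x, name, bandSet = NULL, soilLine = NULL,
                         toleranceNm = 10) {
  if (is(x, "PlotSpectra")) {
    bandSet <- bandSet(x)
    x <- reflectance(x)
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  entry <- .indexRegistry[[name]]
  if (is.null(entry)) stop("unknown vegetation index: ", name)
  if (isTRUE(entry$needsSoil) && is.null(soilLine))
    stop(name, " requires a soil line (C = RSoil870/RSoil670)")
  nominal <- .nominalBands(entry, sensorLabel(bandSet))
  ix <- resolveBand(bandSet, nominal, toleranceNm)
  vals <- apply(x, 1L, function(r) {
    v <- r[ix]
    if (any(is.na(v))) return(NA_real_)
    out <- entry$fn(v, soilLine)
    if (!is.finite(out)) NA_real_ else out
  })
  as.numeric(vals)
}

#' Per-pixel vegetation index map of a hyperspectral cube
#'
#' Applies [computeIndex()] to every pixel of a cube. Pixels where the index
#' is undefined (masked input, zero denominator) are `NA` in the output.
#'
#' @param cube a \linkS4class{HyperCube}.
#' @inheritParams computeIndex
#' @return A single-band \linkS4class{HyperCube} holding the index map (its
#'   band set is a 1-band placeholder centred at 900 nm).
#' @export
indexMap <- function(cube, name, soilLine = NULL, toleranceNm = 10) {
  d <- dim(cube@values)
  flat <- matrix(cube@values, nrow = d[1] * d[2], ncol = d[3])
  vals <- computeIndex(flat, name, bandSet = bandSet(cube),
                       soilLine = soilLine, toleranceNm = toleranceNm)
  out <- array(vals, c(d[1], d[2], 1L))
  HyperCube(SpectralBandSet(sensorLabel(cube@bandSet), 900, 10), out,
            pixelSize = cube@pixelSize, origin = cube@origin)
}

#' Tabulate vegetation indices for a set of plot spectra
#'
#' Computes indices on the plot-aggregated spectrum of each
#' \linkS4class{PlotSpectra} (see [aggregatePlot()]), or on every individual
#' spectrum with `perSpectrum = TRUE`.
#'
#' @param psList list of \linkS4class{PlotSpectra}.
#' @param indices character vector of index names (default: all 16).
#' @param soilLine soil-line ratio for WDVI; WDVI is skipped with a warning
#'   when absent.
#' @param perSpectrum compute per individual spectrum instead of per plot.
#' @return A data.frame with plot_id, treatment, dap, sensor and one column
#'   per index.
#' @export
indexTable <- function(psList, indices = indexNames(), soilLine = NULL,
                       perSpectrum = FALSE) {
  if (is(psList, "PlotSpectra")) psList <- list(psList)
  if (is.null(soilLine) && "WDVI" %in% indices) {
    warning("no soil line supplied; dropping WDVI")
    indices <- setdiff(indices, "WDVI")
  }
  rows <- lapply(psList, function(ps) {
    x <- if (perSpectrum) ps else
      PlotSpectra(ps@plotId, ps@treatment, ps@dap, ps@bandSet,
                  aggregatePlot(ps))
    n <- nrow(reflectance(x))
    out <- data.frame(plot_id = rep(ps@plotId, n),
                      treatment = rep(ps@treatment, n),
                      dap = rep(ps@dap, n),
                      sensor = rep(sensorLabel(ps), n),
                      stringsAsFactors = FALSE)
    for (nm in indices) out[[nm]] <- computeIndex(x, nm, soilLine = soilLine)
    out
  })
  do.call(rbind, rows)
}
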