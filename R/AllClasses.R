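#' @import methods
NULL

## Central S4 containers shared by all pipeline stages.

#' Spectral band definition of a narrow-band sensor
#'
#' Ordered set of band centres (nm) with their full widths at half maximum.
#' Two built-in sensors are provided: a "uav" pushbroom imaging spectrometer
#' with a regular 10 nm grid between 450 and 910 nm, and a "ground" handheld
#' radiometer with 11 discrete bands between 490 and 870 nm.
#'
#' @slot sensorLabel character label ("uav", "ground" or custom).
#' @slot centers numeric, strictly increasing band centres in nm, all within
#'   400--1000 nm.
#' @slot fwhm numeric, positive FWHM per band in nm.
#' @export
setClass("SpectralBandSet",
  representation(sensorLabel = "character", centers = "numeric", fwhm = "numeric"))

setValidity("SpectralBandSet", function(object) {
  msg <- character()
  if (length(object@sensorLabel) != 1L) msg <- c(msg, "sensorLabel must be a single string")
  if (length(object@centers) < 1L) msg <- c(msg, "at least one band required")
  if (length(object@fwhm) != length(object@centers))
    msg <- c(msg, "fwhm and centers must have equal length")
  if (any(diff(object@centers) <= 0)) msg <- c(msg, "band centers must be strictly increasing")
  if (any(object@fwhm <= 0)) msg <- c(msg, "fwhm values must be positive")
  if (any(object@centers < 400 | object@centers > 1000))
    msg <- c(msg, "band centers must lie within [400, 1000] nm")
  if (length(msg)) msg else TRUE
})

#' Construct a SpectralBandSet
#'
#' @param sensorLabel sensor label.
#' @param centers band centres (nm), strictly increasing.
#' @param fwhm FWHM per band (nm); recycled if scalar.
#' @return A \linkS4class{SpectralBandSet}.
#' @export
SpectralBandSet <- function(sensorLabel, centers, fwhm = 10) {
  new("SpectralBandSet", sensorLabel = as.character(sensorLabel),
      centers = as.numeric(centers),
      fwhm = rep_len(as.numeric(fwhm), length(centers)))
}

#' Built-in band sets
#'
#' `uavBandSet()` is the UAV imaging spectrometer grid (450--910 nm, 10 nm
#' spacing and resolution). `groundBandSet()` is the handheld radiometer with
#' 11 bands between 490 and 870 nm (FWHM 7.3--13 nm).
#'
#' @return A \linkS4class{SpectralBandSet}.
#' @export
uavBandSet <- function()
  SpectralBandSet("uav", seq(450, 910, by = 10), fwhm = 10)

#' @rdname uavBandSet
#' @export
groundBandSet <- function()
  SpectralBandSet("ground",
    centers = c(490, 530, 550, 570, 670, 700, 710, 740, 750, 780, 870),
    fwhm    = c(8, 8, 7.3, 8, 11, 12, 12, 13, 13, 11, 12))

#' Reflectance observations of one plot on one date
#'
#' Holds one or more reflectance spectra measured over a single plot on a
#' single date by a single sensor. Reflectance is stored as fractions (0--1);
#' values above 1 are tolerated (specular or calibration artefacts) but
#' negative values are rejected.
#'
#' @slot plotId plot identifier.
#' @slot treatment treatment label ("non-mixed" or "mixed" in the reference
#'   design; free text allowed).
#' @slot dap integer days after planting (> 0).
#' @slot bandSet the \linkS4class{SpectralBandSet} shared by all spectra.
#' @slot reflectance numeric matrix, one row per spectrum, one column per band.
#' @slot weights per-spectrum aggregation weights.
#' @export
setClass("PlotSpectra",
  representation(plotId = "character", treatment = "character", dap = "integer",
                 bandSet = "SpectralBandSet", reflectance = "matrix",
                 weights = "numeric"))

setValidity("PlotSpectra", function(object) {
  msg <- character()
  if (ncol(object@reflectance) != length(object@bandSet@centers))
    msg <- c(msg, "reflectance columns must match the band set")
  if (nrow(object@reflectance) < 1L) msg <- c(msg, "at least one spectrum required")
  if (any(object@reflectance < 0, na.rm = TRUE)) msg <- c(msg, "reflectance must be >= 0")
  if (length(object@weights) != nrow(object@reflectance))
    msg <- c(msg, "one weight per spectrum required")
  if (any(object@weights < 0)) msg <- c(msg, "weights must be >= 0")
  if (length(object@dap) != 1L || is.na(object@dap) || object@dap <= 0L)
    msg <- c(msg, "dap must be a single positive integer")
  if (length(msg)) msg else TRUE
})

#' Construct a PlotSpectra object
#'
#' @param plotId,treatment,dap plot metadata.
#' @param bandSet a \linkS4class{SpectralBandSet}.
#' @param reflectance matrix (rows = spectra) or a single spectrum vector.
#' @param weights optional per-spectrum weights (default equal).
#' @return A \linkS4class{PlotSpectra}.
#' @export
PlotSpectra <- function(plotId, treatment, dap, bandSet, reflectance,
                        weights = NULL) {
  if (is.null(dim(reflectance))) reflectance <- matrix(reflectance, nrow = 1L)
  reflectance <- as.matrix(reflectance)
  if (is.null(weights)) weights <- rep(1, nrow(reflectance))
  new("PlotSpectra", plotId = as.character(plotId),
      treatment = as.character(treatment), dap = as.integer(dap),
      bandSet = bandSet, reflectance = reflectance, weights = as.numeric(weights))
}

#' Band-stacked reflectance raster
#'
#' A simple in-memory hyperspectral cube: a rows x cols x bands array with the
#' band set attached. Pixel (1,1) is the top-left corner; data are row-major
#' in the sense that rows index the raster lines. Coordinates of a pixel
#' centre are \code{origin + (col - 0.5, row - 0.5) * pixelSize} with x to the
#' right and y downward from the top-left origin.
#'
#' @slot bandSet the \linkS4class{SpectralBandSet}.
#' @slot values numeric array (rows, cols, bands); NA marks masked pixels.
#' @slot pixelSize pixel size in map units (m).
#' @slot origin numeric length-2 (x, y) of the top-left raster corner.
#' @export
setClass("HyperCube",
  representation(bandSet = "SpectralBandSet", values = "array",
                 pixelSize = "numeric", origin = "numeric"))

setValidity("HyperCube", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L) msg <- c(msg, "values must be a rows x cols x bands array")
  else if (d[3L] != length(object@bandSet@centers))
    msg <- c(msg, "third array dimension must match the band set")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(object@origin) != 2L) msg <- c(msg, "origin must be length 2")
  if (length(msg)) msg else TRUE
})

#' Construct a HyperCube
#'
#' @param bandSet a \linkS4class{SpectralBandSet}.
#' @param values rows x cols x bands array (a matrix is promoted to one band).
#' @param pixelSize pixel size (m).
#' @param origin top-left (x, y) map coordinates.
#' @return A \linkS4class{HyperCube}.
#' @export
HyperCube <- function(bandSet, values, pixelSize = 0.2, origin = c(0, 0)) {
  if (length(dim(values)) == 2L) values <- array(values, c(dim(values), 1L))
  new("HyperCube", bandSet = bandSet, values = values,
      pixelSize = as.numeric(pixelSize), origin = as.numeric(origin))
}

#' Gap fractions of one hemispherical photograph
#'
#' Gap fractions binned on the fixed angular grid used throughout: 15 zenith
#' rings of 2.5 degrees covering 0--37.5 degrees, and 72 azimuth cells of 5
#' degrees. Each cell carries the number of non-masked pixels it was computed
#' from; cells with zero count have undefined (NA) gap.
#'
#' @slot gap 15 x 72 matrix of gap fractions in [0, 1] (NA where count is 0).
#' @slot counts 15 x 72 matrix of non-negative pixel counts.
#' @export
setClass("GapFractionGrid",
  representation(gap = "matrix", counts = "matrix"))

setValidity("GapFractionGrid", function(object) {
  msg <- character()
  if (!all(dim(object@gap) == c(15L, 72L))) msg <- c(msg, "gap must be 15 x 72")
  if (!all(dim(object@counts) == c(15L, 72L))) msg <- c(msg, "counts must be 15 x 72")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
  pos <- object@counts > 0
  g <- object@gap[pos]
  if (any(is.na(g)) || any(g < 0 | g > 1))
    msg <- c(msg, "gap must lie in [0, 1] wherever counts > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a GapFractionGrid
#'
#' @param gap 15 x 72 matrix of per-cell gap fractions.
#' @param counts 15 x 72 matrix of per-cell non-masked pixel counts
#'   (default: 1 everywhere).
#' @return A \linkS4class{GapFractionGrid}.
#' @export
GapFractionGrid <- function(gap, counts = NULL) {
  gap <- as.matrix(gap)
  if (is.null(counts)) counts <- matrix(1, nrow(gap), ncol(gap))
  gap[counts == 0] <- NA_real_
  new("GapFractionGrid", gap = gap, counts = as.matrix(counts))
}

#' Zenith ring geometry of the gap-fraction grid
#'
#' @return `ringEdges()` gives the 16 ring edges (degrees); `ringCenters()`
#'   the 15 ring mid-points.
#' @export
ringEdges <- function() seq(0, 37.5, by = 2.5)

#' @rdname ringEdges
#' @export
ringCenters <- function() seq(1.25, 36.25, by = 2.5)

#' Canopy structural parameters retrieved from hemispherical photographs
#'
#' @slot lai clumping-adjusted plant area index (m2/m2, in [0, 10]).
#' @slot ala average leaf inclination angle (degrees, in [10, 80]).
#' @slot omega per-ring clumping index profile (15 values in (0, 1]).
#' @slot omegaEffAla effective leaf inclination angle (degrees) used for the
#'   saturated-gap replacement of the winning clumping profile.
#' @slot groundCover fraction of ground covered by vegetation (0--20 degree
#'   view cone), in [0, 1].
#' @slot cost value of the inversion cost function at the optimum.
#' @export
setClass("CanopyParams",
  representation(lai = "numeric", ala = "numeric", omega = "numeric",
                 omegaEffAla = "numeric", groundCover = "numeric",
                 cost = "numeric"))

setValidity("CanopyParams", function(object) {
  msg <- character()
  if (object@lai < 0 || object@lai > 10) msg <- c(msg, "lai must lie in [0, 10]")
  if (object@ala < 10 || object@ala > 80) msg <- c(msg, "ala must lie in [10, 80] degrees")
  om <- object@omega[!is.na(object@omega)]
  if (any(om <= 0 | om > 1)) msg <- c(msg, "omega values must lie in (0, 1]")
  if (object@groundCover < 0 || object@groundCover > 1)
    msg <- c(msg, "groundCover must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Look-up-table grid for the canopy inversion
#'
#' The default grid combines plant area index from 0 to 10 m2/m2 in steps of
#' 0.01 with average leaf inclination angles from 10 to 80 degrees in steps
#' of 2 degrees, and the same 2-degree grid of effective leaf inclination
#' angles for the saturated-gap replacement: 1001 x 36 x 36 candidate triples.
#'
#' @slot laiGrid candidate plant area index values.
#' @slot alaGrid candidate average leaf inclination angles (degrees).
#' @slot effAlaGrid candidate effective inclination angles (degrees).
#' @export
setClass("LutSpec",
  representation(laiGrid = "numeric", alaGrid = "numeric", effAlaGrid = "numeric"))

setValidity("LutSpec", function(object) {
  msg <- character()
  if (any(diff(object@laiGrid) <= 0) || any(object@laiGrid < 0) || any(object@laiGrid > 10))
    msg <- c(msg, "laiGrid must be increasing within [0, 10]")
  for (nm in c("alaGrid", "effAlaGrid")) {
    g <- slot(object, nm)
    if (any(diff(g) <= 0) || any(g < 10) || any(g > 80))
      msg <- c(msg, paste(nm, "must be increasing within [10, 80] degrees"))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LutSpec
#'
#' @param laiStep,alaStep grid steps for plant area index and inclination
#'   angles; the defaults give the full 1001 x 36 x 36 table.
#' @return A \linkS4class{LutSpec}.
#' @export
lutSpec <- function(laiStep = 0.01, alaStep = 2) {
  new("LutSpec", laiGrid = seq(0, 10, by = laiStep),
      alaGrid = seq(10, 80, by = alaStep),
      effAlaGrid = seq(10, 80, by = alaStep))
}

#' Linear VI-to-trait retrieval model
#'
#' An ordinary-least-squares regression of a crop trait on a vegetation
#' index, together with its cross-validated error and per-date mean errors.
#'
#' @slot trait,index,sensorLabel identifiers of the fitted combination.
#' @slot slope,intercept OLS coefficients (trait = intercept + slope * VI).
#' @slot r2 coefficient of determination of the full fit.
#' @slot rmseCv mean RMSE over repeated k-fold cross-validation, trait units.
#' @slot meanErrors named numeric: mean (observed - predicted) per date (DAP).
#' @slot level confidence level used for intervals.
#' @slot x,y the training data (kept for interval computation).
#' @export
setClass("RetrievalModel",
  representation(trait = "character", index = "character", sensorLabel = "character",
                 slope = "numeric", intercept = "numeric", r2 = "numeric",
                 rmseCv = "numeric", meanErrors = "numeric", level = "numeric",
                 x = "numeric", y = "numeric"))

setValidity("RetrievalModel", function(object) {
  msg <- character()
  if (!is.na(object@r2) && (object@r2 < 0 || object@r2 > 1))
    msg <- c(msg, "r2 must lie in [0, 1]")
  if (!is.na(object@rmseCv) && object@rmseCv < 0) msg <- c(msg, "rmseCv must be >= 0")
  if (length(msg)) msg else TRUE
})

## ---- accessors ----

#' Accessors for spectral containers
#'
#' @param object a package object.
#' @return `bandCenters`: numeric band centres (nm); `sensorLabel`: the sensor
#'   label; `nBands`: number of bands; `reflectance`: the reflectance matrix.
#' @export
setGeneric("bandCenters", function(object) standardGeneric("bandCenters"))
#' @rdname bandCenters
#' @export
setGeneric("sensorLabel", function(object) standardGeneric("sensorLabel"))
#' @rdname bandCenters
#' @export
setGeneric("nBands", function(object) standardGeneric("nBands"))
#' @rdname bandCenters
#' @export
setGeneric("reflectance", function(object) standardGeneric("reflectance"))
#' @rdname bandCenters
#' @export
setGeneric("bandSet", function(object) standardGeneric("bandSet"))

#' @rdname bandCenters
setMethod("bandCenters", "SpectralBandSet", function(object) object@centers)
#' @rdname bandCenters
setMethod("sensorLabel", "SpectralBandSet", function(object) object@sensorLabel)
#' @rdname bandCenters
setMethod("nBands", "SpectralBandSet", function(object) length(object@centers))
#' @rdname bandCenters
setMethod("bandCenters", "PlotSpectra", function(object) object@bandSet@centers)
#' @rdname bandCenters
setMethod("sensorLabel", "PlotSpectra", function(object) object@bandSet@sensorLabel)
#' @rdname bandCenters
setMethod("nBands", "PlotSpectra", function(object) length(object@bandSet@centers))
#' @rdname bandCenters
setMethod("reflectance", "PlotSpectra", function(object) object@reflectance)
#' @rdname bandCenters
setMethod("bandSet", "PlotSpectra", function(object) object@bandSet)
#' @rdname bandCenters
setMethod("bandCenters", "HyperCube", function(object) object@bandSet@centers)
#' @rdname bandCenters
setMethod("sensorLabel", "HyperCube", function(object) object@bandSet@sensorLabel)
#' @rdname bandCenters
setMethod("nBands", "HyperCube", function(object) length(object@bandSet@centers))
#' @rdname bandCenters
setMethod("bandSet", "HyperCube", function(object) object@bandSet)

#' Accessors for gap-fraction grids and canopy parameters
#'
#' @param object a \linkS4class{GapFractionGrid} or \linkS4class{CanopyParams}.
#' @return `gapFractions`/`cellCounts`: the 15 x 72 matrices;
#'   `canopyLai`/`canopyAla`/`clumping`: retrieved parameters.
#' @export
setGeneric("gapFractions", function(object) standardGeneric("gapFractions"))
#' @rdname gapFractions
#' @export
setGeneric("cellCounts", function(object) standardGeneric("cellCounts"))
#' @rdname gapFractions
#' @export
setGeneric("canopyLai", function(object) standardGeneric("canopyLai"))
#' @rdname gapFractions
#' @export
setGeneric("canopyAla", function(object) standardGeneric("canopyAla"))
#' @rdname gapFractions
#' @export
setGeneric("clumping", function(object) standardGeneric("clumping"))

#' @rdname gapFractions
setMethod("gapFractions", "GapFractionGrid", function(object) object@gap)
#' @rdname gapFractions
setMethod("cellCounts", "GapFractionGrid", function(object) object@counts)
#' @rdname gapFractions
setMethod("canopyLai", "CanopyParams", function(object) object@lai)
#' @rdname gapFractions
setMethod("canopyAla", "CanopyParams", function(object) object@ala)
#' @rdname gapFractions
setMethod("clumping", "CanopyParams", function(object) object@omega)

## ---- show methods ----

setMethod("show", "SpectralBandSet", function(object) {
  cat(sprintf("SpectralBandSet '%s': %d bands, %g-%g nm\n", object@sensorLabel,
              length(object@centers), min(object@centers), max(object@centers)))
})

setMethod("show", "PlotSpectra", function(object) {
  cat(sprintf("PlotSpectra plot '%s' (%s), %d DAP, sensor '%s': %d spectra x %d bands\n",
              object@plotId, object@treatment, object@dap,
              object@bandSet@sensorLabel, nrow(object@reflectance),
              ncol(object@reflectance)))
})

setMethod("show", "HyperCube", function(object) {
  d <- dim(object@values)
  cat(sprintf("HyperCube %d x %d pixels, %d bands ('%s'), pixel %g m, origin (%g, %g)\n",
              d[1], d[2], d[3], object@bandSet@sensorLabel, object@pixelSize,
              object@origin[1], object@origin[2]))
})

setMethod("show", "GapFractionGrid", function(object) {
  cat(sprintf("GapFractionGrid 15 rings x 72 azimuth cells; %d populated cells, mean gap %.3f\n",
              sum(object@counts > 0),
              stats::weighted.mean(object@gap, object@counts, na.rm = TRUE)))
})

setMethod("show", "CanopyParams", function(object) {
  cat(sprintf(
    "CanopyParams: PAI %.2f, ALA %g deg, mean clumping %.3f (eff. ALA %g deg), ground cover %.3f\n",
    object@lai, object@ala, mean(object@omega, na.rm = TRUE),
    object@omegaEffAla, object@groundCover))
})

setMethod("show", "RetrievalModel", function(object) {
  cat(sprintf("RetrievalModel %s ~ %s [%s]: slope %.4g, intercept %.4g, R2 %.3f, CV-RMSE %.4g\n",
              object@trait, object@index, object@sensorLabel, object@slope,
              object@intercept, object@r2, object@rmseCv))
})

setMethod("show", "LutSpec", function(object) {
  cat(sprintf("LutSpec: %d LAI x %d ALA x %d effective-ALA candidates\n",
              length(object@laiGrid), length(object@alaGrid), length(object@effAlaGrid)))
})
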