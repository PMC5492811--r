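## Synthetic-data generator: emulates the strip-plot field experiment the
## pipeline is designed for, so every stage can be exercised end to end.
## The spectral forward model is a deterministic parametric stand-in for a
## radiative-transfer model (documented in the methods vignette): it carries
## the qualitative chlorophyll/structure signatures the indices respond to,
## not absolute reflectance magnitudes.

# Run `expr` under a temporary RNG state seeded with `seed`.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-stage substream of a root seed (kept below 2^31).
.subSeed <- function(seed, stage) (seed * 1103L + stage * 7919L) %% 2147483629L

#' Configuration of the synthetic field experiment
#'
#' Bundles the design (generalized randomized blocks: 3 blocks x 2
#' treatments x 2 replicates = 12 plots), the acquisition schedule (5 dates,
#' 43--99 days after planting), the treatment effect ("mixed" plots lose
#' extra leaf area and chlorophyll on the last date, emulating late-blight
#' incidence), noise levels, the soil background spectrum and the two sensor
#' band sets.
#'
#' @param seed root seed; all generators derive per-stage substreams from it.
#' @param nBlocks number of blocks.
#' @param repsPerTreatment replicates of each treatment per block.
#' @param dapSchedule acquisition dates in days after planting.
#' @param laiDeclineMixed,chlDeclineMixed extra final-date decline for the
#'   "mixed" treatment (m2/m2 and ug/cm2).
#' @param spectralSd additive reflectance noise sd (fraction units).
#' @param traitSd named numeric: measurement noise sd for `leaf_chl`
#'   (ug/cm2) and `lai` (m2/m2).
#' @param rowConcentration factor (> 1) by which the row-centred ground
#'   footprints concentrate vegetation relative to the plot average.
#' @param nUavPixels UAV pixels retained per plot; ground sensors take 4
#'   footprints.
#' @param soilSpectrum function(wavelengthNm) giving soil reflectance.
#' @param uavBands,groundBands the two \linkS4class{SpectralBandSet}s.
#' @return A list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1,
                             nBlocks = 3,
                             repsPerTreatment = 2,
                             dapSchedule = c(43L, 62L, 75L, 84L, 99L),
                             laiDeclineMixed = 1.0,
                             chlDeclineMixed = 3.0,
                             spectralSd = 0.01,
                             traitSd = c(leaf_chl = 2.0, lai = 0.25),
                             rowConcentration = 1.3,
                             nUavPixels = 60,
                             soilSpectrum = defaultSoilSpectrum,
                             uavBands = uavBandSet(),
                             groundBands = groundBandSet()) {
  if (spectralSd < 0 || any(traitSd < 0)) stop("noise sd must be >= 0")
  if (rowConcentration <= 0) stop("rowConcentration must be positive")
  cfg <- list(seed = seed, nBlocks = nBlocks, repsPerTreatment = repsPerTreatment,
              dapSchedule = as.integer(dapSchedule),
              laiDeclineMixed = laiDeclineMixed, chlDeclineMixed = chlDeclineMixed,
              spectralSd = spectralSd, traitSd = traitSd,
              rowConcentration = rowConcentration, nUavPixels = nUavPixels,
              soilSpectrum = soilSpectrum, uavBands = uavBands,
              groundBands = groundBands)
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Default bare-soil reflectance spectrum
#'
#' A gently rising featureless spectrum typical of dry loamy soil.
#'
#' @param wavelengthNm wavelengths in nm.
#' @return Reflectance fractions.
#' @export
defaultSoilSpectrum <- function(wavelengthNm) 0.08 + 2e-4 * (wavelengthNm - 450)

# Expected (noise-free) trait trajectories.
.traitCurves <- function(dap, treatment, cfg) {
  span <- 43:99
  # leaf chlorophyll declines monotonically over the season
  chl <- 55 - 0.28 * (dap - 43)
  # lai rises to a mid-season plateau then declines
  rise <- 1 / (1 + exp(-(dap - 55) / 6))
  fall <- 1 / (1 + exp((dap - 93) / 4))
  lai <- 0.4 + 3.4 * rise * fall
  mixed <- treatment == "mixed"
  lastDate <- dap == max(cfg$dapSchedule)
  lai[mixed & lastDate] <- pmax(0, lai[mixed & lastDate] - cfg$laiDeclineMixed)
  chl[mixed & lastDate] <- pmax(0, chl[mixed & lastDate] - cfg$chlDeclineMixed)
  list(chl = chl, lai = lai)
}

#' Simulate the per-plot trait table
#'
#' Generates one record per plot and acquisition date. In expectation, leaf
#' chlorophyll declines monotonically over the season; leaf area index rises
#' to a mid-season plateau and declines afterwards, with an extra final-date
#' decline for "mixed" plots; ground cover is `1 - exp(-0.5 * lai)` (nadir
#' Poisson gap with spherical G, clipped to [0, 1]) computed before noise;
#' canopy chlorophyll is `leaf_chl * lai * 0.01`.
#'
#' @param cfg a [simulationConfig()].
#' @return Trait data.frame (see [readTraitTable()] for columns), plus a
#'   `block` column.
#' @export
simulateTraits <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  plots <- expand.grid(block = seq_len(cfg$nBlocks),
                       treatment = c("non-mixed", "mixed"),
                       rep = seq_len(cfg$repsPerTreatment),
                       stringsAsFactors = FALSE)
  plots$plot_id <- sprintf("B%d_%s_%d", plots$block,
                           ifelse(plots$treatment == "mixed", "M", "N"), plots$rep)
  grid <- merge(plots, data.frame(dap = cfg$dapSchedule), by = NULL)
  mu <- .traitCurves(grid$dap, grid$treatment, cfg)
  .withSeed(.subSeed(cfg$seed, 1L), {
    chl <- pmax(0, mu$chl + stats::rnorm(nrow(grid), 0, cfg$traitSd[["leaf_chl"]]))
    lai <- pmax(0, mu$lai + stats::rnorm(nrow(grid), 0, cfg$traitSd[["lai"]]))
  })
  data.frame(plot_id = grid$plot_id, block = grid$block,
             treatment = grid$treatment, dap = grid$dap,
             leaf_chl = chl, lai = lai,
             canopy_chl = chl * lai * 0.01,
             ground_cover = pmin(1, pmax(0, 1 - exp(-0.5 * lai))),
             stringsAsFactors = FALSE)
}

#' Parametric canopy reflectance forward model
#'
#' Deterministic closed-form spectrum of a fully vegetated target: a visible
#' baseline whose depth increases with leaf chlorophyll (Beer-type
#' `exp(-k * chl)` darkening), a green bump centred at 550 nm, a logistic
#' red-edge ramp centred at 720 nm, and a near-infrared plateau
#' `0.28 + 0.20 * (1 - exp(-0.6 * lai))` rising with leaf area:
#' \deqn{R(\lambda) = R_{vis}(\lambda)(1 - s(\lambda)) + R_{nir}s(\lambda)}
#' with `s` the logistic ramp. A stand-in for a radiative-transfer model:
#' shapes and ranks are realistic, absolute magnitudes are nominal.
#'
#' @param leafChl leaf chlorophyll content (ug/cm2, >= 0).
#' @param lai plant area index (>= 0).
#' @param bandSet \linkS4class{SpectralBandSet} to sample at, or a numeric
#'   vector of wavelengths (nm).
#' @return Reflectance fractions at the band centres.
#' @export
vegetationReflectance <- function(leafChl, lai, bandSet) {
  if (leafChl < 0 || lai < 0) stop("leafChl and lai must be >= 0")
  wl <- if (is(bandSet, "SpectralBandSet")) bandCenters(bandSet) else as.numeric(bandSet)
  rMin <- 0.04 + 0.26 * exp(-0.045 * leafChl)
  gBump <- (0.05 + 0.10 * exp(-0.02 * leafChl)) * exp(-((wl - 550) / 40)^2)
  rVis <- rMin + gBump
  rNir <- 0.28 + 0.20 * (1 - exp(-0.6 * lai))
  s <- 1 / (1 + exp(-(wl - 720) / 12))
  rVis * (1 - s) + rNir * s
}

#' Simulate reflectance observations for both sensors
#'
#' Every observation is a linear vegetation/soil mixture
#' `R = f * R_veg + (1 - f) * R_soil + noise` sampled on the sensor's own
#' band set. UAV observations are `nUavPixels` pixels per plot with
#' `f = ground_cover`; ground observations are 4 row-centred footprints with
#' `f = min(1, ground_cover * rowConcentration)`, emulating the preferential
#' over-the-row sampling of the handheld radiometer. Observation-level
#' variability comes from the additive spectral noise.
#'
#' @param traits trait table from [simulateTraits()].
#' @param cfg the [simulationConfig()].
#' @return List with elements `uav` and `ground`, each a list of
#'   \linkS4class{PlotSpectra} (one per plot x date).
#' @export
simulateTwoSensorSpectra <- function(traits, cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  out <- list(uav = list(), ground = list())
  .withSeed(.subSeed(cfg$seed, 2L), {
    for (r in seq_len(nrow(traits))) {
      tr <- traits[r, ]
      for (sensor in c("uav", "ground")) {
        bs <- if (sensor == "uav") cfg$uavBands else cfg$groundBands
        wl <- bandCenters(bs)
        rVeg <- vegetationReflectance(tr$leaf_chl, tr$lai, bs)
        rSoil <- cfg$soilSpectrum(wl)
        n <- if (sensor == "uav") cfg$nUavPixels else 4L
        f <- if (sensor == "uav") rep(tr$ground_cover, n)
             else rep(min(1, tr$ground_cover * cfg$rowConcentration), n)
        spec <- outer(f, rVeg) + outer(1 - f, rSoil)
        if (cfg$spectralSd > 0)
          spec <- spec + matrix(stats::rnorm(length(spec), 0, cfg$spectralSd),
                                nrow(spec))
        spec <- pmax(spec, 0)
        ps <- PlotSpectra(tr$plot_id, tr$treatment, tr$dap, bs, spec)
        out[[sensor]][[length(out[[sensor]]) + 1L]] <- ps
      }
    }
  })
  out
}

#' Simulate gap-fraction fields with known structure
#'
#' Forward model for the hemispherical-photograph inversion. Per zenith
#' ring, cell gap fractions follow a two-component mixture: a fraction `p`
#' of cells are full gaps (between-row holes, gap = 1) and the rest carry a
#' denser canopy with gap `exp(-k / (1 - p))`, where
#' `k = G(theta, chi) * lai / cos(theta)`. `p` is solved per ring so that
#' logarithmic gap averaging applied to the noise-free field returns the
#' target clumping index, while the count-weighted ring mean obeys
#' `P(theta) = exp(-G * omega * lai / cos(theta))`.
#'
#' @param lai true plant area index (>= 0).
#' @param alaDeg true average leaf inclination angle (degrees).
#' @param omegaTarget target clumping index in (0, 1].
#' @param nPhotos number of photographs to generate (default 4).
#' @param seed RNG seed for cell placement and noise.
#' @param noiseSd additive gap-fraction noise sd (default 0).
#' @param baseCount nominal per-cell pixel count.
#' @return List of `nPhotos` \linkS4class{GapFractionGrid}.
#' @export
simulateGapField <- function(lai, alaDeg, omegaTarget, nPhotos = 4, seed = 1,
                             noiseSd = 0, baseCount = 500) {
  if (omegaTarget <= 0 || omegaTarget > 1) stop("omegaTarget must lie in (0, 1]")
  if (lai < 0) stop("lai must be >= 0")
  th <- ringCenters()
  chi <- chiFromAla(alaDeg)
  k <- gFunction(th, chi) * lai / cos(th * pi / 180)
  nCells <- 72L * nPhotos
  ringGap <- matrix(1, 15L, nCells)   # rings x all cells (photos side by side)
  ringW <- matrix(baseCount, 15L, nCells)
  .withSeed(seed, {
    for (i in seq_len(15L)) {
      if (k[i] <= 0) next
      if (omegaTarget == 1) { ringGap[i, ] <- exp(-k[i]); next }
      froot <- function(p) log(p + (1 - p) * exp(-k[i] / (1 - p))) + omegaTarget * k[i]
      if (froot(1e-9) >= 0) { ringGap[i, ] <- exp(-k[i]); next }  # heterogeneity not needed
      p <- stats::uniroot(froot, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
      m <- max(1L, round(p * nCells))
      # cell weights chosen so the count-weighted full-gap fraction equals p
      # exactly; counts are real-valued weights here, which keeps the
      # noise-free field exactly consistent with the target clumping
      w1 <- p * nCells * baseCount / m
      w2 <- (1 - p) * nCells * baseCount / (nCells - m)
      q <- exp(-k[i] / (1 - p))
      holes <- sample.int(nCells, m)
      ringGap[i, ] <- q
      ringGap[i, holes] <- 1
      ringW[i, holes] <- w1
      ringW[i, -holes] <- w2
    }
    if (noiseSd > 0)
      ringGap[] <- pmin(1, pmax(0, ringGap + stats::rnorm(length(ringGap), 0, noiseSd)))
  })
  lapply(seq_len(nPhotos), function(j) {
    colIx <- ((j - 1L) * 72L + 1L):(j * 72L)
    GapFractionGrid(ringGap[, colIx], ringW[, colIx])
  })
}

#' Simulate a vegetation-index mosaic of a plot strip
#'
#' Fixture for the edge-based plot boundary extraction: a single-band raster
#' with rectangular plots at given index levels over a low-value soil
#' background, with additive Gaussian noise. The default layout is a
#' vertical strip of 3 m x 10 m plots separated by 5 m soil buffers, at
#' 0.2 m pixels.
#'
#' @param layout data.frame with columns `plot_id`, `x0`, `y0`, `width`,
#'   `height` (map units, origin at the raster top-left) and optionally
#'   `treatment`; see [defaultStripLayout()].
#' @param viLevels per-plot index values (recycled).
#' @param soilLevel background value.
#' @param noiseSd additive noise sd.
#' @param seed RNG seed.
#' @param pixelSize raster resolution (m).
#' @param marginM soil margin around the layout extent (m).
#' @return A single-band \linkS4class{HyperCube}.
#' @export
simulateMosaic <- function(layout = defaultStripLayout(), viLevels = 0.6,
                           soilLevel = 0.1, noiseSd = 0.02, seed = 1,
                           pixelSize = 0.2, marginM = 2) {
  viLevels <- rep_len(viLevels, nrow(layout))
  x1 <- layout$x0 + layout$width; y1 <- layout$y0 + layout$height
  for (a in seq_len(nrow(layout))) for (b in seq_len(nrow(layout))) {
    if (a < b && layout$x0[a] < x1[b] && layout$x0[b] < x1[a] &&
        layout$y0[a] < y1[b] && layout$y0[b] < y1[a])
      stop("overlapping plots in layout: ", layout$plot_id[a], " / ", layout$plot_id[b])
  }
  wM <- max(x1) + marginM; hM <- max(y1) + marginM
  nc <- ceiling(wM / pixelSize); nr <- ceiling(hM / pixelSize)
  img <- matrix(soilLevel, nr, nc)
  xc <- (seq_len(nc) - 0.5) * pixelSize
  yc <- (seq_len(nr) - 0.5) * pixelSize
  for (a in seq_len(nrow(layout))) {
    rows <- which(yc >= layout$y0[a] & yc < y1[a])
    cols <- which(xc >= layout$x0[a] & xc < x1[a])
    img[rows, cols] <- viLevels[a]
  }
  .withSeed(seed, {
    if (noiseSd > 0) img <- img + matrix(stats::rnorm(length(img), 0, noiseSd), nr)
  })
  HyperCube(SpectralBandSet("vi", 900, 10), img, pixelSize = pixelSize,
            origin = c(0, 0))
}

#' Default strip layout of the synthetic experiment
#'
#' Twelve 3 m x 10 m plots stacked in one vertical strip with 5 m buffers,
#' 2 m in from the left raster edge.
#'
#' @param nPlots number of plots.
#' @return Layout data.frame for [simulateMosaic()].
#' @export
defaultStripLayout <- function(nPlots = 12) {
  data.frame(plot_id = sprintf("P%02d", seq_len(nPlots)),
             x0 = 2, y0 = 2 + (seq_len(nPlots) - 1) * 15,
             width = 3, height = 10, stringsAsFactors = FALSE)
}
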