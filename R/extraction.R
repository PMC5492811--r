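## Plot boundary recovery from vegetation-index maps and per-plot spectra
## extraction. Canny parameters follow the reference workflow: Gaussian
## sigma 0.5, per-segment high threshold equal to the mean gradient
## magnitude of the segment and low threshold 40% of it, with the image
## split into four segments along the strip axis.

# Sobel gradient magnitude and quantized direction of a matrix.
.sobel <- function(x) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- EBImage::filter2(EBImage::Image(x), kx, boundary = "replicate")
  gy <- EBImage::filter2(EBImage::Image(x), t(kx), boundary = "replicate")
  list(gx = EBImage::imageData(gx), gy = EBImage::imageData(gy))
}

# Per-segment hysteresis thresholds: high = mean gradient magnitude of the
# (smoothed) segment, low = 40% of the high threshold.
.cannyThresholds <- function(seg, sigma = 0.5) {
  sm <- if (sigma > 0)
    EBImage::imageData(EBImage::gblur(EBImage::Image(seg), sigma = sigma,
                                      boundary = "replicate"))
  else seg
  g <- .sobel(sm)
  mag <- sqrt(g$gx^2 + g$gy^2)
  hi <- mean(mag)
  list(hi = hi, lo = 0.4 * hi, mag = mag, gx = g$gx, gy = g$gy)
}

# Canny on one segment: returns logical edge mask.
.cannySegment <- function(seg, sigma) {
  if (min(dim(seg)) < 3L) return(matrix(FALSE, nrow(seg), ncol(seg)))
  thr <- .cannyThresholds(seg, sigma)
  mag <- thr$mag
  g <- list(gx = thr$gx, gy = thr$gy)
  hi <- thr$hi
  lo <- thr$lo
  # a numerically flat segment has no edges (guard against fp dust from the
  # separable blur on constant regions)
  if (hi <= 1e-10 * (abs(mean(seg)) + 1))
    return(matrix(FALSE, nrow(seg), ncol(seg)))
  # non-maximum suppression along the quantized gradient direction
  ang <- atan2(g$gy, g$gx)
  sector <- (round(ang / (pi / 4)) %% 4)  # 0: x, 1: diag, 2: y, 3: anti-diag
  nr <- nrow(mag); nc <- ncol(mag)
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mag
  nb <- function(dr, dc) pad[2:(nr + 1) + dr, 2:(nc + 1) + dc]
  # gx is the gradient across columns, gy across rows
  keep <- (sector == 0 & mag >= nb(0, -1) & mag >= nb(0, 1)) |
          (sector == 2 & mag >= nb(-1, 0) & mag >= nb(1, 0)) |
          (sector == 1 & mag >= nb(-1, -1) & mag >= nb(1, 1)) |
          (sector == 3 & mag >= nb(-1, 1) & mag >= nb(1, -1))
  weak <- keep & (mag >= lo)
  strong <- keep & (mag >= hi)
  if (!any(strong)) return(matrix(FALSE, nr, nc))
  # hysteresis: keep weak components that contain a strong pixel
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(weak * 1)))
  keepLabs <- unique(lab[strong])
  keepLabs <- keepLabs[keepLabs > 0]
  weak & (lab %in% keepLabs)
}

#' Canny edge detection on a vegetation-index map
#'
#' The map is divided into `nSegments` horizontal bands (along the strip
#' axis) and Canny edges are computed per segment with segment-specific
#' thresholds: the high threshold is the mean gradient magnitude of the
#' segment and the low threshold 40% of it. Segment results are mosaicked
#' back together.
#'
#' @param viMap numeric matrix or a single-band \linkS4class{HyperCube}.
#' @param sigma Gaussian smoothing width in pixels (default 0.5).
#' @param nSegments number of processing segments (default 4).
#' @return Logical matrix: TRUE at edge pixels.
#' @export
detectEdges <- function(viMap, sigma = 0.5, nSegments = 4) {
  if (is(viMap, "HyperCube")) viMap <- viMap@values[, , 1]
  if (length(dim(viMap)) != 2L) stop("viMap must be a 2-D map")
  viMap[is.na(viMap)] <- 0
  nr <- nrow(viMap)
  bounds <- round(seq(0, nr, length.out = nSegments + 1))
  out <- matrix(FALSE, nr, ncol(viMap))
  for (s in seq_len(nSegments)) {
    rows <- (bounds[s] + 1):bounds[s + 1]
    if (length(rows) < 1) next
    out[rows, ] <- .cannySegment(viMap[rows, , drop = FALSE], sigma)
  }
  out
}

#' Snap nominal plot rectangles to detected edges
#'
#' Refines the across-strip (left/right column) sides of each nominal plot
#' rectangle to the nearest strong edge column within a search window, while
#' the along-strip sides keep their nominal position (the reference workflow
#' trusts the field-measured positions along the flight direction). If no
#' edge evidence falls inside the window the nominal side is kept and a
#' warning is emitted.
#'
#' @param edgeMask logical matrix from [detectEdges()].
#' @param layout nominal layout data.frame (`plot_id`, `x0`, `y0`, `width`,
#'   `height` in map units).
#' @param pixelSize raster resolution (m).
#' @param origin raster top-left (x, y).
#' @param searchPx half-width of the snap window in pixels.
#' @param minSupport minimum fraction of the plot's rows that must carry
#'   edge pixels in the chosen column.
#' @return Layout data.frame with refined `x0`/`width` (map units) plus
#'   `snapped_left`/`snapped_right` logical columns.
#' @export
edgesToPlots <- function(edgeMask, layout, pixelSize = 0.2, origin = c(0, 0),
                         searchPx = 3, minSupport = 0.3) {
  out <- layout
  out$snapped_left <- out$snapped_right <- FALSE
  nr <- nrow(edgeMask); nc <- ncol(edgeMask)
  for (a in seq_len(nrow(layout))) {
    rows <- which((seq_len(nr) - 0.5) * pixelSize + origin[2] >= layout$y0[a] &
                  (seq_len(nr) - 0.5) * pixelSize + origin[2] < layout$y0[a] + layout$height[a])
    if (!length(rows)) next
    snap <- function(xMap) {
      colNominal <- (xMap - origin[1]) / pixelSize  # boundary in pixel units
      cand <- max(1, floor(colNominal - searchPx + 0.5)):min(nc, ceiling(colNominal + searchPx + 0.5))
      support <- colSums(edgeMask[rows, cand, drop = FALSE])
      if (!length(support) || max(support) < minSupport * length(rows)) return(NULL)
      bestCols <- cand[support == max(support)]
      best <- bestCols[which.min(abs(bestCols - colNominal))]
      # an edge pixel sits on a raster column; the boundary passes next to it,
      # keep sub-pixel nominal offset convention: boundary at the pixel edge
      # closest to nominal
      edgeLeft <- (best - 1) * pixelSize + origin[1]
      edgeRight <- best * pixelSize + origin[1]
      if (abs(edgeLeft - xMap) <= abs(edgeRight - xMap)) edgeLeft else edgeRight
    }
    xl <- snap(layout$x0[a])
    xr <- snap(layout$x0[a] + layout$width[a])
    if (is.null(xl)) warning("no edge found for left side of plot ", layout$plot_id[a],
                             "; keeping nominal")
    else { out$x0[a] <- xl; out$snapped_left[a] <- TRUE }
    if (is.null(xr)) warning("no edge found for right side of plot ", layout$plot_id[a],
                             "; keeping nominal")
    else { out$width[a] <- xr - out$x0[a]; out$snapped_right[a] <- TRUE }
  }
  out
}

#' Extract the spectra of all pixels inside a rectangle
#'
#' Pixel-centre containment with half-open upper edges: a pixel belongs to
#' the rectangle when `x0 <= xc < x0 + width` and `y0 <= yc < y0 + height`,
#' which makes pixel counts deterministic and plots disjoint when their
#' rectangles are.
#'
#' @param cube a \linkS4class{HyperCube}.
#' @param rect one-row data.frame (or list) with `plot_id`, `x0`, `y0`,
#'   `width`, `height` and optionally `treatment`, in map units.
#' @param dap,treatment metadata for the returned object (treatment falls
#'   back to the rect's column, then to "unknown").
#' @return A \linkS4class{PlotSpectra} with one spectrum per pixel.
#' @export
extractPolygonSpectra <- function(cube, rect, dap = 1L, treatment = NULL) {
  if (rect$width <= 0 || rect$height <= 0) stop("degenerate zero-area polygon")
  d <- dim(cube@values)
  xc <- cube@origin[1] + (seq_len(d[2]) - 0.5) * cube@pixelSize
  yc <- cube@origin[2] + (seq_len(d[1]) - 0.5) * cube@pixelSize
  cols <- which(xc >= rect$x0 & xc < rect$x0 + rect$width)
  rows <- which(yc >= rect$y0 & yc < rect$y0 + rect$height)
  if (!length(rows) || !length(cols)) stop("polygon contains no pixel centers")
  sub <- cube@values[rows, cols, , drop = FALSE]
  mat <- matrix(sub, nrow = length(rows) * length(cols), ncol = d[3])
  if (is.null(treatment))
    treatment <- if (!is.null(rect$treatment)) rect$treatment else "unknown"
  PlotSpectra(rect$plot_id, treatment, dap, bandSet(cube), mat)
}
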