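## Readers/writers for the plain-file interfaces: spectra tables (CSV),
## band-stacked cubes (ENVI-dialect header + flat binary), trait tables and
## gap-fraction grids (CSV).

#' Aggregate the spectra of a plot to a single spectrum
#'
#' Band-wise weighted arithmetic mean of all member spectra, using the
#' per-spectrum weights stored in the object. Missing values are excluded
#' band-wise.
#'
#' @param ps a \linkS4class{PlotSpectra}.
#' @return Numeric vector: the plot-level spectrum.
#' @export
aggregatePlot <- function(ps) {
  stopifnot(is(ps, "PlotSpectra"))
  r <- reflectance(ps)
  if (nrow(r) == 0L) stop("empty PlotSpectra")
  w <- ps@weights
  if (sum(w) <= 0) stop("weights sum to zero")
  apply(r, 2L, function(col) {
    ok <- !is.na(col)
    if (!any(ok)) return(NA_real_)
    sum(col[ok] * w[ok]) / sum(w[ok])
  })
}

#' Read and write spectra tables
#'
#' The table format is CSV with columns `plot_id`, `treatment`, `dap`,
#' `sensor`, an optional `weight`, then one column per band named by its
#' integer centre in nm. Reflectance is stored as fractions. On reading,
#' band columns must match the supplied band set centres exactly; rows are
#' grouped into one \linkS4class{PlotSpectra} per (plot_id, dap, sensor).
#'
#' @param path CSV file path.
#' @param bandSet expected \linkS4class{SpectralBandSet}.
#' @return `readSpectraTable`: list of \linkS4class{PlotSpectra};
#'   `writeSpectraTable`: invisibly, the path written.
#' @export
readSpectraTable <- function(path, bandSet) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("plot_id", "treatment", "dap", "sensor")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  bandCols <- setdiff(names(df), c(need, "weight"))
  got <- suppressWarnings(as.numeric(bandCols))
  if (any(is.na(got))) stop("non-numeric band column name(s): ",
                            paste(bandCols[is.na(got)], collapse = ", "))
  want <- bandCenters(bandSet)
  if (length(got) != length(want) || any(sort(got) != want))
    stop("band columns do not match the band set centers (expected ",
         paste(want, collapse = ", "), ")")
  ord <- order(got)
  bandCols <- bandCols[ord]
  key <- interaction(df$plot_id, df$dap, df$sensor, drop = TRUE)
  lapply(split(seq_len(nrow(df)), key), function(ix) {
    sub <- df[ix, , drop = FALSE]
    w <- if ("weight" %in% names(sub)) sub$weight else rep(1, nrow(sub))
    PlotSpectra(sub$plot_id[1], sub$treatment[1], sub$dap[1], bandSet,
                as.matrix(sub[, bandCols, drop = FALSE]), weights = w)
  })
}

#' @rdname readSpectraTable
#' @param psList list of \linkS4class{PlotSpectra} sharing one band set.
#' @export
writeSpectraTable <- function(psList, path) {
  if (is(psList, "PlotSpectra")) psList <- list(psList)
  rows <- lapply(psList, function(ps) {
    r <- reflectance(ps)
    out <- data.frame(plot_id = rep(ps@plotId, nrow(r)),
                      treatment = rep(ps@treatment, nrow(r)),
                      dap = rep(ps@dap, nrow(r)),
                      sensor = rep(sensorLabel(ps), nrow(r)),
                      weight = ps@weights, stringsAsFactors = FALSE)
    colnames(r) <- as.character(bandCenters(ps))
    cbind(out, as.data.frame(r, optional = TRUE))
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write band-stacked rasters (ENVI dialect)
#'
#' Cubes are stored as a flat band-sequential (BSQ) little-endian double
#' binary file plus a text header `<path>.hdr` in the ENVI dialect carrying
#' `samples`, `lines`, `bands`, `wavelength = {...}` and the pixel size and
#' origin. Reading a header without wavelength metadata is an error.
#'
#' @param path path of the binary file (header is `<path>.hdr`).
#' @return `readCube`: a \linkS4class{HyperCube}; `writeCube`: invisibly,
#'   the path written.
#' @export
readCube <- function(path) {
  hdrPath <- paste0(path, ".hdr")
  if (!file.exists(hdrPath)) stop("header not found: ", hdrPath)
  hdr <- paste(readLines(hdrPath, warn = FALSE), collapse = "\n")
  getNum <- function(key) {
    m <- regmatches(hdr, regexec(paste0("(?m)^", key, "\\s*=\\s*([-0-9.eE+]+)"), hdr, perl = TRUE))[[1]]
    if (length(m) < 2) stop("header field missing: ", key)
    as.numeric(m[2])
  }
  getList <- function(key) {
    m <- regmatches(hdr, regexec(paste0(key, "\\s*=\\s*\\{([^}]*)\\}"), hdr))[[1]]
    if (length(m) < 2) return(NULL)
    as.numeric(strsplit(m[2], ",")[[1]])
  }
  samples <- getNum("samples"); lines <- getNum("lines"); bands <- getNum("bands")
  wl <- getList("wavelength")
  if (is.null(wl)) stop("no wavelength metadata in header")
  if (length(wl) != bands) stop("wavelength count does not match band count")
  fw <- getList("fwhm")
  if (is.null(fw)) fw <- rep(10, bands)
  ps <- tryCatch(getNum("pixel size"), error = function(e) 1)
  orig <- getList("origin")
  if (is.null(orig)) orig <- c(0, 0)
  n <- samples * lines * bands
  raw <- readBin(path, "double", n = n, size = 8, endian = "little")
  if (length(raw) != n) stop("binary file shorter than header promises")
  # BSQ on disk, sample-fastest; in memory rows = lines, cols = samples
  arr <- aperm(array(raw, c(samples, lines, bands)), c(2, 1, 3))
  sentinel <- -9999
  arr[arr == sentinel] <- NA_real_
  HyperCube(SpectralBandSet("custom", wl, fw), arr, pixelSize = ps, origin = orig)
}

#' @rdname readCube
#' @param cube a \linkS4class{HyperCube}.
#' @export
writeCube <- function(cube, path) {
  d <- dim(cube@values)
  vals <- cube@values
  vals[is.na(vals)] <- -9999
  con <- file(path, "wb")
  writeBin(as.vector(aperm(vals, c(2, 1, 3))), con, size = 8, endian = "little")
  close(con)
  hdr <- c("ENVI",
           paste0("samples = ", d[2]),
           paste0("lines = ", d[1]),
           paste0("bands = ", d[3]),
           "header offset = 0", "file type = ENVI Standard",
           "data type = 5", "interleave = bsq", "byte order = 0",
           paste0("pixel size = ", cube@pixelSize),
           paste0("origin = {", paste(cube@origin, collapse = ", "), "}"),
           paste0("wavelength = {", paste(bandCenters(cube), collapse = ", "), "}"),
           paste0("fwhm = {", paste(cube@bandSet@fwhm, collapse = ", "), "}"))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

#' Read and write trait tables
#'
#' CSV with columns `plot_id`, `treatment`, `dap`, `leaf_chl` (ug/cm2),
#' `lai` (m2/m2), `canopy_chl` (g/m2) and `ground_cover` (fraction).
#' Row consistency `canopy_chl = leaf_chl * lai * 0.01` is checked where all
#' three are present.
#'
#' @param path CSV file path.
#' @param check verify internal consistency (default TRUE).
#' @return A data.frame of trait records.
#' @export
readTraitTable <- function(path, check = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "dap", "leaf_chl", "lai", "canopy_chl", "ground_cover")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (check) validateTraitTable(df)
  df
}

#' @rdname readTraitTable
#' @param traits a trait data.frame.
#' @export
writeTraitTable <- function(traits, path) {
  utils::write.csv(traits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a trait table
#'
#' Checks the trait-record invariants: `lai >= 0`, `ground_cover` in [0, 1],
#' and `canopy_chl` consistent with `leaf_chl * lai * 0.01` (tolerance 1e-6
#' relative) where all three are set.
#'
#' @param traits a trait data.frame.
#' @return Invisibly `TRUE`; errors describe the first violated invariant.
#' @export
validateTraitTable <- function(traits) {
  if (any(traits$lai < 0, na.rm = TRUE)) stop("lai must be >= 0")
  if (any(traits$ground_cover < 0 | traits$ground_cover > 1, na.rm = TRUE))
    stop("ground_cover must lie in [0, 1]")
  ok <- !is.na(traits$leaf_chl) & !is.na(traits$lai) & !is.na(traits$canopy_chl)
  if (any(ok)) {
    expct <- traits$leaf_chl[ok] * traits$lai[ok] * 0.01
    if (any(abs(traits$canopy_chl[ok] - expct) > 1e-6 * pmax(1, abs(expct))))
      stop("canopy_chl inconsistent with leaf_chl * lai * 0.01")
  }
  invisible(TRUE)
}

#' Read and write gap-fraction grids
#'
#' CSV with columns `photo`, `ring` (1--15), `azimuth` (1--72), `gap`,
#' `count`; one file holds all photographs of one plot. Cells absent from
#' the file have count 0.
#'
#' @param path CSV file path.
#' @return `readGapGrids`: list of \linkS4class{GapFractionGrid} (one per
#'   photo); `writeGapGrids`: invisibly, the path.
#' @export
readGapGrids <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("photo", "ring", "azimuth", "gap", "count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  lapply(split(df, df$photo), function(sub) {
    gap <- matrix(NA_real_, 15, 72)
    cnt <- matrix(0, 15, 72)
    ii <- cbind(sub$ring, sub$azimuth)
    gap[ii] <- sub$gap
    cnt[ii] <- sub$count
    GapFractionGrid(gap, cnt)
  })
}

#' @rdname readGapGrids
#' @param grids list of \linkS4class{GapFractionGrid}.
#' @export
writeGapGrids <- function(grids, path) {
  if (is(grids, "GapFractionGrid")) grids <- list(grids)
  rows <- lapply(seq_along(grids), function(j) {
    g <- grids[[j]]
    pos <- which(cellCounts(g) > 0, arr.ind = TRUE)
    data.frame(photo = j, ring = pos[, 1], azimuth = pos[, 2],
               gap = gapFractions(g)[pos], count = cellCounts(g)[pos])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert between reflectance fractions and percent
#'
#' Reflectance is stored internally as fractions (0--1); these helpers
#' convert at the I/O boundary for data sources using percent.
#'
#' @param x reflectance values.
#' @return The converted values.
#' @export
percentToFraction <- function(x) x / 100

#' @rdname percentToFraction
#' @export
fractionToPercent <- function(x) x * 100
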