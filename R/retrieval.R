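## VI-to-trait retrieval: SPAD conversion, canopy chlorophyll, OLS fits,
## repeated k-fold cross-validated RMSE, confidence/prediction intervals and
## per-date mean errors.

#' Convert SPAD readings to leaf chlorophyll content
#'
#' Applies an exponential calibration `a * exp(b * SPAD)` (the common form
#' of published SPAD-to-chlorophyll equations). Coefficients are supplied by
#' the caller — calibrations are crop- and condition-specific and no single
#' pair is hard-coded. The mapping must be strictly increasing over SPAD
#' 0--60, which requires `a > 0` and `b > 0`.
#'
#' @param spad SPAD meter value(s), >= 0.
#' @param calib list with elements `a` and `b`.
#' @return Leaf chlorophyll content in ug/cm2.
#' @export
spadToChl <- function(spad, calib) {
  if (any(spad < 0)) stop("spad must be >= 0")
  if (is.null(calib$a) || is.null(calib$b)) stop("calib must supply a and b")
  if (calib$a <= 0 || calib$b <= 0)
    stop("calibration must be strictly increasing over SPAD 0-60 (a > 0, b > 0)")
  calib$a * exp(calib$b * spad)
}

#' Canopy chlorophyll content
#'
#' Leaf chlorophyll (ug/cm2) times leaf area index, converted to g/m2
#' (1 ug/cm2 = 0.01 g/m2).
#'
#' @param leafChl leaf chlorophyll content (ug/cm2, >= 0).
#' @param lai leaf area index (>= 0).
#' @return Canopy chlorophyll in g/m2.
#' @export
canopyChlorophyll <- function(leafChl, lai) {
  if (any(leafChl < 0) || any(lai < 0)) stop("inputs must be >= 0")
  leafChl * lai * 0.01
}

#' Simple OLS fit of a trait on a vegetation index
#'
#' @param x predictor (VI values), `n >= 3`, non-zero variance.
#' @param y response (trait values).
#' @return List with `slope`, `intercept` and `r2` (coefficient of
#'   determination of the full fit; 0 when `y` is constant).
#' @export
fitOls <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::var(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ssTot
  list(slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]),
       r2 = max(0, min(1, r2)))
}

#' Cross-validated RMSE of a simple linear retrieval
#'
#' Repeated k-fold cross-validation: for each repeat the observations are
#' randomly split into `k` near-equal folds; the model is refit on k-1 folds
#' and squared prediction errors are pooled over the held-out folds before
#' taking the root; the final value is the mean RMSE over repeats.
#'
#' @param x,y predictor and response.
#' @param k number of folds (default 10).
#' @param repeats number of repetitions (default 100).
#' @param seed RNG root seed; repeat `r` is seeded with `seed + r`.
#' @return Mean cross-validated RMSE.
#' @export
cvRmse <- function(x, y, k = 10, repeats = 100, seed = 1) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < k) stop("need at least k observations")
  rmse <- numeric(repeats)
  for (r in seq_len(repeats)) {
    folds <- .withSeed(seed + r, sample(rep_len(seq_len(k), n)))
    sq <- numeric(n)
    for (f in seq_len(k)) {
      test <- folds == f
      xt <- x[!test]; yt <- y[!test]
      mx <- mean(xt); my <- mean(yt)
      b <- sum((xt - mx) * (yt - my)) / sum((xt - mx)^2)
      a <- my - b * mx
      sq[test] <- (y[test] - (a + b * x[test]))^2
    }
    rmse[r] <- sqrt(mean(sq))
  }
  mean(rmse)
}

#' Fit a retrieval model with full diagnostics
#'
#' Combines [fitOls()], [cvRmse()] and [meanErrorByDate()] into a
#' \linkS4class{RetrievalModel}.
#'
#' @param x,y predictor (VI) and response (trait).
#' @param dap days-after-planting of each observation (for per-date errors);
#'   optional.
#' @param trait,index,sensor identifiers stored in the model.
#' @param k,repeats,seed cross-validation settings.
#' @param level confidence level for intervals.
#' @return A \linkS4class{RetrievalModel}.
#' @export
fitRetrieval <- function(x, y, dap = NULL, trait = "trait", index = "index",
                         sensor = "sensor", k = 10, repeats = 100, seed = 1,
                         level = 0.95) {
  fit <- fitOls(x, y)
  rm <- new("RetrievalModel", trait = trait, index = index, sensorLabel = sensor,
            slope = fit$slope, intercept = fit$intercept, r2 = fit$r2,
            rmseCv = cvRmse(x, y, k = k, repeats = repeats, seed = seed),
            meanErrors = numeric(0), level = level,
            x = as.numeric(x), y = as.numeric(y))
  if (!is.null(dap)) rm@meanErrors <- meanErrorByDate(rm, x, y, dap)
  rm
}

#' Predict from a retrieval model
#'
#' @param model a \linkS4class{RetrievalModel}.
#' @param x new VI values.
#' @return Predicted trait values.
#' @export
predictTrait <- function(model, x) model@intercept + model@slope * x

#' Confidence and prediction bands of a retrieval model
#'
#' Standard OLS intervals with t quantiles: the confidence band for the mean
#' response uses standard error `s * sqrt(1/n + (x - xbar)^2 / Sxx)`; the
#' prediction band for a new observation adds the residual variance.
#'
#' @param model a \linkS4class{RetrievalModel}.
#' @param xGrid VI values at which to evaluate the bands.
#' @param level confidence level in (0, 1) (default: the model's).
#' @return data.frame with `x`, `fit`, `conf_lo`, `conf_hi`, `pred_lo`,
#'   `pred_hi`.
#' @export
intervals <- function(model, xGrid, level = model@level) {
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  x <- model@x; y <- model@y
  n <- length(x)
  res <- y - predictTrait(model, x)
  s <- sqrt(sum(res^2) / (n - 2))
  sxx <- sum((x - mean(x))^2)
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 2)
  fit <- predictTrait(model, xGrid)
  seConf <- s * sqrt(1 / n + (xGrid - mean(x))^2 / sxx)
  sePred <- s * sqrt(1 + 1 / n + (xGrid - mean(x))^2 / sxx)
  data.frame(x = xGrid, fit = fit,
             conf_lo = fit - tq * seConf, conf_hi = fit + tq * seConf,
             pred_lo = fit - tq * sePred, pred_hi = fit + tq * sePred)
}

#' Mean prediction error per acquisition date
#'
#' Mean of (observed - predicted) within each date; positive values mean the
#' model underestimates on that date.
#'
#' @param model a \linkS4class{RetrievalModel}.
#' @param x,y observations.
#' @param dap date (days after planting) of each observation.
#' @return Named numeric vector, one mean error per date.
#' @export
meanErrorByDate <- function(model, x, y, dap) {
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) stop("no observations")
  res <- y[ok] - predictTrait(model, x[ok])
  out <- tapply(res, dap[ok], mean)
  stats::setNames(as.numeric(out), names(out))
}

#' Fit all index x trait combinations
#'
#' Joins a vegetation-index table (see [indexTable()]) with a trait table on
#' (plot_id, dap) and fits one retrieval model per index, trait and sensor.
#' The best (lowest cross-validated RMSE) index per trait within each sensor
#' is flagged.
#'
#' @param viTab index table with plot_id, dap, sensor and index columns.
#' @param traits trait table.
#' @param indices,traitNames subsets to fit (defaults: all index columns /
#'   the four standard traits present).
#' @param k,repeats,seed cross-validation settings.
#' @return data.frame with one row per combination: sensor, trait, index,
#'   r2, rmse_cv, best.
#' @export
modelMatrix <- function(viTab, traits,
                        indices = intersect(indexNames(), names(viTab)),
                        traitNames = intersect(c("leaf_chl", "lai", "canopy_chl",
                                                 "ground_cover"), names(traits)),
                        k = 10, repeats = 100, seed = 1) {
  joined <- merge(viTab, traits[, c("plot_id", "dap", traitNames)],
                  by = c("plot_id", "dap"))
  rows <- list()
  for (sensor in unique(joined$sensor)) {
    sub <- joined[joined$sensor == sensor, ]
    for (tr in traitNames) for (ix in indices) {
      fit <- tryCatch({
        f <- fitOls(sub[[ix]], sub[[tr]])
        data.frame(sensor = sensor, trait = tr, index = ix, r2 = f$r2,
                   rmse_cv = cvRmse(sub[[ix]], sub[[tr]], k = k,
                                    repeats = repeats, seed = seed),
                   stringsAsFactors = FALSE)
      }, error = function(e) NULL)
      if (!is.null(fit)) rows[[length(rows) + 1L]] <- fit
    }
  }
  out <- do.call(rbind, rows)
  out$best <- FALSE
  for (sensor in unique(out$sensor)) for (tr in unique(out$trait)) {
    ix <- which(out$sensor == sensor & out$trait == tr)
    if (length(ix)) out$best[ix[which.min(out$rmse_cv[ix])]] <- TRUE
  }
  out
}
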