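## Cross-sensor intercomparison and treatment-discrimination statistics.

#' Intercompare an index between two sensors
#'
#' Pairs observations of the same plot and date, regresses sensor-b values
#' on sensor-a values by OLS and reports the coefficient of determination
#' and the discrepancy of slope `DS = 1 - slope`; DS = 0 means the relation
#' is slope-consistent with the 1:1 line. The default direction regresses
#' the ground sensor (b) on the UAV sensor (a); `flip = TRUE` reverses it.
#'
#' @param viA,viB data.frames with columns plot_id, dap and the index.
#' @param index index column name.
#' @param dapFilter optional dates to keep (e.g. excluding an early date).
#' @param flip reverse the regression direction.
#' @return List with `index`, `slope`, `intercept`, `r2`, `ds`, `n`.
#' @export
intercompare <- function(viA, viB, index, dapFilter = NULL, flip = FALSE) {
  m <- merge(viA[, c("plot_id", "dap", index)], viB[, c("plot_id", "dap", index)],
             by = c("plot_id", "dap"), suffixes = c("_a", "_b"))
  if (!is.null(dapFilter)) m <- m[m$dap %in% dapFilter, ]
  a <- m[[paste0(index, "_a")]]; b <- m[[paste0(index, "_b")]]
  if (flip) { tmp <- a; a <- b; b <- tmp }
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3) stop("need at least 3 paired observations")
  fit <- fitOls(a[ok], b[ok])
  list(index = index, slope = fit$slope, intercept = fit$intercept,
       r2 = fit$r2, ds = 1 - fit$slope, n = sum(ok))
}

#' Fit per-treatment normal distributions
#'
#' Sample mean and sample (n-1 denominator) standard deviation of the index
#' values in each treatment group, describing the normal densities compared
#' by [separation()].
#'
#' @param values numeric index values.
#' @param treatment group labels, one per value.
#' @return data.frame with `treatment`, `mean`, `sd`, `n`.
#' @export
fitTreatmentNormals <- function(values, treatment) {
  ok <- !is.na(values)
  values <- values[ok]; treatment <- treatment[ok]
  out <- do.call(rbind, lapply(split(values, treatment), function(v) {
    if (length(v) < 2) stop("need at least 2 observations per treatment")
    data.frame(mean = mean(v), sd = stats::sd(v), n = length(v))
  }))
  out$treatment <- rownames(out)
  rownames(out) <- NULL
  out[, c("treatment", "mean", "sd", "n")]
}

#' Bhattacharyya coefficient of two normal distributions
#'
#' Overlap measure \eqn{BC = \int \sqrt{t_1(x) t_2(x)}\,dx}, computed by
#' adaptive numeric integration. For normal densities the closed form is
#' \deqn{BC = \sqrt{\frac{2 s_1 s_2}{s_1^2 + s_2^2}}
#'   \exp\!\left(-\frac{(m_1 - m_2)^2}{4 (s_1^2 + s_2^2)}\right)}
#' (available via `method = "closed"`); the numeric integral agrees with it
#' to better than 1e-8. BC is 1 for identical distributions and tends to 0
#' as they separate.
#'
#' @param m1,s1,m2,s2 means and standard deviations (s > 0).
#' @param method "integrate" (default) or "closed".
#' @return BC in [0, 1].
#' @export
bhattacharyyaCoefficient <- function(m1, s1, m2, s2, method = c("integrate", "closed")) {
  if (s1 <= 0 || s2 <= 0) stop("standard deviations must be positive")
  method <- match.arg(method)
  if (method == "closed") {
    bc <- sqrt(2 * s1 * s2 / (s1^2 + s2^2)) *
      exp(-(m1 - m2)^2 / (4 * (s1^2 + s2^2)))
    return(min(1, bc))
  }
  f <- function(x) sqrt(stats::dnorm(x, m1, s1) * stats::dnorm(x, m2, s2))
  lo <- min(m1 - 10 * s1, m2 - 10 * s2)
  hi <- max(m1 + 10 * s1, m2 + 10 * s2)
  bc <- stats::integrate(f, lo, hi, rel.tol = 1e-10, abs.tol = 1e-12,
                         subdivisions = 500L)$value
  min(1, bc)
}

#' Treatment separability of an index
#'
#' Fits a normal distribution to the index values of each of two treatment
#' groups and reports `1 - BC` of the fitted normals: 0 for totally
#' overlapping distributions, 1 for completely separated ones.
#'
#' @param valuesT1,valuesT2 index values of the two treatments.
#' @return List with per-treatment `mean`/`sd`, `b_coeff` and `separation`.
#' @export
separation <- function(valuesT1, valuesT2) {
  n1 <- fitTreatmentNormals(valuesT1, rep("t1", length(valuesT1)))
  n2 <- fitTreatmentNormals(valuesT2, rep("t2", length(valuesT2)))
  if (n1$sd == 0 || n2$sd == 0) stop("degenerate (zero-sd) treatment distribution")
  bc <- bhattacharyyaCoefficient(n1$mean, n1$sd, n2$mean, n2$sd)
  list(t1 = c(mean = n1$mean, sd = n1$sd), t2 = c(mean = n2$mean, sd = n2$sd),
       b_coeff = bc, separation = 1 - bc)
}

#' Separability of every index in a table, by treatment
#'
#' @param viTab index table (see [indexTable()]) with a `treatment` column
#'   holding exactly two levels.
#' @param indices index columns to evaluate.
#' @param dapFilter optional dates to keep.
#' @return data.frame with index, the two group means/sds, b_coeff and
#'   separation.
#' @export
separationTable <- function(viTab, indices = intersect(indexNames(), names(viTab)),
                            dapFilter = NULL) {
  if (!is.null(dapFilter)) viTab <- viTab[viTab$dap %in% dapFilter, ]
  groups <- unique(viTab$treatment)
  if (length(groups) != 2) stop("treatment must have exactly two levels")
  rows <- lapply(indices, function(ix) {
    s <- tryCatch(separation(viTab[[ix]][viTab$treatment == groups[1]],
                             viTab[[ix]][viTab$treatment == groups[2]]),
                  error = function(e) NULL)
    if (is.null(s)) return(NULL)
    data.frame(index = ix, mean_t1 = s$t1[["mean"]], sd_t1 = s$t1[["sd"]],
               mean_t2 = s$t2[["mean"]], sd_t2 = s$t2[["sd"]],
               b_coeff = s$b_coeff, separation = s$separation,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
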