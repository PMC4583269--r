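gompertzInit <- function(t, od) {
  y0 <- min(od)
  A <- max(od) - y0
  slopes <- diff(od) / diff(t)
  iMax <- which.max(slopes)
  muMax <- slopes[iMax]
  tMax <- (t[iMax] + t[iMax + 1L]) / 2
  lag <- if (muMax > 0) max(0, tMax - A / (2 * muMax)) else 0
  list(y0 = y0, A = A, muMax = muMax, lag = lag)
}

#' Fit a modified Gompertz curve to one OD600 time series
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) of the Zwietering-parameterized Gompertz model
#' [gompertzCurve()] to a growth curve, returning the baseline, amplitude,
#' maximum growth rate, lag time and the coefficient of determination on
#' the raw OD values. Starting values come from the data (baseline = min
#' OD, amplitude = range, rate = steepest finite-difference slope, lag from
#' the tangent construction); one restart from perturbed starting values is
#' attempted on failure. Optimizer failure is data, not an exception: the
#' fit is returned with `converged = FALSE` and whatever R-squared the
#' starting-value curve achieves. A flat curve (zero total variance) has an
#' undefined R-squared (NA) and is likewise non-converged.
#'
#' @param times Numeric vector of hours, strictly increasing; or a
#'   data.frame with columns `time_h` and `od600` (then `od` is ignored).
#' @param od OD600 readings, same length as `times`, all >= 0.
#' @param logOd If TRUE, fit the same functional form to `log(od)` rather
#'   than raw OD (parameters are then on the log scale). Default FALSE:
#'   plate-reader OD over 18 h rarely has the dynamic range to reward log
#'   fitting.
#' @return A [GompertzFit-class].
#' @examples
#' t <- seq(0, 18, 0.5)
#' fit <- fitGompertz(t, gompertzCurve(t, 0.05, 1, 0.5, 2))
#' fit
#' @export
fitGompertz <- function(times, od, logOd = FALSE) {
  if (is.data.frame(times)) {
    assertColumns(times, c("time_h", "od600"), "growth curve")
    od <- times$od600
    times <- times$time_h
  }
  if (length(times) != length(od)) {
    stop("'times' and 'od' must have the same length", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing", call. = FALSE)
  }
  if (length(times) < 6L || (max(times) - min(times)) <= 2) {
    stop("need at least 6 time points spanning more than 2 h", call. = FALSE)
  }
  if (any(!is.finite(od)) || any(od < 0)) {
    stop("'od' must be finite and non-negative", call. = FALSE)
  }
  y <- if (logOd) log(pmax(od, 1e-6)) else od

  ssTot <- sum((y - mean(y))^2)
  init <- gompertzInit(times, y)
  fail <- function(r2) {
    new("GompertzFit", y0 = init$y0, A = max(init$A, 0), muMax = max(init$muMax, 0),
        lag = init$lag, rSquared = r2, converged = FALSE)
  }
  if (ssTot == 0) return(fail(NA_real_))
  r2of <- function(pred) 1 - sum((y - pred)^2) / ssTot
  if (init$A <= 0 || init$muMax <= 0) {
    return(fail(max(0, r2of(rep(mean(y), length(y))))))
  }

  tryFit <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ y0 + A * exp(-exp(muMax * exp(1) / A * (lag - t) + 1)),
        data = data.frame(t = times, y = y),
        start = start,
        lower = c(y0 = 0, A = 1e-8, muMax = 0, lag = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
  }
  start <- list(y0 = max(init$y0, 0), A = init$A, muMax = init$muMax,
                lag = init$lag)
  fit <- tryFit(start)
  if (is.null(fit)) {
    # single deterministic restart from perturbed initials
    fit <- tryFit(list(y0 = start$y0 * 0.5, A = start$A * 1.2,
                       muMax = start$muMax * 0.8,
                       lag = max(start$lag * 0.5, 0.1)))
  }
  if (is.null(fit)) {
    pred <- gompertzCurve(times, start$y0, start$A, start$muMax, start$lag)
    return(fail(max(0, r2of(pred))))
  }
  cf <- stats::coef(fit)
  new("GompertzFit",
      y0 = unname(cf["y0"]), A = unname(cf["A"]),
      muMax = unname(cf["muMax"]), lag = unname(cf["lag"]),
      rSquared = r2of(stats::fitted(fit)), converged = TRUE)
}

#' Fit Gompertz curves to every strain and trial
#'
#' Applies [fitGompertz()] to each (strain, trial) group of a long-format
#' growth table.
#'
#' @param growth data.frame with columns `strain`, `trial`, `time_h`,
#'   `od600`.
#' @param logOd Passed to [fitGompertz()].
#' @return data.frame with one row per strain and trial: `strain`, `trial`,
#'   `y0`, `A`, `muMax`, `lag`, `rSquared`, `converged`.
#' @export
fitGrowthCurves <- function(growth, logOd = FALSE) {
  assertColumns(growth, c("strain", "trial", "time_h", "od600"),
                "growth table")
  groups <- split(growth[c("time_h", "od600")],
                  list(growth$strain, growth$trial), drop = TRUE, sep = "\r")
  keys <- strsplit(names(groups), "\r", fixed = TRUE)
  fits <- lapply(groups, function(g) {
    g <- g[order(g$time_h), , drop = FALSE]
    fitGompertz(g$time_h, g$od600, logOd = logOd)
  })
  out <- data.frame(
    strain = vapply(keys, `[`, character(1), 1L),
    trial = as.integer(vapply(keys, `[`, character(1), 2L)),
    y0 = vapply(fits, slot, numeric(1), "y0"),
    A = vapply(fits, slot, numeric(1), "A"),
    muMax = vapply(fits, slot, numeric(1), "muMax"),
    lag = vapply(fits, slot, numeric(1), "lag"),
    rSquared = vapply(fits, slot, numeric(1), "rSquared"),
    converged = vapply(fits, slot, logical(1), "converged"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$strain, out$trial), , drop = FALSE]
}

#' Classify strains by growth-rate quality control
#'
#' Reproduces the screen's growth filter: trials with a poor Gompertz fit
#' (R-squared <= `r2Min`, or no convergence) are discarded; a strain with
#' no usable trial is excluded as `poor_fit_all_trials`; per-strain mean
#' maximum growth rates are compared with the population (mean m, sd s over
#' all strains with usable trials) and strains farther than `nSd * s` from
#' m on either side are excluded as `rate_outlier`. Comparisons at the
#' boundary are strict, so a degenerate population (s = 0) excludes no one.
#'
#' @param fits data.frame from [fitGrowthCurves()] (columns `strain`,
#'   `trial`, `muMax`, `rSquared`, `converged`).
#' @param r2Min Trials with R-squared at or below this are discarded
#'   (default 0.7; the boundary value itself is filtered).
#' @param nSd Width of the rate filter in population sd units (default 1).
#' @param pooled If TRUE, compute the population mean/sd over all usable
#'   per-trial rates pooled rather than over per-strain means (the strain's
#'   own statistic stays the per-strain mean).
#' @return List with elements `status` (data.frame: `strain`, `meanRate`,
#'   `nUsableTrials`, `passed`, `reason`), `populationMean` and
#'   `populationSd`.
#' @examples
#' fits <- data.frame(strain = rep(c("a", "b", "c"), each = 2),
#'                    trial = rep(1:2, 3),
#'                    muMax = c(0.5, 0.52, 0.49, 0.51, 0.5, 0.5),
#'                    rSquared = 0.99, converged = TRUE)
#' classifyGrowth(fits)$status
#' @export
classifyGrowth <- function(fits, r2Min = 0.7, nSd = 1, pooled = FALSE) {
  assertColumns(fits, c("strain", "trial", "muMax", "rSquared", "converged"),
                "fit table")
  usable <- fits$converged & !is.na(fits$rSquared) & fits$rSquared > r2Min
  strains <- unique(fits$strain)
  u <- fits[usable, , drop = FALSE]
  nUse <- table(factor(u$strain, levels = strains))
  meanRate <- tapply(u$muMax, factor(u$strain, levels = strains), mean)
  hasUsable <- nUse > 0

  if (sum(hasUsable) < 3L) {
    stop("fewer than 3 strains have usable growth fits; population ",
         "statistics are undefined", call. = FALSE)
  }
  popVals <- if (pooled) u$muMax else meanRate[hasUsable]
  m <- mean(popVals)
  s <- sd(popVals)

  reason <- rep("ok", length(strains))
  reason[!hasUsable] <- "poor_fit_all_trials"
  outlier <- hasUsable & abs(meanRate - m) > nSd * s
  reason[outlier] <- "rate_outlier"
  status <- data.frame(
    strain = strains,
    meanRate = as.numeric(meanRate),
    nUsableTrials = as.integer(nUse),
    passed = reason == "ok",
    reason = reason,
    stringsAsFactors = FALSE)
  rownames(status) <- NULL
  list(status = status, populationMean = m, populationSd = s)
}
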