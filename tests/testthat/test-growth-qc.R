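test_that("noise-free curves return the generating parameters", {
  t <- seq(0, 18, 0.5)
  grid <- expand.grid(y0 = c(0.03, 0.08), A = c(0.6, 1.2),
                      muMax = c(0.2, 0.5, 0.9), lag = c(0.5, 2, 4))
  for (i in seq_len(nrow(grid))) {
    p <- grid[i, ]
    fit <- fitGompertz(t, gompertzCurve(t, p$y0, p$A, p$muMax, p$lag))
    expect_true(fit@converged)
    expect_gt(fit@rSquared, 0.999)
    expect_equal(fit@y0, p$y0, tolerance = 1e-3)
    expect_equal(fit@A, p$A, tolerance = 1e-3)
    expect_equal(fit@muMax, p$muMax, tolerance = 1e-3)
    expect_equal(fit@lag, p$lag, tolerance = 1e-3)
  }
})

test_that("a flat curve has undefined R-squared and does not converge", {
  t <- seq(0, 18, 0.5)
  fit <- fitGompertz(t, rep(0.05, length(t)))
  expect_false(fit@converged)
  expect_true(is.na(fit@rSquared))
})

test_that("malformed curves are rejected", {
  t <- seq(0, 18, 0.5)
  od <- gompertzCurve(t, 0.05, 1, 0.5, 2)
  expect_error(fitGompertz(rev(t), od), "increasing")
  expect_error(fitGompertz(t, od[-1]), "length")
  expect_error(fitGompertz(t[1:5], od[1:5]), "6 time points")
  expect_error(fitGompertz(c(0, 0.5, 1, 1.2, 1.5, 1.9), rep(0.1, 6)),
               "2 h")
})

test_that("muMax is recovered within 10% under realistic OD noise", {
  t <- seq(0, 18, 0.5)
  relErr <- vapply(1:40, function(s) {
    set.seed(s)
    od <- pmax(gompertzCurve(t, 0.05, 0.9, 0.8, 1.0) + rnorm(37, 0, 0.01), 0)
    abs(fitGompertz(t, od)@muMax - 0.8) / 0.8
  }, numeric(1))
  expect_lt(median(relErr), 0.10)
})

test_that("trial-level QC discards poor fits and flags rate outliers", {
  # two fast strains among 98 slow ones: m = 1.08, s ~ 0.5628
  fits <- fitsTable(sprintf("s%03d", 1:100), c(rep(1, 98), rep(5, 2)))
  res <- classifyGrowth(fits)
  expect_equal(res$populationMean, 1.08)
  expect_equal(res$populationSd, sd(c(rep(1, 98), rep(5, 2))))
  flagged <- res$status$strain[res$status$reason == "rate_outlier"]
  expect_setequal(flagged, c("s099", "s100"))
  expect_true(all(res$status$passed[1:98]))
})

test_that("identical rates give zero spread and everyone passes", {
  fits <- fitsTable(letters[1:5], rep(0.5, 5))
  res <- classifyGrowth(fits)
  expect_equal(res$populationSd, 0)
  expect_true(all(res$status$passed))
})

test_that("R-squared at or below the threshold is filtered, strictly", {
  fits <- rbind(
    fitsTable("bad", rep(0.5, 3), rSquared = 0.6, trial = 1:3),
    fitsTable("edge", rep(0.5, 3), rSquared = 0.7, trial = 1:3),
    fitsTable(rep(c("g1", "g2", "g3"), each = 3), 0.5, rSquared = 0.9,
              trial = rep(1:3, 3)))
  res <- classifyGrowth(fits)
  st <- res$status
  expect_equal(st$reason[st$strain == "bad"], "poor_fit_all_trials")
  # the boundary value 0.7 itself is filtered (<= threshold)
  expect_equal(st$reason[st$strain == "edge"], "poor_fit_all_trials")
  expect_equal(st$nUsableTrials[st$strain == "edge"], 0L)
  # non-converged trials are unusable regardless of R-squared
  fits2 <- rbind(fitsTable("nc", 0.5, converged = FALSE),
                 fitsTable(c("a", "b", "c"), c(0.5, 0.5, 0.5)))
  expect_equal(classifyGrowth(fits2)$status$reason[1], "poor_fit_all_trials")
})

test_that("raising the R-squared threshold never gains usable trials", {
  set.seed(5)
  fits <- fitsTable(sprintf("s%02d", 1:50), rnorm(50, 0.5, 0.05),
                    rSquared = runif(50, 0.4, 1))
  nUsable <- vapply(c(0.5, 0.6, 0.7, 0.8, 0.9), function(r2) {
    sum(classifyGrowth(fits, r2Min = r2)$status$nUsableTrials)
  }, numeric(1))
  expect_true(all(diff(nUsable) <= 0))
})

test_that("population statistics require at least 3 usable strains", {
  fits <- fitsTable(c("a", "b"), c(0.5, 0.6))
  expect_error(classifyGrowth(fits), "fewer than 3")
})

test_that("normally distributed rates flag roughly the 1-sd tail mass", {
  set.seed(9)
  fits <- fitsTable(sprintf("s%04d", 1:2000), rnorm(2000, 0.5, 0.05))
  frac <- mean(!classifyGrowth(fits)$status$passed)
  expect_gt(frac, 0.25)
  expect_lt(frac, 0.38)
})

test_that("pooled population mode uses per-trial rates for m and s", {
  fits <- rbind(fitsTable(rep(c("a", "b", "c"), each = 2),
                          c(0.4, 0.6, 0.5, 0.5, 0.45, 0.55),
                          trial = rep(1:2, 3)))
  perStrain <- classifyGrowth(fits)
  pooled <- classifyGrowth(fits, pooled = TRUE)
  expect_equal(perStrain$populationMean, pooled$populationMean)
  expect_gt(pooled$populationSd, perStrain$populationSd)
})
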