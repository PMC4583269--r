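test_that("generateLibrary is deterministic and respects planted fractions", {
  lib1 <- generateLibrary(nGenes = 3905, seed = 42)
  lib2 <- generateLibrary(nGenes = 3905, seed = 42)
  expect_identical(genes(lib1), genes(lib2))
  expect_identical(trueLogEffect(lib1), trueLogEffect(lib2))
  expect_identical(growthDefective(lib1), growthDefective(lib2))
  expect_identical(categoryMembership(lib1), categoryMembership(lib2))

  # 2.69% of 3,905 genes growth defective, within rounding
  expect_equal(sum(growthDefective(lib1)), round(0.0269 * 3905))
  # planted effect counts match the configured fractions
  eff <- trueLogEffect(lib1)
  expect_equal(sum(eff > 0), round(0.02 * 3905))
  expect_equal(sum(eff < 0), round(0.025 * 3905))
  expect_true(all(eff %in% c(-0.6, 0, 0.6)))

  # every category member exists in the library
  expect_true(all(categoryMembership(lib1)$gene %in% genes(lib1)))
  expect_true(all(plantedCategories(lib1) %in%
                    categoryMembership(lib1)$category))
})

test_that("null library has exactly zero effects everywhere", {
  lib <- generateLibrary(nGenes = 96, fracOver = 0, fracUnder = 0, seed = 7)
  expect_true(all(trueLogEffect(lib) == 0))
})

test_that("generateLibrary rejects invalid designs", {
  expect_error(generateLibrary(nGenes = 95, seed = 1), "96")
  expect_error(generateLibrary(nGenes = 100, categorySizeRange = c(5, 200),
                               seed = 1), "exceed")
  expect_error(generateLibrary(nGenes = 100, fracOver = 0.6, fracUnder = 0.6,
                               seed = 1), "<= 1")
  expect_error(generateLibrary(nGenes = 100), "seed")
})

test_that("blot noise generator matches its configured CV", {
  lib <- generateLibrary(nGenes = 96, fracOver = 0, fracUnder = 0,
                         seed = 3)
  # 96 neutral genes x 52 replicates = 4,992 draws with unit membrane scale
  plan <- stats::setNames(rep(52L, 96), genes(lib))
  blot <- simulateBlotDataset(lib, replicatePlan = plan,
                              membraneScaleSd = 0, wellNoiseCv = 0.278,
                              seed = 4)
  cv <- sd(blot$raw_intensity) / mean(blot$raw_intensity)
  expect_gt(cv, 0.25)
  expect_lt(cv, 0.31)
})

test_that("noise-free blot intensities follow the multiplicative model", {
  lib <- generateLibrary(nGenes = 100, fracOver = 0.01, fracUnder = 0,
                         effectDelta = 1, seed = 5)
  blot <- simulateBlotDataset(lib, extraReplicateCounts = NULL,
                              membraneScaleSd = 0, wellNoiseCv = 0,
                              seed = 6)
  eff <- trueLogEffect(lib)
  hot <- names(eff)[eff == 1]
  neutral <- names(eff)[eff == 0][1]
  expect_length(hot, 1L)
  # same membrane, zero noise: exactly 10x a neutral gene
  for (r in 1:2) {
    iHot <- blot$raw_intensity[blot$strain == hot & blot$replicate == r]
    iNeu <- blot$raw_intensity[blot$strain == neutral & blot$replicate == r]
    expect_equal(iHot, 10 * iNeu)
  }
  # all-neutral, noise-free: identical within a replicate's membranes
  neu <- blot[blot$strain %in% names(eff)[eff == 0], ]
  expect_equal(length(unique(neu$raw_intensity)), 1L)
})

test_that("replicates of one strain land on distinct membranes", {
  s <- smallScreen(nGenes = 200)
  byStrain <- split(s$blot$membrane_id, s$blot$strain)
  expect_true(all(vapply(byStrain, function(m) !anyDuplicated(m),
                         logical(1))))
  # default plan: every strain >= 2 replicates
  reps <- table(s$blot$strain)
  expect_true(all(reps >= 2))
})

test_that("growth simulation reproduces its generating curves exactly", {
  lib <- generateLibrary(nGenes = 96, seed = 8)
  g <- simulateGrowthDataset(lib, odNoiseSd = 0, seed = 9)
  expect_equal(sum(g$strain == genes(lib)[1] & g$trial == 1), 37L)
  gp <- trueGrowthParams(lib)
  one <- g[g$strain == gp$gene[5] & g$trial == 2, ]
  expect_equal(one$od600,
               gompertzCurve(one$time_h, gp$y0[5], gp$A[5], gp$muMax[5],
                             gp$lag[5]),
               tolerance = 1e-12)
  # byte-identical regeneration under the same seed
  expect_identical(g, simulateGrowthDataset(lib, odNoiseSd = 0, seed = 9))
  expect_error(simulateGrowthDataset(lib, tEnd = 18, dt = 0.7, seed = 1),
               "divide")
})

test_that("FCOP simulation honors the generative model and preconditions", {
  lib <- generateLibrary(nGenes = 100, fracOver = 0.01, fracUnder = 0,
                         effectDelta = 0.6, seed = 10)
  eff <- trueLogEffect(lib)
  hot <- names(eff)[eff > 0][1]
  neutral <- names(eff)[eff == 0][1]

  expect_error(simulateFcopDataset(lib, hot, nReplicates = 2, seed = 1),
               ">= 3")
  expect_error(simulateFcopDataset(lib, character(), seed = 1), "non-empty")

  # noise-free: neutral normalizes to exactly 1, effect gene to 10^0.6
  fc0 <- simulateFcopDataset(lib, c(hot, neutral), noiseCv = 0, seed = 2)
  v0 <- fcopVesiculation(fc0)
  expect_equal(v0$value[v0$strain == neutral], 1.0)
  expect_equal(v0$value[v0$strain == hot], 10^0.6)

  # noisy: expected value 10^0.6 ~ 3.98 within sampling error
  fc <- simulateFcopDataset(lib, hot, nReplicates = 200, noiseCv = 0.2,
                            seed = 3)
  v <- fcopVesiculation(fc)
  expect_equal(v$value[v$strain == hot], 10^0.6, tolerance = 0.08)
})
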