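# Independent enumeration oracle for the upper-tail hypergeometric
# probability: direct summation of binomial-coefficient ratios. Kept
# deliberately separate from the distribution-function route the package
# uses.
hyperTailOracle <- function(N, K, n, k) {
  hi <- min(K, n)
  if (k > hi) return(0)
  i <- k:hi
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Small library + blot + growth bundle for pipeline-level tests.
smallScreen <- function(nGenes = 200, seed = 11, odNoiseSd = 0.01, ...) {
  lib <- generateLibrary(nGenes = nGenes, seed = seed, ...)
  list(
    library = lib,
    blot = simulateBlotDataset(lib, extraReplicateCounts = c("3" = 10),
                               seed = seed + 1),
    growth = simulateGrowthDataset(lib, odNoiseSd = odNoiseSd,
                                   seed = seed + 2)
  )
}

# A fits table ready for classifyGrowth without running the optimizer.
fitsTable <- function(strain, muMax, rSquared = 0.99, converged = TRUE,
                      trial = 1L) {
  data.frame(strain = strain, trial = trial, muMax = muMax,
             rSquared = rSquared, converged = converged,
             stringsAsFactors = FALSE)
}
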