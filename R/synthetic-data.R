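#' Generate a ground-truth knockout library
#'
#' Builds a synthetic analogue of an arrayed single-gene knockout collection
#' for end-to-end testing of the screen pipeline. A configurable fraction of
#' genes receives a planted over- or under-vesiculation effect (a +/- log10
#' shift), an independent fraction is made growth defective, and a set of
#' flat functional categories is created of which some ("planted") are
#' filled preferentially with effect genes so that downstream enrichment
#' has known positives.
#'
#' Defaults mirror a genome-scale screen: 3,905 strains, a 0.6 log10 effect
#' size, 2% over- and 2.5% under-vesiculating genes, and a 2.69%
#' growth-defective subpopulation. Normal strains draw their true maximum
#' growth rate from a tight normal distribution (sd `rateSd`); growth
#' defective strains are displaced by `defectShift * rateSd` (low by
#' default, high with `defectDirection = "fast"`), so a one-standard-
#' deviation rate filter recovers approximately the planted fraction.
#'
#' @param nGenes Number of genes (>= 96, one full plate).
#' @param fracOver,fracUnder Fractions of genes planted with +/-
#'   `effectDelta` log10 vesiculation shifts; their sum must be <= 1.
#' @param effectDelta Planted effect size in log10 units (>= 0).
#' @param fracGrowthDefective Fraction of genes with defective growth,
#'   assigned independently of vesiculation effects.
#' @param nCategories Number of functional categories.
#' @param categorySizeRange Length-2 integer vector: category sizes are
#'   drawn uniformly from this range.
#' @param nPlantedCategories Number of categories filled preferentially
#'   with effect genes (must be <= `nCategories`).
#' @param enrichmentOdds Sampling odds of an effect gene vs a neutral gene
#'   when filling a planted category (default 60, giving planted categories
#'   roughly three-quarters effect genes at genome scale).
#' @param baseRate,rateSd Mean and sd of the true maximum growth rate of
#'   normal strains (OD600/h).
#' @param defectShift Displacement of defective strains' rate, in units of
#'   `rateSd`.
#' @param defectDirection `"slow"` (default) or `"fast"`.
#' @param seed Integer seed (required; all randomness is local to the call).
#' @return A [TrueLibrary-class].
#' @examples
#' lib <- generateLibrary(nGenes = 200, seed = 1)
#' lib
#' sum(trueLogEffect(lib) != 0)
#' @export
generateLibrary <- function(nGenes = 3905,
                            fracOver = 0.02,
                            fracUnder = 0.025,
                            effectDelta = 0.6,
                            fracGrowthDefective = 0.0269,
                            nCategories = 40,
                            categorySizeRange = c(5, 80),
                            nPlantedCategories = 4,
                            enrichmentOdds = 60,
                            baseRate = 0.5,
                            rateSd = 0.015,
                            defectShift = 20,
                            defectDirection = c("slow", "fast"),
                            seed) {
  nGenes <- assertCount(nGenes, "nGenes", min = 1L)
  if (nGenes < 96L) {
    stop("'nGenes' must be >= 96: cannot fill a single 96-well plate",
         call. = FALSE)
  }
  assertFraction(fracOver, "fracOver")
  assertFraction(fracUnder, "fracUnder")
  assertFraction(fracGrowthDefective, "fracGrowthDefective")
  if (fracOver + fracUnder > 1) {
    stop("fracOver + fracUnder must be <= 1", call. = FALSE)
  }
  if (!is.numeric(effectDelta) || effectDelta < 0) {
    stop("'effectDelta' must be >= 0", call. = FALSE)
  }
  nCategories <- assertCount(nCategories, "nCategories")
  nPlantedCategories <- assertCount(nPlantedCategories, "nPlantedCategories")
  if (nPlantedCategories > nCategories) {
    stop("'nPlantedCategories' must be <= 'nCategories'", call. = FALSE)
  }
  if (length(categorySizeRange) != 2L ||
      any(categorySizeRange < 1) || categorySizeRange[1] > categorySizeRange[2]) {
    stop("'categorySizeRange' must be an increasing pair of counts >= 1",
         call. = FALSE)
  }
  if (max(categorySizeRange) > nGenes) {
    stop("category sizes cannot exceed 'nGenes'", call. = FALSE)
  }
  defectDirection <- match.arg(defectDirection)
  if (missing(seed)) stop("'seed' must be supplied", call. = FALSE)

  withSeed(seed, {
    gene <- sprintf("g%05d", seq_len(nGenes))
    nOver <- round(fracOver * nGenes)
    nUnder <- round(fracUnder * nGenes)
    effectIdx <- sample.int(nGenes, nOver + nUnder)
    eff <- numeric(nGenes)
    eff[effectIdx[seq_len(nOver)]] <- effectDelta
    if (nUnder > 0) eff[effectIdx[nOver + seq_len(nUnder)]] <- -effectDelta

    nDef <- round(fracGrowthDefective * nGenes)
    defective <- logical(nGenes)
    defective[sample.int(nGenes, nDef)] <- TRUE

    rate <- rnorm(nGenes, baseRate, rateSd)
    shift <- defectShift * rateSd * if (defectDirection == "slow") -1 else 1
    rate[defective] <- rate[defective] + shift
    rate <- pmax(rate, 0.02)
    gp <- data.frame(
      gene = gene,
      y0 = pmax(rnorm(nGenes, 0.05, 0.005), 0.01),
      A = pmax(rnorm(nGenes, 1.0, 0.05), 0.2),
      muMax = rate,
      lag = pmax(rnorm(nGenes, 2.0, 0.3), 0.2),
      stringsAsFactors = FALSE
    )

    catIds <- sprintf("CAT%03d", seq_len(nCategories))
    planted <- if (nPlantedCategories > 0) {
      sample(catIds, nPlantedCategories)
    } else character()
    isEffect <- eff != 0
    membership <- do.call(rbind, lapply(catIds, function(cid) {
      size <- sample(seq(categorySizeRange[1], categorySizeRange[2]), 1L)
      w <- if (cid %in% planted) {
        ifelse(isEffect, enrichmentOdds, 1)
      } else {
        rep(1, nGenes)
      }
      data.frame(gene = sample(gene, size, prob = w),
                 category = cid, stringsAsFactors = FALSE)
    }))

    new("TrueLibrary",
        genes = gene,
        trueLogEffect = eff,
        growthDefective = defective,
        trueGrowthParams = gp,
        categoryMembership = membership,
        plantedCategories = planted)
  })
}

# Array strains onto 96-well membranes in library order (row-major), one
# membrane set per replicate index so replicates of a strain always land on
# different membranes (day-to-day variation is per membrane).
membraneLayout <- function(strains, replicate, wellsPerMembrane = 96L) {
  plate <- (seq_along(strains) - 1L) %/% wellsPerMembrane + 1L
  sprintf("M_r%d_p%03d", replicate, plate)
}

#' Simulate a dot-blot densitometry dataset
#'
#' Generates raw per-well blot intensities for every strain of a
#' [TrueLibrary-class] under a multiplicative model: intensity
#' `I = S_m * 10^effect * (1 + eps)`, where `S_m` is a per-membrane
#' lognormal scale factor capturing day-to-day blotting variation and `eps`
#' is truncated-normal multiplicative noise with coefficient of variation
#' `wellNoiseCv`. Strains are arrayed row-major onto 96-well membranes in
#' library order; each replicate of a strain lands on a different membrane.
#'
#' Every strain gets `baseReplicates` replicates; on top of that, random
#' subsets get extra replicates per `extraReplicateCounts` (defaults mirror
#' a reproducibility design with 272 strains run thrice, 138 four times and
#' 76 five times). Alternatively pass an explicit `replicatePlan`.
#'
#' @param library A [TrueLibrary-class].
#' @param replicatePlan Optional named integer vector (gene -> replicate
#'   count, all >= 2) overriding the default plan.
#' @param baseReplicates Replicates for every strain (default 2).
#' @param extraReplicateCounts Named integer vector: how many strains to
#'   raise to 3, 4, 5, ... replicates (names are the replicate counts).
#' @param membraneScaleSd Lognormal sigma of the per-membrane scale factor.
#' @param wellNoiseCv Coefficient of variation of the per-well
#'   multiplicative noise (>= 0).
#' @param seed Integer seed.
#' @return data.frame with columns `strain`, `membrane_id`, `replicate`,
#'   `raw_intensity`.
#' @examples
#' lib <- generateLibrary(nGenes = 192, seed = 1)
#' blot <- simulateBlotDataset(lib, extraReplicateCounts = c("3" = 10),
#'                             seed = 2)
#' head(blot)
#' @export
simulateBlotDataset <- function(library,
                                replicatePlan = NULL,
                                baseReplicates = 2L,
                                extraReplicateCounts = c("3" = 272, "4" = 138,
                                                         "5" = 76),
                                membraneScaleSd = 0.3,
                                wellNoiseCv = 0.278,
                                seed) {
  stopifnot(is(library, "TrueLibrary"))
  if (wellNoiseCv < 0) stop("'wellNoiseCv' must be >= 0", call. = FALSE)
  if (membraneScaleSd < 0) stop("'membraneScaleSd' must be >= 0", call. = FALSE)
  if (missing(seed)) stop("'seed' must be supplied", call. = FALSE)
  gene <- library@genes

  withSeed(seed, {
    if (is.null(replicatePlan)) {
      plan <- stats::setNames(rep(as.integer(baseReplicates), length(gene)),
                              gene)
      if (length(extraReplicateCounts)) {
        nExtra <- sum(extraReplicateCounts)
        if (nExtra > length(gene)) {
          stop("extra-replicate subsets exceed the number of genes; ",
               "pass an explicit 'replicatePlan' for small libraries",
               call. = FALSE)
        }
        chosen <- sample(gene, nExtra)
        at <- 0L
        for (j in seq_along(extraReplicateCounts)) {
          cnt <- extraReplicateCounts[j]
          plan[chosen[at + seq_len(cnt)]] <-
            as.integer(names(extraReplicateCounts)[j])
          at <- at + cnt
        }
      }
    } else {
      if (is.null(names(replicatePlan)) || !all(gene %in% names(replicatePlan)))
        stop("'replicatePlan' must be named and cover every gene",
             call. = FALSE)
      plan <- as.integer(replicatePlan[gene])
      names(plan) <- gene
      if (any(plan < 2L))
        stop("every strain needs >= 2 replicates", call. = FALSE)
    }

    theta <- 10^library@trueLogEffect
    names(theta) <- gene
    out <- vector("list", max(plan))
    for (r in seq_len(max(plan))) {
      strainsR <- gene[plan >= r]
      memb <- membraneLayout(strainsR, r)
      out[[r]] <- data.frame(strain = strainsR, membrane_id = memb,
                             replicate = r, stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, out)
    membranes <- unique(tab$membrane_id)
    scale <- stats::setNames(
      exp(rnorm(length(membranes), 0, membraneScaleSd)), membranes)
    tab$raw_intensity <- scale[tab$membrane_id] * theta[tab$strain] *
      rPositiveFactor(nrow(tab), wellNoiseCv)
    rownames(tab) <- NULL
    tab[order(tab$replicate, tab$membrane_id), , drop = FALSE]
  })
}

#' Modified Gompertz growth curve
#'
#' The Zwietering parameterization:
#' `od(t) = y0 + A * exp(-exp(muMax * e / A * (lag - t) + 1))`,
#' whose tangent at the inflection has slope `muMax` and intercepts the
#' baseline at `t = lag`.
#'
#' @param t Time (hours), vectorized.
#' @param y0 Baseline OD600.
#' @param A Amplitude (OD600 above baseline).
#' @param muMax Maximum growth rate (OD600/h).
#' @param lag Lag time (hours).
#' @return OD600 values.
#' @examples
#' curve(gompertzCurve(x, 0.05, 1, 0.5, 2), 0, 18, xlab = "h", ylab = "OD600")
#' @export
gompertzCurve <- function(t, y0, A, muMax, lag) {
  y0 + A * exp(-exp(muMax * exp(1) / A * (lag - t) + 1))
}

#' Simulate plate-reader growth curves
#'
#' OD600 trajectories for every strain of a [TrueLibrary-class], following
#' [gompertzCurve()] at the strain's true parameters plus additive Gaussian
#' noise (clipped at 0). Defaults reproduce an 18 h run read every 30 min
#' (37 points including t = 0) in three independent trials.
#'
#' @param library A [TrueLibrary-class].
#' @param tEnd End time in hours.
#' @param dt Reading interval in hours; must divide `tEnd`.
#' @param nTrials Number of independent replicate trials.
#' @param odNoiseSd Additive OD600 noise sd (>= 0).
#' @param seed Integer seed.
#' @return data.frame with columns `strain`, `trial`, `time_h`, `od600`.
#' @examples
#' lib <- generateLibrary(nGenes = 96, seed = 1)
#' g <- simulateGrowthDataset(lib, seed = 2)
#' nrow(g) == 96 * 3 * 37
#' @export
simulateGrowthDataset <- function(library, tEnd = 18, dt = 0.5, nTrials = 3,
                                  odNoiseSd = 0.01, seed) {
  stopifnot(is(library, "TrueLibrary"))
  if (odNoiseSd < 0) stop("'odNoiseSd' must be >= 0", call. = FALSE)
  k <- tEnd / dt
  if (abs(k - round(k)) > 1e-9) {
    stop("'dt' must divide 'tEnd'", call. = FALSE)
  }
  if (missing(seed)) stop("'seed' must be supplied", call. = FALSE)
  times <- seq(0, tEnd, by = dt)
  gp <- library@trueGrowthParams

  withSeed(seed, {
    nT <- length(times)
    base <- gompertzCurve(rep(times, times = nrow(gp)),
                          rep(gp$y0, each = nT), rep(gp$A, each = nT),
                          rep(gp$muMax, each = nT), rep(gp$lag, each = nT))
    out <- vector("list", nTrials)
    for (tr in seq_len(nTrials)) {
      od <- base
      if (odNoiseSd > 0) od <- pmax(od + rnorm(length(od), 0, odNoiseSd), 0)
      out[[tr]] <- data.frame(
        strain = rep(gp$gene, each = nT),
        trial = tr,
        time_h = rep(times, times = nrow(gp)),
        od600 = od,
        stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Simulate a flask-grown culture OMV preparation (FCOP) dataset
#'
#' Orthogonal low-throughput measurements for a subset of strains plus a
#' wild-type control: per replicate, an FM4-64 fluorescence reading
#' proportional to the strain's true vesiculation level (with
#' multiplicative noise of CV `noiseCv`) and a CFU count near 1e9 (with a
#' smaller multiplicative noise tied to `noiseCv`). After
#' [fcopVesiculation()] normalization, a neutral gene's expected value
#' is 1 and a gene with log10 effect d has expected value `10^d`.
#'
#' @param library A [TrueLibrary-class].
#' @param strainSubset Character vector of library genes to measure
#'   (non-empty).
#' @param nReplicates Replicates per strain (>= 3).
#' @param wtLabel Identifier used for the wild-type control rows.
#' @param noiseCv Coefficient of variation of the fluorescence noise.
#' @param seed Integer seed.
#' @return data.frame with columns `strain`, `replicate`, `fm464`, `cfu`;
#'   includes `wtLabel` rows.
#' @examples
#' lib <- generateLibrary(nGenes = 96, seed = 1)
#' fc <- simulateFcopDataset(lib, genes(lib)[1:5], seed = 2)
#' table(fc$strain)
#' @export
simulateFcopDataset <- function(library, strainSubset, nReplicates = 3,
                                wtLabel = "WT", noiseCv = 0.25, seed) {
  stopifnot(is(library, "TrueLibrary"))
  if (length(strainSubset) == 0L) {
    stop("'strainSubset' must be non-empty", call. = FALSE)
  }
  if (!all(strainSubset %in% library@genes)) {
    stop("'strainSubset' contains genes not in the library", call. = FALSE)
  }
  nReplicates <- assertCount(nReplicates, "nReplicates", min = 3L)
  if (noiseCv < 0) stop("'noiseCv' must be >= 0", call. = FALSE)
  if (missing(seed)) stop("'seed' must be supplied", call. = FALSE)

  theta <- c(stats::setNames(10^library@trueLogEffect, library@genes),
             stats::setNames(1, wtLabel))
  strains <- c(wtLabel, unique(strainSubset))
  withSeed(seed, {
    n <- length(strains) * nReplicates
    strain <- rep(strains, each = nReplicates)
    fm <- 1000 * theta[strain] * rPositiveFactor(n, noiseCv)
    cfu <- 1e9 * rPositiveFactor(n, noiseCv / 5)
    data.frame(strain = strain,
               replicate = rep(seq_len(nReplicates), times = length(strains)),
               fm464 = as.numeric(fm), cfu = as.numeric(cfu),
               stringsAsFactors = FALSE)
  })
}

#' Write a complete synthetic screen dataset to disk
#'
#' Writes the blot CSV, growth CSV, annotation TSV, optional FCOP CSV and a
#' ground-truth TSV into `dir` using the same dialects the pipeline readers
#' expect, so a full file-based round trip can be tested.
#'
#' @param library A [TrueLibrary-class].
#' @param dir Output directory (created if needed).
#' @param blot,growth,fcop Data frames from the corresponding simulators
#'   (`fcop` may be NULL).
#' @return Invisibly, a named list of the written paths.
#' @export
writeScreenDataset <- function(library, dir, blot, growth, fcop = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    blot = file.path(dir, "blot.csv"),
    growth = file.path(dir, "growth.csv"),
    annotation = file.path(dir, "annotation.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  utils::write.csv(blot, paths$blot, row.names = FALSE, quote = FALSE)
  utils::write.csv(growth, paths$growth, row.names = FALSE, quote = FALSE)
  ann <- library@categoryMembership
  ann <- data.frame(category_id = ann$category, category_name = ann$category,
                    gene = ann$gene)
  utils::write.table(ann, paths$annotation, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  truth <- data.frame(
    gene = library@genes,
    true_log_effect = library@trueLogEffect,
    growth_defective = library@growthDefective,
    planted_categories = paste(library@plantedCategories, collapse = ","))
  utils::write.table(truth, paths$truth, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(fcop)) {
    paths$fcop <- file.path(dir, "fcop.csv")
    utils::write.csv(fcop, paths$fcop, row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}
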