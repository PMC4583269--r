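#' Pipeline configuration
#'
#' Collects and validates every knob of [runPipeline()]. Unknown arguments
#' are rejected rather than ignored, and all parameters are range-checked
#' here so stage code can assume a sane configuration.
#'
#' @param blot Path to the blot CSV or a blot data.frame.
#' @param growth Path to the growth CSV or a growth data.frame (mandatory:
#'   phenotype calling is only defined on growth-passing strains).
#' @param annotation Optional path to an annotation table or an
#'   [AnnotationSet-class].
#' @param fcop Optional path to an FCOP CSV or an FCOP data.frame.
#' @param wtLabel Wild-type identifier for FCOP normalization.
#' @param nSdGrowth Growth-rate filter width in sd units (default 1).
#' @param nSdCall Vesiculation cutoff width in sd units (default 2).
#' @param r2Min Gompertz fit quality threshold (default 0.7).
#' @param alpha Enrichment flagging threshold (default 0.05).
#' @param average Replicate averaging mode for [scoreStrains()].
#' @param correlation Correlation mode for [methodConcordance()].
#' @param logOd Fit growth curves on the log-OD scale.
#' @param outDir Optional output directory; when set, [runPipeline()]
#'   writes all result tables, audit files and a summary JSON there.
#' @param ... Unknown arguments: always an error.
#' @return A validated `PipelineConfig` (list).
#' @export
pipelineConfig <- function(blot, growth, annotation = NULL, fcop = NULL,
                           wtLabel = "WT", nSdGrowth = 1, nSdCall = 2,
                           r2Min = 0.7, alpha = 0.05,
                           average = c("linear", "log"),
                           correlation = c("pearson", "spearman"),
                           logOd = FALSE, outDir = NULL, ...) {
  extra <- list(...)
  if (length(extra) > 0L) {
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "), call. = FALSE)
  }
  if (missing(blot)) stop("'blot' input is required", call. = FALSE)
  if (missing(growth) || is.null(growth)) {
    stop("'growth' input is required: growth QC is a mandatory stage",
         call. = FALSE)
  }
  stopifnot(nSdGrowth >= 0, nSdCall >= 0, r2Min >= 0, r2Min <= 1)
  assertFraction(alpha, "alpha")
  cfg <- list(blot = blot, growth = growth, annotation = annotation,
              fcop = fcop, wtLabel = wtLabel, nSdGrowth = nSdGrowth,
              nSdCall = nSdCall, r2Min = r2Min, alpha = alpha,
              average = match.arg(average),
              correlation = match.arg(correlation),
              logOd = logOd, outDir = outDir)
  class(cfg) <- "PipelineConfig"
  cfg
}

resolveInput <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

stageStop <- function(stage, e) {
  stop("[", stage, "] ", conditionMessage(e), call. = FALSE)
}

#' Run the full vesiculation screen pipeline
#'
#' Executes the stages in order: blot scoring ([scoreStrains()]), growth QC
#' ([fitGrowthCurves()] + [classifyGrowth()]), phenotype calling
#' ([callPhenotypes()]), then optional enrichment ([enrichCategories()],
#' with the growth-passing scored strains as universe) and FCOP concordance
#' ([fcopVesiculation()] + [methodConcordance()]). Every excluded strain is
#' recorded in the audit trail, which partitions the tested strains exactly
#' into replicate-rejected, growth-excluded and called. When
#' `config$outDir` is set, result tables (TSV), audit files and a summary
#' JSON are written there.
#'
#' @param config A `PipelineConfig` from [pipelineConfig()].
#' @return A [ScreenResult-class].
#' @examples
#' lib <- generateLibrary(nGenes = 192, fracGrowthDefective = 0.03, seed = 1)
#' blot <- simulateBlotDataset(lib, extraReplicateCounts = NULL, seed = 2)
#' growth <- simulateGrowthDataset(lib, seed = 3)
#' res <- runPipeline(pipelineConfig(blot = blot, growth = growth))
#' res
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  blot <- resolveInput(config$blot, readBlotTable)
  growth <- resolveInput(config$growth, readGrowthTable)

  scored <- tryCatch(scoreStrains(blot, average = config$average),
                     error = function(e) stageStop("blot_quant", e))
  tested <- unique(blot$strain)

  missingGrowth <- setdiff(scored$scores$strain, unique(growth$strain))
  if (length(missingGrowth) > 0L) {
    stop("[growth_qc] no growth curves for scored strain(s): ",
         paste(utils::head(missingGrowth, 5), collapse = ", "),
         call. = FALSE)
  }
  fits <- tryCatch(fitGrowthCurves(growth, logOd = config$logOd),
                   error = function(e) stageStop("growth_qc", e))
  gc <- tryCatch(
    classifyGrowth(fits, r2Min = config$r2Min, nSd = config$nSdGrowth),
    error = function(e) stageStop("growth_qc", e))
  passed <- gc$status$strain[gc$status$passed]

  passingScores <- scored$scores[scored$scores$strain %in% passed, ,
                                 drop = FALSE]
  called <- tryCatch(
    callPhenotypes(passingScores, passed, nSd = config$nSdCall),
    error = function(e) stageStop("phenotype_call", e))

  audit <- list(
    replicateRejected = scored$rejects$strain,
    growthExcluded = setdiff(scored$scores$strain, passed),
    called = called$calls$strain)

  significant <- called$calls$strain[called$calls$call != "normal"]
  enrichment <- data.frame()
  if (!is.null(config$annotation)) {
    ann <- if (is(config$annotation, "AnnotationSet")) {
      config$annotation
    } else {
      readAnnotationTable(config$annotation, universe = called$calls$strain)
    }
    enrichment <- tryCatch(
      enrichCategories(intersect(significant, universe(ann)), ann,
                       alpha = config$alpha),
      error = function(e) stageStop("enrichment_stats", e))
  }

  conc <- list()
  if (!is.null(config$fcop)) {
    fcopTab <- resolveInput(config$fcop, readFcopTable)
    conc <- tryCatch({
      fv <- fcopVesiculation(fcopTab, wtLabel = config$wtLabel)
      fv <- fv[fv$strain != config$wtLabel, , drop = FALSE]
      htp <- stats::setNames(called$calls$log10Score, called$calls$strain)
      htp <- htp[names(htp) %in% fv$strain]
      methodConcordance(htp, stats::setNames(fv$value, fv$strain),
                        method = config$correlation)
    }, error = function(e) stageStop("enrichment_stats", e))
  }

  summary <- c(
    list(nTested = length(tested),
         nReplicateRejected = nrow(scored$rejects),
         nGrowthExcluded = length(audit$growthExcluded),
         nPassing = nrow(passingScores)),
    called$summary,
    list(meanCV = collectionCV(passingScores),
         growthRateMean = gc$populationMean,
         growthRateSd = gc$populationSd))

  res <- new("ScreenResult", scores = scored$scores, growth = gc$status,
             calls = called$calls, enrichment = enrichment,
             concordance = conc, summary = summary, audit = audit)
  if (!is.null(config$outDir)) writeScreenResult(res, config$outDir)
  res
}

# Write every piece of a ScreenResult under dir (TSV tables, audit lists,
# summary JSON with 6 significant digits for report values).
writeScreenResult <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeResultTable(res@scores, file.path(dir, "scores.tsv"))
  writeResultTable(res@growth, file.path(dir, "growth_status.tsv"))
  writeResultTable(res@calls, file.path(dir, "phenotype_calls.tsv"))
  if (nrow(res@enrichment)) {
    writeResultTable(res@enrichment, file.path(dir, "enrichment.tsv"))
  }
  for (nm in names(res@audit)) {
    writeLines(res@audit[[nm]],
               file.path(dir, paste0("audit_", nm, ".txt")))
  }
  summ <- res@summary
  if (length(res@concordance)) summ$concordance <- res@concordance
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = 6)
  invisible(dir)
}

#' Recompute screen summary counts from external score/growth tables
#'
#' Re-applies the filter and calling stages to externally supplied
#' per-strain tables (e.g. a published screen's per-strain log10
#' vesiculation scores and mean growth rates): strains with growth rates
#' strictly outside `nSdGrowth` standard deviations of the rate mean are
#' excluded, cutoffs are computed on the remaining scores, and phenotypes
#' are called at `nSdCall` standard deviations. Useful for checking that
#' the stage logic reproduces a screen's reported counts from its own
#' deposited tables.
#'
#' @param vesiculation data.frame with columns `strain`, `log10_score` and
#'   optionally `cv`.
#' @param growthRates data.frame with columns `strain`, `rate` (per-strain
#'   mean maximum growth rate; strains already excluded for poor fits
#'   should simply be absent or carry NA).
#' @param nSdGrowth,nSdCall Filter widths in sd units.
#' @return Named list of counts and statistics: `nTested`,
#'   `nGrowthExcluded`, `nPassing`, `mean`, `sd`, `cutoffLow`,
#'   `cutoffHigh`, `nOver`, `nUnder`, `nSignificant`, and `meanCV` when a
#'   `cv` column is present, plus the per-strain `calls` table.
#' @export
recomputeScreenSummary <- function(vesiculation, growthRates,
                                   nSdGrowth = 1, nSdCall = 2) {
  assertColumns(vesiculation, c("strain", "log10_score"),
                "vesiculation table")
  assertColumns(growthRates, c("strain", "rate"), "growth rate table")
  rates <- growthRates[!is.na(growthRates$rate), , drop = FALSE]
  m <- mean(rates$rate)
  s <- sd(rates$rate)
  passed <- rates$strain[abs(rates$rate - m) <= nSdGrowth * s]
  ves <- vesiculation[vesiculation$strain %in% passed, , drop = FALSE]
  scores <- data.frame(strain = ves$strain, log10Score = ves$log10_score,
                       stringsAsFactors = FALSE)
  called <- callPhenotypes(scores, passed, nSd = nSdCall)
  out <- c(
    list(nTested = length(unique(vesiculation$strain)),
         nGrowthExcluded = length(setdiff(unique(vesiculation$strain),
                                          passed)),
         nPassing = nrow(scores)),
    called$summary)
  if ("cv" %in% names(vesiculation)) {
    out$meanCV <- mean(ves$cv, na.rm = TRUE)
  }
  out$calls <- called$calls
  out
}
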