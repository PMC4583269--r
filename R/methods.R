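#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("genes", "TrueLibrary", function(object) object@genes)

#' @rdname accessors
#' @export
setMethod("trueLogEffect", "TrueLibrary", function(object) {
  stats::setNames(object@trueLogEffect, object@genes)
})

#' @rdname accessors
#' @export
setMethod("growthDefective", "TrueLibrary", function(object) {
  stats::setNames(object@growthDefective, object@genes)
})

#' @rdname accessors
#' @export
setMethod("trueGrowthParams", "TrueLibrary",
          function(object) object@trueGrowthParams)

#' @rdname accessors
#' @export
setMethod("categoryMembership", "TrueLibrary",
          function(object) object@categoryMembership)

#' @rdname accessors
#' @export
setMethod("plantedCategories", "TrueLibrary",
          function(object) object@plantedCategories)

setMethod("show", "TrueLibrary", function(object) {
  eff <- object@trueLogEffect
  cat("TrueLibrary with", length(object@genes), "genes\n")
  cat("  planted effects:", sum(eff > 0), "over /", sum(eff < 0),
      "under (|log10 shift| up to", format(max(abs(eff))), ")\n")
  cat("  growth defective:", sum(object@growthDefective), "\n")
  cat("  categories:", length(unique(object@categoryMembership$category)),
      "(", length(object@plantedCategories), "planted )\n")
})

#' @rdname accessors
#' @export
setMethod("categories", "AnnotationSet", function(object) object@categories)

#' @rdname accessors
#' @export
setMethod("universe", "AnnotationSet", function(object) object@universe)

setMethod("show", "AnnotationSet", function(object) {
  sizes <- lengths(object@categories)
  cat("AnnotationSet:", length(object@categories), "categories over",
      length(object@universe), "genes\n")
  if (length(sizes)) {
    cat("  category sizes:", min(sizes), "-", max(sizes),
        "(median", stats::median(sizes), ")\n")
  }
})

setMethod("show", "GompertzFit", function(object) {
  cat("GompertzFit:",
      if (object@converged) "converged" else "NOT converged", "\n")
  cat(sprintf("  y0 = %.4g, A = %.4g, muMax = %.4g OD/h, lag = %.4g h\n",
              object@y0, object@A, object@muMax, object@lag))
  cat("  R-squared =",
      if (is.na(object@rSquared)) "NA (flat curve)"
      else format(object@rSquared, digits = 4), "\n")
})

#' @rdname accessors
#' @export
setMethod("scores", "ScreenResult", function(object) object@scores)

#' @rdname accessors
#' @export
setMethod("growthStatus", "ScreenResult", function(object) object@growth)

#' @rdname accessors
#' @export
setMethod("phenotypeCalls", "ScreenResult", function(object) object@calls)

#' @rdname accessors
#' @export
setMethod("enrichmentResults", "ScreenResult",
          function(object) object@enrichment)

#' @rdname accessors
#' @export
setMethod("concordance", "ScreenResult", function(object) object@concordance)

#' @rdname accessors
#' @export
setMethod("screenSummary", "ScreenResult", function(object) object@summary)

#' @rdname accessors
#' @export
setMethod("auditTrail", "ScreenResult", function(object) object@audit)

setMethod("show", "ScreenResult", function(object) {
  s <- object@summary
  cat("ScreenResult\n")
  cat("  strains tested:          ", s$nTested, "\n")
  cat("  replicate-rejected:      ", s$nReplicateRejected, "\n")
  cat("  growth-excluded:         ", s$nGrowthExcluded, "\n")
  cat("  passing growth filter:   ", s$nPassing, "\n")
  cat(sprintf("  collection mean (log10): %.4g  sd: %.4g\n", s$mean, s$sd))
  cat(sprintf("  cutoffs: < %.4g or > %.4g\n", s$cutoffLow, s$cutoffHigh))
  cat("  significant:", s$nSignificant, "(", s$nOver, "over /", s$nUnder,
      "under )\n")
  cat(sprintf("  mean replicate CV: %.1f%%\n", 100 * s$meanCV))
  if (nrow(object@enrichment)) {
    cat("  enriched categories (p <= alpha):",
        sum(object@enrichment$flagged), "\n")
  }
  if (length(object@concordance)) {
    cat(sprintf("  FCOP concordance: r = %.3f (p = %.3g), signs agree %d/%d\n",
                object@concordance$correlation, object@concordance$pValue,
                object@concordance$signAgree, object@concordance$signTotal))
  }
})
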