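#' Normalize FCOP measurements to wild type
#'
#' Converts flask-grown culture OMV preparation (FCOP) measurements into
#' per-strain vesiculation values: each replicate's FM4-64 fluorescence is
#' divided by its CFU count, replicate ratios are averaged per strain, and
#' every strain's mean is divided by the wild-type mean. The wild type's
#' own value is therefore exactly 1, and the result is invariant to
#' rescaling all fluorescence readings by a common factor.
#'
#' @param measurements data.frame with columns `strain`, `replicate`,
#'   `fm464` (>= 0) and `cfu` (> 0).
#' @param wtLabel Wild-type strain identifier; must be present with at
#'   least 3 replicates.
#' @return data.frame with columns `strain`, `value`, `nReplicates`.
#' @examples
#' m <- data.frame(strain = c("WT", "WT", "WT", "x"),
#'                 replicate = c(1, 2, 3, 1),
#'                 fm464 = c(1000, 1100, 900, 2000),
#'                 cfu = 1e9)
#' fcopVesiculation(m)
#' @export
fcopVesiculation <- function(measurements, wtLabel = "WT") {
  assertColumns(measurements, c("strain", "replicate", "fm464", "cfu"),
                "FCOP table")
  bad <- which(!(measurements$cfu > 0))
  if (length(bad) > 0L) {
    stop("non-positive CFU in FCOP row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), " (strain ",
         measurements$strain[bad[1]], ")", call. = FALSE)
  }
  if (any(measurements$fm464 < 0)) {
    stop("negative FM4-64 fluorescence values", call. = FALSE)
  }
  if (!wtLabel %in% measurements$strain) {
    stop("wild-type strain '", wtLabel, "' missing from FCOP table",
         call. = FALSE)
  }
  ratio <- measurements$fm464 / measurements$cfu
  byStrain <- split(ratio, measurements$strain)
  if (length(byStrain[[wtLabel]]) < 3L) {
    stop("wild type needs at least 3 FCOP replicates", call. = FALSE)
  }
  wtMean <- mean(byStrain[[wtLabel]])
  out <- data.frame(
    strain = names(byStrain),
    value = vapply(byStrain, mean, numeric(1)) / wtMean,
    nReplicates = lengths(byStrain),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Concordance between screen scores and FCOP values
#'
#' Pairs per-strain high-throughput log10 vesiculation scores with
#' wild-type-normalized FCOP values (compared on the log10 scale) and
#' reports the correlation with a one-sided p-value (alternative: positive
#' association) plus a sign-agreement count: a pair agrees when the signs
#' of the screen score and of log10(FCOP) match, with an exact zero on
#' either side counting as agreement.
#'
#' @param htp Named numeric vector of log10 screen scores.
#' @param fcop Named numeric vector of positive normalized FCOP values.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Named list: `nPairs`, `correlation`, `pValue`, `signAgree`,
#'   `signTotal`.
#' @examples
#' htp <- c(a = 0.5, b = -0.4, c = 0.1)
#' fcop <- c(a = 3, b = 0.5, c = 1.2)
#' methodConcordance(htp, fcop)
#' @export
methodConcordance <- function(htp, fcop, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.null(names(htp)) || is.null(names(fcop))) {
    stop("'htp' and 'fcop' must be named by strain", call. = FALSE)
  }
  common <- intersect(names(htp), names(fcop))
  dropped <- length(htp) + length(fcop) - 2 * length(common)
  if (dropped > 0L) {
    warning(dropped, " unpaired strain entr(ies) dropped", call. = FALSE)
  }
  if (length(common) < 3L) {
    stop("need at least 3 paired strains", call. = FALSE)
  }
  y <- fcop[common]
  if (any(!(y > 0))) {
    stop("FCOP values must be positive to take log10", call. = FALSE)
  }
  x <- as.numeric(htp[common])
  ly <- log10(as.numeric(y))
  ct <- suppressWarnings(
    stats::cor.test(x, ly, method = method, alternative = "greater",
                    exact = FALSE))
  agree <- sign(x) == sign(ly) | x == 0 | ly == 0
  list(nPairs = length(common),
       correlation = unname(ct$estimate),
       pValue = ct$p.value,
       signAgree = sum(agree),
       signTotal = length(common))
}
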