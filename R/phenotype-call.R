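#' Collection cutoffs for phenotype calling
#'
#' Mean, sample standard deviation and the mean +/- `nSd` * sd cutoffs of a
#' vector of log10 vesiculation scores (normally the growth-passing
#' collection).
#'
#' @param scores Numeric vector of log10 scores (>= 3 finite values with
#'   positive spread).
#' @param nSd Cutoff width in sd units (default 2).
#' @return Named list: `mean`, `sd`, `cutoffLow`, `cutoffHigh`.
#' @examples
#' computeCutoffs(c(-1, 0, 1))   # cutoffs at -2 and 2
#' @export
computeCutoffs <- function(scores, nSd = 2) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 3L) {
    stop("need at least 3 finite scores to compute cutoffs", call. = FALSE)
  }
  m <- mean(scores)
  s <- sd(scores)
  if (s == 0) {
    stop("collection has zero score spread; cutoffs are degenerate",
         call. = FALSE)
  }
  list(mean = m, sd = s,
       cutoffLow = m - nSd * s, cutoffHigh = m + nSd * s)
}

#' Call over-/under-vesiculation phenotypes
#'
#' Applies the two-standard-deviation rule to the log10 scores of strains
#' that passed growth QC: a strain is `over` if its score is strictly
#' greater than mean + `nSd` * sd, `under` if strictly less than
#' mean - `nSd` * sd, otherwise `normal` (scores exactly at a cutoff are
#' normal). The cutoffs are computed on the supplied scores themselves,
#' which by contract are already restricted to growth-passing strains;
#' passing a score for a strain absent from `passedStrains` is a pipeline
#' ordering error.
#'
#' @param scores Score data.frame from [scoreStrains()] (needs `strain`,
#'   `log10Score`), restricted to growth-passing strains.
#' @param passedStrains Character vector of strains that passed growth QC.
#' @param nSd Cutoff width in sd units (default 2).
#' @return List with `calls` (data.frame: `strain`, `log10Score`, `call`,
#'   `cutoffLow`, `cutoffHigh`) and `summary` (list: `mean`, `sd`,
#'   `cutoffLow`, `cutoffHigh`, `nOver`, `nUnder`, `nSignificant`,
#'   `nTotal`).
#' @examples
#' s <- data.frame(strain = letters[1:5],
#'                 log10Score = c(-0.1, 0, 0.05, 0.1, 2))
#' callPhenotypes(s, letters[1:5])$summary
#' @export
callPhenotypes <- function(scores, passedStrains, nSd = 2) {
  assertColumns(scores, c("strain", "log10Score"), "score table")
  missing <- setdiff(scores$strain, passedStrains)
  if (length(missing) > 0L) {
    stop("scores contain strain(s) not in the growth pass list (growth QC ",
         "must run first): ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  co <- computeCutoffs(scores$log10Score, nSd = nSd)
  call <- ifelse(scores$log10Score > co$cutoffHigh, "over",
          ifelse(scores$log10Score < co$cutoffLow, "under", "normal"))
  calls <- data.frame(
    strain = scores$strain,
    log10Score = scores$log10Score,
    call = call,
    cutoffLow = co$cutoffLow,
    cutoffHigh = co$cutoffHigh,
    stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  summary <- list(
    mean = co$mean, sd = co$sd,
    cutoffLow = co$cutoffLow, cutoffHigh = co$cutoffHigh,
    nOver = sum(call == "over"),
    nUnder = sum(call == "under"),
    nSignificant = sum(call != "normal"),
    nTotal = length(call))
  list(calls = calls, summary = summary)
}
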