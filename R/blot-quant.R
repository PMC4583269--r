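#' Normalize one membrane's densitometry values to its mean
#'
#' Divides every well's raw intensity by the mean intensity of the membrane,
#' the per-membrane correction for day-to-day blotting variation. Wells with
#' non-positive or missing intensities are excluded from the mean and
#' returned as NA (a missing replicate); the mean of the remaining
#' normalized wells is exactly 1.
#'
#' @param intensities Numeric vector of raw intensities for one membrane.
#' @param membraneId Optional identifier used in error messages.
#' @return Numeric vector of normalized values (NA where excluded), with
#'   attribute `nExcluded` giving the number of excluded wells.
#' @examples
#' normalizeMembrane(c(2, 4, 6))   # 0.5, 1.0, 1.5
#' @export
normalizeMembrane <- function(intensities, membraneId = NULL) {
  if (!is.numeric(intensities) || length(intensities) == 0L) {
    stop("'intensities' must be a non-empty numeric vector", call. = FALSE)
  }
  ok <- !is.na(intensities) & intensities > 0
  if (!any(ok)) {
    stop("membrane ", if (is.null(membraneId)) "" else membraneId,
         " has no positive intensities; cannot normalize", call. = FALSE)
  }
  out <- intensities / mean(intensities[ok])
  out[!ok] <- NA_real_
  attr(out, "nExcluded") <- sum(!ok)
  out
}

#' Score strains from raw blot measurements
#'
#' The core densitometry-to-score step: normalizes each membrane to its
#' mean ([normalizeMembrane()]), pools each strain's normalized replicate
#' values across membranes, and reports the replicate mean on the linear
#' scale, its log10, and the replicate coefficient of variation
#' (sample sd / mean of the unlogged normalized values). Strains with fewer
#' than `minReplicates` usable values go to a rejects table instead of the
#' score table.
#'
#' @param measurements data.frame with columns `strain`, `membrane_id`,
#'   `replicate`, `raw_intensity`. Duplicate (strain, membrane, replicate)
#'   rows are an error.
#' @param minReplicates Minimum usable replicates per strain (default 2).
#' @param average `"linear"` (default: mean of normalized values, then
#'   log10) or `"log"` (mean of log10 normalized values; `meanLinear` is
#'   then the back-transformed score).
#' @return List with elements `scores` (data.frame: `strain`,
#'   `nReplicates`, `meanLinear`, `log10Score`, `cv`) and `rejects`
#'   (data.frame: `strain`, `nReplicates`, `reason`).
#' @examples
#' m <- data.frame(strain = rep(c("a", "b"), 2),
#'                 membrane_id = rep(c("M1", "M2"), each = 2),
#'                 replicate = rep(1:2, each = 2),
#'                 raw_intensity = c(2, 4, 3, 6))
#' scoreStrains(m)$scores
#' @export
scoreStrains <- function(measurements, minReplicates = 2L,
                         average = c("linear", "log")) {
  average <- match.arg(average)
  assertColumns(measurements,
                c("strain", "membrane_id", "replicate", "raw_intensity"),
                "blot measurement table")
  key <- paste(measurements$strain, measurements$membrane_id,
               measurements$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- measurements[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate measurement for strain ", dup$strain, " on membrane ",
         dup$membrane_id, " replicate ", dup$replicate, call. = FALSE)
  }
  norm <- unsplit(
    lapply(split(measurements$raw_intensity, measurements$membrane_id),
           function(x) as.numeric(normalizeMembrane(x))),
    measurements$membrane_id)

  vals <- split(norm, measurements$strain)
  n <- vapply(vals, function(v) sum(!is.na(v)), integer(1))
  keep <- n >= minReplicates
  scoreOne <- function(v) {
    v <- v[!is.na(v)]
    m <- mean(v)
    s <- if (average == "linear") log10(m) else mean(log10(v))
    c(meanLinear = if (average == "linear") m else 10^s,
      log10Score = s,
      cv = sd(v) / m)
  }
  sc <- vapply(vals[keep], scoreOne, numeric(3))
  scoresDf <- data.frame(
    strain = names(vals)[keep],
    nReplicates = unname(n[keep]),
    meanLinear = unname(sc["meanLinear", ]),
    log10Score = unname(sc["log10Score", ]),
    cv = unname(sc["cv", ]),
    stringsAsFactors = FALSE)
  rejectsDf <- data.frame(
    strain = names(vals)[!keep],
    nReplicates = unname(n[!keep]),
    reason = if (any(!keep)) "insufficient replicates" else character(),
    stringsAsFactors = FALSE)
  rownames(scoresDf) <- rownames(rejectsDf) <- NULL
  list(scores = scoresDf, rejects = rejectsDf)
}

#' Mean replicate CV over a strain subset
#'
#' Arithmetic mean of the per-strain coefficients of variation, the
#' collection-level reproducibility figure usually reported for the strains
#' passing the growth filter.
#'
#' @param scores Score data.frame from [scoreStrains()].
#' @param include Optional character vector of strains to average over
#'   (default: all scored strains). Must select at least one strain.
#' @return Mean CV (a fraction, not a percentage).
#' @examples
#' s <- data.frame(strain = c("a", "b"), cv = c(0.2, 0.3))
#' collectionCV(s)   # 0.25
#' @export
collectionCV <- function(scores, include = NULL) {
  assertColumns(scores, c("strain", "cv"), "score table")
  if (!is.null(include)) {
    scores <- scores[scores$strain %in% include, , drop = FALSE]
  }
  if (nrow(scores) == 0L) {
    stop("no strains selected for the CV summary", call. = FALSE)
  }
  mean(scores$cv)
}
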