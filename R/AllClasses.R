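#' @import methods
NULL

#' Ground-truth library for synthetic screens
#'
#' Container for the known truth behind a simulated knockout-library screen:
#' which genes carry planted over-/under-vesiculation effects (as log10
#' shifts), which are growth defective, each gene's true Gompertz growth
#' parameters, and which functional categories were planted as enriched.
#' Built by [generateLibrary()]; consumed by the `simulate*Dataset()`
#' functions and by recovery tests.
#'
#' @slot genes Character vector of unique gene identifiers.
#' @slot trueLogEffect Numeric vector parallel to `genes`: the true log10
#'   vesiculation shift (0 for neutral genes).
#' @slot growthDefective Logical vector parallel to `genes`.
#' @slot trueGrowthParams data.frame with columns `gene`, `y0` (baseline
#'   OD600), `A` (amplitude above baseline), `muMax` (maximum growth rate,
#'   OD600/h) and `lag` (h).
#' @slot categoryMembership data.frame with columns `gene`, `category` (one
#'   row per membership).
#' @slot plantedCategories Character vector of category ids planted as
#'   enriched for effect genes.
#'
#' @seealso [generateLibrary()], [simulateBlotDataset()],
#'   [simulateGrowthDataset()], [simulateFcopDataset()]
#' @export
setClass("TrueLibrary",
  representation(
    genes = "character",
    trueLogEffect = "numeric",
    growthDefective = "logical",
    trueGrowthParams = "data.frame",
    categoryMembership = "data.frame",
    plantedCategories = "character"
  )
)

setValidity("TrueLibrary", function(object) {
  msg <- character()
  n <- length(object@genes)
  if (anyDuplicated(object@genes)) msg <- c(msg, "gene ids must be unique")
  if (length(object@trueLogEffect) != n)
    msg <- c(msg, "trueLogEffect length must match genes")
  if (length(object@growthDefective) != n)
    msg <- c(msg, "growthDefective length must match genes")
  if (any(!is.finite(object@trueLogEffect)))
    msg <- c(msg, "trueLogEffect must be finite")
  gp <- object@trueGrowthParams
  need <- c("gene", "y0", "A", "muMax", "lag")
  if (!all(need %in% names(gp))) {
    msg <- c(msg, "trueGrowthParams must have columns gene, y0, A, muMax, lag")
  } else if (!setequal(gp$gene, object@genes)) {
    msg <- c(msg, "trueGrowthParams must cover exactly the library genes")
  }
  cm <- object@categoryMembership
  if (!all(c("gene", "category") %in% names(cm))) {
    msg <- c(msg, "categoryMembership must have columns gene, category")
  } else {
    if (!all(cm$gene %in% object@genes))
      msg <- c(msg, "category members must exist in the library")
    if (!all(object@plantedCategories %in% cm$category))
      msg <- c(msg, "planted categories must exist in categoryMembership")
  }
  if (length(msg)) msg else TRUE
})

#' Flat functional annotation sets
#'
#' A GO-style flat annotation: named gene sets (categories) over a gene
#' universe, with no ontology graph. Category members outside the universe
#' are dropped at construction with a message. Used by
#' [enrichCategories()].
#'
#' @slot categories Named list of character vectors (category id -> member
#'   genes within the universe).
#' @slot categoryNames Named character vector of human-readable names,
#'   parallel to `categories`.
#' @slot universe Character vector of unique gene identifiers.
#'
#' @seealso [AnnotationSet()], [enrichCategories()], [readAnnotationTable()]
#' @export
setClass("AnnotationSet",
  representation(
    categories = "list",
    categoryNames = "character",
    universe = "character"
  )
)

setValidity("AnnotationSet", function(object) {
  msg <- character()
  if (anyDuplicated(object@universe))
    msg <- c(msg, "universe must not contain duplicates")
  if (is.null(names(object@categories)) ||
      anyDuplicated(names(object@categories)))
    msg <- c(msg, "categories must be uniquely named")
  if (!identical(sort(names(object@categories)),
                 sort(names(object@categoryNames))))
    msg <- c(msg, "categoryNames must be named for exactly the categories")
  bad <- vapply(object@categories,
                function(g) !all(g %in% object@universe), logical(1))
  if (any(bad))
    msg <- c(msg, "all category members must lie in the universe")
  if (length(msg)) msg else TRUE
})

#' Constructor for [AnnotationSet-class]
#'
#' @param membership data.frame with columns `category`, `gene` and
#'   optionally `name` (one row per membership).
#' @param universe Character vector of gene ids defining the background.
#' @return An [AnnotationSet-class]. Members outside `universe` are dropped
#'   with a message reporting the count.
#' @examples
#' ann <- AnnotationSet(
#'   data.frame(category = c("C1", "C1", "C2"),
#'              gene = c("g1", "g2", "g2")),
#'   universe = c("g1", "g2", "g3"))
#' categories(ann)
#' @export
AnnotationSet <- function(membership, universe) {
  assertColumns(membership, c("category", "gene"), "annotation membership")
  universe <- unique(as.character(universe))
  membership$category <- as.character(membership$category)
  membership$gene <- as.character(membership$gene)
  outside <- !(membership$gene %in% universe)
  if (any(outside)) {
    message(sum(outside),
            " annotation membership row(s) outside the universe dropped")
    membership <- membership[!outside, , drop = FALSE]
  }
  cats <- lapply(split(membership$gene, membership$category), unique)
  if ("name" %in% names(membership)) {
    nm <- vapply(split(as.character(membership$name), membership$category),
                 function(x) x[1], character(1))
  } else {
    nm <- stats::setNames(names(cats), names(cats))
  }
  new("AnnotationSet", categories = cats,
      categoryNames = nm[names(cats)], universe = universe)
}

#' Fitted modified Gompertz growth curve
#'
#' Result of [fitGompertz()]: the four Zwietering-parameterized Gompertz
#' parameters, the coefficient of determination on the raw OD values, and a
#' convergence flag. Non-converged fits keep whatever R-squared could be
#' computed (NA when the curve is flat) and are treated as poor fits
#' downstream.
#'
#' @slot y0 Baseline OD600.
#' @slot A Amplitude (OD600 above baseline).
#' @slot muMax Maximum growth rate (OD600 per hour).
#' @slot lag Lag time (hours).
#' @slot rSquared Coefficient of determination (NA if total variance is 0).
#' @slot converged Logical: did the optimizer converge?
#'
#' @seealso [fitGompertz()], [classifyGrowth()]
#' @export
setClass("GompertzFit",
  representation(
    y0 = "numeric", A = "numeric", muMax = "numeric", lag = "numeric",
    rSquared = "numeric", converged = "logical"
  )
)

setValidity("GompertzFit", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L
  if (!all(vapply(list(object@y0, object@A, object@muMax, object@lag,
                       object@rSquared, object@converged), one, logical(1))))
    msg <- c(msg, "all slots must be length 1")
  if (isTRUE(object@converged)) {
    if (!(object@A > 0)) msg <- c(msg, "converged fits require A > 0")
    if (!(object@muMax >= 0)) msg <- c(msg, "converged fits require muMax >= 0")
  }
  if (!is.na(object@rSquared) &&
      (object@rSquared < -1e-8 || object@rSquared > 1 + 1e-8))
    msg <- c(msg, "rSquared must lie in [0, 1] when defined")
  if (length(msg)) msg else TRUE
})

#' Full screen result bundle
#'
#' Returned by [runPipeline()]: per-strain vesiculation scores, growth
#' statuses, phenotype calls, optional enrichment and concordance results,
#' the collection-level summary, and an audit trail partitioning every
#' input strain into replicate-rejected, growth-excluded or called.
#'
#' @slot scores data.frame from [scoreStrains()].
#' @slot growth data.frame from [classifyGrowth()].
#' @slot calls data.frame from [callPhenotypes()].
#' @slot enrichment data.frame from [enrichCategories()] (0 rows when no
#'   annotation was supplied).
#' @slot concordance List from [methodConcordance()] (empty when no FCOP
#'   data were supplied).
#' @slot summary Named list of collection-level statistics and counts.
#' @slot audit Named list of character vectors: `replicateRejected`,
#'   `growthExcluded`, `called`.
#'
#' @seealso [runPipeline()]
#' @export
setClass("ScreenResult",
  representation(
    scores = "data.frame",
    growth = "data.frame",
    calls = "data.frame",
    enrichment = "data.frame",
    concordance = "list",
    summary = "list",
    audit = "list"
  )
)
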