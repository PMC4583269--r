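#' @include AllClasses.R
NULL

#' Accessors for screen objects
#'
#' Accessor generics for the S4 containers used across the package:
#' [TrueLibrary-class], [AnnotationSet-class], [GompertzFit-class] and
#' [ScreenResult-class]. Use these rather than reaching into slots.
#'
#' @param object An S4 object from this package.
#' @return The requested component; see the class documentation for the
#'   shape of each.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genes", function(object) standardGeneric("genes"))

#' @rdname accessors
#' @export
setGeneric("trueLogEffect", function(object) standardGeneric("trueLogEffect"))

#' @rdname accessors
#' @export
setGeneric("growthDefective",
           function(object) standardGeneric("growthDefective"))

#' @rdname accessors
#' @export
setGeneric("trueGrowthParams",
           function(object) standardGeneric("trueGrowthParams"))

#' @rdname accessors
#' @export
setGeneric("categoryMembership",
           function(object) standardGeneric("categoryMembership"))

#' @rdname accessors
#' @export
setGeneric("plantedCategories",
           function(object) standardGeneric("plantedCategories"))

#' @rdname accessors
#' @export
setGeneric("categories", function(object) standardGeneric("categories"))

#' @rdname accessors
#' @export
setGeneric("universe", function(object) standardGeneric("universe"))

#' @rdname accessors
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("growthStatus", function(object) standardGeneric("growthStatus"))

#' @rdname accessors
#' @export
setGeneric("phenotypeCalls", function(object) standardGeneric("phenotypeCalls"))

#' @rdname accessors
#' @export
setGeneric("enrichmentResults",
           function(object) standardGeneric("enrichmentResults"))

#' @rdname accessors
#' @export
setGeneric("concordance", function(object) standardGeneric("concordance"))

#' @rdname accessors
#' @export
setGeneric("screenSummary", function(object) standardGeneric("screenSummary"))

#' @rdname accessors
#' @export
setGeneric("auditTrail", function(object) standardGeneric("auditTrail"))
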