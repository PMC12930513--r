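#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Standard accessors for the package's S4 containers: `wells()` returns a
#' PlateMap's occupied-well table, `labwareId()` and `plateFormat()` its
#' identity; `instructions()`, `deck()` and `stages()` expose an
#' InstructionPlan; `violations()` and `finalWells()` a SimReport;
#' `componentTable()` a ReactionPlan's component rows; `totalDuration()`
#' the run time of a ThermalProfile in seconds.
#'
#' @param x an object of the documented class.
#' @return see Details of each method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wells", function(x) standardGeneric("wells"))

#' @rdname accessors
#' @export
setGeneric("labwareId", function(x) standardGeneric("labwareId"))

#' @rdname accessors
#' @export
setGeneric("plateFormat", function(x) standardGeneric("plateFormat"))

#' @rdname accessors
#' @export
setGeneric("instructions", function(x) standardGeneric("instructions"))

#' @rdname accessors
#' @export
setGeneric("deck", function(x) standardGeneric("deck"))

#' @rdname accessors
#' @export
setGeneric("stages", function(x) standardGeneric("stages"))

#' @rdname accessors
#' @export
setGeneric("initialContents", function(x) standardGeneric("initialContents"))

#' @rdname accessors
#' @export
setGeneric("reactionPlans", function(x) standardGeneric("reactionPlans"))

#' @rdname accessors
#' @export
setGeneric("violations", function(x) standardGeneric("violations"))

#' @rdname accessors
#' @export
setGeneric("finalWells", function(x) standardGeneric("finalWells"))

#' @rdname accessors
#' @export
setGeneric("tipsConsumed", function(x) standardGeneric("tipsConsumed"))

#' @rdname accessors
#' @export
setGeneric("componentTable", function(x) standardGeneric("componentTable"))

#' @rdname accessors
#' @export
setGeneric("waterTopup", function(x) standardGeneric("waterTopup"))

#' @rdname accessors
#' @export
setGeneric("totalDuration", function(x) standardGeneric("totalDuration"))

#' @rdname accessors
#' @export
setGeneric("passed", function(x) standardGeneric("passed"))

#' @rdname accessors
#' @export
setGeneric("findings", function(x) standardGeneric("findings"))
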