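#' @rdname AlterationMatrix
#' @export
setGeneric("alteredStatus", function(x) standardGeneric("alteredStatus"))

#' @rdname AlterationMatrix
#' @export
setGeneric("cancerType", function(x) standardGeneric("cancerType"))

#' @rdname FeatureMatrix
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname FeatureMatrix
#' @export
setGeneric("pairId", function(x) standardGeneric("pairId"))

#' @rdname FeatureMatrix
#' @export
setGeneric("tissueType", function(x) standardGeneric("tissueType"))

#' @rdname FeatureMatrix
#' @export
setGeneric("valueScale", function(x) standardGeneric("valueScale"))

#' @rdname CohortBundle
#' @export
setGeneric("alterations", function(x) standardGeneric("alterations"))

#' @rdname CohortBundle
#' @export
setGeneric("expressionData", function(x) standardGeneric("expressionData"))

#' @rdname CohortBundle
#' @export
setGeneric("survivalData", function(x) standardGeneric("survivalData"))

#' @rdname CohortBundle
#' @export
setGeneric("rppaData", function(x) standardGeneric("rppaData"))

#' @rdname CohortBundle
#' @export
setGeneric("mutantTable", function(x) standardGeneric("mutantTable"))

#' @rdname CohortBundle
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' @rdname PathwayDefinition
#' @export
setGeneric("positiveComponents",
           function(x) standardGeneric("positiveComponents"))

#' @rdname PathwayDefinition
#' @export
setGeneric("negativeComponents",
           function(x) standardGeneric("negativeComponents"))
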