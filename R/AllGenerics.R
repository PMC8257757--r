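## Generics for the S4 surface.  Accessor generics keep user code off slots.

#' @rdname StructureModel-accessors
#' @export
setGeneric("atomRecords", function(x) standardGeneric("atomRecords"))

#' @rdname StructureModel-accessors
#' @export
setGeneric("solventRecords", function(x) standardGeneric("solventRecords"))

#' @rdname StructureModel-accessors
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))

#' @rdname thermo-ops
#' @export
setGeneric("totalDeltaG", function(object) standardGeneric("totalDeltaG"))

#' @rdname thermo-ops
#' @export
setGeneric("activatedFraction",
           function(object, temperature = 298.15)
             standardGeneric("activatedFraction"))

#' @rdname thermo-ops
#' @export
setGeneric("apparentKcat", function(object) standardGeneric("apparentKcat"))

#' @rdname thermo-ops
#' @export
setGeneric("overallRate",
           function(object, esTotal) standardGeneric("overallRate"))

#' @rdname FitResult-accessors
#' @export
setGeneric("amplitude", function(x) standardGeneric("amplitude"))

#' @rdname FitResult-accessors
#' @export
setGeneric("kObs", function(x) standardGeneric("kObs"))

#' @rdname FitResult-accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname TimeCourse-accessors
#' @export
setGeneric("assayTimes", function(x) standardGeneric("assayTimes"))

#' @rdname TimeCourse-accessors
#' @export
setGeneric("productFractions", function(x) standardGeneric("productFractions"))
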