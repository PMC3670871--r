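#' @rdname trueRanking
#' @export
setGeneric("trueRanking", function(x) standardGeneric("trueRanking"))

#' @rdname designSubjects
#' @export
setGeneric("designSubjects",
           function(design, size, rep) standardGeneric("designSubjects"))

#' @rdname jaccardValues
#' @export
setGeneric("jaccardValues", function(x) standardGeneric("jaccardValues"))

#' @rdname rankTable
#' @export
setGeneric("rankTable", function(x) standardGeneric("rankTable"))

#' @rdname rankTable
#' @export
setGeneric("topFeatures", function(x) standardGeneric("topFeatures"))

#' @rdname curveTable
#' @export
setGeneric("curveTable", function(x) standardGeneric("curveTable"))

#' @rdname predictClasses
#' @export
setGeneric("predictClasses",
           function(model, x, ...) standardGeneric("predictClasses"))
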