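#' @rdname toRelative
#' @export
setGeneric("toRelative", function(x, ...) standardGeneric("toRelative"))

#' @rdname collapseToGenus
#' @export
setGeneric("collapseToGenus", function(x, taxonomy, ...)
  standardGeneric("collapseToGenus"))

#' @rdname topTaxa
#' @export
setGeneric("topTaxa", function(x, n, ...) standardGeneric("topTaxa"))

#' @rdname clrTransform
#' @export
setGeneric("clrTransform", function(x, pseudocount = 0.5, ...)
  standardGeneric("clrTransform"))

#' @rdname screenReplicates
#' @export
setGeneric("screenReplicates", function(x, ...)
  standardGeneric("screenReplicates"))

#' @rdname fitResponseModel
#' @export
setGeneric("fitResponseModel", function(x, ...)
  standardGeneric("fitResponseModel"))

#' @rdname searchStableEnsemble
#' @export
setGeneric("searchStableEnsemble", function(x, ...)
  standardGeneric("searchStableEnsemble"))

#' @rdname occupancyIndex
#' @export
setGeneric("occupancyIndex", function(x, ...)
  standardGeneric("occupancyIndex"))

#' @rdname fitNeutralModel
#' @export
setGeneric("fitNeutralModel", function(x, ...)
  standardGeneric("fitNeutralModel"))

#' @rdname nicheBreadth
#' @export
setGeneric("nicheBreadth", function(x, ...) standardGeneric("nicheBreadth"))
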