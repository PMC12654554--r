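#' @include AllClasses.R
NULL

#' @rdname filterFeatures
#' @export
setGeneric("filterFeatures", function(x, ...) standardGeneric("filterFeatures"))

#' @rdname relativeAbundance
#' @export
setGeneric("relativeAbundance",
           function(x, ...) standardGeneric("relativeAbundance"))

#' @rdname alphaDiversity
#' @export
setGeneric("alphaDiversity", function(x, ...) standardGeneric("alphaDiversity"))

#' @rdname brayCurtis
#' @export
setGeneric("brayCurtis", function(x, ...) standardGeneric("brayCurtis"))

#' @rdname aggregateTaxa
#' @export
setGeneric("aggregateTaxa",
           function(x, taxonomy, rank, ...) standardGeneric("aggregateTaxa"))

#' @rdname injectBatchEffect
#' @export
setGeneric("injectBatchEffect",
           function(x, batches, shift, ...) standardGeneric("injectBatchEffect"))
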