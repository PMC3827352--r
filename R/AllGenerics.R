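#' @include AllClasses.R
NULL

#' @export
setGeneric("epochs", function(x, ...) standardGeneric("epochs"))

#' @export
setGeneric("epochs<-", function(x, value) standardGeneric("epochs<-"))

#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))

#' @export
setGeneric("samplingInterval", function(x) standardGeneric("samplingInterval"))

#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @export
setGeneric("computeRatio", function(x, ...) standardGeneric("computeRatio"))
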