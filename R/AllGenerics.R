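#' @include AllClasses.R
NULL

#' @rdname accessors
#' @export
setGeneric("cellId", function(x) standardGeneric("cellId"))

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("animalId", function(x) standardGeneric("animalId"))

#' @rdname accessors
#' @export
setGeneric("site", function(x) standardGeneric("site"))

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname accessors
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))

#' @rdname accessors
#' @export
setGeneric("totalCount", function(x) standardGeneric("totalCount"))

#' @rdname accessors
#' @export
setGeneric("bins", function(x) standardGeneric("bins"))

#' @rdname accessors
#' @export
setGeneric("eventKey", function(x, ...) standardGeneric("eventKey"))
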