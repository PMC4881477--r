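#' @name SomaticConcord-generics
#' @title Accessor generics
#' @description Accessors for the core classes; use these rather than slot
#'   access.
#' @param x an object.
#' @param ... further arguments.
NULL

#' @rdname SomaticConcord-generics
#' @export
setGeneric("labName", function(x) standardGeneric("labName"))

#' @rdname SomaticConcord-generics
#' @export
setGeneric("sampleName", function(x) standardGeneric("sampleName"))

#' @rdname SomaticConcord-generics
#' @export
setGeneric("replicateName", function(x) standardGeneric("replicateName"))

#' @rdname SomaticConcord-generics
#' @export
setGeneric("mutationKeys", function(x, ...) standardGeneric("mutationKeys"))

#' @rdname SomaticConcord-generics
#' @export
setGeneric("callData", function(x, ...) standardGeneric("callData"))

#' @rdname SomaticConcord-generics
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname SomaticConcord-generics
#' @export
setGeneric("regionSize", function(x) standardGeneric("regionSize"))

#' @rdname SomaticConcord-generics
#' @export
setGeneric("regionSizeMb", function(x) standardGeneric("regionSizeMb"))

#' @rdname SomaticConcord-generics
#' @export
setGeneric("concordancePct", function(x) standardGeneric("concordancePct"))

#' @rdname SomaticConcord-generics
#' @export
setGeneric("sensitivityPct", function(x, ...) standardGeneric("sensitivityPct"))
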