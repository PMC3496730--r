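#' @rdname accessors
#' @export
setGeneric("temperatures", function(x) standardGeneric("temperatures"))

#' @rdname accessors
#' @export
setGeneric("fluorescence", function(x) standardGeneric("fluorescence"))

#' @rdname accessors
#' @export
setGeneric("plateLayout", function(x) standardGeneric("plateLayout"))

#' @rdname accessors
#' @export
setGeneric("wellIds", function(x) standardGeneric("wellIds"))

#' @rdname accessors
#' @export
setGeneric("tm", function(x) standardGeneric("tm"))

#' @rdname accessors
#' @export
setGeneric("dHm", function(x) standardGeneric("dHm"))

#' @rdname accessors
#' @export
setGeneric("dCp", function(x) standardGeneric("dCp"))

#' @rdname accessors
#' @export
setGeneric("ddg", function(x) standardGeneric("ddg"))

#' @rdname accessors
#' @export
setGeneric("ddgSigma", function(x) standardGeneric("ddgSigma"))

#' @rdname accessors
#' @export
setGeneric("isFlagged", function(x) standardGeneric("isFlagged"))

#' @rdname accessors
#' @export
setGeneric("fitFlag", function(x) standardGeneric("fitFlag"))
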