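#' Accessor generics for GestureKit containers
#'
#' `records()` and `communications()` return the record-level and
#' communication-level tables of a [CommunicationSet];
#' `actions()` returns the action-definition table of a [GestureCatalogue];
#' `nRecords()` and `nCommunications()` count rows.
#'
#' @param x a GestureKit container.
#' @return A `data.frame` (accessors) or a single integer (counters).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname accessors
#' @export
setGeneric("communications", function(x) standardGeneric("communications"))

#' @rdname accessors
#' @export
setGeneric("actions", function(x) standardGeneric("actions"))

#' @rdname accessors
#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))

#' @rdname accessors
#' @export
setGeneric("nCommunications", function(x) standardGeneric("nCommunications"))

#' @rdname accessors
#' @export
setGeneric("vocabularyVariables", function(x) standardGeneric("vocabularyVariables"))
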