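## Accessor generics and show methods.

#' Accessors
#'
#' Small accessor generics for the core classes: checklist identity,
#' metadata, taxon records and URIs.
#'
#' @param x an object.
#' @return \code{checklistId}: the id token; \code{meta}: a
#'   \linkS4class{ChecklistMeta}; \code{taxa}: a named list of
#'   \linkS4class{TaxonRecord}; \code{taxonUris}: character vector of URIs.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("checklistId", function(x) standardGeneric("checklistId"))

#' @rdname accessors
#' @export
setMethod("checklistId", "ChecklistMeta", function(x) x@checklistId)

#' @rdname accessors
#' @export
setMethod("checklistId", "Checklist", function(x) x@meta@checklistId)

#' @rdname accessors
#' @export
setGeneric("meta", function(x) standardGeneric("meta"))

#' @rdname accessors
#' @export
setMethod("meta", "Checklist", function(x) x@meta)

#' @rdname accessors
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' @rdname accessors
#' @export
setMethod("taxa", "Checklist", function(x) x@taxa)

#' @rdname accessors
#' @export
setMethod("taxa", "Corpus", function(x) {
  out <- unlist(lapply(x@checklists, function(cl) cl@taxa), recursive = FALSE,
                use.names = FALSE)
  names(out) <- vapply(out, function(t) t@uri, character(1))
  out
})

#' @rdname accessors
#' @export
setGeneric("taxonUris", function(x) standardGeneric("taxonUris"))

#' @rdname accessors
#' @export
setMethod("taxonUris", "Checklist", function(x) names(x@taxa))

#' @rdname accessors
#' @export
setMethod("taxonUris", "Corpus", function(x) names(taxa(x)))

#' @rdname accessors
#' @export
setGeneric("checklists", function(x) standardGeneric("checklists"))

#' @rdname accessors
#' @export
setMethod("checklists", "Corpus", function(x) x@checklists)

#' @rdname accessors
#' @export
setGeneric("mappings", function(x) standardGeneric("mappings"))

#' @rdname accessors
#' @export
setMethod("mappings", "Corpus", function(x) x@mappings)

#' @rdname accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname accessors
#' @export
setMethod("events", "Corpus", function(x) x@events)

## show methods -------------------------------------------------------------

setMethod("show", "ChecklistMeta", function(object) {
  cat(sprintf("ChecklistMeta '%s' (%s, %s%s)\n", object@checklistId,
              object@listType,
              if (is.na(object@yearPublished)) "no year"
              else object@yearPublished,
              if (identical(object@code, "unspecified")) ""
              else paste0(", ", object@code)))
})

setMethod("show", "TaxonRecord", function(object) {
  cat(sprintf("TaxonRecord %s [%s] '%s' (%s)\n", object@uri, object@rank,
              object@label, object@status@opinion))
})

setMethod("show", "Checklist", function(object) {
  ranks <- vapply(object@taxa, function(t) t@rank, character(1))
  cat(sprintf("Checklist '%s': %d taxa\n", object@meta@checklistId,
              length(object@taxa)))
  if (length(ranks)) {
    tab <- table(ranks)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
        "\n", sep = "")
  }
})

setMethod("show", "ConceptMapping", function(object) {
  cat(sprintf("<%s> %s <%s> [%s, %s]\n", object@sourceUri, object@relation,
              object@targetUri, object@mode, object@provenance))
})

setMethod("show", "ChangeEvent", function(object) {
  cat(sprintf("ChangeEvent %s: %s (%s) before={%s} after={%s}\n",
              object@eventId, object@changeType, object@when,
              paste(uriLocalName(object@beforeUris), collapse = ","),
              paste(uriLocalName(object@afterUris), collapse = ",")))
})

setMethod("show", "LSID", function(object) {
  cat(formatLsid(object), "\n", sep = "")
})

setMethod("show", "Corpus", function(object) {
  cat(sprintf("Corpus: %d checklist(s), %d taxa, %d mapping(s), %d event(s)\n",
              length(object@checklists), length(taxa(object)),
              length(object@mappings), length(object@events)))
})
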