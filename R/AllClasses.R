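#' @import methods
NULL

## ---------------------------------------------------------------------------
## Checklist metadata
## ---------------------------------------------------------------------------

#' Checklist metadata
#'
#' Identity and publication context of one species checklist: a short
#' URI-safe identifier token (used as the namespace segment of taxon URIs),
#' a title, the publication year, whether the list is static (published once)
#' or dynamic (continuously updated), and the nomenclatural code whose rules
#' the names follow (ICZN for zoology, ICN for botany).
#'
#' @slot checklistId URI-safe token, no \code{/}.
#' @slot title free-text title.
#' @slot yearPublished integer year; mandatory for static lists.
#' @slot listType \code{"static"} or \code{"dynamic"}.
#' @slot code \code{"ICZN"}, \code{"ICN"} or \code{"unspecified"}.
#' @name ChecklistMeta-class
#' @aliases ChecklistMeta-class
#' @exportClass ChecklistMeta
setClass("ChecklistMeta",
  representation(checklistId = "character", title = "character",
                 yearPublished = "integer", listType = "character",
                 code = "character"),
  prototype(title = "", yearPublished = NA_integer_, listType = "static",
            code = "unspecified"))

setValidity("ChecklistMeta", function(object) {
  msg <- character(0)
  if (!isUriSafeToken(object@checklistId))
    msg <- c(msg, "checklistId must be a non-empty URI-safe token (no '/')")
  if (!object@listType %in% c("static", "dynamic"))
    msg <- c(msg, "listType must be 'static' or 'dynamic'")
  if (!object@code %in% c("ICZN", "ICN", "unspecified"))
    msg <- c(msg, "code must be 'ICZN', 'ICN' or 'unspecified'")
  ## the year requirement of static lists is checked by validateChecklist
  ## (issues are data): imperfect metadata must still be loadable
  if (length(msg)) msg else TRUE
})

#' Construct checklist metadata
#'
#' @param checklistId URI-safe token identifying the checklist.
#' @param title optional title.
#' @param yearPublished publication year (mandatory for static lists).
#' @param listType \code{"static"} or \code{"dynamic"}.
#' @param code nomenclatural code: \code{"ICZN"}, \code{"ICN"} or
#'   \code{"unspecified"}.
#' @return A \linkS4class{ChecklistMeta} object.
#' @examples
#' ChecklistMeta("cerambycids1992", yearPublished = 1992, code = "ICZN")
#' @export
ChecklistMeta <- function(checklistId, title = "", yearPublished = NA,
                          listType = c("static", "dynamic"),
                          code = c("unspecified", "ICZN", "ICN")) {
  new("ChecklistMeta", checklistId = checklistId, title = title,
      yearPublished = as.integer(yearPublished),
      listType = match.arg(listType), code = match.arg(code))
}

## ---------------------------------------------------------------------------
## Name components
## ---------------------------------------------------------------------------

#' Authorship of a scientific name
#'
#' Zoological authorship is cited as \code{"Author, Year"}, in parentheses
#' when the species was originally described in a different genus. Botanical
#' names instead catenate the transferring author after the parenthesised
#' original author, e.g. \code{"(L.) A.J. Scot"}, carried here in
#' \code{combinationAuthors}.
#'
#' @slot authors ordered author name tokens of the original description.
#' @slot year 4-digit year of the original description, or \code{NA}.
#' @slot parenthesized logical; zoological parenthesisation flag.
#' @slot combinationAuthors authors of the current combination (botany).
#' @slot raw optional verbatim authorship string as found in the source.
#' @name Authorship-class
#' @exportClass Authorship
setClass("Authorship",
  representation(authors = "character", year = "integer",
                 parenthesized = "logical", combinationAuthors = "character",
                 raw = "character"),
  prototype(authors = character(0), year = NA_integer_, parenthesized = FALSE,
            combinationAuthors = character(0), raw = NA_character_))

setValidity("Authorship", function(object) {
  msg <- character(0)
  if (!is.na(object@year) &&
      (object@year < 1753L || object@year > 9999L))
    msg <- c(msg, "year must be a 4-digit integer >= 1753")
  if (length(object@parenthesized) != 1L || is.na(object@parenthesized))
    msg <- c(msg, "parenthesized must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' @rdname Authorship-class
#' @param authors,year,parenthesized,combinationAuthors,raw see slots.
#' @return An \linkS4class{Authorship} object.
#' @examples
#' Authorship("Mulsant", 1839, parenthesized = TRUE)
#' @export
Authorship <- function(authors = character(0), year = NA,
                       parenthesized = FALSE,
                       combinationAuthors = character(0), raw = NA_character_) {
  new("Authorship", authors = as.character(authors), year = as.integer(year),
      parenthesized = parenthesized,
      combinationAuthors = as.character(combinationAuthors), raw = raw)
}

setClassUnion("AuthorshipOrNULL", c("Authorship", "NULL"))

#' Publication reference
#'
#' @slot role \code{"original"} (the description) or \code{"subsequent"}.
#' @slot citation non-empty citation text.
#' @slot year optional year.
#' @name Publication-class
#' @exportClass Publication
setClass("Publication",
  representation(role = "character", citation = "character", year = "integer"),
  prototype(role = "original", citation = "", year = NA_integer_))

setValidity("Publication", function(object) {
  msg <- character(0)
  if (!object@role %in% c("original", "subsequent"))
    msg <- c(msg, "role must be 'original' or 'subsequent'")
  if (!isScalarString(object@citation) || !nzchar(object@citation))
    msg <- c(msg, "citation must be non-empty")
  if (length(msg)) msg else TRUE
})

#' @rdname Publication-class
#' @param role,citation,year see slots.
#' @export
Publication <- function(citation, role = c("original", "subsequent"),
                        year = NA) {
  new("Publication", role = match.arg(role), citation = citation,
      year = as.integer(year))
}

#' Vernacular (common) name
#'
#' @slot name the common name.
#' @slot language BCP-47-style language tag, e.g. \code{"fi"}.
#' @slot status \code{"accepted"} or \code{"alternative"}.
#' @name VernacularName-class
#' @exportClass VernacularName
setClass("VernacularName",
  representation(name = "character", language = "character",
                 status = "character"),
  prototype(status = "accepted"))

setValidity("VernacularName", function(object) {
  msg <- character(0)
  if (!isScalarString(object@name) || !nzchar(object@name))
    msg <- c(msg, "vernacular name must be non-empty")
  if (!isScalarString(object@language) || !nzchar(object@language))
    msg <- c(msg, "language tag must be non-empty")
  if (!object@status %in% c("accepted", "alternative"))
    msg <- c(msg, "status must be 'accepted' or 'alternative'")
  if (length(msg)) msg else TRUE
})

#' @rdname VernacularName-class
#' @param name,language,status see slots.
#' @export
VernacularName <- function(name, language,
                           status = c("accepted", "alternative")) {
  new("VernacularName", name = name, language = language,
      status = match.arg(status))
}

#' Status of a name/concept within a checklist
#'
#' Combines the current opinion on the concept (valid, synonym, ...) with an
#' optional nomenclatural note and, for dynamic checklists, the time stamp
#' from which the status holds.
#'
#' @slot opinion one of \code{statusVocabulary()}.
#' @slot note optional nomenclatural note (\code{"nomen_alternativum"},
#'   \code{"nomen_correctum"}, \code{"altered_spelling"},
#'   \code{"incorrect_spelling"}, \code{"other"}).
#' @slot timestamp optional instant (ISO-8601 text); required in dynamic
#'   checklists.
#' @name StatusAssignment-class
#' @exportClass StatusAssignment
setClass("StatusAssignment",
  representation(opinion = "character", note = "character",
                 timestamp = "character"),
  prototype(opinion = "valid", note = NA_character_,
            timestamp = NA_character_))

setValidity("StatusAssignment", function(object) {
  msg <- character(0)
  if (!object@opinion %in% statusVocabulary())
    msg <- c(msg, sprintf("unknown opinion '%s'", object@opinion))
  if (!is.na(object@note) &&
      !object@note %in% c("nomen_alternativum", "nomen_correctum",
                          "altered_spelling", "incorrect_spelling", "other"))
    msg <- c(msg, sprintf("unknown nomenclatural note '%s'", object@note))
  if (length(msg)) msg else TRUE
})

#' @rdname StatusAssignment-class
#' @param opinion,note,timestamp see slots.
#' @export
StatusAssignment <- function(opinion = "valid", note = NA_character_,
                             timestamp = NA_character_) {
  new("StatusAssignment", opinion = opinion, note = note,
      timestamp = timestamp)
}

## ---------------------------------------------------------------------------
## Taxon record and checklist
## ---------------------------------------------------------------------------

#' One scientific name and its concept inside one checklist
#'
#' The unit of the model: a record couples a uninomial label (the last
#' epithet for species-group names, the full name for higher taxa) with its
#' rank, its position in the checklist hierarchy (\code{parentUri}), its
#' status, authorship, publications, vernacular names and external
#' identifiers. Identity is the HTTP URI, which is per-checklist: the same
#' scientific name receives a new URI in every static checklist.
#'
#' @slot uri absolute HTTP URI.
#' @slot checklistId token of the containing checklist.
#' @slot rank rank name from the rank vocabulary.
#' @slot label uninomial name text.
#' @slot parentUri URI of the parent taxon, or \code{NA} for roots.
#' @slot status a \linkS4class{StatusAssignment}.
#' @slot authorship an \linkS4class{Authorship} or \code{NULL}.
#' @slot publications list of \linkS4class{Publication}.
#' @slot vernaculars list of \linkS4class{VernacularName}.
#' @slot externalIds character vector of LSIDs or URIs.
#' @slot acceptedUri URI of the valid name when this record is a synonym,
#'   rejected homonym or orthographic variant; \code{NA} otherwise.
#' @slot validFrom optional instant (dynamic lists).
#' @name TaxonRecord-class
#' @exportClass TaxonRecord
setClass("TaxonRecord",
  representation(uri = "character", checklistId = "character",
                 rank = "character", label = "character",
                 parentUri = "character", status = "StatusAssignment",
                 authorship = "AuthorshipOrNULL", publications = "list",
                 vernaculars = "list", externalIds = "character",
                 acceptedUri = "character", validFrom = "character"),
  prototype(parentUri = NA_character_, status = new("StatusAssignment"),
            authorship = NULL, publications = list(), vernaculars = list(),
            externalIds = character(0), acceptedUri = NA_character_,
            validFrom = NA_character_))

setValidity("TaxonRecord", function(object) {
  msg <- character(0)
  if (!isScalarString(object@uri) || !nzchar(object@uri))
    msg <- c(msg, "uri must be non-empty")
  if (!isScalarString(object@label) || !nzchar(object@label))
    msg <- c(msg, "label must be non-empty")
  if (!isScalarString(object@rank))
    msg <- c(msg, "rank must be a single string")
  if (length(msg)) msg else TRUE
})

#' @rdname TaxonRecord-class
#' @param uri,checklistId,rank,label,parentUri,status,authorship,publications
#'   see slots.
#' @param vernaculars,externalIds,acceptedUri,validFrom see slots.
#' @return A \linkS4class{TaxonRecord}.
#' @export
TaxonRecord <- function(uri, checklistId, rank, label,
                        parentUri = NA_character_,
                        status = StatusAssignment(),
                        authorship = NULL, publications = list(),
                        vernaculars = list(), externalIds = character(0),
                        acceptedUri = NA_character_,
                        validFrom = NA_character_) {
  new("TaxonRecord", uri = uri, checklistId = checklistId, rank = rank,
      label = label, parentUri = parentUri, status = status,
      authorship = authorship, publications = publications,
      vernaculars = vernaculars, externalIds = externalIds,
      acceptedUri = acceptedUri, validFrom = validFrom)
}

#' A species checklist
#'
#' Metadata plus taxon records, keyed by URI. Structural invariants (acyclic
#' hierarchy, synonym wiring, ...) are checked by
#' \code{\link{validateChecklist}}, which reports issues as data rather than
#' failing construction: real checklists are imperfect and must still load.
#'
#' @slot meta a \linkS4class{ChecklistMeta}.
#' @slot taxa named list of \linkS4class{TaxonRecord}, names = URIs.
#' @name Checklist-class
#' @exportClass Checklist
setClass("Checklist",
  representation(meta = "ChecklistMeta", taxa = "list"))

setValidity("Checklist", function(object) {
  msg <- character(0)
  if (!all(vapply(object@taxa, is, logical(1), "TaxonRecord")))
    msg <- c(msg, "taxa must all be TaxonRecord objects")
  uris <- vapply(object@taxa, function(t) t@uri, character(1))
  if (length(uris) && !identical(unname(names(object@taxa)), unname(uris)))
    msg <- c(msg, "taxa list must be named by record URIs")
  if (length(msg)) msg else TRUE
})

#' @rdname Checklist-class
#' @param meta,taxa see slots; \code{taxa} may be an unnamed list, names are
#'   derived from the record URIs.
#' @export
Checklist <- function(meta, taxa = list()) {
  names(taxa) <- vapply(taxa, function(t) t@uri, character(1))
  new("Checklist", meta = meta, taxa = taxa)
}

## ---------------------------------------------------------------------------
## Name keys, mappings, general taxa
## ---------------------------------------------------------------------------

#' Normalised matching key of a scientific name
#'
#' The criterion for automatic concept mapping and for diff matching: two
#' taxa match when they share the lower-cased epithet, the canonicalised
#' first-author surname and the year of description. The genus part is
#' deliberately absent so that genus transfers do not break the match.
#'
#' @slot epithet lower-cased label.
#' @slot author canonical first-author token (\code{""} if authorless).
#' @slot year integer year or \code{NA}.
#' @name NameKey-class
#' @exportClass NameKey
setClass("NameKey",
  representation(epithet = "character", author = "character",
                 year = "integer"),
  prototype(author = "", year = NA_integer_))

setValidity("NameKey", function(object) {
  if (!isScalarString(object@epithet) || !nzchar(object@epithet))
    "epithet must be non-empty" else TRUE
})

#' @rdname NameKey-class
#' @param epithet,author,year see slots.
#' @export
NameKey <- function(epithet, author = "", year = NA) {
  new("NameKey", epithet = tolower(epithet), author = author,
      year = as.integer(year))
}

#' A typed, directed assertion between two taxon concepts
#'
#' Relations follow the checklist relation algebra: \emph{congruent}
#' (A = B; symmetric, transitive), \emph{part_of} (A is properly contained
#' in B; directed, transitive), \emph{overlaps} (proper partial
#' intersection; symmetric, not transitive) and \emph{associated} (an
#' undetermined connection, used when expertise to classify the relation is
#' lacking). The mode records whether the comparison is ostensive (shared
#' member species) or intensional (shared characters); it is metadata and
#' never changes the algebra.
#'
#' @slot sourceUri subject taxon URI.
#' @slot targetUri object taxon URI, possibly an external LSID/URI.
#' @slot relation \code{"congruent"}, \code{"part_of"}, \code{"overlaps"} or
#'   \code{"associated"}.
#' @slot mode \code{"intensional"}, \code{"ostensive"} or \code{"n/a"}.
#' @slot provenance \code{"manual"} or \code{"automatic"}.
#' @slot timestamp optional instant.
#' @name ConceptMapping-class
#' @exportClass ConceptMapping
setClass("ConceptMapping",
  representation(sourceUri = "character", targetUri = "character",
                 relation = "character", mode = "character",
                 provenance = "character", timestamp = "character"),
  prototype(mode = "ostensive", provenance = "manual",
            timestamp = NA_character_))

setValidity("ConceptMapping", function(object) {
  msg <- character(0)
  if (!object@relation %in% c("congruent", "part_of", "overlaps",
                              "associated"))
    msg <- c(msg, sprintf("unknown relation '%s'", object@relation))
  if (!object@mode %in% c("intensional", "ostensive", "n/a"))
    msg <- c(msg, sprintf("unknown mode '%s'", object@mode))
  if (!object@provenance %in% c("manual", "automatic"))
    msg <- c(msg, "provenance must be 'manual' or 'automatic'")
  if (identical(object@relation, "associated") &&
      !identical(object@mode, "n/a"))
    msg <- c(msg, "associated mappings carry mode 'n/a'")
  if (identical(object@sourceUri, object@targetUri))
    msg <- c(msg, "source and target must differ")
  if (length(msg)) msg else TRUE
})

#' @rdname ConceptMapping-class
#' @param sourceUri,targetUri,relation,mode,provenance,timestamp see slots.
#' @export
ConceptMapping <- function(sourceUri, targetUri,
                           relation = c("congruent", "part_of", "overlaps",
                                        "associated"),
                           mode = c("ostensive", "intensional", "n/a"),
                           provenance = c("manual", "automatic"),
                           timestamp = NA_character_) {
  relation <- match.arg(relation)
  mode <- if (identical(relation, "associated")) "n/a" else match.arg(mode)
  new("ConceptMapping", sourceUri = sourceUri, targetUri = targetUri,
      relation = relation, mode = mode, provenance = match.arg(provenance),
      timestamp = timestamp)
}

#' A taxon at a high level of abstraction
#'
#' Groups every checklist-level taxon in a corpus that shares one name key;
#' used for coarse automatic mapping, kept separate from manual assertions so
#' that search results can be ranked by reliability.
#'
#' @slot generalId URI of the abstract taxon.
#' @slot memberUris URIs of the member taxa.
#' @slot key the shared \linkS4class{NameKey}.
#' @name TaxonGeneral-class
#' @exportClass TaxonGeneral
setClass("TaxonGeneral",
  representation(generalId = "character", memberUris = "character",
                 key = "NameKey"))

#' @rdname TaxonGeneral-class
#' @param generalId,memberUris,key see slots.
#' @export
TaxonGeneral <- function(generalId, memberUris, key) {
  new("TaxonGeneral", generalId = generalId, memberUris = memberUris,
      key = key)
}

## ---------------------------------------------------------------------------
## Change events
## ---------------------------------------------------------------------------

#' A reified taxonomic, nomenclatural or hierarchical change
#'
#' Modelled change-as-instance: the event links the state before and after
#' the change and carries the concept relations between the two states
#' (e.g. in a lump, every old concept is part of the enlarged surviving
#' concept).
#'
#' @slot eventId URI of the event.
#' @slot changeType one of \code{genus_transfer}, \code{lump}, \code{split},
#'   \code{status_change}, \code{addition}, \code{removal},
#'   \code{hierarchy_change}.
#' @slot beforeUris taxon URIs of the before-state.
#' @slot afterUris taxon URIs of the after-state.
#' @slot relations list of \linkS4class{ConceptMapping} between before and
#'   after concepts.
#' @slot when publication year (static lists) or status time stamp (dynamic
#'   lists), as text.
#' @name ChangeEvent-class
#' @exportClass ChangeEvent
setClass("ChangeEvent",
  representation(eventId = "character", changeType = "character",
                 beforeUris = "character", afterUris = "character",
                 relations = "list", when = "character"),
  prototype(relations = list(), when = NA_character_))

setValidity("ChangeEvent", function(object) {
  msg <- character(0)
  types <- c("genus_transfer", "lump", "split", "status_change",
             "addition", "removal", "hierarchy_change")
  if (!object@changeType %in% types)
    msg <- c(msg, sprintf("unknown change type '%s'", object@changeType))
  if (identical(object@changeType, "lump") && length(object@beforeUris) < 2L)
    msg <- c(msg, "a lump needs at least two before-concepts")
  if (identical(object@changeType, "split") && length(object@afterUris) < 2L)
    msg <- c(msg, "a split needs at least two after-concepts")
  if (is.na(object@when))
    msg <- c(msg, "'when' (year or time stamp) is mandatory")
  if (length(msg)) msg else TRUE
})

#' @rdname ChangeEvent-class
#' @param eventId,changeType,beforeUris,afterUris,relations,when see slots.
#' @export
ChangeEvent <- function(eventId, changeType, beforeUris = character(0),
                        afterUris = character(0), relations = list(),
                        when) {
  new("ChangeEvent", eventId = eventId, changeType = changeType,
      beforeUris = beforeUris, afterUris = afterUris, relations = relations,
      when = as.character(when))
}

## ---------------------------------------------------------------------------
## LSID
## ---------------------------------------------------------------------------

#' A parsed Life Science Identifier
#'
#' An LSID is a URN of six parts: the fixed \code{urn:lsid} head, the
#' authority (a domain), the namespace (the kind of thing identified), the
#' object identifier, and an optional revision for versioning.
#'
#' @slot authority authority domain.
#' @slot namespace namespace part.
#' @slot object object identifier.
#' @slot revision optional revision, \code{NA} when absent.
#' @name LSID-class
#' @exportClass LSID
setClass("LSID",
  representation(authority = "character", namespace = "character",
                 object = "character", revision = "character"),
  prototype(revision = NA_character_))

setValidity("LSID", function(object) {
  msg <- character(0)
  for (part in c("authority", "namespace", "object")) {
    v <- slot(object, part)
    if (!isScalarString(v) || !nzchar(v))
      msg <- c(msg, sprintf("%s must be non-empty", part))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname LSID-class
#' @param authority,namespace,object,revision see slots.
#' @export
LSID <- function(authority, namespace, object, revision = NA_character_) {
  new("LSID", authority = authority, namespace = namespace, object = object,
      revision = revision)
}

## ---------------------------------------------------------------------------
## Corpus
## ---------------------------------------------------------------------------

#' A corpus of checklists with mappings and change events
#'
#' The working set: several checklists loaded together, the concept mappings
#' asserted or derived between their taxa, the reified change events, and
#' the configuration (URI base, seed, rank vocabulary) under which URIs were
#' minted.
#'
#' @slot checklists named list of \linkS4class{Checklist}, names =
#'   checklist ids.
#' @slot mappings list of \linkS4class{ConceptMapping}.
#' @slot events list of \linkS4class{ChangeEvent}.
#' @slot config list with at least \code{uri_base} and \code{uri_seed}.
#' @name Corpus-class
#' @exportClass Corpus
setClass("Corpus",
  representation(checklists = "list", mappings = "list", events = "list",
                 config = "list"),
  prototype(checklists = list(), mappings = list(), events = list(),
            config = list()))

setValidity("Corpus", function(object) {
  msg <- character(0)
  if (!all(vapply(object@checklists, is, logical(1), "Checklist")))
    msg <- c(msg, "checklists must all be Checklist objects")
  uris <- unlist(lapply(object@checklists, function(cl) names(cl@taxa)),
                 use.names = FALSE)
  if (anyDuplicated(uris))
    msg <- c(msg, "taxon URIs must be unique across the corpus")
  if (length(msg)) msg else TRUE
})

#' @rdname Corpus-class
#' @param checklists list of checklists (named by id, or names derived).
#' @param mappings,events,config see slots.
#' @export
Corpus <- function(checklists = list(), mappings = list(), events = list(),
                   config = list()) {
  names(checklists) <- vapply(checklists, function(cl) cl@meta@checklistId,
                              character(1))
  config$uri_base <- config$uri_base %||% "http://example.org/onto"
  new("Corpus", checklists = checklists, mappings = mappings,
      events = events, config = config)
}
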