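## Name assembly and normalised matching keys.
##
## A binominal combination is not stored: it is formed by traversing the
## hierarchy from the species record up to its genus and catenating the
## authorship, rendered per nomenclatural code. Matching keys drop the genus
## part on purpose so genus transfers do not break identity.

.authorTableCache <- new.env(parent = emptyenv())

#' Author abbreviation table
#'
#' Loads the packaged two-column TSV (variant, canonical) of author-name
#' abbreviations, e.g. both \code{L.} and \code{Linn.} stand for Linnaeus.
#' Users may extend it by passing their own file to the functions that take
#' a \code{table} argument; lookups are case- and trailing-period-
#' insensitive.
#'
#' @param path optional path to a user TSV; default is the packaged table.
#' @return A named character vector, names = normalised variants.
#' @export
authorAbbreviations <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.authorTableCache$default)) return(.authorTableCache$default)
    path <- system.file("extdata", "author_abbreviations.tsv",
                        package = "taxmeon")
  }
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  out <- stats::setNames(tab$canonical, .normAuthor(tab$variant))
  if (identical(path, system.file("extdata", "author_abbreviations.tsv",
                                  package = "taxmeon")))
    .authorTableCache$default <- out
  out
}

.normAuthor <- function(x) tolower(sub("\\.+$", "", trimws(x)))

#' Canonicalise an author name token
#'
#' Resolves attested abbreviations to the full surname (seeded with at least
#' \code{L.}/\code{Linn.} -> Linnaeus and \code{Fabr.} -> Fabricius);
#' unknown inputs are returned trimmed but otherwise unchanged. Matching is
#' case-insensitive and ignores trailing periods.
#'
#' @param raw author token, e.g. \code{"Linn."}.
#' @param table abbreviation table from \code{\link{authorAbbreviations}}.
#' @return The canonical author token.
#' @examples
#' canonicalizeAuthor("L.")     # "Linnaeus"
#' canonicalizeAuthor("Mulsant") # unchanged
#' @export
canonicalizeAuthor <- function(raw, table = authorAbbreviations()) {
  stopifnot(isScalarString(raw), nzchar(trimws(raw)))
  hit <- table[.normAuthor(raw)]
  if (!is.na(hit)) unname(hit) else trimws(raw)
}

## Render an authorship per nomenclatural code.
## ICZN: "Author, Year" / multiple authors joined " & " / parenthesised when
## the original genus differs. ICN: "(orig) comb" with no year.
renderAuthorship <- function(a, code = "ICZN") {
  if (is.null(a) || (!length(a@authors) && is.na(a@year))) return("")
  orig <- paste(a@authors, collapse = " & ")
  if (identical(code, "ICN") || length(a@combinationAuthors)) {
    comb <- paste(a@combinationAuthors, collapse = " & ")
    if (nzchar(comb)) return(sprintf("(%s) %s", orig, comb))
    return(orig)
  }
  s <- if (!is.na(a@year)) {
    if (nzchar(orig)) sprintf("%s, %d", orig, a@year) else as.character(a@year)
  } else orig
  if (isTRUE(a@parenthesized)) sprintf("(%s)", s) else s
}

## Walk the parent chain collecting ancestor records (nearest first).
.ancestors <- function(taxon, byUri) {
  out <- list()
  cur <- taxon
  while (!is.na(cur@parentUri)) {
    nxt <- byUri[[cur@parentUri]]
    if (is.null(nxt))
      stop(sprintf("cannot resolve parent '%s' of '%s'", cur@parentUri,
                   cur@uri), call. = FALSE)
    out[[length(out) + 1L]] <- nxt
    cur <- nxt
    if (length(out) > 100L)
      stop(sprintf("parent chain of '%s' does not terminate", taxon@uri),
           call. = FALSE)
  }
  out
}

#' Assemble the complete scientific name of a taxon
#'
#' For species-group taxa the binominal (or trinominal) combination is
#' formed by traversing the hierarchy: the genus name is taken from the
#' nearest genus-rank ancestor, the epithet(s) from the record labels, and
#' the authorship is rendered per the checklist's nomenclatural code —
#' zoological \code{"Author, Year"} (parenthesised when the species was
#' originally described in another genus), botanical
#' \code{"(orig) comb"}. Higher taxa return their label plus authorship.
#'
#' @param taxon a \linkS4class{TaxonRecord}.
#' @param within the containing \linkS4class{Checklist} or a
#'   \linkS4class{Corpus} (the hierarchy stays within one checklist).
#' @return A single string, e.g. \code{"Arhopalus ferus (Mulsant, 1839)"}.
#' @examples
#' cl <- exampleChecklist("arhopalus")
#' sp <- Filter(function(t) t@rank == "species", taxa(cl))[[1]]
#' assembleCompleteName(sp, cl)
#' @export
assembleCompleteName <- function(taxon, within) {
  byUri <- if (is(within, "Corpus")) taxa(within) else within@taxa
  code <- if (is(within, "Corpus")) {
    cl <- within@checklists[[taxon@checklistId]]
    if (is.null(cl)) "unspecified" else cl@meta@code
  } else within@meta@code
  auth <- renderAuthorship(taxon@authorship, code)
  if (!isSpeciesGroup(taxon@rank)) {
    return(trimws(paste(taxon@label, auth)))
  }
  anc <- .ancestors(taxon, byUri)
  ancRanks <- vapply(anc, function(t) t@rank, character(1))
  gi <- which(ancRanks == "genus")[1]
  if (is.na(gi)) gi <- which(isGenusGroup(ancRanks))[1]
  if (is.na(gi))
    stop(sprintf("no genus ancestor reachable from '%s' (parent link '%s')",
                 taxon@uri, taxon@parentUri), call. = FALSE)
  genus <- anc[[gi]]@label
  epithets <- taxon@label
  if (identical(taxon@rank, "subspecies")) {
    si <- which(ancRanks == "species")[1]
    if (!is.na(si)) epithets <- c(anc[[si]]@label, taxon@label)
  }
  trimws(paste(c(genus, epithets, auth), collapse = " "))
}

#' Build the normalised matching key of a taxon
#'
#' The key is the triple (lower-cased label, canonicalised first author,
#' year). Two taxa with the same key are treated as the same name for
#' automatic mapping and for checklist diffing; the genus is excluded so a
#' transferred species keeps its key.
#'
#' @param taxon a \linkS4class{TaxonRecord}.
#' @param table author abbreviation table.
#' @return A \linkS4class{NameKey}.
#' @export
makeNameKey <- function(taxon, table = authorAbbreviations()) {
  a <- taxon@authorship
  author <- if (!is.null(a) && length(a@authors))
    canonicalizeAuthor(a@authors[1], table) else ""
  year <- if (!is.null(a)) a@year else NA_integer_
  NameKey(taxon@label, author, year)
}

#' Serialise a name key for grouping
#'
#' @param key a \linkS4class{NameKey}.
#' @return A single string usable as a grouping key.
#' @export
nameKeyString <- function(key) {
  paste(key@epithet, key@author,
        if (is.na(key@year)) "" else key@year, sep = "|")
}

## key string straight from a record (hot path in mapping/diffing)
recordKey <- function(taxon, table = authorAbbreviations()) {
  nameKeyString(makeNameKey(taxon, table))
}
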