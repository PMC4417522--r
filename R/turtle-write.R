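## Turtle serialisation of the checklist model.
##
## Vocabulary terms live in the published TaxMeOn namespace
## (http://www.yso.fi/onto/taxmeon/) — those identifiers are the ontology's
## own; data resources use the corpus' uri_base. Bibliographic fields use
## Dublin Core. The writer is deterministic: subjects, predicates and
## objects are emitted in canonical sort order, so a corpus written twice
## with the same URI seed produces byte-identical files.

.ns <- c(
  rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  xsd = "http://www.w3.org/2001/XMLSchema#",
  dc = "http://purl.org/dc/elements/1.1/",
  taxmeon = "http://www.yso.fi/onto/taxmeon/")

.tm <- function(local) paste0(.ns[["taxmeon"]], local)
.dc <- function(local) paste0(.ns[["dc"]], local)
.rdfType <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
.rdfsLabel <- "http://www.w3.org/2000/01/rdf-schema#label"

.rankClass <- function(rank) {
  .tm(paste0(toupper(substring(rank, 1, 1)), substring(rank, 2)))
}

.statusClassOf <- c(
  valid = "ValidName", synonym = "Synonym",
  `homonym-rejected` = "RejectedHomonym",
  `orthographic-variant` = "OrthographicVariant",
  undetermined = "Undetermined")

## relation + mode -> TaxMeOn mapping property (only congruentWithTaxonInt
## is attested in the published vocabulary; the Int/Ost variants of the
## other relations are formed by analogy and documented as such)
.mappingPredicate <- function(relation, mode) {
  if (identical(relation, "associated")) return(.tm("isAssociatedWithTaxon"))
  stem <- switch(relation, congruent = "congruentWithTaxon",
                 part_of = "partOfTaxon", overlaps = "overlapsWithTaxon")
  suffix <- switch(mode, intensional = "Int", ostensive = "Ost", "")
  .tm(paste0(stem, suffix))
}

.changeClassOf <- c(
  genus_transfer = "GenusTransfer", lump = "Lump", split = "Split",
  status_change = "StatusChange", addition = "Addition",
  removal = "Removal", hierarchy_change = "HierarchyChange")

## triple accumulator -------------------------------------------------------

.tripleStore <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env
}

.addTriple <- function(store, s, p, o, type = "iri", lang = NA_character_,
                       datatype = NA_character_) {
  store$rows[[length(store$rows) + 1L]] <-
    list(s = s, p = p, o = o, type = type, lang = lang, datatype = datatype)
  invisible(store)
}

.escapeLiteral <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

.compressIri <- function(iri) {
  for (p in names(.ns)) {
    ns <- .ns[[p]]
    if (startsWith(iri, ns)) {
      local <- substring(iri, nchar(ns) + 1L)
      if (grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", local))
        return(paste0(p, ":", local))
    }
  }
  paste0("<", iri, ">")
}

.formatObject <- function(row) {
  if (identical(row$type, "iri")) return(.compressIri(row$o))
  lit <- paste0("\"", .escapeLiteral(row$o), "\"")
  if (!is.na(row$lang)) return(paste0(lit, "@", row$lang))
  if (!is.na(row$datatype))
    return(paste0(lit, "^^", .compressIri(row$datatype)))
  lit
}

.serializeTriples <- function(store) {
  rows <- store$rows
  if (!length(rows)) {
    return(c(sprintf("@prefix %s: <%s> .", names(.ns), unname(.ns)), ""))
  }
  key <- vapply(rows, function(r)
    paste(r$s, r$p != .rdfType, r$p, r$o, sep = "\r"), character(1))
  rows <- rows[!duplicated(key)]
  ord <- order(vapply(rows, `[[`, character(1), "s"),
               vapply(rows, function(r) !identical(r$p, .rdfType),
                      logical(1)),
               vapply(rows, `[[`, character(1), "p"),
               vapply(rows, `[[`, character(1), "o"), method = "radix")
  rows <- rows[ord]
  out <- sprintf("@prefix %s: <%s> .", names(.ns), unname(.ns))
  out <- c(out, "")
  i <- 1L
  n <- length(rows)
  while (i <= n) {
    s <- rows[[i]]$s
    j <- i
    while (j < n && identical(rows[[j + 1L]]$s, s)) j <- j + 1L
    block <- rows[i:j]
    lines <- character(0)
    k <- 1L
    while (k <= length(block)) {
      p <- block[[k]]$p
      l <- k
      while (l < length(block) && identical(block[[l + 1L]]$p, p)) l <- l + 1L
      objs <- vapply(block[k:l], .formatObject, character(1))
      pName <- if (identical(p, .rdfType)) "a" else .compressIri(p)
      lines <- c(lines, paste0("    ", pName, " ",
                               paste(objs, collapse = " , ")))
      k <- l + 1L
    }
    out <- c(out, paste0(.compressIri(s)),
             paste0(lines, c(rep(" ;", length(lines) - 1L), " .")), "")
    i <- j + 1L
  }
  out
}

## corpus -> triples --------------------------------------------------------

.checklistUri <- function(base, id) paste0(base, "/", id)

.taxonTriples <- function(store, t, cl, corpus) {
  base <- corpus@config$uri_base
  u <- t@uri
  .addTriple(store, u, .rdfType, .tm("TaxonInChecklist"))
  if (t@rank %in% rankVocabulary())
    .addTriple(store, u, .rdfType, .rankClass(t@rank))
  .addTriple(store, u, .rdfsLabel, t@label, "literal")
  .addTriple(store, u, .tm("occursInChecklist"),
             .checklistUri(base, cl@meta@checklistId))
  if (!is.na(t@parentUri))
    .addTriple(store, u, .tm("isPartOfHigherTaxon"), t@parentUri)
  cn <- tryCatch(assembleCompleteName(t, cl), error = function(e) NA)
  if (!is.na(cn) && nzchar(cn))
    .addTriple(store, u, .tm("completeTaxonName"), cn, "literal")

  ## status individual
  su <- paste0(u, "/status")
  .addTriple(store, u, .tm("hasStatus"), su)
  .addTriple(store, su, .rdfType,
             .tm(.statusClassOf[[t@status@opinion]]))
  if (!is.na(t@status@note))
    .addTriple(store, su, .tm("hasNomenclaturalNote"), t@status@note,
               "literal")
  if (!is.na(t@status@timestamp))
    .addTriple(store, su, .dc("date"), t@status@timestamp, "literal")

  if (!is.na(t@acceptedUri))
    .addTriple(store, t@acceptedUri, .tm("hasNonvalidName"), u)
  if (!is.na(t@validFrom))
    .addTriple(store, u, .tm("validFrom"), t@validFrom, "literal")

  a <- t@authorship
  if (!is.null(a)) {
    au <- paste0(u, "/auth")
    .addTriple(store, u, .tm("hasScientificNameAuthorship"), au)
    auth <- renderAuthorship(a, cl@meta@code)
    if (nzchar(auth))
      .addTriple(store, au, .tm("completeAuctorumString"), auth, "literal")
    if (!is.na(a@year))
      .addTriple(store, au, .tm("auctorumYear"), as.character(a@year),
                 "literal",
                 datatype = paste0(.ns[["xsd"]], "gYear"))
  }
  for (i in seq_along(t@publications)) {
    p <- t@publications[[i]]
    pu <- paste0(u, "/pub", i)
    pred <- if (identical(p@role, "original")) "publishedOriginallyIn"
            else "publishedIn"
    .addTriple(store, u, .tm(pred), pu)
    .addTriple(store, pu, .dc("bibliographicCitation"), p@citation,
               "literal")
    if (!is.na(p@year))
      .addTriple(store, pu, .dc("date"), as.character(p@year), "literal",
                 datatype = paste0(.ns[["xsd"]], "gYear"))
  }
  for (i in seq_along(t@vernaculars)) {
    v <- t@vernaculars[[i]]
    vu <- paste0(u, "/vern", i)
    .addTriple(store, u, .tm("hasVernacularName"), vu)
    .addTriple(store, vu, .rdfsLabel, v@name, "literal", lang = v@language)
    .addTriple(store, vu, .tm("hasVernacularNameStatus"),
               .tm(if (identical(v@status, "accepted"))
                 "acceptedVernacularName" else "alternativeVernacularName"))
  }
  for (x in t@externalIds)
    .addTriple(store, u, .dc("identifier"), x, "literal")
  invisible(store)
}

#' Write a corpus as TaxMeOn Turtle
#'
#' Serialises checklists, taxa, concept mappings and change events with the
#' TaxMeOn vocabulary: every taxon is typed both as
#' \code{taxmeon:TaxonInChecklist} and as its rank class, the hierarchy uses
#' \code{taxmeon:isPartOfHigherTaxon}, synonymy \code{taxmeon:hasNonvalidName},
#' and a human-oriented \code{taxmeon:completeTaxonName} literal is generated
#' for every assemblable name. Mapping assertions use the mode-specific
#' relation properties (\code{congruentWithTaxonInt/Ost}, ...); change
#' events are written change-as-instance with their before/after links, and
#' their concept relations appear as ordinary mapping triples between the
#' old and new taxa. Output is deterministic (byte-identical for the same
#' corpus and URI seed).
#'
#' @param corpus a \linkS4class{Corpus}; its \code{mappings} and
#'   \code{events} are included.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readTurtle}} for the inverse.
#' @export
writeTurtle <- function(corpus, path) {
  store <- .tripleStore()
  base <- corpus@config$uri_base
  for (cl in corpus@checklists) {
    cu <- .checklistUri(base, cl@meta@checklistId)
    .addTriple(store, cu, .rdfType, .tm("Checklist"))
    if (nzchar(cl@meta@title))
      .addTriple(store, cu, .dc("title"), cl@meta@title, "literal")
    if (!is.na(cl@meta@yearPublished))
      .addTriple(store, cu, .dc("date"),
                 as.character(cl@meta@yearPublished), "literal",
                 datatype = paste0(.ns[["xsd"]], "gYear"))
    .addTriple(store, cu, .tm("listType"), cl@meta@listType, "literal")
    if (!identical(cl@meta@code, "unspecified"))
      .addTriple(store, cu, .tm("hasNomenclaturalCode"), .tm(cl@meta@code))
    for (t in cl@taxa) .taxonTriples(store, t, cl, corpus)
  }
  for (m in corpus@mappings)
    .addTriple(store, m@sourceUri, .mappingPredicate(m@relation, m@mode),
               m@targetUri)
  for (e in corpus@events) {
    .addTriple(store, e@eventId, .rdfType, .tm("TaxonChange"))
    .addTriple(store, e@eventId, .rdfType, .tm(.changeClassOf[[e@changeType]]))
    for (b in e@beforeUris)
      .addTriple(store, e@eventId, .tm("hasChangeBefore"), b)
    for (a in e@afterUris)
      .addTriple(store, e@eventId, .tm("hasChangeAfter"), a)
    if (!is.na(e@when))
      .addTriple(store, e@eventId, .dc("date"), e@when, "literal")
    for (m in e@relations)
      .addTriple(store, m@sourceUri, .mappingPredicate(m@relation, m@mode),
                 m@targetUri)
  }
  writeLines(.serializeTriples(store), path, useBytes = TRUE)
  invisible(path)
}

#' Canonical N-Triples of a Turtle file
#'
#' Parses a Turtle file and returns its triples as sorted canonical lines —
#' two files describe isomorphic graphs (the model emits no blank nodes)
#' exactly when their canonical forms are identical.
#'
#' @param path Turtle file.
#' @return Sorted character vector, one triple per line.
#' @export
canonicalTriples <- function(path) {
  rows <- .parseTurtleFile(path)
  lines <- vapply(rows, function(r) {
    o <- if (identical(r$type, "iri")) paste0("<", r$o, ">") else {
      lit <- paste0("\"", .escapeLiteral(r$o), "\"")
      if (!is.na(r$lang)) paste0(lit, "@", r$lang)
      else if (!is.na(r$datatype)) paste0(lit, "^^<", r$datatype, ">")
      else lit
    }
    sprintf("<%s> <%s> %s .", r$s, r$p, o)
  }, character(1))
  sort(unique(lines))
}
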