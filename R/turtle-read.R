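## Turtle parsing and reconstruction of the checklist model.
##
## The tokenizer/parser covers the Turtle constructs the writer emits (and
## common hand-written variants): @prefix directives, prefixed names, IRI
## references, the 'a' keyword, quoted literals with language tags or
## datatypes, and ';'/',' predicate/object lists. Blank nodes are not part
## of the model. Unknown predicates are skipped with a warning; malformed
## input is a parse error.

.tokenizeTurtle <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  push <- function(type, value) tokens[[length(tokens) + 1L]] <<-
    list(type = type, value = value)
  while (i <= n) {
    ch <- substring(text, i, i)
    if (ch %in% c(" ", "\t", "\r", "\n")) { i <- i + 1L; next }
    if (identical(ch, "#")) {
      while (i <= n && !substring(text, i, i) %in% c("\n")) i <- i + 1L
      next
    }
    if (identical(ch, "<")) {
      j <- regexpr(">", substring(text, i))[1]
      if (j < 0) stop("turtle parse error: unterminated IRI", call. = FALSE)
      push("iri", substring(text, i + 1L, i + j - 2L))
      i <- i + j
      next
    }
    if (identical(ch, "\"")) {
      j <- i + 1L
      val <- character(0)
      repeat {
        if (j > n)
          stop("turtle parse error: unterminated literal", call. = FALSE)
        cj <- substring(text, j, j)
        if (identical(cj, "\\")) {
          esc <- substring(text, j + 1L, j + 1L)
          val <- c(val, switch(esc, n = "\n", t = "\t", r = "\r",
                               "\"" = "\"", "\\" = "\\", esc))
          j <- j + 2L
        } else if (identical(cj, "\"")) {
          j <- j + 1L
          break
        } else {
          val <- c(val, cj)
          j <- j + 1L
        }
      }
      lit <- paste(val, collapse = "")
      lang <- NA_character_
      dt <- NA_character_
      if (identical(substring(text, j, j), "@")) {
        m <- regexpr("^[A-Za-z][A-Za-z0-9-]*", substring(text, j + 1L))
        lang <- regmatches(substring(text, j + 1L), m)
        j <- j + 1L + attr(m, "match.length")
      } else if (identical(substring(text, j, j + 1L), "^^")) {
        push("literal_pending", list(value = lit))
        i <- j + 2L
        ## datatype IRI or prefixed name follows; flag for the parser
        push("datatype_marker", NULL)
        next
      }
      push("literal", list(value = lit, lang = lang, datatype = dt))
      i <- j
      next
    }
    if (ch %in% c(".", ";", ",")) { push("punct", ch); i <- i + 1L; next }
    ## prefixed name, directive, or bare keyword
    m <- regexpr("^[^ \t\r\n;,<\"]+", substring(text, i))
    word <- regmatches(substring(text, i), m)
    ## a bare '.' terminator may be glued: handled because '.' alone matched
    if (identical(word, "a")) push("a", "a")
    else if (word %in% c("@prefix", "@base", "PREFIX", "BASE"))
      push("directive", word)
    else push("pname", word)
    i <- i + attr(m, "match.length")
    next
  }
  tokens
}

.expandPname <- function(pname, prefixes) {
  ## strip a trailing '.' that terminates a statement (tokenizer glue)
  colon <- regexpr(":", pname, fixed = TRUE)[1]
  if (colon < 0)
    stop(sprintf("turtle parse error: expected prefixed name, got '%s'",
                 pname), call. = FALSE)
  p <- substring(pname, 1L, colon - 1L)
  local <- substring(pname, colon + 1L)
  ns <- prefixes[[p]]
  if (is.null(ns))
    stop(sprintf("turtle parse error: undeclared prefix '%s:'", p),
         call. = FALSE)
  paste0(ns, local)
}

## Parse a Turtle file into a list of triple rows
## (s, p, o, type, lang, datatype).
.parseTurtleFile <- function(path) {
  text <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                collapse = "\n")
  toks <- .tokenizeTurtle(text)
  prefixes <- list()
  rows <- list()
  i <- 1L
  n <- length(toks)
  peek <- function() if (i <= n) toks[[i]] else NULL
  take <- function() { t <- peek(); i <<- i + 1L; t }
  resolve <- function(tok) {
    if (is.null(tok))
      stop("turtle parse error: unexpected end of input", call. = FALSE)
    if (identical(tok$type, "iri")) return(list(o = tok$value, type = "iri"))
    if (identical(tok$type, "pname"))
      return(list(o = .expandPname(tok$value, prefixes), type = "iri"))
    if (identical(tok$type, "a"))
      return(list(o = .rdfType, type = "iri"))
    if (identical(tok$type, "literal"))
      return(list(o = tok$value$value, type = "literal",
                  lang = tok$value$lang, datatype = tok$value$datatype))
    if (identical(tok$type, "literal_pending")) {
      marker <- take()
      if (!identical(marker$type, "datatype_marker"))
        stop("turtle parse error: bad datatype", call. = FALSE)
      dtTok <- take()
      dt <- resolve(dtTok)
      return(list(o = tok$value$value, type = "literal", lang = NA_character_,
                  datatype = dt$o))
    }
    stop(sprintf("turtle parse error: unexpected token '%s'",
                 paste(tok$value, collapse = "")), call. = FALSE)
  }
  expectPunct <- function(val) {
    t <- take()
    if (is.null(t) || !identical(t$type, "punct") ||
        !identical(t$value, val))
      stop(sprintf("turtle parse error: expected '%s'", val), call. = FALSE)
  }
  while (!is.null(peek())) {
    tok <- take()
    if (identical(tok$type, "directive")) {
      pTok <- take()
      nsTok <- take()
      if (is.null(pTok) || is.null(nsTok) || !identical(nsTok$type, "iri"))
        stop("turtle parse error: malformed @prefix", call. = FALSE)
      prefixes[[sub(":$", "", pTok$value)]] <- nsTok$value
      if (tok$value %in% c("@prefix", "@base")) expectPunct(".")
      next
    }
    subj <- resolve(tok)
    if (!identical(subj$type, "iri"))
      stop("turtle parse error: literal subject", call. = FALSE)
    repeat {
      pred <- resolve(take())
      if (!identical(pred$type, "iri"))
        stop("turtle parse error: literal predicate", call. = FALSE)
      repeat {
        obj <- resolve(take())
        rows[[length(rows) + 1L]] <-
          list(s = subj$o, p = pred$o, o = obj$o, type = obj$type,
               lang = obj$lang %||% NA_character_,
               datatype = obj$datatype %||% NA_character_)
        sep <- take()
        if (is.null(sep) || !identical(sep$type, "punct"))
          stop("turtle parse error: unexpected end of statement",
               call. = FALSE)
        if (identical(sep$value, ",")) next
        break
      }
      if (identical(sep$value, ";")) {
        ## tolerate a trailing ';' before '.'
        if (!is.null(peek()) && identical(peek()$type, "punct") &&
            identical(peek()$value, ".")) { take(); break }
        next
      }
      if (identical(sep$value, ".")) break
      stop("turtle parse error: expected '.', ';' or ','", call. = FALSE)
    }
  }
  rows
}

## index helpers over parsed triples
.triplesBySubject <- function(rows) {
  split(rows, vapply(rows, `[[`, character(1), "s"))
}

.objOf <- function(trs, pred, first = TRUE) {
  hits <- Filter(function(r) identical(r$p, pred), trs)
  if (!length(hits)) return(if (first) NULL else list())
  if (first) hits[[1]] else hits
}

#' Read a TaxMeOn Turtle file back into a corpus
#'
#' Inverse of \code{\link{writeTurtle}}: reconstructs checklists with their
#' metadata, taxon records (rank, label, hierarchy, status, authorship,
#' publications, vernacular names, synonymy), concept mappings and change
#' events. Relation triples whose endpoints lie in a change event's
#' before/after sets are attached to that event; all other mapping triples
#' become standalone concept mappings. Triples with predicates outside the
#' vocabulary are skipped with one summarising warning; malformed Turtle is
#' a parse error.
#'
#' @param path Turtle file.
#' @return A \linkS4class{Corpus}.
#' @export
readTurtle <- function(path) {
  rows <- .parseTurtleFile(path)
  bys <- .triplesBySubject(rows)

  typesOf <- function(trs)
    vapply(.objOf(trs, .rdfType, first = FALSE), `[[`, character(1), "o")

  ## classify subjects
  subjects <- names(bys)
  isChecklist <- vapply(subjects, function(s)
    .tm("Checklist") %in% typesOf(bys[[s]]), logical(1))
  isTaxon <- vapply(subjects, function(s)
    .tm("TaxonInChecklist") %in% typesOf(bys[[s]]), logical(1))
  isEvent <- vapply(subjects, function(s)
    .tm("TaxonChange") %in% typesOf(bys[[s]]) ||
      any(typesOf(bys[[s]]) %in% .tm(unname(.changeClassOf))),
    logical(1))

  ## checklist metadata
  metas <- list()
  uriBase <- NULL
  for (s in subjects[isChecklist]) {
    trs <- bys[[s]]
    id <- uriLocalName(s)
    uriBase <- uriBase %||% sub(paste0("/", id, "$"), "", s)
    yr <- .objOf(trs, .dc("date"))
    lt <- .objOf(trs, .tm("listType"))
    code <- .objOf(trs, .tm("hasNomenclaturalCode"))
    ttl <- .objOf(trs, .dc("title"))
    metas[[s]] <- ChecklistMeta(
      id, title = if (is.null(ttl)) "" else ttl$o,
      yearPublished = if (is.null(yr)) NA else as.integer(yr$o),
      listType = if (is.null(lt)) "static" else lt$o,
      code = if (is.null(code)) "unspecified" else uriLocalName(code$o))
  }

  rankClasses <- stats::setNames(rankVocabulary(),
                                 vapply(rankVocabulary(), .rankClass,
                                        character(1)))
  statusOpinions <- stats::setNames(names(.statusClassOf),
                                    .tm(unname(.statusClassOf)))
  mappingPreds <- character(0)
  for (rel in c("congruent", "part_of", "overlaps"))
    for (mo in c("intensional", "ostensive", "n/a"))
      mappingPreds[.mappingPredicate(rel, mo)] <- paste(rel, mo, sep = "\r")
  mappingPreds[.tm("isAssociatedWithTaxon")] <- "associated\rn/a"

  knownTaxonPreds <- c(.rdfType, .rdfsLabel, .tm("occursInChecklist"),
                       .tm("isPartOfHigherTaxon"), .tm("completeTaxonName"),
                       .tm("hasStatus"), .tm("hasNonvalidName"),
                       .tm("validFrom"), .tm("hasScientificNameAuthorship"),
                       .tm("publishedIn"), .tm("publishedOriginallyIn"),
                       .tm("hasVernacularName"), .dc("identifier"),
                       names(mappingPreds))

  unknown <- character(0)

  ## taxa
  recordsByChecklist <- list()
  acceptedOf <- list()  # synonym uri -> valid uri (from hasNonvalidName)
  completeNames <- character(0)
  for (s in subjects[isTaxon]) {
    for (r in bys[[s]]) {
      if (identical(r$p, .tm("hasNonvalidName")))
        acceptedOf[[r$o]] <- s
    }
  }
  for (s in subjects[isTaxon]) {
    trs <- bys[[s]]
    tys <- typesOf(trs)
    rank <- rankClasses[tys[tys %in% names(rankClasses)]][1]
    if (is.na(rank)) rank <- "species"
    lab <- .objOf(trs, .rdfsLabel)
    occ <- .objOf(trs, .tm("occursInChecklist"))
    if (is.null(occ)) next
    clUri <- occ$o
    clId <- uriLocalName(clUri)
    par <- .objOf(trs, .tm("isPartOfHigherTaxon"))
    cn <- .objOf(trs, .tm("completeTaxonName"))
    if (!is.null(cn)) completeNames <- c(completeNames, cn$o)

    ## status node
    opinion <- "valid"; ts <- NA_character_; note <- NA_character_
    st <- .objOf(trs, .tm("hasStatus"))
    if (!is.null(st) && !is.null(bys[[st$o]])) {
      strs <- bys[[st$o]]
      sTys <- typesOf(strs)
      hit <- sTys[sTys %in% names(statusOpinions)]
      if (length(hit)) opinion <- unname(statusOpinions[hit[1]])
      tsr <- .objOf(strs, .dc("date"))
      if (!is.null(tsr)) ts <- tsr$o
      nr <- .objOf(strs, .tm("hasNomenclaturalNote"))
      if (!is.null(nr)) note <- nr$o
    }

    ## authorship node
    authorship <- NULL
    an <- .objOf(trs, .tm("hasScientificNameAuthorship"))
    if (!is.null(an) && !is.null(bys[[an$o]])) {
      atrs <- bys[[an$o]]
      str <- .objOf(atrs, .tm("completeAuctorumString"))
      yr <- .objOf(atrs, .tm("auctorumYear"))
      authorship <- if (!is.null(str)) parseAuthorshipText(str$o) else
        Authorship()
      if (!is.null(authorship) && is.na(authorship@year) && !is.null(yr))
        authorship@year <- as.integer(yr$o)
    }

    pubs <- list()
    for (role in c("original", "subsequent")) {
      pred <- if (identical(role, "original")) "publishedOriginallyIn"
              else "publishedIn"
      for (pr in .objOf(trs, .tm(pred), first = FALSE)) {
        ptrs <- bys[[pr$o]]
        if (is.null(ptrs)) next
        cit <- .objOf(ptrs, .dc("bibliographicCitation"))
        pyr <- .objOf(ptrs, .dc("date"))
        if (!is.null(cit))
          pubs[[length(pubs) + 1L]] <-
            Publication(cit$o, role,
                        if (is.null(pyr)) NA else as.integer(pyr$o))
      }
    }

    verns <- list()
    for (vr in .objOf(trs, .tm("hasVernacularName"), first = FALSE)) {
      vtrs <- bys[[vr$o]]
      if (is.null(vtrs)) next
      vl <- .objOf(vtrs, .rdfsLabel)
      vs <- .objOf(vtrs, .tm("hasVernacularNameStatus"))
      if (is.null(vl)) next
      verns[[length(verns) + 1L]] <-
        VernacularName(vl$o, if (is.na(vl$lang)) "und" else vl$lang,
                       if (!is.null(vs) &&
                           grepl("alternative", vs$o)) "alternative"
                       else "accepted")
    }

    ext <- vapply(.objOf(trs, .dc("identifier"), first = FALSE), `[[`,
                  character(1), "o")
    vf <- .objOf(trs, .tm("validFrom"))

    rec <- TaxonRecord(
      uri = s, checklistId = clId, rank = unname(rank),
      label = if (is.null(lab)) uriLocalName(s) else lab$o,
      parentUri = if (is.null(par)) NA_character_ else par$o,
      status = StatusAssignment(opinion, note, ts),
      authorship = authorship, publications = pubs, vernaculars = verns,
      externalIds = ext,
      acceptedUri = acceptedOf[[s]] %||% NA_character_,
      validFrom = if (is.null(vf)) NA_character_ else vf$o)
    recordsByChecklist[[clUri]] <-
      append(recordsByChecklist[[clUri]] %||% list(), list(rec))
  }

  ## events
  eventList <- list()
  eventMembership <- list()  # for attaching relation triples
  for (s in subjects[isEvent]) {
    trs <- bys[[s]]
    tys <- typesOf(trs)
    typeHit <- names(.changeClassOf)[.tm(unname(.changeClassOf)) %in% tys][1]
    if (is.na(typeHit)) next
    before <- vapply(.objOf(trs, .tm("hasChangeBefore"), first = FALSE),
                     `[[`, character(1), "o")
    after <- vapply(.objOf(trs, .tm("hasChangeAfter"), first = FALSE),
                    `[[`, character(1), "o")
    wr <- .objOf(trs, .dc("date"))
    eventList[[s]] <- list(id = s, type = typeHit, before = before,
                           after = after,
                           when = if (is.null(wr)) NA_character_ else wr$o,
                           relations = list())
  }

  ## mapping triples: attach to an event when endpoints match its
  ## before/after sets, otherwise keep as standalone mappings
  maps <- list()
  for (r in rows) {
    rm_ <- mappingPreds[r$p]
    if (is.na(rm_)) next
    parts <- strsplit(rm_, "\r", fixed = TRUE)[[1]]
    cm <- ConceptMapping(r$s, r$o, parts[1], parts[2])
    attached <- FALSE
    for (eid in names(eventList)) {
      ev <- eventList[[eid]]
      inEvent <- (r$s %in% ev$before && r$o %in% ev$after) ||
        (r$s %in% ev$after && r$o %in% ev$before)
      if (inEvent) {
        eventList[[eid]]$relations <-
          append(eventList[[eid]]$relations, list(cm))
        attached <- TRUE
        break
      }
    }
    if (!attached) maps[[length(maps) + 1L]] <- cm
  }

  ## unknown predicates outside every recognised node type
  knownNodePreds <- c(knownTaxonPreds, .dc("title"), .dc("date"),
                      .tm("listType"), .tm("hasNomenclaturalCode"),
                      .tm("hasChangeBefore"), .tm("hasChangeAfter"),
                      .tm("completeAuctorumString"), .tm("auctorumYear"),
                      .dc("bibliographicCitation"),
                      .tm("hasVernacularNameStatus"),
                      .tm("hasNomenclaturalNote"))
  for (r in rows)
    if (!r$p %in% knownNodePreds) unknown <- c(unknown, r$p)
  unknown <- unique(unknown)
  if (length(unknown))
    warning(sprintf("skipped %d unknown predicate(s): %s", length(unknown),
                    paste(unknown, collapse = ", ")), call. = FALSE)

  checklists <- list()
  for (clUri in names(recordsByChecklist)) {
    m <- metas[[clUri]]
    if (is.null(m))
      m <- ChecklistMeta(uriLocalName(clUri), yearPublished = NA,
                         listType = "dynamic")
    checklists[[length(checklists) + 1L]] <-
      Checklist(m, recordsByChecklist[[clUri]])
  }
  events <- lapply(eventList, function(ev)
    ChangeEvent(ev$id, ev$type, ev$before, ev$after, ev$relations, ev$when))
  corpus <- Corpus(checklists, maps, unname(events),
                   config = list(uri_base = uriBase %||%
                                   "http://example.org/onto"))
  attr(corpus, "completeTaxonNames") <- sort(completeNames)
  corpus
}
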