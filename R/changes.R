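## Diffing checklist versions and reifying taxonomic change.
##
## Across static checklists taxa are matched by NameKey, never by URI: each
## scientific name receives a new URI in every static checklist, so only the
## name+authorship identity persists. Detected changes are reified as
## instances linking the before- and after-state concepts with the mapping
## relations (change-as-instance modelling).

## label of the nearest genus-group ancestor, or NA
.genusLabel <- function(taxon, checklist) {
  cur <- taxon
  for (i in 1:100) {
    if (is.na(cur@parentUri)) return(NA_character_)
    cur <- checklist@taxa[[cur@parentUri]]
    if (is.null(cur)) return(NA_character_)
    if (isGenusGroup(cur@rank)) return(cur@label)
  }
  NA_character_
}

## nearest genus-group ancestor URI, or NA
.genusUri <- function(taxon, checklist) {
  cur <- taxon
  for (i in 1:100) {
    if (is.na(cur@parentUri)) return(NA_character_)
    cur <- checklist@taxa[[cur@parentUri]]
    if (is.null(cur)) return(NA_character_)
    if (isGenusGroup(cur@rank)) return(cur@uri)
  }
  NA_character_
}

#' Diff two versions of a checklist
#'
#' Matches taxa between the older and newer checklist by name key and
#' classifies the differences into reified change events:
#' \itemize{
#'   \item a species whose genus differs between the versions is a
#'     \code{genus_transfer} (the concept is unchanged, so the old and new
#'     record are linked congruent);
#'   \item species that turned from valid into synonyms are grouped by their
#'     accepted name into one \code{lump}: every old concept, including the
#'     surviving name's own old concept, is part of the enlarged new concept
#'     (the surviving concept grew);
#'   \item a species-group synonym promoted to valid while its former
#'     accepted name persists as valid is a \code{split} of that name's
#'     concept; other status changes (including higher taxa such as a genus
#'     resurrected from synonymy) are \code{status_change};
#'   \item name keys present only in the older or only in the newer list are
#'     \code{removal} / \code{addition};
#'   \item a parent change that is not a genus transfer is a
#'     \code{hierarchy_change}.
#' }
#' Keys that match more than one taxon on either side are ambiguous: no
#' event is emitted for them and they are reported in the
#' \code{"ambiguous"} attribute of the result (with a warning).
#'
#' Nomenclatural priority is checked on every detected lump: the surviving
#' valid name should be the older one. Violations emit a warning, never an
#' error — checklists do occasionally override priority.
#'
#' @param older,newer \linkS4class{Checklist} objects,
#'   \code{older} published (or stamped) no later than \code{newer}.
#' @param minter URI minter for event identifiers (reserved \code{"changes"}
#'   namespace segment); a throwaway seeded minter is created when omitted.
#' @param table author abbreviation table.
#' @return List of \linkS4class{ChangeEvent}, with attribute
#'   \code{"ambiguous"} holding the withheld key strings.
#' @examples
#' ev <- diffChecklists(exampleChecklist("beetles_1992"),
#'                      exampleChecklist("beetles_2011"))
#' vapply(ev, function(e) e@changeType, character(1))
#' @export
diffChecklists <- function(older, newer, minter = NULL,
                           table = authorAbbreviations()) {
  if (is.null(minter)) minter <- uriMinter(seed = 0L)
  yo <- older@meta@yearPublished
  yn <- newer@meta@yearPublished
  if (!is.na(yo) && !is.na(yn) && yo > yn)
    stop("'older' checklist is published after 'newer'", call. = FALSE)
  defaultWhen <- if (!is.na(yn)) as.character(yn) else {
    ts <- vapply(newer@taxa, function(t) t@status@timestamp, character(1))
    ts <- ts[!is.na(ts)]
    if (length(ts)) max(ts) else NA_character_
  }
  eventWhen <- function(newUris) {
    ts <- vapply(newUris, function(u) {
      t <- newer@taxa[[u]]
      if (is.null(t)) NA_character_ else t@status@timestamp
    }, character(1))
    ts <- ts[!is.na(ts)]
    if (identical(newer@meta@listType, "dynamic") && length(ts)) max(ts)
    else defaultWhen
  }

  keysO <- vapply(older@taxa, recordKey, character(1), table = table)
  keysN <- vapply(newer@taxa, recordKey, character(1), table = table)
  amb <- sort(union(unique(keysO[duplicated(keysO)]),
                    unique(keysN[duplicated(keysN)])))
  if (length(amb))
    warning(sprintf("%d ambiguous name key(s) withheld from the diff: %s",
                    length(amb), paste(amb, collapse = "; ")),
            call. = FALSE)
  okO <- !keysO %in% amb
  okN <- !keysN %in% amb
  oldOf <- stats::setNames(names(older@taxa)[okO], keysO[okO])
  newOf <- stats::setNames(names(newer@taxa)[okN], keysN[okN])
  shared <- sort(intersect(names(oldOf), names(newOf)))

  events <- list()
  emit <- function(type, before, after, relations, when) {
    events[[length(events) + 1L]] <<-
      ChangeEvent(mintUri(minter, "changes"), type, before, after,
                  relations, when)
  }
  lumpGroups <- list()   # accepted new uri -> old uris of new synonyms
  splitGroups <- list()  # old accepted uri -> promoted new uris

  for (k in shared) {
    uo <- oldOf[[k]]; un <- newOf[[k]]
    ot <- older@taxa[[uo]]; nt <- newer@taxa[[un]]
    opO <- ot@status@opinion; opN <- nt@status@opinion

    if (isSpeciesGroup(ot@rank) && isSpeciesGroup(nt@rank)) {
      gO <- .genusLabel(ot, older); gN <- .genusLabel(nt, newer)
      if (!is.na(gO) && !is.na(gN) && !identical(gO, gN)) {
        emit("genus_transfer", uo, un,
             list(ConceptMapping(uo, un, "congruent", "ostensive",
                                 provenance = "automatic")),
             eventWhen(un))
      } else {
        pkO <- if (is.na(ot@parentUri)) NA_character_ else
          unname(keysO[ot@parentUri])
        pkN <- if (is.na(nt@parentUri)) NA_character_ else
          unname(keysN[nt@parentUri])
        if (!sameScalar(pkO, pkN))
          emit("hierarchy_change", uo, un,
               list(ConceptMapping(uo, un, "congruent", "ostensive",
                                   provenance = "automatic")),
               eventWhen(un))
      }
      if (identical(opO, "valid") && opN %in% .nonvalidOpinions &&
          !is.na(nt@acceptedUri)) {
        tgt <- nt@acceptedUri
        lumpGroups[[tgt]] <- c(lumpGroups[[tgt]], uo)
      } else if (opO %in% .nonvalidOpinions && identical(opN, "valid")) {
        tgtOld <- ot@acceptedUri
        kTgtOld <- if (!is.na(tgtOld)) unname(keysO[tgtOld]) else NA_character_
        tgtNewUri <- if (!is.na(kTgtOld) && !is.na(newOf[kTgtOld]))
          unname(newOf[kTgtOld]) else NA_character_
        if (!is.na(tgtOld) && !is.na(tgtNewUri) &&
            identical(newer@taxa[[tgtNewUri]]@status@opinion, "valid")) {
          splitGroups[[tgtOld]] <- c(splitGroups[[tgtOld]], un)
        } else {
          emit("status_change", uo, un,
               list(ConceptMapping(uo, un, "congruent", "ostensive",
                                   provenance = "automatic")),
               eventWhen(un))
        }
      } else if (!identical(opO, opN) &&
                 !(identical(opO, "valid") && opN %in% .nonvalidOpinions)) {
        emit("status_change", uo, un,
             list(ConceptMapping(uo, un, "congruent", "ostensive",
                                 provenance = "automatic")),
             eventWhen(un))
      }
    } else {
      ## higher taxa: status and hierarchy only; their circumscription is a
      ## matter of species content, handled by alignHigherTaxa
      if (!identical(opO, opN)) {
        emit("status_change", uo, un,
             list(ConceptMapping(uo, un, "congruent", "ostensive",
                                 provenance = "automatic")),
             eventWhen(un))
      } else {
        pkO <- if (is.na(ot@parentUri)) NA_character_ else
          unname(keysO[ot@parentUri])
        pkN <- if (is.na(nt@parentUri)) NA_character_ else
          unname(keysN[nt@parentUri])
        if (!sameScalar(pkO, pkN))
          emit("hierarchy_change", uo, un,
               list(ConceptMapping(uo, un, "congruent", "ostensive",
                                   provenance = "automatic")),
               eventWhen(un))
      }
    }
  }

  ## lumps: old concepts (synonymised names + the surviving name's own old
  ## concept) are part of the enlarged surviving concept
  for (tgt in sort(names(lumpGroups))) {
    synOld <- sort(unique(lumpGroups[[tgt]]))
    kTgt <- unname(keysN[tgt])
    tgtOldUri <- if (!is.na(kTgt) && !is.na(oldOf[kTgt])) unname(oldOf[kTgt])
      else NA_character_
    before <- c(if (!is.na(tgtOldUri)) tgtOldUri, synOld)
    if (length(before) >= 2L) {
      rels <- lapply(before, function(u)
        ConceptMapping(u, tgt, "part_of", "ostensive",
                       provenance = "automatic"))
      emit("lump", before, tgt, rels, eventWhen(tgt))
      ## nomenclatural priority: the older name should survive
      if (!is.na(tgtOldUri)) {
        yrOf <- function(u) {
          a <- older@taxa[[u]]@authorship
          if (is.null(a)) NA_integer_ else a@year
        }
        ys <- yrOf(tgtOldUri)
        yo2 <- vapply(synOld, yrOf, integer(1))
        if (!is.na(ys) && any(!is.na(yo2) & yo2 < ys))
          warning(sprintf(
            "lump into '%s' violates nomenclatural priority: a synonym is older than the surviving name",
            newer@taxa[[tgt]]@label), call. = FALSE)
      }
    } else {
      ## surviving name unknown in the older list: plain status changes
      for (u in synOld) {
        un <- unname(newOf[unname(keysO[u])])
        emit("status_change", u, un,
             list(ConceptMapping(u, un, "congruent", "ostensive",
                                 provenance = "automatic")),
             eventWhen(un))
      }
    }
  }

  ## splits: the old concept is divided; each new concept is part of it
  for (tgtOld in sort(names(splitGroups))) {
    promoted <- sort(unique(splitGroups[[tgtOld]]))
    tgtNewUri <- unname(newOf[unname(keysO[tgtOld])])
    after <- c(tgtNewUri, promoted)
    rels <- lapply(after, function(u)
      ConceptMapping(u, tgtOld, "part_of", "ostensive",
                     provenance = "automatic"))
    emit("split", tgtOld, after, rels, eventWhen(after))
  }

  ## additions / removals
  for (k in sort(setdiff(names(oldOf), names(newOf))))
    emit("removal", oldOf[[k]], character(0), list(),
         defaultWhen)
  for (k in sort(setdiff(names(newOf), names(oldOf))))
    emit("addition", character(0), newOf[[k]], list(),
         eventWhen(newOf[[k]]))

  attr(events, "ambiguous") <- amb
  events
}

#' Apply a change event to a dynamic checklist
#'
#' Implements the URI duplication rule for dynamic lists: when a taxonomic,
#' nomenclatural or hierarchical change touches a species, the URIs of the
#' affected species \emph{and of their immediate genus} are duplicated (the
#' genus duplication preserves the lower-level name combinations), while
#' everything above the genus keeps its URI. The old records are retained
#' unchanged so that the concept can still be referred to at a particular
#' time; the new records carry the event's time stamp on their status.
#'
#' For \code{lump} events, \code{afterUris} names the surviving concept
#' among \code{beforeUris} (using its current URI); the other before-taxa
#' become synonyms of the surviving duplicate. For \code{split} events the
#' non-surviving after-taxa (current synonym records) are promoted to valid.
#' \code{status_change} duplicates and assigns \code{newStatus} when given.
#'
#' @param checklist a dynamic \linkS4class{Checklist}.
#' @param event a \linkS4class{ChangeEvent} whose URIs refer to records in
#'   \code{checklist}.
#' @param minter URI minter.
#' @param newStatus optional \linkS4class{StatusAssignment} for
#'   \code{status_change} events.
#' @return A list with elements \code{checklist} (the updated checklist),
#'   \code{event} (the realised event linking old to newly minted URIs) and
#'   \code{minted} (named character vector, old URI -> new URI).
#' @export
applyChange <- function(checklist, event, minter, newStatus = NULL) {
  if (!identical(checklist@meta@listType, "dynamic"))
    stop("applyChange operates on dynamic checklists only", call. = FALSE)
  touched <- union(event@beforeUris, event@afterUris)
  if (!length(touched))
    return(list(checklist = checklist, event = event,
                minted = stats::setNames(character(0), character(0))))
  unknown <- setdiff(touched, names(checklist@taxa))
  if (length(unknown))
    stop(sprintf("event references URIs not in checklist '%s': %s",
                 checklist@meta@checklistId,
                 paste(unknown, collapse = ", ")), call. = FALSE)

  species <- touched[vapply(touched, function(u)
    isSpeciesGroup(checklist@taxa[[u]]@rank), logical(1))]
  genera <- unique(stats::na.omit(vapply(species, function(u)
    .genusUri(checklist@taxa[[u]], checklist), character(1))))
  ## genus-level events (e.g. a genus status change) duplicate the genus too
  genera <- union(genera, touched[vapply(touched, function(u)
    isGenusGroup(checklist@taxa[[u]]@rank), logical(1))])

  affected <- c(sort(species), sort(genera))
  id <- checklist@meta@checklistId
  minted <- stats::setNames(vapply(affected, function(u)
    mintUri(minter, id), character(1)), affected)

  when <- event@when
  survivor <- intersect(event@beforeUris, event@afterUris)
  newTaxa <- list()
  for (u in affected) {
    t <- checklist@taxa[[u]]
    t@uri <- minted[[u]]
    if (!is.na(t@parentUri) && !is.na(minted[t@parentUri]))
      t@parentUri <- unname(minted[t@parentUri])
    op <- t@status@opinion
    if (identical(event@changeType, "lump") && u %in% event@beforeUris &&
        isSpeciesGroup(t@rank)) {
      if (u %in% survivor) {
        op <- "valid"; t@acceptedUri <- NA_character_
      } else {
        op <- "synonym"
        t@acceptedUri <- unname(minted[survivor[1]])
      }
    } else if (identical(event@changeType, "split") &&
               u %in% event@afterUris && isSpeciesGroup(t@rank)) {
      op <- "valid"; t@acceptedUri <- NA_character_
    } else if (identical(event@changeType, "status_change") &&
               !is.null(newStatus) && u %in% event@beforeUris) {
      op <- newStatus@opinion
      if (!op %in% .nonvalidOpinions) t@acceptedUri <- NA_character_
    } else if (!is.na(t@acceptedUri) && !is.na(minted[t@acceptedUri])) {
      t@acceptedUri <- unname(minted[t@acceptedUri])
    }
    t@status <- StatusAssignment(op, t@status@note, when)
    t@validFrom <- when
    newTaxa[[t@uri]] <- t
  }

  relType <- switch(event@changeType,
                    lump = "part_of", split = "part_of", "congruent")
  rels <- lapply(affected, function(u)
    ConceptMapping(u, unname(minted[u]), relType, "ostensive",
                   provenance = "automatic", timestamp = when))
  realised <- ChangeEvent(event@eventId, event@changeType,
                          beforeUris = affected,
                          afterUris = unname(minted[affected]),
                          relations = rels, when = when)
  updated <- Checklist(checklist@meta,
                       c(unname(checklist@taxa), unname(newTaxa)))
  list(checklist = updated, event = realised, minted = minted)
}

#' Timeline of a taxon concept across checklist versions
#'
#' Follows change-event links in both directions from the given URI and
#' returns every version of the concept ordered in time — by the publication
#' year of the containing checklist for static lists, by the status time
#' stamp for dynamic lists, with a stable tie-break on the URI.
#'
#' @param corpus a \linkS4class{Corpus} whose \code{events} connect the
#'   versions.
#' @param uri a taxon URI present in the corpus.
#' @return Data frame with columns \code{when}, \code{status}, \code{uri},
#'   one row per version (a single row when the taxon has no events).
#' @export
temporalOrder <- function(corpus, uri) {
  all <- taxa(corpus)
  if (!uri %in% names(all))
    stop(sprintf("unknown taxon URI '%s'", uri), call. = FALSE)
  ## connected component over event before/after links
  adj <- new.env(parent = emptyenv())
  link <- function(a, b) {
    adj[[a]] <- union(adj[[a]] %||% character(0), b)
    adj[[b]] <- union(adj[[b]] %||% character(0), a)
  }
  for (e in corpus@events) {
    if (length(e@relations)) {
      ## per-concept links: a taxon's timeline follows its own concept
      for (m in e@relations) link(m@sourceUri, m@targetUri)
    } else {
      for (b in e@beforeUris) for (a in e@afterUris) link(b, a)
    }
  }
  comp <- uri
  queue <- uri
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adj[[u]] %||% character(0))
      if (!v %in% comp) { comp <- c(comp, v); queue <- c(queue, v) }
  }
  comp <- comp[comp %in% names(all)]
  whenOf <- function(u) {
    t <- all[[u]]
    cl <- corpus@checklists[[t@checklistId]]
    if (!is.null(cl) && identical(cl@meta@listType, "dynamic")) {
      if (!is.na(t@status@timestamp)) return(t@status@timestamp)
      if (!is.na(t@validFrom)) return(t@validFrom)
    }
    if (!is.null(cl) && !is.na(cl@meta@yearPublished))
      return(as.character(cl@meta@yearPublished))
    NA_character_
  }
  df <- data.frame(
    when = vapply(comp, whenOf, character(1)),
    status = vapply(comp, function(u) all[[u]]@status@opinion, character(1)),
    uri = comp, stringsAsFactors = FALSE, row.names = NULL)
  df[order(df$when, df$uri, na.last = TRUE), , drop = FALSE]
}

#' Write change events as a JSON-lines diff report
#'
#' One JSON object per line per event: type, when, before/after URIs and the
#' relations. Readable by humans and by any JSON-lines consumer.
#'
#' @param events list of \linkS4class{ChangeEvent}.
#' @param path output file; use \code{""} for stdout.
#' @return \code{path}, invisibly.
#' @export
writeDiffReport <- function(events, path = "") {
  esc <- function(x) gsub('"', '\\\\"', x)
  lines <- vapply(events, function(e) {
    rels <- vapply(e@relations, function(m)
      sprintf('{"source":"%s","relation":"%s","target":"%s"}',
              esc(m@sourceUri), m@relation, esc(m@targetUri)), character(1))
    sprintf(paste0('{"type":"%s","when":"%s","before":[%s],',
                   '"after":[%s],"relations":[%s]}'),
            e@changeType, esc(e@when),
            paste(sprintf('"%s"', esc(e@beforeUris)), collapse = ","),
            paste(sprintf('"%s"', esc(e@afterUris)), collapse = ","),
            paste(rels, collapse = ","))
  }, character(1))
  if (identical(path, "")) cat(lines, sep = "\n")
  else writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
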