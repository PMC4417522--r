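## Structural validation of a checklist: issues are data, not exceptions.

.issue <- function(uri, rule, severity, message) {
  data.frame(uri = uri, rule = rule, severity = severity, message = message,
             stringsAsFactors = FALSE)
}

.noIssues <- function() {
  data.frame(uri = character(0), rule = character(0), severity = character(0),
             message = character(0), stringsAsFactors = FALSE)
}

#' Validate a checklist against the model invariants
#'
#' Checks every structural invariant of the checklist model and returns the
#' violations as a data frame, one row per issue, with the offending URI, the
#' rule violated, a severity (\code{"error"} or \code{"warning"}) and a
#' human-readable message. An empty data frame means the checklist is
#' well-formed. Validation never throws: imperfect checklists are common and
#' must remain loadable and inspectable.
#'
#' Errors: hierarchy cycles, parents outside the checklist, species-group
#' records without a reachable genus-group ancestor, synonym wiring
#' inconsistencies (a synonym/variant without an accepted target, an accepted
#' target that is not valid, or an accepted target on a valid record),
#' missing status time stamps in a dynamic list, duplicate URIs, and
#' authorship violations (pre-Linnean years, botanical combination authors in
#' a zoological list). Warnings: rank inversions along a parent chain and
#' homonymous label+rank pairs.
#'
#' The check is idempotent and order-independent: permuting the records
#' yields the same multiset of issues.
#'
#' @param checklist a \linkS4class{Checklist}, or a list of
#'   \linkS4class{TaxonRecord} if \code{meta} is supplied.
#' @param meta a \linkS4class{ChecklistMeta}; taken from \code{checklist}
#'   when that is a \linkS4class{Checklist}.
#' @return A data frame with columns \code{uri}, \code{rule},
#'   \code{severity}, \code{message}.
#' @seealso \code{\link{readChecklistCsv}}, which runs this after loading.
#' @export
validateChecklist <- function(checklist, meta = NULL) {
  if (is(checklist, "Checklist")) {
    meta <- checklist@meta
    records <- unname(checklist@taxa)
  } else {
    stopifnot(is(meta, "ChecklistMeta"))
    records <- unname(checklist)
  }
  issues <- list(.noIssues())
  add <- function(...) issues[[length(issues) + 1L]] <<- .issue(...)

  uris <- vapply(records, function(t) t@uri, character(1))
  byUri <- records
  names(byUri) <- uris

  if (identical(meta@listType, "static") && is.na(meta@yearPublished))
    add("", "static checklist without year", "error",
        sprintf("static checklist '%s' has no publication year",
                meta@checklistId))

  dup <- unique(uris[duplicated(uris)])
  for (u in dup)
    add(u, "duplicate uri", "error",
        sprintf("uri '%s' occurs more than once", u))

  rankIdx <- match(vapply(records, function(t) t@rank, character(1)),
                   rankVocabulary())

  for (i in seq_along(records)) {
    t <- records[[i]]
    if (!nzchar(t@checklistId) || !identical(t@checklistId,
                                             meta@checklistId))
      add(t@uri, "foreign record", "error",
          sprintf("record carries checklist id '%s', expected '%s'",
                  t@checklistId, meta@checklistId))
    if (is.na(rankIdx[i]))
      add(t@uri, "unknown rank", "error",
          sprintf("rank '%s' is not in the rank vocabulary", t@rank))

    ## hierarchy: acyclic, within-checklist, species reach a genus-group rank
    seen <- character(0)
    cur <- t
    genusReached <- FALSE
    repeat {
      if (is.na(cur@parentUri)) break
      if (cur@parentUri %in% c(seen, t@uri)) {
        add(t@uri, "hierarchy cycle", "error",
            sprintf("parent chain of '%s' contains a cycle", t@uri))
        break
      }
      if (!cur@parentUri %in% uris) {
        add(t@uri, "dangling parent", "error",
            sprintf("parent '%s' is not in this checklist", cur@parentUri))
        break
      }
      seen <- c(seen, cur@uri)
      cur <- byUri[[cur@parentUri]]
      if (isGenusGroup(cur@rank)) genusReached <- TRUE
    }
    ## rank monotonicity (immediate parent only; real lists skip ranks);
    ## a self-parent is already a cycle error, not an inversion
    if (!is.na(t@parentUri) && t@parentUri %in% uris &&
        !identical(t@parentUri, t@uri)) {
      pRank <- byUri[[t@parentUri]]@rank
      pi <- match(pRank, rankVocabulary())
      ci <- rankIdx[i]
      if (!is.na(pi) && !is.na(ci) && pi >= ci)
        add(t@uri, "rank inversion", "warning",
            sprintf("'%s' (%s) has parent of rank '%s'", t@label, t@rank,
                    pRank))
    }
    if (isSpeciesGroup(t@rank) && !genusReached)
      add(t@uri, "no genus ancestor", "error",
          sprintf("species-group record '%s' has no genus-group ancestor",
                  t@label))

    ## synonym wiring
    nonvalid <- t@status@opinion %in% .nonvalidOpinions
    if (nonvalid && is.na(t@acceptedUri))
      add(t@uri, "synonym without accepted target", "error",
          sprintf("'%s' is %s but has no accepted target", t@label,
                  t@status@opinion))
    if (!nonvalid && !is.na(t@acceptedUri))
      add(t@uri, "accepted target on valid record", "error",
          sprintf("'%s' has status '%s' but points at an accepted name",
                  t@label, t@status@opinion))
    if (nonvalid && !is.na(t@acceptedUri)) {
      if (!t@acceptedUri %in% uris)
        add(t@uri, "dangling accepted target", "error",
            sprintf("accepted target '%s' is not in this checklist",
                    t@acceptedUri))
      else if (!identical(byUri[[t@acceptedUri]]@status@opinion, "valid"))
        add(t@uri, "accepted target not valid", "error",
            sprintf("accepted target of '%s' has status '%s'", t@label,
                    byUri[[t@acceptedUri]]@status@opinion))
    }

    ## dynamic lists require status time stamps
    if (identical(meta@listType, "dynamic") && is.na(t@status@timestamp))
      add(t@uri, "missing status timestamp", "error",
          sprintf("dynamic checklist record '%s' has no status time stamp",
                  t@label))

    ## authorship
    if (!is.null(t@authorship)) {
      a <- t@authorship
      if (!is.na(a@year) && (a@year < 1753L || a@year > 9999L))
        add(t@uri, "authorship year out of range", "error",
            sprintf("authorship year %d of '%s' predates 1753", a@year,
                    t@label))
      if (length(a@combinationAuthors) && identical(meta@code, "ICZN"))
        add(t@uri, "combination authors under ICZN", "error",
            sprintf("'%s' has botanical combination authors in an ICZN list",
                    t@label))
    }

    ## embedded components
    for (p in t@publications)
      if (!nzchar(p@citation))
        add(t@uri, "empty citation", "error", "publication without citation")
    for (v in t@vernaculars)
      if (!nzchar(v@name) || !nzchar(v@language))
        add(t@uri, "bad vernacular", "error",
            "vernacular name or language empty")
  }

  ## homonyms: identical label+rank pairs within the list (warning only)
  lr <- vapply(records, function(t) paste(t@label, t@rank, sep = "\r"),
               character(1))
  for (k in unique(lr[duplicated(lr)])) {
    for (u in uris[lr == k])
      add(u, "homonymous label", "warning",
          sprintf("label+rank '%s' occurs more than once",
                  sub("\r", " / ", k)))
  }

  out <- do.call(rbind, issues)
  out[order(out$uri, out$rule, out$message), , drop = FALSE]
}
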