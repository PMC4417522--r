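## Synthetic checklists and revisions.
##
## Names are drawn from a pronounceable syllable generator with collision
## checking, so every record has a unique NameKey by construction — the
## regime in which diffing is exact. Authorship years are uniform on
## 1758–2000; lumps synthesised here always respect nomenclatural priority
## (the oldest name survives), so the priority-warning path is exercised by
## a separate, deliberately violating fixture in the tests.

.syllables <- c("ba", "be", "bi", "bo", "bu", "ca", "ce", "ci", "co", "cu",
                "da", "de", "di", "do", "du", "fa", "fe", "fi", "fo", "fu",
                "ga", "ge", "gi", "go", "gu", "la", "le", "li", "lo", "lu",
                "ma", "me", "mi", "mo", "mu", "na", "ne", "ni", "no", "nu",
                "pa", "pe", "pi", "po", "pu", "ra", "re", "ri", "ro", "ru",
                "sa", "se", "si", "so", "su", "ta", "te", "ti", "to", "tu")

.authorPool <- c("Virtanen", "Korhonen", "Nieminen", "Laine", "Heikkinen",
                 "Koskinen", "Jarvinen", "Lehtonen", "Salminen", "Tuominen")

.randomWord <- function(nSyl = 3L) {
  paste(sample(.syllables, nSyl, replace = TRUE), collapse = "")
}

.freshWord <- function(used, nSyl = 3L, capital = FALSE) {
  for (i in 1:1000) {
    w <- .randomWord(nSyl)
    if (capital) w <- paste0(toupper(substring(w, 1, 1)), substring(w, 2))
    if (!w %in% used) return(w)
  }
  stop("could not generate a fresh name", call. = FALSE)
}

#' A revision specification
#'
#' Counts of each change type to inject into a synthetic revision, plus the
#' seed driving the random choices. Used by \code{\link{mutateChecklist}}
#' and the parameter-recovery experiments.
#'
#' @slot nTransfers,nLumps,nSplits,nAdditions,nRemovals non-negative counts.
#' @slot seed integer seed.
#' @name RevisionSpec-class
#' @exportClass RevisionSpec
setClass("RevisionSpec",
  representation(nTransfers = "integer", nLumps = "integer",
                 nSplits = "integer", nAdditions = "integer",
                 nRemovals = "integer", seed = "integer"),
  prototype(nTransfers = 0L, nLumps = 0L, nSplits = 0L, nAdditions = 0L,
            nRemovals = 0L, seed = 1L))

setValidity("RevisionSpec", function(object) {
  counts <- c(object@nTransfers, object@nLumps, object@nSplits,
              object@nAdditions, object@nRemovals)
  if (any(is.na(counts)) || any(counts < 0L))
    "all change counts must be non-negative" else TRUE
})

#' @rdname RevisionSpec-class
#' @param nTransfers,nLumps,nSplits,nAdditions,nRemovals,seed see slots.
#' @export
RevisionSpec <- function(nTransfers = 0, nLumps = 0, nSplits = 0,
                         nAdditions = 0, nRemovals = 0, seed = 1) {
  new("RevisionSpec", nTransfers = as.integer(nTransfers),
      nLumps = as.integer(nLumps), nSplits = as.integer(nSplits),
      nAdditions = as.integer(nAdditions), nRemovals = as.integer(nRemovals),
      seed = as.integer(seed))
}

.randomAuthorship <- function(usedYears = integer(0)) {
  Authorship(sample(.authorPool, 1), sample(1758:2000, 1))
}

#' Generate a synthetic checklist
#'
#' Builds a valid checklist of \code{nGenera} genera, each holding a
#' uniform-random number of species in \code{speciesPerGenus}, with a
#' fraction \code{synonymRate} of the species-group records wired as
#' synonyms of a valid congener via the accepted-name link. All name keys
#' are unique; the result always passes \code{\link{validateChecklist}} and
#' is identical across runs with the same seed.
#'
#' @param nGenera number of genera (>= 1).
#' @param speciesPerGenus length-2 range (min, max) of species per genus.
#' @param synonymRate fraction in [0, 1) of species records that are
#'   synonyms.
#' @param seed integer seed.
#' @param checklistId,year,listType checklist identity; dynamic lists stamp
#'   every status with \code{year-01-01}.
#' @param uriBase base for minted URIs.
#' @return A \linkS4class{Checklist}.
#' @examples
#' cl <- generateChecklist(3, c(2, 4), 0.1, seed = 42)
#' nrow(validateChecklist(cl))  # 0
#' @export
generateChecklist <- function(nGenera, speciesPerGenus = c(3L, 6L),
                              synonymRate = 0, seed = 1L,
                              checklistId = "synthetic", year = 2000L,
                              listType = c("static", "dynamic"),
                              uriBase = "http://example.org/onto") {
  stopifnot(nGenera >= 1, length(speciesPerGenus) == 2L,
            speciesPerGenus[1] >= 1, synonymRate >= 0, synonymRate < 1)
  listType <- match.arg(listType)
  meta <- ChecklistMeta(checklistId, title = "synthetic checklist",
                        yearPublished = year, listType = listType,
                        code = "ICZN")
  ts <- if (identical(listType, "dynamic"))
    sprintf("%d-01-01", year) else NA_character_
  withSeed(seed, {
    minter <- uriMinter(uriBase, seed = sample.int(.Machine$integer.max, 1))
    usedLabels <- character(0)
    taxaList <- list()
    for (g in seq_len(nGenera)) {
      gLab <- .freshWord(usedLabels, capital = TRUE)
      usedLabels <- c(usedLabels, gLab)
      gUri <- mintUri(minter, checklistId)
      taxaList[[gUri]] <- TaxonRecord(
        gUri, checklistId, "genus", gLab,
        status = StatusAssignment("valid", timestamp = ts),
        authorship = .randomAuthorship(), validFrom = ts)
      nSp <- sample(speciesPerGenus[1]:speciesPerGenus[2], 1)
      spUris <- character(0)
      for (s in seq_len(nSp)) {
        sLab <- .freshWord(usedLabels)
        usedLabels <- c(usedLabels, sLab)
        sUri <- mintUri(minter, checklistId)
        ## first species of a genus is always valid so synonyms have a target
        isSyn <- s > 1L && stats::runif(1) < synonymRate
        accepted <- if (isSyn) sample(spUris, 1) else NA_character_
        taxaList[[sUri]] <- TaxonRecord(
          sUri, checklistId, "species", sLab, parentUri = gUri,
          status = StatusAssignment(if (isSyn) "synonym" else "valid",
                                    timestamp = ts),
          authorship = .randomAuthorship(),
          acceptedUri = accepted, validFrom = ts)
        if (!isSyn) spUris <- c(spUris, sUri)
      }
    }
    ## a positive rate guarantees at least one synonym: small lists can
    ## otherwise draw none, leaving the stated fraction unrepresented
    if (synonymRate > 0) {
      anySyn <- any(vapply(taxaList, function(t)
        identical(t@status@opinion, "synonym"), logical(1)))
      if (!anySyn) {
        byGenus <- split(names(taxaList), vapply(taxaList, function(t)
          if (is.na(t@parentUri)) t@uri else t@parentUri, character(1)))
        for (g in byGenus) {
          sp <- g[vapply(taxaList[g], function(t)
            identical(t@rank, "species"), logical(1))]
          if (length(sp) >= 2L) {
            u <- sp[length(sp)]
            t <- taxaList[[u]]
            t@status <- StatusAssignment("synonym", timestamp = ts)
            t@acceptedUri <- sp[1]
            taxaList[[u]] <- t
            break
          }
        }
      }
    }
    cl <- Checklist(meta, unname(taxaList))
    attr(cl, "minter") <- minter
    cl
  })
}

## eligibility bookkeeping for mutateChecklist: a taxon takes part in at
## most one injected change so the truth multiset is unambiguous
.pickFree <- function(candidates, free, n) {
  pool <- intersect(candidates, free)
  if (length(pool) < n) return(NULL)
  ## sample() treats a length-1 vector as 1:x; guard
  if (length(pool) == 1L) pool else sample(pool, n)
}

#' Mutate a checklist into a revision with known ground truth
#'
#' Applies the requested numbers of genus transfers, lumps, splits,
#' additions and removals to randomly chosen eligible taxa and returns both
#' the revised checklist (a new static version: new checklist id, year + 1,
#' fresh URIs for every record — scientific names get a new URI in each
#' static checklist) and the injected events as ground truth for recovery
#' experiments. Lumps synonymise the younger of two valid congeners under
#' the older (priority is respected); splits promote an existing synonym
#' back to valid, so the source checklist needs a non-zero synonym rate to
#' support them. An infeasible specification fails with a message naming the
#' shortfall.
#'
#' @param checklist a \linkS4class{Checklist} from
#'   \code{\link{generateChecklist}} (or any valid checklist with unique
#'   name keys).
#' @param spec a \linkS4class{RevisionSpec}.
#' @return A list with \code{checklist} (the revision) and \code{truth}
#'   (list of \linkS4class{ChangeEvent} whose before/after URIs refer to the
#'   original and revised checklists respectively).
#' @export
mutateChecklist <- function(checklist, spec) {
  meta <- checklist@meta
  newId <- paste0(meta@checklistId, "rev")
  newYear <- if (is.na(meta@yearPublished)) NA_integer_
             else meta@yearPublished + 1L
  newMeta <- ChecklistMeta(newId, title = meta@title,
                           yearPublished = newYear,
                           listType = meta@listType, code = meta@code)
  ts <- if (identical(meta@listType, "dynamic"))
    sprintf("%d-01-01", newYear) else NA_character_
  when <- as.character(if (!is.na(ts)) ts else newYear)

  withSeed(spec@seed, {
    minter <- uriMinter(sub("/[^/]+/[^/]+$", "",
                            names(checklist@taxa)[1]) %||%
                          "http://example.org/onto",
                        seed = sample.int(.Machine$integer.max, 1))
    old <- checklist@taxa
    uris <- names(old)
    newUri <- stats::setNames(vapply(uris, function(u)
      mintUri(minter, newId), character(1)), uris)

    isSpecies <- vapply(old, function(t) isSpeciesGroup(t@rank), logical(1))
    isValid <- vapply(old, function(t)
      identical(t@status@opinion, "valid"), logical(1))
    isSyn <- vapply(old, function(t)
      identical(t@status@opinion, "synonym"), logical(1))
    hasSyn <- vapply(uris, function(u)
      any(vapply(old, function(t) identical(t@acceptedUri, u), logical(1))),
      logical(1))
    genusUris <- uris[vapply(old, function(t) identical(t@rank, "genus"),
                             logical(1))]
    ## plain valid species without attached synonyms
    plainValid <- uris[isSpecies & isValid & !hasSyn]
    free <- uris
    truth <- list()
    cur <- lapply(old, identity)
    names(cur) <- uris
    eventN <- 0L
    evId <- function() {
      eventN <<- eventN + 1L
      sprintf("%s/%s/e%d", sub("/[^/]+$", "",
                               sub("/[^/]+$", "", uris[1])), "changes",
              eventN)
    }
    need <- function(what, got, want) {
      if (is.null(got))
        stop(sprintf("infeasible revision spec: need %d eligible taxa for %s",
                     want, what), call. = FALSE)
      got
    }

    ## genus transfers: move a plain valid species to a different genus
    if (spec@nTransfers > 0) {
      if (length(genusUris) < 2L)
        stop("infeasible revision spec: transfers need at least two genera",
             call. = FALSE)
      chosen <- need("genus transfers",
                     .pickFree(plainValid, free, spec@nTransfers),
                     spec@nTransfers)
      for (u in chosen) {
        free <- setdiff(free, u)
        t <- cur[[u]]
        target <- sample(setdiff(genusUris, t@parentUri), 1)
        t@parentUri <- target
        a <- t@authorship
        if (!is.null(a)) { a@parenthesized <- TRUE; t@authorship <- a }
        cur[[u]] <- t
        truth[[length(truth) + 1L]] <- ChangeEvent(
          evId(), "genus_transfer", u, unname(newUri[u]),
          list(ConceptMapping(u, unname(newUri[u]), "congruent",
                              "ostensive", provenance = "automatic")),
          when)
      }
    }

    ## lumps: within one genus, the younger of two valid species becomes a
    ## synonym of the older (priority respected)
    if (spec@nLumps > 0) {
      done <- 0L
      for (i in seq_len(spec@nLumps)) {
        found <- FALSE
        for (g in sample(genusUris)) {
          cands <- intersect(plainValid, free)
          cands <- cands[vapply(cur[cands], function(t)
            identical(t@parentUri, g), logical(1))]
          yrs <- vapply(cur[cands], function(t)
            if (is.null(t@authorship)) NA_integer_ else t@authorship@year,
            integer(1))
          cands <- cands[!is.na(yrs)]
          yrs <- yrs[!is.na(yrs)]
          if (length(cands) < 2L || length(unique(yrs)) < 2L) next
          pair <- sample(seq_along(cands), 2)
          if (yrs[pair[1]] > yrs[pair[2]]) pair <- rev(pair)
          survivor <- cands[pair[1]]; absorbed <- cands[pair[2]]
          free <- setdiff(free, c(survivor, absorbed))
          t <- cur[[absorbed]]
          t@status <- StatusAssignment("synonym", timestamp = ts)
          t@acceptedUri <- survivor
          cur[[absorbed]] <- t
          truth[[length(truth) + 1L]] <- ChangeEvent(
            evId(), "lump", c(survivor, absorbed), unname(newUri[survivor]),
            list(ConceptMapping(survivor, unname(newUri[survivor]),
                                "part_of", "ostensive",
                                provenance = "automatic"),
                 ConceptMapping(absorbed, unname(newUri[survivor]),
                                "part_of", "ostensive",
                                provenance = "automatic")),
            when)
          found <- TRUE
          break
        }
        if (!found)
          stop(sprintf(
            "infeasible revision spec: no genus offers two free valid species of different ages for lump %d",
            i), call. = FALSE)
        done <- done + 1L
      }
    }

    ## splits: promote an existing synonym to valid; its accepted name stays
    if (spec@nSplits > 0) {
      synPool <- uris[isSyn & isSpecies]
      synPool <- synPool[vapply(cur[synPool], function(t)
        t@acceptedUri %in% free, logical(1))]
      chosen <- need("splits", .pickFree(synPool, free, spec@nSplits),
                     spec@nSplits)
      for (u in chosen) {
        t <- cur[[u]]
        tgt <- t@acceptedUri
        free <- setdiff(free, c(u, tgt))
        t@status <- StatusAssignment("valid", timestamp = ts)
        t@acceptedUri <- NA_character_
        cur[[u]] <- t
        truth[[length(truth) + 1L]] <- ChangeEvent(
          evId(), "split", tgt, unname(newUri[c(tgt, u)]),
          list(ConceptMapping(unname(newUri[tgt]), tgt, "part_of",
                              "ostensive", provenance = "automatic"),
               ConceptMapping(unname(newUri[u]), tgt, "part_of",
                              "ostensive", provenance = "automatic")),
          when)
      }
    }

    ## removals: drop a plain valid species
    if (spec@nRemovals > 0) {
      chosen <- need("removals",
                     .pickFree(plainValid, free, spec@nRemovals),
                     spec@nRemovals)
      for (u in chosen) {
        free <- setdiff(free, u)
        cur[[u]] <- NULL
        truth[[length(truth) + 1L]] <- ChangeEvent(
          evId(), "removal", u, character(0), list(), when)
      }
    }

    ## rewrite surviving records with fresh URIs and the new checklist id
    usedLabels <- vapply(old, function(t) t@label, character(1))
    out <- list()
    for (u in names(cur)) {
      t <- cur[[u]]
      t@uri <- unname(newUri[u])
      t@checklistId <- newId
      if (!is.na(t@parentUri)) t@parentUri <- unname(newUri[t@parentUri])
      if (!is.na(t@acceptedUri))
        t@acceptedUri <- unname(newUri[t@acceptedUri])
      if (!is.na(ts) && is.na(t@status@timestamp))
        t@status <- StatusAssignment(t@status@opinion, t@status@note, ts)
      out[[t@uri]] <- t
    }

    ## additions: brand-new species in existing genera
    if (spec@nAdditions > 0) {
      for (i in seq_len(spec@nAdditions)) {
        g <- sample(genusUris, 1)
        sLab <- .freshWord(usedLabels)
        usedLabels <- c(usedLabels, sLab)
        sUri <- mintUri(minter, newId)
        out[[sUri]] <- TaxonRecord(
          sUri, newId, "species", sLab, parentUri = unname(newUri[g]),
          status = StatusAssignment("valid", timestamp = ts),
          authorship = .randomAuthorship(), validFrom = ts)
        truth[[length(truth) + 1L]] <- ChangeEvent(
          evId(), "addition", character(0), sUri, list(), when)
      }
    }

    list(checklist = Checklist(newMeta, unname(out)), truth = truth)
  })
}
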