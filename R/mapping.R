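## The concept-mapping engine.
##
## Species concepts in two checklists are linked congruent when they share
## the same name and authorship (the NameKey). Taxa above the species level
## are never matched by name: their alignment is always derived from the
## species they contain, projected through the species congruences. The
## relation algebra (congruent symmetric+transitive, part_of transitive,
## overlap symmetric non-transitive) is closed by fixpoint iteration.

.speciesRecords <- function(checklist) {
  Filter(function(t) isSpeciesGroup(t@rank), checklist@taxa)
}

.higherRecords <- function(checklist) {
  Filter(function(t) !isSpeciesGroup(t@rank), checklist@taxa)
}

#' Map species concepts between two checklists
#'
#' Species-group taxa with equal name keys (same epithet, same canonicalised
#' authorship, same year) are linked as congruent, by default with ostensive
#' mode — checklists present a classification by membership, not by
#' characters. Mappings are emitted once per pair, flagged as automatic.
#' When one key matches several taxa on either side (homonyms), no
#' congruence is asserted; instead each candidate pair is emitted as an
#' \code{associated} suggestion, the relation for taxonomically unresolved
#' connections.
#'
#' @param listA,listB validated \linkS4class{Checklist} objects.
#' @param mode \code{"ostensive"} (default) or \code{"intensional"}.
#' @param table author abbreviation table.
#' @return List of \linkS4class{ConceptMapping} (possibly empty).
#' @examples
#' a <- exampleChecklist("beetles_1992")
#' b <- exampleChecklist("beetles_2011")
#' length(mapSpecies(a, b))  # 3 congruent species pairs
#' @export
mapSpecies <- function(listA, listB, mode = c("ostensive", "intensional"),
                       table = authorAbbreviations()) {
  mode <- match.arg(mode)
  spA <- .speciesRecords(listA)
  spB <- .speciesRecords(listB)
  keysA <- vapply(spA, recordKey, character(1), table = table)
  keysB <- vapply(spB, recordKey, character(1), table = table)
  out <- list()
  for (k in sort(unique(keysA[keysA %in% keysB]))) {
    aUris <- names(spA)[keysA == k]
    bUris <- names(spB)[keysB == k]
    if (length(aUris) == 1L && length(bUris) == 1L) {
      if (identical(aUris, bUris)) next  # self-pairing suppressed
      out[[length(out) + 1L]] <-
        ConceptMapping(aUris, bUris, "congruent", mode,
                       provenance = "automatic")
    } else {
      for (ua in aUris) for (ub in bUris) {
        if (identical(ua, ub)) next
        out[[length(out) + 1L]] <-
          ConceptMapping(ua, ub, "associated", provenance = "automatic")
      }
    }
  }
  out
}

## All species-group descendant URIs of a taxon within its checklist.
.descendantSpecies <- function(uri, checklist) {
  kids <- names(checklist@taxa)[vapply(checklist@taxa, function(t)
    identical(t@parentUri, uri), logical(1))]
  out <- character(0)
  for (k in kids) {
    t <- checklist@taxa[[k]]
    if (isSpeciesGroup(t@rank)) out <- c(out, k)
    out <- c(out, .descendantSpecies(k, checklist))
  }
  out
}

#' Align higher taxa by their species content
#'
#' Comparison of taxa above the species level is always based on the
#' species: two higher taxa of equal rank are congruent only if the species
#' belonging to them are the same, once species identity is projected
#' through the supplied species congruences. Proper containment yields
#' \code{part_of} (directed), a remaining non-empty intersection yields
#' \code{overlaps}; disjoint pairs are not linked at all. A species with no
#' congruent partner counts as private content and blocks congruence — this
#' is why a species newly recorded in one region can demote a genus pair
#' from congruent to part_of.
#'
#' @param listA,listB \linkS4class{Checklist} objects.
#' @param speciesMaps species congruences from \code{\link{mapSpecies}} (or
#'   manual mappings of the same shape).
#' @return List of \linkS4class{ConceptMapping}, mode ostensive, provenance
#'   automatic.
#' @export
alignHigherTaxa <- function(listA, listB, speciesMaps) {
  ## species identity under the congruence: union-find over congruent
  ## edges, each class represented by its smallest member URI (direction
  ## and prior closure of the input therefore do not matter)
  parent <- new.env(parent = emptyenv())
  find <- function(u) {
    while (!is.null(parent[[u]]) && !identical(parent[[u]], u))
      u <- parent[[u]]
    u
  }
  for (m in speciesMaps) {
    if (!identical(m@relation, "congruent")) next
    ra <- find(m@sourceUri); rb <- find(m@targetUri)
    if (!identical(ra, rb)) {
      lo <- min(ra, rb); hi <- max(ra, rb)
      parent[[hi]] <- lo
    }
  }
  project <- function(uris) {
    vapply(uris, find, character(1), USE.NAMES = FALSE)
  }
  hiA <- .higherRecords(listA)
  hiB <- .higherRecords(listB)
  out <- list()
  for (ua in sort(names(hiA))) {
    sA <- unique(project(.descendantSpecies(ua, listA)))
    if (!length(sA)) next
    for (ub in sort(names(hiB))) {
      if (identical(ua, ub)) next
      if (!identical(hiA[[ua]]@rank, hiB[[ub]]@rank)) next
      sB <- unique(project(.descendantSpecies(ub, listB)))
      if (!length(sB)) next
      common <- intersect(sA, sB)
      if (!length(common)) next
      rel <- if (setequal(sA, sB)) {
        ConceptMapping(ua, ub, "congruent", "ostensive",
                       provenance = "automatic")
      } else if (all(sA %in% sB)) {
        ConceptMapping(ua, ub, "part_of", "ostensive",
                       provenance = "automatic")
      } else if (all(sB %in% sA)) {
        ConceptMapping(ub, ua, "part_of", "ostensive",
                       provenance = "automatic")
      } else {
        ConceptMapping(ua, ub, "overlaps", "ostensive",
                       provenance = "automatic")
      }
      out[[length(out) + 1L]] <- rel
    }
  }
  out
}

#' Automatically group taxa sharing name and authorship
#'
#' Partitions every taxon of the corpus by name key and creates one abstract
#' taxon (\linkS4class{TaxonGeneral}) per key. Taxa that share the same name
#' and authorship are thereby automatically mapped to the same abstract
#' instance; these machine-generated groupings are kept apart from manual
#' concept mappings so results can be ranked by reliability.
#'
#' @param corpus a \linkS4class{Corpus}.
#' @param table author abbreviation table.
#' @return List of \linkS4class{TaxonGeneral}; member sets are disjoint and
#'   jointly cover all taxa.
#' @export
autoMapGeneral <- function(corpus, table = authorAbbreviations()) {
  all <- taxa(corpus)
  if (!length(all)) return(list())
  keys <- vapply(all, recordKey, character(1), table = table)
  base <- corpus@config$uri_base %||% "http://example.org/onto"
  out <- list()
  for (k in sort(unique(keys))) {
    members <- sort(names(all)[keys == k])
    kk <- all[[members[1]]]
    gid <- paste0(base, "/general/",
                  utils::URLencode(gsub("\\|", "_", k), reserved = TRUE))
    out[[length(out) + 1L]] <-
      TaxonGeneral(gid, members, makeNameKey(kk, table))
  }
  out
}

## Canonical triple key of a mapping (for dedup during closure).
.mapKey <- function(s, r, t) paste(s, r, t, sep = "\r")

#' Close a set of concept mappings under the relation algebra
#'
#' Computes the least fixpoint that adds (i) the reverses of the symmetric
#' relations (congruent, overlaps), (ii) transitive edges through congruent
#' chains and part_of chains, and (iii) the composition of congruence with
#' containment (A congruent B, B part_of C implies A part_of C, and
#' symmetrically). Overlap is never propagated and \code{associated} is
#' never expanded. Derived edges are flagged \code{provenance="automatic"};
#' they inherit the mode of their parents when those agree and carry
#' \code{"n/a"} otherwise — mode is metadata and never alters the algebra.
#'
#' @param maps list of \linkS4class{ConceptMapping}.
#' @return The closed list (input edges first, then derived edges).
#' @export
closeMappings <- function(maps) {
  seen <- new.env(parent = emptyenv())
  edges <- list()
  addEdge <- function(s, r, t, mode, prov) {
    if (identical(s, t)) return(FALSE)
    k <- .mapKey(s, r, t)
    if (!is.null(seen[[k]])) return(FALSE)
    seen[[k]] <- TRUE
    edges[[length(edges) + 1L]] <<-
      ConceptMapping(s, t, r, mode, provenance = prov)
    TRUE
  }
  for (m in maps)
    addEdge(m@sourceUri, m@relation, m@targetUri, m@mode, m@provenance)

  combineMode <- function(m1, m2) if (identical(m1, m2)) m1 else "n/a"

  repeat {
    changed <- FALSE
    snap <- edges
    for (e in snap) {
      if (e@relation %in% c("congruent", "overlaps"))
        changed <- addEdge(e@targetUri, e@relation, e@sourceUri, e@mode,
                           "automatic") || changed
    }
    snap <- edges
    byRel <- split(snap, vapply(snap, function(e) e@relation, character(1)))
    cong <- byRel[["congruent"]] %||% list()
    part <- byRel[["part_of"]] %||% list()
    compose <- function(lhs, rhs, outRel) {
      for (e1 in lhs) for (e2 in rhs) {
        if (!identical(e1@targetUri, e2@sourceUri)) next
        changed <<- addEdge(e1@sourceUri, outRel, e2@targetUri,
                            combineMode(e1@mode, e2@mode),
                            "automatic") || changed
      }
    }
    compose(cong, cong, "congruent")
    compose(part, part, "part_of")
    compose(cong, part, "part_of")
    compose(part, cong, "part_of")
    if (!changed) break
  }
  edges
}

#' Detect contradictory concept mappings
#'
#' Closes the mappings, then flags pairs asserted with incompatible
#' relations: congruent and part_of on the same ordered pair (equality
#' contradicts proper containment), part_of in both directions
#' (antisymmetry), and congruent together with overlaps (overlap requires
#' the concepts to differ).
#'
#' @param maps list of \linkS4class{ConceptMapping}.
#' @return Data frame with columns \code{source}, \code{target},
#'   \code{conflict}; zero rows when consistent.
#' @export
validateMappings <- function(maps) {
  closed <- closeMappings(maps)
  rel <- new.env(parent = emptyenv())
  for (e in closed) {
    k <- paste(e@sourceUri, e@targetUri, sep = "\r")
    rel[[k]] <- union(rel[[k]] %||% character(0), e@relation)
  }
  out <- list()
  add <- function(s, t, what) out[[length(out) + 1L]] <<-
    data.frame(source = s, target = t, conflict = what,
               stringsAsFactors = FALSE)
  for (k in sort(ls(rel))) {
    st <- strsplit(k, "\r", fixed = TRUE)[[1]]
    r <- rel[[k]]
    if (all(c("congruent", "part_of") %in% r))
      add(st[1], st[2], "congruent+part_of")
    if (all(c("congruent", "overlaps") %in% r))
      add(st[1], st[2], "congruent+overlaps")
    if ("part_of" %in% r && st[1] < st[2]) {
      back <- rel[[paste(st[2], st[1], sep = "\r")]]
      if (!is.null(back) && "part_of" %in% back)
        add(st[1], st[2], "part_of both directions")
    }
  }
  if (!length(out))
    return(data.frame(source = character(0), target = character(0),
                      conflict = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Export / import concept mappings as TSV
#'
#' Five tab-separated UTF-8 columns: source, relation, mode, target,
#' provenance.
#'
#' @param maps list of \linkS4class{ConceptMapping}.
#' @param path file path.
#' @return \code{readMappingsTsv} returns a list of
#'   \linkS4class{ConceptMapping}; \code{writeMappingsTsv} returns
#'   \code{path} invisibly.
#' @export
writeMappingsTsv <- function(maps, path) {
  df <- data.frame(
    source = vapply(maps, function(m) m@sourceUri, character(1)),
    relation = vapply(maps, function(m) m@relation, character(1)),
    mode = vapply(maps, function(m) m@mode, character(1)),
    target = vapply(maps, function(m) m@targetUri, character(1)),
    provenance = vapply(maps, function(m) m@provenance, character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeMappingsTsv
#' @export
readMappingsTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  lapply(seq_len(nrow(df)), function(i)
    ConceptMapping(df$source[i], df$target[i], df$relation[i], df$mode[i],
                   df$provenance[i]))
}
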