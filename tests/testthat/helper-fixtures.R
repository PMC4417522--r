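# In-code fixtures and independent oracles shared across the test files.

# Small hand-built checklist: one genus, two valid species, optionally a
# synonym of the first species.
tinyChecklist <- function(id = "tiny", year = 2000L, withSynonym = FALSE,
                          listType = "static") {
  ts <- if (identical(listType, "dynamic")) "2000-01-01" else NA_character_
  u <- function(x) sprintf("http://example.org/onto/%s/%s", id, x)
  taxa <- list(
    TaxonRecord(u("g1"), id, "genus", "Aus",
                status = StatusAssignment("valid", timestamp = ts),
                authorship = Authorship("Smith", 1800), validFrom = ts),
    TaxonRecord(u("s1"), id, "species", "bus", parentUri = u("g1"),
                status = StatusAssignment("valid", timestamp = ts),
                authorship = Authorship("Smith", 1801), validFrom = ts),
    TaxonRecord(u("s2"), id, "species", "cus", parentUri = u("g1"),
                status = StatusAssignment("valid", timestamp = ts),
                authorship = Authorship("Jones", 1805), validFrom = ts))
  if (withSynonym)
    taxa <- c(taxa, list(
      TaxonRecord(u("s3"), id, "species", "dus", parentUri = u("g1"),
                  status = StatusAssignment("synonym", timestamp = ts),
                  authorship = Authorship("Jones", 1810),
                  acceptedUri = u("s1"), validFrom = ts)))
  Checklist(ChecklistMeta(id, yearPublished = year, listType = listType,
                          code = "ICZN"), taxa)
}

# Build a two-checklist corpus with chosen species sets per genus; species
# are shared across lists when they have the same epithet/author/year.
# speciesOf: named list genusLabel -> character vector of epithets.
checklistFromSets <- function(id, year, speciesOf) {
  u <- function(x) sprintf("http://example.org/onto/%s/%s", id, x)
  taxa <- list()
  i <- 0L
  for (g in names(speciesOf)) {
    i <- i + 1L
    gUri <- u(paste0("g", i))
    taxa[[gUri]] <- TaxonRecord(gUri, id, "genus", g,
                                authorship = Authorship("Auct", 1800L))
    for (ep in speciesOf[[g]]) {
      sUri <- u(paste0("s", length(taxa)))
      taxa[[sUri]] <- TaxonRecord(sUri, id, "species", ep,
                                  parentUri = gUri,
                                  authorship = Authorship("Auct", 1850L))
    }
  }
  Checklist(ChecklistMeta(id, yearPublished = year, code = "ICZN"),
            unname(taxa))
}

# Independent brute-force fixpoint oracle for the relation algebra, using
# boolean adjacency matrices (a different computation path from
# closeMappings' edge-list iteration).
closureOracle <- function(maps, nodes) {
  n <- length(nodes)
  C <- P <- O <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (m in maps) {
    if (m@relation == "congruent") C[m@sourceUri, m@targetUri] <- TRUE
    if (m@relation == "part_of") P[m@sourceUri, m@targetUri] <- TRUE
    if (m@relation == "overlaps") O[m@sourceUri, m@targetUri] <- TRUE
  }
  repeat {
    C2 <- C | t(C)
    O2 <- O | t(O)
    C2 <- C2 | (C2 %*% C2 > 0)
    P2 <- P | (P %*% P > 0) | (C2 %*% P > 0) | (P %*% C2 > 0)
    diag(C2) <- FALSE; diag(P2) <- FALSE; diag(O2) <- FALSE
    if (identical(C2, C) && identical(P2, P) && identical(O2, O)) break
    C <- C2; P <- P2; O <- O2
  }
  out <- character(0)
  for (i in nodes) for (j in nodes) {
    if (C[i, j]) out <- c(out, paste(i, "congruent", j))
    if (P[i, j]) out <- c(out, paste(i, "part_of", j))
    if (O[i, j]) out <- c(out, paste(i, "overlaps", j))
  }
  sort(out)
}

relationTriples <- function(maps) {
  sort(unique(vapply(maps, function(m)
    paste(m@sourceUri, m@relation, m@targetUri), character(1))))
}

# Label-based signature of an event multiset: URIs differ between original
# and revision, labels identify the participants.
eventSignatures <- function(events, labelOf) {
  sort(vapply(events, function(e)
    paste(e@changeType,
          paste(sort(unname(labelOf[e@beforeUris])), collapse = ","),
          paste(sort(unname(labelOf[e@afterUris])), collapse = ","),
          sep = "|"), character(1)))
}

labelLookup <- function(...) {
  out <- character(0)
  for (cl in list(...)) {
    out <- c(out, vapply(taxa(cl), function(t) t@label, character(1)))
  }
  out
}

# Write a minimal Darwin Core Archive into a directory and return its path.
makeDwcaFixture <- function(dir = tempfile("dwca"), vernacular = TRUE) {
  dir.create(dir, showWarnings = FALSE)
  writeLines(c(
    '<archive xmlns="http://rs.tdwg.org/dwc/text/">',
    ' <core encoding="UTF-8" fieldsTerminatedBy="\\t" ignoreHeaderLines="1"',
    '       rowType="http://rs.tdwg.org/dwc/terms/Taxon">',
    '  <files><location>taxon.txt</location></files>',
    '  <id index="0"/>',
    '  <field index="0" term="http://rs.tdwg.org/dwc/terms/taxonID"/>',
    '  <field index="1" term="http://rs.tdwg.org/dwc/terms/scientificName"/>',
    '  <field index="2" term="http://rs.tdwg.org/dwc/terms/taxonRank"/>',
    '  <field index="3" term="http://rs.tdwg.org/dwc/terms/parentNameUsageID"/>',
    '  <field index="4" term="http://rs.tdwg.org/dwc/terms/acceptedNameUsageID"/>',
    '  <field index="5" term="http://rs.tdwg.org/dwc/terms/scientificNameAuthorship"/>',
    '  <field index="6" term="http://rs.tdwg.org/dwc/terms/taxonomicStatus"/>',
    ' </core>',
    if (vernacular) c(
      ' <extension encoding="UTF-8" fieldsTerminatedBy="\\t" ignoreHeaderLines="1"',
      '            rowType="http://rs.gbif.org/terms/1.0/VernacularName">',
      '  <files><location>vernacular.txt</location></files>',
      '  <coreid index="0"/>',
      '  <field index="1" term="http://rs.gbif.org/terms/1.0/vernacularName"/>',
      '  <field index="2" term="http://purl.org/dc/terms/language"/>',
      ' </extension>') else NULL,
    '</archive>'), file.path(dir, "meta.xml"))
  writeLines(c(
    paste("taxonID", "scientificName", "taxonRank", "parentNameUsageID",
          "acceptedNameUsageID", "scientificNameAuthorship",
          "taxonomicStatus", sep = "\t"),
    "g1\tAus\tgenus\t\t\tSmith, 1800\taccepted",
    "s1\tAus bus\tspecies\tg1\t\t(Smith, 1801)\taccepted",
    "s2\tAus cus\tspecies\tg1\ts1\tJones, 1805\tsynonym"),
    file.path(dir, "taxon.txt"))
  if (vernacular)
    writeLines(c("taxonID\tvernacularName\tlanguage", "s1\tkirva\tfi"),
               file.path(dir, "vernacular.txt"))
  dir
}
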