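test_that("the beetle revision yields two transfers and one status change", {
  a <- exampleChecklist("beetles_1992")
  b <- exampleChecklist("beetles_2011")
  ev <- diffChecklists(a, b)
  types <- sort(vapply(ev, function(e) e@changeType, character(1)))
  expect_identical(types, c("genus_transfer", "genus_transfer",
                            "status_change"))
  labelOf <- labelLookup(a, b)
  transferred <- sort(unlist(lapply(ev, function(e)
    if (e@changeType == "genus_transfer") labelOf[e@beforeUris])))
  expect_identical(unname(transferred), c("pubescens", "revestita"))
  statusChanged <- unlist(lapply(ev, function(e)
    if (e@changeType == "status_change") labelOf[e@beforeUris]))
  expect_identical(unname(statusChanged), "Pedostrangalia")
  # aethiops and Leptura produce no event; events carry the newer year
  expect_true(all(vapply(ev, function(e) e@when, character(1)) == "2011"))
  # transfers link the old and new concept congruently
  tr <- Filter(function(e) e@changeType == "genus_transfer", ev)[[1]]
  expect_identical(tr@relations[[1]]@relation, "congruent")
})

test_that("the dynamic synonymisation is one lump with part_of links", {
  t0 <- exampleChecklist("aus_t0")
  t1 <- exampleChecklist("aus_t1")
  expect_length(taxa(t0), 3L)
  ev <- diffChecklists(t0, t1)
  expect_length(ev, 1L)
  e <- ev[[1]]
  expect_identical(e@changeType, "lump")
  labelOf <- labelLookup(t0, t1)
  expect_setequal(unname(labelOf[e@beforeUris]), c("bus", "cus"))
  expect_identical(unname(labelOf[e@afterUris]), "bus")
  expect_true(all(vapply(e@relations, function(m) m@relation,
                         character(1)) == "part_of"))
  expect_true(all(vapply(e@relations, function(m) m@targetUri,
                         character(1)) == e@afterUris))
  # dynamic lists date the event by the status time stamp
  expect_identical(e@when, "2013-06-01")
})

test_that("identical checklists produce no events", {
  a <- exampleChecklist("beetles_1992")
  a2 <- exampleChecklist("beetles_1992", seed = 777)
  expect_length(diffChecklists(a, a2), 0L)
})

test_that("additions, removals and promotions classify correctly", {
  old <- tinyChecklist("v1", 2000, withSynonym = TRUE)
  u <- function(x) sprintf("http://example.org/onto/%s/%s", "v2", x)
  ts <- taxa(old)
  # revision: dus promoted to valid (split of bus), cus removed, eus added
  taxa2 <- list(
    TaxonRecord(u("g1"), "v2", "genus", "Aus",
                authorship = Authorship("Smith", 1800)),
    TaxonRecord(u("s1"), "v2", "species", "bus", parentUri = u("g1"),
                authorship = Authorship("Smith", 1801)),
    TaxonRecord(u("s3"), "v2", "species", "dus", parentUri = u("g1"),
                authorship = Authorship("Jones", 1810)),
    TaxonRecord(u("s4"), "v2", "species", "eus", parentUri = u("g1"),
                authorship = Authorship("Brown", 1900)))
  newer <- Checklist(ChecklistMeta("v2", yearPublished = 2005,
                                   code = "ICZN"), taxa2)
  ev <- diffChecklists(old, newer)
  types <- sort(vapply(ev, function(e) e@changeType, character(1)))
  expect_identical(types, c("addition", "removal", "split"))
  sp <- Filter(function(e) e@changeType == "split", ev)[[1]]
  labelOf <- labelLookup(old, newer)
  expect_identical(unname(labelOf[sp@beforeUris]), "bus")
  expect_setequal(unname(labelOf[sp@afterUris]), c("bus", "dus"))
  # the divided concept: each new concept is part of the old one
  expect_true(all(vapply(sp@relations, function(m) m@targetUri,
                         character(1)) == sp@beforeUris))
})

test_that("ambiguous keys are withheld and reported", {
  id <- "amb1"
  u <- function(x) paste0("http://x/", id, "/", x)
  g <- TaxonRecord(u("g"), id, "genus", "Aus")
  s1 <- TaxonRecord(u("s1"), id, "species", "bus", parentUri = u("g"))
  old <- Checklist(ChecklistMeta(id, yearPublished = 2000), list(g, s1))
  id2 <- "amb2"
  v <- function(x) paste0("http://x/", id2, "/", x)
  g2 <- TaxonRecord(v("g"), id2, "genus", "Aus")
  t1 <- TaxonRecord(v("t1"), id2, "species", "bus", parentUri = v("g"))
  t2 <- TaxonRecord(v("t2"), id2, "subspecies", "bus", parentUri = v("t1"))
  newer <- Checklist(ChecklistMeta(id2, yearPublished = 2001),
                     list(g2, t1, t2))
  expect_warning(ev <- diffChecklists(old, newer), "ambiguous")
  expect_length(ev, 0L)
  expect_true(length(attr(ev, "ambiguous")) == 1L)
})

test_that("lumps that override nomenclatural priority warn", {
  old <- tinyChecklist("p1", 2000)           # bus 1801, cus 1805
  u <- function(x) sprintf("http://example.org/onto/%s/%s", "p2", x)
  taxa2 <- list(
    TaxonRecord(u("g1"), "p2", "genus", "Aus",
                authorship = Authorship("Smith", 1800)),
    ## the *younger* name cus survives; bus becomes its synonym
    TaxonRecord(u("s1"), "p2", "species", "bus", parentUri = u("g1"),
                status = StatusAssignment("synonym"),
                authorship = Authorship("Smith", 1801),
                acceptedUri = u("s2")),
    TaxonRecord(u("s2"), "p2", "species", "cus", parentUri = u("g1"),
                authorship = Authorship("Jones", 1805)))
  newer <- Checklist(ChecklistMeta("p2", yearPublished = 2005,
                                   code = "ICZN"), taxa2)
  expect_warning(ev <- diffChecklists(old, newer), "priority")
  expect_identical(vapply(ev, function(e) e@changeType, character(1)),
                   "lump")
})

test_that("applying a lump duplicates the species and their genus only", {
  t0 <- exampleChecklist("aus_t0")
  species <- names(Filter(function(t) t@rank == "species", taxa(t0)))
  bus <- names(Filter(function(t) t@label == "bus", taxa(t0)))
  ev <- ChangeEvent("http://example.org/onto/changes/e1", "lump",
                    beforeUris = species, afterUris = bus,
                    when = "2013-06-01")
  res <- applyChange(t0, ev, uriMinter(seed = 3))
  expect_length(res$minted, 3L)  # bus', cus' and the genus Aus'
  upd <- taxa(res$checklist)
  expect_length(upd, 6L)         # old records retained
  newCus <- upd[[unname(res$minted[setdiff(species, bus)])]]
  expect_identical(newCus@status@opinion, "synonym")
  expect_identical(newCus@acceptedUri, unname(res$minted[bus]))
  expect_identical(newCus@status@timestamp, "2013-06-01")
  # the new species hang from the duplicated genus
  newBus <- upd[[unname(res$minted[bus])]]
  aus <- names(Filter(function(t) t@rank == "genus", taxa(t0)))
  expect_identical(newBus@parentUri, unname(res$minted[aus]))
  # nothing above the genus was touched, old URIs persist
  expect_true(all(names(taxa(t0)) %in% names(upd)))
})

test_that("a species status change duplicates the species and its genus", {
  t0 <- exampleChecklist("aus_t0")
  bus <- names(Filter(function(t) t@label == "bus", taxa(t0)))
  ev <- ChangeEvent("http://example.org/onto/changes/e2", "status_change",
                    beforeUris = bus, afterUris = bus, when = "2014-01-01")
  res <- applyChange(t0, ev, uriMinter(seed = 4))
  expect_length(res$minted, 2L)
  # an event touching nothing is a no-op
  ev0 <- ChangeEvent("http://example.org/onto/changes/e3", "status_change",
                     when = "2014-01-01")
  res0 <- applyChange(t0, ev0, uriMinter(seed = 5))
  expect_identical(taxonUris(res0$checklist), taxonUris(t0))
  # unknown URIs are an error
  evBad <- ChangeEvent("http://example.org/onto/changes/e4", "status_change",
                       beforeUris = "http://nowhere/x", when = "2014")
  expect_error(applyChange(t0, evBad, uriMinter(seed = 6)),
               "not in checklist")
  # static checklists refuse
  expect_error(applyChange(exampleChecklist("beetles_1992"), ev,
                           uriMinter(seed = 7)), "dynamic")
})

test_that("timelines order concept versions in time", {
  a <- exampleChecklist("beetles_1992")
  b <- exampleChecklist("beetles_2011")
  ev <- diffChecklists(a, b)
  corpus <- Corpus(list(a, b), events = ev)
  pub92 <- names(Filter(function(t) t@label == "pubescens", taxa(a)))
  tl <- temporalOrder(corpus, pub92)
  expect_identical(tl$when, c("1992", "2011"))
  expect_identical(tl$status, c("valid", "valid"))
  # taxon with no events: single-row timeline
  aeth <- names(Filter(function(t) t@label == "aethiops", taxa(a)))
  corpusNoEv <- Corpus(list(a, b))
  expect_identical(nrow(temporalOrder(corpusNoEv, aeth)), 1L)
  expect_error(temporalOrder(corpus, "http://nowhere/x"), "unknown")
})

test_that("after an applied lump the surviving name has a two-step timeline", {
  t0 <- exampleChecklist("aus_t0")
  species <- names(Filter(function(t) t@rank == "species", taxa(t0)))
  bus <- names(Filter(function(t) t@label == "bus", taxa(t0)))
  ev <- ChangeEvent("http://example.org/onto/changes/e1", "lump",
                    beforeUris = species, afterUris = bus,
                    when = "2013-06-01")
  res <- applyChange(t0, ev, uriMinter(seed = 8))
  corpus <- Corpus(list(res$checklist), events = list(res$event))
  tl <- temporalOrder(corpus, bus)
  expect_identical(tl$when, c("2012-01-01", "2013-06-01"))
  expect_identical(tl$uri, c(bus, unname(res$minted[bus])))
})

test_that("diff reports serialise as JSON lines", {
  a <- exampleChecklist("beetles_1992")
  b <- exampleChecklist("beetles_2011")
  ev <- diffChecklists(a, b)
  f <- tempfile(fileext = ".jsonl")
  writeDiffReport(ev, f)
  lines <- readLines(f)
  expect_length(lines, 3L)
  parsed <- lapply(lines, jsonlite::fromJSON)
  expect_setequal(vapply(parsed, `[[`, character(1), "type"),
                  c("genus_transfer", "status_change"))
})
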