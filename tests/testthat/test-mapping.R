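test_that("species sharing name and authorship map congruent across lists", {
  a <- exampleChecklist("beetles_1992")
  b <- exampleChecklist("beetles_2011")
  maps <- mapSpecies(a, b)
  expect_length(maps, 3L)
  expect_true(all(vapply(maps, function(m) m@relation, character(1)) ==
                    "congruent"))
  expect_true(all(vapply(maps, function(m) m@mode, character(1)) ==
                    "ostensive"))
  expect_true(all(vapply(maps, function(m) m@provenance, character(1)) ==
                    "automatic"))
  # the key ignores the genus: pubescens matched despite the transfer
  labs <- vapply(maps, function(m) {
    taxa(a)[[m@sourceUri]]@label
  }, character(1))
  expect_setequal(labs, c("pubescens", "revestita", "aethiops"))
})

test_that("disjoint checklists and self-mapping yield nothing", {
  a <- checklistFromSets("da", 2000, list(Aus = c("bus")))
  b <- checklistFromSets("db", 2001, list(Xus = c("yus")))
  expect_length(mapSpecies(a, b), 0L)
  expect_length(mapSpecies(a, a), 0L)
})

test_that("homonymous keys yield associated suggestions, not congruences", {
  id <- "hom"
  u <- function(x) paste0("http://x/", id, "/", x)
  g <- TaxonRecord(u("g"), id, "genus", "Aus")
  s1 <- TaxonRecord(u("s1"), id, "species", "bus", parentUri = u("g"),
                    authorship = Authorship("Smith", 1800))
  cl1 <- Checklist(ChecklistMeta(id, yearPublished = 2000), list(g, s1))
  id2 <- "hom2"
  v <- function(x) paste0("http://x/", id2, "/", x)
  g2 <- TaxonRecord(v("g"), id2, "genus", "Aus")
  t1 <- TaxonRecord(v("t1"), id2, "species", "bus", parentUri = v("g"),
                    authorship = Authorship("Smith", 1800))
  t2 <- TaxonRecord(v("t2"), id2, "subspecies", "bus", parentUri = v("t1"),
                    authorship = Authorship("Smith", 1800))
  cl2 <- Checklist(ChecklistMeta(id2, yearPublished = 2001),
                   list(g2, t1, t2))
  maps <- mapSpecies(cl1, cl2)
  expect_true(length(maps) == 2L)
  expect_true(all(vapply(maps, function(m) m@relation, character(1)) ==
                    "associated"))
  expect_true(all(vapply(maps, function(m) m@mode, character(1)) == "n/a"))
})

test_that("higher taxa align by species content", {
  # identical content -> congruent
  a <- checklistFromSets("ha", 2000, list(Arhopalus = c("ferus", "rusticus")))
  b <- checklistFromSets("hb", 2001, list(Arhopalus = c("ferus", "rusticus")))
  maps <- alignHigherTaxa(a, b, mapSpecies(a, b))
  expect_length(maps, 1L)
  expect_identical(maps[[1]]@relation, "congruent")

  # proper containment -> part_of with the right direction
  b2 <- checklistFromSets("hc", 2001,
                          list(Arhopalus = c("ferus", "rusticus", "novus")))
  maps <- alignHigherTaxa(a, b2, mapSpecies(a, b2))
  expect_length(maps, 1L)
  expect_identical(maps[[1]]@relation, "part_of")
  expect_identical(maps[[1]]@sourceUri, names(Filter(function(t)
    t@rank == "genus", taxa(a)))[1])

  # disjoint -> no mapping at all
  b3 <- checklistFromSets("hd", 2001, list(Arhopalus = c("alius")))
  expect_length(alignHigherTaxa(a, b3, mapSpecies(a, b3)), 0L)

  # partial intersection -> overlaps
  b4 <- checklistFromSets("he", 2001, list(Arhopalus = c("ferus", "alius")))
  maps <- alignHigherTaxa(a, b4, mapSpecies(a, b4))
  expect_length(maps, 1L)
  expect_identical(maps[[1]]@relation, "overlaps")
})

test_that("one private species demotes a congruent genus pair to part_of", {
  a <- checklistFromSets("ra", 2000, list(Aus = c("bus", "cus")))
  b <- checklistFromSets("rb", 2001, list(Aus = c("bus", "cus")))
  expect_identical(alignHigherTaxa(a, b, mapSpecies(a, b))[[1]]@relation,
                   "congruent")
  bPlus <- checklistFromSets("rc", 2001, list(Aus = c("bus", "cus", "dus")))
  maps <- alignHigherTaxa(a, bPlus, mapSpecies(a, bPlus))
  expect_identical(maps[[1]]@relation, "part_of")
})

test_that("higher-taxon alignment matches a set-comparison oracle", {
  set.seed(21)
  epithets <- paste0("sp", 1:9)
  for (trial in 1:40) {
    sa <- sample(epithets, sample(1:6, 1))
    sb <- sample(epithets, sample(1:6, 1))
    a <- checklistFromSets(paste0("oa", trial), 2000, list(Gus = sa))
    b <- checklistFromSets(paste0("ob", trial), 2001, list(Gus = sb))
    maps <- alignHigherTaxa(a, b, mapSpecies(a, b))
    common <- intersect(sa, sb)
    expected <- if (!length(common)) character(0)
      else if (setequal(sa, sb)) "congruent"
      else if (all(sa %in% sb)) "part_of"
      else if (all(sb %in% sa)) "part_of"
      else "overlaps"
    got <- vapply(maps, function(m) m@relation, character(1))
    expect_identical(got, expected)
    if (identical(expected, "part_of")) {
      smaller <- if (all(sa %in% sb)) "oa" else "ob"
      expect_match(maps[[1]]@sourceUri, smaller)
    }
  }
})

test_that("alignment depends only on species-set structure, not URIs", {
  a <- checklistFromSets("ua", 2000, list(Aus = c("bus", "cus")))
  b <- checklistFromSets("ub", 2001, list(Aus = c("bus", "cus", "dus")))
  relocate <- function(cl, newId) {
    taxa2 <- lapply(unname(taxa(cl)), function(t) {
      t@uri <- sub("http://x?[^/]*//[^/]+/", sprintf("http://elsewhere/%s/",
                                                     newId), t@uri)
      t@uri <- gsub("example.org/onto", paste0("other/", newId), t@uri)
      if (!is.na(t@parentUri))
        t@parentUri <- gsub("example.org/onto", paste0("other/", newId),
                            t@parentUri)
      t
    })
    Checklist(cl@meta, taxa2)
  }
  m1 <- alignHigherTaxa(a, b, mapSpecies(a, b))
  a2 <- relocate(a, "zz")
  m2 <- alignHigherTaxa(a2, b, mapSpecies(a2, b))
  expect_identical(vapply(m1, function(m) m@relation, character(1)),
                   vapply(m2, function(m) m@relation, character(1)))
})

test_that("general taxa partition the corpus by name key", {
  cls <- lapply(1:3, function(i)
    checklistFromSets(paste0("g", i), 2000 + i, list(Aus = c("bus", "cus"))))
  corpus <- Corpus(cls)
  gen <- autoMapGeneral(corpus)
  allMembers <- unlist(lapply(gen, function(g) g@memberUris))
  expect_false(anyDuplicated(allMembers) > 0)           # disjoint
  expect_setequal(allMembers, taxonUris(corpus))        # covering
  sizes <- vapply(gen, function(g) length(g@memberUris), integer(1))
  expect_setequal(sizes, 3L)  # every name occurs in all three lists
})

test_that("homonymous authorships split general taxa", {
  id1 <- "ga"; id2 <- "gb"
  mk <- function(id, author) {
    u <- paste0("http://x/", id, "/s1")
    Checklist(ChecklistMeta(id, yearPublished = 2000),
              list(TaxonRecord(paste0("http://x/", id, "/g"), id, "genus",
                               "Aus"),
                   TaxonRecord(u, id, "species", "bus",
                               parentUri = paste0("http://x/", id, "/g"),
                               authorship = Authorship(author, 1800))))
  }
  corpus <- Corpus(list(mk(id1, "Smith"), mk(id2, "Jones")))
  gen <- autoMapGeneral(corpus)
  # genus key shared, species keys differ by author -> 1 + 2 groups
  expect_length(gen, 3L)
})

test_that("relation closure follows the algebra on directed examples", {
  cm <- function(s, r, t) ConceptMapping(paste0("http://x/", s),
                                         paste0("http://x/", t), r,
                                         if (r == "associated") "n/a"
                                         else "ostensive")
  # congruent chains close transitively and symmetrically
  closed <- closeMappings(list(cm("A", "congruent", "B"),
                               cm("B", "congruent", "C")))
  trip <- relationTriples(closed)
  expect_true("http://x/A congruent http://x/C" %in% trip)
  expect_true("http://x/C congruent http://x/A" %in% trip)
  # part_of chains close transitively but not symmetrically
  closed <- closeMappings(list(cm("A", "part_of", "B"),
                               cm("B", "part_of", "C")))
  trip <- relationTriples(closed)
  expect_true("http://x/A part_of http://x/C" %in% trip)
  expect_false("http://x/C part_of http://x/A" %in% trip)
  # overlap is not transitive
  closed <- closeMappings(list(cm("A", "overlaps", "B"),
                               cm("B", "overlaps", "C")))
  trip <- relationTriples(closed)
  expect_false("http://x/A overlaps http://x/C" %in% trip)
  expect_true("http://x/B overlaps http://x/A" %in% trip)
  # congruence composes with containment
  closed <- closeMappings(list(cm("A", "congruent", "B"),
                               cm("B", "part_of", "C")))
  expect_true("http://x/A part_of http://x/C" %in% relationTriples(closed))
  # associated is inert
  closed <- closeMappings(list(cm("A", "associated", "B")))
  expect_identical(relationTriples(closed),
                   "http://x/A associated http://x/B")
})

test_that("closure equals the brute-force fixpoint oracle on random graphs", {
  set.seed(99)
  for (trial in 1:60) {
    n <- sample(2:8, 1)
    nodes <- paste0("http://x/n", seq_len(n))
    k <- sample(1:10, 1)
    maps <- lapply(seq_len(k), function(i) {
      st <- sample(nodes, 2)
      r <- sample(c("congruent", "part_of", "overlaps"), 1)
      ConceptMapping(st[1], st[2], r, "ostensive")
    })
    got <- relationTriples(closeMappings(maps))
    expect_identical(got, closureOracle(maps, nodes))
  }
})

test_that("contradictory assertions are detected after closure", {
  cm <- function(s, r, t) ConceptMapping(paste0("http://x/", s),
                                         paste0("http://x/", t), r,
                                         "ostensive")
  expect_identical(
    validateMappings(list(cm("A", "congruent", "B"),
                          cm("A", "part_of", "B")))$conflict,
    "congruent+part_of")
  res <- validateMappings(list(cm("A", "part_of", "B"),
                               cm("B", "part_of", "A")))
  expect_true("part_of both directions" %in% res$conflict)
  res <- validateMappings(list(cm("A", "congruent", "B"),
                               cm("A", "overlaps", "B")))
  expect_true("congruent+overlaps" %in% res$conflict)
  # a consistent closure of the worked example is clean
  a <- exampleChecklist("beetles_1992")
  b <- exampleChecklist("beetles_2011")
  sp <- mapSpecies(a, b)
  hi <- alignHigherTaxa(a, b, sp)
  expect_identical(nrow(validateMappings(c(sp, hi))), 0L)
})

test_that("mappings round-trip through the TSV exchange format", {
  a <- exampleChecklist("beetles_1992")
  b <- exampleChecklist("beetles_2011")
  maps <- c(mapSpecies(a, b), alignHigherTaxa(a, b, mapSpecies(a, b)))
  f <- tempfile(fileext = ".tsv")
  writeMappingsTsv(maps, f)
  back <- readMappingsTsv(f)
  expect_identical(relationTriples(back), relationTriples(maps))
  expect_identical(vapply(back, function(m) m@mode, character(1)),
                   vapply(maps, function(m) m@mode, character(1)))
})
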