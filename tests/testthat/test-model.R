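test_that("a well-formed checklist validates cleanly", {
  cl <- tinyChecklist(withSynonym = TRUE)
  expect_s4_class(cl, "Checklist")
  expect_identical(nrow(validateChecklist(cl)), 0L)
})

test_that("hierarchy violations are reported as error issues", {
  id <- "broken"
  u <- function(x) paste0("http://x/", id, "/", x)
  selfParent <- TaxonRecord(u("a"), id, "genus", "Aus", parentUri = u("a"))
  issues <- validateChecklist(
    Checklist(ChecklistMeta(id, yearPublished = 2000), list(selfParent)))
  expect_identical(issues$rule, "hierarchy cycle")
  expect_identical(issues$severity, "error")

  orphanSpecies <- TaxonRecord(u("b"), id, "species", "bus")
  issues <- validateChecklist(
    Checklist(ChecklistMeta(id, yearPublished = 2000), list(orphanSpecies)))
  expect_true("no genus ancestor" %in% issues$rule)

  dangling <- TaxonRecord(u("c"), id, "species", "cus",
                          parentUri = u("nowhere"))
  issues <- validateChecklist(
    Checklist(ChecklistMeta(id, yearPublished = 2000), list(dangling)))
  expect_true("dangling parent" %in% issues$rule)
})

test_that("synonym wiring is enforced", {
  id <- "syn"
  u <- function(x) paste0("http://x/", id, "/", x)
  g <- TaxonRecord(u("g"), id, "genus", "Aus")
  # synonym without an accepted target
  s <- TaxonRecord(u("s"), id, "species", "bus", parentUri = u("g"),
                   status = StatusAssignment("synonym"))
  issues <- validateChecklist(
    Checklist(ChecklistMeta(id, yearPublished = 2000), list(g, s)))
  expect_true("synonym without accepted target" %in% issues$rule)

  # accepted target that is itself a synonym
  s1 <- TaxonRecord(u("s1"), id, "species", "bus", parentUri = u("g"),
                    status = StatusAssignment("synonym"),
                    acceptedUri = u("s2"))
  s2 <- TaxonRecord(u("s2"), id, "species", "cus", parentUri = u("g"),
                    status = StatusAssignment("synonym"),
                    acceptedUri = u("s1"))
  issues <- validateChecklist(
    Checklist(ChecklistMeta(id, yearPublished = 2000), list(g, s1, s2)))
  expect_true("accepted target not valid" %in% issues$rule)

  # accepted link on a valid record
  v <- TaxonRecord(u("v"), id, "species", "dus", parentUri = u("g"),
                   acceptedUri = u("s1"))
  issues <- validateChecklist(
    Checklist(ChecklistMeta(id, yearPublished = 2000), list(g, s1, s2, v)))
  expect_true("accepted target on valid record" %in% issues$rule)
})

test_that("dynamic checklists require status time stamps", {
  cl <- tinyChecklist(listType = "dynamic")
  expect_identical(nrow(validateChecklist(cl)), 0L)
  bare <- TaxonRecord("http://x/tiny/extra", "tiny", "genus", "Xus")
  cl2 <- Checklist(cl@meta, c(unname(taxa(cl)), bare))
  issues <- validateChecklist(cl2)
  expect_true("missing status timestamp" %in% issues$rule)
})

test_that("homonymous labels and rank inversions warn but do not error", {
  id <- "warns"
  u <- function(x) paste0("http://x/", id, "/", x)
  g <- TaxonRecord(u("g"), id, "genus", "Aus")
  a <- TaxonRecord(u("a"), id, "species", "bus", parentUri = u("g"),
                   authorship = Authorship("Smith", 1800))
  b <- TaxonRecord(u("b"), id, "species", "bus", parentUri = u("g"),
                   authorship = Authorship("Jones", 1900))
  # a genus placed under a species: rank inversion
  inv <- TaxonRecord(u("inv"), id, "genus", "Cus", parentUri = u("a"))
  issues <- validateChecklist(
    Checklist(ChecklistMeta(id, yearPublished = 2000),
              list(g, a, b, inv)))
  expect_true(all(c("homonymous label", "rank inversion") %in% issues$rule))
  expect_true(all(issues$severity[issues$rule %in%
    c("homonymous label", "rank inversion")] == "warning"))
})

test_that("validation is order-independent and idempotent", {
  cl <- tinyChecklist(withSynonym = TRUE)
  broken <- unname(taxa(cl))
  broken[[4]]@acceptedUri <- NA_character_  # synonym loses its target
  meta <- meta(cl)
  i1 <- validateChecklist(Checklist(meta, broken))
  for (perm in list(c(4, 2, 3, 1), c(2, 4, 1, 3))) {
    i2 <- validateChecklist(Checklist(meta, broken[perm]))
    expect_identical(i1[order(i1$uri, i1$rule), c("uri", "rule")],
                     i2[order(i2$uri, i2$rule), c("uri", "rule")])
  }
  expect_identical(i1, validateChecklist(Checklist(meta, broken)))
})
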