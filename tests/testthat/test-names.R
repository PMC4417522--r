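test_that("author canonicalisation resolves attested abbreviations", {
  expect_identical(canonicalizeAuthor("L."), "Linnaeus")
  expect_identical(canonicalizeAuthor("Linn."), "Linnaeus")
  expect_identical(canonicalizeAuthor("Fabr."), "Fabricius")
  # case- and trailing-period-insensitive
  expect_identical(canonicalizeAuthor("l"), "Linnaeus")
  expect_identical(canonicalizeAuthor("FABR."), "Fabricius")
  # unknown inputs pass through trimmed
  expect_identical(canonicalizeAuthor("  Mulsant "), "Mulsant")
  # user-extensible table
  tab <- c(authorAbbreviations(), stats::setNames("Poda", "pod"))
  expect_identical(canonicalizeAuthor("Pod.", table = tab), "Poda")
})

test_that("complete names are assembled by hierarchy traversal", {
  ar <- exampleChecklist("arhopalus")
  ferus <- Filter(function(t) t@rank == "species", taxa(ar))[[1]]
  expect_identical(assembleCompleteName(ferus, ar),
                   "Arhopalus ferus (Mulsant, 1839)")

  ba <- exampleChecklist("bassia")
  scoparia <- Filter(function(t) t@rank == "species", taxa(ba))[[1]]
  expect_identical(assembleCompleteName(scoparia, ba),
                   "Bassia scoparia (L.) A.J. Scot")

  b92 <- exampleChecklist("beetles_1992")
  leptura <- Filter(function(t) t@label == "Leptura", taxa(b92))[[1]]
  expect_identical(assembleCompleteName(leptura, b92),
                   "Leptura Linnaeus, 1758")
})

test_that("multiple zoological authors are joined with ampersands", {
  cl <- tinyChecklist()
  sp <- taxa(cl)[[2]]
  sp@authorship <- Authorship(c("Smith", "Jones"), 1900,
                              parenthesized = FALSE)
  expect_identical(assembleCompleteName(sp, cl), "Aus bus Smith & Jones, 1900")
  sp@authorship@parenthesized <- TRUE
  expect_identical(assembleCompleteName(sp, cl),
                   "Aus bus (Smith & Jones, 1900)")
})

test_that("trinominal names append the subspecies epithet", {
  id <- "tri"
  u <- function(x) paste0("http://x/", id, "/", x)
  g <- TaxonRecord(u("g"), id, "genus", "Aus")
  s <- TaxonRecord(u("s"), id, "species", "bus", parentUri = u("g"))
  ss <- TaxonRecord(u("ss"), id, "subspecies", "cus", parentUri = u("s"),
                    authorship = Authorship("Smith", 1900))
  cl <- Checklist(ChecklistMeta(id, yearPublished = 2000, code = "ICZN"),
                  list(g, s, ss))
  expect_identical(assembleCompleteName(ss, cl), "Aus bus cus Smith, 1900")
})

test_that("a broken parent link is a named error", {
  id <- "err"
  u <- function(x) paste0("http://x/", id, "/", x)
  s <- TaxonRecord(u("s"), id, "species", "bus", parentUri = u("gone"))
  cl <- Checklist(ChecklistMeta(id, yearPublished = 2000), list(s))
  expect_error(assembleCompleteName(s, cl), "gone")
})

test_that("moving a species between genera changes only the genus part", {
  a <- exampleChecklist("beetles_1992")
  b <- exampleChecklist("beetles_2011")
  pub92 <- Filter(function(t) t@label == "pubescens", taxa(a))[[1]]
  pub11 <- Filter(function(t) t@label == "pubescens", taxa(b))[[1]]
  n92 <- assembleCompleteName(pub92, a)
  n11 <- assembleCompleteName(pub11, b)
  expect_match(n92, "^Leptura pubescens")
  expect_match(n11, "^Pedostrangalia pubescens")
})

test_that("name keys fold case and authorship variants, keep year strict", {
  id <- "keys"
  mk <- function(label, author, year) {
    makeNameKey(TaxonRecord(paste0("http://x/", label, author, year), id,
                            "species", label,
                            authorship = Authorship(author, year)))
  }
  expect_identical(nameKeyString(mk("ferus", "Mulsant", 1839)),
                   "ferus|Mulsant|1839")
  expect_identical(nameKeyString(mk("Pubescens", "Fabricius", 1787)),
                   nameKeyString(mk("pubescens", "Fabr.", 1787)))
  expect_false(identical(nameKeyString(mk("aethiops", "Poda", 1761)),
                         nameKeyString(mk("aethiops", "Poda", 1767))))
})
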