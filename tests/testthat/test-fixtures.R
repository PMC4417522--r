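test_that("generated checklists are valid, seeded and sized as requested", {
  cl <- generateChecklist(5, c(3, 6), 0.1, seed = 42)
  expect_identical(nrow(validateChecklist(cl)), 0L)
  ranks <- vapply(taxa(cl), function(t) t@rank, character(1))
  expect_identical(sum(ranks == "genus"), 5L)
  nSp <- sum(ranks == "species")
  expect_true(nSp >= 15 && nSp <= 30)
  # same seed, same checklist; different seed, different checklist
  cl2 <- generateChecklist(5, c(3, 6), 0.1, seed = 42)
  expect_identical(taxonUris(cl), taxonUris(cl2))
  expect_identical(vapply(taxa(cl), function(t) t@label, character(1)),
                   vapply(taxa(cl2), function(t) t@label, character(1)))
  cl3 <- generateChecklist(5, c(3, 6), 0.1, seed = 43)
  expect_false(identical(taxonUris(cl), taxonUris(cl3)))
})

test_that("the synonym rate is honoured at its extremes", {
  cl0 <- generateChecklist(4, c(3, 5), 0, seed = 1)
  ops <- vapply(taxa(cl0), function(t) t@status@opinion, character(1))
  expect_true(all(ops == "valid"))
  cl <- generateChecklist(10, c(4, 8), 0.3, seed = 2)
  ops <- vapply(Filter(function(t) t@rank == "species", taxa(cl)),
                function(t) t@status@opinion, character(1))
  frac <- mean(ops == "synonym")
  expect_gt(frac, 0.1)
  expect_lt(frac, 0.5)
  # name keys unique by construction
  keys <- vapply(taxa(cl), function(t) nameKeyString(makeNameKey(t)),
                 character(1))
  expect_false(anyDuplicated(keys) > 0)
})

test_that("mutation applies the requested changes and stays valid", {
  cl <- generateChecklist(5, c(3, 6), 0.2, seed = 5)
  res <- mutateChecklist(cl, RevisionSpec(2, 1, 1, 2, 1, seed = 99))
  expect_identical(nrow(validateChecklist(res$checklist)), 0L)
  types <- table(vapply(res$truth, function(e) e@changeType, character(1)))
  expect_identical(types[["genus_transfer"]], 2L)
  expect_identical(types[["lump"]], 1L)
  expect_identical(types[["split"]], 1L)
  expect_identical(types[["addition"]], 2L)
  expect_identical(types[["removal"]], 1L)
  # synthesised lumps respect priority: the surviving name is the older
  lump <- Filter(function(e) e@changeType == "lump", res$truth)[[1]]
  labelOf <- labelLookup(cl, res$checklist)
  survivorLabel <- unname(labelOf[lump@afterUris])
  yearOf <- function(lab) {
    t <- Filter(function(x) identical(x@label, lab), taxa(cl))[[1]]
    t@authorship@year
  }
  beforeLabels <- unname(labelOf[lump@beforeUris])
  expect_identical(yearOf(survivorLabel),
                   min(vapply(beforeLabels, yearOf, integer(1))))
})

test_that("an infeasible revision spec names the shortfall", {
  cl <- generateChecklist(1, c(2, 3), 0, seed = 7)
  expect_error(mutateChecklist(cl, RevisionSpec(nTransfers = 1, seed = 1)),
               "two genera")
  expect_error(mutateChecklist(cl, RevisionSpec(nSplits = 1, seed = 1)),
               "splits")
})

test_that("the diff recovers injected events exactly across seeds", {
  hits <- 0L
  trials <- 15L
  for (s in seq_len(trials)) {
    cl <- generateChecklist(5, c(3, 6), 0.15, seed = s, checklistId = "syn")
    res <- mutateChecklist(cl, RevisionSpec(2, 1, 1, 2, 1, seed = s + 500))
    labelOf <- labelLookup(cl, res$checklist)
    detected <- suppressWarnings(diffChecklists(cl, res$checklist))
    if (identical(eventSignatures(detected, labelOf),
                  eventSignatures(res$truth, labelOf)))
      hits <- hits + 1L
  }
  expect_identical(hits, trials)
})
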