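test_that("minted URIs follow the scheme and never repeat", {
  m <- uriMinter(seed = 42)
  u1 <- mintUri(m, "cerambycids")
  u2 <- mintUri(m, "cerambycids")
  expect_match(u1, "^http://example\\.org/onto/cerambycids/p[0-9]+$")
  expect_false(identical(u1, u2))
  many <- replicate(500, mintUri(m, "cerambycids"))
  expect_false(anyDuplicated(c(u1, u2, many)) > 0)
})

test_that("minting is reproducible from the seed", {
  seq1 <- { m <- uriMinter(seed = 7); replicate(10, mintUri(m, "x")) }
  seq2 <- { m <- uriMinter(seed = 7); replicate(10, mintUri(m, "x")) }
  seq3 <- { m <- uriMinter(seed = 8); replicate(10, mintUri(m, "x")) }
  expect_identical(seq1, seq2)
  expect_false(identical(seq1, seq3))
})

test_that("the minter does not disturb the caller's RNG stream", {
  set.seed(1)
  a <- stats::runif(1)
  set.seed(1)
  m <- uriMinter(seed = 99)
  invisible(mintUri(m, "x"))
  b <- stats::runif(1)
  expect_identical(a, b)
})

test_that("invalid checklist tokens are rejected when minting", {
  m <- uriMinter(seed = 1)
  expect_error(mintUri(m, "has/slash"), "invalid checklist id")
  expect_error(mintUri(m, ""), "invalid checklist id")
})

test_that("the printed Catalogue of Life LSID parses positionally", {
  txt <- paste0("urn:lsid:catalogueoflife.org:",
                "d782a602-29c1-102b-9a4a-00304854f820:col2012acv16")
  l <- parseLsid(txt)
  expect_identical(l@authority, "catalogueoflife.org")
  expect_identical(l@namespace, "d782a602-29c1-102b-9a4a-00304854f820")
  expect_identical(l@object, "col2012acv16")
  expect_true(is.na(l@revision))
  expect_identical(formatLsid(l), txt)
})

test_that("malformed LSIDs fail with a named defect", {
  expect_error(parseLsid("lsid:foo:bar:baz"), "missing urn prefix")
  expect_error(parseLsid("urn:lsid:only:two"), "authority:namespace:object")
  expect_error(parseLsid("urn:lsid:a:b:c:d:e"), "too many parts")
})

test_that("parse and format are mutual inverses on generated LSIDs", {
  set.seed(11)
  pool <- c(letters, LETTERS, 0:9, "-", "_", ".")
  rnd <- function() paste(sample(pool, sample(3:12, 1), replace = TRUE),
                          collapse = "")
  for (i in 1:50) {
    l <- LSID(rnd(), rnd(), rnd(),
              if (i %% 2 == 0) rnd() else NA_character_)
    expect_identical(parseLsid(formatLsid(l)), l)
  }
})
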