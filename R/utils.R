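#' Controlled vocabularies
#'
#' Ordered rank vocabulary (highest first) and the taxon status vocabulary
#' used throughout the package. The rank list is a pragmatic subset of the
#' TDWG rank hierarchy, extensible via the \code{rank_vocabulary} entry of a
#' corpus configuration.
#'
#' @return A character vector of rank names (for \code{rankVocabulary}) or
#'   status opinions (for \code{statusVocabulary}).
#' @export
rankVocabulary <- function() {
  c("kingdom", "phylum", "class", "order", "family", "subfamily",
    "tribe", "genus", "subgenus", "species", "subspecies")
}

#' @rdname rankVocabulary
#' @export
statusVocabulary <- function() {
  c("valid", "synonym", "homonym-rejected", "orthographic-variant",
    "undetermined")
}

## Opinions that require an accepted_uri pointing at the valid name
.nonvalidOpinions <- c("synonym", "homonym-rejected", "orthographic-variant")

## Species-group and genus-group ranks (zoological sense)
.speciesGroupRanks <- c("species", "subspecies")
.genusGroupRanks <- c("genus", "subgenus")

#' Is a rank species-group / genus-group?
#'
#' @param rank character rank name.
#' @return logical scalar.
#' @export
isSpeciesGroup <- function(rank) rank %in% .speciesGroupRanks

#' @rdname isSpeciesGroup
#' @export
isGenusGroup <- function(rank) rank %in% .genusGroupRanks

## Run code under a fixed seed without clobbering the caller's RNG stream.
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

## scalar helpers -----------------------------------------------------------

isScalarString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

## NA-safe scalar equality
sameScalar <- function(a, b) {
  if (is.na(a) && is.na(b)) return(TRUE)
  if (is.na(a) || is.na(b)) return(FALSE)
  a == b
}

## URI-safe token: letters, digits, and unreserved punctuation, no '/'
isUriSafeToken <- function(x) {
  isScalarString(x) && nzchar(x) && grepl("^[A-Za-z0-9._~-]+$", x)
}

## Last path segment of an HTTP URI
uriLocalName <- function(uri) sub("^.*/", "", uri)
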