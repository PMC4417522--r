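## HTTP URI minting and LSID parsing/formatting.
##
## Data URIs follow the scheme BASE/CHECKLIST_ID/LOCAL_ID where LOCAL_ID is
## "p" followed by a randomly generated number, unique within the corpus
## session. The generator is seeded so a run is reproducible; the seed is
## part of the corpus configuration.

#' Create a seeded URI minter
#'
#' The minter owns its own random stream (it never disturbs the caller's
#' RNG) and a registry of every URI it has issued, so local identifiers are
#' unique across the whole corpus session and the full sequence is
#' reproducible from the seed.
#'
#' @param base base URI, no trailing slash. The published scheme used a
#'   production namespace; the default here is deliberately a neutral
#'   example domain — set your own before publishing data.
#' @param seed integer seed.
#' @return A minter object (environment) for \code{\link{mintUri}}.
#' @examples
#' m <- uriMinter(seed = 1)
#' mintUri(m, "cerambycids")
#' @export
uriMinter <- function(base = "http://example.org/onto", seed = 1L) {
  m <- new.env(parent = emptyenv())
  m$base <- sub("/+$", "", base)
  m$seed <- as.integer(seed)
  m$used <- new.env(parent = emptyenv())
  m$state <- withSeed(seed, get(".Random.seed", envir = globalenv()))
  class(m) <- "UriMinter"
  m
}

## Draw from the minter's private RNG stream.
.minterDraw <- function(m, n = 1L, max = 999999999L) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  assign(".Random.seed", m$state, envir = genv)
  on.exit({
    m$state <- get(".Random.seed", envir = genv)
    if (had) assign(".Random.seed", old, envir = genv)
    else rm(".Random.seed", envir = genv)
  })
  sample.int(max, n)
}

#' Mint a new HTTP URI for a checklist resource
#'
#' Returns \code{BASE/checklistId/pNUMBER} with a randomly generated NUMBER
#' unique within the minter's session; deterministic given the minter's
#' seed. Collisions are retried a bounded number of times.
#'
#' @param minter a minter from \code{\link{uriMinter}}.
#' @param checklistId URI-safe checklist token (or a reserved segment such
#'   as \code{"changes"}).
#' @param retries maximum collision retries before failing.
#' @return A single URI string.
#' @export
mintUri <- function(minter, checklistId, retries = 100L) {
  if (!isUriSafeToken(checklistId))
    stop(sprintf("invalid checklist id '%s'", checklistId), call. = FALSE)
  for (i in seq_len(retries)) {
    uri <- sprintf("%s/%s/p%d", minter$base, checklistId,
                   .minterDraw(minter))
    if (is.null(minter$used[[uri]])) {
      minter$used[[uri]] <- TRUE
      return(uri)
    }
  }
  stop("URI minting exhausted: too many collisions", call. = FALSE)
}

## Register externally created URIs so the minter never reissues them.
registerUri <- function(minter, uris) {
  for (u in uris) minter$used[[u]] <- TRUE
  invisible(minter)
}

#' Parse a Life Science Identifier
#'
#' Splits the text after the fixed \code{urn:lsid:} head on \code{":"} into
#' authority, namespace, object and the optional revision. Parsing is
#' positional, not semantic: identifiers are parsed exactly as printed even
#' when a conventional namespace segment is absent.
#'
#' @param text an LSID string.
#' @return An \linkS4class{LSID}.
#' @examples
#' parseLsid(paste0("urn:lsid:catalogueoflife.org:",
#'                  "d782a602-29c1-102b-9a4a-00304854f820:col2012acv16"))
#' @export
parseLsid <- function(text) {
  stopifnot(isScalarString(text))
  if (!grepl("^urn:lsid:", text, ignore.case = TRUE))
    stop(sprintf("not an LSID: missing urn prefix in '%s'", text),
         call. = FALSE)
  rest <- sub("^urn:lsid:", "", text, ignore.case = TRUE)
  parts <- strsplit(rest, ":", fixed = TRUE)[[1]]
  if (length(parts) < 3L)
    stop(sprintf("not an LSID: expected authority:namespace:object in '%s'",
                 text), call. = FALSE)
  if (length(parts) > 4L)
    stop(sprintf("not an LSID: too many parts in '%s'", text), call. = FALSE)
  if (any(!nzchar(parts[1:3])))
    stop(sprintf("not an LSID: empty part in '%s'", text), call. = FALSE)
  LSID(parts[1], parts[2], parts[3],
       if (length(parts) == 4L) parts[4] else NA_character_)
}

#' Format a Life Science Identifier
#'
#' Canonical colon-joined serialisation with the \code{urn:lsid:} head; the
#' revision is appended only when present. \code{parseLsid} and
#' \code{formatLsid} are mutual inverses on valid input.
#'
#' @param lsid an \linkS4class{LSID}.
#' @return The LSID string.
#' @export
formatLsid <- function(lsid) {
  stopifnot(is(lsid, "LSID"))
  parts <- c("urn:lsid", lsid@authority, lsid@namespace, lsid@object)
  if (!is.na(lsid@revision)) parts <- c(parts, lsid@revision)
  paste(parts, collapse = ":")
}
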