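## Darwin Core Archive ingestion: the star-shaped archive's meta.xml
## descriptor is parsed for the taxon core (and optional vernacular-name
## extension), DwC terms are mapped onto taxon records, and the authorship
## text is parsed into structured form with the verbatim string preserved.

.dwcLocal <- function(term) sub("^.*[/#]", "", term)

## Parse one file block (<core> or <extension>) of meta.xml.
.dwcaReadTable <- function(node, dir) {
  loc <- xml2::xml_text(xml2::xml_find_first(node, ".//files/location"))
  sep <- xml2::xml_attr(node, "fieldsTerminatedBy")
  if (is.na(sep)) sep <- "\\t"
  sep <- switch(sep, "\\t" = "\t", "," = ",", sep)
  skip <- as.integer(xml2::xml_attr(node, "ignoreHeaderLines"))
  if (is.na(skip)) skip <- 0L
  df <- utils::read.table(file.path(dir, loc), sep = sep, header = skip > 0L,
                          quote = "\"", stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8",
                          na.strings = NULL, comment.char = "")
  fields <- xml2::xml_find_all(node, ".//field")
  idx <- as.integer(xml2::xml_attr(fields, "index")) + 1L
  terms <- .dwcLocal(xml2::xml_attr(fields, "term"))
  idNode <- xml2::xml_find_first(node, ".//id | .//coreid")
  out <- data.frame(row.names = seq_len(nrow(df)))
  if (!inherits(idNode, "xml_missing"))
    out$id <- df[[as.integer(xml2::xml_attr(idNode, "index")) + 1L]]
  for (i in seq_along(terms)) out[[terms[i]]] <- df[[idx[i]]]
  out
}

## Parse a zoological/botanical authorship string into an Authorship.
parseAuthorshipText <- function(text, code = "unspecified") {
  text <- trimws(text)
  if (!nzchar(text)) return(NULL)
  m <- regmatches(text, regexec("^\\((.+?),\\s*(\\d{4})\\)$", text))[[1]]
  if (length(m))
    return(Authorship(strsplit(m[2], " & ", fixed = TRUE)[[1]],
                      as.integer(m[3]), parenthesized = TRUE, raw = text))
  m <- regmatches(text, regexec("^(.+?),\\s*(\\d{4})$", text))[[1]]
  if (length(m))
    return(Authorship(strsplit(m[2], " & ", fixed = TRUE)[[1]],
                      as.integer(m[3]), raw = text))
  m <- regmatches(text, regexec("^\\((.+?)\\)\\s+(.+)$", text))[[1]]
  if (length(m))
    return(Authorship(strsplit(m[2], " & ", fixed = TRUE)[[1]],
                      parenthesized = TRUE,
                      combinationAuthors = strsplit(m[3], " & ",
                                                    fixed = TRUE)[[1]],
                      raw = text))
  Authorship(strsplit(text, " & ", fixed = TRUE)[[1]], raw = text)
}

.dwcStatusMap <- function(x) {
  x <- tolower(trimws(x))
  if (x %in% c("accepted", "valid")) "valid"
  else if (grepl("synonym", x)) "synonym"
  else if (grepl("misspell|orthograph", x)) "orthographic-variant"
  else "undetermined"
}

#' Read the taxon core of a Darwin Core Archive
#'
#' Parses the archive's \code{meta.xml} descriptor, loads the taxon core
#' file and maps the Darwin Core terms (\code{taxonID},
#' \code{scientificName}, \code{taxonRank}, \code{parentNameUsageID},
#' \code{acceptedNameUsageID}, \code{scientificNameAuthorship},
#' \code{taxonomicStatus}) onto taxon records; a vernacular-name extension,
#' when present, attaches common names. Authorship text is parsed into
#' structured form with the verbatim string kept in \code{raw}. For
#' species-group rows bearing a full \code{scientificName}, the label is the
#' last epithet (the uninomial convention of the model).
#'
#' @param path directory of an unpacked archive, or a \code{.zip} file.
#' @param meta optional \linkS4class{ChecklistMeta}; defaults to a static
#'   checklist named after the archive directory.
#' @param minter URI minter; created from \code{seed} when omitted.
#' @param seed seed for the default minter.
#' @return A \linkS4class{Checklist} with attribute \code{"issues"}; the
#'   original \code{taxonID}s are kept in \code{externalIds}.
#' @export
readDwcaCore <- function(path, meta = NULL, minter = NULL, seed = 1L) {
  if (grepl("\\.zip$", path)) {
    dir <- file.path(tempdir(), paste0("dwca-", basename(path)))
    utils::unzip(path, exdir = dir)
    path <- dir
  }
  metaFile <- file.path(path, "meta.xml")
  if (!file.exists(metaFile))
    stop(sprintf("no meta.xml descriptor under '%s'", path), call. = FALSE)
  doc <- xml2::xml_ns_strip(xml2::read_xml(metaFile))
  core <- xml2::xml_find_first(doc, ".//core")
  if (inherits(core, "xml_missing"))
    stop("archive descriptor has no core element", call. = FALSE)
  tab <- .dwcaReadTable(core, path)
  if (is.null(tab$taxonID)) tab$taxonID <- tab$id
  if (is.null(tab$taxonID))
    stop("taxon core has no taxonID", call. = FALSE)

  if (is.null(meta))
    meta <- ChecklistMeta(gsub("[^A-Za-z0-9._~-]", "-", basename(path)),
                          yearPublished = as.integer(format(Sys.Date(), "%Y")))
  if (is.null(minter)) minter <- uriMinter(seed = seed)

  ids <- tab$taxonID
  uris <- stats::setNames(vapply(ids, function(i)
    mintUri(minter, meta@checklistId), character(1)), ids)
  ref <- function(col) {
    if (is.null(tab[[col]])) return(rep(NA_character_, nrow(tab)))
    ifelse(nzchar(tab[[col]]) & tab[[col]] %in% ids,
           unname(uris[tab[[col]]]), NA_character_)
  }
  parentUris <- ref("parentNameUsageID")
  acceptedRaw <- ref("acceptedNameUsageID")

  col <- function(name) tab[[name]] %||% rep("", nrow(tab))
  ranks <- tolower(col("taxonRank"))
  sciNames <- col("scientificName")
  authTexts <- col("scientificNameAuthorship")
  statuses <- col("taxonomicStatus")

  taxaList <- lapply(seq_len(nrow(tab)), function(i) {
    rank <- if (nzchar(ranks[i])) ranks[i] else "species"
    ## uninomial label: last epithet for species-group names
    nameParts <- strsplit(trimws(sciNames[i]), "\\s+")[[1]]
    label <- if (isSpeciesGroup(rank) && length(nameParts) > 1L)
      nameParts[length(nameParts)] else sciNames[i]
    opinion <- .dwcStatusMap(statuses[i])
    ## self-referential acceptedNameUsageID (common DwC idiom) is no synonymy
    accepted <- acceptedRaw[i]
    if (!is.na(accepted) && identical(accepted, unname(uris[ids[i]])))
      accepted <- NA_character_
    if (opinion %in% .nonvalidOpinions && is.na(accepted))
      opinion <- "undetermined"
    if (!opinion %in% .nonvalidOpinions) accepted <- NA_character_
    TaxonRecord(
      uri = unname(uris[ids[i]]), checklistId = meta@checklistId,
      rank = rank, label = label, parentUri = parentUris[i],
      status = StatusAssignment(opinion),
      authorship = parseAuthorshipText(authTexts[i], meta@code),
      externalIds = ids[i], acceptedUri = accepted)
  })

  ## optional vernacular extension
  exts <- xml2::xml_find_all(doc, ".//extension")
  for (e in exts) {
    rt <- xml2::xml_attr(e, "rowType")
    if (is.na(rt) || !grepl("VernacularName", rt)) next
    vt <- .dwcaReadTable(e, path)
    if (is.null(vt$vernacularName)) next
    nameCol <- vt$vernacularName
    for (j in seq_len(nrow(vt))) {
      tid <- vt$id[j]
      k <- which(ids == tid)
      if (!length(k) || !nzchar(nameCol[j])) next
      lang <- (vt$language %||% rep("und", nrow(vt)))[j]
      taxaList[[k[1]]]@vernaculars <-
        c(taxaList[[k[1]]]@vernaculars,
          VernacularName(nameCol[j], if (nzchar(lang)) lang else "und"))
    }
  }

  cl <- Checklist(meta, taxaList)
  issues <- validateChecklist(cl)
  if (nrow(issues))
    warning(sprintf("archive '%s' loaded with %d validation issue(s)",
                    meta@checklistId, nrow(issues)), call. = FALSE)
  attr(cl, "issues") <- issues
  cl
}
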