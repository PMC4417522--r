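## Checklist CSV dialect: comma-separated, quoted fields, UTF-8, one header
## row; list-valued cells joined with '|'. Mandatory columns: taxon_id,
## rank, label, parent_id, status. Optional: accepted_id, authors, year,
## parenthesized, combination_authors, vernacular, language, external_ids,
## timestamp.

.csvRequired <- c("taxon_id", "rank", "label", "parent_id", "status")
.csvOptional <- c("accepted_id", "authors", "year", "parenthesized",
                  "combination_authors", "vernacular", "language",
                  "external_ids", "timestamp")

.splitCell <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0)
  else trimws(strsplit(x, "|", fixed = TRUE)[[1]])
}

#' Read a checklist from the CSV dialect
#'
#' Loads one checklist, minting an HTTP URI for every row and resolving the
#' file-local \code{taxon_id} references (\code{parent_id},
#' \code{accepted_id}) to those URIs. Dangling references or missing
#' mandatory columns abort with an error listing the offending row numbers.
#' The loaded checklist is validated; any issues are attached as the
#' \code{"issues"} attribute and surfaced as a warning.
#'
#' @param path CSV file path.
#' @param meta a \linkS4class{ChecklistMeta} describing the file.
#' @param minter URI minter; one is created from \code{seed} when omitted.
#' @param seed seed for the default minter.
#' @return A \linkS4class{Checklist} with attribute \code{"issues"}.
#' @examples
#' cl <- exampleChecklist("beetles_1992")
#' length(taxa(cl))  # 5
#' @export
readChecklistCsv <- function(path, meta, minter = NULL, seed = 1L) {
  if (is.null(minter)) minter <- uriMinter(seed = seed)
  df <- utils::read.csv(path, header = TRUE, colClasses = "character",
                        fileEncoding = "UTF-8", na.strings = NULL)
  missingCols <- setdiff(.csvRequired, names(df))
  if (length(missingCols))
    stop(sprintf("checklist CSV '%s' lacks mandatory column(s): %s", path,
                 paste(missingCols, collapse = ", ")), call. = FALSE)
  for (col in .csvOptional)
    if (!col %in% names(df)) df[[col]] <- character(nrow(df))
  if (!nrow(df)) {
    cl <- Checklist(meta, list())
    attr(cl, "issues") <- validateChecklist(cl)
    return(cl)
  }

  ids <- df$taxon_id
  uris <- vapply(ids, function(i) mintUri(minter, meta@checklistId),
                 character(1))
  names(uris) <- ids

  resolve <- function(col) {
    vals <- df[[col]]
    bad <- which(nzchar(vals) & !vals %in% ids)
    if (length(bad))
      stop(sprintf("checklist CSV '%s': dangling %s in row(s) %s", path,
                   col, paste(bad, collapse = ", ")), call. = FALSE)
    ifelse(nzchar(vals), unname(uris[vals]), NA_character_)
  }
  parentUris <- resolve("parent_id")
  acceptedUris <- resolve("accepted_id")

  taxaList <- lapply(seq_len(nrow(df)), function(i) {
    authors <- .splitCell(df$authors[i])
    comb <- .splitCell(df$combination_authors[i])
    year <- suppressWarnings(as.integer(df$year[i]))
    authorship <- if (length(authors) || !is.na(year) || length(comb))
      Authorship(authors, year,
                 parenthesized = tolower(df$parenthesized[i]) %in%
                   c("true", "t", "1", "yes"),
                 combinationAuthors = comb)
    else NULL
    verns <- list()
    vn <- .splitCell(df$vernacular[i])
    vl <- .splitCell(df$language[i])
    if (length(vn) && length(vn) == length(vl))
      verns <- Map(VernacularName, vn, vl)
    ts <- if (nzchar(df$timestamp[i])) df$timestamp[i] else NA_character_
    TaxonRecord(
      uri = unname(uris[i]), checklistId = meta@checklistId,
      rank = df$rank[i], label = df$label[i], parentUri = parentUris[i],
      status = StatusAssignment(df$status[i], timestamp = ts),
      authorship = authorship, vernaculars = unname(verns),
      externalIds = .splitCell(df$external_ids[i]),
      acceptedUri = acceptedUris[i], validFrom = ts)
  })
  cl <- Checklist(meta, taxaList)
  issues <- validateChecklist(cl)
  if (nrow(issues))
    warning(sprintf("checklist '%s' loaded with %d validation issue(s)",
                    meta@checklistId, nrow(issues)), call. = FALSE)
  attr(cl, "issues") <- issues
  cl
}

#' Write a checklist to the CSV dialect
#'
#' Inverse of \code{\link{readChecklistCsv}}: URIs are shortened back to
#' their local names as \code{taxon_id}s.
#'
#' @param checklist a \linkS4class{Checklist}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeChecklistCsv <- function(checklist, path) {
  ts <- unname(checklist@taxa)
  localOf <- stats::setNames(vapply(ts, function(t) uriLocalName(t@uri),
                                    character(1)),
                             vapply(ts, function(t) t@uri, character(1)))
  cell <- function(x) paste(x, collapse = "|")
  rows <- lapply(ts, function(t) {
    a <- t@authorship
    data.frame(
      taxon_id = unname(localOf[t@uri]),
      rank = t@rank, label = t@label,
      parent_id = if (is.na(t@parentUri)) "" else unname(localOf[t@parentUri]),
      status = t@status@opinion,
      accepted_id = if (is.na(t@acceptedUri)) ""
        else unname(localOf[t@acceptedUri]),
      authors = if (is.null(a)) "" else cell(a@authors),
      year = if (is.null(a) || is.na(a@year)) "" else a@year,
      parenthesized = if (is.null(a)) "" else tolower(a@parenthesized),
      combination_authors = if (is.null(a)) "" else cell(a@combinationAuthors),
      vernacular = cell(vapply(t@vernaculars, function(v) v@name,
                               character(1))),
      language = cell(vapply(t@vernaculars, function(v) v@language,
                             character(1))),
      external_ids = cell(t@externalIds),
      timestamp = if (is.na(t@status@timestamp)) "" else t@status@timestamp,
      stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
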