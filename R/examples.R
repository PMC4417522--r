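## Packaged worked examples: the long-horn beetle checklists (1992 vs 2011
## classification of Leptura/Pedostrangalia), the fictitious dynamic genus
## Aus (a synonymisation of bus and cus), a minimal Arhopalus ferus list for
## zoological name assembly, and a Bassia scoparia list for botanical
## authorship.

.exampleMeta <- list(
  beetles_1992 = function() ChecklistMeta("cerambycids1992",
    title = "Long-horn beetles (1992)", yearPublished = 1992,
    listType = "static", code = "ICZN"),
  beetles_2011 = function() ChecklistMeta("cerambycids2011",
    title = "Long-horn beetles (2011)", yearPublished = 2011,
    listType = "static", code = "ICZN"),
  aus_t0 = function() ChecklistMeta("aus", title = "Genus Aus (dynamic)",
    listType = "dynamic", code = "ICZN"),
  aus_t1 = function() ChecklistMeta("aus", title = "Genus Aus (dynamic)",
    listType = "dynamic", code = "ICZN"),
  arhopalus = function() ChecklistMeta("cerambycids",
    title = "Arhopalus (minimal)", yearPublished = 2012, listType = "static",
    code = "ICZN"),
  bassia = function() ChecklistMeta("plants", title = "Bassia (minimal)",
    yearPublished = 2012, listType = "static", code = "ICN"))

#' Load a packaged example checklist
#'
#' Available names: \code{"beetles_1992"} and \code{"beetles_2011"} (two
#' static long-horn beetle classifications in which \emph{pubescens} and
#' \emph{revestita} moved from \emph{Leptura} to \emph{Pedostrangalia} and
#' \emph{Pedostrangalia} rose from synonymy), \code{"aus_t0"} /
#' \code{"aus_t1"} (a dynamic list in which \emph{cus} is synonymised under
#' \emph{bus}), \code{"arhopalus"} (zoological authorship) and
#' \code{"bassia"} (botanical authorship).
#'
#' @param name example name.
#' @param minter optional URI minter; a fresh seeded minter is created per
#'   call, so repeated loads are reproducible.
#' @param seed seed for the default minter.
#' @return A \linkS4class{Checklist}.
#' @examples
#' exampleChecklist("beetles_1992")
#' @export
exampleChecklist <- function(name, minter = NULL, seed = NULL) {
  if (!name %in% names(.exampleMeta))
    stop(sprintf("unknown example '%s'; available: %s", name,
                 paste(names(.exampleMeta), collapse = ", ")),
         call. = FALSE)
  path <- system.file("extdata", paste0(name, ".csv"), package = "taxmeon")
  if (is.null(seed))
    seed <- match(name, names(.exampleMeta)) * 1000L
  readChecklistCsv(path, .exampleMeta[[name]](), minter = minter,
                   seed = seed)
}

#' @rdname exampleChecklist
#' @export
exampleChecklistNames <- function() names(.exampleMeta)
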