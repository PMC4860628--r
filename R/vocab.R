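# Organ-anchored mapping between safety-lexicon finding terms and MeSH
# disease descriptors. The map constrains user input: a query names an
# organ, a lexicon finding and a MeSH disease, and is accepted only when
# the three were co-mapped in the master term file.

TERM_MAP_HEADER <- c("Organ", "LexiconTerm", "MeshName", "MeshID")
MESH_ID_PATTERN <- "^MESH:D[0-9]{6}$"

#' Load a safety-lexicon / MeSH term map
#'
#' Reads the 4-column master mapping file (tab-separated; header
#' `Organ  LexiconTerm  MeshName  MeshID`; `#` lines ignored) that assigns
#' safety-lexicon finding terms and MeSH disease descriptors to common
#' organ/tissue labels. Fields are trimmed of surrounding whitespace and
#' compared case-sensitively. Duplicate (organ, lexicon term, MeSH id)
#' triples are collapsed to one row with a warning.
#'
#' @param path path to the mapping TSV.
#' @return an object of class `term_map`: list with `rows` (data frame with
#'   columns `organ`, `lexicon_term`, `mesh_name`, `mesh_id`, `line`),
#'   `organs` (distinct organ labels) and `path`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("Organ\tLexiconTerm\tMeshName\tMeshID",
#'              "muscle\tmyolysis\tMuscular Diseases\tMESH:D009135"), tf)
#' map <- load_term_map(tf)
#' terms_for_organ(map, "muscle")
#' @export
load_term_map <- function(path) {
  raw <- read_tox_tsv(path, TERM_MAP_HEADER)
  rows <- data.frame(organ = raw$Organ,
                     lexicon_term = raw$LexiconTerm,
                     mesh_name = raw$MeshName,
                     mesh_id = raw$MeshID,
                     line = raw$line,
                     stringsAsFactors = FALSE)
  empty <- !nzchar(rows$organ) | !nzchar(rows$lexicon_term) |
    !nzchar(rows$mesh_name) | !nzchar(rows$mesh_id)
  if (any(empty)) {
    stop(sprintf("%s line %d: empty field in term mapping row",
                 path, rows$line[which(empty)[1L]]), call. = FALSE)
  }
  bad_id <- !grepl(MESH_ID_PATTERN, rows$mesh_id)
  if (any(bad_id)) {
    stop(sprintf("%s line %d: MeshID '%s' does not match MESH:D######",
                 path, rows$line[which(bad_id)[1L]],
                 rows$mesh_id[which(bad_id)[1L]]), call. = FALSE)
  }
  key <- paste(rows$organ, rows$lexicon_term, rows$mesh_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("%s: %d duplicate term-mapping row(s) collapsed",
                    path, sum(dup)), call. = FALSE)
    rows <- rows[!dup, , drop = FALSE]
    rownames(rows) <- NULL
  }
  new_term_map(rows, path)
}

new_term_map <- function(rows, path = NA_character_) {
  structure(list(rows = rows,
                 organs = sort(unique(rows$organ)),
                 path = path),
            class = "term_map")
}

#' Write a term map back to its file dialect
#'
#' @param map a `term_map`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_term_map <- function(map, path) {
  stopifnot(inherits(map, "term_map"))
  df <- map$rows
  names(df)[match(c("organ", "lexicon_term", "mesh_name", "mesh_id"), names(df))] <-
    TERM_MAP_HEADER
  write_tox_tsv(df, path, TERM_MAP_HEADER)
}

#' List the lexicon and MeSH terms mapped to an organ
#'
#' Selecting an organ restricts the finding vocabulary on both sides of the
#' mapping; this returns those restrictions. An organ absent from the map is
#' a valid empty result, not an error.
#'
#' @param map a `term_map`.
#' @param organ organ/tissue label (case-sensitive after trimming).
#' @return list with `lexicon_terms` (sorted, de-duplicated character vector)
#'   and `mesh_terms` (data frame `mesh_name`, `mesh_id`, sorted by name then
#'   id, de-duplicated).
#' @export
terms_for_organ <- function(map, organ) {
  stopifnot(inherits(map, "term_map"))
  sel <- map$rows[map$rows$organ == trim(organ), , drop = FALSE]
  lex <- sort(unique(sel$lexicon_term))
  mesh <- unique(sel[, c("mesh_name", "mesh_id"), drop = FALSE])
  mesh <- mesh[order(mesh$mesh_name, mesh$mesh_id), , drop = FALSE]
  rownames(mesh) <- NULL
  list(lexicon_terms = lex, mesh_terms = mesh)
}

#' Validate a user's organ / lexicon-term / MeSH-id selection
#'
#' Accepts the selection only if some mapping row carries exactly that
#' (organ, lexicon term, MeSH id) triple, i.e. the two finding terms were
#' co-mapped for that organ.
#'
#' @param map a `term_map`.
#' @param organ,lexicon_term,mesh_id the selection, trimmed before comparison.
#' @return list with `accepted` (logical) and, when rejected, `reason`: one of
#'   `"unknown organ"`, `"term not mapped to organ"`, `"pair not co-mapped"`.
#' @export
validate_selection <- function(map, organ, lexicon_term, mesh_id) {
  stopifnot(inherits(map, "term_map"))
  organ <- trim(organ); lexicon_term <- trim(lexicon_term); mesh_id <- trim(mesh_id)
  if (!organ %in% map$organs) {
    return(list(accepted = FALSE, reason = "unknown organ"))
  }
  sel <- map$rows[map$rows$organ == organ, , drop = FALSE]
  if (!lexicon_term %in% sel$lexicon_term) {
    return(list(accepted = FALSE, reason = "term not mapped to organ"))
  }
  hit <- sel$lexicon_term == lexicon_term & sel$mesh_id == mesh_id
  if (!any(hit)) {
    return(list(accepted = FALSE, reason = "pair not co-mapped"))
  }
  list(accepted = TRUE, reason = NULL)
}

#' @export
print.term_map <- function(x, ...) {
  cat(sprintf("<term_map> %d mapping(s) across %d organ(s)\n",
              nrow(x$rows), length(x$organs)))
  if (length(x$organs)) cat("  organs:", paste(x$organs, collapse = ", "), "\n")
  invisible(x)
}
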