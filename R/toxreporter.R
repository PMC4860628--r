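# Gene-level toxicity evidence scoreboard: per-source evidence flags for a
# gene against a disease term, and a summary score placing the gene's link
# count relative to every other gene in the evidence table.

EVIDENCE_HEADER <- c("GeneSymbol", "Source", "MeshID", "Reference")
EVIDENCE_SOURCES <- c("omim", "mouse_phenotype", "gene_ontology",
                      "literature", "expression")

#' Load a gene-level toxicity evidence table
#'
#' Each row links a gene to a MeSH disease term through one evidence
#' source (OMIM-style disease genetics, mouse phenotype, Gene Ontology,
#' literature, tissue expression) with a citation. Dialect: tab-separated,
#' header `GeneSymbol  Source  MeshID  Reference`; unknown source tokens
#' are an error naming the line.
#'
#' @param path evidence TSV.
#' @return data frame with columns `gene_symbol`, `source`, `mesh_id`,
#'   `reference`, `line`.
#' @export
load_evidence <- function(path) {
  raw <- read_tox_tsv(path, EVIDENCE_HEADER)
  bad <- !raw$Source %in% EVIDENCE_SOURCES
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("%s line %d: unknown evidence source '%s'",
                 path, raw$line[i], raw$Source[i]), call. = FALSE)
  }
  out <- data.frame(gene_symbol = raw$GeneSymbol, source = raw$Source,
                    mesh_id = raw$MeshID, reference = raw$Reference,
                    line = raw$line, stringsAsFactors = FALSE)
  tox_log(sprintf("evidence table: %d row(s), %d gene(s)",
                  nrow(out), length(unique(out$gene_symbol))))
  attr(out, "source_file") <- path
  out
}

#' Per-source evidence flags for a gene and disease term
#'
#' One flag per evidence source: present when at least one table row links
#' the gene to the term through that source, with the matching citations.
#'
#' @param table evidence table from [load_evidence()].
#' @param gene_symbol gene symbol.
#' @param mesh_id MeSH disease identifier.
#' @return named list over the five sources; each element a list with
#'   `present` (logical) and `references` (character vector of citations).
#' @export
evidence_flags <- function(table, gene_symbol, mesh_id) {
  sel <- table[table$gene_symbol == gene_symbol & table$mesh_id == mesh_id, ,
               drop = FALSE]
  out <- lapply(EVIDENCE_SOURCES, function(src) {
    refs <- sel$reference[sel$source == src]
    list(present = length(refs) > 0L, references = refs)
  })
  setNames(out, EVIDENCE_SOURCES)
}

#' Relative link-count summary score for a gene
#'
#' Counts the evidence rows linking the gene to the disease term and
#' places that count relative to all other genes in the table: the score
#' is the percentage of distinct genes whose link count for the term does
#' not exceed this gene's (a percentile, so the best-linked gene always
#' scores 100).
#'
#' @inheritParams evidence_flags
#' @return list of class `tox_score` with `gene_symbol`, `mesh_id`,
#'   `link_count` and `score` in `[0, 100]`.
#' @export
tox_score <- function(table, gene_symbol, mesh_id) {
  if (nrow(table) == 0L) {
    stop("tox_score requires a non-empty evidence table", call. = FALSE)
  }
  genes <- unique(table$gene_symbol)
  counts <- vapply(genes, function(g) {
    sum(table$gene_symbol == g & table$mesh_id == mesh_id)
  }, 1L)
  link_count <- sum(table$gene_symbol == gene_symbol & table$mesh_id == mesh_id)
  structure(list(gene_symbol = gene_symbol,
                 mesh_id = mesh_id,
                 link_count = link_count,
                 score = 100 * sum(counts <= link_count) / length(genes)),
            class = "tox_score")
}

#' @export
print.tox_score <- function(x, ...) {
  cat(sprintf("<tox_score> %s vs %s: %d link(s), score %.1f/100\n",
              x$gene_symbol, x$mesh_id, x$link_count, x$score))
  invisible(x)
}
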