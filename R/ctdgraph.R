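# Chemical-gene-disease knowledge graph in the CTD flat-file dialect.
# Curated relationships carry direct evidence (marker/mechanism or
# therapeutic) or are inferred through co-interacting third partners;
# inferred gene-disease links can also be recomputed here with an
# upper-tail hypergeometric enrichment over shared chemical partners.

CHEM_DISEASE_HEADER <- c("ChemicalName", "ChemicalID", "CasRN", "DiseaseName",
                         "DiseaseID", "DirectEvidence", "InferenceGeneSymbol",
                         "InferenceScore", "OmimIDs", "PubMedIDs")
GENE_DISEASE_HEADER <- c("GeneSymbol", "GeneID", "DiseaseName", "DiseaseID",
                         "DirectEvidence", "InferenceChemicalName",
                         "InferenceScore", "OmimIDs", "PubMedIDs")
CHEM_GENE_HEADER <- c("ChemicalName", "ChemicalID", "CasRN", "GeneSymbol",
                      "GeneID", "Organism", "OrganismID", "Interaction",
                      "InteractionActions", "PubMedIDs")

EVIDENCE_CLASSES <- c("direct_marker_mechanism", "direct_therapeutic", "inferred")

# classify one relationship row; errors name the offending line
classify_evidence <- function(direct_evidence, intermediate, path, line) {
  if (direct_evidence == "marker/mechanism") return("direct_marker_mechanism")
  if (direct_evidence == "therapeutic") return("direct_therapeutic")
  if (direct_evidence == "") {
    if (nzchar(intermediate)) return("inferred")
    stop(sprintf("%s line %d: row has neither DirectEvidence nor an inference intermediate",
                 path, line), call. = FALSE)
  }
  stop(sprintf("%s line %d: unknown DirectEvidence token '%s'",
               path, line, direct_evidence), call. = FALSE)
}

parse_assertions <- function(raw, subject_col, intermediate_col, path) {
  n <- nrow(raw)
  evidence <- character(n)
  for (i in seq_len(n)) {
    evidence[[i]] <- classify_evidence(raw$DirectEvidence[[i]],
                                       raw[[intermediate_col]][[i]],
                                       path, raw$line[[i]])
  }
  score <- suppressWarnings(as.numeric(raw$InferenceScore))
  score[evidence != "inferred"] <- NA_real_
  data.frame(subject_id = raw[[subject_col]],
             object_id = raw$DiseaseID,
             evidence = evidence,
             intermediates = ifelse(evidence == "inferred",
                                    raw[[intermediate_col]], ""),
             inference_score = score,
             pubmed_ids = raw$PubMedIDs,
             source_file = rep(path, n),
             line = raw$line,
             stringsAsFactors = FALSE)
}

#' Load a chemical-gene-disease knowledge graph from CTD-dialect files
#'
#' Reads the three relationship tables (chemical-disease, gene-disease,
#' chemical-gene) in the CTD download dialect: tab-separated, `#` comment
#' lines ignored, multi-valued fields `|`-delimited. Each relationship row
#' is classified as direct marker/mechanism, direct therapeutic, or
#' inferred (empty `DirectEvidence` with a named inference intermediate);
#' any other `DirectEvidence` token is an error naming the line.
#'
#' @param chem_disease_path,gene_disease_path,chem_gene_path the three files.
#' @return an object of class `knowledge_graph`: list with `chem_disease`
#'   and `gene_disease` assertion tables, the `chem_gene` interaction table,
#'   and `universe_size`, the number of distinct chemicals appearing in
#'   `chem_gene` (the population for enrichment tests).
#' @export
load_knowledge_graph <- function(chem_disease_path, gene_disease_path,
                                 chem_gene_path) {
  cd_raw <- read_tox_tsv(chem_disease_path, CHEM_DISEASE_HEADER)
  gd_raw <- read_tox_tsv(gene_disease_path, GENE_DISEASE_HEADER)
  cg_raw <- read_tox_tsv(chem_gene_path, CHEM_GENE_HEADER)

  chem_disease <- parse_assertions(cd_raw, "ChemicalID", "InferenceGeneSymbol",
                                   chem_disease_path)
  gene_disease <- parse_assertions(gd_raw, "GeneSymbol", "InferenceChemicalName",
                                   gene_disease_path)
  missing_cg <- !nzchar(cg_raw$ChemicalID) | !nzchar(cg_raw$GeneSymbol)
  if (any(missing_cg)) {
    stop(sprintf("%s line %d: empty ChemicalID or GeneSymbol",
                 chem_gene_path, cg_raw$line[which(missing_cg)[1L]]),
         call. = FALSE)
  }
  chem_gene <- data.frame(chem_id = cg_raw$ChemicalID,
                          gene_symbol = cg_raw$GeneSymbol,
                          organism = cg_raw$Organism,
                          actions = cg_raw$InteractionActions,
                          pubmed_ids = cg_raw$PubMedIDs,
                          source_file = rep(chem_gene_path, nrow(cg_raw)),
                          line = cg_raw$line,
                          stringsAsFactors = FALSE)
  tox_log(sprintf(
    "knowledge graph: %d chem-disease, %d gene-disease, %d chem-gene rows",
    nrow(chem_disease), nrow(gene_disease), nrow(chem_gene)))
  new_knowledge_graph(chem_disease, gene_disease, chem_gene)
}

new_knowledge_graph <- function(chem_disease, gene_disease, chem_gene) {
  structure(list(chem_disease = chem_disease,
                 gene_disease = gene_disease,
                 chem_gene = chem_gene,
                 universe_size = length(unique(chem_gene$chem_id))),
            class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf(paste0("<knowledge_graph> %d chem-disease, %d gene-disease ",
                     "assertion(s); %d chem-gene interaction(s); universe %d\n"),
              nrow(x$chem_disease), nrow(x$gene_disease),
              nrow(x$chem_gene), x$universe_size))
  invisible(x)
}

link_bundle <- function(assertions) {
  out <- lapply(EVIDENCE_CLASSES, function(cl) {
    sel <- assertions[assertions$evidence == cl, , drop = FALSE]
    rownames(sel) <- NULL
    sel
  })
  structure(setNames(out, EVIDENCE_CLASSES), class = "link_bundle")
}

bundle_size <- function(bundle) {
  sum(vapply(unclass(bundle), nrow, 1L))
}

#' @export
print.link_bundle <- function(x, ...) {
  cat(sprintf("<link_bundle> direct M: %d, direct T: %d, inferred: %d\n",
              nrow(x$direct_marker_mechanism), nrow(x$direct_therapeutic),
              nrow(x$inferred)))
  invisible(x)
}

#' Curated links between a gene and a disease
#'
#' Returns the stored assertions for the pair, partitioned by evidence
#' class. A pair absent from the graph yields three empty tables.
#'
#' @param kg a `knowledge_graph`.
#' @param gene_symbol HUGO-style gene symbol.
#' @param disease_id MeSH-style disease identifier.
#' @return a `link_bundle`: list of assertion tables
#'   `direct_marker_mechanism`, `direct_therapeutic`, `inferred`.
#' @export
gene_disease_links <- function(kg, gene_symbol, disease_id) {
  stopifnot(inherits(kg, "knowledge_graph"))
  sel <- kg$gene_disease[kg$gene_disease$subject_id == gene_symbol &
                           kg$gene_disease$object_id == disease_id, ,
                         drop = FALSE]
  link_bundle(sel)
}

#' Curated links between a chemical and a disease
#'
#' @inheritParams gene_disease_links
#' @param chem_id chemical identifier (MeSH-style or internal).
#' @return a `link_bundle`, as for [gene_disease_links()].
#' @export
chem_disease_links <- function(kg, chem_id, disease_id) {
  stopifnot(inherits(kg, "knowledge_graph"))
  sel <- kg$chem_disease[kg$chem_disease$subject_id == chem_id &
                           kg$chem_disease$object_id == disease_id, ,
                         drop = FALSE]
  link_bundle(sel)
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X` hypergeometric with population size `N`, `K`
#' successes and `n` draws — the probability of observing at least `k`
#' shared partners by chance. Computed exactly (no normal approximation).
#'
#' @param k observed overlap count, `0 <= k <= min(K, n)`.
#' @param K the subject's partner count.
#' @param n the disease's partner count.
#' @param N population (universe) size; `K, n <= N`.
#' @return the tail probability in `[0, 1]`.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (!(k >= 0 && K >= 0 && n >= 0 && N >= 0 &&
        k <= min(K, n) && K <= N && n <= N)) {
    stop(sprintf("invalid hypergeometric arguments: k=%s K=%s n=%s N=%s",
                 k, K, n, N), call. = FALSE)
  }
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Recompute an inferred gene-disease association
#'
#' An inferred association is carried by chemicals that both interact with
#' the gene and hold a direct marker/mechanism assertion to the disease.
#' If any such intermediate chemicals exist, the association is scored by
#' an upper-tail hypergeometric enrichment over shared partners:
#' `-log10 P(X >= k)` with `k` the intermediate count, `K` the gene's
#' chemical-partner count, `n` the number of chemicals holding direct
#' marker/mechanism evidence for the disease (restricted to the chem-gene
#' universe, the sampling population), and `N` the universe size.
#' Therapeutic links never seed intermediates.
#'
#' @param kg a `knowledge_graph`.
#' @param gene_symbol gene symbol.
#' @param disease_id disease identifier.
#' @return an inferred assertion row (data frame with `subject_id`,
#'   `object_id`, `evidence`, `intermediates`, `inference_score`,
#'   `pubmed_ids`, `source_file`, `line`, plus `recomputed = TRUE`), or
#'   `NULL` when no intermediate chemical exists.
#' @export
compute_inferred_gene_disease <- function(kg, gene_symbol, disease_id) {
  stopifnot(inherits(kg, "knowledge_graph"))
  partners <- unique(kg$chem_gene$chem_id[kg$chem_gene$gene_symbol == gene_symbol])
  if (length(partners) == 0L) return(NULL)
  universe <- unique(kg$chem_gene$chem_id)
  direct_m <- unique(kg$chem_disease$subject_id[
    kg$chem_disease$evidence == "direct_marker_mechanism" &
      kg$chem_disease$object_id == disease_id])
  direct_m <- intersect(direct_m, universe)
  intermediates <- sort(intersect(partners, direct_m))
  if (length(intermediates) == 0L) return(NULL)
  p <- hypergeom_upper_tail(length(intermediates), length(partners),
                            length(direct_m), kg$universe_size)
  data.frame(subject_id = gene_symbol,
             object_id = disease_id,
             evidence = "inferred",
             intermediates = join_pipes(intermediates),
             inference_score = -log10(p),
             pubmed_ids = "",
             source_file = "recomputed",
             line = NA_integer_,
             recomputed = TRUE,
             stringsAsFactors = FALSE)
}
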