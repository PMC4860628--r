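# Shared builders for in-memory fixtures: temp TSV files in the package
# dialects, random fingerprints, and hand-assembled knowledge graphs.

write_tsv_lines <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

term_map_file <- function(rows = character(0)) {
  write_tsv_lines(c("Organ\tLexiconTerm\tMeshName\tMeshID", rows))
}

# worked-example style map: muscle/myolysis + liver/necrosis
example_term_map <- function() {
  load_term_map(term_map_file(c(
    "muscle\tmyolysis\tMuscular Diseases\tMESH:D009135",
    "liver\tnecrosis\tChemical and Drug Induced Liver Injury\tMESH:D056486")))
}

rand_fp <- function(length = 64L, density = 0.3) {
  bit_fp(which(runif(length) < density) - 1L, length)
}

# assertion table in the knowledge-graph internal shape
assertion_df <- function(subject, object, evidence, intermediates = "",
                         score = NA_real_, pubmed = "") {
  n <- length(subject)
  data.frame(subject_id = subject, object_id = object, evidence = evidence,
             intermediates = rep_len(intermediates, n),
             inference_score = rep_len(score, n),
             pubmed_ids = rep_len(pubmed, n),
             source_file = rep("in-memory", n), line = seq_len(n),
             stringsAsFactors = FALSE)
}

empty_assertions <- function() {
  assertion_df(character(0), character(0), character(0))
}

chem_gene_df <- function(chem, gene) {
  n <- length(chem)
  data.frame(chem_id = chem, gene_symbol = gene,
             organism = rep("Homo sapiens", n), actions = rep("", n),
             pubmed_ids = rep("", n), source_file = rep("in-memory", n),
             line = seq_len(n), stringsAsFactors = FALSE)
}

make_kg <- function(chem_disease = empty_assertions(),
                    gene_disease = empty_assertions(),
                    chem_gene = chem_gene_df(character(0), character(0))) {
  toxlinker:::new_knowledge_graph(chem_disease, gene_disease, chem_gene)
}

# brute-force similarity search: score everything, filter, sort, cap
oracle_search <- function(index, query, threshold, max_hits) {
  scores <- numeric(nrow(index$records))
  for (i in seq_along(scores)) {
    a <- index$fingerprints[[i]]$bits
    b <- query$bits
    u <- length(union(a, b))
    scores[i] <- if (u == 0L) 0 else length(intersect(a, b)) / u
  }
  keep <- which(scores >= threshold)
  ord <- keep[order(-scores[keep], index$records$chem_id[keep])]
  ord <- utils::head(ord, max_hits)
  data.frame(chem_id = index$records$chem_id[ord], score = scores[ord],
             stringsAsFactors = FALSE)
}

# exhaustive hypergeometric tail by enumerating every draw of size n
enumerate_upper_tail <- function(k, K, n, N) {
  if (k == 0) return(1)
  if (n == 0) return(0)  # k >= 1 impossible; unreachable given k <= min(K, n)
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)  # successes are elements 1..K
  mean(overlaps >= k)
}

# random knowledge graph for inference-oracle checks; chem_disease may name
# chemicals outside the chem_gene universe
random_kg <- function(n_chem = 30L, n_gene = 6L, n_disease = 3L,
                      n_cg = 60L, n_cd = 40L) {
  chems <- sprintf("MESH:C%06d", seq_len(n_chem))
  genes <- sprintf("G%02d", seq_len(n_gene))
  diseases <- sprintf("MESH:D%06d", seq_len(n_disease))
  cg <- unique(data.frame(chem = sample(chems, n_cg, replace = TRUE),
                          gene = sample(genes, n_cg, replace = TRUE),
                          stringsAsFactors = FALSE))
  extra <- sprintf("MESH:C9%05d", 1:5)  # outside the universe
  cd <- unique(data.frame(chem = sample(c(chems, extra), n_cd, replace = TRUE),
                          disease = sample(diseases, n_cd, replace = TRUE),
                          evidence = sample(c("direct_marker_mechanism",
                                              "direct_therapeutic"),
                                            n_cd, replace = TRUE),
                          stringsAsFactors = FALSE))
  make_kg(chem_disease = assertion_df(cd$chem, cd$disease, cd$evidence),
          chem_gene = chem_gene_df(cg$chem, cg$gene))
}

# independent double-loop oracle for the recomputed inferred association
oracle_inferred <- function(kg, gene, disease) {
  partners <- character(0)
  for (i in seq_len(nrow(kg$chem_gene))) {
    if (kg$chem_gene$gene_symbol[i] == gene) {
      partners <- union(partners, kg$chem_gene$chem_id[i])
    }
  }
  if (length(partners) == 0L) return(NULL)
  universe <- unique(kg$chem_gene$chem_id)
  direct_m <- character(0)
  for (i in seq_len(nrow(kg$chem_disease))) {
    if (kg$chem_disease$object_id[i] == disease &&
        kg$chem_disease$evidence[i] == "direct_marker_mechanism" &&
        kg$chem_disease$subject_id[i] %in% universe) {
      direct_m <- union(direct_m, kg$chem_disease$subject_id[i])
    }
  }
  inter <- sort(intersect(partners, direct_m))
  if (length(inter) == 0L) return(NULL)
  p <- hypergeom_upper_tail(length(inter), length(partners),
                            length(direct_m), length(universe))
  list(intermediates = inter, score = -log10(p))
}

# small CTD-dialect file triple with planted rows around HMGCR / D009135
example_kg_files <- function() {
  cd <- write_tsv_lines(c(
    paste("ChemicalName", "ChemicalID", "CasRN", "DiseaseName", "DiseaseID",
          "DirectEvidence", "InferenceGeneSymbol", "InferenceScore",
          "OmimIDs", "PubMedIDs", sep = "\t"),
    "toxstatin-like\tMESH:C086276\t\tMuscular Diseases\tMESH:D009135\tmarker/mechanism\t\t\t\t20000001|20000002",
    "analog-b\tMESH:C000002\t\tMuscular Diseases\tMESH:D009135\t\tSLCO1B1\t4.2\t\t20000003"))
  gd <- write_tsv_lines(c(
    paste("GeneSymbol", "GeneID", "DiseaseName", "DiseaseID", "DirectEvidence",
          "InferenceChemicalName", "InferenceScore", "OmimIDs", "PubMedIDs",
          sep = "\t"),
    "HMGCR\t3156\tMuscular Diseases\tMESH:D009135\tmarker/mechanism\t\t\t\t21221107",
    "SLCO1B1\t10599\tMuscular Diseases\tMESH:D009135\ttherapeutic\t\t\t\t21677300",
    "SLCO1B1\t10599\tMuscular Diseases\tMESH:D009135\t\ttoxstatin-like\t3.3\t\t21677301",
    "SLCO1B1\t10599\tMuscular Diseases\tMESH:D009135\t\tanalog-b\t2.2\t\t21677302"))
  cg <- write_tsv_lines(c(
    paste("ChemicalName", "ChemicalID", "CasRN", "GeneSymbol", "GeneID",
          "Organism", "OrganismID", "Interaction", "InteractionActions",
          "PubMedIDs", sep = "\t"),
    "toxstatin-like\tMESH:C086276\t\tHMGCR\t3156\tHomo sapiens\t9606\tdecreases activity\tdecreases^activity\t20000004",
    "toxstatin-like\tMESH:C086276\t\tSLCO1B1\t10599\tHomo sapiens\t9606\tdecreases transport\tdecreases^transport\t20000005",
    "analog-b\tMESH:C000002\t\tSLCO1B1\t10599\tHomo sapiens\t9606\tdecreases transport\tdecreases^transport\t20000006"))
  list(chem_disease = cd, gene_disease = gd, chem_gene = cg)
}
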