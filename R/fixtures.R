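# Synthetic, schema-valid input bundles with planted structure: analog
# series of invented SMILES, chemical-gene-disease chains realized as
# knowledge-graph rows, assay/evidence/findings tables, and one fully
# deterministic worked-example bundle that mirrors the classic
# statin-myolysis investigation topology (invented structures, real gene
# symbols).

#' Specify a synthetic fixture bundle
#'
#' @param seed integer seed driving the noise rows (planted content is
#'   seed-independent).
#' @param n_chemicals total library size; must cover the analog series.
#' @param n_analog_series,series_size number and size of analog series
#'   sharing a scaffold.
#' @param n_genes,n_diseases entity counts.
#' @param planted_chains data frame with columns `chem`, `gene`, `disease`
#'   (indices into the generated entities) realized as one chem-gene row
#'   plus direct marker/mechanism chem-disease and gene-disease rows each;
#'   default plants one chain per disease.
#' @param noise_density fraction of random extra rows per table, in `[0, 1)`.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_chemicals = 40L, n_analog_series = 5L,
                         series_size = 4L, n_genes = 10L, n_diseases = 3L,
                         planted_chains = NULL, noise_density = 0.2) {
  stopifnot(n_chemicals >= n_analog_series * series_size,
            n_analog_series >= 1, series_size >= 1, n_genes >= 1,
            n_diseases >= 1, noise_density >= 0, noise_density < 1)
  if (is.null(planted_chains)) {
    planted_chains <- data.frame(chem = seq_len(n_diseases),
                                 gene = seq_len(n_diseases),
                                 disease = seq_len(n_diseases))
  }
  stopifnot(all(planted_chains$chem <= n_chemicals),
            all(planted_chains$gene <= n_genes),
            all(planted_chains$disease <= n_diseases))
  structure(list(seed = as.integer(seed), n_chemicals = as.integer(n_chemicals),
                 n_analog_series = as.integer(n_analog_series),
                 series_size = as.integer(series_size),
                 n_genes = as.integer(n_genes),
                 n_diseases = as.integer(n_diseases),
                 planted_chains = planted_chains,
                 noise_density = noise_density),
            class = "fixture_spec")
}

# entity naming
fx_chem_id <- function(k) sprintf("MESH:C%06d", k)
fx_chem_internal_id <- function(k) sprintf("PF-%07d", k)
fx_gene <- function(g) sprintf("TG%02dX", g)
fx_disease_id <- function(d) sprintf("MESH:D%06d", 900000 + d)
fx_disease_name <- function(d) sprintf("Synthetic Disease %d", d)

# deterministic scaffold per analog series: a carbocycle, a linker and a
# heteroatom whose identity/placement separates the series
scaffold_for_series <- function(i) {
  ring <- if (i %% 2 == 0) "C1CCCCC1" else "C1CCCC1"
  het <- c("N", "O", "S")[(i %% 3) + 1L]
  paste0(ring, strrep("C", 2L + (i %% 4)), het, strrep("C", (i %% 2) + 1L))
}

ANALOG_SUBSTITUENTS <- c("C", "O", "N", "S", "CC", "CO", "CN", "CS")

# member j of series i: scaffold plus one terminal substituent
analog_smiles <- function(i, j) {
  sub <- ANALOG_SUBSTITUENTS[((j - 1L) %% length(ANALOG_SUBSTITUENTS)) + 1L]
  paste0(scaffold_for_series(i), strrep("C", (j - 1L) %/% length(ANALOG_SUBSTITUENTS)),
         sub)
}

# random linear chain over {C, N, O, S}, carbon-weighted; always valid
random_chain_smiles <- function() {
  len <- sample(4:9, 1L)
  atoms <- sample(c("C", "C", "C", "C", "N", "O", "S"), len, replace = TRUE)
  atoms[1L] <- "C"
  paste(atoms, collapse = "")
}

fixture_smiles <- function(spec) {
  n_series <- spec$n_analog_series * spec$series_size
  series <- unlist(lapply(seq_len(spec$n_analog_series), function(i) {
    vapply(seq_len(spec$series_size), function(j) analog_smiles(i, j),
           character(1))
  }))
  extra <- if (spec$n_chemicals > n_series) {
    withr::with_seed(spec$seed, {
      replicate(spec$n_chemicals - n_series, random_chain_smiles())
    })
  } else character(0)
  c(series, extra)
}

#' Generate a synthetic chemical library
#'
#' Emits `n_chemicals` records in the chemical library dialect: the analog
#' series first (members of a series share a scaffold and differ by one
#' substituent, so within-series Tanimoto similarity exceeds between-series
#' similarity), then random linear-chain singletons. Byte-identical for the
#' same seed; the analog series do not depend on the seed at all.
#'
#' @param spec a [fixture_spec()].
#' @param path output TSV; `NULL` returns the data frame only.
#' @param internal_ids use internal-style (`PF-…`) identifiers instead of
#'   MeSH-style ones.
#' @return the library data frame (`ChemicalID`, `ChemicalName`, `SMILES`),
#'   invisibly when written to a file.
#' @export
generate_library <- function(spec, path = NULL, internal_ids = FALSE) {
  stopifnot(inherits(spec, "fixture_spec"))
  smiles <- fixture_smiles(spec)
  k <- seq_len(spec$n_chemicals)
  df <- data.frame(
    ChemicalID = if (internal_ids) fx_chem_internal_id(k) else fx_chem_id(k),
    ChemicalName = sprintf("synthetic compound %03d", k),
    SMILES = smiles, stringsAsFactors = FALSE)
  if (!is.null(path)) {
    write_tox_tsv(df, path, CHEM_LIBRARY_HEADER)
    return(invisible(df))
  }
  df
}

# draw n random (i, j) pairs avoiding a set of forbidden keys; deterministic
# under the caller's RNG state
random_pairs <- function(n, max_i, max_j, forbidden_keys) {
  out_i <- integer(0); out_j <- integer(0)
  guard <- 0L
  while (length(out_i) < n && guard < 100L * (n + 1L)) {
    guard <- guard + 1L
    i <- sample.int(max_i, 1L); j <- sample.int(max_j, 1L)
    key <- paste(i, j)
    if (key %in% forbidden_keys || key %in% paste(out_i, out_j)) next
    out_i <- c(out_i, i); out_j <- c(out_j, j)
  }
  list(i = out_i, j = out_j)
}

#' Generate a synthetic knowledge fixture bundle
#'
#' Writes schema-valid relationship, assay, evidence, findings and term-map
#' files into `dir`. Every planted (chem, gene, disease) chain appears as
#' one chem-gene interaction row, one direct marker/mechanism chem-disease
#' row, one direct marker/mechanism gene-disease row, one sub-cutoff IC50
#' assay row, one evidence row and one study-finding row, so the chain is
#' recoverable by every downstream workflow. Noise rows are random,
#' seed-driven, and never duplicate a planted key; planted rows are
#' identical across seeds.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if absent).
#' @return named list of the written file paths.
#' @export
generate_knowledge_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pc <- spec$planted_chains
  n_noise <- if (spec$noise_density > 0) {
    max(1L, round(nrow(pc) * spec$noise_density / (1 - spec$noise_density)))
  } else 0L

  chem_name <- function(k) sprintf("synthetic compound %03d", k)

  # planted rows (seed-independent)
  cg <- data.frame(ChemicalName = chem_name(pc$chem),
                   ChemicalID = fx_chem_id(pc$chem), CasRN = "",
                   GeneSymbol = fx_gene(pc$gene),
                   GeneID = as.character(100000 + pc$gene),
                   Organism = "Homo sapiens", OrganismID = "9606",
                   Interaction = "chemical affects activity of gene",
                   InteractionActions = "affects^activity",
                   PubMedIDs = as.character(30000000 + pc$chem),
                   stringsAsFactors = FALSE)
  cd <- data.frame(ChemicalName = chem_name(pc$chem),
                   ChemicalID = fx_chem_id(pc$chem), CasRN = "",
                   DiseaseName = fx_disease_name(pc$disease),
                   DiseaseID = fx_disease_id(pc$disease),
                   DirectEvidence = "marker/mechanism",
                   InferenceGeneSymbol = "", InferenceScore = "",
                   OmimIDs = "", PubMedIDs = as.character(31000000 + pc$chem),
                   stringsAsFactors = FALSE)
  gd <- data.frame(GeneSymbol = fx_gene(pc$gene),
                   GeneID = as.character(100000 + pc$gene),
                   DiseaseName = fx_disease_name(pc$disease),
                   DiseaseID = fx_disease_id(pc$disease),
                   DirectEvidence = "marker/mechanism",
                   InferenceChemicalName = "", InferenceScore = "",
                   OmimIDs = "", PubMedIDs = as.character(32000000 + pc$gene),
                   stringsAsFactors = FALSE)
  assays <- data.frame(CompoundID = fx_chem_internal_id(pc$chem),
                       GeneSymbol = fx_gene(pc$gene), AssayType = "IC50",
                       Value = "500", Unit = "nM", stringsAsFactors = FALSE)
  evidence <- data.frame(GeneSymbol = fx_gene(pc$gene), Source = "literature",
                         MeshID = fx_disease_id(pc$disease),
                         Reference = sprintf("PMID:%d", 32000000 + pc$gene),
                         stringsAsFactors = FALSE)
  findings <- data.frame(CompoundID = fx_chem_internal_id(pc$chem),
                         StudyID = sprintf("ST-%03d", seq_len(nrow(pc))),
                         StudyTitle = sprintf("4-week toxicity study %d",
                                              seq_len(nrow(pc))),
                         Species = "rat",
                         LexiconFinding = sprintf("finding %d", pc$disease),
                         ReportPath = sprintf("reports/st-%03d.pdf",
                                              seq_len(nrow(pc))),
                         stringsAsFactors = FALSE)
  d <- seq_len(spec$n_diseases)
  term_map <- data.frame(Organ = sprintf("organ %d", d),
                         LexiconTerm = sprintf("finding %d", d),
                         MeshName = fx_disease_name(d),
                         MeshID = fx_disease_id(d), stringsAsFactors = FALSE)

  # seed-driven noise rows on the three relationship tables
  if (n_noise > 0L) {
    noise <- withr::with_seed(spec$seed + 1L, {
      list(cg = random_pairs(n_noise, spec$n_chemicals, spec$n_genes,
                             paste(pc$chem, pc$gene)),
           cd = random_pairs(n_noise, spec$n_chemicals, spec$n_diseases,
                             paste(pc$chem, pc$disease)),
           gd = random_pairs(n_noise, spec$n_genes, spec$n_diseases,
                             paste(pc$gene, pc$disease)),
           cd_ev = sample(c("marker/mechanism", "therapeutic"), n_noise,
                          replace = TRUE),
           gd_ev = sample(c("marker/mechanism", "therapeutic"), n_noise,
                          replace = TRUE))
    })
    cg <- rbind(cg, data.frame(
      ChemicalName = chem_name(noise$cg$i), ChemicalID = fx_chem_id(noise$cg$i),
      CasRN = "", GeneSymbol = fx_gene(noise$cg$j),
      GeneID = as.character(100000 + noise$cg$j), Organism = "Homo sapiens",
      OrganismID = "9606", Interaction = "chemical affects activity of gene",
      InteractionActions = "affects^activity",
      PubMedIDs = as.character(33000000 + seq_along(noise$cg$i)),
      stringsAsFactors = FALSE))
    cd <- rbind(cd, data.frame(
      ChemicalName = chem_name(noise$cd$i), ChemicalID = fx_chem_id(noise$cd$i),
      CasRN = "", DiseaseName = fx_disease_name(noise$cd$j),
      DiseaseID = fx_disease_id(noise$cd$j), DirectEvidence = noise$cd_ev,
      InferenceGeneSymbol = "", InferenceScore = "", OmimIDs = "",
      PubMedIDs = as.character(34000000 + seq_along(noise$cd$i)),
      stringsAsFactors = FALSE))
    gd <- rbind(gd, data.frame(
      GeneSymbol = fx_gene(noise$gd$i),
      GeneID = as.character(100000 + noise$gd$i),
      DiseaseName = fx_disease_name(noise$gd$j),
      DiseaseID = fx_disease_id(noise$gd$j), DirectEvidence = noise$gd_ev,
      InferenceChemicalName = "", InferenceScore = "", OmimIDs = "",
      PubMedIDs = as.character(35000000 + seq_along(noise$gd$i)),
      stringsAsFactors = FALSE))
  }

  paths <- list(
    chem_gene = file.path(dir, "chem_gene.tsv"),
    chem_disease = file.path(dir, "chem_disease.tsv"),
    gene_disease = file.path(dir, "gene_disease.tsv"),
    assays = file.path(dir, "assays.tsv"),
    evidence = file.path(dir, "evidence.tsv"),
    findings = file.path(dir, "findings.tsv"),
    term_map = file.path(dir, "term_map.tsv"))
  write_tox_tsv(cg, paths$chem_gene, CHEM_GENE_HEADER)
  write_tox_tsv(cd, paths$chem_disease, CHEM_DISEASE_HEADER)
  write_tox_tsv(gd, paths$gene_disease, GENE_DISEASE_HEADER)
  write_tox_tsv(assays, paths$assays, ASSAY_HEADER)
  write_tox_tsv(evidence, paths$evidence, EVIDENCE_HEADER)
  write_tox_tsv(findings, paths$findings, FINDINGS_HEADER)
  write_tox_tsv(term_map, paths$term_map, TERM_MAP_HEADER)
  paths
}

#' Simulate fingerprints for classifier benchmarking
#'
#' Actives share a planted block of informative bits (high per-bit
#' probability) over a sparse random background; inactives carry the
#' background alone. Used to test whether a trained per-target model
#' recovers the planted signal.
#'
#' @param seed RNG seed.
#' @param n_active,n_inactive set sizes.
#' @param fp_length fingerprint bit count.
#' @param n_informative number of planted discriminative bits (positions
#'   `0 … n_informative - 1`).
#' @param p_active,p_inactive per-bit probability of an informative bit in
#'   each class.
#' @param p_background per-bit probability of every other bit, both classes.
#' @return list with `actives` and `inactives`, lists of [bit_fp()].
#' @export
simulate_activity_fingerprints <- function(seed, n_active = 200L,
                                           n_inactive = 200L,
                                           fp_length = 256L,
                                           n_informative = 20L,
                                           p_active = 0.9, p_inactive = 0.1,
                                           p_background = 0.1) {
  stopifnot(n_informative < fp_length)
  draw <- function(p_info) {
    probs <- c(rep(p_info, n_informative),
               rep(p_background, fp_length - n_informative))
    bit_fp(which(runif(fp_length) < probs) - 1L, fp_length)
  }
  withr::with_seed(seed, {
    list(actives = lapply(seq_len(n_active), function(i) draw(p_active)),
         inactives = lapply(seq_len(n_inactive), function(i) draw(p_inactive)))
  })
}

#' Write the deterministic worked-example bundle
#'
#' A self-contained bundle reproducing the topology of the classic
#' statin-myolysis investigation: a query compound whose public twin holds
#' a direct marker/mechanism link to Muscular Diseases (MESH:D009135), a
#' primary target (HMGCR) with a direct curated gene-disease link, a
#' sub-10-uM transporter off-target (SLCO1B1) also directly linked, analog
#' series providing similarity hits and internal study findings, and
#' per-target models trained so the primary target is among the predicted
#' targets. All structures are invented analog SMILES; only gene symbols
#' and the disease descriptor are real vocabulary. Fully deterministic:
#' identical output on every call.
#'
#' @param dir output directory (created if absent).
#' @param fp_type fingerprint family used to train the bundled models.
#' @return named list of written paths, including `config`, ready for
#'   [load_bundle()]; the query compound is internal id `PF-0000001`
#'   (public twin `MESH:C000001`), primary target `HMGCR`, adverse finding
#'   (`muscle`, `myolysis`, `MESH:D009135`).
#' @export
worked_example <- function(dir, fp_type = "FP2") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  s1 <- vapply(1:4, function(j) analog_smiles(1L, j), character(1))
  s2 <- vapply(1:4, function(j) analog_smiles(2L, j), character(1))
  s3 <- vapply(1:4, function(j) analog_smiles(3L, j), character(1))

  external <- data.frame(
    ChemicalID = fx_chem_id(1:12),
    ChemicalName = c("toxstatin", sprintf("toxstatin analog %d", 2:4),
                     sprintf("cyclohexine %d", 1:4),
                     sprintf("pentacline %d", 1:4)),
    SMILES = c(s1, s2, s3), stringsAsFactors = FALSE)
  internal <- data.frame(
    ChemicalID = fx_chem_internal_id(1:4),
    ChemicalName = c("toxstatin (internal)", "toxstatin analog 2 (internal)",
                     "toxstatin analog 3 (internal)", "cyclohexine 1 (internal)"),
    SMILES = c(s1[1:3], s2[1]), stringsAsFactors = FALSE)

  term_map <- data.frame(
    Organ = c("muscle", "liver"),
    LexiconTerm = c("myolysis", "hepatic necrosis"),
    MeshName = c("Muscular Diseases", "Chemical and Drug Induced Liver Injury"),
    MeshID = c("MESH:D009135", "MESH:D056486"), stringsAsFactors = FALSE)

  cg_pairs <- list(
    c(1, "HMGCR"), c(1, "SLCO1B1"), c(2, "HMGCR"), c(3, "SLCO1B1"),
    c(5, "CYP3A4"), c(6, "ABCB1"), c(7, "EGFR"), c(8, "NR1I2"),
    c(9, "CYP3A4"), c(10, "ABCB1"), c(11, "EGFR"), c(12, "NR1I2"))
  cg <- data.frame(
    ChemicalName = external$ChemicalName[as.integer(vapply(cg_pairs, `[`, "", 1))],
    ChemicalID = fx_chem_id(as.integer(vapply(cg_pairs, `[`, "", 1))),
    CasRN = "",
    GeneSymbol = vapply(cg_pairs, `[`, "", 2),
    GeneID = as.character(200000 + seq_along(cg_pairs)),
    Organism = "Homo sapiens", OrganismID = "9606",
    Interaction = "chemical affects activity of gene",
    InteractionActions = "affects^activity",
    PubMedIDs = as.character(20000100 + seq_along(cg_pairs)),
    stringsAsFactors = FALSE)

  cd <- data.frame(
    ChemicalName = external$ChemicalName[c(1, 2, 3, 9)],
    ChemicalID = fx_chem_id(c(1, 2, 3, 9)), CasRN = "",
    DiseaseName = c("Muscular Diseases", "Muscular Diseases",
                    "Muscular Diseases",
                    "Chemical and Drug Induced Liver Injury"),
    DiseaseID = c("MESH:D009135", "MESH:D009135", "MESH:D009135",
                  "MESH:D056486"),
    DirectEvidence = c("marker/mechanism", "marker/mechanism", "",
                       "marker/mechanism"),
    InferenceGeneSymbol = c("", "", "SLCO1B1", ""),
    InferenceScore = c("", "", "3.10", ""),
    OmimIDs = "",
    PubMedIDs = c("20000001|20000002", "20000006", "20000007", "20000008"),
    stringsAsFactors = FALSE)

  gd <- data.frame(
    GeneSymbol = c("HMGCR", "SLCO1B1", "CYP3A4", "EGFR"),
    GeneID = as.character(300001:300004),
    DiseaseName = c("Muscular Diseases", "Muscular Diseases",
                    "Chemical and Drug Induced Liver Injury",
                    "Chemical and Drug Induced Liver Injury"),
    DiseaseID = c("MESH:D009135", "MESH:D009135", "MESH:D056486",
                  "MESH:D056486"),
    DirectEvidence = c("marker/mechanism", "marker/mechanism", "",
                       "therapeutic"),
    InferenceChemicalName = c("", "", "cyclohexine 1", ""),
    InferenceScore = c("", "", "2.00", ""),
    OmimIDs = "",
    PubMedIDs = c("20000003", "20000004|20000005", "20000009", "20000010"),
    stringsAsFactors = FALSE)

  assays <- data.frame(
    CompoundID = fx_chem_internal_id(rep(1L, 6)),
    GeneSymbol = c("HMGCR", "SLCO1B1", "SLCO1B1", "CYP3A4", "ABCB1", "EGFR"),
    AssayType = c("IC50", "IC50", "EC50", "EC50", "IC50", "Ki"),
    Value = c("10", "500", "2", "9.5", "12", "0.2"),
    Unit = c("nM", "nM", "uM", "uM", "uM", "uM"), stringsAsFactors = FALSE)

  evidence <- data.frame(
    GeneSymbol = c("HMGCR", "HMGCR", "HMGCR", "SLCO1B1", "CYP3A4", "ABCB1",
                   "EGFR"),
    Source = c("omim", "literature", "mouse_phenotype", "literature",
               "expression", "gene_ontology", "literature"),
    MeshID = c(rep("MESH:D009135", 4), rep("MESH:D056486", 3)),
    Reference = c("OMIM:142910", "PMID:20000003", "MGI:96159",
                  "PMID:20000004", "GTEx:liver", "GO:0008559",
                  "PMID:20000010"),
    stringsAsFactors = FALSE)

  findings <- data.frame(
    CompoundID = fx_chem_internal_id(c(2L, 2L, 3L)),
    StudyID = c("ST-001", "ST-001", "ST-002"),
    StudyTitle = c("4-week repeat-dose rat toxicity study",
                   "4-week repeat-dose rat toxicity study",
                   "2-week repeat-dose mouse toxicity study"),
    Species = c("rat", "rat", "mouse"),
    LexiconFinding = c("myolysis", "hepatic necrosis", "hepatic necrosis"),
    ReportPath = c("reports/st-001.pdf", "reports/st-001.pdf",
                   "reports/st-002.pdf"),
    stringsAsFactors = FALSE)

  # per-target models trained on the analog series: the query's series is
  # the active class for its own targets, the other series are decoys
  fps <- setNames(fingerprint_canonical(
    vapply(c(s1, s2, s3), canonicalize, character(1)), fp_type),
    c(paste0("s1_", 1:4), paste0("s2_", 1:4), paste0("s3_", 1:4)))
  fp_s1 <- fps[1:4]; fp_s2 <- fps[5:8]; fp_s3 <- fps[9:12]
  models <- list(
    train_target_model("HMGCR", fp_s1, fp_s2),
    train_target_model("SLCO1B1", fp_s1, fp_s3),
    train_target_model("CYP3A4", fp_s2, fp_s1),
    train_target_model("ABCB1", fp_s3, fp_s1))

  paths <- list(
    term_map = file.path(dir, "term_map.tsv"),
    external_library = file.path(dir, "library_external.tsv"),
    internal_library = file.path(dir, "library_internal.tsv"),
    chem_disease = file.path(dir, "chem_disease.tsv"),
    gene_disease = file.path(dir, "gene_disease.tsv"),
    chem_gene = file.path(dir, "chem_gene.tsv"),
    assays = file.path(dir, "assays.tsv"),
    models = file.path(dir, "models.json"),
    evidence = file.path(dir, "evidence.tsv"),
    findings = file.path(dir, "findings.tsv"))
  write_tox_tsv(term_map, paths$term_map, TERM_MAP_HEADER)
  write_tox_tsv(external, paths$external_library, CHEM_LIBRARY_HEADER)
  write_tox_tsv(internal, paths$internal_library, CHEM_LIBRARY_HEADER)
  write_tox_tsv(cd, paths$chem_disease, CHEM_DISEASE_HEADER)
  write_tox_tsv(gd, paths$gene_disease, GENE_DISEASE_HEADER)
  write_tox_tsv(cg, paths$chem_gene, CHEM_GENE_HEADER)
  write_tox_tsv(assays, paths$assays, ASSAY_HEADER)
  save_target_models(models, paths$models)
  write_tox_tsv(evidence, paths$evidence, EVIDENCE_HEADER)
  write_tox_tsv(findings, paths$findings, FINDINGS_HEADER)

  config <- file.path(dir, "config.json")
  jsonlite::write_json(lapply(paths, basename), config, auto_unbox = TRUE)
  c(list(config = config), paths)
}

#' The worked-example query
#'
#' The query matching the [worked_example()] bundle: internal compound
#' `PF-0000001` against primary target HMGCR and the muscle/myolysis/
#' Muscular Diseases adverse-finding triple, at default thresholds.
#'
#' @param ... overrides passed to [new_query()].
#' @return a `tox_query`.
#' @export
worked_example_query <- function(...) {
  args <- list(compound_id = "PF-0000001", primary_target = "HMGCR",
               organ = "muscle", lexicon_term = "myolysis",
               mesh_id = "MESH:D009135",
               created = "2026-01-01T00:00:00Z")
  override <- list(...)
  args[names(override)] <- override
  do.call(new_query, args)
}
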