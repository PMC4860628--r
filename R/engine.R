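# End-to-end orchestration: load the data bundle, run a validated query
# through every evidence workflow, assemble the six-section hypothesis
# report, render it (JSON or markdown) and persist queries for rerun.

FINDINGS_HEADER <- c("CompoundID", "StudyID", "StudyTitle", "Species",
                     "LexiconFinding", "ReportPath")
REPORT_SECTIONS <- c("polypharmacology", "activity_profile",
                     "external_similarity", "internal_similarity",
                     "ctd_gene_disease", "tox_reporter")
SECTION_TITLES <- c(
  polypharmacology = "Polypharmacology (predicted secondary targets)",
  activity_profile = "Activity Profile (known secondary targets)",
  external_similarity = "External Compound Similarity",
  internal_similarity = "Internal Compound Similarity",
  ctd_gene_disease = "CTD Gene-Disease Association (primary target)",
  tox_reporter = "ToxReporter (gene evidence flags and summary score)")

#' Load an internal-study findings table
#'
#' Dialect: tab-separated, header
#' `CompoundID  StudyID  StudyTitle  Species  LexiconFinding  ReportPath`.
#'
#' @param path findings TSV.
#' @return data frame with snake_case columns plus `line`.
#' @export
load_findings <- function(path) {
  raw <- read_tox_tsv(path, FINDINGS_HEADER)
  out <- data.frame(compound_id = raw$CompoundID, study_id = raw$StudyID,
                    study_title = raw$StudyTitle, species = raw$Species,
                    lexicon_finding = raw$LexiconFinding,
                    report_path = raw$ReportPath, line = raw$line,
                    stringsAsFactors = FALSE)
  attr(out, "source_file") <- path
  out
}

#' Load a complete data bundle from a declarative config document
#'
#' The config is a JSON object mapping bundle components to file paths
#' (relative paths resolved against the config's directory): `term_map`,
#' `external_library`, `internal_library`, `chem_disease`, `gene_disease`,
#' `chem_gene`, `assays`, `models`, `evidence`, `findings`.
#'
#' @param config_path path to the JSON config.
#' @param fp_type fingerprint family used for both library indexes.
#' @return an object of class `data_bundle` holding the term map, the two
#'   chemical indexes, the knowledge graph, assay records, target models,
#'   evidence table and findings table.
#' @export
load_bundle <- function(config_path, fp_type = "FP2") {
  cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  base <- dirname(normalizePath(config_path))
  resolve <- function(key) {
    p <- cfg[[key]]
    if (is.null(p)) stop("config is missing component '", key, "'", call. = FALSE)
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    p
  }
  structure(list(
    term_map = load_term_map(resolve("term_map")),
    external_index = build_index(read_chem_library(resolve("external_library"),
                                                   "external"), fp_type),
    internal_index = build_index(read_chem_library(resolve("internal_library"),
                                                   "internal"), fp_type),
    knowledge_graph = load_knowledge_graph(resolve("chem_disease"),
                                           resolve("gene_disease"),
                                           resolve("chem_gene")),
    assay_records = load_assay_table(resolve("assays")),
    target_models = load_target_models(resolve("models")),
    evidence_table = load_evidence(resolve("evidence")),
    findings_table = load_findings(resolve("findings")),
    config_path = config_path),
    class = "data_bundle")
}

#' @export
print.data_bundle <- function(x, ...) {
  cat("<data_bundle>\n")
  cat(sprintf("  term map: %d row(s); external library: %d; internal library: %d\n",
              nrow(x$term_map$rows), nrow(x$external_index$records),
              nrow(x$internal_index$records)))
  cat(sprintf("  knowledge graph universe: %d chemical(s); %d assay row(s); %d model(s)\n",
              x$knowledge_graph$universe_size, nrow(x$assay_records),
              length(x$target_models)))
  invisible(x)
}

#' Construct a query
#'
#' The user's input triple — compound, primary target, adverse finding
#' (organ, safety-lexicon term, MeSH disease term) — plus workflow
#' thresholds with their conventional defaults: 50% similarity, 100
#' maximum hits, 10 uM potency cutoff, 0.5 predicted-activity probability.
#'
#' @param compound_id compound identifier (internal or MeSH-style).
#' @param primary_target HUGO-style gene symbol of the intended target.
#' @param organ,lexicon_term,mesh_id adverse-finding description, validated
#'   against the bundle's term map at run time.
#' @param smiles optional structure; when `NULL` the compound must be
#'   resolvable in one of the bundle's libraries.
#' @param similarity_threshold,max_hits,activity_cutoff_um,prob_threshold
#'   workflow thresholds.
#' @param created creation timestamp (UTC ISO-8601); defaults to now.
#' @return an object of class `tox_query`.
#' @export
new_query <- function(compound_id, primary_target, organ, lexicon_term,
                      mesh_id, smiles = NULL,
                      similarity_threshold = 0.5, max_hits = 100,
                      activity_cutoff_um = 10, prob_threshold = 0.5,
                      created = NULL) {
  stopifnot(similarity_threshold >= 0, similarity_threshold <= 1,
            max_hits >= 1, activity_cutoff_um > 0,
            prob_threshold >= 0, prob_threshold <= 1)
  q <- list(compound_id = compound_id, smiles = smiles,
            primary_target = primary_target, organ = organ,
            lexicon_term = lexicon_term, mesh_id = mesh_id,
            similarity_threshold = similarity_threshold,
            max_hits = as.integer(max_hits),
            activity_cutoff_um = activity_cutoff_um,
            prob_threshold = prob_threshold,
            created = created %||%
              format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  q$query_id <- paste0("q-", substr(content_hash(q), 1L, 12L))
  structure(q, class = "tox_query")
}

# md5 of the JSON serialization (tools::md5sum wants a file)
content_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                           null = "null")), tf)
  unname(tools::md5sum(tf))
}

#' @export
print.tox_query <- function(x, ...) {
  cat(sprintf("<tox_query> %s: %s / %s / %s (%s, %s)\n", x$query_id,
              x$compound_id, x$primary_target, x$mesh_id, x$organ,
              x$lexicon_term))
  invisible(x)
}

# link_bundle -> plain nested list for report entries
bundle_to_list <- function(bundle) {
  lapply(unclass(bundle), function(df) assertions_to_list(df))
}

assertions_to_list <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    list(subject_id = df$subject_id[i],
         object_id = df$object_id[i],
         evidence = df$evidence[i],
         intermediates = split_pipes(df$intermediates[i]),
         inference_score = if (is.na(df$inference_score[i])) NULL else
           df$inference_score[i],
         pubmed_ids = split_pipes(df$pubmed_ids[i]),
         provenance = list(source_file = df$source_file[i],
                           line = if (is.na(df$line[i])) NULL else df$line[i]))
  })
}

findings_to_list <- function(df, source_file) {
  lapply(seq_len(nrow(df)), function(i) {
    list(compound_id = df$compound_id[i], study_id = df$study_id[i],
         study_title = df$study_title[i], species = df$species[i],
         lexicon_finding = df$lexicon_finding[i],
         report_path = df$report_path[i],
         provenance = list(source_file = source_file, line = df$line[i]))
  })
}

resolve_compound <- function(bundle, query) {
  if (!is.null(query$smiles)) return(query$smiles)
  for (index in list(bundle$internal_index, bundle$external_index)) {
    hit <- match(query$compound_id, index$records$chem_id)
    if (!is.na(hit)) return(index$records$smiles[hit])
  }
  stop(sprintf("compound '%s' has no SMILES and is not in any library",
               query$compound_id), call. = FALSE)
}

#' Run a query through the full evidence workflow
#'
#' Validates the adverse-finding selection against the term map, resolves
#' the compound structure, and populates the six report sections:
#' predicted secondary targets (polypharmacology), known secondary targets
#' (activity profile), external and internal similarity searches, the
#' primary target's curated gene-disease links (with a recomputed inferred
#' association when shared chemical partners exist), and the gene-level
#' evidence flags plus relative summary score. Every secondary target and
#' similar compound is cross-checked against the knowledge graph for links
#' to the query's disease term. The result is a pure function of bundle
#' and query.
#'
#' @param bundle a `data_bundle` from [load_bundle()].
#' @param query a `tox_query` from [new_query()].
#' @return an object of class `tox_report` with the query and the six
#'   named sections.
#' @export
run_query <- function(bundle, query) {
  stopifnot(inherits(bundle, "data_bundle"), inherits(query, "tox_query"))
  v <- validate_selection(bundle$term_map, query$organ, query$lexicon_term,
                          query$mesh_id)
  if (!v$accepted) {
    stop(sprintf("adverse-finding selection rejected: %s", v$reason),
         call. = FALSE)
  }
  kg <- bundle$knowledge_graph
  known_genes <- unique(c(kg$gene_disease$subject_id, kg$chem_gene$gene_symbol,
                          bundle$assay_records$gene_symbol,
                          bundle$evidence_table$gene_symbol,
                          vapply(bundle$target_models,
                                 function(m) m$gene_symbol, character(1))))
  if (!query$primary_target %in% known_genes) {
    warning(sprintf("primary target '%s' not found in any data source",
                    query$primary_target), call. = FALSE)
  }
  smiles <- resolve_compound(bundle, query)
  fp <- fingerprint(smiles, bundle$external_index$fp_type)

  # predicted off-targets, each cross-checked against the disease term
  pred <- predicted_targets(bundle$target_models, fp, query$prob_threshold)
  polypharmacology <- lapply(seq_len(nrow(pred)), function(i) {
    list(gene_symbol = pred$gene_symbol[i],
         probability = pred$probability[i],
         links = bundle_to_list(gene_disease_links(kg, pred$gene_symbol[i],
                                                   query$mesh_id)),
         provenance = list(source_file = "target_models",
                           key = pred$gene_symbol[i]))
  })

  # known off-targets from assay potencies
  prof <- activity_profile(bundle$assay_records, query$compound_id,
                           query$primary_target, query$activity_cutoff_um)
  assay_src <- attr(bundle$assay_records, "source_file") %||% "assays"
  activity <- lapply(seq_len(nrow(prof)), function(i) {
    rows <- bundle$assay_records[
      bundle$assay_records$compound_id == query$compound_id &
        bundle$assay_records$gene_symbol == prof$gene_symbol[i], , drop = FALSE]
    list(gene_symbol = prof$gene_symbol[i],
         potency_um = prof$potency_um[i],
         links = bundle_to_list(gene_disease_links(kg, prof$gene_symbol[i],
                                                   query$mesh_id)),
         provenance = list(source_file = assay_src, line = rows$line))
  })

  # similar public-domain compounds with chem-disease cross-check
  ext_hits <- similarity_search(bundle$external_index, fp,
                                query$similarity_threshold, query$max_hits)
  external <- lapply(seq_len(nrow(ext_hits)), function(i) {
    list(chem_id = ext_hits$chem_id[i], name = ext_hits$name[i],
         score = ext_hits$score[i],
         links = bundle_to_list(chem_disease_links(kg, ext_hits$chem_id[i],
                                                   query$mesh_id)),
         provenance = list(
           source_file = attr(bundle$external_index$records, "source_file") %||%
             "external_library",
           line = ext_hits$line[i]))
  })

  # similar proprietary compounds with study-finding cross-check
  int_hits <- similarity_search(bundle$internal_index, fp,
                                query$similarity_threshold, query$max_hits)
  findings_src <- attr(bundle$findings_table, "source_file") %||% "findings"
  internal <- lapply(seq_len(nrow(int_hits)), function(i) {
    frows <- bundle$findings_table[
      bundle$findings_table$compound_id == int_hits$chem_id[i], , drop = FALSE]
    matching <- frows[frows$lexicon_finding == query$lexicon_term, ,
                      drop = FALSE]
    other <- frows[frows$lexicon_finding != query$lexicon_term, , drop = FALSE]
    list(chem_id = int_hits$chem_id[i], name = int_hits$name[i],
         score = int_hits$score[i],
         matching_findings = findings_to_list(matching, findings_src),
         any_other_adverse_finding = nrow(other) > 0L,
         other_findings = findings_to_list(other, findings_src),
         provenance = list(
           source_file = attr(bundle$internal_index$records, "source_file") %||%
             "internal_library",
           line = int_hits$line[i]))
  })

  # primary target vs disease: curated links + recomputed inference
  primary_links <- gene_disease_links(kg, query$primary_target, query$mesh_id)
  recomputed <- compute_inferred_gene_disease(kg, query$primary_target,
                                              query$mesh_id)
  ctd_section <- list(list(
    gene_symbol = query$primary_target,
    links = bundle_to_list(primary_links),
    recomputed_inferred = if (is.null(recomputed)) NULL else
      c(assertions_to_list(recomputed)[[1L]], list(recomputed = TRUE)),
    provenance = list(source_file = kg$gene_disease$source_file[1L] %||%
                        "gene_disease", key = query$primary_target)))

  # gene evidence flags + relative summary score
  flags <- evidence_flags(bundle$evidence_table, query$primary_target,
                          query$mesh_id)
  score <- if (nrow(bundle$evidence_table) > 0L) {
    s <- tox_score(bundle$evidence_table, query$primary_target, query$mesh_id)
    list(link_count = s$link_count, score = s$score)
  } else NULL
  tox_section <- list(list(
    gene_symbol = query$primary_target, mesh_id = query$mesh_id,
    flags = flags, summary = score,
    provenance = list(
      source_file = attr(bundle$evidence_table, "source_file") %||% "evidence",
      key = query$primary_target)))

  structure(list(query = query,
                 sections = list(polypharmacology = polypharmacology,
                                 activity_profile = activity,
                                 external_similarity = external,
                                 internal_similarity = internal,
                                 ctd_gene_disease = ctd_section,
                                 tox_reporter = tox_section)),
            class = "tox_report")
}

#' @export
print.tox_report <- function(x, ...) {
  cat(sprintf("<tox_report> %s\n", x$query$query_id))
  for (s in REPORT_SECTIONS) {
    cat(sprintf("  %-20s %d entr%s\n", s, length(x$sections[[s]]),
                if (length(x$sections[[s]]) == 1L) "y" else "ies"))
  }
  invisible(x)
}

report_to_list <- function(report) {
  list(query = unclass(report$query),
       sections = report$sections[REPORT_SECTIONS])
}

#' Render a report as JSON or markdown
#'
#' JSON rendering is lossless with stable key order (two runs on the same
#' bundle and query render byte-identically). Markdown rendering shows the
#' six titled sections with similarity as percent to one decimal place,
#' evidence-class labels and reference identifiers.
#'
#' @param report a `tox_report`.
#' @param format `"json"` or `"markdown"`.
#' @return a single string.
#' @export
render_report <- function(report, format = c("json", "markdown")) {
  format <- match.arg(format)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(report_to_list(report),
                                         auto_unbox = TRUE, digits = NA,
                                         null = "null", pretty = TRUE)))
  }
  q <- report$query
  lines <- c(sprintf("# Hypothesis report: %s / %s / %s", q$compound_id,
                     q$primary_target, q$mesh_id),
             "",
             sprintf("Adverse finding: %s (%s); lexicon term: %s. Query %s, created %s.",
                     q$mesh_id, q$organ, q$lexicon_term, q$query_id, q$created),
             "")
  pct <- function(x) sprintf("%.1f%%", 100 * x)
  describe_links <- function(links) {
    n_m <- length(links$direct_marker_mechanism)
    n_t <- length(links$direct_therapeutic)
    n_i <- length(links$inferred)
    refs <- unlist(lapply(unlist(unname(links), recursive = FALSE),
                          function(a) a$pubmed_ids))
    lab <- sprintf("direct marker/mechanism: %d, direct therapeutic: %d, inferred: %d",
                   n_m, n_t, n_i)
    if (length(refs)) lab <- paste0(lab, " [refs: ",
                                    paste(unique(refs), collapse = ", "), "]")
    lab
  }
  for (s in REPORT_SECTIONS) {
    lines <- c(lines, sprintf("## %s", SECTION_TITLES[[s]]), "")
    entries <- report$sections[[s]]
    if (length(entries) == 0L) {
      lines <- c(lines, "no findings", "")
      next
    }
    for (e in entries) {
      item <- switch(s,
        polypharmacology = sprintf("- %s (P(active) = %.3f) — %s",
                                   e$gene_symbol, e$probability,
                                   describe_links(e$links)),
        activity_profile = sprintf("- %s (min potency %.3g uM) — %s",
                                   e$gene_symbol, e$potency_um,
                                   describe_links(e$links)),
        external_similarity = sprintf("- %s (%s, similarity %s) — %s",
                                      e$chem_id, e$name, pct(e$score),
                                      describe_links(e$links)),
        internal_similarity = sprintf(
          "- %s (%s, similarity %s) — %d matching study finding(s)%s",
          e$chem_id, e$name, pct(e$score), length(e$matching_findings),
          if (isTRUE(e$any_other_adverse_finding))
            "; other adverse findings on record" else ""),
        ctd_gene_disease = sprintf("- %s — %s%s", e$gene_symbol,
                                   describe_links(e$links),
                                   if (!is.null(e$recomputed_inferred))
                                     sprintf("; recomputed inferred score %.3f via %s",
                                             e$recomputed_inferred$inference_score,
                                             paste(e$recomputed_inferred$intermediates,
                                                   collapse = ", "))
                                   else ""),
        tox_reporter = {
          on <- names(Filter(function(f) f$present, e$flags))
          sprintf("- %s — flags: %s%s", e$gene_symbol,
                  if (length(on)) paste(on, collapse = ", ") else "none",
                  if (!is.null(e$summary))
                    sprintf("; %d link(s), summary score %.1f/100",
                            e$summary$link_count, e$summary$score) else "")
        })
      lines <- c(lines, item)
    }
    lines <- c(lines, "")
  }
  paste(lines, collapse = "\n")
}

.query_counter <- new.env(parent = emptyenv())

#' Persist a query to a file-based store
#'
#' Serializes the query as one JSON document in the store directory. Every
#' save assigns a fresh identifier (content hash plus save timestamp), so
#' saving the same query twice yields two store entries.
#'
#' @param store directory path (created if absent).
#' @param query a `tox_query`.
#' @return the assigned query id.
#' @export
persist_query <- function(store, query) {
  stopifnot(inherits(query, "tox_query"))
  if (!dir.exists(store)) dir.create(store, recursive = TRUE)
  n <- (.query_counter$n %||% 0L) + 1L
  .query_counter$n <- n
  stamp <- format(Sys.time(), "%Y%m%d%H%M%OS6", tz = "UTC")
  query$query_id <- sprintf("q-%s-%s-%d",
                            substr(content_hash(unclass(query)), 1L, 8L),
                            stamp, n)
  jsonlite::write_json(unclass(query), file.path(store,
                                                 paste0(query$query_id, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  query$query_id
}

#' List queries saved in a store
#'
#' Corrupt documents are skipped with a warning.
#'
#' @param store directory path.
#' @return data frame with `query_id`, `created`, `compound_id`,
#'   `primary_target`, `mesh_id`.
#' @export
list_queries <- function(store) {
  files <- sort(list.files(store, pattern = "\\.json$", full.names = TRUE))
  rows <- lapply(files, function(f) {
    q <- tryCatch(jsonlite::read_json(f, simplifyVector = TRUE),
                  error = function(e) NULL)
    if (is.null(q) || is.null(q$query_id)) {
      warning("skipping unreadable query document: ", f, call. = FALSE)
      return(NULL)
    }
    data.frame(query_id = q$query_id, created = q$created,
               compound_id = q$compound_id, primary_target = q$primary_target,
               mesh_id = q$mesh_id, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) {
    return(data.frame(query_id = character(0), created = character(0),
                      compound_id = character(0),
                      primary_target = character(0), mesh_id = character(0)))
  }
  do.call(rbind, rows)
}

#' Load a persisted query
#'
#' @param store directory path.
#' @param query_id identifier assigned by [persist_query()].
#' @return the `tox_query`.
#' @export
load_query <- function(store, query_id) {
  path <- file.path(store, paste0(query_id, ".json"))
  if (!file.exists(path)) {
    stop("unknown query id: ", query_id, call. = FALSE)
  }
  q <- jsonlite::read_json(path, simplifyVector = TRUE)
  q$smiles <- q$smiles %||% NULL
  structure(q, class = "tox_query")
}

#' Rerun a persisted query against a bundle
#'
#' Equivalent to [run_query()] on the loaded query; rerunning against an
#' updated bundle reflects the bundle's new content.
#'
#' @param store directory path.
#' @param bundle a `data_bundle`.
#' @param query_id identifier assigned by [persist_query()].
#' @return a `tox_report`.
#' @export
rerun_query <- function(store, bundle, query_id) {
  run_query(bundle, load_query(store, query_id))
}
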