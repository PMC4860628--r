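# the worked-example bundle is loaded once and reused across blocks
we_dir <- tempfile("we")
we_paths <- worked_example(we_dir)
we_bundle <- suppressMessages(load_bundle(we_paths$config))
we_report <- suppressMessages(run_query(we_bundle, worked_example_query()))

test_that("a report always carries the six named sections", {
  expect_s3_class(we_report, "tox_report")
  expect_equal(names(we_report$sections),
               c("polypharmacology", "activity_profile", "external_similarity",
                 "internal_similarity", "ctd_gene_disease", "tox_reporter"))
})

test_that("the worked example reproduces the expected linkage pattern", {
  ctd <- we_report$sections$ctd_gene_disease[[1L]]
  expect_equal(ctd$gene_symbol, "HMGCR")
  expect_gte(length(ctd$links$direct_marker_mechanism), 1L)
  expect_false(is.null(ctd$recomputed_inferred))
  expect_gt(ctd$recomputed_inferred$inference_score, 0)

  ext <- we_report$sections$external_similarity
  expect_equal(ext[[1L]]$score, 1)  # the compound's public twin, self-match
  expect_gte(length(ext[[1L]]$links$direct_marker_mechanism), 1L)

  act <- we_report$sections$activity_profile
  genes <- vapply(act, function(e) e$gene_symbol, character(1))
  expect_true("SLCO1B1" %in% genes)
  expect_false("HMGCR" %in% genes)  # primary target excluded
  slco <- act[[which(genes == "SLCO1B1")]]
  expect_lt(slco$potency_um, 10)
  expect_gte(length(slco$links$direct_marker_mechanism), 1L)

  pred <- vapply(we_report$sections$polypharmacology,
                 function(e) e$gene_symbol, character(1))
  expect_true("HMGCR" %in% pred)

  int <- we_report$sections$internal_similarity
  ids <- vapply(int, function(e) e$chem_id, character(1))
  analog <- int[[which(ids == "PF-0000002")]]
  expect_equal(length(analog$matching_findings), 1L)
  expect_true(analog$any_other_adverse_finding)

  summary <- we_report$sections$tox_reporter[[1L]]
  expect_true(summary$flags$omim$present)
  expect_equal(summary$summary$score, 100)
})

test_that("every report entry carries provenance", {
  for (section in we_report$sections) {
    for (entry in section) {
      expect_true(!is.null(entry$provenance$source_file))
      expect_true(!is.null(entry$provenance$line) ||
                    !is.null(entry$provenance$key))
    }
  }
})

test_that("an empty knowledge graph still yields all six sections", {
  d <- tempfile("empty")
  paths <- worked_example(d)
  for (key in c("chem_disease", "gene_disease", "chem_gene")) {
    writeLines(readLines(paths[[key]])[1L], paths[[key]])
  }
  bundle <- suppressMessages(load_bundle(paths$config))
  report <- suppressMessages(run_query(bundle, worked_example_query()))
  expect_equal(length(report$sections), 6L)
  ctd <- report$sections$ctd_gene_disease[[1L]]
  expect_equal(length(ctd$links$direct_marker_mechanism), 0L)
  expect_null(ctd$recomputed_inferred)
  for (e in report$sections$external_similarity) {
    expect_equal(sum(lengths(e$links)), 0L)
  }
})

test_that("invalid queries are rejected and unknown targets warned about", {
  expect_error(run_query(we_bundle,
                         worked_example_query(organ = "kidney")),
               "unknown organ")
  expect_error(run_query(we_bundle,
                         worked_example_query(mesh_id = "MESH:D056486")),
               "pair not co-mapped")
  expect_error(suppressWarnings(run_query(
    we_bundle, worked_example_query(compound_id = "PF-9999999",
                                    primary_target = "HMGCR"))),
    "no SMILES")
  expect_warning(run_query(we_bundle,
                           worked_example_query(primary_target = "ZZZ9")),
                 "not found in any data source")
})

test_that("JSON rendering is lossless and markdown renders all six sections", {
  json <- render_report(we_report, "json")
  parsed <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  expect_equal(names(parsed$sections), names(we_report$sections))
  expect_equal(parsed$query$compound_id, "PF-0000001")
  expect_equal(parsed$sections$ctd_gene_disease[[1L]]$gene_symbol, "HMGCR")
  expect_equal(
    length(parsed$sections$external_similarity),
    length(we_report$sections$external_similarity))
  expect_equal(
    parsed$sections$activity_profile[[1L]]$potency_um,
    we_report$sections$activity_profile[[1L]]$potency_um)

  md <- render_report(we_report, "markdown")
  expect_length(gregexpr("\n## ", md)[[1L]], 6L)
  expect_match(md, "100.0%", fixed = TRUE)  # self-match similarity formatting

  # an empty report renders six headers with "no findings" bodies
  empty_report <- we_report
  empty_report$sections <- lapply(empty_report$sections, function(x) list())
  md0 <- render_report(empty_report, "markdown")
  expect_equal(length(gregexpr("no findings", md0)[[1L]]), 6L)
})

test_that("reports are a pure function of bundle and query", {
  r2 <- suppressMessages(run_query(we_bundle, worked_example_query()))
  expect_identical(render_report(we_report, "json"), render_report(r2, "json"))
})

test_that("query persistence round-trips, lists and skips corrupt documents", {
  store <- tempfile("store")
  q <- worked_example_query()
  id1 <- persist_query(store, q)
  id2 <- persist_query(store, q)
  expect_false(identical(id1, id2))

  back <- load_query(store, id1)
  for (field in c("compound_id", "primary_target", "organ", "lexicon_term",
                  "mesh_id", "similarity_threshold", "max_hits",
                  "activity_cutoff_um", "prob_threshold", "created")) {
    expect_equal(back[[field]], q[[field]])
  }

  writeLines("{ not json", file.path(store, "broken.json"))
  expect_warning(listing <- list_queries(store), "unreadable")
  expect_setequal(listing$query_id, c(id1, id2))

  expect_error(load_query(store, "q-does-not-exist"), "unknown query id")
})

test_that("rerunning a persisted query reproduces the report and sees bundle updates", {
  store <- tempfile("store")
  id <- persist_query(store, worked_example_query())
  r <- suppressMessages(rerun_query(store, we_bundle, id))
  # persisting assigns a fresh query id; the evidence content is unchanged
  expect_equal(r$sections, we_report$sections)

  # adding a direct assertion to the graph surfaces in the rerun
  d <- tempfile("upd")
  paths <- worked_example(d)
  gd <- readLines(paths$gene_disease)
  writeLines(c(gd, "HMGCR\t300001\tMuscular Diseases\tMESH:D009135\ttherapeutic\t\t\t\t20000099"),
             paths$gene_disease)
  updated <- suppressMessages(load_bundle(paths$config))
  r2 <- suppressMessages(rerun_query(store, updated, id))
  ctd <- r2$sections$ctd_gene_disease[[1L]]
  expect_equal(length(ctd$links$direct_therapeutic), 1L)
})
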