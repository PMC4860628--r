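test_that("CTD-dialect files load with correct evidence classification", {
  files <- example_kg_files()
  kg <- load_knowledge_graph(files$chem_disease, files$gene_disease,
                             files$chem_gene)
  expect_s3_class(kg, "knowledge_graph")
  expect_equal(nrow(kg$chem_disease), 2L)
  expect_equal(nrow(kg$gene_disease), 4L)
  expect_equal(kg$universe_size, 2L)

  # direct marker/mechanism row retrievable in its bundle slot
  b <- gene_disease_links(kg, "HMGCR", "MESH:D009135")
  expect_equal(nrow(b$direct_marker_mechanism), 1L)
  expect_equal(b$direct_marker_mechanism$pubmed_ids, "21221107")
  expect_equal(nrow(b$direct_therapeutic), 0L)
  expect_equal(nrow(b$inferred), 0L)

  # inferred passthrough keeps its intermediate and precomputed score
  inf <- kg$chem_disease[kg$chem_disease$evidence == "inferred", ]
  expect_equal(inf$intermediates, "SLCO1B1")
  expect_equal(inf$inference_score, 4.2)

  # one direct T + two inferred rows partition as (0, 1, 2)
  b2 <- gene_disease_links(kg, "SLCO1B1", "MESH:D009135")
  expect_equal(c(nrow(b2$direct_marker_mechanism), nrow(b2$direct_therapeutic),
                 nrow(b2$inferred)), c(0L, 1L, 2L))

  # unknown pair is an all-empty bundle
  expect_equal(toxlinker:::bundle_size(
    gene_disease_links(kg, "NOSUCH", "MESH:D009135")), 0L)
  expect_equal(toxlinker:::bundle_size(
    chem_disease_links(kg, "MESH:C999999", "MESH:D009135")), 0L)
})

test_that("every loaded assertion is retrievable through exactly one bundle slot", {
  files <- example_kg_files()
  kg <- load_knowledge_graph(files$chem_disease, files$gene_disease,
                             files$chem_gene)
  for (tbl in list(kg$gene_disease, kg$chem_disease)) {
    lookup <- if (identical(tbl, kg$gene_disease)) gene_disease_links else
      chem_disease_links
    for (i in seq_len(nrow(tbl))) {
      b <- lookup(kg, tbl$subject_id[i], tbl$object_id[i])
      slot <- b[[tbl$evidence[i]]]
      expect_true(tbl$line[i] %in% slot$line)
      others <- setdiff(names(b), tbl$evidence[i])
      for (o in others) expect_false(tbl$line[i] %in% b[[o]]$line)
    }
  }
})

test_that("malformed relationship rows are rejected with their line number", {
  files <- example_kg_files()
  bad_cd <- write_tsv_lines(c(
    readLines(files$chem_disease)[1],
    "x\tMESH:C1\t\td\tMESH:D000001\tbiomarker\t\t\t\t1"))
  expect_error(load_knowledge_graph(bad_cd, files$gene_disease,
                                    files$chem_gene),
               "line 2: unknown DirectEvidence token 'biomarker'")
  dangling <- write_tsv_lines(c(
    readLines(files$chem_disease)[1],
    "x\tMESH:C1\t\td\tMESH:D000001\t\t\t\t\t1"))
  expect_error(load_knowledge_graph(dangling, files$gene_disease,
                                    files$chem_gene),
               "line 2.*neither DirectEvidence nor an inference")
  truncated <- write_tsv_lines("ChemicalName\tChemicalID\tCasRN")
  expect_error(load_knowledge_graph(truncated, files$gene_disease,
                                    files$chem_gene), "header")
})

test_that("header-only relationship files give an empty graph", {
  files <- example_kg_files()
  empty <- lapply(files, function(f) write_tsv_lines(readLines(f)[1]))
  kg <- load_knowledge_graph(empty$chem_disease, empty$gene_disease,
                             empty$chem_gene)
  expect_equal(nrow(kg$chem_disease) + nrow(kg$gene_disease) +
                 nrow(kg$chem_gene), 0L)
  expect_equal(kg$universe_size, 0L)
})

test_that("hypergeometric upper tail matches the combinatorial oracle", {
  # full-overlap draw: C(3,3) * C(7,0) / C(10,3) = 1/120
  expect_equal(hypergeom_upper_tail(3, 3, 3, 10),
               choose(3, 3) * choose(7, 0) / choose(10, 3))
  expect_equal(hypergeom_upper_tail(0, 5, 3, 10), 1)
  expect_equal(hypergeom_upper_tail(4, 4, 4, 4), 1)
  expect_error(hypergeom_upper_tail(5, 3, 4, 10), "invalid")
  expect_error(hypergeom_upper_tail(2, 11, 4, 10), "invalid")

  # exhaustive enumeration of all draws for a grid of small populations,
  # plus monotone non-increase in k
  for (N in c(1L, 4L, 7L)) {
    for (K in 0:N) {
      for (n in 0:N) {
        prev <- 1
        for (k in 0:min(K, n)) {
          p <- hypergeom_upper_tail(k, K, n, N)
          expect_equal(p, enumerate_upper_tail(k, K, n, N))
          expect_lte(p, prev + 1e-12)
          prev <- p
        }
      }
    }
  }
})

test_that("recomputed inference finds shared-partner intermediates and scores them", {
  # 3 chemicals all interacting with the gene, all with direct M evidence,
  # universe of 10
  chems <- sprintf("MESH:C%06d", 1:10)
  kg <- make_kg(
    chem_disease = assertion_df(chems[1:3], "MESH:D000001",
                                "direct_marker_mechanism"),
    chem_gene = chem_gene_df(chems, c(rep("TG01X", 3), rep("OTHER", 7))))
  a <- compute_inferred_gene_disease(kg, "TG01X", "MESH:D000001")
  expect_equal(strsplit(a$intermediates, "|", fixed = TRUE)[[1L]], chems[1:3])
  expect_equal(a$inference_score, -log10(1 / choose(10, 3)))
  expect_equal(a$evidence, "inferred")

  # gene without chemical partners, and empty intersection, both give NULL
  expect_null(compute_inferred_gene_disease(kg, "NOSUCH", "MESH:D000001"))
  kg2 <- make_kg(
    chem_disease = assertion_df(chems[4:5], "MESH:D000001",
                                "direct_marker_mechanism"),
    chem_gene = chem_gene_df(chems[1:3], rep("TG01X", 3)))
  expect_null(compute_inferred_gene_disease(kg2, "TG01X", "MESH:D000001"))

  # therapeutic evidence never seeds intermediates
  kg3 <- make_kg(
    chem_disease = assertion_df(chems[1], "MESH:D000001", "direct_therapeutic"),
    chem_gene = chem_gene_df(chems[1], "TG01X"))
  expect_null(compute_inferred_gene_disease(kg3, "TG01X", "MESH:D000001"))
})

test_that("recomputed inference agrees with a double-loop oracle on random graphs", {
  withr::with_seed(23, {
    for (rep in 1:25) {
      kg <- random_kg()
      gene <- sample(unique(kg$chem_gene$gene_symbol), 1L)
      disease <- sample(unique(kg$chem_disease$object_id), 1L)
      got <- compute_inferred_gene_disease(kg, gene, disease)
      want <- oracle_inferred(kg, gene, disease)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_equal(strsplit(got$intermediates, "|", fixed = TRUE)[[1L]],
                     want$intermediates)
        expect_equal(got$inference_score, want$score)
      }
    }
  })
})
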