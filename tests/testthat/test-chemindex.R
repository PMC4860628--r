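test_that("canonicalization is deterministic and write-order invariant", {
  c1 <- canonicalize("CCO")
  expect_identical(canonicalize("CCO"), c1)
  expect_identical(canonicalize("OCC"), c1)
  # independent oracle: the toolkit's own canonical form of both spellings
  expect_identical(ChemmineOB::convertFormat("SMI", "CAN", "CCO\n"),
                   ChemmineOB::convertFormat("SMI", "CAN", "OCC\n"))
  expect_error(canonicalize("C1CC"), class = "toxlinker_parse_error")
  expect_error(canonicalize(""), class = "toxlinker_parse_error")
})

test_that("fingerprints are deterministic, canonical-invariant and discriminative", {
  f1 <- fingerprint("CCO")
  expect_s3_class(f1, "bit_fp")
  expect_identical(fingerprint("CCO")$bits, f1$bits)
  expect_identical(fingerprint("OCC")$bits, f1$bits)
  expect_false(identical(fingerprint("c1ccccc1")$bits, f1$bits))
  expect_error(fingerprint("C1CC"), class = "toxlinker_parse_error")
})

test_that("tanimoto matches its set definition and conventions", {
  fp <- function(bits) bit_fp(bits, 16L)
  expect_equal(tanimoto(fp(c(1, 5, 9)), fp(c(1, 5, 9))), 1)
  expect_equal(tanimoto(fp(c(1, 2)), fp(c(3, 4))), 0)
  expect_equal(tanimoto(fp(1:3), fp(2:4)), 0.5)
  expect_equal(tanimoto(fp(integer(0)), fp(integer(0))), 0)
  expect_error(tanimoto(fp(1), bit_fp(1, 32L)), "length mismatch")
})

test_that("tanimoto is symmetric, reflexive and monotone under shared/unshared edits", {
  withr::with_seed(7, {
    for (i in 1:25) {
      a <- rand_fp(64L); b <- rand_fp(64L)
      expect_equal(tanimoto(a, b), tanimoto(b, a))
      if (length(a$bits) > 0L) expect_equal(tanimoto(a, a), 1)
      # adding one bit to both sets cannot decrease similarity
      free <- setdiff(0:63, union(a$bits, b$bits))
      if (length(free) > 0L) {
        shared <- free[[1L]]
        expect_gte(tanimoto(bit_fp(c(a$bits, shared), 64L),
                            bit_fp(c(b$bits, shared), 64L)),
                   tanimoto(a, b))
      }
      # removing a bit present in only one set cannot decrease similarity
      only_a <- setdiff(a$bits, b$bits)
      if (length(only_a) > 0L && length(a$bits) > 1L) {
        expect_gte(tanimoto(bit_fp(setdiff(a$bits, only_a[[1L]]), 64L), b),
                   tanimoto(a, b))
      }
    }
  })
})

test_that("index construction skips unparseable records and rejects duplicate ids", {
  recs <- data.frame(chem_id = c("A", "B", "C"),
                     name = c("ethanol", "broken", "benzene"),
                     smiles = c("CCO", "C1CC", "c1ccccc1"),
                     stringsAsFactors = FALSE)
  expect_warning(idx <- build_index(recs), "skipped 1")
  expect_equal(nrow(idx$records), 2L)
  expect_equal(idx$skipped$chem_id, "B")
  expect_length(idx$fingerprints, 2L)

  ok <- build_index(recs[c(1, 3), ])
  expect_equal(nrow(ok$skipped), 0L)

  empty <- build_index(recs[0, ])
  expect_equal(nrow(empty$records), 0L)

  recs$chem_id <- c("A", "A", "C")
  expect_error(build_index(recs), "duplicate.*A")
})

test_that("similarity search honors threshold, cap and deterministic tie-breaks", {
  base <- bit_fp(c(0:9), 64L)
  near <- bit_fp(c(0:8, 20), 64L)   # tanimoto 9/11
  far <- bit_fp(40:49, 64L)         # 0
  recs <- data.frame(chem_id = c("C2", "C1", "C3"),
                     name = paste0("m", 1:3),
                     smiles = "", source = "external", line = 1:3,
                     stringsAsFactors = FALSE)
  idx <- toxlinker:::new_chem_index(recs, list(base, near, far))
  hits <- similarity_search(idx, base, threshold = 0.5, max_hits = 100)
  expect_equal(hits$chem_id, c("C2", "C1"))
  expect_equal(hits$score[[1L]], 1)

  # exact-threshold hit is retained (inclusive comparison): query 0:2 scores
  # 3/6 = 0.5 against C2's fingerprint and 3/4 against C1's
  a <- bit_fp(0:5, 64L); b <- bit_fp(0:3, 64L)
  idx2 <- toxlinker:::new_chem_index(recs[1:2, ], list(a, b))
  expect_equal(similarity_search(idx2, bit_fp(0:2, 64L), threshold = 0.5,
                                 max_hits = 10)$chem_id, c("C1", "C2"))

  # nothing reaches a threshold of 1 without an exact match
  expect_equal(nrow(similarity_search(idx, bit_fp(c(0:9, 12), 64L),
                                      threshold = 1, max_hits = 10)), 0L)

  # ties resolved by identifier; cap applied after filtering
  n <- 150L
  ids <- sprintf("CMP%03d", sample(seq_len(n)))
  recs150 <- data.frame(chem_id = ids, name = ids, smiles = "",
                        source = "external", line = seq_len(n),
                        stringsAsFactors = FALSE)
  idx150 <- toxlinker:::new_chem_index(recs150,
                                       rep(list(base), n))
  hits150 <- similarity_search(idx150, base)
  expect_equal(nrow(hits150), 100L)
  expect_equal(hits150$chem_id, sort(ids)[1:100])

  expect_error(similarity_search(idx, bit_fp(0, 32L), 0.5, 10),
               "length.*does not match")
})

test_that("similarity search agrees with the brute-force oracle on random libraries", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      n <- sample(1:120, 1L)
      fps <- replicate(n, rand_fp(128L, runif(1, 0.05, 0.5)),
                       simplify = FALSE)
      recs <- data.frame(chem_id = sprintf("C%04d", sample(seq_len(n))),
                         name = "x", smiles = "", source = "external",
                         line = seq_len(n), stringsAsFactors = FALSE)
      idx <- toxlinker:::new_chem_index(recs, fps)
      query <- rand_fp(128L, 0.3)
      threshold <- runif(1, 0, 0.8)
      max_hits <- sample(1:50, 1L)
      got <- similarity_search(idx, query, threshold, max_hits)
      want <- oracle_search(idx, query, threshold, max_hits)
      expect_equal(got$chem_id, want$chem_id)
      expect_equal(got$score, want$score)
    }
  })
})
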