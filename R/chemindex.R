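# Structure canonicalization, hashed binary fingerprints and thresholded,
# capped Tanimoto similarity search over chemical libraries. OpenBabel
# (through ChemmineOB/ChemmineR) supplies the structure perception; the
# search itself — inclusive threshold, deterministic tie-breaks, top-k cap —
# is defined here.

CHEM_LIBRARY_HEADER <- c("ChemicalID", "ChemicalName", "SMILES")

#' Canonicalize a SMILES string
#'
#' Maps structurally identical SMILES inputs to one canonical string
#' (OpenBabel canonical SMILES), so that fingerprints and library lookups
#' are independent of how the structure was written.
#'
#' @param smiles a single SMILES string.
#' @return the canonical SMILES string.
#' @examples
#' canonicalize("OCC") == canonicalize("CCO")
#' @export
canonicalize <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(trim(smiles))) {
    stop(structure_parse_error(smiles))
  }
  out <- ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\n"))
  can <- trim(sub("\t.*$", "", strsplit(out, "\n", fixed = TRUE)[[1L]][1L]))
  if (is.na(can) || !nzchar(can)) {
    stop(structure_parse_error(smiles))
  }
  can
}

structure_parse_error <- function(smiles) {
  errorCondition(sprintf("cannot parse SMILES: '%s'", smiles),
                 smiles = smiles,
                 class = c("toxlinker_parse_error", "error", "condition"))
}

#' Construct a binary fingerprint from bit positions
#'
#' @param bits integer vector of set bit positions, 0-based, all `< length`.
#' @param length total bit count.
#' @return an object of class `bit_fp` with fields `length` and `bits`
#'   (sorted, duplicate-free, 0-based positions).
#' @export
bit_fp <- function(bits, length) {
  length <- as.integer(length)
  stopifnot(length > 0L)
  bits <- sort(unique(as.integer(bits)))
  if (any(bits < 0L) || any(bits >= length)) {
    stop("bit positions must lie in [0, length)", call. = FALSE)
  }
  structure(list(length = length, bits = bits), class = "bit_fp")
}

#' @export
print.bit_fp <- function(x, ...) {
  cat(sprintf("<bit_fp> %d/%d bits set\n", length(x$bits), x$length))
  invisible(x)
}

# fingerprint widths of the supported OpenBabel families
FP_LENGTHS <- c(FP2 = 1024L, FP3 = 64L, FP4 = 512L, MACCS = 256L)

#' Compute a hashed substructure fingerprint for a SMILES string
#'
#' Canonicalizes the structure, then computes a fixed-length hashed binary
#' substructure fingerprint. The default family, `FP2`, encodes hashed
#' linear fragments up to seven atoms into 1024 bits; it is deterministic
#' and invariant to the SMILES writing (equal canonical structures give
#' equal fingerprints).
#'
#' @param smiles a single SMILES string.
#' @param fp_type fingerprint family, one of `"FP2"`, `"FP3"`, `"FP4"`,
#'   `"MACCS"`.
#' @return a [bit_fp()].
#' @export
fingerprint <- function(smiles, fp_type = "FP2") {
  fp_type <- match.arg(fp_type, names(FP_LENGTHS))
  can <- canonicalize(smiles)
  fingerprint_canonical(can, fp_type)
}

# fingerprint a vector of already-canonical SMILES in one OpenBabel pass
fingerprint_canonical <- function(canonical, fp_type = "FP2") {
  sdf <- ChemmineR::smiles2sdf(setNames(canonical, seq_along(canonical)))
  m <- ChemmineR::fingerprintOB(sdf, fp_type)@fpma
  fps <- lapply(seq_len(nrow(m)), function(i) {
    bit_fp(which(m[i, ] != 0) - 1L, ncol(m))
  })
  if (length(canonical) == 1L) fps[[1L]] else fps
}

#' Tanimoto similarity between two binary fingerprints
#'
#' `|A intersect B| / |A union B|` over set bit positions; two all-zero
#' fingerprints score 0 by convention.
#'
#' @param a,b [bit_fp()] objects of equal length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "bit_fp"), inherits(b, "bit_fp"))
  if (a$length != b$length) {
    stop(sprintf("fingerprint length mismatch: %d vs %d", a$length, b$length),
         call. = FALSE)
  }
  u <- length(a$bits) + length(b$bits)
  if (u == 0L) return(0)
  i <- length(intersect(a$bits, b$bits))
  i / (u - i)
}

#' Read a chemical library TSV
#'
#' Dialect: tab-separated, header `ChemicalID  ChemicalName  SMILES`,
#' `#` lines ignored. The same dialect serves the external (MeSH-identified,
#' CTD-style) and internal (proprietary-identified) libraries.
#'
#' @param path library file.
#' @param source `"external"` or `"internal"`, recorded on each record.
#' @return data frame with columns `chem_id`, `name`, `smiles`, `source`,
#'   `line`.
#' @export
read_chem_library <- function(path, source = c("external", "internal")) {
  source <- match.arg(source)
  raw <- read_tox_tsv(path, CHEM_LIBRARY_HEADER)
  empty <- !nzchar(raw$ChemicalID) | !nzchar(raw$SMILES)
  if (any(empty)) {
    stop(sprintf("%s line %d: empty ChemicalID or SMILES",
                 path, raw$line[which(empty)[1L]]), call. = FALSE)
  }
  out <- data.frame(chem_id = raw$ChemicalID, name = raw$ChemicalName,
                    smiles = raw$SMILES,
                    source = source, line = raw$line,
                    stringsAsFactors = FALSE)
  attr(out, "source_file") <- path
  out
}

#' Build a fingerprint index over a chemical library
#'
#' Canonicalizes and fingerprints every record. Records whose SMILES cannot
#' be parsed are not indexed; they are reported in `skipped` with a reason
#' and a logged warning. Index order is input order.
#'
#' @param records data frame as returned by [read_chem_library()] (columns
#'   `chem_id`, `name`, `smiles`; optional `source`, `line`).
#' @param fp_type fingerprint family, see [fingerprint()].
#' @return an object of class `chem_index`: list with `records` (indexed
#'   rows), `fingerprints` (aligned list of [bit_fp()]), `fp_length`,
#'   `fp_type` and `skipped` (data frame `chem_id`, `reason`).
#' @export
build_index <- function(records, fp_type = "FP2") {
  fp_type <- match.arg(fp_type, names(FP_LENGTHS))
  stopifnot(is.data.frame(records),
            all(c("chem_id", "name", "smiles") %in% names(records)))
  dup <- duplicated(records$chem_id)
  if (any(dup)) {
    stop("duplicate chemical identifier in library: ",
         records$chem_id[which(dup)[1L]], call. = FALSE)
  }
  if (is.null(records$source)) records$source <- rep("external", nrow(records))
  if (is.null(records$line)) records$line <- seq_len(nrow(records))

  n <- nrow(records)
  canonical <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  # canonicalize once per distinct SMILES string
  for (smi in unique(records$smiles)) {
    idx <- which(records$smiles == smi)
    can <- tryCatch(canonicalize(smi), toxlinker_parse_error = function(e) NULL)
    if (is.null(can)) {
      reason[idx] <- sprintf("unparseable SMILES: '%s'", smi)
    } else {
      canonical[idx] <- can
    }
  }
  ok <- is.na(reason)
  skipped <- data.frame(chem_id = records$chem_id[!ok],
                        reason = reason[!ok], stringsAsFactors = FALSE)
  if (nrow(skipped) > 0L) {
    warning(sprintf("build_index: skipped %d unparseable record(s): %s",
                    nrow(skipped), paste(skipped$chem_id, collapse = ", ")),
            call. = FALSE)
  }
  fingerprints <- vector("list", sum(ok))
  kept <- records[ok, , drop = FALSE]
  rownames(kept) <- NULL
  if (nrow(kept) > 0L) {
    ucan <- unique(canonical[ok])
    ufp <- fingerprint_canonical(ucan, fp_type)
    if (length(ucan) == 1L) ufp <- list(ufp)
    fingerprints <- ufp[match(canonical[ok], ucan)]
  }
  structure(list(records = kept,
                 fingerprints = fingerprints,
                 fp_length = FP_LENGTHS[[fp_type]],
                 fp_type = fp_type,
                 skipped = skipped),
            class = "chem_index")
}

# assemble an index from prebuilt fingerprints (tests, property oracles)
new_chem_index <- function(records, fingerprints, fp_type = "FP2") {
  lens <- unique(vapply(fingerprints, function(f) f$length, 1L))
  stopifnot(nrow(records) == length(fingerprints), length(lens) <= 1L)
  structure(list(records = records, fingerprints = fingerprints,
                 fp_length = if (length(lens)) lens else FP_LENGTHS[[fp_type]],
                 fp_type = fp_type,
                 skipped = data.frame(chem_id = character(0),
                                      reason = character(0))),
            class = "chem_index")
}

#' @export
print.chem_index <- function(x, ...) {
  cat(sprintf("<chem_index> %d compound(s), %s (%d bits), %d skipped\n",
              nrow(x$records), x$fp_type, x$fp_length, nrow(x$skipped)))
  invisible(x)
}

#' Thresholded, capped Tanimoto similarity search
#'
#' Scores every indexed compound against the query fingerprint and returns
#' those at or above the similarity threshold, ranked by score descending
#' with ties broken by chemical identifier ascending, truncated to
#' `max_hits`. A library copy of the query compound itself is a legitimate
#' hit and is not excluded. Defaults mirror the conventional search
#' settings: 50% similarity, at most 100 hits.
#'
#' @param index a `chem_index`.
#' @param query a [bit_fp()] with the index's bit length.
#' @param threshold minimum Tanimoto similarity, inclusive, in `[0, 1]`.
#' @param max_hits cap applied after threshold filtering (top-k).
#' @return data frame of hits: `chem_id`, `name`, `smiles`, `source`,
#'   `line`, `score`.
#' @export
similarity_search <- function(index, query, threshold = 0.5, max_hits = 100) {
  stopifnot(inherits(index, "chem_index"), inherits(query, "bit_fp"),
            threshold >= 0, threshold <= 1, max_hits >= 1)
  if (nrow(index$records) > 0L && query$length != index$fp_length) {
    stop(sprintf("query fingerprint length %d does not match index length %d",
                 query$length, index$fp_length), call. = FALSE)
  }
  scores <- vapply(index$fingerprints, tanimoto, numeric(1), b = query)
  hits <- index$records
  hits$score <- scores
  hits <- hits[hits$score >= threshold, , drop = FALSE]
  hits <- hits[order(-hits$score, hits$chem_id), , drop = FALSE]
  hits <- head(hits, max_hits)
  rownames(hits) <- NULL
  hits
}
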