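# Secondary pharmacology: known off-targets from assay potency data
# (activity profile) and predicted off-targets from per-target Bernoulli
# naive Bayes fingerprint classifiers, one trainable model per target with
# probabilistic output.

ASSAY_HEADER <- c("CompoundID", "GeneSymbol", "AssayType", "Value", "Unit")
ASSAY_TYPES <- c("IC50", "EC50", "Ki")
UNIT_TO_UM <- c(nM = 1e-3, uM = 1, mM = 1e3)

#' Load an in vitro assay potency table
#'
#' Dialect: tab-separated, header
#' `CompoundID  GeneSymbol  AssayType  Value  Unit`, with
#' `AssayType` one of IC50/EC50/Ki and `Unit` one of nM/uM/mM. Potencies
#' are normalized to micromolar; row order is preserved.
#'
#' @param path assay TSV.
#' @return data frame with columns `compound_id`, `gene_symbol`,
#'   `assay_type`, `potency_um`, `line`.
#' @export
load_assay_table <- function(path) {
  raw <- read_tox_tsv(path, ASSAY_HEADER)
  bad_type <- !raw$AssayType %in% ASSAY_TYPES
  if (any(bad_type)) {
    i <- which(bad_type)[1L]
    stop(sprintf("%s line %d: unknown assay type '%s'",
                 path, raw$line[i], raw$AssayType[i]), call. = FALSE)
  }
  bad_unit <- !raw$Unit %in% names(UNIT_TO_UM)
  if (any(bad_unit)) {
    i <- which(bad_unit)[1L]
    stop(sprintf("%s line %d: unknown unit '%s' (expected nM, uM or mM)",
                 path, raw$line[i], raw$Unit[i]), call. = FALSE)
  }
  value <- suppressWarnings(as.numeric(raw$Value))
  bad_value <- is.na(value) | value <= 0
  if (any(bad_value)) {
    i <- which(bad_value)[1L]
    stop(sprintf("%s line %d: potency value '%s' is not a positive number",
                 path, raw$line[i], raw$Value[i]), call. = FALSE)
  }
  out <- data.frame(compound_id = raw$CompoundID,
                    gene_symbol = raw$GeneSymbol,
                    assay_type = raw$AssayType,
                    potency_um = value * UNIT_TO_UM[raw$Unit],
                    line = raw$line,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "source_file") <- path
  out
}

#' Known secondary targets of a compound from assay data
#'
#' Targets where the compound demonstrated an IC50 or EC50 strictly below
#' the potency cutoff (default 10 uM). The primary target is excluded, Ki
#' records are ignored, and multiple qualifying assays per target collapse
#' to the minimum potency (logged). Ordered by that minimum potency
#' ascending, ties by gene symbol.
#'
#' @param records assay table from [load_assay_table()].
#' @param compound_id compound to profile.
#' @param primary_target gene symbol to exclude (the intended target).
#' @param cutoff_um potency cutoff in micromolar, exclusive.
#' @return data frame with `gene_symbol` and the compound's minimum
#'   `potency_um` per target, in rank order.
#' @export
activity_profile <- function(records, compound_id, primary_target,
                             cutoff_um = 10) {
  stopifnot(cutoff_um > 0)
  sel <- records[records$compound_id == compound_id &
                   records$assay_type %in% c("IC50", "EC50") &
                   records$potency_um < cutoff_um &
                   records$gene_symbol != primary_target, , drop = FALSE]
  if (nrow(sel) == 0L) {
    return(data.frame(gene_symbol = character(0), potency_um = numeric(0)))
  }
  collapsed <- table(sel$gene_symbol)
  if (any(collapsed > 1L)) {
    tox_log(sprintf("activity_profile: %s collapsed to minimum potency",
                    paste(names(collapsed)[collapsed > 1L], collapse = ", ")))
  }
  pot <- tapply(sel$potency_um, sel$gene_symbol, min)
  out <- data.frame(gene_symbol = names(pot), potency_um = as.numeric(pot),
                    stringsAsFactors = FALSE)
  out <- out[order(out$potency_um, out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Train a per-target two-class Bernoulli fingerprint classifier
#'
#' One model per target: each fingerprint bit is modelled as a Bernoulli
#' variable per class with Laplace-smoothed conditionals
#' `theta = (count + smoothing) / (n_class + 2 * smoothing)`, and class
#' priors equal to the class frequencies. Smoothing keeps every
#' conditional strictly inside (0, 1) even for bits constant in a class.
#'
#' @param gene_symbol the target the model predicts activity against.
#' @param actives,inactives non-empty lists of [bit_fp()] of one common
#'   length: fingerprints of compounds active / inactive at the target.
#' @param smoothing Laplace pseudo-count, default 1.
#' @return an object of class `target_model` with fields `gene_symbol`,
#'   `fp_length`, `prior_active`, `prior_inactive`, `theta_active`,
#'   `theta_inactive` (per-bit conditional probabilities).
#' @export
train_target_model <- function(gene_symbol, actives, inactives, smoothing = 1) {
  if (length(actives) == 0L || length(inactives) == 0L) {
    stop("need at least one active and one inactive fingerprint", call. = FALSE)
  }
  all_fp <- c(actives, inactives)
  lens <- unique(vapply(all_fp, function(f) f$length, 1L))
  if (length(lens) != 1L) {
    stop("fingerprint length mismatch in training set", call. = FALSE)
  }
  fp_length <- lens
  bit_counts <- function(fps) {
    counts <- numeric(fp_length)
    for (f in fps) counts[f$bits + 1L] <- counts[f$bits + 1L] + 1
    counts
  }
  n_a <- length(actives); n_i <- length(inactives)
  theta_a <- (bit_counts(actives) + smoothing) / (n_a + 2 * smoothing)
  theta_i <- (bit_counts(inactives) + smoothing) / (n_i + 2 * smoothing)
  structure(list(gene_symbol = gene_symbol,
                 fp_length = fp_length,
                 prior_active = n_a / (n_a + n_i),
                 prior_inactive = n_i / (n_a + n_i),
                 theta_active = theta_a,
                 theta_inactive = theta_i),
            class = "target_model")
}

#' @export
print.target_model <- function(x, ...) {
  cat(sprintf("<target_model> %s: %d-bit Bernoulli naive Bayes, prior P(active) = %.3f\n",
              x$gene_symbol, x$fp_length, x$prior_active))
  invisible(x)
}

#' Posterior probability that a compound is active at a target
#'
#' Evaluates the two-class Bernoulli model in log space and returns
#' `P(active | fingerprint)`.
#'
#' @param model a `target_model`.
#' @param fp query [bit_fp()] of the model's bit length.
#' @return probability in `[0, 1]`.
#' @export
predict_probability <- function(model, fp) {
  stopifnot(inherits(model, "target_model"), inherits(fp, "bit_fp"))
  if (fp$length != model$fp_length) {
    stop(sprintf("fingerprint length %d does not match model length %d",
                 fp$length, model$fp_length), call. = FALSE)
  }
  on <- logical(model$fp_length)
  on[fp$bits + 1L] <- TRUE
  class_loglik <- function(prior, theta) {
    log(prior) + sum(log(theta[on])) + sum(log1p(-theta[!on]))
  }
  la <- class_loglik(model$prior_active, model$theta_active)
  li <- class_loglik(model$prior_inactive, model$theta_inactive)
  1 / (1 + exp(li - la))
}

#' Predicted secondary targets of a compound
#'
#' Applies every per-target model to the compound's fingerprint and keeps
#' targets whose activity probability reaches the threshold (inclusive),
#' ranked by probability descending with ties broken by gene symbol.
#'
#' @param models list of `target_model` objects.
#' @param fp query [bit_fp()].
#' @param prob_threshold minimum posterior probability, default 0.5.
#' @return data frame with `gene_symbol` and `probability`, ranked.
#' @export
predicted_targets <- function(models, fp, prob_threshold = 0.5) {
  if (length(models) == 0L) {
    return(data.frame(gene_symbol = character(0), probability = numeric(0)))
  }
  out <- data.frame(
    gene_symbol = vapply(models, function(m) m$gene_symbol, character(1)),
    probability = vapply(models, predict_probability, numeric(1), fp = fp),
    stringsAsFactors = FALSE)
  out <- out[out$probability >= prob_threshold, , drop = FALSE]
  out <- out[order(-out$probability, out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize trained target models to JSON
#'
#' @param models list of `target_model` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_target_models <- function(models, path) {
  doc <- lapply(models, function(m) {
    list(gene = m$gene_symbol, length = m$fp_length,
         prior_active = m$prior_active, prior_inactive = m$prior_inactive,
         theta_active = m$theta_active, theta_inactive = m$theta_inactive)
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load target models from their JSON serialization
#'
#' @param path file written by [save_target_models()].
#' @return list of `target_model` objects.
#' @export
load_target_models <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(doc, function(m) {
    structure(list(gene_symbol = m$gene, fp_length = as.integer(m$length),
                   prior_active = m$prior_active,
                   prior_inactive = m$prior_inactive,
                   theta_active = as.numeric(m$theta_active),
                   theta_inactive = as.numeric(m$theta_inactive)),
              class = "target_model")
  })
}
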