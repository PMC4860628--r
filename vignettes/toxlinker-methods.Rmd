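---
title: "Methods and design of the toxlinker evidence workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the toxlinker evidence workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxlinker)
```

`toxlinker` automates the evidence sweep that opens an investigative
toxicology project: given a compound, its primary pharmacological target
and a description of an adverse finding, it aggregates every local source
of direct and inferred linkage between them and reports the result in six
sections. This vignette documents the underlying models and procedures,
the tunable parameters, the synthetic-data generator, and the design
choices that were genuinely open.

## The workflow

A query names a compound (identifier and, optionally, a SMILES
structure), a primary target gene symbol, and an adverse finding
expressed as an organ, a safety-lexicon finding term and a MeSH disease
descriptor. Execution proceeds in three stages:

1. **Input validation.** The finding triple must be co-mapped in the
   master term map — an organ-anchored table pairing safety-lexicon terms
   with MeSH disease descriptors. Organ selection restricts both
   vocabularies; validation distinguishes an unknown organ, a term not
   mapped to the organ, and a term pair that was never co-mapped.
   Comparison is case-sensitive after whitespace trimming, because both
   vocabularies are controlled and silent aliasing would mask input
   errors.
2. **Compute.** The compound structure is canonicalized and
   fingerprinted; similarity searches run over an external (public,
   MeSH-identified) and an internal (proprietary-identified) library;
   assay potencies and per-target classifiers yield known and predicted
   secondary targets.
3. **Cross-check and report.** Every secondary target and similar
   compound is checked against the knowledge graph for links to the query
   disease term; internal similarity hits are checked against the study
   findings table; the primary target additionally gets a gene-evidence
   scoreboard. All six sections are always present, each entry carrying
   provenance (source file and line, or model key).

The report is a pure function of the data bundle and the query: two runs
render byte-identical JSON.

## Structures, fingerprints and similarity

SMILES canonicalization and fingerprinting are delegated to OpenBabel
through ChemmineOB/ChemmineR. The default fingerprint is **FP2**, a
hashed linear-fragment (path) fingerprint of fixed width 1024 bits. The
package treats the fingerprint family as a configurable parameter
(FP2/FP3/FP4/MACCS) with two contracts: determinism across runs, and
canonical invariance (two SMILES spellings of the same structure yield
identical bit sets). FP2's 1024-bit width was adopted as the package
default because it is the widest hashed-path family OpenBabel provides at
fixed width; nothing downstream depends on the width, since all scoring
is ratio-based.

Similarity is the Tanimoto coefficient over set bits, with three
deliberately pinned conventions:

* the threshold comparison is **inclusive** (`score >= threshold`), so a
  hit exactly at the default 50% boundary remains visible;
* the hit cap (default 100) applies **after** threshold filtering —
  it is a top-k of qualifying hits, not a scan budget;
* ties are broken by chemical identifier ascending, making ranked output
  deterministic; and a library copy of the query compound is never
  excluded, since a self-match carrying curated disease links is itself
  evidence.

Two all-zero fingerprints score 0 by convention (similarity between
featureless structures is not evidence of anything).

## The knowledge graph and the recomputed inference

Relationship files use the Comparative Toxicogenomics Database download
dialect (tab-separated, `#` comments, `|`-delimited multi-values). Every
row is classified by its `DirectEvidence` token: `marker/mechanism`,
`therapeutic`, or — when the token is empty and an inference intermediate
is named — `inferred`. An empty token with no intermediate violates the
evidence model and is rejected with its line number rather than guessed
at.

Precomputed inference scores in input files are passed through verbatim.
Independently, the package recomputes inferred gene–disease associations
and labels them as recomputed in the report: the intermediates are the
chemicals that both interact with the gene and hold direct
marker/mechanism evidence for the disease, and the association is scored
`-log10` of an upper-tail hypergeometric probability with population N =
the number of distinct chemicals in the chemical–gene table, K = the
gene's partner count, n = the disease's direct-M chemical count, k = the
overlap. Numerical notes:

* the tail is computed exactly via `stats::phyper` (no normal
  approximation); `P(X >= 0) = 1` by definition;
* the disease-side count n is restricted to chemicals present in the
  chemical–gene universe. A chemical with curated disease evidence but no
  recorded gene interactions lies outside the sampling population of the
  test, and counting it could make n exceed N;
* only marker/mechanism evidence seeds intermediates — a therapeutic
  relationship between a chemical and a disease is evidence of treatment,
  not of a toxicity mechanism;
* an empty intersection returns no association at all rather than a
  score of zero, mirroring how curated inferred rows only exist when an
  intermediate exists.

Chemical–disease inference in the opposite direction (via shared genes)
is not recomputed; curated inferred chemical–disease rows are passed
through. This keeps the recomputation confined to the one direction the
report's primary-pharmacology section needs.

## Secondary pharmacology

**Known off-targets.** The activity profile admits assay records of type
IC50 or EC50 with potency strictly below the cutoff (default 10 µM,
matching the conventional screening threshold; the strict inequality
keeps a potency of exactly 10 µM out). Ki records are excluded: binding
affinity without a functional direction is not treated as demonstrated
activity here. Potencies are normalized to micromolar from nM/µM/mM at
load time. When several qualifying assays exist for one target they
collapse to the minimum potency, with a log message so the collapse is
never silent; the profile is ordered by that minimum, ties by symbol. The
primary target is excluded — it is reported by its own section.

**Predicted off-targets.** One trainable classifier per target, a
two-class Bernoulli naive Bayes over fingerprint bits:

$$\theta_{b,c} = \frac{n_{b,c} + s}{n_c + 2s}, \qquad
P(\text{active} \mid f) \propto \pi_a \prod_b
\theta_{b,a}^{f_b} (1-\theta_{b,a})^{1-f_b}$$

with Laplace smoothing `s = 1` (keeping every conditional strictly inside
(0, 1) even for bits constant in a class) and class-frequency priors,
evaluated in log space. The model count and the target identities come
entirely from the training data — nothing is hard-coded. The default
reporting threshold is a posterior of 0.5, inclusive, configurable per
query.

A property worth knowing about this family: with very small and
*unbalanced* classes, the smoothing pseudo-counts on the many unset bits
systematically favor the larger class (each unset bit contributes
`log(1 - s/(n_c + 2s))`, which is closer to zero for larger `n_c`). The
worked-example bundle therefore trains its models with balanced classes
(one analog series as actives, one other series as inactives). At
realistic training sizes (hundreds per class, as in the parameter-recovery
tests) the effect is negligible.

## The gene evidence scoreboard

The five-source evidence table is a generic stand-in for institutional
integrations (OMIM-style disease genetics, mouse phenotype, Gene
Ontology, literature, tissue expression): those are services, not
algorithms, and the table preserves exactly what the report consumes —
per-source flags with citations. The summary score is a **relative
link-count percentile**: 100 × (number of genes in the table whose link
count for the term does not exceed the query gene's) / (number of genes).
The `<=` rule means the best-linked gene always scores 100 and tied genes
share a score; the percentile is computed globally over the table rather
than within organ, since the evidence table carries no organ structure.
A gene absent from the table scores as a zero-link gene; an empty table
is an error for scoring (there is no population) but still yields
all-absent flags in the report.

## The synthetic-data generator

All inputs are generated, none downloaded. The generator emulates:

* **analog series** — invented SMILES built from a per-series scaffold (a
  carbocycle plus a linker with a series-specific heteroatom) and one
  terminal substituent per member, so within-series Tanimoto similarity
  exceeds between-series similarity; random singletons are linear chains
  over C/N/O/S, valence-safe by construction;
* **planted chains** — each (chemical, gene, disease) triple is realized
  as one chemical–gene row plus direct marker/mechanism chemical–disease
  and gene–disease rows, a sub-cutoff IC50 assay row, an evidence row and
  a study finding, so every workflow can recover it;
* **noise** — random extra relationship rows at a configurable density
  (default 0.2 of total rows), never colliding with planted keys.

Planted content is seed-independent; only noise and the random singleton
structures derive from the seed, so regeneration with a new seed
perturbs the background but never the signal. The worked-example bundle
is fully deterministic (byte-identical on every call) and reproduces the
statin–myolysis linkage topology — a directly linked primary target, a
self-matching public compound with a direct chemical–disease link, a
sub-10 µM transporter off-target with a direct gene–disease link — using
invented structures, because the investigation it mirrors prints no
structures and embedding real drug structures would add nothing the
workflow tests.

What the generator does **not** emulate: realistic potency distributions
(values are chosen, or log-uniform, not assay-calibrated), chemical-space
diversity beyond small chains and rings, curation noise (conflicting
evidence for one pair), or ontology structure in the disease vocabulary.
Passing tests on these fixtures therefore demonstrate the correctness of
the aggregation and statistics, not predictive performance on real
chemistry.

The classifier benchmark is a separate generator: actives share a planted
block of informative bits (present with probability 0.9 in actives, 0.1
in inactives) over a sparse background (0.1 everywhere). With 200
compounds per class, a model trained on half recovers the signal with
held-out AUC ≥ 0.9 and outranks ≥ 95% of label-shuffled decoy models —
the package's parameter-recovery check, run at these sizes because they
are the smallest at which the benchmark is stable across seeds.

## Persistence and determinism

Queries serialize to single JSON documents in a store directory; every
save assigns a fresh identifier (content hash + timestamp + counter), so
saving twice yields two entries — reruns are first-class, and a rerun
against an updated bundle reflects the new content. Corrupt store
documents are skipped with a warning rather than failing the listing.

Determinism is treated as a contract throughout: fingerprints and
canonicalization are deterministic, search ties are broken
lexicographically, report JSON has stable key order, and fixtures are
byte-identical per seed. The test suite checks these properties directly.

## Known limitations

* The recomputed enrichment is a standard shared-partner hypergeometric
  test, not the published inference statistic of any external database;
  recomputed scores are labelled as such and precomputed scores pass
  through unchanged.
* No ontology traversal: MeSH descriptors are opaque identifiers, so a
  query for a broader disease term will not match rows curated to a
  narrower one.
* Fingerprints are 2D substructure hashes; stereochemistry and 3D shape
  do not contribute to similarity.
* The evidence scoreboard scores relative to the genes present in the
  supplied table; a sparsely populated table inflates percentiles.
* Problem sizes in the shipped tests and benchmarks are desk-scale
  (libraries ≤ 500, universes ≤ 200, 400 training fingerprints), chosen
  as the smallest sizes at which the statistical properties under test
  are stable.
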