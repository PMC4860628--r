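# toxlinker

Evidence aggregation for investigative toxicology hypothesis generation.

When a preclinical toxicology study turns up a serious adverse finding, an
investigative toxicologist typically starts with three pieces of
information: the structure of the compound, its intended pharmacological
target, and a description of the finding. `toxlinker` automates the
first-pass evidence sweep that follows, aggregating direct and inferred
links between the compound, its structural analogs, its known and predicted
secondary targets, and the adverse finding — and renders the result as a
six-section hypothesis report. It is aimed at safety scientists and
computational toxicologists who want a reproducible, file-based version of
this workflow that runs entirely on local tab-separated inputs.

## What it computes

**Structural similarity.** Compounds are canonicalized and encoded as
hashed binary substructure fingerprints (OpenBabel FP2, 1024 bits, via
ChemmineR/ChemmineOB). Library searches use the Tanimoto coefficient

    T(A, B) = |A ∩ B| / |A ∪ B|

over set bit positions, with an inclusive threshold (default 50%), a
post-filter cap on hits (default 100), and deterministic tie-breaking by
chemical identifier. The query compound matching itself in a public
library is a legitimate — and informative — hit.

**Knowledge-graph links.** Chemical–disease, gene–disease and
chemical–gene relationships are read in the Comparative Toxicogenomics
Database flat-file dialect. Each curated assertion is classified as direct
marker/mechanism (M), direct therapeutic (T), or inferred via a named
third partner. In addition to passing through precomputed inference
scores, the package recomputes inferred gene–disease associations from
shared chemical partners with an upper-tail hypergeometric enrichment: for
a gene with K chemical partners, a disease with n direct-M chemicals, and
k shared between them in a universe of N chemicals,

    score = −log10 P(X ≥ k),  X ~ Hypergeometric(N, K, n)

Only marker/mechanism evidence seeds intermediates; therapeutic links are
not treated as toxicity mechanism evidence.

**Secondary pharmacology.** Known off-targets come from an assay potency
table: targets with an IC50 or EC50 strictly below 10 µM (Ki excluded),
minus the primary target. Predicted off-targets come from per-target
two-class Bernoulli naive Bayes classifiers over fingerprint bits with
Laplace smoothing, θ = (count + s)/(n + 2s), reporting the posterior
P(active | fingerprint); targets at or above probability 0.5 are reported.

**Gene evidence scoreboard.** A five-source evidence table (OMIM-style
disease genetics, mouse phenotype, Gene Ontology, literature, tissue
expression) yields per-source flags plus a summary score: the percentage
of genes in the table whose link count for the disease term does not
exceed the query gene's (a percentile, 0–100).

## Worked example

The package ships a deterministic worked-example generator that mirrors
the classic statin–myolysis investigation topology with invented analog
structures and real gene symbols (the query compound `PF-0000001`
"toxstatin", primary target HMGCR, adverse finding myolysis / Muscular
Diseases `MESH:D009135`):

```r
library(toxlinker)
paths  <- worked_example("example_bundle")
bundle <- load_bundle(paths$config)
report <- run_query(bundle, worked_example_query())
cat(render_report(report, "markdown"))
```

Selected output (abridged):

```
## Polypharmacology (predicted secondary targets)
- HMGCR (P(active) = 1.000) — direct marker/mechanism: 1, ... [refs: 20000003]
- SLCO1B1 (P(active) = 1.000) — direct marker/mechanism: 1, ... [refs: 20000004, 20000005]

## Activity Profile (known secondary targets)
- SLCO1B1 (min potency 0.5 uM) — direct marker/mechanism: 1, ...
- CYP3A4 (min potency 9.5 uM) — direct marker/mechanism: 0, ...

## External Compound Similarity
- MESH:C000001 (toxstatin, similarity 100.0%) — direct marker/mechanism: 1, ...
- MESH:C000002 (toxstatin analog 2, similarity 80.8%) — direct marker/mechanism: 1, ...

## CTD Gene-Disease Association (primary target)
- HMGCR — direct marker/mechanism: 1, ...; recomputed inferred score 1.740
  via MESH:C000001, MESH:C000002

## ToxReporter (gene evidence flags and summary score)
- HMGCR — flags: omim, mouse_phenotype, literature; 3 link(s), summary score 100.0/100
```

Reading the report: the primary target carries a directly curated
marker/mechanism link to the disease term (and a recomputed shared-partner
enrichment of 1.740, i.e. p ≈ 0.018); the compound's public twin matches
itself at 100% similarity and is itself directly linked to the finding; a
sub-10 µM transporter off-target (SLCO1B1, 0.5 µM) is directly linked as
well — together the direct (via the compound) and indirect (via SLCO1B1)
threads that such an investigation is meant to surface. Internal
similarity hits additionally carry matching study findings and an alert
flag when *any* adverse finding is on record for the analog.

A thin command-line front end wraps the same functions:

```sh
exec/toxlinker fixtures worked-example --out example_bundle
exec/toxlinker run --config example_bundle/config.json \
    --compound-id PF-0000001 --target HMGCR \
    --organ muscle --lexicon-term myolysis --mesh-id MESH:D009135 \
    --format markdown --save
exec/toxlinker queries list
```

Queries are persisted as JSON documents and can be rerun with
`rerun_query()` (or `toxlinker queries rerun <id>`) as the underlying
tables are updated.

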