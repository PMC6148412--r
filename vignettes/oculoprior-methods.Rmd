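---
title: "Phenotype-driven variant prioritization: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-driven variant prioritization: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculoprior)
```

## The problem

Exome sequencing of a small high-myopia cohort yields tens of thousands of
variant calls per patient, while the expected number of causal alleles is
on the order of one per patient. A genome-wide association or burden test
is hopeless at this sample size, so the strategy implemented here trades
discovery breadth for prior-driven precision: a variant is only considered
a candidate when it is simultaneously *rare*, *predicted damaging*, and
located in a gene with *independent phenotype evidence* for eye disease —
either a known high-myopia gene or an ocular-disease gene lying inside a
myopia (MYP) linkage interval. This vignette records the models behind
each stage, the tunable parameters with their defaults and rationale, what
the synthetic data do and do not emulate, and the design choices that were
genuinely open.

## Consensus calling

Callers disagree substantially on indels and on genotypes; requiring a
site to be reported by at least `min_callers = 2` of 4 callers suppresses
caller-specific artifacts at modest sensitivity cost. Two choices were
open and are worth recording:

- **Site-level, not genotype-level agreement.** Callers disagree on
  genotype far more than on site, and no genotype-concordance rule is part
  of the method being implemented. Agreement is therefore evaluated on the
  normalized variant key only; the consensus genotype is the modal
  genotype of the supporting callers, with ties resolved to `het` — the
  conservative choice for downstream reporting that is centred on
  heterozygous candidates.
- **Exact normalized-key matching for indels.** Keys are made parsimonious
  (shared suffix trimmed, then shared prefix, keeping one anchor base), so
  equivalent representations collide; no fuzzy positional window is used,
  keeping the operation deterministic and testable. Full left-alignment
  against the reference sequence is out of scope because the pipeline
  never loads a reference genome.

## The filter cascade

Stages are conjunctive; the retained set is the intersection of four
predicates, so stage order cannot change membership, only the stage to
which a rejection is attributed (we attribute it to the first failing
stage in the order frequency → impact → phenotype-gene → dominant
exclusion). Parameters, all exposed in `cascade_config()`:

| parameter | default | units | rationale |
|---|---|---|---|
| `max_af_threshold` | 0.005 | allele frequency | rare-variant cutoff applied to the maximum over 1000G/ExAC/ESP; read as inclusive (≤), the standard convention; absence in all three databases counts as 0 |
| `min_pathogenic_votes` | 6 | votes (of 8) | pathogenicity consensus across the fixed panel SIFT, PolyPhen2, LRT, MutationTaster, MutationAssessor, FATHMM, CADD, DANN |
| `panel_size` | 8 | tools | the vote denominator is the panel, not the available predictions: a missing prediction is a non-pathogenic vote (conservative) |
| `splice_score_threshold` | 0.6 | score in [0,1] | splice-region variants count as LoF when an adaptive-boosting splice impact score reaches 0.6, that score's published recommended cutoff; the method class, not a specific cutoff, is inherent to the approach, so the threshold is config-exposed |
| `min_callers` | 2 | callers | consensus support required upstream |
| `apply_dominant_exclusion` | TRUE | — | see below |

Frameshift, stop-gained and canonical splice-site variants bypass the
predictor vote entirely — the in-silico missense panel is meaningless for
them. Zygosity is reported but never filtered on: single heterozygotes in
recessive genes are retained as risk candidates, which matches how the
candidate table treats AR genes, and makes the cascade deliberately
inclusive; compound-heterozygote phasing and segregation analysis are out
of scope.

The **phenotype-gene stage** needs two facts per gene: membership in the
evidence table (58 known high-myopia genes and 651 further ocular-disease
genes assembled from HPO's myopia phenotype term, RetNet, and OMIM — the
two classes partition their union, with "known" taking precedence) and QTL
membership. QTL membership is evaluated **at the variant position**, not
from gene annotation: this matches how candidates are assigned to loci in
the motivating cohort and removes the need for a gene-model file. Interval
queries run on a `GenomicRanges` index; a property test keeps the index
honest against a naive linear scan.

The **dominant-exclusion stage** encodes a clinical-review rule as a
transparent computation: if a gene carries a dominant OMIM ocular-disease
label and none of that disease's characteristic phenotype terms appear
among the carrier's phenotype terms, a dominant pathogenic allele is
implausible and the variant is excluded. Matching is term-set intersection
on curated labels supplied in configuration — deliberately no ontology
reasoning, so every exclusion is auditable from the decision trail.

Carrier-count allele frequencies use the heterozygote identity
AF = n_het / (2 · n_individuals); `maf_from_het_count()` keeps the raw
value and rounds to 2 significant figures only for display.

## Enrichment

`hypergeom_upper(k, K, n, N)` is the exact upper tail
P(X ≥ k), X ~ Hypergeom(N, K, n), evaluated in log space through the
distribution's survival function; an exhaustive enumeration over all
C(20,5) draws pins it down in the tests. BH adjustment is applied **per
namespace** (BP/MF/CC/pathway), matching how per-namespace term panels are
usually reported. Two conventions matter and are deliberate:

- `N` and `n` count only genes with at least one annotation in the
  namespace under test; unannotated genes otherwise deflate every p-value.
- No ancestor propagation over the term hierarchy: annotations are used as
  given. Whether the original analysis propagated is unknown; off is the
  assumption-free default and closure is a config-level concern.

`unique_terms()` contrasts two analyses by set difference on their
significant term sets. A subtlety worth recording: when the candidate set
is a subset of the comparison set, a term annotating *only* the candidates
is significant in **both** analyses; candidate-unique terms arise in
practice because their gene sets extend well beyond the phenotype list,
so the larger analysis sees an unremarkable overlap. The synthetic
fixtures for this operation plant exactly that structure.

## Expression analysis

RNA-seq matrices are transformed as log₂(RPKM + 0.001); the pseudocount
preserves zeros at a finite floor (≈ −9.97) and the transform is exactly
invertible, which the tests verify. Microarray matrices are already on a
normalized log-like scale and pass through.

The set-vs-rest test had one genuinely open choice: the unit of
replication. We test **per-gene means within a tissue** with a one-sided
Welch t-test (set > rest), because genes are the exchangeable units when
the claim is about a gene *set*, and Welch avoids assuming equal
variances between a 700-gene set and an 18,000-gene rest. Testing
per-sample values instead would treat correlated samples as independent
replicates and overstate significance. The null behaviour of the chosen
test is calibrated by simulation (type-I rate ≈ 5% and uniform p-values
under random gene sets).

Heatmap ordering uses correlation distance (1 − Pearson r) with average
linkage — the common heatmap default; rows and columns are sorted by name
before clustering so the leaf order is reproducible regardless of input
order (the deterministic tie rule).

The per-gene tissue class is an operationalization of a qualitative
reading of expression profiles, and its thresholds are inventions, not
inherited values: `retina_high` when mean(retina)/mean(sclera) ≥ 2 on the
linear scale, `retina_and_sclera` when both means exceed the matrix
median. Both knobs are arguments of `tissue_class()`.

## Network analysis

The FI subnetwork joins candidate genes through **linker genes**: for
every candidate pair at shortest-path distance ≤ `max_path_len = 2` in the
parent network, all intermediate nodes of all shortest paths are inserted;
the subnetwork is the induced subgraph on candidates ∪ linkers. The
original tool's linker algorithm is not published in algorithmic detail;
shortest-path insertion with a length cap reproduces the observed
behaviour ("scattered candidates joined by hub-like linkers")
deterministically, and the cap is config-exposed. A BFS oracle over all
candidate pairs verifies the implementation on random graphs.

Module detection is greedy (CNM-style) modularity maximization — chosen
for determinism and the absence of a tunable module count. One numerical
fix proved necessary: the fast-greedy dendrogram in `igraph` is cut at its
own recorded maximum, which can leave a spurious split when the final
merge changes Q by ≈ 0 (a complete graph is the minimal example). We
rescan all cut levels, take the maximum-modularity partition, and resolve
ties toward fewer modules; vertices are processed in lexicographic name
order so the partition is reproducible. The module count on any real FI
network snapshot is a property of that snapshot; it is reported, never
asserted.

Each module's principal process is the lowest-FDR biological-process term
from a per-module enrichment run. Switching the background from the
genome universe to the eye-disease gene list asks a sharper question —
what distinguishes a module *beyond being eye-related at all* — and
typically demotes broad vision terms, which the tests demonstrate on a
constructed fixture.

## What the synthetic data emulate — and what they do not

`generate_cohort()` produces the full input bundle under the study's
conditions: 20 patients, 4 callers with 2-of-4 consensus, a 58 + 651 gene
evidence list, 26 QTL intervals, and a configurable number of planted true
candidates (default 20) and decoys. Decoys each violate **exactly one**
criterion — common allele frequency, insufficient votes, non-eye gene,
ocular gene outside every QTL, dominant-phenotype mismatch, or
single-caller support — so every rejection path is independently
decidable, and the cascade's recovery is exact by construction (verified
over 20 seeds). Annotation values not fixed by the design are drawn at
the weakest levels consistent with their role (e.g. true candidates are
absent from the frequency databases or below threshold).

`generate_expression()` plants a +2 SD shift of the 709-gene eye set in
the eye tissues over a log-normal baseline, and noise-free per-gene
tissue profiles for the class-recovery checks (the planted profile *is*
the class definition; leaving sampling noise in the profiled tissues
would make "100% recovery" a coin flip at the class boundary).
`generate_network()` draws a 4-block planted-partition graph
(p_in = 0.8, p_out = 0.05, 15 nodes per block).

Passing these tests shows the machinery is correct and calibrated under
its stated model; it does **not** show that real cohorts satisfy the
model. In particular the synthetic data have no linkage disequilibrium,
no caller-specific error profiles, no annotation errors, independent
genes in the expression model, and planted-partition rather than
scale-free network topology. Results that depend on external database
snapshots — exact GO term lists, specific linker genes such as EP300 or
CTNNB1, the four-module split of the real FI network, raw per-sample
variant counts — are inherently not reproducible from this package and
are covered by property tests instead.

## Problem sizes used in the test suite

The shipped tests run the expression claim at full scale (19,000 genes,
709-gene set) once, and use reduced sizes elsewhere — cohorts with 5–30
background variants per patient, 2,000–5,000-gene universes for
enrichment calibration, 1,000-replicate null simulations — chosen so the
whole suite exercises every property at comfortable statistical power
while remaining quick to run on a laptop. All sizes are arguments, not
constants.

## Known limitations

- The cascade treats the annotation table as ground truth; predictor
  binarization (e.g. how "possibly damaging" calls were mapped) must be
  done, and documented, by the data preparer.
- Whether the frequency cutoff should apply to sub-population rather than
  global AFs is unspecified in the method; the implementation takes the
  maximum over whatever frequency columns are provided.
- Hemizygous male X calls are preserved as given (`hemi` when the GT is
  haploid); no ploidy correction is attempted.
- No compound-heterozygote, segregation, or ACMG logic: the output is a
  prioritized candidate list, not a clinical classification.
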