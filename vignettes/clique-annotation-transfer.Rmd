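---
title: "Ortholog-clique-based GO annotation transfer: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ortholog-clique-based GO annotation transfer: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cliqueGO)
```

## The problem and the model

Annotation transfer from a single pairwise ortholog call inherits every
error of that call. cliqueGO instead requires *cliques*: sets of genes,
one per species, that are pairwise 1-to-1 orthologs under **two**
independent lines of evidence (DNA and protein reciprocal best hits,
intersected). A clique of size k is a k-way mutual agreement, and the
number of species in a gene's largest clique (its Ortholog Clique
Level, OCL) grades how broadly conserved the gene is.

Given cliques, annotation transfer is a three-step procedure for a
chosen target species:

1. every GO term directly annotated to any clique member becomes a
   candidate for the clique's target gene;
2. each candidate is scored by the phylogenetically weighted sum
   `GO_score(go, c) = sum_i delta(go, i) / G_score(i)`, where
   `delta(go, i)` indicates whether species *i*'s clique gene carries
   the term directly, and `G_score(i)` is an integer group score (1 =
   the target's own proximity group, 6 = most distant). Candidates at
   or above the threshold `G_T = 0.5` survive;
3. surviving candidates are refined against the GO DAG so that only
   terms adding specificity are accepted.

The key assumptions are: orthologs retain function (so annotation is
transferable at all); direct annotations are the evidence — no
ancestor propagation is applied before either the overlap statistic or
the score, since propagation would inflate both uniformly; and
phylogenetic proximity, not annotation quality, is the right weight
for a donor species.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| e-value cutoff | 1e-5, inclusive | BLAST e-value | conventional RBBH stringency; inclusive so a hit exactly at the cutoff counts |
| minimum clique size | 3 | species | a pair is just the RBBH call again; three species is the smallest mutual corroboration |
| group scores | 1–6 per species | — | integer proximity classes; the ten-plant wheat configuration ships as `defaultPlantGroups()` |
| score threshold `G_T` | 0.5, inclusive | score | one annotation in a group-2 species (a close relative of the target) contributes exactly 1/2, and that single close witness is deemed sufficient; the threshold is inclusive precisely so this case passes. A strict mode is available |
| clique mode | maximal | — | see below |

Under the default ten-species configuration the attainable score bound
is `sum(1/G) = 4.3166667` (printed as 4.32), and an original term of a
target gene always scores at least 1, the target's own contribution.

## Numerical and structural choices

**Maximal vs all cliques.** Every non-maximal clique is contained in a
maximal one and contributes no candidate term or score its superset
does not; enumerating all cliques only inflates output
combinatorially. The default therefore reports maximal cliques, with
`mode = "all"` available for compatibility with solvers that emit
every clique. Per-gene OCL (the *maximum* clique size over
memberships) is identical between modes. Enumeration itself is
delegated to igraph's exact clique routines; an exhaustive
subset-enumeration oracle in the test suite verifies both modes on
randomized multipartite graphs (by default 100 graphs of up to ~15
nodes, a size at which the 2^n oracle is still exact and fast).

**"Deeper or on a different path."** Acceptance in step 3 is defined
by the ancestor *relation*, not by numeric depth: a candidate is
accepted iff it is not an original term and not a proper ancestor of
one. Numeric depth is ambiguous in a DAG (shortest vs longest root
path); the ancestor relation is not, and it is what "adds specificity"
means operationally. Numeric path length — the *shortest* parent-path
to the namespace root, the common convention — is computed only for
reporting the depth distribution of accepted terms.

**Namespace roots.** A root is a placeholder; it is accepted only when
the gene has no original annotation in that namespace. This rule takes
precedence over the generic ancestor test so that a gene whose only
annotation in a namespace is an obsolete (hence parentless) term still
refuses the root.

**Obsolete terms.** Retained in the parsed DAG, flagged, and never
silently accepted: a candidate hitting one is `flagged-obsolete`, and
only with `resolveObsolete = TRUE` does its `replaced_by` pointer
re-enter the candidate set. Transfer of an obsolete term is recorded
rather than counted as enrichment.

**Empty term sets.** The overlap statistic divides by the smallest
member set; if any member is unannotated the overlap is defined as 0 —
an unannotated member offers no supporting evidence, and this keeps
the statistic consistent with the random-clique null, which is
dominated by zeros.

**Ties and collisions.** Best-hit selection breaks ties by bitscore,
then e-value, then lexicographic subject id; multiple HSP rows per
(query, subject) collapse to the best-bitscore row first; longest-
transcript selection breaks length ties to the smallest transcript id.
When a target gene sits in several cliques, per-(gene, term) records
are unioned keeping the maximum score. All of these make byte-identical
reruns possible, which the pipeline tests assert.

**Reported precision.** Scores are rounded to 2 decimals in written
outputs only; comparisons and stored values keep full precision.

## What the synthetic generator emulates — and what it does not

`scenarioSpec()` defaults describe the study shape the package was
built around: 10 species under the wheat group-score configuration,
one planted clique at each size 3–10, 20 background genes per species,
a three-namespace ontology of depth 3 and branching 3, background
annotation density 0.3, and a 0.1 decoy-hit rate. Planted clique
members are unique mutual best hits with e-values log-uniform in
[1e-50, 1e-10]; decoys are either sub-threshold (e-values in [1e-4, 1])
or significant but non-reciprocal, so recovery of exactly the planted
pairs is guaranteed by construction, and the tests assert it.

Planted cliques span the target plus its k−1 phylogenetically closest
species (smallest group scores first). This is a deliberate guarantee,
not a sample: it ensures every planted transferable term clears the
0.5 threshold, so the planted truth is recoverable by design and any
failure to recover it is an implementation defect, not bad luck.
Each clique carries its transferable terms (leaves, absent from the
target) on all non-target members; cliques in "annotated" target mode
additionally share common leaf terms across *all* members — these
drive the overlap statistic of well-formed cliques above the null —
and give the target a parent of a transferable term, exercising the
deeper-than-original acceptance.

What passing these tests shows is that the machinery is exact:
recovery, scoring and refinement behave as specified under inputs with
known truth. What it does not show is robustness to the features of
real data the generator omits: many-to-many homology and recent
paralogy (decoys here are never reciprocal; real paralogs can be),
annotation errors and evidence-code heterogeneity in the donor
species, fragmented gene models, and GO releases far larger and less
regular than the generated ontologies. Genome-scale counts from real
downloads are outside what the synthetic scenarios can reproduce.

## Problem sizes in the shipped suites

Test scenarios use the default 10-species spec (~52 planted-clique
genes plus 200 background genes, ~1,400 similarity rows), 100
random graphs for the enumeration oracle, 25 random DAGs (≤ 50 terms)
for the ancestor oracle, and 320 random pseudo-cliques for the null
concentration check — sizes at which the exhaustive oracles remain
exact while the full suite runs in well under a minute.

## Known limitations

- Only 1-to-1 orthology is used; genes whose orthology is genuinely
  many-to-many never enter a clique and cannot be annotated by this
  route.
- Group scores are integers per species, a coarse proxy for
  phylogenetic distance; branch lengths are not used.
- `is_a` and `part_of` are treated identically; regulates-type
  relations are ignored, matching go-basic usage but losing whatever
  specificity those edges carry.
- The random-clique null draws species subsets uniformly for k < N;
  the original procedure's subset choice for sub-maximal sizes is not
  specified anywhere, so this is a documented stand-in. Gene pools for
  the null are the annotated genes the pipeline has seen, which
  slightly *raises* the null overlap relative to pools that include
  unannotated genes — a conservative direction.
- Candidate scores are computed per clique; evidence is never summed
  across cliques (the maximum is kept), so multi-clique corroboration
  is deliberately not rewarded twice.
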