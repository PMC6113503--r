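---
title: "Tracking Gene Ontology annotation histories and enrichment stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking Gene Ontology annotation histories and enrichment stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gochrono)
```

## The problem

The Gene Ontology and its annotation corpus are revised monthly. A gene
set that was "enriched for DNA repair" in 2006 was tested against a
different ontology and a different annotation set than the same gene
list tested today, and there is no guarantee the headline terms
survive. `gochrono` treats the GO/GOA release stream as first-class
data: dated editions go in, historical statistics and time-anchored
enrichment results come out, and a permutation null decides whether two
results separated by years are still more alike than chance.

## The edition model

An **ontology edition** is one dated DAG. Only `is_a` and `part_of`
edges are kept: these are the relations along which annotation
inference is sound under the true-path rule, and historical release
files exclude cross-aspect links anyway (we additionally enforce this
at parse time). Obsolete terms are retained as markers but stripped of
edges; annotations pointing at them are dropped with a logged count,
the conservative reading when no replacement term is on record.
Secondary (`alt_id`) accessions resolve to their primary term, because
the annotation files often lag a rename by a few editions.

An **annotation edition** is one species' direct gene–term records at
one date. Records carrying a `NOT` qualifier are excluded (they assert
absence, and every counting statistic here presumes positive
annotation). Records are unique up to (accession, term, evidence):
repeated rows differing only in reference collapse. Gene identifiers
are rewritten through the secondary-to-primary accession table
(`parse_secondary_mapping()`), with chains collapsed to the terminal
primary and a hard error on genuinely ambiguous secondaries; unknown
accessions pass through, since most identifiers are already primary.

Each annotation edition is paired with the ontology release **closest
at or before** its date (`match_ontology()`) — an annotation file can
only have been curated against an ontology that already existed. Note
the contrast with the **nearest-edition** rule (`nearest_edition()`)
used to anchor a hit list's t0 at its publication date, which minimizes
absolute distance and breaks ties toward the earlier edition; the two
rules serve different questions and both are implemented as stated.

Propagation materializes, per gene, the reflexive transitive closure of
its direct terms. `gene_to_direct ⊆ gene_to_propagated` holds by
construction and is property-tested against a brute-force reachability
oracle on random DAGs.

## Historical statistics

* `gene_count_series()` — direct or propagated term counts per edition,
  with the taxon mean over *annotated* genes as overlay. (Averaging
  over all known genes would conflate annotation change with catalogue
  growth; annotated genes are the population the other statistics use.)
* `semantic_similarity_series()` — Jaccard index of the gene's term set
  at each edition against a reference edition. Both-sets-empty is
  defined as 1: an unannotated gene has not changed. The default uses
  direct annotations, where churn is actually visible; propagation
  smooths it away.
* `multifunctionality()` — `MF(g) = Σ_t 1/(n_t (N − n_t))` over the
  gene's propagated terms. The weight is the reciprocal of the number
  of ways to split the annotated genome into "has t" / "lacks t", so
  terms near half-coverage carry the least specificity per gene and
  universal terms (n_t = N) carry none. A rank-normalized score in
  [0, 1] is exposed for cross-edition comparison, since the raw scale
  drifts with N.
* `term_gene_count_series()` — genes per term, direct or propagated,
  optionally split automatic/curated. A gene counts as *curated* when
  any direct record at or beneath the term is non-IEA; curation
  precedence keeps the two categories a partition.
* `species_trends()` — per edition: annotated genes, mean direct and
  mean propagated annotations per gene, and mean propagated genes per
  term over terms with at least one annotated gene (terms nobody uses
  would otherwise make the statistic a function of ontology size).
* `annotation_rank_stability()` — Spearman correlation (average ranks
  on ties) of per-gene direct counts between two editions, the measure
  of whether annotation inequality persists.

## Enrichment anchored in time

`run_enrichment()` is a deliberately plain overrepresentation test:
hypergeometric upper tail P(X ≥ k) for each term, Benjamini–Hochberg
step-up over the tested terms, significance at q ≤ 0.05. Defaults
follow standard practice for real GOA corpora: Biological Process only,
term size 20–200 genes. Design points worth stating:

* The background is the set of all annotated genes at that edition and
  is not user-settable; hit-list genes outside it are dropped (the urn
  model requires the sample to come from the urn), with an
  `empty-overlap` error distinct from "no significant terms".
* Term size K counts **propagated** genes by default (`term_size_mode`
  switches to direct): propagated coverage is what "genes annotated
  with the term" means everywhere else in the package.
* BH is applied after the size/aspect filter, over exactly the tested
  terms. Filtering first and adjusting over the survivors is the only
  order in which the size filter actually reduces the multiplicity
  burden.
* Ties in p are preserved; ordering of the result table (p, then q,
  then term id) and everything downstream is deterministic, and
  reordering GAF input lines cannot change a result.

## Stability of enrichment results

For each dated hit list, enrichment runs at t0 and t_now; lists with
fewer than five significant terms at both time points are excluded
(comparing noise to noise is uninformative). Two similarity measures
are reported:

* **complete Jaccard** over all significant terms;
* **top-term-parents Jaccard**: the five smallest-p significant terms
  (ties by q, then term id — the ranking basis had to be fixed
  somewhere, and p is the primary statistic), each expanded by its
  ancestors *in its own edition's ontology*, then compared. This
  credits agreement at coarser granularity when the leaves shift.

The null re-pairs E0 of each list with E1 of a different, randomly
chosen list — a uniform permutation with fixed points rejected, i.e. a
derangement, resampled fresh each of 1,000 rounds and pooled, with the
same ≥5-term retention rule. A list is **stable** when its observed
Jaccard strictly exceeds the empirical 95th percentile of the pooled
null (percentile = fraction of null values strictly below, ×100). The
strict inequality matters: with discrete Jaccard values, "≥" would flag
ties with the threshold atom. Retained lists are binned by age — up to
10 years, 10–12, 12–16, right-closed; anything older than 16 years
lands in the oldest bin with a warning.

Calibration is a testable property: when observed pairs are themselves
drawn by re-pairing, the stable-flag rate must sit in the 99% binomial
interval around 5%, and does in the test suite.

## The synthetic generator

`simulation_params()` / `simulate_preset()` generate complete studies.
What is emulated, and why:

* **Monthly cadence**: 28-day spacing by default (the archives' median
  inter-edition gap), with optional jitter over the observed 13–40-day
  range to exercise date matching.
* **Ontology growth**: a rooted random DAG per aspect (terms attach
  under 1–2 same-aspect parents, 80% `is_a` / 20% `part_of`); Poisson
  term births each edition and occasional leaf obsoletions.
* **Annotation inequality**: per-gene gain rates follow a Zipf profile
  (`i^−0.7` by default), giving the persistent heavy-tailed
  annotation-count distribution seen in real corpora; its persistence
  is measured by `annotation_rank_stability()`.
* **Recency bias**: 40% of new annotations land on terms minted within
  the last two years, so fresh, finer terms gain coverage and hit
  lists accumulate significant terms over time — without it a uniform
  target choice starves new terms and the corpus-wide growth in
  significant-term counts disappears.
* **Churn**: active IEA records pause for 1–2 editions with a small
  probability and then return; only automatic records churn, matching
  how such oscillations present in real histories.
* **Redundancy purges**: at a discontinuity edition every direct
  annotation implied by another direct annotation of the same gene is
  removed, the ontology is frozen, and all other dynamics pause — so
  mean direct counts drop while mean propagated counts are *exactly*
  unchanged, the fingerprint that distinguishes a bookkeeping clean-up
  from a knowledge change.
* **Module drift**: each hit list is built around a mid-size Biological
  Process term at its publication edition (75% module genes, 25%
  noise). Afterwards, with per-edition probability `drift_rate`, 10% of
  the module genes have their module-linked annotations rewired
  elsewhere. Older lists accumulate more rewiring, which is what makes
  stability fall off with age under the `drift` preset.

**Presets and scale.** The presets run 210 editions × 28 days ≈ 16.1
years — exactly spanning the stability age bins — with 400 genes, ~400
initial terms growing by ~4 per edition, and 300 hit lists of 30 genes.
The ontology is kept term-rich relative to the gene count so that
hit-list modules are diverse (few accidental module collisions between
unrelated lists) and so that newly minted terms keep entering the
tested size band, the mechanism behind the corpus-wide growth in
significant-term counts.
Analyses of synthetic corpora use a term-size band of 10–100 genes,
proportionate to the 400-gene background (the 20–200 default is meant
for real, 20,000-gene backgrounds). The unit-test fixtures are smaller
(tens of genes, ≤30 editions); the full scale is exercised by the
acceptance suite and `scripts/acceptance.R`.

**What the generator does not emulate** — hence what passing tests do
not show about real data: no real ontology topology (depth and fan-out
are homogeneous), no evidence-code ecology beyond IEA/curated, no
species differences, no curation campaigns or batch imports (beyond the
stylized purge), no correlation between hit-list composition and
multifunctionality, and publication dates uniform over editions rather
than clustered as in literature corpora. Parameters are chosen to
produce the qualitative regimes above, not fitted to the archives.

## Numerical and degenerate-input choices

* Hypergeometric tails come from `stats::phyper(k−1, …, lower.tail =
  FALSE)`; BH from `stats::p.adjust`. Both are verified in the tests
  against independent brute-force implementations (exact binomial
  summation over every urn up to N = 30; a literal step-up scan) to
  1e-12.
* Jaccard of two empty sets is 1 throughout the package; the corpus
  filter makes the case unreachable in stability reports.
* The empirical 95th percentile uses the inverse-ECDF definition
  (`quantile(type = 1)`): an order statistic of the pooled sample, so
  pooling order cannot matter.
* Dates are `Date` objects end to end; ages are divided by 365.25.
* Every stochastic routine takes an explicit seed and restores the
  caller's RNG state, so library use, tests and the CLI are bit-for-bit
  reproducible.

## Limitations

The multifunctionality-corrected enrichment methods, GSEA-style ranked
tests, user-settable backgrounds, GPAD/GPI input dialects, annotation
extensions and the pre-2004 three-file ontology format are all out of
scope. The store is a plain-text directory with a manifest — adequate
for desk-scale corpora, not for serving a web application.
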