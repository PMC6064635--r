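---
title: "Ontology-term analytics for literature corpora: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-term analytics for literature corpora: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Literature on a clinical topic accumulates faster than it can be read.
`ontotag` treats a body of citation abstracts as an ecological community:
each *search cell* — one disease group crossed with one keyword category and
one pair of publication years — is a sample, and the ontology terms found in
that cell's abstracts are its species. Community-ecology machinery
(dissimilarity, ordination, variance partitioning, per-term rank tests) then
asks the questions a systematic reviewer would: do disease groups use
distinct vocabularies, is usage converging over time, and which individual
terms drive the differences?

The package covers the full path: parsing MEDLINE (tagged) and BibTeX
citation exports, dictionary tagging against an ontology lexicon, building
and normalising the cell-by-term table, and the downstream statistics.

## Tagging model

A lexicon row is a term: a stable id, one of nine ontology namespaces
(organisms -2, environments -27, diseases/phenotypes -26, tissues -25,
biological process -21, molecular function -22, cellular component -23,
genes/proteins 0, small molecules -1), a canonical name and synonyms.
Canonical name plus synonyms are the term's *surface forms*.

The matcher contract is deliberately small and fully deterministic:

* text and surface forms are NFC-normalised and case-folded; internal
  whitespace in a form matches any whitespace run;
* a match may not begin or end inside an alphanumeric run, so `oat` never
  fires inside `coats`, while hyphens inside a form (`omega-3`) are literal;
* at each position the longest surface form wins, and the scan resumes after
  a match, so spans never overlap;
* a surface form shared by several terms credits every owning term.

Within a document, matches are reduced to *presence*: a term counts at most
once per abstract however often it is mentioned. A document with at least
one present term is *annotated*. There is no stemming, abbreviation
expansion, or context disambiguation — spelling variants must be listed as
synonyms. This keeps every annotation auditable, at the cost of vocabulary
coverage; results are only as good as the lexicon.

## The frequency table and its normalisation

`build_counts()` tabulates, per cell and term, the number of documents in
which the term is present, alongside the cell's annotated-document total.
Terms with fewer than `min_total = 5` presence hits across all cells are
removed before analysis; the filter runs *before* any curated term subset is
applied, so the subset selects among already-reliable terms. The filter
counts presence hits (not raw mentions) for consistency with the presence
rule.

Because literature volume varies enormously across diseases and years, raw
counts are not comparable. *Document-based normalisation* divides each
cell's counts by its annotated-document denominator. The default scope
(`cell`) uses the cell's own denominator, treating the three keyword
categories as replicate searches; the `group_yearpair` scope instead pools
the denominators of all categories for a disease and year pair, for users
who regard the categories as one search. Both are exposed because either
reading of "papers annotated for this condition and year" is defensible;
the per-cell scope is the default since the categories serve as replicates
in every downstream test.

Rankings of the most frequent terms aggregate by *summing* normalised
frequencies over a group's cells across the whole timeline, so a term at
frequency 0.3 in many year pairs outranks one that spiked once; sums (not
means) are used so the aggregate reflects persistence, and values above 1
are expected. Ties are broken lexicographically by term id so ranks are
reproducible.

## Statistical core

All multivariate statistics run on the normalised cell-by-term matrix.

**Bray–Curtis dissimilarity.** `d(i, j) = Σ|x_i − x_j| / Σ(x_i + x_j)`,
0 for identical composition, 1 for disjoint; a pair of all-zero rows is 0 by
convention.

**NMDS.** `nmds()` minimises Kruskal stress-1,
`sqrt(Σ(d̂ − ḋ)² / Σ ḋ²)`, where `ḋ` are configuration distances and `d̂`
is the isotonic regression of `ḋ` on the rank order of the input
dissimilarities (primary/weak tie handling: tied input values impose no
order among themselves, implemented by sub-ordering tied blocks on the
current configuration distances). Each start alternates the isotonic fit
with a Guttman majorisation step until the stress improvement falls below
`tol = 1e-8`, with a guard that keeps the previous configuration if a step
would increase stress — so the recorded stress trace is non-increasing by
construction. The first start is the classical-scaling configuration; the
remaining `n_starts − 1` (default 20 in total) are seeded random
configurations, and the best is returned. Being non-metric, a zero-stress
solution constrains only the rank order of distances, not their values.

**PERMANOVA.** One-factor variance partitioning of squared distances:
`SS_total = Σ_{i<j} d²/N`, `SS_within = Σ_g Σ_{i<j∈g} d²/n_g`, pseudo-F
`(SS_between/(a−1))/(SS_within/(N−a))`, `R² = SS_between/SS_total`. The
p-value permutes labels with an explicit seed and uses the add-one
convention `(1 + #{F* ≥ F})/(1 + n_perm)`, so the smallest attainable p at
999 permutations is 0.001. For small samples `exact = TRUE` enumerates every
distinct label arrangement and reports the exact fraction. Only the
one-factor design is implemented; the pipeline fits disease group and year
pair as separate single factors.

**LCBD.** On the Hellinger-transformed matrix
(`y = sqrt(x / rowSum)`), column-centred squared deviations are summed per
row; each sample's share of the total sum of squares is its local
contribution to beta diversity. Values sum to 1; a small value means the
sample sits near the group centroid. The pipeline computes LCBD per disease
group over that group's cells, giving a temporal profile whose decline
signals convergence of the literature. When all rows are identical the
decomposition is undefined and the result is flagged degenerate with a
uniform `1/n`.

**Per-term tests.** `differential_scan()` runs a Kruskal–Wallis test per
term across the levels of one factor (disease group, time interval, or year
pair), with the normalised values of all category-by-year-pair cells at a
level as replicates. Benjamini–Hochberg correction is applied across all
terms of one scan — one family per scan, matching how per-interval result
tables are usually reported — and Dunn's pairwise z tests follow for terms
with adjusted p below `alpha = 0.05`, their pairwise family again
BH-adjusted. Terms with zero variance across replicates are skipped and
reported rather than tested. Summary percentages of significant terms are
truncated (not rounded) to two decimals, the convention used in the
reference tables this output mirrors. Kruskal–Wallis and BH go through
`stats::kruskal.test()` and `stats::p.adjust()`; the fully tied sample is
defined as `H = 0, p = 1`, and a vanishing Dunn variance term yields
`z = 0, p = 1`.

The default time intervals are 1991–1998, 1999–2004, 2005–2010 and
2011–2016; interval binning refuses a year pair that straddles an interval
boundary rather than silently splitting it. The record-level publication
year is informational only — the cell's year pair is authoritative, because
the sampling unit is the search, not the paper.

## The synthetic-corpus generator

Real corpora depend on a live search engine and a proprietary tagger, so
validation runs on generated corpora with known truth. Each term is planted
in each document independently with probability

`p(term, group, τ) = plogis(β0_term + γ_{term,group} + δ_term · τ)`

where `τ` is the 0-based year-pair index. The defaults mirror the study
grid at desk scale: 4 disease groups × 3 keyword categories × 13 year pairs
(1991–2016) × 20 documents = 3,120 documents, baseline logit −1.5, no group
or time effects unless requested, seed 20180726. An anchor term with
`p = 1` makes every document annotated, so normalisation denominators equal
the document count exactly and expected normalised frequencies equal `p` —
expected-value tests then need no denominator noise correction.

Planted terms appear as one uniformly chosen surface form inserted into the
document text between filler words. Two safeguards protect the
exact-recovery contract: the filler vocabulary is validated to share no
whole token with any surface form, and each planted form is placed in its
own gap between filler tokens so two forms can never sit adjacent and
concatenate into a longer lexicon form (`omega-6` directly followed by
`fatty acids` would otherwise read as `omega-6 fatty acids`). Presence
draws and text-layout draws use separate seeded streams (`seed` and
`seed + 1`), so `simulate_counts()` — which skips text generation — yields
exactly the counts that generating, parsing and tagging the files would;
that equivalence is itself tested, and replicate simulation studies use the
fast path.

What the generator does *not* emulate: natural language (filler text is a
bag of method-section words), mention multiplicity (presence is drawn
directly), abstract length variation, lexicon ambiguity or misspellings,
citation-network structure, and denominator noise when the anchor is
enabled. Passing recovery tests therefore demonstrate the correctness of
the tagging and counting machinery under the stated matching contract, not
robustness to noisy real-world text.

Study conditions used by the test suite and the acceptance script, fixed in
advance: group-effect detection plants `γ = 2` on 10 of the 40 toy-lexicon
terms with 50 documents per cell over 50 seeded replicates; differential
sensitivity plants a five-fold prevalence shift (baseline p ≈ 0.1 vs 0.5)
for one term in one group with 8 replicate cells per level; temporal
convergence gives 12 drift terms starting at `p = 0.5` (maximal sampling
variance and fastest logistic movement) with slopes ±0.45 so probabilities
saturate towards 0/1 over the 13 year pairs — late cells then have both
smaller sampling variance and near-stationary composition, producing the
falling LCBD profile. The permutation-test size check uses 600 null
datasets of 12 samples at 199 permutations. These sizes keep the full suite
within a few minutes on one CPU while leaving comfortable margins on the
rate thresholds.

## Numerical and design choices

* All stochastic operations take explicit integer seeds; the pipeline
  default is 20180726. Reruns are byte-identical.
* Permutation p-values never report 0 (add-one convention).
* Bray–Curtis on a pair of all-zero rows is 0; Hellinger of a zero row is a
  zero row; degenerate LCBD is uniform and flagged.
* Duplicate citation ids within one cell are dropped (first wins, with a
  warning); the same id may appear in different cells, as overlapping
  searches legitimately return the same paper twice.
* BibTeX ids resolve in priority order: a `pmid` field, a `note` field
  containing `PMID: <digits>`, then an all-digit entry key; entries with no
  resolvable id are skipped and counted.
* Unparseable publication dates leave the year missing with a warning; the
  cell assignment, not the record year, drives all statistics.
* The rare-term filter threshold (5), significance threshold (0.05),
  permutation count (999) and NMDS dimensionality (2) are package defaults
  chosen to match standard practice for this analysis type; all are
  arguments.

## Limitations

* Dictionary tagging has no notion of context: negated or speculative
  mentions count, and homonyms credit every term sharing the surface form.
* Corpus-level results depend entirely on the supplied lexicon; the bundled
  40-term lexicon is a test vocabulary, not a curated ontology.
* PERMANOVA is one-factor; interactions between disease group and time are
  not modelled.
* LCBD significance is not assessed (no permutation test is attached to the
  decomposition); the series is descriptive.
* NMDS configurations are identified only up to rotation, reflection,
  translation and monotone distance transforms.
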