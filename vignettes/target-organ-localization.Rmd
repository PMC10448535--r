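---
title: "Target-organ localization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target-organ localization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herborgan)
options(herborgan.quiet = TRUE)
```

`herborgan` estimates *where in the body* a medicinal herb acts, by
carrying a compound table through target aggregation, interaction-network
core selection, and two independent organ-localization read-outs: gene-set
enrichment against a gene–organ catalog, and overexpression linking
against gene-by-tissue expression atlases. This vignette explains the
statistical models behind each stage, the tunable parameters and their
defaults, what the synthetic benchmark does and does not establish, and
the design decisions taken where more than one reasonable convention
exists.

## The screening and aggregation model

Compound records arrive from several databases that disagree on
identifiers and naming. Records are merged transitively whenever they
share any identifier, with PubChem CID the most trusted key, then
InChIKey, then CAS, and last a *normalized name* (case-folded, whitespace
collapsed, Greek letters spelled out, so "Β-ecdysterone" and
"beta-Ecdysterone" unite). When merged records disagree on OB or DL the
maximum is kept: the screen asks whether a compound can be active, and a
higher score from any source is evidence that it can. Activity requires
OB ≥ 30 % *and* DL ≥ 0.18, both inclusive, exactly as the thresholds are
conventionally typeset; a record missing either score cannot demonstrate
activity and is excluded (with a logged count, never an error).

Target associations carry per-source confidence semantics: letter grades
for curated literature sources (grades A–C pass by default) and a
similarity score for predicted links (score ≥ 30 passes, inclusive — a
cutoff stated as an equality is read as a threshold). Sources without a
stated rule pass unchanged. The target union is the sorted set of
distinct symbols; sorting uses C collation so results cannot depend on
the session locale.

## Core-target selection

The interaction network keeps edges with combined score strictly above
`min_score` (default 0.9 — the "high confidence" convention; a score of
exactly 0.9 is *not* high confidence). Scores are auto-normalized from
the 0–1000 integer export scale when any score exceeds 1; a file mixing
integer-scale and fractional scores is rejected rather than guessed at.
Degree is the unweighted incident-edge count — the threshold "twice the
mean degree" is only meaningful for raw counts — and the mean is taken
*after* removing isolated nodes, matching the convention of hiding
disconnected nodes before topology analysis. A gene is a core target when
its degree strictly exceeds `multiplier × mean` (default multiplier 2).
Since the degrees sum to *n*·mean, the core can never be the whole
network; on hub-planted graphs the rule recovers exactly the planted hubs
(tested across 100 seeds).

## Enrichment and depletion statistics

All tests condition on the margins of the 2×2 table: universe size `N`,
term size `K`, list size `n`, overlap `k`, with the overlap
hypergeometric under the null. Three constructions are offered:

* **classical**: `P(X ≥ k)` — the plain one-sided Fisher tail;
* **EASE**: `P(X ≥ k − 1)` — one overlap gene is discounted before the
  tail is taken, so a single-hit term scores 1. This is the conservative
  variant popularized by functional-annotation servers, and is the
  default analogue for that style of analysis;
* **mid-p**: `P(X > k) + P(X = k)/2` — half weight on the observed
  table. For discrete tests the classical tail is conservative (its
  attained level is below nominal); the mid-p recovers calibration and
  is the convention of phenotype-catalog organ enrichment. Depletion is
  the mirrored lower tail, and the two mid-p directions are exactly
  complementary, a property the test suite asserts to 1e-12.

The test suite pins all three to brute-force oracles: exhaustive
enumeration of every possible gene list for universes up to `N = 12`, and
direct probability-mass summation.

Multiple testing uses Benjamini–Hochberg. When depletion is tested, both
directions of every term enter *one* BH family (2·m hypotheses); each
term is then reported once, in its fold-direction (`fold > 1` or exact
ties report as enriched), carrying the p-values of that direction. This
one-family choice is the conservative reading of an output that reports
an FDR per term without describing family construction. The universe
defaults to all catalog genes; an explicit background file can override
it, which is the closest reproducible analogue of a server-side
background. Depletion of `k = 0` terms is a legitimate test (a large term
entirely avoided by the list is informatively depleted); enrichment of
empty terms is not, and empty terms are rejected at catalog construction.

## Expression linking

Two linking rules connect a gene to tissues where it is *overexpressed*:

* **above-mean**: expression strictly above the gene's own cross-tissue
  mean;
* **positive-Z**: row-standardized expression strictly above 0, with the
  sample standard deviation (`ddof = 1`, overridable to 0 — the choice
  cannot change which tissues link, since `z > 0 ⇔ x > mean`, and the
  suite verifies the two rules coincide on every non-constant row).

Constant rows are flagged rather than divided by zero and produce no
links. Consensus across two atlases takes the per-cell **maximum** —
the convention used for consensus normalized expression (nTPM) — over the
*intersection* of gene sets (a consensus is undefined for a gene absent
from one source) and the *union* of tissues (a tissue measured by one
source carries that source's value). Duplicate gene rows within one file
collapse by per-tissue maximum for the same reason.

For highest-expression assignment, tissues are regrouped into organ
groups (the shipped `organ_grouping()` maps 15 hematopoietic cell types
and whole tissues onto 8 organ groups, e.g. CD33⁺ myeloid cells → bone
marrow); a group's value is the maximum over its member tissues, and the
gene goes to the argmax group. Exact ties break to the lexicographically
smallest group name — an arbitrary but deterministic rule — and are
counted in the result's attributes.

## The synthetic benchmark

The generators produce every input class with planted truth, emulating
the study conditions rather than any real export:

* `gen_compounds()` — 170 compounds, 10 % active (OB ~ U(30, 70),
  DL ~ U(0.18, 0.9); inactives fail at least one bound), 15 % listed
  under a second source;
* `gen_ppi()` — 200 genes, 3 hubs wired at probability 0.8 against a
  0.01 background, planted scores 0.901–1.000 and decoy scores ≤ 0.9;
* `gen_catalog_and_list()` — 150 terms over a 7,000-gene universe. Decoy
  term sizes are drawn from a normal around **1,000 genes** (sd 250,
  truncated to [50, 3000]): a catalog linking ~7,000 genes to ~150 body
  parts through ~150,000 associations averages ~1,000 genes per term,
  and realistic term sizes matter because the discreteness of the
  hypergeometric — and hence the attained level of the test — depends
  directly on `K`. The enriched term (100 genes) receives list genes
  with probability 0.6; the depleted term (1,000 genes) avoids the list
  entirely. At smaller depleted-term sizes a zero overlap is simply not
  surprising (`P(X = 0) ≈ 0.11` at `K = 300` for a 50-gene list), so the
  depleted term is planted at the catalog's mean size, where
  `P(X = 0) ≈ 4.5e-4` and the adjusted depletion signal is detectable;
* `gen_atlas()` — lognormal baselines per gene, multiplicative noise of
  CV 0.3, and a fold-4 boost on the planted group's tissues; a second
  re-noised atlas shares the truth for consensus tests;
* `gen_study()` — one call wiring all of the above at study scale:
  17 planted actives, source lists of 207/312/78 genes with a 448-gene
  union, 44 planted hubs, and 84-/54-tissue atlases under the 8-group
  map.

Every generator is a pure function of its arguments including the seed.
What passing these benchmarks shows: the filters, the degree rule, the
tests and the linking rules recover exactly what was planted, at
calibrated error rates, under a noise model chosen to be fair to them
(lognormal noise with a multiplicative boost is the simplest model under
which both linking rules and the argmax assignment are consistent).
What it does not show: performance on real exports, where symbol
mismatches, correlated annotation terms, heavy-tailed expression, and
probe-level artifacts all exist. The printed-table checks (the
17-compound screen and the 44-gene group structure) are the only
real-data anchors shipped.

## Numerical choices and degenerate inputs

* Strict inequalities wherever the convention is "greater than"
  (score > 0.9, degree > 2 × mean, expression above mean, Z > 0);
  inclusive bounds wherever it is "at least" (OB, DL, association score).
* `p_adj` is clipped to ≥ `p_raw` and ≤ 1; BH is delegated to
  `stats::p.adjust` behind domain validation and cross-checked against a
  hand-rolled step-up oracle in the tests.
* Empty networks refuse core selection (a mean degree of an empty set is
  meaningless); header-only tables parse to empty results without error;
  empty graphs export to valid (empty) GraphML.
* The generator refuses `hub_p ≤ spoke_p` unless forced, because planted
  truth would be unrecoverable by construction.
* Pipeline reports carry no timestamp, so identical inputs and
  configuration give byte-identical reports.

## Problem sizes in the shipped test suite

The suite enumerates all universes up to `N = 12` for the exact-test
oracles, runs 200 null draws for calibration, 100 catalogs for
planted-term ranking, 100 graphs for hub recovery, 50 atlases (plus 10
at fold 1) for group assignment, and one full end-to-end study rerun for
byte-stability — sizes chosen so the whole suite completes in about two
minutes while keeping every Monte-Carlo margin far from its threshold.

## Known limitations

* Gene symbols are compared case-sensitively after trimming; alias
  resolution must happen upstream (an optional two-column mapping is
  honored before the union). A warning fires when >10 % of symbols
  contain lowercase letters, the usual sign of unmapped non-human genes.
* The catalog is taken as given; curation-level or phenotype-frequency
  filtering that shapes a phenotype catalog is out of scope.
* Enrichment p-values computed against a shipped synthetic catalog are
  not comparable to any server's output, which depends on that server's
  annotation tables and background.
* The mid-p construction is the standard one; proprietary variants of
  "mid-range corrected" p-values may differ in unpublished details, so a
  classical-tails option is kept alongside.
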