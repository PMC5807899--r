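---
title: "Classifying C2H2 zinc-finger proteins: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying C2H2 zinc-finger proteins: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfsubsets)
```

`zfsubsets` implements a rule-based pipeline for surveying a C2H2
zinc-finger protein (ZFP) family: finger detection, finger typing, an
eleven-way protein-level classification, and the downstream analyses such a
survey typically reports (subset-collapsed phylogeny, term enrichment,
expression patterns, qPCR concordance, regulatory-network intersection).
This vignette explains the models and decision rules, the tunable
parameters, what the synthetic-data generators emulate, and the numerical
choices made where the design was open.

## The finger model

A C2H2 finger is modelled as four coordinating residues
`C .. C .. H .. H` with three spacings:

* `c_gap` — residues strictly between the two cysteines, canonical 2,
  scanned over `[1, 4]`;
* `spacer` — residues strictly between the second cysteine and the first
  histidine, canonical 12, scanned over `[6, 25]`;
* `h_gap` — residues strictly between the two histidines, canonical 3,
  scanned over `[1, 8]`.

The six residues ending at the first histidine (the *hexamer*) carry the
plant-specific motif QALGGH. We interpret the terminal H of QALGGH as the
first coordinating histidine, which makes the canonical motif layout
`C-X2-C-X7-QALGG-H-X3-H` consistent with a spacer of 12 (7 arbitrary
residues plus QALGG). All typing logic builds on this reading.

The `spacer` bounds are configuration, not ground truth: the long-spacer
(Z1) and short-spacer (Z2) variants have no published bounds, so the
defaults simply need to admit both. They are exposed in `scan_params()` and
recorded in every manifest.

### Scanning and tie-breaking

`scan_domains()` is a greedy left-to-right scanner: the leftmost cysteine
admitting any valid quadruple starts the next domain; among that window's
candidates the finger with spacer closest to 12 wins, ties broken toward
the smaller spacer, then the smaller `h_gap`, then the smaller `c_gap`; and
scanning resumes after the accepted second histidine, so reported fingers
never overlap. The ranking favours the canonical geometry and makes the
scan deterministic. The test suite verifies the scanner against an
independent brute-force enumerator of all quadruples on several hundred
seeded strings over the minimal `{A, C, H}` alphabet (lengths 12–60; the
shortest possible finger is 12 residues) and on random full-alphabet
proteins.

Fingers lacking the second histidine (D-type) are *not* called ab initio —
an unanchored single-histidine pattern over-predicts grossly. They enter
through `load_domain_annotations()`, which locates the coordinating
residues inside externally annotated domain windows (the route a SMART
export takes): the first two cysteines, the first histidine after them,
and the last histidine of the window when distinct.

## Finger typing

`type_domains()` applies a geometry-first decision order, which makes the
rule set a total partition:

1. second histidine absent → **D**;
2. spacer ≠ 12 → **Z** (Z1 if > 12, Z2 if < 12);
3. spacer 12, hexamer exactly QALGGH, `c_gap` 2, `h_gap` 3 → **Q**;
4. anything else at spacer 12 → **M**, subclass `M1`–`M5` by the Hamming
   mismatches of the five variable hexamer positions against QALGG.

Two edge cases the source rules leave open are resolved as follows and
flagged in a `note` column: a spacer-12 finger with a canonical motif but
modified C/H gaps is M1 with 0 degradations (modified gaps license M), and
a fully degraded spacer-12 finger remains M5 — M is the spacer-12
catch-all. Whether M-type was ever meant to include spacer ≠ 12 fingers is
unknowable from the published rules; our partition sends those to Z, which
is the one place reproductions of a published per-finger table could
disagree.

## Protein-level classification

`call_arrangements()` measures the gap between consecutive fingers from the
end of the previous domain to the start of the next (exclusive), on the
annotated window bounds when available and otherwise on the `c1..h2` span.
A pair is tandem-linked iff its gap is ≤ 11 residues. A protein is
`tandem` (all gaps ≤ 11), `dispersed` (all ≥ 12), `mixed`, or `single`.

`classify_proteins()` then assigns the subset: tandem runs of 2–5 fingers
→ `Gm-t1-SF`; longer runs → `Gm-t2-SF`; single fingers → `Gm-1i-<family>-SF`
(M1–M5 collapse to M, Z1/Z2 to Z); dispersed pairs → `Gm-2i-Q-SF`,
`Gm-2i-M-SF`, or `Gm-2i-Mix-SF` for differing families; dispersed triples
and quadruples → `Gm-3i-SF` / `Gm-4i-SF`. Three open cases are decided and
flagged rather than dropped:

* tandem runs of 6–8 fingers (unobserved in the soybean survey, which saw
  2–5 and 9) go to the long-array subset `Gm-t2-SF` with a warning;
  `t2_policy = "unclassified"` selects the stricter alternative;
* proteins mixing a tandem run with distant fingers are classified by their
  longest tandem run — the published survey classified every protein, which
  implies tandem precedence — and carry a note;
* dispersed pairs of identical non-Q/non-M families (Z/Z, D/D) go to
  `Gm-2i-Mix-SF` with a note, since no `Gm-2i-Z/D` subset exists.

Five or more dispersed fingers fall outside the scheme and are returned
`unclassified` with a reason; unclassified rows always carry one.

Duplication accounting (`classify_duplication_status()`) expects symmetric
partner claims and splits genes into retained pairs (counted once per
unordered pair), retained singletons (a duplication block but no surviving
partner), and non-duplicated genes. The simple one-partner model cannot
represent a gene retained in several overlapping duplications; published
totals that count such genes can therefore exceed twice the pair count.

## Phylogeny

`p_distance()` is the proportion of differing sites under pairwise deletion
of gap columns; a pair with no comparable sites is an error naming the
pair. `nj_tree()` delegates the Saitou–Nei agglomeration to `ape::nj()`
(clamping negative branch lengths to zero with a warning), and
`bootstrap_support()` resamples alignment columns with replacement;
replicate `r` draws from a stream derived from `(seed, r)`, so replicates
are order-independent and the whole computation is reproducible
bit-for-bit from the master seed. Support is the percentage of replicate
trees containing each internal bipartition of the point tree; degenerate
replicates (a pair with no comparable sites) are skipped and counted.

`compress_by_subset()` midpoint-roots the unrooted NJ tree, collapses every
maximal clade whose leaves share one subset label into a node annotated
with the label, leaf count and minimum internal support, and orders
children deterministically by (label, size) — the presentational "flip"
that aggregates equal subsets. It also reports internal branches joining
two or more distinct subsets with support above 50%, the conventional
cutoff for calling a branch supported. Collapsed-node sizes always sum to
the original leaf count, and compression is idempotent.

## Enrichment

`enrich()` performs two one-sided hypergeometric tests per term, reporting
the direction chosen by the sign of `k − nK/N` (ties count as over): the
over-tail `P(X ≥ k)` or under-tail `P(X ≤ k)`. This mirrors survey tables
that print an explicit Over/Under-represented column rather than a
two-sided p. The source analyses say only "corrected p-value"; we default
to Benjamini–Hochberg within each direction, with Bonferroni selectable,
and record the choice in the result's metadata. Tails are verified against
exhaustive enumeration of all draws for every configuration with N ≤ 12.

## Expression, qPCR and networks

**Pattern calls.** A gene is *expressed* in a condition when its value
reaches `expressed_threshold` (default 1 in FPKM-like units; no published
threshold exists, so the choice is exposed and recorded in the output).
Patterns are assigned in a fixed order so every gene gets exactly one:
silent (nowhere), constitutive (everywhere), symbiosis-specific (only in
symbiotic tissues — nodule, root, root hair by default), tissue-specific
(exactly one non-symbiotic condition), broad (the rest). "Tissue-specific"
is deliberately narrow (one condition); multi-tissue proper subsets read as
broad.

**Heatmap ordering.** `hclust_order()` uses `log2(x + 1)`, Euclidean
distance and average linkage — the common defaults of expression heatmap
tools, whose exact settings in any given published figure are unknown — and
takes the deterministic leaf order produced by `stats::hclust`'s merge
sequence. Published heatmap figures are therefore emulated in procedure,
not reproduced pixel-wise.

**qPCR.** `ddct_fold_change()` averages Ct replicates first, then forms
ΔCt = Ct(target) − Ct(reference), ΔΔCt = ΔCt(sample) − ΔCt(calibrator) and
the fold change 2^−ΔΔCt. The fold is invariant to shifting all Ct values by
a constant. *Concordance* between qPCR and RNA-seq is defined as agreement
of the sign of the log2 fold change, with a fold of exactly 1 counting as
concordant with either direction; published concordance percentages depend
entirely on this definition, which is why it is stated prominently.

**Networks.** Co-expression edges keep candidate pairs with Pearson
|r| > 0.9 (strict, the conventional cutoff for these maps), signed by the
sign of r; zero-variance genes yield no edges and a warning. Candidate
pairs are restricted to the regulatory map's pairs rather than all-vs-all,
matching the construction order of map first, co-expression second.
Intersection keeps a directed map edge iff the co-expression set contains
the same gene pair (orientation-free on the co-expression side), and the
final filter drops edges whose endpoints are expressed in no nodule-stage
condition, de-duplicates parallel edges, and retains self-loops flagged
`self_regulation`.

## The synthetic-data generators

The generators define the study conditions under which the pipeline is
tested; they are pure functions of (parameters, seed).

* `gen_proteins()` draws background residues uniformly from the 18 amino
  acids excluding C and H, so planted fingers are provably the only
  matches and planted-truth scoring is exact; `hostile = TRUE` reintroduces
  C/H for robustness exercises without that guarantee. Fingers follow the
  type recipes exactly (Q canonical; M with 1–5 sampled degradations;
  Z1 spacers 13–20, Z2 spacers 6–11; D without the terminal histidine);
  tandem linkers are 1–11 residues and dispersed linkers 12–40, matching
  the < 12 / > 11 arrangement rule with margin on both sides.
* `gen_expression()` plants one pattern per gene (base signal 100 under
  multiplicative log-normal noise, σ = 0.2 by default — a realistic
  FPKM-scale dispersion that keeps expressed cells well clear of the
  threshold of 1). At σ = 0 recovery is exact by construction.
* `gen_alignment()` evolves each subset's taxa i.i.d. from an independent
  random ancestor (per-site substitution probability 0.05), giving
  within-subset p-distances well below between-subset ones. No indels, no
  rate heterogeneity: it emulates the separation structure a family
  alignment shows, not realistic sequence evolution.
* `gen_networks()` plants co-expressed targets as near-linear functions of
  their regulator (|r| > 0.95 by construction) and rejection-samples
  non-planted targets to |r| ≤ 0.8, leaving a margin on both sides of the
  0.9 threshold so the recovered intersection equals the planted one
  exactly.

Passing tests on these data show the decision rules and their
implementation are correct under planted truth; they do not show robustness
to fingers that violate the consensus spacings, to annotation errors in
real SMART exports, or to expression noise far above the planted
dispersion.

## Problem sizes and determinism

The shipped test suite and acceptance script run desk-scale problems: a
321-protein cohort matching a genome-wide soybean survey's composition,
recovery cohorts of 11 × 50 proteins at three seeds, 50 random additive
matrices of up to 12 taxa, the full N ≤ 12 hypergeometric sweep, a
12 × 13 qPCR grid, and 100-edge network intersections at overlaps 0, 0.3
and 1. Bootstrap runs in the pipeline default to 100 replicates (family
surveys conventionally report 1000; the support estimator is identical,
only the sampling error differs).

Every stage is deterministic given its configuration and seed: reruns
produce byte-identical outputs, which the suite checks by hashing whole run
directories. Known limitations: neighbor joining inherits `ape::nj`'s
tie-breaking on exactly tied Q-criteria, so taxon input order can matter on
degenerate (tied) distance matrices; midpoint rooting is only meaningful
when branch lengths are informative; and the one-partner duplication model
cannot express multi-way tandem duplications.
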