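# zfsubsets

Rule-based classification of C2H2 zinc-finger proteins (ZFPs) into eleven
subsets, with the downstream analyses used in genome-wide family surveys of
plant transcription factors.

C2H2 zinc fingers coordinate a zinc ion through two cysteines and two
histidines and follow, in plants, the consensus

```
X2 - C - X(1~4) - C - X12 - H - X(1~8) - H
```

with the conserved hexapeptide **QALGGH** ending at the first coordinating
histidine. `zfsubsets` detects these fingers ab initio from protein
sequence (or ingests a SMART-export-like domain table), types each finger as

* **Q** — canonical: spacer 12, exact QALGGH, canonical C/H gaps,
* **M1–M5** — spacer 12 with 1–5 degraded positions in QALGG (or modified
  C/H gaps),
* **Z1/Z2** — Cys2–His1 spacer longer/shorter than 12,
* **D** — second coordinating histidine missing,

and then classifies each protein by the arrangement (tandem arrays are
adjacent fingers linked by < 12 residues; dispersed fingers are separated by
more than 11), number and types of its fingers into
`Gm-t1-SF`, `Gm-t2-SF`, `Gm-1i-{Q,M,Z,D}-SF`, `Gm-2i-{Q,M,Mix}-SF`,
`Gm-3i-SF` and `Gm-4i-SF`.

Around the classifier the package provides the survey's companion analyses:

* molecular weight and isoelectric point of each protein (charge bisection
  with EMBOSS-style pKa values);
* whole-genome-duplication accounting (retained pairs, singletons,
  non-duplicated genes) and a chromosome link table;
* neighbor-joining phylogeny on p-distances with column-bootstrap supports
  and compression of subset-uniform clades for family-level display;
* hypergeometric over/under-representation of annotation terms
  (Benjamini–Hochberg or Bonferroni corrected);
* tissue expression-pattern calls (silent / constitutive / broad /
  tissue-specific / symbiosis-specific) and heatmap row/column ordering;
* relative qPCR quantification by the 2^−ΔΔCT method and direction
  concordance with RNA-seq fold changes;
* regulatory-network construction: Pearson co-expression edges at
  |r| > 0.9, intersection with a regulatory map, nodule-expression
  filtering, and SIF/GraphML export.

A synthetic-data module generates every input the pipeline consumes —
proteins with planted fingers of known type and arrangement, expression
matrices with planted patterns, alignments with subset structure, edge lists
with planted overlaps — together with the ground truth needed to score each
stage exactly.

## Worked example

```r
library(zfsubsets)

g <- gen_proteins(c("Gm-1i-Q-SF" = 3L, "Gm-t1-SF" = 2L, "Gm-2i-Mix-SF" = 2L),
                  seed = 42)
typed <- g$annotations |>
  load_domain_annotations(g$proteins) |>
  type_domains()
dplyr::select(typed, protein_id, start, end, spacer, hexamer, family, subclass)
#>    protein_id start   end spacer hexamer family subclass
#>  1 SYN00001       6    26     12 QALGGH  Q      none
#>  4 SYN00004       3    23     12 VAYGGH  M      M2
#>  6 SYN00004      54    74      7 RKFLAH  Z      Z2
#> 11 SYN00006      53    72     12 QALGGH  D      none
#>  ... (13 fingers in total)

classify_proteins(typed)
#>   protein_id n_domains arrangement longest_tandem_run label        reason note
#> 1 SYN00001           1 single                       1 Gm-1i-Q-SF   <NA>   <NA>
#> 4 SYN00004           4 tandem                       4 Gm-t1-SF     <NA>   <NA>
#> 6 SYN00006           2 dispersed                    1 Gm-2i-Mix-SF <NA>   <NA>
#>  ... one row per protein; every planted label is recovered.

compute_properties(g$proteins[1:3, ])
#>   id       length    mw    pi
#> 1 SYN00001     32 3507.  4.35
#> 2 SYN00002     28 3242.  6.49
#> 3 SYN00003     32 3679.  5.51
```

Each finger row reports the coordinating-residue positions, the Cys2–His1
spacer, and the six residues ending at the first histidine (the QALGGH
slot); the protein rows show the arrangement call and the resulting subset.
`summarize_subsets()` tabulates proteins per subset / finger number /
Q-finger count, `tidy()`/`glance()` give broom-style views of every result
object, and `autoplot()` draws the subset bar chart or enrichment volcano.

The whole analysis can also be driven through `run_stage()` /
`run_pipeline()` (stages `simulate`, `scan`, `type`, `classify`, `phylo`,
`enrich`, `express`, `qpcr`, `network`, `report`), which write TSV outputs
and JSON manifests into a run directory; a thin command-line wrapper lives
at `inst/scripts/zf-pipeline.R`.

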