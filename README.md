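# finechrom

Fine-scale chromatin contact analysis for bridge-linker proximity-ligation
data, of the kind produced by chemical-crosslinking assisted proximity
capture (CAP-C) in *Arabidopsis*: contact maps at ~200 bp resolution that
resolve structure *within* genes — promoter–promoter and enhancer–promoter
loops, and Pol II pausing-associated contact enrichment downstream of 5'
splice sites — and how that structure responds to cold stress.

The package covers the full analysis path:

- **Contact processing** — splitting chimeric reads at the bridge linker
  (`GTCAGAAAGATATCGCGT`), MAPQ ≥ 10 / self-ligation / duplicate filtering,
  binning into sparse contact matrices, vanilla-coverage (VC)
  normalization, distance-decay curves with power-law exponent fits, and
  replicate correlation.
- **Stable-contact calling** — a re-implemented distance-decay binomial
  model: distances are partitioned into equal-occupancy bins, the raw
  expected contact probability per bin is
  `p(s) = contacts(s) / (N · locus pairs(s))`, smoothed monotone
  non-increasing by weighted pool-adjacent-violators; each occupied bin
  pair with observed count `k` is scored by `P(X ≥ k), X ~ Binomial(N,
  p(s))`, with Benjamini–Hochberg control over all tested pairs
  (`q ≤ 0.01` by default).
- **Annotation and classification** — anchors labelled promoter >
  enhancer > gene body > intergenic; E-P contacts split
  proximal/distal and upstream/downstream of the interacting promoter;
  cis P-P contacts classified tandem / divergent / convergent.
- **Primed PPI networks** — contacts present in all three temperature
  conditions (22 °C, 3 h and 12 h at 4 °C) collapsed to one edge per gene
  pair, with degree tables and hotspot (extreme-degree promoter)
  detection, plus contact enrichment profiles over site sets against a
  shuffle null.
- **Profiles** — normalized contact density per gene (contacts with both
  ends in the gene body per kb per million contacts), top/bottom
  percentile stratification, scaled TSS→TTS metagene profiles, per-bp
  profiles around (first) 5' splice sites with per-condition Z-scoring,
  and Spearman correlation against activity tracks.
- **Co-expression testing** — mean pairwise Pearson correlation of
  PPI-connected gene pairs against two permutation nulls (random pairs of
  the same number; random pairs with a matched distance distribution),
  1000 replicates, add-one empirical p-values.
- **Synthetic data** — a seeded generator producing a toy genome with the
  statistical structure the analysis assumes (truncated power-law
  background, planted loops at known fold, pausing-window contacts with
  condition dynamics, correlated expression for loop-connected pairs) and
  the ground truth needed for recovery testing.

## Worked example

```r
library(finechrom)

res <- run_demo(seed = 7, out_dir = "demo_out", n_reps = 200)
v <- validate_against_truth(res)
round(c(sensitivity = v$sensitivity_mean,
        fdr_structured = v$fdr_structured_mean), 2)
#>    sensitivity fdr_structured
#>           0.84           0.05
unlist(v$ss_mean_z)
#>      22C   cold3h  cold12h
#> 2.196240 2.018749 2.171561
c(p_A = v$coexpr_p_A, p_B = v$coexpr_p_B)
#>         p_A         p_B
#> 0.004975124 0.004975124
```

The demo simulates three cold-treatment conditions, calls stable contacts
per condition, intersects them into a primed set, classifies and networks
them, and tests co-expression. The numbers above say: 84% of the planted
loops were recovered at this (deliberately shallow) demo depth with ~5%
structure-aware false discovery; the Z-scored contact signal over the
+0..+50 bp window downstream of first 5' splice sites ordered
22 °C > 12 h > 3 h, the cold-drop-and-recovery pattern; and PPI-connected
gene pairs were more co-expressed than either null (p ≈ 0.005 at 200
null replicates).

A thin CLI wraps the same functions: `inst/scripts/finechrom demo --seed 7`.

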