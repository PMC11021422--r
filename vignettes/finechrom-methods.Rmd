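---
title: "Models and design choices in finechrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in finechrom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

finechrom analyses fine-scale (~200 bp) chromatin contact maps from
bridge-linker proximity ligation. This vignette explains the statistical
models, the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the choices made where the design
was genuinely open. Everything quantitative that the package claims is
computed by its test suite or by `scripts/acceptance.R`; this document only
explains the reasoning.

## Coordinates and containers

All internal coordinates are 0-based half-open; GFF3's 1-based closed
intervals are converted at the boundary, once. Contact pairs are kept in
canonical order — end 1 not after end 2 in chromosome order (the order of
the chromosome-sizes file) then position — so that binning, duplicates and
set operations never depend on read orientation. Contact matrices are
sparse upper-triangle tables `(chrom, bin_i, chrom, bin_j, count)` with
`bin = floor(pos / resolution)` at 200 bp default resolution, the scale at
which the assay resolves intra-genic structure.

## Contact filtering

Three filters, in order: minimum per-end mapping quality (default 10),
a self-ligation guard removing intra-chromosomal pairs closer than two
bins (the assay cannot distinguish a genuine sub-400 bp contact from
religation of adjacent fragments; the threshold is configurable because no
published value exists for this chemistry), and exact-duplicate collapse
on both coordinates *and* both strands — a PCR-duplicate proxy chosen
because the pipeline deliberately does not consume alignment metadata.
The filter report partitions the input exactly
(`input = output + mapq + min_distance + duplicates`), which the tests
assert.

## The expected model and stable-contact calling

The caller asks, for every occupied intra-chromosomal bin pair, whether
its count `k` exceeds what the distance decay predicts. The expectation is
estimated from the data itself:

1. Contacts are grouped by bin distance and partitioned into
   equal-occupancy distance bins (default 100) so each estimate rests on
   comparable evidence. Two guards split bins further: a distance carrying
   a full bin's worth of contacts becomes a singleton (otherwise a sharp
   feature near the minimum distance would be averaged with its
   neighbours), and no bin may span more than a quarter-octave
   (`d_hi/d_lo ≤ 1.25`), bounding the decay variation a single probability
   has to represent.
2. The raw per-locus-pair probability in a bin is
   `p = contacts / (N · possible locus pairs at those distances)`, where
   `N` is the matrix total and possible pairs are counted per chromosome
   (`B − d` pairs at bin distance `d`).
3. Raw probabilities are smoothed monotone non-increasing with weighted
   pool-adjacent-violators — deterministic and assumption-light, chosen
   over a spline fit at this scale.

Tested distances run from two bins to **half the longest chromosome** by
default. Beyond that the number of available locus pairs (`B − d`)
collapses, the per-pair rate is dominated by that geometry rather than by
distance decay, and a distance-binned expectation misfits badly — we
measured order-of-magnitude FDR inflation when testing the full range on
simulated data. Bounded testing is also what published implementations of
this model do; the bound is configurable.

Significance is the upper-tail binomial `P(X ≥ k | N, p(s))` with
Benjamini–Hochberg over all tested pairs and a default `q ≤ 0.01`; the
cutoff is a package default (recorded in outputs) because the study this
design follows defers to a cited pipeline without printing one. Only
occupied pairs are *enumerated*, but calibration must be judged against
the full family of possible pairs (unoccupied pairs simply have p = 1);
the acceptance tests check sub-uniformity on that family. Inter-chromosomal
pairs are not tested — the expectation is distance-based by construction —
and this is a stated scope limit.

"Primed" contacts are the exact anchor-wise intersection of the
per-condition call sets (a ±1-bin slack is available behind a flag).

## Classification conventions

Anchor labels follow the precedence promoter > enhancer > gene body >
intergenic. The promoter window is 500 bp upstream to 100 bp downstream
of the TSS, strand-aware — the source analyses never define their window,
so it is configurable and logged. E-P contacts are proximal within
2,000 bp of anchor-midpoint separation (again configurable; the
proximal/distal split is reported without a printed cutoff anywhere we
could follow), and upstream/downstream is measured from the promoter's
TSS in transcription direction. Cis P-P orientation takes the left (lower
TSS) gene as reference: equal strands are tandem, `(−,+)` divergent,
`(+,−)` convergent; the classifier is invariant to argument order and is
tested against an exhaustive enumeration of all strand/side cases.
Anchors touching several promoters produce one edge per gene pair,
deduplicated — consistent with hotspot promoters contacting very many
genes.

## Profiles

Per-gene contact density is contacts with *both* ends inside the gene
body, per kb of gene length, per million library contacts. Both the
length and depth normalizations are declared choices (the figure legends
this mirrors do not print a formula) and configurable. Positional
profiles count contact *ends* (each pair contributes two), matching
coverage-track semantics. Metagene profiles rescale each body to 100 bins
with fixed-width flanks, reversing minus-strand genes. 5'SS profiles run
−100..+200 bp around the (first) 5' splice site in transcription
direction; per-condition Z-scoring over the window — `z = (x − mean)/sd`
with the population (n-denominator) sd — is the device used to compare
libraries of different depths, as in the condition-comparison figures this
reproduces. Genes overlapping other genes are retained (Arabidopsis-like
density); the resulting profile contamination is accepted and documented.

Spearman correlations use midranks; p-values are exact (full permutation
enumeration) for n ≤ 9 and t-approximate otherwise.

## Co-expression testing

The statistic is the mean pairwise Pearson r of PPI-connected gene pairs
across the 9 expression samples (3 conditions × 3 replicates; computing
across condition means only is also supported, since the source procedure
does not say which it used). Two nulls, 1000 replicates each by default:
model A draws the same number of random distinct pairs; model B matches
the observed cis distance multiset within quarter-octave (log2 width
0.25) bins, with nearest-bin fallback, and matches trans pairs with
random trans pairs. The empirical p uses the add-one estimator
`(1 + #{null ≥ obs}) / (1 + reps)`, one-sided in the direction of higher
co-expression. On a narrow loop-distance band the model-B candidate pool
partially overlaps the observed pairs, which makes B conservative; the
generator therefore leaves half of its close gene pairs unconnected so
the matched null has genuine members.

## The synthetic-data generator

The generator is first-class, tested code. Its defaults are the study
conditions the recovery experiments run under:

- **Genome**: 5 chromosomes × 600 kb (3 Mb total), 500 non-overlapping
  genes with log-normal lengths around 2 kb, 80% multi-exon (first exon
  100–400 bp, so first-5'SS anchors sit inside the body), enhancers in
  intergenic space.
- **Background**: intra-chromosomal distances from the truncated power
  law `s^(−α)` on [1 kb, chromosome length) via inverse-CDF sampling,
  α = 1 by default; 5% inter-chromosomal pairs; 5% low-MAPQ ends; 1%
  exact duplicates.
- **Planted loops**: 200 anchor pairs at 8-fold the local background
  expectation, emitted as `Poisson((fold − 1)·λ)` extra pairs in the
  anchor bin pair, where λ comes from the analytic distance law. Anchor
  separations are log-uniform on **1–2 kb**. That band is where this
  assay's fine-scale loops live (within-gene and adjacent-promoter
  contacts), and a power calculation shows it is also the regime where an
  8-fold enrichment is physically detectable at 2×10⁶ pairs and 200 bp
  bins: the per-bin-pair background mean is ≈2–4 there, versus <1 beyond
  ~3 kb where no caller could reach 90% sensitivity at this depth. Half
  of the close gene pairs become P-P loops; enhancer-promoter loops are
  placed at the same separations.
- **Pausing dynamics**: each gene emits Poisson gene-body contacts with
  one end uniform in [0, +50] bp downstream of its first 5'SS (covering
  the ~25 bp pausing offset) and the other end uniform in the gene body,
  scaled by a log-normal per-gene activity factor and condition weights
  22C = 1, cold3h = 0.3, cold12h = 0.7 — a sharp drop after 3 h of cold
  and partial recovery by 12 h. The magnitudes are free parameters (no
  quantitative effect size is published); these defaults give a clear but
  not saturating signal.
- **Activity and expression**: activity tracks paint gene bodies with
  values rank-coupled to the planted contact intensity at a target
  Spearman of 0.4 (the order of magnitude reported for contact–activity
  correlations on real data); the normal-score mixing coefficient is
  `2·sin(π·ρ_s/6)` so the rank target is hit exactly in expectation.
  Expression uses a shared latent factor per loop-connected component:
  `x = √ρ·f + √(1−ρ)·ε`, giving pairwise correlation ρ (default 0.5)
  within components, independent elsewhere.
- **Reads**: chimeric reads are `flank1 + linker + flank2` with 50–200 bp
  random flanks (DNaseI-fragment scale) and the true coordinates encoded
  in the read name; 20% of reads are linker-free decoys. Alignment is out
  of scope — coordinates are known by construction.

What passing tests on this generator do **not** show about real data: the
background has no domain structure, no centromere/telomere geometry, no
restriction/accessibility bias, and the genome has no sequence, so
mapping artefacts and repeat families are absent. Hub promoters
(hotspots) exist in the ground-truth network and in the expression model,
but are *not* planted as extra contacts: a promoter contacting dozens of
genes chromosome-wide is only callable at sequencing depths far beyond
these simulations, so hotspot detection is validated at the network level
instead.

## Numerical and degenerate-input conventions

Ties in stratification and sampling are broken by gene id for
determinism. The decay fit refuses fewer than 3 occupied distance bins.
`vc_normalize` of an all-zero matrix warns and returns its input;
single-pass vanilla coverage is not idempotent (its fixed points are
uniform-coverage matrices), so the tests assert mass conservation and the
fixed-point property rather than idempotence. Empirical p-values use the
add-one estimator and cannot be zero. Every stochastic stage derives its
seed from the master seed by a stable per-stage hash, so disabling one
stage never perturbs another; fixed-seed runs are bit-identical, which
the acceptance suite checks by hashing outputs.

## Problem sizes

The recovery experiments run at the scales stated above (3 Mb / 2×10⁶
pairs); the profile-ordering and co-expression calibration experiments
use smaller genomes (2 × 300 kb, 150–200 genes, 1–2×10⁵ pairs per
condition) with 20 seeded runs and 200 repeated experiments respectively
— sizes chosen so each recovers its planted effect with a comfortable
noise margin. The packaged demo (`run_demo()`) is shallower still
(5×10⁵ pairs), which is why its printed loop sensitivity (~0.8) is below
the full-scale result (~0.93-0.96): at fixed fold, detection power falls with
depth — an honest property of the model, not a defect.

## Known limitations

Only vanilla-coverage correction is implemented (no iterative balancing);
inter-chromosomal contacts are never tested for enrichment; enhancers are
an input, not discovered; the linker match is exact by default with a
one-mismatch option, not a full adapter-trimming aligner; and the
co-expression nulls assume the annotation provides enough same-chromosome
gene pairs per distance bin — at toy scales the matched null is
conservative, as discussed above.
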