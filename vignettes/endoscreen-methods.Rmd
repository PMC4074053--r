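---
title: "Distribution-shape screening statistics and the feature parsimony tree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distribution-shape screening statistics and the feature parsimony tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(endoscreen)
```

## The problem

Image-based RNAi screens on printed cell arrays measure endocytic activity
in every segmented cell: a fluid-phase probe (dextran) reports on
clathrin-independent CLIC/GEEC ("CG") uptake, transferrin on
clathrin-dependent ("CD") uptake, and 27 per-cell features summarize
intensities, endosome morphology, receptor surface levels, colocalization
and cell/nuclear geometry (`feature_catalog()`). Each slide carries a
10 x 30 well grid with 30 negative-control wells, 8 positive-control
wells, and one dsRNA per remaining well; every gene is screened on three
replicate slides with a few hundred cells per well.

Summary statistics built from per-well means and variances suffer from
slide-positional artifacts (row, column and edge biases) strong enough to
differ between negative wells of the same slide. The observation this
package operationalizes is that the *shape* of the single-cell
distribution — what remains after removing each well's location and scale
— is both robust to those artifacts and informative about perturbations.

## The shape Z-score

For a test well with per-cell values $x$ and the in-slide negative
controls, the package computes the two-sample Kolmogorov–Smirnov
sup-statistic

$$D = \sup_v \left| \hat F_{\text{test}}(v) - \hat F_{\text{neg}}(v) \right|$$

and standardizes it into $Z = (D - \mu_D)/\sigma_D$, where $\mu_D$ and
$\sigma_D$ describe the null distribution of $D$ on that slide and
feature. The calibration is slide-local and self-contained: the negative
wells are split once per slide into a *reference* half and an
*evaluation* half (`split_negatives()`); $\mu_D, \sigma_D$ come from
leave-one-out comparisons of each reference well against the pool of the
others (`calibrate_null()`); test wells are compared against the full
reference pool (`zscore_well()`); and the held-out evaluation negatives,
which never touch the calibration, measure the realized false-positive
rate (`evaluate_fp_tp()`). The exact scaling used in the original
supplementary material is not public; this leave-one-out construction
satisfies its published contract — null mean approximately 0, unit scale,
pooled comparisons against negatives on every slide — and is the
package's own choice.

With `shape_mode = TRUE` (the default) every per-well sample is
affine-normalized — mean subtracted, divided by the SD — before any
comparison. Two consequences matter:

* any well-level multiplicative or additive artifact cancels exactly, so
  positional biases do not inflate the false-positive rate;
* pure location or scale effects of a knockdown are *invisible*; only
  changes in distribution shape (e.g. an emerging subpopulation) register.
  A mode with normalization off exists for intensity features whose
  location shifts are of interest; hit direction is in any case left to
  the secondary assay, as the KS statistic is unsigned.

Wells with fewer than `min_cells = 50` cells per feature are reported as
missing rather than scored (the threshold is the package's choice; wells
seed roughly 100–150 cells, so this mainly drops seeding failures).

## Hit calling and the permutation yardstick

A gene is a hit for a feature when at least 2 of its 3 replicate Z-scores
reach the threshold, inclusively (`Z >= 3`; `call_hits()`). Missing
replicates count as failures, and genes with fewer than two scored
replicates are flagged unevaluable. The 27 per-feature bits form the
gene's binary feature vector (`binarize()`); genes with an all-zero
vector are not hits.

`permutation_hit_curve()` compares hit counts against datasets with gene
labels randomly permuted within each replicate. Because the screen itself
assigns genes to wells by one independent permutation per replicate, a
fully-null screen is *exactly* exchangeable with these permuted datasets;
the permutation spread is therefore the correct yardstick for the
observed count. The primary count is hit (gene, feature) pairs — the
statistic whose per-feature marginals the permutation preserves — with
distinct-gene counts reported alongside; a variant that shuffles
independently per feature is provided (`scope = "feature"`), but it
destroys the within-well correlation between features (wells share cells)
and so understates the variability of the observed count.

## The feature parsimony tree

To organize phenotypes, the roles are inverted: the 27 features are the
"species" and each hit gene's binary feature vector is a "character".
Genes hitting fewer than two features are uninformative and attach to
their single leaf (`filter_nontrivial()`). Tree fit is Fitch/Hartigan
small parsimony for unordered binary states with unit cost, generalized
to polytomies, under a gain-rooting convention: every character is absent
at the origin, so a character present in all taxa still costs one (root)
gain. The search (`search_tree()`) uses random-order stepwise addition
followed by best-improvement NNI hill-climbing, repeated from 25 shuffled
taxon orders; with 27 taxa this restart scheme routinely reaches the
optima found by exhaustive enumeration on small instances. Branch support
comes from 100 half-jackknife replicates — each retains a random half of
the characters — combined by strict majority-rule consensus
(`jackknife_consensus()`; the consensus and support counting are done by
*ape*, the scoring and search are package code, compiled via Rcpp because
100 replicates x 25 restarts is not practical in pure R).

`assign_characters()` then roots the consensus at the least-populated
internal node (fewest characters in state 1; ties break to the lowest
node id with a warning) and reconstructs each character's minimum-change
gain/loss events. Among equally parsimonious reconstructions the one with
the fewest losses is chosen (losses are interpreted as assay false
negatives), then ties keep the parent state. Every reconstruction
reproduces its character's leaf pattern exactly — asserted in the test
suite. Note that rooting at a *node* of the consensus can place the root
inside what is, in unrooted terms, one side of a split; planted-clade
recovery is therefore evaluated on unrooted bipartitions.

GO pull-up (`pull_up()`) re-reads the tree with annotations: a term
present at every leaf of a clade rises to that clade's root, a term at a
single leaf stays there, and occurrences in unconnected clades keep
separate homes; the published list of generic cellular-component terms
(cytoplasm, nucleus, membrane, intracellular, extracellular region,
plasma membrane) is forced to the root. The original algorithm for
"connected nodes" is not specified; the subtree-coverage (lowest common
ancestor) semantics here is the package's stand-in and is documented as
such.

## Enrichment

Annotation and screen-list enrichment is the upper-tail hypergeometric
(`hypergeom_test()`, via `stats::phyper`), Benjamini–Hochberg corrected
by default (the original work does not name its correction).
Interaction enrichment (`interaction_enrichment()`) counts
confidence-filtered edges (STRING-style scores, inclusive `>= 0.400` cut)
with both endpoints inside a node and compares against 10,000 permuted
networks that keep the total number of interactions constant — by
default, uniform endpoint rewiring without self-edges or duplicates; a
degree-preserving double-edge-swap variant is provided because the
original permutation's constraint on degrees is unstated. Empirical
p-values carry a +1 pseudo-count so they are never zero.

## Secondary quadrant classification

In the secondary assay each gene has 3 test wells flanked by 3 local
positive and 6 local negative control wells. Fold ratios are means over
test replicates divided by the local negative mean; per-axis significance
is a two-sided Welch t-test (the pooled-variance form is behind a flag),
gated at p < 0.10. Quadrants follow the ratio directions: both up = 1,
both down = 3, chase-driven patterns (significant chase with pulse flat
or opposed) = 2, pulse-driven patterns = 4; a gene with no significant
axis is unclassified. Whether the original figure required one or both
axes to be significant is not stated; "either axis" is the default here,
and the significance class (pulse-only / chase-only / both) is stored
orthogonally to the quadrant. The exact binomial sign test
(`binomial_sign_test()`) summarizes per-feature confirmation against
fair-coin expectation.

## The synthetic-data generator

Every stage is testable against `generate_primary_screen()` and friends,
which emulate the screen's structure with known ground truth:

* geometry: 10 x 30 wells, 30 negative + 8 positive controls per slide,
  triplicate slides, negative-binomial cells per well with mean 150 and
  dispersion 10 (wells seed ~100–150 cells);
* baselines: log-normal for intensities, gamma for counts and sizes,
  beta for bounded fractions — stipulated heavy-tailed/bounded families,
  *not* fitted to real data (none are published at per-cell resolution);
* artifacts: multiplicative per-well row gradient x column gradient x
  edge factor, default magnitude 15% (the original reports the biases but
  not their size), applied to unbounded features only — mirroring the
  observation that geometric features are comparatively robust;
* effects: `shift` (additive, in baseline SDs), `scale`
  (multiplicative), and `skew` — a fraction of cells (default 0.5)
  shifted by the effect size, producing a genuine shape change. Under
  the default shape normalization only `skew` is detectable, which is
  precisely the property the screen statistic is built around;
* positive controls receive a strong skew effect on a fixed feature set.

What passing tests on this generator do *not* show: realistic cell
morphology or optics (spots are ideal Gaussians over a smooth background),
realistic feature-feature dependence (features are drawn independently
within a well apart from shared cell counts), or the real data's
distribution families. Conclusions about detection power transfer only to
the extent that real perturbations change distribution shape at least as
strongly as the planted mixtures.

## Numerical and design choices

* KS statistic: exact tie handling (ECDF difference evaluated after
  absorbing all occurrences of each pooled value); C++ for speed.
* Circularity: $4\pi A / P^2$ with the chain-code perimeter weighted
  0.948 per axial and 1.340 per diagonal step and the ratio capped at 1;
  with these weights a rasterized disk of radius 10 scores ~1.0, whereas
  plain $\sqrt 2$ weights would put it near 0.92.
* Endosome detection: Otsu threshold on within-mask intensities, floored
  at 3x the MAD-based noise level, minimum spot area 2 px, 8-connected
  components (the published pipeline leaves these unspecified).
* `NucFluct` is the coefficient of variation of nuclear-channel intensity
  in the nuclear mask and `NucDist` the nuclear-to-cell centroid distance
  — stand-ins for definitions the original does not give.
* Problem sizes in the test suite and acceptance script — 500-gene null
  screens, 250-gene recovery screens with 100 affected genes, 100
  jackknife replicates x 25 restarts, 9,999-permutation enrichment — were
  chosen to exercise the study's stated conditions at full replicate
  structure while remaining comfortably reproducible on a laptop core.

## Known limitations

* The Z-score's exact published scaling is unavailable; only its contract
  is reproduced, so absolute Z values are not comparable to the published
  tables, though thresholded behaviour is.
* Reproducing the published event counts (e.g. total gains/losses)
  requires the original hit matrix and PHYLIP's exact tie-breaking;
  neither is bit-reproducible here by design.
* Segmentation is out of scope: masks are inputs, and the nuclear-seeded
  fallback (`segment_cells()`) is a convenience, not a validated
  segmentation method.
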