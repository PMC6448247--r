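---
title: "Methods: co-localization quantification and category-level enrichment"
author: "graftquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-localization quantification and category-level enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graftquant)
```

# Scope

Studies of grafted cells (for example mesenchymal stem cells transplanted
into the injured spinal cord) commonly need two bespoke computations that
sit outside the standard toolchain:

1. **Co-expression counting.** How many reporter-positive cells in a
   confocal section also express a second marker? The answer comes from an
   automated image-analysis chain rather than manual counting.
2. **Category-level enrichment reporting.** Hundreds of significant GO/KEGG
   terms per contrast are unreadable; they are manually binned into coarse
   functional categories, and each category is called significant or not by
   combining term-level and gene-level evidence.

`graftquant` implements both, together with the assumption-driven test
selection commonly used for the accompanying group comparisons, and
synthetic-data generators with full ground truth so every stage is
verifiable without any external data.

# The quantification chain

The imaging arm mirrors a classical ImageJ-macro design. For an image with
up to three registered channels:

1. **Channel combination.** Each selected channel is min-max rescaled to
   [0, 1] and the rescaled channels are multiplied pixel-wise. Only pixels
   bright in *every* selected channel stay bright, which is precisely the
   pixel-level meaning of co-localization. A constant channel rescales to 1
   if positive (a uniformly bright channel should not veto the product) and
   to 0 if empty. Consequently, two channels that are constant at any
   positive level multiply to the constant 1.
2. **Binarization.** The product is thresholded. The default is Otsu's
   method (deterministic, standard, close to common macro defaults, via
   `EBImage::otsu`); isodata inter-means iteration and a fixed threshold
   are available. Pixels at or above the threshold are foreground; a
   featureless (constant) grid yields an empty mask rather than an
   arbitrary split.
3. **Watershed.** Touching cells are separated by a watershed on the
   Euclidean distance transform. The user-facing parameter is
   `watershedMinDistance` (pixels), the minimum seed separation, with
   default 14 px — about 0.7 of the expected cell diameter for the
   10 px-radius cells the defaults target. Internally this maps to
   `EBImage::watershed(distmap(mask), tolerance = 0.5,
   ext = round(minDistance/3))`; this mapping splits fused pairs of unequal
   radii reliably, whereas larger neighbourhood radii merge their seeds.
4. **Gating.** Every labelled object is measured (area in pixels,
   perimeter, circularity, centroid) and retained if it falls inside the
   user-defined area and circularity ranges. Defaults
   (`minArea = 40` px², `minCircularity = 0.5`) are deliberately
   permissive; they should be tightened to the magnification at hand.

The co-expressing count comes from the product image; the reference count
comes from running the *same* chain on the reference channel alone. Their
ratio is the per-section co-expression fraction. A zero reference count
flags the fraction as undefined instead of returning 0 or NaN.

## Perimeter and circularity

Circularity is `4·pi·area / perimeter²`, capped at 1: exactly 1 for an
ideal disk and `pi/4 ≈ 0.785` for an ideal square. On a pixel grid the
value depends entirely on the perimeter estimator, so the choice is fixed
and documented: the length of the crack boundary (the staircase between
foreground and background pixels) with every 90° corner replaced by its
chord, i.e. `perimeter = edges − (1 − √2/2)·corners`, corners read off 2×2
pixel configurations. This estimator returns ≈ `4s` for an axis-aligned
square of side `s` (circularity 0.809 at `s = 20`, within 0.03 of `pi/4`)
and ≈ `2·pi·r` within a few percent for digital disks (circularity 0.87 at
`r = 20`). Circularities of digitized disks *decrease* toward ~0.84 at
small radii (r ≈ 10); the default gate of 0.5 accommodates this.

Centroids are reported in R's native 1-based (row, col) convention, the
convention of every matrix-based image container in this ecosystem.

## Per-animal aggregation

Sections belonging to one animal are pooled — summed counts, then one
fraction per animal — before the group mean and its t-based 95% confidence
interval are computed (`mean ± t₀.₉₇₅,ₙ₋₁·SE`). Pooling weights sections by
how many reference cells they contain, which is the natural estimator when
sections vary in cell number; averaging per-section fractions is available
as an option. A single animal yields a mean with the CI flagged undefined.

# The enrichment aggregation arm

## Gene selection and ORA

Differentially expressed genes are selected per contrast at `FDR < 0.01`
and `|log2FC| ≥ 1`, the sign of the fold change assigning the direction;
up- and downregulated lists are analyzed separately. Over-representation of
each gene set is the upper-tail hypergeometric probability `P(X ≥ k)` for
the observed overlap `k` between the query (n genes) and the set (K genes)
in a universe of N genes.

Two configuration surfaces have no canonical answer and are therefore
explicit parameters with documented defaults:

* **Universe** — all genes present in the supplied DE table. This is the
  most defensible choice when the table already reflects expression
  filtering, and it is what the `runEnrichmentPipeline` orchestrator uses.
* **Adjustment family** — Benjamini-Hochberg within one aspect (BP, MF,
  CC, KEGG) × contrast × direction, matching the convention that terms are
  exported "per method, contrast and direction". Terms with adjusted
  p strictly below 0.01 are exported with their overlap genes.

Gene sets with fewer than 5 genes after universe intersection are skipped
by default (tiny sets give unstable p-values).

## Categories and the dual significance rule

Exported terms are mapped to coarse categories through a two-column
term→category table. This mapping is inherently manual curation: the
package treats it as an input, and ships only a clearly labelled synthetic
example (`inst/extdata/example_category_map_synthetic.tsv`) demonstrating
the format. Per category and contrast × direction the pipeline reports:

* `nTerms` — number of unique significant terms,
* `medianFdr` — median of their term-level FDRs,
* `nGenes` — size of the union of the terms' overlap genes (the unique
  genes constituting the category's terms; counting against the whole
  universe instead is possible by supplying those unions directly),
* `fdrExact` — BH-adjusted competitive gene-set test p-value, adjusted
  across categories within one contrast × direction,
* `significant` — TRUE iff `medianFdr < 0.05` **and** `fdrExact < 0.05`,
  both strict.

Categories are ordered by descending `nTerms`; ties break by ascending
`medianFdr`, then name. Categories with fewer than ten unique terms are
omitted from the final report (configurable).

## The correlation-adjusted competitive test

The competitive test asks whether the category's genes carry larger
differential-expression scores than the remaining genes. Scores are signed
normal quantiles of the per-gene two-sided p-values (the raw p when the DE
table carries one, otherwise the FDR — a conservative fallback since FDR ≥
p). With `m` set genes among `G` scored genes:

* `rho_bar` — mean pairwise Pearson correlation of the set genes' rows of
  the expression matrix after within-group centering (removing the
  treatment effect so only residual correlation remains),
* `VIF = max(1 + (m − 1)·rho_bar, 1)` — the variance inflation of a mean
  of `m` equicorrelated scores; negative estimates are reported but never
  deflate the test,
* `t = (mean_in − mean_out) / (sp·sqrt(VIF/m + 1/(G − m)))` with the
  pooled score SD `sp`.

Inter-gene correlation is the reason this construction exists: a set of
`m = 20` genes with `rho_bar = 0.3` behaves like roughly `m/VIF ≈ 3`
independent genes, and a test that ignores this rejects true nulls many
times too often (the package's calibration tests measure ~0.43 instead of
0.05 at the nominal level).

**Degrees of freedom.** When `rho_bar` is estimated from expression data,
the two-sided p-value is referenced against a t distribution with
`min(n − g, G − 2)` degrees of freedom (`n` samples, `g` groups) rather
than the asymptotic `G − 2`: the correlation estimate carries only the
residual degrees of freedom of the expression design, and the wider
reference absorbs its sampling noise. This is the same device used by the
established competitive-test implementations and is what keeps the
measured null rejection rate at the nominal level (with `G − 2` the
measured size ran systematically above 0.055). With user-supplied scores
and no expression matrix the classical `G − 2` is used and the test
reduces exactly to the two-sample t-test on scores. Identical scores
(zero pooled SD) are an explicit error, not a silent `t = 0`, because no
comparison is possible in that degenerate state.

`rho_bar`, `VIF` and the t statistic are all exposed in the output for
auditability.

# Assumption-driven test selection

`compareGroups()` encodes the decision tree as a pure function with a full
audit trail:

1. Shapiro-Wilk normality per group; "normally distributed" for the
   multi-group case means *every* group passes at `alphaAssumption`
   (default 0.05) — the strictest consistent reading.
2. Homogeneity of variances: Bartlett's test under normality,
   Fligner-Killeen's otherwise.
3. Both assumptions hold → Student's t-test (2 groups) or one-way ANOVA
   with Tukey's post hoc (more); otherwise Wilcoxon rank-sum or
   Kruskal-Wallis with Holm-adjusted pairwise Wilcoxon comparisons.

All standard tests are the canonical base-R implementations; the module's
contribution is the selection logic and the recorded `TestDecision` object
(per-group normality p-values, which variance test ran, the chosen branch,
omnibus p, adjusted pairwise table). Wilcoxon p-values follow R's default
small-sample behaviour (exact where possible, otherwise normal
approximation with continuity correction). Groups with fewer than three
values are rejected by name, since the assumption tests are undefined
there. `summarizeValues()` reports both summary conventions — mean with
t-based 95% CI and median with 25th/75th percentiles (linear
interpolation, R's type-7 default) — leaving the choice to the caller.

# Synthetic data: what it emulates and what it does not

## Images

`simulateColocImage()` plants disk-like cells (radius 8–12 px by default)
rendered as filled disks with a 2 px Gaussian-falloff rim — a smooth,
anti-aliased profile that exercises thresholding realistically — plus
additive Gaussian noise clipped to [0, 1]. Ground truth records every
center, radius and planted co-localized pair. Three structural controls
matter:

* `colocFraction` — exactly `round(f·n)` channel-2 cells sit on channel-1
  cells;
* `touchingFraction` — that share of cells is planted closer than two
  radii to a same-channel neighbour, forcing the watershed to work;
* all remaining placements keep at least `2·rmax + 6` px separation, so no
  *accidental* cross-channel overlap contaminates the planted truth, and
  requesting more cells than the frame can hold is an explicit packing
  error.

Not emulated: realistic point-spread functions, 3-D stacks, bleed-through,
uneven illumination, autofluorescence. Passing the recovery tests
therefore shows the chain is correct *given* disk-like cells and additive
noise; it does not certify segmentation quality on arbitrary real
sections, which is why the pipeline writes QC overlays and the original
workflow kept a manual-count fallback.

## Enrichment studies

`simulateEnrichmentStudy()` builds all inputs from one generative model so
they are mutually consistent: category gene pools are disjoint; terms
sample genes from their category's pool; a two-group log2 expression
matrix gives planted-category genes a mean shift of `effectLogFC` (per-gene
spread 0.15·|effect|, so a zero effect is an exact null) and an
equicorrelated residual structure via one shared latent factor per planted
category and sample, which realizes a mean pairwise correlation of exactly
`rhoWithin`; the DE table is then *computed* from that matrix by per-gene
two-sample t-tests with BH adjustment. The shared-factor construction
cannot produce negative equicorrelation, so `rhoWithin < 0` is rejected
with the theoretical bound `−1/(m−1)` named in the message.

Not emulated: overlapping categories, gene-set size heterogeneity,
count-based mean-variance relationships (the matrix is Gaussian on the
log2 scale), hierarchical GO structure, annotation bias.

# Problem sizes and numerical conventions

The package's own verification suite uses these study sizes, chosen to
give stable Monte-Carlo estimates at desk scale:

* imaging recovery: 20 seeds × 30 cells per channel on 384² px frames,
  noise-free/non-touching for exact oracle equality and 5% noise / 30%
  touching for tolerance-based recovery (±5% counts, ±0.05 fraction);
* competitive-test calibration: 2000 null repetitions (20-gene set among
  200 genes, `rhoWithin = 0.3`, 10 samples/group);
* end-to-end recovery: 100 studies at `effectLogFC = 2`,
  `rhoWithin = 0.2`, 6 samples/group, 2 planted categories of 6, plus 40
  null studies;
* decision-tree calibration: 2000 null comparisons of three n = 10
  Gaussian groups (Kolmogorov–Smirnov distance of omnibus p from uniform).

Other conventions: all randomness flows through one seeded generator per
generator call (identical seeds give bit-identical output, and the RNG
state of the caller is restored); hypergeometric tails use `stats::phyper`;
BH/Holm use `stats::p.adjust`; report files carry a provenance header
(package version, seed, config hash) and reruns with identical
configuration are byte-identical.

# Known limitations

* The imaging chain is 2-D; orthogonal projections must be made upstream.
* Pixel-level co-localization by channel multiplication cannot distinguish
  true double labelling from spatial overlap of distinct cells in crowded
  fields; the QC overlays exist to catch this.
* The competitive test assumes approximately equicorrelated sets; strongly
  structured correlation (e.g. two anti-correlated subclusters) is only
  summarized by its mean.
* The term→category mapping is manual curation by design. Results inherit
  its subjectivity, and the shipped example mapping is illustrative only.
* Intensity-based co-localization coefficients (Pearson, Manders), GO
  graph propagation and network-topology analyses are out of scope.
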