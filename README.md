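# graftquant

Quantitative tooling for grafted-cell studies, built around two bespoke
computations that the standard toolchain does not provide:

1. **Automated co-localization cell counting.** In multi-channel confocal
   sections of transplanted, reporter-labelled cells (e.g. mCherry⁺
   mesenchymal stem cells in spinal cord tissue), the fraction of grafted
   cells co-expressing a second marker is estimated by a macro-style
   chain: the selected channels are rescaled and multiplied pixel-wise,
   the product is binarized (Otsu by default), touching cells are split by
   a distance-transform watershed, candidates are gated by area and
   circularity (4πA/P², capped at 1), and counts from the product image
   are divided by counts from the reference channel. Sections pool into
   per-animal fractions, summarized as mean ± t-based 95% CI.

2. **Category-level enrichment aggregation.** Per contrast and direction,
   differentially expressed genes (FDR < 0.01, |log2FC| ≥ 1) are tested
   for gene-set over-representation with the upper-tail hypergeometric
   probability P(X ≥ k), BH-adjusted within each aspect (GO BP/MF/CC,
   KEGG). Terms with FDR < 0.01 are aggregated into manually curated
   categories; each category is reported with its unique term count,
   median term FDR, unique gene union, and a competitive gene-set test
   that accounts for inter-gene correlation through a variance inflation
   factor, VIF = 1 + (m−1)·ρ̄, with ρ̄ the mean pairwise correlation of
   within-group-centered expression of the category's m genes:

       t = (mean_in − mean_out) / (sp · sqrt(VIF/m + 1/(G−m)))

   A category is significant iff median FDR < 0.05 **and** the BH-adjusted
   competitive p ("exact FDR") < 0.05. Categories rank by term count.

Supporting modules provide assumption-driven test selection (Shapiro-Wilk →
Bartlett/Fligner-Killeen → t/ANOVA+Tukey or Wilcoxon/Kruskal-Wallis+Holm)
and synthetic-data generators with complete ground truth: images with a
controllable planted co-localization fraction, touching-cell clusters and
noise; enrichment studies with planted enriched categories and
controllable within-set inter-gene correlation.

See the methods vignette (`vignettes/graftquant-methods.Rmd`) for the
model details, parameter guidance and known limitations.

## Worked example

```r
library(graftquant)

## --- imaging arm: a synthetic section with known truth ---
sim <- simulateColocImage(30, colocFraction = 0.5, noiseSigma = 0.05,
                          touchingFraction = 0.3, shape = c(384L, 384L),
                          seed = 1)
params <- QuantParams(selectedChannels = c(1, 2))
countCoexpressing(sim$image, params)[c("coexpressingCount",
                                       "referenceCount", "fraction")]
#> $coexpressingCount
#> [1] 15
#> $referenceCount
#> [1] 30
#> $fraction
#> [1] 0.5
```

Half of the 30 planted cells were planted as double-positive, and the
chain recovers exactly that: 15 of 30 reference cells co-express, fraction
0.50 — despite 5% noise and 30% of cells touching a neighbour.

```r
## --- enrichment arm: two planted categories among six ---
st <- simulateEnrichmentStudy(nPlanted = 2, seed = 11)
rep <- runEnrichmentPipeline(
  st$deTables, st$geneSets, st$termCategories,
  aspects = setNames(st$termInfo$aspect, st$termInfo$term),
  expression = SummarizedExperiment::assay(st$expression),
  groups = st$expression$group)
rep$report[, c("category", "nTerms", "medianFdr", "nGenes", "fdrExact",
               "significant")]
#>      category nTerms medianFdr nGenes fdrExact significant
#> 1 category_02     10  5.42e-14     65 3.11e-06        TRUE
#> 2 category_01     10  8.97e-12     60 1.17e-03        TRUE
```

Exactly the two planted categories appear, each backed by 10 significant
terms; `medianFdr` is the median of the term-level BH FDRs, `fdrExact` the
BH-adjusted correlation-aware competitive test, and `significant` is their
conjunction at 0.05. The four unplanted categories produced no significant
terms and are absent.

```r
## --- assumption-driven comparison ---
g <- list(sham  = c(5.1, 4.8, 5.3, 5.0, 4.9),
          graft = c(6.2, 6.0, 6.5, 6.1, 6.4))
compareGroups(g)
#> Assumption-driven group comparison
#>   Shapiro-Wilk normality p per group:
#>     sham         0.9276
#>     graft        0.754
#>   variance homogeneity (bartlett): p = 0.8874
#>   chosen test: t-test, omnibus p = 1.111e-05
```

Both groups pass normality, variances are homogeneous, so the tree picks
Student's t — and records every branch decision for the audit trail.

A thin command-line front end over the same functions is available at
`inst/scripts/graftquant.R` (subcommands `simulate`, `quantify`, `enrich`,
`compare`).

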