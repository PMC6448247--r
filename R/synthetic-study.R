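#' Simulate a differential-expression study with planted enriched categories
#'
#' Builds a mutually consistent synthetic study for the enrichment
#' aggregation pipeline: a gene universe partitioned into category gene
#' pools, gene sets (terms) drawn from those pools, a term-to-category map,
#' a two-group log2 expression matrix, and a per-contrast DE table computed
#' from that matrix. Genes of planted categories receive a group-mean shift
#' of `effectLogFC` log2 units and, within each planted category, an
#' equicorrelated noise structure (one shared latent factor per category and
#' sample), so that the mean pairwise within-group Pearson correlation
#' equals `rhoWithin`. Background genes are independent nulls.
#'
#' Because the DE statistics (log2 fold change, p, Benjamini-Hochberg FDR)
#' are computed from the simulated expression matrix with per-gene
#' two-sample t-tests, DE table, expression and gene sets are consistent
#' with one another by construction.
#'
#' Setting `effectLogFC = 0` with `nPlanted > 0` yields a null study that
#' still carries the planted correlation structure, which is how the
#' calibration of the correlation-adjusted competitive test is exercised.
#'
#' @param nGenes genes in the universe.
#' @param nTerms number of gene sets (terms), spread across categories.
#' @param nCategories number of categories (disjoint gene pools).
#' @param nPlanted number of truly enriched categories (the first ones).
#' @param effectLogFC mean group difference (log2 units) of planted genes.
#' @param rhoWithin target mean pairwise correlation within planted
#'   category pools; must lie in `[0, 1)` for the shared-factor
#'   construction (the equicorrelation bound `-1/(m-1)` is reported in the
#'   error for negative requests).
#' @param nSamplesPerGroup samples per group (>= 3).
#' @param genesPerCategory size of each category's gene pool.
#' @param genesPerTerm genes sampled per term from its category pool.
#' @param withinSd within-group SD of log2 expression noise.
#' @param contrast name of the single simulated contrast.
#' @param seed integer seed.
#' @return a list of class `SimulatedStudy` with elements `universe`,
#'   `deTables` (named list of data.frames gene/log2fc/pValue/fdr/contrast),
#'   `geneSets` (named list of gene vectors), `termInfo` (data.frame
#'   term/aspect/category), `termCategories` (named character),
#'   `plantedCategories`, and `expression`
#'   (\link[SummarizedExperiment]{SummarizedExperiment} with a `group`
#'   column).
#' @examples
#' study <- simulateEnrichmentStudy(nGenes = 300, nTerms = 12,
#'   nCategories = 4, nPlanted = 1, seed = 1)
#' head(study$deTables[[1]])
#' @export
simulateEnrichmentStudy <- function(nGenes = 1200L,
                                    nTerms = 60L,
                                    nCategories = 6L,
                                    nPlanted = 2L,
                                    effectLogFC = 2,
                                    rhoWithin = 0.2,
                                    nSamplesPerGroup = 6L,
                                    genesPerCategory = 80L,
                                    genesPerTerm = 15L,
                                    withinSd = 0.5,
                                    contrast = "treated_vs_control",
                                    seed = 1L) {
  stopifnot(nPlanted <= nCategories, nSamplesPerGroup >= 3L,
            nCategories * genesPerCategory <= nGenes,
            genesPerTerm <= genesPerCategory)
  m <- genesPerCategory
  if (rhoWithin >= 1 || rhoWithin < -1 / (m - 1))
    stop(sprintf(
      "rhoWithin must lie in [%.4f, 1) for sets of %d genes (equicorrelation bound -1/(m-1))",
      -1 / (m - 1), m))
  if (rhoWithin < 0)
    stop("the shared-factor construction requires rhoWithin >= 0; ",
         sprintf("requested %.3f (theoretical equicorrelation bound is %.4f)",
                 rhoWithin, -1 / (m - 1)))

  withSeed(seed, {
    universe <- sprintf("g%05d", seq_len(nGenes))
    categories <- sprintf("category_%02d", seq_len(nCategories))
    planted <- categories[seq_len(nPlanted)]

    # disjoint category pools at the front of the universe
    poolIdx <- split(seq_len(nCategories * genesPerCategory),
                     rep(seq_len(nCategories), each = genesPerCategory))
    pools <- lapply(poolIdx, function(i) universe[i])
    names(pools) <- categories

    aspects <- c("BP", "MF", "CC", "KEGG")
    termCat <- categories[rep(seq_len(nCategories), length.out = nTerms)]
    termIds <- sprintf("term_%03d", seq_len(nTerms))
    geneSets <- lapply(seq_len(nTerms), function(i)
      sample(pools[[termCat[i]]], genesPerTerm))
    names(geneSets) <- termIds
    termInfo <- data.frame(term = termIds,
                           aspect = aspects[rep(seq_along(aspects),
                                                length.out = nTerms)],
                           category = termCat)
    termCategories <- stats::setNames(termCat, termIds)

    # expression: 2 groups, baseline + effect + (factor-correlated) noise
    nS <- 2L * nSamplesPerGroup
    group <- rep(c("control", "treated"), each = nSamplesPerGroup)
    baseline <- stats::rnorm(nGenes, mean = 8, sd = 1)
    delta <- numeric(nGenes)
    plantedGenes <- unlist(pools[planted], use.names = FALSE)
    # gene-to-gene spread of the planted effect scales with the effect so
    # that effectLogFC = 0 yields an exact null
    delta[match(plantedGenes, universe)] <- stats::rnorm(
      length(plantedGenes), mean = effectLogFC,
      sd = 0.15 * abs(effectLogFC))

    eps <- matrix(stats::rnorm(nGenes * nS, 0, withinSd), nGenes, nS)
    if (rhoWithin > 0 && nPlanted > 0) {
      for (cat in planted) {
        gi <- match(pools[[cat]], universe)
        f <- stats::rnorm(nS, 0, withinSd)       # shared latent per sample
        eps[gi, ] <- sqrt(rhoWithin) * matrix(f, length(gi), nS,
                                              byrow = TRUE) +
          sqrt(1 - rhoWithin) * eps[gi, ]
      }
    }
    expr <- baseline + outer(delta, as.numeric(group == "treated")) + eps
    dimnames(expr) <- list(universe, sprintf("s%02d", seq_len(nS)))

    de <- deFromExpression(expr, group, contrast = contrast)

    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(log2expr = expr),
      colData = S4Vectors::DataFrame(group = group,
                                     row.names = colnames(expr)))

    structure(list(universe = universe,
                   deTables = stats::setNames(list(de), contrast),
                   geneSets = geneSets,
                   termInfo = termInfo,
                   termCategories = termCategories,
                   plantedCategories = planted,
                   expression = se),
              class = "SimulatedStudy")
  })
}

# Per-gene equal-variance two-sample t-tests on the rows of a log2
# expression matrix, vectorized; BH-adjusted p-values.
deFromExpression <- function(expr, group, contrast = "contrast") {
  g2 <- group == unique(group)[2L]
  n1 <- sum(!g2); n2 <- sum(g2)
  m1 <- rowMeans(expr[, !g2, drop = FALSE])
  m2 <- rowMeans(expr[, g2, drop = FALSE])
  v1 <- rowSums((expr[, !g2, drop = FALSE] - m1)^2) / (n1 - 1L)
  v2 <- rowSums((expr[, g2, drop = FALSE] - m2)^2) / (n2 - 1L)
  sp <- sqrt(((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L))
  tt <- (m2 - m1) / (sp * sqrt(1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tt), df = n1 + n2 - 2L)
  data.frame(gene = rownames(expr),
             log2fc = m2 - m1,
             pValue = p,
             fdr = stats::p.adjust(p, method = "BH"),
             contrast = contrast,
             row.names = NULL)
}

#' @export
print.SimulatedStudy <- function(x, ...) {
  cat(sprintf(
    "SimulatedStudy: %d genes, %d terms in %d categories (%d planted)\n",
    length(x$universe), length(x$geneSets),
    length(unique(x$termCategories)), length(x$plantedCategories)))
  cat(sprintf("  contrasts: %s; expression: %d x %d\n",
              paste(names(x$deTables), collapse = ", "),
              nrow(x$expression), ncol(x$expression)))
  invisible(x)
}
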