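#' Aggregate exported terms into categories
#'
#' For one contrast x direction, groups the exported (significant) terms by
#' their manually assigned category and computes, per category: the number
#' of unique terms, the median of the term-level FDRs, and the number of
#' unique genes in the union of the terms' overlap genes.
#'
#' @param terms data.frame of exported terms (see
#'   [exportSignificantTerms()]) sharing one contrast and direction.
#' @param categoryMap named character vector mapping term id to category
#'   name (each term maps to exactly one category).
#' @return data.frame with columns `contrast`, `direction`, `category`,
#'   `nTerms`, `medianFdr`, `nGenes`, `genes` (list column: the unique gene
#'   union per category).
#' @export
summarizeCategories <- function(terms, categoryMap) {
  if (is.null(terms) || nrow(terms) == 0L)
    stop("no exported terms to aggregate")
  if (length(unique(terms$contrast)) > 1L ||
      length(unique(terms$direction)) > 1L)
    stop("terms must share one contrast and one direction")
  unmapped <- setdiff(terms$term, names(categoryMap))
  if (length(unmapped) > 0L)
    stop("terms without a category: ", paste(unmapped, collapse = ", "))
  terms <- terms[!duplicated(terms$term), , drop = FALSE]
  cat_ <- categoryMap[terms$term]
  out <- lapply(unique(cat_), function(cc) {
    i <- cat_ == cc
    genes <- unique(unlist(terms$overlapGenes[i], use.names = FALSE))
    data.frame(contrast = terms$contrast[1L], direction = terms$direction[1L],
               category = cc, nTerms = sum(i),
               medianFdr = stats::median(terms$fdr[i]),
               nGenes = length(genes), genes = I(list(genes)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Mean inter-gene correlation of a gene set
#'
#' Mean pairwise Pearson correlation of within-group-centered expression
#' rows restricted to the set's genes. Centering within groups removes the
#' treatment effect so that the estimate reflects residual (noise)
#' correlation only.
#'
#' @param expression numeric matrix, genes x samples, rownames = gene ids.
#' @param groups character/factor of length `ncol(expression)`.
#' @param setGenes gene ids (at least 2 present in the matrix).
#' @return numeric(1), the mean off-diagonal correlation.
#' @export
interGeneCorrelation <- function(expression, groups, setGenes) {
  rows <- intersect(setGenes, rownames(expression))
  if (length(rows) < 2L)
    stop("need at least 2 set genes present in the expression matrix")
  x <- expression[rows, , drop = FALSE]
  for (g in unique(groups)) {
    j <- groups == g
    x[, j] <- x[, j, drop = FALSE] - rowMeans(x[, j, drop = FALSE])
  }
  cm <- stats::cor(t(x))
  mean(cm[lower.tri(cm)])
}

#' Competitive gene-set test accounting for inter-gene correlation
#'
#' Tests whether the genes of a set carry larger differential-expression
#' scores than the genes outside it, inflating the null variance of the
#' set mean by the variance inflation factor `VIF = 1 + (m - 1) *
#' rho_bar` (floored at 1), where `rho_bar` is the mean pairwise inter-gene
#' correlation estimated from the expression matrix via
#' [interGeneCorrelation()]. The statistic is
#' `t = (mean_in - mean_out) / (sp * sqrt(VIF/m + 1/(G - m)))`
#' with a pooled score SD `sp` and a two-sided p-value from a t reference
#' with `G - 2` degrees of freedom. Without an expression matrix,
#' `rho_bar = 0` (with a warning) and the test degenerates to the ordinary
#' competitive two-sample t-test on scores.
#'
#' @param geneScores data.frame with columns `gene` and `score` (directional
#'   per-gene statistics, e.g. signed z-scores), one contrast.
#' @param setGenes gene ids of the set (>= 2 scored genes required).
#' @param expression optional genes x samples matrix for `rho_bar`.
#' @param groups group labels for `expression` columns.
#' @param vifFloor lower bound of the VIF (default 1; negative `rho_bar` is
#'   estimated and reported but never deflates the test).
#' @param forceVif optional numeric overriding the VIF entirely (used to
#'   demonstrate the effect of ignoring correlation; not for analysis).
#' @return a list with `m`, `G`, `rhoBar`, `vif`, `tStat`, `df`, `pValue`.
#'
#' @details When `rho_bar` is estimated from an expression matrix, the
#' reference distribution uses `min(n - g, G - 2)` degrees of freedom
#' (`n` samples, `g` groups): the correlation estimate carries only the
#' residual degrees of freedom of the expression design, and referencing
#' the statistic against that df absorbs its sampling noise, keeping the
#' test's size at the nominal level. With scores supplied alone the
#' classical `G - 2` is used.
#' @examples
#' sc <- data.frame(gene = letters[1:6], score = c(2, 1, 0, 1, -1, 0.5))
#' competitiveGeneSetTest(sc, c("a", "b"))
#' @export
competitiveGeneSetTest <- function(geneScores, setGenes,
                                   expression = NULL, groups = NULL,
                                   vifFloor = 1, forceVif = NULL) {
  stopifnot(all(c("gene", "score") %in% names(geneScores)))
  inSet <- geneScores$gene %in% setGenes
  m <- sum(inSet)
  G <- nrow(geneScores)
  if (m < 2L) stop("competitive test requires at least 2 scored set genes")
  if (G <= m) stop("no genes outside the set to compare against")
  rhoBar <- 0
  df <- G - 2
  if (!is.null(expression)) {
    rhoBar <- interGeneCorrelation(expression, groups,
                                   geneScores$gene[inSet])
    df <- min(ncol(expression) - length(unique(groups)), G - 2)
  } else if (is.null(forceVif)) {
    warning("no expression matrix supplied; rho_bar = 0 ",
            "(ordinary competitive t-test)")
  }
  vif <- if (!is.null(forceVif)) forceVif
         else max(1 + (m - 1) * rhoBar, vifFloor)
  sIn <- geneScores$score[inSet]
  sOut <- geneScores$score[!inSet]
  sp2 <- ((m - 1) * stats::var(sIn) + (G - m - 1) * stats::var(sOut)) /
    (G - 2)
  if (sp2 <= 0)
    stop("zero pooled score SD: all gene scores are identical")
  tStat <- (mean(sIn) - mean(sOut)) /
    (sqrt(sp2) * sqrt(vif / m + 1 / (G - m)))
  p <- 2 * stats::pt(-abs(tStat), df = df)
  list(m = m, G = G, rhoBar = rhoBar, vif = vif, tStat = tStat,
       df = df, pValue = p)
}

# Directional per-gene scores from a DE table: signed normal quantiles of
# the two-sided p-value (raw p when present, FDR otherwise -- conservative).
scoresFromDeTable <- function(table) {
  p <- if ("pValue" %in% names(table)) table$pValue else table$fdr
  p <- pmin(pmax(p, 1e-300), 1)
  z <- stats::qnorm(p / 2, lower.tail = FALSE) * sign(table$log2fc)
  data.frame(gene = table$gene, score = z)
}

#' Apply the dual significance rule to category summaries
#'
#' A category is significant when its median term FDR and its competitive
#' gene-set test exact FDR are both strictly below `alpha` (default 0.05).
#'
#' @param summaries data.frame with columns `medianFdr` and `fdrExact`.
#' @param alpha the dual threshold.
#' @return `summaries` with a logical column `significant`.
#' @export
decideSignificance <- function(summaries, alpha = 0.05) {
  stopifnot(all(c("medianFdr", "fdrExact") %in% names(summaries)))
  summaries$significant <- summaries$medianFdr < alpha &
    summaries$fdrExact < alpha
  summaries
}

#' Order categories by number of supporting terms
#'
#' Descending by `nTerms`; ties broken by ascending `medianFdr`, then
#' category name.
#'
#' @param summaries data.frame of category summaries sharing one contrast
#'   and direction.
#' @return the reordered data.frame.
#' @export
rankCategories <- function(summaries) {
  o <- order(-summaries$nTerms, summaries$medianFdr, summaries$category)
  out <- summaries[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop sparsely supported categories from the report
#'
#' Categories backed by fewer than `minTerms` unique terms (default 10)
#' are omitted for interpretability.
#'
#' @param summaries ranked category summaries.
#' @param minTerms retention threshold (`nTerms >= minTerms` retained).
#' @return the retained subset.
#' @export
filterReport <- function(summaries, minTerms = 10L) {
  out <- summaries[summaries$nTerms >= minTerms, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Category-level analysis for one contrast and direction
#'
#' Aggregates exported terms into categories, runs the competitive gene-set
#' test on each category's unique gene union, adjusts the competitive
#' p-values with Benjamini-Hochberg across categories (the "exact FDR"),
#' applies the dual significance rule, ranks, and (optionally) filters.
#'
#' @param exported exported term results for one contrast x direction.
#' @param categoryMap named character, term id -> category.
#' @param deTable the contrast's DE table (for per-gene scores).
#' @param expression optional genes x samples matrix (inter-gene
#'   correlation estimation); `groups` must accompany it.
#' @param groups group labels of the expression columns.
#' @param alpha dual-rule threshold.
#' @param minTerms report retention threshold; `NULL` skips filtering.
#' @return ranked data.frame with columns `contrast`, `direction`,
#'   `category`, `nTerms`, `medianFdr`, `nGenes`, `rhoBar`, `vif`,
#'   `fdrExact`, `significant`.
#' @export
categoryAnalysis <- function(exported, categoryMap, deTable,
                             expression = NULL, groups = NULL,
                             alpha = 0.05, minTerms = 10L) {
  summ <- summarizeCategories(exported, categoryMap)
  scores <- scoresFromDeTable(deTable)
  comp <- lapply(seq_len(nrow(summ)), function(i) {
    r <- competitiveGeneSetTest(scores, summ$genes[[i]],
                                expression = expression, groups = groups)
    data.frame(rhoBar = r$rhoBar, vif = r$vif, tStat = r$tStat,
               pComp = r$pValue)
  })
  comp <- do.call(rbind, comp)
  summ <- cbind(summ, comp)
  summ$fdrExact <- adjustBH(summ$pComp)
  summ <- decideSignificance(summ, alpha = alpha)
  summ <- rankCategories(summ)
  if (!is.null(minTerms)) summ <- filterReport(summ, minTerms = minTerms)
  summ
}
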