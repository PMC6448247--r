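#' Select differentially expressed genes for one direction
#'
#' A gene is called upregulated when `fdr < fdrCutoff` and `log2fc >=
#' lfcCutoff`, downregulated when `fdr < fdrCutoff` and `log2fc <=
#' -lfcCutoff` (defaults FDR < 0.01 and |log2FC| >= 1). Up- and
#' downregulated lists are analyzed separately downstream.
#'
#' @param table data.frame with columns `gene`, `log2fc`, `fdr` for one
#'   contrast.
#' @param direction `"up"` or `"down"`.
#' @param fdrCutoff,lfcCutoff selection thresholds.
#' @return character vector of gene ids.
#' @examples
#' tab <- data.frame(gene = c("a", "b"), log2fc = c(2, 0.5),
#'                   fdr = c(0.005, 0.005))
#' selectDegs(tab, "up")
#' @export
selectDegs <- function(table, direction = c("up", "down"),
                       fdrCutoff = 0.01, lfcCutoff = 1) {
  direction <- match.arg(direction)
  stopifnot(all(c("gene", "log2fc", "fdr") %in% names(table)))
  if (anyDuplicated(table$gene))
    stop("gene ids must be unique within a contrast table")
  keep <- table$fdr < fdrCutoff &
    if (direction == "up") table$log2fc >= lfcCutoff
    else table$log2fc <= -lfcCutoff
  table$gene[keep]
}

#' Hypergeometric over-representation test of one gene set
#'
#' Upper-tail hypergeometric probability `P(X >= k)` of observing at least
#' the realized overlap between a query gene list (n draws) and a gene set
#' (K annotated genes) from a universe of N genes.
#'
#' @param query character vector of query gene ids (must be a subset of the
#'   universe).
#' @param setGenes character vector, the gene set.
#' @param universe character vector, the gene universe.
#' @return a list with `k`, `K`, `n`, `N`, `pValue` and `overlapGenes`.
#'   `K = 0` (no annotated gene in the universe) returns p = 1 with a
#'   warning.
#' @examples
#' oraTest(letters[1:5], letters[1:5], letters[1:20])$pValue  # 1/choose(20,5)
#' @export
oraTest <- function(query, setGenes, universe) {
  bad <- setdiff(query, universe)
  if (length(bad) > 0L)
    stop("query genes not in universe: ", paste(bad, collapse = ", "))
  setU <- intersect(setGenes, universe)
  K <- length(setU)
  n <- length(unique(query))
  N <- length(unique(universe))
  overlap <- intersect(query, setU)
  k <- length(overlap)
  if (K == 0L) {
    warning("gene set has no genes in the universe; p = 1")
    return(list(k = 0L, K = 0L, n = n, N = N, pValue = 1,
                overlapGenes = character(0)))
  }
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  list(k = k, K = K, n = n, N = N, pValue = p, overlapGenes = overlap)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, aligned to the input order, monotone in p rank
#' and capped at 1.
#'
#' @param pValues numeric vector of p-values in \[0, 1\].
#' @return numeric vector of the same length.
#' @export
adjustBH <- function(pValues) {
  stopIfNotProportion(pValues, "p-values")
  stats::p.adjust(pValues, method = "BH")
}

#' Run over-representation analysis over a gene-set collection
#'
#' Applies [oraTest()] to every gene set large enough after intersection
#' with the universe, then adjusts p-values with Benjamini-Hochberg within
#' each family. The adjustment family follows the export rule: one family
#' per aspect (BP/MF/CC/KEGG) x contrast x direction, so `aspects` should
#' be supplied whenever the collection mixes aspects.
#'
#' @param query character vector of (DE) gene ids.
#' @param geneSets named list of gene-id vectors.
#' @param universe character vector; by default all genes of the DE table
#'   should be supplied by the caller.
#' @param aspects optional named character (same names as `geneSets`)
#'   giving each set's aspect; when absent all sets form one family.
#' @param contrast,direction identifiers carried into the result.
#' @param minSetSize sets with fewer universe genes are skipped (default 5).
#' @return data.frame (one row per tested set): `term`, `aspect`,
#'   `contrast`, `direction`, `k`, `K`, `n`, `N`, `pValue`, `fdr`,
#'   `overlapGenes` (list column).
#' @export
oraAnalysis <- function(query, geneSets, universe, aspects = NULL,
                        contrast = NA_character_,
                        direction = NA_character_,
                        minSetSize = 5L) {
  if (is.null(aspects))
    aspects <- stats::setNames(rep("ALL", length(geneSets)), names(geneSets))
  res <- lapply(names(geneSets), function(id) {
    setU <- intersect(geneSets[[id]], universe)
    if (length(setU) < minSetSize) return(NULL)
    r <- oraTest(query, setU, universe)
    data.frame(term = id, aspect = aspects[[id]], contrast = contrast,
               direction = direction, k = r$k, K = r$K, n = r$n, N = r$N,
               pValue = r$pValue, fdr = NA_real_,
               overlapGenes = I(list(r$overlapGenes)))
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    return(data.frame(term = character(0), aspect = character(0),
                      contrast = character(0), direction = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), pValue = numeric(0), fdr = numeric(0),
                      overlapGenes = I(list())))
  for (a in unique(res$aspect)) {
    i <- res$aspect == a
    res$fdr[i] <- adjustBH(res$pValue[i])
  }
  rownames(res) <- NULL
  res
}

#' Export significant terms
#'
#' Retains terms with adjusted p below the export threshold (strictly;
#' FDR < 0.01 by default), carrying their overlap genes. Term results are
#' expected to be adjusted within their aspect x contrast x direction
#' family already (see [oraAnalysis()]).
#'
#' @param results data.frame as returned by [oraAnalysis()].
#' @param fdrCutoff export threshold (strict inequality).
#' @return the retained subset of `results`.
#' @export
exportSignificantTerms <- function(results, fdrCutoff = 0.01) {
  results[!is.na(results$fdr) & results$fdr < fdrCutoff, , drop = FALSE]
}
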