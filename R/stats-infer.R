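#' Assumption-driven group comparison
#'
#' Implements a fixed decision tree for comparing independent groups of
#' measurements. Normality is assessed per group with Shapiro-Wilk;
#' homogeneity of variances with Bartlett's test when every group passed
#' normality (at `alphaAssumption`) and with Fligner-Killeen's test
#' otherwise. When both assumptions hold, two groups are compared with
#' Student's t-test and more groups with one-way ANOVA followed by Tukey's
#' post hoc test; when either fails, two groups are compared with the
#' Wilcoxon rank-sum test and more groups with the Kruskal-Wallis H test
#' followed by pairwise Wilcoxon comparisons with Holm adjustment. Every
#' branch outcome is recorded in the returned [TestDecision-class].
#'
#' @param groups named list of numeric vectors (one per group), or a
#'   data.frame with columns `group` and `value`.
#' @param alphaAssumption significance level for the assumption tests
#'   (default 0.05).
#' @return a [TestDecision-class].
#' @examples
#' set.seed(1)
#' g <- list(a = rnorm(10), b = rnorm(10, 1), c = rnorm(10))
#' compareGroups(g)
#' @export
compareGroups <- function(groups, alphaAssumption = 0.05) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "value") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  stopifnot(length(groups) >= 2L)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  small <- names(groups)[vapply(groups, length, integer(1L)) < 3L]
  if (length(small) > 0L)
    stop("groups with fewer than 3 values (assumption tests impossible): ",
         paste(small, collapse = ", "))

  normP <- vapply(groups, function(x) {
    if (stats::sd(x) == 0) return(0)   # degenerate: clearly non-normal
    stats::shapiro.test(x)$p.value
  }, numeric(1L))
  allNormal <- all(normP > alphaAssumption)

  values <- unlist(groups, use.names = FALSE)
  glab <- factor(rep(names(groups), vapply(groups, length, integer(1L))))
  varTest <- if (allNormal) "bartlett" else "fligner-killeen"
  varP <- tryCatch({
    if (allNormal) stats::bartlett.test(values, glab)$p.value
    else stats::fligner.test(values, glab)$p.value
  }, error = function(e) 0)
  parametric <- allNormal && varP > alphaAssumption

  k <- length(groups)
  if (k == 2L) {
    if (parametric) {
      ht <- stats::t.test(groups[[1L]], groups[[2L]], var.equal = TRUE)
      chosen <- "t-test"
    } else {
      ht <- suppressWarnings(stats::wilcox.test(groups[[1L]], groups[[2L]]))
      chosen <- "wilcoxon"
    }
    omnibus <- ht$p.value
    pairwise <- data.frame(group1 = names(groups)[1L],
                           group2 = names(groups)[2L],
                           p.adj = omnibus)
  } else {
    if (parametric) {
      fit <- stats::aov(values ~ glab)
      omnibus <- summary(fit)[[1L]][["Pr(>F)"]][1L]
      tk <- stats::TukeyHSD(fit)$glab
      pr <- strsplit(rownames(tk), "-", fixed = TRUE)
      pairwise <- data.frame(group1 = vapply(pr, `[`, "", 1L),
                             group2 = vapply(pr, `[`, "", 2L),
                             p.adj = tk[, "p adj"])
      chosen <- "anova+tukey"
    } else {
      omnibus <- stats::kruskal.test(values, glab)$p.value
      pw <- suppressWarnings(
        stats::pairwise.wilcox.test(values, glab, p.adjust.method = "holm"))
      pm <- pw$p.value
      pairs <- which(!is.na(pm), arr.ind = TRUE)
      pairwise <- data.frame(group1 = rownames(pm)[pairs[, 1L]],
                             group2 = colnames(pm)[pairs[, 2L]],
                             p.adj = pm[pairs])
      chosen <- "kruskal-wallis+holm"
    }
  }
  rownames(pairwise) <- NULL
  new("TestDecision",
      normalityP = normP,
      varianceTestUsed = varTest,
      varianceP = varP,
      chosenTest = chosen,
      omnibusP = omnibus,
      pairwise = pairwise,
      alphaAssumption = alphaAssumption)
}

#' Holm step-down multiple-testing adjustment
#'
#' @param pValues numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values aligned to the input order, monotone and
#'   capped at 1.
#' @export
holmAdjust <- function(pValues) {
  stopIfNotProportion(pValues, "p-values")
  stats::p.adjust(pValues, method = "holm")
}

#' Summarize a sample both parametrically and robustly
#'
#' Returns the mean with its t-based 95% confidence interval alongside the
#' median with the 25th and 75th percentiles (linear interpolation), so the
#' caller can report whichever suits the distributional behaviour of the
#' data. With a single value the CI is flagged undefined.
#'
#' @param values numeric vector (>= 1 finite value).
#' @param level confidence level for the mean CI.
#' @return a list with `n`, `mean`, `ciLower`, `ciUpper`, `ciDefined`,
#'   `median`, `q25`, `q75`.
#' @examples
#' summarizeValues(c(1, 2, 3))
#' @export
summarizeValues <- function(values, level = 0.95) {
  values <- values[is.finite(values)]
  if (length(values) < 1L) stop("no finite values to summarize")
  ci <- meanCI(values, level = level)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(n = length(values), mean = ci$mean,
       ciLower = ci$lower, ciUpper = ci$upper, ciDefined = ci$defined,
       median = q[2L], q25 = q[1L], q75 = q[3L])
}
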