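# Category aggregation, the correlation-adjusted competitive test, the dual
# significance rule, ranking and report filtering.

mkTerms <- function(fdrs, genes, cats = NULL) {
  n <- length(fdrs)
  data.frame(term = sprintf("t%02d", seq_len(n)),
             aspect = "BP", contrast = "c1", direction = "up",
             k = lengths(genes), K = 10L, n = 20L, N = 100L,
             pValue = fdrs / 2, fdr = fdrs,
             overlapGenes = I(genes))
}

test_that("category summaries compute median FDR and unique gene unions", {
  terms <- mkTerms(c(0.001, 0.002, 0.003),
                   list(c("A", "B"), c("B", "C"), c("C")))
  map <- setNames(rep("cat1", 3), terms$term)
  s <- summarizeCategories(terms, map)
  expect_equal(s$nTerms, 3L)
  expect_equal(s$medianFdr, 0.002)
  expect_equal(s$nGenes, 3L)
  expect_setequal(s$genes[[1]], c("A", "B", "C"))
  expect_error(summarizeCategories(terms[0, ], map), "no exported terms")
})

test_that("median FDR equals the sort-and-middle oracle on a larger category", {
  set.seed(5)
  fdrs <- runif(12, 0, 0.01)
  terms <- mkTerms(fdrs, replicate(12, sample(letters, 3), simplify = FALSE))
  map <- setNames(rep("big", 12), terms$term)
  s <- summarizeCategories(terms, map)
  srt <- sort(fdrs)
  expect_equal(s$medianFdr, (srt[6] + srt[7]) / 2)
})

test_that("competitive test reduces to the classical two-sample t when VIF=1", {
  set.seed(8)
  sc <- data.frame(gene = sprintf("g%02d", 1:12),
                   score = c(2, 1, rnorm(10)))
  r <- competitiveGeneSetTest(sc, c("g01", "g02"), forceVif = 1)
  tOracle <- bruteTwoSampleT(sc$score[1:2], sc$score[3:12])
  expect_equal(r$tStat, tOracle, tolerance = 1e-9)
  expect_equal(r$df, 10)
  # and against the canonical implementation as a second, independent route
  tt <- t.test(sc$score[1:2], sc$score[3:12], var.equal = TRUE)
  expect_equal(r$tStat, unname(tt$statistic), tolerance = 1e-9)
  expect_equal(r$pValue, tt$p.value, tolerance = 1e-9)
})

test_that("degenerate competitive-test inputs raise explicit errors", {
  sc <- data.frame(gene = letters[1:6], score = rep(1, 6))
  expect_error(suppressWarnings(competitiveGeneSetTest(sc, c("a", "b"))),
               "zero pooled")
  sc2 <- data.frame(gene = letters[1:6], score = rnorm(6))
  expect_error(competitiveGeneSetTest(sc2, "a"), "at least 2")
  expect_error(competitiveGeneSetTest(sc2, letters[1:6]), "outside")
})

test_that("VIF construction floors at 1 and reflects planted correlation", {
  st <- simulateEnrichmentStudy(nGenes = 200, nTerms = 4, nCategories = 2,
                                nPlanted = 1, effectLogFC = 0,
                                rhoWithin = 0.3, nSamplesPerGroup = 30,
                                genesPerCategory = 25, seed = 13)
  de <- st$deTables[[1]]
  sc <- zScores(de)
  pool <- unique(unlist(
    st$geneSets[names(which(st$termCategories == st$plantedCategories))]))
  ex <- SummarizedExperiment::assay(st$expression)
  r <- competitiveGeneSetTest(sc, pool, expression = ex,
                              groups = st$expression$group)
  expect_equal(r$vif, 1 + (r$m - 1) * r$rhoBar)
  expect_gt(r$rhoBar, 0.15)
  expect_gte(r$vif, 1)
  # uncorrelated background genes: estimated rho near 0, VIF floored at 1
  bg <- tail(st$universe, 20)
  rBg <- competitiveGeneSetTest(sc, bg, expression = ex,
                                groups = st$expression$group)
  expect_lt(abs(rBg$rhoBar), 0.1)
  expect_gte(rBg$vif, 1)
})

test_that("missing expression degenerates to rho = 0 with a warning", {
  sc <- data.frame(gene = letters[1:10], score = rnorm(10))
  expect_warning(r <- competitiveGeneSetTest(sc, letters[1:3]), "rho")
  expect_equal(r$rhoBar, 0)
  expect_equal(r$vif, 1)
})

test_that("the dual rule requires both FDRs strictly below the threshold", {
  s <- data.frame(medianFdr = c(0.04, 0.04, 0.05, 0.06),
                  fdrExact = c(0.06, 0.04, 0.01, 0.01))
  out <- decideSignificance(s)
  expect_equal(out$significant, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("categories rank by term count with the stated tie-breaks", {
  s <- data.frame(category = c("d", "a", "b", "c", "e"),
                  nTerms = c(11, 159, 46, 22, 11),
                  medianFdr = c(2e-4, 2.1e-4, 3.6e-4, 1.7e-6, 1.9e-4))
  r <- rankCategories(s)
  expect_equal(r$nTerms, c(159, 46, 22, 11, 11))
  # tie at 11 broken by ascending median FDR
  expect_equal(r$category[4:5], c("e", "d"))
  # ranking is a permutation
  expect_setequal(r$category, s$category)
  expect_equal(rankCategories(s[2, , drop = FALSE])$category, "a")
})

test_that("the report filter drops categories with fewer than ten terms", {
  s <- data.frame(category = c("a", "b", "c"), nTerms = c(9, 10, 30),
                  medianFdr = 0.001)
  out <- filterReport(s)
  expect_equal(out$category, c("b", "c"))
  # predicate oracle on a mixed list
  expect_identical(filterReport(s, 10L)$category,
                   s$category[s$nTerms >= 10])
})

test_that("null competitive-test calibration holds and ignoring VIF inflates",
{
  nrep <- 400
  rej <- rej1 <- logical(nrep)
  for (i in seq_len(nrep)) {
    st <- simulateEnrichmentStudy(nGenes = 200, nTerms = 1, nCategories = 1,
      nPlanted = 1, effectLogFC = 0, rhoWithin = 0.3, nSamplesPerGroup = 10,
      genesPerCategory = 20, genesPerTerm = 20, seed = 40000 + i)
    de <- st$deTables[[1]]
    sc <- zScores(de)
    r <- competitiveGeneSetTest(sc, st$geneSets[[1]],
      expression = SummarizedExperiment::assay(st$expression),
      groups = st$expression$group)
    r1 <- competitiveGeneSetTest(sc, st$geneSets[[1]], forceVif = 1)
    rej[i] <- r$pValue < 0.05
    rej1[i] <- r1$pValue < 0.05
  }
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)   # wider than the 2000-rep band: 400 reps here
  expect_gt(mean(rej1), 0.1)
})
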