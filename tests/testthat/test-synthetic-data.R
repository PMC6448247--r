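# Generators: planted ground truth, reproducibility, degenerate inputs.

test_that("empty image request yields empty channels and ground truth", {
  sim <- simulateColocImage(0, colocFraction = 0.7, seed = 1)
  expect_equal(nChannels(sim$image), 2L)
  expect_true(all(vapply(channels(sim$image), max, numeric(1)) == 0))
  expect_equal(nrow(sim$truth@colocPairs), 0L)
  expect_equal(truthColocCount(sim$truth), 0L)
})

test_that("planted co-localization structure matches the requested fraction", {
  sim <- simulateColocImage(10, colocFraction = 1, noiseSigma = 0, seed = 1)
  expect_equal(nrow(sim$truth@colocPairs), 10L)
  sim2 <- simulateColocImage(20, colocFraction = 0.5, noiseSigma = 0, seed = 7)
  expect_equal(nrow(sim2$truth@colocPairs), 10L)
  # pixel-overlap count on noise-free masks equals the planted count exactly
  expect_equal(truthColocCount(sim2$truth), 10L)
  # coloc pairs reference coincident centers
  cp <- sim2$truth@colocPairs
  a <- sim2$truth@centers[[1]][cp$indexA, , drop = FALSE]
  b <- sim2$truth@centers[[2]][cp$indexB, , drop = FALSE]
  expect_true(all(sqrt(rowSums((a - b)^2)) <= 1))
})

test_that("image generation is bit-identical under a fixed seed", {
  a <- simulateColocImage(15, colocFraction = 0.4, noiseSigma = 0.03,
                          touchingFraction = 0.2, seed = 42)
  b <- simulateColocImage(15, colocFraction = 0.4, noiseSigma = 0.03,
                          touchingFraction = 0.2, seed = 42)
  expect_identical(channels(a$image), channels(b$image))
  expect_identical(a$truth@centers, b$truth@centers)
  c <- simulateColocImage(15, colocFraction = 0.4, noiseSigma = 0.03,
                          touchingFraction = 0.2, seed = 43)
  expect_false(identical(channels(a$image), channels(c$image)))
})

test_that("impossible packing raises an explicit error", {
  expect_error(
    simulateColocImage(500, colocFraction = 0, shape = c(128L, 128L),
                       seed = 1),
    "packing")
  expect_error(
    simulateColocImage(10, colocFraction = 0, shape = c(20L, 20L), seed = 1),
    "too small")
})

test_that("enrichment study is internally consistent and reproducible", {
  st <- simulateEnrichmentStudy(nGenes = 400, nTerms = 16, nCategories = 4,
                                nPlanted = 1, seed = 3)
  expect_true(all(unlist(st$geneSets) %in% st$universe))
  expect_true(all(st$plantedCategories %in% st$termCategories))
  expect_equal(sort(names(st$geneSets)), sort(names(st$termCategories)))
  expect_equal(ncol(st$expression), 12L)
  expect_equal(nrow(st$deTables[[1]]), 400L)
  st2 <- simulateEnrichmentStudy(nGenes = 400, nTerms = 16, nCategories = 4,
                                 nPlanted = 1, seed = 3)
  expect_identical(st$deTables, st2$deTables)
  expect_identical(
    SummarizedExperiment::assay(st$expression),
    SummarizedExperiment::assay(st2$expression))
})

test_that("a null study (no planted categories) carries no real signal", {
  st <- simulateEnrichmentStudy(nGenes = 2000, nTerms = 20, nCategories = 5,
                                nPlanted = 0, seed = 5)
  de <- st$deTables[[1]]
  hits <- sum(de$fdr < 0.01 & abs(de$log2fc) >= 1)
  expect_lte(hits, 2L)  # BH false positives only
})

test_that("planted within-set correlation converges to the requested value", {
  st <- simulateEnrichmentStudy(nGenes = 300, nTerms = 8, nCategories = 2,
                                nPlanted = 1, effectLogFC = 0,
                                rhoWithin = 0.4, nSamplesPerGroup = 100,
                                genesPerCategory = 30, seed = 9)
  ex <- SummarizedExperiment::assay(st$expression)
  gr <- st$expression$group
  plantedPool <- unique(unlist(
    st$geneSets[names(which(st$termCategories == st$plantedCategories))]))
  rhoPlanted <- interGeneCorrelation(ex, gr, plantedPool)
  expect_lt(abs(rhoPlanted - 0.4), 0.05)
  bgGenes <- tail(st$universe, 30)
  rhoBg <- interGeneCorrelation(ex, gr, bgGenes)
  expect_lt(abs(rhoBg), 0.05)
})

test_that("rho outside the feasible range errors naming the bound", {
  expect_error(
    simulateEnrichmentStudy(nGenes = 200, nTerms = 4, nCategories = 2,
                            nPlanted = 1, rhoWithin = 1.2,
                            genesPerCategory = 20, seed = 1),
    "-1/(m-1)", fixed = TRUE)
  expect_error(
    simulateEnrichmentStudy(nGenes = 200, nTerms = 4, nCategories = 2,
                            nPlanted = 1, rhoWithin = -0.5,
                            genesPerCategory = 20, seed = 1),
    "bound")
})
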