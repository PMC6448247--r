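#' Run the full enrichment aggregation pipeline
#'
#' For every contrast and direction: select differentially expressed genes,
#' run over-representation analysis per aspect family, export significant
#' terms, aggregate them into categories, run the correlation-adjusted
#' competitive gene-set test on each category's unique gene union, apply
#' the dual significance rule, rank and filter. Deterministic given inputs.
#'
#' @param deTables named list of DE data.frames (one per contrast) with
#'   columns `gene`, `log2fc`, `fdr` (optionally `pValue`).
#' @param geneSets named list of gene-id vectors.
#' @param categoryMap named character, term id -> category.
#' @param aspects optional named character, term id -> aspect (BP/MF/CC/
#'   KEGG); one adjustment family per aspect when given.
#' @param expression optional genes x samples matrix (or the
#'   `SimulatedStudy` SummarizedExperiment assay) for inter-gene
#'   correlation; `groups` must accompany it.
#' @param groups group labels of the expression columns.
#' @param degFdr,degLfc DE gene selection thresholds (defaults 0.01, 1).
#' @param termFdr term export threshold (default 0.01).
#' @param categoryAlpha dual-rule threshold (default 0.05).
#' @param reportMinTerms report retention threshold (default 10; `NULL`
#'   retains all).
#' @param minSetSize minimum gene-set size after universe intersection.
#' @param outDir optional directory; when given, the term table and the
#'   category report are written as TSV with provenance headers.
#' @param seed recorded in output headers (the pipeline itself is
#'   deterministic).
#' @return a list with `terms` (all exported terms) and `report` (the
#'   Table-2-style category report across contrasts and directions).
#' @examples
#' study <- simulateEnrichmentStudy(nGenes = 400, nTerms = 24,
#'   nCategories = 4, nPlanted = 1, seed = 1)
#' res <- runEnrichmentPipeline(study$deTables, study$geneSets,
#'   study$termCategories,
#'   aspects = setNames(study$termInfo$aspect, study$termInfo$term),
#'   expression = SummarizedExperiment::assay(study$expression),
#'   groups = study$expression$group, reportMinTerms = NULL)
#' res$report[, c("category", "nTerms", "medianFdr", "fdrExact",
#'                "significant")]
#' @export
runEnrichmentPipeline <- function(deTables, geneSets, categoryMap,
                                  aspects = NULL,
                                  expression = NULL, groups = NULL,
                                  degFdr = 0.01, degLfc = 1,
                                  termFdr = 0.01, categoryAlpha = 0.05,
                                  reportMinTerms = 10L, minSetSize = 5L,
                                  outDir = NULL, seed = NA) {
  stopifnot(is.list(deTables), length(deTables) > 0L)
  if (is.null(names(deTables)))
    names(deTables) <- paste0("contrast", seq_along(deTables))
  allTerms <- list()
  allReport <- list()
  for (contrast in names(deTables)) {
    de <- deTables[[contrast]]
    universe <- de$gene
    for (direction in c("up", "down")) {
      stage <- sprintf("%s/%s", contrast, direction)
      query <- selectDegs(de, direction, fdrCutoff = degFdr,
                          lfcCutoff = degLfc)
      if (length(query) == 0L) next
      ora <- tryCatch(
        oraAnalysis(query, geneSets, universe, aspects = aspects,
                    contrast = contrast, direction = direction,
                    minSetSize = minSetSize),
        error = function(e) stop("ORA failed for ", stage, ": ",
                                 conditionMessage(e), call. = FALSE))
      exported <- exportSignificantTerms(ora, fdrCutoff = termFdr)
      if (nrow(exported) == 0L) next
      allTerms[[stage]] <- exported
      rep_ <- tryCatch(
        categoryAnalysis(exported, categoryMap, de,
                         expression = expression, groups = groups,
                         alpha = categoryAlpha, minTerms = reportMinTerms),
        error = function(e) stop("category aggregation failed for ", stage,
                                 ": ", conditionMessage(e), call. = FALSE))
      allReport[[stage]] <- rep_
    }
  }
  terms <- if (length(allTerms)) do.call(rbind, allTerms) else NULL
  report <- if (length(allReport)) do.call(rbind, allReport) else
    data.frame(contrast = character(0), direction = character(0),
               category = character(0), nTerms = integer(0),
               medianFdr = numeric(0), nGenes = integer(0),
               rhoBar = numeric(0), vif = numeric(0), tStat = numeric(0),
               pComp = numeric(0), fdrExact = numeric(0),
               significant = logical(0))
  if (!is.null(terms)) rownames(terms) <- NULL
  rownames(report) <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    cfg <- list(degFdr = degFdr, degLfc = degLfc, termFdr = termFdr,
                categoryAlpha = categoryAlpha,
                reportMinTerms = reportMinTerms, minSetSize = minSetSize)
    if (!is.null(terms)) {
      tOut <- terms
      tOut$genes <- NULL
      writeReportTsv(tOut, file.path(outDir, "terms.tsv"), cfg, seed)
    }
    rOut <- report
    rOut$genes <- NULL
    writeReportTsv(rOut, file.path(outDir, "category_report.tsv"), cfg, seed)
  }
  list(terms = terms, report = report)
}

#' Run the imaging quantification pipeline over a manifest
#'
#' Quantifies every image listed in the manifest (per-image co-expressing
#' and reference counts), pools sections into per-animal co-expression
#' fractions, and summarizes the group by mean and 95% CI. Unreadable
#' images are skipped with a warning and reported in the result.
#'
#' @param manifest data.frame with columns `file`, `animalId`, `sectionId`
#'   (paths to TIFF/PNG images), or with a column `image` holding
#'   [MultiChannelImage-class] objects in a list.
#' @param params a [QuantParams-class].
#' @param outDir optional directory for the per-image table and the group
#'   summary (TSV with provenance headers) plus QC overlay PNGs.
#' @param seed recorded in output headers.
#' @return a list with `perImage` (data.frame), `group` (see
#'   [estimateFractionPerGroup()]), `skipped` (character vector of failed
#'   files), and `ok` (logical: TRUE iff nothing was skipped).
#' @export
runImagingPipeline <- function(manifest, params, outDir = NULL, seed = NA) {
  if (is.null(manifest) || nrow(manifest) == 0L)
    stop("empty image manifest")
  stopifnot(all(c("animalId", "sectionId") %in% names(manifest)))
  rows <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(manifest))) {
    img <- tryCatch({
      if ("image" %in% names(manifest)) manifest$image[[i]]
      else readImageChannels(manifest$file[i])
    }, error = function(e) e)
    if (inherits(img, "error")) {
      warning("skipping unreadable image ",
              if ("file" %in% names(manifest)) manifest$file[i] else i,
              ": ", conditionMessage(img))
      skipped <- c(skipped,
                   if ("file" %in% names(manifest)) manifest$file[i]
                   else as.character(i))
      next
    }
    r <- countCoexpressing(img, params,
                           sectionId = as.character(manifest$sectionId[i]),
                           animalId = as.character(manifest$animalId[i]))
    rows[[length(rows) + 1L]] <- data.frame(
      animalId = r$animalId, sectionId = r$sectionId,
      coexpressingCount = r$coexpressingCount,
      referenceCount = r$referenceCount,
      fraction = r$fraction)
    if (!is.null(outDir)) {
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      writeQcOverlay(img, params, file.path(
        outDir, sprintf("qc_%s_%s.png", r$animalId, r$sectionId)))
    }
  }
  if (length(rows) == 0L) stop("no readable images in manifest")
  perImage <- do.call(rbind, rows)
  group <- estimateFractionPerGroup(perImage)
  if (!is.null(outDir)) {
    writeReportTsv(perImage, file.path(outDir, "per_image_counts.tsv"),
                   list(params = "QuantParams"), seed)
    writeReportTsv(group$perAnimal,
                   file.path(outDir, "per_animal_fractions.tsv"),
                   list(params = "QuantParams"), seed)
  }
  list(perImage = perImage, group = group, skipped = skipped,
       ok = length(skipped) == 0L)
}

# QC overlay: reference channel in grey, gated object outlines marked in
# red (reference) and green (co-expressing product objects).
writeQcOverlay <- function(image, params, path) {
  ref <- rescale01(combineChannels(image, params@referenceChannel))
  rgb <- array(rep(ref, 3L), dim = c(dim(ref), 3L))
  paint <- function(rgb, grid, channel) {
    mask <- binarizeImage(grid, params)
    lab <- splitTouching(mask, params)
    keep <- filterObjects(lab, params)$label
    obj <- matrix(lab %in% keep & lab > 0, nrow(lab), ncol(lab))
    # outline = object pixels adjacent to non-object pixels
    er <- obj
    er[-1, ] <- er[-1, ] & obj[-nrow(obj), ]
    er[-nrow(obj), ] <- er[-nrow(obj), ] & obj[-1, ]
    er[, -1] <- er[, -1] & obj[, -ncol(obj)]
    er[, -ncol(obj)] <- er[, -ncol(obj)] & obj[, -1]
    outline <- obj & !er
    for (k in 1:3) {
      plane <- rgb[, , k]
      plane[outline] <- as.numeric(k == channel)
      rgb[, , k] <- plane
    }
    rgb
  }
  rgb <- paint(rgb, combineChannels(image, params@referenceChannel), 1L)
  rgb <- paint(rgb, combineChannels(image, params@selectedChannels), 2L)
  png::writePNG(rgb, path)
  invisible(path)
}
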