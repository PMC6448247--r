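# Readers and writers for the pipeline's on-disk formats: TIFF/PNG images,
# TSV tables, GMT gene-set collections, YAML run configs.

#' Read a multi-channel image from TIFF or PNG
#'
#' Multi-page TIFFs map pages to channels; RGB PNGs (and RGB TIFFs) map
#' color planes to channels.
#'
#' @param path file path (`.tif`, `.tiff` or `.png`).
#' @param sourceId identifier stored on the image; defaults to the file
#'   name.
#' @return a [MultiChannelImage-class].
#' @export
readImageChannels <- function(path, sourceId = basename(path)) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    chans <- unlist(lapply(pages, planeList), recursive = FALSE)
  } else if (ext == "png") {
    a <- png::readPNG(path)
    chans <- planeList(a)
  } else {
    stop("unsupported image format: ", ext)
  }
  MultiChannelImage(chans, sourceId = sourceId)
}

# split a 2-D or 3-D array into a list of matrices (drop alpha plane)
planeList <- function(a) {
  if (length(dim(a)) == 2L) return(list(a))
  n <- min(dim(a)[3L], 3L)
  lapply(seq_len(n), function(k) a[, , k])
}

#' Write a multi-channel image as a multi-page TIFF
#'
#' One page per channel; intensities are clipped to \[0, 1\].
#'
#' @param image a [MultiChannelImage-class]
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeImageChannels <- function(image, path) {
  pages <- lapply(channels(image), function(m) pmin(pmax(m, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Tab-separated with at least the columns `gene`, `log2fc`, `fdr`
#' (optionally `pValue`, `contrast`).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readDeTable <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene", "log2fc", "fdr")
  if (!all(need %in% names(d)))
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  d
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file (term id, description, then tab-separated gene ids).
#' @return named list of gene-id character vectors.
#' @export
readGmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets as GMT
#'
#' @param geneSets named list of gene-id vectors.
#' @param path output path.
#' @param descriptions optional character vector of term descriptions
#'   (defaults to the term ids).
#' @return the path, invisibly.
#' @export
writeGmt <- function(geneSets, path, descriptions = names(geneSets)) {
  lines <- vapply(seq_along(geneSets), function(i) {
    paste(c(names(geneSets)[i], descriptions[i], geneSets[[i]]),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a term-to-category mapping
#'
#' Two-column TSV (`term`, `category`); every term must map to exactly one
#' category.
#'
#' @param path TSV path.
#' @return named character vector (term id -> category).
#' @export
readCategoryMap <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(d) < 2L) stop("category map needs two columns (term, category)")
  names(d)[1:2] <- c("term", "category")
  if (anyDuplicated(d$term))
    stop("terms mapped to more than one category: ",
         paste(unique(d$term[duplicated(d$term)]), collapse = ", "))
  stats::setNames(d$category, d$term)
}

#' Read a run configuration
#'
#' A YAML file of key/value pairs (paths, thresholds, quantification
#' parameters, seed). Unknown keys are preserved.
#'
#' @param path YAML path.
#' @return named list.
#' @export
readRunConfig <- function(path) {
  yaml::read_yaml(path)
}

# Write a TSV with a provenance comment header (version, seed, config hash).
writeReportTsv <- function(d, path, config = list(), seed = NA) {
  listCols <- vapply(d, is.list, logical(1L))
  for (j in which(listCols))
    d[[j]] <- vapply(d[[j]], paste, character(1L), collapse = ";")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# graftquant %s | seed=%s | config=%s",
                     as.character(utils::packageVersion("graftquant")),
                     as.character(seed), configHash(config)), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
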