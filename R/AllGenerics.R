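#' Number of channels in an image
#' @param x a [MultiChannelImage-class]
#' @return integer(1)
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Extract the channel list of an image
#' @param x a [MultiChannelImage-class]
#' @return list of numeric matrices
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))

#' Image dimensions (rows, cols)
#' @param x a [MultiChannelImage-class]
#' @return integer(2)
#' @export
setGeneric("imageShape", function(x) standardGeneric("imageShape"))

#' @rdname nChannels
setMethod("nChannels", "MultiChannelImage", function(x) length(x@channels))

#' @rdname channels
setMethod("channels", "MultiChannelImage", function(x) x@channels)

#' @rdname imageShape
setMethod("imageShape", "MultiChannelImage",
          function(x) as.integer(dim(x@channels[[1L]])))

setMethod("show", "MultiChannelImage", function(object) {
  d <- dim(object@channels[[1L]])
  cat(sprintf("MultiChannelImage: %d channel(s), %d x %d px",
              length(object@channels), d[1L], d[2L]))
  if (!is.na(object@sourceId)) cat(sprintf(" [%s]", object@sourceId))
  cat("\n")
  rng <- vapply(object@channels, function(m) range(m), numeric(2L))
  for (k in seq_along(object@channels))
    cat(sprintf("  channel %d: intensity range [%.4g, %.4g]\n",
                k, rng[1L, k], rng[2L, k]))
})

setMethod("show", "QuantParams", function(object) {
  cat("QuantParams\n")
  cat("  selected channels :", paste(object@selectedChannels, collapse = ", "),
      "\n")
  cat("  reference channel :", object@referenceChannel, "\n")
  cat("  threshold         :", object@thresholdMethod,
      if (object@thresholdMethod == "fixed")
        sprintf("(%.4g)", object@fixedThreshold) else "", "\n")
  cat(sprintf("  area gate         : [%g, %g] px^2\n",
              object@minArea, object@maxArea))
  cat(sprintf("  circularity gate  : [%g, %g]\n",
              object@minCircularity, object@maxCircularity))
  cat(sprintf("  watershed min dist: %g px\n", object@watershedMinDistance))
})

setMethod("show", "ImageGroundTruth", function(object) {
  n <- vapply(object@centers, nrow, integer(1L))
  cat(sprintf(
    "ImageGroundTruth: %s cells per channel, %d co-localized pair(s), %d x %d px\n",
    paste(n, collapse = "/"), nrow(object@colocPairs),
    object@shape[1L], object@shape[2L]))
})

setMethod("show", "TestDecision", function(object) {
  cat("Assumption-driven group comparison\n")
  cat("  Shapiro-Wilk normality p per group:\n")
  for (g in names(object@normalityP))
    cat(sprintf("    %-12s %.4g\n", g, object@normalityP[[g]]))
  cat(sprintf("  variance homogeneity (%s): p = %.4g\n",
              object@varianceTestUsed, object@varianceP))
  cat(sprintf("  chosen test: %s, omnibus p = %.4g\n",
              object@chosenTest, object@omnibusP))
  if (nrow(object@pairwise)) {
    cat("  pairwise (adjusted):\n")
    for (i in seq_len(nrow(object@pairwise)))
      cat(sprintf("    %s vs %s: p.adj = %.4g\n",
                  object@pairwise$group1[i], object@pairwise$group2[i],
                  object@pairwise$p.adj[i]))
  }
})
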