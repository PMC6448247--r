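#' @import methods
NULL

#' Multi-channel fluorescence image
#'
#' Container for up to three registered two-dimensional intensity grids,
#' one per confocal channel. All channels share one pixel grid; intensities
#' are finite and non-negative (arbitrary units, typically rescaled to
#' \[0, 1\] before analysis).
#'
#' @slot channels list of numeric matrices of identical dimension (1 to 3).
#' @slot pixelSize numeric(1), physical pixel size in micrometres per pixel,
#'   or `NA_real_` when unknown. Informational only; all gating parameters
#'   are expressed in pixels.
#' @slot sourceId character(1) identifier of the originating section/animal.
#'
#' @seealso [MultiChannelImage()], [combineChannels()], [countCoexpressing()]
#' @exportClass MultiChannelImage
setClass("MultiChannelImage",
  representation(
    channels = "list",
    pixelSize = "numeric",
    sourceId = "character"
  ),
  prototype(pixelSize = NA_real_, sourceId = NA_character_)
)

setValidity("MultiChannelImage", function(object) {
  ch <- object@channels
  if (length(ch) < 1L || length(ch) > 3L)
    return("number of channels must be between 1 and 3")
  if (!all(vapply(ch, is.matrix, logical(1L))))
    return("every channel must be a numeric matrix")
  dims <- vapply(ch, dim, integer(2L))
  if (length(ch) > 1L && any(dims[, -1L, drop = FALSE] != dims[, 1L]))
    return("all channels must have identical dimensions")
  vals <- unlist(ch, use.names = FALSE)
  if (any(!is.finite(vals)))
    return("channel intensities must be finite")
  if (any(vals < 0))
    return("channel intensities must be non-negative")
  if (length(object@pixelSize) != 1L)
    return("pixelSize must be a single value")
  TRUE
})

#' Construct a MultiChannelImage
#'
#' @param channels a list of numeric matrices (1--3 channels, equal shape),
#'   or a single matrix which is wrapped as a one-channel image.
#' @param pixelSize optional micrometres per pixel.
#' @param sourceId optional section/animal identifier.
#' @return a [MultiChannelImage-class] object.
#' @examples
#' img <- MultiChannelImage(list(matrix(0, 8, 8), matrix(1, 8, 8)))
#' nChannels(img)
#' @export
MultiChannelImage <- function(channels, pixelSize = NA_real_,
                              sourceId = NA_character_) {
  if (is.matrix(channels)) channels <- list(channels)
  channels <- lapply(channels, function(m) {
    storage.mode(m) <- "double"
    m
  })
  new("MultiChannelImage", channels = channels,
      pixelSize = as.numeric(pixelSize), sourceId = as.character(sourceId))
}

#' Segmentation and gating parameters for the quantification chain
#'
#' User-defined settings of the automated co-localization macro: which
#' channels enter the product image, how the product is binarized, the
#' watershed seed separation, and the size and circularity gates applied
#' to candidate cells.
#'
#' @slot selectedChannels integer vector of channel indices multiplied
#'   together for co-localization (non-empty).
#' @slot referenceChannel integer(1); channel quantified alone to obtain the
#'   reference (denominator) cell count, by default the first selected one.
#' @slot thresholdMethod one of `"otsu"`, `"isodata"`, `"fixed"`.
#' @slot fixedThreshold numeric(1); threshold used iff `thresholdMethod ==
#'   "fixed"` (intensities are on the rescaled \[0, 1\] scale).
#' @slot minArea,maxArea object area gate in square pixels.
#' @slot minCircularity,maxCircularity circularity gate in \[0, 1\], where
#'   circularity is `4 * pi * area / perimeter^2`, capped at 1.
#' @slot watershedMinDistance numeric(1) pixels; minimum separation of
#'   watershed seeds, typically about 0.7 times the expected cell diameter.
#'
#' @seealso [QuantParams()]
#' @exportClass QuantParams
setClass("QuantParams",
  representation(
    selectedChannels = "integer",
    referenceChannel = "integer",
    thresholdMethod = "character",
    fixedThreshold = "numeric",
    minArea = "numeric",
    maxArea = "numeric",
    minCircularity = "numeric",
    maxCircularity = "numeric",
    watershedMinDistance = "numeric"
  )
)

setValidity("QuantParams", function(object) {
  if (length(object@selectedChannels) < 1L)
    return("selectedChannels must be non-empty")
  if (anyDuplicated(object@selectedChannels))
    return("selectedChannels must be unique")
  if (!object@thresholdMethod %in% c("otsu", "isodata", "fixed"))
    return("thresholdMethod must be one of 'otsu', 'isodata', 'fixed'")
  if (object@minArea > object@maxArea)
    return("minArea must be <= maxArea")
  if (object@minCircularity < 0 || object@maxCircularity > 1 ||
      object@minCircularity > object@maxCircularity)
    return("circularity gates must satisfy 0 <= min <= max <= 1")
  if (object@watershedMinDistance <= 0)
    return("watershedMinDistance must be positive")
  TRUE
})

#' Construct quantification parameters
#'
#' Defaults suit disk-like cells of roughly 8--12 px radius; they are
#' deliberately permissive so that the size/circularity gates, not the
#' defaults, carry the biological decisions. See the package vignette for
#' guidance on setting them for a given magnification.
#'
#' @param selectedChannels channel indices entering the product image.
#' @param referenceChannel channel counted alone as denominator; defaults to
#'   the first selected channel.
#' @param thresholdMethod `"otsu"` (default), `"isodata"` or `"fixed"`.
#' @param fixedThreshold threshold on the rescaled \[0, 1\] intensity scale,
#'   required when `thresholdMethod = "fixed"`.
#' @param minArea,maxArea retained object area range, square pixels.
#' @param minCircularity,maxCircularity retained circularity range.
#' @param watershedMinDistance minimum watershed seed separation, pixels.
#' @return a [QuantParams-class] object.
#' @examples
#' QuantParams(selectedChannels = c(1, 2), minArea = 40)
#' @export
QuantParams <- function(selectedChannels = 1L,
                        referenceChannel = selectedChannels[1L],
                        thresholdMethod = c("otsu", "isodata", "fixed"),
                        fixedThreshold = NA_real_,
                        minArea = 40, maxArea = Inf,
                        minCircularity = 0.5, maxCircularity = 1,
                        watershedMinDistance = 14) {
  thresholdMethod <- match.arg(thresholdMethod)
  if (thresholdMethod == "fixed" && !is.finite(fixedThreshold))
    stop("thresholdMethod 'fixed' requires a finite fixedThreshold")
  new("QuantParams",
      selectedChannels = as.integer(selectedChannels),
      referenceChannel = as.integer(referenceChannel),
      thresholdMethod = thresholdMethod,
      fixedThreshold = as.numeric(fixedThreshold),
      minArea = as.numeric(minArea), maxArea = as.numeric(maxArea),
      minCircularity = as.numeric(minCircularity),
      maxCircularity = as.numeric(maxCircularity),
      watershedMinDistance = as.numeric(watershedMinDistance))
}

#' Ground truth of a simulated co-localization image
#'
#' Bookkeeping of every planted cell: per-channel centers and radii, which
#' channel-2 cells were planted on top of channel-1 cells, the noise level
#' and the image shape. Produced by [simulateColocImage()]; consumed by the
#' pixel-overlap oracle [truthColocCount()].
#'
#' @slot centers list (one element per channel) of n x 2 matrices of
#'   (row, col) cell centers, 1-based pixel coordinates.
#' @slot radii list of numeric vectors, one radius (px) per planted cell.
#' @slot colocPairs data.frame with columns `channelA`, `channelB`,
#'   `indexA`, `indexB`: planted co-localized cell pairs.
#' @slot noiseSigma numeric(1), additive Gaussian noise SD on \[0, 1\] scale.
#' @slot shape integer(2), image dimensions (rows, cols).
#' @exportClass ImageGroundTruth
setClass("ImageGroundTruth",
  representation(
    centers = "list",
    radii = "list",
    colocPairs = "data.frame",
    noiseSigma = "numeric",
    shape = "integer"
  )
)

setValidity("ImageGroundTruth", function(object) {
  if (length(object@centers) != length(object@radii))
    return("centers and radii must have one element per channel")
  for (k in seq_along(object@centers)) {
    ctr <- object@centers[[k]]
    if (nrow(ctr) != length(object@radii[[k]]))
      return("each center needs a radius")
    if (any(object@radii[[k]] <= 0)) return("radii must be positive")
    if (nrow(ctr) > 0 &&
        (any(ctr < 1) || any(ctr[, 1L] > object@shape[1L]) ||
         any(ctr[, 2L] > object@shape[2L])))
      return("all centers must lie inside the image")
  }
  cp <- object@colocPairs
  need <- c("channelA", "channelB", "indexA", "indexB")
  if (!all(need %in% names(cp)))
    return("colocPairs must have columns channelA, channelB, indexA, indexB")
  if (nrow(cp) > 0) {
    for (i in seq_len(nrow(cp))) {
      a <- object@centers[[cp$channelA[i]]][cp$indexA[i], ]
      b <- object@centers[[cp$channelB[i]]][cp$indexB[i], ]
      if (sqrt(sum((a - b)^2)) > 1)
        return("co-localized pair centers must agree within 1 px")
    }
  }
  TRUE
})

#' Outcome of the assumption-driven test-selection workflow
#'
#' Full audit trail of the decision tree: per-group normality p-values, the
#' variance-homogeneity test used and its p-value, the test that was chosen,
#' its omnibus p-value, and the multiplicity-adjusted pairwise comparisons.
#'
#' @slot normalityP named numeric, Shapiro-Wilk p per group.
#' @slot varianceTestUsed `"bartlett"` or `"fligner-killeen"`.
#' @slot varianceP numeric(1).
#' @slot chosenTest one of `"anova+tukey"`, `"kruskal-wallis+holm"`,
#'   `"t-test"`, `"wilcoxon"`.
#' @slot omnibusP numeric(1).
#' @slot pairwise data.frame with columns `group1`, `group2`, `p.adj`.
#' @slot alphaAssumption numeric(1), significance level used for the
#'   assumption tests.
#' @seealso [compareGroups()]
#' @exportClass TestDecision
setClass("TestDecision",
  representation(
    normalityP = "numeric",
    varianceTestUsed = "character",
    varianceP = "numeric",
    chosenTest = "character",
    omnibusP = "numeric",
    pairwise = "data.frame",
    alphaAssumption = "numeric"
  )
)

setValidity("TestDecision", function(object) {
  ok <- c("anova+tukey", "kruskal-wallis+holm", "t-test", "wilcoxon")
  if (!object@chosenTest %in% ok)
    return(paste("chosenTest must be one of:", paste(ok, collapse = ", ")))
  p <- c(object@normalityP, object@varianceP, object@omnibusP)
  p <- p[!is.na(p)]
  if (any(p < 0 | p > 1)) return("all p-values must lie in [0, 1]")
  TRUE
})
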