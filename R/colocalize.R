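#' Combine selected channels into a co-localization product image
#'
#' Each selected channel is min-max rescaled to \[0, 1\] and the rescaled
#' channels are multiplied pixel-wise, so that only pixels bright in every
#' selected channel remain bright in the product. A single selected channel
#' is returned rescaled and unchanged otherwise. A constant channel rescales
#' to all-1 when its constant is positive and to all-0 when it is zero
#' (a uniformly bright channel should not veto co-localization; an empty
#' one must).
#'
#' @param image a [MultiChannelImage-class]
#' @param selected integer vector of channel indices (subset of available)
#' @return numeric matrix in \[0, 1\]
#' @examples
#' img <- simulateColocImage(5, seed = 1)$image
#' prod <- combineChannels(img, c(1, 2))
#' range(prod)
#' @export
combineChannels <- function(image, selected) {
  stopifnot(is(image, "MultiChannelImage"))
  selected <- as.integer(selected)
  if (length(selected) == 0L) stop("channel selection must be non-empty")
  if (!all(selected %in% seq_len(nChannels(image))))
    stop("selected channels not available: ",
         paste(setdiff(selected, seq_len(nChannels(image))), collapse = ", "))
  out <- NULL
  for (k in selected) {
    ch <- rescale01(image@channels[[k]])
    out <- if (is.null(out)) ch else out * ch
  }
  out
}

# min-max rescale to [0, 1]; constant channel -> 1 if positive else 0.
rescale01 <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi == lo) {
    return(matrix(as.numeric(hi > 0), nrow(m), ncol(m)))
  }
  (m - lo) / (hi - lo)
}

#' Binarize an intensity grid
#'
#' Converts the (product) image to a binary mask: pixels with intensity at
#' or above the threshold are foreground. The threshold is chosen by Otsu's
#' method (default), the isodata inter-means iteration, or supplied as a
#' fixed value. A constant grid yields an all-false mask: there is nothing
#' to segment in a featureless image.
#'
#' @param grid numeric matrix of finite intensities
#' @param params a [QuantParams-class]; `thresholdMethod` and
#'   `fixedThreshold` are used.
#' @return logical matrix
#' @export
binarizeImage <- function(grid, params = QuantParams()) {
  stopifnot(is.matrix(grid), all(is.finite(grid)))
  if (min(grid) == max(grid)) {
    return(matrix(FALSE, nrow(grid), ncol(grid)))
  }
  thr <- switch(params@thresholdMethod,
    otsu = {
      rng <- range(grid)
      EBImage::otsu(EBImage::Image((grid - rng[1L]) / (rng[2L] - rng[1L]))) *
        (rng[2L] - rng[1L]) + rng[1L]
    },
    isodata = isodataThreshold(grid),
    fixed = {
      if (!is.finite(params@fixedThreshold))
        stop("threshold method 'fixed' requires fixedThreshold")
      params@fixedThreshold
    }
  )
  grid >= thr
}

# Isodata (iterative inter-means) threshold: t is repeatedly replaced by the
# midpoint of the mean below and the mean at/above t until it stabilizes.
isodataThreshold <- function(grid, tol = 1e-8, maxIter = 200L) {
  v <- as.numeric(grid)
  t0 <- mean(range(v))
  for (i in seq_len(maxIter)) {
    lo <- v[v < t0]; hi <- v[v >= t0]
    if (length(lo) == 0L || length(hi) == 0L) break
    t1 <- (mean(lo) + mean(hi)) / 2
    if (abs(t1 - t0) < tol) return(t1)
    t0 <- t1
  }
  t0
}

#' Split touching cells by distance-transform watershed
#'
#' Connected foreground is partitioned by a watershed on the Euclidean
#' distance transform, so that two disks fused by a thin neck separate into
#' two labels while an isolated disk keeps one. Seed separation is governed
#' by `watershedMinDistance` (pixels): maxima closer than roughly that
#' distance are merged into a single seed.
#'
#' @param mask logical (or 0/1 numeric) matrix
#' @param params a [QuantParams-class]; `watershedMinDistance` is used.
#' @return integer matrix of labels (0 = background); an empty mask yields
#'   an all-zero label grid.
#' @export
splitTouching <- function(mask, params = QuantParams()) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (!any(m > 0)) {
    return(matrix(0L, nrow(mask), ncol(mask)))
  }
  dm <- EBImage::distmap(m)
  ext <- max(1L, round(params@watershedMinDistance / 3))
  w <- EBImage::watershed(dm, tolerance = 0.5, ext = ext)
  lab <- EBImage::imageData(w)
  storage.mode(lab) <- "integer"
  lab
}

# Crack-boundary perimeter with 45-degree corner cutting. The staircase
# boundary between foreground and background pixels is measured and every
# 90-degree corner is replaced by its chord, removing (1 - sqrt(2)/2) per
# corner. Corners are read off 2x2 pixel configurations: blocks with one or
# three foreground pixels carry one corner, diagonal blocks carry two.
# On digital shapes this gives ~4s for an axis-aligned square of side s and
# ~2*pi*r (within a few percent) for a disk of radius r.
crackPerimeter <- function(mask) {
  m <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  edges <- sum(m[-1L, ] != m[-nrow(m), ]) + sum(m[, -1L] != m[, -ncol(m)])
  a <- m[-nrow(m), -ncol(m)]; b <- m[-nrow(m), -1L]
  cc <- m[-1L, -ncol(m)];     d <- m[-1L, -1L]
  s <- a + b + cc + d
  corners <- sum(s == 1) + sum(s == 3) +
    2 * sum(s == 2 & ((a == 1 & d == 1) | (b == 1 & cc == 1)))
  edges - (1 - sqrt(2) / 2) * corners
}

#' Circularity of a shape
#'
#' `4 * pi * area / perimeter^2`, capped at 1. Equals exactly 1 for an ideal
#' disk (area `pi r^2`, perimeter `2 pi r`) and `pi / 4` for an ideal square.
#'
#' @param area area (px^2 or any consistent unit)
#' @param perimeter perimeter (same length unit)
#' @return numeric in (0, 1]
#' @examples
#' circularity(pi * 10^2, 2 * pi * 10)  # ideal disk -> 1
#' circularity(20^2, 4 * 20)            # ideal square -> pi/4
#' @export
circularity <- function(area, perimeter) {
  pmin(1, 4 * pi * area / perimeter^2)
}

#' Measure and gate segmented objects
#'
#' Computes area (pixel count), perimeter (crack-boundary estimator with
#' corner cutting), circularity and centroid for every label, then retains
#' objects inside the configured area and circularity gates.
#'
#' @param labels integer label matrix from [splitTouching()]
#' @param params a [QuantParams-class]; area and circularity gates are used.
#' @return data.frame with columns `label`, `area`, `perimeter`,
#'   `circularity`, `centroidRow`, `centroidCol` (1-based pixel
#'   coordinates), one row per retained object.
#' @export
filterObjects <- function(labels, params = QuantParams()) {
  nlab <- max(labels)
  empty <- data.frame(label = integer(0), area = numeric(0),
                      perimeter = numeric(0), circularity = numeric(0),
                      centroidRow = numeric(0), centroidCol = numeric(0))
  if (nlab < 1L) return(empty)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  rows <- (idx - 1L) %% nrow(labels) + 1L
  cols <- (idx - 1L) %/% nrow(labels) + 1L
  area <- tabulate(lab, nbins = nlab)
  crow <- tapply(rows, lab, mean)
  ccol <- tapply(cols, lab, mean)
  present <- which(area > 0L)
  perim <- vapply(present, function(l) {
    sel <- lab == l
    r0 <- range(rows[sel]); c0 <- range(cols[sel])
    sub <- matrix(0, r0[2L] - r0[1L] + 1L, c0[2L] - c0[1L] + 1L)
    sub[cbind(rows[sel] - r0[1L] + 1L, cols[sel] - c0[1L] + 1L)] <- 1
    crackPerimeter(sub)
  }, numeric(1L))
  out <- data.frame(label = present,
                    area = as.numeric(area[present]),
                    perimeter = perim,
                    circularity = circularity(area[present], perim),
                    centroidRow = as.numeric(crow[as.character(present)]),
                    centroidCol = as.numeric(ccol[as.character(present)]))
  keep <- out$area >= params@minArea & out$area <= params@maxArea &
    out$circularity >= params@minCircularity &
    out$circularity <= params@maxCircularity
  out[keep, , drop = FALSE]
}

# The full macro chain on one grid: binarize -> watershed -> gate.
segmentGrid <- function(grid, params) {
  mask <- binarizeImage(grid, params)
  labels <- splitTouching(mask, params)
  filterObjects(labels, params)
}

#' Count co-expressing cells in a multi-channel image
#'
#' Runs the full quantification chain twice: on the product of the selected
#' channels (cells positive for every selected marker) and on the reference
#' channel alone (all cells positive for the reference marker). The
#' co-expression fraction is their ratio. A zero reference count leaves the
#' fraction explicitly undefined (`fractionDefined = FALSE`) rather than
#' silently zero.
#'
#' @param image a [MultiChannelImage-class]
#' @param params a [QuantParams-class]
#' @param sectionId,animalId optional identifiers carried into the result.
#' @return a list with elements `coexpressingCount`, `referenceCount`,
#'   `fraction`, `fractionDefined`, `sectionId`, `animalId`, and the two
#'   gated object tables `coexpressingObjects`, `referenceObjects`.
#' @examples
#' sim <- simulateColocImage(12, colocFraction = 0.5, seed = 3)
#' countCoexpressing(sim$image, QuantParams(selectedChannels = c(1, 2)))
#' @export
countCoexpressing <- function(image, params,
                              sectionId = NA_character_,
                              animalId = NA_character_) {
  stopifnot(is(image, "MultiChannelImage"), is(params, "QuantParams"))
  prodGrid <- combineChannels(image, params@selectedChannels)
  coObjects <- segmentGrid(prodGrid, params)
  refGrid <- combineChannels(image, params@referenceChannel)
  refObjects <- segmentGrid(refGrid, params)
  co <- nrow(coObjects)
  ref <- nrow(refObjects)
  list(coexpressingCount = co,
       referenceCount = ref,
       fraction = if (ref > 0L) co / ref else NA_real_,
       fractionDefined = ref > 0L,
       sectionId = sectionId, animalId = animalId,
       coexpressingObjects = coObjects,
       referenceObjects = refObjects)
}

#' Per-animal co-expression fractions with a group summary
#'
#' Sections belonging to one animal are pooled (summed counts) into one
#' fraction per animal by default; `perSection = "average"` instead averages
#' the per-section fractions. The group is summarized by the mean fraction
#' with a t-based 95% confidence interval; with a single animal the CI is
#' flagged undefined.
#'
#' @param results data.frame with columns `animalId`, `coexpressingCount`,
#'   `referenceCount` (one row per section), e.g. rows assembled from
#'   [countCoexpressing()] output.
#' @param perSection `"pool"` (default) or `"average"`.
#' @param level confidence level.
#' @return a list with `perAnimal` (data.frame: animalId, fraction) and
#'   `mean`, `lower`, `upper`, `ciDefined`, `nAnimals`.
#' @export
estimateFractionPerGroup <- function(results, perSection = c("pool", "average"),
                                     level = 0.95) {
  perSection <- match.arg(perSection)
  if (is.null(results) || nrow(results) == 0L)
    stop("no co-expression results supplied")
  stopifnot(all(c("animalId", "coexpressingCount", "referenceCount") %in%
                  names(results)))
  split_ <- split(results, results$animalId)
  frac <- vapply(split_, function(d) {
    if (perSection == "pool") {
      refs <- sum(d$referenceCount)
      if (refs == 0) return(NA_real_)
      sum(d$coexpressingCount) / refs
    } else {
      f <- d$coexpressingCount / d$referenceCount
      mean(f[is.finite(f)])
    }
  }, numeric(1L))
  perAnimal <- data.frame(animalId = names(frac), fraction = as.numeric(frac),
                          row.names = NULL)
  ok <- perAnimal$fraction[is.finite(perAnimal$fraction)]
  ci <- meanCI(ok, level = level)
  list(perAnimal = perAnimal, mean = ci$mean, lower = ci$lower,
       upper = ci$upper, ciDefined = ci$defined, nAnimals = ci$n)
}
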