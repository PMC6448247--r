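#' Simulate a multi-channel section image with planted co-localization
#'
#' Generates disk-like fluorescent cells on a dark background with a known
#' co-localization structure, emulating a stained section imaged in two (or
#' three) confocal channels. A controllable fraction of channel-2 cells is
#' planted exactly on top of channel-1 cells (co-expressing cells); a
#' controllable fraction of same-channel cells is placed closer than two
#' radii apart to exercise watershed splitting; all remaining cells are kept
#' well separated so that no accidental cross-channel overlap occurs.
#'
#' Cells are rendered as filled disks with a Gaussian intensity falloff over
#' a 2 px rim (an anti-aliased soft edge), overlapping cells combining by
#' maximum intensity, plus optional additive Gaussian noise clipped to
#' \[0, 1\].
#'
#' @param nCellsPerChannel number of cells planted in every channel.
#' @param colocFraction proportion in \[0, 1\]; `round(colocFraction *
#'   nCellsPerChannel)` channel-2 cells are centered on channel-1 cells.
#' @param radiusRange length-2 numeric, cell radius range in pixels.
#' @param touchingFraction proportion of each channel's cells planted as
#'   touching neighbours (center distance 0.8 times the summed radii).
#' @param noiseSigma SD of additive Gaussian noise on the \[0, 1\] scale.
#' @param shape image dimensions (rows, cols) in pixels.
#' @param nChannels number of channels (2 or 3; channel 3, when present, is
#'   an independent marker with no planted co-localization).
#' @param seed integer seed; identical seeds reproduce identical output.
#' @return a list with elements `image` ([MultiChannelImage-class]) and
#'   `truth` ([ImageGroundTruth-class]).
#' @examples
#' sim <- simulateColocImage(10, colocFraction = 0.5, seed = 1)
#' sim$truth
#' @export
simulateColocImage <- function(nCellsPerChannel,
                               colocFraction = 0.5,
                               radiusRange = c(8, 12),
                               touchingFraction = 0,
                               noiseSigma = 0,
                               shape = c(256L, 256L),
                               nChannels = 2L,
                               seed = 1L) {
  stopifnot(nCellsPerChannel >= 0, nChannels >= 1L, nChannels <= 3L,
            length(radiusRange) == 2L, all(radiusRange > 0),
            noiseSigma >= 0)
  stopIfNotProportion(colocFraction, "colocFraction")
  stopIfNotProportion(touchingFraction, "touchingFraction")
  shape <- as.integer(shape)
  n <- as.integer(nCellsPerChannel)
  rmax <- max(radiusRange)
  margin <- rmax + 3
  minSep <- 2 * rmax + 6
  if (n > 0 && (shape[1L] < 2 * margin || shape[2L] < 2 * margin))
    stop("image too small for the requested cell radius")

  withSeed(seed, {
    placed <- matrix(numeric(0), ncol = 2L)  # all centers, all channels
    centers <- vector("list", nChannels)
    radii <- vector("list", nChannels)

    drawRadius <- function(k) stats::runif(k, radiusRange[1L], radiusRange[2L])

    # Place one independent center at >= minSep from everything placed.
    placeFree <- function() {
      for (try in seq_len(500L)) {
        p <- c(stats::runif(1, margin, shape[1L] - margin),
               stats::runif(1, margin, shape[2L] - margin))
        if (nrow(placed) == 0L ||
            min(sqrt((placed[, 1L] - p[1L])^2 + (placed[, 2L] - p[2L])^2)) >=
              minSep)
          return(p)
      }
      stop("cannot place ", n, " cells of radius <= ", rmax, " in a ",
           shape[1L], " x ", shape[2L], " image: impossible packing")
    }

    # Place a touching partner next to `anchor`: center distance below two
    # radii (so the pair fuses into one blob), while staying clear of every
    # other already-placed cell (no accidental third-party overlap).
    placeTouching <- function(anchor, rAnchor, rNew, others) {
      clearance <- 2 * rmax + 2
      for (try in seq_len(720L)) {
        ang <- stats::runif(1, 0, 2 * pi)
        d <- 0.8 * (rAnchor + rNew)
        p <- anchor + d * c(cos(ang), sin(ang))
        inside <- all(p >= margin) && p[1L] <= shape[1L] - margin &&
          p[2L] <= shape[2L] - margin
        if (!inside) next
        if (nrow(others) == 0L ||
            min(sqrt((others[, 1L] - p[1L])^2 + (others[, 2L] - p[2L])^2)) >=
              clearance)
          return(p)
      }
      NULL
    }

    nColoc <- round(colocFraction * n)
    colocPairs <- data.frame(channelA = integer(0), channelB = integer(0),
                             indexA = integer(0), indexB = integer(0))

    for (ch in seq_len(nChannels)) {
      ctr <- matrix(NA_real_, n, 2L)
      rad <- drawRadius(n)
      nCopied <- 0L
      if (ch == 2L && nColoc > 0L) {
        # first nColoc channel-2 cells sit exactly on channel-1 cells
        pick <- sample.int(n, nColoc)
        ctr[seq_len(nColoc), ] <- centers[[1L]][pick, , drop = FALSE]
        rad[seq_len(nColoc)] <- radii[[1L]][pick]
        nCopied <- nColoc
        colocPairs <- rbind(colocPairs, data.frame(
          channelA = 1L, channelB = 2L,
          indexA = pick, indexB = seq_len(nColoc)))
      }
      nFree <- n - nCopied
      nTouch <- min(round(touchingFraction * n), max(nFree - 1L, 0L))
      nIndep <- nFree - nTouch
      idx <- nCopied
      for (i in seq_len(nIndep)) {
        idx <- idx + 1L
        p <- placeFree()
        ctr[idx, ] <- p
        placed <- rbind(placed, p)
      }
      for (i in seq_len(nTouch)) {
        idx <- idx + 1L
        # anchor on a same-channel independent cell placed in this channel
        anchors <- seq.int(nCopied + 1L, nCopied + nIndep)
        p <- NULL
        for (a in sample(anchors)) {
          anchor <- ctr[a, ]
          others <- placed[sqrt((placed[, 1L] - anchor[1L])^2 +
                                (placed[, 2L] - anchor[2L])^2) > 1e-9, ,
                           drop = FALSE]
          p <- placeTouching(anchor, rad[a], rad[idx], others)
          if (!is.null(p)) break
        }
        if (is.null(p))
          stop("cannot place touching cell pair: impossible packing")
        ctr[idx, ] <- p
        placed <- rbind(placed, p)
      }
      centers[[ch]] <- ctr
      radii[[ch]] <- rad
    }

    chans <- lapply(seq_len(nChannels), function(ch) {
      m <- renderCells(centers[[ch]], radii[[ch]], shape)
      if (noiseSigma > 0)
        m <- m + matrix(stats::rnorm(prod(shape), 0, noiseSigma),
                        shape[1L], shape[2L])
      pmin(pmax(m, 0), 1)
    })

    img <- MultiChannelImage(chans, sourceId = sprintf("sim-seed%d", seed))
    truth <- new("ImageGroundTruth",
                 centers = centers, radii = radii, colocPairs = colocPairs,
                 noiseSigma = noiseSigma, shape = shape)
    list(image = img, truth = truth)
  })
}

# Render disks with a soft 2 px Gaussian rim; combine by max intensity.
renderCells <- function(centers, radii, shape) {
  m <- matrix(0, shape[1L], shape[2L])
  if (nrow(centers) == 0L) return(m)
  for (i in seq_len(nrow(centers))) {
    r <- radii[i]
    r0 <- max(r - 2, 1)
    ext <- ceiling(r + 4)
    rows <- max(1L, floor(centers[i, 1L] - ext)):
      min(shape[1L], ceiling(centers[i, 1L] + ext))
    cols <- max(1L, floor(centers[i, 2L] - ext)):
      min(shape[2L], ceiling(centers[i, 2L] + ext))
    d <- sqrt(outer((rows - centers[i, 1L])^2, (cols - centers[i, 2L])^2, "+"))
    prof <- ifelse(d <= r0, 1, exp(-((d - r0)^2) / 2))
    m[rows, cols] <- pmax(m[rows, cols], prof)
  }
  m
}

#' Hard-disk masks of the planted cells
#'
#' Binary ground-truth masks (pixel within radius of a planted center),
#' one per channel, independent of any thresholding or segmentation.
#'
#' @param truth an [ImageGroundTruth-class]
#' @return list of logical matrices, one per channel
#' @export
truthMasks <- function(truth) {
  lapply(seq_along(truth@centers), function(ch) {
    m <- matrix(FALSE, truth@shape[1L], truth@shape[2L])
    ctr <- truth@centers[[ch]]
    if (nrow(ctr) == 0L) return(m)
    rowg <- matrix(seq_len(truth@shape[1L]), truth@shape[1L], truth@shape[2L])
    colg <- matrix(seq_len(truth@shape[2L]), truth@shape[1L], truth@shape[2L],
                   byrow = TRUE)
    for (i in seq_len(nrow(ctr))) {
      m <- m | ((rowg - ctr[i, 1L])^2 + (colg - ctr[i, 2L])^2 <=
                  truth@radii[[ch]][i]^2)
    }
    m
  })
}

#' Pixel-overlap oracle count of co-localized cells
#'
#' Counts connected components of the intersection of the ground-truth
#' hard-disk masks of two channels. This is a brute-force geometric count
#' that bypasses the entire quantification chain (no thresholding, no
#' watershed, no gating), so it serves as an independent oracle for
#' [countCoexpressing()] on noise-free images.
#'
#' @param truth an [ImageGroundTruth-class]
#' @param channelPair integer(2), the two channels intersected.
#' @return integer(1), number of overlap components.
#' @export
truthColocCount <- function(truth, channelPair = c(1L, 2L)) {
  masks <- truthMasks(truth)
  inter <- masks[[channelPair[1L]]] & masks[[channelPair[2L]]]
  if (!any(inter)) return(0L)
  lab <- EBImage::bwlabel(inter)
  as.integer(max(lab))
}
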