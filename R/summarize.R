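#' Summarisation configuration
#'
#' @param gapT slice-gap threshold: two flagged slices separated by at most
#'   \code{gapT} slices belong to the same region (run-time flexible,
#'   default 3).
#' @param peripheralFraction position of the two fallback peripheral slices
#'   as a fraction of the volume depth (default 0.1); the third fallback
#'   slice is central.
#' @return a list of class \code{summaryConfig}.
#' @export
summaryConfig <- function(gapT = 3L, peripheralFraction = 0.1) {
  stopifnot(gapT >= 0, peripheralFraction > 0, peripheralFraction < 0.5)
  structure(list(gapT = as.integer(gapT),
                 peripheralFraction = peripheralFraction),
            class = "summaryConfig")
}

#' Group flagged slices into regions
#'
#' Greedy left-to-right merge: a new region starts whenever the gap to the
#' previous flagged slice exceeds \code{gapT}; gaps of at most \code{gapT}
#' merge.  Within a region consecutive flags therefore differ by at most
#' \code{gapT}, and adjacent regions are separated by more.
#'
#' @param flagged strictly increasing integer slice indices.
#' @param gapT non-negative gap threshold.
#' @return list of regions, each with \code{flagged}, \code{first},
#'   \code{median}, \code{last}.
#' @examples
#' r <- groupRegions(c(10, 11, 12, 40, 42, 80), gapT = 3)
#' vapply(r, function(x) c(x$first, x$median, x$last), numeric(3))
#' @export
groupRegions <- function(flagged, gapT = 3L) {
  stopifnot(gapT >= 0)
  flagged <- as.integer(flagged)
  if (length(flagged) == 0) return(list())
  if (is.unsorted(flagged, strictly = TRUE))
    stop("flagged indices must be strictly increasing without duplicates")
  breaks <- which(diff(flagged) > gapT)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(flagged))
  lapply(seq_along(starts), function(i)
    makeRegion(flagged[starts[i]:ends[i]]))
}

makeRegion <- function(flagged) {
  k <- length(flagged)
  list(flagged = flagged, first = flagged[1],
       median = flagged[(k + 1L) %/% 2L],  # lower median: always a flag
       last = flagged[k])
}

#' Keyframe triple of a region
#'
#' First, median and last flagged slice.  For even-sized regions the lower
#' median is used so the reported scan is always one the classifier flagged
#' (the midpoint of the span need not be).
#'
#' @param region a region from [groupRegions()].
#' @return integer triple (first, median, last).
#' @examples
#' regionKeyframes(groupRegions(c(40, 42), gapT = 3)[[1]])   # 40 40 42
#' @export
regionKeyframes <- function(region) {
  if (length(region$flagged) == 0) stop("empty region")
  c(region$first, region$median, region$last)
}

#' Summarise per-slice relevance flags
#'
#' Groups flagged slices into regions and emits 3 keyframes per region (the
#' 3M rule).  When nothing was flagged, three default slices are returned:
#' two peripheral (at fractions p and 1 - p of the depth) and one central.
#'
#' @param flagged strictly increasing flagged slice indices (1-based), e.g.
#'   \code{which(predictSlices(net, stack)$flag)}.
#' @param nSlices number of slices in the volume (>= 3).
#' @param config a [summaryConfig()].
#' @param volumeId identifier carried into the summary.
#' @return an \linkS4class{OCTSummary}.
#' @examples
#' summarizeVolume(integer(), nSlices = 100)   # fallback: 10, 50, 91
#' @export
summarizeVolume <- function(flagged, nSlices, config = summaryConfig(),
                            volumeId = "volume") {
  if (nSlices < 3) stop("volume must have at least 3 slices")
  flagged <- as.integer(flagged)
  if (length(flagged) && (min(flagged) < 1 || max(flagged) > nSlices))
    stop("flagged indices outside 1..", nSlices)
  if (length(flagged) == 0) {
    p <- max(1L, as.integer(round(config$peripheralFraction * nSlices)))
    kf <- as.integer(c(p, ceiling(nSlices / 2), nSlices + 1L - p))
    return(new("OCTSummary", volumeId = volumeId, gapT = config$gapT,
               regions = list(), keyframes = kf, fallback = TRUE,
               nSlices = as.integer(nSlices)))
  }
  regs <- groupRegions(flagged, config$gapT)
  kf <- as.integer(unlist(lapply(regs, regionKeyframes)))
  new("OCTSummary", volumeId = volumeId, gapT = config$gapT, regions = regs,
      keyframes = kf, fallback = FALSE, nSlices = as.integer(nSlices))
}

#' En-face projection of a volume
#'
#' Collapses each A-scan by its mean intensity along depth: one row per
#' B-scan, one column per A-scan.
#'
#' @param volume an \linkS4class{OCTVolume}.
#' @return matrix \code{nSlices x nCols}.
#' @export
enfaceProjection <- function(volume) {
  d <- dim(volume@pixels)
  t(apply(volume@pixels, 3, colMeans))
}

regionPalette <- function(n) {
  base <- c("#1f77b4", "#d62728", "#2ca02c", "#ff7f0e", "#9467bd",
            "#8c564b", "#e377c2", "#17becf")
  rep(base, length.out = max(n, 1))
}

#' Render the visual summary
#'
#' Writes two PNGs: the en-face projection with region extents overlaid as
#' colour bands (keyframe rows emphasised), and a montage of the keyframe
#' B-scans with colour-coded borders in region order (duplicate keyframes
#' within a triple are deduplicated in the montage).
#'
#' @param volume the summarised \linkS4class{OCTVolume}.
#' @param summary an \linkS4class{OCTSummary} for the same volume.
#' @param enfacePath,montagePath output PNG paths.
#' @return (invisibly) a manifest list: per-keyframe data.frame
#'   \code{frames} (slice, region, role) in montage order plus the two
#'   paths.
#' @export
renderSummary <- function(volume, summary,
                          enfacePath = tempfile(fileext = ".png"),
                          montagePath = tempfile(fileext = ".png")) {
  if (nSlices(volume) != summary@nSlices)
    stop("volume and summary refer to different slice counts")
  if (any(summary@keyframes < 1 | summary@keyframes > nSlices(volume)))
    stop("keyframe index out of range")
  ef <- enfaceProjection(volume)
  ef <- (ef - min(ef)) / max(1e-12, diff(range(ef)))
  rgb <- array(rep(ef, 3), c(dim(ef), 3))
  cols <- regionPalette(length(summary@regions))
  blend <- function(rows, colHex, alpha) {
    cv <- grDevices::col2rgb(colHex) / 255
    for (ch in 1:3)
      rgb[rows, , ch] <<- (1 - alpha) * rgb[rows, , ch] + alpha * cv[ch]
  }
  if (summary@fallback) {
    for (s in summary@keyframes) blend(s, "#aaaaaa", 0.6)
  } else {
    for (i in seq_along(summary@regions)) {
      r <- summary@regions[[i]]
      blend(r$first:r$last, cols[i], 0.25)
      blend(unique(regionKeyframes(r)), cols[i], 0.6)
    }
  }
  png::writePNG(rgb, enfacePath)

  # montage of deduplicated keyframes, region order preserved
  if (summary@fallback) {
    frames <- data.frame(slice = summary@keyframes, region = 0L,
                         role = c("peripheral", "central", "peripheral"))
  } else {
    frames <- do.call(rbind, lapply(seq_along(summary@regions), function(i) {
      kf <- regionKeyframes(summary@regions[[i]])
      data.frame(slice = kf, region = i,
                 role = c("first", "median", "last"))
    }))
  }
  shown <- frames[!duplicated(frames[c("slice", "region")]), ]
  d <- dim(volume@pixels)
  bw <- 3L  # border width
  tile <- array(0, c(d[1] + 2 * bw, (d[2] + 2 * bw) * nrow(shown), 3))
  for (j in seq_len(nrow(shown))) {
    sl <- volume@pixels[, , shown$slice[j]]
    cv <- grDevices::col2rgb(
      if (shown$region[j] == 0) "#aaaaaa" else cols[shown$region[j]]) / 255
    off <- (j - 1) * (d[2] + 2 * bw)
    for (ch in 1:3) {
      tile[, off + seq_len(d[2] + 2 * bw), ch] <- cv[ch]
      tile[bw + seq_len(d[1]), off + bw + seq_len(d[2]), ch] <- sl
    }
  }
  png::writePNG(clamp01(tile), montagePath)
  invisible(list(frames = frames, shown = shown,
                 enface = enfacePath, montage = montagePath))
}
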