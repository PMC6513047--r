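#' @import methods
NULL

VALID_LABELS <- c("normal", "relevant", "poor_quality")

setOldClass("networkConfig")

#' OCTVolume: an ordered stack of SDOCT B-scans
#'
#' Container for a volumetric SDOCT acquisition: a 3-D array of grayscale
#' B-scans (rows = axial depth, columns = lateral position, third dimension =
#' slice order), per-slice labels, optional ground-truth layer surfaces
#' (available for synthetic phantoms only) and acquisition metadata.
#'
#' @slot pixels numeric 3-D array \code{rows x cols x slices}, intensities in
#'   \code{[0, 1]}.
#' @slot labels character vector, one of \code{"normal"}, \code{"relevant"},
#'   \code{"poor_quality"} per slice.
#' @slot surfaces list of per-slice surface sets (each a list with numeric
#'   vectors \code{ilm}, \code{ez}, \code{rpe} of per-column row positions,
#'   1-based), or an empty list when unknown.
#' @slot physicalExtent numeric length-2, lateral x azimuthal extent in mm.
#' @slot volumeId character scalar identifier.
#'
#' @examples
#' vol <- generateVolume(phantomConfig(nRows = 64, nCols = 96, nSlices = 8))
#' vol
#' nSlices(vol)
#' table(sliceLabels(vol))
#' @export
setClass("OCTVolume",
  representation(
    pixels = "array",
    labels = "character",
    surfaces = "list",
    physicalExtent = "numeric",
    volumeId = "character"
  )
)

setValidity("OCTVolume", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (length(d) != 3L) msg <- c(msg, "pixels must be a 3-D array")
  else {
    if (length(object@labels) != d[3])
      msg <- c(msg, "one label per slice required")
    if (length(object@surfaces) > 0 && length(object@surfaces) != d[3])
      msg <- c(msg, "surfaces must be empty or one set per slice")
  }
  if (!all(object@labels %in% VALID_LABELS))
    msg <- c(msg, sprintf("labels must be in {%s}",
                          paste(VALID_LABELS, collapse = ", ")))
  for (s in object@surfaces) {
    if (!all(c("ilm", "ez", "rpe") %in% names(s))) {
      msg <- c(msg, "each surface set needs ilm, ez, rpe")
      break
    }
    if (!all(s$ilm < s$ez & s$ez < s$rpe)) {
      msg <- c(msg, "surface ordering ILM < EZ < RPE violated")
      break
    }
    if (any(s$ilm < 1) || any(s$rpe > d[1])) {
      msg <- c(msg, "surfaces outside the axial extent")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' DenovoNet: the compact skip-connected B-scan classifier
#'
#' Seven 3x3 convolutional layers with ReLU, each followed (per pooling mode)
#' by 2x2 max pooling of the channel concatenation of the layer's input and
#' output; global average pooling; fully connected 2-way softmax.  Weights
#' for convolutional layer i are stored as a matrix of shape
#' \code{filters x (9 * in_channels)} matching the internal im2col layout.
#'
#' @slot config list as produced by [networkConfig()].
#' @slot convW list of 7 weight matrices.
#' @slot convB list of 7 bias vectors.
#' @slot fcW numeric matrix \code{n_classes x n_channels} (609 channels with
#'   default filter widths).
#' @slot fcB numeric vector of class biases.
#'
#' @examples
#' net <- buildDenovoNet(networkConfig(), seed = 1)
#' countTrainable(net)
#' @export
setClass("DenovoNet",
  representation(
    config = "networkConfig",
    convW = "list",
    convB = "list",
    fcW = "matrix",
    fcB = "numeric"
  )
)

setValidity("DenovoNet", function(object) {
  msg <- character()
  fw <- object@config$filterWidths
  if (length(object@convW) != length(fw) || length(object@convB) != length(fw))
    msg <- c(msg, "one weight matrix and bias vector per conv layer required")
  chIn <- 1
  for (i in seq_along(object@convW)) {
    if (!all(dim(object@convW[[i]]) == c(fw[i], 9 * chIn))) {
      msg <- c(msg, sprintf("conv layer %d weights have wrong shape", i))
      break
    }
    chIn <- chIn + fw[i]
  }
  if (!length(msg) && !all(dim(object@fcW) == c(object@config$nClasses, chIn)))
    msg <- c(msg, "fully connected weights have wrong shape")
  if (length(msg)) msg else TRUE
})

#' OCTSummary: region-grouped keyframe summary of a volume
#'
#' Result of the summarisation rules: flagged slices grouped into regions
#' (consecutive flags at gaps of at most the threshold \code{gapT}), each
#' reduced to a (first, median, last) keyframe triple; or the three-slice
#' fallback when nothing was flagged.
#'
#' @slot volumeId character scalar.
#' @slot gapT integer slice-gap threshold used for grouping.
#' @slot regions list of regions, each a list with \code{flagged},
#'   \code{first}, \code{median}, \code{last} (1-based slice indices).
#' @slot keyframes integer vector: 3 entries per region in region order
#'   (duplicates within a triple retained), or the 3 fallback slices.
#' @slot fallback logical, TRUE when the fallback rule was applied.
#' @slot nSlices integer, number of slices in the summarised volume.
#'
#' @examples
#' summarizeVolume(c(10, 11, 12, 40, 42, 80), nSlices = 100)
#' @export
setClass("OCTSummary",
  representation(
    volumeId = "character",
    gapT = "integer",
    regions = "list",
    keyframes = "integer",
    fallback = "logical",
    nSlices = "integer"
  )
)

setValidity("OCTSummary", function(object) {
  msg <- character()
  if (!object@fallback && length(object@keyframes) != 3L * length(object@regions))
    msg <- c(msg, "expected exactly 3 keyframes per region")
  if (object@fallback && length(object@keyframes) != 3L)
    msg <- c(msg, "fallback must contain exactly 3 slices")
  for (r in object@regions) {
    if (!(r$first <= r$median && r$median <= r$last) ||
        !(r$median %in% r$flagged)) {
      msg <- c(msg, "region keyframe invariant violated")
      break
    }
  }
  if (length(msg)) msg else TRUE
})
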