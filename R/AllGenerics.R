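#' @rdname OCTVolume-class
#' @param x,object an \linkS4class{OCTVolume}
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' @rdname OCTVolume-class
#' @export
setGeneric("sliceLabels", function(x) standardGeneric("sliceLabels"))

#' @rdname OCTVolume-class
#' @param i slice index (1-based)
#' @export
setGeneric("getSlice", function(x, i) standardGeneric("getSlice"))

#' @rdname OCTVolume-class
#' @export
setGeneric("trueSurfaces", function(x, i) standardGeneric("trueSurfaces"))

#' @rdname OCTVolume-class
#' @export
setGeneric("volumeId", function(x) standardGeneric("volumeId"))

#' @rdname DenovoNet-class
#' @param object a \linkS4class{DenovoNet}
#' @export
setGeneric("countTrainable", function(object) standardGeneric("countTrainable"))

#' @rdname DenovoNet-class
#' @export
setGeneric("netConfig", function(object) standardGeneric("netConfig"))

#' @rdname OCTSummary-class
#' @param object an \linkS4class{OCTSummary}
#' @export
setGeneric("keyframes", function(object) standardGeneric("keyframes"))

#' @rdname OCTSummary-class
#' @export
setGeneric("regions", function(object) standardGeneric("regions"))

#' @rdname OCTVolume-class
setMethod("nSlices", "OCTVolume", function(x) dim(x@pixels)[3])

#' @rdname OCTVolume-class
setMethod("sliceLabels", "OCTVolume", function(x) x@labels)

#' @rdname OCTVolume-class
setMethod("getSlice", "OCTVolume", function(x, i) {
  stopifnot(i >= 1, i <= nSlices(x))
  x@pixels[, , i]
})

#' @rdname OCTVolume-class
setMethod("trueSurfaces", "OCTVolume", function(x, i) {
  if (length(x@surfaces) == 0) return(NULL)
  x@surfaces[[i]]
})

#' @rdname OCTVolume-class
setMethod("volumeId", "OCTVolume", function(x) x@volumeId)

setMethod("show", "OCTVolume", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("OCTVolume '%s': %d B-scans of %d x %d px (%.1f x %.1f mm)\n",
              object@volumeId, d[3], d[1], d[2],
              object@physicalExtent[1], object@physicalExtent[2]))
  tab <- table(factor(object@labels, levels = VALID_LABELS))
  cat(sprintf("  labels: %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  if (length(object@surfaces))
    cat("  ground-truth surfaces: ILM / EZ / RPE available\n")
})

#' @rdname DenovoNet-class
setMethod("countTrainable", "DenovoNet", function(object) {
  sum(vapply(object@convW, length, 0L)) +
    sum(vapply(object@convB, length, 0L)) +
    length(object@fcW) + length(object@fcB)
})

#' @rdname DenovoNet-class
setMethod("netConfig", "DenovoNet", function(object) object@config)

setMethod("show", "DenovoNet", function(object) {
  cfg <- object@config
  cat(sprintf(
    "DenovoNet: 7 conv layers (3x3) + GAP + %d-way softmax\n", cfg$nClasses))
  cat(sprintf("  filters: %s | input %d x %d | pooling: %s\n",
              paste(cfg$filterWidths, collapse = ","),
              cfg$inputShape[1], cfg$inputShape[2], cfg$poolingMode))
  cat(sprintf("  trainable parameters: %s (%.1f million)\n",
              format(countTrainable(object), big.mark = ","),
              countTrainable(object) / 1e6))
})

#' @rdname OCTSummary-class
setMethod("keyframes", "OCTSummary", function(object) object@keyframes)

#' @rdname OCTSummary-class
setMethod("regions", "OCTSummary", function(object) object@regions)

setMethod("show", "OCTSummary", function(object) {
  cat(sprintf("OCTSummary '%s': %d region(s), T = %d\n",
              object@volumeId, length(object@regions), object@gapT))
  if (object@fallback) {
    cat(sprintf("  no slices flagged; fallback keyframes: %s\n",
                paste(object@keyframes, collapse = ", ")))
  } else {
    for (r in object@regions)
      cat(sprintf("  region %d-%d: keyframes (%d, %d, %d), %d flagged\n",
                  r$first, r$last, r$first, r$median, r$last,
                  length(r$flagged)))
  }
})
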