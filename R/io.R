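#' Write / read an OCT volume as multi-page TIFF plus JSON sidecar
#'
#' Pixels are stored as one 32-bit grayscale TIFF page per B-scan (lossless
#' up to the 32-bit sample quantisation, below 2^-32 per pixel); labels,
#' surfaces and metadata go to a \code{<path>.json} sidecar so the pair
#' round-trips an \linkS4class{OCTVolume}.
#'
#' @param volume an \linkS4class{OCTVolume}.
#' @param path output TIFF path; the sidecar is written to
#'   \code{paste0(path, ".json")}.
#' @return \code{writeVolume}: the TIFF path, invisibly.
#' @examples
#' vol <- generateVolume(phantomConfig(nRows = 32, nCols = 48, nSlices = 8))
#' tf <- tempfile(fileext = ".tiff")
#' writeVolume(vol, tf)
#' all.equal(readVolume(tf)@pixels, vol@pixels, tolerance = 1e-9)
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "OCTVolume"))
  if (nSlices(volume) == 0) stop("cannot write a volume with 0 slices")
  pages <- lapply(seq_len(nSlices(volume)), function(s) volume@pixels[, , s])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sidecar <- list(
    volume_id = volume@volumeId,
    n_slices = nSlices(volume),
    labels = volume@labels,
    physical_extent_mm = volume@physicalExtent
  )
  if (length(volume@surfaces)) sidecar$surfaces <- volume@surfaces
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("TIFF file not found: ", path)
  sidecarPath <- paste0(path, ".json")
  if (!file.exists(sidecarPath)) stop("sidecar not found: ", sidecarPath)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
  for (field in c("volume_id", "n_slices", "labels", "physical_extent_mm"))
    if (is.null(meta[[field]]))
      stop(sprintf("sidecar %s: missing field '%s'", sidecarPath, field))
  if (meta$n_slices != length(pages))
    stop(sprintf("sidecar %s: n_slices (%d) does not match TIFF pages (%d)",
                 sidecarPath, meta$n_slices, length(pages)))
  if (!all(meta$labels %in% VALID_LABELS))
    stop(sprintf("sidecar %s: unknown label '%s' in field 'labels'",
                 sidecarPath,
                 setdiff(meta$labels, VALID_LABELS)[1]))
  px <- array(0, c(dim(pages[[1]]), length(pages)))
  for (s in seq_along(pages)) px[, , s] <- pages[[s]]
  surfaces <- list()
  if (!is.null(meta$surfaces)) {
    surfaces <- lapply(seq_len(meta$n_slices), function(s) {
      sf <- if (is.data.frame(meta$surfaces)) {
        list(ilm = meta$surfaces$ilm[[s]], ez = meta$surfaces$ez[[s]],
             rpe = meta$surfaces$rpe[[s]])
      } else meta$surfaces[[s]]
      lapply(sf, as.numeric)
    })
  }
  new("OCTVolume", pixels = px, labels = as.character(meta$labels),
      surfaces = surfaces, physicalExtent = as.numeric(meta$physical_extent_mm),
      volumeId = as.character(meta$volume_id))
}
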