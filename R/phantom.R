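#' Phantom generator configuration
#'
#' Describes the geometry and noise of a synthetic AMD SDOCT phantom volume.
#' Full-scale defaults (512 axial px, 1000 A-scans, 100 B-scans over a
#' 6.7 x 6.7 mm area centred on the fovea) match the acquisition protocol the
#' package emulates; [deskPhantomConfig()] gives the half-scale geometry used
#' throughout the test suite.
#'
#' The phantom is a five-level layered retina: vitreous above the internal
#' limiting membrane (ILM), inner retina down to the ellipsoid zone (EZ), a
#' bright EZ band, a bright retinal pigment epithelium (RPE) band, and
#' choroid below.  A Gaussian foveal dip pulls the ILM towards the RPE at the
#' volume centre, and low-frequency undulation varies the surfaces smoothly
#' across columns and slices.  Speckle is multiplicative Gamma noise with
#' mean 1 (shape \code{1/speckle^2}); \code{speckle = 0} yields the exact
#' noiseless rendering.
#'
#' @param nRows axial pixels per A-scan (>= 8).
#' @param nCols A-scans per B-scan (>= 8).
#' @param nSlices B-scans per volume (>= 8).
#' @param levels named intensities in \code{[0,1]} for
#'   \code{vitreous, inner, ellipsoid, rpe, choroid}.
#' @param fovealDipDepth depth of the foveal dip in pixels.
#' @param fovealDipWidth lateral Gaussian sigma of the dip in pixels.
#' @param speckle multiplicative speckle strength (sd of the Gamma factor);
#'   0 disables noise.
#' @param seed integer seed; identical config (including seed) gives a
#'   bit-identical volume.
#' @return a validated list of class \code{phantomConfig}.
#' @examples
#' cfg <- deskPhantomConfig()
#' vol <- generateVolume(cfg)
#' vol
#' @export
phantomConfig <- function(nRows = 512L, nCols = 1000L, nSlices = 100L,
                          levels = c(vitreous = 0.06, inner = 0.42,
                                     ellipsoid = 0.80, rpe = 0.92,
                                     choroid = 0.30),
                          fovealDipDepth = round(0.07 * nRows),
                          fovealDipWidth = round(0.15 * nCols),
                          speckle = 0.2, seed = 1L) {
  stopifnot(nRows >= 8, nCols >= 8, nSlices >= 8)
  need <- c("vitreous", "inner", "ellipsoid", "rpe", "choroid")
  if (!all(need %in% names(levels)))
    stop("levels must name: ", paste(need, collapse = ", "))
  if (any(levels < 0 | levels > 1)) stop("intensity levels must lie in [0,1]")
  if (speckle < 0) stop("speckle strength must be >= 0")
  structure(list(
    nRows = as.integer(nRows), nCols = as.integer(nCols),
    nSlices = as.integer(nSlices), levels = levels[need],
    fovealDipDepth = fovealDipDepth, fovealDipWidth = fovealDipWidth,
    speckle = speckle, seed = as.integer(seed)
  ), class = "phantomConfig")
}

#' @rdname phantomConfig
#' @param ... overrides passed on to [phantomConfig()].
#' @export
deskPhantomConfig <- function(...) {
  args <- list(nRows = 256L, nCols = 512L, nSlices = 24L)
  args[names(list(...))] <- list(...)
  do.call(phantomConfig, args)
}

#' Lesion specification for the phantom
#'
#' @param kind one of \code{"drusen"}, \code{"ped"}, \code{"ga"},
#'   \code{"erm"}.  Drusen and pigment epithelial detachments (PED) are
#'   Gaussian-profile upward displacements of the RPE (drusen narrow, PED
#'   broad); geographic atrophy (GA) replaces the RPE band by vitreous
#'   intensity and brightens the underlying choroid; an epiretinal membrane
#'   (ERM) is a thin bright line a few pixels above the ILM.
#' @param sliceRange inclusive 1-based slice interval \code{c(lo, hi)}.
#' @param lateralCenter lesion centre column.
#' @param width lateral support in pixels.
#' @param amplitude surface displacement in pixels (drusen/PED) or intensity
#'   delta (GA/ERM); must be >= 0.  Amplitude 0 leaves the affected slices
#'   labelled \code{"normal"}.
#' @return a list of class \code{lesionSpec}.
#' @export
lesionSpec <- function(kind = c("drusen", "ped", "ga", "erm"),
                       sliceRange, lateralCenter, width, amplitude) {
  kind <- match.arg(kind)
  stopifnot(length(sliceRange) == 2, sliceRange[1] <= sliceRange[2],
            width > 0, amplitude >= 0)
  structure(list(kind = kind, sliceRange = as.integer(sliceRange),
                 lateralCenter = lateralCenter, width = width,
                 amplitude = amplitude), class = "lesionSpec")
}

#' Artifact specification for the phantom
#'
#' Slices covered by any artifact carry the ground-truth label
#' \code{"poor_quality"}.
#'
#' @param kind \code{"shadow"} (columns attenuated), \code{"low_contrast"}
#'   (contrast compressed about the image mean) or \code{"mirror"} (the top
#'   40 percent of the vertically flipped scan composited over the image,
#'   emulating an incorrect mirror position).
#' @param sliceRange inclusive 1-based slice interval.
#' @param columnRange inclusive column interval (shadow only).
#' @param factor attenuation (shadow, default 0.25) or contrast factor
#'   (low_contrast, default 0.35).
#' @return a list of class \code{artifactSpec}.
#' @export
artifactSpec <- function(kind = c("shadow", "low_contrast", "mirror"),
                         sliceRange, columnRange = NULL, factor = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(sliceRange) == 2, sliceRange[1] <= sliceRange[2])
  if (is.null(factor))
    factor <- switch(kind, shadow = 0.25, low_contrast = 0.35, mirror = NA)
  if (kind == "shadow" && is.null(columnRange))
    stop("shadow artifacts need a columnRange")
  structure(list(kind = kind, sliceRange = as.integer(sliceRange),
                 columnRange = columnRange, factor = factor),
            class = "artifactSpec")
}

covers <- function(spec, sliceIndex) {
  sliceIndex >= spec$sliceRange[1] && sliceIndex <= spec$sliceRange[2]
}

checkSpecBounds <- function(spec, idx, what, config) {
  if (spec$sliceRange[1] < 1 || spec$sliceRange[2] > config$nSlices)
    stop(sprintf("%s %d ('%s'): sliceRange [%d, %d] outside 1..%d",
                 what, idx, spec$kind, spec$sliceRange[1], spec$sliceRange[2],
                 config$nSlices))
  if (what == "lesion") {
    lo <- spec$lateralCenter - spec$width / 2
    hi <- spec$lateralCenter + spec$width / 2
    if (lo < 1 || hi > config$nCols)
      stop(sprintf("lesion %d ('%s'): lateral support [%.0f, %.0f] outside 1..%d",
                   idx, spec$kind, lo, hi, config$nCols))
  }
  if (spec$kind == "shadow" &&
      (spec$columnRange[1] < 1 || spec$columnRange[2] > config$nCols))
    stop(sprintf("artifact %d ('shadow'): columnRange outside 1..%d",
                 idx, config$nCols))
  invisible(TRUE)
}

# Layer surfaces for one slice: per-column ILM/EZ/RPE rows (1-based,
# fractional), before lesions.
baseSurfaces <- function(config, sliceIndex) {
  nR <- config$nRows; nC <- config$nCols; nS <- config$nSlices
  ph <- withSeed(config$seed, stats::runif(4, 0, 2 * pi))
  col <- seq_len(nC)
  s <- sliceIndex
  und <- 0.012 * nR * sin(2 * pi * col / nC * 1.3 + ph[1] +
                            0.5 * sin(2 * pi * s / nS + ph[2])) +
         0.006 * nR * sin(2 * pi * col / nC * 3.1 + ph[3] +
                            0.4 * sin(2 * pi * s / nS + ph[4]))
  rpe <- 0.54 * nR + und
  thickness <- 0.19 * nR
  dipAmp <- config$fovealDipDepth *
    exp(-0.5 * ((s - (nS + 1) / 2) / (0.18 * nS))^2)
  cc <- (nC + 1) / 2
  ilm <- rpe - thickness +
    dipAmp * exp(-0.5 * ((col - cc) / config$fovealDipWidth)^2)
  ezOff <- max(3, 0.03 * nR)
  ez <- rpe - ezOff
  ilm <- pmin(ilm, ez - 2)
  list(ilm = pmax(2, ilm), ez = ez, rpe = rpe)
}

#' Generate a single phantom B-scan
#'
#' Renders the layered retina for one slice, applies any covering lesions
#' and artifacts, adds speckle, and returns the scan with its ground-truth
#' label and layer surfaces.  Output is fully determined by
#' \code{(config, lesions, artifacts, sliceIndex)}.
#'
#' @param config a [phantomConfig()].
#' @param lesions list of [lesionSpec()] objects.
#' @param artifacts list of [artifactSpec()] objects.
#' @param sliceIndex 1-based slice position within the volume.
#' @return list with \code{pixels} (rows x cols matrix in \code{[0,1]}),
#'   \code{sliceIndex}, \code{label} and \code{surfaces} (\code{ilm},
#'   \code{ez}, \code{rpe} per-column rows).
#' @examples
#' b <- generateBScan(deskPhantomConfig(), sliceIndex = 12)
#' b$label
#' @export
generateBScan <- function(config, lesions = list(), artifacts = list(),
                          sliceIndex = 1L) {
  stopifnot(inherits(config, "phantomConfig"),
            sliceIndex >= 1, sliceIndex <= config$nSlices)
  for (i in seq_along(lesions))
    checkSpecBounds(lesions[[i]], i, "lesion", config)
  for (i in seq_along(artifacts))
    checkSpecBounds(artifacts[[i]], i, "artifact", config)

  nR <- config$nRows; nC <- config$nCols
  lv <- config$levels
  surf <- baseSurfaces(config, sliceIndex)
  ilm <- surf$ilm; ez <- surf$ez; rpe <- surf$rpe
  col <- seq_len(nC)

  active <- Filter(function(l) covers(l, sliceIndex) && l$amplitude > 0, lesions)
  gaSpecs <- list(); ermSpecs <- list()
  for (l in active) {
    if (l$kind %in% c("drusen", "ped")) {
      len <- l$sliceRange[2] - l$sliceRange[1] + 1
      m <- sin(pi * (sliceIndex - l$sliceRange[1] + 0.5) / len)
      prof <- l$amplitude * m *
        exp(-0.5 * ((col - l$lateralCenter) / (l$width / 6))^2)
      prof[abs(col - l$lateralCenter) > l$width / 2] <- 0
      rpe <- rpe - prof
      ez <- ez - prof
    } else if (l$kind == "ga") gaSpecs <- c(gaSpecs, list(l))
    else ermSpecs <- c(ermSpecs, list(l))
  }
  # enforce ILM < EZ < RPE after displacement
  ez <- pmin(ez, rpe - 1)
  ilm <- pmin(ilm, ez - 1)
  ilm <- pmax(ilm, 2); ez <- pmax(ez, ilm + 0.5); rpe <- pmax(rpe, ez + 0.5)

  bandEz <- max(2, round(3 * nR / 512))
  bandRpe <- max(2, round(5 * nR / 512))
  rpe <- pmin(rpe, nR - bandRpe)
  ez <- pmin(ez, rpe - 0.5)
  ilm <- pmin(ilm, ez - 0.5)

  rowIdx <- matrix(seq_len(nR), nR, nC)
  ILM <- matrix(ilm, nR, nC, byrow = TRUE)
  EZ <- matrix(ez, nR, nC, byrow = TRUE)
  RPE <- matrix(rpe, nR, nC, byrow = TRUE)
  img <- matrix(lv[["vitreous"]], nR, nC)
  img[rowIdx >= ILM & rowIdx < EZ] <- lv[["inner"]]
  img[rowIdx >= EZ & rowIdx < EZ + bandEz] <- lv[["ellipsoid"]]
  img[rowIdx >= EZ + bandEz & rowIdx < RPE] <- 0.6 * lv[["inner"]]
  img[rowIdx >= RPE & rowIdx < RPE + bandRpe] <- lv[["rpe"]]
  img[rowIdx >= RPE + bandRpe] <- lv[["choroid"]]

  for (l in gaSpecs) {
    mask <- abs(col - l$lateralCenter) <= l$width / 2
    sel <- rowIdx >= RPE & rowIdx < RPE + bandRpe
    sel[, !mask] <- FALSE
    img[sel] <- lv[["vitreous"]]
    below <- rowIdx >= RPE + bandRpe
    below[, !mask] <- FALSE
    img[below] <- clamp01(img[below] + l$amplitude)
  }
  for (l in ermSpecs) {
    mask <- abs(col - l$lateralCenter) <= l$width / 2
    gap <- max(3, round(5 * nR / 512))
    lt <- max(1, round(2 * nR / 512))
    sel <- rowIdx >= ILM - gap - lt & rowIdx < ILM - gap
    sel[, !mask] <- FALSE
    img[sel] <- clamp01(lv[["inner"]] + l$amplitude)
  }

  coveringArtifacts <- Filter(function(a) covers(a, sliceIndex), artifacts)
  for (a in coveringArtifacts) {
    if (a$kind == "shadow") {
      cr <- a$columnRange[1]:a$columnRange[2]
      img[, cr] <- img[, cr] * a$factor
    } else if (a$kind == "low_contrast") {
      img <- mean(img) + a$factor * (img - mean(img))
    } else {  # mirror
      top <- round(0.4 * nR)
      flipped <- img[nR:1, , drop = FALSE]
      img[1:top, ] <- pmax(img[1:top, ], flipped[1:top, ])
    }
  }

  if (config$speckle > 0) {
    k <- 1 / config$speckle^2
    sliceSeed <- deriveSeed(config$seed, sliceIndex)
    noise <- withSeed(sliceSeed,
                      stats::rgamma(nR * nC, shape = k, rate = k))
    img <- img * matrix(noise, nR, nC)
  }
  img <- clamp01(img)

  label <- if (length(coveringArtifacts)) "poor_quality"
           else if (length(active)) "relevant" else "normal"
  list(pixels = img, sliceIndex = as.integer(sliceIndex), label = label,
       surfaces = list(ilm = ilm, ez = ez, rpe = rpe))
}

#' Generate a phantom SDOCT volume
#'
#' @inheritParams generateBScan
#' @param volumeId identifier stored in the volume.
#' @param physicalExtent lateral x azimuthal extent in mm.
#' @return an \linkS4class{OCTVolume} with ground-truth labels and surfaces.
#' @examples
#' vol <- generateVolume(deskPhantomConfig(),
#'   lesions = list(lesionSpec("drusen", c(8, 14), 256, 40, 12)))
#' sliceLabels(vol)[6:16]
#' @export
generateVolume <- function(config, lesions = list(), artifacts = list(),
                           volumeId = "phantom",
                           physicalExtent = c(6.7, 6.7)) {
  slices <- lapply(seq_len(config$nSlices), function(s)
    generateBScan(config, lesions, artifacts, s))
  px <- array(0, c(config$nRows, config$nCols, config$nSlices))
  for (s in seq_along(slices)) px[, , s] <- slices[[s]]$pixels
  new("OCTVolume", pixels = px,
      labels = vapply(slices, `[[`, "", "label"),
      surfaces = lapply(slices, `[[`, "surfaces"),
      physicalExtent = physicalExtent, volumeId = volumeId)
}

#' Sample a random pathology/artifact configuration for one volume
#'
#' Draws 1 to \code{maxLesions} lesions of random kind, extent and amplitude
#' (scaled to the phantom geometry) and, with probability \code{pArtifact},
#' one acquisition artifact.  Used by [generateCohort()] to emulate a mixed
#' clinical population.
#'
#' @param config a [phantomConfig()].
#' @param seed integer seed.
#' @param maxLesions maximum number of lesions.
#' @param pArtifact probability the volume carries one artifact.
#' @return list with elements \code{lesions} and \code{artifacts}.
#' @export
samplePathology <- function(config, seed, maxLesions = 3, pArtifact = 0.5) {
  nS <- config$nSlices; nC <- config$nCols; nR <- config$nRows
  withSeed(seed, {
    nLes <- sample(seq_len(maxLesions), 1)
    lesions <- lapply(seq_len(nLes), function(i) {
      kind <- sample(c("drusen", "ped", "ga", "erm"), 1)
      len <- max(2, round(stats::runif(1, 0.15, 0.45) * nS))
      lo <- sample(seq_len(max(1, nS - len + 1)), 1)
      widthFrac <- switch(kind,
        drusen = stats::runif(1, 0.03, 0.055), ped = stats::runif(1, 0.08, 0.2),
        ga = stats::runif(1, 0.1, 0.25), erm = stats::runif(1, 0.15, 0.4))
      width <- widthFrac * nC
      center <- stats::runif(1, 0.2 * nC + width / 2, 0.8 * nC - width / 2)
      amp <- switch(kind,
        drusen = stats::runif(1, 0.035, 0.07) * nR,
        ped = stats::runif(1, 0.08, 0.15) * nR,
        ga = stats::runif(1, 0.25, 0.4),
        erm = stats::runif(1, 0.3, 0.5))
      lesionSpec(kind, c(lo, min(nS, lo + len - 1)), center, width, amp)
    })
    artifacts <- list()
    if (stats::runif(1) < pArtifact) {
      kind <- sample(c("shadow", "low_contrast", "mirror"), 1)
      len <- max(1, round(stats::runif(1, 0.1, 0.4) * nS))
      lo <- sample(seq_len(max(1, nS - len + 1)), 1)
      colRange <- NULL
      if (kind == "shadow") {
        w <- round(stats::runif(1, 0.1, 0.3) * nC)
        c0 <- sample(seq_len(nC - w), 1)
        colRange <- c(c0, c0 + w)
      }
      artifacts <- list(artifactSpec(kind, c(lo, min(nS, lo + len - 1)),
                                     columnRange = colRange))
    }
    list(lesions = lesions, artifacts = artifacts)
  })
}

#' Generate a cohort of phantom volumes
#'
#' Emulates a mixed study population: a fraction of healthy volumes (no
#' lesions) and diseased volumes with randomly sampled pathology; both may
#' carry acquisition artifacts.
#'
#' @inheritParams samplePathology
#' @param nVolumes number of volumes.
#' @param fracNormal fraction of lesion-free volumes (default 0.3, the
#'   healthy proportion of a typical AMD study population).
#' @return list of \linkS4class{OCTVolume} objects with ids
#'   \code{"vol001"}, ...
#' @export
generateCohort <- function(nVolumes, config = deskPhantomConfig(), seed = 1,
                           fracNormal = 0.3, pArtifact = 0.5,
                           maxLesions = 3) {
  healthy <- withSeed(deriveSeed(seed, 0),
                      sample(seq_len(nVolumes)) <= round(fracNormal * nVolumes))
  lapply(seq_len(nVolumes), function(v) {
    vseed <- deriveSeed(seed, v)
    path <- samplePathology(config, vseed, maxLesions = maxLesions,
                            pArtifact = pArtifact)
    if (healthy[v]) path$lesions <- list()
    cfg <- config
    cfg$seed <- vseed
    generateVolume(cfg, path$lesions, path$artifacts,
                   volumeId = sprintf("vol%03d", v))
  })
}
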