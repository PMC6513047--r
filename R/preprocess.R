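#' Preprocessing configuration
#'
#' Parameters of the retina localisation and standardisation chain: the
#' B-scan is filtered with a first-order Gaussian derivative along the axial
#' axis (scale \code{sigma}), the absolute response is thresholded by Otsu's
#' method, the two largest 8-connected components (the ILM and EZ/RPE
#' interface bands) define a bounding box of at least \code{minBoxHeight}
#' pixels, and the crop is resized to \code{300 x 512} (transfer path) or
#' further halved to \code{150 x 256} (de novo path).  Training-time
#' augmentation ranges are also held here.
#'
#' @param sigma Gaussian derivative scale in pixels (> 0).
#' @param minBoxHeight minimum crop height in pixels at full scale (512
#'   axial rows); \code{NULL} scales 300 px proportionally for images with a
#'   different axial extent.
#' @param targetHeight,targetWidth output size of the transfer path; the de
#'   novo path halves both.
#' @param rotationRange augmentation rotation limit in degrees (uniform in
#'   \code{[-r, r]}).
#' @param translationRange augmentation translation limit in pixels per axis.
#' @param contrastRange 2-vector, uniform contrast scale interval about the
#'   image mean.
#' @param flipProb probability of a horizontal (lateral) flip.
#' @return a list of class \code{preprocessConfig}.
#' @export
preprocessConfig <- function(sigma = 6.0, minBoxHeight = NULL,
                             targetHeight = 300L, targetWidth = 512L,
                             rotationRange = 5, translationRange = 10,
                             contrastRange = c(0.3, 1.7), flipProb = 0.5) {
  stopifnot(sigma > 0, targetHeight >= 8, targetWidth >= 8,
            rotationRange >= 0, translationRange >= 0,
            length(contrastRange) == 2, contrastRange[1] <= contrastRange[2],
            flipProb >= 0, flipProb <= 1)
  structure(list(sigma = sigma, minBoxHeight = minBoxHeight,
                 targetHeight = as.integer(targetHeight),
                 targetWidth = as.integer(targetWidth),
                 rotationRange = rotationRange,
                 translationRange = translationRange,
                 contrastRange = contrastRange, flipProb = flipProb),
            class = "preprocessConfig")
}

# Effective minimum box height for an image with nRows axial pixels:
# 300 px at full scale (512 rows), proportional otherwise.
effectiveMinBoxHeight <- function(config, nRows) {
  h <- config$minBoxHeight
  if (is.null(h)) h <- round(300 * nRows / 512)
  min(h, nRows)
}

#' Axial Gaussian-derivative response
#'
#' Convolves each A-scan (column) with a first-order derivative-of-Gaussian
#' kernel along the axial (row) axis, with edge replication, and returns the
#' absolute response.  Retinal interfaces (ILM, EZ, RPE) are horizontal
#' intensity steps, so they produce the strongest responses.
#'
#' @param image 2-D numeric matrix (rows = axial).
#' @param sigma derivative scale in pixels.
#' @return non-negative matrix of the same shape.
#' @examples
#' b <- generateBScan(deskPhantomConfig(speckle = 0), sliceIndex = 4)
#' r <- axialGradientResponse(b$pixels, 6)
#' # strongest response near the true ILM
#' abs(which.max(r[, 256]) - b$surfaces$ilm[256]) <= 3
#' @export
axialGradientResponse <- function(image, sigma = 6.0) {
  if (!is.matrix(image)) stop("image must be a 2-D matrix")
  stopifnot(sigma > 0)
  r <- ceiling(3 * sigma)
  x <- seq(-r, r)
  kernel <- -x / sigma^2 * exp(-x^2 / (2 * sigma^2))
  kernel <- kernel / sum(x * kernel) * -1  # unit response to a unit ramp
  abs(cpp_conv_rows(image, kernel))
}

#' Otsu threshold over a 256-bin histogram
#'
#' Threshold maximising the between-class variance of the 256-bin histogram
#' spanning the data range; computed by the cumulative-moment formulation.
#' The returned value is the boundary between the optimal cut's bins.
#'
#' @param response numeric matrix or vector with at least 2 distinct values.
#' @param nBins histogram resolution (default 256).
#' @return scalar threshold.
#' @export
otsuThreshold <- function(response, nBins = 256L) {
  v <- as.numeric(response)
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("degenerate histogram: input is constant, no threshold exists")
  edges <- seq(rng[1], rng[2], length.out = nBins + 1)
  idx <- pmin(nBins, findInterval(v, edges, rightmost.closed = TRUE))
  counts <- tabulate(idx, nBins)
  p <- counts / sum(counts)
  centers <- (edges[-1] + edges[-(nBins + 1)]) / 2
  w0 <- cumsum(p)[-nBins]
  mu0 <- cumsum(p * centers)[-nBins]
  muT <- sum(p * centers)
  valid <- w0 > 0 & w0 < 1
  between <- rep(-Inf, nBins - 1)
  between[valid] <- (muT * w0[valid] - mu0[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  cut <- which.max(between)
  edges[cut + 1]
}

#' Largest connected components of a binary image
#'
#' 8-connected component labeling (breadth-first flood fill); components are
#' ranked by pixel count, ties broken by smaller topmost row.
#'
#' @param bw logical matrix.
#' @param k number of components to keep (default 2: the ILM and EZ/RPE
#'   response bands).
#' @return list with \code{labels} (integer matrix of all component labels),
#'   \code{keep} (ids of the up-to-k selected components, ranked),
#'   \code{sizes} (their pixel counts) and \code{short} (TRUE when fewer
#'   than \code{k} components exist).
#' @export
largestComponents <- function(bw, k = 2L) {
  stopifnot(is.matrix(bw))
  lab <- cpp_label8(matrix(as.logical(bw), nrow(bw), ncol(bw)))
  n <- max(lab)
  if (n == 0)
    return(list(labels = lab, keep = integer(), sizes = integer(),
                short = TRUE))
  sizes <- tabulate(lab[lab > 0], n)
  topRow <- vapply(seq_len(n), function(i)
    min(row(lab)[lab == i]), 0L)
  ord <- order(-sizes, topRow)
  keep <- ord[seq_len(min(k, n))]
  list(labels = lab, keep = keep, sizes = sizes[keep], short = n < k)
}

#' Retina bounding box from localisation components
#'
#' The raw axial span runs from the topmost to the bottommost row of the
#' selected components.  A span shorter than the minimum height is expanded
#' symmetrically about its centre, then shifted to fit inside the image.
#'
#' @param components result of [largestComponents()].
#' @param nRows axial image extent.
#' @param minBoxHeight minimum box height in pixels.
#' @return list of class \code{retinaBox} with 1-based inclusive rows
#'   \code{top}, \code{bottom} and \code{height}.
#' @examples
#' # components spanning rows 121..141 and 261..286 in a 512-row scan
#' bw <- matrix(FALSE, 512, 40)
#' bw[121:141, 1:18] <- TRUE; bw[261:286, 1:22] <- TRUE
#' retinaBoundingBox(largestComponents(bw), 512, 300)
#' @export
retinaBoundingBox <- function(components, nRows, minBoxHeight = 300L) {
  if (length(components$keep) == 0)
    stop("no components found; caller should fall back to the full image")
  lab <- components$labels
  sel <- lab %in% components$keep
  rows <- row(lab)[sel]
  top0 <- min(rows) - 1L            # 0-based inclusive top
  bottom0 <- max(rows)              # 0-based exclusive bottom
  minH <- min(minBoxHeight, nRows)
  if (bottom0 - top0 < minH) {
    centre <- (top0 + bottom0) %/% 2
    top0 <- centre - minH %/% 2
    bottom0 <- top0 + minH
    if (top0 < 0) { bottom0 <- bottom0 - top0; top0 <- 0 }
    if (bottom0 > nRows) { top0 <- top0 - (bottom0 - nRows); bottom0 <- nRows }
    top0 <- max(top0, 0)
  }
  structure(list(top = top0 + 1L, bottom = bottom0,
                 height = bottom0 - top0), class = "retinaBox")
}

#' Locate the retina in a single B-scan
#'
#' Runs the full localisation chain (derivative response, Otsu threshold,
#' two largest components, box expansion).  When thresholding finds no
#' components the full image is returned with a warning.
#'
#' @param image B-scan matrix.
#' @param config a [preprocessConfig()].
#' @return a \code{retinaBox}.
#' @export
locateRetina <- function(image, config = preprocessConfig()) {
  minH <- effectiveMinBoxHeight(config, nrow(image))
  resp <- axialGradientResponse(image, config$sigma)
  comps <- tryCatch({
    thr <- otsuThreshold(resp)
    largestComponents(resp > thr, k = 2L)
  }, error = function(e) list(keep = integer()))
  if (length(comps$keep) == 0) {
    warning("retina localisation failed; using the full image")
    return(structure(list(top = 1L, bottom = nrow(image),
                          height = nrow(image)), class = "retinaBox"))
  }
  retinaBoundingBox(comps, nrow(image), minH)
}

#' Standardise a B-scan for classification
#'
#' Crops the B-scan to its retina bounding box, resizes bilinearly to
#' 300 x 512 (\code{path = "transfer"}) and additionally halves to 150 x 256
#' (\code{path = "denovo"}), then rescales intensities to \code{[0, 1]}.
#'
#' @param image B-scan matrix (>= 8 rows).
#' @param config a [preprocessConfig()].
#' @param path \code{"denovo"} (default) or \code{"transfer"}.
#' @param box optional precomputed \code{retinaBox}.
#' @return standardized matrix: 150 x 256 (denovo) or 300 x 512 (transfer).
#' @export
preprocessBScan <- function(image, config = preprocessConfig(),
                            path = c("denovo", "transfer"), box = NULL) {
  path <- match.arg(path)
  if (nrow(image) < 8) stop("image must have at least 8 rows")
  if (is.null(box)) box <- locateRetina(image, config)
  crop <- image[box$top:box$bottom, , drop = FALSE]
  out <- resizeBilinear(crop, config$targetHeight, config$targetWidth)
  if (path == "denovo")
    out <- resizeBilinear(out, config$targetHeight %/% 2L,
                          config$targetWidth %/% 2L)
  rng <- range(out)
  if (rng[1] < rng[2]) out <- (out - rng[1]) / (rng[2] - rng[1])
  else out <- out * 0
  out
}

#' Standardise every B-scan of a volume
#'
#' @param volume an \linkS4class{OCTVolume}.
#' @inheritParams preprocessBScan
#' @return an \linkS4class{OCTVolume} of standardized slices (labels and id
#'   preserved; ground-truth surfaces dropped, as they no longer apply to
#'   the cropped geometry).
#' @export
preprocessVolume <- function(volume, config = preprocessConfig(),
                             path = c("denovo", "transfer")) {
  path <- match.arg(path)
  n <- nSlices(volume)
  first <- preprocessBScan(getSlice(volume, 1), config, path)
  px <- array(0, c(dim(first), n))
  px[, , 1] <- first
  if (n > 1)
    for (s in 2:n)
      px[, , s] <- preprocessBScan(getSlice(volume, s), config, path)
  new("OCTVolume", pixels = px, labels = sliceLabels(volume),
      surfaces = list(), physicalExtent = volume@physicalExtent,
      volumeId = volume@volumeId)
}

#' Draw augmentation parameters
#'
#' Samples one set of augmentation parameters from the session RNG:
#' rotation ~ U(-r, r) degrees, translation ~ U(-t, t) pixels per axis,
#' contrast scale ~ U(lo, hi), horizontal flip with probability
#' \code{flipProb}.
#'
#' @param config a [preprocessConfig()].
#' @return list with \code{angle}, \code{dx}, \code{dy}, \code{contrast},
#'   \code{flip}.
#' @export
augmentParams <- function(config = preprocessConfig()) {
  list(
    angle = stats::runif(1, -config$rotationRange, config$rotationRange),
    dx = stats::runif(1, -config$translationRange, config$translationRange),
    dy = stats::runif(1, -config$translationRange, config$translationRange),
    contrast = stats::runif(1, config$contrastRange[1],
                            config$contrastRange[2]),
    flip = stats::runif(1) < config$flipProb
  )
}

#' Apply augmentation with explicit parameters
#'
#' Order: rotate, translate, contrast-scale about the image mean, flip
#' horizontally; the result is clipped to \code{[0, 1]}.  With zero ranges
#' the transform is the identity.
#'
#' @param image matrix in \code{[0, 1]}.
#' @param params as produced by [augmentParams()].
#' @return augmented matrix of the same shape.
#' @export
applyAugment <- function(image, params) {
  out <- image
  if (params$angle != 0)
    out <- matrix(EBImage::imageData(EBImage::rotate(
      EBImage::Image(out), params$angle, output.dim = dim(out),
      bg.col = 0)), nrow(out), ncol(out))
  dy <- round(params$dy); dx <- round(params$dx)
  if (dy != 0 || dx != 0) {
    sh <- matrix(0, nrow(out), ncol(out))
    srcR <- seq_len(nrow(out)) - dy
    srcC <- seq_len(ncol(out)) - dx
    okR <- srcR >= 1 & srcR <= nrow(out)
    okC <- srcC >= 1 & srcC <= ncol(out)
    sh[okR, okC] <- out[srcR[okR], srcC[okC]]
    out <- sh
  }
  if (params$contrast != 1) {
    m <- mean(out)
    out <- m + params$contrast * (out - m)
  }
  if (params$flip) out <- out[, ncol(out):1, drop = FALSE]
  clamp01(out)
}

#' Randomly augment a B-scan
#'
#' Convenience wrapper: draws parameters with [augmentParams()] from the
#' session RNG and applies them.
#'
#' @inheritParams applyAugment
#' @param config a [preprocessConfig()].
#' @return augmented matrix.
#' @export
augmentImage <- function(image, config = preprocessConfig()) {
  applyAugment(image, augmentParams(config))
}
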