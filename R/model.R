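#' Network configuration for the de novo classifier
#'
#' Seven 3x3 convolutional layers with ReLU; after each layer the layer
#' input and output are concatenated along channels (the skip connection)
#' and, per pooling mode, max-pooled in a 2x2 window.  A global average
#' pooling (GAP) layer feeds a fully connected 2-way softmax.  With the
#' default filter widths the GAP vector has 1 + sum(filterWidths) = 609
#' channels and the network holds 1,389,700 trainable parameters.
#'
#' \code{poolingMode = "literal"} pools after every layer (a 150 x 256 input
#' reaches 1 x 2); \code{"cam_friendly"} pools after layers 1-5 only,
#' leaving a 4 x 8 final map for higher-resolution class activation maps.
#' The trainable-parameter count is identical in both modes.
#'
#' @param filterWidths 7 conv filter counts.
#' @param inputShape input rows and columns (de novo path: 150 x 256).
#' @param nClasses output classes (2: normal vs relevant).
#' @param poolingMode \code{"literal"} or \code{"cam_friendly"}.
#' @return a list of class \code{networkConfig}.
#' @export
networkConfig <- function(filterWidths = c(32L, 64L, 64L, 64L, 128L, 128L, 128L),
                          inputShape = c(150L, 256L), nClasses = 2L,
                          poolingMode = c("literal", "cam_friendly")) {
  poolingMode <- match.arg(poolingMode)
  if (length(filterWidths) != 7L)
    stop("exactly 7 conv layers required (got ", length(filterWidths), ")")
  stopifnot(all(filterWidths >= 1), length(inputShape) == 2, nClasses >= 2)
  structure(list(filterWidths = as.integer(filterWidths),
                 inputShape = as.integer(inputShape),
                 nClasses = as.integer(nClasses),
                 poolingMode = poolingMode),
            class = "networkConfig")
}

poolSchedule <- function(config) {
  if (config$poolingMode == "literal") rep(TRUE, 7)
  else c(rep(TRUE, 5), FALSE, FALSE)
}

#' Build the de novo network
#'
#' Initialises conv weights with He-scaled Gaussians (sd
#' \code{sqrt(2 / fan_in)}), biases at zero, and the fully connected layer
#' with small Gaussians.
#'
#' @param config a [networkConfig()].
#' @param seed integer seed for the initialisation.
#' @return a \linkS4class{DenovoNet}.
#' @examples
#' net <- buildDenovoNet(networkConfig(), seed = 1)
#' countTrainable(net)   # 1,389,700
#' @export
buildDenovoNet <- function(config = networkConfig(), seed = 1L) {
  fw <- config$filterWidths
  withSeed(seed, {
    chIn <- 1L
    convW <- vector("list", 7L)
    convB <- vector("list", 7L)
    for (i in seq_len(7L)) {
      fanIn <- 9L * chIn
      convW[[i]] <- matrix(stats::rnorm(fw[i] * fanIn, sd = sqrt(2 / fanIn)),
                           fw[i], fanIn)
      convB[[i]] <- numeric(fw[i])
      chIn <- chIn + fw[i]
    }
    fcW <- matrix(stats::rnorm(config$nClasses * chIn, sd = sqrt(2 / chIn)),
                  config$nClasses, chIn)
    new("DenovoNet", config = config, convW = convW, convB = convB,
        fcW = fcW, fcB = numeric(config$nClasses))
  })
}

#' Closed-form trainable-parameter count
#'
#' Layer-wise sum \code{sum_i (9 * ch_in(i) * f_i + f_i)} with
#' \code{ch_in(i+1) = ch_in(i) + f_i}, plus the fully connected
#' \code{(1 + sum f_i) -> nClasses} weights and biases.  Used as the
#' independent cross-check of [countTrainable()].
#'
#' @param filterWidths conv filter counts.
#' @param nClasses output classes.
#' @return integer parameter count.
#' @export
paramCountFormula <- function(filterWidths = c(32L, 64L, 64L, 64L, 128L,
                                               128L, 128L), nClasses = 2L) {
  chIn <- 1L
  total <- 0L
  for (f in filterWidths) {
    total <- total + 9L * chIn * f + f
    chIn <- chIn + f
  }
  total + nClasses * chIn + nClasses
}

#' Balanced cross-entropy loss
#'
#' \deqn{L = \sum_i [ -C_2 y_i \log \hat y_i - C_1 (1 - y_i) \log(1 - \hat
#' y_i) ]}{L = sum_i [ -C2 y_i log(p_i) - C1 (1 - y_i) log(1 - p_i) ]}
#' where \eqn{C_1} counts the relevant (\eqn{y = 1}) and \eqn{C_2} the
#' normal samples in the batch.  Each class's term is weighted by the other
#' class's count, so the two classes contribute with equal total weight
#' (\eqn{C_1 C_2} each) regardless of imbalance.  Probabilities are clipped
#' to \code{[epsClip, 1 - epsClip]} before the logarithm.
#'
#' @param y 0/1 true labels (1 = relevant).
#' @param yhat predicted probabilities of the relevant class.
#' @param epsClip probability floor.
#' @return scalar loss (natural log, >= 0).
#' @examples
#' balancedCrossEntropy(c(1, 0), c(0.5, 0.5))   # -2 log 0.5 = 1.386294
#' @export
balancedCrossEntropy <- function(y, yhat, epsClip = 1e-7) {
  if (length(y) == 0) stop("empty batch")
  stopifnot(length(y) == length(yhat), all(y %in% c(0, 1)))
  p <- pmin(pmax(yhat, epsClip), 1 - epsClip)
  C1 <- sum(y == 1)
  C2 <- sum(y == 0)
  sum(-C2 * y * log(p) - C1 * (1 - y) * log(1 - p))
}

stackToCube <- function(stack, inputShape) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  d <- dim(stack)
  if (length(d) != 3 || d[1] != inputShape[1] || d[2] != inputShape[2])
    stop(sprintf("input stack must be %d x %d x n (got %s)",
                 inputShape[1], inputShape[2], paste(d, collapse = " x ")))
  stack
}

#' Per-slice relevance probabilities and flags
#'
#' Runs the network forward over a stack of standardized (de novo path)
#' B-scans and thresholds the softmax probability of the relevant class at
#' 0.5.
#'
#' @param net a \linkS4class{DenovoNet}.
#' @param stack matrix (one image) or rows x cols x n array, or an
#'   \linkS4class{OCTVolume} of preprocessed slices.
#' @return data.frame with \code{slice}, \code{probability}, \code{flag}.
#' @export
predictSlices <- function(net, stack) {
  if (is(stack, "OCTVolume")) stack <- stack@pixels
  cube <- stackToCube(stack, net@config$inputShape)
  fwd <- cpp_net_forward(net@convW, net@convB, net@fcW, net@fcB, cube,
                         poolSchedule(net@config))
  prob <- fwd$probs[, 2L]
  data.frame(slice = seq_len(dim(cube)[3]), probability = prob,
             flag = prob >= 0.5)
}

#' Class activation map
#'
#' CAM of class \code{classIndex}: the weighted sum
#' \eqn{\sum_k w_k^c f_k(x, y)} of the final feature maps (the GAP inputs)
#' under the class's fully connected weights, plus a bilinearly upsampled
#' copy at input resolution.
#'
#' @param net a \linkS4class{DenovoNet}.
#' @param image one standardized B-scan (input shape).
#' @param classIndex 1 (normal) or 2 (relevant).
#' @return list with \code{map} (final feature-map resolution) and
#'   \code{upsampled} (input resolution).
#' @export
computeCAM <- function(net, image, classIndex = 2L) {
  if (!classIndex %in% seq_len(net@config$nClasses))
    stop("classIndex must be in 1..", net@config$nClasses)
  feats <- cpp_net_features(net@convW, net@convB, net@fcW, net@fcB,
                            stackToCube(image, net@config$inputShape)[, , 1],
                            poolSchedule(net@config))
  w <- net@fcW[classIndex, ]
  map <- matrix(0, dim(feats)[1], dim(feats)[2])
  for (k in seq_len(dim(feats)[3])) map <- map + w[k] * feats[, , k]
  list(map = map,
       upsampled = resizeBilinear(map, net@config$inputShape[1],
                                  net@config$inputShape[2]))
}

# Internal: final feature maps for a single image (used by tests/oracles).
netFeatureMaps <- function(net, image) {
  cpp_net_features(net@convW, net@convB, net@fcW, net@fcB,
                   stackToCube(image, net@config$inputShape)[, , 1],
                   poolSchedule(net@config))
}
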