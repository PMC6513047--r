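#' Training configuration
#'
#' Adam hyperparameters follow the published recipe (learning rate 1e-6,
#' beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8; at most 150 epochs).  Two
#' early-stopping rules are available: \code{"loss_delta"} stops when the
#' validation loss has not improved by more than \code{minDelta} for
#' \code{patience} consecutive epochs, \code{"val_auc_plateau"} stops when
#' the validation AUC is unchanged (within 1e-4) for \code{patience} epochs.
#'
#' @param learningRate Adam step size.
#' @param beta1,beta2,epsilon Adam moment decay rates and stabiliser.
#' @param maxEpochs hard epoch cap.
#' @param batchSize minibatch size.
#' @param stopRule \code{"loss_delta"} (default) or \code{"val_auc_plateau"}.
#' @param minDelta minimum absolute validation-loss improvement under
#'   \code{"loss_delta"}.
#' @param patience early-stopping patience in epochs.
#' @param fractions train/validation/test volume fractions (must sum to 1).
#' @param nFolds cross-validation folds.
#' @param seed seed controlling shuffling and augmentation.
#' @return a list of class \code{trainConfig}.
#' @export
trainConfig <- function(learningRate = 1e-6, beta1 = 0.9, beta2 = 0.999,
                        epsilon = 1e-8, maxEpochs = 150L, batchSize = 16L,
                        stopRule = c("loss_delta", "val_auc_plateau"),
                        minDelta = 0.1, patience = 10L,
                        fractions = c(train = 0.75, val = 0.10, test = 0.15),
                        nFolds = 10L, seed = 1L) {
  stopRule <- match.arg(stopRule)
  stopifnot(learningRate > 0, maxEpochs >= 1, batchSize >= 1,
            length(fractions) == 3, patience >= 1)
  if (abs(sum(fractions) - 1) > 1e-8) stop("split fractions must sum to 1")
  structure(list(learningRate = learningRate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, maxEpochs = as.integer(maxEpochs),
                 batchSize = as.integer(batchSize), stopRule = stopRule,
                 minDelta = minDelta, patience = as.integer(patience),
                 fractions = fractions, nFolds = as.integer(nFolds),
                 seed = as.integer(seed)), class = "trainConfig")
}

#' Volume-level train/validation/test split
#'
#' Whole volumes are allocated to one set each, so B-scans from a single
#' volume never straddle sets.  Set sizes are \code{round(fraction * N)} for
#' validation and test, with the remainder in training.
#'
#' @param volumeIds character or integer vector of volume identifiers.
#' @param fractions train/val/test fractions summing to 1.
#' @param seed integer seed; the split is deterministic given the seed.
#' @return list with \code{train}, \code{val}, \code{test} id vectors.
#' @examples
#' sp <- splitVolumes(sprintf("vol%02d", 1:20), seed = 7)
#' lengths(sp)   # 15, 2, 3
#' @export
splitVolumes <- function(volumeIds,
                         fractions = c(train = 0.75, val = 0.10, test = 0.15),
                         seed = 1L) {
  n <- length(volumeIds)
  if (n < 3) stop("need at least 3 volumes (one per set)")
  if (abs(sum(fractions) - 1) > 1e-8) stop("split fractions must sum to 1")
  nVal <- round(fractions[[2]] * n)
  nTest <- round(fractions[[3]] * n)
  perm <- withSeed(seed, sample(volumeIds))
  list(test = sort(perm[seq_len(nTest)]),
       val = sort(perm[nTest + seq_len(nVal)]),
       train = sort(perm[-(seq_len(nTest + nVal))]))[c("train", "val", "test")]
}

#' Independent cross-validation folds
#'
#' Each fold is an independent volume-level re-split at the configured
#' fractions under a derived sub-seed, so every fold's test volumes are
#' unseen by that fold's training and validation.
#'
#' @inheritParams splitVolumes
#' @param nFolds number of folds (>= 2).
#' @return list of \code{nFolds} splits as returned by [splitVolumes()].
#' @export
makeFolds <- function(volumeIds, nFolds = 10L,
                      fractions = c(train = 0.75, val = 0.10, test = 0.15),
                      seed = 1L) {
  if (nFolds < 2) stop("nFolds must be >= 2")
  lapply(seq_len(nFolds), function(k)
    splitVolumes(volumeIds, fractions, deriveSeed(seed, k)))
}

#' Early-stopping decision
#'
#' @param history data.frame with per-epoch \code{val_loss} and
#'   \code{val_auc} columns (see [trainClassifier()]).
#' @param config a [trainConfig()].
#' @return TRUE when training should stop.
#' @examples
#' h <- data.frame(val_loss = c(1.00, 0.95, 0.94), val_auc = c(.7, .8, .9))
#' shouldStop(h, trainConfig(minDelta = 0.1, patience = 2))
#' @export
shouldStop <- function(history, config = trainConfig()) {
  n <- nrow(history)
  if (n == 0) stop("history is empty")
  if (n >= config$maxEpochs) return(TRUE)
  if (config$stopRule == "loss_delta") {
    best <- history$val_loss[1]
    wait <- 0L
    for (i in seq_len(n)[-1]) {
      if (best - history$val_loss[i] > config$minDelta) wait <- 0L
      else wait <- wait + 1L
      best <- min(best, history$val_loss[i])
    }
    wait >= config$patience
  } else {
    if (n <= config$patience) return(FALSE)
    recent <- history$val_auc[(n - config$patience):n]
    all(abs(recent - recent[1]) <= 1e-4)
  }
}

adamUpdate <- function(state, grads, config) {
  state$t <- state$t + 1L
  lr <- config$learningRate *
    sqrt(1 - config$beta2^state$t) / (1 - config$beta1^state$t)
  for (nm in names(grads)) {
    state$m[[nm]] <- config$beta1 * state$m[[nm]] +
      (1 - config$beta1) * grads[[nm]]
    state$v[[nm]] <- config$beta2 * state$v[[nm]] +
      (1 - config$beta2) * grads[[nm]]^2
    state$par[[nm]] <- state$par[[nm]] -
      lr * state$m[[nm]] / (sqrt(state$v[[nm]]) + config$epsilon)
  }
  state
}

flattenNet <- function(net) {
  par <- list()
  for (i in seq_len(7)) {
    par[[sprintf("W%d", i)]] <- net@convW[[i]]
    par[[sprintf("b%d", i)]] <- net@convB[[i]]
  }
  par$fcW <- net@fcW
  par$fcB <- net@fcB
  par
}

unflattenNet <- function(net, par) {
  for (i in seq_len(7)) {
    net@convW[[i]] <- par[[sprintf("W%d", i)]]
    net@convB[[i]] <- par[[sprintf("b%d", i)]]
  }
  net@fcW <- par$fcW
  net@fcB <- par$fcB
  net
}

gradsToList <- function(g) {
  out <- list()
  for (i in seq_len(7)) {
    out[[sprintf("W%d", i)]] <- g$convW[[i]]
    out[[sprintf("b%d", i)]] <- as.numeric(g$convB[[i]])
  }
  out$fcW <- g$fcW
  out$fcB <- as.numeric(g$fcB)
  out
}

# Eq-1 class-balance weights for a batch: samples of each class are
# weighted by the other class's count.
batchWeights <- function(y) {
  C1 <- sum(y == 1)
  C2 <- sum(y == 0)
  ifelse(y == 1, C2, C1)
}

#' Train the de novo classifier
#'
#' Minimises the balanced cross-entropy (class counts recomputed per batch)
#' with Adam over shuffled minibatches; every training image is passed
#' through the random augmentation pipeline each epoch.  Validation loss and
#' AUC are recorded per epoch and drive the early-stopping rule.
#'
#' Slices labelled \code{poor_quality} must be excluded by the caller (see
#' [collectSlices()]); training inputs are binary normal/relevant stacks.
#'
#' @param net a \linkS4class{DenovoNet}.
#' @param trainX,valX standardized image stacks (rows x cols x n).
#' @param trainY,valY 0/1 labels (1 = relevant).
#' @param config a [trainConfig()].
#' @param preConfig a [preprocessConfig()] providing augmentation ranges.
#' @param augment logical; set FALSE to disable augmentation.
#' @param verbose print per-epoch progress.
#' @return list with \code{net} (trained), \code{history} (data.frame:
#'   epoch, train_loss, val_loss, val_auc) and \code{stopReason}.
#' @export
trainClassifier <- function(net, trainX, trainY, valX, valY,
                            config = trainConfig(),
                            preConfig = preprocessConfig(),
                            augment = TRUE, verbose = FALSE) {
  trainX <- stackToCube(trainX, net@config$inputShape)
  valX <- stackToCube(valX, net@config$inputShape)
  nTrain <- dim(trainX)[3]
  if (nTrain == 0 || length(valY) == 0) stop("empty training or validation set")
  stopifnot(length(trainY) == nTrain, dim(valX)[3] == length(valY))
  if (length(unique(trainY)) < 2)
    warning("single-class training set: the absent class has weight 0 and ",
            "the loss degenerates")

  pool <- poolSchedule(net@config)
  par <- flattenNet(net)
  state <- list(par = par, m = lapply(par, function(p) p * 0),
                v = lapply(par, function(p) p * 0), t = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_auc = numeric())
  stopReason <- "max_epochs"

  withSeed(config$seed, {
    for (epoch in seq_len(config$maxEpochs)) {
      ord <- sample(nTrain)
      epochLoss <- 0
      for (start in seq(1, nTrain, by = config$batchSize)) {
        idx <- ord[start:min(start + config$batchSize - 1, nTrain)]
        batch <- trainX[, , idx, drop = FALSE]
        if (augment)
          for (j in seq_along(idx))
            batch[, , j] <- augmentImage(batch[, , j], preConfig)
        y <- trainY[idx]
        g <- cpp_net_grad(state$par[paste0("W", 1:7)],
                          state$par[paste0("b", 1:7)],
                          state$par$fcW, state$par$fcB, batch,
                          as.integer(y), batchWeights(y), pool, 1e-7)
        epochLoss <- epochLoss + g$loss
        state <- adamUpdate(state, gradsToList(g), config)
      }
      cur <- unflattenNet(net, state$par)
      valProb <- predictSlices(cur, valX)$probability
      valLoss <- balancedCrossEntropy(valY, valProb)
      valAuc <- if (length(unique(valY)) == 2) rocAuc(valY, valProb) else NA_real_
      history[epoch, ] <- list(epoch, epochLoss, valLoss, valAuc)
      if (verbose)
        message(sprintf("epoch %3d  train %.3f  val %.3f  auc %s", epoch,
                        epochLoss, valLoss, format(valAuc, digits = 4)))
      if (shouldStop(history, config)) {
        stopReason <- if (epoch >= config$maxEpochs) "max_epochs"
                      else config$stopRule
        break
      }
    }
  })
  list(net = unflattenNet(net, state$par), history = history,
       stopReason = stopReason)
}

#' Pool usable slices from volumes into a labelled stack
#'
#' Standardises every slice of the given volumes (de novo path), drops
#' \code{poor_quality} slices, and returns the stack with binary labels.
#'
#' @param volumes list of \linkS4class{OCTVolume}.
#' @param ids volume ids to include (default: all).
#' @param config a [preprocessConfig()].
#' @return list with \code{x} (150 x 256 x n array), \code{y} (0/1,
#'   1 = relevant) and \code{volume} (id per slice).
#' @export
collectSlices <- function(volumes, ids = NULL, config = preprocessConfig()) {
  vids <- vapply(volumes, volumeId, "")
  if (is.null(ids)) ids <- vids
  use <- volumes[vids %in% ids]
  stacks <- lapply(use, preprocessVolume, config = config, path = "denovo")
  keep <- lapply(stacks, function(v) which(sliceLabels(v) != "poor_quality"))
  total <- sum(lengths(keep))
  d <- dim(stacks[[1]]@pixels)[1:2]
  x <- array(0, c(d, total))
  y <- integer(total)
  vol <- character(total)
  at <- 0L
  for (i in seq_along(stacks)) {
    for (s in keep[[i]]) {
      at <- at + 1L
      x[, , at] <- stacks[[i]]@pixels[, , s]
      y[at] <- as.integer(sliceLabels(stacks[[i]])[s] == "relevant")
      vol[at] <- volumeId(stacks[[i]])
    }
  }
  list(x = x, y = y, volume = vol)
}
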