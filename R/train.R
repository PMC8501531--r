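## Training harness: Adam optimization of the U-Net under a selectable loss
## (plain MSE or sharp loss), with reduce-on-plateau learning-rate
## scheduling, seeded shuffling, best-validation checkpointing and k-fold
## cross-validation utilities.

#' Training configuration
#'
#' Defaults follow the standard recipe for this task: Adam, batch size 2,
#' initial learning rate 0.001, learning rate reduced by a factor of 0.1
#' when the validation loss has not decreased for 5 epochs, floored at
#' 1e-7, and tenfold cross-validation.
#'
#' @slot learningRate initial Adam learning rate.
#' @slot batchSize cases per optimization step.
#' @slot lrDecayFactor multiplicative learning-rate decay on plateau.
#' @slot lrPatience plateau length (validation epochs) triggering decay.
#' @slot lrFloor lowest admissible learning rate.
#' @slot maxEpochs training epochs.
#' @slot cvFolds folds for cross-validation.
#' @slot seed seed for shuffling (weight init is seeded by the model config).
#' @slot lossName `"mse"` or `"sharp"`.
#' @slot lossCfg the [LossConfig-class] for the sharp loss.
#' @slot monitorMse if TRUE the plateau scheduler watches plain validation
#'   MSE instead of the training objective (comparable across variants).
#' @aliases TrainConfig
#' @seealso [trainConfig()], [trainUNet()]
#' @exportClass TrainConfig
setClass("TrainConfig", representation(
  learningRate = "numeric", batchSize = "integer", lrDecayFactor = "numeric",
  lrPatience = "integer", lrFloor = "numeric", maxEpochs = "integer",
  cvFolds = "integer", seed = "integer", lossName = "character",
  lossCfg = "LossConfig", monitorMse = "logical"))

setValidity("TrainConfig", function(object) {
  msgs <- character()
  if (object@lrFloor >= object@learningRate)
    msgs <- c(msgs, "lrFloor must be below learningRate")
  if (object@batchSize < 1L) msgs <- c(msgs, "batchSize must be >= 1")
  if (object@cvFolds < 2L) msgs <- c(msgs, "cvFolds must be >= 2")
  if (!object@lossName %in% c("mse", "sharp"))
    msgs <- c(msgs, "lossName must be 'mse' or 'sharp'")
  if (length(msgs)) msgs else TRUE
})

#' Create a training configuration
#'
#' @param learningRate,batchSize,lrDecayFactor,lrPatience,lrFloor,maxEpochs
#'   optimizer and schedule settings (see [TrainConfig-class]).
#' @param cvFolds folds for [crossValidate()].
#' @param seed shuffling seed.
#' @param lossName `"mse"` or `"sharp"`.
#' @param lossCfg a [LossConfig-class].
#' @param monitorMse monitor plain MSE for scheduling instead of the
#'   training objective.
#' @return A validated [TrainConfig-class].
#' @export
trainConfig <- function(learningRate = 0.001, batchSize = 2,
                        lrDecayFactor = 0.1, lrPatience = 5,
                        lrFloor = 1e-7, maxEpochs = 50, cvFolds = 10,
                        seed = 1, lossName = "sharp",
                        lossCfg = lossConfig(), monitorMse = FALSE) {
  new("TrainConfig", learningRate = as.numeric(learningRate),
      batchSize = as.integer(batchSize),
      lrDecayFactor = as.numeric(lrDecayFactor),
      lrPatience = as.integer(lrPatience), lrFloor = as.numeric(lrFloor),
      maxEpochs = as.integer(maxEpochs), cvFolds = as.integer(cvFolds),
      seed = as.integer(seed), lossName = lossName, lossCfg = lossCfg,
      monitorMse = isTRUE(monitorMse))
}

## ---- reduce-on-plateau scheduler -------------------------------------

#' Initialize a reduce-on-plateau learning-rate schedule
#'
#' The schedule watches a validation metric; every epoch without strict
#' improvement over the best value seen increments a wait counter, and once
#' the counter reaches `patience` the learning rate is multiplied by
#' `factor` (never below `floor`) and the counter resets.
#'
#' @param lr initial learning rate.
#' @param factor decay factor (default 0.1).
#' @param patience epochs without improvement before decaying (default 5).
#' @param floor lowest learning rate (default 1e-7).
#' @return A schedule state list for [updatePlateau()].
#' @export
plateauSchedule <- function(lr = 0.001, factor = 0.1, patience = 5,
                            floor = 1e-7) {
  list(lr = lr, factor = factor, patience = as.integer(patience),
       floor = floor, best = Inf, wait = 0L, nDecays = 0L)
}

#' Advance a plateau schedule by one validation epoch
#'
#' @param state schedule state from [plateauSchedule()].
#' @param valLoss the epoch's validation loss.
#' @return Updated state; `state$decayed` is TRUE when this epoch triggered
#'   a learning-rate decay.
#' @examples
#' s <- plateauSchedule(0.001)
#' for (v in rep(1, 6)) s <- updatePlateau(s, v)
#' s$lr  # 1e-4 after a 6-epoch plateau
#' @export
updatePlateau <- function(state, valLoss) {
  state$decayed <- FALSE
  if (is.finite(valLoss) && valLoss < state$best) {
    state$best <- valLoss
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= state$patience) {
      newLr <- max(state$lr * state$factor, state$floor)
      state$decayed <- newLr < state$lr
      state$lr <- newLr
      state$wait <- 0L
      state$nDecays <- state$nDecays + as.integer(state$decayed)
    }
  }
  state
}

## ---- Adam ------------------------------------------------------------

.adamInit <- function(params) {
  zero <- function(x) if (is.list(x)) lapply(x, zero) else x * 0
  list(m = zero(params), v = zero(params), t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      if (!is.null(names(p))) {  # align subtrees by name, not position
        g <- g[names(p)]; m <- m[names(p)]; v <- v[names(p)]
      }
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  out <- upd(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}

## ---- training --------------------------------------------------------

.caseInput <- function(case) {
  if (is(case$encoded, "EncodedVolume")) case$encoded@voxels else case$encoded
}

.evalLoss <- function(model, cases, lossFns) {
  vals <- vapply(cases, function(cs) {
    pred <- predictDose(model, .caseInput(cs))
    lossFns$loss(pred, cs$doseNorm)
  }, numeric(1))
  mean(vals)
}

#' Train a U-Net on paired (encoded ROI, normalized dose) cases
#'
#' Minimizes the configured loss with Adam over shuffled mini-batches,
#' evaluating the validation loss each epoch, driving the reduce-on-plateau
#' schedule, and retaining the best-validation parameters. Aborts with a
#' diagnostic if the loss becomes non-finite.
#'
#' @param model a [UNetModel-class] from [buildUNet()].
#' @param trainCases list of cases, each with `encoded`
#'   ([EncodedVolume-class] or array) and `doseNorm` (array in \[0, 1\]).
#' @param valCases validation cases for scheduling/checkpointing; if empty,
#'   the training loss is monitored instead.
#' @param tcfg a [TrainConfig-class].
#' @param verbose print per-epoch progress.
#' @return list with `model` (best checkpoint), `finalModel`, `history`
#'   (data.frame epoch/trainLoss/valLoss/lr) and `schedule` (final state).
#' @export
trainUNet <- function(model, trainCases, valCases = list(),
                      tcfg = trainConfig(), verbose = FALSE) {
  stopifnot(is(model, "UNetModel"), length(trainCases) >= 1)
  validObject(tcfg)
  lossFns <- lossByName(tcfg@lossName, tcfg@lossCfg)
  mseFns <- lossByName("mse")
  dims <- dim(.caseInput(trainCases[[1]]))
  adam <- .adamInit(model@params)
  sched <- plateauSchedule(tcfg@learningRate, tcfg@lrDecayFactor,
                           tcfg@lrPatience, tcfg@lrFloor)
  hist <- data.frame(epoch = integer(), trainLoss = numeric(),
                     valLoss = numeric(), lr = numeric())
  best <- list(loss = Inf, params = model@params, bnStats = model@bnStats)
  withr::with_seed(tcfg@seed, {
    for (epoch in seq_len(tcfg@maxEpochs)) {
      ord <- sample.int(length(trainCases))
      batches <- split(ord, ceiling(seq_along(ord) / tcfg@batchSize))
      epochLoss <- 0
      for (bi in batches) {
        xs <- lapply(trainCases[bi], .caseInput)
        ys <- lapply(trainCases[bi], `[[`, "doseNorm")
        B <- length(bi)
        x <- .casesToMatrix(xs)
        y <- .casesToMatrix(ys)
        fw <- .unetForward(model, x, dims, B, training = TRUE)
        model@bnStats <- fw$bnStats
        loss <- lossFns$loss(fw$out, y)
        if (!is.finite(loss))
          stop(sprintf("training diverged at epoch %d (loss = %g)",
                       epoch, loss))
        dout <- lossFns$gradient(fw$out, y)
        grads <- .unetBackward(model, fw, dout)
        step <- .adamStep(model@params, grads, adam, sched$lr)
        model@params <- step$params
        adam <- step$state
        epochLoss <- epochLoss + loss * B
      }
      trainLoss <- epochLoss / length(trainCases)
      monFns <- if (tcfg@monitorMse) mseFns else lossFns
      valLoss <- if (length(valCases)) .evalLoss(model, valCases, monFns)
                 else trainLoss
      sched <- updatePlateau(sched, valLoss)
      hist <- rbind(hist, data.frame(epoch = epoch, trainLoss = trainLoss,
                                     valLoss = valLoss, lr = sched$lr))
      if (valLoss < best$loss)
        best <- list(loss = valLoss, params = model@params,
                     bnStats = model@bnStats)
      if (verbose)
        message(sprintf("epoch %3d  train %.5g  val %.5g  lr %g",
                        epoch, trainLoss, valLoss, sched$lr))
    }
  })
  bestModel <- model
  bestModel@params <- best$params
  bestModel@bnStats <- best$bnStats
  list(model = bestModel, finalModel = model, history = hist,
       schedule = sched)
}

## ---- dataset splitting -----------------------------------------------

#' Split a dataset into training and held-out test cases
#'
#' @param cases list of cases (e.g. from [generateDataset()]).
#' @param nTest number of test cases, `0 < nTest < length(cases)`.
#' @param seed seed for the random selection.
#' @return list with `train` and `test`; disjoint, exhaustive and
#'   reproducible for a fixed seed.
#' @export
splitDataset <- function(cases, nTest, seed = 1L) {
  n <- length(cases)
  if (nTest <= 0) stop("nTest must be positive")
  if (nTest >= n) stop("nTest must be smaller than the number of cases")
  testIdx <- withr::with_seed(as.integer(seed), sample.int(n, nTest))
  list(train = cases[setdiff(seq_len(n), testIdx)], test = cases[testIdx])
}

#' Assign cases to cross-validation folds
#'
#' Folds are disjoint, cover all cases and differ in size by at most one
#' (larger folds first).
#'
#' @param n number of cases.
#' @param k number of folds, `2 <= k <= n`.
#' @param seed optional seed; if given, case order is shuffled first.
#' @return integer vector of fold ids (1..k) per case.
#' @export
cvFolds <- function(n, k, seed = NULL) {
  if (k > n) stop("more folds than cases")
  sizes <- n %/% k + as.integer(seq_len(k) <= n %% k)
  assign <- rep.int(seq_len(k), sizes)
  if (!is.null(seed))
    assign <- withr::with_seed(as.integer(seed),
                               assign[order(sample.int(n))])
  assign
}

#' k-fold cross-validation of U-Net training
#'
#' Trains one model per fold (training on the other folds, validating on
#' the held-out fold) and collects the per-epoch loss histories.
#'
#' @param cases list of cases.
#' @param k number of folds (defaults to `tcfg@cvFolds`).
#' @param ucfg a [UNetConfig-class].
#' @param tcfg a [TrainConfig-class].
#' @param verbose print progress.
#' @return list with `folds` (assignment vector), `histories` (one
#'   data.frame per fold), `valLoss` (final validation loss per fold) and
#'   `bestFold`.
#' @export
crossValidate <- function(cases, k = NULL, ucfg = unetConfig(),
                          tcfg = trainConfig(), verbose = FALSE) {
  if (is.null(k)) k <- tcfg@cvFolds
  n <- length(cases)
  assign <- cvFolds(n, k, seed = tcfg@seed)
  histories <- vector("list", k)
  valLoss <- numeric(k)
  for (f in seq_len(k)) {
    fit <- trainUNet(buildUNet(ucfg), cases[assign != f],
                     cases[assign == f], tcfg, verbose = verbose)
    histories[[f]] <- fit$history
    valLoss[f] <- min(fit$history$valLoss)
  }
  list(folds = assign, histories = histories, valLoss = valLoss,
       bestFold = which.min(valLoss))
}
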