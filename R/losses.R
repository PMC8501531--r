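## Sharp loss: a sigmoid-modulated MSE loss for dose-imbalanced volumetric
## regression. All dose arguments here live on the normalized [0, 1] scale
## (1.0 == cfg@doseNorm cGy); cGy appears only at I/O and reporting
## boundaries.

# numerically stable logistic: never exponentiates a positive argument, and
# clamped into the open unit interval so saturation at large |z| cannot
# collapse the factor to exactly 0 or 1 at double precision
.stableSigmoid <- function(z) {
  out <- numeric(length(z))
  pos <- z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  pmin(pmax(out, .Machine$double.xmin), 1 - 2^-48)
}

.checkPair <- function(pred, truth) {
  if (length(pred) == 0L) stop("empty volume: loss is undefined")
  dp <- dim(pred); dt <- dim(truth)
  if (!identical(as.integer(dp), as.integer(dt)) ||
      length(pred) != length(truth))
    stop("prediction and ground truth must share the same shape")
  if (any(!is.finite(pred)) || any(!is.finite(truth)))
    stop("non-finite dose values")
  invisible(TRUE)
}

#' Sigmoid modulating factor of the sharp loss
#'
#' The per-voxel weight applied to the squared error:
#' `1 / (1 + exp(-(d - shift) * gamma))`, a logistic function of the
#' ground-truth normalized dose `d`, shifted by `shift` (default 0.03) so
#' that zero-dose voxels sit on the suppressed shoulder. The factor is
#' strictly increasing in `d` for `gamma > 0`, bounded in (0, 1) for finite
#' `gamma`, and equals 0.5 exactly at `d = shift`.
#'
#' @param d ground-truth dose on the normalized \[0, 1\] scale; vector or
#'   array (the factor is applied voxelwise).
#' @param cfg a [LossConfig-class].
#' @return Weights in (0, 1), same shape as `d`.
#' @examples
#' modulatingFactor(0, lossConfig(gamma = 100))    # ~0.047
#' modulatingFactor(0.03, lossConfig(gamma = 7))   # exactly 0.5
#' @export
modulatingFactor <- function(d, cfg = lossConfig()) {
  stopifnot(is(cfg, "LossConfig"))
  validObject(cfg)
  if (any(!is.finite(d))) stop("non-finite dose values")
  w <- .stableSigmoid((d - cfg@shift) * cfg@gamma)
  if (!is.null(dim(d))) dim(w) <- dim(d)
  w
}

#' Mean-squared-error loss
#'
#' The per-voxel mean of squared prediction errors over the whole volume,
#' the conventional baseline objective for voxelwise dose regression.
#'
#' @param pred predicted normalized dose (array or vector). Predictions may
#'   leave \[0, 1\]; the loss does not clamp.
#' @param truth ground-truth normalized dose, same shape.
#' @return A non-negative scalar; 0 iff `pred == truth` elementwise.
#' @export
mseLoss <- function(pred, truth) {
  .checkPair(pred, truth)
  mean((pred - truth)^2)
}

#' Sharp loss: sigmoid-modulated MSE
#'
#' The mean over voxels of `w(truth_i) * (pred_i - truth_i)^2` with
#' `w` the [modulatingFactor()]. Low ground-truth-dose voxels (mostly
#' outside the body) receive weights near 0, so the optimization signal
#' concentrates on clinically relevant high-dose regions; above the
#' demarcation dose the loss is within `demarcationRatio` of the plain MSE.
#'
#' @inheritParams mseLoss
#' @param cfg a [LossConfig-class]; `gamma = 0` gives exactly half the MSE
#'   loss (the sigmoid is constant 1/2).
#' @return A non-negative scalar, strictly below [mseLoss()] whenever the
#'   MSE is positive and `gamma` is finite.
#' @export
sharpLoss <- function(pred, truth, cfg = lossConfig()) {
  .checkPair(pred, truth)
  w <- modulatingFactor(truth, cfg)
  mean(w * (pred - truth)^2)
}

#' Demarcation dose of the sharp loss
#'
#' The ground-truth dose `D0` (in cGy) at which the sharp loss reaches
#' `demarcationRatio` (default 0.99) of the MSE loss, i.e. the solution of
#' `modulatingFactor(d) = ratio` mapped back to cGy:
#' `doseNorm * (shift + log(ratio / (1 - ratio)) / gamma)`.
#' Voxels above `D0` are weighted essentially like plain MSE; below it the
#' weight decays towards 0. `D0` is strictly decreasing in `gamma`; as
#' `gamma` grows the demarcation point approaches `shift * doseNorm`
#' (180 cGy at the defaults).
#'
#' @param cfg a [LossConfig-class] with `gamma > 0` (at `gamma = 0` no
#'   finite demarcation point exists).
#' @return Dose in cGy.
#' @examples
#' demarcationDose(lossConfig(gamma = 100))  # 455.71 cGy
#' @export
demarcationDose <- function(cfg = lossConfig()) {
  stopifnot(is(cfg, "LossConfig"))
  validObject(cfg)
  if (cfg@gamma == 0)
    stop("gamma = 0: the modulating factor is constant 1/2, ",
         "no finite demarcation point exists")
  r <- cfg@demarcationRatio
  cfg@doseNorm * (cfg@shift + log(r / (1 - r)) / cfg@gamma)
}

#' Analytic gradient of the sharp loss
#'
#' The per-voxel derivative of [sharpLoss()] with respect to the prediction:
#' `(2 / n) * w(truth_i) * (pred_i - truth_i)`. Used as the top-of-network
#' error signal during training.
#'
#' @inheritParams sharpLoss
#' @return An array of the same shape as `pred`; zero exactly where
#'   `pred == truth`.
#' @export
sharpLossGradient <- function(pred, truth, cfg = lossConfig()) {
  .checkPair(pred, truth)
  w <- modulatingFactor(truth, cfg)
  g <- (2 / length(pred)) * w * (pred - truth)
  if (!is.null(dim(pred))) dim(g) <- dim(pred)
  g
}

#' Gradient of the MSE loss
#'
#' `(2 / n) * (pred_i - truth_i)`, the baseline error signal.
#'
#' @inheritParams mseLoss
#' @return An array of the same shape as `pred`.
#' @export
mseLossGradient <- function(pred, truth) {
  .checkPair(pred, truth)
  g <- (2 / length(pred)) * (pred - truth)
  if (!is.null(dim(pred))) dim(g) <- dim(pred)
  g
}

#' Resolve a loss by name
#'
#' Configuration files select the training objective by name; this maps the
#' name to a `(loss, gradient)` pair closed over a [LossConfig-class].
#'
#' @param name `"mse"` or `"sharp"`.
#' @param cfg a [LossConfig-class] (used by `"sharp"` only).
#' @return list with elements `name`, `loss(pred, truth)` and
#'   `gradient(pred, truth)`.
#' @export
lossByName <- function(name = c("mse", "sharp"), cfg = lossConfig()) {
  name <- match.arg(name)
  if (name == "mse") {
    list(name = "mse", loss = mseLoss, gradient = mseLossGradient)
  } else {
    list(name = "sharp",
         loss = function(pred, truth) sharpLoss(pred, truth, cfg),
         gradient = function(pred, truth) sharpLossGradient(pred, truth, cfg))
  }
}
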