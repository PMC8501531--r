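#' @import methods
NULL

#' Voxel array of a volume
#'
#' @param x a volume object.
#' @return The 3D array of voxel values.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' Voxel spacing of a volume
#'
#' @param x a volume object.
#' @return numeric(3), mm per axis.
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' Encode organ labels as scalar ROI codes
#'
#' @param lv a [LabelVolume-class].
#' @return An [EncodedVolume-class] with codes per [roiCodeTable()].
#' @export
setGeneric("encodeROI", function(lv) standardGeneric("encodeROI"))

#' Decode scalar ROI codes back to organ labels
#'
#' @param ev an [EncodedVolume-class] whose values come from [encodeROI()].
#' @return A [LabelVolume-class].
#' @export
setGeneric("decodeROI", function(ev) standardGeneric("decodeROI"))

#' Organ label codes used by the phantom and the ROI encoding
#'
#' Integer label ids (as stored in a [LabelVolume-class]) and the scalar ROI
#' codes the network consumes. The scalar codes follow the clinical encoding
#' convention for left-breast plans: PTV 1.000, ipsilateral lung 0.833,
#' heart 0.667, contralateral lung 0.500, spinal cord 0.333, other tissues
#' 0.167, outside the body 0.
#'
#' @return A data.frame with columns `label` (integer id), `organ`
#'   (character) and `code` (numeric ROI code).
#' @examples
#' roiCodeTable()
#' @export
roiCodeTable <- function() {
  data.frame(
    label = 0:6,
    organ = c("outside", "other_tissue", "spinal_cord", "contralateral_lung",
              "heart", "ipsilateral_lung", "ptv"),
    code  = c(0, 0.167, 0.333, 0.500, 0.667, 0.833, 1.000),
    stringsAsFactors = FALSE
  )
}

.validSpacing <- function(spacing) {
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    return("spacing must be 3 positive finite values (mm per axis)")
  TRUE
}

#' Virtual base class for volumetric data with voxel spacing
#'
#' Holds a 3D array of voxel values (axial slices on the first axis) plus the
#' voxel spacing in millimetres for each axis.
#'
#' @slot voxels 3D array of voxel values.
#' @slot spacing numeric(3), mm per axis.
#' @aliases VoxelVolume
#' @exportClass VoxelVolume
setClass("VoxelVolume", representation("VIRTUAL",
  voxels = "array", spacing = "numeric"))

setValidity("VoxelVolume", function(object) {
  msgs <- character()
  if (length(dim(object@voxels)) != 3L)
    msgs <- c(msgs, "voxels must be a 3D array")
  sp <- .validSpacing(object@spacing)
  if (!isTRUE(sp)) msgs <- c(msgs, sp)
  if (length(msgs)) msgs else TRUE
})

#' Per-voxel organ labels
#'
#' Integer organ labels per voxel, following the id scheme of
#' [roiCodeTable()]. Labels are mutually exclusive: each voxel carries
#' exactly one organ id.
#'
#' @aliases LabelVolume
#' @seealso [LabelVolume()], [encodeROI()]
#' @exportClass LabelVolume
setClass("LabelVolume", contains = "VoxelVolume")

setValidity("LabelVolume", function(object) {
  v <- object@voxels
  if (any(!is.finite(v)) || any(v != round(v)) || any(v < 0) || any(v > 6))
    return("labels must be integers in 0..6 (see roiCodeTable())")
  TRUE
})

#' Scalar ROI codes in [0, 1], the network input
#'
#' Each voxel holds the scalar code of its organ per [roiCodeTable()].
#'
#' @aliases EncodedVolume
#' @seealso [encodeROI()], [decodeROI()]
#' @exportClass EncodedVolume
setClass("EncodedVolume", contains = "VoxelVolume")

setValidity("EncodedVolume", function(object) {
  v <- object@voxels
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    return("encoded ROI values must lie in [0, 1]")
  TRUE
})

#' Per-voxel absorbed dose in centigray
#'
#' Dose is stored in cGy; normalization to the unit scale (division by the
#' loss configuration's `doseNorm`, 6000 cGy by default) happens only at the
#' loss/model boundary.
#'
#' @aliases DoseVolume
#' @seealso [DoseVolume()], [generateDose()]
#' @exportClass DoseVolume
setClass("DoseVolume", contains = "VoxelVolume")

setValidity("DoseVolume", function(object) {
  v <- object@voxels
  if (any(!is.finite(v))) return("dose values must be finite")
  if (any(v < 0)) return("dose values must be non-negative (cGy)")
  TRUE
})

#' Construct a LabelVolume
#'
#' @param labels 3D integer array of organ ids (0..6, see [roiCodeTable()]).
#' @param spacing numeric(3), voxel spacing in mm (axial, row, column).
#' @return A [LabelVolume-class] object.
#' @examples
#' lv <- LabelVolume(array(0L, c(4, 4, 4)), spacing = c(5, 2, 2))
#' @export
LabelVolume <- function(labels, spacing) {
  storage.mode(labels) <- "integer"
  new("LabelVolume", voxels = labels, spacing = as.numeric(spacing))
}

#' Construct an EncodedVolume
#'
#' @param codes 3D numeric array of ROI codes in \[0, 1\].
#' @param spacing numeric(3), voxel spacing in mm.
#' @return An [EncodedVolume-class] object.
#' @export
EncodedVolume <- function(codes, spacing) {
  new("EncodedVolume", voxels = codes, spacing = as.numeric(spacing))
}

#' Construct a DoseVolume
#'
#' @param dose 3D numeric array of doses in cGy.
#' @param spacing numeric(3), voxel spacing in mm.
#' @return A [DoseVolume-class] object.
#' @export
DoseVolume <- function(dose, spacing) {
  new("DoseVolume", voxels = dose, spacing = as.numeric(spacing))
}

#' @describeIn voxels Voxel array of a volume
#' @export
setMethod("voxels", "VoxelVolume", function(x) x@voxels)

#' @describeIn spacing Voxel spacing (mm) of a volume
#' @export
setMethod("spacing", "VoxelVolume", function(x) x@spacing)

#' @rdname voxels
#' @param x a [VoxelVolume-class]
#' @export
setMethod("dim", "VoxelVolume", function(x) dim(x@voxels))

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@voxels)
  cat(class(object), sprintf("%d x %d x %d voxels, spacing %s mm\n",
      d[1], d[2], d[3], paste(format(object@spacing, digits = 3),
                              collapse = " x ")))
  v <- object@voxels
  cat(sprintf("  range [%g, %g]\n", min(v), max(v)))
  invisible(object)
})

#' Sharp-loss configuration
#'
#' Parameters of the sigmoid-modulated MSE ("sharp") loss: the sigmoid
#' steepness `gamma`, the positive shift of the sigmoid along the normalized
#' dose axis (`shift`, default 0.03), the dose normalization constant
#' (`doseNorm`, default 6000 cGy: a normalized value of 1 corresponds to
#' 6000 cGy), and the demarcation ratio at which the sharp loss is declared
#' to have caught up with the MSE loss (default 0.99).
#'
#' @slot gamma dimensionless sigmoid steepness, `>= 0`.
#' @slot shift sigmoid shift on the normalized dose scale.
#' @slot doseNorm normalization constant in cGy.
#' @slot demarcationRatio ratio in (0, 1) defining the demarcation dose.
#' @aliases LossConfig
#' @seealso [lossConfig()], [sharpLoss()], [demarcationDose()]
#' @exportClass LossConfig
setClass("LossConfig", representation(
  gamma = "numeric", shift = "numeric",
  doseNorm = "numeric", demarcationRatio = "numeric"))

setValidity("LossConfig", function(object) {
  msgs <- character()
  if (length(object@gamma) != 1L || !is.finite(object@gamma) ||
      object@gamma < 0)
    msgs <- c(msgs, "gamma must be a single finite value >= 0")
  if (length(object@shift) != 1L || !is.finite(object@shift))
    msgs <- c(msgs, "shift must be a single finite value")
  if (length(object@doseNorm) != 1L || !is.finite(object@doseNorm) ||
      object@doseNorm <= 0)
    msgs <- c(msgs, "doseNorm must be a single positive value (cGy)")
  r <- object@demarcationRatio
  if (length(r) != 1L || !is.finite(r) || r <= 0 || r >= 1)
    msgs <- c(msgs, "demarcationRatio must lie strictly in (0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' Create a sharp-loss configuration
#'
#' @param gamma sigmoid steepness (dimensionless, `>= 0`); 100 is the
#'   recommended operating point.
#' @param shift sigmoid shift on the normalized dose scale (default 0.03,
#'   i.e. 180 cGy at the default normalization).
#' @param doseNorm dose normalization constant in cGy (default 6000).
#' @param demarcationRatio the sharp/MSE ratio defining the demarcation dose
#'   (default 0.99).
#' @return A validated [LossConfig-class].
#' @examples
#' cfg <- lossConfig(gamma = 100)
#' demarcationDose(cfg)  # 455.71 cGy
#' @export
lossConfig <- function(gamma = 100, shift = 0.03, doseNorm = 6000,
                       demarcationRatio = 0.99) {
  new("LossConfig", gamma = as.numeric(gamma), shift = as.numeric(shift),
      doseNorm = as.numeric(doseNorm),
      demarcationRatio = as.numeric(demarcationRatio))
}

setMethod("show", "LossConfig", function(object) {
  cat(sprintf(
    "LossConfig: gamma = %g, shift = %g, doseNorm = %g cGy, ratio = %g\n",
    object@gamma, object@shift, object@doseNorm, object@demarcationRatio))
  invisible(object)
})
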