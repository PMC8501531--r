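## Synthetic left-thorax phantom: anatomy labels and tangential-beam dose.
## The generator emulates the statistical structure of clinical left-breast
## VMAT plans -- in particular the dose imbalance (about 74.5% of voxels
## outside the body at zero dose, about 77.3% of in-body voxels below
## 500 cGy) -- with a deliberately simple analytic beam model, not a
## transport simulation.

#' Phantom generator configuration
#'
#' Geometry and physics knobs for the synthetic left-thorax phantom.
#' Axes are (axial slice, anterior-to-posterior, patient-right-to-left).
#'
#' @slot grid integer(3) voxel extents (slices, rows, columns).
#' @slot spacing numeric(3) mm per axis; default 5 mm slices and an
#'   in-plane spacing giving a 500 mm field of view.
#' @slot prescription prescribed dose in cGy (default 5000).
#' @slot coverageQuantile PTV volume fraction the prescription must cover
#'   (default 0.95: the dose is scaled so D95 equals the prescription).
#' @slot attenuationMu effective depth-attenuation coefficient, 1/mm.
#' @slot penumbraSigmaMm Gaussian beam-edge blur, mm.
#' @slot apertureMarginMm field margin around the PTV projection, mm.
#' @slot jitterFrac relative size/position jitter of anatomy per seed.
#' @slot bodyAspect anterior-posterior over left-right body semi-axis ratio.
#' @slot noiseSd relative amplitude of the smooth dose heterogeneity field.
#' @slot targetOutsideFraction voxel fraction outside the body the anatomy
#'   is solved for (default 0.7452).
#' @slot targetLowDoseFraction nominal in-body fraction below 500 cGy the
#'   default beam geometry was calibrated to (default 0.7730).
#' @aliases PhantomConfig
#' @seealso [phantomConfig()], [generateAnatomy()], [generateDose()]
#' @exportClass PhantomConfig
setClass("PhantomConfig", representation(
  grid = "integer", spacing = "numeric", prescription = "numeric",
  coverageQuantile = "numeric", attenuationMu = "numeric",
  penumbraSigmaMm = "numeric", apertureMarginMm = "numeric",
  jitterFrac = "numeric", bodyAspect = "numeric", noiseSd = "numeric",
  targetOutsideFraction = "numeric", targetLowDoseFraction = "numeric"))

setValidity("PhantomConfig", function(object) {
  msgs <- character()
  if (length(object@grid) != 3L || any(object@grid < 8L))
    msgs <- c(msgs, "grid must have 3 extents, each >= 8")
  sp <- .validSpacing(object@spacing)
  if (!isTRUE(sp)) msgs <- c(msgs, sp)
  if (object@prescription <= 0)
    msgs <- c(msgs, "prescription must be positive (cGy)")
  q <- object@coverageQuantile
  if (q <= 0 || q >= 1)
    msgs <- c(msgs, "coverageQuantile must lie in (0, 1)")
  f <- object@targetOutsideFraction
  if (f <= 0 || f >= 1)
    msgs <- c(msgs, "targetOutsideFraction must lie in (0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' Create a phantom configuration
#'
#' @param grid voxel extents (slices, rows, columns); the desk-scale default
#'   is 32 x 96 x 96, `fullScale = TRUE` selects 64 x 256 x 256.
#' @param spacing mm per axis; by default 5 mm slices and a 500 mm in-plane
#'   field of view divided by the grid.
#' @param prescription,coverageQuantile dose scaling: the generated dose is
#'   scaled so the PTV dose at `coverageQuantile` coverage equals
#'   `prescription` (D95 = 5000 cGy at the defaults).
#' @param attenuationMu,penumbraSigmaMm,apertureMarginMm beam physics:
#'   exponential depth falloff, Gaussian field-edge blur and field margin.
#' @param jitterFrac,bodyAspect,noiseSd anatomy jitter, body ellipse aspect
#'   ratio, and relative amplitude of the smooth dose heterogeneity.
#' @param targetOutsideFraction,targetLowDoseFraction imbalance targets the
#'   geometry is solved/calibrated for (0.7452 and 0.7730 by default).
#' @param fullScale logical; use the full 64 x 256 x 256 grid.
#' @return A validated [PhantomConfig-class].
#' @examples
#' cfg <- phantomConfig(grid = c(16, 32, 32))  # tiny grid for quick runs
#' @export
phantomConfig <- function(grid = c(32L, 96L, 96L), spacing = NULL,
                          prescription = 5000, coverageQuantile = 0.95,
                          attenuationMu = 0.005, penumbraSigmaMm = 6,
                          apertureMarginMm = 5, jitterFrac = 0.05,
                          bodyAspect = 0.55, noiseSd = 0.03,
                          targetOutsideFraction = 0.7452,
                          targetLowDoseFraction = 0.7730,
                          fullScale = FALSE) {
  if (fullScale) grid <- c(64L, 256L, 256L)
  grid <- as.integer(grid)
  if (is.null(spacing)) spacing <- c(5, 500 / grid[2], 500 / grid[3])
  new("PhantomConfig", grid = grid, spacing = as.numeric(spacing),
      prescription = as.numeric(prescription),
      coverageQuantile = as.numeric(coverageQuantile),
      attenuationMu = as.numeric(attenuationMu),
      penumbraSigmaMm = as.numeric(penumbraSigmaMm),
      apertureMarginMm = as.numeric(apertureMarginMm),
      jitterFrac = as.numeric(jitterFrac),
      bodyAspect = as.numeric(bodyAspect), noiseSd = as.numeric(noiseSd),
      targetOutsideFraction = as.numeric(targetOutsideFraction),
      targetLowDoseFraction = as.numeric(targetLowDoseFraction))
}

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf(
    "PhantomConfig: %s voxels, %s mm, Rx %g cGy to D%g\n",
    paste(object@grid, collapse = " x "),
    paste(format(object@spacing, digits = 3), collapse = " x "),
    object@prescription, 100 * object@coverageQuantile))
  invisible(object)
})

# coordinate grids (voxel-center indices) for a (nz, ny, nx) array
.coordGrids <- function(grid) {
  nz <- grid[1]; ny <- grid[2]; nx <- grid[3]
  list(
    z = array(rep(seq_len(nz), times = ny * nx), dim = grid),
    y = array(rep(rep(seq_len(ny), each = nz), times = nx), dim = grid),
    x = array(rep(seq_len(nx), each = nz * ny), dim = grid))
}

.ellipsoidMask <- function(g, c0, semi) {
  ((g$x - c0[1]) / semi[1])^2 + ((g$y - c0[2]) / semi[2])^2 +
    ((g$z - c0[3]) / semi[3])^2 <= 1
}

#' Generate a synthetic left-thorax anatomy
#'
#' Builds a labelled thorax: an elliptical body cylinder (its in-plane
#' semi-axes are solved analytically so the outside-body voxel fraction
#' matches `targetOutsideFraction`), two lung ellipsoids, a heart ellipsoid
#' left of the midline, a posterior spinal-cord cylinder, and a half-
#' ellipsoid PTV on the left anterior chest wall clipped to the body.
#' Organs never overlap (assignment precedence, PTV restricted to soft
#' tissue) and the PTV lies strictly inside the axial extent. Sizes and
#' positions are jittered per seed; a fixed seed gives identical output.
#'
#' @param cfg a [PhantomConfig-class].
#' @param seed integer seed; the generator is deterministic given
#'   `(cfg, seed)`.
#' @return A [LabelVolume-class].
#' @export
generateAnatomy <- function(cfg = phantomConfig(), seed = 1L) {
  stopifnot(is(cfg, "PhantomConfig"))
  validObject(cfg)
  withr::with_seed(as.integer(seed), .generateAnatomyImpl(cfg))
}

.generateAnatomyImpl <- function(cfg) {
  grid <- cfg@grid
  nz <- grid[1]; ny <- grid[2]; nx <- grid[3]
  j <- cfg@jitterFrac
  jit <- function(scale = 1) 1 + scale * stats::runif(1, -j, j)

  aspect <- cfg@bodyAspect * jit(0.6)
  # solve the body ellipse area for the outside-voxel target
  fOut <- cfg@targetOutsideFraction + stats::runif(1, -0.01, 0.01)
  ax <- sqrt((1 - fOut) * nx * ny / (pi * aspect))
  ay <- ax * aspect
  cx <- nx / 2 + stats::runif(1, -0.02, 0.02) * nx
  cy <- ny / 2 + stats::runif(1, -0.02, 0.02) * ny

  g <- .coordGrids(grid)
  body <- ((g$x - cx) / ax)^2 + ((g$y - cy) / ay)^2 <= 1

  labels <- array(0L, dim = grid)
  labels[body] <- 1L  # other tissue

  tbl <- roiCodeTable()
  id <- function(organ) tbl$label[tbl$organ == organ]

  # posterior midline spinal cord, full axial extent
  cordR <- max(1.2, 0.05 * ax) * jit(0.5)
  cord <- ((g$x - cx)^2 + (g$y - (cy + 0.72 * ay))^2) <= cordR^2
  labels[cord & body] <- id("spinal_cord")

  # lungs: contralateral (patient right, low x), ipsilateral (left)
  contra <- .ellipsoidMask(g,
    c(cx - 0.45 * ax * jit(0.3), cy + 0.08 * ay * jit(), nz / 2),
    c(0.30 * ax * jit(), 0.55 * ay * jit(), 0.42 * nz * jit()))
  labels[contra & body & labels == 1L] <- id("contralateral_lung")
  ipsi <- .ellipsoidMask(g,
    c(cx + 0.46 * ax * jit(0.3), cy + 0.10 * ay * jit(), nz / 2),
    c(0.27 * ax * jit(), 0.50 * ay * jit(), 0.42 * nz * jit()))
  labels[ipsi & body & labels == 1L] <- id("ipsilateral_lung")

  # heart: anterior, left of midline, mid-to-caudal slices
  heart <- .ellipsoidMask(g,
    c(cx + 0.13 * ax * jit(), cy - 0.12 * ay * jit(), 0.45 * nz * jit(0.4)),
    c(0.22 * ax * jit(), 0.30 * ay * jit(), 0.24 * nz * jit()))
  labels[heart & body & labels == 1L] <- id("heart")

  # PTV: half-ellipsoid on the left anterior surface, clipped to soft tissue
  theta <- (40 + stats::runif(1, -6, 6)) * pi / 180
  pc <- c(cx + 0.80 * ax * sin(theta), cy - 0.80 * ay * cos(theta),
          nz / 2 * (1 + stats::runif(1, -0.05, 0.05)))
  psemi <- c(0.34 * ax * jit(), 0.34 * ay * jit(), 0.30 * nz * jit())
  ptv <- .ellipsoidMask(g, pc, psemi)
  labels[ptv & labels == 1L] <- id("ptv")

  if (!any(labels == id("ptv")))
    stop("grid too small to place all organs: the PTV is empty")
  for (org in c("spinal_cord", "contralateral_lung", "heart",
                "ipsilateral_lung"))
    if (!any(labels == id(org)))
      stop("grid too small to place all organs: ", org, " is empty")

  LabelVolume(labels, cfg@spacing)
}

#' @describeIn encodeROI Map organ labels to scalar ROI codes
#' @export
setMethod("encodeROI", "LabelVolume", function(lv) {
  tbl <- roiCodeTable()
  v <- lv@voxels
  if (any(!(v %in% tbl$label))) stop("unknown label id in volume")
  codes <- tbl$code[match(v, tbl$label)]
  dim(codes) <- dim(v)
  EncodedVolume(codes, lv@spacing)
})

#' @describeIn decodeROI Map scalar ROI codes back to organ labels
#' @export
setMethod("decodeROI", "EncodedVolume", function(ev) {
  tbl <- roiCodeTable()
  v <- ev@voxels
  idx <- apply(abs(outer(as.vector(v), tbl$code, "-")), 1, which.min)
  if (any(abs(as.vector(v) - tbl$code[idx]) > 1e-6))
    stop("encoded values do not match any ROI code")
  labels <- tbl$label[idx]
  dim(labels) <- dim(v)
  LabelVolume(labels, ev@spacing)
})

# separable Gaussian smoothing of a 3D array (zero padding at edges)
.gaussSmooth3d <- function(arr, sigmaVox) {
  d <- dim(arr)
  for (axis in 1:3) {
    s <- sigmaVox[min(axis, length(sigmaVox))]
    if (s <= 0) next
    r <- max(1L, ceiling(2 * s))
    k <- stats::dnorm(-r:r, sd = s)
    k <- k / sum(k)
    out <- array(0, d)
    for (j in -r:r) {
      w <- k[j + r + 1]
      n <- d[axis]
      src <- seq_len(n) - j
      ok <- src >= 1 & src <= n
      if (!any(ok)) next
      dst <- which(ok)
      if (axis == 1) out[dst, , ] <- out[dst, , ] + w * arr[src[ok], , ]
      else if (axis == 2) out[, dst, ] <- out[, dst, ] + w * arr[, src[ok], ]
      else out[, , dst] <- out[, , dst] + w * arr[, , src[ok]]
    }
    arr <- out
  }
  arr
}

# per-voxel radiological depth to the body entry point along -u (mm)
.beamDepth <- function(body, grid, spacing, posMm, u, stepMm) {
  nz <- grid[1]; ny <- grid[2]; nx <- grid[3]
  maxPath <- sqrt(sum((grid * spacing)^2))
  nSteps <- ceiling(maxPath / stepMm)
  depth <- numeric(nrow(posMm))
  for (k in seq_len(nSteps)) {
    px <- posMm[, 1] - k * stepMm * u[1]
    py <- posMm[, 2] - k * stepMm * u[2]
    ix <- floor(px / spacing[3]) + 1L
    iy <- floor(py / spacing[2]) + 1L
    inGrid <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
    if (!any(inGrid)) break
    ixc <- pmin(pmax(ix, 1L), nx); iyc <- pmin(pmax(iy, 1L), ny)
    idx <- posMm[, 4] + nz * (iyc - 1L) + nz * ny * (ixc - 1L)
    hit <- inGrid & body[idx]
    depth[hit] <- depth[hit] + stepMm
  }
  depth
}

#' Generate a tangential-beam dose distribution for an anatomy
#'
#' Computes an analytic two-field tangential dose: two opposed beams whose
#' common axis runs tangent to the left chest wall through the PTV centroid,
#' each with exponential depth attenuation from its body entry point and
#' Gaussian penumbra at the field edges. The summed dose is modulated by a
#' smooth heterogeneity field, lightly smoothed, masked to zero outside the
#' body, and scaled so the PTV dose at `coverageQuantile` coverage equals
#' the prescription (D95 = 5000 cGy at the defaults), then capped at 1.2
#' times the prescription.
#'
#' @param lv a [LabelVolume-class] from [generateAnatomy()].
#' @param cfg the [PhantomConfig-class] used for the anatomy.
#' @param seed integer seed (beam-angle jitter and heterogeneity noise).
#' @return A [DoseVolume-class] in cGy; exactly zero outside the body.
#' @export
generateDose <- function(lv, cfg = phantomConfig(), seed = 1L) {
  stopifnot(is(lv, "LabelVolume"), is(cfg, "PhantomConfig"))
  withr::with_seed(as.integer(seed) + 104729L, .generateDoseImpl(lv, cfg))
}

.generateDoseImpl <- function(lv, cfg) {
  grid <- dim(lv@voxels)
  sp <- lv@spacing
  nz <- grid[1]; ny <- grid[2]; nx <- grid[3]
  labels <- lv@voxels
  body <- labels > 0L
  tbl <- roiCodeTable()
  ptv <- labels == tbl$label[tbl$organ == "ptv"]
  if (!any(ptv)) stop("empty PTV: cannot scale the dose")

  g <- .coordGrids(grid)
  xmm <- (g$x - 0.5) * sp[3]
  ymm <- (g$y - 0.5) * sp[2]
  zmm <- (g$z - 0.5) * sp[1]

  pc <- c(mean(xmm[ptv]), mean(ymm[ptv]), mean(zmm[ptv]))

  # beam axis: tangent to the left anterior chest at the PTV, +-5 deg jitter
  phi <- (50 + stats::runif(1, -5, 5)) * pi / 180
  u <- c(cos(phi), sin(phi))           # in-plane (x, y) direction
  w <- c(-u[2], u[1])                  # in-plane perpendicular

  tCo <- (xmm - pc[1]) * w[1] + (ymm - pc[2]) * w[2]
  tRange <- range(tCo[ptv])
  zRange <- range(zmm[ptv]) - pc[3]
  m <- cfg@apertureMarginMm
  s <- cfg@penumbraSigmaMm
  prof <- (stats::pnorm((tRange[2] + m - tCo) / s) -
           stats::pnorm((tRange[1] - m - tCo) / s)) *
          (stats::pnorm((zRange[2] + m - (zmm - pc[3])) / s) -
           stats::pnorm((zRange[1] - m - (zmm - pc[3])) / s))

  cand <- which(prof > 1e-3 & body)
  dose <- array(0, grid)
  if (length(cand)) {
    posMm <- cbind(xmm[cand], ymm[cand], zmm[cand], g$z[cand])
    stepMm <- min(sp) / 2
    for (sgn in c(1, -1)) {
      depth <- .beamDepth(body, grid, sp, posMm, sgn * u, stepMm)
      dose[cand] <- dose[cand] + prof[cand] * exp(-cfg@attenuationMu * depth)
    }
  }

  if (cfg@noiseSd > 0) {
    het <- .gaussSmooth3d(array(stats::rnorm(prod(grid)), grid),
                          sigmaVox = c(1.5, 3, 3))
    het <- het / max(stats::sd(het), 1e-12)
    dose <- dose * (1 + cfg@noiseSd * het)
  }
  dose <- .gaussSmooth3d(dose, sigmaVox = c(0.6, 0.8, 0.8))
  dose[!body] <- 0
  dose[dose < 0] <- 0

  q <- stats::quantile(dose[ptv], probs = 1 - cfg@coverageQuantile,
                       type = 7, names = FALSE)
  if (q <= 0) stop("degenerate PTV dose: cannot scale to prescription")
  dose <- dose * (cfg@prescription / q)
  dose[dose > 1.2 * cfg@prescription] <- 1.2 * cfg@prescription
  DoseVolume(dose, sp)
}

#' Generate a full phantom case (anatomy, ROI encoding and dose)
#'
#' @inheritParams generateDose
#' @param cfg a [PhantomConfig-class].
#' @param seed integer seed.
#' @param id case identifier string.
#' @return list with `id`, `labels` ([LabelVolume-class]), `encoded`
#'   ([EncodedVolume-class]), `dose` ([DoseVolume-class], cGy) and
#'   `doseNorm` (3D array, dose divided by 6000 cGy).
#' @export
generatePhantom <- function(cfg = phantomConfig(), seed = 1L,
                            id = sprintf("case_%04d", seed)) {
  lv <- generateAnatomy(cfg, seed)
  dv <- generateDose(lv, cfg, seed)
  list(id = id, labels = lv, encoded = encodeROI(lv), dose = dv,
       doseNorm = dv@voxels / 6000)
}

#' Generate a paired phantom dataset
#'
#' Produces `nCases` independent phantoms (distinct seeded anatomies and
#' doses) as pairs of network input (encoded ROI volume) and target
#' (dose normalized by `doseNorm` cGy), reproducibly from `(cfg, seed)`.
#'
#' @param cfg a [PhantomConfig-class].
#' @param nCases number of cases, `>= 1`.
#' @param seed integer base seed; case `i` uses a seed derived from it.
#' @param doseNorm normalization constant in cGy (default 6000).
#' @return list of cases as in [generatePhantom()]; `doseNorm` entries lie
#'   in \[0, 1\].
#' @export
generateDataset <- function(cfg = phantomConfig(), nCases = 10L, seed = 1L,
                            doseNorm = 6000) {
  stopifnot(nCases >= 1)
  lapply(seq_len(nCases), function(i) {
    si <- (as.integer(seed) + 7919L * i) %% 2147483647L
    ph <- generatePhantom(cfg, seed = si, id = sprintf("case_%03d", i))
    ph$doseNorm <- ph$dose@voxels / doseNorm
    ph
  })
}

#' Dose-imbalance statistics of a phantom or clinical case
#'
#' Reports the voxel fraction outside the body, the fraction of in-body
#' voxels below 500 cGy, and the in-body dose-band occupancy. These are the
#' quantities that drive the dose-imbalance problem the sharp loss targets.
#'
#' @param lv a [LabelVolume-class].
#' @param dose a [DoseVolume-class] of identical shape.
#' @param breaks in-body dose band boundaries in cGy (half-open
#'   `[low, high)` intervals).
#' @param lowDoseCGy threshold for the low-dose fraction (default 500 cGy).
#' @return list with `outsideFraction`, `inBodyLowDoseFraction`,
#'   `perBandFractions` (named, sums to 1 over in-body voxels) and
#'   `defined` (FALSE when there are no in-body voxels, in which case the
#'   in-body statistics are NA).
#' @export
imbalanceStats <- function(lv, dose,
                           breaks = c(0, 500, 1000, 2000, 3000, 4000, 5000,
                                      Inf),
                           lowDoseCGy = 500) {
  stopifnot(is(lv, "LabelVolume"), is(dose, "DoseVolume"))
  if (!identical(dim(lv@voxels), dim(dose@voxels)))
    stop("label and dose volumes must share the same shape")
  inBody <- lv@voxels > 0L
  outsideFraction <- 1 - mean(inBody)
  if (!any(inBody)) {
    bands <- rep(NA_real_, length(breaks) - 1)
    names(bands) <- .bandNames(breaks)
    return(list(outsideFraction = outsideFraction,
                inBodyLowDoseFraction = NA_real_,
                perBandFractions = bands, defined = FALSE))
  }
  d <- dose@voxels[inBody]
  counts <- .bandCounts(d, breaks)
  list(outsideFraction = outsideFraction,
       inBodyLowDoseFraction = mean(d < lowDoseCGy),
       perBandFractions = counts / length(d),
       defined = TRUE)
}

.bandNames <- function(breaks) {
  lo <- breaks[-length(breaks)]; hi <- breaks[-1]
  ifelse(is.infinite(hi), sprintf(">%g", lo), sprintf("%g-%g", lo, hi))
}

# half-open [low, high) band occupancy
.bandCounts <- function(d, breaks) {
  idx <- findInterval(d, breaks, left.open = FALSE, rightmost.closed = FALSE)
  idx[idx < 1] <- 1L
  idx[idx > length(breaks) - 1] <- length(breaks) - 1L
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  names(counts) <- .bandNames(breaks)
  counts
}
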