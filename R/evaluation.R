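## Quantitative evaluation of predicted dose distributions: mean absolute
## difference (MAD) globally, by ground-truth dose band and by organ; error
## standard deviation inside the body; mean dose gradients; DVH curves and
## clinical DVH metrics (D_x, V_x, mean dose, homogeneity and conformity
## indices); and the paired Wilcoxon signed-rank comparison.

.asArray <- function(x) if (is(x, "VoxelVolume")) x@voxels else x

#' Mean absolute difference between two dose volumes
#'
#' `MAD = mean(|pred_i - truth_i|)` over the masked voxels. The metric is
#' symmetric in its two arguments.
#'
#' @param pred,truth [DoseVolume-class] objects or arrays (cGy), same shape.
#' @param mask optional logical array restricting the evaluated region.
#' @return MAD in cGy; `NA` (with a warning) for an empty mask.
#' @export
madError <- function(pred, truth, mask = NULL) {
  p <- .asArray(pred); t <- .asArray(truth)
  if (!identical(dim(p), dim(t)))
    stop("prediction and ground truth must share the same shape")
  if (is.null(mask)) mask <- rep(TRUE, length(p))
  if (!sum(mask)) {
    warning("empty mask: MAD is undefined")
    return(NA_real_)
  }
  mean(abs(p[mask] - t[mask]))
}

#' Mean Euclidean-norm dose gradient over a region
#'
#' Central differences per axis (one-sided at the volume boundary), each
#' divided by the axis spacing in mm; the per-voxel gradient magnitude is
#' averaged over the masked voxels.
#'
#' @param dose a [DoseVolume-class] (its spacing is used) or an array with
#'   `spacing` supplied.
#' @param mask optional logical array.
#' @param spacing mm per axis (taken from `dose` when it is a volume).
#' @return Mean gradient magnitude in cGy/mm; `NA` with a warning for an
#'   empty mask.
#' @export
doseGradientMean <- function(dose, mask = NULL, spacing = NULL) {
  d <- .asArray(dose)
  if (is.null(spacing)) {
    if (!is(dose, "VoxelVolume"))
      stop("spacing must be supplied for array input")
    spacing <- dose@spacing
  }
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (is.null(mask)) mask <- array(TRUE, dim(d))
  if (!sum(mask)) {
    warning("empty mask: gradient is undefined")
    return(NA_real_)
  }
  gsq <- array(0, dim(d))
  for (axis in 1:3) {
    n <- dim(d)[axis]
    g <- array(0, dim(d))
    if (n > 1) {
      idx <- function(i) switch(axis,
        d[i, , , drop = FALSE], d[, i, , drop = FALSE],
        d[, , i, drop = FALSE])
      asn <- function(i, val) switch(axis,
        g[i, , ] <<- val, g[, i, ] <<- val, g[, , i] <<- val)
      if (n > 2)
        asn(2:(n - 1), (idx(3:n) - idx(1:(n - 2))) / (2 * spacing[axis]))
      asn(1, (idx(2) - idx(1)) / spacing[axis])
      asn(n, (idx(n) - idx(n - 1)) / spacing[axis])
    }
    gsq <- gsq + g^2
  }
  mean(sqrt(gsq)[mask])
}

#' Per-dose-band MAD report with in-body error standard deviation
#'
#' Reproduces the standard banded error report: MAD over the whole region,
#' outside the body, inside the body, and within half-open ground-truth
#' dose bands `[low, high)` partitioning the in-body region; plus the mean
#' ground-truth dose gradient of each band and the standard deviation of
#' the signed prediction error inside the body. Bands are defined on the
#' ground-truth dose.
#'
#' @param pred,truth [DoseVolume-class] objects or arrays in cGy.
#' @param lv a [LabelVolume-class] giving the body (label > 0).
#' @param breaks band boundaries in cGy.
#' @return list with `table` (data.frame: region, nVoxels, mad,
#'   meanGradient) and `insideStd` (cGy). Empty bands have `NA` MAD.
#' @export
bandReport <- function(pred, truth, lv,
                       breaks = c(0, 500, 1000, 2000, 3000, 4000, 5000,
                                  Inf)) {
  p <- .asArray(pred); t <- .asArray(truth)
  if (!identical(dim(p), dim(t)) || !identical(dim(p), dim(lv@voxels)))
    stop("pred, truth and labels must share the same shape")
  sp <- lv@spacing
  inBody <- lv@voxels > 0L
  regions <- list(whole = array(TRUE, dim(p)), outside = !inBody,
                  inside = inBody)
  lo <- breaks[-length(breaks)]; hi <- breaks[-1]
  for (i in seq_along(lo))
    regions[[.bandNames(breaks)[i]]] <- inBody & t >= lo[i] & t < hi[i]
  rows <- lapply(names(regions), function(nm) {
    m <- regions[[nm]]
    nv <- sum(m)
    data.frame(region = nm, nVoxels = nv,
               mad = if (nv) mean(abs(p[m] - t[m])) else NA_real_,
               meanGradient = if (nv)
                 doseGradientMean(DoseVolume(t, sp), m) else NA_real_)
  })
  tab <- do.call(rbind, rows)
  insideStd <- if (any(inBody)) stats::sd(p[inBody] - t[inBody])
               else NA_real_
  list(table = tab, insideStd = insideStd)
}

#' Cumulative dose-volume histogram
#'
#' For each dose level, the fraction of the masked volume receiving at
#' least that dose. The curve is monotone non-increasing, equals 1 at
#' level 0 and 0 above the masked maximum.
#'
#' @param dose a [DoseVolume-class] or array in cGy.
#' @param mask logical array selecting the structure; must be non-empty.
#' @param binWidth dose-level step in cGy.
#' @return data.frame with `dose` (cGy) and `fraction`.
#' @export
dvh <- function(dose, mask, binWidth = 10) {
  d <- .asArray(dose)[mask]
  if (!length(d)) stop("empty mask: DVH is undefined")
  levels <- seq(0, max(d) + binWidth, by = binWidth)
  frac <- vapply(levels, function(lv) mean(d >= lv), numeric(1))
  data.frame(dose = levels, fraction = frac)
}

.dx <- function(d, x) {
  if (any(x <= 0 | x > 100)) stop("D_x requires x in (0, 100]")
  stats::quantile(d, probs = 1 - x / 100, type = 7, names = FALSE)
}

#' Clinical DVH metrics for a structure
#'
#' `D_x`: the dose level covered by at least x% of the structure volume
#' (linear-interpolated percentile of the voxel doses); `V_x`: the percent
#' of the structure receiving at least x cGy; and the mean dose.
#'
#' @param dose a [DoseVolume-class] or array in cGy.
#' @param mask logical array selecting the structure; non-empty.
#' @param dPercents percents for `D_x` (e.g. 95 for D95).
#' @param vLevels dose levels in cGy for `V_x` (e.g. 3000 for V30).
#' @return list with `D` (named, cGy), `V` (named, percent) and `mean`
#'   (cGy).
#' @export
dvhMetrics <- function(dose, mask, dPercents = c(95), vLevels = c(3000)) {
  d <- .asArray(dose)[mask]
  if (!length(d)) stop("empty mask: DVH metrics are undefined")
  D <- vapply(dPercents, function(x) .dx(d, x), numeric(1))
  if (length(D)) names(D) <- paste0("D", dPercents)
  V <- vapply(vLevels, function(lv) 100 * mean(d >= lv), numeric(1))
  if (length(V)) names(V) <- paste0("V", vLevels)
  list(D = D, V = V, mean = mean(d))
}

#' Homogeneity index of the target dose
#'
#' `HI = (D1 - D99) / prescription`: the spread between the near-maximum
#' and near-minimum target dose relative to the prescription; 0 for a
#' perfectly uniform target dose.
#'
#' @param dose a [DoseVolume-class] or array in cGy.
#' @param ptvMask logical array selecting the PTV; non-empty.
#' @param prescription prescription dose in cGy (default 5000).
#' @return Dimensionless HI `>= 0`.
#' @export
homogeneityIndex <- function(dose, ptvMask, prescription = 5000) {
  d <- .asArray(dose)[ptvMask]
  if (!length(d)) stop("empty PTV: HI is undefined")
  (.dx(d, 1) - .dx(d, 99)) / prescription
}

#' Conformity index of the prescription isodose
#'
#' `CI = |PTV n V_level|^2 / (|PTV| * |V_level|)` where `V_level` is the
#' set of voxels receiving at least `level` cGy; 1 iff the isodose volume
#' coincides exactly with the PTV, 0 when they are disjoint.
#'
#' @param dose a [DoseVolume-class] or array in cGy.
#' @param ptvMask logical array selecting the PTV; non-empty.
#' @param level isodose level in cGy (default the 5000 cGy prescription).
#' @return CI in \[0, 1\]; 0 with a warning when no voxel reaches `level`.
#' @export
conformityIndex <- function(dose, ptvMask, level = 5000) {
  d <- .asArray(dose)
  if (!sum(ptvMask)) stop("empty PTV: CI is undefined")
  vLevel <- d >= level
  nLevel <- sum(vLevel)
  if (!nLevel) {
    warning("no voxel reaches the isodose level: CI = 0")
    return(0)
  }
  sum(ptvMask & vLevel)^2 / (sum(ptvMask) * nLevel)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test of paired samples. Zero differences are dropped, tied
#' absolute differences receive mid-ranks, the null distribution of the
#' positive-rank sum is enumerated exactly over all sign assignments for
#' `n <= exactMax`, and a normal approximation with continuity and tie
#' correction is used above.
#'
#' @param a,b paired numeric vectors of equal length.
#' @param exactMax largest n for the exact enumeration null (default 15).
#' @return list with `statistic` (positive-rank sum `V`), `p` (two-sided),
#'   `n` (non-zero pairs), `exact` and `degenerate` (TRUE with `p = NA`
#'   when every difference is zero).
#' @export
wilcoxonSignedRank <- function(a, b, exactMax = 15L) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (!n) {
    warning("all paired differences are zero: test is undefined")
    return(list(statistic = NA_real_, p = NA_real_, n = 0L, exact = NA,
                degenerate = TRUE))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exactMax) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    sums <- as.vector(signs %*% r)
    pGE <- mean(sums >= V - 1e-9)
    pLE <- mean(sums <= V + 1e-9)
    p <- min(1, 2 * min(pGE, pLE))
    exact <- TRUE
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2)) / 2
    cc <- sign(V - mu) * 0.5
    z <- (V - mu - cc) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  list(statistic = V, p = p, n = n, exact = exact, degenerate = FALSE)
}

#' Full evaluation of one predicted case
#'
#' Convenience wrapper producing the banded MAD report, per-organ MAD, and
#' clinical DVH metrics for PTV (D95, HI, CI), heart (mean, V30),
#' ipsilateral lung (mean, V5, V20, V30) and both lungs combined.
#'
#' @param pred predicted dose, [DoseVolume-class] or array in cGy.
#' @param truth ground-truth [DoseVolume-class] or array in cGy.
#' @param lv the case's [LabelVolume-class].
#' @param prescription prescription dose in cGy.
#' @return list with `bands` (from [bandReport()]), `roiMad` (named
#'   vector, cGy) and `clinical` (data.frame structure/metric/value).
#' @export
evaluateCase <- function(pred, truth, lv, prescription = 5000) {
  p <- .asArray(pred); t <- .asArray(truth)
  tbl <- roiCodeTable()
  organs <- c("ptv", "ipsilateral_lung", "heart", "contralateral_lung",
              "spinal_cord")
  roiMad <- vapply(organs, function(org) {
    m <- lv@voxels == tbl$label[tbl$organ == org]
    if (sum(m)) mean(abs(p[m] - t[m])) else NA_real_
  }, numeric(1))
  bands <- bandReport(p, t, lv)
  ptv <- lv@voxels == tbl$label[tbl$organ == "ptv"]
  heart <- lv@voxels == tbl$label[tbl$organ == "heart"]
  ipsi <- lv@voxels == tbl$label[tbl$organ == "ipsilateral_lung"]
  lungs <- ipsi | lv@voxels == tbl$label[tbl$organ == "contralateral_lung"]
  clin <- function(structure, dose) {
    rows <- list()
    if (structure == "ptv") {
      mm <- dvhMetrics(dose, ptv, dPercents = 95, vLevels = numeric())
      rows <- list(c("PTV", "D95", mm$D[["D95"]]),
                   c("PTV", "HI", homogeneityIndex(dose, ptv, prescription)),
                   c("PTV", "CI", suppressWarnings(
                     conformityIndex(dose, ptv, prescription))))
    } else if (structure == "heart") {
      mm <- dvhMetrics(dose, heart, dPercents = numeric(), vLevels = 3000)
      rows <- list(c("Heart", "Mean", mm$mean),
                   c("Heart", "V30", mm$V[["V3000"]]))
    } else if (structure == "ipsi") {
      mm <- dvhMetrics(dose, ipsi, dPercents = numeric(),
                       vLevels = c(500, 2000, 3000))
      rows <- list(c("IpsiLung", "Mean", mm$mean),
                   c("IpsiLung", "V5", mm$V[["V500"]]),
                   c("IpsiLung", "V20", mm$V[["V2000"]]),
                   c("IpsiLung", "V30", mm$V[["V3000"]]))
    } else {
      mm <- dvhMetrics(dose, lungs, dPercents = numeric(),
                       vLevels = c(500, 2000, 3000))
      rows <- list(c("WholeLung", "Mean", mm$mean),
                   c("WholeLung", "V5", mm$V[["V500"]]),
                   c("WholeLung", "V20", mm$V[["V2000"]]),
                   c("WholeLung", "V30", mm$V[["V3000"]]))
    }
    rows
  }
  rows <- list()
  for (str in c("ptv", "heart", "ipsi", "lungs"))
    for (which in c("truth", "pred")) {
      dd <- if (which == "truth") t else p
      for (rr in clin(str, dd))
        rows[[length(rows) + 1L]] <-
          data.frame(structure = rr[1], metric = rr[2], source = which,
                     value = as.numeric(rr[3]))
    }
  list(bands = bands, roiMad = roiMad, clinical = do.call(rbind, rows))
}
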