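test_that("anatomy generation is deterministic and well-formed", {
  cfg <- tinyPhantomConfig()
  lv1 <- generateAnatomy(cfg, seed = 5)
  lv2 <- generateAnatomy(cfg, seed = 5)
  expect_identical(voxels(lv1), voxels(lv2))
  lv3 <- generateAnatomy(cfg, seed = 6)
  expect_false(identical(voxels(lv1), voxels(lv3)))
  tbl <- roiCodeTable()
  for (s in 1:3) {
    lv <- generateAnatomy(cfg, seed = s)
    v <- voxels(lv)
    expect_true(all(v %in% 0:6))
    # every organ is present and organs are mutually exclusive by storage
    expect_setequal(sort(unique(as.vector(v))), 0:6)
    # PTV fully inside the body and the axial extent
    ptvZ <- which(apply(v == 6L, 1, any))
    expect_gt(min(ptvZ), 1)
    expect_lt(max(ptvZ), dim(v)[1])
  }
})

test_that("outside-body fraction tracks the configured target", {
  cfg <- phantomConfig()  # desk-scale default
  fr <- vapply(1:5, function(s)
    1 - mean(voxels(generateAnatomy(cfg, seed = s)) > 0), numeric(1))
  expect_true(all(abs(fr - cfg@targetOutsideFraction) < 0.05))
})

test_that("ROI encoding matches the clinical code table and round-trips", {
  cfg <- tinyPhantomConfig()
  lv <- generateAnatomy(cfg, seed = 2)
  ev <- encodeROI(lv)
  v <- voxels(lv); e <- voxels(ev)
  expect_identical(unname(e[v == 6L][1]), 1.000)  # PTV
  expect_identical(unname(e[v == 5L][1]), 0.833)  # ipsilateral lung
  expect_identical(unname(e[v == 4L][1]), 0.667)  # heart
  expect_identical(unname(e[v == 3L][1]), 0.500)  # contralateral lung
  expect_identical(unname(e[v == 2L][1]), 0.333)  # spinal cord
  expect_identical(unname(e[v == 1L][1]), 0.167)  # other tissue
  expect_identical(unname(e[v == 0L][1]), 0)      # outside body
  expect_identical(voxels(decodeROI(ev)), voxels(lv))
  bad <- LabelVolume(array(0L, c(4, 4, 4)), c(5, 5, 5))
  bad@voxels[1] <- 9L  # bypass constructor validity on purpose
  expect_error(encodeROI(bad), "unknown")
  badCodes <- EncodedVolume(array(0.42, c(2, 2, 2)), c(5, 5, 5))
  expect_error(decodeROI(badCodes), "ROI code")
})

test_that("dose generation is deterministic, masked and prescription-scaled", {
  cfg <- tinyPhantomConfig()
  lv <- generateAnatomy(cfg, seed = 4)
  dv1 <- generateDose(lv, cfg, seed = 4)
  dv2 <- generateDose(lv, cfg, seed = 4)
  expect_equal(voxels(dv1), voxels(dv2), tolerance = 1e-12)
  d <- voxels(dv1); v <- voxels(lv)
  expect_true(all(d[v == 0L] == 0))
  expect_true(all(d >= 0 & d <= 1.2 * cfg@prescription))
  # D95 of the PTV equals the prescription by construction
  d95 <- quantile(d[v == 6L], probs = 1 - cfg@coverageQuantile, type = 7,
                  names = FALSE)
  expect_equal(d95, cfg@prescription, tolerance = 1e-6)
})

test_that("dose gradients concentrate at the PTV boundary", {
  cfg <- tinyPhantomConfig()
  ph <- generatePhantom(cfg, seed = 9)
  v <- voxels(ph$labels); d <- voxels(ph$dose)
  # per-voxel gradient magnitude via single-voxel masks is too slow; use
  # the same central-difference field through a coarse numeric check
  shift <- function(a, ax, by) {
    idx <- lapply(dim(a), seq_len)
    idx[[ax]] <- pmin(pmax(idx[[ax]] + by, 1L), dim(a)[ax])
    a[idx[[1]], idx[[2]], idx[[3]]]
  }
  sp <- spacing(ph$dose)
  gm <- sqrt(((shift(d, 1, 1) - shift(d, 1, -1)) / (2 * sp[1]))^2 +
             ((shift(d, 2, 1) - shift(d, 2, -1)) / (2 * sp[2]))^2 +
             ((shift(d, 3, 1) - shift(d, 3, -1)) / (2 * sp[3]))^2)
  ptv <- v == 6L
  grow <- function(m, k) {
    for (i in seq_len(k))
      m <- m | shift(m, 1, 1) | shift(m, 1, -1) | shift(m, 2, 1) |
           shift(m, 2, -1) | shift(m, 3, 1) | shift(m, 3, -1)
    m
  }
  # 3-voxel band straddling the PTV surface
  shell <- (grow(ptv, 3) & !ptv) | (ptv & grow(!ptv, 3))
  inBody <- v > 0L
  expect_gt(mean(gm[shell & inBody]), median(gm[inBody]))
})

test_that("generated datasets are reproducible, paired and normalized", {
  cfg <- tinyPhantomConfig()
  ds1 <- generateDataset(cfg, nCases = 3, seed = 11)
  ds2 <- generateDataset(cfg, nCases = 3, seed = 11)
  expect_identical(lapply(ds1, function(x) voxels(x$labels)),
                   lapply(ds2, function(x) voxels(x$labels)))
  expect_equal(lapply(ds1, `[[`, "doseNorm"), lapply(ds2, `[[`, "doseNorm"),
               tolerance = 1e-15)
  # distinct anatomies across cases
  expect_false(identical(voxels(ds1[[1]]$labels), voxels(ds1[[2]]$labels)))
  for (cs in ds1) {
    expect_true(all(cs$doseNorm >= 0 & cs$doseNorm <= 1))
    expect_identical(dim(cs$doseNorm), dim(voxels(cs$encoded)))
  }
  expect_identical(ds1[[2]]$id, "case_002")
})

test_that("imbalance statistics are exact on a hand-built volume", {
  labels <- array(c(0L, 0L, 0L, 1L, 1L, 1L, 6L, 6L), c(2, 2, 2))
  dose <- array(c(0, 0, 0, 100, 600, 1500, 5200, 4800), c(2, 2, 2))
  st <- imbalanceStats(LabelVolume(labels, c(5, 5, 5)),
                       DoseVolume(dose, c(5, 5, 5)))
  expect_equal(st$outsideFraction, 3 / 8)
  expect_equal(st$inBodyLowDoseFraction, 1 / 5)
  expect_equal(sum(st$perBandFractions), 1, tolerance = 1e-9)
  expect_equal(unname(st$perBandFractions[["1000-2000"]]), 1 / 5)
  expect_equal(unname(st$perBandFractions[[">5000"]]), 1 / 5)
  expect_true(st$defined)
  # permutation applied consistently to both inputs leaves fractions alone
  pm <- permuteAll(list(labels, dose))
  st2 <- imbalanceStats(LabelVolume(pm[[1]], c(5, 5, 5)),
                        DoseVolume(pm[[2]], c(5, 5, 5)))
  expect_equal(st2$outsideFraction, st$outsideFraction)
  expect_equal(sort(st2$perBandFractions), sort(st$perBandFractions))
  # all-outside volume: in-body statistics undefined but flagged
  st3 <- imbalanceStats(LabelVolume(array(0L, c(2, 2, 2)), c(5, 5, 5)),
                        DoseVolume(array(0, c(2, 2, 2)), c(5, 5, 5)))
  expect_equal(st3$outsideFraction, 1)
  expect_false(st3$defined)
  expect_true(is.na(st3$inBodyLowDoseFraction))
  expect_error(
    imbalanceStats(LabelVolume(array(0L, c(2, 2, 2)), c(5, 5, 5)),
                   DoseVolume(array(0, c(2, 2, 4)), c(5, 5, 5))),
    "shape")
})
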