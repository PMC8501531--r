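test_that("MAD matches direct arithmetic and is symmetric", {
  x <- array(runif(24, 0, 6000), c(2, 3, 4))
  expect_identical(madError(x, x), 0)
  expect_equal(madError(x + 35, x), 35)
  expect_equal(madError(c(100, 300, 0), c(200, 250, 0)), 50)
  a <- x + rnorm(24, sd = 50); a[a < 0] <- 0
  expect_equal(madError(a, x), madError(x, a))
  expect_warning(v <- madError(x, x, mask = array(FALSE, dim(x))), "empty")
  expect_true(is.na(v))
})

test_that("band report agrees with brute force and conserves its partition", {
  hc <- handCase()
  rep <- bandReport(hc$pred, hc$truth, hc$labels)
  tab <- rep$table
  p <- voxels(hc$pred); t <- voxels(hc$truth); v <- voxels(hc$labels)
  inB <- v > 0
  # brute-force per-region means
  bf <- function(mask) mean(abs(p[mask] - t[mask]))
  expect_equal(tab$mad[tab$region == "whole"], bf(array(TRUE, dim(p))))
  expect_equal(tab$mad[tab$region == "outside"], bf(!inB))
  expect_equal(tab$mad[tab$region == "inside"], bf(inB))
  expect_equal(tab$mad[tab$region == "0-500"], bf(inB & t < 500))
  expect_equal(tab$mad[tab$region == "4000-5000"],
               bf(inB & t >= 4000 & t < 5000))
  expect_equal(tab$mad[tab$region == ">5000"], bf(inB & t >= 5000))
  # empty bands are flagged undefined
  expect_true(is.na(tab$mad[tab$region == "1000-2000"]))
  # signed-error std inside the body
  expect_equal(rep$insideStd, sd((p - t)[inB]))
  # voxel-weighted recombination of band MADs reproduces the inside MAD
  bands <- tab[!(tab$region %in% c("whole", "outside", "inside")), ]
  keep <- bands$nVoxels > 0
  expect_equal(sum(bands$mad[keep] * bands$nVoxels[keep]) /
                 sum(bands$nVoxels[keep]),
               tab$mad[tab$region == "inside"], tolerance = 1e-9)
  # and outside + inside recombine to the whole region
  expect_equal((tab$mad[tab$region == "outside"] *
                  tab$nVoxels[tab$region == "outside"] +
                tab$mad[tab$region == "inside"] *
                  tab$nVoxels[tab$region == "inside"]) /
                 tab$nVoxels[tab$region == "whole"],
               tab$mad[tab$region == "whole"], tolerance = 1e-9)
  # identical volumes: all zero
  rep0 <- bandReport(hc$truth, hc$truth, hc$labels)
  expect_true(all(rep0$table$mad[rep0$table$nVoxels > 0] == 0))
  expect_equal(rep0$insideStd, 0)
})

test_that("mean dose gradient matches the analytic ramp and unit contract", {
  sp <- c(5, 2, 2)
  expect_equal(doseGradientMean(DoseVolume(array(7, c(4, 6, 6)), sp)), 0)
  # linear ramp of slope k cGy/mm along the axial axis
  k <- 12
  ramp <- array(rep((0:7) * k * sp[1], times = 36), c(8, 6, 6))
  interior <- array(FALSE, c(8, 6, 6)); interior[2:7, , ] <- TRUE
  dv <- DoseVolume(ramp, sp)
  expect_equal(doseGradientMean(dv, interior), k)
  # doubling the spacing halves the gradient
  dv2 <- DoseVolume(ramp, sp * 2)
  expect_equal(doseGradientMean(dv2, interior), k / 2)
  expect_warning(g <- doseGradientMean(dv, array(FALSE, dim(ramp))), "empty")
  expect_true(is.na(g))
})

test_that("the DVH is a proper survival curve of the masked doses", {
  d <- array(c(10, 20, 30, 40), c(1, 1, 4))
  m <- array(TRUE, c(1, 1, 4))
  curve <- dvh(d, m, binWidth = 5)
  expect_equal(curve$fraction[curve$dose == 0], 1)
  expect_equal(curve$fraction[curve$dose == 25], 0.5)
  expect_true(all(diff(curve$fraction) <= 0))
  expect_equal(curve$fraction[curve$dose > 40], 0)
  # single-voxel mask: step function at its dose
  m1 <- array(c(FALSE, FALSE, TRUE, FALSE), c(1, 1, 4))
  c1 <- dvh(d, m1, binWidth = 10)
  expect_equal(c1$fraction, as.numeric(c1$dose <= 30))
  expect_error(dvh(d, array(FALSE, c(1, 1, 4))), "empty")
})

test_that("DVH metrics follow the interpolated-percentile convention", {
  u <- array(5000, c(2, 2, 2)); m <- array(TRUE, c(2, 2, 2))
  mm <- dvhMetrics(u, m, dPercents = c(95, 100), vLevels = 3000)
  expect_equal(unname(mm$D[["D95"]]), 5000)
  expect_equal(mm$mean, 5000)
  expect_equal(unname(mm$V[["V3000"]]), 100)
  d <- array(c(10, 20, 30, 40), c(1, 1, 4))
  ma <- array(TRUE, c(1, 1, 4))
  expect_equal(dvhMetrics(d, ma)$mean, 25)
  # D100 is the masked minimum
  expect_equal(unname(dvhMetrics(d, ma, dPercents = 100)$D[["D100"]]), 10)
  expect_error(dvhMetrics(d, ma, dPercents = 101), "0, 100")
  # one-sided inverse consistency up to the one-voxel discretization of
  # the interpolated percentile: at least x% - one voxel receives >= D_x
  set.seed(2)
  dd <- array(runif(64, 0, 6000), c(4, 4, 4))
  mall <- array(TRUE, c(4, 4, 4))
  for (x in c(20, 50, 95)) {
    Dx <- dvhMetrics(dd, mall, dPercents = x)$D[[1]]
    expect_gte(100 * mean(dd >= Dx) + 100 / 64, x)
  }
})

test_that("homogeneity index is zero for uniform dose and 0.2 for the split", {
  m <- array(TRUE, c(1, 10, 20))
  expect_equal(homogeneityIndex(array(5000, c(1, 10, 20)), m), 0)
  half <- array(c(rep(5500, 100), rep(4500, 100)), c(1, 10, 20))
  expect_equal(homogeneityIndex(half, m), 0.2)
  # invariant to voxel ordering
  pm <- permuteAll(list(half))[[1]]
  expect_equal(homogeneityIndex(pm, m), homogeneityIndex(half, m))
  expect_error(homogeneityIndex(half, array(FALSE, dim(half))), "empty")
})

test_that("conformity index covers its exact, disjoint and partial cases", {
  d <- array(0, c(1, 10, 30))
  ptv <- array(FALSE, c(1, 10, 30)); ptv[1, , 1:10] <- TRUE  # 100 voxels
  d[ptv] <- 5200
  expect_equal(conformityIndex(d, ptv), 1)
  # isodose volume disjoint from the PTV
  d2 <- array(0, c(1, 10, 30)); d2[1, , 11:20] <- 5200
  expect_equal(conformityIndex(d2, ptv), 0)
  # 200-voxel isodose volume fully covering the 100-voxel PTV
  d3 <- array(0, c(1, 10, 30)); d3[1, , 1:20] <- 5200
  expect_equal(conformityIndex(d3, ptv), 0.5)
  expect_warning(ci0 <- conformityIndex(array(0, c(1, 10, 30)), ptv),
                 "isodose")
  expect_equal(ci0, 0)
})

test_that("exact Wilcoxon p matches exhaustive sign-flip enumeration", {
  # independent oracle: enumerate sign assignments with bit arithmetic
  oracle <- function(a, b) {
    d <- a - b; d <- d[d != 0]; n <- length(d)
    r <- rank(abs(d)); V <- sum(r[d > 0])
    tot <- 2^n
    sums <- vapply(0:(tot - 1), function(s)
      sum(r[bitwAnd(s, 2^(seq_len(n) - 1)) > 0]), numeric(1))
    min(1, 2 * min(mean(sums >= V - 1e-9), mean(sums <= V + 1e-9)))
  }
  set.seed(5)
  a <- rnorm(8); b <- rnorm(8)
  w <- wilcoxonSignedRank(a, b)
  expect_equal(w$p, oracle(a, b))
  # frozen cross-check against the reference exact implementation
  expect_equal(w$statistic, 23)
  expect_equal(w$p, 0.546875)
  expect_equal(w$p, wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value)
  # with ties (mid-ranks) the enumeration still defines the null
  a2 <- c(1, 2, 3, 4, 5, 6); b2 <- c(0, 0.9, 4.1, 2.9, 4, 7.1)
  w2 <- wilcoxonSignedRank(a2, b2)
  expect_equal(w2$p, oracle(a2, b2))
  # symmetry: swapping the samples mirrors the statistic, p unchanged
  w3 <- wilcoxonSignedRank(b, a)
  expect_equal(w3$p, w$p)
  expect_equal(w3$statistic + w$statistic, 8 * 9 / 2)
  # all-zero differences: flagged undefined
  expect_warning(wz <- wilcoxonSignedRank(a, a), "zero")
  expect_true(wz$degenerate)
  expect_true(is.na(wz$p))
  # large-sample branch stays close to the reference approximation
  set.seed(9)
  a4 <- rnorm(30); b4 <- rnorm(30, mean = 0.4)
  w4 <- wilcoxonSignedRank(a4, b4)
  ref <- wilcox.test(a4, b4, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_false(w4$exact)
  expect_equal(w4$p, ref$p.value, tolerance = 1e-10)
})

test_that("scalar metrics are invariant under consistent voxel permutation", {
  hc <- handCase()
  p <- voxels(hc$pred); t <- voxels(hc$truth); v <- voxels(hc$labels)
  pm <- permuteAll(list(p, t, v))
  sp <- c(5, 5, 5)
  expect_equal(madError(pm[[1]], pm[[2]]), madError(p, t))
  r1 <- bandReport(p, t, hc$labels)
  r2 <- bandReport(pm[[1]], pm[[2]],
                   LabelVolume(array(as.integer(pm[[3]]), dim(v)), sp))
  expect_equal(r2$table$mad, r1$table$mad)
  expect_equal(r2$insideStd, r1$insideStd)
  ptv <- v == 6L; ptvPm <- pm[[3]] == 6
  expect_equal(conformityIndex(pm[[2]], ptvPm), conformityIndex(t, ptv))
})

test_that("case evaluation emits the full report schema", {
  cfg <- tinyPhantomConfig()
  ph <- generatePhantom(cfg, seed = 3)
  pred <- voxels(ph$dose) * 0.9
  ev <- evaluateCase(pred, ph$dose, ph$labels)
  expect_named(ev, c("bands", "roiMad", "clinical"))
  expect_setequal(names(ev$roiMad),
                  c("ptv", "ipsilateral_lung", "heart",
                    "contralateral_lung", "spinal_cord"))
  expect_true(all(ev$roiMad >= 0))
  expect_true(all(c("PTV", "Heart", "IpsiLung", "WholeLung") %in%
                    ev$clinical$structure))
  expect_true(all(c("D95", "HI", "CI", "Mean", "V5", "V20", "V30") %in%
                    ev$clinical$metric))
})
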