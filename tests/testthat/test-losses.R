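test_that("modulating factor reproduces its analytic landmarks", {
  cfg100 <- lossConfig(gamma = 100)
  # suppressed shoulder at zero dose
  expect_equal(round(modulatingFactor(0, cfg100), 3), 0.047)
  # midpoint sits exactly at the shift for any gamma
  for (g in c(0.5, 1, 25, 100, 500))
    expect_identical(modulatingFactor(0.03, lossConfig(gamma = g)), 0.5)
  # demarcation ratio at the demarcation dose
  expect_equal(modulatingFactor(455.71 / 6000, cfg100), 0.99,
               tolerance = 5e-5)
  # frozen value from an independent logistic evaluator:
  # plogis((0.2 - 0.03) * 25) computed with stats::plogis
  expect_equal(modulatingFactor(0.2, lossConfig(gamma = 25)),
               0.985936372956754, tolerance = 1e-12)
})

test_that("modulating factor is monotone, bounded and sharpens to a step", {
  d <- seq(0, 1, length.out = 201)
  for (g in c(1, 25, 100, 500)) {
    w <- modulatingFactor(d, lossConfig(gamma = g))
    expect_true(all(w > 0 & w < 1))
    expect_true(all(diff(w) >= 0))
    # strict monotonicity on the unsaturated part of the dose axis
    du <- d[abs((d - 0.03) * g) < 30]
    expect_true(all(diff(modulatingFactor(du, lossConfig(gamma = g))) > 0))
  }
  # gamma = 0 collapses to the constant 1/2
  expect_equal(modulatingFactor(d, lossConfig(gamma = 0)), rep(0.5, 201))
  # large gamma approaches a step at the shift
  stepCfg <- lossConfig(gamma = 1e4)
  expect_lt(modulatingFactor(0.02, stepCfg), 1e-4)
  expect_gt(modulatingFactor(0.04, stepCfg), 1 - 1e-4)
  # input validation
  expect_error(modulatingFactor(NaN, lossConfig()), "finite")
  expect_error(lossConfig(gamma = -1), "gamma")
})

test_that("MSE loss matches direct arithmetic and validates its inputs", {
  x <- array(runif(24), c(2, 3, 4))
  expect_identical(mseLoss(x, x), 0)
  expect_equal(mseLoss(x + 0.1, x), 0.01)
  expect_equal(mseLoss(c(0.5, 0.2), c(0.4, 0.4)), 0.025)
  expect_error(mseLoss(x, array(0, c(2, 3, 5))), "shape")
  expect_error(mseLoss(numeric(), numeric()), "empty")
})

test_that("sharp loss is a strict underestimate of MSE with exact limits", {
  cfg <- lossConfig(gamma = 100)
  x <- array(runif(30), c(5, 3, 2))
  expect_identical(sharpLoss(x, x, cfg), 0)
  # gamma = 0: exactly half the MSE everywhere
  set.seed(1)
  p <- runif(50); t <- runif(50)
  expect_equal(sharpLoss(p, t, lossConfig(gamma = 0)), 0.5 * mseLoss(p, t))
  # single voxel at the demarcation dose: ratio demarcationRatio
  d0 <- demarcationDose(cfg) / 6000
  e <- 0.17
  expect_equal(sharpLoss(d0 + e, d0, cfg) / mseLoss(d0 + e, d0), 0.99,
               tolerance = 1e-9)
  # strict ordering for every gamma in the study grid
  set.seed(7)
  for (g in c(1, 25, 50, 100, 250, 500)) {
    cfgG <- lossConfig(gamma = g)
    for (i in 1:25) {
      pp <- runif(40); tt <- runif(40)
      sl <- sharpLoss(pp, tt, cfgG)
      expect_gt(sl, 0)
      expect_lt(sl, mseLoss(pp, tt))
    }
  }
})

test_that("sharp loss behaves as a voxel mean", {
  cfg <- lossConfig(gamma = 50)
  set.seed(3)
  p <- runif(60); t <- runif(60)
  # permutation invariance
  perm <- sample.int(60)
  expect_equal(sharpLoss(p[perm], t[perm], cfg), sharpLoss(p, t, cfg))
  # doubling the volume leaves the mean unchanged
  expect_equal(sharpLoss(c(p, p), c(t, t), cfg), sharpLoss(p, t, cfg))
  # truth everywhere above the demarcation dose: at least 0.99 x MSE
  d0 <- demarcationDose(cfg) / 6000
  tt <- runif(40, min = d0, max = 1)
  pp <- tt + rnorm(40, sd = 0.05)
  expect_gte(sharpLoss(pp, tt, cfg), 0.99 * mseLoss(pp, tt))
})

test_that("demarcation dose has the analytic closed form and limits", {
  expect_equal(demarcationDose(lossConfig(gamma = 100)), 455.71,
               tolerance = 0.005)
  expect_equal(demarcationDose(lossConfig(gamma = 50)), 731.41,
               tolerance = 0.005)
  # closed form agrees with a numeric root-find of the modulating factor
  for (g in c(2, 10, 100, 400)) {
    cfg <- lossConfig(gamma = g)
    root <- uniroot(function(d) modulatingFactor(d, cfg) - 0.99,
                    c(0, 10), tol = 1e-12)$root
    expect_equal(demarcationDose(cfg) / 6000, root, tolerance = 1e-6)
  }
  # strictly decreasing in gamma, approaching the shift-only limit
  gs <- c(1, 5, 25, 100, 500, 5000)
  d0s <- vapply(gs, function(g) demarcationDose(lossConfig(gamma = g)),
                numeric(1))
  expect_true(all(diff(d0s) < 0))
  expect_equal(demarcationDose(lossConfig(gamma = 1e8)), 0.03 * 6000,
               tolerance = 1e-3)
  expect_error(demarcationDose(lossConfig(gamma = 0)), "demarcation")
})

test_that("analytic sharp-loss gradient matches finite differences", {
  cfg <- lossConfig(gamma = 100)
  set.seed(11)
  p <- runif(20); t <- runif(20)
  expect_identical(sharpLossGradient(t, t, cfg), t * 0)
  g <- sharpLossGradient(p, t, cfg)
  h <- 1e-6
  for (i in sample.int(20, 8)) {
    pp <- p; pm <- p
    pp[i] <- pp[i] + h; pm[i] <- pm[i] - h
    fd <- (sharpLoss(pp, t, cfg) - sharpLoss(pm, t, cfg)) / (2 * h)
    expect_equal(g[i], fd, tolerance = 1e-5)
  }
  # gamma = 0: exactly half the MSE gradient
  g0 <- sharpLossGradient(p, t, lossConfig(gamma = 0))
  expect_equal(g0, 0.5 * mseLossGradient(p, t))
})

test_that("loss registry dispatches by name", {
  l <- lossByName("sharp", lossConfig(gamma = 100))
  expect_equal(l$loss(c(0.5), c(0.4)),
               sharpLoss(0.5, 0.4, lossConfig(gamma = 100)))
  m <- lossByName("mse")
  expect_equal(m$loss(c(0.5), c(0.4)), 0.01, tolerance = 1e-12)
  expect_error(lossByName("dice"))
})
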