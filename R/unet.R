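## A compact CPU U-Net for voxelwise dose regression, written on BLAS-backed
## matrix primitives: feature maps are channels x voxels matrices, same-
## padding convolution is im2col + GEMM, and backpropagation is explicit.
## The network follows the encoder/decoder recipe used for dose prediction:
## `depth` down levels of [3x3x3 conv -> ReLU -> batch norm] x2 with 2x2x2
## max pooling between levels (the deepest level is the bottleneck and does
## not pool), `depth - 1` up levels of transposed-convolution upsampling,
## skip concatenation and two more conv modules, and a final 1x1x1
## convolution with linear activation so the output grid equals the input
## grid. In 2D mode kernels are 1x3x3 and pooling 1x2x2, so axial slices
## are processed independently by the same code path.

#' U-Net architecture configuration
#'
#' @slot spatialDims 2 or 3; in 2D mode the axial axis is never mixed.
#' @slot depth number of down levels including the bottleneck (default 5).
#' @slot baseChannels feature channels at the first level (default 16).
#' @slot channelGrowth channel multiplier per level (default 2).
#' @slot upsampleMode `"transposed"` (learned transposed convolution) or
#'   `"interpolate"` (nearest-neighbour upsampling followed by a 3-kernel
#'   convolution).
#' @slot paddingMode only `"same"` is supported: the network's I/O contract
#'   (output grid equals input grid) cannot be met under valid padding.
#' @slot bnOrder `"relu_bn"` (conv, ReLU, then batch norm) or the
#'   conventional `"bn_relu"`.
#' @slot seed initialization seed.
#' @aliases UNetConfig
#' @seealso [unetConfig()], [buildUNet()]
#' @exportClass UNetConfig
setClass("UNetConfig", representation(
  spatialDims = "integer", depth = "integer", baseChannels = "integer",
  channelGrowth = "numeric", upsampleMode = "character",
  paddingMode = "character", bnOrder = "character", seed = "integer"))

setValidity("UNetConfig", function(object) {
  msgs <- character()
  if (!object@spatialDims %in% c(2L, 3L))
    msgs <- c(msgs, "spatialDims must be 2 or 3")
  if (object@depth < 1L) msgs <- c(msgs, "depth must be >= 1")
  if (object@baseChannels < 1L) msgs <- c(msgs, "baseChannels must be >= 1")
  if (!object@upsampleMode %in% c("transposed", "interpolate"))
    msgs <- c(msgs, "upsampleMode must be 'transposed' or 'interpolate'")
  if (!identical(object@paddingMode, "same"))
    msgs <- c(msgs, paste("only paddingMode = 'same' is supported: valid",
                          "padding cannot preserve the output grid"))
  if (!object@bnOrder %in% c("relu_bn", "bn_relu"))
    msgs <- c(msgs, "bnOrder must be 'relu_bn' or 'bn_relu'")
  if (length(msgs)) msgs else TRUE
})

#' Create a U-Net configuration
#'
#' @param spatialDims 2 or 3.
#' @param depth down levels including the bottleneck; the full-scale
#'   network uses 5 (5 down + 4 up + output projection).
#' @param baseChannels first-level channels.
#' @param channelGrowth per-level channel multiplier.
#' @param upsampleMode `"transposed"` or `"interpolate"`.
#' @param paddingMode `"same"` (the only supported mode).
#' @param bnOrder `"relu_bn"` (default, conv then ReLU then batch norm) or
#'   `"bn_relu"`.
#' @param seed initialization seed.
#' @return A validated [UNetConfig-class].
#' @export
unetConfig <- function(spatialDims = 3, depth = 5, baseChannels = 16,
                       channelGrowth = 2, upsampleMode = "transposed",
                       paddingMode = "same", bnOrder = "relu_bn", seed = 1) {
  new("UNetConfig", spatialDims = as.integer(spatialDims),
      depth = as.integer(depth), baseChannels = as.integer(baseChannels),
      channelGrowth = as.numeric(channelGrowth),
      upsampleMode = upsampleMode, paddingMode = paddingMode,
      bnOrder = bnOrder, seed = as.integer(seed))
}

#' A built U-Net model
#'
#' Created by [buildUNet()]; holds the configuration, the trainable
#' parameters and the batch-normalization running statistics.
#'
#' @slot config the [UNetConfig-class].
#' @slot params nested list of parameter arrays.
#' @slot bnStats nested list of running mean/variance per batch-norm module.
#' @aliases UNetModel
#' @exportClass UNetModel
setClass("UNetModel", representation(
  config = "UNetConfig", params = "list", bnStats = "list"))

setMethod("show", "UNetModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "UNetModel: %dD, depth %d, base %d channels (%s upsampling)\n",
    cfg@spatialDims, cfg@depth, cfg@baseChannels, cfg@upsampleMode))
  cat(sprintf("  %d trainable parameters\n", nUNetParams(object)))
  invisible(object)
})

.kernelOf <- function(cfg) if (cfg@spatialDims == 3L) c(3L, 3L, 3L) else c(1L, 3L, 3L)
.poolOf   <- function(cfg) if (cfg@spatialDims == 3L) c(2L, 2L, 2L) else c(1L, 2L, 2L)
.channelsOf <- function(cfg)
  as.integer(round(cfg@baseChannels * cfg@channelGrowth^(seq_len(cfg@depth) - 1)))

## ---- index-map cache -------------------------------------------------

.idxCache <- new.env(parent = emptyenv())

.intGrids <- function(dims) {
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  list(z = rep_len(seq_len(nz), nz * ny * nx),
       y = rep(rep(seq_len(ny), each = nz), times = nx),
       x = rep(seq_len(nx), each = nz * ny))
}

# gather indices for same-padding im2col; index B*N + 1 is the zero column
.convIdx <- function(dims, kern, B) {
  key <- paste("c", paste(dims, collapse = "."), paste(kern, collapse = "."),
               B, sep = "_")
  if (!is.null(.idxCache[[key]])) return(.idxCache[[key]])
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  N <- prod(dims)
  g <- .intGrids(dims)
  r <- (kern - 1L) %/% 2L
  off <- expand.grid(dz = -r[1]:r[1], dy = -r[2]:r[2], dx = -r[3]:r[3])
  pad <- B * N + 1L
  idx <- lapply(seq_len(nrow(off)), function(k) {
    zz <- g$z + off$dz[k]; yy <- g$y + off$dy[k]; xx <- g$x + off$dx[k]
    ok <- zz >= 1L & zz <= nz & yy >= 1L & yy <= ny & xx >= 1L & xx <= nx
    base <- zz + nz * (yy - 1L) + nz * ny * (xx - 1L)
    out <- integer(B * N)
    for (b in seq_len(B)) {
      v <- base + (b - 1L) * N
      v[!ok] <- pad
      out[((b - 1L) * N + 1L):(b * N)] <- v
    }
    out
  })
  .idxCache[[key]] <- idx
  idx
}

# fine-grid indices per pooling offset; block structure is disjoint
.poolIdx <- function(dims, p, B) {
  key <- paste("p", paste(dims, collapse = "."), paste(p, collapse = "."),
               B, sep = "_")
  if (!is.null(.idxCache[[key]])) return(.idxCache[[key]])
  dc <- dims %/% p
  nz <- dims[1]; ny <- dims[2]
  N <- prod(dims); Nc <- prod(dc)
  gc <- .intGrids(dc)
  off <- expand.grid(oz = 0:(p[1] - 1L), oy = 0:(p[2] - 1L),
                     ox = 0:(p[3] - 1L))
  idx <- lapply(seq_len(nrow(off)), function(o) {
    zf <- (gc$z - 1L) * p[1] + off$oz[o] + 1L
    yf <- (gc$y - 1L) * p[2] + off$oy[o] + 1L
    xf <- (gc$x - 1L) * p[3] + off$ox[o] + 1L
    base <- zf + nz * (yf - 1L) + nz * ny * (xf - 1L)
    out <- integer(B * Nc)
    for (b in seq_len(B))
      out[((b - 1L) * Nc + 1L):(b * Nc)] <- base + (b - 1L) * N
    out
  })
  .idxCache[[key]] <- idx
  idx
}

## ---- primitive layers ------------------------------------------------

# fully expanded linear gather indices into the zero-augmented feature
# matrix (C x (B*N + 1)); one vector gather replaces K submatrix copies
.convIdxBig <- function(dims, kern, B, C) {
  key <- paste("cb", paste(dims, collapse = "."),
               paste(kern, collapse = "."), B, C, sep = "_")
  if (!is.null(.idxCache[[key]])) return(.idxCache[[key]])
  base <- do.call(rbind, .convIdx(dims, kern, B))  # K x (B*N) column indices
  K <- nrow(base)
  big <- C * (base - 1L)
  big <- big[rep(seq_len(K), each = C), , drop = FALSE] + seq_len(C)
  storage.mode(big) <- "integer"
  .idxCache[[key]] <- big
  big
}

.im2col <- function(x, dims, kern, B) {
  big <- .convIdxBig(dims, kern, B, nrow(x))
  xaug <- cbind(x, 0)
  cols <- xaug[big]
  dim(cols) <- dim(big)
  cols
}

.convFwd <- function(x, W, b, dims, kern, B) {
  cols <- .im2col(x, dims, kern, B)
  list(y = W %*% cols + b, cols = cols)
}

# gradient w.r.t. the conv input: convolution of dy with the flipped kernel
.convBwd <- function(dy, W, cols, dims, kern, B, Cin) {
  Cout <- nrow(W)
  K <- ncol(W) %/% Cin
  dW <- tcrossprod(dy, cols)
  db <- rowSums(dy)
  Wb <- matrix(0, Cin, K * Cout)
  for (k in seq_len(K)) {
    kf <- K + 1L - k
    Wb[, ((k - 1L) * Cout + 1L):(k * Cout)] <-
      t(W[, ((kf - 1L) * Cin + 1L):(kf * Cin), drop = FALSE])
  }
  dcols <- .im2col(dy, dims, kern, B)
  list(dx = Wb %*% dcols, dW = dW, db = db)
}

.poolFwd <- function(x, pidx) {
  P <- length(pidx)
  cur <- x[, pidx[[1]], drop = FALSE]
  amax <- matrix(1L, nrow(cur), ncol(cur))
  for (o in 2:P) {
    cand <- x[, pidx[[o]], drop = FALSE]
    m <- cand > cur
    cur[m] <- cand[m]
    amax[m] <- o
  }
  list(y = cur, amax = amax)
}

.poolBwd <- function(dy, amax, pidx, nFine) {
  dx <- matrix(0, nrow(dy), nFine)
  for (o in seq_along(pidx)) {
    tmp <- dy
    tmp[amax != o] <- 0
    dx[, pidx[[o]]] <- tmp
  }
  dx
}

.upconvFwd <- function(x, W, b, pidx) {
  P <- length(pidx)
  Cout <- length(b)
  yb <- W %*% x
  y <- matrix(0, Cout, P * ncol(x))
  for (o in seq_len(P))
    y[, pidx[[o]]] <- yb[((o - 1L) * Cout + 1L):(o * Cout), , drop = FALSE]
  y + b
}

.upconvBwd <- function(dy, x, W, pidx) {
  P <- length(pidx)
  Cout <- nrow(dy)
  dyb <- matrix(0, P * Cout, ncol(x))
  for (o in seq_len(P))
    dyb[((o - 1L) * Cout + 1L):(o * Cout), ] <- dy[, pidx[[o]], drop = FALSE]
  list(dx = crossprod(W, dyb), dW = tcrossprod(dyb, x), db = rowSums(dy))
}

.nearestUpFwd <- function(x, pidx) {
  y <- matrix(0, nrow(x), length(pidx) * ncol(x))
  for (o in seq_along(pidx)) y[, pidx[[o]]] <- x
  y
}

.nearestUpBwd <- function(dy, pidx, nCoarse) {
  dx <- matrix(0, nrow(dy), nCoarse)
  for (o in seq_along(pidx)) dx <- dx + dy[, pidx[[o]], drop = FALSE]
  dx
}

.bnEps <- 1e-5
.bnMomentum <- 0.1

.bnFwd <- function(x, g, beta, stats, training) {
  if (training) {
    mu <- rowMeans(x)
    xc <- x - mu
    v <- rowMeans(xc^2)
    invstd <- 1 / sqrt(v + .bnEps)
    xhat <- xc * invstd
    stats$mean <- (1 - .bnMomentum) * stats$mean + .bnMomentum * mu
    stats$var <- (1 - .bnMomentum) * stats$var + .bnMomentum * v
    list(y = g * xhat + beta, xhat = xhat, invstd = invstd, stats = stats)
  } else {
    invstd <- 1 / sqrt(stats$var + .bnEps)
    list(y = g * ((x - stats$mean) * invstd) + beta,
         xhat = NULL, invstd = NULL, stats = stats)
  }
}

.bnBwd <- function(dy, g, xhat, invstd) {
  N <- ncol(dy)
  dg <- rowSums(dy * xhat)
  dbeta <- rowSums(dy)
  dxh <- dy * g
  dx <- (invstd / N) * (N * dxh - rowSums(dxh) - xhat * rowSums(dxh * xhat))
  list(dx = dx, dg = dg, dbeta = dbeta)
}

## ---- conv module: conv -> (ReLU/BN in configured order) --------------

.moduleFwd <- function(x, prm, stats, dims, kern, B, order, training) {
  cv <- .convFwd(x, prm$W, prm$b, dims, kern, B)
  if (order == "relu_bn") {
    r <- pmax(cv$y, 0)
    bn <- .bnFwd(r, prm$g, prm$beta, stats, training)
    list(y = bn$y, stats = bn$stats,
         cache = list(cols = cv$cols, pre = cv$y, xhat = bn$xhat,
                      invstd = bn$invstd))
  } else {
    bn <- .bnFwd(cv$y, prm$g, prm$beta, stats, training)
    r <- pmax(bn$y, 0)
    list(y = r, stats = bn$stats,
         cache = list(cols = cv$cols, pre = bn$y, xhat = bn$xhat,
                      invstd = bn$invstd))
  }
}

.moduleBwd <- function(dy, prm, cache, dims, kern, B, order, Cin) {
  if (order == "relu_bn") {
    bn <- .bnBwd(dy, prm$g, cache$xhat, cache$invstd)
    dr <- bn$dx
    dr[cache$pre <= 0] <- 0
    cb <- .convBwd(dr, prm$W, cache$cols, dims, kern, B, Cin)
  } else {
    dr <- dy
    dr[cache$pre <= 0] <- 0
    bn <- .bnBwd(dr, prm$g, cache$xhat, cache$invstd)
    cb <- .convBwd(bn$dx, prm$W, cache$cols, dims, kern, B, Cin)
  }
  list(dx = cb$dx,
       grads = list(W = cb$dW, b = cb$db, g = bn$dg, beta = bn$dbeta))
}

## ---- construction ----------------------------------------------------

.heInit <- function(nOut, nIn, fanIn) {
  matrix(stats::rnorm(nOut * nIn, sd = sqrt(2 / fanIn)), nOut, nIn)
}

.newModuleParams <- function(Cin, Cout, K) {
  list(W = .heInit(Cout, Cin * K, Cin * K), b = numeric(Cout),
       g = rep(1, Cout), beta = numeric(Cout))
}

.newBnStats <- function(Cout) list(mean = numeric(Cout), var = rep(1, Cout))

#' Build a U-Net model
#'
#' Constructs the network with seeded He-initialized convolutions, unit-gain
#' batch-norm modules and a zero-initialized output projection (an untrained
#' model therefore predicts exactly zero dose everywhere).
#'
#' @param cfg a [UNetConfig-class].
#' @return A [UNetModel-class].
#' @examples
#' m <- buildUNet(unetConfig(depth = 3, baseChannels = 4))
#' nUNetParams(m) == unetParameterCount(unetConfig(depth = 3, baseChannels = 4))
#' @export
buildUNet <- function(cfg = unetConfig()) {
  stopifnot(is(cfg, "UNetConfig"))
  validObject(cfg)
  withr::with_seed(cfg@seed, .buildUNetImpl(cfg))
}

.buildUNetImpl <- function(cfg) {
  K <- prod(.kernelOf(cfg))
  P <- prod(.poolOf(cfg))
  cs <- .channelsOf(cfg)
  depth <- cfg@depth
  down <- vector("list", depth)
  downStats <- vector("list", depth)
  for (l in seq_len(depth)) {
    cin <- if (l == 1L) 1L else cs[l - 1L]
    down[[l]] <- list(conv1 = .newModuleParams(cin, cs[l], K),
                      conv2 = .newModuleParams(cs[l], cs[l], K))
    downStats[[l]] <- list(conv1 = .newBnStats(cs[l]),
                           conv2 = .newBnStats(cs[l]))
  }
  up <- list(); upStats <- list()
  if (depth > 1L) {
    up <- vector("list", depth - 1L)
    upStats <- vector("list", depth - 1L)
    for (l in seq_len(depth - 1L)) {
      if (cfg@upsampleMode == "transposed") {
        upl <- list(W = .heInit(P * cs[l], cs[l + 1L], cs[l + 1L]),
                    b = numeric(cs[l]))
      } else {
        upl <- list(W = .heInit(cs[l], cs[l + 1L] * K, cs[l + 1L] * K),
                    b = numeric(cs[l]))
      }
      up[[l]] <- list(up = upl,
                      conv1 = .newModuleParams(2L * cs[l], cs[l], K),
                      conv2 = .newModuleParams(cs[l], cs[l], K))
      upStats[[l]] <- list(conv1 = .newBnStats(cs[l]),
                           conv2 = .newBnStats(cs[l]))
    }
  }
  out <- list(W = matrix(0, 1L, cs[1L]), b = 0)
  new("UNetModel", config = cfg,
      params = list(down = down, up = up, out = out),
      bnStats = list(down = downStats, up = upStats))
}

#' Number of trainable parameters of a built model
#'
#' @param model a [UNetModel-class].
#' @return Integer count over all weights, biases and batch-norm gains/offsets.
#' @export
nUNetParams <- function(model) {
  stopifnot(is(model, "UNetModel"))
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else n <<- n + length(x)
    invisible(NULL)
  }
  walk(model@params)
  n
}

#' Closed-form parameter count implied by a configuration
#'
#' Sums, level by level, the convolution kernels and biases, the batch-norm
#' gains and offsets, the upsampling operators and the output projection.
#' Must agree with [nUNetParams()] on the built model.
#'
#' @param cfg a [UNetConfig-class].
#' @return Integer parameter count.
#' @export
unetParameterCount <- function(cfg = unetConfig()) {
  K <- prod(.kernelOf(cfg)); P <- prod(.poolOf(cfg))
  cs <- .channelsOf(cfg)
  conv <- function(cin, cout) cout * (cin * K + 1) + 2 * cout  # + batch norm
  n <- 0
  for (l in seq_len(cfg@depth)) {
    cin <- if (l == 1L) 1L else cs[l - 1L]
    n <- n + conv(cin, cs[l]) + conv(cs[l], cs[l])
  }
  if (cfg@depth > 1L) for (l in seq_len(cfg@depth - 1L)) {
    n <- n + if (cfg@upsampleMode == "transposed")
      P * cs[l] * cs[l + 1L] + cs[l] else cs[l] * (cs[l + 1L] * K + 1)
    n <- n + conv(2L * cs[l], cs[l]) + conv(cs[l], cs[l])
  }
  as.integer(n + cs[1L] + 1L)
}

## ---- forward / backward over a batch ---------------------------------

.checkDivisible <- function(dims, cfg) {
  p <- .poolOf(cfg)
  need <- p^(cfg@depth - 1L)
  bad <- which(dims %% need != 0L)
  if (length(bad))
    stop(sprintf(
      "input extent %d on axis %d is not divisible by %d (depth %d pooling)",
      dims[bad[1]], bad[1], need[bad[1]], cfg@depth))
  invisible(TRUE)
}

# x: 1 x (B*N) matrix of encoded ROI values; returns output plus caches
.unetForward <- function(model, x, dims, B, training = FALSE) {
  cfg <- model@config
  .checkDivisible(dims, cfg)
  kern <- .kernelOf(cfg); p <- .poolOf(cfg)
  depth <- cfg@depth
  prm <- model@params
  stats <- model@bnStats
  order <- cfg@bnOrder
  cache <- list(down = vector("list", depth), up = list(), dims = dims,
                B = B)
  enc <- vector("list", depth)
  cur <- x
  curDims <- dims
  dimsAt <- vector("list", depth)
  for (l in seq_len(depth)) {
    dimsAt[[l]] <- curDims
    m1 <- .moduleFwd(cur, prm$down[[l]]$conv1, stats$down[[l]]$conv1,
                     curDims, kern, B, order, training)
    m2 <- .moduleFwd(m1$y, prm$down[[l]]$conv2, stats$down[[l]]$conv2,
                     curDims, kern, B, order, training)
    stats$down[[l]]$conv1 <- m1$stats
    stats$down[[l]]$conv2 <- m2$stats
    cur <- m2$y
    lc <- list(m1 = m1$cache, m2 = m2$cache)
    if (l < depth) {
      enc[[l]] <- cur
      pidx <- .poolIdx(curDims, p, B)
      pl <- .poolFwd(cur, pidx)
      lc$amax <- pl$amax
      lc$nFine <- ncol(cur)
      cur <- pl$y
      curDims <- curDims %/% p
    }
    cache$down[[l]] <- lc
  }
  if (depth > 1L) {
    cache$up <- vector("list", depth - 1L)
    for (l in rev(seq_len(depth - 1L))) {
      fineDims <- dimsAt[[l]]
      pidx <- .poolIdx(fineDims, p, B)
      uc <- list(xCoarse = cur)
      if (cfg@upsampleMode == "transposed") {
        upc <- .upconvFwd(cur, prm$up[[l]]$up$W, prm$up[[l]]$up$b, pidx)
      } else {
        nn <- .nearestUpFwd(cur, pidx)
        cv <- .convFwd(nn, prm$up[[l]]$up$W, prm$up[[l]]$up$b, fineDims,
                       kern, B)
        upc <- cv$y
        uc$upCols <- cv$cols
      }
      merged <- rbind(enc[[l]], upc)
      m1 <- .moduleFwd(merged, prm$up[[l]]$conv1, stats$up[[l]]$conv1,
                       fineDims, kern, B, order, training)
      m2 <- .moduleFwd(m1$y, prm$up[[l]]$conv2, stats$up[[l]]$conv2,
                       fineDims, kern, B, order, training)
      stats$up[[l]]$conv1 <- m1$stats
      stats$up[[l]]$conv2 <- m2$stats
      uc$m1 <- m1$cache; uc$m2 <- m2$cache
      uc$cSkip <- nrow(enc[[l]])
      cache$up[[l]] <- uc
      cur <- m2$y
      curDims <- fineDims
    }
  }
  cache$head <- cur
  out <- prm$out$W %*% cur + prm$out$b
  list(out = out, cache = cache, bnStats = stats, dimsAt = dimsAt)
}

# dout: 1 x (B*N); returns gradient tree matching model@params
.unetBackward <- function(model, fw, dout) {
  cfg <- model@config
  kern <- .kernelOf(cfg); p <- .poolOf(cfg)
  depth <- cfg@depth
  prm <- model@params
  order <- cfg@bnOrder
  B <- fw$cache$B
  dimsAt <- fw$dimsAt
  grads <- list(down = vector("list", depth),
                up = if (depth > 1L) vector("list", depth - 1L) else list(),
                out = list())
  grads$out <- list(W = tcrossprod(dout, fw$cache$head),
                    b = sum(dout))
  cur <- crossprod(prm$out$W, dout)
  dEnc <- vector("list", depth)  # gradient flowing into each skip
  if (depth > 1L) {
    # decoder ran coarse-to-fine, so backprop runs fine-to-coarse
    for (l in seq_len(depth - 1L)) {
      fineDims <- dimsAt[[l]]
      uc <- fw$cache$up[[l]]
      cs1 <- nrow(prm$up[[l]]$conv2$W)  # channels at this level
      b2 <- .moduleBwd(cur, prm$up[[l]]$conv2, uc$m2, fineDims, kern, B,
                       order, cs1)
      b1 <- .moduleBwd(b2$dx, prm$up[[l]]$conv1, uc$m1, fineDims, kern, B,
                       order, 2L * uc$cSkip)
      grads$up[[l]] <- list(conv1 = b1$grads, conv2 = b2$grads)
      dMerged <- b1$dx
      dEnc[[l]] <- dMerged[seq_len(uc$cSkip), , drop = FALSE]
      dUp <- dMerged[-seq_len(uc$cSkip), , drop = FALSE]
      pidx <- .poolIdx(fineDims, p, B)
      if (cfg@upsampleMode == "transposed") {
        ub <- .upconvBwd(dUp, uc$xCoarse, prm$up[[l]]$up$W, pidx)
        grads$up[[l]]$up <- list(W = ub$dW, b = ub$db)
        cur <- ub$dx
      } else {
        Cin <- nrow(uc$xCoarse)
        cb <- .convBwd(dUp, prm$up[[l]]$up$W, uc$upCols, fineDims, kern, B,
                       Cin)
        grads$up[[l]]$up <- list(W = cb$dW, b = cb$db)
        cur <- .nearestUpBwd(cb$dx, pidx, ncol(uc$xCoarse))
      }
    }
    # cur is now the gradient at the bottleneck output
  }
  for (l in rev(seq_len(depth))) {
    lc <- fw$cache$down[[l]]
    curDims <- dimsAt[[l]]
    if (l < depth) {
      pidx <- .poolIdx(curDims, p, B)
      dPooled <- .poolBwd(cur, lc$amax, pidx, lc$nFine)
      cur <- dPooled + dEnc[[l]]
    }
    cs <- nrow(prm$down[[l]]$conv2$W)
    cin1 <- if (l == 1L) 1L else nrow(prm$down[[l - 1L]]$conv2$W)
    b2 <- .moduleBwd(cur, prm$down[[l]]$conv2, lc$m2, curDims, kern, B,
                     order, cs)
    b1 <- .moduleBwd(b2$dx, prm$down[[l]]$conv1, lc$m1, curDims, kern, B,
                     order, cin1)
    grads$down[[l]] <- list(conv1 = b1$grads, conv2 = b2$grads)
    cur <- b1$dx
  }
  grads
}

## ---- prediction ------------------------------------------------------

.casesToMatrix <- function(arrs) {
  do.call(cbind, lapply(arrs, function(a) matrix(as.numeric(a), nrow = 1L)))
}

#' Predict a normalized dose volume from an encoded ROI volume
#'
#' Runs the network in evaluation mode (batch-norm running statistics).
#' The output grid equals the input grid; values are unconstrained reals
#' from the linear output head unless `clampNegative = TRUE`.
#'
#' @param model a trained (or freshly built) [UNetModel-class].
#' @param roi an [EncodedVolume-class] or a 3D array of ROI codes.
#' @param clampNegative clamp predictions to `[0, Inf)` for reporting.
#' @return A 3D array of predicted dose on the normalized \[0, 1\] scale.
#' @export
predictDose <- function(model, roi, clampNegative = FALSE) {
  stopifnot(is(model, "UNetModel"))
  arr <- if (is(roi, "EncodedVolume")) roi@voxels else roi
  if (length(dim(arr)) != 3L) stop("roi must be a 3D volume")
  dims <- dim(arr)
  fw <- .unetForward(model, .casesToMatrix(list(arr)), dims, 1L,
                     training = FALSE)
  out <- array(as.numeric(fw$out), dim = dims)
  if (clampNegative) out[out < 0] <- 0
  out
}
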