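# Periodic U-Net: a classic encoder-decoder with skip connections where
# every convolution uses circular padding, so the whole network is exactly
# translation-equivariant on the torus for shifts divisible by the total
# downsampling factor 2^depth.  Forward and backward passes are assembled
# here from the compiled conv/pool/upsample primitives.

.prelu <- function(z, a) {
  hw <- prod(dim(z)[1:2])
  pmax(z, 0) + pmin(z, 0) * rep(a, each = hw)
}

.preluBwd <- function(dy, z, a) {
  hw <- prod(dim(z)[1:2])
  arep <- rep(a, each = hw)
  pos <- z > 0
  dz <- dy * (pos + arep * !pos)
  da <- colSums(matrix(dy * pmin(z, 0), nrow = hw))
  list(dz = dz, da = da)
}

.heInit <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}

.channels <- function(config) config$baseChannels * 2^(seq_len(config$depth + 1) - 1)

.initWeights <- function(config) {
  ch <- .channels(config)
  k <- config$kernel
  w <- list()
  addConv <- function(name, cin, cout, kk = k) {
    w[[paste0(name, ".w")]] <<- .heInit(kk, kk, cin, cout)
    w[[paste0(name, ".b")]] <<- numeric(cout)
  }
  addBlock <- function(name, cin, cout) {
    addConv(paste0(name, ".conv1"), cin, cout)
    w[[paste0(name, ".conv1.a")]] <<- rep(0.25, cout)
    addConv(paste0(name, ".conv2"), cout, cout)
    w[[paste0(name, ".conv2.a")]] <<- rep(0.25, cout)
  }
  for (l in seq_len(config$depth))
    addBlock(paste0("enc", l), if (l == 1) config$inChannels else ch[l - 1], ch[l])
  addBlock("bot", ch[config$depth], ch[config$depth + 1])
  for (l in rev(seq_len(config$depth))) {
    addConv(paste0("dec", l, ".up"), ch[l + 1], ch[l])
    w[[paste0("dec", l, ".up.a")]] <- rep(0.25, ch[l])
    addBlock(paste0("dec", l), 2 * ch[l], ch[l])
  }
  addConv("head", ch[1], config$outChannels, kk = 1L)
  if (isTRUE(config$residual)) w[["head.w"]][] <- 0   # start at the identity map
  w
}

#' Build an untrained periodic U-Net surrogate
#'
#' Constructs the surrogate network: `depth` encoder levels of two circular
#' 3x3 convolutions with PReLU activations followed by 2x2 max pooling, a
#' bottleneck block, and a mirrored decoder of nearest-neighbor upsampling,
#' skip-connection concatenation and two further convolutions per level,
#' closed by a 1x1 convolution to the two output channels.  The mask channel
#' is produced as logits and mapped through a sigmoid at prediction time;
#' the field channel is linear (clipped at zero on output).  Weight
#' initialization is seeded and He-scaled.
#'
#' The published architecture is schematic, so the numerics here (depth 4,
#' base width 32 doubling per level, 3x3 kernels) are a standard U-Net
#' reconstruction, all configurable.
#'
#' @param depth number of down/upsampling levels; the lattice size must be
#'   divisible by `2^depth`.
#' @param baseChannels channels of the first level (doubling per level).
#' @param kernel odd convolution kernel size.
#' @param inChannels,outChannels I/O channels (two: mask and field).
#' @param horizon MCS the network advances per evaluation (metadata).
#' @param maskWeight,fieldWeight loss weights: binary cross-entropy on the
#'   mask channel and mean-squared error on the field channel (published
#'   weighting 1 and 10).
#' @param residual predict the change from the input frame rather than the
#'   frame itself: the input mask (scaled to logits `+-maskResidualScale`)
#'   and field are added to the corresponding output heads, and the head
#'   convolution starts at zero, so the untrained network is the identity
#'   map and training learns the 100-MCS update.  Standard practice for
#'   time-stepping surrogates; disable for a direct image-to-image network.
#' @param maskResidualScale logit magnitude representing the binary input
#'   mask on the residual path.
#' @param lr,batchSize Adam learning rate and minibatch size defaults used
#'   by [trainSurrogate()].
#' @param seed RNG seed for weight initialization.
#' @return an untrained [UNetSurrogate-class].
#' @examples
#' net <- buildSurrogate(depth = 2L, baseChannels = 4L, seed = 1)
#' net
#' @export
buildSurrogate <- function(depth = 4L, baseChannels = 32L, kernel = 3L,
                           inChannels = 2L, outChannels = 2L, horizon = 100,
                           maskWeight = 1, fieldWeight = 10,
                           residual = TRUE, maskResidualScale = 4,
                           lr = 1e-3, batchSize = 16L, seed = 1L) {
  if (kernel %% 2L != 1L) stop("kernel size must be odd")
  config <- list(depth = as.integer(depth), baseChannels = as.integer(baseChannels),
                 kernel = as.integer(kernel), inChannels = as.integer(inChannels),
                 outChannels = as.integer(outChannels), horizon = horizon,
                 maskWeight = maskWeight, fieldWeight = fieldWeight,
                 residual = isTRUE(residual), maskResidualScale = maskResidualScale,
                 lr = lr, batchSize = as.integer(batchSize), seed = as.integer(seed))
  set.seed(seed)
  new("UNetSurrogate", config = config, weights = .initWeights(config),
      history = data.frame())
}

.convBlockFwd <- function(w, name, x) {
  z1 <- cpp_conv_fwd(x, w[[paste0(name, ".conv1.w")]], w[[paste0(name, ".conv1.b")]])
  h1 <- .prelu(z1, w[[paste0(name, ".conv1.a")]])
  z2 <- cpp_conv_fwd(h1, w[[paste0(name, ".conv2.w")]], w[[paste0(name, ".conv2.b")]])
  h2 <- .prelu(z2, w[[paste0(name, ".conv2.a")]])
  list(out = h2, x = x, z1 = z1, h1 = h1, z2 = z2)
}

.convBlockBwd <- function(w, name, cache, dy, grads) {
  pb2 <- .preluBwd(dy, cache$z2, w[[paste0(name, ".conv2.a")]])
  grads[[paste0(name, ".conv2.a")]] <- grads[[paste0(name, ".conv2.a")]] + pb2$da
  cb2 <- cpp_conv_bwd(cache$h1, w[[paste0(name, ".conv2.w")]], pb2$dz)
  grads[[paste0(name, ".conv2.w")]] <- grads[[paste0(name, ".conv2.w")]] + cb2$dw
  grads[[paste0(name, ".conv2.b")]] <- grads[[paste0(name, ".conv2.b")]] + cb2$db
  pb1 <- .preluBwd(cb2$dx, cache$z1, w[[paste0(name, ".conv1.a")]])
  grads[[paste0(name, ".conv1.a")]] <- grads[[paste0(name, ".conv1.a")]] + pb1$da
  cb1 <- cpp_conv_bwd(cache$x, w[[paste0(name, ".conv1.w")]], pb1$dz)
  grads[[paste0(name, ".conv1.w")]] <- grads[[paste0(name, ".conv1.w")]] + cb1$dw
  grads[[paste0(name, ".conv1.b")]] <- grads[[paste0(name, ".conv1.b")]] + cb1$db
  list(dx = cb1$dx, grads = grads)
}

.unetForward <- function(w, config, x, keepCache = FALSE) {
  depth <- config$depth
  enc <- vector("list", depth)
  pools <- vector("list", depth)
  h <- x
  for (l in seq_len(depth)) {
    enc[[l]] <- .convBlockFwd(w, paste0("enc", l), h)
    pl <- cpp_maxpool_fwd(enc[[l]]$out)
    pools[[l]] <- pl$idx
    h <- pl$y
  }
  bot <- .convBlockFwd(w, "bot", h)
  h <- bot$out
  dec <- vector("list", depth)
  ups <- vector("list", depth)
  for (l in rev(seq_len(depth))) {
    up <- cpp_upsample_fwd(h)
    zu <- cpp_conv_fwd(up, w[[paste0("dec", l, ".up.w")]], w[[paste0("dec", l, ".up.b")]])
    hu <- .prelu(zu, w[[paste0("dec", l, ".up.a")]])
    skip <- enc[[l]]$out
    cat3 <- array(c(hu, skip), dim = c(dim(hu)[1], dim(hu)[2],
                                       dim(hu)[3] + dim(skip)[3]))
    dec[[l]] <- .convBlockFwd(w, paste0("dec", l), cat3)
    ups[[l]] <- list(up = up, zu = zu, nup = dim(hu)[3])
    h <- dec[[l]]$out
  }
  out <- cpp_conv_fwd(h, w[["head.w"]], w[["head.b"]])
  if (isTRUE(config$residual)) {
    out[, , 1] <- out[, , 1] + config$maskResidualScale * (2 * x[, , 1] - 1)
    out[, , 2] <- out[, , 2] + x[, , 2]
  }
  if (!keepCache) return(list(out = out))
  list(out = out, enc = enc, pools = pools, bot = bot, dec = dec, ups = ups)
}

.unetBackward <- function(w, config, cache, dout, grads) {
  depth <- config$depth
  hb <- cpp_conv_bwd(cache$dec[[1]]$out, w[["head.w"]], dout)
  grads[["head.w"]] <- grads[["head.w"]] + hb$dw
  grads[["head.b"]] <- grads[["head.b"]] + hb$db
  dh <- hb$dx
  dskip <- vector("list", depth)
  for (l in seq_len(depth)) {
    bb <- .convBlockBwd(w, paste0("dec", l), cache$dec[[l]], dh, grads)
    grads <- bb$grads
    nup <- cache$ups[[l]]$nup
    dcat <- bb$dx
    dhu <- dcat[, , seq_len(nup), drop = FALSE]
    dskip[[l]] <- dcat[, , nup + seq_len(dim(dcat)[3] - nup), drop = FALSE]
    pb <- .preluBwd(dhu, cache$ups[[l]]$zu, w[[paste0("dec", l, ".up.a")]])
    grads[[paste0("dec", l, ".up.a")]] <- grads[[paste0("dec", l, ".up.a")]] + pb$da
    cb <- cpp_conv_bwd(cache$ups[[l]]$up, w[[paste0("dec", l, ".up.w")]], pb$dz)
    grads[[paste0("dec", l, ".up.w")]] <- grads[[paste0("dec", l, ".up.w")]] + cb$dw
    grads[[paste0("dec", l, ".up.b")]] <- grads[[paste0("dec", l, ".up.b")]] + cb$db
    dh <- cpp_upsample_bwd(cb$dx)
  }
  bb <- .convBlockBwd(w, "bot", cache$bot, dh, grads)
  grads <- bb$grads
  dh <- bb$dx
  for (l in rev(seq_len(depth))) {
    dEncOut <- cpp_maxpool_bwd(dh, cache$pools[[l]],
                               dim(cache$enc[[l]]$out)[1],
                               dim(cache$enc[[l]]$out)[2]) + dskip[[l]]
    bb <- .convBlockBwd(w, paste0("enc", l), cache$enc[[l]], dEncOut, grads)
    grads <- bb$grads
    dh <- bb$dx
  }
  grads
}

.frameToArray <- function(frame)
  array(c(frame@mask, frame@field), dim = c(dim(frame@mask), 2L))

.sigmoid <- function(z) 1 / (1 + exp(-z))

# stable BCE from logits plus its gradient, and the weighted field MSE
.lossAndGrad <- function(out, target, maskWeight, fieldWeight) {
  zm <- out[, , 1]
  pf <- out[, , 2]
  ym <- target[, , 1]
  yf <- target[, , 2]
  n <- length(zm)
  bce <- mean(pmax(zm, 0) - zm * ym + log1p(exp(-abs(zm))))
  mse <- mean((pf - yf)^2)
  dout <- array(0, dim = dim(out))
  dout[, , 1] <- maskWeight * (.sigmoid(zm) - ym) / n
  dout[, , 2] <- fieldWeight * 2 * (pf - yf) / n
  list(loss = maskWeight * bce + fieldWeight * mse, bce = bce, mse = mse,
       dout = dout)
}

#' Composite surrogate loss
#'
#' Binary cross-entropy between the predicted mask probabilities and the
#' binary target mask, plus `fieldWeight` (default 10) times the
#' mean-squared error of the field channel.
#'
#' @param prediction,target [TwoChannelFrame-class] objects of one shape;
#'   the target mask must be strictly binary.
#' @param maskWeight,fieldWeight loss weights (defaults 1 and 10).
#' @param eps probability clipping bound inside the logarithms.
#' @return the loss, with components attached as attributes `bce` and `mse`.
#' @examples
#' m <- matrix(c(1, 0, 0, 1), 2)
#' f1 <- new("TwoChannelFrame", mask = m, field = m * 0, mcs = 0,
#'           simId = "a", normalization = 1)
#' compositeLoss(f1, f1) < 1e-10
#' @export
compositeLoss <- function(prediction, target, maskWeight = 1, fieldWeight = 10,
                          eps = 1e-12) {
  stopifnot(is(prediction, "TwoChannelFrame"), is(target, "TwoChannelFrame"))
  if (!identical(dim(prediction@mask), dim(target@mask))) stop("shape mismatch")
  if (!all(target@mask %in% c(0, 1))) stop("target mask must be binary")
  p <- pmin(pmax(prediction@mask, eps), 1 - eps)
  bce <- -mean(target@mask * log(p) + (1 - target@mask) * log(1 - p))
  mse <- mean((prediction@field - target@field)^2)
  structure(maskWeight * bce + fieldWeight * mse, bce = bce, mse = mse)
}

.adamStep <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(weights)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    weights[[nm]] <- weights[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(weights = weights, state = state)
}

.zeroLike <- function(weights) lapply(weights, function(x) x * 0)

#' Train the surrogate on a paired dataset
#'
#' Seeded minibatch Adam on the train split of `dataset`, minimizing the
#' combined mask binary cross-entropy and 10x-weighted field MSE.  The test
#' split is scored once per epoch.  Training aborts with a diagnostic if the
#' loss turns non-finite.
#'
#' @param model an untrained (or previously trained) [UNetSurrogate-class].
#' @param dataset a [PairDataset-class] with a non-empty train split.
#' @param epochs training epochs (published protocol: 100).
#' @param lr,batchSize optimizer settings; default from the model config.
#' @param lrDecay multiplicative learning-rate factor applied after each
#'   epoch (1 = constant); a mild decay (e.g. 0.85 over ~20 epochs) settles
#'   the boundary-probability calibration at the end of training.
#' @param seed RNG seed for shuffling (weight init is seeded separately in
#'   [buildSurrogate()]).
#' @param maxTestPairs cap on test pairs scored per epoch (for speed).
#' @param verbose print per-epoch losses.
#' @return the trained [UNetSurrogate-class] with its `history` filled
#'   (per-epoch train/test loss and components, wall time).
#' @export
trainSurrogate <- function(model, dataset, epochs = 100, lr = NULL,
                           batchSize = NULL, seed = 1L, lrDecay = 1,
                           maxTestPairs = 200L, verbose = FALSE) {
  stopifnot(is(model, "UNetSurrogate"), is(dataset, "PairDataset"))
  if (!length(dataset@trainIdx)) stop("dataset has an empty train split")
  config <- model@config
  if (is.null(lr)) lr <- config$lr
  if (is.null(batchSize)) batchSize <- config$batchSize
  sz <- dim(dataset@frames[[1]]@mask)
  if (any(sz %% 2^config$depth != 0))
    stop("lattice size must be divisible by 2^depth = ", 2^config$depth)
  w <- model@weights
  state <- list(t = 0, m = .zeroLike(w), v = .zeroLike(w))
  set.seed(seed)
  history <- vector("list", epochs)
  testIdx <- dataset@testIdx
  if (length(testIdx) > maxTestPairs) testIdx <- testIdx[seq_len(maxTestPairs)]
  pairArrays <- function(i) {
    pr <- dataset@pairs[i, ]
    list(x = .frameToArray(dataset@frames[[pr[1]]]),
         y = .frameToArray(dataset@frames[[pr[2]]]))
  }
  for (ep in seq_len(epochs)) {
    t0 <- proc.time()[["elapsed"]]
    order <- sample(dataset@trainIdx)
    batches <- split(order, ceiling(seq_along(order) / batchSize))
    epLoss <- epBce <- epMse <- 0
    for (bt in batches) {
      grads <- .zeroLike(w)
      bl <- 0
      for (i in bt) {
        pa <- pairArrays(i)
        fwd <- .unetForward(w, config, pa$x, keepCache = TRUE)
        lg <- .lossAndGrad(fwd$out, pa$y, config$maskWeight, config$fieldWeight)
        if (!is.finite(lg$loss))
          stop(sprintf("training diverged (non-finite loss) at epoch %d; lower lr (%.3g)", ep, lr))
        grads <- .unetBackward(w, config, fwd, lg$dout / length(bt), grads)
        bl <- bl + lg$loss
        epLoss <- epLoss + lg$loss; epBce <- epBce + lg$bce; epMse <- epMse + lg$mse
      }
      up <- .adamStep(w, grads, state, lr)
      w <- up$weights
      state <- up$state
    }
    lr <- lr * lrDecay
    ntr <- length(order)
    testLoss <- testBce <- testMse <- NA_real_
    if (length(testIdx)) {
      tl <- tb <- tm <- 0
      for (i in testIdx) {
        pa <- pairArrays(i)
        fwd <- .unetForward(w, config, pa$x)
        lg <- .lossAndGrad(fwd$out, pa$y, config$maskWeight, config$fieldWeight)
        tl <- tl + lg$loss; tb <- tb + lg$bce; tm <- tm + lg$mse
      }
      testLoss <- tl / length(testIdx); testBce <- tb / length(testIdx)
      testMse <- tm / length(testIdx)
    }
    history[[ep]] <- data.frame(
      epoch = ep, trainLoss = epLoss / ntr, trainBce = epBce / ntr,
      trainMse = epMse / ntr, testLoss = testLoss, testBce = testBce,
      testMse = testMse, seconds = proc.time()[["elapsed"]] - t0)
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  test %s  (%.1fs)", ep,
                      epLoss / ntr,
                      ifelse(is.na(testLoss), "-", sprintf("%.5f", testLoss)),
                      history[[ep]]$seconds))
  }
  new("UNetSurrogate", config = model@config, weights = w,
      history = rbind(model@history, do.call(rbind, history)))
}

#' Predict one horizon ahead
#'
#' Runs the surrogate once on a two-channel frame, returning the predicted
#' frame one horizon (nominally 100 MCS) later.  The mask channel holds
#' occupancy probabilities in (0, 1) - binarization is left to the metrics -
#' and the field channel is clipped at zero to respect non-negativity.
#'
#' @param model a [UNetSurrogate-class].
#' @param frame a [TwoChannelFrame-class] whose shape is divisible by
#'   `2^depth`.
#' @return the predicted [TwoChannelFrame-class].
#' @export
predictFrame <- function(model, frame) {
  stopifnot(is(model, "UNetSurrogate"), is(frame, "TwoChannelFrame"))
  sz <- dim(frame@mask)
  if (any(sz %% 2^model@config$depth != 0))
    stop("frame size must be divisible by 2^depth = ", 2^model@config$depth)
  out <- .unetForward(model@weights, model@config, .frameToArray(frame))$out
  new("TwoChannelFrame",
      mask = .sigmoid(out[, , 1]), field = pmax(out[, , 2], 0),
      mcs = frame@mcs + model@config$horizon, simId = frame@simId,
      normalization = frame@normalization)
}

#' Recursive surrogate rollout
#'
#' Applies the surrogate iteratively, feeding each prediction back as the
#' next input.  By default the continuous mask probabilities are fed back
#' unthresholded (the smoothing they carry is part of the surrogate's
#' documented failure mode at long horizons); `binarize = TRUE` thresholds
#' the mask at 0.5 between iterations instead.
#'
#' @param model a [UNetSurrogate-class] or a function mapping a frame to
#'   the next frame.
#' @param frame the initial [TwoChannelFrame-class].
#' @param nIterations number of recursive steps (>= 1).
#' @param binarize threshold the fed-back mask at 0.5.
#' @return list of `nIterations` predicted frames at nominal MCS
#'   `t0 + horizon`, `t0 + 2 horizon`, ...
#' @export
rolloutSurrogate <- function(model, frame, nIterations, binarize = FALSE) {
  stopifnot(nIterations >= 1)
  predictor <- if (is.function(model)) model else function(fr) predictFrame(model, fr)
  frames <- vector("list", nIterations)
  for (i in seq_len(nIterations)) {
    frame <- predictor(frame)
    frames[[i]] <- frame
    if (binarize && i < nIterations) frame@mask <- (frame@mask >= 0.5) + 0
  }
  frames
}

.MODEL_FORMAT <- 1L

#' Persist and reload surrogate checkpoints
#'
#' RDS containers with a format stamp; the round trip is exact.
#'
#' @param model a [UNetSurrogate-class].
#' @param path file path.
#' @return `saveSurrogate()` returns `path` invisibly; `loadSurrogate()`
#'   the model.
#' @export
saveSurrogate <- function(model, path) {
  stopifnot(is(model, "UNetSurrogate"))
  saveRDS(list(format = .MODEL_FORMAT, model = model), path)
  invisible(path)
}

#' @rdname saveSurrogate
#' @export
loadSurrogate <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, .MODEL_FORMAT))
    stop("not a cpmunet surrogate checkpoint (or unsupported format version)")
  obj$model
}
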