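#' U-Net model specification
#'
#' Configuration of the bundled U-Net predictor. Defaults reproduce the
#' reference architecture and hyperparameters: 3x3 (2D/2.5D) or 3x3x3 (3D)
#' convolutions with stride 1 and zero padding, 2x max pooling, 4 levels,
#' 32 first-layer features, ReLU activations, nearest upsampling followed
#' by convolution, a dual-class softmax output, Adam with binary
#' cross-entropy at initial learning rate 1e-4, batch 12 (2D/2.5D) or 6
#' (3D), 150 (2D/2.5D) or 200 (3D) epochs, learning-rate decay by 0.95
#' after 10 stalled validation epochs and early stopping after 50. The
#' default input sizes (512 x 512 in-plane, 64 x 64 x 128 patches) are
#' configuration, not a constraint: the network is fully convolutional and
#' runs on any input whose spatial extent is divisible by 2^(depth - 1).
#'
#' @param mode "2d" (single-slice input), "2.5d" (three-channel axial
#'   slabs) or "3d" (volumetric patches).
#' @param depth number of resolution levels (>= 1).
#' @param firstFeatures feature channels at the first level (>= 1).
#' @param inputShape expected spatial input extent (informational; used for
#'   validation at build time).
#' @param view anatomical view for 2d mode ("axial", "coronal",
#'   "sagittal").
#' @param patchShape patch shape for 3d mode.
#' @param lr0 initial Adam learning rate.
#' @param batch mini-batch size.
#' @param epochs epoch cap.
#' @param lrFactor,lrPatience plateau decay factor and window (epochs).
#' @param esPatience early-stopping window (epochs).
#' @param tau binarisation threshold for \code{\link{binarize}}.
#' @return A list of class "unetSpec".
#' @export
unetSpec <- function(mode = c("2d", "2.5d", "3d"),
                     depth = 4L, firstFeatures = 32L,
                     inputShape = NULL, view = "axial",
                     patchShape = c(64L, 64L, 128L),
                     lr0 = 1e-4, batch = NULL, epochs = NULL,
                     lrFactor = 0.95, lrPatience = 10L, esPatience = 50L,
                     tau = 0.5) {
  mode <- match.arg(mode)
  if (is.null(inputShape))
    inputShape <- if (mode == "3d") patchShape else c(512L, 512L)
  if (is.null(batch)) batch <- if (mode == "3d") 6L else 12L
  if (is.null(epochs)) epochs <- if (mode == "3d") 200L else 150L
  spec <- list(mode = mode, nd = if (mode == "3d") 3L else 2L,
               channels = if (mode == "2.5d") 3L else 1L,
               depth = as.integer(depth),
               firstFeatures = as.integer(firstFeatures),
               inputShape = as.integer(inputShape), view = view,
               patchShape = as.integer(patchShape), lr0 = lr0,
               batch = as.integer(batch), epochs = as.integer(epochs),
               lrFactor = lrFactor, lrPatience = as.integer(lrPatience),
               esPatience = as.integer(esPatience), tau = tau)
  class(spec) <- "unetSpec"
  .checkSpec(spec)
  spec
}

.checkSpec <- function(spec) {
  if (spec$depth < 1L) stop("spec error: depth must be >= 1")
  if (spec$firstFeatures < 1L) stop("spec error: firstFeatures must be >= 1")
  if (spec$batch < 1L) stop("spec error: batch must be >= 1")
  if (spec$lr0 <= 0) stop("spec error: lr0 must be > 0")
  div <- 2L^(spec$depth - 1L)
  if (any(spec$inputShape %% div != 0L))
    stop("spec error: spatial extent ",
         paste(spec$inputShape, collapse = "x"),
         " not divisible by 2^(depth-1) = ", div)
  if (spec$mode == "2d" && !spec$view %in% c("axial", "coronal", "sagittal"))
    stop("spec error: unknown view ", spec$view)
  invisible(spec)
}

#' Map HU intensities to the unit interval for network input
#'
#' Clamps to [-1000, 3100] HU (air to metal) and rescales linearly to
#' [0, 1]. Applied to every frame/patch before inference so the network
#' sees a fixed intensity scale.
#'
#' @param x numeric array of HU values.
#' @return Array of the same shape with values in [0, 1].
#' @export
normalizeHU <- function(x) {
  (pmin(pmax(x, -1000), 3100) + 1000) / 4100
}

#' Build an untrained U-Net predictor
#'
#' Constructs the network of the given specification: per level two
#' convolutions each followed by ReLU, downsampling by 2x max pooling,
#' nearest upsampling followed by convolution with skip concatenation on
#' the way up, and a final 1x1(x1) convolution to a dual-class softmax.
#' Parameter initialisation (He normal) is driven entirely by \code{seed},
#' so two builds with the same seed predict identically.
#'
#' @param spec a \code{\link{unetSpec}}.
#' @param seed integer RNG seed for weight initialisation.
#' @param name identifier used when the predictor's masks join a
#'   \linkS4class{PredictionSet}.
#' @return A list of class "unetPredictor" with the spec, the layer graph
#'   and the name.
#' @export
buildPredictor <- function(spec, seed = 1L, name = spec$mode) {
  stopifnot(inherits(spec, "unetSpec"))
  .checkSpec(spec)
  nd <- spec$nd
  FF <- spec$firstFeatures
  net <- .withSeed(seed, {
    enc <- vector("list", spec$depth)
    cin <- spec$channels
    for (l in seq_len(spec$depth)) {
      cout <- FF * 2L^(l - 1L)
      enc[[l]] <- list(c1 = .newConv(3L, nd, cin, cout, TRUE),
                       c2 = .newConv(3L, nd, cout, cout, TRUE))
      cin <- cout
    }
    dec <- vector("list", max(spec$depth - 1L, 0L))
    for (l in rev(seq_len(spec$depth - 1L))) {
      cHere <- FF * 2L^(l - 1L)
      dec[[l]] <- list(
        up = .newConv(3L, nd, cHere * 2L, cHere, TRUE),
        c1 = .newConv(3L, nd, cHere * 2L, cHere, TRUE),
        c2 = .newConv(3L, nd, cHere, cHere, TRUE))
    }
    out <- .newConv(1L, nd, FF, 2L, FALSE)
    list(enc = enc, dec = dec, out = out)
  })
  pred <- list(spec = spec, net = net, name = name)
  class(pred) <- "unetPredictor"
  pred
}

.allLayers <- function(net) {
  ls <- list()
  for (lv in net$enc) ls <- c(ls, lv)
  for (lv in net$dec) ls <- c(ls, lv)
  c(ls, list(net$out))
}

#' Number of trainable parameters of a predictor
#'
#' @param pred a predictor from \code{\link{buildPredictor}}.
#' @return Total count of convolution weights and biases.
#' @export
countParams <- function(pred) {
  sum(vapply(.allLayers(pred$net), function(L)
    length(L$W) + length(L$b), numeric(1)))
}

# Forward pass on one sample; returns foreground probabilities and, when
# train = TRUE, the caches needed for backprop.
.unetForward <- function(pred, x, train = FALSE) {
  nd <- pred$spec$nd
  depth <- pred$spec$depth
  net <- pred$net
  skips <- vector("list", max(depth - 1L, 0L))
  caches <- list(enc = vector("list", depth),
                 pool = vector("list", max(depth - 1L, 0L)),
                 dec = vector("list", max(depth - 1L, 0L)))
  h <- x
  for (l in seq_len(depth)) {
    f1 <- .convForward(net$enc[[l]]$c1, h)
    f2 <- .convForward(net$enc[[l]]$c2, f1$y)
    h <- f2$y
    if (train) caches$enc[[l]] <- list(c1 = f1$cache, c2 = f2$cache)
    if (l < depth) {
      skips[[l]] <- h
      p <- .poolForward(h, nd)
      h <- p$y
      if (train) caches$pool[[l]] <- p$cache
    }
  }
  for (l in rev(seq_len(depth - 1L))) {
    u <- .upForward(h, nd)
    fu <- .convForward(net$dec[[l]]$up, u)
    cc <- .concatChannels(fu$y, skips[[l]], nd)
    f1 <- .convForward(net$dec[[l]]$c1, cc)
    f2 <- .convForward(net$dec[[l]]$c2, f1$y)
    h <- f2$y
    if (train)
      caches$dec[[l]] <- list(up = fu$cache, c1 = f1$cache, c2 = f2$cache,
                              cSkip = dim(skips[[l]])[nd + 1L])
  }
  fo <- .convForward(net$out, h)
  logits <- fo$y
  sp <- dim(logits)[seq_len(nd)]
  l1 <- array(logits[.channelIndex(logits, 1L, nd)], sp)
  l2 <- array(logits[.channelIndex(logits, 2L, nd)], sp)
  p <- stats::plogis(l2 - l1)
  if (train) {
    caches$out <- fo$cache
    list(p = p, caches = caches)
  } else {
    list(p = p)
  }
}

.channelIndex <- function(a, ch, nd) {
  P <- prod(dim(a)[seq_len(nd)])
  (ch - 1L) * P + seq_len(P)
}

# Backward pass for one sample given target y (0/1 array) and the caches;
# accumulates gradients in the layer environments and returns the BCE loss.
.unetBackward <- function(pred, fw, y) {
  nd <- pred$spec$nd
  depth <- pred$spec$depth
  net <- pred$net
  p <- fw$p
  P <- length(p)
  eps <- 1e-12
  loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  g <- (p - y) / P          # d loss / d (l2 - l1)
  sp <- dim(p)
  dLogits <- array(0, c(sp, 2L))
  dLogits[.channelIndex(dLogits, 1L, nd)] <- -g
  dLogits[.channelIndex(dLogits, 2L, nd)] <- g
  h <- .convBackward(net$out, fw$caches$out, dLogits)
  dSkip <- vector("list", max(depth - 1L, 0L))
  for (l in seq_len(depth - 1L)) {        # decoders, shallow to deep
    cc <- fw$caches$dec[[l]]
    h <- .convBackward(net$dec[[l]]$c2, cc$c2, h)
    h <- .convBackward(net$dec[[l]]$c1, cc$c1, h)
    parts <- .splitChannels(h, net$dec[[l]]$up$cOut, nd)
    dSkip[[l]] <- parts[[2]]
    du <- .convBackward(net$dec[[l]]$up, cc$up, parts[[1]])
    h <- .upBackward(du, nd)
  }
  for (l in rev(seq_len(depth))) {        # encoders, deep to shallow
    h <- .convBackward(net$enc[[l]]$c2, fw$caches$enc[[l]]$c2, h)
    h <- .convBackward(net$enc[[l]]$c1, fw$caches$enc[[l]]$c1, h)
    if (l > 1L)
      h <- .poolBackward(fw$caches$pool[[l - 1L]], h, nd) + dSkip[[l - 1L]]
  }
  loss
}

.bceLoss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

# --- plateau / early-stop callbacks ------------------------------------

.cbInit <- function(lr0) {
  list(best = Inf, wait = 0L, esWait = 0L, lr = lr0, seen = 0L, stop = FALSE)
}

# One epoch-end update. The first observed loss is the baseline and counts
# toward the stall window, so a validation loss frozen from epoch 1 decays
# the learning rate at epochs 10, 20, ... and stops training at epoch 50
# under the default windows.
.cbStep <- function(cb, val, factor, patience, esPatience) {
  improved <- cb$seen > 0L && val < cb$best
  if (cb$seen == 0L) cb$best <- val
  cb$seen <- cb$seen + 1L
  if (improved) {
    cb$best <- val
    cb$wait <- 0L
    cb$esWait <- 0L
  } else {
    cb$wait <- cb$wait + 1L
    cb$esWait <- cb$esWait + 1L
  }
  if (cb$wait >= patience) {
    cb$lr <- cb$lr * factor
    cb$wait <- 0L
  }
  if (cb$esWait >= esPatience) cb$stop <- TRUE
  cb
}

#' Learning-rate schedule implied by a validation-loss trajectory
#'
#' Pure replay of the training callbacks (reduce-on-plateau by
#' \code{factor} after \code{patience} stalled epochs; early stop after
#' \code{esPatience}) over a given sequence of validation losses. Useful
#' for auditing the scheduler arithmetic: a frozen loss sequence yields
#' lr0 * factor^2 after 20 epochs and a halt at epoch 50 with the
#' defaults.
#'
#' @param valLosses numeric vector of per-epoch validation losses.
#' @param lr0 initial learning rate.
#' @param factor multiplicative decay (default 0.95).
#' @param patience stalled-epoch window for decay (default 10).
#' @param esPatience stalled-epoch window for early stopping (default 50).
#' @return A data.frame with columns epoch, lr (rate in force during that
#'   epoch's update), and attribute "stopEpoch" (NA if never triggered).
#' @export
plateauSchedule <- function(valLosses, lr0, factor = 0.95, patience = 10L,
                            esPatience = 50L) {
  cb <- .cbInit(lr0)
  lrs <- numeric(0)
  stopEpoch <- NA_integer_
  for (e in seq_along(valLosses)) {
    lrs <- c(lrs, cb$lr)
    cb <- .cbStep(cb, valLosses[e], factor, patience, esPatience)
    if (cb$stop) { stopEpoch <- e; break }
  }
  out <- data.frame(epoch = seq_along(lrs), lr = lrs,
                    lrAfter = utils::head(c(lrs[-1], cb$lr), length(lrs)))
  attr(out, "stopEpoch") <- stopEpoch
  attr(out, "finalLr") <- cb$lr
  out
}

#' Train a U-Net predictor
#'
#' Optimises binary cross-entropy with Adam at the spec's initial learning
#' rate. After any \code{lrPatience}-epoch window without validation-loss
#' improvement the learning rate is multiplied by \code{lrFactor}; training
#' stops early after \code{esPatience} stalled epochs or at the epoch cap.
#' Gradients are averaged over mini-batches of the spec's batch size;
#' sample order is reshuffled each epoch under the given seed, so repeated
#' runs are bit-identical.
#'
#' @param pred an (untrained or trained) predictor from
#'   \code{\link{buildPredictor}}.
#' @param trainPairs,valPairs lists of \code{list(x = input array with
#'   channel dimension, y = binary target array)}; see
#'   \code{\link{makeTrainingPairs}}. Inputs are expected on the
#'   \code{\link{normalizeHU}} scale.
#' @param epochs optional override of the spec's epoch cap.
#' @param seed RNG seed for shuffling.
#' @param verbose print per-epoch losses.
#' @return A list with elements \code{predictor} (updated in place) and
#'   \code{history} (data.frame epoch, loss, valLoss, lr).
#' @export
trainPredictor <- function(pred, trainPairs, valPairs, epochs = NULL,
                           seed = 1L, verbose = FALSE) {
  stopifnot(inherits(pred, "unetPredictor"))
  spec <- pred$spec
  if (length(trainPairs) == 0L || length(valPairs) == 0L)
    stop("data error: empty training or validation set")
  for (pr in c(trainPairs, valPairs))
    if (!all(pr$y %in% c(0, 1)))
      stop("data error: targets must be binary")
  if (is.null(epochs)) epochs <- spec$epochs
  layers <- .allLayers(pred$net)
  cb <- .cbInit(spec$lr0)
  t <- 0L
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     valLoss = numeric(0), lr = numeric(0))
  orders <- .withSeed(seed, lapply(seq_len(epochs), function(e)
    sample(length(trainPairs))))
  for (e in seq_len(epochs)) {
    ord <- orders[[e]]
    lossSum <- 0
    i <- 1L
    while (i <= length(ord)) {
      batch <- ord[i:min(i + spec$batch - 1L, length(ord))]
      .zeroGrads(layers)
      for (j in batch) {
        pr <- trainPairs[[j]]
        fw <- .unetForward(pred, pr$x, train = TRUE)
        lossSum <- lossSum + .unetBackward(pred, fw, pr$y)
      }
      t <- t + 1L
      .adamStep(layers, cb$lr, scale = 1 / length(batch), t = t)
      i <- i + spec$batch
    }
    valLoss <- mean(vapply(valPairs, function(pr)
      .bceLoss(.unetForward(pred, pr$x)$p, pr$y), numeric(1)))
    hist <- rbind(hist, data.frame(
      epoch = e, loss = lossSum / length(ord), valLoss = valLoss, lr = cb$lr))
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f  val %.5f  lr %.2e",
                      e, lossSum / length(ord), valLoss, cb$lr))
    cb <- .cbStep(cb, valLoss, spec$lrFactor, spec$lrPatience, spec$esPatience)
    if (cb$stop) break
  }
  list(predictor = pred, history = hist)
}

#' Build training pairs from a volume and its ground-truth mask
#'
#' Decomposes the volume according to the predictor mode (view slices,
#' 2.5D slabs, or 3D patches), normalises intensities with
#' \code{\link{normalizeHU}} and pairs each frame/patch with its target.
#'
#' @param vol a \linkS4class{ScanVolume}.
#' @param mask the matching ground-truth \linkS4class{BinaryMask}.
#' @param spec a \code{\link{unetSpec}} (decides the decomposition).
#' @param keep optional integer indices of frames/patches to keep.
#' @return List of \code{list(x, y)} pairs for
#'   \code{\link{trainPredictor}}.
#' @export
makeTrainingPairs <- function(vol, mask, spec, keep = NULL) {
  stopifnot(is(vol, "ScanVolume"), is(mask, "BinaryMask"))
  .checkCongruent(vol, mask, "volume and mask")
  pairs <- switch(spec$mode,
    "2d" = {
      vs <- extractSlices(vol, spec$view)
      ms <- extractSlices(mask, spec$view)
      lapply(seq_along(vs@frames), function(i) {
        x <- normalizeHU(vs@frames[[i]])
        dim(x) <- c(dim(x), 1L)
        list(x = x, y = ms@frames[[i]] * 1)
      })
    },
    "2.5d" = {
      sl <- makeSlabs(vol)
      ms <- extractSlices(mask, "axial")
      lapply(seq_along(sl@frames), function(i)
        list(x = normalizeHU(sl@frames[[i]]), y = ms@frames[[i]] * 1))
    },
    "3d" = {
      vg <- tilePatches(vol, spec$patchShape)
      mg <- tilePatches(mask, spec$patchShape)
      lapply(seq_along(vg@patches), function(i) {
        x <- normalizeHU(vg@patches[[i]])
        dim(x) <- c(dim(x), 1L)
        list(x = x, y = mg@patches[[i]] * 1)
      })
    })
  if (!is.null(keep)) pairs <- pairs[keep]
  pairs
}

#' Predict a foreground-probability volume
#'
#' Decomposes the volume per the predictor's mode (2d: slices of the
#' spec's view; 2.5d: three-channel axial slabs; 3d: non-overlapping
#' patches with trailing zero padding), runs inference frame by frame and
#' reassembles a full-volume probability map in [0, 1].
#'
#' @param pred a predictor from \code{\link{buildPredictor}}.
#' @param vol a \linkS4class{ScanVolume}.
#' @return A \linkS4class{ScanVolume} of foreground probabilities with the
#'   source shape.
#' @export
predictVolume <- function(pred, vol) {
  stopifnot(inherits(pred, "unetPredictor"), is(vol, "ScanVolume"))
  spec <- pred$spec
  div <- 2L^(spec$depth - 1L)
  if (spec$mode == "2d") {
    vs <- extractSlices(vol, spec$view)
    sh <- dim(vs@frames[[1]])
    if (any(sh %% div != 0L))
      stop("spec error: frame shape ", paste(sh, collapse = "x"),
           " not divisible by 2^(depth-1)")
    probs <- lapply(vs@frames, function(f) {
      x <- normalizeHU(f)
      dim(x) <- c(dim(x), 1L)
      .unetForward(pred, x)$p
    })
    out <- new("ViewStack", view = spec$view, frames = probs,
               indexMap = vs@indexMap, sourceDim = vs@sourceDim,
               kind = "volume", spacing = vs@spacing)
    stackToVolume(out)
  } else if (spec$mode == "2.5d") {
    sl <- makeSlabs(vol)
    sh <- dim(sl@frames[[1]])[1:2]
    if (any(sh %% div != 0L))
      stop("spec error: frame shape ", paste(sh, collapse = "x"),
           " not divisible by 2^(depth-1)")
    probs <- lapply(sl@frames, function(f) .unetForward(pred, normalizeHU(f))$p)
    out <- new("ViewStack", view = "axial", frames = probs,
               indexMap = sl@indexMap, sourceDim = sl@sourceDim,
               kind = "volume", spacing = sl@spacing)
    stackToVolume(out)
  } else {
    if (any(spec$patchShape %% div != 0L))
      stop("spec error: patch shape not divisible by 2^(depth-1)")
    vg <- tilePatches(vol, spec$patchShape)
    probs <- lapply(vg@patches, function(p) {
      x <- normalizeHU(p)
      dim(x) <- c(dim(x), 1L)
      .unetForward(pred, x)$p
    })
    out <- new("PatchGrid", patchShape = vg@patchShape, patches = probs,
               offsets = vg@offsets, pad = vg@pad, sourceDim = vg@sourceDim,
               kind = "volume", spacing = vg@spacing)
    assemblePatches(out)
  }
}

#' Binarise a probability volume
#'
#' Thresholds the foreground probability at tau; a voxel exactly at tau is
#' foreground, so the default tau = 0.5 reproduces the dual-class softmax
#' argmax with ties resolved to foreground.
#'
#' @param prob a \linkS4class{ScanVolume} of probabilities in [0, 1].
#' @param tau threshold strictly inside (0, 1); default 0.5.
#' @return A \linkS4class{BinaryMask}.
#' @export
binarize <- function(prob, tau = 0.5) {
  stopifnot(is(prob, "ScanVolume"))
  if (!is.finite(tau) || tau <= 0 || tau >= 1)
    stop("parameter error: tau must lie strictly inside (0, 1)")
  rng <- range(prob@data)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("probability volume has values outside [0, 1]")
  BinaryMask(prob@data >= tau, prob@spacing)
}
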