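#' Segmentation training configuration
#'
#' Defaults mirror the full-scale training recipe of the CAD system
#' (Adam, learning rate 1e-5, 500 epochs, weight decay 5e-4, cross-entropy
#' loss); desk-scale runs on small phantoms override the learning rate and
#' epoch count, since a shallow network on 32-pixel images trains at a much
#' larger step size.
#'
#' @param learningRate Adam step size (> 0).
#' @param epochs number of passes over the training set (>= 1).
#' @param weightDecay additive L2 weight-decay coefficient.
#' @param optimizer only "adam" is implemented.
#' @param loss only "cross_entropy" (pixel-wise binary) is implemented.
#' @param encoderDepth number of downsampling stages (>= 2).
#' @param baseChannels channels of the first encoder block.
#' @param seed integer seed for weight initialization.
#' @return list of class \code{segTrainConfig}.
#' @export
segTrainConfig <- function(learningRate = 1e-5, epochs = 500L,
                           weightDecay = 5e-4, optimizer = "adam",
                           loss = "cross_entropy", encoderDepth = 2L,
                           baseChannels = 8L, seed = 1L) {
  stopifnot(learningRate > 0, epochs >= 1, encoderDepth >= 2,
            baseChannels >= 1, optimizer == "adam",
            loss == "cross_entropy")
  structure(list(learningRate = learningRate, epochs = as.integer(epochs),
                 weightDecay = weightDecay, optimizer = optimizer,
                 loss = loss, encoderDepth = as.integer(encoderDepth),
                 baseChannels = as.integer(baseChannels),
                 seed = as.integer(seed)),
            class = "segTrainConfig")
}

#' Train the encoder-decoder segmenter
#'
#' Trains a small U-Net-style network: residual conv units with 2x
#' max-pooling in the encoder, stepwise 2x nearest-neighbour upsampling
#' with skip connections in the decoder, and a 1x1 convolution head
#' producing per-pixel foreground logits. Optimized with Adam on the
#' pixel-wise binary cross-entropy against the ground-truth masks, one
#' image per step, in fixed case order — training is fully deterministic
#' given the config seed.
#'
#' @param cases list of \linkS4class{LesionImage} objects with ground-truth
#'   masks; all images must share dimensions divisible by
#'   \code{2^encoderDepth}.
#' @param config a \code{\link{segTrainConfig}}.
#' @return a \linkS4class{SegmenterModel} carrying the per-epoch loss trace.
#' @export
trainSegmenter <- function(cases, config = segTrainConfig()) {
  stopifnot(length(cases) >= 1)
  dims <- dim(lesionPixels(cases[[1]]))
  for (i in seq_along(cases)) {
    img <- lesionPixels(cases[[i]])
    msk <- lesionMask(cases[[i]])
    if (is.null(msk))
      stopWithClass("missingMaskError",
                    "training case %d has no ground-truth mask", i)
    if (!identical(dim(img), dims) || !identical(dim(msk), dims))
      stopWithClass("dimensionError",
                    "image/mask dimensions of case %d differ from case 1", i)
  }
  depth <- config$encoderDepth
  if (any(dims %% 2^depth != 0))
    stopWithClass("dimensionError",
                  "image side %dx%d not divisible by 2^%d",
                  dims[1], dims[2], depth)
  geom <- unetGeometry(dims[1], dims[2], depth)
  params <- withLocalSeed(config$seed,
                          initUnetParams(depth, config$baseChannels))
  mState <- adamInit(params)
  vState <- adamInit(params)
  xs <- lapply(cases, function(cs) matrix(as.vector(lesionPixels(cs)) / 255))
  ys <- lapply(cases, function(cs) matrix(as.vector(lesionMask(cs))))
  nPix <- prod(dims)
  trace <- numeric(config$epochs)
  t <- 0
  for (ep in seq_len(config$epochs)) {
    lossSum <- 0
    for (i in seq_along(xs)) {
      fw <- unetForward(xs[[i]], params, geom, depth)
      z <- fw$logits
      y <- ys[[i]]
      # stable BCE-with-logits: mean softplus(z) - y z
      lossSum <- lossSum + mean(pmax(z, 0) + log1p(exp(-abs(z))) - y * z)
      dLogits <- (1 / (1 + exp(-z)) - y) / nPix
      grads <- unetBackward(dLogits, fw, params, geom, depth)
      t <- t + 1
      upd <- adamStep(params, grads, mState, vState,
                      lr = config$learningRate, wd = config$weightDecay,
                      t = t)
      params <- upd$p; mState <- upd$m; vState <- upd$v
    }
    trace[ep] <- lossSum / length(xs)
    if (!is.finite(trace[ep]))
      stopWithClass("trainingDivergedError",
                    "non-finite loss at epoch %d", ep)
  }
  new("SegmenterModel",
      params = params,
      config = c(config, list(inputDim = dims)),
      lossTrace = trace)
}

#' Per-pixel foreground probability map
#'
#' @param model a trained \linkS4class{SegmenterModel}.
#' @param image a \linkS4class{LesionImage} or gray-level matrix with the
#'   model's input dimensions.
#' @return matrix of foreground probabilities in [0, 1].
#' @export
probabilityMap <- function(model, image) {
  img <- if (is(image, "LesionImage")) lesionPixels(image) else image
  dims <- model@config$inputDim
  if (!identical(dim(img), dims))
    stopWithClass("dimensionError",
                  "image is %dx%d but the model expects %dx%d",
                  nrow(img), ncol(img), dims[1], dims[2])
  depth <- model@config$encoderDepth
  geom <- unetGeometry(dims[1], dims[2], depth)
  fw <- unetForward(matrix(as.vector(img) / 255), model@params, geom, depth)
  matrix(1 / (1 + exp(-fw$logits)), dims[1], dims[2])
}

#' Segment a lesion with a trained model
#'
#' Thresholds the probability map at \code{threshold} (pixels with
#' probability >= threshold are foreground) and keeps only the largest
#' 8-connected component, since the downstream shape features assume a
#' single lesion. An empty post-threshold mask raises an
#' \code{emptySegmentationError}: the case has no usable segmentation and
#' its features are undefined.
#'
#' @param model a \linkS4class{SegmenterModel}.
#' @param image a \linkS4class{LesionImage} or gray-level matrix.
#' @param threshold binarization threshold in (0, 1), default 0.5.
#' @return binary matrix (largest foreground component).
#' @export
segmentLesion <- function(model, image, threshold = 0.5) {
  p <- probabilityMap(model, image)
  m <- p >= threshold
  if (!any(m))
    stopWithClass("emptySegmentationError",
                  "no pixel reached threshold %.3g: empty segmentation",
                  threshold)
  largestComponent(m)
}

#' Dice similarity coefficient of two binary masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; defined as 1 when both masks are empty.
#'
#' @param a,b binary matrices of identical dimensions.
#' @return scalar in [0, 1].
#' @export
#' @examples
#' m <- matrix(0, 4, 4); m[2:3, 2:3] <- 1
#' diceCoef(m, m)
diceCoef <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stopWithClass("dimensionError", "mask dimensions differ")
  sa <- sum(a > 0); sb <- sum(b > 0)
  if (sa + sb == 0) return(1)
  2 * sum(a > 0 & b > 0) / (sa + sb)
}
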