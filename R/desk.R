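#' @include training.R
NULL

#' Desk-scale study configuration
#'
#' The reduced-resolution conditions used for the end-to-end synthetic
#' learning checks on one CPU: a U-Scar-Lat at 64 x 64 with scaled widths
#' (encoder 4/8/16/32 with the usual two convolution blocks per level,
#' latent 32, branches 32/16, dropout 0.1), balanced class weighting
#' (alpha 0.5, focusing gamma 0, lateral branch weight 2) and Adam at
#' lr 1.5e-3, batch 8, 30 epochs (patience set to the cap, as the
#' classifier converges after the decoder) and per-epoch crop-offset
#' augmentation of 4 px. The architecture is
#' identical to the full-scale networks; only widths and regularisation
#' are scaled. Chosen once and fixed; the methods vignette discusses the
#' rationale (including why the focusing term is disabled at this sample
#' size).
#'
#' @return `deskNetworkConfig()`: a [NetworkConfig-class];
#'   `deskLossConfig()`: list with `weights` and `focal`;
#'   `deskOptimizerConfig()`: list of optimiser settings.
#' @export
deskNetworkConfig <- function() {
  networkConfig("u_scar_lat", inputSize = 64L,
                encoderChannels = c(4L, 8L, 16L, 32L), latentDim = 32L,
                branchLayers = c(32L, 16L), dropout = 0.1, groups = 4L,
                convsPerLevel = 2L)
}

#' @rdname deskNetworkConfig
#' @export
deskLossConfig <- function() {
  list(weights = lossWeights(W_x = 1, W_kl = 0.001, W_s = 1, W_l = 2),
       focal = focalParams(alpha = c(septal = 0.5, lateral = 0.5),
                           gamma = c(septal = 0, lateral = 0)))
}

#' @rdname deskNetworkConfig
#' @export
deskOptimizerConfig <- function() {
  # patience equals the epoch cap: the classifier learns late relative to
  # the decoder, so validation-loss early stopping would truncate it
  list(lr = 1.5e-3, batchSize = 8L, maxEpochs = 30L, patience = 30L,
       augmentShift = 4L)
}
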