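#' @include networks.R
NULL

#' Loss weights for the combined objective
#'
#' The total training loss is
#' `W_x * L_decoder + W_kl * L_KL + W_s * L_septal + W_l * L_lateral`,
#' each component carrying its own weight. Defaults keep the KL weight
#' small (0.001) to avoid posterior collapse of the variational latent.
#'
#' @param W_x,W_kl,W_s,W_l non-negative component weights.
#' @return list of weights
#' @export
lossWeights <- function(W_x = 1, W_kl = 0.001, W_s = 1, W_l = 1) {
  w <- list(W_x = W_x, W_kl = W_kl, W_s = W_s, W_l = W_l)
  if (any(unlist(w) < 0)) stop("lossWeights: weights must be >= 0")
  w
}

#' Focal-loss parameters per region
#'
#' `alpha` weights the positive class (negatives receive `1 - alpha`);
#' `gamma` is the focusing exponent that down-weights easy examples. The
#' default `alpha = 0.05` reflects the strong class imbalance of scar
#' cohorts (about 11-18\% positive slices), `gamma = 2` is the usual
#' focusing strength.
#'
#' @param alpha named numeric in (0, 1], one value per region.
#' @param gamma named numeric >= 0 per region.
#' @return list with elements `alpha`, `gamma`
#' @export
focalParams <- function(alpha = c(septal = 0.05, lateral = 0.05),
                        gamma = c(septal = 2, lateral = 2)) {
  if (any(alpha <= 0 | alpha > 1)) stop("focalParams: alpha must be in (0, 1]")
  if (any(gamma < 0)) stop("focalParams: gamma must be >= 0")
  list(alpha = alpha, gamma = gamma)
}

#' Focal loss
#'
#' `-alpha * (1 - p)^gamma * log(p)` averaged over the batch, where `p`
#' is the probability the model assigns to the true class. With
#' `gamma = 0, alpha = 1` this reduces to plain cross-entropy. `p` is
#' clamped at `1e-7` to avoid `log(0)`.
#'
#' @param p numeric vector of true-class probabilities in `[0, 1]`.
#' @param alpha weighting term.
#' @param gamma focusing term.
#' @return mean loss (scalar)
#' @examples
#' focalLoss(0.5, alpha = 1, gamma = 0)      # log(2)
#' focalLoss(0.5, alpha = 0.05, gamma = 2)   # 0.05 * 0.25 * log(2)
#' @export
focalLoss <- function(p, alpha = 1, gamma = 2) {
  if (any(p < 0 | p > 1)) stop("focalLoss: p must lie in [0, 1]")
  p <- pmax(p, 1e-7)
  mean(-alpha * (1 - p)^gamma * log(p))
}

#' Decoder reconstruction / segmentation loss
#'
#' Mean binary cross-entropy between the decoder output and its target,
#' averaged over pixels (and channels for the 3-channel segmentation of
#' the U-Scar variants).
#'
#' @param target array in `[0, 1]` (normalised image, or binary
#'   segmentation channels).
#' @param decoded array of predicted probabilities, same shape.
#' @return mean loss (scalar)
#' @export
decoderLoss <- function(target, decoded) {
  if (!identical(dim(target), dim(decoded)) &&
      length(target) != length(decoded))
    stop("decoderLoss: target and decoded shapes differ")
  p <- pmin(pmax(decoded, 1e-7), 1 - 1e-7)
  mean(-(target * log(p) + (1 - target) * log(1 - p)))
}

#' Kullback-Leibler divergence to a unit Gaussian
#'
#' For a diagonal Gaussian with mean `mu` and standard deviation `sigma`,
#' `0.5 * (mu^2 + sigma^2 - 1 - log(sigma^2))` per dimension, summed over
#' dimensions and averaged over the batch. Zero iff `mu = 0, sigma = 1`.
#'
#' @param mu latent means: vector (one sample) or `(N, L)` matrix.
#' @param sigma latent standard deviations, same shape, all > 0.
#' @return mean KL divergence (scalar)
#' @export
klLoss <- function(mu, sigma) {
  if (any(sigma <= 0)) stop("klLoss: sigma must be > 0")
  if (is.null(dim(mu))) { mu <- rbind(mu); sigma <- rbind(sigma) }
  perDim <- 0.5 * (mu^2 + sigma^2 - 1 - log(sigma^2))
  mean(rowSums(perDim))
}

#' Combined training loss
#'
#' Weighted sum of the decoder, KL and per-region focal components.
#' Setting a weight to zero removes that component exactly; a positive
#' septal/lateral weight with no matching classification branch in the
#' output is a contract error.
#'
#' @param output a [NetworkOutput-class]
#' @param sample list with `image` (for `vae_scar`) or `seg` (for the
#'   U-Scar variants) as the decoder target, and `labels`: named logical
#'   (single sample) or `(N, 2)`-ish data.frame/matrix with septal/lateral
#'   columns.
#' @param weights from [lossWeights()].
#' @param focal from [focalParams()].
#' @return list with `total` and `components` (named numeric: decoder,
#'   kl, septal, lateral; inactive components are 0).
#' @export
totalLoss <- function(output, sample, weights = lossWeights(),
                      focal = focalParams()) {
  comps <- c(decoder = 0, kl = 0, septal = 0, lateral = 0)
  if (weights$W_x > 0) {
    target <- if (dim(output@decoded)[4] == 1) sample$image else sample$seg
    if (is.null(target)) stop("totalLoss: decoder target missing from sample")
    target <- array(target, dim(output@decoded))
    comps["decoder"] <- decoderLoss(target, .sigmoid(output@decoded))
  }
  if (weights$W_kl > 0)
    comps["kl"] <- klLoss(output@latentMean, exp(0.5 * output@latentLogVar))
  labs <- .labelsMatrix(sample$labels, nrow(output@latentMean))
  for (rg in .REGIONS) {
    w <- if (rg == "septal") weights$W_s else weights$W_l
    if (w == 0) next
    pr <- output@classProbs[[rg]]
    if (is.null(pr))
      stop("totalLoss: weight for '", rg,
           "' is positive but the output has no such branch")
    y <- labs[, rg]
    pTrue <- ifelse(y, pr[, 2], pr[, 1])
    a <- ifelse(y, focal$alpha[rg], 1 - focal$alpha[rg])
    comps[rg] <- mean(-a * (1 - pTrue)^focal$gamma[rg] * log(pmax(pTrue, 1e-7)))
  }
  total <- weights$W_x * comps["decoder"] + weights$W_kl * comps["kl"] +
    weights$W_s * comps["septal"] + weights$W_l * comps["lateral"]
  list(total = unname(total), components = comps)
}

.labelsMatrix <- function(labels, n) {
  if (is.null(labels)) {
    m <- matrix(FALSE, n, 2)
  } else if (is.data.frame(labels)) {
    m <- cbind(as.logical(labels$septal_scar), as.logical(labels$lateral_scar))
  } else if (is.matrix(labels)) {
    m <- labels
  } else {
    m <- matrix(rep(c(isTRUE(labels[["septal"]]), isTRUE(labels[["lateral"]])),
                    each = n), n, 2)
  }
  colnames(m) <- .REGIONS
  m
}

# forward + loss + parameter gradients for one batch (numerically stable
# logit-space arithmetic; the public loss functions above define the values)
.lossAndGrad <- function(net, images, target, labels, weights, focal,
                         train = TRUE) {
  e <- net@params
  .zeroGrads(e$layers)
  fw <- .netForward(net, images, train = train)
  N <- nrow(fw$mu)
  comps <- c(decoder = 0, kl = 0, septal = 0, lateral = 0)

  dDec <- array(0, dim(fw$decoded))
  if (weights$W_x > 0) {
    L <- fw$decoded
    t <- array(target, dim(L))
    comps["decoder"] <- mean(pmax(L, 0) - L * t + log1p(exp(-abs(L))))
    dDec <- weights$W_x * (.sigmoid(L) - t) / length(L)
  }
  dMu <- matrix(0, N, ncol(fw$mu)); dLv <- dMu
  if (weights$W_kl > 0) {
    comps["kl"] <- mean(rowSums(0.5 * (fw$mu^2 + exp(fw$lv) - 1 - fw$lv)))
    dMu <- weights$W_kl * fw$mu / N
    dLv <- weights$W_kl * 0.5 * (exp(fw$lv) - 1) / N
  }
  labs <- .labelsMatrix(labels, N)
  dLogits <- list()
  for (rg in names(fw$logits)) {
    w <- if (rg == "septal") weights$W_s else weights$W_l
    if (w == 0) { dLogits[[rg]] <- matrix(0, N, 2); next }
    pr <- fw$probs[[rg]]
    y <- labs[, rg]
    ti <- ifelse(y, 2L, 1L)
    pt <- pmin(pmax(pr[cbind(seq_len(N), ti)], 1e-7), 1 - 1e-7)
    a <- ifelse(y, focal$alpha[rg], 1 - focal$alpha[rg])
    gmm <- focal$gamma[rg]
    comps[rg] <- mean(-a * (1 - pt)^gmm * log(pt))
    dpt <- a * (gmm * (1 - pt)^(gmm - 1) * log(pt) - (1 - pt)^gmm / pt)
    isT <- cbind(ti == 1L, ti == 2L)
    dlg <- (dpt * pt / N) * (isT - pr) * w
    dLogits[[rg]] <- dlg
  }
  .netBackward(net, fw, dDec, dMu, dLv, dLogits)
  total <- weights$W_x * comps["decoder"] + weights$W_kl * comps["kl"] +
    weights$W_s * comps["septal"] + weights$W_l * comps["lateral"]
  list(total = unname(total), components = comps, fw = fw)
}
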