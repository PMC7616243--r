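#' @include AllClasses.R nn_layers.R
NULL

#' NetworkOutput: one forward pass
#'
#' @slot decoded decoder logits, `(H, W, N, C)`: 1 channel (image
#'   reconstruction) for `vae_scar`, 3 channels (endo/epi/RV segmentation)
#'   for the U-Scar variants.
#' @slot latentMean,latentLogVar `(N, latentDim)` matrices.
#' @slot classProbs named list (one entry per branch) of `(N, 2)` softmax
#'   matrices, columns (negative, positive); each row sums to 1.
#' @export
setClass("NetworkOutput",
  representation(decoded = "array", latentMean = "matrix",
                 latentLogVar = "matrix", classProbs = "list")
)

setMethod("show", "NetworkOutput", function(object) {
  d <- dim(object@decoded)
  cat(sprintf("NetworkOutput: decoded %dx%dx%d (n=%d), latent %d, branches: %s\n",
              d[1], d[2], d[4], d[3], ncol(object@latentMean),
              paste(names(object@classProbs), collapse = ", ")))
})

.branchBlock <- function(inF, outF, dropout, groups) {
  list(linear = .linearLayer(inF, outF),
       gn = .gn1dLayer(outF, groups),
       prelu = .prelu1dLayer(outF),
       drop = .dropoutLayer(dropout))
}

#' Build a scar-classification network
#'
#' Constructs the encoder-decoder with a variational latent bottleneck
#' and fully connected classification branches. The encoder is a stack of
#' stride-2 3x3 convolutions, each followed by group normalisation and
#' PReLU; a global average pool and two linear maps produce the latent
#' mean and log-variance. The decoder mirrors the encoder with
#' nearest-neighbour upsampling; for the U-Scar variants each decoder
#' level concatenates the matching encoder feature map (skip connection)
#' and the output is 3-channel segmentation logits, while `vae_scar`
#' reconstructs the input image without skips. Each classification branch
#' is a stack of (linear, group norm, PReLU, dropout) blocks with a final
#' 2-way linear layer read out through a softmax.
#'
#' @param config a [NetworkConfig-class]
#' @param seed optional integer; when given, weight initialisation is run
#'   under a private RNG stream.
#' @return a [ScarNetwork-class]
#' @examples
#' net <- buildNetwork(networkConfig("u_scar_lat", inputSize = 64,
#'   encoderChannels = c(8, 16, 32, 64), latentDim = 32,
#'   branchLayers = c(64, 32)), seed = 1)
#' @export
buildNetwork <- function(config, seed = NULL) {
  validObject(config)
  build <- function() {
    ch <- config@encoderChannels
    depth <- length(ch)
    useSkips <- config@variant %in% c("u_scar", "u_scar_lat")
    outC <- if (config@variant == "vae_scar") 1L else 3L
    h0 <- config@inputSize %/% (2^depth)
    if (h0 < 1) stop("buildNetwork: input size ", config@inputSize,
                     " too small for encoder depth ", depth)
    cTop <- ch[depth]
    net <- new.env(parent = emptyenv())
    net$depth <- depth; net$useSkips <- useSkips; net$outC <- outC
    net$h0 <- h0; net$cTop <- cTop; net$ch <- ch
    nConv <- max(1L, config@convsPerLevel)
    lay <- list()
    net$enc <- vector("list", depth)
    inC <- 1L
    for (i in seq_len(depth)) {
      blocks <- list()
      for (b in seq_len(nConv)) {
        blk <- list(conv = .convLayer(if (b == 1) inC else ch[i], ch[i],
                                      k = 3, stride = if (b == 1) 2 else 1),
                    gn = .gnLayer(ch[i], config@groups),
                    prelu = .preluLayer(ch[i]))
        blocks[[b]] <- blk
        sfx <- if (b == 1) "" else paste0("b", b, "_")
        lay[[paste0("enc", i, "_", sfx, "conv")]] <- blk$conv
        lay[[paste0("enc", i, "_", sfx, "gn")]] <- blk$gn
        lay[[paste0("enc", i, "_", sfx, "prelu")]] <- blk$prelu
      }
      net$enc[[i]] <- blocks
      inC <- ch[i]
    }
    net$gap <- .flattenLayer()
    net$muHead <- .linearLayer(h0 * h0 * cTop, config@latentDim)
    net$lvHead <- .linearLayer(h0 * h0 * cTop, config@latentDim)
    # start near-deterministic (sigma ~ e^-3): with a unit-scale sigma at
    # initialisation the reparameterisation noise swamps mu and the
    # classification branches learn to ignore the latent entirely
    net$lvHead$par$b[] <- -6
    lay[["mu_head"]] <- net$muHead
    lay[["lv_head"]] <- net$lvHead
    net$decFC <- .linearLayer(config@latentDim, h0 * h0 * cTop)
    lay[["dec_fc"]] <- net$decFC
    net$dec <- vector("list", depth)
    prevC <- cTop
    for (j in seq_len(depth)) {
      featIdx <- depth - j          # encoder feature concatenated (0 = none)
      skipC <- if (useSkips && featIdx >= 1) ch[featIdx] else 0L
      outLevC <- if (featIdx >= 1) ch[featIdx] else ch[1]
      blocks <- list()
      # decoder levels use a single block: the extra depth matters for the
      # encoder representation, while the decoder is supplemented by skips
      for (b in seq_len(1L)) {
        blk <- list(conv = .convLayer(if (b == 1) prevC + skipC else outLevC,
                                      outLevC, k = 3, stride = 1),
                    gn = .gnLayer(outLevC, config@groups),
                    prelu = .preluLayer(outLevC))
        blocks[[b]] <- blk
        sfx <- if (b == 1) "" else paste0("b", b, "_")
        lay[[paste0("dec", j, "_", sfx, "conv")]] <- blk$conv
        lay[[paste0("dec", j, "_", sfx, "gn")]] <- blk$gn
        lay[[paste0("dec", j, "_", sfx, "prelu")]] <- blk$prelu
      }
      lev <- list(up = .upsampleLayer(), blocks = blocks,
                  featIdx = featIdx, prevC = prevC, skipC = skipC)
      net$dec[[j]] <- lev
      prevC <- outLevC
    }
    net$outConv <- .convLayer(prevC, outC, k = 1, stride = 1)
    lay[["out_conv"]] <- net$outConv
    net$branches <- list()
    for (rg in config@branches) {
      blocks <- list()
      inF <- config@latentDim
      for (bi in seq_along(config@branchLayers)) {
        w <- config@branchLayers[bi]
        blk <- .branchBlock(inF, w, config@dropout, config@groups)
        blocks[[bi]] <- blk
        for (nm in names(blk))
          lay[[paste0("branch_", rg, "_", bi, "_", nm)]] <- blk[[nm]]
        inF <- w
      }
      fin <- .linearLayer(inF, 2L)
      lay[[paste0("branch_", rg, "_out")]] <- fin
      net$branches[[rg]] <- list(blocks = blocks, final = fin)
    }
    net$layers <- lay
    net
  }
  env <- if (is.null(seed)) build() else .withSeed(seed, build())
  new("ScarNetwork", config = config, params = env)
}

# internal forward; returns a plain list incl. caches needed by backward
.netForward <- function(net, x, train = FALSE) {
  e <- net@params
  feats <- vector("list", e$depth)
  h <- x
  for (i in seq_len(e$depth)) {
    for (blk in e$enc[[i]])
      h <- blk$prelu$forward(blk$gn$forward(blk$conv$forward(h, train), train), train)
    feats[[i]] <- h
  }
  zi <- e$gap$forward(h)
  mu <- e$muHead$forward(zi)
  lv <- e$lvHead$forward(zi)
  lv <- pmin(pmax(lv, -15), 15)          # keep sigma finite
  N <- nrow(mu)
  eps <- if (train) matrix(rnorm(length(mu)), N) else NULL
  z <- if (train) mu + exp(0.5 * lv) * eps else mu
  zfc <- e$decFC$forward(z, train)
  h <- aperm(array(zfc, c(N, e$h0, e$h0, e$cTop)), c(2, 3, 1, 4))
  for (j in seq_len(e$depth)) {
    lev <- e$dec[[j]]
    h <- lev$up$forward(h)
    if (lev$skipC > 0) {
      sk <- feats[[lev$featIdx]]
      d <- dim(h)
      h <- array(c(h, sk), c(d[1], d[2], d[3], d[4] + dim(sk)[4]))
    }
    for (blk in lev$blocks)
      h <- blk$prelu$forward(blk$gn$forward(blk$conv$forward(h, train), train), train)
  }
  decoded <- e$outConv$forward(h, train)
  logits <- list(); probs <- list()
  for (rg in names(e$branches)) {
    br <- e$branches[[rg]]
    hb <- z
    for (blk in br$blocks)
      hb <- blk$drop$forward(
        blk$prelu$forward(blk$gn$forward(blk$linear$forward(hb, train), train), train),
        train)
    lg <- br$final$forward(hb, train)
    logits[[rg]] <- lg
    probs[[rg]] <- .softmax2(lg)
  }
  list(decoded = decoded, mu = mu, lv = lv, z = z, eps = eps,
       logits = logits, probs = probs, train = train)
}

# internal backward: takes gradients wrt decoded logits, mu, lv (direct terms,
# e.g. KL) and branch logits; accumulates parameter gradients
.netBackward <- function(net, fw, dDecoded, dMu, dLv, dLogits) {
  e <- net@params
  dh <- e$outConv$backward(dDecoded)
  dskip <- vector("list", e$depth)
  for (j in rev(seq_len(e$depth))) {
    lev <- e$dec[[j]]
    for (blk in rev(lev$blocks))
      dh <- blk$conv$backward(blk$gn$backward(blk$prelu$backward(dh)))
    if (lev$skipC > 0) {
      d <- dim(dh)
      dprev <- dh[, , , seq_len(lev$prevC), drop = FALSE]
      dskip[[lev$featIdx]] <- dh[, , , lev$prevC + seq_len(lev$skipC), drop = FALSE]
      dh <- dprev
    }
    dh <- lev$up$backward(dh)
  }
  N <- nrow(fw$mu)
  dzfc <- matrix(aperm(dh, c(3, 1, 2, 4)), N)
  dz <- e$decFC$backward(dzfc)
  for (rg in names(e$branches)) {
    br <- e$branches[[rg]]
    db <- br$final$backward(dLogits[[rg]])
    for (blk in rev(br$blocks))
      db <- blk$linear$backward(blk$gn$backward(blk$prelu$backward(blk$drop$backward(db))))
    dz <- dz + db
  }
  dMuT <- dMu + dz
  dLvT <- dLv
  if (fw$train) dLvT <- dLvT + dz * fw$eps * 0.5 * exp(0.5 * fw$lv)
  dzi <- e$muHead$backward(dMuT) + e$lvHead$backward(dLvT)
  g <- e$gap$backward(dzi)
  for (i in rev(seq_len(e$depth))) {
    for (blk in rev(e$enc[[i]]))
      g <- blk$conv$backward(blk$gn$backward(blk$prelu$backward(g)))
    if (i > 1 && !is.null(dskip[[i - 1]])) g <- g + dskip[[i - 1]]
  }
  invisible(NULL)
}

#' Run a forward pass
#'
#' In `train` mode the latent vector is sampled by reparameterisation
#' (`z = mu + sigma * eps`) and dropout is active; in `eval` mode `z = mu`
#' and the pass is deterministic.
#'
#' @param network a [ScarNetwork-class]
#' @param images `(H, W)` matrix, `(H, W, N)` or `(H, W, N, 1)` array of
#'   inputs in `[0, 1]`.
#' @param mode `"eval"` or `"train"`.
#' @return a [NetworkOutput-class]
#' @export
forwardNetwork <- function(network, images, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  x <- .asInputTensor(images, network@config@inputSize)
  fw <- .netForward(network, x, train = (mode == "train"))
  new("NetworkOutput", decoded = fw$decoded, latentMean = fw$mu,
      latentLogVar = fw$lv, classProbs = fw$probs)
}

.asInputTensor <- function(images, inputSize) {
  if (is.matrix(images)) images <- array(images, c(dim(images), 1, 1))
  else if (length(dim(images)) == 3) images <- array(images, c(dim(images), 1))
  d <- dim(images)
  if (d[1] != inputSize || d[2] != inputSize)
    stop("forwardNetwork: input is ", d[1], "x", d[2],
         " but the network expects ", inputSize, "x", inputSize)
  images
}

#' Per-region scar probability for one sample
#'
#' Runs the network in eval mode and returns the softmax probability of
#' the positive (scar) class for each classification branch. The binary
#' decision threshold used for sensitivity/specificity downstream is 0.5.
#'
#' @param network a [ScarNetwork-class]
#' @param sample a preprocessed sample (list with an `image` element) or a
#'   bare image matrix.
#' @return named numeric vector of positive-class probabilities.
#' @export
predictSlice <- function(network, sample) {
  img <- if (is.list(sample)) sample$image else sample
  out <- forwardNetwork(network, img, mode = "eval")
  vapply(out@classProbs, function(p) p[1, 2], numeric(1))
}

#' Flat list of network parameters
#'
#' @param network a [ScarNetwork-class]
#' @return named list of numeric arrays (`<layer>.<param>`).
#' @export
networkParameters <- function(network) {
  lay <- network@params$layers
  out <- list()
  for (nm in names(lay)) {
    e <- lay[[nm]]
    if (is.null(e$par)) next
    for (pn in names(e$par)) out[[paste0(nm, ".", pn)]] <- e$par[[pn]]
  }
  out
}

#' Save / load a network checkpoint
#'
#' The checkpoint embeds the architecture as JSON alongside the weights,
#' so a saved network can be rebuilt without the original config object.
#'
#' @param network a [ScarNetwork-class]
#' @param path checkpoint file path.
#' @return `path` (save); the rebuilt [ScarNetwork-class] (load).
#' @export
saveNetwork <- function(network, path) {
  cfg <- network@config
  cfgJson <- jsonlite::toJSON(list(
    variant = cfg@variant, inputSize = cfg@inputSize,
    latentDim = cfg@latentDim, encoderChannels = cfg@encoderChannels,
    branchLayers = cfg@branchLayers, dropout = cfg@dropout,
    branches = cfg@branches, groups = cfg@groups,
    convsPerLevel = cfg@convsPerLevel), auto_unbox = TRUE)
  saveRDS(list(config_json = as.character(cfgJson),
               params = networkParameters(network)), path)
  invisible(path)
}

#' @rdname saveNetwork
#' @export
loadNetwork <- function(path) {
  ck <- readRDS(path)
  cj <- jsonlite::fromJSON(ck$config_json)
  cfg <- networkConfig(variant = cj$variant, inputSize = cj$inputSize,
                       latentDim = cj$latentDim,
                       encoderChannels = cj$encoderChannels,
                       branchLayers = cj$branchLayers, dropout = cj$dropout,
                       branches = cj$branches, groups = cj$groups,
                       convsPerLevel = cj$convsPerLevel %||% 1L)
  net <- buildNetwork(cfg, seed = 0)
  lay <- net@params$layers
  for (nm in names(ck$params)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    lay[[parts[1]]]$par[[parts[2]]] <- ck$params[[nm]]
  }
  net
}
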