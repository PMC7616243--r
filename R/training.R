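#' @include networks.R losses.R preprocess.R
NULL

#' Patient-stratified cross-validation folds
#'
#' Grouped k-fold at patient level: all slices of a patient fall in the
#' same fold, every patient appears in exactly one validation fold. When
#' `strata` is supplied (e.g. patient-level scar status), patients are
#' shuffled and dealt round-robin within each stratum so folds are
#' balanced on it.
#'
#' @param patientIds character vector of distinct patient ids.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @param strata optional named vector (by patient id) of stratum labels.
#' @return list of [FoldSplit-class]
#' @export
makeFolds <- function(patientIds, k = 5L, seed = 1L, strata = NULL) {
  patientIds <- unique(as.character(patientIds))
  if (length(patientIds) < k)
    stop("makeFolds: fewer patients (", length(patientIds),
         ") than folds (", k, ")")
  .withSeed(seed, {
    assign <- integer(length(patientIds))
    names(assign) <- patientIds
    groups <- if (is.null(strata)) list(patientIds)
      else split(patientIds, strata[patientIds])
    nxt <- sample.int(k, 1) - 1L
    for (g in groups) {
      g <- sample(g)
      for (p in g) {
        assign[p] <- nxt %% k
        nxt <- nxt + 1L
      }
    }
    lapply(0:(k - 1), function(f) {
      new("FoldSplit", foldIndex = as.integer(f),
          trainPatients = patientIds[assign != f],
          valPatients = patientIds[assign == f])
    })
  })
}

.subsetSamples <- function(samples, idx) {
  list(images = samples$images[, , idx, , drop = FALSE],
       seg = samples$seg[, , idx, , drop = FALSE],
       labels = samples$labels[idx, , drop = FALSE])
}

.decoderTarget <- function(samples, variant) {
  if (variant == "vae_scar") samples$images else samples$seg
}

.activeWeights <- function(weights, branches) {
  if (!"septal" %in% branches) weights$W_s <- 0
  if (!"lateral" %in% branches) weights$W_l <- 0
  weights
}

#' Train a scar-classification network
#'
#' Mini-batch Adam training of the combined objective (decoder + KL +
#' per-region focal losses). Fully seeded: data order, dropout masks and
#' latent reparameterisation noise all derive from `seed`. Early stopping
#' monitors the validation loss when `valSamples` is given.
#'
#' @param samples training set from [prepareDataset()].
#' @param config a [NetworkConfig-class]
#' @param lossConfig list with `weights` ([lossWeights()]) and `focal`
#'   ([focalParams()]).
#' @param optimizerConfig list: `lr` (default 1e-4), `batchSize` (16),
#'   `maxEpochs` (200), `patience` (10, epochs without validation
#'   improvement before stopping).
#' @param seed integer seed.
#' @param valSamples optional validation set (evaluated with `z = mu`,
#'   dropout off).
#' @param verbose print per-epoch losses.
#' @return list: `network` ([ScarNetwork-class]), `curves` (data.frame
#'   epoch/train_loss/val_loss), `components` (final-epoch loss
#'   breakdown).
#' @export
trainModel <- function(samples, config, lossConfig = list(),
                       optimizerConfig = list(), seed = 1L,
                       valSamples = NULL, verbose = FALSE) {
  weights <- .activeWeights(lossConfig$weights %||% lossWeights(),
                            config@branches)
  focal <- lossConfig$focal %||% focalParams()
  oc <- modifyList(list(lr = 1e-4, batchSize = 16L, maxEpochs = 200L,
                        patience = 10L, augmentShift = 0L), optimizerConfig)
  n <- dim(samples$images)[3]
  if (n == 0) stop("trainModel: empty training set")
  for (rg in config@branches) {
    y <- samples$labels[[paste0(rg, "_scar")]]
    if (length(unique(y)) < 2)
      warning("trainModel: single-class training set for the ", rg,
              " branch; focal loss remains defined, AUC will not")
  }
  .withSeed(seed, {
    net <- buildNetwork(config)
    opt <- .adamInit(net@params$layers)
    target <- .decoderTarget(samples, config@variant)
    curves <- data.frame(epoch = integer(), train_loss = numeric(),
                         val_loss = numeric())
    best <- Inf; bad <- 0L; comps <- NULL
    for (ep in seq_len(oc$maxEpochs)) {
      ord <- sample.int(n)
      tot <- 0; nb <- 0
      for (s in seq(1, n, by = oc$batchSize)) {
        idx <- ord[s:min(s + oc$batchSize - 1, n)]
        bi <- samples$images[, , idx, , drop = FALSE]
        bt <- target[, , idx, , drop = FALSE]
        if (oc$augmentShift > 0) {
          sh <- .rollBatch(bi, bt, oc$augmentShift)
          bi <- sh$images; bt <- sh$target
        }
        lg <- .lossAndGrad(net, bi, bt,
                           samples$labels[idx, , drop = FALSE],
                           weights, focal, train = TRUE)
        .adamStep(net@params$layers, opt, lr = oc$lr)
        tot <- tot + lg$total; nb <- nb + 1
        comps <- lg$components
      }
      vl <- NA_real_
      if (!is.null(valSamples))
        vl <- .evalLoss(net, valSamples, weights, focal)
      curves <- rbind(curves, data.frame(epoch = ep, train_loss = tot / nb,
                                         val_loss = vl))
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %s", ep, tot / nb,
                        ifelse(is.na(vl), "-", sprintf("%.4f", vl))))
      if (!is.null(valSamples)) {
        if (vl < best - 1e-6) { best <- vl; bad <- 0L }
        else {
          bad <- bad + 1L
          if (bad >= oc$patience) break
        }
      }
    }
    list(network = net, curves = curves, components = comps)
  })
}

# per-epoch translation augmentation: the crop-offset jitter of the
# preprocessing stage, re-drawn every epoch instead of frozen into shards.
# images and decoder targets shift together; labels are unchanged.
.rollBatch <- function(images, target, maxShift) {
  d <- dim(images)
  for (k in seq_len(d[3])) {
    dr <- sample(-maxShift:maxShift, 1)
    dc <- sample(-maxShift:maxShift, 1)
    if (dr == 0 && dc == 0) next
    shift1 <- function(m) {
      out <- matrix(0, d[1], d[2])
      rs <- max(1, 1 + dr):min(d[1], d[1] + dr)
      cs <- max(1, 1 + dc):min(d[2], d[2] + dc)
      out[rs, cs] <- m[rs - dr, cs - dc]
      out
    }
    for (ch in seq_len(d[4])) images[, , k, ch] <- shift1(images[, , k, ch])
    for (ch in seq_len(dim(target)[4])) target[, , k, ch] <- shift1(target[, , k, ch])
  }
  list(images = images, target = target)
}

.evalLoss <- function(net, samples, weights, focal, batchSize = 32L) {
  n <- dim(samples$images)[3]
  target <- .decoderTarget(samples, net@config@variant)
  tot <- 0
  for (s in seq(1, n, by = batchSize)) {
    idx <- s:min(s + batchSize - 1, n)
    fw <- .netForward(net, samples$images[, , idx, , drop = FALSE],
                      train = FALSE)
    out <- new("NetworkOutput", decoded = fw$decoded, latentMean = fw$mu,
               latentLogVar = fw$lv, classProbs = fw$probs)
    tl <- totalLoss(out, list(image = samples$images[, , idx, , drop = FALSE],
                              seg = samples$seg[, , idx, , drop = FALSE],
                              labels = samples$labels[idx, , drop = FALSE]),
                    weights = weights, focal = focal)
    tot <- tot + tl$total * length(idx)
  }
  tot / n
}

#' Predict scar probabilities for a dataset
#'
#' @param network a [ScarNetwork-class]
#' @param samples dataset from [prepareDataset()].
#' @param batchSize evaluation batch size.
#' @return data.frame with patient_id, slice_index and one probability
#'   column per branch (`p_septal`, `p_lateral`).
#' @export
predictDataset <- function(network, samples, batchSize = 32L) {
  n <- dim(samples$images)[3]
  out <- samples$labels[, c("patient_id", "slice_index"), drop = FALSE]
  for (rg in network@config@branches) out[[paste0("p_", rg)]] <- NA_real_
  for (s in seq(1, n, by = batchSize)) {
    idx <- s:min(s + batchSize - 1, n)
    fw <- .netForward(network, samples$images[, , idx, , drop = FALSE],
                      train = FALSE)
    for (rg in names(fw$probs))
      out[[paste0("p_", rg)]][idx] <- fw$probs[[rg]][, 2]
  }
  out
}

#' Classification metrics with AUC confidence intervals
#'
#' AUC is the Mann-Whitney rank statistic with a DeLong 95\% confidence
#' interval; sensitivity and specificity are taken at the 0.5 decision
#' threshold. Accuracy is the plain accuracy for a single region and the
#' mean of per-region accuracies otherwise. With a single-class label
#' vector the AUC is reported as `NA` with a reason.
#'
#' @param probabilities numeric vector in `[0, 1]`, or named list of
#'   vectors (one per region).
#' @param labels logical/0-1 vector or named list matching
#'   `probabilities`.
#' @param region region name used when `probabilities` is a bare vector.
#' @return a [MetricsReport-class]
#' @examples
#' evaluate(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))   # AUC 0.75
#' @export
evaluate <- function(probabilities, labels, region = "lateral") {
  if (!is.list(probabilities)) {
    probabilities <- setNames(list(probabilities), region)
    labels <- setNames(list(labels), region)
  }
  rows <- list(); accs <- numeric()
  for (rg in names(probabilities)) {
    p <- as.numeric(probabilities[[rg]])
    y <- as.logical(labels[[rg]])
    if (any(p < 0 | p > 1)) stop("evaluate: probabilities must lie in [0, 1]")
    if (length(p) != length(y)) stop("evaluate: length mismatch")
    pred <- p >= 0.5
    sens <- if (sum(y) > 0) sum(pred & y) / sum(y) else NA_real_
    spec <- if (sum(!y) > 0) sum(!pred & !y) / sum(!y) else NA_real_
    accs <- c(accs, mean(pred == y))
    if (length(unique(y)) < 2) {
      rows[[rg]] <- data.frame(region = rg, auc = NA_real_,
                               auc_ci_low = NA_real_, auc_ci_high = NA_real_,
                               sensitivity = sens, specificity = spec,
                               n_slices = length(y), n_positive = sum(y),
                               auc_reason = "single-class labels")
    } else {
      r <- pROC::roc(response = y, predictor = p, quiet = TRUE,
                     direction = "<", levels = c(FALSE, TRUE))
      # ci.auc warns (informationally) when AUC is exactly 1
      ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
      rows[[rg]] <- data.frame(region = rg, auc = as.numeric(pROC::auc(r)),
                               auc_ci_low = ci[1], auc_ci_high = ci[3],
                               sensitivity = sens, specificity = spec,
                               n_slices = length(y), n_positive = sum(y),
                               auc_reason = "")
    }
  }
  new("MetricsReport", perRegion = do.call(rbind, rows),
      accuracy = mean(accs))
}

#' Patient-stratified cross-validation of a network configuration
#'
#' Trains one model per fold on the training-version samples (random crop
#' offsets) and predicts the fold's validation patients on the
#' evaluation-version samples (centred crops, `z = mu`). Validation
#' predictions are pooled across folds before the ROC computation, and
#' per-fold metrics are retained.
#'
#' @param dataset list with `train` and `eval` sample sets (identical
#'   row order; see [prepareDataset()]), or a single sample set used for
#'   both.
#' @param config a [NetworkConfig-class]
#' @param lossConfig,optimizerConfig see [trainModel()].
#' @param k number of folds.
#' @param seed seed for folds and per-fold training.
#' @return list: `pooled` ([MetricsReport-class]), `perFold` (list of
#'   reports), `predictions` (pooled data.frame), `folds`.
#' @export
crossValidate <- function(dataset, config, lossConfig = list(),
                          optimizerConfig = list(), k = 5L, seed = 1L) {
  if (!is.null(dataset$images)) dataset <- list(train = dataset, eval = dataset)
  labels <- dataset$train$labels
  pats <- unique(labels$patient_id)
  status <- vapply(pats, function(p) {
    rowsP <- labels[labels$patient_id == p, , drop = FALSE]
    any(unlist(rowsP[paste0(config@branches, "_scar")]))
  }, logical(1))
  folds <- makeFolds(pats, k = k, seed = seed, strata = status)
  preds <- list(); perFold <- list()
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    trIdx <- which(labels$patient_id %in% fold@trainPatients)
    vaIdx <- which(labels$patient_id %in% fold@valPatients)
    stopifnot(length(intersect(trIdx, vaIdx)) == 0)
    fit <- trainModel(.subsetSamples(dataset$train, trIdx), config,
                      lossConfig = lossConfig,
                      optimizerConfig = optimizerConfig,
                      seed = seed + 1000L * f,
                      valSamples = .subsetSamples(dataset$eval, vaIdx))
    pr <- predictDataset(fit$network, .subsetSamples(dataset$eval, vaIdx))
    pr$fold <- fold@foldIndex
    preds[[f]] <- cbind(pr,
                        labels[vaIdx, paste0(config@branches, "_scar"),
                               drop = FALSE])
    perFold[[f]] <- tryCatch(
      evaluate(setNames(lapply(config@branches, function(rg) pr[[paste0("p_", rg)]]),
                        config@branches),
               setNames(lapply(config@branches, function(rg)
                 labels[vaIdx, paste0(rg, "_scar")]), config@branches)),
      error = function(e) NULL)
  }
  pooled <- do.call(rbind, preds)
  report <- evaluate(
    setNames(lapply(config@branches, function(rg) pooled[[paste0("p_", rg)]]),
             config@branches),
    setNames(lapply(config@branches, function(rg) pooled[[paste0(rg, "_scar")]]),
             config@branches))
  list(pooled = report, perFold = perFold, predictions = pooled,
       folds = folds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
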