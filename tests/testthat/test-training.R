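test_that("folds are a balanced patient-level partition, deterministic per seed", {
  pats <- sprintf("P%02d", 1:10)
  folds <- makeFolds(pats, k = 5, seed = 1)
  expect_length(folds, 5)
  valSets <- lapply(folds, function(f) f@valPatients)
  expect_true(all(vapply(valSets, length, 1L) == 2))
  expect_setequal(unlist(valSets), pats)
  expect_equal(anyDuplicated(unlist(valSets)), 0)
  for (f in folds)
    expect_length(intersect(f@trainPatients, f@valPatients), 0)
  expect_identical(lapply(makeFolds(pats, k = 5, seed = 1),
                          function(f) f@valPatients), valSets)
  # another seed reshuffles but preserves the partition invariants
  folds2 <- makeFolds(pats, k = 5, seed = 2)
  expect_setequal(unlist(lapply(folds2, function(f) f@valPatients)), pats)
  expect_false(identical(lapply(folds2, function(f) f@valPatients), valSets))
  expect_error(makeFolds(pats[1:3], k = 5), "fewer patients")
})

test_that("stratified folds spread scar-positive patients across folds", {
  pats <- sprintf("P%02d", 1:20)
  status <- setNames(rep(c(TRUE, FALSE), c(5, 15)), pats)
  folds <- makeFolds(pats, k = 5, seed = 3, strata = status)
  posPerFold <- vapply(folds, function(f) sum(status[f@valPatients]), 1)
  expect_true(all(posPerFold == 1))
})

test_that("evaluate: perfect, uninformative and 4-point worked examples", {
  perfect <- evaluate(c(1, 1, 0, 0), c(1, 1, 0, 0))
  pr <- perRegion(perfect)
  expect_equal(pr$auc, 1)
  expect_equal(pr$sensitivity, 1)
  expect_equal(pr$specificity, 1)

  # constant predictor: AUC 0.5 (rank statistic, all ties)
  flat <- evaluate(rep(0.5, 40), rep(c(1, 0), 20))
  expect_equal(perRegion(flat)$auc, 0.5)

  fourPoint <- evaluate(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))
  expect_equal(perRegion(fourPoint)$auc, 0.75)
  # pair-counting oracle agrees with the rank-statistic implementation
  expect_equal(pairCountAUC(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  set.seed(31)
  for (i in 1:10) {
    p <- runif(30); y <- rbinom(30, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(perRegion(evaluate(p, y))$auc, pairCountAUC(p, y),
                 tolerance = 1e-12)
  }
  # DeLong interval brackets the point estimate
  pr4 <- perRegion(fourPoint)
  expect_lte(pr4$auc_ci_low, pr4$auc)
  expect_gte(pr4$auc_ci_high, pr4$auc)

  single <- evaluate(c(0.2, 0.8), c(1, 1))
  expect_true(is.na(perRegion(single)$auc))
  expect_match(perRegion(single)$auc_reason, "single-class")
})

test_that("accuracy averages across regions for multi-branch reports", {
  rep2 <- evaluate(list(septal = c(0.9, 0.1), lateral = c(0.9, 0.9)),
                   list(septal = c(1, 0), lateral = c(1, 0)))
  # septal accuracy 1, lateral accuracy 0.5
  expect_equal(rep2@accuracy, 0.75)
  expect_identical(sort(perRegion(rep2)$region), c("lateral", "septal"))
})

test_that("training is seeded-deterministic and decreases the loss on a separable set", {
  set.seed(13)
  n <- 24
  # trivially separable images: positives carry a bright square
  imgs <- array(runif(16 * 16 * n, 0, 0.2), c(16, 16, n, 1))
  y <- rep(c(TRUE, FALSE), n / 2)
  for (i in which(y)) imgs[5:12, 5:12, i, 1] <- imgs[5:12, 5:12, i, 1] + 0.7
  seg <- array(0, c(16, 16, n, 3)); seg[5:12, 5:12, , 2] <- 1
  labs <- data.frame(septal_scar = FALSE, lateral_scar = y)
  ds <- list(images = imgs, seg = seg, labels = labs)
  cfg <- networkConfig("u_scar_lat", inputSize = 16,
                       encoderChannels = c(4L, 8L), latentDim = 6L,
                       branchLayers = c(16L), groups = 2L)
  fit1 <- trainModel(ds, cfg,
                     lossConfig = list(focal = focalParams(
                       alpha = c(septal = 0.25, lateral = 0.25),
                       gamma = c(septal = 2, lateral = 2))),
                     optimizerConfig = list(lr = 1e-3, batchSize = 8,
                                            maxEpochs = 8), seed = 5)
  expect_lt(tail(fit1$curves$train_loss, 1), fit1$curves$train_loss[1])
  fit2 <- trainModel(ds, cfg,
                     lossConfig = list(focal = focalParams(
                       alpha = c(septal = 0.25, lateral = 0.25),
                       gamma = c(septal = 2, lateral = 2))),
                     optimizerConfig = list(lr = 1e-3, batchSize = 8,
                                            maxEpochs = 8), seed = 5)
  expect_identical(fit1$curves$train_loss, fit2$curves$train_loss)
  # a lateral-only model never produces a septal branch or loss term
  expect_named(fit1$network@params$branches, "lateral")
  expect_equal(unname(fit1$components["septal"]), 0)
})

test_that("single-class branches warn but training continues", {
  set.seed(3)
  imgs <- array(runif(16 * 16 * 8), c(16, 16, 8, 1))
  seg <- array(0, c(16, 16, 8, 3))
  labs <- data.frame(septal_scar = FALSE, lateral_scar = rep(FALSE, 8))
  cfg <- networkConfig("u_scar_lat", inputSize = 16,
                       encoderChannels = c(4L, 8L), latentDim = 4L,
                       branchLayers = c(8L), groups = 2L)
  expect_warning(
    fit <- trainModel(list(images = imgs, seg = seg, labels = labs), cfg,
                      optimizerConfig = list(maxEpochs = 1, batchSize = 8),
                      seed = 1),
    "single-class")
  expect_s4_class(fit$network, "ScarNetwork")
})
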