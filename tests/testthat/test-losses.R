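test_that("focal loss matches hand arithmetic and reduces to cross-entropy", {
  expect_equal(focalLoss(1, alpha = 0.3, gamma = 2), 0)
  expect_equal(focalLoss(0.5, alpha = 1, gamma = 0), log(2), tolerance = 1e-9)
  # 0.05 * (1 - 0.5)^2 * log(2)
  expect_equal(focalLoss(0.5, alpha = 0.05, gamma = 2), 0.05 * 0.25 * log(2),
               tolerance = 1e-9)
  expect_equal(focalLoss(0.5, alpha = 0.05, gamma = 2), 0.0086643,
               tolerance = 1e-4)
  expect_error(focalLoss(1.2), "\\[0, 1\\]")
  # gamma = 0, alpha = 1 equals plain cross-entropy on a grid
  p <- seq(0.05, 0.95, by = 0.05)
  expect_equal(vapply(p, focalLoss, 1, alpha = 1, gamma = 0), -log(p),
               tolerance = 1e-9)
  # non-negative and decreasing in p
  fl <- vapply(p, focalLoss, 1, alpha = 0.3, gamma = 2)
  expect_true(all(fl >= 0))
  expect_true(all(diff(fl) < 0))
})

test_that("decoder BCE matches closed forms and a hand-computed 2x2 example", {
  x <- matrix(0.5, 4, 4)
  expect_equal(decoderLoss(x, x), log(2), tolerance = 1e-9)
  # saturated perfect reconstruction is ~0
  t <- matrix(c(0, 1, 1, 0), 2)
  expect_lt(decoderLoss(t, pmin(pmax(t, 1e-7), 1 - 1e-7)), 1e-5)
  # hand-computed: targets (1,0,1,0), predictions (0.9,0.2,0.6,0.4)
  tgt <- matrix(c(1, 0, 1, 0), 2)
  prd <- matrix(c(0.9, 0.2, 0.6, 0.4), 2)
  hand <- -mean(c(log(0.9), log(0.8), log(0.6), log(0.6)))
  expect_equal(decoderLoss(tgt, prd), hand, tolerance = 1e-12)
})

test_that("KL divergence: closed form, non-negativity, zero iff standard normal", {
  expect_equal(klLoss(0, 1), 0)
  expect_equal(klLoss(rep(0, 8), rep(1, 8)), 0)
  expect_equal(klLoss(1, 1), 0.5)
  expect_equal(klLoss(c(1, 1), c(1, 1)), 1)   # 0.5 per dimension, summed
  set.seed(2)
  for (i in 1:20) {
    mu <- rnorm(5); sg <- exp(rnorm(5, 0, 0.5))
    expect_gte(klLoss(mu, sg), 0)
    if (max(abs(mu)) > 1e-3 || max(abs(sg - 1)) > 1e-3)
      expect_gt(klLoss(mu, sg), 0)
  }
  expect_error(klLoss(0, -1), "sigma")
})

test_that("total loss is linear in each weight and drops zero-weighted terms", {
  cfg <- networkConfig("u_scar", inputSize = 16,
                       encoderChannels = c(4L, 8L), latentDim = 4L,
                       branchLayers = c(8L), dropout = 0, groups = 2L)
  net <- buildNetwork(cfg, seed = 3)
  set.seed(5)
  img <- matrix(runif(256), 16, 16)
  out <- forwardNetwork(net, img, mode = "eval")
  smp <- list(image = img, seg = array(rbinom(16 * 16 * 3, 1, 0.3), c(16, 16, 3)),
              labels = c(septal = TRUE, lateral = FALSE))
  base <- totalLoss(out, smp, lossWeights(0, 0, 0, 0))
  expect_equal(base$total, 0)
  onlyX <- totalLoss(out, smp, lossWeights(1, 0, 0, 0))
  expect_equal(onlyX$total, onlyX$components[["decoder"]])
  full <- totalLoss(out, smp, lossWeights(1, 0.5, 2, 3))
  expect_equal(full$total,
               full$components[["decoder"]] + 0.5 * full$components[["kl"]] +
                 2 * full$components[["septal"]] + 3 * full$components[["lateral"]],
               tolerance = 1e-12)
  # linearity in W_kl holding components fixed
  a <- totalLoss(out, smp, lossWeights(1, 1, 1, 1))$total
  b <- totalLoss(out, smp, lossWeights(1, 3, 1, 1))$total
  c2 <- totalLoss(out, smp, lossWeights(1, 2, 1, 1))$total
  expect_equal(c2, (a + b) / 2, tolerance = 1e-12)
})

test_that("a positive region weight without the matching branch is a contract error", {
  cfg <- networkConfig("u_scar_lat", inputSize = 16,
                       encoderChannels = c(4L, 8L), latentDim = 4L,
                       branchLayers = c(8L), dropout = 0, groups = 2L)
  net <- buildNetwork(cfg, seed = 1)
  out <- forwardNetwork(net, matrix(0.5, 16, 16), mode = "eval")
  smp <- list(seg = array(0, c(16, 16, 3)),
              labels = c(septal = FALSE, lateral = FALSE))
  expect_error(totalLoss(out, smp, lossWeights(W_s = 1)), "septal")
  # with the septal weight off it evaluates fine
  expect_silent(totalLoss(out, smp, lossWeights(W_s = 0)))
})
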