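tinyConfig <- function(variant = "u_scar", inputSize = 16L, dropout = 0) {
  networkConfig(variant, inputSize = inputSize,
                encoderChannels = c(4L, 8L), latentDim = 6L,
                branchLayers = c(10L), dropout = dropout, groups = 2L)
}

test_that("variant contracts: branch count, latent size, decoder channels", {
  latNet <- buildNetwork(tinyConfig("u_scar_lat"), seed = 1)
  expect_length(latNet@params$branches, 1)
  expect_named(latNet@params$branches, "lateral")

  # default latent dimensionality is 128
  expect_identical(networkConfig("u_scar")@latentDim, 128L)

  out <- forwardNetwork(buildNetwork(tinyConfig("u_scar"), seed = 1),
                        matrix(0.5, 16, 16))
  expect_identical(dim(out@decoded)[4], 3L)       # 3-channel segmentation
  outV <- forwardNetwork(buildNetwork(tinyConfig("vae_scar"), seed = 1),
                         matrix(0.5, 16, 16))
  expect_identical(dim(outV@decoded)[4], 1L)      # image reconstruction
  expect_identical(ncol(out@latentMean), 6L)
})

test_that("decoder output spatial size equals the input size across scales", {
  for (sz in c(64L, 128L, 256L)) {
    cfg <- networkConfig("u_scar_lat", inputSize = sz,
                         encoderChannels = c(2L, 4L), latentDim = 4L,
                         branchLayers = c(8L), groups = 2L)
    net <- buildNetwork(cfg, seed = 1)
    out <- forwardNetwork(net, matrix(0.5, sz, sz))
    expect_identical(dim(out@decoded)[1:2], c(sz, sz))
  }
})

test_that("eval mode is deterministic; train mode is seeded-reproducible", {
  net <- buildNetwork(tinyConfig(dropout = 0.5), seed = 2)
  x <- matrix(runif(256), 16, 16)
  a <- forwardNetwork(net, x, mode = "eval")
  b <- forwardNetwork(net, x, mode = "eval")
  expect_identical(a@classProbs, b@classProbs)
  expect_identical(a@decoded, b@decoded)
  set.seed(7); tr1 <- forwardNetwork(net, x, mode = "train")
  set.seed(7); tr2 <- forwardNetwork(net, x, mode = "train")
  expect_identical(tr1@classProbs, tr2@classProbs)
  set.seed(8); tr3 <- forwardNetwork(net, x, mode = "train")
  expect_false(identical(tr1@classProbs, tr3@classProbs))
})

test_that("class probabilities are a softmax: rows sum to 1, closed-form check", {
  net <- buildNetwork(tinyConfig(), seed = 4)
  out <- forwardNetwork(net, matrix(runif(256), 16, 16))
  for (p in out@classProbs)
    expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-6)
  # logits (0, ln 3) -> positive-class probability 0.75; monotone in the logit
  sm <- cardioscar:::.softmax2(rbind(c(0, log(3))))
  expect_equal(sm[1, 2], 0.75, tolerance = 1e-12)
  lg <- seq(-3, 3, by = 0.5)
  ps <- cardioscar:::.softmax2(cbind(0, lg))[, 2]
  expect_true(all(diff(ps) > 0))
  expect_equal(cardioscar:::.softmax2(rbind(c(1, 1)))[1, 2], 0.5)
})

test_that("one optimisation step on a fixed batch decreases the total loss", {
  cfg <- tinyConfig("u_scar")
  net <- buildNetwork(cfg, seed = 6)
  set.seed(11)
  x <- array(runif(16 * 16 * 4), c(16, 16, 4, 1))
  seg <- array(rbinom(16 * 16 * 4 * 3, 1, 0.3), c(16, 16, 4, 3))
  labs <- data.frame(septal_scar = c(TRUE, FALSE, TRUE, FALSE),
                     lateral_scar = c(FALSE, TRUE, TRUE, FALSE))
  w <- lossWeights(); fp <- focalParams()
  before <- cardioscar:::.lossAndGrad(net, x, seg, labs, w, fp,
                                      train = FALSE)$total
  opt <- cardioscar:::.adamInit(net@params$layers)
  cardioscar:::.lossAndGrad(net, x, seg, labs, w, fp, train = FALSE)
  cardioscar:::.adamStep(net@params$layers, opt, lr = 1e-3)
  after <- cardioscar:::.lossAndGrad(net, x, seg, labs, w, fp,
                                     train = FALSE)$total
  expect_lt(after, before)
})

test_that("analytic gradients match finite differences", {
  cfg <- tinyConfig("u_scar")
  net <- buildNetwork(cfg, seed = 2)
  set.seed(1)
  x <- array(runif(16 * 16 * 2), c(16, 16, 2, 1))
  seg <- array(rbinom(16 * 16 * 2 * 3, 1, 0.3), c(16, 16, 2, 3))
  labs <- data.frame(septal_scar = c(TRUE, FALSE), lateral_scar = c(FALSE, TRUE))
  w <- lossWeights(W_x = 1, W_kl = 0.01, W_s = 0.7, W_l = 1.3)
  fp <- focalParams(alpha = c(septal = 0.3, lateral = 0.2),
                    gamma = c(septal = 2, lateral = 0))
  loss <- function() cardioscar:::.lossAndGrad(net, x, seg, labs, w, fp,
                                               train = FALSE)$total
  lay <- net@params$layers
  for (nm in c("enc1_conv", "enc2_gn", "dec2_conv", "mu_head", "lv_head",
               "branch_lateral_1_linear", "branch_septal_out", "out_conv",
               "dec1_prelu")) {
    e <- lay[[nm]]
    pn <- names(e$par)[1]
    lg <- cardioscar:::.lossAndGrad(net, x, seg, labs, w, fp, train = FALSE)
    ana <- e$grad[[pn]][1]
    h <- 1e-5
    orig <- e$par[[pn]][1]
    e$par[[pn]][1] <- orig + h; fp1 <- loss()
    e$par[[pn]][1] <- orig - h; fm1 <- loss()
    e$par[[pn]][1] <- orig
    num <- (fp1 - fm1) / (2 * h)
    expect_equal(ana, num, tolerance = 1e-4,
                 label = paste("gradient of", nm, pn))
  }
})

test_that("u_scar with branches disabled is a plain segmentation U-Net", {
  cfg <- networkConfig("u_scar", inputSize = 16,
                       encoderChannels = c(4L, 8L), latentDim = 6L,
                       branchLayers = c(10L), dropout = 0, groups = 2L,
                       branches = character(0))
  net <- buildNetwork(cfg, seed = 5)
  x <- matrix(runif(256), 16, 16)
  out1 <- forwardNetwork(net, x)
  expect_length(out1@classProbs, 0)
  expect_identical(dim(out1@decoded)[4], 3L)
})

test_that("checkpoints round-trip through save/load", {
  net <- buildNetwork(tinyConfig("u_scar_lat"), seed = 9)
  x <- matrix(runif(256), 16, 16)
  before <- predictSlice(net, x)
  f <- tempfile(fileext = ".rds")
  saveNetwork(net, f)
  net2 <- loadNetwork(f)
  expect_equal(predictSlice(net2, x), before, tolerance = 1e-12)
  expect_identical(net2@config@variant, "u_scar_lat")
})
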