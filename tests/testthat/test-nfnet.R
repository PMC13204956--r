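ms <- asNamespace("mscascade")

test_that("forward pass honours the shape contract at the reference geometry", {
  m <- buildModel(modelConfig(), seed = 1)
  set.seed(1)
  X <- array(rnorm(8 * 2560 * 3), c(8, 2560, 3))
  fw <- ms$modelForward(m, X)
  expect_equal(dim(fw$logits), c(2, 3))
  ## temporal axis: 2560 -> 1280 after the stride-2 stem -> 320 after pooling
  expect_equal(ncol(fw$attention), 320)
  expect_error(modelConfig(attnEmbed = 63), "divisible")
})

test_that("the proposed variant contains no normalization layers", {
  expect_equal(countNormLayers(buildModel(modelConfig(
    blockWidths = c(4, 4)), seed = 1)), 0L)
  expect_equal(countNormLayers(buildModel(modelConfig(
    blockWidths = c(4, 4), variant = "nfnet_no_attn"), seed = 1)), 0L)
  expect_equal(countNormLayers(buildModel(modelConfig(
    blockWidths = c(4, 4), variant = "conv_bn"), seed = 1)), 4L)
})

test_that("single-sample inference equals batched inference without batch norm", {
  cfg <- smallModelConfig()
  m <- buildModel(cfg, seed = 2)
  set.seed(2)
  xs <- lapply(1:4, function(i) matrix(rnorm(8 * 512), 8))
  Pbatch <- predictEpochs(structure(c(m, list(classes = c("a", "b"))),
                                    class = "nfnetModel"), xs)
  Psingle <- do.call(rbind, lapply(xs, function(x)
    predictEpochs(structure(c(m, list(classes = c("a", "b"))),
                            class = "nfnetModel"), list(x))))
  expect_equal(Pbatch, Psingle, tolerance = 1e-12)
  expect_equal(rowSums(Pbatch), rep(1, 4), tolerance = 1e-9)
  ## duplicated epochs give identical probability rows
  Pdup <- predictEpochs(structure(c(m, list(classes = c("a", "b"))),
                                  class = "nfnetModel"), xs[c(1, 1)])
  expect_equal(Pdup[1, ], Pdup[2, ])
})

test_that("batch-norm inference differs between train-time statistics regimes", {
  ## the property the normalizer-free design buys: conv_bn in training mode
  ## depends on batch composition, the proposed variant never does
  cfg <- smallModelConfig(variant = "conv_bn")
  m <- buildModel(cfg, seed = 3)
  set.seed(3)
  X2 <- array(rnorm(8 * 512 * 2), c(8, 512, 2))
  f2 <- ms$modelForward(m, X2, training = TRUE)
  f1 <- ms$modelForward(m, X2[, , 1, drop = FALSE], training = TRUE)
  expect_gt(max(abs(f2$logits[, 1] - f1$logits[, 1])), 1e-6)
})

test_that("AGC clips unit-wise per the norm-ratio rule", {
  ## zero gradient unchanged
  expect_equal(agcClip(numeric(3), c(1, 2, 3)), numeric(3))
  ## ||W|| = 1, ||G|| = 1, lambda 0.04 -> clipped norm 0.04
  g <- agcClip(c(1, 0), c(0, 1))
  expect_equal(sqrt(sum(g^2)), 0.04)
  ## zero weights: eps branch gives norm lambda*eps = 4e-5
  g0 <- agcClip(c(1, 0), c(0, 0))
  expect_equal(sqrt(sum(g0^2)), 4e-5)
  ## small gradients pass through untouched
  expect_equal(agcClip(c(0.01, 0), c(0, 1)), c(0.01, 0))
  ## matrix: rows are units; clipped norm <= max(||G||, lambda*max(||W||,eps))
  set.seed(4)
  for (i in 1:50) {
    G <- matrix(rnorm(12, sd = 2), 3)
    W <- matrix(rnorm(12, sd = 0.3), 3)
    Gc <- agcClip(G, W)
    gn <- sqrt(rowSums(G^2)); gc <- sqrt(rowSums(Gc^2))
    wn <- pmax(sqrt(rowSums(W^2)), 1e-3)
    expect_true(all(gc <= pmax(gn, 0.04 * wn) + 1e-12))
    expect_true(all(gc <= gn + 1e-12))
    ## direction preserved
    for (r in 1:3) if (gn[r] > 0)
      expect_equal(sum(G[r, ] * Gc[r, ]) / (gn[r] * gc[r]), 1,
                   tolerance = 1e-9)
  }
})

test_that("class weights are inverse-frequency with mean about one", {
  expect_equal(classWeights(c(59, 29)), c(0.7458, 1.5172), tolerance = 1e-4)
  expect_equal(classWeights(c(10, 10, 10)), rep(1, 3))
  expect_equal(classWeights(c(59, 29)), classWeights(c(590, 290)))
  expect_error(classWeights(c(5, 0)), "zero-count")
  ## balanced counts: weighted loss equals unweighted loss
  set.seed(5)
  logits <- matrix(rnorm(8), 2)
  y <- c(1L, 2L, 1L, 2L)
  lw <- ms$ceLossFwd(logits, y, classWeights(c(2, 2)))
  lu <- ms$ceLossFwd(logits, y, NULL)
  expect_equal(lw$loss, lu$loss)
})

test_that("early stopping halts after patience non-improving epochs", {
  cfg <- modelConfig(inChannels = 2, stemKernel = 5, blockKernel = 3,
                     blockWidths = c(4), poolStride = 2, attnHeads = 2,
                     attnEmbed = 4, dropout = 0)
  set.seed(6)
  xs <- lapply(1:8, function(i) matrix(rnorm(2 * 64), 2))
  y <- rep(c("a", "b"), 4)
  ## learning rate so small the validation loss is constant by construction
  tc <- trainConfig(lr = 1e-20, batchSize = 4, patience = 3, maxEpochs = 50)
  m <- buildModel(cfg, seed = 6)
  m <- trainModel(m, xs, y, xs[1:4], y[1:4],
                  tc, trainSubjects = "s1", valSubjects = "s2")
  expect_equal(nrow(m$history), 3 + 1)
  expect_equal(m$bestEpoch, 1)
})

test_that("training is deterministic given the seed", {
  cfg <- modelConfig(inChannels = 2, stemKernel = 5, blockKernel = 3,
                     blockWidths = c(4), poolStride = 2, attnHeads = 2,
                     attnEmbed = 4, dropout = 0.2)
  set.seed(7)
  xs <- lapply(1:8, function(i) matrix(rnorm(2 * 64), 2))
  y <- rep(c("a", "b"), 4)
  tc <- trainConfig(lr = 1e-3, batchSize = 4, patience = 5, maxEpochs = 6)
  run <- function() {
    m <- buildModel(cfg, seed = 8)
    trainModel(m, xs, y, xs[1:4], y[1:4], tc,
               trainSubjects = "s1", valSubjects = "s2")$history
  }
  expect_identical(run(), run())
})

test_that("training separates strongly separable synthetic fused epochs", {
  set.seed(9)
  mk <- function(cls) {
    x <- matrix(abs(rnorm(8 * 512, sd = 0.05)), 8)
    x[if (cls == 1) 1:4 else 5:8, ] <-
      x[if (cls == 1) 1:4 else 5:8, ] + 0.8
    x
  }
  trX <- c(lapply(1:16, function(i) mk(1)), lapply(1:16, function(i) mk(2)))
  trY <- rep(c("a", "b"), each = 16)
  vaX <- c(lapply(1:4, function(i) mk(1)), lapply(1:4, function(i) mk(2)))
  vaY <- rep(c("a", "b"), each = 4)
  m <- buildModel(smallModelConfig(), seed = 10)
  m <- trainModel(m, trX, trY, vaX, vaY,
                  smallTrainConfig(maxEpochs = 20),
                  trainSubjects = "s1", valSubjects = "s2")
  P <- predictEpochs(m, trX)
  expect_gte(mean(colnames(P)[max.col(P)] == trY), 0.95)
  Pv <- predictEpochs(m, vaX)
  expect_gte(mean(colnames(Pv)[max.col(Pv)] == vaY), 0.95)
})

test_that("train/validation subject overlap is a hard error", {
  cfg <- modelConfig(inChannels = 2, stemKernel = 3, blockKernel = 3,
                     blockWidths = c(4), poolStride = 2, attnHeads = 1,
                     attnEmbed = 4)
  xs <- lapply(1:4, function(i) matrix(rnorm(2 * 32), 2))
  m <- buildModel(cfg, seed = 1)
  expect_error(
    trainModel(m, xs, c("a", "b", "a", "b"), xs, c("a", "b", "a", "b"),
               trainConfig(maxEpochs = 1),
               trainSubjects = c("s1", "s2"), valSubjects = c("s2", "s3")),
    "leakage")
})

test_that("attention maps are distributions with an upsampled projection", {
  m <- buildModel(smallModelConfig(), seed = 11)
  m$classes <- c("a", "b")
  set.seed(11)
  xs <- lapply(1:3, function(i) matrix(rnorm(8 * 2560), 8))
  att <- extractAttention(m, xs)
  expect_equal(dim(att$weights), c(3, 160))   # 2560 / 2 / 8 at poolStride 8
  expect_true(all(att$weights >= 0))
  expect_equal(rowSums(att$weights), rep(1, 3), tolerance = 1e-9)
  expect_equal(ncol(att$upsampled), 2560)
  expect_equal(rowSums(att$upsampled), rep(1, 3), tolerance = 1e-9)
  mNo <- buildModel(smallModelConfig(variant = "nfnet_no_attn"), seed = 1)
  expect_error(extractAttention(mNo, xs), "no attention")
})

test_that("attention allocation attributes mass by row energy share", {
  T_ <- 64
  att <- structure(list(upsampled = matrix(1 / T_, 1, T_)),
                   class = "AttentionMap")
  ## all energy in target rows -> 1
  x <- matrix(0, 8, T_)
  x[5:8, ] <- 0.7
  expect_equal(as.numeric(attentionAllocation(att, list(x), 5:8)), 1)
  ## target rows silent -> 0
  expect_equal(as.numeric(attentionAllocation(att, list(x), 1:4)), 0)
  ## uniform attention, equal energy everywhere, 4 of 8 target rows -> 0.5
  xu <- matrix(0.5, 8, T_)
  expect_equal(as.numeric(attentionAllocation(att, list(xu), 1:4)), 0.5)
  expect_error(attentionAllocation(att, list(xu), integer(0)), "empty")
  expect_error(attentionAllocation(att, list(xu), 9), "1..8")
})

test_that("attention shifts toward the rows that carry the class signal", {
  ## train on epochs whose discriminative events live in the delta block
  ## (rows 5-8); attention allocation there should differ between classes
  set.seed(12)
  mkA <- function() {            # class with transient row-5:8 bursts
    x <- matrix(abs(rnorm(8 * 512, sd = 0.1)) + 0.4, 8)
    for (b in 1:3) {
      at <- sample(40:470, 1)
      x[5:8, at:(at + 20)] <- 0.05
    }
    x
  }
  mkB <- function() matrix(abs(rnorm(8 * 512, sd = 0.1)) + 0.4, 8)
  trX <- c(lapply(1:14, function(i) mkA()), lapply(1:14, function(i) mkB()))
  trY <- rep(c("burst", "flat"), each = 14)
  vaX <- c(lapply(1:3, function(i) mkA()), lapply(1:3, function(i) mkB()))
  vaY <- rep(c("burst", "flat"), each = 3)
  m <- buildModel(smallModelConfig(), seed = 13)
  m <- trainModel(m, trX, trY, vaX, vaY, smallTrainConfig(maxEpochs = 20),
                  trainSubjects = "s1", valSubjects = "s2")
  testA <- lapply(1:8, function(i) mkA())
  testB <- lapply(1:8, function(i) mkB())
  attA <- extractAttention(m, testA)
  attB <- extractAttention(m, testB)
  scA <- attentionAllocation(attA, testA, 5:8)
  scB <- attentionAllocation(attB, testB, 5:8)
  ## the burst class diverts target-row energy share, so the two groups
  ## separate under a rank test
  mw <- mannWhitneyU(scA, scB)
  expect_lt(mw$p, 0.05)
})
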