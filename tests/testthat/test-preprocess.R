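test_that("average re-reference zeroes the spatial mean and is idempotent", {
  x <- matrix(c(3, 1), 2, 1)
  rec <- Recording(x, rate = 100, channels = c("a", "b"))
  out <- rereferenceAverage(rec)
  expect_equal(as.numeric(eegData(out)), c(1, -1))
  set.seed(1)
  rec2 <- Recording(matrix(rnorm(5 * 40), 5), rate = 100)
  r1 <- rereferenceAverage(rec2)
  expect_lt(max(abs(colMeans(eegData(r1)))), 1e-12)
  expect_equal(eegData(rereferenceAverage(r1)), eegData(r1))
  z <- Recording(matrix(0, 3, 10), rate = 10)
  expect_equal(eegData(rereferenceAverage(z)), matrix(0, 3, 10),
               ignore_attr = TRUE)
  expect_error(rereferenceAverage(Recording(matrix(1, 1, 10), rate = 10)),
               ">= 2 channels")
  ## GFP is invariant under average re-referencing
  expect_equal(gfp(rec2), gfp(r1))
})

test_that("band-pass keeps in-band tones and suppresses out-of-band tones", {
  rec <- toneRecording(c(10, 10), rate = 256, durationS = 6)
  mid <- 500:1000
  outA <- bandpass(rec, "alpha")
  expect_gte(max(abs(eegData(outA)[1, mid])), 0.9)
  rec2 <- toneRecording(c(2, 2), rate = 256, durationS = 6)
  out2 <- bandpass(rec2, "alpha")
  expect_lte(max(abs(eegData(out2)[1, mid])), 0.1)
  z <- Recording(matrix(0, 2, 512), rate = 256)
  expect_equal(max(abs(eegData(bandpass(z, "delta")))), 0)
  expect_error(bandpass(rec, bandSpec("x", 100, 140)), "Nyquist")
})

test_that("resampling follows the round(L*p/q) length contract", {
  rec <- toneRecording(c(10, 10), rate = 256, durationS = 2)
  expect_identical(eegData(resampleRecording(rec, 256)), eegData(rec))
  ## 300 s at 500 Hz down to 256 Hz -> 76800 samples
  tt <- seq(0, 300 - 1 / 500, by = 1 / 500)
  rec2 <- Recording(rbind(sin(2 * pi * 5 * tt), cos(2 * pi * 5 * tt)),
                    rate = 500, channels = c("a", "b"))
  out <- resampleRecording(rec2, 256)
  expect_equal(ncol(eegData(out)), 76800)
  expect_equal(samplingRate(out), 256)
  sp <- stats::spec.pgram(stats::ts(eegData(out)[1, ], frequency = 256),
                          plot = FALSE)
  expect_equal(sp$freq[which.max(sp$spec)], 5, tolerance = 0.05)
  expect_error(resampleRecording(rec, -1), "positive")
  expect_message(resampleRecording(rec, 300), "upsampling")
})

test_that("epoch counts follow the strict-end boundary convention", {
  ## 300 s at 256 Hz, 10 s / 5 s windows -> 58 epochs of 2560 samples
  rec <- Recording(matrix(0, 2, 300 * 256), rate = 256)
  es <- epochRecording(rec)
  expect_equal(nEpochs(es), 58)
  expect_equal(ncol(epochs(es)[[1]]), 2560)
  ## 20 s -> 2 epochs; 9 s -> 0 with a warning
  expect_equal(nEpochs(epochRecording(Recording(matrix(0, 2, 20 * 256),
                                                rate = 256))), 2)
  expect_warning(
    es0 <- epochRecording(Recording(matrix(0, 2, 9 * 256), rate = 256)),
    "shorter")
  expect_equal(nEpochs(es0), 0)
})

test_that("epoch count formula matches brute-force window enumeration", {
  set.seed(42)
  for (i in 1:1000) {
    L <- sample(10:5000, 1)
    W <- sample(2:2000, 1)
    S <- sample(1:500, 1)
    brute <- if (L > W) sum((0:((L %/% S) + 1)) * S + W < L) else 0L
    expect_identical(epochCount(L, W, S), as.integer(brute))
  }
})

test_that("epoch content covers [k*S, k*S + W) and commutes with channel permutation", {
  set.seed(3)
  x <- matrix(rnorm(4 * 3000), 4)
  rec <- Recording(x, rate = 100, channels = letters[1:4])
  es <- epochRecording(rec, windowS = 10, stepS = 4)
  expect_equal(epochs(es)[[2]], x[, 401:1400], ignore_attr = TRUE)
  perm <- c(3, 1, 4, 2)
  recP <- Recording(x[perm, ], rate = 100, channels = letters[1:4][perm])
  fe <- function(r) epochs(epochRecording(bandpass(r, "alpha"), 10, 4))
  e1 <- fe(rec)
  e2 <- fe(recP)
  for (k in seq_along(e1))
    expect_equal(e2[[k]], e1[[k]][perm, ], ignore_attr = TRUE)
})
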