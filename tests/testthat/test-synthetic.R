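test_that("prototypes realize the canonical geometries on the montage", {
  p <- makePrototypes()
  expect_equal(sqrt(rowSums(p^2)), rep(1, 4), ignore_attr = TRUE)
  expect_equal(rowMeans(p), rep(0, 4), ignore_attr = TRUE, tolerance = 1e-12)
  R <- abs(p %*% t(p))
  diag(R) <- 0
  expect_lt(max(R), 0.9)
  mon <- montage1020()
  ## A: extrema in right-anterior and left-posterior channels
  iMax <- which.max(p["A", ])
  iMin <- which.min(p["A", ])
  expect_true(mon$x[iMax] > 0 && mon$y[iMax] > 0)
  expect_true(mon$x[iMin] < 0 && mon$y[iMin] < 0)
  ## C: anterior-posterior midline gradient
  expect_gt(stats::cor(p["C", ], mon$y), 0.99)
  expect_error(makePrototypes(data.frame(channel = "a", x = 1)), "montage")
})

test_that("subject simulation is seed-deterministic with valid ground truth", {
  spec <- cohortSpec(durationS = 5)
  s1 <- simulateSubject("AD", spec, seed = 5)
  s2 <- simulateSubject("AD", spec, seed = 5)
  expect_identical(eegData(s1$recording), eegData(s2$recording))
  expect_identical(s1$groundTruth$stateSequence, s2$groundTruth$stateSequence)
  s3 <- simulateSubject("AD", spec, seed = 6)
  expect_false(identical(eegData(s1$recording), eegData(s3$recording)))
  gt <- s1$groundTruth
  expect_length(gt$stateSequence, 5 * 256)
  ## segment durations within the configured bounds (interior segments)
  dur <- gt$segmentDurationsMs
  interior <- dur[-length(dur)]
  expect_true(all(interior >= 55 & interior <= 125))
  expect_error(simulateSubject("XX", spec), "unknown class")
})

test_that("class effects shape band power as described", {
  spec <- cohortSpec(durationS = 20)
  bandPower <- function(rec, lo, hi) {
    x <- eegData(rec)["O1", ]
    sp <- stats::spec.pgram(stats::ts(x, frequency = 256), spans = 11,
                            plot = FALSE)
    sum(sp$spec[sp$freq >= lo & sp$freq <= hi])
  }
  hc <- simulateSubject("HC", spec, seed = 21)$recording
  expect_gt(bandPower(hc, 8, 13), bandPower(hc, 0.5, 4))
  ad <- simulateSubject("AD", cohortSpec(durationS = 20,
                                         alphaAttenuation = 0.3),
                        seed = 21)$recording
  expect_lt(bandPower(ad, 8, 13) / bandPower(hc, 8, 13), 1)
})

test_that("cohort generation is reproducible with unique labelled subjects", {
  spec <- cohortSpec(nPerClass = c(AD = 2, FTD = 2, HC = 2), durationS = 2,
                     seed = 31)
  co <- simulateCohort(spec)
  expect_length(co$recordings, 6)
  expect_false(anyDuplicated(names(co$recordings)) > 0)
  expect_equal(as.numeric(table(vapply(co$recordings, groupLabel,
                                       ""))[c("AD", "FTD", "HC")]),
               c(2, 2, 2))
  co2 <- simulateCohort(spec)
  expect_identical(lapply(co$groundTruths, `[[`, "stateSequence"),
                   lapply(co2$groundTruths, `[[`, "stateSequence"))
})

test_that("clustering GFP peaks of a noise-light subject recovers the planted maps", {
  spec <- cohortSpec(durationS = 20, noiseSd = 0.02)
  sim <- simulateSubject("HC", spec, seed = 41)
  rec <- rereferenceAverage(sim$recording)
  g <- gfp(rec)
  pk <- detectGfpPeaks(g)
  maps <- t(eegData(rec)[, pk])
  ts <- modifiedKmeans(maps, seed = 42, gfpValues = g[pk],
                       channels = channelNames(rec))
  proto <- makePrototypes()
  R <- abs(mscascade:::normalizeMaps(templateMaps(ts)) %*% t(proto))
  a <- hungarianAssign(1 - R)
  expect_true(all(R[cbind(1:4, a)] >= 0.95))
  expect_equal(sort(a), 1:4)
})

test_that("noise-free backfit argmax reproduces the planted state sequence", {
  spec <- cohortSpec(durationS = 10, noiseSd = 0)
  sim <- simulateSubject("HC", spec, seed = 51)
  x <- eegData(sim$recording)
  ss <- backfitSoft(x, prototypeTemplates())
  pred <- rownames(softValues(ss))[max.col(t(softValues(ss)),
                                           ties.method = "first")]
  expect_gte(mean(pred == sim$groundTruth$stateSequence), 0.99)
})
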