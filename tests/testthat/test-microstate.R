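test_that("GFP matches its definition on hand-computable maps", {
  expect_equal(gfp(c(5, 5, 5)), 0)
  expect_equal(gfp(c(1, -1)), 1)
  set.seed(1)
  v <- rnorm(19)
  expect_equal(gfp(v + 3.7), gfp(v))
  m <- cbind(c(1, -1), c(5, 5), c(0, 2))
  expect_equal(gfp(m), c(1, 0, 1))
  expect_error(gfp(3), ">= 2 channels")
})

test_that("GFP peak detection returns strict interior maxima only", {
  expect_identical(detectGfpPeaks(c(0, 1, 0, 2, 0)), c(2L, 4L))
  expect_length(detectGfpPeaks(1:10), 0)
  expect_length(detectGfpPeaks(10:1), 0)
  ## plateaus are not strict maxima; endpoints never returned
  expect_length(detectGfpPeaks(c(1, 2, 2, 1)), 0)
  expect_error(detectGfpPeaks(c(1, 2)), "short")
})

test_that("spatial correlation is Pearson over channels with polarity option", {
  set.seed(2)
  x <- rnorm(19)
  expect_equal(spatialCorr(x, x), 1)
  expect_equal(spatialCorr(x, -x, polarityInvariant = FALSE), -1)
  expect_equal(spatialCorr(x, -x), 1)
  expect_equal(spatialCorr(c(1, -1, 0, 0), c(0, 0, 1, -1)), 0)
  expect_error(spatialCorr(rep(1, 4), x[1:4]), "zero-variance")
  y <- rnorm(19)
  expect_equal(spatialCorr(x, y, polarityInvariant = FALSE),
               stats::cor(x, y))
})

test_that("GEV matches hand cases and is sign-invariant", {
  proto <- makePrototypes()
  ## maps identical to templates -> GEV 1
  expect_equal(as.numeric(gev(proto, proto)), 1)
  ## single map with best |rho| 0.5 -> GEV 0.25
  a <- c(1, -1, 0, 0)
  b <- c(1, 0, -1, 0)   # rho(a, b) = 0.5
  expect_equal(as.numeric(gev(rbind(b), rbind(a))), 0.25)
  ## orthogonal mean-zero maps -> 0
  t1 <- rbind(c(1, -1, 0, 0))
  m1 <- rbind(c(0, 0, 1, -1))
  expect_equal(as.numeric(gev(t1, m1)), 0)
  ## sign flips of templates or maps change nothing
  set.seed(4)
  maps <- matrix(rnorm(30 * 19), 30)
  s <- sample(c(-1, 1), 30, replace = TRUE)
  expect_equal(as.numeric(gev(proto, maps)),
               as.numeric(gev(-proto, maps * s)))
  ## all-zero GFP weights are rejected
  expect_error(gev(proto, maps, gfpValues = rep(0, 30)), "all-zero GFP")
})

test_that("modified k-means recovers planted prototypes under sign flips and noise", {
  proto <- makePrototypes()
  set.seed(7)
  n <- 200
  idx <- sample(1:4, n, replace = TRUE)
  maps <- proto[idx, ] * sample(c(-1, 1), n, replace = TRUE) +
    matrix(rnorm(n * 19, sd = 0.1), n)
  ts <- modifiedKmeans(maps, seed = 11, channels = colnames(proto))
  R <- abs(mscascade:::normalizeMaps(templateMaps(ts)) %*% t(proto))
  ## each recovered template matches a distinct prototype
  a <- hungarianAssign(1 - R)
  expect_true(all(R[cbind(1:4, a)] >= 0.95))
  expect_equal(sort(a), 1:4)
  ## restart winner beats 100 random template sets on GEV
  set.seed(12)
  g0 <- gevTotal(ts)
  for (i in 1:100) {
    rnd <- mscascade:::normalizeMaps(matrix(rnorm(4 * 19), 4))
    expect_gte(g0, as.numeric(gev(rnd, maps)))
  }
})

test_that("single-cluster k-means returns the map up to sign", {
  set.seed(8)
  v <- rnorm(19)
  maps <- (v %o% rep(1, 25) * rep(sample(c(-1, 1), 25, replace = TRUE),
                                  each = 19)) |> t()
  res <- modifiedKmeans(maps, K = 1, seed = 1)
  expect_equal(abs(spatialCorr(res$maps[1, ], v)), 1, tolerance = 1e-9)
  expect_error(modifiedKmeans(maps[1:2, ], K = 4), "at least K")
})

test_that("degenerate all-identical maps are reported", {
  v <- rnorm(19)
  maps <- t(v %o% rep(1, 10))
  expect_warning(modifiedKmeans(maps, K = 4, seed = 1), "degenerate")
})

test_that("Hungarian assignment equals exhaustive search", {
  set.seed(10)
  for (i in 1:120) {
    cost <- matrix(runif(16), 4)
    a <- hungarianAssign(cost)
    expect_equal(attr(a, "cost"), bruteForceAssignmentCost(cost),
                 tolerance = 1e-12)
    expect_setequal(a, 1:4)
  }
  for (n in c(2, 5, 6)) {
    cost <- matrix(runif(n * n), n)
    a <- hungarianAssign(cost)
    expect_equal(attr(a, "cost"), bruteForceAssignmentCost(cost),
                 tolerance = 1e-12)
  }
  expect_error(hungarianAssign(matrix(1, 2, 3)), "square")
})

test_that("canonical labelling recovers known permutations of the prototypes", {
  proto <- makePrototypes()
  ts <- prototypeTemplates()
  out <- labelCanonical(ts)
  expect_identical(templateLabels(out), c("A", "B", "C", "D"))
  expect_equal(attr(out, "alignmentCost"), 0, tolerance = 1e-9)
  ## a shuffled, sign-flipped prototype set recovers the same labels
  perm <- c(3, 1, 4, 2)
  ts2 <- ts
  ts2@maps <- proto[perm, ] * c(-1, 1, -1, 1)
  rownames(ts2@maps) <- c("A", "B", "C", "D")
  out2 <- labelCanonical(ts2)
  R <- abs(templateMaps(out2) %*% t(proto))
  expect_true(all(diag(R) > 0.999))
})

test_that("cross-band alignment recovers permutations against brute force", {
  proto <- makePrototypes()
  anchor <- prototypeTemplates()
  set.seed(13)
  for (i in 1:50) {
    perm <- sample(4)
    noisy <- mscascade:::normalizeMaps(
      proto[perm, ] + matrix(rnorm(4 * 19, sd = 0.05), 4))
    narrow <- anchor
    narrow@band <- "alpha"
    narrow@maps <- noisy
    rownames(narrow@maps) <- c("A", "B", "C", "D")
    out <- alignBands(narrow, anchor)
    ## after alignment, row labelled X matches prototype X
    R <- abs(templateMaps(out) %*% t(proto))
    expect_true(all(diag(R) > 0.9))
    ## Hungarian total cost equals exhaustive minimum on the cost matrix
    D <- attr(out, "costMatrix")
    expect_equal(attr(hungarianAssign(D), "cost"),
                 bruteForceAssignmentCost(D), tolerance = 1e-12)
  }
  bad <- anchor
  bad@channels <- paste0("x", 1:19)
  expect_error(alignBands(bad, anchor), "montage")
})

test_that("soft backfitting yields [0,1] trajectories with exact template hits", {
  ts <- prototypeTemplates()
  proto <- makePrototypes()
  set.seed(14)
  T_ <- 40
  x <- matrix(rnorm(19 * T_), 19)
  x[, 5] <- 3.2 * proto["B", ]          # scaled template frame
  x[, 9] <- 0                           # zero-variance frame
  ss <- backfitSoft(x, ts, subjectId = "s", epochIndex = 2L)
  v <- softValues(ss)
  expect_equal(dim(v), c(4, T_))
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(unname(v["B", 5]), 1, tolerance = 1e-9)
  expect_identical(ss@flaggedFrames, 9L)
  expect_equal(v[, 9], c(A = 0, B = 0, C = 0, D = 0))
  ## polarity: flipping the frame sign changes nothing
  ss2 <- backfitSoft(-x, ts)
  expect_equal(softValues(ss2), v, ignore_attr = TRUE)
  ## signed mode keeps the sign (returned as a plain matrix)
  r3 <- backfitSoft(x, ts, polarityInvariant = FALSE)
  expect_true(is.matrix(r3))
  expect_equal(abs(r3), v, ignore_attr = TRUE)
  expect_true(any(r3 < 0))
  expect_error(backfitSoft(x[1:5, ], ts), "montage")
})

test_that("default 10 s epoch backfits to a (4, 2560) tensor", {
  ts <- prototypeTemplates()
  set.seed(15)
  x <- matrix(rnorm(19 * 2560), 19)
  expect_equal(dim(softValues(backfitSoft(x, ts))), c(4, 2560))
})

test_that("band fusion stacks rows in fixed order and round trips", {
  ts <- prototypeTemplates("alpha")
  td <- prototypeTemplates("delta")
  set.seed(16)
  x <- matrix(rnorm(19 * 100), 19)
  y <- matrix(rnorm(19 * 100), 19)
  sa <- backfitSoft(x, ts, subjectId = "s", epochIndex = 1L)
  sd_ <- backfitSoft(y, td, subjectId = "s", epochIndex = 1L)
  fe <- fuseBands(sa, sd_, "stage1", label = "HC")
  v <- fusedValues(fe)
  expect_equal(dim(v), c(8, 100))
  expect_equal(v[1, ], softValues(sa)["A", ], ignore_attr = TRUE)
  expect_equal(v[1:4, ], softValues(sa), ignore_attr = TRUE)
  expect_equal(v[5:8, ], softValues(sd_), ignore_attr = TRUE)
  ## mismatches rejected
  sOther <- backfitSoft(y, td, subjectId = "other", epochIndex = 1L)
  expect_error(fuseBands(sa, sOther, "stage1"), "mismatch")
  sShort <- backfitSoft(y[, 1:50], td, subjectId = "s", epochIndex = 1L)
  expect_error(fuseBands(sa, sShort, "stage1"), "mismatch")
})

test_that("microstate statistics match the hand-worked segment example", {
  lab <- c(rep("A", 128), rep("B", 128), rep("A", 256))
  st <- microstateStats(lab, rate = 256)
  expect_equal(st$coverage, c(A = 0.75, B = 0.25, C = 0, D = 0))
  expect_equal(st$occurrence[c("A", "B")], c(A = 1, B = 0.5))
  expect_equal(st$meanDwellMs[c("A", "B")], c(A = 750, B = 500))
  ## segment-level transition rows are stochastic over observed transitions
  expect_equal(st$transitions["A", "B"], 1)
  expect_equal(st$transitions["B", "A"], 1)
  expect_setequal(st$emptyRows, c("C", "D"))
})

test_that("degenerate and random sequences keep statistics consistent", {
  st <- microstateStats(rep("A", 100), rate = 100)
  expect_equal(st$coverage[["A"]], 1)
  expect_true(all(st$transitions == 0))
  expect_setequal(st$emptyRows, c("A", "B", "C", "D"))
  set.seed(17)
  for (i in 1:20) {
    lab <- sample(c("A", "B", "C", "D"), 300, replace = TRUE)
    st <- microstateStats(lab, rate = 250)
    expect_equal(sum(st$coverage), 1)
    rs <- rowSums(st$transitions)
    expect_true(all(abs(rs[rs > 0] - 1) < 1e-12))
  }
})

test_that("template sets serialize to JSON and back", {
  ts <- prototypeTemplates("alpha")
  path <- withr::local_tempfile(fileext = ".json")
  writeTemplateSet(ts, path)
  back <- readTemplateSet(path)
  expect_equal(templateMaps(back), templateMaps(ts), tolerance = 1e-12)
  expect_identical(templateLabels(back), templateLabels(ts))
  expect_identical(bandName(back), "alpha")
})
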