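## Shared fixtures, all generated in code.

## TemplateSet holding the built-in canonical prototypes verbatim
prototypeTemplates <- function(band = "broadband") {
  proto <- makePrototypes()
  new("TemplateSet", band = band, maps = proto, labels = rownames(proto),
      gevTotal = 1, gevPerMap = rep(0.25, 4), nPeakMaps = 4,
      channels = colnames(proto))
}

## small deterministic multichannel recording of pure tones
toneRecording <- function(freqs = c(10, 10), rate = 256, durationS = 4,
                          subjectId = "tone") {
  tt <- seq(0, durationS - 1 / rate, by = 1 / rate)
  x <- t(vapply(seq_along(freqs),
                function(i) sin(2 * pi * freqs[i] * tt + i), tt))
  Recording(x, rate = rate,
            channels = paste0("ch", seq_along(freqs)),
            subjectId = subjectId)
}

## all 24 permutations of 1:4 (brute-force assignment oracle)
perms4 <- local({
  g <- as.matrix(expand.grid(rep(list(1:4), 4)))
  g[apply(g, 1, function(r) length(unique(r)) == 4), , drop = FALSE]
})

bruteForceAssignmentCost <- function(cost) {
  n <- nrow(cost)
  perms <- if (n == 4) perms4 else {
    g <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
    g[apply(g, 1, function(r) length(unique(r)) == n), , drop = FALSE]
  }
  min(apply(perms, 1, function(pm) sum(cost[cbind(seq_len(n), pm)])))
}

## reduced-size classifier profile used for synthetic cohort runs
smallModelConfig <- function(...) {
  args <- utils::modifyList(
    list(blockWidths = c(8, 16), attnEmbed = 16, poolStride = 8,
         dropout = 0.3),
    list(...))
  do.call(modelConfig, args)
}
smallTrainConfig <- function(...) {
  args <- utils::modifyList(
    list(lr = 2e-3, batchSize = 16, patience = 8, maxEpochs = 30),
    list(...))
  do.call(trainConfig, args)
}
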