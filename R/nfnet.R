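#' Model configuration for the normalizer-free 1D classifier
#'
#' Defaults follow the reference architecture: a large-receptive-field stem
#' convolution (kernel 15, stride 2), normalizer-free residual blocks with
#' 1x1 projection shortcuts and kernel-7 convolutions, max-pooling with
#' stride 4, multi-head self-attention (4 heads, embedding 64), global
#' average pooling, dropout 0.5 and a linear head. Variants:
#' \code{"proposed"} (no normalization anywhere), \code{"conv_bn"}
#' (conv/batch-norm/ReLU blocks, no residual), \code{"nfnet_no_attn"}
#' (attention module omitted).
#'
#' @param inChannels input rows (8 for a two-band fusion).
#' @param stemKernel,stemStride stem convolution geometry.
#' @param blockKernel residual block kernel size.
#' @param blockWidths channel widths of the residual blocks; the stem
#'   outputs \code{blockWidths[1]} channels.
#' @param poolStride max-pooling stride.
#' @param attnHeads,attnEmbed self-attention heads and embedding width
#'   (embed divisible by heads).
#' @param dropout dropout probability before the head.
#' @param nClasses output classes.
#' @param variant architecture variant (see above).
#' @return list of class \code{ModelConfig}.
#' @export
modelConfig <- function(inChannels = 8, stemKernel = 15, stemStride = 2,
                        blockKernel = 7, blockWidths = c(32, 64, 64),
                        poolStride = 4, attnHeads = 4, attnEmbed = 64,
                        dropout = 0.5, nClasses = 2,
                        variant = c("proposed", "conv_bn", "nfnet_no_attn")) {
  variant <- match.arg(variant)
  if (any(blockWidths <= 0)) stop("block widths must be positive")
  if (attnEmbed %% attnHeads != 0)
    stop("attnEmbed must be divisible by attnHeads")
  structure(list(inChannels = inChannels, stemKernel = stemKernel,
                 stemStride = stemStride, blockKernel = blockKernel,
                 blockWidths = blockWidths, poolStride = poolStride,
                 attnHeads = attnHeads, attnEmbed = attnEmbed,
                 dropout = dropout, nClasses = nClasses, variant = variant),
            class = "ModelConfig")
}

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with learning rate 1e-4,
#' batch size 32, early stopping after 20 epochs without validation-loss
#' improvement, adaptive gradient clipping with lambda 0.04 and epsilon
#' 1e-3, and seed 42.
#'
#' @param lr Adam learning rate.
#' @param batchSize minibatch size.
#' @param patience early-stopping patience in epochs.
#' @param maxEpochs epoch cap.
#' @param agcLambda,agcEps AGC clipping threshold and zero-weight guard.
#' @param classWeights optional per-class loss weights (else computed from
#'   training label counts).
#' @param seed RNG seed for initialisation, shuffling and dropout.
#' @param valFraction subject fraction held out for validation by the LOSO
#'   splitter.
#' @return list of class \code{TrainConfig}.
#' @export
trainConfig <- function(lr = 1e-4, batchSize = 32, patience = 20,
                        maxEpochs = 200, agcLambda = 0.04, agcEps = 1e-3,
                        classWeights = NULL, seed = 42, valFraction = 0.2) {
  stopifnot(lr > 0, batchSize >= 1, patience >= 1, maxEpochs >= 1,
            agcLambda > 0, agcEps > 0, valFraction > 0, valFraction < 1)
  structure(list(lr = lr, batchSize = batchSize, patience = patience,
                 maxEpochs = maxEpochs, agcLambda = agcLambda,
                 agcEps = agcEps, classWeights = classWeights, seed = seed,
                 valFraction = valFraction),
            class = "TrainConfig")
}

#' Build an untrained model
#'
#' Forward contract: input (inChannels, T, batch) arrays map to
#' (nClasses, batch) logits through stem convolution, residual (or conv-BN)
#' blocks, max-pooling, self-attention (unless ablated), global average
#' pooling, dropout and the linear head. The \code{proposed} variant
#' contains no normalization layers anywhere, so single-sample and batched
#' inference are identical.
#'
#' @param config a \code{\link{modelConfig}}.
#' @param seed RNG seed for weight initialisation.
#' @return list of class \code{nfnetModel}.
#' @export
buildModel <- function(config = modelConfig(), seed = 42) {
  runWithSeed(seed, {
    widths <- config$blockWidths
    params <- list(stem = conv1dInit(config$inChannels, widths[1],
                                     config$stemKernel))
    inC <- widths[1]
    blocks <- list()
    for (i in seq_along(widths)) {
      outC <- widths[i]
      bl <- list(conv1 = conv1dInit(inC, outC, config$blockKernel),
                 conv2 = conv1dInit(outC, outC, config$blockKernel))
      if (config$variant == "conv_bn") {
        bl$bn1 <- bnInit(outC)
        bl$bn2 <- bnInit(outC)
      } else {
        bl$proj <- conv1dInit(inC, outC, 1L)
      }
      blocks[[i]] <- bl
      inC <- outC
    }
    params$blocks <- blocks
    feat <- inC
    if (config$variant != "nfnet_no_attn") {
      params$attn <- mhsaInit(inC, config$attnEmbed, config$attnHeads)
      feat <- config$attnEmbed
    }
    params$head <- linearInit(feat, config$nClasses)
    structure(list(config = config, params = params, trained = FALSE),
              class = "nfnetModel")
  })
}

#' Count normalization layers in a model
#'
#' Architectural introspection: the \code{proposed} and
#' \code{nfnet_no_attn} variants must report zero.
#'
#' @param model an \code{nfnetModel}.
#' @return integer count of batch-norm layers.
#' @export
countNormLayers <- function(model) {
  sum(vapply(model$params$blocks,
             function(bl) sum(c("bn1", "bn2") %in% names(bl)), 0L))
}

## Full forward pass. Returns logits, attention (B x Tpost or NULL) and,
## when `backprop`, the caches needed for the backward pass.
modelForward <- function(model, X, training = FALSE, backprop = FALSE) {
  cfg <- model$config
  pr <- model$params
  caches <- list()
  st <- conv1dFwd(X, pr$stem, stride = cfg$stemStride)
  caches$stem <- st$cache
  r0 <- reluFwd(st$out)
  caches$stemRelu <- r0$cache
  H <- r0$out
  caches$blocks <- list()
  for (i in seq_along(pr$blocks)) {
    bl <- pr$blocks[[i]]
    cb <- list()
    if (cfg$variant == "conv_bn") {
      c1 <- conv1dFwd(H, bl$conv1); cb$c1 <- c1$cache
      b1 <- bnFwd(c1$out, bl$bn1, training = training)
      model$params$blocks[[i]]$bn1 <- b1$layer
      cb$b1 <- b1$cache
      a1 <- reluFwd(b1$out); cb$a1 <- a1$cache
      c2 <- conv1dFwd(a1$out, bl$conv2); cb$c2 <- c2$cache
      b2 <- bnFwd(c2$out, bl$bn2, training = training)
      model$params$blocks[[i]]$bn2 <- b2$layer
      cb$b2 <- b2$cache
      a2 <- reluFwd(b2$out); cb$a2 <- a2$cache
      H <- a2$out
    } else {
      ## NF-ResBlock: 1x1 projection shortcut + conv-ReLU-conv main branch
      p <- conv1dFwd(H, bl$proj, stride = 1L, pad = 0L); cb$p <- p$cache
      c1 <- conv1dFwd(H, bl$conv1); cb$c1 <- c1$cache
      a1 <- reluFwd(c1$out); cb$a1 <- a1$cache
      c2 <- conv1dFwd(a1$out, bl$conv2); cb$c2 <- c2$cache
      H <- p$out + c2$out
      ar <- reluFwd(H); cb$ar <- ar$cache
      H <- ar$out
    }
    caches$blocks[[i]] <- cb
  }
  mp <- maxPoolFwd(H, cfg$poolStride)
  caches$pool <- mp$cache
  H <- mp$out
  attn <- NULL
  if (cfg$variant != "nfnet_no_attn") {
    at <- mhsaFwd(H, pr$attn)
    caches$attn <- at$cache
    attn <- at$attention
    H <- at$out
  }
  gp <- gapFwd(H)
  caches$gap <- gp$cache
  dp <- dropoutFwd(gp$out, cfg$dropout, training = training)
  caches$drop <- dp$cache
  hd <- linearFwd(dp$out, pr$head)
  caches$head <- hd$cache
  list(logits = hd$out, attention = attn, model = model,
       caches = if (backprop) caches else NULL)
}

## Backward pass; returns gradients in the same nesting as model$params.
modelBackward <- function(model, caches, dLogits) {
  cfg <- model$config
  grads <- list()
  hb <- linearBwd(dLogits, caches$head)
  grads$head <- list(W = hb$dW, b = hb$db)
  dG <- dropoutBwd(hb$dX, caches$drop)
  dH <- gapBwd(dG, caches$gap)
  if (cfg$variant != "nfnet_no_attn") {
    ab <- mhsaBwd(dH, caches$attn)
    g <- ab$grads
    grads$attn <- list(proj = list(W = g$proj.W, b = g$proj.b),
                       Wq = list(W = g$Wq.W, b = g$Wq.b),
                       Wk = list(W = g$Wk.W, b = g$Wk.b),
                       Wv = list(W = g$Wv.W, b = g$Wv.b),
                       Wo = list(W = g$Wo.W, b = g$Wo.b))
    dH <- ab$dX
  }
  dH <- maxPoolBwd(dH, caches$pool)
  grads$blocks <- vector("list", length(model$params$blocks))
  for (i in rev(seq_along(model$params$blocks))) {
    cb <- caches$blocks[[i]]
    if (cfg$variant == "conv_bn") {
      d2 <- reluBwd(dH, cb$a2)
      bb2 <- bnBwd(d2, cb$b2)
      cc2 <- conv1dBwd(bb2$dX, cb$c2)
      d1 <- reluBwd(cc2$dX, cb$a1)
      bb1 <- bnBwd(d1, cb$b1)
      cc1 <- conv1dBwd(bb1$dX, cb$c1)
      grads$blocks[[i]] <- list(
        conv1 = list(W = cc1$dW, b = cc1$db),
        conv2 = list(W = cc2$dW, b = cc2$db),
        bn1 = list(gamma = bb1$dgamma, beta = bb1$dbeta),
        bn2 = list(gamma = bb2$dgamma, beta = bb2$dbeta))
      dH <- cc1$dX
    } else {
      dSum <- reluBwd(dH, cb$ar)
      pb <- conv1dBwd(dSum, cb$p)
      cc2 <- conv1dBwd(dSum, cb$c2)
      d1 <- reluBwd(cc2$dX, cb$a1)
      cc1 <- conv1dBwd(d1, cb$c1)
      grads$blocks[[i]] <- list(
        conv1 = list(W = cc1$dW, b = cc1$db),
        conv2 = list(W = cc2$dW, b = cc2$db),
        proj = list(W = pb$dW, b = pb$db))
      dH <- pb$dX + cc1$dX
    }
  }
  dS <- reluBwd(dH, caches$stemRelu)
  sb <- conv1dBwd(dS, caches$stem, needInput = FALSE)   # input layer
  grads$stem <- list(W = sb$dW, b = sb$db)
  grads
}

#' Adaptive gradient clipping
#'
#' Unit-wise clipping of a gradient against its parameter: for unit i (a row
#' of a weight matrix, or a whole bias vector), when
#' \code{||G_i||_F / max(||W_i||_F, eps) > lambda} the gradient is rescaled
#' to \code{lambda * max(||W_i||_F, eps) / ||G_i||_F * G_i}, else left
#' unchanged. Never increases a unit's gradient norm and preserves its
#' direction. \code{eps} guards zero-initialised weights (clipped norm
#' lambda*eps).
#'
#' @param G gradient: matrix, vector, or (nested) list of such.
#' @param W matching parameter(s).
#' @param lambda clipping threshold (default 0.04).
#' @param eps parameter-norm floor (default 1e-3).
#' @return clipped gradient(s), same shape as \code{G}.
#' @export
agcClip <- function(G, W, lambda = 0.04, eps = 1e-3) {
  if (is.list(G)) {
    return(mapply(agcClip, G, W,
                  MoreArgs = list(lambda = lambda, eps = eps),
                  SIMPLIFY = FALSE))
  }
  if (is.matrix(G)) {
    wn <- pmax(sqrt(rowSums(W^2)), eps)
    gn <- sqrt(rowSums(G^2))
    fac <- ifelse(gn > lambda * wn & gn > 0, lambda * wn / gn, 1)
    G * fac
  } else {
    wn <- max(sqrt(sum(W^2)), eps)
    gn <- sqrt(sum(G^2))
    if (gn > lambda * wn && gn > 0) G * (lambda * wn / gn) else G
  }
}

#' Inverse-frequency class weights
#'
#' \code{w_c = N_total / (K * n_c)}: mean ~1, balanced counts give all 1,
#' invariant to scaling all counts.
#'
#' @param counts positive per-class counts (named or positional).
#' @return numeric weights, same order as \code{counts}.
#' @export
classWeights <- function(counts) {
  if (any(counts <= 0)) stop("zero-count class")
  w <- sum(counts) / (length(counts) * counts)
  w
}

## Adam state mirrors the parameter nesting lazily via environments
adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     adamEps = 1e-8) {
  state$t <- state$t + 1
  t <- state$t
  walk <- function(p, g, path) {
    if (is.numeric(p)) {
      if (is.null(g)) return(p)
      key <- paste(path, collapse = ".")
      m <- state$m[[key]]; v <- state$v[[key]]
      if (is.null(m)) { m <- p * 0; v <- p * 0 }
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      state$m[[key]] <- m
      state$v[[key]] <- v
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      return(p - lr * mhat / (sqrt(vhat) + adamEps))
    }
    if (is.list(p)) {
      for (nm in names(p)) {
        if (nm %in% c("k", "inC", "outC", "heads", "embed", "runMean",
                      "runVar", "momentum", "eps")) next
        p[[nm]] <- walk(p[[nm]], g[[nm]], c(path, nm))
      }
    }
    p
  }
  params <- walk(params, grads, character(0))
  list(params = params, state = state)
}

## grads nested like params; clip every weight/bias against its parameter
agcClipGrads <- function(grads, params, lambda, eps) {
  walk <- function(g, p) {
    if (is.numeric(g)) return(agcClip(g, p, lambda, eps))
    if (is.list(g)) {
      for (nm in names(g)) {
        if (is.null(g[[nm]])) next
        g[[nm]] <- walk(g[[nm]], p[[nm]])
      }
    }
    g
  }
  walk(grads, params)
}

stackEpochs <- function(epochList) {
  d <- dim(epochList[[1]])
  X <- array(0, c(d[1], d[2], length(epochList)))
  for (i in seq_along(epochList)) X[, , i] <- epochList[[i]]
  X
}

#' Train the classifier
#'
#' Adam with adaptive gradient clipping on every parameter each step,
#' weighted cross-entropy, early stopping on validation loss with the
#' configured patience, restoring the best-validation-epoch weights.
#' Training and validation sets must come from disjoint subjects (hard
#' error otherwise - the leakage guard).
#'
#' @param model an untrained \code{\link{buildModel}} result.
#' @param trainX list of (inChannels x T) matrices or
#'   \linkS4class{FusedEpoch}s.
#' @param trainY integer class labels (1-based) or character labels.
#' @param valX,valY validation set in the same form.
#' @param tconf a \code{\link{trainConfig}}.
#' @param classes class label order mapping labels to logit units; default
#'   is locale-independent (radix) sorted unique labels.
#' @param trainSubjects,valSubjects subject ids backing the leakage check;
#'   inferred from FusedEpoch provenance when omitted.
#' @return the trained model; \code{$history} holds per-epoch train/val
#'   losses, \code{$classes} the label set.
#' @export
trainModel <- function(model, trainX, trainY, valX, valY,
                       tconf = trainConfig(), classes = NULL,
                       trainSubjects = NULL, valSubjects = NULL) {
  getSubj <- function(xs) {
    if (length(xs) && is(xs[[1]], "FusedEpoch"))
      vapply(xs, subjectId, "") else NULL
  }
  if (is.null(trainSubjects)) trainSubjects <- getSubj(trainX)
  if (is.null(valSubjects)) valSubjects <- getSubj(valX)
  if (!is.null(trainSubjects) && !is.null(valSubjects)) {
    overlap <- intersect(unique(trainSubjects), unique(valSubjects))
    if (length(overlap))
      stop("leakage: subjects in both train and val: ",
           paste(overlap, collapse = ", "))
  }
  toMat <- function(xs) lapply(xs, function(x)
    if (is(x, "FusedEpoch")) fusedValues(x) else as.matrix(x))
  trainX <- toMat(trainX); valX <- toMat(valX)
  obs <- unique(as.character(c(trainY, valY)))
  if (is.null(classes)) {
    classes <- obs[order(obs, method = "radix")]   # locale-independent
  } else if (!all(obs %in% classes)) {
    stop("labels outside the declared class set")
  }
  yTr <- match(as.character(trainY), classes)
  yVa <- match(as.character(valY), classes)
  w <- tconf$classWeights
  if (is.null(w)) w <- classWeights(tabulate(yTr, length(classes)))
  Xtr <- stackEpochs(trainX)
  Xva <- stackEpochs(valX)
  nTr <- length(yTr)
  runWithSeed(tconf$seed, {
    state <- new.env()
    state$t <- 0; state$m <- list(); state$v <- list()
    best <- list(loss = Inf, params = model$params, epoch = 0)
    history <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                          valLoss = numeric(0))
    for (ep in seq_len(tconf$maxEpochs)) {
      ord <- sample.int(nTr)
      starts <- seq(1, nTr, by = tconf$batchSize)
      epLoss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + tconf$batchSize - 1, nTr)]
        fw <- modelForward(model, Xtr[, , idx, drop = FALSE],
                           training = TRUE, backprop = TRUE)
        model <- fw$model                      # BN running stats, if any
        ls <- ceLossFwd(fw$logits, yTr[idx], w)
        epLoss <- epLoss + ls$loss * length(idx)
        grads <- modelBackward(model, fw$caches, ls$dLogits)
        grads <- agcClipGrads(grads, model$params,
                              tconf$agcLambda, tconf$agcEps)
        upd <- adamStep(model$params, grads, state, tconf$lr)
        model$params <- upd$params
      }
      vw <- modelForward(model, Xva, training = FALSE)
      vl <- ceLossFwd(vw$logits, yVa, w)$loss
      history <- rbind(history, data.frame(
        epoch = ep, trainLoss = epLoss / nTr, valLoss = vl))
      if (vl < best$loss - 1e-12) {
        best <- list(loss = vl, params = model$params, epoch = ep)
      } else if (ep - best$epoch >= tconf$patience) break
    }
    model$params <- best$params
    model$trained <- TRUE
    model$history <- history
    model$classes <- classes
    model$classWeightsUsed <- w
    model$bestEpoch <- best$epoch
    model
  })
}

#' Predict class probabilities for epochs
#'
#' Softmax probabilities per epoch; rows sum to 1. Inference is
#' batch-size-invariant for normalizer-free variants.
#'
#' @param model trained \code{nfnetModel}.
#' @param epochsX list of matrices or \linkS4class{FusedEpoch}s.
#' @return matrix (epochs x classes), columns named by class.
#' @export
predictEpochs <- function(model, epochsX) {
  xs <- lapply(epochsX, function(x)
    if (is(x, "FusedEpoch")) fusedValues(x) else as.matrix(x))
  X <- stackEpochs(xs)
  fw <- modelForward(model, X, training = FALSE)
  P <- softmaxRows(t(fw$logits))
  colnames(P) <- model$classes
  P
}

#' Extract temporal attention weights
#'
#' Head-averaged post-softmax self-attention received by each post-pooling
#' time step (a distribution over the temporal axis summing to 1), plus a
#' nearest-neighbour upsampled projection back to the input sample axis for
#' overlay on the fused sequence heatmaps.
#'
#' @param model trained model with an attention module.
#' @param epochsX list of matrices or \linkS4class{FusedEpoch}s.
#' @param inputLength length of the upsampled projection axis (defaults to
#'   the input T of the supplied epochs).
#' @return list of class \code{AttentionMap}: \code{weights}
#'   (epochs x Tpost), \code{upsampled} (epochs x inputLength, each row
#'   still summing to 1).
#' @export
extractAttention <- function(model, epochsX, inputLength = NULL) {
  if (model$config$variant == "nfnet_no_attn")
    stop("model variant has no attention module")
  xs <- lapply(epochsX, function(x)
    if (is(x, "FusedEpoch")) fusedValues(x) else as.matrix(x))
  if (is.null(inputLength)) inputLength <- ncol(xs[[1]])
  X <- stackEpochs(xs)
  fw <- modelForward(model, X, training = FALSE)
  W <- fw$attention                            # B x Tpost
  Tpost <- ncol(W)
  fac <- inputLength / Tpost
  up <- W[, rep(seq_len(Tpost), each = ceiling(fac)), drop = FALSE]
  up <- up[, seq_len(inputLength), drop = FALSE] / fac
  structure(list(weights = W, upsampled = up), class = "AttentionMap")
}

#' Attention allocation score toward target rows
#'
#' Attributes each time step's attention mass to the target rows in
#' proportion to their share of the total row energy (absolute soft values)
#' at that step; the score is the attention-weighted mean attribution over
#' time, in [0, 1]. Subject-level scores average over the subject's epochs.
#'
#' @param att an \code{AttentionMap} from \code{\link{extractAttention}}.
#' @param fused list of \linkS4class{FusedEpoch}s (or 8 x T matrices)
#'   matching the attention rows.
#' @param targetRows indices in 1..8 of the target band/class rows.
#' @return numeric vector of per-epoch scores; \code{attr(,"mean")} is the
#'   subject-level mean.
#' @export
attentionAllocation <- function(att, fused, targetRows) {
  if (!length(targetRows)) stop("empty target row set")
  if (any(targetRows < 1 | targetRows > 8)) stop("targetRows must be in 1..8")
  xs <- lapply(fused, function(x)
    if (is(x, "FusedEpoch")) fusedValues(x) else as.matrix(x))
  scores <- vapply(seq_along(xs), function(i) {
    v <- abs(xs[[i]])
    a <- att$upsampled[i, ]
    tot <- colSums(v)
    share <- ifelse(tot > 0, colSums(v[targetRows, , drop = FALSE]) / tot, 0)
    sum(a * share) / sum(a)
  }, 0)
  attr(scores, "mean") <- mean(scores)
  scores
}
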