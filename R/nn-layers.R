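## Primitive differentiable layers for the 1D classifier, pure R matrix ops.
## Batch tensors are 3D arrays dim (channels, time, batch); convolutions run
## through an im2col reshape so the heavy lifting is a single BLAS matmul.
## Each *Fwd returns list(out, cache); each *Bwd consumes (dOut, cache) and
## returns list(dX, grads...).

conv1dInit <- function(inC, outC, k, seedless = FALSE) {
  fan <- inC * k
  W <- matrix(stats::rnorm(outC * fan, sd = sqrt(2 / fan)), outC, fan)
  list(W = W, b = numeric(outC), k = k, inC = inC, outC = outC)
}

conv1dFwd <- function(X, layer, stride = 1L, pad = (layer$k - 1L) %/% 2L) {
  d <- dim(X); C <- d[1]; T_ <- d[2]; B <- d[3]
  k <- layer$k
  Tp <- T_ + 2L * pad
  Tout <- (Tp - k) %/% stride + 1L
  S <- im2colOperator(k, stride, Tout, T_, pad, B)  # (T*B, k*Tout*B) sparse
  Xf <- X
  dim(Xf) <- c(C, T_ * B)
  M <- as.matrix(Xf %*% S)                  # columns ordered (j, t, b)
  dim(M) <- c(C * k, Tout * B)
  Y <- layer$W %*% M + layer$b
  dim(Y) <- c(layer$outC, Tout, B)
  list(out = Y,
       cache = list(M = M, dims = c(C, T_, B, Tp, Tout), stride = stride,
                    pad = pad, k = k, W = layer$W))
}

conv1dBwd <- function(dY, cache, needInput = TRUE) {
  cd <- cache$dims
  C <- cd[1]; T_ <- cd[2]; B <- cd[3]; Tp <- cd[4]; Tout <- cd[5]
  k <- cache$k; stride <- cache$stride; pad <- cache$pad
  outC <- nrow(cache$W)
  dim(dY) <- c(outC, Tout * B)
  dW <- tcrossprod(dY, cache$M)
  db <- rowSums(dY)
  if (!needInput) return(list(dX = NULL, dW = dW, db = db))
  dM <- crossprod(cache$W, dY)              # (C*k) x (Tout*B)
  ## col2im scatter-add: per batch sample, one sparse matmul maps the
  ## (k, Tout) window grid back onto the (unpadded) time axis
  S <- im2colOperator(k, stride, Tout, T_, pad, B)
  dim(dM) <- c(C, k * Tout * B)
  dX <- as.matrix(Matrix::tcrossprod(dM, S))
  dim(dX) <- c(C, T_, B)
  list(dX = dX, dW = dW, db = db)
}

## memoised block-diagonal sparse ((T*B) x (k*Tout*B)) 0/1 gather: within
## each batch block, column (j, t) reads input time (t-1)*stride + j - pad;
## out-of-range (padding) entries are zero rows
.im2colMemo <- new.env(parent = emptyenv())
im2colOperator <- function(k, stride, Tout, T_, pad, B) {
  key <- paste(k, stride, Tout, T_, pad, B, sep = "_")
  S <- .im2colMemo[[key]]
  if (is.null(S)) {
    src <- as.vector(outer(seq_len(k), (0:(Tout - 1L)) * stride, "+")) - pad
    keep <- src >= 1L & src <= T_
    src <- src[keep]
    col <- which(keep)
    nb <- k * Tout
    i <- rep(src, B) + rep((0:(B - 1L)) * T_, each = length(src))
    j <- rep(col, B) + rep((0:(B - 1L)) * nb, each = length(col))
    S <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                              dims = c(T_ * B, nb * B))
    .im2colMemo[[key]] <- S
  }
  S
}

reluFwd <- function(X) {
  mask <- X > 0
  list(out = X * mask, cache = mask)
}
reluBwd <- function(dY, mask) dY * mask

maxPoolFwd <- function(X, k = 4L) {
  d <- dim(X); C <- d[1]; T_ <- d[2]; B <- d[3]
  Tout <- T_ %/% k
  Xr <- X[, seq_len(Tout * k), , drop = FALSE]
  dim(Xr) <- c(C, k, Tout, B)
  Y <- Xr[, 1, , , drop = FALSE]
  dim(Y) <- c(C, Tout, B)
  for (j in 2:k) {
    s <- Xr[, j, , , drop = FALSE]
    dim(s) <- c(C, Tout, B)
    Y <- pmax(Y, s)
  }
  list(out = Y, cache = list(Xr = Xr, Y = Y, k = k, dims = c(C, T_, B, Tout)))
}

maxPoolBwd <- function(dY, cache) {
  cd <- cache$dims
  C <- cd[1]; T_ <- cd[2]; B <- cd[3]; Tout <- cd[4]
  k <- cache$k
  dXr <- array(0, c(C, k, Tout, B))
  taken <- array(FALSE, c(C, Tout, B))
  for (j in seq_len(k)) {
    s <- cache$Xr[, j, , , drop = FALSE]
    dim(s) <- c(C, Tout, B)
    sel <- (s == cache$Y) & !taken          # gradient to first max only
    taken <- taken | sel
    dXr[, j, , ] <- dY * sel
  }
  dX <- array(0, c(C, T_, B))
  dim(dXr) <- c(C, k * Tout, B)
  dX[, seq_len(k * Tout), ] <- dXr
  dX
}

## Per-channel batch normalisation over (time, batch); training mode uses
## batch statistics and maintains running averages for inference.
bnInit <- function(C) {
  list(gamma = rep(1, C), beta = numeric(C),
       runMean = numeric(C), runVar = rep(1, C), momentum = 0.1, eps = 1e-5)
}

bnFwd <- function(X, layer, training = TRUE) {
  d <- dim(X); C <- d[1]
  Xm <- X; dim(Xm) <- c(C, d[2] * d[3])
  if (training) {
    mu <- rowMeans(Xm)
    va <- rowMeans((Xm - mu)^2)
    layer$runMean <- (1 - layer$momentum) * layer$runMean + layer$momentum * mu
    layer$runVar <- (1 - layer$momentum) * layer$runVar + layer$momentum * va
  } else {
    mu <- layer$runMean
    va <- layer$runVar
  }
  inv <- 1 / sqrt(va + layer$eps)
  Xh <- (Xm - mu) * inv
  Y <- layer$gamma * Xh + layer$beta
  dim(Y) <- d
  list(out = Y, layer = layer,
       cache = list(Xh = Xh, inv = inv, gamma = layer$gamma, dims = d,
                    training = training))
}

bnBwd <- function(dY, cache) {
  d <- cache$dims; C <- d[1]; n <- d[2] * d[3]
  dYm <- dY; dim(dYm) <- c(C, n)
  dgamma <- rowSums(dYm * cache$Xh)
  dbeta <- rowSums(dYm)
  if (cache$training) {
    dXh <- dYm * cache$gamma
    dXm <- cache$inv * (dXh - rowMeans(dXh) - cache$Xh * rowMeans(dXh * cache$Xh))
  } else {
    dXm <- dYm * cache$gamma * cache$inv
  }
  dim(dXm) <- d
  list(dX = dXm, dgamma = dgamma, dbeta = dbeta)
}

linearInit <- function(inF, outF) {
  list(W = matrix(stats::rnorm(outF * inF, sd = sqrt(2 / inF)), outF, inF),
       b = numeric(outF))
}

## X: (inF, B) -> (outF, B)
linearFwd <- function(X, layer) {
  list(out = layer$W %*% X + layer$b, cache = list(X = X, W = layer$W))
}
linearBwd <- function(dY, cache) {
  list(dX = crossprod(cache$W, dY), dW = dY %*% t(cache$X), db = rowSums(dY))
}

softmaxRows <- function(Z) {
  mx <- Z[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))]
  E <- exp(Z - mx)
  E / rowSums(E)
}

mhsaInit <- function(C, embed, heads) {
  if (embed %% heads != 0) stop("embed dimension must be divisible by heads")
  list(proj = conv1dInit(C, embed, 1L),
       Wq = linearInit(embed, embed), Wk = linearInit(embed, embed),
       Wv = linearInit(embed, embed), Wo = linearInit(embed, embed),
       heads = heads, embed = embed)
}

## Multi-head self-attention over the temporal axis with a residual
## connection; input (C, T, B) is first projected to the embedding width by
## a 1x1 convolution. Head-averaged attention matrices are cached per
## sample for interpretability.
mhsaFwd <- function(X, layer) {
  p <- conv1dFwd(X, layer$proj, stride = 1L, pad = 0L)
  E3 <- p$out                                # (embed, T, B)
  d <- dim(E3); Cd <- d[1]; T_ <- d[2]; B <- d[3]
  h <- layer$heads; dh <- Cd %/% h
  scale <- 1 / sqrt(dh)
  out <- array(0, d)
  caches <- vector("list", B)
  attn <- matrix(0, B, T_)                   # head+query-averaged, rows sum 1
  for (bi in seq_len(B)) {
    E <- t(E3[, , bi])                       # T x embed
    Q <- E %*% t(layer$Wq$W) + rep(layer$Wq$b, each = T_)
    K <- E %*% t(layer$Wk$W) + rep(layer$Wk$b, each = T_)
    V <- E %*% t(layer$Wv$W) + rep(layer$Wv$b, each = T_)
    H <- matrix(0, T_, Cd)
    A <- vector("list", h)
    Amean <- matrix(0, T_, T_)
    for (hi in seq_len(h)) {
      cols <- ((hi - 1) * dh + 1):(hi * dh)
      S <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) * scale
      A[[hi]] <- softmaxRows(S)
      H[, cols] <- A[[hi]] %*% V[, cols, drop = FALSE]
      Amean <- Amean + A[[hi]] / h
    }
    O <- H %*% t(layer$Wo$W) + rep(layer$Wo$b, each = T_)
    out[, , bi] <- t(E + O)                  # residual
    attn[bi, ] <- colMeans(Amean)
    caches[[bi]] <- list(E = E, Q = Q, K = K, V = V, H = H, A = A)
  }
  list(out = out, attention = attn,
       cache = list(proj = p$cache, caches = caches, dims = d,
                    layer = layer[c("heads", "embed")],
                    Wq = layer$Wq$W, Wk = layer$Wk$W, Wv = layer$Wv$W,
                    Wo = layer$Wo$W))
}

mhsaBwd <- function(dY, cache) {
  d <- cache$dims; Cd <- d[1]; T_ <- d[2]; B <- d[3]
  h <- cache$layer$heads; dh <- Cd %/% h
  scale <- 1 / sqrt(dh)
  dWq <- matrix(0, Cd, Cd); dWk <- matrix(0, Cd, Cd)
  dWv <- matrix(0, Cd, Cd); dWo <- matrix(0, Cd, Cd)
  dbq <- numeric(Cd); dbk <- numeric(Cd); dbv <- numeric(Cd); dbo <- numeric(Cd)
  dE3 <- array(0, d)
  for (bi in seq_len(B)) {
    cb <- cache$caches[[bi]]
    dOut <- t(dY[, , bi])                    # T x embed, into residual sum
    dO <- dOut
    dE <- dOut                               # residual path
    dH <- dO %*% cache$Wo
    dWo <- dWo + t(dO) %*% cb$H
    dbo <- dbo + colSums(dO)
    dQ <- matrix(0, T_, Cd); dK <- matrix(0, T_, Cd); dV <- matrix(0, T_, Cd)
    for (hi in seq_len(h)) {
      cols <- ((hi - 1) * dh + 1):(hi * dh)
      A <- cb$A[[hi]]
      dHh <- dH[, cols, drop = FALSE]
      dA <- dHh %*% t(cb$V[, cols, drop = FALSE])
      dV[, cols] <- t(A) %*% dHh
      dS <- A * (dA - rowSums(dA * A))       # softmax backward (rows)
      dQ[, cols] <- (dS %*% cb$K[, cols, drop = FALSE]) * scale
      dK[, cols] <- (t(dS) %*% cb$Q[, cols, drop = FALSE]) * scale
    }
    dWq <- dWq + t(dQ) %*% cb$E; dbq <- dbq + colSums(dQ)
    dWk <- dWk + t(dK) %*% cb$E; dbk <- dbk + colSums(dK)
    dWv <- dWv + t(dV) %*% cb$E; dbv <- dbv + colSums(dV)
    dE <- dE + dQ %*% cache$Wq + dK %*% cache$Wk + dV %*% cache$Wv
    dE3[, , bi] <- t(dE)
  }
  pb <- conv1dBwd(dE3, cache$proj)
  list(dX = pb$dX,
       grads = list(proj.W = pb$dW, proj.b = pb$db,
                    Wq.W = dWq, Wq.b = dbq, Wk.W = dWk, Wk.b = dbk,
                    Wv.W = dWv, Wv.b = dbv, Wo.W = dWo, Wo.b = dbo))
}

## Global average pooling over time: (C, T, B) -> (C, B)
gapFwd <- function(X) {
  d <- dim(X)
  M <- X
  dim(M) <- c(d[1] * d[2], d[3])
  Y <- rowsum(M, group = rep(seq_len(d[1]), times = d[2])) / d[2]
  list(out = Y, cache = d)
}
gapBwd <- function(dY, d) {
  dX <- array(0, d)
  g <- dY / d[2]
  for (t in seq_len(d[2])) dX[, t, ] <- g
  dX
}

dropoutFwd <- function(X, p, training = TRUE) {
  if (!training || p <= 0) return(list(out = X, cache = NULL))
  mask <- (stats::runif(length(X)) > p) / (1 - p)
  dim(mask) <- dim(X)
  list(out = X * mask, cache = mask)
}
dropoutBwd <- function(dY, mask) if (is.null(mask)) dY else dY * mask

## Weighted softmax cross-entropy. logits: (K, B); y: integer class 1..K;
## w: per-class weights. Loss = sum_b w[y_b] * nll_b / sum_b w[y_b].
ceLossFwd <- function(logits, y, w = NULL) {
  K <- nrow(logits); B <- ncol(logits)
  if (is.null(w)) w <- rep(1, K)
  P <- t(softmaxRows(t(logits)))
  wy <- w[y]
  nll <- -log(pmax(P[cbind(y, seq_len(B))], 1e-12))
  loss <- sum(wy * nll) / sum(wy)
  dZ <- P
  dZ[cbind(y, seq_len(B))] <- dZ[cbind(y, seq_len(B))] - 1
  dZ <- dZ * rep(wy, each = K) / sum(wy)
  list(loss = loss, dLogits = dZ, probs = t(P))
}
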