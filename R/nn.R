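# Hand-rolled training engine for the multi-branch EEGNet-style network.
#
# No deep-learning framework is available to (or wanted by) this package:
# forward passes, backpropagation, batch normalization, Adam and the
# max-norm constraint are implemented here, with the depthwise convolution
# inner loops in src/conv.cpp and the dense temporal convolution expressed
# as an im2col GEMM so BLAS does the heavy lifting.
#
# Activation layout convention: matrices of (T * n) rows and M feature
# columns, time fastest within each sample's contiguous row block.

BN_EPS <- 1e-3       # batch-norm epsilon (Keras default)
BN_MOMENTUM <- 0.99  # running-stat momentum

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

# ---- parameter initialization --------------------------------------------

init_net <- function(spec) {
  params <- list()
  bnstate <- list()
  C <- spec$n_channels; W <- spec$window_len; K <- spec$n_classes
  fused <- 0L
  for (i in seq_along(spec$branches)) {
    b <- spec$branches[[i]]
    F1 <- b$n_temporal_filters; k <- b$temporal_kernel_len
    D <- b$depth_multiplier; M <- F1 * D
    F2 <- b$n_separable_filters; ks <- b$separable_kernel_len
    p <- function(nm) paste0("b", i, ".", nm)
    params[[p("Wt")]] <- glorot(k, k * F1, c(k, F1))
    params[[p("g1")]] <- rep(1, F1); params[[p("be1")]] <- rep(0, F1)
    params[[p("Wd")]] <- glorot(C, C * D, c(C, M))
    params[[p("g2")]] <- rep(1, M); params[[p("be2")]] <- rep(0, M)
    params[[p("Ws")]] <- glorot(ks * M, ks * M, c(ks, M))
    params[[p("Wp")]] <- glorot(M, F2, c(M, F2))
    params[[p("g3")]] <- rep(1, F2); params[[p("be3")]] <- rep(0, F2)
    for (s in c("bn1", "bn2", "bn3")) {
      dimn <- switch(s, bn1 = F1, bn2 = M, bn3 = F2)
      bnstate[[p(paste0(s, ".mu"))]] <- rep(0, dimn)
      bnstate[[p(paste0(s, ".var"))]] <- rep(1, dimn)
    }
    fused <- fused + F2 * ((W %/% b$pool1_len) %/% b$pool2_len)
  }
  params[["head.Wf"]] <- glorot(fused, K, c(fused, K))
  params[["head.bf"]] <- rep(0, K)
  list(spec = spec, params = params, bn = bnstate, fused_dim = fused)
}

branch_feature_dims <- function(spec) {
  vapply(spec$branches, function(b)
    b$n_separable_filters * ((spec$window_len %/% b$pool1_len) %/% b$pool2_len),
    integer(1))
}

count_params <- function(net) {
  sum(vapply(net$params, length, integer(1)))
}

# ---- primitive layers -----------------------------------------------------

conv_temporal_im2col <- function(Xm, k) {
  W <- nrow(Xm); S <- ncol(Xm)
  padL <- (k - 1L) %/% 2L; padR <- k - 1L - padL
  Xp <- rbind(matrix(0, padL, S), Xm, matrix(0, padR, S))
  Xcol <- matrix(0, W * S, k)
  for (j in seq_len(k))
    Xcol[, j] <- as.vector(Xp[j:(j + W - 1L), , drop = FALSE])
  Xcol
}

conv_temporal_fw <- function(Xm, K) {
  Xcol <- conv_temporal_im2col(Xm, nrow(K))
  list(Y = Xcol %*% K, W = nrow(Xm), S = ncol(Xm))
}

conv_temporal_bw <- function(Xm, K, dY) {
  k <- nrow(K); W <- nrow(Xm); S <- ncol(Xm)
  padL <- (k - 1L) %/% 2L
  Xcol <- conv_temporal_im2col(Xm, k)
  dK <- crossprod(Xcol, dY)
  dXcol <- tcrossprod(dY, K)
  dXp <- matrix(0, W + k - 1L, S)
  for (j in seq_len(k))
    dXp[j:(j + W - 1L), ] <- dXp[j:(j + W - 1L), ] + matrix(dXcol[, j], W, S)
  list(dX = dXp[padL + seq_len(W), , drop = FALSE], dK = dK)
}

bn_fw <- function(x, gamma, beta, run_mu, run_var, train) {
  if (train) {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    v <- colMeans(xc * xc)
    invstd <- 1 / sqrt(v + BN_EPS)
    xhat <- sweep(xc, 2, invstd, "*")
    y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
    list(y = y, xhat = xhat, invstd = invstd,
         new_mu = BN_MOMENTUM * run_mu + (1 - BN_MOMENTUM) * mu,
         new_var = BN_MOMENTUM * run_var + (1 - BN_MOMENTUM) * v)
  } else {
    xhat <- sweep(sweep(x, 2, run_mu), 2, 1 / sqrt(run_var + BN_EPS), "*")
    list(y = sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+"))
  }
}

bn_bw <- function(cache, gamma, dY) {
  n <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, gamma, "*")
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
  dx <- sweep(t1 - t2, 2, cache$invstd, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

elu_fw <- function(x) {
  y <- x
  neg <- x < 0
  y[neg] <- exp(x[neg]) - 1
  y
}

elu_bw <- function(y, x, dY) {
  g <- dY
  neg <- x < 0
  g[neg] <- dY[neg] * (y[neg] + 1)
  g
}

# average pooling along time (drop trailing remainder), segment length T
pool_fw <- function(x, T, p) {
  n <- nrow(x) %/% T
  T2 <- T %/% p
  used <- as.vector(outer(seq_len(T2 * p), (seq_len(n) - 1L) * T, "+"))
  xu <- x[used, , drop = FALSE]
  dim(xu) <- c(p, T2 * n, ncol(x))
  list(y = colMeans(xu), used = used, n = n, T = T, T2 = T2, p = p, M = ncol(x))
}

pool_bw <- function(cache, dY) {
  dxu <- dY[rep(seq_len(cache$T2 * cache$n), each = cache$p), , drop = FALSE] / cache$p
  dx <- matrix(0, cache$T * cache$n, cache$M)
  dx[cache$used, ] <- dxu
  dx
}

dropout_fw <- function(x, prob, train) {
  if (!train || prob <= 0) return(list(y = x, mask = NULL))
  mask <- matrix(stats::rbinom(length(x), 1, 1 - prob) / (1 - prob),
                 nrow(x), ncol(x))
  list(y = x * mask, mask = mask)
}

# ---- branch and network forward/backward ---------------------------------

branch_fw <- function(pr, bn, b, i, Xm, C, n, train) {
  p <- function(nm) paste0("b", i, ".", nm)
  W <- nrow(Xm)
  cache <- list()
  ct <- conv_temporal_fw(Xm, pr[[p("Wt")]])           # (W*S) x F1
  cache$Xm <- Xm
  b1 <- bn_fw(ct$Y, pr[[p("g1")]], pr[[p("be1")]],
              bn[[p("bn1.mu")]], bn[[p("bn1.var")]], train)
  cache$bn1 <- b1
  A <- b1$y; dim(A) <- c(W, C * n, b$n_temporal_filters)
  cache$A <- A
  H2 <- cpp_dwspatial_fw(A, pr[[p("Wd")]], C, b$depth_multiplier)  # (W*n) x M
  b2 <- bn_fw(H2, pr[[p("g2")]], pr[[p("be2")]],
              bn[[p("bn2.mu")]], bn[[p("bn2.var")]], train)
  cache$bn2 <- b2
  e2 <- elu_fw(b2$y); cache$e2_x <- b2$y; cache$e2_y <- e2
  pl1 <- pool_fw(e2, W, b$pool1_len); cache$pl1 <- pl1
  dr1 <- dropout_fw(pl1$y, b$dropout_p, train); cache$dr1 <- dr1
  T1 <- pl1$T2
  H3 <- cpp_dwconv1d_same_fw(dr1$y, pr[[p("Ws")]], T1)
  cache$H3in <- dr1$y; cache$T1 <- T1
  P <- H3 %*% pr[[p("Wp")]]                            # (T1*n) x F2
  cache$H3 <- H3
  b3 <- bn_fw(P, pr[[p("g3")]], pr[[p("be3")]],
              bn[[p("bn3.mu")]], bn[[p("bn3.var")]], train)
  cache$bn3 <- b3
  e3 <- elu_fw(b3$y); cache$e3_x <- b3$y; cache$e3_y <- e3
  pl2 <- pool_fw(e3, T1, b$pool2_len); cache$pl2 <- pl2
  dr2 <- dropout_fw(pl2$y, b$dropout_p, train); cache$dr2 <- dr2
  # flatten: per-sample feature vector over (time, filter)
  T2 <- pl2$T2; F2 <- b$n_separable_filters
  Z <- dr2$y; dim(Z) <- c(T2, n, F2)
  feat <- t(matrix(aperm(Z, c(1, 3, 2)), T2 * F2, n))  # n x (T2*F2)
  cache$T2 <- T2
  list(feat = feat, cache = cache)
}

branch_bw <- function(pr, b, i, cache, dFeat, C, n) {
  p <- function(nm) paste0("b", i, ".", nm)
  grads <- list()
  T2 <- cache$T2; F2 <- b$n_separable_filters
  dZ <- aperm(array(t(dFeat), c(T2, F2, n)), c(1, 3, 2))
  dim(dZ) <- c(T2 * n, F2)
  if (!is.null(cache$dr2$mask)) dZ <- dZ * cache$dr2$mask
  dE3 <- pool_bw(cache$pl2, dZ)
  dB3 <- elu_bw(cache$e3_y, cache$e3_x, dE3)
  bb3 <- bn_bw(cache$bn3, pr[[p("g3")]], dB3)
  grads[[p("g3")]] <- bb3$dgamma; grads[[p("be3")]] <- bb3$dbeta
  dP <- bb3$dx
  grads[[p("Wp")]] <- crossprod(cache$H3, dP)
  dH3 <- tcrossprod(dP, pr[[p("Wp")]])
  sep <- cpp_dwconv1d_same_bw(cache$H3in, pr[[p("Ws")]], dH3, cache$T1)
  grads[[p("Ws")]] <- sep$dK
  dD1 <- sep$dX
  if (!is.null(cache$dr1$mask)) dD1 <- dD1 * cache$dr1$mask
  dE2 <- pool_bw(cache$pl1, dD1)
  dB2 <- elu_bw(cache$e2_y, cache$e2_x, dE2)
  bb2 <- bn_bw(cache$bn2, pr[[p("g2")]], dB2)
  grads[[p("g2")]] <- bb2$dgamma; grads[[p("be2")]] <- bb2$dbeta
  sp <- cpp_dwspatial_bw(cache$A, pr[[p("Wd")]], bb2$dx, C, b$depth_multiplier)
  grads[[p("Wd")]] <- sp$dWd
  dA <- sp$dA; dim(dA) <- c(nrow(cache$Xm) * C * n, b$n_temporal_filters)
  bb1 <- bn_bw(cache$bn1, pr[[p("g1")]], dA)
  grads[[p("g1")]] <- bb1$dgamma; grads[[p("be1")]] <- bb1$dbeta
  ct <- conv_temporal_bw(cache$Xm, pr[[p("Wt")]], bb1$dx)
  grads[[p("Wt")]] <- ct$dK
  grads
}

# X: array (n, C, W) -> softmax probabilities, optional caches for backprop
net_forward <- function(net, X, train = FALSE, keep_cache = train) {
  spec <- net$spec
  n <- dim(X)[1]; C <- dim(X)[2]; W <- dim(X)[3]
  if (C != spec$n_channels || W != spec$window_len)
    stopf("input is %d x %d but the model expects %d x %d",
          C, W, spec$n_channels, spec$window_len)
  Xm <- matrix(aperm(X, c(3, 2, 1)), nrow = W)  # (W, C*n), channel then sample
  feats <- vector("list", length(spec$branches))
  caches <- vector("list", length(spec$branches))
  newbn <- net$bn
  for (i in seq_along(spec$branches)) {
    br <- branch_fw(net$params, net$bn, spec$branches[[i]], i, Xm, C, n, train)
    feats[[i]] <- br$feat
    if (keep_cache) caches[[i]] <- br$cache
    if (train) {
      p <- function(nm) paste0("b", i, ".", nm)
      newbn[[p("bn1.mu")]] <- br$cache$bn1$new_mu
      newbn[[p("bn1.var")]] <- br$cache$bn1$new_var
      newbn[[p("bn2.mu")]] <- br$cache$bn2$new_mu
      newbn[[p("bn2.var")]] <- br$cache$bn2$new_var
      newbn[[p("bn3.mu")]] <- br$cache$bn3$new_mu
      newbn[[p("bn3.var")]] <- br$cache$bn3$new_var
    }
  }
  Fmat <- do.call(cbind, feats)
  logits <- sweep(Fmat %*% net$params[["head.Wf"]], 2, net$params[["head.bf"]], "+")
  probs <- softmax_rows(logits)
  list(probs = probs, Fmat = Fmat, caches = caches, new_bn = newbn, n = n)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# cross-entropy losses on softmax outputs; returns loss and dLoss/dLogits
loss_grad <- function(probs, onehot, loss = c("categorical", "binary")) {
  loss <- match.arg(loss)
  n <- nrow(probs); K <- ncol(probs)
  p <- pmin(pmax(probs, 1e-7), 1 - 1e-7)
  if (loss == "categorical") {
    L <- -mean(rowSums(onehot * log(p)))
    dlogits <- (probs - onehot) / n
  } else {
    L <- -mean(onehot * log(p) + (1 - onehot) * log(1 - p))
    dLdp <- -(onehot / p - (1 - onehot) / (1 - p)) / (n * K)
    dlogits <- probs * (dLdp - rowSums(dLdp * probs))
  }
  list(loss = L, dlogits = dlogits)
}

net_backward <- function(net, fwd, dlogits) {
  spec <- net$spec
  grads <- list()
  grads[["head.Wf"]] <- crossprod(fwd$Fmat, dlogits)
  grads[["head.bf"]] <- colSums(dlogits)
  dF <- tcrossprod(dlogits, net$params[["head.Wf"]])
  dims <- branch_feature_dims(spec)
  off <- 0L
  C <- spec$n_channels; n <- fwd$n
  for (i in seq_along(spec$branches)) {
    dFeat <- dF[, off + seq_len(dims[i]), drop = FALSE]
    off <- off + dims[i]
    grads <- c(grads, branch_bw(net$params, spec$branches[[i]], i,
                                fwd$caches[[i]], dFeat, C, n))
  }
  grads
}

# ---- optimizer ------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# max-norm 1.0 constraint on each depthwise spatial filter (EEGNet convention)
apply_maxnorm <- function(params, spec, max_norm = 1) {
  for (i in seq_along(spec$branches)) {
    nm <- paste0("b", i, ".Wd")
    w <- params[[nm]]
    nrm <- sqrt(colSums(w * w))
    over <- nrm > max_norm
    if (any(over)) {
      w[, over] <- sweep(w[, over, drop = FALSE], 2, nrm[over] / max_norm, "/")
      params[[nm]] <- w
    }
  }
  params
}
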