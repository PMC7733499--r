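# Minimal feed-forward networks used by the classification/regression heads
# and the reduced full-training mode: a one-hidden-layer MLP and a
# one-conv-layer network, both trained with Adam. Written as plain
# state-passing functions; all randomness (init, dropout, batches) comes
# from the caller's seeded stream.

heInit <- function(nrowW, ncolW) {
  matrix(rnorm(nrowW * ncolW, 0, sqrt(2 / nrowW)), nrowW, ncolW)
}

adamNew <- function(shapes) {
  lapply(shapes, function(s) list(m = array(0, dim = s), v = array(0, dim = s)))
}

adamStep <- function(opt, grads, params, lr, t, b1 = 0.9, b2 = 0.999,
                     eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt[[nm]]$m <- b1 * opt[[nm]]$m + (1 - b1) * g
    opt[[nm]]$v <- b2 * opt[[nm]]$v + (1 - b2) * g^2
    mh <- opt[[nm]]$m / (1 - b1^t)
    vh <- opt[[nm]]$v / (1 - b2^t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(opt = opt, params = params)
}

softmaxRows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

# ---- MLP ---------------------------------------------------------------

mlpNew <- function(d, hidden, K, task = c("softmax", "sigmoid"),
                   lr = 1e-3, dropout = 0, l1 = 0, l2 = 0) {
  task <- match.arg(task)
  params <- if (hidden > 0) {
    list(W1 = heInit(d, hidden), b1 = rep(0, hidden),
         W2 = heInit(hidden, K), b2 = rep(0, K))
  } else {
    list(W2 = heInit(d, K), b2 = rep(0, K))
  }
  list(params = params, opt = adamNew(lapply(params, dim2)), t = 0L,
       hidden = hidden, task = task, lr = lr, dropout = dropout,
       l1 = l1, l2 = l2, d = d, K = K)
}

dim2 <- function(x) if (is.matrix(x)) dim(x) else length(x)

mlpForward <- function(net, X, training = FALSE) {
  p <- net$params
  if (net$hidden > 0) {
    Z1 <- sweep(X %*% p$W1, 2, p$b1, "+")
    A1 <- pmax(Z1, 0)
    mask <- NULL
    if (training && net$dropout > 0) {
      mask <- matrix(runif(length(A1)) >= net$dropout, nrow(A1), ncol(A1))
      A1 <- A1 * mask / (1 - net$dropout)   # inverted dropout
    }
    S <- sweep(A1 %*% p$W2, 2, p$b2, "+")
    list(S = S, A1 = A1, Z1 = Z1, mask = mask)
  } else {
    list(S = sweep(X %*% p$W2, 2, p$b2, "+"))
  }
}

# one minibatch gradient step; Y is one-hot (softmax) or a column of
# targets in (0,1) (sigmoid + squared error)
mlpStep <- function(net, X, Y) {
  fw <- mlpForward(net, X, training = TRUE)
  n <- nrow(X)
  if (net$task == "softmax") {
    P <- softmaxRows(fw$S)
    dS <- (P - Y) / n
  } else {
    P <- 1 / (1 + exp(-fw$S))
    dS <- 2 * (P - Y) * P * (1 - P) / n
  }
  p <- net$params
  grads <- list()
  if (net$hidden > 0) {
    grads$W2 <- t(fw$A1) %*% dS
    grads$b2 <- colSums(dS)
    dA1 <- dS %*% t(p$W2)
    if (!is.null(fw$mask)) dA1 <- dA1 * fw$mask / (1 - net$dropout)
    dZ1 <- dA1 * (fw$Z1 > 0)
    grads$W1 <- t(X) %*% dZ1
    grads$b1 <- colSums(dZ1)
  } else {
    grads$W2 <- t(X) %*% dS
    grads$b2 <- colSums(dS)
  }
  if (net$l2 > 0 || net$l1 > 0) {
    for (nm in intersect(names(grads), c("W1", "W2"))) {
      grads[[nm]] <- grads[[nm]] + 2 * net$l2 * p[[nm]] +
        net$l1 * sign(p[[nm]])
    }
  }
  net$t <- net$t + 1L
  upd <- adamStep(net$opt, grads, p, net$lr, net$t)
  net$opt <- upd$opt
  net$params <- upd$params
  net
}

mlpPredict <- function(net, X) {
  S <- mlpForward(net, X, training = FALSE)$S
  if (net$task == "softmax") softmaxRows(S) else 1 / (1 + exp(-S))
}

# ---- reduced conv net --------------------------------------------------
# conv (nFilters x fsize x fsize x 3, stride) -> ReLU -> coarse regional
# average pooling (poolGrid x poolGrid regions, preserving coarse spatial
# layout) -> linear softmax; trained end-to-end

convNew <- function(nFilters, fsize, stride, K, lr = 1e-3, poolGrid = 3L) {
  d <- fsize * fsize * 3L
  g2 <- poolGrid * poolGrid
  params <- list(F = heInit(d, nFilters), bF = rep(0, nFilters),
                 W = heInit(nFilters * g2, K), b = rep(0, K))
  list(params = params, opt = adamNew(lapply(params, dim2)), t = 0L,
       nFilters = nFilters, fsize = fsize, stride = stride, K = K, lr = lr,
       poolGrid = as.integer(poolGrid))
}

im2colRGB <- function(img, fsize, stride) {
  cbind(im2col(img[, , 1], fsize, stride),
        im2col(img[, , 2], fsize, stride),
        im2col(img[, , 3], fsize, stride))
}

# pooling-region index (1..g^2) of each response-map position, column-major
# over (i, j) to match im2col's position order
poolRegions <- function(nI, nJ, g) {
  ri <- pmin(ceiling(seq_len(nI) / (nI / g)), g)
  rj <- pmin(ceiling(seq_len(nJ) / (nJ / g)), g)
  as.vector(outer(ri, rj, function(a, b) (b - 1L) * g + a))
}

convForwardBatch <- function(net, imgs) {
  p <- net$params
  cols <- lapply(imgs, im2colRGB, fsize = net$fsize, stride = net$stride)
  P <- nrow(cols[[1]])
  Xc <- do.call(rbind, cols)
  Z <- sweep(Xc %*% p$F, 2, p$bF, "+")
  A <- pmax(Z, 0)
  n <- length(imgs)
  g <- net$poolGrid
  g2 <- g * g
  nI <- length(seq(1L, dim(imgs[[1]])[1] - net$fsize + 1L, by = net$stride))
  nJ <- length(seq(1L, dim(imgs[[1]])[2] - net$fsize + 1L, by = net$stride))
  reg <- poolRegions(nI, nJ, g)
  cnt <- tabulate(reg, g2)
  grp <- rep((seq_len(n) - 1L) * g2, each = P) + rep(reg, n)
  R <- rowsum(A, grp) / rep(cnt, n)          # (n*g2) x K, image-major
  G <- do.call(cbind, lapply(seq_len(g2), function(r)
    R[(seq_len(n) - 1L) * g2 + r, , drop = FALSE]))
  S <- sweep(G %*% p$W, 2, p$b, "+")
  list(S = S, G = G, A = A, Z = Z, Xc = Xc, P = P, n = n,
       reg = reg, cnt = cnt)
}

convStep <- function(net, imgs, Y) {
  fw <- convForwardBatch(net, imgs)
  n <- fw$n
  Pr <- softmaxRows(fw$S)
  dS <- (Pr - Y) / n
  p <- net$params
  grads <- list()
  grads$W <- t(fw$G) %*% dS
  grads$b <- colSums(dS)
  dG <- dS %*% t(p$W)                         # n x (g2*K)
  g2 <- net$poolGrid^2
  K <- net$nFilters
  # scatter region gradients back to response-map positions
  dA <- matrix(0, n * fw$P, K)
  for (r in seq_len(g2)) {
    block <- dG[, ((r - 1L) * K + 1L):(r * K), drop = FALSE] / fw$cnt[r]
    rows <- which(rep(fw$reg, n) == r)
    dA[rows, ] <- block[rep(seq_len(n), each = fw$cnt[r]), , drop = FALSE]
  }
  dZ <- dA * (fw$Z > 0)
  grads$F <- t(fw$Xc) %*% dZ
  grads$bF <- colSums(dZ)
  net$t <- net$t + 1L
  upd <- adamStep(net$opt, grads, p, net$lr, net$t)
  net$opt <- upd$opt
  net$params <- upd$params
  net
}

convPredict <- function(net, imgs, chunk = 256L) {
  out <- NULL
  for (s in seq(1L, length(imgs), by = chunk)) {
    idx <- s:min(s + chunk - 1L, length(imgs))
    S <- convForwardBatch(net, imgs[idx])$S
    out <- rbind(out, softmaxRows(S))
  }
  out
}
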