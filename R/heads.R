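# Tile-level models: transfer-learning classification heads over feature
# caches, a reduced full-training convolutional mode for mutation status,
# the purity regression head, and the nucleus-patch classifier.

#' Transfer-learning head configuration
#'
#' Defaults follow the reference pipeline: a 1024-unit fully connected
#' layer with 20\% dropout trained for 2000 steps in batches of 512 by Adam
#' with softmax output. Desk-scale analyses pass smaller values.
#'
#' @param hidden_units hidden layer width (0 = plain softmax regression).
#' @param dropout dropout fraction in \[0,1).
#' @param batch_size minibatch size.
#' @param steps number of gradient steps (>= 1).
#' @param lr Adam learning rate (a fixed documented default; the training
#'   procedure deliberately does no hyperparameter search).
#' @param seed training seed (init, dropout, undersampling stream).
#' @return list of class \code{HeadConfig}.
#' @export
headConfig <- function(hidden_units = 1024L, dropout = 0.20,
                       batch_size = 512L, steps = 2000L, lr = 1e-3,
                       seed = 1L) {
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0,1)")
  if (steps < 1) stop("steps must be >= 1")
  structure(list(hidden_units = as.integer(hidden_units), dropout = dropout,
                 batch_size = as.integer(batch_size),
                 steps = as.integer(steps), lr = lr,
                 seed = as.integer(seed)),
            class = "HeadConfig")
}

#' Reduced full-training configuration
#'
#' Configuration of the desk-scale fully trained network (one trainable
#' convolution layer, ReLU, global average pooling, softmax), used for
#' mutation-status and nucleus classification where transfer features are
#' too weak.
#'
#' @param n_filters,filter_size,stride convolution layer shape.
#' @param pool_grid pooling regions per axis (coarse spatial average
#'   pooling; 1 recovers global average pooling).
#' @param batch_size,steps,lr,seed as in \code{\link{headConfig}}.
#' @return list of class \code{FullConfig}.
#' @export
fullConfig <- function(n_filters = 8L, filter_size = 5L, stride = 2L,
                       pool_grid = 3L, batch_size = 32L, steps = 400L,
                       lr = 2e-3, seed = 1L) {
  structure(list(n_filters = as.integer(n_filters),
                 filter_size = as.integer(filter_size),
                 stride = as.integer(stride),
                 pool_grid = as.integer(pool_grid),
                 batch_size = as.integer(batch_size),
                 steps = as.integer(steps), lr = lr,
                 seed = as.integer(seed)),
            class = "FullConfig")
}

#' Purity regression head configuration
#'
#' A 256-unit ReLU layer with 25\% dropout, elastic-net penalties of 1e-4,
#' and a single sigmoid output, trained for 20 epochs.
#'
#' @param hidden_units,dropout,l1_penalty,l2_penalty,epochs,batch_size,lr,seed
#'   see description.
#' @return list of class \code{PurityHeadConfig}.
#' @export
purityHeadConfig <- function(hidden_units = 256L, dropout = 0.25,
                             l1_penalty = 1e-4, l2_penalty = 1e-4,
                             epochs = 20L, batch_size = 32L, lr = 5e-3,
                             seed = 1L) {
  if (l1_penalty < 0 || l2_penalty < 0) stop("penalties must be >= 0")
  structure(list(hidden_units = as.integer(hidden_units), dropout = dropout,
                 l1_penalty = l1_penalty, l2_penalty = l2_penalty,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 seed = as.integer(seed)),
            class = "PurityHeadConfig")
}

#' Class-balanced index stream by rejection undersampling
#'
#' Examples are drawn uniformly; a draw from class c is accepted with
#' probability min(count)/count(c), so the accepted stream is balanced 1:1
#' (1:...:1 for multi-class) in expectation and the minority class is never
#' rejected.
#'
#' @param labels per-example class labels.
#' @param n_draws number of accepted indices to return.
#' @param seed integer seed.
#' @return integer vector of accepted example indices (with replacement).
#' @export
undersampleStream <- function(labels, n_draws, seed = 1L) {
  cnt <- table(labels)
  if (any(cnt == 0) || length(cnt) < 2L)
    stop("every class needs at least one example")
  acc <- min(cnt) / cnt
  pAccept <- as.numeric(acc[as.character(labels)])
  n <- length(labels)
  withSeed(seed, {
    out <- integer(0)
    while (length(out) < n_draws) {
      m <- ceiling((n_draws - length(out)) / mean(pAccept)) + 16L
      cand <- sample.int(n, m, replace = TRUE)
      keep <- runif(m) < pAccept[cand]
      out <- c(out, cand[keep])
    }
    out[seq_len(n_draws)]
  })
}

featureMatrix <- function(x) {
  if (is(x, "CacheSet")) cacheFeatures(x) else as.matrix(x)
}

#' Train a transfer-learning classification head
#'
#' Fits a one-hidden-layer softmax network on feature caches using the
#' undersampled balanced stream. Classes are ordered by sorted label name;
#' features are standardized with statistics stored on the model.
#'
#' @param caches a \code{\linkS4class{CacheSet}} or feature matrix.
#' @param labels per-tile class labels (length = tile count).
#' @param config a \code{\link{headConfig}}.
#' @return model object of class \code{transferHead}.
#' @export
trainHead <- function(caches, labels, config = headConfig()) {
  X <- featureMatrix(caches)
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2L) stop("training set contains a single class")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Y <- outer(as.character(labels), classes, "==") * 1
  stream <- undersampleStream(labels, config$steps * config$batch_size,
                              seed = config$seed)
  net <- withSeed(config$seed + 1L, {
    net <- mlpNew(ncol(Xs), config$hidden_units, length(classes),
                  task = "softmax", lr = config$lr, dropout = config$dropout)
    for (s in seq_len(config$steps)) {
      idx <- stream[((s - 1L) * config$batch_size + 1L):(s * config$batch_size)]
      net <- mlpStep(net, Xs[idx, , drop = FALSE], Y[idx, , drop = FALSE])
    }
    net
  })
  structure(list(net = net, classes = classes, center = ctr, scale = scl,
                 extractor_id = if (is(caches, "CacheSet"))
                   caches@extractorId else "matrix",
                 config = config),
            class = "transferHead")
}

#' Per-tile class probabilities from a trained model
#'
#' @param model a \code{transferHead}, \code{fullModel} or
#'   \code{nucleusModel}.
#' @param caches \code{\linkS4class{CacheSet}} (transfer models) or list of
#'   pixel tiles (full models).
#' @return data.frame with slide_id/row/col (when available), one
#'   \code{prob_<class>} column per class (rows sum to 1), and
#'   \code{predicted_class} (argmax; ties broken toward the lowest class
#'   index).
#' @export
predictTiles <- function(model, caches) {
  if (inherits(model, "transferHead")) {
    X <- featureMatrix(caches)
    if (ncol(X) == 0 || nrow(X) == 0) {
      out <- data.frame(slide_id = character(0), row = integer(0),
                        col = integer(0))
      return(out)
    }
    if (ncol(X) != length(model$center)) stop("cache vector length mismatch")
    if (is(caches, "CacheSet") &&
        !identical(caches@extractorId, model$extractor_id))
      stop("extractor_id mismatch between model and caches")
    Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
    P <- mlpPredict(model$net, Xs)
    info <- if (is(caches, "CacheSet"))
      cacheInfo(caches)[, c("slide_id", "row", "col")]
    else data.frame(slide_id = "slide", row = seq_len(nrow(X)) - 1L, col = 0L)
  } else {
    imgs <- if (is.list(caches) && !is.null(caches[[1]]$pixels))
      lapply(caches, `[[`, "pixels") else caches
    P <- convPredict(model$net, imgs)
    info <- if (is.list(caches) && !is.null(caches[[1]]$slide_id))
      data.frame(slide_id = vapply(caches, `[[`, "", "slide_id"),
                 row = vapply(caches, `[[`, 0L, "row"),
                 col = vapply(caches, `[[`, 0L, "col"))
    else data.frame(slide_id = "slide", row = seq_along(imgs) - 1L, col = 0L)
  }
  colnames(P) <- paste0("prob_", model$classes)
  pred <- model$classes[max.col(P, ties.method = "first")]
  cbind(info, as.data.frame(P), predicted_class = pred,
        stringsAsFactors = FALSE)
}

#' Keep only tiles a tumor/normal model calls tumor
#'
#' Used before mutation training: tumor slides are assumed to contain
#' admixed normal tiles, and only predicted-tumor tiles are kept. Slides
#' whose tiles are all excluded are dropped with a warning.
#'
#' @param caches a \code{\linkS4class{CacheSet}} of tumor-slide tiles.
#' @param model a trained tumor/normal \code{transferHead}.
#' @param tumorClass label that counts as tumor.
#' @return the filtered \code{CacheSet}.
#' @export
prefilterTumorTiles <- function(caches, model, tumorClass = "tumor") {
  pred <- predictTiles(model, caches)
  keep <- pred$predicted_class == tumorClass
  lost <- setdiff(unique(cacheInfo(caches)$slide_id),
                  unique(cacheInfo(caches)$slide_id[keep]))
  if (length(lost))
    warning("slides dropped (no predicted-tumor tiles): ",
            paste(lost, collapse = ", "))
  new("CacheSet", features = cacheFeatures(caches)[keep, , drop = FALSE],
      info = cacheInfo(caches)[keep, , drop = FALSE],
      extractorId = caches@extractorId)
}

#' Fully train the reduced convolutional network on pixel tiles
#'
#' Trains the whole network (trainable convolution filters + softmax head)
#' end-to-end on pixels, with the same balanced-stream undersampling as the
#' transfer heads. The architecture is a deliberately narrow desk-scale
#' variant of a full backbone; the prediction contract matches
#' \code{\link{trainHead}}.
#'
#' @param tiles list of tile records (with \code{pixels}) or bare pixel
#'   arrays.
#' @param labels per-tile class labels.
#' @param config a \code{\link{fullConfig}}.
#' @return model object of class \code{fullModel}.
#' @export
trainFull <- function(tiles, labels, config = fullConfig()) {
  imgs <- if (!is.null(tiles[[1]]$pixels)) lapply(tiles, `[[`, "pixels")
          else tiles
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2L) stop("training set contains a single class")
  Y <- outer(as.character(labels), classes, "==") * 1
  stream <- undersampleStream(labels, config$steps * config$batch_size,
                              seed = config$seed)
  net <- withSeed(config$seed + 1L, {
    net <- convNew(config$n_filters, config$filter_size, config$stride,
                   length(classes), lr = config$lr,
                   poolGrid = config$pool_grid)
    for (s in seq_len(config$steps)) {
      idx <- stream[((s - 1L) * config$batch_size + 1L):(s * config$batch_size)]
      net <- convStep(net, imgs[idx], Y[idx, , drop = FALSE])
    }
    net
  })
  structure(list(net = net, classes = classes, config = config),
            class = "fullModel")
}

#' Adjusted purity logit and its inverse
#'
#' \code{adjustedPurityLogit(P) = log((P + 0.05) / (1.05 - P))}: a logit
#' shifted away from 0 and 1 so extreme purities stay finite and stable.
#' Strictly increasing on \[0,1\]; \code{inverseAdjustedPurityLogit}
#' recovers P exactly.
#'
#' @param P purity fraction(s) in \[0,1\].
#' @return real value(s).
#' @export
adjustedPurityLogit <- function(P) {
  if (any(P < 0 | P > 1)) stop("purity must lie in [0,1]")
  log((P + 0.05) / (1.05 - P))
}

#' @rdname adjustedPurityLogit
#' @param z adjusted-logit value(s).
#' @export
inverseAdjustedPurityLogit <- function(z) {
  Q <- exp(z)
  (1.05 * Q - 0.05) / (1 + Q)
}

# per-channel histogram equalization by empirical CDF mapping
#' Histogram-equalize an RGB image per channel
#' @param img H x W x 3 array in \[0,1\].
#' @return equalized array.
#' @export
histEqualize <- function(img) {
  for (c3 in seq_len(dim(img)[3])) {
    ch <- img[, , c3]
    r <- rank(ch, ties.method = "average")
    img[, , c3] <- (r - 0.5) / length(ch)
  }
  img
}

#' Train the tile-level purity regression head
#'
#' Regresses tile purity through the adjusted-logit link: since
#' sigma(adjustedPurityLogit(P)) = (P + 0.05)/1.1, the sigmoid-output
#' network is trained against that target and predictions are inverted by
#' 1.1 p - 0.05 (clamped to \[0,1\]). Tiles are histogram-equalized before
#' feature extraction by the calling pipeline. Trains for
#' \code{config$epochs} epochs and keeps the epoch > 10 with the best test
#' MSE among epochs whose test MSE exceeds the train MSE (falling back to
#' best test MSE after epoch 10, with a warning, when none qualifies).
#'
#' @param trainX,trainPurity training features (matrix or CacheSet) and
#'   purity targets in \[0,1\].
#' @param testX,testPurity held-out features/targets driving epoch
#'   selection.
#' @param config a \code{\link{purityHeadConfig}}.
#' @return model object of class \code{purityHead} with fields
#'   \code{epoch_selected} and \code{epoch_log}.
#' @export
trainPurityHead <- function(trainX, trainPurity, testX, testPurity,
                            config = purityHeadConfig()) {
  if (config$epochs < 11L) stop("fewer than 11 epochs: selection rule needs epoch > 10")
  X <- featureMatrix(trainX); Xt <- featureMatrix(testX)
  ctr <- colMeans(X); scl <- apply(X, 2, sd); scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Xts <- sweep(sweep(Xt, 2, ctr), 2, scl, "/")
  y <- matrix((trainPurity + 0.05) / 1.1, ncol = 1)
  yt <- matrix((testPurity + 0.05) / 1.1, ncol = 1)
  n <- nrow(Xs)
  snap <- vector("list", config$epochs)
  log <- data.frame(epoch = seq_len(config$epochs), train_mse = NA_real_,
                    test_mse = NA_real_)
  net <- withSeed(config$seed, {
    net <- mlpNew(ncol(Xs), config$hidden_units, 1L, task = "sigmoid",
                  lr = config$lr, dropout = config$dropout,
                  l1 = config$l1_penalty, l2 = config$l2_penalty)
    for (e in seq_len(config$epochs)) {
      perm <- sample.int(n)
      for (s in seq(1L, n, by = config$batch_size)) {
        idx <- perm[s:min(s + config$batch_size - 1L, n)]
        net <- mlpStep(net, Xs[idx, , drop = FALSE], y[idx, , drop = FALSE])
      }
      snap[[e]] <- net$params
      log$train_mse[e] <- mean((mlpPredict(net, Xs) - y)^2)
      log$test_mse[e] <- mean((mlpPredict(net, Xts) - yt)^2)
    }
    net
  })
  cand <- log$epoch > 10L & log$test_mse > log$train_mse
  if (!any(cand)) {
    warning("no epoch > 10 with test MSE above train MSE; using best test MSE")
    cand <- log$epoch > 10L
  }
  eSel <- log$epoch[cand][which.min(log$test_mse[cand])]
  net$params <- snap[[eSel]]
  structure(list(net = net, center = ctr, scale = scl,
                 epoch_selected = eSel, epoch_log = log, config = config),
            class = "purityHead")
}

#' Predict tile purity from a trained purity head
#'
#' @param model a \code{purityHead}.
#' @param X features (matrix or CacheSet).
#' @return purity predictions in \[0,1\].
#' @export
predictPurity <- function(model, X) {
  Xs <- sweep(sweep(featureMatrix(X), 2, model$center), 2, model$scale, "/")
  p <- mlpPredict(model$net, Xs)
  pmin(1, pmax(0, 1.1 * as.numeric(p) - 0.05))
}

#' Extract nucleus patches from an annotated ROI
#'
#' Histogram-equalizes the ROI image once (normalizing acquisition
#' differences between datasets while preserving within-image nucleus
#' contrast), then crops a square window centered on each annotated nucleus
#' (shifted inward at image borders). Equalization is applied before both
#' training and inference.
#'
#' @param roi a \code{SyntheticROI} (or list with \code{image},
#'   \code{nuclei}).
#' @param patchSize window edge (px); the classifier operates at 32.
#' @param equalize apply per-channel histogram equalization to the ROI.
#' @return list of patch records: \code{pixels}, \code{class}.
#' @export
nucleusPatches <- function(roi, patchSize = 32L, equalize = TRUE) {
  img <- roi$image
  if (equalize) img <- histEqualize(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  half <- patchSize %/% 2L
  lapply(seq_len(nrow(roi$nuclei)), function(k) {
    cx <- round(roi$nuclei$x[k]) + 1L
    cy <- round(roi$nuclei$y[k]) + 1L
    x0 <- min(max(cx - half, 1L), w - patchSize + 1L)
    y0 <- min(max(cy - half, 1L), h - patchSize + 1L)
    px <- img[y0:(y0 + patchSize - 1L), x0:(x0 + patchSize - 1L), ,
              drop = FALSE]
    list(pixels = px, class = roi$nuclei$class[k])
  })
}

#' Train the nucleus tumor/normal classifier
#'
#' Fully trains the reduced convolutional network on 32x32
#' histogram-equalized nucleus patches and predicts per-nucleus tumor
#' probabilities.
#'
#' @param patches list of patch records from \code{\link{nucleusPatches}}.
#' @param labels per-patch classes (defaults to the patch records' own).
#' @param config a \code{\link{fullConfig}}.
#' @return model object of class \code{nucleusModel}.
#' @export
trainNucleusClassifier <- function(patches, labels = NULL,
                                   config = fullConfig()) {
  if (is.null(labels)) labels <- vapply(patches, `[[`, "", "class")
  m <- trainFull(patches, labels, config)
  class(m) <- c("nucleusModel", class(m))
  m
}

#' Per-nucleus tumor probability
#'
#' @param model a \code{nucleusModel}.
#' @param patches list of patch records.
#' @return numeric vector of tumor probabilities in \[0,1\].
#' @export
predictNuclei <- function(model, patches) {
  P <- convPredict(model$net, lapply(patches, `[[`, "pixels"))
  P[, match("tumor", model$classes)]
}
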