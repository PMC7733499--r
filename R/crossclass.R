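# Cross-classification analysis: train x test AUC matrices, UPGMA
# clustering, the Gamma-index phenotype association test, tile-logit
# correlation matrices, canonical-tissue tabulation, and the mutation
# cross-correlation analysis.

#' Build the train x test cross-classification AUC matrix
#'
#' Cell (i, j) is the slide-level ROC AUC (TPF score) of the classifier
#' trained on tissue i applied to the test cohort of tissue j; the diagonal
#' is self-classification. Confidence intervals are attached per cell.
#'
#' @param models named list of \code{transferHead} models, one per tissue.
#' @param testCaches named list of \code{\linkS4class{CacheSet}} test
#'   cohorts, same tissue names.
#' @param metadata slide metadata with \code{slide_id} and \code{label}.
#' @param tumorClass positive class.
#' @param level CI level.
#' @return a \code{\linkS4class{CrossMatrix}}.
#' @export
buildCrossMatrix <- function(models, testCaches, metadata,
                             tumorClass = "tumor", level = 0.95) {
  tissues <- names(models)
  stopifnot(setequal(tissues, names(testCaches)))
  n <- length(tissues)
  auc <- lo <- hi <- matrix(NA_real_, n, n,
                            dimnames = list(tissues, tissues))
  for (j in seq_len(n)) {
    caches <- testCaches[[tissues[j]]]
    labs <- metadata$label[match(unique(cacheInfo(caches)$slide_id),
                                 metadata$slide_id)]
    if (length(unique(labs)) < 2L)
      stop("test cohort ", tissues[j], " lacks a class")
    for (i in seq_len(n)) {
      pred <- predictTiles(models[[tissues[i]]], caches)
      sc <- slideScores(pred, metadata[, c("slide_id", "label")],
                        tumorClass = tumorClass)
      res <- slideAUC(sc$tpf, sc$label, positive = tumorClass, level = level)
      auc[i, j] <- res$auc_roc
      lo[i, j] <- res$ci_low
      hi[i, j] <- res$ci_high
    }
  }
  new("CrossMatrix", tissues = tissues, auc = auc, ciLow = lo, ciHigh = hi,
      trainOrder = integer(0), testOrder = integer(0))
}

#' UPGMA clustering of a cross-classification matrix
#'
#' Average-linkage (UPGMA) hierarchical clustering on Euclidean distances
#' between matrix rows (train axis) and between columns (test axis). Leaf
#' orders are deterministic given the input.
#'
#' @param cm a \code{\linkS4class{CrossMatrix}} or plain numeric matrix.
#' @return list: \code{matrix} (the CrossMatrix with orders filled in, when
#'   one was given), \code{trainOrder}, \code{testOrder} (leaf-order
#'   indices), \code{trainHclust}, \code{testHclust}.
#' @export
clusterMatrix <- function(cm) {
  m <- if (is(cm, "CrossMatrix")) cm@auc else cm
  if (any(!is.finite(m))) stop("non-finite matrix entries")
  hcTrain <- hclust(dist(m, method = "euclidean"), method = "average")
  hcTest <- hclust(dist(t(m), method = "euclidean"), method = "average")
  out <- list(trainOrder = hcTrain$order, testOrder = hcTest$order,
              trainHclust = hcTrain, testHclust = hcTest)
  if (is(cm, "CrossMatrix")) {
    cm@trainOrder <- as.integer(hcTrain$order)
    cm@testOrder <- as.integer(hcTest$order)
    out$matrix <- cm
  }
  out
}

#' Newick text for a clustering dendrogram
#'
#' @param hc an \code{hclust} object (e.g. from \code{\link{clusterMatrix}}).
#' @return single Newick string.
#' @export
dendroNewick <- function(hc) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the ape package is required for Newick export")
  ape::write.tree(ape::as.phylo(hc))
}

#' Phenotype match matrix A
#'
#' A_ij = 1 iff tissues i and j share a phenotype label; tissues labeled
#' "Other" are dropped before construction; zero diagonal.
#'
#' @param phenotypes named character vector, one label per tissue
#'   (possibly "Other").
#' @return binary symmetric matrix over the retained tissues.
#' @export
phenotypeMatchMatrix <- function(phenotypes) {
  keep <- phenotypes != "Other"
  ph <- phenotypes[keep]
  A <- outer(ph, ph, "==") * 1
  diag(A) <- 0
  dimnames(A) <- list(names(ph), names(ph))
  A
}

#' Dendrogram adjacency weight matrix W
#'
#' W_ij = 1 iff tissues i and j are immediate neighbors in the dendrogram
#' leaf order (restricted to the retained tissues), else 0.
#'
#' @param leafOrder character vector of tissue names in leaf order.
#' @return binary symmetric matrix with zero diagonal.
#' @export
adjacencyWeights <- function(leafOrder) {
  n <- length(leafOrder)
  W <- matrix(0, n, n, dimnames = list(leafOrder, leafOrder))
  if (n >= 2) for (k in seq_len(n - 1)) {
    W[leafOrder[k], leafOrder[k + 1]] <- 1
    W[leafOrder[k + 1], leafOrder[k]] <- 1
  }
  W
}

#' Gamma-index permutation test of phenotype-clustering association
#'
#' Gamma = sum_ij A_ij W_ij. The null distribution permutes tissue
#' phenotype labels, i.e. permutes rows and columns of A jointly while W is
#' fixed; p = (1 + #\{Gamma_perm >= Gamma_obs\}) / (1 + n_permutations).
#'
#' @param A phenotype match matrix (\code{\link{phenotypeMatchMatrix}}).
#' @param W adjacency weights (\code{\link{adjacencyWeights}}), on the same
#'   tissues (rows matched by name when both are named).
#' @param n_permutations permutation count.
#' @param seed integer seed.
#' @return a \code{\linkS4class{GammaTest}}.
#' @export
gammaPermutationTest <- function(A, W, n_permutations = 10000L, seed = 1L) {
  if (!is.null(rownames(A)) && !is.null(rownames(W)))
    W <- W[rownames(A), rownames(A)]
  stopifnot(all(dim(A) == dim(W)))
  gammaObs <- sum(A * W)
  n <- nrow(A)
  if (all(A == 0)) {
    warning("degenerate A (all zero): p = 1")
    return(new("GammaTest", A = A, W = W, gamma = gammaObs, pValue = 1,
               nPermutations = as.integer(n_permutations)))
  }
  exceed <- withSeed(seed, {
    sum(vapply(seq_len(n_permutations), function(i) {
      perm <- sample.int(n)
      sum(A[perm, perm] * W) >= gammaObs
    }, TRUE))
  })
  new("GammaTest", A = A, W = W, gamma = gammaObs,
      pValue = (1 + exceed) / (1 + n_permutations),
      nPermutations = as.integer(n_permutations))
}

#' Tile-logit correlation between two classifiers on one test cohort
#'
#' Both models predict every tile of the cohort; the Pearson correlation of
#' their stabilized tumor logits is returned. \code{tumor_only} restricts
#' to tiles from tumor-labeled slides (the cohort caches must carry a
#' \code{label} column).
#'
#' @param modelA,modelB trained heads sharing the cohort's feature space.
#' @param caches test cohort \code{\linkS4class{CacheSet}}.
#' @param tumor_only restrict to tumor slides.
#' @param positiveClass class whose probability is logit-transformed.
#' @return Pearson correlation over pooled tiles.
#' @export
tileLogitCorrelation <- function(modelA, modelB, caches, tumor_only = FALSE,
                                 positiveClass = "tumor") {
  info <- cacheInfo(caches)
  idx <- if (tumor_only) which(info$label == "tumor") else seq_len(nrow(info))
  if (length(idx) < 3L) stop("fewer than 3 tiles")
  sub <- new("CacheSet",
             features = cacheFeatures(caches)[idx, , drop = FALSE],
             info = info[idx, , drop = FALSE],
             extractorId = caches@extractorId)
  pcol <- paste0("prob_", positiveClass)
  la <- tumorLogit(predictTiles(modelA, sub)[[pcol]])
  lb <- tumorLogit(predictTiles(modelB, sub)[[pcol]])
  if (sd(la) == 0 || sd(lb) == 0) stop("zero-variance logits")
  cor(la, lb)
}

#' All pairwise tile-logit correlations, indexed by test tissue
#'
#' @param models named list of heads (one per tissue).
#' @param cachesByTissue named list of test-cohort CacheSets.
#' @param tumor_only restrict to tumor slides.
#' @param positiveClass logit class.
#' @return 3-d array \[model_a, model_b, test_tissue\] of Pearson r.
#' @export
pairwiseTileCorrelations <- function(models, cachesByTissue,
                                     tumor_only = FALSE,
                                     positiveClass = "tumor") {
  tis <- names(models)
  tst <- names(cachesByTissue)
  arr <- array(NA_real_, dim = c(length(tis), length(tis), length(tst)),
               dimnames = list(tis, tis, tst))
  pcol <- paste0("prob_", positiveClass)
  for (k in seq_along(tst)) {
    caches <- cachesByTissue[[k]]
    info <- cacheInfo(caches)
    idx <- if (tumor_only) which(info$label == "tumor")
           else seq_len(nrow(info))
    sub <- new("CacheSet",
               features = cacheFeatures(caches)[idx, , drop = FALSE],
               info = info[idx, , drop = FALSE],
               extractorId = caches@extractorId)
    logits <- vapply(tis, function(t)
      tumorLogit(predictTiles(models[[t]], sub)[[pcol]]),
      numeric(length(idx)))
    arr[, , k] <- cor(logits)
  }
  arr
}

#' Aggregate pairwise tile correlations over test tissues
#'
#' @param corrArray array from \code{\link{pairwiseTileCorrelations}}.
#' @return list: \code{average} (mean over test tissues), \code{max},
#'   \code{argmax_tissue} (name of the maximizing test tissue per cell).
#' @export
aggregateTileCorrelations <- function(corrArray) {
  avg <- apply(corrArray, c(1, 2), mean)
  mx <- apply(corrArray, c(1, 2), max)
  am <- apply(corrArray, c(1, 2), function(v)
    dimnames(corrArray)[[3]][which.max(v)])
  list(average = avg, max = mx, argmax_tissue = am)
}

#' Canonical-tissue tally with binomial tail p-values
#'
#' For each unordered classifier pair, the k distinct test tissues with the
#' highest tile-logit correlation are listed; the tally counts appearances
#' per tissue. Under the uniform null each tissue is expected
#' k * C(n,2) / n times; the one-sided p-value per tissue is the upper
#' binomial tail with C(n,2) trials and success probability k/n.
#'
#' @param corrArray array from \code{\link{pairwiseTileCorrelations}} (the
#'   test-tissue axis is tallied).
#' @param k list length per pair (default 3).
#' @return list: \code{counts} (named), \code{expected}, \code{p_values},
#'   \code{k}, \code{n_pairs}.
#' @export
canonicalTally <- function(corrArray, k = 3L) {
  tis <- dimnames(corrArray)[[1]]
  tst <- dimnames(corrArray)[[3]]
  n <- length(tst)
  if (k >= n) stop("k must be smaller than the number of test tissues")
  counts <- setNames(rep(0L, n), tst)
  nPairs <- 0L
  for (i in seq_along(tis)) {
    for (j in seq_along(tis)) {
      if (j <= i) next
      nPairs <- nPairs + 1L
      top <- tst[order(corrArray[i, j, ], decreasing = TRUE)[seq_len(k)]]
      counts[top] <- counts[top] + 1L
    }
  }
  pv <- pbinom(counts - 1L, nPairs, k / n, lower.tail = FALSE)
  list(counts = counts, expected = k * nPairs / n, p_values = pv,
       k = as.integer(k), n_pairs = nPairs)
}

#' Uniform-null expected canonical-tally count
#'
#' \code{k * choose(n, 2) / n}: how often each of n tissues would appear in
#' the per-pair top-k lists if tissues were drawn uniformly.
#'
#' @param n number of tissues.
#' @param k list length per pair.
#' @return expected count.
#' @export
canonicalExpectedCount <- function(n, k = 3L) {
  k * choose(n, 2) / n
}

#' Benjamini-Hochberg step-up FDR control
#'
#' @param p_values raw p-values.
#' @param q FDR level.
#' @return list: \code{adjusted} (BH-adjusted p), \code{reject} (logical at
#'   level q).
#' @export
bhFDR <- function(p_values, q = 0.05) {
  adj <- p.adjust(p_values, method = "BH")
  list(adjusted = adj, reject = adj <= q)
}

#' Fisher z test for Pearson correlations
#'
#' z = atanh(r) with standard error 1/sqrt(n - 3); two-sided normal
#' p-value. Vectorized over cells; combine with \code{\link{bhFDR}} across
#' a correlation matrix.
#'
#' @param r correlation(s).
#' @param n sample size(s) behind each correlation.
#' @return list(z, statistic, p).
#' @export
fisherZTest <- function(r, n) {
  z <- atanh(r)
  stat <- z * sqrt(pmax(n - 3, 0))
  list(z = z, statistic = stat, p = 2 * pnorm(-abs(stat)))
}

#' Mutation tile-logit cross-correlation matrix
#'
#' Cell (i, j) correlates the mutant-probability logits of the classifier
#' trained on tissue i with those of the classifier trained on tissue j,
#' both applied to tissue j's (tumor-tile prefiltered) test set — so each
#' column's test set is the second classifier's own training tissue. The
#' matrix is not symmetric. Row and column averages exclude the diagonal.
#'
#' @param models named list of mutation heads by tissue.
#' @param testCaches named list of prefiltered tumor-tile CacheSets by
#'   tissue.
#' @param positiveClass mutant class name.
#' @return list: \code{matrix}, \code{row_avg}, \code{col_avg}.
#' @export
mutationCrossCorrelation <- function(models, testCaches,
                                     positiveClass = "mutant") {
  tis <- names(models)
  n <- length(tis)
  m <- matrix(NA_real_, n, n, dimnames = list(train = tis, test = tis))
  pcol <- paste0("prob_", positiveClass)
  for (j in seq_len(n)) {
    caches <- testCaches[[tis[j]]]
    lj <- tumorLogit(predictTiles(models[[tis[j]]], caches)[[pcol]])
    for (i in seq_len(n)) {
      li <- tumorLogit(predictTiles(models[[tis[i]]], caches)[[pcol]])
      m[i, j] <- if (i == j) 1 else cor(li, lj)
    }
  }
  offDiag <- function(v, drop) mean(v[-drop])
  list(matrix = m,
       row_avg = vapply(seq_len(n), function(i) offDiag(m[i, ], i), 0),
       col_avg = vapply(seq_len(n), function(j) offDiag(m[, j], j), 0))
}
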