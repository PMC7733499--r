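# Cross-classification matrices, UPGMA clustering, Gamma test, tile-logit
# correlations, canonical tally, BH/Fisher-z.

test_that("off-diagonal cell count is n(n-1); 19 tissues give 342", {
  for (n in c(3, 5, 19)) {
    m <- matrix(runif(n * n), n, n)
    expect_equal(sum(row(m) != col(m)), n * (n - 1))
  }
  expect_equal(19 * 18, 342)
})

test_that("cross matrix reproduces self-AUCs and planted transfer", {
  heads <- smallHeads()
  md <- cohortMetadata(smallCohort())
  cm <- buildCrossMatrix(heads$models, heads$testCaches, md)
  m <- aucMatrix(cm)
  # diagonal equals the slide_metrics self-AUC computed by hand
  t1 <- names(heads$models)[1]
  pred <- predictTiles(heads$models[[t1]], heads$testCaches[[t1]])
  sc <- slideScores(pred, md[, c("slide_id", "label")])
  expect_equal(unname(m[t1, t1]),
               slideAUC(sc$tpf, sc$label)$auc_roc)
  expect_true(all(m >= 0 & m <= 1))
  expect_true(all(cm@ciLow <= cm@auc + 1e-12))
  expect_true(all(cm@ciHigh >= cm@auc - 1e-12))
})

test_that("UPGMA clustering matches an exhaustive merge oracle", {
  # identical rows merge first at height 0
  m <- rbind(c(1, 0, 0, 0), c(1, 0, 0, 0), c(0, 1, 1, 0), c(0, 0.5, 1, 1))
  cl <- clusterMatrix(m)
  expect_equal(cl$trainHclust$height[1], 0)
  expect_setequal(abs(cl$trainHclust$merge[1, ]), c(1, 2))
  # 4x4 hand matrices vs brute-force UPGMA enumeration
  set.seed(13)
  for (i in 1:10) {
    mm <- matrix(runif(16), 4, 4)
    d <- dist(mm)
    hc <- hclust(d, method = "average")
    or <- bruteUPGMA(d)
    expect_equal(sort(hc$height), sort(or$heights), tolerance = 1e-12)
    # the final merge heights agree pairwise in order
    expect_equal(hc$height, or$heights, tolerance = 1e-12)
  }
  # permuting the input leaves the dendrogram topology unchanged
  mm <- matrix(runif(36), 6, 6)
  rownames(mm) <- letters[1:6]
  hc1 <- hclust(dist(mm), method = "average")
  perm <- c(4, 2, 6, 1, 3, 5)
  hc2 <- hclust(dist(mm[perm, ]), method = "average")
  expect_equal(sort(hc1$height), sort(hc2$height))
  co1 <- stats::cophenetic(hc1)
  co2 <- stats::cophenetic(hc2)
  expect_equal(as.matrix(co2)[letters[1:6], letters[1:6]],
               as.matrix(co1)[letters[1:6], letters[1:6]])
  expect_error(clusterMatrix(matrix(c(1, NA, 1, 1), 2, 2)), "non-finite")
})

test_that("phenotype match matrix drops Other and marks equal phenotypes", {
  ph <- c(t1 = "a", t2 = "a", t3 = "b", t4 = "Other")
  A <- phenotypeMatchMatrix(ph)
  expect_equal(dim(A), c(3, 3))
  expect_equal(sum(A), 2)              # one unordered pair, both orientations
  expect_equal(A["t1", "t2"], 1)
  allSame <- phenotypeMatchMatrix(c(x = "a", y = "a", z = "a"))
  expect_equal(sum(allSame), 3 * 2)
  expect_true(all(diag(allSame) == 0))
  allDiff <- phenotypeMatchMatrix(c(x = "a", y = "b", z = "c"))
  expect_equal(sum(allDiff), 0)
})

test_that("adjacency weights mark immediate neighbors only", {
  W <- adjacencyWeights(c("x", "y", "z"))
  expect_equal(W["x", "y"], 1)
  expect_equal(W["y", "z"], 1)
  expect_equal(W["x", "z"], 0)
  expect_equal(sum(W[upper.tri(W)]), 2)  # n - 1 adjacent pairs
  # order reversal leaves W unchanged
  W2 <- adjacencyWeights(c("z", "y", "x"))
  expect_equal(W2[rownames(W), colnames(W)], W)
  n <- 7
  Wn <- adjacencyWeights(letters[1:n])
  expect_equal(sum(Wn[upper.tri(Wn)]), n - 1)
})

test_that("Gamma statistic and permutation test behave", {
  # A = W on n = 4: Gamma = sum W = 2(n-1) by hand
  W <- adjacencyWeights(c("a", "b", "c", "d"))
  gt <- gammaPermutationTest(W, W, n_permutations = 500, seed = 1)
  expect_equal(gt@gamma, 6)  # hand sum: 3 adjacent pairs, both orientations
  # disjoint support: Gamma 0, p near 1
  A0 <- matrix(0, 4, 4, dimnames = dimnames(W))
  A0["a", "c"] <- A0["c", "a"] <- 1
  W0 <- adjacencyWeights(c("a", "b", "c", "d"))
  W0["a", "c"] <- W0["c", "a"] <- 0   # ensure no overlap
  gt0 <- gammaPermutationTest(A0, W0, n_permutations = 300, seed = 2)
  expect_equal(gt0@gamma, 0)
  expect_gt(gt0@pValue, 0.5)
  # planted association: phenotype blocks equal to adjacency blocks
  ph <- c(a = "g1", b = "g1", c = "g1", d = "g2", e = "g2", f = "g2",
          g = "g3", h = "g3")
  A <- phenotypeMatchMatrix(ph)
  Wp <- adjacencyWeights(names(ph))
  gtp <- gammaPermutationTest(A, Wp, n_permutations = 10000, seed = 3)
  expect_lt(gtp@pValue, 0.05)
  # degenerate all-zero A warns and returns p = 1
  expect_warning(gz <- gammaPermutationTest(A0 * 0, W, 100, 1), "degenerate")
  expect_equal(gz@pValue, 1)
})

test_that("Gamma permutation test is calibrated at the 5% level", {
  # under random phenotypes, rejection rate ~ alpha (binomial CI)
  nrep <- 400
  W <- adjacencyWeights(letters[1:8])
  rej <- withr::with_seed(29, {
    vapply(seq_len(nrep), function(i) {
      ph <- setNames(sample(c("g1", "g2"), 8, replace = TRUE), letters[1:8])
      while (length(unique(ph)) < 2)
        ph <- setNames(sample(c("g1", "g2"), 8, replace = TRUE), letters[1:8])
      A <- phenotypeMatchMatrix(ph)
      gammaPermutationTest(A, W, n_permutations = 199,
                           seed = i)@pValue <= 0.05
    }, TRUE)
  })
  rate <- mean(rej)
  # permutation p-values are valid but conservative under discreteness:
  # the rate must not exceed alpha by more than binomial noise
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / nrep))
})

test_that("tile-logit correlations: identity, null, planted sharing", {
  heads <- smallHeads()
  t1 <- names(heads$models)[1]; t2 <- names(heads$models)[2]
  ca <- heads$testCaches[[t1]]
  expect_equal(tileLogitCorrelation(heads$models[[t1]], heads$models[[t1]],
                                    ca), 1)
  # two models trained on tissues sharing the malignancy signature
  # correlate positively on either test set
  r12 <- tileLogitCorrelation(heads$models[[t1]], heads$models[[t2]], ca)
  expect_gt(r12, 0.3)
  rTum <- tileLogitCorrelation(heads$models[[t1]], heads$models[[t2]], ca,
                               tumor_only = TRUE)
  expect_gt(rTum, 0)  # survives restriction to tumor slides
  expect_error(tileLogitCorrelation(heads$models[[t1]], heads$models[[t2]],
                                    subsetCaches(ca, character(0))),
               "3 tiles")
})

test_that("correlation aggregation: max dominates average, argmax matches scan", {
  set.seed(23)
  arr <- array(runif(3 * 3 * 4, -1, 1), dim = c(3, 3, 4),
               dimnames = list(paste0("m", 1:3), paste0("m", 1:3),
                               paste0("t", 1:4)))
  agg <- aggregateTileCorrelations(arr)
  expect_true(all(agg$max >= agg$average - 1e-12))
  for (i in 1:3) for (j in 1:3) {
    expect_equal(agg$average[i, j], mean(arr[i, j, ]))
    expect_equal(agg$argmax_tissue[i, j],
                 paste0("t", which.max(arr[i, j, ])))
  }
  # single test tissue: average equals max
  arr1 <- arr[, , 1, drop = FALSE]
  agg1 <- aggregateTileCorrelations(arr1)
  expect_equal(agg1$average, agg1$max)
})

test_that("canonical tally conserves counts and matches the uniform null", {
  expect_equal(canonicalExpectedCount(19, 3), 27)
  set.seed(41)
  n <- 6
  arr <- array(runif(n * n * 5), dim = c(n, n, 5),
               dimnames = list(paste0("m", 1:n), paste0("m", 1:n),
                               paste0("t", 1:5)))
  tal <- canonicalTally(arr, k = 2)
  expect_equal(sum(tal$counts), 2 * choose(n, 2))  # conservation
  expect_equal(tal$expected, 2 * choose(n, 2) / 5)
  expect_true(all(tal$p_values >= 0 & tal$p_values <= 1))
  expect_error(canonicalTally(arr, k = 5), "smaller")
  # Monte-Carlo: uniform draws hit the expected count on average (k = 1,
  # 4 test tissues)
  tot <- withr::with_seed(57, {
    reps <- vapply(1:300, function(i) {
      a <- array(runif(4 * 4 * 4), dim = c(4, 4, 4),
                 dimnames = list(paste0("m", 1:4), paste0("m", 1:4),
                                 paste0("t", 1:4)))
      canonicalTally(a, k = 1)$counts[["t1"]]
    }, 0)
    mean(reps)
  })
  expect_lt(abs(tot - choose(4, 2) / 4), 0.15)  # expected 1.5
})

test_that("BH step-up equals brute force; Fisher z matches closed forms", {
  p <- c(0.01, 0.04, 0.03, 0.2, 0.9)
  got <- bhFDR(p)
  expect_equal(got$adjusted, bruteBH(p))
  expect_equal(got$adjusted, p.adjust(p, "BH"))
  expect_true(all(bhFDR(rep(0, 5))$reject))
  expect_equal(bhFDR(0.03)$adjusted, 0.03)  # single p: adjusted = raw
  fz <- fisherZTest(0.5, 100)
  expect_equal(fz$z, atanh(0.5))
  expect_equal(fz$z, 0.5493, tolerance = 1e-4)
  expect_equal(fisherZTest(0, 50)$p, 1)
  expect_lt(fisherZTest(0.3, 1000)$p, fisherZTest(0.3, 30)$p)
})

test_that("mutation cross-correlation averages exclude the diagonal", {
  # 3x3 toy: hand-check the row/column average contract
  m <- rbind(c(1, 0.3, 0.1), c(0.2, 1, 0.4), c(0.6, 0.5, 1))
  rowAvg <- c(mean(c(0.3, 0.1)), mean(c(0.2, 0.4)), mean(c(0.6, 0.5)))
  colAvg <- c(mean(c(0.2, 0.6)), mean(c(0.3, 0.5)), mean(c(0.1, 0.4)))
  off <- function(v, d) mean(v[-d])
  expect_equal(vapply(1:3, function(i) off(m[i, ], i), 0), rowAvg)
  expect_equal(vapply(1:3, function(j) off(m[, j], j), 0), colAvg)
})

test_that("mutation cross-correlation runs on a synthetic two-tissue cohort", {
  co <- fixture("mutCohort", function() {
    generateCohort(defaultTissueSpecs(2), c(tumor = 10, normal = 4),
                   seed = 77, tileGrid = c(6, 6), tileSize = 32)
  })
  md <- cohortMetadata(co)
  ca <- fixture("mutCaches", function() cohortCaches(co))
  tissues <- sort(unique(md$tissue))
  models <- testC <- setNames(vector("list", 2), tissues)
  for (t in tissues) {
    tum <- md[md$tissue == t & md$label == "tumor", ]
    tumC <- subsetCaches(ca, tum$slide_id)
    # latent tumor tiles stand in for the prefilter here; the prefilter
    # itself is exercised in test-heads
    keep <- cacheInfo(tumC)$latent == "tumor"
    tumC <- new("CacheSet",
                features = cacheFeatures(tumC)[keep, , drop = FALSE],
                info = cacheInfo(tumC)[keep, , drop = FALSE],
                extractorId = tumC@extractorId)
    models[[t]] <- trainHead(tumC, cacheInfo(tumC)$mutation_status,
                             deskHeadConfig(seed = 9))
    testC[[t]] <- tumC
  }
  mc <- mutationCrossCorrelation(models, testC)
  expect_equal(unname(diag(mc$matrix)), c(1, 1))
  expect_true(all(abs(mc$matrix) <= 1))
  expect_equal(mc$row_avg[1], mc$matrix[1, 2])
  expect_equal(mc$col_avg[1], mc$matrix[2, 1])
})
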