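# TPF aggregation, logits, AUCs with CIs, per-tile metrics, purity
# correlation, heatmaps.

test_that("TPF is the exact argmax-tumor tile fraction", {
  df <- data.frame(slide_id = "s", row = 0:3, col = 0L,
                   prob_tumor = c(0.6, 0.4, 0.9, 0.2),
                   prob_normal = c(0.4, 0.6, 0.1, 0.8),
                   predicted_class = c("tumor", "normal", "tumor", "normal"),
                   stringsAsFactors = FALSE)
  tpf <- computeTPF(df)
  expect_equal(tpf$tpf, 0.5)
  expect_equal(tpf$mean_prob, mean(c(0.6, 0.4, 0.9, 0.2)))
  expect_equal(tpf$n_tiles, 4L)
  # hand-enumerated two-tile case
  df2 <- df[1:2, ]
  df2$prob_tumor <- c(0.6, 0.4); df2$prob_normal <- c(0.4, 0.6)
  df2$predicted_class <- c("tumor", "normal")
  expect_equal(computeTPF(df2)$tpf, 0.5)
  expect_equal(computeTPF(df2)$mean_prob, 0.5)
  # all-normal predictions
  df3 <- df; df3$predicted_class <- "normal"
  expect_equal(computeTPF(df3)$tpf, 0)
  expect_error(computeTPF(df[0, ]), "zero tiles")
  # order invariance
  expect_equal(computeTPF(df[sample(4), ])$tpf, 0.5)
})

test_that("stabilized tumor logit matches closed forms", {
  expect_equal(tumorLogit(0.5), 0)
  expect_equal(tumorLogit(1), log(1.0001 / 1e-4))
  expect_equal(tumorLogit(1), 9.2104, tolerance = 1e-4)
  expect_equal(tumorLogit(0), -tumorLogit(1))
  expect_true(all(is.finite(tumorLogit(c(0, 1e-9, 0.999999, 1)))))
  expect_error(tumorLogit(-0.1), "\\[0,1\\]")
})

test_that("ROC AUC equals the all-pairs brute-force oracle (with ties)", {
  # hand case: 3 pos {0.9, 0.8, 0.4}, 3 neg {0.3, 0.6, 0.1} -> 8/9
  s <- c(0.9, 0.8, 0.4, 0.3, 0.6, 0.1)
  l <- rep(c("pos", "neg"), each = 3)
  expect_equal(slideAUC(s, l, positive = "pos")$auc_roc, 8 / 9)
  # random instances up to n = 200, discrete scores to force ties
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    lab <- sample(c("pos", "neg"), n, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1:2] <- c("pos", "neg")
    sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    expect_equal(rocAUC(sc, lab, "pos"), bruteAUC(sc, lab, "pos"))
  }
  # perfect separation
  expect_equal(slideAUC(c(1, 1, 0, 0), c("pos", "pos", "neg", "neg"),
                        positive = "pos")$auc_roc, 1)
})

test_that("PR AUC is 1 for perfect separation and sane on the hand case", {
  r <- slideAUC(c(0.9, 0.8, 0.4, 0.3, 0.6, 0.1),
                rep(c("pos", "neg"), each = 3), positive = "pos")
  expect_true(r$auc_pr > 0.7 && r$auc_pr <= 1)
  expect_equal(slideAUC(c(1, 1, 0, 0), c("pos", "pos", "neg", "neg"),
                        positive = "pos")$auc_pr, 1)
})

test_that("analytic AUC CI behaves and agrees with the bootstrap", {
  # symmetric about 0.5 at the null
  ci <- aucConfidenceInterval(0.5, 500, 500)
  expect_equal(ci[1] + ci[2], 1, tolerance = 1e-10)
  # monotone width in n
  w10 <- diff(aucConfidenceInterval(0.8, 10, 10))
  w1000 <- diff(aucConfidenceInterval(0.8, 1000, 1000))
  expect_gt(w10, w1000)
  # CI brackets the estimate
  expect_true(ci[1] <= 0.5 && ci[2] >= 0.5)
  # degenerate AUC = 1 stays inside [0,1]
  ci1 <- aucConfidenceInterval(1, 20, 20)
  expect_true(all(ci1 >= 0 & ci1 <= 1))
  # binormal scores: analytic vs 10,000-replicate bootstrap
  set.seed(17)
  sc <- c(rnorm(60, 1), rnorm(60, 0))
  lab <- rep(c("pos", "neg"), each = 60)
  a <- rocAUC(sc, lab, "pos")
  an <- aucConfidenceInterval(a, 60, 60)
  bo <- aucBootstrapCI(sc, lab, "pos", nBoot = 10000, seed = 2)
  # intervals overlap and widths agree within 20%
  expect_true(an[1] < bo[2] && bo[1] < an[2])
  expect_lt(abs(diff(an) - diff(bo)) / diff(bo), 0.20)
})

test_that("per-tile confusion metrics match hand arithmetic", {
  truth <- c(rep("tumor", 10), rep("normal", 10))
  pred <- c(rep("tumor", 8), rep("normal", 2),   # TP=8, FN=2
            rep("tumor", 1), rep("normal", 9))   # FP=1, TN=9
  m <- tileMetrics(truth, pred)
  expect_equal(m$precision, 8 / 9)
  expect_equal(m$recall, 0.8)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$accuracy, 17 / 20)
  perfect <- tileMetrics(truth, truth, scores = (truth == "tumor") * 1)
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1, recall = 1,
                                  specificity = 1, auc = 1))
  allT <- tileMetrics(truth, rep("tumor", 20))
  expect_equal(allT$recall, 1)
  expect_equal(allT$specificity, 0)
  expect_error(tileMetrics(rep("tumor", 5), rep("tumor", 5)), "both classes")
})

test_that("micro and macro AUC coincide on a balanced 2-class toy set", {
  # 6 slides, 2 balanced classes; brute-force check
  S <- cbind(A = c(0.9, 0.8, 0.6, 0.4, 0.3, 0.2),
             B = c(0.1, 0.2, 0.4, 0.6, 0.7, 0.8))
  lab <- rep(c("A", "B"), each = 3)
  r <- microMacroAUC(S, lab)
  expect_equal(r$micro, r$macro)
  aucA <- bruteAUC(S[, "A"], ifelse(lab == "A", "pos", "neg"))
  aucB <- bruteAUC(S[, "B"], ifelse(lab == "B", "pos", "neg"))
  expect_equal(r$macro, mean(c(aucA, aucB)))
  # perfect multiclass
  S2 <- cbind(A = c(1, 1, 0, 0), B = c(0, 0, 1, 1))
  r2 <- microMacroAUC(S2, rep(c("A", "B"), each = 2))
  expect_equal(r2$micro, 1)
  expect_equal(r2$macro, 1)
  # absent class excluded with a warning
  expect_warning(microMacroAUC(cbind(S, C = runif(6)), lab), "absent")
})

test_that("Welch test handles unequal variances with non-pooled dof", {
  x <- c(1, 1.1, 0.9, 1.05, 0.95)
  expect_equal(welchTPFTest(x, x)$t, 0)
  expect_equal(welchTPFTest(x, x)$p, 1)
  set.seed(3)
  a <- rnorm(50, 0.9, 0.05); b <- rnorm(50, 0.2, 0.2)
  wt <- welchTPFTest(a, b)
  expect_lt(wt$p, 1e-4)
  # textbook Welch-Satterthwaite dof
  va <- var(a) / 50; vb <- var(b) / 50
  dof <- (va + vb)^2 / (va^2 / 49 + vb^2 / 49)
  expect_equal(wt$df, dof)
  expect_lt(dof, 98)  # strictly below the pooled dof
})

test_that("purity permutation correlation: identity, null, Bonferroni", {
  p <- seq(0.2, 0.9, length.out = 12)
  r1 <- purityCorrelation(p, p, n_permutations = 200, seed = 1)
  expect_equal(r1$r, 1)
  expect_equal(r1$p_raw, 1 / 201)
  set.seed(5)
  r0 <- purityCorrelation(rnorm(200), rnorm(200), n_permutations = 200,
                          seed = 2)
  expect_lt(abs(r0$r), 0.2)
  expect_gt(r0$p_raw, 0.01)
  rb <- purityCorrelation(p, p + rnorm(12, 0, 0.1), n_permutations = 200,
                          seed = 3, n_cohorts = 5)
  expect_gte(rb$p_adjusted, rb$p_raw)
  expect_lte(rb$p_adjusted, 1)
  expect_error(purityCorrelation(rep(0.5, 10), p[1:10]), "zero-variance")
  expect_error(purityCorrelation(p[1:2], p[1:2]), ">= 3")
})

test_that("mutation slide score is the tile mean", {
  expect_equal(mutationSlideScore(rep(0.7, 10)), 0.7)
  expect_equal(mutationSlideScore(c(0.2, 0.4, 0.9)), 0.5)
  expect_error(mutationSlideScore(numeric(0)), "zero tiles")
})

test_that("prediction heatmaps place tiles on the grid and flag gaps", {
  df <- data.frame(row = c(0L, 0L, 1L), col = c(0L, 1L, 0L),
                   prob_tumor = c(0.2, 0.8, 0.5))
  hm <- predictionHeatmap(df)
  expect_equal(dim(hm$map), c(2, 2))
  expect_equal(hm$map[1, 2], 0.8)
  expect_true(is.na(hm$map[2, 2]))          # background gap flagged
  expect_equal(mean(hm$map, na.rm = TRUE), 0.5)  # gaps excluded from stats
  # uniform probabilities give a uniform map
  dfu <- expand.grid(row = 0:1, col = 0:1)
  dfu$prob_tumor <- 0.3
  expect_true(all(predictionHeatmap(dfu)$map == 0.3))
  dup <- rbind(df, df[1, ])
  expect_error(predictionHeatmap(dup), "duplicate")
})
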