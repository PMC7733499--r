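# Slide-level aggregation and metrics: tumor-predicted fraction (TPF),
# stabilized logits, ROC/PR AUC with analytic CIs, per-tile confusion
# metrics, micro/macro multiclass AUC, Welch tests, purity permutation
# correlations, and spatial prediction heatmaps.

#' Tumor-predicted fraction for one slide
#'
#' Each tile takes the class with the highest softmax probability; the TPF
#' is the exact fraction of tiles labeled tumor and is the slide-level
#' classification score. The mean tumor probability is recorded alongside
#' (the slide score used in mutation mode).
#'
#' @param tileProbs data.frame from \code{\link{predictTiles}} restricted to
#'   one slide.
#' @param tumorClass name of the tumor class.
#' @return one-row data.frame: \code{slide_id}, \code{tpf},
#'   \code{mean_prob}, \code{n_tiles}.
#' @export
computeTPF <- function(tileProbs, tumorClass = "tumor") {
  if (nrow(tileProbs) == 0) stop("slide has zero tiles")
  pcol <- paste0("prob_", tumorClass)
  data.frame(slide_id = tileProbs$slide_id[1],
             tpf = mean(tileProbs$predicted_class == tumorClass),
             mean_prob = mean(tileProbs[[pcol]]),
             n_tiles = nrow(tileProbs),
             stringsAsFactors = FALSE)
}

#' Slide scores for a whole prediction table
#'
#' Applies \code{\link{computeTPF}} per slide and joins true labels.
#'
#' @param tileProbs data.frame from \code{\link{predictTiles}}.
#' @param metadata optional slide metadata with \code{slide_id} and
#'   \code{label} (and any other columns to join).
#' @param tumorClass name of the tumor class.
#' @return data.frame, one row per slide.
#' @export
slideScores <- function(tileProbs, metadata = NULL, tumorClass = "tumor") {
  out <- do.call(rbind, lapply(split(tileProbs, tileProbs$slide_id),
                               computeTPF, tumorClass = tumorClass))
  rownames(out) <- NULL
  if (!is.null(metadata))
    out <- merge(out, metadata, by = "slide_id", sort = TRUE)
  out
}

#' Stabilized tumor logit
#'
#' \code{log((p + eps) / (1 - p + eps))} with eps = 1e-4, finite for all
#' probabilities including 0 and 1.
#'
#' @param p tumor probability in \[0,1\].
#' @param eps stabilizer.
#' @return real logit value(s).
#' @export
tumorLogit <- function(p, eps = 1e-4) {
  if (any(p < 0 | p > 1)) stop("probability must lie in [0,1]")
  log((p + eps) / (1 - p + eps))
}

# midrank Mann-Whitney ROC AUC (ties counted 1/2)
rocAUC <- function(scores, labels, positive) {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# average-precision PR AUC with tied scores grouped
prAUC <- function(scores, labels, positive) {
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- pos[o]
  grp <- cumsum(!duplicated(s))
  tpCum <- tapply(cumsum(y), grp, max)
  nCum <- tapply(seq_along(y), grp, max)
  prec <- tpCum / nCum
  rec <- tpCum / sum(y)
  sum(diff(c(0, rec)) * prec)
}

#' Slide-level ROC and PR AUC with confidence interval
#'
#' ROC AUC is the midrank Mann-Whitney statistic over slide scores (TPF or
#' mean probability); PR AUC is average precision. The CI is the analytic
#' binormal interval of \code{\link{aucConfidenceInterval}}.
#'
#' @param scores per-slide scores.
#' @param labels per-slide true labels.
#' @param positive positive class name.
#' @param level CI level.
#' @return list: \code{auc_roc}, \code{auc_pr}, \code{ci_low},
#'   \code{ci_high}, \code{n_pos}, \code{n_neg}, \code{method}.
#' @export
slideAUC <- function(scores, labels, positive = "tumor", level = 0.95) {
  auc <- rocAUC(scores, labels, positive)
  ci <- aucConfidenceInterval(auc, sum(labels == positive),
                              sum(labels != positive), level)
  list(auc_roc = auc, auc_pr = prAUC(scores, labels, positive),
       ci_low = ci[1], ci_high = ci[2],
       n_pos = sum(labels == positive), n_neg = sum(labels != positive),
       method = "binormal-reiser")
}

#' Analytic binormal confidence interval for an AUC
#'
#' Avoids bootstrap cost by the binormal stress-strength approximation: the
#' AUC maps to an effect size d = sqrt(2) * qnorm(AUC), whose sampling
#' variance is approximated by \code{(n_pos + n_neg)/(n_pos n_neg) +
#' d^2 / (2 (n_pos + n_neg - 2))}; the normal interval on d is mapped back
#' through pnorm and truncated to \[0,1\]. Degenerate AUCs (0 or 1) are
#' pulled in by half a pair-count so the transform stays finite.
#'
#' @param auc observed ROC AUC.
#' @param n_pos,n_neg class counts (>= 1).
#' @param level confidence level.
#' @return c(ci_low, ci_high).
#' @seealso \code{\link{aucBootstrapCI}} for the seeded bootstrap
#'   cross-check.
#' @export
aucConfidenceInterval <- function(auc, n_pos, n_neg, level = 0.95) {
  if (n_pos < 1 || n_neg < 1) stop("class counts must be positive")
  eps <- 1 / (2 * n_pos * n_neg)
  a <- min(max(auc, eps), 1 - eps)
  d <- sqrt(2) * qnorm(a)
  se <- sqrt((n_pos + n_neg) / (n_pos * n_neg) +
               d^2 / (2 * max(n_pos + n_neg - 2, 1)))
  z <- qnorm(1 - (1 - level) / 2)
  lo <- pnorm((d - z * se) / sqrt(2))
  hi <- pnorm((d + z * se) / sqrt(2))
  # the interval always brackets the observed AUC, including degenerate 0/1
  c(min(max(0, lo), auc), max(min(1, hi), auc))
}

#' Bootstrap confidence interval for an AUC (cross-check)
#'
#' Stratified resampling within classes; percentile interval.
#'
#' @param scores,labels,positive as in \code{\link{slideAUC}}.
#' @param nBoot replicates.
#' @param level CI level.
#' @param seed integer seed.
#' @return c(ci_low, ci_high).
#' @export
aucBootstrapCI <- function(scores, labels, positive = "tumor",
                           nBoot = 10000L, level = 0.95, seed = 1L) {
  posIdx <- which(labels == positive)
  negIdx <- which(labels != positive)
  withSeed(seed, {
    reps <- vapply(seq_len(nBoot), function(i) {
      idx <- c(sample(posIdx, length(posIdx), replace = TRUE),
               sample(negIdx, length(negIdx), replace = TRUE))
      rocAUC(scores[idx], labels[idx], positive)
    }, 0)
    unname(quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2)))
  })
}

#' Per-tile confusion-matrix metrics
#'
#' Accuracy, precision, recall, specificity at the argmax decision, plus
#' per-tile ROC AUC when scores are supplied.
#'
#' @param trueLabels,predLabels per-tile true and predicted classes.
#' @param scores optional per-tile positive-class probabilities.
#' @param positive positive class name.
#' @return named list of metrics.
#' @export
tileMetrics <- function(trueLabels, predLabels, scores = NULL,
                        positive = "tumor") {
  if (length(unique(trueLabels)) < 2L) stop("both classes must be present")
  tp <- sum(trueLabels == positive & predLabels == positive)
  fp <- sum(trueLabels != positive & predLabels == positive)
  fn <- sum(trueLabels == positive & predLabels != positive)
  tn <- sum(trueLabels != positive & predLabels != positive)
  list(accuracy = (tp + tn) / (tp + tn + fp + fn),
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = tp / (tp + fn),
       specificity = tn / (tn + fp),
       auc = if (!is.null(scores)) rocAUC(scores, trueLabels, positive)
             else NA_real_)
}

#' Micro- and macro-averaged multiclass AUC
#'
#' Macro: unweighted mean of one-vs-rest ROC AUCs over classes present in
#' the test labels (absent classes are excluded with a warning). Micro: ROC
#' AUC over the pooled (score, indicator) pairs of all classes.
#'
#' @param scoreMatrix n x K matrix of class scores, columns named by class.
#' @param labels length-n true class labels.
#' @return list(micro, macro, per_class).
#' @export
microMacroAUC <- function(scoreMatrix, labels) {
  classes <- colnames(scoreMatrix)
  if (length(classes) < 2L) stop("need >= 2 classes")
  present <- classes[classes %in% labels]
  if (length(present) < length(classes))
    warning("classes absent from test set excluded from macro average: ",
            paste(setdiff(classes, present), collapse = ", "))
  perClass <- vapply(present, function(k) {
    rocAUC(scoreMatrix[, k], ifelse(labels == k, "pos", "neg"), "pos")
  }, 0)
  pooledScores <- as.vector(scoreMatrix[, present, drop = FALSE])
  pooledLabels <- as.vector(vapply(present, function(k)
    ifelse(labels == k, "pos", "neg"), character(length(labels))))
  list(micro = rocAUC(pooledScores, pooledLabels, "pos"),
       macro = mean(perClass), per_class = perClass)
}

#' Welch's t test between tumor and normal TPF distributions
#'
#' @param tpfTumor,tpfNormal per-slide TPF values by true label.
#' @return list(t, df, p).
#' @export
welchTPFTest <- function(tpfTumor, tpfNormal) {
  ht <- t.test(tpfTumor, tpfNormal, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' TPF-purity Pearson correlation with a permutation test
#'
#' Pearson r between per-slide TPF and annotated purity; significance by
#' permuting the dependent variable (purity), two-sided on |r|, with
#' Bonferroni adjustment across cohorts.
#'
#' @param tpf per-slide TPF.
#' @param purity per-slide annotated purity.
#' @param n_permutations permutation count.
#' @param seed integer seed.
#' @param n_cohorts Bonferroni factor (number of cohorts tested).
#' @return list(r, p_raw, p_adjusted, n_slides).
#' @export
purityCorrelation <- function(tpf, purity, n_permutations = 10000L,
                              seed = 1L, n_cohorts = 1L) {
  if (length(tpf) < 3L) stop("need >= 3 slides")
  if (sd(tpf) == 0 || sd(purity) == 0) stop("zero-variance input")
  r <- cor(tpf, purity)
  exceed <- withSeed(seed, {
    sum(vapply(seq_len(n_permutations), function(i) {
      abs(cor(tpf, sample(purity))) >= abs(r)
    }, TRUE))
  })
  p <- (1 + exceed) / (1 + n_permutations)
  list(r = r, p_raw = p, p_adjusted = min(1, p * n_cohorts),
       n_slides = length(tpf))
}

#' Slide-level mutation score
#'
#' Mean tile mutation probability over the slide's (prefiltered) tumor
#' tiles.
#'
#' @param tileProbs vector of per-tile mutant-class probabilities.
#' @return mean probability.
#' @export
mutationSlideScore <- function(tileProbs) {
  if (length(tileProbs) == 0) stop("slide has zero tiles")
  mean(tileProbs)
}

#' Spatial probability heatmap of a slide
#'
#' Arranges per-tile probabilities on the slide's tile grid; grid positions
#' with no kept tile (background) are NA and excluded from statistics. The
#' rendered image uses a blue-white-red colormap.
#'
#' @param tileProbs data.frame with \code{row}, \code{col} (0-based) and the
#'   probability column.
#' @param probColumn name of the probability column.
#' @param gridDim optional c(rows, cols); defaults to the bounding grid.
#' @param file optional PNG path to write the rendered map.
#' @return list: \code{map} (rows x cols numeric matrix with NAs),
#'   \code{image} (rows x cols x 3 array).
#' @export
predictionHeatmap <- function(tileProbs, probColumn = "prob_tumor",
                              gridDim = NULL, file = NULL) {
  if (anyDuplicated(tileProbs[, c("row", "col")]))
    stop("duplicate grid coordinates")
  if (is.null(gridDim))
    gridDim <- c(max(tileProbs$row) + 1L, max(tileProbs$col) + 1L)
  map <- matrix(NA_real_, gridDim[1], gridDim[2])
  map[cbind(tileProbs$row + 1L, tileProbs$col + 1L)] <- tileProbs[[probColumn]]
  img <- array(0, dim = c(gridDim, 3))
  v <- map; v[is.na(v)] <- 0.5
  img[, , 1] <- pmin(1, 2 * v)            # red ramps up above 0.5
  img[, , 2] <- 1 - abs(2 * v - 1)        # white at 0.5
  img[, , 3] <- pmin(1, 2 * (1 - v))      # blue ramps up below 0.5
  for (c3 in 1:3) img[, , c3][is.na(map)] <- 0.25  # background dark gray
  if (!is.null(file)) png::writePNG(img, file)
  list(map = map, image = img)
}
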