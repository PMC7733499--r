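# End-to-end experiment conveniences tying the modules together: per-tissue
# training with held-out test cohorts, and the mutation transfer-vs-full
# ordering experiment.

#' Subset a CacheSet to a set of slides
#'
#' @param caches a \code{\linkS4class{CacheSet}}.
#' @param slideIds slide ids to keep.
#' @return the subset \code{CacheSet}.
#' @export
subsetCaches <- function(caches, slideIds) {
  keep <- cacheInfo(caches)$slide_id %in% slideIds
  new("CacheSet", features = cacheFeatures(caches)[keep, , drop = FALSE],
      info = cacheInfo(caches)[keep, , drop = FALSE],
      extractorId = caches@extractorId)
}

#' Pixel tile records for selected slides of a cohort
#'
#' Tiles slides on the cohort grid and attaches latent labels and slide
#' metadata to each record (fields \code{latent}, \code{label},
#' \code{mutation_status}).
#'
#' @param cohort a \code{\linkS4class{SyntheticCohort}}.
#' @param slideIds slides to tile (default all).
#' @return list of tile records with \code{pixels}.
#' @export
cohortTileRecords <- function(cohort, slideIds = NULL) {
  md <- cohortMetadata(cohort)
  if (is.null(slideIds)) slideIds <- md$slide_id
  out <- list()
  for (sid in slideIds) {
    i <- match(sid, md$slide_id)
    tls <- tileImage(slideImage(cohort, sid), size = cohort@tileSize,
                     step = cohort@tileSize, slide_id = sid)
    lat <- slideTileLabels(cohort, sid)
    tls <- lapply(tls, function(t) {
      t$latent <- lat[t$row + 1L, t$col + 1L]
      t$label <- md$label[i]
      t$mutation_status <- md$mutation_status[i]
      t
    })
    out <- c(out, tls)
  }
  out
}

#' Train per-tissue tumor/normal heads with held-out test cohorts
#'
#' For each tissue: split slides (stratified, 70/30 by default), train a
#' transfer head on the training tiles under the naive tile-label
#' assumption (every tile inherits its slide's label), and keep the test
#' tiles as that tissue's test cohort.
#'
#' @param caches cohort-wide \code{\linkS4class{CacheSet}} from
#'   \code{\link{cohortCaches}}.
#' @param metadata slide metadata (\code{\link{cohortMetadata}}).
#' @param config a \code{\link{headConfig}}.
#' @param ratio training fraction.
#' @param splitMode \code{\link{splitTrainTest}} mode.
#' @param seed split seed (per-tissue seeds derived from it).
#' @return list: \code{models}, \code{testCaches} (both named by tissue),
#'   \code{splits}.
#' @export
trainTissueHeads <- function(caches, metadata, config = headConfig(),
                             ratio = 0.7, splitMode = "slide", seed = 1L) {
  tissues <- sort(unique(metadata$tissue))
  seeds <- childSeeds(seed, length(tissues))
  models <- testCaches <- splits <- setNames(vector("list", length(tissues)),
                                             tissues)
  for (k in seq_along(tissues)) {
    md <- metadata[metadata$tissue == tissues[k], ]
    sp <- splitTrainTest(md, ratio = ratio, mode = splitMode,
                         seed = seeds[k])
    trainC <- subsetCaches(caches, sp$train)
    cfg <- config
    cfg$seed <- seeds[k]
    models[[k]] <- trainHead(trainC, cacheInfo(trainC)$label, cfg)
    testCaches[[k]] <- subsetCaches(caches, sp$test)
    splits[[k]] <- sp
  }
  list(models = models, testCaches = testCaches, splits = splits)
}

#' Transfer-vs-full mutation classification experiment
#'
#' Reproduces the mutation pipeline on one tissue of a synthetic cohort:
#' tumor slides are split 70/30; a tumor/normal head trained on the same
#' tissue prefilters predicted-tumor tiles; then mutation status is
#' classified (a) by a transfer head over caches and (b) by the fully
#' trained reduced network over pixels. Slide scores are mean mutant
#' probabilities; both slide-level AUCs are returned.
#'
#' @param cohort a \code{\linkS4class{SyntheticCohort}}.
#' @param tissue tissue to analyze (default: first).
#' @param caches optional precomputed \code{\link{cohortCaches}} result.
#' @param headCfg transfer-head config (also used for the prefilter model).
#' @param fullCfg \code{\link{fullConfig}} for the fully trained network.
#' @param extractor feature extractor for caches.
#' @param ratio,seed split parameters.
#' @return list: \code{transfer_auc}, \code{full_auc}, \code{n_test},
#'   \code{scores} (per-slide table).
#' @export
mutationOrderingExperiment <- function(cohort, tissue = NULL, caches = NULL,
                                       headCfg = headConfig(hidden_units = 16L,
                                                            batch_size = 64L,
                                                            steps = 300L),
                                       fullCfg = fullConfig(),
                                       extractor = surrogateExtractor(),
                                       ratio = 0.7, seed = 1L) {
  md <- cohortMetadata(cohort)
  if (is.null(tissue)) tissue <- sort(unique(md$tissue))[1]
  if (is.null(caches)) caches <- cohortCaches(cohort, extractor)
  seeds <- childSeeds(seed, 3L)

  mdT <- md[md$tissue == tissue, ]
  # tumor/normal prefilter model on this tissue's slides
  tnCfg <- headCfg; tnCfg$seed <- seeds[1]
  tisC <- subsetCaches(caches, mdT$slide_id)
  tnModel <- trainHead(tisC, cacheInfo(tisC)$label, tnCfg)

  tum <- mdT[mdT$label == "tumor", ]
  tum$label <- tum$mutation_status   # stratify the split on mutation status
  sp <- splitTrainTest(tum, ratio = ratio, mode = "slide", seed = seeds[2])

  tumC <- prefilterTumorTiles(subsetCaches(caches, tum$slide_id), tnModel)
  trainC <- subsetCaches(tumC, sp$train)
  testC <- subsetCaches(tumC, sp$test)

  # (a) transfer head on caches
  mutCfg <- headCfg; mutCfg$seed <- seeds[3]
  thead <- trainHead(trainC, cacheInfo(trainC)$mutation_status, mutCfg)
  predT <- predictTiles(thead, testC)
  predT$prob <- predT$prob_mutant

  # (b) fully trained reduced network on the same tiles' pixels
  recs <- cohortTileRecords(cohort, tum$slide_id)
  key <- function(df) paste(df$slide_id, df$row, df$col)
  recKeys <- vapply(recs, function(t) paste(t$slide_id, t$row, t$col), "")
  trainRecs <- recs[match(key(cacheInfo(trainC)), recKeys)]
  testRecs <- recs[match(key(cacheInfo(testC)), recKeys)]
  fullCfg$seed <- seeds[3]
  fmodel <- trainFull(trainRecs, cacheInfo(trainC)$mutation_status, fullCfg)
  predF <- predictTiles(fmodel, testRecs)

  slideLab <- setNames(tum$mutation_status, tum$slide_id)
  scoreOf <- function(pred, pcol) {
    s <- tapply(pred[[pcol]], pred$slide_id, mutationSlideScore)
    data.frame(slide_id = names(s), score = as.numeric(s),
               label = slideLab[names(s)], stringsAsFactors = FALSE)
  }
  sT <- scoreOf(predT, "prob_mutant")
  sF <- scoreOf(predF, "prob_mutant")
  list(transfer_auc = rocAUC(sT$score, sT$label, "mutant"),
       full_auc = rocAUC(sF$score, sF$label, "mutant"),
       n_test = nrow(sT),
       scores = merge(sT, sF, by = c("slide_id", "label"),
                      suffixes = c("_transfer", "_full")))
}
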