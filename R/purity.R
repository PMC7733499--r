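# Tile-based vs nucleus-based tumor purity estimation on nucleus-annotated
# ROIs. The tile route regresses purity from tile features (overlapping
# windows); the nucleus route averages per-nucleus tumor probabilities.

# per-window purity target: fraction of annotated tumor nuclei whose
# centers fall inside the half-open window (center rule)
tilePurityTargets <- function(roi, tileSize, step) {
  tls <- tileImage(roi$image, size = tileSize, step = step,
                   slide_id = roi$roi_id)
  out <- lapply(tls, function(t) {
    inWin <- roi$nuclei$x >= t$origin_x & roi$nuclei$x < t$origin_x + tileSize &
             roi$nuclei$y >= t$origin_y & roi$nuclei$y < t$origin_y + tileSize
    n <- sum(inWin)
    t$n_nuclei <- n
    t$purity <- if (n > 0) mean(roi$nuclei$class[inWin] == "tumor") else NA_real_
    t
  })
  out[!vapply(out, function(t) is.na(t$purity), TRUE)]
}

#' Tile features and purity targets from annotated ROIs
#'
#' Cuts each ROI into overlapping windows, histogram-equalizes them,
#' extracts features, and pairs them with the center-rule purity target
#' (fraction of tumor nuclei among nuclei whose centers fall in the
#' window). Windows containing no nucleus are dropped.
#'
#' @param rois list of \code{SyntheticROI}.
#' @param tileSize,step window size and stride (px).
#' @param extractor feature extractor closure.
#' @param equalize histogram-equalize tiles before extraction.
#' @return list: \code{features} matrix, \code{purity} targets,
#'   \code{roi_id} per window.
#' @export
tilePurityData <- function(rois, tileSize = 64L, step = 32L,
                           extractor = surrogateExtractor(),
                           equalize = TRUE) {
  feats <- NULL; pur <- numeric(0); rid <- character(0)
  for (roi in rois) {
    if (dim(roi$image)[1] < tileSize || dim(roi$image)[2] < tileSize) {
      message("ROI ", roi$roi_id, " smaller than tile size: skipped")
      next
    }
    tls <- tilePurityTargets(roi, tileSize, step)
    if (!length(tls)) next
    X <- t(vapply(tls, function(t) {
      px <- if (equalize) histEqualize(t$pixels) else t$pixels
      extractor(px)
    }, numeric(attr(extractor, "feature_dim"))))
    feats <- rbind(feats, X)
    pur <- c(pur, vapply(tls, `[[`, 0, "purity"))
    rid <- c(rid, rep(roi$roi_id, length(tls)))
  }
  list(features = feats, purity = pur, roi_id = rid)
}

#' Evaluate the tile-based purity regressor on ROIs
#'
#' Each ROI's prediction is the mean over its overlapping-tile predictions;
#' the ground truth is the annotation-derived ROI purity (tumor nuclei /
#' total nuclei). ROIs smaller than the tile size are skipped with a
#' message.
#'
#' @param regressor a \code{purityHead} from \code{\link{trainPurityHead}}.
#' @param rois list of \code{SyntheticROI}.
#' @param tileSize,step,extractor,equalize as in
#'   \code{\link{tilePurityData}}.
#' @return list: \code{estimates} (data.frame roi_id, method,
#'   predicted_purity, true_purity), \code{report} (MAE, RMSE, n_rois,
#'   mean_true, mean_predicted).
#' @export
evaluateTilePurity <- function(regressor, rois, tileSize = 64L, step = 32L,
                               extractor = surrogateExtractor(),
                               equalize = TRUE) {
  est <- NULL
  for (roi in rois) {
    if (dim(roi$image)[1] < tileSize || dim(roi$image)[2] < tileSize) {
      message("ROI ", roi$roi_id, " smaller than tile size: skipped")
      next
    }
    dat <- tilePurityData(list(roi), tileSize, step, extractor, equalize)
    if (is.null(dat$features)) next
    pred <- mean(predictPurity(regressor, dat$features))
    est <- rbind(est, data.frame(roi_id = roi$roi_id,
                                 method = "tile_regression",
                                 predicted_purity = pred,
                                 true_purity = roi$purity,
                                 stringsAsFactors = FALSE))
  }
  list(estimates = est, report = purityReport(est))
}

purityReport <- function(est) {
  err <- est$predicted_purity - est$true_purity
  data.frame(method = est$method[1], mae = mean(abs(err)),
             rmse = sqrt(mean(err^2)), n_rois = nrow(est),
             mean_true = mean(est$true_purity),
             mean_predicted = mean(est$predicted_purity),
             stringsAsFactors = FALSE)
}

#' Nucleus-based ROI purity
#'
#' Predicted purity is the mean (equivalently the sum divided by the
#' nucleus count) of per-nucleus tumor probabilities over all annotated
#' nuclei.
#'
#' @param model a \code{nucleusModel}.
#' @param roi a \code{SyntheticROI} with annotated nuclei.
#' @param patchSize nucleus window edge (px).
#' @return predicted purity in \[0,1\].
#' @export
nucleusAggregatePurity <- function(model, roi, patchSize = 32L) {
  if (nrow(roi$nuclei) == 0) stop("ROI contains zero nuclei")
  mean(predictNuclei(model, nucleusPatches(roi, patchSize)))
}

#' Compare purity estimation methods on a common ROI set
#'
#' @param estimates data.frame stacking per-ROI estimates of all methods
#'   (columns roi_id, method, predicted_purity, true_purity); every method
#'   must cover the same ROI set.
#' @param nBoot bootstrap replicates for the CI on pairwise MAE
#'   differences.
#' @param seed integer seed.
#' @return list: \code{table} (per-method MAE/RMSE, ranked by MAE),
#'   \code{differences} (pairwise MAE differences with bootstrap CIs).
#' @export
compareMethods <- function(estimates, nBoot = 2000L, seed = 1L) {
  methods <- unique(estimates$method)
  roiSets <- lapply(methods, function(m)
    sort(estimates$roi_id[estimates$method == m]))
  if (length(methods) > 1 &&
      !all(vapply(roiSets[-1], identical, TRUE, roiSets[[1]])))
    stop("methods cover different ROI sets")
  tab <- do.call(rbind, lapply(methods, function(m)
    purityReport(estimates[estimates$method == m, ])))
  tab <- tab[order(tab$mae), ]
  rownames(tab) <- NULL
  diffs <- NULL
  if (length(methods) > 1) {
    wide <- lapply(methods, function(m) {
      e <- estimates[estimates$method == m, ]
      e <- e[order(e$roi_id), ]
      abs(e$predicted_purity - e$true_purity)
    })
    names(wide) <- methods
    nR <- length(wide[[1]])
    for (a in seq_along(methods)) for (b in seq_along(methods)) {
      if (b <= a) next
      d <- wide[[a]] - wide[[b]]
      ci <- withSeed(seed, {
        reps <- vapply(seq_len(nBoot), function(i)
          mean(d[sample.int(nR, nR, replace = TRUE)]), 0)
        quantile(reps, c(0.025, 0.975))
      })
      diffs <- rbind(diffs, data.frame(
        method_a = methods[a], method_b = methods[b],
        mae_diff = mean(d), ci_low = unname(ci[1]), ci_high = unname(ci[2]),
        stringsAsFactors = FALSE))
    }
  }
  list(table = tab, differences = diffs)
}
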