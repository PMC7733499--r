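#' @import methods
#' @importFrom stats rnorm runif rpois sd cor quantile pnorm qnorm pt pbinom
#'   hclust dist as.dendrogram order.dendrogram p.adjust t.test predict
#'   complete.cases aggregate setNames
#' @importFrom utils head write.table read.table
NULL

#' SyntheticCohort: a rendered multi-tissue image cohort with ground truth
#'
#' Container for a synthetic histology cohort: per-slide RGB images rendered
#' tile-by-tile from planted texture signatures, slide metadata, and the
#' latent per-tile tumor/normal labels that generated them.
#'
#' @slot slides named list of slide image arrays (height x width x 3, values
#'   in \[0,1\]), one per slide id.
#' @slot metadata data.frame with one row per slide: \code{slide_id},
#'   \code{patient_id}, \code{tissue}, \code{label} ("tumor"/"normal"),
#'   \code{purity}, \code{subtype}, \code{mutation_status}.
#' @slot tileLabels named list of character matrices (rows x cols) holding
#'   the latent label of each tile ("tumor"/"normal").
#' @slot tissues named list of tissue specifications (see
#'   \code{\link{tissueSpec}}).
#' @slot sharedSignature numeric texture parameter vector shared across
#'   tissues (the cohort-wide malignancy component).
#' @slot tileSize integer edge length in pixels of one tile.
#' @slot seed integer master seed the cohort was generated from.
#' @export
setClass("SyntheticCohort",
  representation(
    slides = "list",
    metadata = "data.frame",
    tileLabels = "list",
    tissues = "list",
    sharedSignature = "numeric",
    tileSize = "integer",
    seed = "integer"
  )
)

setValidity("SyntheticCohort", function(object) {
  md <- object@metadata
  need <- c("slide_id", "patient_id", "tissue", "label", "purity",
            "subtype", "mutation_status")
  if (!all(need %in% colnames(md)))
    return(paste("metadata must contain columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(md$slide_id)) return("duplicate slide_id in metadata")
  if (!setequal(names(object@slides), md$slide_id))
    return("slides and metadata slide ids disagree")
  if (any(md$purity < 0 | md$purity > 1)) return("purity outside [0,1]")
  if (any(md$purity[md$label == "normal"] != 0))
    return("normal slides must have purity 0")
  for (sid in md$slide_id) {
    lab <- object@tileLabels[[sid]]
    p <- md$purity[md$slide_id == sid]
    if (abs(mean(lab == "tumor") - p) > 1e-12)
      return(sprintf("slide %s: purity does not equal tumor-tile fraction", sid))
  }
  TRUE
})

#' CacheSet: fixed-length feature vectors ("caches") for a set of tiles
#'
#' One row per kept tile; the feature matrix is the output of a pluggable
#' backbone (default: the bundled fixed-seed surrogate extractor).
#'
#' @slot features numeric matrix, tiles x feature dimension.
#' @slot info data.frame with columns \code{slide_id}, \code{row}, \code{col}
#'   (0-based grid indices) and optionally per-tile annotations.
#' @slot extractorId character scalar identifying the backbone; all caches in
#'   a set share it.
#' @export
setClass("CacheSet",
  representation(features = "matrix", info = "data.frame",
                 extractorId = "character")
)

setValidity("CacheSet", function(object) {
  if (nrow(object@features) != nrow(object@info))
    return("features and info row counts differ")
  if (!all(c("slide_id", "row", "col") %in% colnames(object@info)))
    return("info must contain slide_id, row, col")
  if (length(object@extractorId) != 1L) return("extractorId must be length 1")
  TRUE
})

#' CrossMatrix: train-tissue x test-tissue slide-level AUC grid
#'
#' @slot tissues character vector of tissue names (axis labels).
#' @slot auc numeric n x n matrix; cell (i, j) is the slide-level ROC AUC of
#'   the classifier trained on tissue i applied to the test cohort of
#'   tissue j.
#' @slot ciLow,ciHigh numeric n x n matrices of per-cell confidence bounds.
#' @slot trainOrder,testOrder integer permutations from UPGMA clustering of
#'   the rows (train axis) and columns (test axis); empty until
#'   \code{\link{clusterMatrix}} is applied.
#' @export
setClass("CrossMatrix",
  representation(tissues = "character", auc = "matrix",
                 ciLow = "matrix", ciHigh = "matrix",
                 trainOrder = "integer", testOrder = "integer")
)

setValidity("CrossMatrix", function(object) {
  n <- length(object@tissues)
  if (!all(dim(object@auc) == c(n, n))) return("auc must be n x n")
  v <- object@auc[is.finite(object@auc)]
  if (any(v < 0 | v > 1)) return("AUC entries must lie in [0,1]")
  TRUE
})

#' GammaTest: Gamma-index association between phenotype and dendrogram order
#'
#' The Gamma index couples a binary phenotype-match matrix A (same organ, or
#' same adeno-ness) to a binary adjacency matrix W derived from a dendrogram
#' leaf order: Gamma = sum_ij A_ij W_ij. Significance is assessed by
#' permuting phenotype labels across tissues.
#'
#' @slot A,W symmetric binary matrices with zero diagonal.
#' @slot gamma observed Gamma statistic (nonnegative integer-valued).
#' @slot pValue permutation p-value.
#' @slot nPermutations number of permutations used.
#' @export
setClass("GammaTest",
  representation(A = "matrix", W = "matrix", gamma = "numeric",
                 pValue = "numeric", nPermutations = "integer")
)

setValidity("GammaTest", function(object) {
  for (nm in c("A", "W")) {
    M <- slot(object, nm)
    if (!isTRUE(all.equal(M, t(M)))) return(paste(nm, "must be symmetric"))
    if (any(diag(M) != 0)) return(paste(nm, "must have zero diagonal"))
    if (!all(M %in% c(0, 1))) return(paste(nm, "must be binary"))
  }
  if (object@gamma < 0) return("gamma must be nonnegative")
  TRUE
})

# ---- accessors ----------------------------------------------------------

#' @describeIn SyntheticCohort-class slide metadata table
#' @param object a SyntheticCohort
#' @export
setGeneric("cohortMetadata", function(object) standardGeneric("cohortMetadata"))
#' @export
setMethod("cohortMetadata", "SyntheticCohort", function(object) object@metadata)

#' @describeIn SyntheticCohort-class one slide's rendered image
#' @param slideId slide identifier
#' @export
setGeneric("slideImage", function(object, slideId) standardGeneric("slideImage"))
#' @export
setMethod("slideImage", "SyntheticCohort", function(object, slideId) {
  img <- object@slides[[slideId]]
  if (is.null(img)) stop("unknown slide id: ", slideId)
  img
})

#' @describeIn SyntheticCohort-class latent per-tile labels for one slide
#' @export
setGeneric("slideTileLabels",
           function(object, slideId) standardGeneric("slideTileLabels"))
#' @export
setMethod("slideTileLabels", "SyntheticCohort", function(object, slideId) {
  lab <- object@tileLabels[[slideId]]
  if (is.null(lab)) stop("unknown slide id: ", slideId)
  lab
})

#' @describeIn CacheSet-class the tiles x dim feature matrix
#' @param object a CacheSet
#' @export
setGeneric("cacheFeatures", function(object) standardGeneric("cacheFeatures"))
#' @export
setMethod("cacheFeatures", "CacheSet", function(object) object@features)

#' @describeIn CacheSet-class per-tile info table
#' @export
setGeneric("cacheInfo", function(object) standardGeneric("cacheInfo"))
#' @export
setMethod("cacheInfo", "CacheSet", function(object) object@info)

#' @describeIn CrossMatrix-class the AUC grid (train rows x test columns)
#' @param object a CrossMatrix
#' @export
setGeneric("aucMatrix", function(object) standardGeneric("aucMatrix"))
#' @export
setMethod("aucMatrix", "CrossMatrix", function(object) {
  m <- object@auc
  dimnames(m) <- list(train = object@tissues, test = object@tissues)
  m
})

# ---- show methods -------------------------------------------------------

setMethod("show", "SyntheticCohort", function(object) {
  md <- object@metadata
  cat("SyntheticCohort:", nrow(md), "slides,",
      length(unique(md$tissue)), "tissues,",
      "tile size", object@tileSize, "px\n")
  cat("  labels:", paste(sprintf("%s=%d", names(table(md$label)),
                                 table(md$label)), collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "CacheSet", function(object) {
  cat("CacheSet:", nrow(object@features), "tiles x",
      ncol(object@features), "features; extractor", object@extractorId, "\n")
  invisible(object)
})

setMethod("show", "CrossMatrix", function(object) {
  n <- length(object@tissues)
  off <- object@auc[row(object@auc) != col(object@auc)]
  cat(sprintf("CrossMatrix: %d tissues; mean off-diagonal AUC %.3f (n=%d cells)\n",
              n, mean(off), length(off)))
  invisible(object)
})

setMethod("show", "GammaTest", function(object) {
  cat(sprintf("GammaTest: Gamma = %g, p = %.4g (%d permutations)\n",
              object@gamma, object@pValue, object@nPermutations))
  invisible(object)
})
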