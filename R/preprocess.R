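# Tiling, magnification normalization, background removal and feature-cache
# extraction. Tiles are enumerated row-major over half-open windows with
# 0-based origins; partial edge windows are discarded (no padding).

#' Normalize image magnification to 20x
#'
#' 40x inputs are downsampled by a factor of 2 per axis with 2x2 area
#' averaging (odd trailing rows/columns are cropped); 20x inputs pass
#' through unchanged.
#'
#' @param image H x W x 3 array.
#' @param declared_mag "20x" or "40x".
#' @return image at 20x.
#' @export
normalizeMagnification <- function(image, declared_mag = c("20x", "40x")) {
  declared_mag <- match.arg(declared_mag)
  if (declared_mag == "20x") return(image)
  h <- dim(image)[1] %/% 2L * 2L
  w <- dim(image)[2] %/% 2L * 2L
  out <- array(0, dim = c(h %/% 2L, w %/% 2L, dim(image)[3]))
  ri <- seq(1L, h, by = 2L)
  ci <- seq(1L, w, by = 2L)
  for (c3 in seq_len(dim(image)[3])) {
    ch <- image[seq_len(h), seq_len(w), c3]
    out[, , c3] <- (ch[ri, ci] + ch[ri + 1L, ci] +
                      ch[ri, ci + 1L] + ch[ri + 1L, ci + 1L]) / 4
  }
  out
}

#' Cut an image into fixed-size tiles
#'
#' @param image H x W x 3 array.
#' @param size tile edge length (px).
#' @param step stride between window origins (px); \code{step = size} gives
#'   non-overlapping tiles, smaller steps overlapping ones.
#' @param slide_id identifier stored on each tile record.
#' @return list of tile records (\code{slide_id}, \code{row}, \code{col}
#'   0-based window indices, \code{origin_x}, \code{origin_y} 0-based pixel
#'   origins, \code{pixels}); empty list when the image is smaller than one
#'   window.
#' @export
tileImage <- function(image, size = 512L, step = size, slide_id = "slide") {
  size <- as.integer(size); step <- as.integer(step)
  if (size < 1L || step < 1L) stop("size and step must be >= 1")
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h < size || w < size) return(list())
  oy <- seq(0L, h - size, by = step)
  ox <- seq(0L, w - size, by = step)
  tiles <- vector("list", length(oy) * length(ox))
  k <- 0L
  for (r in seq_along(oy)) {
    for (cc in seq_along(ox)) {
      k <- k + 1L
      tiles[[k]] <- list(
        slide_id = slide_id, row = r - 1L, col = cc - 1L,
        origin_x = ox[cc], origin_y = oy[r],
        pixels = image[(oy[r] + 1L):(oy[r] + size),
                       (ox[cc] + 1L):(ox[cc] + size), , drop = FALSE])
    }
  }
  tiles
}

#' Background filtering by HSV saturation
#'
#' The tissue fraction of a tile is the fraction of pixels whose HSV
#' saturation exceeds \code{satCutoff}; unstained background and fat are
#' low-saturation and drop out. A tile is kept iff its tissue fraction is at
#' least \code{threshold} (inclusive).
#'
#' @param tile a tile record from \code{\link{tileImage}} (or a bare pixel
#'   array).
#' @param threshold minimum tissue fraction to keep the tile.
#' @param satCutoff saturation cutoff defining a "tissue" pixel.
#' @return the tile record with \code{tissue_fraction} and logical
#'   \code{keep} fields added.
#' @export
removeBackground <- function(tile, threshold = 0.25, satCutoff = 0.05) {
  px <- if (is.list(tile)) tile$pixels else tile
  mx <- pmax(px[, , 1], px[, , 2], px[, , 3])
  mn <- pmin(px[, , 1], px[, , 2], px[, , 3])
  sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
  tf <- mean(sat > satCutoff)
  if (!is.list(tile)) tile <- list(pixels = px)
  tile$tissue_fraction <- tf
  tile$keep <- tf >= threshold
  tile
}

#' Fixed-seed surrogate feature extractor
#'
#' A deterministic stand-in for a pretrained backbone: per-channel means and
#' standard deviations plus the mean rectified responses of a fixed-seed
#' bank of smoothed random 5x5 filters applied to luminance. Smoothing makes
#' the bank low-pass, so coarse morphology (blob density, stain color,
#' texture energy) dominates the representation. The returned closure maps a
#' tile pixel array to a length-\code{dim} vector and carries an
#' \code{extractor_id} attribute.
#'
#' @param dim feature dimension (>= 7; 6 pooled-color features + filters).
#' @param seed seed fixing the filter bank.
#' @param filterSize filter edge length (px).
#' @return function(pixels) -> numeric vector.
#' @export
surrogateExtractor <- function(dim = 48L, seed = 20240817L, filterSize = 5L) {
  stopifnot(dim >= 7L)
  nf <- dim - 6L
  fb <- withSeed(seed, {
    raw <- array(rnorm(filterSize^2 * nf), dim = c(filterSize, filterSize, nf))
    box <- matrix(1 / 9, 3, 3)
    sm <- matrix(0, filterSize^2, nf)
    for (k in seq_len(nf)) {
      f <- raw[, , k]
      # 3x3 box smoothing with zero padding, then zero-mean unit-norm
      g <- matrix(0, filterSize, filterSize)
      for (di in -1:1) for (dj in -1:1) {
        si <- pmin(pmax(seq_len(filterSize) + di, 1L), filterSize)
        sj <- pmin(pmax(seq_len(filterSize) + dj, 1L), filterSize)
        g <- g + f[si, sj] / 9
      }
      g <- g - mean(g)
      sm[, k] <- g / sqrt(sum(g^2))
    }
    sm
  })
  id <- sprintf("surrogate-d%d-s%d-f%d", dim, seed, filterSize)
  fun <- function(pixels) {
    lum <- 0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
    cm <- c(mean(pixels[, , 1]), mean(pixels[, , 2]), mean(pixels[, , 3]))
    cs <- c(sd(pixels[, , 1]), sd(pixels[, , 2]), sd(pixels[, , 3]))
    cols <- im2col(lum, filterSize, 1L)
    resp <- cols %*% fb
    c(cm, cs, colMeans(pmax(resp, 0)))
  }
  attr(fun, "extractor_id") <- id
  attr(fun, "feature_dim") <- as.integer(dim)
  fun
}

# valid-mode im2col: rows = window positions (row-major), cols = unrolled
# filterSize^2 patch, matching the filter's column-major unrolling
im2col <- function(mat, fsize, stride = 1L) {
  h <- nrow(mat); w <- ncol(mat)
  oi <- seq(1L, h - fsize + 1L, by = stride)
  oj <- seq(1L, w - fsize + 1L, by = stride)
  out <- matrix(0, length(oi) * length(oj), fsize * fsize)
  k <- 0L
  for (dj in seq_len(fsize)) {
    for (di in seq_len(fsize)) {
      k <- k + 1L
      out[, k] <- as.vector(mat[oi + di - 1L, oj + dj - 1L, drop = FALSE])
    }
  }
  out
}

#' Extract feature caches for a list of tiles
#'
#' One cache per tile, order preserved; all caches in the returned set share
#' the extractor's vector length and id.
#'
#' @param tiles list of tile records (from \code{\link{tileImage}}), each
#'   with a \code{pixels} array.
#' @param extractor a feature extractor closure such as
#'   \code{\link{surrogateExtractor}()}.
#' @param info optional data.frame of extra per-tile columns to carry along
#'   (same row order as \code{tiles}).
#' @return a \code{\linkS4class{CacheSet}}.
#' @export
extractFeatures <- function(tiles, extractor = surrogateExtractor(),
                            info = NULL) {
  n <- length(tiles)
  id <- attr(extractor, "extractor_id")
  if (is.null(id)) id <- "custom"
  if (n == 0) {
    return(new("CacheSet", features = matrix(0, 0, 0),
               info = data.frame(slide_id = character(0), row = integer(0),
                                 col = integer(0)), extractorId = id))
  }
  v1 <- extractor(tiles[[1]]$pixels)
  feats <- matrix(0, n, length(v1))
  feats[1, ] <- v1
  if (n > 1) for (k in 2:n) {
    v <- extractor(tiles[[k]]$pixels)
    if (length(v) != ncol(feats))
      stop("extractor vector length changed within a run")
    feats[k, ] <- v
  }
  base <- data.frame(
    slide_id = vapply(tiles, `[[`, "", "slide_id"),
    row = vapply(tiles, `[[`, 0L, "row"),
    col = vapply(tiles, `[[`, 0L, "col"),
    stringsAsFactors = FALSE)
  if (!is.null(info)) base <- cbind(base, info)
  new("CacheSet", features = feats, info = base, extractorId = id)
}

#' Shuffle caches into fixed-size shards
#'
#' Caches from one holdout group are shuffled by seed and cut into shards of
#' \code{group_size} (the last shard may be smaller). Mixing holdout groups
#' in one call is refused; shard the groups separately.
#'
#' @param caches a \code{\linkS4class{CacheSet}}.
#' @param group_size shard capacity.
#' @param seed shuffle seed.
#' @param holdout optional per-cache group labels; must be constant.
#' @return list of \code{CacheSet} shards.
#' @export
shardCaches <- function(caches, group_size = 10000L, seed = 1L,
                        holdout = NULL) {
  if (!is.null(holdout) && length(unique(holdout)) > 1L)
    stop("caches from different holdout groups may not share a shard run")
  n <- nrow(cacheFeatures(caches))
  perm <- withSeed(seed, sample.int(n))
  starts <- seq(1L, n, by = group_size)
  lapply(seq_along(starts), function(s) {
    idx <- perm[starts[s]:min(starts[s] + group_size - 1L, n)]
    new("CacheSet", features = cacheFeatures(caches)[idx, , drop = FALSE],
        info = cacheInfo(caches)[idx, , drop = FALSE],
        extractorId = caches@extractorId)
  })
}

#' Drop slides with too few kept tiles
#'
#' @param tileCounts named integer vector of kept-tile counts per slide, or
#'   a \code{CacheSet} (counts derived from its info table).
#' @param min_tiles minimum count; slides with strictly fewer are removed.
#' @return character vector of retained slide ids.
#' @export
filterMinTiles <- function(tileCounts, min_tiles = 50L) {
  if (is(tileCounts, "CacheSet")) {
    tab <- table(cacheInfo(tileCounts)$slide_id)
    tileCounts <- setNames(as.integer(tab), names(tab))
  }
  names(tileCounts)[tileCounts >= min_tiles]
}

#' Run the preprocessing pipeline over a synthetic cohort
#'
#' Tiles every slide on the cohort's own tile grid, applies background
#' filtering, extracts caches, and attaches the slide metadata and latent
#' tile labels to the cache info table (columns \code{label},
#' \code{tissue}, \code{latent}, \code{mutation_status}, \code{subtype},
#' \code{purity}).
#'
#' @param cohort a \code{\linkS4class{SyntheticCohort}}.
#' @param extractor feature extractor closure.
#' @param threshold,satCutoff background-filter parameters.
#' @return a \code{\linkS4class{CacheSet}} covering all kept tiles.
#' @export
cohortCaches <- function(cohort, extractor = surrogateExtractor(),
                         threshold = 0.25, satCutoff = 0.05) {
  md <- cohortMetadata(cohort)
  allTiles <- list()
  extra <- NULL
  for (i in seq_len(nrow(md))) {
    sid <- md$slide_id[i]
    tls <- tileImage(slideImage(cohort, sid), size = cohort@tileSize,
                     step = cohort@tileSize, slide_id = sid)
    lat <- slideTileLabels(cohort, sid)
    keepRec <- lapply(tls, removeBackground, threshold = threshold,
                      satCutoff = satCutoff)
    kept <- keepRec[vapply(keepRec, `[[`, TRUE, "keep")]
    if (!length(kept)) next
    allTiles <- c(allTiles, kept)
    extra <- rbind(extra, data.frame(
      latent = vapply(kept, function(t) lat[t$row + 1L, t$col + 1L], ""),
      label = md$label[i], tissue = md$tissue[i],
      mutation_status = md$mutation_status[i],
      subtype = md$subtype[i], purity = md$purity[i],
      tissue_fraction = vapply(kept, `[[`, 0, "tissue_fraction"),
      stringsAsFactors = FALSE))
  }
  extractFeatures(allTiles, extractor, info = extra)
}
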