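# Synthetic multi-tissue cohort generator. Textures are Gabor-like oriented
# band-pass waves plus elliptical "nucleus" blobs on a stained background;
# signal strength is controlled by named parameter vectors so the planted
# structure (shared malignancy component, tissue-specific components,
# mutation perturbation) is separable and tunable.

# run expr with a private RNG stream; the caller's stream is untouched
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# child seeds below 2^31, drawn from the parent stream (documented scheme:
# the master stream draws per-slide seeds; each slide stream draws its
# per-tile seeds)
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(2147483646L, n))
}

#' Texture signature parameter vector
#'
#' A named numeric vector parameterizing one texture family: nucleus-blob
#' density (expected blobs per 1024 px^2), blob radius (px), oriented
#' band-pass frequency (cycles/px) / orientation (radians) / amplitude
#' (intensity units), background RGB means, and blob contrast (how much
#' darker a blob center is than the background).
#'
#' @param density,radius,freq,orient,amp,r,g,b,contrast see description.
#' @return named numeric vector of length 9.
#' @export
textureSignature <- function(density = 8, radius = 2, freq = 0.08,
                             orient = 0, amp = 0.03,
                             r = 0.85, g = 0.72, b = 0.83, contrast = 0.25) {
  c(density = density, radius = radius, freq = freq, orient = orient,
    amp = amp, r = r, g = g, b = b, contrast = contrast)
}

#' Tissue specification for the synthetic cohort generator
#'
#' @param name short unique tissue name.
#' @param normal_signature texture parameters of the tissue's normal
#'   morphology (\code{\link{textureSignature}}).
#' @param specific_tumor_signature texture parameters of the
#'   tissue-specific tumor component.
#' @param shared_weight fraction in \[0,1\] mixing the cohort-wide shared
#'   malignancy signature into this tissue's tumor texture.
#' @param noise_sd pixel-noise standard deviation (intensity units).
#' @return a list of class \code{TissueSpec}.
#' @export
tissueSpec <- function(name, normal_signature, specific_tumor_signature,
                       shared_weight = 0.8, noise_sd = 0.02) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (shared_weight < 0 || shared_weight > 1)
    stop("shared_weight must lie in [0,1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(name = name,
                 normal_signature = normal_signature,
                 specific_tumor_signature = specific_tumor_signature,
                 shared_weight = shared_weight,
                 noise_sd = noise_sd),
            class = "TissueSpec")
}

#' Cohort-wide shared malignancy signature
#'
#' High blob density, fine high-contrast texture and a hematoxylin-like
#' purple shift: the features the generator plants as "shared across cancer
#' types but absent from normal tissue".
#' @return named numeric texture parameter vector.
#' @export
sharedMalignancySignature <- function() {
  textureSignature(density = 40, radius = 2.5, freq = 0.35, orient = 0,
                   amp = 0.10, r = 0.55, g = 0.35, b = 0.65, contrast = 0.45)
}

#' Default tissue panel
#'
#' Builds \code{n} tissues whose normal signatures differ by color tint and
#' texture orientation, and whose specific tumor components shift each
#' tissue along its own idiosyncratic direction (moderate density increase,
#' rotated texture, tissue-specific tint) so that tumors stay separable from
#' normals within a tissue even at \code{shared_weight = 0}.
#'
#' @param n number of tissues (>= 2).
#' @param shared_weight shared-malignancy mixing weight, recycled over
#'   tissues; set one entry to 0 to plant a poorly cross-classifiable
#'   tissue.
#' @param noise_sd pixel noise, recycled.
#' @return list of \code{TissueSpec}.
#' @export
defaultTissueSpecs <- function(n = 4, shared_weight = 0.8, noise_sd = 0.02) {
  stopifnot(n >= 2)
  shared_weight <- rep_len(shared_weight, n)
  noise_sd <- rep_len(noise_sd, n)
  tints <- matrix(c( 0.05,  0.00, -0.04,
                    -0.04,  0.05,  0.00,
                     0.00, -0.04,  0.05,
                     0.04,  0.04, -0.05,
                    -0.05, -0.03,  0.04,
                     0.03, -0.05,  0.03), ncol = 3, byrow = TRUE)
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    tint <- tints[((i - 1L) %% nrow(tints)) + 1L, ]
    nrm <- textureSignature(density = 8, radius = 2, freq = 0.08,
                            orient = (i - 1) * pi / n, amp = 0.03,
                            r = 0.85 + tint[1], g = 0.72 + tint[2],
                            b = 0.83 + tint[3], contrast = 0.25)
    # the specific component departs from normal against the shared
    # malignancy axis (no density increase, a green/brighter rather than
    # purple/darker shift, rotated texture): a tissue at shared_weight = 0
    # stays self-classifiable but cross-transfers poorly
    spc <- textureSignature(density = 8, radius = 2.0, freq = 0.08,
                            orient = (i - 1) * pi / n + pi / 4, amp = 0.03,
                            r = 0.85 + tint[1],
                            g = 0.72 + tint[2] + 0.08,
                            b = 0.83 + tint[3],
                            contrast = 0.25)
    specs[[i]] <- tissueSpec(sprintf("T%02d", i), nrm, spc,
                             shared_weight = shared_weight[i],
                             noise_sd = noise_sd[i])
  }
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' Render one synthetic tile
#'
#' Normal tiles are drawn from the tissue's normal signature only. Tumor
#' tiles are drawn from the convex mixture
#' \code{shared_weight * shared + (1 - shared_weight) * specific} of the
#' cohort-wide shared signature and the tissue-specific tumor signature,
#' applied parameter-wise.
#'
#' @param tissue a \code{\link{tissueSpec}}.
#' @param latent "tumor" or "normal".
#' @param shared_signature shared malignancy parameter vector.
#' @param seed integer seed; rendering is deterministic given it.
#' @param size tile edge length in pixels (default 512; desk-scale cohorts
#'   use 32).
#' @return size x size x 3 array in \[0,1\].
#' @export
renderTile <- function(tissue, latent = c("tumor", "normal"),
                       shared_signature = sharedMalignancySignature(),
                       seed = 1L, size = 512L) {
  latent <- match.arg(latent)
  size <- as.integer(size)
  if (size < 4L) stop("invalid tile size")
  sig <- if (latent == "normal") {
    tissue$normal_signature
  } else {
    w <- tissue$shared_weight
    w * shared_signature + (1 - w) * tissue$specific_tumor_signature
  }
  withSeed(seed, renderTexture(sig, tissue$noise_sd, size))
}

# draw a size x size x 3 texture from a signature, using the current stream
renderTexture <- function(sig, noise_sd, size) {
  xy <- seq_len(size)
  X <- matrix(xy, size, size, byrow = TRUE)
  Y <- matrix(xy, size, size)
  phase <- runif(1, 0, 2 * pi)
  wave <- sig[["amp"]] *
    sin(2 * pi * sig[["freq"]] *
          (X * cos(sig[["orient"]]) + Y * sin(sig[["orient"]])) + phase)
  base <- array(0, dim = c(size, size, 3))
  cols <- c(sig[["r"]], sig[["g"]], sig[["b"]])
  nblob <- rpois(1, sig[["density"]] * size * size / 1024)
  dark <- matrix(0, size, size)
  if (nblob > 0) {
    cx <- runif(nblob, 1, size)
    cy <- runif(nblob, 1, size)
    rad <- sig[["radius"]] * runif(nblob, 0.75, 1.25)
    for (k in seq_len(nblob)) {
      d2 <- (X - cx[k])^2 + (Y - cy[k])^2
      dark <- dark + sig[["contrast"]] * exp(-d2 / (2 * rad[k]^2))
    }
  }
  for (c3 in 1:3) {
    ch <- cols[c3] + wave - dark +
      matrix(rnorm(size * size, 0, noise_sd), size, size)
    base[, , c3] <- pmin(1, pmax(0, ch))
  }
  base
}

# fine phase-jittered grating used as the planted mutation signature; the
# shared part is the fixed frequency/orientation, the tissue part a small
# tint. Amplitude is small so pooled tile statistics barely move.
applyMutationSignature <- function(tile, seed, amp = 0.02, freq = 0.45,
                                   orient = 1.1, tint = c(0, 0, 0)) {
  size <- dim(tile)[1]
  withSeed(seed, {
    xy <- seq_len(size)
    X <- matrix(xy, size, size, byrow = TRUE)
    Y <- matrix(xy, size, size)
    phase <- runif(1, 0, 2 * pi)
    g <- amp * sin(2 * pi * freq * (X * cos(orient) + Y * sin(orient)) + phase)
    for (c3 in 1:3) {
      tile[, , c3] <- pmin(1, pmax(0, tile[, , c3] + g + tint[c3]))
    }
  })
  tile
}

drawPurity <- function(dist, n) {
  type <- if (is.null(dist$type)) "uniform" else dist$type
  p <- switch(type,
    uniform = {
      if (dist$min < 0 || dist$max > 1 || dist$min > dist$max)
        stop("purity distribution outside [0,1]")
      runif(n, dist$min, dist$max)
    },
    truncnorm = {
      out <- numeric(0)
      while (length(out) < n) {
        cand <- rnorm(2 * (n - length(out)), dist$mean, dist$sd)
        out <- c(out, cand[cand >= 0 & cand <= 1])
      }
      out[seq_len(n)]
    },
    constant = {
      if (dist$value < 0 || dist$value > 1)
        stop("purity distribution outside [0,1]")
      rep(dist$value, n)
    },
    stop("unknown purity distribution type: ", type)
  )
  p
}

#' Generate a synthetic multi-tissue cohort
#'
#' Renders every slide tile-by-tile from latent per-tile labels, so the
#' ground truth is pixel-exact: a slide's recorded purity equals the
#' realized fraction of tumor-latent tiles exactly. Mutant samples carry an
#' additional fine-grating texture perturbation on their tumor tiles, with a
#' cross-tissue shared component.
#'
#' @param specs list of \code{\link{tissueSpec}} (>= 2 tissues).
#' @param slidesPerTissue named counts, e.g. \code{c(tumor = 4, normal = 4)}.
#' @param purityDistribution list describing the tumor-slide purity law:
#'   \code{list(type="uniform", min=, max=)},
#'   \code{list(type="truncnorm", mean=, sd=)} (truncated to \[0,1\]) or
#'   \code{list(type="constant", value=)}.
#' @param seed master integer seed; the full cohort is a deterministic
#'   function of it.
#' @param tileGrid c(rows, cols) of tiles per slide.
#' @param tileSize tile edge length in pixels.
#' @param mutationRate fraction of tumor patients carrying the planted
#'   mutation (per-patient Bernoulli).
#' @param mutationAmp amplitude of the mutation grating (0 disables the
#'   pixel-level perturbation while keeping labels).
#' @param matchedFraction fraction of normal slides attached to a tumor
#'   patient (matched adjacent normals); the rest belong to normal-only
#'   patients.
#' @param nSubtypes number of subtype labels assigned to tumor slides (a
#'   small per-subtype tint makes them learnable).
#' @return a \code{\linkS4class{SyntheticCohort}}.
#' @export
generateCohort <- function(specs,
                           slidesPerTissue = c(tumor = 4, normal = 4),
                           purityDistribution = list(type = "uniform",
                                                     min = 0.4, max = 0.95),
                           seed = 1L,
                           tileGrid = c(8L, 8L),
                           tileSize = 32L,
                           mutationRate = 0.5,
                           mutationAmp = 0.02,
                           matchedFraction = 0.5,
                           nSubtypes = 1L) {
  if (length(specs) < 2L) stop("at least 2 tissues are required")
  if (any(slidesPerTissue < 1L)) stop("counts must be >= 1 per class")
  nT <- as.integer(slidesPerTissue[["tumor"]])
  nN <- as.integer(slidesPerTissue[["normal"]])
  shared <- sharedMalignancySignature()
  nTiles <- prod(tileGrid)
  nSlides <- (nT + nN) * length(specs)

  masterSeeds <- childSeeds(seed, 2L)
  slideSeeds <- childSeeds(masterSeeds[1], nSlides)

  md <- NULL
  slides <- list()
  tileLabs <- list()
  idx <- 0L
  withSeed(masterSeeds[2], {
    for (sp in specs) {
      purs <- drawPurity(purityDistribution, nT)
      mutPat <- runif(nT) < mutationRate
      subty <- if (nSubtypes > 1L)
        sample(sprintf("S%d", seq_len(nSubtypes)), nT, replace = TRUE)
      else rep("S1", nT)
      nMatched <- floor(nN * matchedFraction)
      for (j in seq_len(nT + nN)) {
        idx <- idx + 1L
        isTumor <- j <= nT
        if (isTumor) {
          pat <- sprintf("%s-P%03d", sp$name, j)
          lab <- "tumor"
          kTum <- round(purs[j] * nTiles)
          mut <- if (mutPat[j]) "mutant" else "wildtype"
          sub <- subty[j]
        } else {
          jn <- j - nT
          # first nMatched normals belong to tumor patients (adjacent normal)
          pat <- if (jn <= nMatched) sprintf("%s-P%03d", sp$name, jn)
                 else sprintf("%s-N%03d", sp$name, jn)
          lab <- "normal"
          kTum <- 0L
          mut <- "wildtype"
          sub <- NA_character_
        }
        sid <- sprintf("%s-%s-%02d", sp$name, ifelse(isTumor, "TU", "NO"), j)
        latent <- matrix("normal", tileGrid[1], tileGrid[2])
        if (kTum > 0) {
          pos <- sample.int(nTiles, kTum)
          latent[pos] <- "tumor"
        }
        row0 <- data.frame(slide_id = sid, patient_id = pat,
                           tissue = sp$name, label = lab,
                           purity = mean(latent == "tumor"),
                           subtype = sub, mutation_status = mut,
                           stringsAsFactors = FALSE)
        md <- rbind(md, row0)
        tileLabs[[sid]] <- latent
        slides[[sid]] <- renderSlide(sp, latent, shared, slideSeeds[idx],
                                     tileSize, mut == "mutant", mutationAmp,
                                     sub)
      }
    }
  })
  new("SyntheticCohort", slides = slides, metadata = md,
      tileLabels = tileLabs, tissues = specs, sharedSignature = shared,
      tileSize = as.integer(tileSize), seed = as.integer(seed))
}

renderSlide <- function(sp, latent, shared, slideSeed, tileSize,
                        mutant, mutationAmp, subtype) {
  nr <- nrow(latent); nc <- ncol(latent)
  tileSeeds <- childSeeds(slideSeed, 2L * nr * nc)
  img <- array(0, dim = c(nr * tileSize, nc * tileSize, 3))
  k <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      k <- k + 1L
      tl <- renderTile(sp, latent[i, j], shared, tileSeeds[k], tileSize)
      if (latent[i, j] == "tumor" && !is.na(subtype) && subtype != "S1") {
        # small subtype tint so subtype labels are learnable
        sIdx <- as.integer(sub("S", "", subtype))
        tl[, , 1] <- pmin(1, pmax(0, tl[, , 1] + 0.03 * (sIdx - 1)))
      }
      if (mutant && latent[i, j] == "tumor" && mutationAmp > 0) {
        tl <- applyMutationSignature(tl, tileSeeds[nr * nc + k],
                                     amp = mutationAmp)
      }
      rr <- ((i - 1L) * tileSize + 1L):(i * tileSize)
      cc <- ((j - 1L) * tileSize + 1L):(j * tileSize)
      img[rr, cc, ] <- tl
    }
  }
  img
}

#' Generate a nucleus-annotated synthetic ROI
#'
#' Produces an RGB region with round "nuclei" of two classes planted at
#' uniform positions. Tumor nuclei are larger and darker than normal nuclei
#' by a configurable offset. The stromal background carries a low-frequency
#' blotch whose amplitude is proportional to the ROI's purity — an
#' intercellular purity cue visible to tile-level regressors but carrying no
#' per-nucleus class information.
#'
#' @param n_nuclei number of nuclei (>= 1).
#' @param purity fraction in \[0,1\]; the number of tumor nuclei is
#'   \code{round(purity * n_nuclei)}.
#' @param seed integer seed.
#' @param width,height ROI size in pixels.
#' @param tumorRadius,normalRadius nucleus radii (px).
#' @param tumorIntensity,normalIntensity nucleus center intensities (darker
#'   = smaller value).
#' @param stromalCoupling logical; disable to remove the purity-correlated
#'   background cue.
#' @return list of class \code{SyntheticROI}: \code{roi_id}, \code{image},
#'   \code{nuclei} (data.frame x, y, radius, class; 0-based pixel centers),
#'   \code{purity} (annotation-derived ground truth).
#' @export
generateROI <- function(n_nuclei, purity, seed = 1L,
                        width = 160L, height = 140L,
                        tumorRadius = 5.0, normalRadius = 2.5,
                        tumorIntensity = 0.25, normalIntensity = 0.60,
                        stromalCoupling = TRUE) {
  if (n_nuclei < 1) stop("n_nuclei must be >= 1")
  if (purity < 0 || purity > 1) stop("purity must lie in [0,1]")
  nTum <- round(purity * n_nuclei)
  withSeed(seed, {
    img <- array(0, dim = c(height, width, 3))
    base <- c(0.88, 0.80, 0.86)
    X <- matrix(seq_len(width), height, width, byrow = TRUE)
    Y <- matrix(seq_len(height), height, width)
    blotch <- 0
    if (stromalCoupling) {
      ph <- runif(2, 0, 2 * pi)
      blotch <- 0.18 * purity *
        (sin(2 * pi * X / 41 + ph[1]) * sin(2 * pi * Y / 37 + ph[2]))
    }
    cls <- c(rep("tumor", nTum), rep("normal", n_nuclei - nTum))
    rad <- ifelse(cls == "tumor", tumorRadius, normalRadius) *
      runif(n_nuclei, 0.9, 1.1)
    margin <- ceiling(max(rad)) + 1
    # nuclei do not coincide: rejection-sample centers with a minimum
    # separation (best effort after 200 tries)
    minSep <- 1.1 * (tumorRadius + normalRadius)
    cx <- cy <- numeric(n_nuclei)
    for (k in seq_len(n_nuclei)) {
      for (try in 1:200) {
        px <- runif(1, margin, width - margin)
        py <- runif(1, margin, height - margin)
        if (k == 1 || min((cx[seq_len(k - 1)] - px)^2 +
                          (cy[seq_len(k - 1)] - py)^2) >= minSep^2) break
      }
      cx[k] <- px; cy[k] <- py
    }
    inten <- ifelse(cls == "tumor", tumorIntensity, normalIntensity)
    dark <- matrix(0, height, width)
    for (k in seq_len(n_nuclei)) {
      d2 <- (X - cx[k])^2 + (Y - cy[k])^2
      dark <- pmax(dark, (base[1] - inten[k]) * exp(-d2 / (2 * (rad[k] / 1.6)^2)))
    }
    for (c3 in 1:3) {
      ch <- base[c3] + blotch - dark +
        matrix(rnorm(height * width, 0, 0.015), height, width)
      img[, , c3] <- pmin(1, pmax(0, ch))
    }
    nuc <- data.frame(x = cx - 1, y = cy - 1, radius = rad, class = cls,
                      stringsAsFactors = FALSE)
    structure(list(roi_id = sprintf("ROI-%d", seed), image = img,
                   nuclei = nuc, purity = nTum / n_nuclei),
              class = "SyntheticROI")
  })
}

#' Binary mutation status from an impact-annotated mutation table
#'
#' A sample is called mutant for a gene iff the table contains at least one
#' row for that sample and gene whose impact category is MODERATE or HIGH;
#' otherwise wildtype.
#'
#' @param table data.frame with columns \code{sample_id}, \code{gene},
#'   \code{impact} (LOW/MODERATE/HIGH/MODIFIER).
#' @param gene gene symbol to label.
#' @param samples optional character vector of sample ids to label
#'   (defaults to the samples present in the table).
#' @return named character vector, values "mutant"/"wildtype".
#' @export
labelMutations <- function(table, gene, samples = NULL) {
  if (nrow(table) > 0) {
    ok <- c("LOW", "MODERATE", "HIGH", "MODIFIER")
    bad <- setdiff(unique(table$impact), ok)
    if (length(bad))
      stop("unknown impact category: ", paste(bad, collapse = ", "))
  }
  if (is.null(samples)) samples <- unique(table$sample_id)
  hit <- table$gene == gene & table$impact %in% c("MODERATE", "HIGH")
  mut <- unique(table$sample_id[hit])
  setNames(ifelse(samples %in% mut, "mutant", "wildtype"), samples)
}

#' Train/test split of a slide metadata table
#'
#' @param slides metadata data.frame (as from
#'   \code{\link{cohortMetadata}}) with \code{slide_id}, \code{patient_id},
#'   \code{label}.
#' @param ratio training fraction in (0,1).
#' @param mode "slide" stratifies by class at the slide level; "patient"
#'   splits patients (grouped by whether they own adjacent-normal slides)
#'   and assigns all their slides to one side; "matched_patient" restricts
#'   to patients owning both tumor and normal slides before splitting.
#' @param seed integer seed.
#' @return list with character vectors \code{train} and \code{test} of slide
#'   ids; disjoint by construction.
#' @export
splitTrainTest <- function(slides, ratio = 0.7,
                           mode = c("slide", "patient", "matched_patient"),
                           seed = 1L) {
  mode <- match.arg(mode)
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie in (0,1)")
  withSeed(seed, {
    if (mode == "slide") {
      train <- character(0)
      for (lv in unique(slides$label)) {
        ids <- slides$slide_id[slides$label == lv]
        k <- round(ratio * length(ids))
        train <- c(train, sample(ids, k))
      }
      test <- setdiff(slides$slide_id, train)
    } else {
      sl <- slides
      if (mode == "matched_patient") {
        tab <- table(sl$patient_id, sl$label)
        matched <- rownames(tab)[tab[, "tumor"] > 0 & tab[, "normal"] > 0]
        sl <- sl[sl$patient_id %in% matched, , drop = FALSE]
        if (nrow(sl) == 0) stop("no matched patients in cohort")
      }
      hasNormal <- tapply(sl$label == "normal", sl$patient_id, any)
      trainPat <- character(0)
      for (grp in c(TRUE, FALSE)) {
        pats <- names(hasNormal)[hasNormal == grp]
        if (!length(pats)) next
        k <- round(ratio * length(pats))
        trainPat <- c(trainPat, sample(pats, k))
      }
      train <- sl$slide_id[sl$patient_id %in% trainPat]
      test <- setdiff(sl$slide_id, train)
    }
    for (side in list(train = train, test = test)) {
      lv <- slides$label[slides$slide_id %in% side]
      if (length(unique(slides$label)) > length(unique(lv)))
        warning("a class is absent from one split at the requested ratio")
    }
    list(train = train, test = test)
  })
}

#' Write a cohort to disk as lossless PNGs and a TSV metadata table
#'
#' @param cohort a \code{\linkS4class{SyntheticCohort}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the metadata file path.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  md <- cohortMetadata(cohort)
  for (sid in md$slide_id) {
    png::writePNG(slideImage(cohort, sid), file.path(dir, paste0(sid, ".png")))
  }
  path <- file.path(dir, "metadata.tsv")
  write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ROI images and their nucleus annotation TSV
#'
#' @param rois list of \code{SyntheticROI}.
#' @param dir output directory.
#' @return invisibly, the nuclei TSV path (columns roi_id, x, y, radius,
#'   class).
#' @export
writeROIs <- function(rois, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nuc <- do.call(rbind, lapply(rois, function(r) {
    png::writePNG(r$image, file.path(dir, paste0(r$roi_id, ".png")))
    cbind(roi_id = r$roi_id, r$nuclei)
  }))
  path <- file.path(dir, "nuclei.tsv")
  write.table(nuc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
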