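# Synthetic cohort generator: bookkeeping, determinism, planted structure.

test_that("cohort bookkeeping: counts, metadata rows, purity identity", {
  specs <- defaultTissueSpecs(2)
  co <- generateCohort(specs, c(tumor = 4, normal = 4), seed = 1,
                       tileGrid = c(4, 4), tileSize = 16)
  md <- cohortMetadata(co)
  expect_equal(nrow(md), 16L)
  expect_equal(length(co@slides), 16L)
  expect_equal(sum(md$label == "tumor"), 8L)
  # purity equals the tumor-latent tile fraction exactly (validity enforces
  # it; check directly for one slide of each label)
  for (sid in md$slide_id[c(1, nrow(md))]) {
    expect_identical(md$purity[md$slide_id == sid],
                     mean(slideTileLabels(co, sid) == "tumor"))
  }
  expect_true(all(md$purity[md$label == "normal"] == 0))
  # normal slides contain no tumor-latent tiles
  for (sid in md$slide_id[md$label == "normal"])
    expect_true(all(slideTileLabels(co, sid) == "normal"))
})

test_that("identical seeds reproduce identical cohorts byte for byte", {
  specs <- defaultTissueSpecs(2)
  a <- generateCohort(specs, c(tumor = 2, normal = 2), seed = 5,
                      tileGrid = c(3, 3), tileSize = 16)
  b <- generateCohort(specs, c(tumor = 2, normal = 2), seed = 5,
                      tileGrid = c(3, 3), tileSize = 16)
  expect_identical(cohortMetadata(a), cohortMetadata(b))
  expect_identical(a@slides, b@slides)
  c2 <- generateCohort(specs, c(tumor = 2, normal = 2), seed = 6,
                       tileGrid = c(3, 3), tileSize = 16)
  expect_false(identical(a@slides, c2@slides))
})

test_that("generator rejects invalid inputs", {
  expect_error(generateCohort(defaultTissueSpecs(2)[1],
                              c(tumor = 2, normal = 2)), "2 tissues")
  expect_error(generateCohort(defaultTissueSpecs(2),
                              c(tumor = 0, normal = 2)), "counts")
  expect_error(generateCohort(defaultTissueSpecs(2), c(tumor = 2, normal = 2),
                              purityDistribution = list(type = "uniform",
                                                        min = 0.5, max = 1.4)),
               "\\[0,1\\]")
  expect_error(tissueSpec("x", textureSignature(), textureSignature(),
                          shared_weight = 1.2), "\\[0,1\\]")
})

test_that("normal tiles ignore the shared signature; zero weight detaches it", {
  sp <- defaultTissueSpecs(2)[[1]]
  other <- textureSignature(density = 100, r = 0.1, g = 0.9, b = 0.1)
  n1 <- renderTile(sp, "normal", sharedMalignancySignature(), seed = 3,
                   size = 24)
  n2 <- renderTile(sp, "normal", other, seed = 3, size = 24)
  expect_identical(n1, n2)
  sp0 <- sp; sp0$shared_weight <- 0
  t1 <- renderTile(sp0, "tumor", sharedMalignancySignature(), seed = 3,
                   size = 24)
  t2 <- renderTile(sp0, "tumor", other, seed = 3, size = 24)
  expect_identical(t1, t2)
})

test_that("shared_weight 1 makes tumor textures indistinguishable across tissues", {
  specs <- defaultTissueSpecs(2, shared_weight = 1)
  stat <- function(sp, seeds) vapply(seeds, function(s)
    mean(renderTile(sp, "tumor", size = 24, seed = s)), 0)
  s1 <- stat(specs[[1]], 1:60)
  s2 <- stat(specs[[2]], 61:120)
  # same texture distribution: a two-sample test finds no difference
  expect_gt(t.test(s1, s2)$p.value, 0.01)
  # sanity: at weight 0 the same statistic does separate the tissues from
  # the shared signature's own level
  specs0 <- defaultTissueSpecs(2, shared_weight = 0)
  s3 <- stat(specs0[[1]], 1:60)
  expect_lt(t.test(s1, s3)$p.value, 1e-6)
})

test_that("ROI generator: rounding, degenerate purity, annotation bookkeeping", {
  roi <- generateROI(100, 0.58, seed = 2)
  expect_equal(sum(roi$nuclei$class == "tumor"), 58L)
  expect_equal(roi$purity, 0.58)
  roi0 <- generateROI(40, 0, seed = 3)
  expect_true(all(roi0$nuclei$class == "normal"))
  # centers inside the image (0-based)
  expect_true(all(roi$nuclei$x >= 0 & roi$nuclei$x < 160))
  expect_true(all(roi$nuclei$y >= 0 & roi$nuclei$y < 140))
  expect_error(generateROI(10, 1.2), "\\[0,1\\]")
  expect_error(generateROI(0, 0.5), "n_nuclei")
})

test_that("truncated-normal ROI purities reproduce the cohort mean", {
  # colorectal-style spread: mean 0.58, sd 0.192, truncated to [0,1]
  purs <- withr::with_seed(9, {
    p <- rnorm(400, 0.58, 0.192)
    p[p >= 0 & p <= 1][1:300]
  })
  rois <- lapply(seq_along(purs), function(i)
    generateROI(50, purs[i], seed = i))
  got <- vapply(rois, `[[`, 0, "purity")
  expect_lt(abs(mean(got) - 0.58), 3 * 0.192 / sqrt(length(got)) + 0.01)
})

test_that("mutation labeling follows the MODERATE/HIGH rule", {
  tab <- data.frame(
    sample_id = c("s1", "s2", "s2", "s3", "s4"),
    gene = c("TP53", "TP53", "TP53", "TP53", "KRAS"),
    impact = c("HIGH", "LOW", "LOW", "MODERATE", "HIGH"),
    stringsAsFactors = FALSE)
  got <- labelMutations(tab, "TP53")
  expect_identical(got[["s1"]], "mutant")     # one HIGH row suffices
  expect_identical(got[["s2"]], "wildtype")   # only LOW rows
  expect_identical(got[["s3"]], "mutant")
  expect_identical(got[["s4"]], "wildtype")   # other gene does not count
  # empty table: everyone wildtype
  empty <- tab[0, ]
  expect_identical(unname(labelMutations(empty, "TP53",
                                         samples = c("a", "b"))),
                   c("wildtype", "wildtype"))
  bad <- tab; bad$impact[1] <- "SEVERE"
  expect_error(labelMutations(bad, "TP53"), "unknown impact")
})

test_that("train/test splits honor stratification and patient disjointness", {
  md <- cohortMetadata(smallCohort())
  md1 <- md[md$tissue == md$tissue[1], ]
  sp <- splitTrainTest(md1, ratio = 0.7, mode = "slide", seed = 4)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), md1$slide_id)
  # stratified 70/30 on 6+6 slides: 4+4 train, 2+2 test
  trLab <- md1$label[md1$slide_id %in% sp$train]
  expect_equal(unname(table(trLab)["tumor"]), 4L, ignore_attr = TRUE)
  expect_equal(unname(table(trLab)["normal"]), 4L, ignore_attr = TRUE)

  spp <- splitTrainTest(md, ratio = 0.7, mode = "patient", seed = 4)
  trPat <- md$patient_id[md$slide_id %in% spp$train]
  tePat <- md$patient_id[md$slide_id %in% spp$test]
  expect_length(intersect(trPat, tePat), 0)

  spm <- splitTrainTest(md, ratio = 0.5, mode = "matched_patient", seed = 4)
  used <- md[md$slide_id %in% c(spm$train, spm$test), ]
  # brute-force membership: every used patient owns both a tumor and a
  # normal slide in the full metadata
  for (p in unique(used$patient_id)) {
    own <- md$label[md$patient_id == p]
    expect_true(all(c("tumor", "normal") %in% own))
  }
  # and no matched patient was silently dropped
  tab <- table(md$patient_id, md$label)
  matched <- rownames(tab)[tab[, "tumor"] > 0 & tab[, "normal"] > 0]
  expect_setequal(unique(used$patient_id), matched)
})

test_that("10 tumor + 10 normal at ratio 0.7 gives a 7+7 / 3+3 slide split", {
  md <- data.frame(slide_id = sprintf("s%02d", 1:20),
                   patient_id = sprintf("p%02d", 1:20),
                   label = rep(c("tumor", "normal"), each = 10),
                   stringsAsFactors = FALSE)
  sp <- splitTrainTest(md, ratio = 0.7, mode = "slide", seed = 1)
  trLab <- md$label[md$slide_id %in% sp$train]
  expect_equal(sum(trLab == "tumor"), 7L)
  expect_equal(sum(trLab == "normal"), 7L)
  expect_length(sp$test, 6L)
})

test_that("cohort round-trips through PNG + TSV on disk", {
  co <- smallCohort()
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  md <- read.table(file.path(dir, "metadata.tsv"), header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  expect_equal(nrow(md), nrow(cohortMetadata(co)))
  img <- png::readPNG(file.path(dir, paste0(md$slide_id[1], ".png")))
  orig <- slideImage(co, md$slide_id[1])
  expect_equal(dim(img), dim(orig))
  expect_lt(max(abs(img - orig)), 1 / 255)  # 8-bit quantization only
})
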