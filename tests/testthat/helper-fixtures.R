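# Shared fixtures, generated in code and memoized for the test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small 2-tissue cohort + caches + per-tissue heads, reused across files
smallCohort <- function() {
  fixture("smallCohort", function() {
    specs <- defaultTissueSpecs(2)
    generateCohort(specs, c(tumor = 6, normal = 6), seed = 101,
                   tileGrid = c(6, 6), tileSize = 32)
  })
}

smallCaches <- function() {
  fixture("smallCaches", function() cohortCaches(smallCohort()))
}

smallHeads <- function() {
  fixture("smallHeads", function() {
    trainTissueHeads(smallCaches(), cohortMetadata(smallCohort()),
                     headConfig(hidden_units = 16L, batch_size = 64L,
                                steps = 200L),
                     seed = 7)
  })
}

deskHeadConfig <- function(seed = 1L) {
  headConfig(hidden_units = 16L, batch_size = 64L, steps = 300L, seed = seed)
}

# brute-force all-pairs ROC AUC oracle (ties counted 1/2)
bruteAUC <- function(scores, labels, positive = "pos") {
  ps <- scores[labels == positive]
  ns <- scores[labels != positive]
  tot <- 0
  for (a in ps) for (b in ns) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(ps) * length(ns))
}

# brute-force UPGMA: exhaustive repeated merging of the closest pair with
# average linkage; returns merge heights and member sets
bruteUPGMA <- function(d) {
  n <- attr(d, "Size")
  D <- as.matrix(d)
  clusters <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  active <- seq_len(n)
  heights <- numeric(0)
  merges <- list()
  while (length(active) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (ai in seq_along(active)) for (bi in seq_along(active)) {
      if (bi <= ai) next
      i <- active[ai]; j <- active[bi]
      h <- D[i, j]
      if (h < bh - 1e-12) { bh <- h; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    newMembers <- sort(c(clusters[[i]], clusters[[j]]))
    # UPGMA update: size-weighted average of distances
    k <- length(clusters) + 1L
    Dnew <- rep(NA_real_, k)
    for (m in active) {
      if (m %in% c(i, j)) next
      Dnew[m] <- (sizes[i] * D[i, m] + sizes[j] * D[j, m]) /
        (sizes[i] + sizes[j])
    }
    D <- rbind(cbind(D, NA_real_), NA_real_)
    D[k, seq_len(k - 1)] <- Dnew[seq_len(k - 1)]
    D[seq_len(k - 1), k] <- Dnew[seq_len(k - 1)]
    D[k, k] <- 0
    clusters[[k]] <- newMembers
    sizes[k] <- sizes[i] + sizes[j]
    active <- c(setdiff(active, c(i, j)), k)
    heights <- c(heights, bh)
    merges[[length(merges) + 1L]] <- newMembers
  }
  list(heights = heights, merges = merges)
}

# brute-force BH step-up adjusted p-values
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
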