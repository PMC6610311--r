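# Shared fixtures and independent oracles. The oracles are deliberately
# naive (explicit loops, no shared code with the package internals) so
# they can arbitrate the vectorized implementations.

fourTipTree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

# Floyd-Warshall shortest paths over the tree's edge graph; returns the
# tip-by-tip distance matrix. Independent of ape::cophenetic.phylo.
fwDistances <- function(tree) {
  nTips <- length(tree$tip.label)
  nNode <- nTips + tree$Nnode
  d <- matrix(Inf, nNode, nNode)
  diag(d) <- 0
  for (k in seq_len(nrow(tree$edge))) {
    i <- tree$edge[k, 1]
    j <- tree$edge[k, 2]
    w <- tree$edge.length[k]
    d[i, j] <- min(d[i, j], w)
    d[j, i] <- d[i, j]
  }
  for (k in seq_len(nNode))
    for (i in seq_len(nNode))
      for (j in seq_len(nNode))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  out <- d[seq_len(nTips), seq_len(nTips)]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

# Brute-force MNTD: explicit double loop over present taxa.
bruteMntd <- function(x, d, weighted = FALSE) {
  present <- which(x > 0)
  if (length(present) < 2) return(NA_real_)
  mins <- numeric(length(present))
  for (a in seq_along(present)) {
    best <- Inf
    for (b in seq_along(present)) {
      if (a == b) next
      best <- min(best, d[present[a], present[b]])
    }
    mins[a] <- best
  }
  if (weighted) {
    w <- x[present] / sum(x[present])
    sum(w * mins)
  } else mean(mins)
}

# Brute-force betaMNTD: per-side nearest-neighbor loops, then the
# symmetrized weighted average.
bruteBetaMntd <- function(x, y, d, weighted = TRUE) {
  ia <- which(x > 0)
  ib <- which(y > 0)
  minsA <- numeric(length(ia))
  for (a in seq_along(ia)) {
    best <- Inf
    for (b in seq_along(ib)) best <- min(best, d[ia[a], ib[b]])
    minsA[a] <- best
  }
  minsB <- numeric(length(ib))
  for (b in seq_along(ib)) {
    best <- Inf
    for (a in seq_along(ia)) best <- min(best, d[ia[a], ib[b]])
    minsB[b] <- best
  }
  wa <- if (weighted) x[ia] / sum(x[ia]) else rep(1 / length(ia), length(ia))
  wb <- if (weighted) y[ib] / sum(y[ib]) else rep(1 / length(ib), length(ib))
  0.5 * (sum(wa * minsA) + sum(wb * minsB))
}

# Elementwise Bray-Curtis oracle.
bruteBray <- function(x, y) {
  num <- 0
  den <- 0
  for (i in seq_along(x)) {
    num <- num + abs(x[i] - y[i])
    den <- den + x[i] + y[i]
  }
  num / den
}

# Random rooted tree with branch lengths, for property tests.
randomTree <- function(nTips, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rtree(nTips)
  tree$tip.label <- sprintf("t%02d", seq_len(nTips))
  tree
}

# Random aligned count table over a tree's tips.
randomTable <- function(tree, nSamples, lambda = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  m <- matrix(stats::rpois(n * nSamples, lambda), n, nSamples,
              dimnames = list(tree$tip.label,
                              sprintf("s%02d", seq_len(nSamples))))
  # guarantee >= 2 present taxa per sample
  for (s in seq_len(nSamples)) {
    while (sum(m[, s] > 0) < 2) m[, s] <- stats::rpois(n, lambda)
  }
  m
}

smallCommunitySet <- function(seed = 42, nTaxa = 16, nSamples = 3,
                              nGroups = 2, depth = 100,
                              scenario = "neutral") {
  simulateScenario(scenarioConfig(scenario, nTaxa = nTaxa,
                                  nSamplesPerGroup = nSamples,
                                  nGroups = nGroups, depth = depth,
                                  seed = seed))
}
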