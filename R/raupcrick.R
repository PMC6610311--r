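#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|x - y|) / sum(x + y)` over taxa; 0 for identical communities,
#' 1 for communities sharing no taxa.
#'
#' @param x,y non-negative abundance vectors of equal length, each with a
#'   positive total.
#' @return dissimilarity in `[0, 1]`.
#' @examples
#' brayCurtis(c(1, 1, 0), c(0, 1, 1))  # 0.5
#' @export
brayCurtis <- function(x, y) {
  if (length(x) != length(y))
    stop("abundance vectors must have equal length")
  if (sum(x) <= 0 || sum(y) <= 0)
    stop("Bray-Curtis undefined for a zero-total community")
  sum(abs(x - y)) / sum(x + y)
}

#' Metacommunity occupancy and abundance profile
#'
#' Per taxon, the number of samples where it occurs (occupancy) and its
#' total abundance across samples — the weights of the Raup-Crick null:
#' taxa are drawn into null communities with probability proportional to
#' occupancy, and individuals are allocated proportionally to total
#' abundance.
#'
#' @param counts taxa-by-samples count matrix or [CommunitySet-class].
#' @return `data.frame` with columns `taxon_id`, `occupancy`, `total`.
#' @export
metacommunityProfile <- function(counts) {
  if (is(counts, "CommunitySet")) counts <- communityCounts(counts)
  counts <- .asCountMatrix(counts)
  data.frame(
    taxon_id = rownames(counts),
    occupancy = as.integer(rowSums(counts > 0)),
    total = rowSums(counts),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' One Raup-Crick null draw for a sample pair
#'
#' Assembles two null communities independently: (i) taxa are drawn
#' without replacement, with probability proportional to metacommunity
#' occupancy, until the observed richness is reached; (ii) each drawn
#' taxon receives one individual and the remaining `n - richness`
#' individuals are distributed multinomially among the drawn taxa with
#' probability proportional to their metacommunity abundance totals.
#' Returns the Bray-Curtis dissimilarity between the two null communities.
#'
#' @param profile a [metacommunityProfile()] data.frame.
#' @param richnessA,richnessB observed richness of each sample.
#' @param nA,nB observed total abundance of each sample
#'   (`n >= richness`).
#' @param returnCommunities also return the two null abundance vectors
#'   (used by tests asserting richness/abundance conservation).
#' @return the null Bray-Curtis value, or (with
#'   `returnCommunities = TRUE`) `list(bray, x, y)`.
#' @export
nullPairBray <- function(profile, richnessA, richnessB, nA, nB,
                         returnCommunities = FALSE) {
  occ <- profile$occupancy
  tot <- profile$total
  nTaxa <- length(occ)
  if (richnessA < 1L || richnessB < 1L) stop("richness must be >= 1")
  if (nA < richnessA || nB < richnessB)
    stop("total abundance must be >= richness")
  if (sum(occ > 0) < max(richnessA, richnessB))
    stop("fewer taxa with occupancy > 0 than the requested richness")
  x <- .nullFill(occ, tot, richnessA, nA, nTaxa)
  y <- .nullFill(occ, tot, richnessB, nB, nTaxa)
  bc <- sum(abs(x - y)) / (nA + nB)
  if (returnCommunities) list(bray = bc, x = x, y = y) else bc
}

.nullFill <- function(occ, tot, richness, n, nTaxa) {
  ids <- sample.int(nTaxa, richness, prob = occ)
  x <- numeric(nTaxa)
  x[ids] <- 1
  if (n > richness) {
    pr <- tot[ids]
    if (sum(pr) <= 0) pr <- rep(1, length(ids))
    x[ids] <- x[ids] + stats::rmultinom(1L, n - richness, prob = pr)[, 1L]
  }
  x
}

#' Bray-Curtis Raup-Crick metric (RC-bray)
#'
#' Ranks each pair's observed Bray-Curtis dissimilarity against `reps`
#' draws from the two-stage probabilistic assembly null (see
#' [nullPairBray()]):
#' `p = (#\{null < obs\} + 0.5 #\{null = obs\}) / reps` and
#' `rc = 2 (p - 0.5)`, mapping to `[-1, +1]`. `rc < -0.95` marks pairs
#' significantly more similar than the null (homogenizing dispersal, given
#' `|betaNTI| < 2`); `rc > +0.95` significantly less similar (dispersal
#' limitation). Floating-point ties use a relative tolerance of 1e-12.
#'
#' @param x a [CommunitySet-class] or taxa-by-samples count matrix.
#' @param reps number of null draws per pair (default 999).
#' @param seed integer seed for reproducible draws.
#' @param pairs `"within"`, `"all"` (CommunitySet) or an explicit
#'   2-column matrix of sample names/indices.
#' @param scope metacommunity scope for the null weights: `"all"` pools
#'   every sample in `x` (default); `"group"` (CommunitySet only) builds
#'   a separate profile per sample group.
#' @param ... passed between methods.
#' @return `data.frame` with one row per pair: `sample_a`, `sample_b`,
#'   `bray_curtis`, `rc_bray`, `reps`.
#' @name rcBray
NULL

#' @rdname rcBray
#' @export
setMethod("rcBray", "CommunitySet", function(x, reps = 999L, seed = NULL,
                                             pairs = c("within", "all"),
                                             scope = c("all", "group"),
                                             ...) {
  counts <- communityCounts(x)
  scope <- match.arg(scope)
  if (is.character(pairs))
    pairs <- .selectPairs(colnames(counts), sampleGroups(x),
                          match.arg(pairs))
  if (scope == "all")
    return(rcBray(counts, reps = reps, seed = seed, pairs = pairs))
  # per-group profiles: run each group's pairs against its own pool
  groups <- sampleGroups(x)
  pairs <- .resolvePairs(pairs, colnames(counts), ncol(counts))
  ga <- groups[pairs[, 1L]]
  gb <- groups[pairs[, 2L]]
  if (any(ga != gb))
    stop("scope = 'group' requires within-group pairs")
  out <- vector("list", 0L)
  for (g in unique(ga)) {
    inG <- which(groups == g)
    sub <- counts[, inG, drop = FALSE]
    sel <- ga == g
    localPairs <- cbind(match(pairs[sel, 1L], inG),
                        match(pairs[sel, 2L], inG))
    gseed <- if (is.null(seed)) NULL else
      as.integer((as.numeric(seed) + 7L * match(g, unique(ga))) %%
                   .Machine$integer.max)
    out[[g]] <- rcBray(sub, reps = reps, seed = gseed, pairs = localPairs)
  }
  do.call(rbind, out)
})

#' @rdname rcBray
#' @export
setMethod("rcBray", "matrix", function(x, reps = 999L, seed = NULL,
                                       pairs = NULL, ...) {
  x <- .asCountMatrix(x)
  if (reps < 1L) stop("reps must be >= 1")
  totals <- colSums(x)
  pairs <- .resolvePairs(pairs, colnames(x), ncol(x))
  used <- unique(c(pairs))
  if (any(totals[used] <= 0))
    stop("RC-bray requires a positive total in every selected sample")
  profile <- metacommunityProfile(x)
  occ <- profile$occupancy
  tot <- profile$total
  nTaxa <- nrow(x)
  richness <- colSums(x > 0)
  if (!is.null(seed)) set.seed(seed)
  np <- nrow(pairs)
  obs <- numeric(np)
  rc <- numeric(np)
  for (k in seq_len(np)) {
    a <- pairs[k, 1L]
    b <- pairs[k, 2L]
    obs[k] <- brayCurtis(x[, a], x[, b])
    tol <- .relTol(obs[k])
    below <- 0
    ties <- 0
    for (r in seq_len(reps)) {
      xa <- .nullFill(occ, tot, richness[a], totals[a], nTaxa)
      xb <- .nullFill(occ, tot, richness[b], totals[b], nTaxa)
      bc <- sum(abs(xa - xb)) / (totals[a] + totals[b])
      if (bc < obs[k] - tol) below <- below + 1
      else if (bc <= obs[k] + tol) ties <- ties + 1
    }
    p <- (below + 0.5 * ties) / reps
    rc[k] <- 2 * (p - 0.5)
  }
  data.frame(
    sample_a = colnames(x)[pairs[, 1L]], sample_b = colnames(x)[pairs[, 2L]],
    bray_curtis = obs, rc_bray = rc, reps = as.integer(reps),
    row.names = NULL, stringsAsFactors = FALSE)
})
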