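#' Mean nearest taxon distance (MNTD) of one community
#'
#' For each taxon present in the community, the phylogenetic distance to
#' its closest relative also present; averaged either uniformly
#' (`weighted = FALSE`) or by relative abundance (`weighted = TRUE`).
#' Communities with fewer than two present taxa have no nearest taxon and
#' return `NA` with a warning (an explicit undefined flag, not silent NaN
#' propagation).
#'
#' @param x abundance vector for one sample. If named, names are matched
#'   against the labels of `dist`; otherwise positions are used.
#' @param dist symmetric taxon-by-taxon cophenetic distance matrix (see
#'   [copheneticMatrix()]).
#' @param weighted weight nearest-taxon distances by relative abundance.
#' @return a single distance, or `NA_real_` if richness < 2.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' d <- copheneticMatrix(tr)
#' mntd(c(A = 1, B = 1, C = 1, D = 0), d)  # 8/3
#' @export
mntd <- function(x, dist, weighted = FALSE) {
  x <- .alignAbundance(x, dist)
  idx <- which(x > 0)
  if (length(idx) < 2L) {
    warning("MNTD undefined: fewer than 2 taxa present")
    return(NA_real_)
  }
  .mntdAt(dist, idx, idx,
          w = if (weighted) x[idx] / sum(x[idx]) else NULL)
}

# MNTD of the taxa `perm_idx` (row/col indices into dist, already
# permuted if under a null); uniform weights when w is NULL.
.mntdAt <- function(dist, rows, cols, w = NULL) {
  sub <- dist[rows, cols, drop = FALSE]
  diag(sub) <- Inf
  mins <- .rowMins(sub)
  if (is.null(w)) mean(mins) else sum(w * mins)
}

.alignAbundance <- function(x, dist) {
  labels <- rownames(dist)
  if (!is.null(names(x))) {
    missing <- setdiff(names(x)[x > 0], labels)
    if (length(missing))
      stop("taxa absent from distance matrix: ",
           paste(missing, collapse = ", "))
    full <- stats::setNames(numeric(length(labels)), labels)
    full[names(x)[names(x) %in% labels]] <- x[names(x) %in% labels]
    return(full)
  }
  if (length(x) != nrow(dist))
    stop("unnamed abundance vector must match the distance matrix size")
  x
}

#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' Phylogenetic turnover between two communities: for each taxon in one
#' community, the distance to its nearest taxon in the other (zero if the
#' taxon itself occurs in both), averaged per side and symmetrized:
#' \deqn{0.5 \left[\sum_{i \in a} w_{ia} \min_{j \in b} d_{ij} +
#'       \sum_{j \in b} w_{jb} \min_{i \in a} d_{ij}\right]}
#' with weights `w` the within-sample relative abundances
#' (`weighted = TRUE`) or `1/richness` (`weighted = FALSE`).
#'
#' @param x,y abundance vectors for the two samples (named or positional,
#'   as in [mntd()]).
#' @inheritParams mntd
#' @return a single non-negative distance; 0 when `x` and `y` occupy the
#'   same taxa.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' d <- copheneticMatrix(tr)
#' betaMNTD(c(A = 1, B = 1, C = 0, D = 0), c(A = 0, B = 0, C = 1, D = 1), d)
#' @export
betaMNTD <- function(x, y, dist, weighted = TRUE) {
  x <- .alignAbundance(x, dist)
  y <- .alignAbundance(y, dist)
  ia <- which(x > 0)
  ib <- which(y > 0)
  if (length(ia) == 0L || length(ib) == 0L)
    stop("betaMNTD requires at least one present taxon in each community")
  wa <- if (weighted) x[ia] / sum(x[ia]) else rep(1 / length(ia), length(ia))
  wb <- if (weighted) y[ib] / sum(y[ib]) else rep(1 / length(ib), length(ib))
  .betaMntdAt(dist, ia, ib, wa, wb)
}

.betaMntdAt <- function(dist, ia, ib, wa, wb) {
  sub <- dist[ia, ib, drop = FALSE]
  0.5 * (sum(wa * .rowMins(sub)) + sum(wb * .colMins(sub)))
}

#' Shuffle the taxa labels of a distance matrix
#'
#' The "taxa.labels" randomization: rows and columns are jointly permuted
#' by one uniform random permutation, so the multiset of distances is
#' unchanged while taxon identities are randomized.
#'
#' @param dist labelled symmetric distance matrix.
#' @param seed optional integer seed for a reproducible permutation.
#' @return the permuted matrix, carrying the original labels in permuted
#'   positions.
#' @export
shuffleLabels <- function(dist, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- sample.int(nrow(dist))
  out <- dist[p, p, drop = FALSE]
  dimnames(out) <- dimnames(dist)
  out
}

#' Standardized effect size of MNTD (SES.MNTD)
#'
#' Per-sample MNTD compared against its taxa-labels null distribution:
#' `reps` random permutations of the distance-matrix labels, one shared
#' permutation per rep across all samples, with
#' `ses = (obs - mean(null)) / sd(null)`. Negative values indicate
#' phylogenetic clustering of co-occurring taxa; positive values
#' overdispersion. Samples with richness < 2 or a degenerate null
#' (`sd = 0`, e.g. a star phylogeny or a community holding every taxon)
#' are flagged undefined.
#'
#' @param x a [CommunitySet-class], or a taxa-by-samples count matrix
#'   (then `dist` is required).
#' @param dist taxon distance matrix matching the rows of the counts.
#' @param reps number of label permutations (default 999).
#' @param weighted abundance-weight the MNTD (default `FALSE`, the
#'   convention for within-sample SES.MNTD).
#' @param seed integer seed for reproducible permutations.
#' @param samples optional subset of sample names to analyze.
#' @param ... passed between methods.
#' @return `data.frame` with one row per sample: `sample_id`, `richness`,
#'   `mntd_obs`, `null_mean`, `null_sd`, `ses_mntd`, `reps`, `weighted`,
#'   `undefined`.
#' @name sesMNTD
NULL

#' @rdname sesMNTD
#' @export
setMethod("sesMNTD", "CommunitySet", function(x, reps = 999L,
                                              weighted = FALSE, seed = NULL,
                                              samples = NULL, ...) {
  counts <- communityCounts(x)
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  d <- copheneticMatrix(communityTree(x), order = rownames(counts))
  sesMNTD(counts, dist = d, reps = reps, weighted = weighted, seed = seed)
})

#' @rdname sesMNTD
#' @export
setMethod("sesMNTD", "matrix", function(x, dist, reps = 999L,
                                        weighted = FALSE, seed = NULL, ...) {
  .checkAlignedDist(x, dist)
  if (reps < 1L) stop("reps must be >= 1")
  n <- nrow(x)
  ns <- ncol(x)
  idx <- .presenceIndex(x)
  w <- if (weighted) .sampleWeights(x, idx, TRUE) else
    vector("list", ns)
  ok <- lengths(idx) >= 2L
  obs <- rep(NA_real_, ns)
  for (s in which(ok))
    obs[s] <- .mntdAt(dist, idx[[s]], idx[[s]], w[[s]])
  if (!is.null(seed)) set.seed(seed)
  nullv <- matrix(NA_real_, nrow = reps, ncol = ns)
  for (r in seq_len(reps)) {
    p <- sample.int(n)
    for (s in which(ok)) {
      pi <- p[idx[[s]]]
      nullv[r, s] <- .mntdAt(dist, pi, pi, w[[s]])
    }
  }
  nullMean <- colMeans(nullv)
  nullSd <- apply(nullv, 2L, stats::sd)
  degenerate <- ok & (is.na(nullSd) | nullSd <= .relTol(1) * pmax(1, nullMean))
  undefined <- !ok | degenerate
  if (any(degenerate))
    warning(sprintf("SES.MNTD undefined for %d sample(s): null sd = 0",
                    sum(degenerate)))
  ses <- ifelse(undefined, NA_real_, (obs - nullMean) / nullSd)
  data.frame(
    sample_id = colnames(x), richness = lengths(idx), mntd_obs = obs,
    null_mean = nullMean, null_sd = nullSd, ses_mntd = ses,
    reps = as.integer(reps), weighted = weighted, undefined = undefined,
    row.names = NULL, stringsAsFactors = FALSE)
})

.checkAlignedDist <- function(counts, dist) {
  if (nrow(counts) != nrow(dist))
    stop("count table and distance matrix have different taxon counts")
  if (!is.null(rownames(counts)) && !is.null(rownames(dist)) &&
      !identical(rownames(counts), rownames(dist)))
    stop("count table and distance matrix taxa are not in the same order")
  invisible(TRUE)
}

#' Beta nearest taxon index (betaNTI)
#'
#' For each sample pair, the observed [betaMNTD()] standardized against
#' its taxa-labels null: `reps` random joint permutations of the distance
#' matrix labels (one permutation per rep shared across all pairs), with
#' `betaNTI = (obs - mean(null)) / sd(null)`. `betaNTI < -2` indicates
#' significantly less phylogenetic turnover than expected (homogeneous
#' selection); `> +2` more than expected (variable selection). Pairs with
#' a degenerate null (`sd = 0`) are flagged undefined.
#'
#' @param x a [CommunitySet-class], or a taxa-by-samples count matrix
#'   (then `dist` is required).
#' @param dist taxon distance matrix matching the rows of the counts.
#' @param reps number of label permutations (default 999).
#' @param weighted abundance-weight betaMNTD (default `TRUE`, the
#'   convention of the null-modeling framework this implements).
#' @param seed integer seed for reproducible permutations.
#' @param pairs `"within"` (same-group pairs only; default for
#'   `CommunitySet`) or `"all"`, or an explicit 2-column matrix of sample
#'   names/indices.
#' @param ... passed between methods.
#' @return `data.frame` with one row per pair: `sample_a`, `sample_b`,
#'   `beta_mntd`, `null_mean`, `null_sd`, `beta_nti`, `reps`, `weighted`,
#'   `undefined`.
#' @name betaNTI
NULL

#' @rdname betaNTI
#' @export
setMethod("betaNTI", "CommunitySet", function(x, reps = 999L,
                                              weighted = TRUE, seed = NULL,
                                              pairs = c("within", "all"),
                                              ...) {
  counts <- communityCounts(x)
  d <- copheneticMatrix(communityTree(x), order = rownames(counts))
  if (is.character(pairs))
    pairs <- .selectPairs(colnames(counts), sampleGroups(x),
                          match.arg(pairs))
  betaNTI(counts, dist = d, reps = reps, weighted = weighted, seed = seed,
          pairs = pairs)
})

#' @rdname betaNTI
#' @export
setMethod("betaNTI", "matrix", function(x, dist, reps = 999L,
                                        weighted = TRUE, seed = NULL,
                                        pairs = NULL, ...) {
  .checkAlignedDist(x, dist)
  if (reps < 1L) stop("reps must be >= 1")
  ns <- ncol(x)
  pairs <- .resolvePairs(pairs, colnames(x), ns)
  idx <- .presenceIndex(x)
  if (any(lengths(idx)[unique(c(pairs))] == 0L))
    stop("betaNTI requires at least one present taxon per sample")
  w <- .sampleWeights(x, idx, weighted)
  n <- nrow(x)
  used <- sort(unique(c(pairs)))
  obs <- .betaMntdAllPairs(dist, idx, w, pairs, seq_len(n), used)
  if (!is.null(seed)) set.seed(seed)
  np <- nrow(pairs)
  nullSum <- numeric(np)
  nullSumSq <- numeric(np)
  for (r in seq_len(reps)) {
    p <- sample.int(n)
    v <- .betaMntdAllPairs(dist, idx, w, pairs, p, used)
    nullSum <- nullSum + v
    nullSumSq <- nullSumSq + v * v
  }
  nullMean <- nullSum / reps
  nullSd <- if (reps > 1L)
    sqrt(pmax(0, (nullSumSq - nullSum^2 / reps) / (reps - 1L))) else
    rep(NA_real_, np)
  undefined <- is.na(nullSd) | nullSd <= .relTol(1) * pmax(1, nullMean)
  if (any(undefined))
    warning(sprintf("betaNTI undefined for %d pair(s): null sd = 0",
                    sum(undefined)))
  bnti <- ifelse(undefined, NA_real_, (obs - nullMean) / nullSd)
  data.frame(
    sample_a = colnames(x)[pairs[, 1L]], sample_b = colnames(x)[pairs[, 2L]],
    beta_mntd = obs, null_mean = nullMean, null_sd = nullSd,
    beta_nti = bnti, reps = as.integer(reps), weighted = weighted,
    undefined = undefined, row.names = NULL, stringsAsFactors = FALSE)
})

.resolvePairs <- function(pairs, sampleNames, ns) {
  if (is.null(pairs)) return(.selectPairs(seq_len(ns), mode = "all"))
  if (is.character(pairs) && length(pairs) <= 2L && is.null(dim(pairs)))
    stop("character pair modes require a CommunitySet (group labels)")
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("pairs must be a 2-column matrix")
  if (is.character(pairs)) {
    m <- matrix(match(pairs, sampleNames), ncol = 2L)
    if (anyNA(m)) stop("unknown sample name in pairs")
    pairs <- m
  }
  storage.mode(pairs) <- "integer"
  if (any(pairs[, 1L] == pairs[, 2L]))
    stop("pairs must consist of two distinct samples")
  pairs
}

# betaMNTD for every pair under one label permutation `p`. Builds the
# taxon-by-sample matrix of nearest-in-sample distances once, then reads
# each pair off it; a taxon shared by both samples contributes 0 because
# the matrix diagonal survives relabeling.
.betaMntdAllPairs <- function(dist, idx, w, pairs, p, used) {
  n <- nrow(dist)
  M <- matrix(NA_real_, n, length(idx))
  for (s in used)
    M[, s] <- .rowMins(dist[p, p[idx[[s]]], drop = FALSE])
  out <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1L]
    b <- pairs[k, 2L]
    out[k] <- 0.5 * (sum(w[[a]] * M[idx[[a]], b]) +
                     sum(w[[b]] * M[idx[[b]], a]))
  }
  out
}

#' Write per-sample SES.MNTD results to TSV
#'
#' @param ses the `data.frame` returned by [sesMNTD()].
#' @param path output file path.
#' @export
writeSesMntd <- function(ses, path) {
  utils::write.table(ses, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
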