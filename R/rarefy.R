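#' Rarefy a count table to fixed depth
#'
#' Classic rarefaction: each sample is subsampled without replacement to
#' exactly `depth` individuals (via [vegan::rrarefy()]). Samples whose
#' total is below `depth` are dropped with a warning; if no sample reaches
#' the depth the call fails. A fixed `seed` makes the draw reproducible.
#'
#' The study convention this mirrors is subsampling 16S libraries to a
#' common depth (e.g. 1,073 bacterial or 116 archaeal reads per sample)
#' before any diversity or null-model computation.
#'
#' @param counts taxa-by-samples matrix of non-negative integers, or a
#'   [CommunitySet-class] (rarefied in place, metadata preserved).
#' @param depth target number of individuals per sample (>= 1).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return same type as `counts`, with every retained column summing to
#'   exactly `depth`.
#' @examples
#' m <- matrix(c(50, 50, 0, 900, 0, 0), nrow = 3,
#'             dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' rarefyTable(m, depth = 10, seed = 1)
#' @export
rarefyTable <- function(counts, depth, seed = NULL) {
  if (is(counts, "CommunitySet")) {
    m <- rarefyTable(communityCounts(counts), depth, seed)
    return(CommunitySet(communityTree(counts), m,
                        sampleData(counts)[colnames(m), , drop = FALSE],
                        groupField = counts@groupField, align = TRUE))
  }
  counts <- .asCountMatrix(counts)
  .checkCountCells(counts, "rarefyTable input")
  if (!is.numeric(depth) || length(depth) != 1L || depth < 1 ||
      depth != round(depth))
    stop("depth must be a positive integer")
  totals <- colSums(counts)
  low <- totals < depth
  if (all(low))
    stop(sprintf("all %d samples have fewer than %d individuals", ncol(counts),
                 depth))
  if (any(low))
    warning(sprintf("dropping %d sample(s) below rarefaction depth %d: %s",
                    sum(low), depth,
                    paste(colnames(counts)[low], collapse = ", ")))
  keep <- counts[, !low, drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  # vegan warns when a table holds no singleton counts (advisory only)
  out <- withCallingHandlers(
    t(vegan::rrarefy(t(keep), sample = depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  storage.mode(out) <- "double"
  dimnames(out) <- dimnames(keep)
  out
}
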