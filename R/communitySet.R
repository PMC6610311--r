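#' Construct a CommunitySet
#'
#' Bundles a rooted phylogeny, a taxa-by-samples count table and sample
#' metadata into a validated [CommunitySet-class] object. With
#' `align = TRUE` (the default) the tree and table are first pruned to
#' their common taxa via [alignTreeTable()].
#'
#' @param tree rooted `ape::phylo` tree with branch lengths.
#' @param counts numeric matrix of non-negative integer counts, taxa in
#'   rows (rownames), samples in columns (colnames).
#' @param metadata `data.frame` of per-sample metadata. May carry sample
#'   names as rownames or in a `sample_id` column.
#' @param groupField name of the metadata column with the sample group
#'   label (default `"group"`).
#' @param align prune tree and table to their shared taxa before
#'   validation.
#'
#' @return a `CommunitySet`.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' counts <- matrix(c(5, 3, 0, 2, 0, 7, 1, 1), nrow = 4,
#'                  dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
#' md <- data.frame(group = c("top", "top"), row.names = c("s1", "s2"))
#' cs <- CommunitySet(tr, counts, md)
#' cs
#' @export
CommunitySet <- function(tree, counts, metadata, groupField = "group",
                         align = TRUE) {
  counts <- .asCountMatrix(counts)
  metadata <- .asSampleMetadata(metadata, colnames(counts))
  if (align) {
    aligned <- alignTreeTable(tree, counts)
    tree <- aligned$tree
    counts <- aligned$counts
  }
  new("CommunitySet", tree = tree, counts = counts, metadata = metadata,
      groupField = groupField)
}

.asCountMatrix <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix")
  storage.mode(counts) <- "double"
  counts
}

.asSampleMetadata <- function(metadata, samples) {
  if (!is.data.frame(metadata)) stop("metadata must be a data.frame")
  if ("sample_id" %in% colnames(metadata) &&
      anyDuplicated(metadata$sample_id) == 0L)
    rownames(metadata) <- metadata$sample_id
  missing <- setdiff(samples, rownames(metadata))
  if (length(missing))
    stop("metadata is missing samples: ", paste(missing, collapse = ", "))
  metadata
}

#' Prune a tree and a count table to their shared taxa
#'
#' Drops tree tips absent from the table and table rows absent from the
#' tree, warning with the dropped names on each side. The retained taxon
#' order is the table's row order; the tree is pruned with
#' [ape::keep.tip()].
#'
#' @param tree `ape::phylo` tree.
#' @param counts taxa-by-samples count matrix with rownames.
#' @return `list(tree = , counts = )` restricted to the common taxa.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' m <- matrix(1, 3, 2, dimnames = list(c("B", "C", "E"), c("s1", "s2")))
#' suppressWarnings(alignTreeTable(tr, m))
#' @export
alignTreeTable <- function(tree, counts) {
  counts <- .asCountMatrix(counts)
  if (is.null(rownames(counts))) stop("counts must have taxon rownames")
  common <- intersect(rownames(counts), tree$tip.label)
  if (length(common) < 2L)
    stop("fewer than 2 taxa shared between tree and table")
  dropTree <- setdiff(tree$tip.label, common)
  dropTable <- setdiff(rownames(counts), common)
  if (length(dropTree))
    warning(sprintf("dropping %d tree tip(s) absent from table: %s",
                    length(dropTree), paste(dropTree, collapse = ", ")))
  if (length(dropTable))
    warning(sprintf("dropping %d table taxa absent from tree: %s",
                    length(dropTable), paste(dropTable, collapse = ", ")))
  list(tree = ape::keep.tip(tree, common),
       counts = counts[common, , drop = FALSE])
}

#' @rdname CommunitySet-class
#' @export
setMethod("communityTree", "CommunitySet", function(x) x@tree)

#' @rdname CommunitySet-class
#' @export
setMethod("communityCounts", "CommunitySet", function(x) x@counts)

#' @rdname CommunitySet-class
#' @export
setMethod("sampleData", "CommunitySet", function(x) x@metadata)

#' @rdname CommunitySet-class
#' @export
setMethod("taxonNames", "CommunitySet", function(x) rownames(x@counts))

#' @rdname CommunitySet-class
#' @export
setMethod("sampleNames", "CommunitySet", function(x) colnames(x@counts))

#' @rdname CommunitySet-class
#' @export
setMethod("sampleGroups", "CommunitySet", function(x) {
  g <- x@metadata[colnames(x@counts), x@groupField]
  stats::setNames(as.character(g), colnames(x@counts))
})

setMethod("show", "CommunitySet", function(object) {
  cat("CommunitySet\n")
  cat(sprintf("  %d taxa x %d samples; tree with %d tips\n",
              nrow(object@counts), ncol(object@counts),
              length(object@tree$tip.label)))
  g <- table(sampleGroups(object))
  cat(sprintf("  groups (%s): %s\n", object@groupField,
              paste(sprintf("%s=%d", names(g), g), collapse = ", ")))
  cat(sprintf("  column totals: %s\n",
              paste(utils::head(colSums(object@counts), 6), collapse = ", ")))
})

#' @rdname TurnoverResult-class
#' @export
setMethod("turnoverPairs", "TurnoverResult", function(x) x@pairs)

setMethod("show", "TurnoverResult", function(object) {
  cat("TurnoverResult\n")
  cat(sprintf("  %d sample pairs (%s); betaNTI reps = %d, RC-bray reps = %d, %s\n",
              nrow(object@pairs), object@pairScope, object@repsBnti,
              object@repsRc,
              if (object@weighted) "abundance-weighted" else "unweighted"))
  tab <- table(factor(object@pairs$process_label,
                      levels = c(assemblyProcesses(), "undefined")))
  for (nm in names(tab)) if (tab[[nm]] > 0)
    cat(sprintf("    %-24s %d\n", nm, tab[[nm]]))
})

#' @rdname ProcessSummary-class
#' @export
setMethod("processFractions", "ProcessSummary", function(x) x@fractions)

#' @rdname ProcessSummary-class
#' @export
setMethod("processCounts", "ProcessSummary", function(x) x@counts)

setMethod("show", "ProcessSummary", function(object) {
  cat("ProcessSummary\n")
  for (g in unique(object@fractions$group)) {
    cnt <- object@counts[object@counts$group == g, ]
    cat(sprintf("  %s (n_pairs = %d, undefined = %d)\n", g, cnt$n_pairs,
                cnt$n_undefined))
    fr <- object@fractions[object@fractions$group == g, ]
    for (k in seq_len(nrow(fr))) if (fr$fraction[k] > 0)
      cat(sprintf("    %-24s %.3f\n", fr$process[k], fr$fraction[k]))
  }
})
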