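#' Read and validate a rooted Newick tree
#'
#' Wraps [ape::read.tree()] with the validation this package needs: the
#' tree must parse, be rooted, have at least two uniquely labelled tips,
#' and carry a finite non-negative branch length on every edge.
#'
#' @param path path to a Newick file.
#' @return an `ape::phylo` tree.
#' @export
readTree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- tryCatch(ape::read.tree(path), error = function(e)
    stop(sprintf("Newick parse failure in '%s': %s", path,
                 conditionMessage(e)), call. = FALSE))
  if (is.null(tree)) stop("Newick parse failure in '", path, "'")
  validateTree(tree, context = path)
  tree
}

#' @rdname readTree
#' @param tree an `ape::phylo` object to validate in place.
#' @param context label used in error messages.
#' @param rooted require the tree to be rooted (the file-input contract;
#'   distance computations also accept basal polytomies).
#' @export
validateTree <- function(tree, context = "tree", rooted = TRUE) {
  if (!inherits(tree, "phylo")) stop(context, ": not a phylo object")
  if (length(tree$tip.label) < 2L)
    stop(context, ": tree must have at least 2 tips")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop(sprintf("%s: duplicate tip labels: %s", context,
                 paste(dup, collapse = ", ")))
  }
  if (is.null(tree$edge.length) ||
      length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length))
    stop(context, ": every edge must have a branch length")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop(context, ": branch lengths must be finite and >= 0")
  if (rooted && !ape::is.rooted(tree))
    stop(context, ": tree must be rooted")
  invisible(tree)
}

#' Write a tree to Newick
#'
#' @param tree an `ape::phylo` tree.
#' @param path output file path.
#' @export
writeTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read an OTU count table from TSV
#'
#' Expects a tab-delimited file with taxon IDs in the first column and
#' sample IDs in the header (taxa as rows). Set `transpose = TRUE` for the
#' samples-as-rows layout. Cells must be non-negative integers; violations
#' are reported with their row and column.
#'
#' @param path path to the TSV file.
#' @param transpose input has samples as rows, taxa as columns.
#' @return numeric matrix, taxa in rows, samples in columns.
#' @export
readCommunityTable <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("table file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("empty or malformed community table: ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated IDs in first column of ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) &
                 !is.na(m), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                   rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]], path))
    stop("non-numeric community table: ", path)
  }
  .checkCountCells(m, path)
  if (transpose) m <- t(m)
  storage.mode(m) <- "double"
  m
}

.checkCountCells <- function(m, context) {
  bad <- which(!is.finite(m) | m < 0 | abs(m - round(m)) > 1e-8,
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf(
      "invalid count %s at row '%s', column '%s' in %s (need non-negative integers)",
      format(m[bad[1, 1], bad[1, 2]]), rownames(m)[bad[1, 1]],
      colnames(m)[bad[1, 2]], context))
  invisible(m)
}

#' Write an OTU count table to TSV
#'
#' @param counts taxa-by-samples matrix.
#' @param path output file path.
#' @param idColumn header for the taxon-ID column.
#' @export
writeCommunityTable <- function(counts, path, idColumn = "taxon_id") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- idColumn
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata from TSV
#'
#' First column (or a `sample_id` column) holds the sample ID; remaining
#' columns are metadata, including the grouping variable.
#'
#' @param path path to the TSV file.
#' @param groupField column that must be present (default `"group"`).
#' @return `data.frame` with sample IDs as rownames.
#' @export
readSampleMetadata <- function(path, groupField = "group") {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  idcol <- if ("sample_id" %in% colnames(df)) "sample_id" else colnames(df)[1L]
  ids <- as.character(df[[idcol]])
  if (anyDuplicated(ids))
    stop("duplicated sample IDs in ", path)
  rownames(df) <- ids
  if (!groupField %in% colnames(df))
    stop(sprintf("metadata %s lacks group column '%s'", path, groupField))
  if (anyNA(df[[groupField]]))
    stop("missing group label(s) in ", path)
  df
}

#' Write pairwise turnover results to long-format TSV
#'
#' One row per unordered sample pair with the columns `sample_a`,
#' `sample_b`, `group_a`, `group_b`, `beta_mntd`, `beta_nti`,
#' `bray_curtis`, `rc_bray`, `process_label`, ordered lexicographically by
#' pair so reruns are byte-comparable.
#'
#' @param results a [TurnoverResult-class] or its `pairs` data.frame.
#' @param path output file path.
#' @export
writeTurnoverResults <- function(results, path) {
  df <- if (is(results, "TurnoverResult")) turnoverPairs(results) else results
  if (!is.data.frame(df) || nrow(df) == 0L)
    stop("no turnover results to write")
  swap <- df$sample_a > df$sample_b
  if (any(swap)) {
    tmp <- df$sample_a[swap]
    df$sample_a[swap] <- df$sample_b[swap]
    df$sample_b[swap] <- tmp
    tmp <- df$group_a[swap]
    df$group_a[swap] <- df$group_b[swap]
    df$group_b[swap] <- tmp
  }
  df <- df[order(df$sample_a, df$sample_b), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTurnoverResults
#' @export
readTurnoverResults <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a process summary as JSON and tidy TSV
#'
#' @param summary a [ProcessSummary-class].
#' @param jsonPath output JSON path (or `NULL` to skip).
#' @param tsvPath output TSV path (or `NULL` to skip).
#' @export
writeProcessSummary <- function(summary, jsonPath = NULL, tsvPath = NULL) {
  fr <- processFractions(summary)
  cnt <- processCounts(summary)
  if (!is.null(jsonPath)) {
    out <- lapply(split(fr, fr$group), function(d)
      as.list(stats::setNames(d$fraction, d$process)))
    for (g in names(out)) {
      row <- cnt[cnt$group == g, ]
      out[[g]]$n_pairs <- row$n_pairs
      out[[g]]$n_undefined <- row$n_undefined
    }
    jsonlite::write_json(out, jsonPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(tsvPath)) {
    tidy <- merge(fr, cnt, by = "group", sort = FALSE)
    utils::write.table(tidy, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(summary)
}

#' Export a pairwise distance matrix as TSV
#'
#' @param d symmetric labelled distance matrix.
#' @param path output path; labels go in the header and first column.
#' @export
writeDistanceMatrix <- function(d, path) {
  df <- data.frame(taxon_id = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
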