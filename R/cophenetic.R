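#' Cophenetic (patristic) distance matrix of a phylogeny
#'
#' Returns the symmetric matrix of tip-to-tip path-length distances —
#' the sum of branch lengths along the unique path between every pair of
#' tips — computed once and consumed by all null models (which permute
#' its labels rather than recompute paths).
#'
#' @param tree a rooted `ape::phylo` tree with branch lengths.
#' @param order optional character vector of tip labels giving the
#'   row/column order of the result (e.g. the taxa order of an aligned
#'   count table).
#' @return labelled symmetric numeric matrix with zero diagonal.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' copheneticMatrix(tr)["A", "C"]  # 4
#' @export
copheneticMatrix <- function(tree, order = NULL) {
  validateTree(tree, rooted = FALSE)
  d <- ape::cophenetic.phylo(tree)
  if (!is.null(order)) {
    if (!setequal(order, rownames(d)))
      stop("requested taxon order does not match the tree's tips")
    d <- d[order, order, drop = FALSE]
  }
  d
}
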