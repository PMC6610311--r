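#' @import methods
NULL

setOldClass("phylo")

#' CommunitySet: a phylogeny, an OTU count table and sample metadata
#'
#' The central container of the package: a rooted phylogenetic tree with
#' branch lengths, a taxa-by-samples matrix of non-negative integer counts,
#' and a per-sample metadata table carrying at least a grouping variable
#' (e.g. soil horizon). The object is validated so that the taxa of the
#' count table and the tips of the tree are the same set, every sample has
#' exactly one metadata row, and counts are non-negative and finite.
#'
#' Use [CommunitySet()] to construct one (optionally pruning tree and table
#' to their common taxa), and the accessors [communityTree()],
#' [communityCounts()], [sampleData()], [taxonNames()], [sampleNames()].
#'
#' @slot tree a rooted `ape::phylo` tree with branch lengths; tip labels
#'   match the rownames of `counts` as a set.
#' @slot counts numeric matrix, taxa in rows, samples in columns,
#'   non-negative integer-valued entries.
#' @slot metadata `data.frame` with one row per sample; rownames are the
#'   sample names; must contain the grouping column named by `groupField`.
#' @slot groupField name of the metadata column holding the sample group.
#'
#' @name CommunitySet-class
#' @rdname CommunitySet-class
#' @exportClass CommunitySet
setClass("CommunitySet",
  representation(
    tree = "phylo",
    counts = "matrix",
    metadata = "data.frame",
    groupField = "character"
  )
)

setValidity("CommunitySet", function(object) {
  msg <- character()
  counts <- object@counts
  tree <- object@tree
  md <- object@metadata
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    msg <- c(msg, "counts must have taxon rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    msg <- c(msg, "duplicated taxon names in counts")
  if (anyDuplicated(colnames(counts)))
    msg <- c(msg, "duplicated sample names in counts")
  if (any(!is.finite(counts)) || any(counts < 0))
    msg <- c(msg, "counts must be finite and non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    msg <- c(msg, "counts must be integer-valued")
  if (!inherits(tree, "phylo")) {
    msg <- c(msg, "tree must be a 'phylo' object")
  } else {
    if (is.null(tree$edge.length))
      msg <- c(msg, "tree must have branch lengths")
    else if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
      msg <- c(msg, "branch lengths must be finite and >= 0")
    if (anyDuplicated(tree$tip.label))
      msg <- c(msg, "duplicated tip labels in tree")
    if (length(tree$tip.label) < 2)
      msg <- c(msg, "tree must have at least 2 tips")
    if (!is.null(rownames(counts)) &&
        !setequal(tree$tip.label, rownames(counts)))
      msg <- c(msg, "tree tip labels and count table taxa differ; align first")
  }
  if (!is.null(colnames(counts))) {
    if (!all(colnames(counts) %in% rownames(md)))
      msg <- c(msg, "every sample must have a metadata row")
  }
  if (length(object@groupField) != 1L || !object@groupField %in% colnames(md))
    msg <- c(msg, sprintf(
      "metadata must contain the group column '%s'",
      paste(object@groupField, collapse = ",")))
  if (length(msg)) msg else TRUE
})

#' TurnoverResult: pairwise turnover metrics and process labels
#'
#' Holds, for a set of unordered sample pairs, the observed phylogenetic
#' turnover (betaMNTD), its standardized effect size against the
#' taxa-labels null (betaNTI), the observed Bray-Curtis dissimilarity, the
#' Raup-Crick metric (RC-bray), and the inferred assembly process label.
#'
#' @slot pairs `data.frame` with columns `sample_a`, `sample_b`, `group_a`,
#'   `group_b`, `beta_mntd`, `beta_nti`, `bray_curtis`, `rc_bray`,
#'   `process_label`.
#' @slot repsBnti integer, randomizations used for betaNTI.
#' @slot repsRc integer, randomizations used for RC-bray.
#' @slot weighted logical, abundance weighting used for betaMNTD/betaNTI.
#' @slot pairScope `"within"` or `"all"` pair selection.
#'
#' @name TurnoverResult-class
#' @rdname TurnoverResult-class
#' @exportClass TurnoverResult
setClass("TurnoverResult",
  representation(
    pairs = "data.frame",
    repsBnti = "integer",
    repsRc = "integer",
    weighted = "logical",
    pairScope = "character"
  )
)

setValidity("TurnoverResult", function(object) {
  need <- c("sample_a", "sample_b", "group_a", "group_b", "beta_mntd",
            "beta_nti", "bray_curtis", "rc_bray", "process_label")
  missing <- setdiff(need, colnames(object@pairs))
  if (length(missing))
    return(sprintf("pairs is missing columns: %s",
                   paste(missing, collapse = ", ")))
  rc <- object@pairs$rc_bray
  if (any(is.finite(rc) & (rc < -1 - 1e-12 | rc > 1 + 1e-12)))
    return("rc_bray outside [-1, +1]")
  bc <- object@pairs$bray_curtis
  if (any(is.finite(bc) & (bc < -1e-12 | bc > 1 + 1e-12)))
    return("bray_curtis outside [0, 1]")
  ok <- object@pairs$process_label %in% c(assemblyProcesses(), "undefined")
  if (!all(ok)) return("unknown process_label value")
  TRUE
})

#' ProcessSummary: per-group fractions of assembly processes
#'
#' Per sample group, the fraction of defined within-group pairs assigned to
#' each of the five assembly processes, plus counts of defined and
#' undefined pairs. Fractions are over defined pairs and sum to 1 per group
#' (when the group has any defined pair).
#'
#' @slot fractions `data.frame` with columns `group`, `process`, `fraction`.
#' @slot counts `data.frame` with columns `group`, `n_pairs`, `n_undefined`.
#'
#' @name ProcessSummary-class
#' @rdname ProcessSummary-class
#' @exportClass ProcessSummary
setClass("ProcessSummary",
  representation(
    fractions = "data.frame",
    counts = "data.frame"
  )
)

setValidity("ProcessSummary", function(object) {
  fr <- object@fractions
  if (!all(c("group", "process", "fraction") %in% colnames(fr)))
    return("fractions must have columns group, process, fraction")
  if (any(is.finite(fr$fraction) &
          (fr$fraction < -1e-12 | fr$fraction > 1 + 1e-12)))
    return("fractions outside [0, 1]")
  for (g in unique(fr$group)) {
    s <- sum(fr$fraction[fr$group == g])
    np <- object@counts$n_pairs[match(g, object@counts$group)]
    if (!is.na(np) && np > 0 && abs(s - 1) > 1e-12)
      return(sprintf("fractions for group '%s' do not sum to 1", g))
  }
  TRUE
})
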