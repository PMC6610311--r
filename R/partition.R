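#' The five community assembly processes
#'
#' @return character vector of the five process labels, in display order.
#' @export
assemblyProcesses <- function() {
  c("homogeneous_selection", "variable_selection", "homogenizing_dispersal",
    "dispersal_limitation", "undominated")
}

#' Classify a sample pair's turnover into an assembly process
#'
#' Applies the standard joint thresholds on the beta nearest taxon index
#' and the Raup-Crick metric, vectorized over pairs:
#' \itemize{
#'   \item `betaNTI < -2`: homogeneous selection
#'   \item `betaNTI > +2`: variable selection
#'   \item `|betaNTI| <= 2` and `rc > +0.95`: dispersal limitation
#'   \item `|betaNTI| <= 2` and `rc < -0.95`: homogenizing dispersal
#'   \item `|betaNTI| <= 2` and `|rc| <= 0.95`: undominated
#' }
#' Selection uses strict inequalities, so values exactly at the ±2 or
#' ±0.95 boundaries fall to the non-selection / undominated branch. A
#' non-finite `betaNTI` — or a non-finite `rc` when it is needed — yields
#' the label `"undefined"`.
#'
#' @param betaNti numeric vector of betaNTI values.
#' @param rcBray numeric vector of RC-bray values (recycled if length 1).
#' @return character vector of process labels (one of
#'   [assemblyProcesses()] or `"undefined"`).
#' @examples
#' classifyPair(c(-3.5, 0.5, 0.5, 0.5, 2.0), c(0.2, 0.97, -0.97, 0.2, 0.99))
#' @export
classifyPair <- function(betaNti, rcBray) {
  n <- max(length(betaNti), length(rcBray))
  betaNti <- rep_len(betaNti, n)
  rcBray <- rep_len(rcBray, n)
  lab <- rep("undefined", n)
  okB <- is.finite(betaNti)
  lab[okB & betaNti < -2] <- "homogeneous_selection"
  lab[okB & betaNti > 2] <- "variable_selection"
  mid <- okB & abs(betaNti) <= 2
  okR <- is.finite(rcBray)
  lab[mid & okR & rcBray > 0.95] <- "dispersal_limitation"
  lab[mid & okR & rcBray < -0.95] <- "homogenizing_dispersal"
  lab[mid & okR & abs(rcBray) <= 0.95] <- "undominated"
  lab
}

#' Summarize assembly-process fractions per sample group
#'
#' Counts, per group, the within-group pairs carrying each process label
#' and converts them to fractions over the defined pairs (undefined pairs
#' are counted separately and excluded from the denominator). Groups with
#' fewer than two samples are omitted with a warning.
#'
#' @param results a [TurnoverResult-class] or a data.frame with columns
#'   `group_a`, `group_b`, `process_label`.
#' @param metadata optional sample metadata (`data.frame`, rownames =
#'   sample IDs) used to detect groups with fewer than two samples; by
#'   default groups are taken from the results.
#' @param groupField metadata column holding the group (default
#'   `"group"`).
#' @return a [ProcessSummary-class].
#' @export
partitionFractions <- function(results, metadata = NULL,
                               groupField = "group") {
  df <- if (is(results, "TurnoverResult")) turnoverPairs(results) else results
  if (!all(c("group_a", "group_b", "process_label") %in% colnames(df)))
    stop("results must carry group_a, group_b and process_label")
  within <- df[df$group_a == df$group_b, , drop = FALSE]
  groups <- unique(within$group_a)
  if (!is.null(metadata)) {
    sizes <- table(metadata[[groupField]])
    small <- names(sizes)[sizes < 2L]
    if (length(small))
      warning(sprintf("omitting group(s) with < 2 samples: %s",
                      paste(small, collapse = ", ")))
    groups <- union(groups, setdiff(names(sizes), small))
    groups <- setdiff(groups, small)
  }
  procs <- assemblyProcesses()
  frList <- list()
  cntList <- list()
  for (g in groups) {
    lab <- within$process_label[within$group_a == g]
    defined <- lab[lab != "undefined"]
    counts <- table(factor(defined, levels = procs))
    nDef <- length(defined)
    frac <- if (nDef > 0) as.numeric(counts) / nDef else
      rep(NA_real_, length(procs))
    frList[[g]] <- data.frame(group = g, process = procs, fraction = frac,
                              stringsAsFactors = FALSE)
    cntList[[g]] <- data.frame(group = g, n_pairs = nDef,
                               n_undefined = sum(lab == "undefined"),
                               stringsAsFactors = FALSE)
  }
  new("ProcessSummary",
      fractions = do.call(rbind, c(frList, list(make.row.names = FALSE))),
      counts = do.call(rbind, c(cntList, list(make.row.names = FALSE))))
}
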