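# Internal helpers shared across modules.

# Row-wise minima of a numeric matrix without apply() overhead.
.rowMins <- function(m) {
  out <- m[, 1L]
  nc <- ncol(m)
  if (nc > 1L) for (j in 2L:nc) out <- pmin(out, m[, j])
  out
}

.colMins <- function(m) .rowMins(t(m))

# Relative tolerance used for floating-point tie/zero decisions.
.relTol <- function(x, tol = 1e-12) tol * max(1, abs(x))

# Column indices of taxa present in each sample.
.presenceIndex <- function(counts) {
  lapply(seq_len(ncol(counts)), function(s) which(counts[, s] > 0))
}

# Per-sample weight vectors over present taxa: relative abundance if
# weighted, else 1/richness.
.sampleWeights <- function(counts, idx, weighted) {
  lapply(seq_along(idx), function(s) {
    i <- idx[[s]]
    if (length(i) == 0L) return(numeric(0))
    if (weighted) counts[i, s] / sum(counts[i, s]) else
      rep(1 / length(i), length(i))
  })
}

# Unordered sample pairs as a 2-column index matrix. mode "within" keeps
# only pairs sharing a group label; "all" keeps every pair.
.selectPairs <- function(sampleNames, groups = NULL,
                         mode = c("within", "all")) {
  mode <- match.arg(mode)
  n <- length(sampleNames)
  if (n < 2L) stop("need at least 2 samples to form pairs")
  pairs <- t(utils::combn(n, 2L))
  if (mode == "within") {
    if (is.null(groups))
      stop("pair mode 'within' requires sample group labels")
    keep <- groups[pairs[, 1L]] == groups[pairs[, 2L]]
    pairs <- pairs[keep, , drop = FALSE]
  }
  if (nrow(pairs) == 0L)
    stop("pair selection produced no sample pairs")
  pairs
}

# Deterministic derivation of per-stage seeds from one top-level seed.
# Stages are numbered so that reruns and stage-wise runs agree; kept
# below 2^31 for R's 32-bit integers.
.stageSeed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offsets <- c(rarefy = 11L, sesmntd = 23L, bnti = 37L, rcbray = 53L,
               tree = 67L, trait = 79L, community = 97L)
  if (!stage %in% names(offsets)) stop("unknown seed stage: ", stage)
  as.integer((as.numeric(seed) * 1000L + offsets[[stage]]) %% .Machine$integer.max)
}

# Timestamped message to stderr; optionally appended to a log file.
.log <- function(..., logfile = NULL) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  paste0(...))
  message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
  invisible(line)
}
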