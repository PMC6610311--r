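#' Scenario configuration for the synthetic-data generator
#'
#' Bundles and validates the parameters of a simulated community-assembly
#' scenario. Defaults mirror the structure of a horizon-stratified 16S
#' survey: 128 OTUs, 4 groups (named after soil horizons when 4 or fewer)
#' of 6 samples each, and 1,073 individuals per sample.
#'
#' @param scenario one of `"homogeneous_selection"`,
#'   `"variable_selection"`, `"drift"`, `"homogenizing_dispersal"`,
#'   `"dispersal_limitation"`, `"neutral"`.
#' @param nTaxa number of OTU tips (>= 2).
#' @param nSamplesPerGroup samples per group (>= 1).
#' @param nGroups number of sample groups (>= 1).
#' @param depth individuals per sample (>= 1).
#' @param filterWidth Gaussian niche-filter width, in trait units
#'   (`> 0`); smaller = stronger selection.
#' @param traitSigma Brownian-motion rate, trait units per unit branch
#'   length (`> 0`).
#' @param migrationRate mixing fraction `m` in `[0, 1]` between the shared
#'   metacommunity pool and each sample's idiosyncratic founder draw;
#'   scenario defaults: 1 for homogenizing dispersal, 0 for drift and
#'   dispersal limitation.
#' @param nFounders founder individuals per sample in the drift-type
#'   scenarios; scenario defaults: 100 for drift, 20 for dispersal
#'   limitation.
#' @param envSpacing spacing between group environment optima under
#'   variable selection, in trait units; default `4.5 * filterWidth`
#'   (well-separated niches, at least 4 filter widths apart).
#' @param lotterySigma standard deviation (log scale) of the per-sample
#'   neutral lottery multiplying the selection scenarios' filter weights.
#'   It represents stochastic recruitment among similarly fit taxa, so
#'   replicate communities share clades rather than identical OTUs; 0
#'   disables it.
#' @param poolSigma standard deviation (log scale) of the shared
#'   metacommunity pool's log-normal relative abundances.
#' @param seed integer seed driving all randomness of the scenario.
#' @return a validated `list` of class `"ScenarioConfig"`.
#' @export
scenarioConfig <- function(scenario = c("homogeneous_selection",
                                        "variable_selection", "drift",
                                        "homogenizing_dispersal",
                                        "dispersal_limitation", "neutral"),
                           nTaxa = 128L, nSamplesPerGroup = 6L,
                           nGroups = 4L, depth = 1073L, filterWidth = 0.3,
                           traitSigma = 1, migrationRate = NULL,
                           nFounders = NULL, envSpacing = NULL,
                           lotterySigma = 2, poolSigma = NULL, seed = 1L) {
  scenario <- match.arg(scenario)
  if (is.null(migrationRate))
    migrationRate <- switch(scenario, homogenizing_dispersal = 1,
                            drift = 0, dispersal_limitation = 0, 0)
  if (is.null(nFounders))
    nFounders <- switch(scenario, dispersal_limitation = 50L, 100L)
  if (is.null(envSpacing)) envSpacing <- 4.5 * filterWidth
  # the neutral calibration scenario uses a mild pool so that the
  # empirical occupancy/abundance profile mirrors its generating weights
  if (is.null(poolSigma)) poolSigma <- if (scenario == "neutral") 0.5 else 1
  cfg <- list(scenario = scenario, nTaxa = as.integer(nTaxa),
              nSamplesPerGroup = as.integer(nSamplesPerGroup),
              nGroups = as.integer(nGroups), depth = as.integer(depth),
              filterWidth = filterWidth, traitSigma = traitSigma,
              migrationRate = migrationRate,
              nFounders = as.integer(nFounders), envSpacing = envSpacing,
              lotterySigma = lotterySigma, poolSigma = poolSigma,
              seed = as.integer(seed))
  bad <- character()
  if (cfg$nTaxa < 2L) bad <- c(bad, "nTaxa must be >= 2")
  for (f in c("nSamplesPerGroup", "nGroups", "depth"))
    if (cfg[[f]] < 1L) bad <- c(bad, sprintf("%s must be >= 1", f))
  if (!is.finite(cfg$filterWidth) || cfg$filterWidth <= 0)
    bad <- c(bad, "filterWidth must be > 0")
  if (!is.finite(cfg$traitSigma) || cfg$traitSigma < 0)
    bad <- c(bad, "traitSigma must be >= 0")
  if (cfg$migrationRate < 0 || cfg$migrationRate > 1)
    bad <- c(bad, "migrationRate must be in [0, 1]")
  if (cfg$nFounders < 1L) bad <- c(bad, "nFounders must be >= 1")
  if (!is.finite(cfg$lotterySigma) || cfg$lotterySigma < 0)
    bad <- c(bad, "lotterySigma must be >= 0")
  if (!is.finite(cfg$poolSigma) || cfg$poolSigma < 0)
    bad <- c(bad, "poolSigma must be >= 0")
  if (length(bad)) stop(paste(bad, collapse = "; "))
  class(cfg) <- "ScenarioConfig"
  cfg
}

#' Simulate an ultrametric pure-birth (Yule) tree
#'
#' Stand-in for an inferred OTU phylogeny: a Yule tree with `nTaxa` tips,
#' rescaled so every tip sits at depth 1 from the root.
#'
#' @param nTaxa number of tips (>= 2).
#' @param seed integer seed.
#' @return an `ape::phylo` tree, ultrametric with root depth 1.
#' @export
simulateTree <- function(nTaxa, seed = NULL) {
  if (nTaxa < 2L) stop("nTaxa must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(nTaxa, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("OTU%03d", seq_len(nTaxa))
  tree
}

#' Evolve a phylogenetically conserved trait by Brownian motion
#'
#' Simulates one continuous trait from a root value of 0 along the tree's
#' branches (via [phytools::fastBM()]), so tip variance accumulates as
#' `sigma^2 * root-to-tip path length` and close relatives stay similar —
#' the conservation that makes niche-based selection detectable by
#' nearest-taxon metrics.
#'
#' @param tree an `ape::phylo` tree.
#' @param sigma Brownian rate (trait units per unit branch length);
#'   `sigma = 0` is accepted as the degenerate all-zero trait.
#' @param seed integer seed.
#' @return named numeric vector of tip trait values.
#' @export
evolveTrait <- function(tree, sigma, seed = NULL) {
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0)
    return(stats::setNames(numeric(length(tree$tip.label)), tree$tip.label))
  if (!is.null(seed)) set.seed(seed)
  phytools::fastBM(tree, a = 0, sig2 = sigma^2)
}

#' Simulate community tables under a known assembly process
#'
#' Builds a taxa-by-samples count table plus sample metadata under the
#' process named in `config`:
#' \describe{
#'   \item{homogeneous_selection}{every sample filtered toward one shared
#'     environment optimum `e` (the trait median): expected relative
#'     abundance of taxon `i` is proportional to
#'     `exp(-(trait_i - e)^2 / (2 filterWidth^2))`, multiplied by an
#'     independent per-sample log-normal recruitment lottery
#'     (`lotterySigma`) so that replicate communities share the selected
#'     clades rather than identical OTUs.}
#'   \item{variable_selection}{as above, but each group receives its own
#'     optimum, spaced `envSpacing` apart (well separated relative to the
#'     filter width), so turnover between groups is deterministic.}
#'   \item{drift / dispersal_limitation}{no filtering: a shared log-normal
#'     metacommunity pool, but each sample passes through an independent
#'     founder bottleneck of `nFounders` individuals (smaller for
#'     dispersal limitation), so compositions diverge stochastically.}
#'   \item{homogenizing_dispersal}{mass effects: every sample drawn
#'     straight from the shared pool (`migrationRate = 1`), so samples are
#'     more similar than a random assembly null expects.}
#'   \item{neutral}{each sample assembled by the same two-stage process
#'     the Raup-Crick null assumes (taxa drawn by pool weight, individuals
#'     filled by pool weight), giving turnover typical of the null.}
#' }
#' Counts are multinomial with total `depth` per sample; all randomness
#' flows from `config$seed`.
#'
#' @param config a [scenarioConfig()].
#' @param tree tree from [simulateTree()] (or compatible) whose tips name
#'   the taxa.
#' @param traits named trait vector covering all tips (from
#'   [evolveTrait()]); used by the selection scenarios.
#' @return `list(counts = matrix, metadata = data.frame)`.
#' @export
simulateCommunities <- function(config, tree, traits) {
  stopifnot(inherits(config, "ScenarioConfig"))
  taxa <- tree$tip.label
  if (!all(taxa %in% names(traits)))
    stop("traits must cover every tip of the tree")
  traits <- traits[taxa]
  n <- length(taxa)
  G <- config$nGroups
  k <- config$nSamplesPerGroup
  depth <- config$depth
  groupNames <- if (G <= 4L) c("Oi", "Oe", "OA", "A")[seq_len(G)] else
    sprintf("G%d", seq_len(G))
  set.seed(.stageSeed(config$seed, "community"))
  # shared metacommunity pool (log-normal relative abundances)
  pool <- exp(stats::rnorm(n, 0, config$poolSigma))
  pool <- pool / sum(pool)
  counts <- matrix(0, n, G * k,
                   dimnames = list(taxa, paste0(
                     rep(groupNames, each = k), "_",
                     sprintf("%02d", rep(seq_len(k), G)))))
  groups <- rep(groupNames, each = k)
  envs <- .scenarioEnvironments(config, traits, groupNames)
  for (s in seq_len(ncol(counts))) {
    g <- match(groups[s], groupNames)
    p <- switch(
      config$scenario,
      homogeneous_selection = ,
      variable_selection = {
        w <- .filterWeights(traits, envs[g], config$filterWidth)
        lottery <- exp(stats::rnorm(n, 0, config$lotterySigma))
        w <- w * lottery
        w / sum(w)
      },
      homogenizing_dispersal = ,
      drift = ,
      dispersal_limitation = {
        founder <- stats::rmultinom(1L, config$nFounders, prob = pool)[, 1L]
        f <- founder / sum(founder)
        config$migrationRate * pool + (1 - config$migrationRate) * f
      },
      neutral = NULL)
    if (config$scenario == "neutral") {
      richness <- max(2L, min(n, as.integer(round(n / 2))))
      ids <- sample.int(n, richness, prob = pool)
      x <- numeric(n)
      x[ids] <- 1
      if (depth > richness)
        x[ids] <- x[ids] +
          stats::rmultinom(1L, depth - richness, prob = pool[ids])[, 1L]
      counts[, s] <- x
    } else {
      counts[, s] <- stats::rmultinom(1L, depth, prob = p)[, 1L]
    }
  }
  metadata <- data.frame(sample_id = colnames(counts), group = groups,
                         row.names = colnames(counts),
                         stringsAsFactors = FALSE)
  list(counts = counts, metadata = metadata)
}

.filterWeights <- function(traits, e, width) {
  w <- exp(-(traits - e)^2 / (2 * width^2))
  if (sum(w) <= 0) {
    # environment far beyond every taxon: fall back to the nearest taxon
    w <- as.numeric(abs(traits - e) == min(abs(traits - e)))
  }
  w / sum(w)
}

.scenarioEnvironments <- function(config, traits, groupNames) {
  G <- length(groupNames)
  center <- stats::median(traits)
  if (config$scenario == "variable_selection") {
    offsets <- (seq_len(G) - (G + 1) / 2) * config$envSpacing
    center + offsets
  } else {
    rep(center, G)
  }
}

#' Simulate a full scenario as a CommunitySet
#'
#' Convenience wrapper: tree, Brownian trait and community tables in one
#' call, seeded from `config$seed` (tree, trait and community stages use
#' seeds derived deterministically from it).
#'
#' @param config a [scenarioConfig()].
#' @return a [CommunitySet-class]; the generating configuration and trait
#'   vector are attached as attributes `"scenario"` and `"traits"`.
#' @examples
#' cs <- simulateScenario(scenarioConfig("neutral", nTaxa = 16,
#'                                       nSamplesPerGroup = 2, nGroups = 2,
#'                                       depth = 50, seed = 7))
#' cs
#' @export
simulateScenario <- function(config) {
  stopifnot(inherits(config, "ScenarioConfig"))
  tree <- simulateTree(config$nTaxa, seed = .stageSeed(config$seed, "tree"))
  traits <- evolveTrait(tree, config$traitSigma,
                        seed = .stageSeed(config$seed, "trait"))
  sim <- simulateCommunities(config, tree, traits)
  cs <- CommunitySet(tree, sim$counts, sim$metadata, groupField = "group")
  attr(cs, "scenario") <- config
  attr(cs, "traits") <- traits
  cs
}

#' Write a simulated scenario to disk
#'
#' Emits `tree.nwk`, `table.tsv`, `metadata.tsv` and `truth.json` (the
#' generating scenario and parameters) into `dir`.
#'
#' @param config a [scenarioConfig()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeScenario <- function(config, dir) {
  cs <- simulateScenario(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeTree(communityTree(cs), file.path(dir, "tree.nwk"))
  writeCommunityTable(communityCounts(cs), file.path(dir, "table.tsv"))
  utils::write.table(sampleData(cs), file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(attr(cs, "scenario")),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
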