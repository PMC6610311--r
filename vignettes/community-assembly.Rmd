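---
title: "Inferring community assembly processes with phylogenetic null models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring community assembly processes with phylogenetic null models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloAssembly)
```

## The inference problem

Two samples of a microbial community can differ because the environment
selects different taxa (deterministic turnover), or simply because
colonization, drift and dispersal played out differently (stochastic
turnover). `phyloAssembly` separates these using two complementary null
models applied to every pair of samples:

1. **Phylogenetic turnover** (βMNTD, standardized to βNTI) asks whether
   the taxa replacing each other between two samples are closer or more
   distant relatives than expected if taxon identities were random.
2. **Compositional turnover** (Bray-Curtis, ranked into RC~bray~) asks
   whether two samples share more or less abundance than expected if
   each community were reassembled at random from the metacommunity,
   holding its richness and size fixed.

The joint thresholds partition pairs into five processes: βNTI < −2 →
*homogeneous selection*; βNTI > +2 → *variable selection*; otherwise
RC~bray~ > +0.95 → *dispersal limitation*, RC~bray~ < −0.95 →
*homogenizing dispersal*, and |RC~bray~| ≤ 0.95 → *undominated* (drift
plus weak or opposing processes). Per-group fractions of these labels
(e.g. per soil horizon) are the analysis endpoint.

## Models and conventions

### The taxa-labels null

βNTI and SES.MNTD standardize their observed metric against `reps`
(default 999) random joint permutations of the labels of the cached
patristic distance matrix. One permutation per rep is shared by all
samples and pairs, which is what label permutation on a distance matrix
means and keeps values comparable within a rep. Two consequences worth
knowing:

- The diagonal is invariant, so a taxon occurring in both samples of a
  pair contributes zero nearest-taxon distance in the observed *and* in
  every null rep. Signal comes from the taxa that differ between the
  samples.
- A community containing every taxon, a star phylogeny, or an identical
  pair of samples makes the null distribution degenerate (`sd = 0`).
  Such results are flagged `undefined` — carried explicitly end to end,
  excluded from process fractions, and counted in the output — never
  silently dropped. The same flag covers richness < 2, where no nearest
  taxon exists.

Degeneracy is decided by `sd <= 1e-12 * max(1, mean)`; selection of the
label permutations is driven by one integer seed, and every stage of the
pipeline derives its own sub-seed deterministically from the top-level
seed, so identical configuration and seed reproduce all numeric outputs
byte for byte.

### Abundance weighting

The literature is split on weighting. Defaults here: βMNTD/βNTI are
abundance-weighted (the convention of the null-modeling framework the
five-process partition comes from), SES.MNTD is unweighted (the
within-sample convention of the common tooling). Both are flags
(`weighted`), and outputs record the choice. For the unweighted βMNTD we
use the side-averaged form (each community's mean nearest-taxon
distance, then the average of the two), which differs from the pooled
mean some implementations use when richness is unequal; the weighted
form is identical to the common implementation.

### The Raup-Crick null

Each null draw reassembles the two communities of a pair independently:
taxa are drawn without replacement, with probability proportional to
their occupancy across samples, until the observed richness is reached;
one individual seeds each drawn taxon and the remaining individuals are
distributed multinomially in proportion to metacommunity abundance
totals. The observed Bray-Curtis value is located in the null sample as
`p = (#below + ½·#ties) / reps` with ties at a relative tolerance of
1e-12, and `RC = 2(p − ½)`. Null draws conserve each sample's richness
and total abundance exactly. The metacommunity profile defaults to all
samples passed to the run; a per-group scope is available
(`scope = "group"`) since the pooling convention varies between studies.

### Boundary conventions

Exactly ±2 in βNTI is not selection, and exactly ±0.95 in RC~bray~ is
undominated: the published rules are strict inequalities and the package
follows them literally. The five regions tile the (βNTI, RC~bray~) plane
with no gaps or overlaps — a grid sweep including the boundary lines is
part of the test suite.

### Rarefaction

Counts are rarefied without replacement to a fixed depth (the classic
convention, matching mothur's subsampling) in a single seeded draw;
multiple-rarefaction averaging is deliberately not implemented, as the
downstream nulls expect a realized count table. Samples below the target
depth are dropped with a warning rather than padded — padding would
invent observations.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `reps` (βNTI, SES.MNTD, RC~bray~) | 999 | null randomizations per metric |
| `weighted` | TRUE (βNTI), FALSE (SES.MNTD) | abundance weighting |
| `pairs` | `"within"` | compare samples within groups, or `"all"` |
| `depth` | data-dependent | rarefaction depth, individuals/sample |
| RC tie tolerance | 1e-12 (relative) | floating-point equality of null and observed |

999 reps bounds the resolution of βNTI (null mean/sd estimated from 999
values) and of RC~bray~ (percentile steps of 1/999); raising reps
sharpens both at linear cost.

## What the synthetic-data generator emulates

`simulateScenario()` produces the structure of a horizon-stratified 16S
survey: a pure-birth (Yule) tree rescaled to root depth 1 with 128 OTU
tips, 4 groups (named Oi/Oe/OA/A when ≤ 4) of 6 samples, and multinomial
count columns of exactly 1,073 individuals — the bacterial rarefaction
depth typical of such surveys. A single continuous niche trait evolves
by Brownian motion (rate `traitSigma`, trait units per unit branch
length, default 1), so close relatives have similar niches — the
conservation βNTI needs to detect selection at all.

Scenario mechanics and defaults:

- **Selection scenarios**: expected relative abundance ∝
  `exp(−(trait − e)² / (2·filterWidth²))` around an environmental
  optimum `e`; `filterWidth = 0.3` trait units (roughly a third of the
  trait spread — moderate-to-strong filtering). Homogeneous selection
  shares one optimum (the trait median) across all samples; variable
  selection spaces group optima `envSpacing = 4.5·filterWidth` apart
  (well beyond the 4-widths separation at which niches stop
  overlapping). A per-sample log-normal recruitment lottery
  (`lotterySigma = 2`, log scale) multiplies the filter weights: without
  it, replicate samples contain essentially identical dominant OTUs and
  — because shared taxa contribute zero under the taxa-labels null —
  selection would leave no detectable phylogenetic signal. The lottery
  represents stochastic recruitment among similarly fit taxa, so
  replicate communities share clades rather than identical OTUs.
- **Drift / dispersal limitation**: no filtering; a shared log-normal
  metacommunity pool (`poolSigma = 1`), with each sample passing through
  an independent founder bottleneck (`nFounders`: 100 for drift, 50 for
  dispersal limitation) before multinomial amplification to full depth.
- **Homogenizing dispersal**: mass effects — every sample drawn straight
  from the shared pool (`migrationRate = 1`), with `migrationRate`
  interpolating between pool and founder composition in general.
- **Neutral** (the calibration scenario): each sample is assembled by
  the same two-stage draw the Raup-Crick null assumes, from a mild pool
  (`poolSigma = 0.5`), so its pairwise turnover is null-typical by
  construction; it anchors the calibration tests that βNTI and RC~bray~
  are centered when nothing but chance operates.

### What the generator does *not* emulate

Sequencing error, chimeras, compositional (relative-abundance) artifacts,
OTU clustering noise, spatially structured dispersal, multiple
interacting traits, and the scale of real surveys (thousands of OTUs).
Passing tests on these simulations demonstrate the correctness and
calibration of the statistics, not their power on any particular real
dataset.

## Known limitations

- **Power of βNTI at this community scale.** With 128 tips, sample
  richness of a few dozen and abundance weighting, the βNTI null
  standard deviation is large relative to attainable clustering signal:
  even communities confined to a single tight clade — stronger
  clustering than any Gaussian trait filter produces under Brownian
  traits on a Yule tree — rarely push βNTI below −2. In this regime the
  homogeneous-selection scenario is classified mostly as stochastic
  turnover; the within-package recovery tests document this expected
  shortfall rather than masking it. Detection strengthens with tree
  size and richness, which is where the published applications (10³–10⁴
  OTUs) operate, and variable selection — whose between-environment
  signal is much larger — is recovered as the modal process at the
  default scale.
- **RC~bray~ conditions away part of dispersal limitation.** Because the
  null holds observed richness fixed and reuses the empirical
  occupancy/abundance profile, founder-sampling stochasticity is partly
  absorbed into the null itself; dispersal-limitation simulations
  therefore split between `dispersal_limitation` and `undominated`
  rather than being labelled uniformly.
- Zero-length terminal branches are allowed; nearest-taxon logic
  tolerates ties at distance 0.

## Problem sizes used by the test suite

Unit tests run on trees of 3–32 tips with 19–199 randomizations; the
oracle-equivalence property compares against brute-force double loops on
500+ random communities of ≤ 6 taxa over trees of ≤ 8 tips at 1e-12
tolerance. Null-calibration checks use 150–250 communities (and ~10³
sample pairs across replicate datasets) at the full 999 randomizations
on 32-tip trees. Scenario-recovery checks run the complete pipeline at
the generator defaults: 128 taxa, 4 × 6 samples, depth 1,073, 999
randomizations.
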