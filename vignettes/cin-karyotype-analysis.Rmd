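---
title: "Modeling and measuring chromosomal instability in single-cell karyotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and measuring chromosomal instability in single-cell karyotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cinscape)
```

## The problem

Chromosomal instability (CIN) — the ongoing gain and loss of whole
chromosomes and chromosome segments across cell divisions — turns a clonal
cell population into a mosaic of related karyotypes. Shallow single-cell
whole-genome sequencing (scWGS) measures this mosaic directly: reads from
each cell are binned along the genome, converted to integer copy-number
states, and the population is summarized by per-sample scores, a consensus
karyotype, and a census of cells deviating from it. Multiplex interphase
FISH (miFISH) provides an orthogonal, probe-level view of the same clonal
structure, and DNA-content flow profiles reveal ploidy shifts such as
whole-genome doubling (WGD).

`cinscape` implements this analysis stack end to end, together with a
generative simulator that produces populations with the statistical
structure such experiments exhibit — so every analysis component can be
validated against a known ground truth.

## Coordinate system

All profiles live on a `genome_layout`: ordered chromosomes partitioned
into fixed-width bins (0-based, half-open, BED convention). The bundled
default is the hg38 primary assembly, chromosomes 1–22 plus X at 1-Mb bins
(3044 bins, 3031 Mb); chromosome Y is omitted because the bundled founder
models a female-derived fallopian-tube epithelial line. Published scWGS
analyses of this kind do not agree on a single bin size, so `bin_size` is a
parameter; 1 Mb is a common, conservative default at shallow depth.

## The branching-process simulator

`simulate_population()` grows a population from a single founder cell.
Every generation each cell divides, and three event classes can occur:

* **Whole-chromosome mis-segregation** (probability `p_mis` per chromosome
  per division): one daughter gains one copy of the chromosome, the sister
  loses one. Events are reciprocal, so the per-bin sum of the daughters is
  always exactly twice the parent — a conservation law the test-suite
  checks over thousands of random divisions.
* **Segmental aneuploidy** (`p_seg` per division): a distal segment from a
  uniformly chosen bin boundary of a uniformly chosen chromosome is
  exchanged reciprocally between the daughters. Only the copy-number
  consequence of a rearrangement is modeled; breakpoint sequences and
  fusion structure are out of scope.
* **Whole-genome doubling** (`p_wgd` per division): the division is
  replaced by a cytokinesis failure leaving a single daughter with every
  bin doubled. The mechanism of WGD in vivo is not resolved by the data
  this package emulates; cytokinesis failure was chosen because it
  conserves copy number and needs no extra parameters.

Viability filtering removes cells with zero copies of any bin (nullisomy
is lethal; monosomy, including monosomy X, is viable) and cells exceeding
the copy cap (`max_copy`, default 8 — deeper states are neither observed
in the emulated assays nor reliably countable by FISH). The population is
then down-sampled uniformly to `carrying_capacity`, Wright–Fisher style,
which bounds memory while preserving lineage structure statistically:
sampled cells share ancestry, so subclonal events are shared in families,
as in real populations.

A WGD subclone can also be *induced* at a configured generation
(`wgd_generation`, `wgd_fraction`). A single spontaneous WGD cell would
usually drift to extinction under neutral down-sampling, so mixed
diploid/tetraploid populations are produced deterministically by doubling
a fixed fraction of cells mid-history.

### Bundled presets

Four presets describe the generative scenarios used throughout the
examples and tests. All share a near-diploid founder with clonal
monosomies of 9p, chromosome 15 and X.

| preset | clonal aberrations on top of the founder | rates | history |
|---|---|---|---|
| `fne1` | none | all 0 | 10 generations |
| `p1`   | +3, +5, −18, +20 | `p_mis` 8e-4, `p_seg` 4e-4 | 16 generations |
| `pb2`  | segmental −1q, −2q, −6q, +6p, −12p, −13q | `p_mis` 1.2e-3, `p_seg` 8e-4 | 18 generations, 40% WGD at generation 8 |
| `pb3`  | −1q, −4, −16, then WGD | `p_mis` 1.2e-3, `p_seg` 8e-4 | WGD at generation 1, 14 generations |

Two design decisions here were genuinely open and deserve comment:

* **Private clonal markers.** Each derived preset seeds its lineage with a
  small set of clonal aberrations absent from the others. This models the
  single-cell cloning bottleneck by which sublines are established —
  whatever aneuploidies the founding cell carries become clonal in the
  subline. It also makes "recover the lineages by clustering" a
  well-posed task: the between-lineage marker distances (0.17–0.19 in
  mean per-bin units) were chosen to clearly exceed the within-lineage
  spread produced by drift at the preset rates, including its occasional
  multi-chromosome outliers. Without such markers, two near-diploid
  lineages differing only in subclonal drift are not separable by any
  clustering method.
* **Event rates.** Per-division rates of this kind are not directly
  measurable from end-point data, so the presets use rates at which
  roughly a quarter to a half of sampled cells deviate from their
  consensus after the simulated history — the "low-level CIN" regime the
  emulated experiments describe — ordered `fne1 < p1 < pb2/pb3`. They are
  scenario definitions, not fitted estimates.

### Sequencing, FISH and DNA-content emulation

`simulate_read_counts()` draws negative-binomial counts with mean
`d · CN[b] · gc[b]` (default depth `d` = 50 reads/copy/bin, NB size 100,
i.e. ~40% extra-Poisson variance at a disomic bin). GC-like multiplicative
bias factors are taken as *known* — the package deliberately contains no
GC estimation from sequence, since no FASTA handling is in scope.
`simulate_mifish()` reports the copy-number state at each probe's bin,
perturbed by ±1 with a configurable error rate. `simulate_dna_content()`
maps mean copy number to relative DNA content (1.0 ≡ 2c), doubles a
configurable G2 fraction, and applies multiplicative Gaussian noise —
enough structure to produce the 2c/4c/8c peak patterns that distinguish
cycling diploids from cycling tetraploids, with no claim to model full
cell-cycle kinetics.

What the generator does *not* emulate matters for interpreting green
tests: real scWGS carries mappability and replication-timing artifacts,
GC bias is estimated rather than known, segmental breakpoints recur at
fragile sites rather than uniformly, and selection acts on specific gene
dosages. Passing tests demonstrate the analysis stack is correct under
the stated generative model, not that it is robust to every artifact of
real libraries.

## Copy-number calling

`call_cells()` runs four explicit stages per cell:

1. **Normalization** — counts are divided by the known bias factors and
   scaled to genome-wide median 1.
2. **Segmentation** — recursive binary splitting within each chromosome:
   the boundary maximizing the reduction in within-segment sum of squares
   is accepted when the reduction exceeds `gain_threshold` (default 0.1)
   times the chromosome's total sum of squares and both sides keep at
   least `min_seg` (default 3) bins. The procedure is deterministic (ties
   to the lowest breakpoint) and was preferred to an HMM because every
   accepted split is an auditable, testable decision.
3. **Ploidy-scale fitting** — a grid search for the scale `s` minimizing
   the length-weighted distance of scaled segment medians from integers,
   constrained so the scaled overall median rounds to a candidate base
   ploidy; ties resolve toward the lower ploidy. A perfectly flat genome
   is genuinely scale-degenerate (it fits base 1 as well as base 2); the
   experimental resolution is the flow-sort gate, honored via
   `ploidy_gate`: cells sorted at 2c constrain candidates to {1,2,3},
   at 4c to {3,4,5}. All bundled founders carry monosomies, which break
   the degeneracy in practice.
4. **State calling** — `round(s · segment median)` (half-up, for
   determinism across platforms), clipped to `[0, max_copy]`.

At default depth the caller recovers simulated karyotypes with median
per-cell bin accuracy ≥99%; residual errors are almost entirely
single-bin boundary shifts at true breakpoints and rare `min_seg`-sized
spurious segments at chromosome ends. The defaults are this package's
choices and are not claimed to replicate any published caller's settings.

## Karyotype scores

For a population of `N` cells over `B` bins with total binned length `G`
Mb:

* **Structural score** `S = (Σ within-chromosome adjacent-bin state
  transitions) / (G · N)` — transitions per Mb per cell. Whole-chromosome
  aneuploidies contribute nothing; `S` isolates segmental rearrangement
  burden. Division is by the whole binned genome length, giving a single
  sample-level scalar.
* **Aneuploidy score** `A = mean |CN − ψ|` with reference ploidy `ψ`
  (default 2). A flat WGD population scores 2.0, so tetraploid samples
  separate on this axis while contributing nothing structural.
* **Heterogeneity score** `H = mean_b (1 − m_b/N)`, `m_b` the modal-state
  count at bin `b` — the mean fraction of cells deviating from the bin
  mode.

The consensus karyotype takes each bin's modal state, breaking ties
toward the state closest to the population's overall modal ploidy and
then toward the lower state. The deviation census flags cells differing
from the consensus over at least `min_run` consecutive bins of one
chromosome; `min_run` defaults to 1, which on called (noisy) profiles
counts isolated miscalled bins as deviations — raise it to 2–3 when
censusing called rather than simulated profiles if single-bin noise is a
concern. All three scores are verified against naive double-loop
reference implementations to 1e-12.

## Population structure and WGD detection

Cells are compared by mean absolute per-bin state difference
(Manhattan/`B`), clustered agglomeratively with average linkage
(`stats::hclust`), and cut to `k` groups. Distance and linkage are
configurable; the defaults are robust to single-bin noise and put ploidy
first: a diploid cell and its doubled counterpart are 2.0 apart while
drift-scale differences are a few hundredths, so trees split by ploidy
before genotype.

WGD ancestry between two subpopulations is tested by the
consensus-doubling relation: `consensus_high == 2 · consensus_low` at a
fraction `q` (default 0.9) of bins. Losses fixed before the doubling
appear as monosomies in the diploid consensus and disomies in the
tetraploid one and therefore *satisfy* the relation; post-WGD drift
erodes it only where events reach consensus, which is why `q` sits below
1.

DNA-content distributions are classified against fixed peak positions
1.0/2.0/4.0 (2c/4c/8c) with a relative tolerance of 0.15 and a 5%
minimum peak mass — deliberately simple mode detection rather than
mixture fitting, matching the discrete way such profiles are read. A
population showing both 4c and 8c peaks is flagged as a cycling
tetraploid; 2c + 4c alone is a normally cycling diploid.

## miFISH analysis

The bundled panel holds one centromere probe (CCP10) and 19 gene probes
in four hybridization groups of five, anchored at representative hg38
coordinates (the anchors place probes in bins; they are not analytic
inputs). Per cell, the modal signal count classifies ploidy (2 → 2c,
4 → 4c, otherwise "other"). Cells deviating from the sample's modal
pattern at 1–2 loci (`noise_max`, default 2) are flagged as within the
assay's technical error and contribute the modal pattern to clonality
statistics — so sporadic counting errors neither create spurious
subclones nor break clonal calls. Per probe and direction, an aberration
present in ≥95% of cells (`clonal_fraction`; kept below 1 for the same
reason) is clonal, in ≥2 cells subclonal, and singletons are not
reported. Clones are enumerated as distinct full signal-count vectors,
sorted by frequency then lexicographically.

## Numerical and degenerate-input conventions

* Rounding of scaled states is half-up (`floor(x + 0.5)`), not banker's.
* Modal quantities break ties toward the lower state everywhere; the
  consensus additionally prefers states near the overall modal ploidy.
* `heterogeneity_score` of a single cell is 0; empty populations,
  all-zero counts, off-layout probes and regions, nullisomic
  mis-segregation and extinct populations raise named errors.
* One global seed drives each pipeline stage through fixed substreams;
  identical configurations reproduce bit-identical output files.

## Problem sizes used in validation

The shipped tests and the acceptance script simulate 50–100 cells per
preset on the full hg38 1-Mb layout for end-to-end claims (calling
accuracy, cluster recovery, WGD detection), and use a 3-chromosome,
30-bin toy layout for hand-checkable oracles, conservation laws and
rate-monotonicity (20 replicates per rate). These sizes give stable
statistics for every threshold tested while keeping a full run in the
order of a minute.

## Known limitations

* The caller assumes known per-bin bias factors and will not correct
  biases it is not told about.
* Absolute ploidy of a flat genome is undetermined without a sort gate —
  an intrinsic limit of ratio data, not an implementation gap.
* The simulator's uniform breakpoints and selection-free drift are
  simplifications; population-level quantities (census percentages,
  score magnitudes) depend on preset rates and should be read as
  scenario outputs, not biological estimates.
* Clustering with `k` fixed inherits the usual arbitrariness of cutting
  a dendrogram; `k` is a parameter, and no claim is made that four is
  the "true" number of clusters in any real sample.
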