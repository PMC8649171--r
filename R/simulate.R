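#' Simulation parameters for a CIN branching process
#'
#' Per-division event rates and population-control settings for
#' [simulate_population()]. Defaults describe a karyotypically stable
#' population (all rates zero).
#'
#' @param p_mis probability, per chromosome per division, of a whole-chromosome
#'   mis-segregation (one daughter gains a copy, the sister loses one).
#' @param p_seg probability, per division, of one reciprocal segmental event: a
#'   distal segment from a uniformly chosen breakpoint on a uniformly chosen
#'   chromosome is gained by one daughter and lost by the sister.
#' @param p_wgd probability, per division, that cytokinesis fails and the
#'   division yields a single daughter with a doubled genome (WGD).
#' @param generations number of synchronous generations simulated.
#' @param carrying_capacity maximum number of cells retained per generation
#'   (uniform Wright-Fisher-style down-sampling).
#' @param sample_size number of cells emitted at the end (uniform sample;
#'   must not exceed `carrying_capacity`).
#' @param nullisomy_lethal if `TRUE` (default), a cell with zero copies of any
#'   bin is removed. Monosomies (including monosomy X) remain viable.
#' @param max_copy copy-number cap; cells exceeding it anywhere are removed
#'   (default 8).
#' @param wgd_generation optional generation at which a WGD subclone is
#'   induced deterministically (doubling a fraction `wgd_fraction` of the
#'   population before that generation's divisions); `NA` disables.
#' @param wgd_fraction fraction of cells doubled at `wgd_generation`.
#' @param seed RNG seed used by [simulate_population()] when not overridden.
#' @return A list of class `cin_params`.
#' @export
cin_params <- function(p_mis = 0, p_seg = 0, p_wgd = 0, generations = 10,
                       carrying_capacity = 200, sample_size = 50,
                       nullisomy_lethal = TRUE, max_copy = 8,
                       wgd_generation = NA, wgd_fraction = 0, seed = NULL) {
  for (p in c(p_mis, p_seg, p_wgd))
    if (!is.finite(p) || p < 0 || p > 1) stop("event probabilities must lie in [0, 1]")
  if (generations < 0) stop("generations must be >= 0")
  if (max_copy < 1) stop("max_copy must be >= 1")
  if (sample_size > carrying_capacity)
    stop("sample_size must not exceed carrying_capacity")
  if (!is.na(wgd_generation) && (wgd_fraction < 0 || wgd_fraction > 1))
    stop("wgd_fraction must lie in [0, 1]")
  structure(list(p_mis = p_mis, p_seg = p_seg, p_wgd = p_wgd,
                 generations = as.integer(generations),
                 carrying_capacity = as.integer(carrying_capacity),
                 sample_size = as.integer(sample_size),
                 nullisomy_lethal = isTRUE(nullisomy_lethal),
                 max_copy = as.integer(max_copy),
                 wgd_generation = if (is.na(wgd_generation)) NA_integer_ else as.integer(wgd_generation),
                 wgd_fraction = wgd_fraction, seed = seed),
            class = "cin_params")
}

#' Build a founder copy-number profile
#'
#' A flat profile at `base_ploidy` with copy-number deltas applied over
#' genomic regions (e.g. clonal monosomies of a founding clone).
#'
#' @param layout a [build_layout()] object.
#' @param base_ploidy integer baseline copy number (default 2).
#' @param aberrations data.frame with columns `chromosome`, `start`, `end`
#'   (bp, 0-based half-open) and `delta` (integer copy change), or `NULL`.
#' @return Integer vector of length `layout$n_bins`, named by [bin_labels()].
#' @examples
#' lay <- layout_toy()
#' f <- founder_profile(lay, 2, data.frame(chromosome = "chrB", start = 0,
#'                                         end = 10e6, delta = -1))
#' table(f)
#' @export
founder_profile <- function(layout, base_ploidy = 2, aberrations = NULL) {
  prof <- rep(as.integer(base_ploidy), layout$n_bins)
  if (!is.null(aberrations) && nrow(aberrations) > 0) {
    for (i in seq_len(nrow(aberrations))) {
      idx <- region_to_bins(layout, aberrations$chromosome[i],
                            aberrations$start[i], aberrations$end[i])
      prof[idx] <- prof[idx] + as.integer(aberrations$delta[i])
    }
  }
  if (any(prof < 0)) stop("founder profile has negative copy number")
  names(prof) <- bin_labels(layout)
  prof
}

#' Reciprocal whole-chromosome mis-segregation
#'
#' Distributes one chromosome unevenly between daughters: every bin of the
#' chromosome gains one copy in one daughter and loses one in the sister, so
#' the per-bin daughter sum equals twice the parent.
#'
#' @param parent integer copy-number profile (one cell).
#' @param layout the profile's [build_layout()].
#' @param chromosome chromosome name.
#' @param direction +1 (daughter A gains) or -1 (daughter A loses).
#' @return List with integer profiles `a` and `b`.
#' @export
apply_missegregation <- function(parent, layout, chromosome, direction = 1L) {
  ci <- match(chromosome, layout$chromosomes$chromosome)
  if (is.na(ci)) stop("unknown chromosome: ", chromosome)
  idx <- which(layout$bins$chromosome == chromosome)
  if (any(parent[idx] < 1L))
    stop("cannot mis-segregate nullisomic chromosome ", chromosome)
  direction <- if (direction >= 0) 1L else -1L
  a <- b <- as.integer(parent)
  a[idx] <- a[idx] + direction
  b[idx] <- b[idx] - direction
  names(a) <- names(b) <- names(parent)
  list(a = a, b = b)
}

#' Whole-genome doubling of a profile
#'
#' @param profile integer copy-number profile (vector) or population matrix.
#' @return The input with every copy-number state doubled.
#' @export
apply_wgd <- function(profile) {
  storage.mode(profile) <- "integer"
  profile * 2L
}

# viability filter: copy cap everywhere; optional nullisomy lethality
viable_cells <- function(mat, params) {
  ok <- matrixStats_rowMax(mat) <= params$max_copy
  if (params$nullisomy_lethal) ok <- ok & (matrixStats_rowMin(mat) >= 1L)
  ok
}

# row-wise max/min without extra deps
matrixStats_rowMax <- function(m) if (nrow(m) == 0L) integer(0) else apply(m, 1L, max)
matrixStats_rowMin <- function(m) if (nrow(m) == 0L) integer(0) else apply(m, 1L, min)

#' Simulate a cell population under chromosomal instability
#'
#' Branching process from a single founder cell. Each generation every cell
#' divides; with probability `p_wgd` the division is replaced by a
#' cytokinesis failure yielding one tetraploidized daughter; otherwise each
#' chromosome mis-segregates independently with probability `p_mis`
#' (reciprocal, see [apply_missegregation()]) and, with probability `p_seg`,
#' a distal segment from a uniformly chosen breakpoint of a uniformly chosen
#' chromosome is exchanged reciprocally. Inviable cells (nullisomy, copy cap)
#' are removed, the population is down-sampled uniformly to
#' `carrying_capacity`, and a final uniform sample of `sample_size` cells is
#' returned. Identical parameters and seed give a bit-identical matrix.
#'
#' @param founder integer founder profile (see [founder_profile()]).
#' @param params a [cin_params()] object.
#' @param layout the founder's [build_layout()].
#' @param seed RNG seed; defaults to `params$seed` (if `NULL`, the current
#'   RNG state is used).
#' @return Integer matrix, `sample_size` rows (cells) by `layout$n_bins`
#'   columns, with cell ids as row names and [bin_labels()] as column names.
#' @export
simulate_population <- function(founder, params, layout, seed = params$seed) {
  if (length(founder) != layout$n_bins)
    stop("founder length does not match layout bin count")
  if (any(founder < 0)) stop("founder profile has negative copy number")
  if (!is.null(seed)) set.seed(seed)

  n_chrom <- nrow(layout$chromosomes)
  cbl <- chrom_bin_list(layout)
  chrom_sizes <- lengths(cbl)

  pop <- matrix(as.integer(founder), nrow = 1L)
  if (!all(viable_cells(pop, params)))
    stop("founder violates viability rules (nullisomy or copy cap)")

  for (g in seq_len(params$generations)) {
    if (!is.na(params$wgd_generation) && g == params$wgd_generation &&
        params$wgd_fraction > 0) {
      n_d <- max(1L, round(params$wgd_fraction * nrow(pop)))
      sel <- sample.int(nrow(pop), n_d)
      pop[sel, ] <- pop[sel, , drop = FALSE] * 2L
    }

    n <- nrow(pop)
    is_wgd <- stats::runif(n) < params$p_wgd
    wgd_daughters <- pop[is_wgd, , drop = FALSE] * 2L

    par <- pop[!is_wgd, , drop = FALSE]
    a <- par
    b <- par
    np <- nrow(par)
    if (np > 0L && params$p_mis > 0) {
      ev <- which(matrix(stats::runif(np * n_chrom) < params$p_mis,
                         np, n_chrom), arr.ind = TRUE)
      if (nrow(ev) > 0L) {
        dirs <- sample(c(1L, -1L), nrow(ev), replace = TRUE)
        for (r in seq_len(nrow(ev))) {
          cell <- ev[r, 1L]; idx <- cbl[[ev[r, 2L]]]
          if (any(par[cell, idx] < 1L)) next  # nothing to mis-segregate
          a[cell, idx] <- a[cell, idx] + dirs[r]
          b[cell, idx] <- b[cell, idx] - dirs[r]
        }
      }
    }
    if (np > 0L && params$p_seg > 0) {
      has_seg <- which(stats::runif(np) < params$p_seg)
      for (cell in has_seg) {
        ci <- sample.int(n_chrom, 1L)
        if (chrom_sizes[ci] < 2L) next
        brk <- sample.int(chrom_sizes[ci] - 1L, 1L)  # uniform internal boundary
        idx <- cbl[[ci]][(brk + 1L):chrom_sizes[ci]] # distal segment
        if (any(par[cell, idx] < 1L)) next
        d <- sample(c(1L, -1L), 1L)
        a[cell, idx] <- a[cell, idx] + d
        b[cell, idx] <- b[cell, idx] - d
      }
    }

    pop <- rbind(a, b, wgd_daughters)
    pop <- pop[viable_cells(pop, params), , drop = FALSE]
    if (nrow(pop) == 0L)
      stop(sprintf("population went extinct at generation %d", g))
    if (nrow(pop) > params$carrying_capacity)
      pop <- pop[sample.int(nrow(pop), params$carrying_capacity), , drop = FALSE]
  }

  if (params$sample_size > nrow(pop))
    stop(sprintf(paste0("cannot sample %d cells: only %d survive after ",
                        "generation %d (population contracted toward extinction)"),
                 params$sample_size, nrow(pop), params$generations))
  pop <- pop[sample.int(nrow(pop), params$sample_size), , drop = FALSE]
  dimnames(pop) <- list(sprintf("cell_%03d", seq_len(nrow(pop))),
                        bin_labels(layout))
  pop
}

#' Read-count model for simulated shallow single-cell sequencing
#'
#' Counts are negative binomial with mean
#' `mean_reads_per_copy * CN[b] * gc_factor[b] + background` and size
#' (inverse-overdispersion) `dispersion`; `dispersion = Inf` gives Poisson
#' counts.
#'
#' @param mean_reads_per_copy expected reads per copy per bin (depth `d`).
#' @param dispersion negative-binomial size parameter (> 0; `Inf` = Poisson).
#' @param gc_factor positive multiplicative per-bin bias, recycled to the bin
#'   count (default 1: no bias).
#' @param background additive mean count for zero-copy bins (default 0).
#' @return A list of class `count_model`.
#' @export
count_model <- function(mean_reads_per_copy = 50, dispersion = 100,
                        gc_factor = 1, background = 0) {
  if (mean_reads_per_copy <= 0) stop("mean_reads_per_copy must be > 0")
  if (!(dispersion > 0)) stop("dispersion must be > 0")
  if (any(gc_factor <= 0)) stop("gc factors must be > 0")
  structure(list(mean_reads_per_copy = mean_reads_per_copy,
                 dispersion = dispersion, gc_factor = gc_factor,
                 background = background),
            class = "count_model")
}

#' Simulate binned read counts from copy-number profiles
#'
#' @param profiles integer profile vector or population matrix (cells x bins).
#' @param model a [count_model()].
#' @param seed optional RNG seed.
#' @return Integer counts with the same shape and dimnames as `profiles`.
#' @export
simulate_read_counts <- function(profiles, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vec <- is.null(dim(profiles))
  m <- if (vec) matrix(profiles, nrow = 1L) else profiles
  gc <- rep_len(model$gc_factor, ncol(m))
  mu <- sweep(m * model$mean_reads_per_copy, 2L, gc, `*`) + model$background
  counts <- if (is.infinite(model$dispersion)) {
    stats::rpois(length(mu), lambda = mu)
  } else {
    stats::rnbinom(length(mu), mu = mu, size = model$dispersion)
  }
  counts <- matrix(as.integer(counts), nrow = nrow(m), dimnames = dimnames(m))
  if (vec) counts[1L, ] else counts
}

#' Simulate miFISH signal counts from copy-number profiles
#'
#' The true signal count of a probe is the copy-number state at the probe's
#' bin; with probability `error_rate` the reported count is perturbed by
#' plus or minus one (floored at 0), emulating hybridization/counting error.
#'
#' @param profiles integer profile vector or population matrix.
#' @param panel a miFISH panel (see [mifish_panel()]).
#' @param layout the profiles' [build_layout()].
#' @param error_rate per-probe perturbation probability.
#' @param seed optional RNG seed.
#' @return Integer matrix, cells x probes (probe names as columns).
#' @export
simulate_mifish <- function(profiles, panel, layout, error_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- if (is.null(dim(profiles))) matrix(profiles, nrow = 1L,
                                          dimnames = list("cell_001", NULL))
       else profiles
  pb <- probe_bins(panel, layout)
  counts <- m[, pb, drop = FALSE]
  colnames(counts) <- panel$probe
  if (error_rate > 0) {
    hit <- matrix(stats::runif(length(counts)) < error_rate, nrow = nrow(counts))
    shift <- matrix(sample(c(1L, -1L), length(counts), replace = TRUE),
                    nrow = nrow(counts))
    counts <- counts + hit * shift
    counts[counts < 0L] <- 0L
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Simulate per-cell DNA content
#'
#' DNA content is expressed relative to a diploid G1 genome: a flat diploid
#' cell has value 1.0 (2c), a flat tetraploid 2.0 (4c). Each cell's value is
#' `mean(CN)/2`, doubled with probability `g2_fraction` (cells in G2 after
#' replication), times multiplicative Gaussian noise with coefficient of
#' variation `cv`.
#'
#' @param population copy-number matrix (cells x bins) or profile vector.
#' @param cv coefficient of variation of the measurement noise (>= 0).
#' @param g2_fraction fraction of cells in G2 (doubled content).
#' @param seed optional RNG seed.
#' @return Numeric vector, one value per cell.
#' @export
simulate_dna_content <- function(population, cv = 0.05, g2_fraction = 0,
                                 seed = NULL) {
  if (cv < 0) stop("cv must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  m <- if (is.null(dim(population))) matrix(population, nrow = 1L) else population
  base <- rowMeans(m) / 2
  n <- length(base)
  g2 <- stats::runif(n) < g2_fraction
  base[g2] <- base[g2] * 2
  base * (1 + stats::rnorm(n, 0, cv))
}

#' Gate cells on simulated DNA content
#'
#' Emulates the flow sort applied before single-cell sequencing: retain cells
#' whose DNA content lies within a relative tolerance of the 2c (1.0) or 4c
#' (2.0) value.
#'
#' @param values DNA-content values from [simulate_dna_content()].
#' @param gate `"2c"`, `"4c"` or `"none"`.
#' @param tolerance relative half-width of the gate (default 0.2).
#' @return Logical vector: `TRUE` for cells inside the gate.
#' @export
gate_dna_content <- function(values, gate = c("none", "2c", "4c"),
                             tolerance = 0.2) {
  gate <- match.arg(gate)
  centre <- switch(gate, none = return(rep(TRUE, length(values))),
                   "2c" = 1, "4c" = 2)
  abs(values - centre) <= tolerance * centre
}

# -- bundled presets ---------------------------------------------------------

# FNE1-like founder: diploid with clonal monosomies of 9p, chromosome 15 and X
fne1_aberrations <- function() {
  data.frame(
    chromosome = c("chr9", "chr15", "chrX"),
    start = c(0, 0, 0),
    end = c(43e6, hg38_chrom_lengths[["chr15"]], hg38_chrom_lengths[["chrX"]]),
    delta = c(-1L, -1L, -1L),
    stringsAsFactors = FALSE
  )
}

#' Bundled simulation presets
#'
#' Four named generative scenarios used throughout the package's examples and
#' tests. All share a near-diploid founder with clonal monosomies of 9p,
#' chromosome 15 and X:
#' \describe{
#'   \item{`fne1`}{karyotypically stable parental line: all event rates 0.}
#'   \item{`p1`}{low-level CIN after p53 loss. The subclone's founding cell
#'     additionally carries trisomies 3, 5 and 20 and monosomy 18 (clonal
#'     aberrations fixed by single-cell cloning).}
#'   \item{`pb2`}{moderate CIN with private clonal segmental losses on
#'     chromosomes 1q, 2q, 6q, 12p and 13q plus a 6p gain; a WGD subclone is
#'     induced mid-history, yielding a mixed diploid/tetraploid population
#'     whose tetraploid consensus doubles the diploid one.}
#'   \item{`pb3`}{fully tetraploid lineage: clonal pre-WGD losses of 1q,
#'     chromosome 4 and chromosome 16, WGD at generation 1, elevated rates.}
#' }
#'
#' @param name preset name: `"fne1"`, `"p1"`, `"pb2"` or `"pb3"`.
#' @param layout layout to realize the founder on (default [layout_hg38()]).
#' @return List with elements `name`, `layout`, `founder` (integer profile)
#'   and `params` ([cin_params()]).
#' @export
cin_preset <- function(name = c("fne1", "p1", "pb2", "pb3"),
                       layout = layout_hg38()) {
  name <- match.arg(name)
  ab <- fne1_aberrations()
  add <- function(...) rbind(ab, data.frame(..., stringsAsFactors = FALSE))
  len <- function(chrom) hg38_chrom_lengths[[chrom]]
  spec <- switch(name,
    fne1 = list(
      aberrations = ab,
      params = cin_params(p_mis = 0, p_seg = 0, p_wgd = 0, generations = 10,
                          carrying_capacity = 150, sample_size = 50)),
    p1 = list(
      aberrations = add(
        chromosome = c("chr3", "chr5", "chr18", "chr20"),
        start = c(0, 0, 0, 0),
        end = c(len("chr3"), len("chr5"), len("chr18"), len("chr20")),
        delta = c(1L, 1L, -1L, 1L)),
      params = cin_params(p_mis = 8e-4, p_seg = 4e-4, p_wgd = 0,
                          generations = 16, carrying_capacity = 150,
                          sample_size = 50)),
    pb2 = list(
      aberrations = add(
        chromosome = c("chr1", "chr2", "chr6", "chr6", "chr12", "chr13"),
        start = c(125e6, 90e6, 60e6, 0, 0, 20e6),
        end = c(len("chr1"), len("chr2"), len("chr6"), 60e6, 35e6, len("chr13")),
        delta = c(-1L, -1L, -1L, 1L, -1L, -1L)),
      params = cin_params(p_mis = 1.2e-3, p_seg = 8e-4, p_wgd = 0,
                          generations = 18, carrying_capacity = 200,
                          sample_size = 60, wgd_generation = 8,
                          wgd_fraction = 0.4)),
    pb3 = list(
      aberrations = add(
        chromosome = c("chr1", "chr4", "chr16"),
        start = c(125e6, 0, 0),
        end = c(len("chr1"), len("chr4"), len("chr16")),
        delta = c(-1L, -1L, -1L)),
      params = cin_params(p_mis = 1.2e-3, p_seg = 8e-4, p_wgd = 0,
                          generations = 14, carrying_capacity = 150,
                          sample_size = 50, wgd_generation = 1,
                          wgd_fraction = 1))
  )
  list(name = name, layout = layout,
       founder = founder_profile(layout, 2, spec$aberrations),
       params = spec$params)
}
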