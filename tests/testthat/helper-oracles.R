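# Naive reference implementations used as independent oracles. These stay
# deliberately loop-based and unvectorized so they share no code path with the
# package implementations they check.

naive_structural <- function(pop, layout) {
  total <- 0
  for (c in seq_len(nrow(pop))) {
    for (chrom in layout$chromosomes$chromosome) {
      idx <- which(layout$bins$chromosome == chrom)
      states <- pop[c, idx]
      for (b in seq_len(length(states) - 1)) {
        if (states[b] != states[b + 1]) total <- total + 1
      }
    }
  }
  total / (layout$total_mb * nrow(pop))
}

naive_aneuploidy <- function(pop, psi) {
  acc <- 0
  for (c in seq_len(nrow(pop)))
    for (b in seq_len(ncol(pop)))
      acc <- acc + abs(pop[c, b] - psi)
  acc / (nrow(pop) * ncol(pop))
}

naive_heterogeneity <- function(pop) {
  n <- nrow(pop)
  if (n == 1) return(0)
  acc <- 0
  for (b in seq_len(ncol(pop))) {
    counts <- table(pop[, b])
    acc <- acc + (1 - max(counts) / n)
  }
  acc / ncol(pop)
}

# exhaustive (cell, chromosome, run-start) scan for the deviation census
naive_census_flags <- function(pop, consensus, layout, min_run = 1) {
  flags <- logical(nrow(pop))
  for (c in seq_len(nrow(pop))) {
    for (chrom in layout$chromosomes$chromosome) {
      idx <- which(layout$bins$chromosome == chrom)
      for (s in seq_len(length(idx) - min_run + 1)) {
        run <- idx[s:(s + min_run - 1)]
        if (all(pop[c, run] != consensus[run])) flags[c] <- TRUE
      }
    }
  }
  flags
}

# random toy population: block-structured so modes and runs are non-trivial
rand_toy_pop <- function(n_cells, layout, max_state = 6) {
  base <- sample(1:3, layout$n_bins, replace = TRUE)
  pop <- matrix(rep(base, each = n_cells), nrow = n_cells)
  # sprinkle whole-chromosome and segmental deviations
  for (c in seq_len(n_cells)) {
    if (stats::runif(1) < 0.6) {
      chrom <- sample(layout$chromosomes$chromosome, 1)
      idx <- which(layout$bins$chromosome == chrom)
      span <- sort(sample(seq_along(idx), 2))
      pop[c, idx[span[1]:span[2]]] <- sample(0:max_state, 1)
    }
  }
  storage.mode(pop) <- "integer"
  pop
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# independent probe -> bin lookup: linear scan over the bin table
probe_bins_for_test <- function(panel, layout) {
  vapply(seq_len(nrow(panel)), function(i) {
    which(layout$bins$chromosome == panel$chromosome[i] &
            layout$bins$start <= panel$position[i] &
            layout$bins$end > panel$position[i])
  }, integer(1))
}

toy3 <- layout_toy()
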