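#' Structural score of a cell population
#'
#' Number of copy-number state transitions between adjacent bins within a
#' chromosome, summed over all cells and chromosomes, per Mb of binned
#' genome, normalized to the number of cells analysed:
#' `S = sum(transitions) / (G * N)` with `G = layout$total_mb`. Transitions
#' are never counted across chromosome boundaries, so a population of cells
#' that are flat within every chromosome (including whole-chromosome
#' aneuploidies) scores exactly 0.
#'
#' @param pop integer copy-number matrix, cells x bins.
#' @param layout the population's [build_layout()].
#' @return Non-negative scalar (transitions per Mb per cell).
#' @examples
#' lay <- build_layout(c(chr1 = 10e6), 1e6)
#' pop <- matrix(c(2, 2, 2, 3, 3, 3, 2, 2, 2, 2), nrow = 1)
#' structural_score(pop, lay)  # 2 transitions / 10 Mb = 0.2
#' @export
structural_score <- function(pop, layout) {
  pop <- as_pop_matrix(pop)
  if (ncol(pop) != layout$n_bins) stop("matrix does not match layout bin count")
  # transitions: adjacent columns on the same chromosome with differing states
  ci <- bin_chrom_index(layout)
  same_chrom <- ci[-1L] == ci[-length(ci)]
  if (!any(same_chrom)) return(0)
  left <- which(same_chrom)
  trans <- sum(pop[, left + 1L, drop = FALSE] != pop[, left, drop = FALSE])
  trans / (layout$total_mb * nrow(pop))
}

#' Aneuploidy score
#'
#' Mean absolute deviation of copy-number states from the reference ploidy:
#' `A = mean(|CN - psi|)` over all cells and bins. A flat tetraploid
#' population scores 2 against `reference_ploidy = 2`, which is what
#' separates WGD populations from diploid ones on this axis.
#'
#' @param pop integer copy-number matrix, cells x bins.
#' @param reference_ploidy euploid reference `psi` (default 2).
#' @return Non-negative scalar.
#' @export
aneuploidy_score <- function(pop, reference_ploidy = 2) {
  pop <- as_pop_matrix(pop)
  if (reference_ploidy < 1) stop("reference_ploidy must be >= 1")
  mean(abs(pop - reference_ploidy))
}

#' Heterogeneity score
#'
#' Mean, over bins, of the fraction of cells not carrying the bin's modal
#' state: `H = mean_b(1 - m_b / N)` where `m_b` is the count of cells at the
#' modal state of bin `b` (ties: the maximal count). 0 when all cells are
#' identical; bounded above by 1.
#'
#' @param pop integer copy-number matrix, cells x bins.
#' @return Scalar in `[0, 1]`.
#' @export
heterogeneity_score <- function(pop) {
  pop <- as_pop_matrix(pop)
  n <- nrow(pop)
  if (n == 1L) return(0)
  m_b <- apply(pop, 2L, function(col) max(tabulate(col + 1L)))
  mean(1 - m_b / n)
}

#' Consensus karyotype of a population
#'
#' Per-bin modal copy-number state across cells. Ties are broken toward the
#' state closest to the population's overall modal ploidy, then toward the
#' lower state — so consensus profiles are deterministic.
#'
#' @param pop integer copy-number matrix, cells x bins.
#' @return Integer profile of length `ncol(pop)`.
#' @export
consensus_profile <- function(pop) {
  pop <- as_pop_matrix(pop)
  overall <- modal_state(as.vector(pop))
  cons <- apply(pop, 2L, function(col) {
    tab <- tabulate(col + 1L)
    states <- which(tab == max(tab)) - 1L
    states[order(abs(states - overall), states)][1L]
  })
  cons <- as.integer(cons)
  names(cons) <- colnames(pop)
  cons
}

# modal value of a non-negative integer vector, ties toward the lower state
modal_state <- function(x) {
  tab <- tabulate(x + 1L)
  which.max(tab) - 1L
}

#' Per-cell deviation census
#'
#' Flags every cell that differs from the population consensus over at least
#' `min_run` consecutive bins of a single chromosome, and reports the flagged
#' fraction. With the default `min_run = 1` any deviating bin flags the
#' cell.
#'
#' @param pop integer copy-number matrix, cells x bins.
#' @param layout the population's [build_layout()].
#' @param min_run minimum run length (bins) of consecutive deviation.
#' @param consensus optional externally supplied consensus profile; by
#'   default [consensus_profile()] of `pop`.
#' @return List with `flags` (logical per cell), `fraction` (flagged / N)
#'   and `consensus`.
#' @examples
#' lay <- layout_toy()
#' pop <- matrix(2L, nrow = 35, ncol = lay$n_bins)
#' pop[1:2, 1:10] <- 3L   # two cells with a whole-chromosome gain
#' deviation_census(pop, lay)$fraction  # 2/35
#' @export
deviation_census <- function(pop, layout, min_run = 1,
                             consensus = consensus_profile(pop)) {
  pop <- as_pop_matrix(pop)
  if (min_run < 1) stop("min_run must be >= 1")
  ci <- bin_chrom_index(layout)
  diff_mat <- sweep(pop, 2L, consensus, `!=`)
  flags <- vapply(seq_len(nrow(pop)), function(i) {
    d <- diff_mat[i, ]
    any(vapply(split(d, ci), function(dc) {
      r <- rle(dc)
      any(r$values & r$lengths >= min_run)
    }, logical(1)))
  }, logical(1))
  names(flags) <- rownames(pop)
  list(flags = flags, fraction = mean(flags), consensus = consensus)
}

#' Sample-level karyotype score report
#'
#' Computes the structural, aneuploidy and heterogeneity scores and the
#' deviation census for one population.
#'
#' @param pop integer copy-number matrix, cells x bins.
#' @param layout the population's [build_layout()].
#' @param reference_ploidy euploid reference for [aneuploidy_score()].
#' @param min_run census run length, see [deviation_census()].
#' @return Object of class `score_report`: list with `n_cells`, `structural`,
#'   `aneuploidy`, `heterogeneity`, `deviation_fraction`, `reference_ploidy`.
#' @export
score_report <- function(pop, layout, reference_ploidy = 2, min_run = 1) {
  pop <- as_pop_matrix(pop)
  census <- deviation_census(pop, layout, min_run = min_run)
  structure(list(
    n_cells = nrow(pop),
    structural = structural_score(pop, layout),
    aneuploidy = aneuploidy_score(pop, reference_ploidy),
    heterogeneity = heterogeneity_score(pop),
    deviation_fraction = census$fraction,
    reference_ploidy = reference_ploidy
  ), class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf(paste0("score_report (%d cells, psi = %g)\n",
                     "  structural:    %.4f transitions/Mb/cell\n",
                     "  aneuploidy:    %.4f\n",
                     "  heterogeneity: %.4f\n",
                     "  deviating:     %.1f%% of cells\n"),
              x$n_cells, x$reference_ploidy, x$structural, x$aneuploidy,
              x$heterogeneity, 100 * x$deviation_fraction))
  invisible(x)
}

#' @export
as.data.frame.score_report <- function(x, ...) {
  data.frame(n_cells = x$n_cells, structural = x$structural,
             aneuploidy = x$aneuploidy, heterogeneity = x$heterogeneity,
             deviation_fraction = x$deviation_fraction,
             reference_ploidy = x$reference_ploidy)
}

# coerce to a validated integer cells x bins matrix
as_pop_matrix <- function(pop) {
  if (is.null(dim(pop))) pop <- matrix(pop, nrow = 1L)
  if (nrow(pop) == 0L) stop("empty population")
  if (any(pop < 0)) stop("copy-number states must be non-negative")
  storage.mode(pop) <- "integer"
  pop
}
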