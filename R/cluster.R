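#' Karyotype distance
#'
#' Mean absolute copy-number difference per bin (Manhattan distance divided
#' by the bin count). Symmetric, zero iff the profiles are identical; a
#' diploid profile and its WGD are exactly 2 apart.
#'
#' @param a,b integer copy-number profiles of equal length.
#' @return Non-negative scalar.
#' @export
karyotype_distance <- function(a, b) {
  if (length(a) != length(b)) stop("profiles have mismatched bin counts")
  mean(abs(a - b))
}

#' Pairwise karyotype distance matrix
#'
#' @param pop integer copy-number matrix, cells x bins.
#' @return A [stats::dist] object (Manhattan / number of bins).
#' @export
karyotype_dist <- function(pop) {
  pop <- as_pop_matrix(pop)
  stats::dist(pop, method = "manhattan") / ncol(pop)
}

#' Hierarchical clustering of single-cell karyotypes
#'
#' Agglomerative clustering on [karyotype_dist()] (average linkage by
#' default), cut to `k` clusters. Because inter-ploidy distances dominate
#' (a flat WGD sits 2 units from its diploid origin while subclonal drift
#' contributes a few hundredths), the tree separates cells by ploidy first
#' and by genotype within ploidy — mirroring how single-cell karyotype
#' heatmaps organize.
#'
#' @param pop integer copy-number matrix, cells x bins.
#' @param k number of clusters (1 <= k <= N).
#' @param linkage linkage method passed to [stats::hclust()] (default
#'   `"average"`).
#' @return Object of class `karyotype_clusters`: list with `hclust` (the
#'   tree), `labels` (integer cluster id per cell), `k`, `consensus`
#'   (k x bins matrix of per-cluster [consensus_profile()]s), `ploidy`
#'   (per-cluster modal state of the consensus) and `sizes`.
#' @export
cluster_karyotypes <- function(pop, k, linkage = "average") {
  pop <- as_pop_matrix(pop)
  n <- nrow(pop)
  if (k < 1 || k > n) stop("k must lie in [1, number of cells]")
  if (is.null(rownames(pop))) rownames(pop) <- sprintf("cell_%03d", seq_len(n))
  hc <- stats::hclust(karyotype_dist(pop), method = linkage)
  labels <- if (n == 1L) stats::setNames(1L, rownames(pop))
            else stats::cutree(hc, k = k)
  consensus <- do.call(rbind, lapply(seq_len(k), function(g)
    consensus_profile(pop[labels == g, , drop = FALSE])))
  rownames(consensus) <- paste0("cluster_", seq_len(k))
  structure(list(hclust = hc, labels = labels, k = k, consensus = consensus,
                 ploidy = apply(consensus, 1L, modal_state),
                 sizes = as.vector(table(factor(labels, levels = seq_len(k))))),
            class = "karyotype_clusters")
}

#' @export
print.karyotype_clusters <- function(x, ...) {
  cat(sprintf("karyotype_clusters: %d cells in %d clusters\n",
              length(x$labels), x$k))
  for (g in seq_len(x$k))
    cat(sprintf("  cluster %d: %d cells, modal ploidy %d\n",
                g, x$sizes[g], x$ploidy[g]))
  invisible(x)
}

#' Write a karyotype tree in Newick format
#'
#' Converts the clustering dendrogram to a phylogeny (merge heights as branch
#' lengths) and writes Newick text.
#'
#' @param clusters a [cluster_karyotypes()] result.
#' @param path output file path.
#' @export
write_tree_newick <- function(clusters, path) {
  ape::write.tree(ape::as.phylo(clusters$hclust), file = path)
  invisible(path)
}

#' Modal ploidy of a single profile
#'
#' Modal copy-number state across bins, ties toward the lower state.
#'
#' @param profile integer copy-number profile.
#' @return Integer ploidy.
#' @export
infer_cell_ploidy <- function(profile) {
  if (length(profile) == 0L) stop("empty profile")
  modal_state(as.integer(profile))
}

#' Test the WGD consensus-doubling relation
#'
#' A tetraploid subpopulation that arose by whole-genome doubling of a
#' related diploid subpopulation carries twice the diploid consensus almost
#' everywhere; in particular pre-WGD monosomies reappear as disomies on the
#' tetraploid background. The test passes when
#' `consensus_high[b] == 2 * consensus_low[b]` for at least a fraction `q`
#' of bins.
#'
#' @param consensus_low,consensus_high integer consensus profiles of the
#'   lower- and higher-ploidy subpopulation (equal length).
#' @param q minimum matching bin fraction in `(0, 1]` (default 0.9).
#' @return List with `is_wgd_pair` (logical), `match_fraction` and `mask`
#'   (per-bin logical).
#' @export
detect_wgd_relation <- function(consensus_low, consensus_high, q = 0.9) {
  if (length(consensus_low) != length(consensus_high))
    stop("profiles have mismatched bin counts")
  if (q <= 0 || q > 1) stop("q must lie in (0, 1]")
  mask <- consensus_high == 2L * consensus_low
  list(is_wgd_pair = mean(mask) >= q, match_fraction = mean(mask), mask = mask)
}

#' Classify a DNA-content distribution into 2c/4c/8c peaks
#'
#' Detects peaks of the per-cell DNA-content distribution at the 2c (1.0),
#' 4c (2.0) and 8c (4.0) positions: a peak requires at least `min_mass` of
#' the cells within a relative tolerance of the position. A population with
#' both 4c and 8c peaks contains cells replicating a tetraploid genome and
#' is flagged `cycling_tetraploid`; a plain 2c + 4c pattern is a normally
#' cycling diploid and carries no flag.
#'
#' @param values DNA-content values (1.0 = 2c; see
#'   [simulate_dna_content()]); at least 10 values.
#' @param peak_tolerance relative half-width around each peak position
#'   (default 0.15).
#' @param min_mass minimum cell fraction for a peak (default 0.05).
#' @return List with `peaks` (character subset of `c("2c","4c","8c")`),
#'   `fractions` (named mass at each position) and `cycling_tetraploid`.
#' @export
classify_dna_content <- function(values, peak_tolerance = 0.15,
                                 min_mass = 0.05) {
  if (length(values) < 10L) stop("need at least 10 DNA-content values")
  centres <- c("2c" = 1, "4c" = 2, "8c" = 4)
  fractions <- vapply(centres, function(ct)
    mean(abs(values - ct) <= peak_tolerance * ct), numeric(1))
  peaks <- names(centres)[fractions >= min_mass]
  list(peaks = peaks, fractions = fractions,
       cycling_tetraploid = all(c("4c", "8c") %in% peaks))
}
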