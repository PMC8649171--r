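#' Write / read a copy-number (or count) matrix as TSV
#'
#' Rows are cells, columns are bins labelled `"chrom:start-end"` (0-based,
#' half-open); the first column holds cell ids. Reading validates the header
#' against the layout's bins and every entry for integer, non-negative
#' values, reporting the offending cell and bin on failure.
#'
#' @param mat integer matrix, cells x bins, with [bin_labels()] column names.
#' @param path file path.
#' @export
write_cn_matrix <- function(mat, path) {
  df <- data.frame(cell = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cn_matrix
#' @param layout the [build_layout()] the matrix must conform to.
#' @return `read_cn_matrix()` returns an integer matrix with cell row names.
#' @export
read_cn_matrix <- function(path, layout) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L || names(tab)[1L] != "cell")
    stop("matrix file must start with a 'cell' column: ", path)
  expected <- bin_labels(layout)
  got <- names(tab)[-1L]
  if (length(got) != length(expected) || any(got != expected)) {
    bad <- which(got != expected[seq_along(got)])[1L]
    stop(sprintf("bin header mismatch at column %d: got '%s', expected '%s'",
                 bad + 1L, got[bad], expected[bad]))
  }
  cells <- tab[[1L]]
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m) || any(is.na(m)) || any(m != floor(m))) {
    idx <- which(is.na(m) | suppressWarnings(m != floor(m)), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer state for cell '%s' at bin '%s'",
                 cells[idx[1L]], expected[idx[2L]]))
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative state for cell '%s' at bin '%s'",
                 cells[idx[1L]], expected[idx[2L]]))
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- list(cells, expected)
  m
}

#' Write / read one cell's segments as BED5
#'
#' Columns: chrom, start, end (0-based half-open), state, segment median.
#' Segments must partition the genome without overlap.
#'
#' @param segments a [segment_bins()] frame.
#' @param states integer per-bin states (used to annotate each segment's
#'   called state), or `NULL` to write the rounded median.
#' @param path file path.
#' @export
write_segments_bed <- function(segments, path, states = NULL) {
  ord <- order(match(segments$chromosome, unique(segments$chromosome)),
               segments$start)
  segments <- segments[ord, ]
  by_chrom <- split(segments, segments$chromosome)
  for (ch in by_chrom) {
    if (nrow(ch) > 1L && any(ch$start[-1L] < ch$end[-nrow(ch)]))
      stop("overlapping segments on ", ch$chromosome[1L])
  }
  st <- if (is.null(states)) floor(segments$median_ratio + 0.5)
        else states[segments$start_bin]
  bed <- data.frame(chrom = segments$chromosome,
                    start = as.integer(segments$start),
                    end = as.integer(segments$end),
                    state = as.integer(st),
                    median = sprintf("%.6g", segments$median_ratio))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_segments_bed
#' @return `read_segments_bed()` returns a data.frame with columns `chrom`,
#'   `start`, `end`, `state`, `median`.
#' @export
read_segments_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "state",
                                         "median"))
  bed$median <- as.numeric(bed$median)
  bed
}

#' Default pipeline configuration
#'
#' Fully resolved parameter set for [run_pipeline()]; any element may be
#' overridden via `...` or a YAML file whose top-level keys match.
#'
#' @param preset simulation preset name (see [cin_preset()]).
#' @param seed global seed; each stage derives its own substream.
#' @param ... overrides for `bin_size`, `depth`, `dispersion`, `min_seg`,
#'   `gain_threshold`, `max_copy`, `reference_ploidy`, `min_run`, `k`,
#'   `linkage`, `mifish_error_rate`, `clonal_fraction`, `noise_max`, `cv`,
#'   `g2_fraction`.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(preset = "fne1", seed = 1, ...) {
  cfg <- list(preset = preset, seed = seed, bin_size = 1e6,
              depth = 50, dispersion = 100,
              min_seg = 3, gain_threshold = 0.1, max_copy = 8,
              reference_ploidy = 2, min_run = 1,
              k = 2, linkage = "average",
              mifish_error_rate = 0.02, clonal_fraction = 0.95, noise_max = 2,
              cv = 0.05, g2_fraction = 0.3)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with keys as in [run_config()].
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

# stage-specific RNG substreams derived from the global seed (kept < 2^31)
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, counts = 211L, mifish = 307L, dna = 401L)
  (as.integer(seed) * 7919L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full analysis pipeline on a simulated preset
#'
#' simulate -> read counts -> copy-number calling -> scoring -> clustering
#' -> miFISH, writing every output as TSV/Newick into `out_dir` together
#' with the fully resolved configuration (`config.yaml`). Identical
#' configurations (including seed) reproduce bit-identical outputs.
#'
#' @param config a [run_config()] (or path to a YAML accepted by
#'   [read_config()]).
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results
#'   (`population`, `counts`, `calls`, `scores`, `clusters`, `mifish`,
#'   `dna`) and `files` (paths written).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  preset <- cin_preset(config$preset,
                       layout = layout_hg38(bin_size = config$bin_size))
  layout <- preset$layout

  pop <- simulate_population(preset$founder, preset$params, layout,
                             seed = stage_seed(config$seed, "simulate"))
  counts <- simulate_read_counts(pop, count_model(config$depth,
                                                  config$dispersion),
                                 seed = stage_seed(config$seed, "counts"))
  # honor the sort gate implied by each cell's true modal ploidy
  gates <- ifelse(apply(pop, 1L, infer_cell_ploidy) >= 3, "4c", "2c")
  calls <- call_cells(counts, layout, min_seg = config$min_seg,
                      gain_threshold = config$gain_threshold,
                      ploidy_gate = gates, max_copy = config$max_copy)
  scores <- score_report(calls$profiles, layout,
                         reference_ploidy = config$reference_ploidy,
                         min_run = config$min_run)
  clusters <- cluster_karyotypes(calls$profiles, k = config$k,
                                 linkage = config$linkage)
  fish <- simulate_mifish(pop, mifish_panel(), layout,
                          error_rate = config$mifish_error_rate,
                          seed = stage_seed(config$seed, "mifish"))
  fish_report <- mifish_report(fish, mifish_panel(),
                               clonal_fraction = config$clonal_fraction,
                               noise_max = config$noise_max)
  dna <- simulate_dna_content(pop, cv = config$cv,
                              g2_fraction = config$g2_fraction,
                              seed = stage_seed(config$seed, "dna"))

  paths <- list(
    config = file.path(out_dir, "config.yaml"),
    population = file.path(out_dir, "population.tsv"),
    counts = file.path(out_dir, "counts.tsv"),
    called = file.path(out_dir, "called.tsv"),
    scores = file.path(out_dir, "scores.tsv"),
    labels = file.path(out_dir, "cluster_labels.tsv"),
    consensus = file.path(out_dir, "cluster_consensus.tsv"),
    tree = file.path(out_dir, "tree.nwk"),
    clonality = file.path(out_dir, "mifish_clonality.tsv"),
    clones = file.path(out_dir, "mifish_clones.tsv"),
    dna = file.path(out_dir, "dna_content.tsv")
  )
  yaml::write_yaml(unclass(config), paths$config)
  write_cn_matrix(pop, paths$population)
  write_cn_matrix(counts, paths$counts)
  write_cn_matrix(calls$profiles, paths$called)
  utils::write.table(cbind(sample = config$preset,
                           as.data.frame(scores)),
                     paths$scores, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(cell = names(clusters$labels),
                                cluster = as.integer(clusters$labels)),
                     paths$labels, sep = "\t", quote = FALSE, row.names = FALSE)
  write_cn_matrix(clusters$consensus, paths$consensus)
  write_tree_newick(clusters, paths$tree)
  utils::write.table(fish_report$clonality, paths$clonality, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fish_report$clones, paths$clones, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(cell = rownames(pop), dna_content = dna),
                     paths$dna, sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(population = pop, counts = counts, calls = calls,
                 scores = scores, clusters = clusters, mifish = fish_report,
                 dna = dna, files = paths))
}
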