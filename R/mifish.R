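#' Load a miFISH probe panel
#'
#' A panel is a TSV with columns `probe`, `cytoband`, `chromosome`,
#' `position` (bp anchor) and `group` (hybridization panel, up to five
#' probes each — the assay hybridizes panels of five probes in succession).
#'
#' @param path panel TSV path.
#' @return Object of class `mifish_panel` (a data.frame).
#' @export
load_panel <- function(path) {
  tab <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                  error = function(e) stop("cannot parse panel file ", path,
                                           ": ", conditionMessage(e)))
  req <- c("probe", "cytoband", "chromosome", "position", "group")
  if (nrow(tab) == 0L) stop("panel file is empty: ", path)
  if (!all(req %in% names(tab)))
    stop("panel file must have columns ", paste(req, collapse = ", "))
  if (anyDuplicated(tab$probe))
    stop("duplicate probe names: ",
         paste(unique(tab$probe[duplicated(tab$probe)]), collapse = ", "))
  if (any(table(tab$group) > 5L))
    stop("a hybridization group holds at most 5 probes")
  if (any(!is.finite(tab$position) | tab$position < 0))
    stop("probe positions must be non-negative")
  class(tab) <- c("mifish_panel", "data.frame")
  tab
}

#' @rdname load_panel
#' @param panel a `mifish_panel`.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundled 20-locus miFISH panel
#'
#' One centromere probe (CCP10) and 19 gene probes in four hybridization
#' groups of five, anchored at representative hg38 gene coordinates.
#' @return A `mifish_panel` (see [load_panel()]).
#' @export
mifish_panel <- function() {
  load_panel(system.file("extdata", "mifish_panel.tsv", package = "cinscape",
                         mustWork = TRUE))
}

# map each probe to its layout bin; errors if a probe falls off the layout
probe_bins <- function(panel, layout) {
  vapply(seq_len(nrow(panel)), function(i) {
    idx <- tryCatch(
      region_to_bins(layout, panel$chromosome[i], panel$position[i],
                     panel$position[i] + 1),
      error = function(e) stop("probe ", panel$probe[i], " is off-layout: ",
                               conditionMessage(e)))
    idx[1L]
  }, integer(1))
}

#' DNA-content class of one miFISH cell
#'
#' Modal probe signal count (ties toward the lower count): 2 maps to `"2c"`,
#' 4 to `"4c"`, anything else to `"other"`.
#'
#' @param counts integer signal counts, one per probe.
#' @return `"2c"`, `"4c"` or `"other"`.
#' @export
estimate_cell_ploidy <- function(counts) {
  if (length(counts) == 0L) stop("cell has no probe counts")
  mode <- modal_state(as.integer(counts))
  if (mode == 2L) "2c" else if (mode == 4L) "4c" else "other"
}

#' Per-probe gain/loss call for one cell
#'
#' @param counts integer signal counts, one per probe (named or in panel
#'   order).
#' @param reference reference signal count per probe, recycled (default 2,
#'   the diploid baseline).
#' @return Character vector in `{"loss", "neutral", "gain"}` per probe.
#' @export
score_mifish_cell <- function(counts, reference = 2) {
  ref <- rep_len(reference, length(counts))
  out <- ifelse(counts < ref, "loss", ifelse(counts > ref, "gain", "neutral"))
  names(out) <- names(counts)
  out
}

#' Flag cells within miFISH technical error
#'
#' Computes the sample's modal signal pattern (per-probe modal count, ties
#' toward the lower count). Cells deviating from it at 1 to `noise_max`
#' probes are flagged as within technical error and contribute the modal
#' pattern to downstream clonality statistics; cells deviating at more loci
#' keep their observed pattern.
#'
#' @param cells integer matrix, cells x probes.
#' @param noise_max maximum deviating loci attributable to technical error
#'   (default 2).
#' @return List with `effective` (matrix used for clonality statistics),
#'   `flagged` (logical per cell), `n_deviations` (per cell) and
#'   `modal_pattern`.
#' @export
filter_noise <- function(cells, noise_max = 2) {
  if (noise_max < 0) stop("noise_max must be >= 0")
  cells <- as_mifish_matrix(cells)
  modal_pattern <- apply(cells, 2L, modal_state)
  ndev <- rowSums(sweep(cells, 2L, modal_pattern, `!=`))
  flagged <- ndev >= 1L & ndev <= noise_max
  effective <- cells
  effective[flagged, ] <- rep(modal_pattern, each = sum(flagged))
  list(effective = effective, flagged = flagged, n_deviations = ndev,
       modal_pattern = modal_pattern)
}

#' Clonal and subclonal aberration calls across cells
#'
#' After noise filtering ([filter_noise()]), each (probe, direction) is
#' called clonal when the aberration is present in at least
#' `clonal_fraction` of analysed cells, subclonal when present in at least
#' two cells but below the clonal threshold, and neutral/singleton
#' otherwise.
#'
#' @param cells integer matrix, cells x probes.
#' @param reference reference count per probe, recycled (default 2).
#' @param clonal_fraction clonality threshold in `(0.5, 1]` (default 0.95;
#'   kept below 1 so that residual technical error cannot break a clonal
#'   call).
#' @param noise_max passed to [filter_noise()] (`0` disables filtering).
#' @return data.frame with one row per probe: `probe`, `loss_fraction`,
#'   `gain_fraction`, `loss_status`, `gain_status` (each in
#'   `{"clonal", "subclonal", "none"}`) and `status`, a single summary label.
#' @export
classify_clonality <- function(cells, reference = 2, clonal_fraction = 0.95,
                               noise_max = 2) {
  cells <- as_mifish_matrix(cells)
  if (clonal_fraction <= 0.5 || clonal_fraction > 1)
    stop("clonal_fraction must lie in (0.5, 1]")
  eff <- filter_noise(cells, noise_max)$effective
  n <- nrow(eff)
  ref <- rep_len(reference, ncol(eff))
  call_dir <- function(count) {
    frac <- count / n
    ifelse(frac >= clonal_fraction, "clonal",
           ifelse(count >= 2L, "subclonal", "none"))
  }
  losses <- colSums(sweep(eff, 2L, ref, `<`))
  gains <- colSums(sweep(eff, 2L, ref, `>`))
  loss_status <- call_dir(losses)
  gain_status <- call_dir(gains)
  status <- ifelse(loss_status == "clonal", "clonal_loss",
            ifelse(gain_status == "clonal", "clonal_gain",
            ifelse(loss_status == "subclonal" & gain_status == "subclonal",
                   "subclonal_mixed",
            ifelse(loss_status == "subclonal", "subclonal_loss",
            ifelse(gain_status == "subclonal", "subclonal_gain", "neutral")))))
  data.frame(probe = colnames(eff),
             loss_fraction = losses / n, gain_fraction = gains / n,
             loss_status = loss_status, gain_status = gain_status,
             status = status, stringsAsFactors = FALSE, row.names = NULL)
}

#' Enumerate clones from miFISH signal patterns
#'
#' Distinct full signal-count vectors with their frequencies, sorted by
#' decreasing frequency, then lexicographically by pattern. Frequencies sum
#' to the number of cells.
#'
#' @param cells integer matrix, cells x probes.
#' @return data.frame with `pattern` (probe counts joined by `/`),
#'   `frequency`, and one count column per probe.
#' @export
enumerate_clones <- function(cells) {
  cells <- as_mifish_matrix(cells)
  key <- apply(cells, 1L, paste, collapse = "/")
  tab <- table(key)
  ord <- order(-as.vector(tab), names(tab))
  patterns <- names(tab)[ord]
  counts <- do.call(rbind, lapply(patterns, function(p)
    as.integer(strsplit(p, "/", fixed = TRUE)[[1L]])))
  colnames(counts) <- colnames(cells)
  cbind(data.frame(pattern = patterns, frequency = as.vector(tab)[ord],
                   stringsAsFactors = FALSE),
        as.data.frame(counts))
}

#' Full miFISH sample report
#'
#' Combines per-cell ploidy classes, noise filtering, clonality calls and
#' the clone table for one sample.
#'
#' @param cells integer matrix, cells x probes (columns must match the
#'   panel's probes when `panel` is given).
#' @param panel optional `mifish_panel` used to validate probe columns.
#' @param reference reference count per probe (default 2).
#' @param clonal_fraction,noise_max see [classify_clonality()].
#' @return Object of class `mifish_report`: list with `n_cells`,
#'   `ploidy_class` (per cell), `ploidy_table`, `n_flagged`, `clonality`
#'   and `clones`.
#' @export
mifish_report <- function(cells, panel = NULL, reference = 2,
                          clonal_fraction = 0.95, noise_max = 2) {
  cells <- as_mifish_matrix(cells)
  if (!is.null(panel)) {
    missing <- setdiff(panel$probe, colnames(cells))
    if (length(missing) > 0)
      stop("cells lack counts for panel probes: ",
           paste(missing, collapse = ", "))
    cells <- cells[, panel$probe, drop = FALSE]
  }
  ploidy_class <- apply(cells, 1L, estimate_cell_ploidy)
  noise <- filter_noise(cells, noise_max)
  structure(list(
    n_cells = nrow(cells),
    ploidy_class = ploidy_class,
    ploidy_table = table(factor(ploidy_class, levels = c("2c", "4c", "other"))),
    n_flagged = sum(noise$flagged),
    clonality = classify_clonality(cells, reference, clonal_fraction, noise_max),
    clones = enumerate_clones(cells)
  ), class = "mifish_report")
}

#' @export
print.mifish_report <- function(x, ...) {
  cat(sprintf("mifish_report: %d cells (%s); %d within technical error\n",
              x$n_cells,
              paste(names(x$ploidy_table), x$ploidy_table, sep = "=",
                    collapse = ", "),
              x$n_flagged))
  ab <- x$clonality[x$clonality$status != "neutral", ]
  if (nrow(ab) > 0) {
    cat("aberrations:\n")
    for (i in seq_len(nrow(ab)))
      cat(sprintf("  %-8s %s (loss %.0f%%, gain %.0f%%)\n", ab$probe[i],
                  ab$status[i], 100 * ab$loss_fraction[i],
                  100 * ab$gain_fraction[i]))
  }
  cat(sprintf("%d distinct clones\n", nrow(x$clones)))
  invisible(x)
}

as_mifish_matrix <- function(cells) {
  if (is.data.frame(cells)) cells <- as.matrix(cells)
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = 1L,
                                           dimnames = list(NULL, names(cells)))
  if (nrow(cells) == 0L) stop("empty cell set")
  if (any(cells < 0)) stop("signal counts must be non-negative")
  storage.mode(cells) <- "integer"
  cells
}
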