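#' Build a binned genome layout
#'
#' Partitions an ordered set of chromosomes into fixed-width bins. The layout
#' is the shared coordinate system of every copy-number profile, score and
#' simulated event in the package. Coordinates are 0-based, half-open (BED
#' convention); the last bin of each chromosome may be shorter than
#' `bin_size`.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp
#'   (names are chromosome names, order is preserved), or a two-column
#'   data.frame with columns `chromosome` and `length`.
#' @param bin_size bin width in bp (default 1 Mb).
#'
#' @return An object of class `genome_layout`: a list with elements
#'   `chromosomes` (data.frame: `chromosome`, `length`), `bin_size`, `bins`
#'   (data.frame: `chromosome`, `start`, `end`, one row per bin, genome
#'   order), `n_bins`, and `total_mb` (total binned genome length in Mb, the
#'   `G` used by [structural_score()]).
#' @examples
#' layout <- build_layout(c(chr1 = 10e6), bin_size = 1e6)
#' layout$n_bins    # 10
#' layout$total_mb  # 10
#' @seealso [layout_hg38()], [layout_toy()], [region_to_bins()]
#' @export
build_layout <- function(chrom_lengths, bin_size = 1e6) {
  if (is.data.frame(chrom_lengths)) {
    chroms <- data.frame(chromosome = as.character(chrom_lengths$chromosome),
                         length = as.numeric(chrom_lengths$length),
                         stringsAsFactors = FALSE)
  } else {
    if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
      stop("chrom_lengths must be named by chromosome")
    chroms <- data.frame(chromosome = names(chrom_lengths),
                         length = as.numeric(chrom_lengths),
                         stringsAsFactors = FALSE)
  }
  if (nrow(chroms) == 0L) stop("chromosome list is empty")
  if (anyDuplicated(chroms$chromosome)) stop("duplicate chromosome names")
  if (any(!is.finite(chroms$length)) || any(chroms$length <= 0))
    stop("all chromosome lengths must be positive")
  if (!is.finite(bin_size) || bin_size <= 0) stop("bin_size must be positive")

  bins <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    len <- chroms$length[i]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chromosome = chroms$chromosome[i],
               start = starts,
               end = pmin(starts + bin_size, len),
               stringsAsFactors = FALSE)
  }))
  rownames(bins) <- NULL
  layout <- list(
    chromosomes = chroms,
    bin_size = bin_size,
    bins = bins,
    n_bins = nrow(bins),
    total_mb = sum(bins$end - bins$start) / 1e6
  )
  class(layout) <- "genome_layout"
  layout
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %d chromosomes, %d bins of %s bp (%.1f Mb total)\n",
              nrow(x$chromosomes), x$n_bins,
              format(x$bin_size, big.mark = ","), x$total_mb))
  invisible(x)
}

# integer chromosome index (into layout$chromosomes) for each bin
bin_chrom_index <- function(layout) {
  match(layout$bins$chromosome, layout$chromosomes$chromosome)
}

# list of bin-index vectors, one per chromosome, in layout order
chrom_bin_list <- function(layout) {
  split(seq_len(layout$n_bins), factor(layout$bins$chromosome,
                                       levels = layout$chromosomes$chromosome))
}

#' Map a genomic region to bin indices
#'
#' Returns the (1-based) indices of every layout bin overlapping the region,
#' using 0-based half-open coordinates on both sides. Overlap of a single bp
#' is sufficient.
#'
#' @param layout a [build_layout()] object.
#' @param chromosome chromosome name.
#' @param start,end region boundaries in bp, 0-based half-open
#'   (`0 <= start < end <= chromosome length`).
#' @return Integer vector of contiguous bin indices.
#' @examples
#' layout <- build_layout(c(chr1 = 10e6), 1e6)
#' region_to_bins(layout, "chr1", 0, 1)         # first bin only
#' region_to_bins(layout, "chr1", 0.5e6, 1.5e6) # spans bins 1 and 2
#' @export
region_to_bins <- function(layout, chromosome, start, end) {
  ci <- match(chromosome, layout$chromosomes$chromosome)
  if (is.na(ci)) stop("unknown chromosome: ", chromosome)
  len <- layout$chromosomes$length[ci]
  if (!is.finite(start) || !is.finite(end) || start < 0 || end > len || start >= end)
    stop(sprintf("invalid region %s:%s-%s (chromosome length %s)",
                 chromosome, format(start), format(end), format(len)))
  on_chrom <- which(layout$bins$chromosome == chromosome)
  b <- layout$bins[on_chrom, ]
  on_chrom[b$start < end & b$end > start]
}

#' Bin labels of a layout
#'
#' `"chrom:start-end"` strings (0-based half-open), used as column names of
#' copy-number and count matrices.
#' @param layout a [build_layout()] object.
#' @return Character vector of length `layout$n_bins`.
#' @export
bin_labels <- function(layout) {
  sprintf("%s:%d-%d", layout$bins$chromosome,
          as.integer(layout$bins$start), as.integer(layout$bins$end))
}

# hg38 primary-assembly chromosome lengths, chr1-22 + X (no Y: the bundled
# founder models a female-derived line)
hg38_chrom_lengths <- c(
  chr1 = 248956422, chr2 = 242193529, chr3 = 198295559, chr4 = 190214555,
  chr5 = 181538259, chr6 = 170805979, chr7 = 159345973, chr8 = 145138636,
  chr9 = 138394717, chr10 = 133797422, chr11 = 135086622, chr12 = 133275309,
  chr13 = 114364328, chr14 = 107043718, chr15 = 101991189, chr16 = 90338345,
  chr17 = 83257441, chr18 = 80373285, chr19 = 58617616, chr20 = 64444167,
  chr21 = 46709983, chr22 = 50818468, chrX = 156040895
)

#' Bundled hg38 layout (chromosomes 1-22 and X)
#'
#' hg38 primary-assembly chromosome lengths binned at `bin_size`. Chromosome Y
#' is omitted: the bundled founder karyotypes model a female-derived epithelial
#' line.
#' @param bin_size bin width in bp (default 1 Mb).
#' @return A [build_layout()] object.
#' @export
layout_hg38 <- function(bin_size = 1e6) build_layout(hg38_chrom_lengths, bin_size)

#' Tiny toy layout for examples and hand-checked tests
#'
#' Three 10-Mb chromosomes at 1-Mb bins (30 bins).
#' @return A [build_layout()] object.
#' @export
layout_toy <- function() {
  build_layout(c(chrA = 10e6, chrB = 10e6, chrC = 10e6), 1e6)
}

#' Read / write a layout chromosome table
#'
#' The on-disk form is a two-column TSV (`chromosome`, `length`).
#' @param path file path.
#' @param bin_size bin width passed to [build_layout()].
#' @return `read_layout()` returns a [build_layout()] object.
#' @export
read_layout <- function(path, bin_size = 1e6) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chromosome", "length") %in% names(tab)))
    stop("layout file must have columns 'chromosome' and 'length': ", path)
  build_layout(tab[, c("chromosome", "length")], bin_size)
}

#' @rdname read_layout
#' @param layout a [build_layout()] object.
#' @export
write_layout <- function(layout, path) {
  utils::write.table(layout$chromosomes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export layout bins as BED3
#'
#' @param layout a [build_layout()] object.
#' @param path output file path.
#' @export
write_bins_bed <- function(layout, path) {
  bed <- data.frame(chrom = layout$bins$chromosome,
                    start = as.integer(layout$bins$start),
                    end = as.integer(layout$bins$end))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
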