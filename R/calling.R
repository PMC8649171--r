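#' Normalize binned read counts to copy-number ratios
#'
#' Divides counts by the per-bin GC bias factor and rescales so the
#' genome-wide median ratio equals 1 (i.e. one unit corresponds to the cell's
#' median copy signal; the absolute scale is resolved later by
#' [fit_ploidy_scale()]).
#'
#' @param counts integer count vector for one cell.
#' @param gc_factor positive per-bin bias factors, recycled (default 1).
#' @return Numeric ratio vector, median 1.
#' @export
normalize_counts <- function(counts, gc_factor = 1) {
  if (all(counts == 0)) stop("all-zero counts: cannot normalize")
  r <- counts / rep_len(gc_factor, length(counts))
  med <- stats::median(r)
  if (med <= 0) stop("median normalized signal is zero; profile too sparse")
  r / med
}

# best binary split of x: returns list(k, reduction) where k is the last index
# of the left part; reduction is the drop in within-segment SSE. cumsum-based.
best_split <- function(x, min_seg) {
  n <- length(x)
  if (n < 2L * min_seg) return(NULL)
  cs <- cumsum(x)
  tot <- cs[n]
  ks <- min_seg:(n - min_seg)
  # SSE reduction = S1^2/k + S2^2/(n-k) - S^2/n  (variance about segment means)
  red <- cs[ks]^2 / ks + (tot - cs[ks])^2 / (n - ks) - tot^2 / n
  i <- which.max(red)                      # ties: first (lowest) breakpoint
  list(k = ks[i], reduction = red[i])
}

#' Segment a normalized profile by recursive binary splitting
#'
#' Within each chromosome, the bin boundary maximizing the reduction in
#' within-segment sum of squared deviations is found recursively; a split is
#' accepted only if the reduction exceeds `gain_threshold` times the
#' chromosome's total sum of squares about its mean and both sides have at
#' least `min_seg` bins. Breakpoints never cross chromosome boundaries, so
#' segments partition the genome. Deterministic (ties to the lowest
#' breakpoint).
#'
#' @param normalized ratio vector from [normalize_counts()].
#' @param layout the profile's [build_layout()].
#' @param min_seg minimum segment length in bins (default 3).
#' @param gain_threshold fraction of the chromosome's total variance a split
#'   must explain to be accepted (default 0.1).
#' @return Object of class `segmented_profile`: a data.frame with one row per
#'   segment (`chromosome`, `start_bin`, `end_bin` 1-based inclusive global
#'   bin indices, `start`, `end` in bp, `n_bins`, `median_ratio`).
#' @export
segment_bins <- function(normalized, layout, min_seg = 3, gain_threshold = 0.1) {
  if (min_seg < 1) stop("min_seg must be >= 1")
  if (length(normalized) != layout$n_bins)
    stop("profile length does not match layout bin count")
  cbl <- chrom_bin_list(layout)

  segs <- list()
  for (ci in seq_along(cbl)) {
    idx <- cbl[[ci]]
    x <- normalized[idx]
    thr <- gain_threshold * sum((x - mean(x))^2)
    # recursive splitting over (lo, hi) local indices
    stack <- list(c(1L, length(x)))
    bounds <- integer(0)
    while (length(stack) > 0L) {
      rng <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      sp <- best_split(x[rng[1L]:rng[2L]], min_seg)
      if (!is.null(sp) && sp$reduction > thr && sp$reduction > 0) {
        cut <- rng[1L] + sp$k - 1L
        bounds <- c(bounds, cut)
        stack <- c(stack, list(c(rng[1L], cut)), list(c(cut + 1L, rng[2L])))
      }
    }
    starts <- c(1L, sort(bounds) + 1L)
    ends <- c(sort(bounds), length(x))
    for (s in seq_along(starts)) {
      loc <- starts[s]:ends[s]
      segs[[length(segs) + 1L]] <- data.frame(
        chromosome = layout$chromosomes$chromosome[ci],
        start_bin = idx[starts[s]], end_bin = idx[ends[s]],
        start = layout$bins$start[idx[starts[s]]],
        end = layout$bins$end[idx[ends[s]]],
        n_bins = length(loc),
        median_ratio = stats::median(x[loc]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  class(out) <- c("segmented_profile", "data.frame")
  out
}

#' Fit the ploidy scale of a segmented profile
#'
#' Finds the multiplicative scale `s` that maps median-1 ratios onto integer
#' copy-number states: `s` minimizes the length-weighted distance of scaled
#' segment medians to the nearest integers, subject to the scaled overall
#' median rounding to one of the candidate base ploidies. Ties are broken
#' toward the lower ploidy. When cells were flow-sorted before sequencing,
#' restrict the candidates via `ploidy_gate` (2c: `{1,2,3}`; 4c: `{3,4,5}`).
#'
#' @param segmented a [segment_bins()] result.
#' @param candidate_ploidies integer base-ploidy candidates (default 1:8).
#' @param ploidy_gate `"none"`, `"2c"` or `"4c"`; overrides
#'   `candidate_ploidies` when not `"none"`.
#' @param step scale-grid resolution (default 0.001).
#' @return List with `scale`, `base_ploidy` and `fit_error` (the minimized
#'   weighted distance).
#' @export
fit_ploidy_scale <- function(segmented, candidate_ploidies = 1:8,
                             ploidy_gate = c("none", "2c", "4c"),
                             step = 0.001) {
  ploidy_gate <- match.arg(ploidy_gate)
  if (ploidy_gate == "2c") candidate_ploidies <- 1:3
  if (ploidy_gate == "4c") candidate_ploidies <- 3:5
  if (length(candidate_ploidies) == 0) stop("candidate ploidy grid is empty")
  med <- segmented$median_ratio
  w <- segmented$n_bins
  if (all(med == 0)) stop("degenerate all-zero segmentation")
  # overall median copy signal = length-weighted median of segment medians
  om <- weighted_median(med, w)
  if (om <= 0) stop("degenerate segmentation: overall median is zero")

  best <- NULL
  for (p in sort(unique(as.integer(candidate_ploidies)))) {
    s_lo <- (p - 0.5) / om
    s_hi <- (p + 0.5) / om
    s_grid <- seq(max(step, s_lo), s_hi - step / 2, by = step)
    if (length(s_grid) == 0L) next
    sm <- outer(s_grid, med)                       # scaled medians
    err <- as.vector(abs(sm - round(sm)) %*% w)
    i <- which.min(err)
    # strict improvement only: equal-error candidates resolve to lower ploidy
    if (is.null(best) || err[i] < best$fit_error - 1e-12) {
      best <- list(scale = s_grid[i], base_ploidy = p, fit_error = err[i])
    }
  }
  if (is.null(best)) stop("no admissible scale for the candidate ploidies")
  best
}

weighted_median <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= 0.5)[1L]]
}

#' Call integer copy-number states from a segmentation
#'
#' Each bin's state is its segment's scaled median rounded half-up, clipped
#' to `[0, max_copy]`.
#'
#' @param segmented a [segment_bins()] result.
#' @param scale ploidy scale `s` (see [fit_ploidy_scale()]).
#' @param layout the profile's [build_layout()].
#' @param max_copy upper clip (default 8).
#' @return Integer profile of length `layout$n_bins`.
#' @export
call_states <- function(segmented, scale, layout, max_copy = 8) {
  if (scale <= 0) stop("scale must be > 0")
  states <- integer(layout$n_bins)
  seg_state <- pmin(pmax(floor(scale * segmented$median_ratio + 0.5), 0), max_copy)
  for (i in seq_len(nrow(segmented)))
    states[segmented$start_bin[i]:segmented$end_bin[i]] <- seg_state[i]
  names(states) <- bin_labels(layout)
  states
}

#' Call copy-number profiles for a population of cells
#'
#' End-to-end caller: [normalize_counts()] then [segment_bins()],
#' [fit_ploidy_scale()] and [call_states()] per cell.
#'
#' @param counts integer count matrix, cells x bins.
#' @param layout the [build_layout()] the counts were binned on.
#' @param gc_factor per-bin bias factors assumed known (default 1).
#' @param min_seg,gain_threshold segmentation controls, see [segment_bins()].
#' @param ploidy_gate `"none"`, `"2c"` or `"4c"`, a single value or one per
#'   cell (sort gate of each cell).
#' @param max_copy state cap (default 8).
#' @return Object of class `cn_calls`: list with `profiles` (integer matrix,
#'   same shape as `counts`), `segments` (list of [segment_bins()] frames),
#'   `base_ploidy` and `scale` (per-cell vectors).
#' @export
call_cells <- function(counts, layout, gc_factor = 1, min_seg = 3,
                       gain_threshold = 0.1, ploidy_gate = "none",
                       max_copy = 8) {
  n <- nrow(counts)
  gates <- rep_len(ploidy_gate, n)
  profiles <- matrix(0L, n, ncol(counts), dimnames = dimnames(counts))
  segments <- vector("list", n)
  base_ploidy <- integer(n)
  scale <- numeric(n)
  for (i in seq_len(n)) {
    r <- normalize_counts(counts[i, ], gc_factor)
    seg <- segment_bins(r, layout, min_seg = min_seg,
                        gain_threshold = gain_threshold)
    fit <- fit_ploidy_scale(seg, ploidy_gate = gates[i])
    profiles[i, ] <- call_states(seg, fit$scale, layout, max_copy = max_copy)
    segments[[i]] <- seg
    base_ploidy[i] <- fit$base_ploidy
    scale[i] <- fit$scale
  }
  structure(list(profiles = profiles, segments = segments,
                 base_ploidy = base_ploidy, scale = scale),
            class = "cn_calls")
}

#' @export
print.cn_calls <- function(x, ...) {
  cat(sprintf("cn_calls: %d cells x %d bins; base ploidies: %s\n",
              nrow(x$profiles), ncol(x$profiles),
              paste(names(table(x$base_ploidy)), table(x$base_ploidy),
                    sep = "x", collapse = ", ")))
  invisible(x)
}
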