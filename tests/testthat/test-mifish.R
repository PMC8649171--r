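test_that("the bundled panel has 20 loci in four groups of five", {
  panel <- mifish_panel()
  expect_equal(nrow(panel), 20L)
  expect_equal(as.vector(table(panel$group)), rep(5L, 4))
  expect_true("CCP10" %in% panel$probe)
  expect_equal(panel$cytoband[panel$probe == "RB1"], "13q14.2")
})

test_that("panel files round-trip and malformed panels are rejected", {
  panel <- mifish_panel()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel(panel, path)
  expect_equal(load_panel(path), panel)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("probe\tcytoband\tchromosome\tposition\tgroup", empty)
  expect_error(load_panel(empty), "empty")

  dup <- withr::local_tempfile(fileext = ".tsv")
  df <- rbind(panel, panel[1, ])
  write.table(df, dup, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_panel(dup), "duplicate")
})

test_that("probes off the layout raise a named error", {
  tiny <- layout_toy()
  expect_error(simulate_mifish(founder_profile(tiny, 2), mifish_panel(), tiny),
               "off-layout")
})

fne1_cell <- function() {
  panel <- mifish_panel()
  counts <- setNames(rep(2L, 20), panel$probe)
  counts["CDKN2A"] <- 1L
  counts
}

test_that("per-cell ploidy classes follow the modal count", {
  expect_equal(estimate_cell_ploidy(fne1_cell()), "2c")
  pb3m <- setNames(rep(4L, 20), mifish_panel()$probe)
  pb3m["TP53"] <- 3L
  expect_equal(estimate_cell_ploidy(pb3m), "4c")
  expect_equal(estimate_cell_ploidy(rep(3L, 20)), "other")
  # tie between 2 and 4 resolves to the lower mode -> 2c
  expect_equal(estimate_cell_ploidy(c(rep(2L, 10), rep(4L, 10))), "2c")
})

test_that("gain/loss scoring matches elementwise comparison", {
  s <- score_mifish_cell(fne1_cell(), 2)
  expect_equal(unname(s[names(s) == "CDKN2A"]), "loss")
  expect_true(all(s[names(s) != "CDKN2A"] == "neutral"))
  expect_true(all(score_mifish_cell(rep(2L, 20), 2) == "neutral"))

  set.seed(12)
  for (i in 1:20) {
    counts <- sample(0:6, 20, replace = TRUE)
    ref <- sample(1:4, 20, replace = TRUE)
    s <- score_mifish_cell(counts, ref)
    oracle <- character(20)
    for (p in 1:20) oracle[p] <- if (counts[p] < ref[p]) "loss"
      else if (counts[p] > ref[p]) "gain" else "neutral"
    expect_equal(unname(s), oracle)
  }
})

test_that("noise filtering flags minor deviations without changing clonality", {
  base <- fne1_cell()
  cells <- matrix(rep(base, each = 100), nrow = 100,
                  dimnames = list(NULL, names(base)))
  # seven cells deviate at 1-2 loci (within miFISH technical error)
  set.seed(66)
  for (i in 1:7) {
    loci <- sample(20, sample(1:2, 1))
    cells[i, loci] <- cells[i, loci] + sample(c(-1L, 1L), length(loci),
                                              replace = TRUE)
  }
  nf <- filter_noise(cells, noise_max = 2)
  expect_equal(sum(nf$flagged), 7L)
  expect_equal(nf$modal_pattern, base)
  # clonality statistics are computed from the modal-substituted patterns
  clon <- classify_clonality(cells, reference = 2)
  expect_equal(clon$status[clon$probe == "CDKN2A"], "clonal_loss")
  expect_true(all(clon$status[clon$probe != "CDKN2A"] == "neutral"))

  expect_equal(sum(filter_noise(cells, noise_max = 0)$flagged), 0L)

  # flag set agrees with brute-force deviation counting
  ndev <- apply(cells, 1, function(x) sum(x != base))
  expect_equal(unname(nf$flagged), ndev >= 1 & ndev <= 2)
})

test_that("clonality thresholds separate clonal, subclonal and singleton events", {
  base <- fne1_cell()
  cells <- matrix(rep(base, each = 100), nrow = 100,
                  dimnames = list(NULL, names(base)))
  cells[1:30, "MYC"] <- 3L       # subclonal gain (30%)
  cells[5, "PTEN"] <- 1L         # singleton: not reported
  clon <- classify_clonality(cells, reference = 2, noise_max = 0)
  expect_equal(clon$status[clon$probe == "CDKN2A"], "clonal_loss")
  expect_equal(clon$status[clon$probe == "MYC"], "subclonal_gain")
  expect_equal(clon$status[clon$probe == "PTEN"], "neutral")

  # PB2M-like: COX2 and RB1 lost in every cell alongside CDKN2A
  pb2 <- cells
  pb2[, "COX2"] <- 1L; pb2[, "RB1"] <- 1L
  clon2 <- classify_clonality(pb2, reference = 2, noise_max = 0)
  clonal_losses <- clon2$probe[clon2$status == "clonal_loss"]
  expect_setequal(clonal_losses, c("CDKN2A", "COX2", "RB1"))
})

test_that("clone enumeration is deterministic and conserves cell counts", {
  base <- fne1_cell()
  cells <- matrix(rep(base, each = 5), nrow = 5,
                  dimnames = list(NULL, names(base)))
  expect_equal(nrow(enumerate_clones(cells[1:3, ])), 1L)
  cells[2, "MYC"] <- 3L
  cells[3, "MYC"] <- 3L
  cells[4, "PTEN"] <- 1L
  clones <- enumerate_clones(cells)
  expect_equal(nrow(clones), 3L)
  expect_equal(clones$frequency, c(2L, 2L, 1L))
  expect_equal(sum(clones$frequency), 5L)

  set.seed(90)
  big <- matrix(sample(1:3, 1000 * 20, replace = TRUE), nrow = 1000,
                dimnames = list(NULL, names(base)))
  clones_big <- enumerate_clones(big)
  # independent set-count oracle
  expect_equal(nrow(clones_big), length(unique(apply(big, 1, paste,
                                                     collapse = "-"))))
  expect_equal(sum(clones_big$frequency), 1000L)
})

test_that("clonality calls are invariant to cell order", {
  base <- fne1_cell()
  cells <- matrix(rep(base, each = 50), nrow = 50,
                  dimnames = list(NULL, names(base)))
  cells[1:20, "MYC"] <- 3L
  perm <- sample(50)
  expect_equal(classify_clonality(cells[perm, ]), classify_clonality(cells))
})

test_that("zero-error simulation round-trips through scoring against the founder", {
  preset <- cin_preset("pb3")
  lay <- preset$layout
  panel <- mifish_panel()
  profile <- apply_wgd(preset$founder)
  counts <- simulate_mifish(profile, panel, lay, error_rate = 0)
  ref <- simulate_mifish(founder_profile(lay, 2), panel, lay, error_rate = 0)
  s <- score_mifish_cell(counts[1, ], ref[1, ])
  pb <- probe_bins_for_test(panel, lay)
  truth <- ifelse(profile[pb] < 2, "loss", ifelse(profile[pb] > 2, "gain",
                                                  "neutral"))
  expect_equal(unname(s), unname(truth))
})

test_that("the full sample report summarizes a mixed population coherently", {
  base <- fne1_cell()
  dip <- matrix(rep(base, each = 60), nrow = 60,
                dimnames = list(NULL, names(base)))
  tet <- matrix(rep(2L * base, each = 40), nrow = 40,
                dimnames = list(NULL, names(base)))
  rep <- mifish_report(rbind(dip, tet), mifish_panel())
  expect_equal(rep$n_cells, 100L)
  expect_equal(unname(rep$ploidy_table["2c"]), 60L)
  expect_equal(unname(rep$ploidy_table["4c"]), 40L)
  expect_equal(sum(rep$clones$frequency), 100L)
  # against the diploid reference the loss is confined to the 2c fraction:
  # the tetraploid cells show two CDKN2A copies, so the call is subclonal
  cdkn2a <- rep$clonality[rep$clonality$probe == "CDKN2A", ]
  expect_equal(cdkn2a$loss_fraction, 0.6)
  expect_equal(cdkn2a$status, "subclonal_loss")
})
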