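test_that("with all rates zero every cell equals the founder", {
  f <- founder_profile(toy3, 2, data.frame(chromosome = "chrB", start = 0,
                                           end = 10e6, delta = -1))
  params <- cin_params(generations = 8, carrying_capacity = 60,
                       sample_size = 20)
  pop <- simulate_population(f, params, toy3, seed = 7)
  expect_true(all(apply(pop, 1, function(x) all(x == f))))
})

test_that("the parental founder consensus carries monosomies at 9p, 15 and X", {
  preset <- cin_preset("fne1")
  lay <- preset$layout
  pop <- simulate_population(preset$founder, preset$params, lay, seed = 5)
  cons <- consensus_profile(pop)
  mono <- c(region_to_bins(lay, "chr9", 0, 43e6),
            region_to_bins(lay, "chr15", 0,
                           lay$chromosomes$length[lay$chromosomes$chromosome == "chr15"]),
            region_to_bins(lay, "chrX", 0,
                           lay$chromosomes$length[lay$chromosomes$chromosome == "chrX"]))
  expect_true(all(cons[mono] == 1L))
  expect_true(all(cons[-mono] == 2L))
})

test_that("mis-segregation is reciprocal and conserves per-bin copy sums", {
  parent <- founder_profile(toy3, 2)
  d <- apply_missegregation(parent, toy3, "chrA", 1)
  idx <- which(toy3$bins$chromosome == "chrA")
  expect_true(all(d$a[idx] == 3L) && all(d$b[idx] == 1L))
  expect_equal(d$a[-idx], parent[-idx])

  # monosomic chromosome: daughters go disomic / nullisomic
  f <- founder_profile(toy3, 2, data.frame(chromosome = "chrB", start = 0,
                                           end = 10e6, delta = -1))
  d2 <- apply_missegregation(f, toy3, "chrB", -1)
  idxB <- which(toy3$bins$chromosome == "chrB")
  expect_true(all(d2$a[idxB] == 0L) && all(d2$b[idxB] == 2L))
  # nullisomic chromosome cannot mis-segregate
  expect_error(apply_missegregation(d2$a, toy3, "chrB"), "nullisomic")

  set.seed(99)
  for (i in 1:1000) {
    parent <- sample(1:6, toy3$n_bins, replace = TRUE)
    names(parent) <- bin_labels(toy3)
    chrom <- sample(toy3$chromosomes$chromosome, 1)
    d <- apply_missegregation(parent, toy3, chrom, sample(c(1, -1), 1))
    expect_equal(d$a + d$b, 2L * as.integer(parent), ignore_attr = TRUE)
  }
})

test_that("WGD doubles every bin; monosomies become disomies; twice WGD is octoploid", {
  f <- founder_profile(toy3, 2, data.frame(chromosome = "chrB", start = 0,
                                           end = 4e6, delta = -1))
  t1 <- apply_wgd(f)
  expect_equal(as.vector(t1), as.vector(2L * f))
  idx <- region_to_bins(toy3, "chrB", 0, 4e6)
  expect_true(all(t1[idx] == 2L))       # pre-WGD monosomy -> disomy
  expect_true(all(t1[-idx] == 4L))
  expect_true(all(apply_wgd(apply_wgd(founder_profile(toy3, 2))) == 8L))
})

test_that("identical seeds give bit-identical populations, different seeds differ", {
  preset <- cin_preset("p1")
  a <- simulate_population(preset$founder, preset$params, preset$layout, seed = 21)
  b <- simulate_population(preset$founder, preset$params, preset$layout, seed = 21)
  expect_identical(a, b)
  c <- simulate_population(preset$founder, preset$params, preset$layout, seed = 22)
  expect_false(identical(a, c))
})

test_that("extinction is reported by name", {
  f <- founder_profile(toy3, 2)
  # every division is a WGD; the copy cap kills all tetraploid daughters
  params <- cin_params(p_wgd = 1, max_copy = 3, generations = 3,
                       carrying_capacity = 10, sample_size = 2)
  expect_error(simulate_population(f, params, toy3, seed = 1), "extinct")
})

test_that("population deviation fraction matches an independent lineage oracle", {
  # one lineage = g divisions; each division each chromosome mis-segregates
  # with p_mis. The oracle tracks whole-chromosome copies directly, with no
  # viability filtering; the population run disables lethality to match.
  # Cells inside one population share ancestry, so the deviating fraction of
  # a single run is a noisy estimate; average over independent replicate
  # runs and use the empirical between-run spread.
  p_mis <- 0.01; g <- 10
  f <- founder_profile(toy3, 2)
  params <- cin_params(p_mis = p_mis, generations = g,
                       carrying_capacity = 50, sample_size = 20,
                       nullisomy_lethal = FALSE, max_copy = 64)
  fracs <- vapply(1:100, function(s) {
    pop <- simulate_population(f, params, toy3, seed = 3000 + s)
    mean(apply(pop, 1, function(x) any(x != f)))
  }, numeric(1))
  frac_sim <- mean(fracs)
  se_sim <- stats::sd(fracs) / sqrt(length(fracs))

  set.seed(131)
  n_rep <- 10000
  copies <- matrix(2L, n_rep, 3)  # per-chromosome copy counts, one row per lineage
  for (div in seq_len(g)) {
    for (chrom in 1:3) {
      hit <- runif(n_rep) < p_mis
      can <- copies[, chrom] >= 1L
      delta <- ifelse(hit & can, sample(c(1L, -1L), n_rep, replace = TRUE), 0L)
      copies[, chrom] <- copies[, chrom] + delta
    }
  }
  frac_oracle <- mean(apply(copies, 1, function(x) any(x != 2L)))
  se <- se_sim + sqrt(frac_oracle * (1 - frac_oracle) / n_rep)
  expect_lt(abs(frac_sim - frac_oracle), 3 * se + 1e-9)
})

test_that("read counts follow the stated mean and scale linearly with copy number", {
  f2 <- founder_profile(toy3, 2)
  # Poisson limit: empirical mean within 3 s.e. of d * CN * gc
  d <- 50; gc <- 1.2
  m <- count_model(mean_reads_per_copy = d, dispersion = Inf, gc_factor = gc)
  counts <- simulate_read_counts(matrix(2L, 1000, 30), m, seed = 8)
  mu <- 2 * d * gc
  se <- sqrt(mu / length(counts))
  expect_lt(abs(mean(counts) - mu), 3 * se)

  # zero copies, zero background -> always zero
  m0 <- count_model(dispersion = 10)
  expect_true(all(simulate_read_counts(rep(0L, 30), m0, seed = 9) == 0L))

  # doubling CN doubles the empirical mean (paired seeds)
  mnb <- count_model(mean_reads_per_copy = 20, dispersion = 5)
  c2 <- simulate_read_counts(matrix(2L, 1000, 30), mnb, seed = 10)
  c4 <- simulate_read_counts(matrix(4L, 1000, 30), mnb, seed = 10)
  expect_lt(abs(mean(c4) / mean(c2) - 2), 0.05)
})

test_that("miFISH simulation reports founder states exactly at zero error", {
  preset <- cin_preset("fne1")
  counts <- simulate_mifish(preset$founder, mifish_panel(), preset$layout,
                            error_rate = 0)
  expect_equal(unname(counts[1, "CDKN2A"]), 1L)  # 9p monosomy covers CDKN2A
  gene_probes <- setdiff(colnames(counts), "CDKN2A")
  expect_true(all(counts[1, gene_probes] == 2L))

  tet <- apply_wgd(founder_profile(preset$layout, 2))
  ct <- simulate_mifish(tet, mifish_panel(), preset$layout, error_rate = 0)
  expect_true(all(ct == 4L))
})

test_that("miFISH error rate matches a binomial oracle", {
  lay <- layout_hg38()
  flat <- founder_profile(lay, 2)
  pop <- matrix(rep(flat, each = 10000), nrow = 10000)
  colnames(pop) <- bin_labels(lay)
  counts <- simulate_mifish(pop, mifish_panel(), lay, error_rate = 0.05,
                            seed = 77)
  dev_freq <- colMeans(counts != 2L)
  se <- sqrt(0.05 * 0.95 / 10000)
  expect_true(all(abs(dev_freq - 0.05) < 3.5 * se))
})

test_that("DNA content encodes ploidy and G2 doubling", {
  dip <- matrix(2L, 20, 30)
  expect_true(all(simulate_dna_content(dip, cv = 0, g2_fraction = 0) == 1.0))
  tet <- matrix(4L, 20, 30)
  expect_true(all(simulate_dna_content(tet, cv = 0, g2_fraction = 0) == 2.0))
  v <- simulate_dna_content(matrix(4L, 2000, 10), cv = 0, g2_fraction = 0.3,
                            seed = 14)
  expect_lt(abs(mean(v == 4.0) - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))
  expect_true(all(v %in% c(2.0, 4.0)))
})

test_that("DNA-content gates select the intended ploidy fraction", {
  mix <- rbind(matrix(2L, 30, 30), matrix(4L, 20, 30))
  v <- simulate_dna_content(mix, cv = 0.03, g2_fraction = 0, seed = 4)
  expect_equal(sum(gate_dna_content(v, "2c")), 30)
  expect_equal(sum(gate_dna_content(v, "4c")), 20)
  expect_true(all(gate_dna_content(v, "none")))
})
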