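test_that("proportion of polymorphic SNPs uses a strict MAF cutoff", {
  freqs <- tibble::tibble(
    population = "a",
    p = c(0.5, 0.005, 0.0),
    maf = pmin(p, 1 - p)
  )
  expect_equal(prop_polymorphic(freqs)$pn, 1 / 3)

  mono <- dplyr::mutate(freqs, p = 0, maf = 0)
  expect_equal(prop_polymorphic(mono)$pn, 0)
  all_poly <- dplyr::mutate(freqs, p = 0.5, maf = 0.5)
  expect_equal(prop_polymorphic(all_poly)$pn, 1)

  expect_error(prop_polymorphic(dplyr::mutate(freqs, p = NA_real_)),
               "no sites")
})

test_that("observed heterozygosity is per-sample het fraction with sample SD", {
  g <- make_geno(rbind(c(1L, 1L, 0L, 2L),
                       c(0L, 0L, 2L, 2L)))
  ho <- observed_heterozygosity(g)
  expect_equal(ho$ho, c(0.5, 0))

  # population mean +- SD over samples {0.2, 0.4}
  g2 <- make_geno(rbind(c(1L, 0L, 0L, 0L, 0L),
                        c(1L, 1L, 0L, 0L, 0L)))
  pops <- tibble::tibble(sample = c("s1", "s2"), population = "a")
  summ <- diversity_summary(g2, pops, step = 1e5)
  expect_equal(summ$ho_mean, 0.3)
  expect_equal(summ$ho_sd, sd(c(0.2, 0.4)))

  # all-missing sample flagged, excluded from the mean
  g3 <- make_geno(rbind(c(1L, 1L), c(NA_integer_, NA_integer_)))
  ho3 <- observed_heterozygosity(g3)
  expect_true(is.na(ho3$ho[2]))
})

test_that("expected heterozygosity averages 2p(1-p) over variable sites", {
  freqs <- tibble::tibble(population = "a", p = 0.5, maf = 0.5)
  expect_equal(expected_heterozygosity(freqs)$he_mean, 0.5)

  freqs2 <- tibble::tibble(population = "a", p = c(0.5, 0.1),
                           maf = pmin(p, 1 - p))
  expect_equal(expected_heterozygosity(freqs2)$he_mean, mean(c(0.5, 0.18)))

  fixed <- tibble::tibble(population = "a", p = c(0, 1), maf = 0)
  expect_error(expected_heterozygosity(fixed), "no variable sites")
})

test_that("windowed pi matches the pairwise-difference oracle and is additive", {
  # one site, 2 diploid samples (4 alleles), p = 0.5
  g <- make_geno(rbind(1L, 1L), pos = 500)
  pops <- tibble::tibble(sample = c("s1", "s2"), population = "a")
  w <- nucleotide_diversity_windows(g, pops, "a")
  # oracle: 2 ref + 2 alt alleles -> 4 differing pairs of 6 -> 2/3 per site
  alleles <- c(0, 0, 1, 1)
  prs <- combn(4, 2)
  oracle_site_pi <- mean(alleles[prs[1, ]] != alleles[prs[2, ]])
  expect_equal(oracle_site_pi, 2 / 3)
  expect_equal(w$pi[w$n_snps == 1], oracle_site_pi / 1e5)
  expect_equal(w$pi[w$n_snps == 1], 6.666667e-06, tolerance = 1e-6)

  # empty windows emit zero
  g2 <- make_geno(rbind(c(1L, 1L), c(1L, 1L)), pos = c(500, 300500))
  w2 <- nucleotide_diversity_windows(g2, pops, "a")
  expect_true(any(w2$n_snps == 0))
  expect_equal(w2$pi[w2$n_snps == 0], rep(0, sum(w2$n_snps == 0)))

  # two identical sites double the single-site window value
  g3 <- make_geno(rbind(c(1L, 1L), c(1L, 1L)), pos = c(400, 600))
  w3 <- nucleotide_diversity_windows(g3, pops, "a")
  expect_equal(max(w3$pi), 2 * oracle_site_pi / 1e5)
})

test_that("site pi uses the unbiased n/(n-1) correction from called alleles", {
  # 3 samples, one missing -> 4 called alleles at the site
  g <- make_geno(rbind(1L, 1L, NA_integer_), pos = 100)
  pops <- tibble::tibble(sample = paste0("s", 1:3), population = "a")
  w <- nucleotide_diversity_windows(g, pops, "a")
  expect_equal(w$pi[1], (2 * 0.5 * 0.5 * 4 / 3) / 1e5)
})

test_that("IBS distance matches hand counts and the shared-allele oracle", {
  # identical genotypes -> DST = 1, D = 0
  g <- make_geno(rbind(c(0L, 1L, 2L), c(0L, 1L, 2L)))
  d <- pairwise_ibs_distance(g)
  expect_equal(d$dst, 1)
  expect_equal(d$d, 0)

  # opposite homozygotes -> DST = 0, D = 1
  g2 <- make_geno(rbind(c(0L, 0L), c(2L, 2L)))
  d2 <- pairwise_ibs_distance(g2)
  expect_equal(d2$d, 1)

  # N = 2: one IBS2 site, one IBS1 site
  g3 <- make_geno(rbind(c(0L, 0L), c(0L, 1L)))
  d3 <- pairwise_ibs_distance(g3)
  expect_equal(d3$dst, 0.75)
  expect_equal(d3$d, 0.25)

  # exhaustive oracle on random genotypes, including missing data
  withr::local_seed(3)
  calls <- matrix(sample(c(0L, 1L, 2L, NA), 4 * 200, replace = TRUE), nrow = 4)
  g4 <- make_geno(calls)
  d4 <- pairwise_ibs_distance(g4)
  for (k in seq_len(nrow(d4))) {
    o <- ibs_oracle_pair(calls[match(d4$sample1[k], g4$samples), ],
                         calls[match(d4$sample2[k], g4$samples), ])
    expect_equal(d4$ibs0[k], o$ibs0)
    expect_equal(d4$ibs1[k], o$ibs1)
    expect_equal(d4$ibs2[k], o$ibs2)
    expect_equal(d4$ibs0[k] + d4$ibs1[k] + d4$ibs2[k], d4$n[k])
  }
  m <- ibs_distance_matrix(d4)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 4))
})

test_that("diversity statistics respect their ranges on simulated data", {
  sim <- simulate_genotypes(sim_config(n_pops = 2L, samples_per_pop = 6L,
                                       chrom_lengths = c(chr1 = 2e6),
                                       n_snps = 4000L, seed = 5))
  summ <- diversity_summary(sim$genotypes, sim$pop_map)
  expect_true(all(summ$pn >= 0 & summ$pn <= 1))
  expect_true(all(summ$ho_mean >= 0 & summ$ho_mean <= 1))
  expect_true(all(summ$he_mean >= 0 & summ$he_mean <= 1))
  expect_true(all(summ$pi_mean >= 0))
  expect_true(all(summ$d_mean >= 0 & summ$d_mean <= 1))
})

test_that("mean He matches the genotype-count enumeration under weak drift", {
  # With a uniform ancestral frequency law and F -> 0, the population allele
  # count at a site is discrete-uniform on 0..2n, so the expected sample He
  # over polymorphic sites is mean over c = 1..2n-1 of 2 (c/2n)(1 - c/2n).
  n <- 10L
  cc <- 1:(2 * n - 1)
  analytic <- mean(2 * (cc / (2 * n)) * (1 - cc / (2 * n)))
  expect_equal(analytic, 0.35)  # closed form for 2n = 20

  sim <- simulate_genotypes(sim_config(
    n_pops = 1L, samples_per_pop = n, chrom_lengths = c(chr1 = 1e7),
    n_snps = 30000L, drift = 0.001, missing_rate = 0, seed = 9
  ))
  he <- expected_heterozygosity(allele_frequencies(sim$genotypes, sim$pop_map))
  expect_equal(he$he_mean, analytic, tolerance = 0.01)
})
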