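test_that("site FST matches hand arithmetic", {
  expect_equal(fst_site(0.5, 0.5), 0)
  expect_equal(fst_site(1, 0), 1)
  expect_equal(fst_site(0.8, 0.2), 0.36)
  expect_true(is.na(fst_site(0, 0)))  # pooled-fixed site undefined
  expect_true(is.na(fst_site(1, 1)))
})

test_that("site FST lies in [0, 1] over a dense frequency grid", {
  p <- seq(0, 1, by = 0.01)
  grid <- expand.grid(p1 = p, p2 = p)
  v <- fst_site(grid$p1, grid$p2)
  defined <- !is.na(v)
  expect_true(all(v[defined] >= 0 & v[defined] <= 1))
  # undefined exactly where the pooled frequency is fixed
  expect_equal(!defined, (grid$p1 + grid$p2) %in% c(0, 2))
})

test_that("window FST averages per-site values and enforces min_snps", {
  # two pops of 5 samples; three sites with exact frequencies
  co <- cohort_from_counts(
    list(a = c(8L, 5L, 10L), b = c(2L, 5L, 0L)),  # p1 = .8,.5,1; p2 = .2,.5,0
    n_samples = 5L
  )
  w <- fst_windows(co$g, co$pops, "a", "b", window = 1e5, step = 1e5,
                   min_snps = 1L)
  expect_equal(w$fst[1], mean(c(0.36, 0, 1)))
  expect_equal(w$n_snps[1], 3L)

  expect_error(fst_windows(co$g, co$pops, "a", "b", min_snps = 30L),
               "min_snps")
  expect_error(fst_windows(co$g, co$pops, "a", "a"), "must differ")
})

test_that("the ratio-of-sums dialect equals a direct Weir-Cockerham computation", {
  withr::local_seed(13)
  co <- cohort_from_counts(
    list(a = sample(0:10, 40, replace = TRUE),
         b = sample(0:10, 40, replace = TRUE)),
    n_samples = 5L
  )
  w <- fst_windows(co$g, co$pops, "a", "b", window = 1e5, step = 1e5,
                   min_snps = 1L, dialect = "wc")
  # independent per-site recomputation from first principles
  fr <- allele_frequencies(co$g, co$pops)
  a_sum <- 0; abc_sum <- 0
  for (i in seq_len(40)) {
    p1 <- fr$p[fr$population == "a"][i]; p2 <- fr$p[fr$population == "b"][i]
    het1 <- mean(co$g$calls[1:5, i] == 1); het2 <- mean(co$g$calls[6:10, i] == 1)
    n1 <- 5; n2 <- 5; r <- 2; nbar <- 5
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (p1 + p2) / 2
    if (pbar == 0 || pbar == 1) next
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (het1 + het2) / 2
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
    a_sum <- a_sum + a
    abc_sum <- abc_sum + a + b + hbar / 2
  }
  expect_equal(w$fst[1], a_sum / abc_sum)
})

test_that("pooled heterozygosity matches hand arithmetic and its bounds", {
  # 10 samples; minor-allele counts {2, 5, 8} of 20 alleles per site
  co <- cohort_from_counts(list(a = c(2L, 5L, 8L)), n_samples = 10L)
  w <- hp_windows(co$g, co$pops, "a", window = 1e5, step = 1e5)
  expect_equal(w$sum_maj[1], 18 + 15 + 12)
  expect_equal(w$sum_min[1], 2 + 5 + 8)
  expect_equal(w$hp[1], 2 * 45 * 15 / 60^2)
  expect_equal(w$hp[1], 0.375)

  # fixation -> 0; balanced -> 0.5 (iff equal sums)
  fix <- cohort_from_counts(list(a = c(0L, 0L)), n_samples = 10L)
  expect_equal(hp_windows(fix$g, fix$pops, "a")$hp[1], 0)
  bal <- cohort_from_counts(list(a = c(10L, 10L)), n_samples = 10L)
  expect_equal(hp_windows(bal$g, bal$pops, "a")$hp[1], 0.5)

  withr::local_seed(17)
  for (rep in 1:20) {
    co2 <- cohort_from_counts(list(a = sample(0:20, 30, replace = TRUE)),
                              n_samples = 10L)
    w2 <- hp_windows(co2$g, co2$pops, "a", window = 1e5, step = 1e5)
    expect_true(all(w2$hp >= 0 & w2$hp <= 0.5))
    expect_equal(w2$hp == 0.5, w2$sum_maj == w2$sum_min)
  }
})

test_that("planted sweeps depress Hp monotonically with sweep strength", {
  hp_in_sweep <- vapply(c(0.3, 0.1, 0.02), function(ceiling_maf) {
    cfg <- sim_config(
      n_pops = 2L, chrom_lengths = c(chr1 = 5e6), n_snps = 10000L,
      sweeps = tibble::tibble(population = "pop1", chrom = "chr1",
                              start = 2e6 + 1, end = 2.1e6,
                              max_maf = ceiling_maf),
      seed = 71
    )
    sim <- simulate_genotypes(cfg)
    w <- hp_windows(sim$genotypes, sim$pop_map, "pop1")
    mean(w$hp[w$start >= 2e6 - 5e4 & w$end <= 2.1e6 + 5e4])
  }, numeric(1))
  expect_true(all(diff(hp_in_sweep) < 0))
})

test_that("Z-scores center and scale a scan", {
  expect_equal(zscore(c(0, 1, 2)), c(-1, 0, 1))
  expect_error(zscore(rep(3, 5), label = "flat"), "flat")
  expect_error(zscore(1), "fewer than two")

  withr::local_seed(19)
  x <- rnorm(500)
  z <- zscore(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
})

test_that("outlier tail counts follow the ceiling rule", {
  expect_equal(outlier_count(100, 0.01), 1L)
  expect_equal(outlier_count(101, 0.01), 2L)
  expect_equal(outlier_count(300, 0.01), 3L)
})

test_that("intersected outlier windows merge into candidate regions", {
  # three consecutive 25-kb-step windows extreme in both scans
  grid <- tibble::tibble(
    chrom = "chr1",
    start = 1 + (0:399) * 25000,
    end = start + 1e5,
    n_snps = 50L
  )
  withr::local_seed(23)
  zf <- dplyr::mutate(grid, z = 0)
  zh <- dplyr::mutate(grid, z = 0)
  idx <- 101:103
  zf$z[idx] <- c(6, 7, 5)
  zh$z[idx] <- c(-6, -8, -5)
  zf$z[-idx] <- rnorm(397, sd = 0.1)
  zh$z[-idx] <- rnorm(397, sd = 0.1)
  cand <- call_outliers(zf, zh, tail = 0.01)  # 4 windows per tail
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$start, zf$start[101])
  expect_equal(cand$end, zf$end[103])
  expect_equal(cand$n_windows, 3L)
  expect_equal(cand$peak_zfst, 7)
  expect_equal(cand$trough_zhp, -8)

  # disjoint tails -> no candidates
  zh2 <- zh
  zh2$z <- rev(zh$z)
  cand2 <- call_outliers(zf, zh2, tail = 0.005)
  expect_equal(nrow(cand2), 0L)

  # differing grids intersect only on shared window identity
  zh3 <- zh[-101, ]
  cand3 <- call_outliers(zf, zh3, tail = 0.01)
  expect_equal(cand3$start, zf$start[102])
})

test_that("neutral scans almost never intersect at 0.1% tails", {
  zero_regions <- 0L
  for (s in 1:10) {
    cfg <- sim_config(n_pops = 2L, n_snps = 10000L, seed = 2000 + s)
    sim <- simulate_genotypes(cfg)
    zf <- zscore_windows(fst_windows(sim$genotypes, sim$pop_map,
                                     "pop1", "pop2"))
    zh <- zscore_windows(hp_windows(sim$genotypes, sim$pop_map, "pop1"))
    cand <- call_outliers(zf, zh, tail = 0.001)
    zero_regions <- zero_regions + (nrow(cand) == 0L)
  }
  expect_gte(zero_regions, 9L)
})
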