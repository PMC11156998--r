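#' Proportion of polymorphic SNPs (Pn)
#'
#' Fraction of sites with minor-allele frequency strictly greater than the
#' threshold, among sites where the population's frequency is defined.
#'
#' @param freqs Allele-frequency tibble from [allele_frequencies()].
#' @param maf_threshold Strict MAF cutoff (default 0.01).
#' @return A tibble per population: `n_sites` (defined sites),
#'   `n_polymorphic`, `pn`.
#' @export
prop_polymorphic <- function(freqs, maf_threshold = 0.01) {
  out <- freqs |>
    dplyr::filter(!is.na(.data$p)) |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      n_polymorphic = sum(.data$maf > maf_threshold),
      pn = .data$n_polymorphic / .data$n_sites,
      .groups = "drop"
    )
  if (nrow(out) == 0L) {
    stop("no sites with a defined allele frequency", call. = FALSE)
  }
  out
}

#' Observed heterozygosity per sample
#'
#' Proportion of heterozygous calls among non-missing calls in each genome.
#' Samples with no called genotype are flagged (`ho = NA`) and excluded from
#' population means by [diversity_summary()].
#'
#' @param g A [geno_matrix()].
#' @param pops Optional population map; adds a `population` column.
#' @return A tibble per sample: `n_called`, `n_het`, `ho`.
#' @export
observed_heterozygosity <- function(g, pops = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  n_called <- unname(rowSums(!is.na(g$calls)))
  n_het <- unname(rowSums(g$calls == 1L, na.rm = TRUE))
  out <- tibble::tibble(
    sample = g$samples,
    n_called = n_called,
    n_het = n_het,
    ho = ifelse(n_called > 0L, n_het / n_called, NA_real_)
  )
  if (!is.null(pops)) {
    out <- dplyr::left_join(out, tibble::as_tibble(pops), by = "sample") |>
      dplyr::relocate("population", .after = "sample")
  }
  out
}

#' Expected heterozygosity per population
#'
#' Site-wise expected heterozygosity 2p(1-p) from population allele
#' frequencies, averaged over sites polymorphic in that population. Errors if
#' a population has no variable site.
#'
#' @param freqs Allele-frequency tibble from [allele_frequencies()].
#' @return A tibble per population: `n_sites` (variable sites), `he_mean`,
#'   `he_sd` (sample SD over sites).
#' @export
expected_heterozygosity <- function(freqs) {
  out <- freqs |>
    dplyr::filter(!is.na(.data$p), .data$p > 0, .data$p < 1) |>
    dplyr::mutate(he = 2 * .data$p * (1 - .data$p)) |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      he_mean = mean(.data$he),
      he_sd = stats::sd(.data$he),
      .groups = "drop"
    )
  missing_pops <- setdiff(unique(freqs$population), out$population)
  if (length(missing_pops)) {
    stop("no variable sites for population(s): ",
         paste(missing_pops, collapse = ", "), call. = FALSE)
  }
  out
}

#' Windowed nucleotide diversity (pi)
#'
#' Sliding-window nucleotide diversity for one population: per site the
#' unbiased heterozygosity estimate `2p(1-p) * n/(n-1)` (n = called allele
#' count), summed per window and divided by the full window length in bp —
#' the VCFtools `--window-pi` convention, so monomorphic and unsequenced
#' positions dilute the per-bp value. Empty windows inside the scanned range
#' are emitted with `pi = 0`.
#'
#' @param g A [geno_matrix()].
#' @param pops Population map.
#' @param population Population label to scan.
#' @param window,step Window and step size in bp (defaults 100 kb / 50 kb).
#' @return A tibble per window: `chrom`, `start`, `end` (half-open bp),
#'   `n_snps`, `pi`.
#' @export
nucleotide_diversity_windows <- function(g, pops, population,
                                         window = 1e5, step = 5e4) {
  stopifnot(inherits(g, "geno_matrix"))
  ids <- pop_samples(g, pops, population)
  m <- g$calls[match(ids, g$samples), , drop = FALSE]
  n_called <- colSums(!is.na(m))
  n_alleles <- 2 * n_called
  p <- ifelse(n_called > 0L, colSums(m, na.rm = TRUE) / n_alleles, NA_real_)
  site_pi <- ifelse(
    n_alleles >= 2L & !is.na(p),
    2 * p * (1 - p) * n_alleles / (n_alleles - 1),
    0
  )

  v <- g$variants
  purrr::map_dfr(split(seq_len(nrow(v)), v$chrom), function(idx) {
    pos <- v$pos[idx]
    ws <- window_sums(pos, list(pi_sum = site_pi[idx]), window, step)
    grid <- tibble::tibble(win = window_grid_range(pos, window, step))
    dplyr::left_join(grid, ws, by = "win") |>
      dplyr::mutate(
        chrom = v$chrom[idx[1]],
        n_snps = dplyr::coalesce(.data$n_snps, 0L),
        pi = dplyr::coalesce(.data$pi_sum, 0) / window
      ) |>
      dplyr::bind_cols(window_bounds(grid$win, window, step)) |>
      dplyr::select("chrom", "start", "end", "n_snps", "pi")
  }) |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Pairwise identity-by-state distance
#'
#' For every unordered sample pair, counts loci sharing 0, 1 or 2 alleles
#' identical by state over mutually non-missing sites, the PLINK similarity
#' `DST = (IBS2 + 0.5 * IBS1) / N` and the distance `D = 1 - DST`. Pairs with
#' no co-called site are flagged (`dst = NA`).
#'
#' @param g A [geno_matrix()].
#' @param pops Optional population map; adds population columns and lets
#'   [diversity_summary()] average within-population distances.
#' @return A tibble per pair: `sample1`, `sample2`, `ibs0`, `ibs1`, `ibs2`,
#'   `n`, `dst`, `d`.
#' @export
pairwise_ibs_distance <- function(g, pops = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  ns <- n_samples(g)
  if (ns < 2L) stop("need at least two samples", call. = FALSE)
  pairs <- utils::combn(ns, 2L)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    a <- g$calls[i, ]; b <- g$calls[j, ]
    ok <- !is.na(a) & !is.na(b)
    dif <- abs(a[ok] - b[ok])
    n <- sum(ok)
    ibs2 <- sum(dif == 0L); ibs1 <- sum(dif == 1L); ibs0 <- sum(dif == 2L)
    dst <- if (n > 0L) (ibs2 + 0.5 * ibs1) / n else NA_real_
    tibble::tibble(
      sample1 = g$samples[i], sample2 = g$samples[j],
      ibs0 = ibs0, ibs1 = ibs1, ibs2 = ibs2, n = n,
      dst = dst, d = 1 - dst
    )
  })
  if (!is.null(pops)) {
    pm <- tibble::as_tibble(pops)
    res <- res |>
      dplyr::left_join(dplyr::rename(pm, sample1 = "sample", pop1 = "population"),
                       by = "sample1") |>
      dplyr::left_join(dplyr::rename(pm, sample2 = "sample", pop2 = "population"),
                       by = "sample2")
  }
  res
}

#' Square IBS distance matrix
#'
#' @param dist Pair tibble from [pairwise_ibs_distance()].
#' @return A symmetric numeric matrix of `d` with zero diagonal.
#' @export
ibs_distance_matrix <- function(dist) {
  ids <- sort(unique(c(dist$sample1, dist$sample2)))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  m[cbind(dist$sample1, dist$sample2)] <- dist$d
  m[cbind(dist$sample2, dist$sample1)] <- dist$d
  m
}

#' Per-population diversity summary table
#'
#' Assembles the standard per-population diversity report: Pn, observed and
#' expected heterozygosity (mean +/- SD over samples / sites), windowed
#' nucleotide diversity (mean +/- SD over windows), mean within-population
#' IBS distance, and optionally F_ROH (mean +/- SD over samples) when ROH
#' segments are supplied. SDs are sample SDs (n-1).
#'
#' @param g A [geno_matrix()].
#' @param pops Population map.
#' @param roh_segments Optional ROH segment tibble from [detect_roh()].
#' @param autosome_length Genome length used for F_ROH (default 2.4e9 bp).
#' @param window,step Window parameters for the pi scan.
#' @param maf_threshold Strict MAF cutoff for Pn.
#' @return One tibble row per population.
#' @export
diversity_summary <- function(g, pops, roh_segments = NULL,
                              autosome_length = 2.4e9,
                              window = 1e5, step = 5e4,
                              maf_threshold = 0.01) {
  pops <- tibble::as_tibble(pops)
  freqs <- allele_frequencies(g, pops)
  pn <- prop_polymorphic(freqs, maf_threshold)
  he <- expected_heterozygosity(freqs)
  ho <- observed_heterozygosity(g, pops) |>
    dplyr::filter(!is.na(.data$ho)) |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(n = dplyr::n(), ho_mean = mean(.data$ho),
                     ho_sd = stats::sd(.data$ho), .groups = "drop")
  pi <- purrr::map_dfr(unique(pops$population), function(pop) {
    w <- nucleotide_diversity_windows(g, pops, pop, window, step)
    tibble::tibble(population = pop, pi_mean = mean(w$pi),
                   pi_sd = stats::sd(w$pi))
  })
  d <- pairwise_ibs_distance(g, pops) |>
    dplyr::filter(.data$pop1 == .data$pop2) |>
    dplyr::group_by(population = .data$pop1) |>
    dplyr::summarise(d_mean = mean(.data$d), d_sd = stats::sd(.data$d),
                     .groups = "drop")
  out <- pn |>
    dplyr::select("population", "pn") |>
    dplyr::left_join(ho, by = "population") |>
    dplyr::left_join(dplyr::select(he, "population", "he_mean", "he_sd"),
                     by = "population") |>
    dplyr::left_join(pi, by = "population") |>
    dplyr::left_join(d, by = "population")
  if (!is.null(roh_segments)) {
    fr <- froh(roh_segments, autosome_length, samples = g$samples) |>
      dplyr::left_join(pops, by = "sample") |>
      dplyr::group_by(.data$population) |>
      dplyr::summarise(froh_mean = mean(.data$froh),
                       froh_sd = stats::sd(.data$froh), .groups = "drop")
    out <- dplyr::left_join(out, fr, by = "population") |>
      dplyr::relocate("froh_mean", "froh_sd", .after = "he_sd")
  }
  out
}
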