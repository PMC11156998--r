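#' Configuration for the Balding-Nichols cohort simulator
#'
#' Describes a synthetic resequencing cohort: several populations drifted
#' from a shared ancestral allele-frequency pool, optional planted sweep
#' windows (depleted minor-allele frequency in a target population) and
#' planted autozygous tracts (forced homozygosity in chosen individuals).
#' The default cohort — 3 populations of 10 diploid samples, 2 chromosomes
#' of 10 Mb, 40,000 SNPs, drift F = 0.05, 1% missing calls — exercises the
#' whole pipeline in seconds.
#'
#' @param n_pops Number of populations (labelled `pop1`, `pop2`, ...).
#' @param samples_per_pop Diploid samples per population.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param n_snps Integer vector of SNP counts per chromosome (recycled).
#' @param ancestral_shape Two Beta shape parameters for the ancestral
#'   alternate-allele frequency law (default `c(1, 1)`, uniform).
#' @param drift Per-population drift parameter F in (0, 1) (recycled).
#' @param sweeps Optional tibble of planted sweeps: `population`, `chrom`,
#'   `start`, `end`, `max_maf` (residual minor-allele-frequency ceiling).
#'   Overlapping sweeps for the same population/chromosome are an error.
#' @param roh_tracts Optional tibble of planted autozygous tracts: `sample`,
#'   `chrom`, `start`, `end`.
#' @param missing_rate I.i.d. missing-call probability.
#' @param seed Integer seed; the emitted cohort is fully reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 3L, samples_per_pop = 10L,
                       chrom_lengths = c(chr1 = 1e7, chr2 = 1e7),
                       n_snps = 20000L,
                       ancestral_shape = c(1, 1),
                       drift = 0.05,
                       sweeps = NULL, roh_tracts = NULL,
                       missing_rate = 0.01, seed = 1L) {
  n_pops <- as.integer(n_pops)
  n_snps <- rep_len(as.integer(n_snps), length(chrom_lengths))
  drift <- rep_len(drift, n_pops)
  stopifnot(
    n_pops >= 1L, samples_per_pop >= 1L,
    all(chrom_lengths > 0), all(n_snps >= 1L),
    all(n_snps <= chrom_lengths),
    length(ancestral_shape) == 2L, all(ancestral_shape > 0),
    all(drift > 0), all(drift < 1),
    missing_rate >= 0, missing_rate < 1
  )
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  pops <- paste0("pop", seq_len(n_pops))
  if (!is.null(sweeps)) {
    sweeps <- tibble::as_tibble(sweeps)
    stopifnot(all(c("population", "chrom", "start", "end", "max_maf") %in%
                    names(sweeps)))
    check_in_bounds(sweeps, chrom_lengths, "sweep")
    stopifnot(all(sweeps$population %in% pops),
              all(sweeps$max_maf >= 0), all(sweeps$max_maf < 0.5))
    by_target <- split(sweeps, paste(sweeps$population, sweeps$chrom))
    for (s in by_target) {
      s <- s[order(s$start), ]
      if (nrow(s) > 1L && any(s$start[-1] <= s$end[-nrow(s)])) {
        stop("overlapping sweeps for one population/chromosome", call. = FALSE)
      }
    }
  }
  if (!is.null(roh_tracts)) {
    roh_tracts <- tibble::as_tibble(roh_tracts)
    stopifnot(all(c("sample", "chrom", "start", "end") %in% names(roh_tracts)))
    check_in_bounds(roh_tracts, chrom_lengths, "tract")
  }
  structure(
    list(n_pops = n_pops, samples_per_pop = as.integer(samples_per_pop),
         chrom_lengths = chrom_lengths, n_snps = n_snps,
         ancestral_shape = ancestral_shape, drift = drift,
         sweeps = sweeps, roh_tracts = roh_tracts,
         missing_rate = missing_rate, seed = as.integer(seed),
         populations = pops),
    class = "sim_config"
  )
}

check_in_bounds <- function(tbl, chrom_lengths, what) {
  ok <- tbl$chrom %in% names(chrom_lengths) &
    tbl$start >= 1 & tbl$end <= chrom_lengths[tbl$chrom] &
    tbl$start <= tbl$end
  if (!all(ok)) {
    stop(what, " interval(s) outside chromosome bounds", call. = FALSE)
  }
}

#' Simulate a cohort under the Balding-Nichols model
#'
#' Draws an ancestral alternate-allele frequency `p ~ Beta(shape1, shape2)`
#' per SNP, population frequencies
#' `p_k ~ Beta(p (1-F)/F, (1-p)(1-F)/F)` and genotypes
#' `~ Binomial(2, p_k)` per sample. Inside a sweep window the target
#' population's frequency is resampled so that its minor-allele frequency is
#' at most the configured ceiling (pushed toward the ancestral major
#' allele); inside a planted tract the named sample's genotypes are forced
#' homozygous for the population-major allele. Missing calls are dropped
#' i.i.d. last. Everything is reproducible from the config seed.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_cohort`: `genotypes` (a [geno_matrix()]),
#'   `pop_map` (tibble), and `truth` (list with `freqs`, the populations x
#'   variants frequency matrix; `sweeps`; `roh_tracts`).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, simulate_impl(cfg))
}

simulate_impl <- function(cfg) {
  chroms <- names(cfg$chrom_lengths)
  pops <- cfg$populations
  n_pop <- cfg$n_pops
  n_per <- cfg$samples_per_pop
  samples <- as.vector(vapply(
    pops, function(p) sprintf("%s_s%02d", p, seq_len(n_per)),
    character(n_per)
  ))
  pop_of <- rep(pops, each = n_per)

  # positions: uniform without replacement, sorted, per chromosome
  variants <- purrr::map2_dfr(chroms, seq_along(chroms), function(ch, i) {
    tibble::tibble(
      chrom = ch,
      pos = sort(sample.int(cfg$chrom_lengths[[i]], cfg$n_snps[[i]])),
      ref = "A", alt = "C"
    )
  })
  m <- nrow(variants)

  shp <- cfg$ancestral_shape
  p_anc <- stats::rbeta(m, shp[1], shp[2])
  # keep ancestral frequencies away from exact fixation so the Beta
  # parameters below stay proper
  eps <- 1e-6
  p_anc <- pmin(pmax(p_anc, eps), 1 - eps)

  freqs <- matrix(NA_real_, n_pop, m, dimnames = list(pops, NULL))
  for (k in seq_len(n_pop)) {
    f <- cfg$drift[k]
    freqs[k, ] <- stats::rbeta(m, p_anc * (1 - f) / f,
                               (1 - p_anc) * (1 - f) / f)
  }

  # planted sweeps: force the target population toward the ancestral major
  # allele, residual MAF ~ Uniform(0, max_maf)
  if (!is.null(cfg$sweeps)) {
    for (i in seq_len(nrow(cfg$sweeps))) {
      sw <- cfg$sweeps[i, ]
      idx <- which(variants$chrom == sw$chrom & variants$pos >= sw$start &
                     variants$pos <= sw$end)
      if (!length(idx)) next
      maf <- stats::runif(length(idx), 0, sw$max_maf)
      major_is_alt <- p_anc[idx] >= 0.5
      freqs[sw$population, idx] <- ifelse(major_is_alt, 1 - maf, maf)
    }
  }

  calls <- matrix(NA_integer_, length(samples), m,
                  dimnames = list(samples, NULL))
  for (k in seq_len(n_pop)) {
    rows <- which(pop_of == pops[k])
    calls[rows, ] <- matrix(
      stats::rbinom(length(rows) * m, 2L, rep(freqs[k, ], each = length(rows))),
      nrow = length(rows)
    )
  }

  # planted autozygous tracts: homozygous for the population-major allele
  if (!is.null(cfg$roh_tracts)) {
    for (i in seq_len(nrow(cfg$roh_tracts))) {
      tr <- cfg$roh_tracts[i, ]
      row <- match(tr$sample, samples)
      if (is.na(row)) stop("tract names unknown sample: ", tr$sample,
                           call. = FALSE)
      idx <- which(variants$chrom == tr$chrom & variants$pos >= tr$start &
                     variants$pos <= tr$end)
      pk <- freqs[pop_of[row], idx]
      calls[row, idx] <- ifelse(pk >= 0.5, 2L, 0L)
    }
  }

  if (cfg$missing_rate > 0) {
    drop <- stats::runif(length(calls)) < cfg$missing_rate
    calls[drop] <- NA_integer_
  }

  structure(
    list(
      genotypes = geno_matrix(calls, variants, samples),
      pop_map = tibble::tibble(sample = samples, population = pop_of),
      truth = list(freqs = freqs, sweeps = cfg$sweeps,
                   roh_tracts = cfg$roh_tracts, p_ancestral = p_anc)
    ),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort>\n")
  print(x$genotypes)
  cat("populations:",
      paste(unique(x$pop_map$population), collapse = ", "), "\n")
  invisible(x)
}
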