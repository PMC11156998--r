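#' Per-population allele frequencies
#'
#' Computes the alternate-allele frequency of every variant in every
#' population, excluding missing genotypes site-wise from the denominator.
#' Sites where a population has no called genotype get `p = NA` (flagged
#' undefined) rather than a value.
#'
#' @param g A [geno_matrix()].
#' @param pops Population map (tibble `sample`, `population`). If `NULL`, all
#'   samples form one population labelled `"all"`.
#'
#' @return A tibble with one row per (variant, population):
#'   `chrom`, `pos`, `population`, `n_called` (diploid samples with a call),
#'   `n_alt` (alt-allele count), `p` (alt frequency, `NA` if undefined) and
#'   `maf` (minor-allele frequency).
#' @export
#' @examples
#' g <- geno_matrix(rbind(a = c(0L, 1L), b = c(1L, 2L), c = c(2L, NA)),
#'                  tibble::tibble(chrom = "1", pos = c(1L, 2L),
#'                                 ref = "A", alt = "C"))
#' allele_frequencies(g)
allele_frequencies <- function(g, pops = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  if (is.null(pops)) {
    pops <- tibble::tibble(sample = g$samples, population = "all")
  }
  pops <- tibble::as_tibble(pops)
  counts <- pop_allele_counts(g, pops)
  purrr::imap_dfr(counts, function(ct, pop) {
    tibble::tibble(
      chrom = g$variants$chrom,
      pos = g$variants$pos,
      population = pop,
      n_called = ct$n_called,
      n_alt = ct$n_alt,
      p = ifelse(ct$n_called > 0L, ct$n_alt / (2 * ct$n_called), NA_real_)
    )
  }) |>
    dplyr::mutate(maf = pmin(.data$p, 1 - .data$p))
}

# per-population per-site call counts: n_called, n_alt, n_het
# (the single genotype-tallying kernel behind every frequency-based statistic)
pop_allele_counts <- function(g, pops) {
  unknown <- setdiff(pops$sample, g$samples)
  if (length(unknown)) {
    stop("population map names unknown sample(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  split(pops$sample, pops$population) |>
    lapply(function(ids) {
      m <- g$calls[match(ids, g$samples), , drop = FALSE]
      list(
        n_called = colSums(!is.na(m)),
        n_alt = colSums(m, na.rm = TRUE),
        n_het = colSums(m == 1L, na.rm = TRUE)
      )
    })
}

# frequency matrix (populations x variants) for multi-population statistics;
# NA where a population has no called genotype at the site
pop_freq_matrix <- function(g, pops, populations) {
  counts <- pop_allele_counts(g, pops)
  missing_pop <- setdiff(populations, names(counts))
  if (length(missing_pop)) {
    stop("unknown population label(s): ",
         paste(missing_pop, collapse = ", "), call. = FALSE)
  }
  t(vapply(populations, function(pop) {
    ct <- counts[[pop]]
    ifelse(ct$n_called > 0L, ct$n_alt / (2 * ct$n_called), NA_real_)
  }, numeric(n_variants(g))))
}
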