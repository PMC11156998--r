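#' Diploid genotype matrix
#'
#' Compact in-memory container for biallelic diploid genotypes: an integer
#' matrix of alternate-allele dosages (samples in rows, variants in columns)
#' plus a variant table. Calls are coded `0` (hom-ref), `1` (het), `2`
#' (hom-alt) and `NA` (missing); phasing is ignored throughout because every
#' statistic in the package depends only on the unordered genotype class.
#'
#' @param calls Integer matrix, samples x variants, values in `{0, 1, 2, NA}`.
#' @param variants Data frame with columns `chrom`, `pos` (1-based bp, as in
#'   VCF), `ref`, `alt`; one row per column of `calls`. Positions must be
#'   strictly increasing within each chromosome.
#' @param samples Character vector of sample ids, one per row of `calls`.
#'
#' @return An object of class `geno_matrix`.
#' @export
#' @examples
#' g <- geno_matrix(
#'   calls = rbind(s1 = c(0L, 1L), s2 = c(2L, NA)),
#'   variants = tibble::tibble(chrom = "chr1", pos = c(100L, 200L),
#'                             ref = "A", alt = "C"),
#'   samples = c("s1", "s2")
#' )
#' g
geno_matrix <- function(calls, variants, samples = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  variants <- tibble::as_tibble(variants)
  if (is.null(samples)) {
    stop("`samples` must be supplied when `calls` has no rownames", call. = FALSE)
  }
  samples <- as.character(samples)
  rownames(calls) <- samples
  colnames(calls) <- NULL

  stopifnot(
    nrow(calls) == length(samples),
    ncol(calls) == nrow(variants),
    all(c("chrom", "pos", "ref", "alt") %in% names(variants))
  )
  if (nrow(calls) < 1L || ncol(calls) < 1L) {
    stop("a geno_matrix needs at least one sample and one variant", call. = FALSE)
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids", call. = FALSE)
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    stop("calls must be 0, 1, 2 or NA", call. = FALSE)
  }
  # enforce sorted, unique coordinates
  ord <- order(variants$chrom, variants$pos)
  if (!identical(ord, seq_len(nrow(variants)))) {
    variants <- variants[ord, ]
    calls <- calls[, ord, drop = FALSE]
  }
  if (any(duplicated(variants[c("chrom", "pos")]))) {
    stop("duplicate (chrom, pos) coordinates in variant table", call. = FALSE)
  }

  structure(
    list(calls = calls, variants = variants, samples = samples),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  nmiss <- sum(is.na(x$calls))
  cat(sprintf(
    "<geno_matrix> %d samples x %d variants on %d chromosome(s); %.2f%% missing\n",
    length(x$samples), nrow(x$variants),
    length(unique(x$variants$chrom)),
    100 * nmiss / length(x$calls)
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Number of samples / variants in a genotype matrix
#' @param g A [geno_matrix()].
#' @return Integer count.
#' @export
n_samples <- function(g) length(g$samples)

#' @rdname n_samples
#' @export
n_variants <- function(g) nrow(g$variants)

#' Subset a genotype matrix by sample or chromosome
#'
#' @param g A [geno_matrix()].
#' @param samples Optional character vector of sample ids to keep.
#' @param chroms Optional character vector of chromosome labels to keep.
#' @return A new `geno_matrix`.
#' @export
subset_geno <- function(g, samples = NULL, chroms = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  keep_s <- if (is.null(samples)) g$samples else samples
  missing_s <- setdiff(keep_s, g$samples)
  if (length(missing_s)) {
    stop("unknown sample id(s): ", paste(missing_s, collapse = ", "), call. = FALSE)
  }
  keep_v <- if (is.null(chroms)) rep(TRUE, n_variants(g)) else g$variants$chrom %in% chroms
  if (!any(keep_v)) stop("no variants left after chromosome filter", call. = FALSE)
  geno_matrix(
    g$calls[match(keep_s, g$samples), keep_v, drop = FALSE],
    g$variants[keep_v, ],
    samples = keep_s
  )
}

#' Population assignments for a genotype matrix
#'
#' Validates a sample-to-population map against a genotype matrix: every
#' mapped sample must exist in the matrix and (by default) every population
#' must contain at least two samples, the minimum for frequency-based
#' statistics.
#'
#' @param g A [geno_matrix()].
#' @param pop_map Data frame with columns `sample` and `population`.
#' @param min_pop_size Minimum samples per population (default 2).
#' @return A tibble (`sample`, `population`) in matrix sample order.
#' @export
pop_map <- function(g, pop_map, min_pop_size = 2L) {
  stopifnot(inherits(g, "geno_matrix"))
  pm <- tibble::as_tibble(pop_map)
  stopifnot(all(c("sample", "population") %in% names(pm)))
  unknown <- setdiff(pm$sample, g$samples)
  if (length(unknown)) {
    stop("population map names sample(s) absent from the genotype matrix: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sizes <- table(pm$population)
  small <- names(sizes)[sizes < min_pop_size]
  if (length(small)) {
    stop("population(s) below the minimum size of ", min_pop_size, ": ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  pm[order(match(pm$sample, g$samples)), c("sample", "population")]
}

# samples of one population, with validation
pop_samples <- function(g, pops, population) {
  pops <- tibble::as_tibble(pops)
  if (!population %in% pops$population) {
    stop("unknown population label: ", population, call. = FALSE)
  }
  intersect(g$samples, pops$sample[pops$population == population])
}
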