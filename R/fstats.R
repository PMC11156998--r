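#' f3 admixture statistic
#'
#' `f3(A; B, C) = mean over sites of (a - b)(a - c)` with `a`, `b`, `c` the
#' population alternate-allele frequencies. A significantly negative Z
#' indicates that A is admixed between sources related to B and C. The
#' standard error comes from a delete-one block jackknife over consecutive
#' SNP blocks, accommodating linkage.
#'
#' No finite-sample (heterozygosity) bias correction is applied by default;
#' `correct_bias = TRUE` subtracts `het_a / (2 * n_a)` site-wise from the
#' product, the usual correction for sampling noise in the target frequency.
#'
#' @param g A [geno_matrix()].
#' @param pops Population map.
#' @param a,b,c Distinct population labels (target first).
#' @param block_size SNPs per jackknife block (default 500); the trailing
#'   partial block is merged into the last full one.
#' @param correct_bias Apply the target-population sampling correction.
#' @return An object of class `fstat`; see [tidy.fstat()].
#' @export
f3 <- function(g, pops, a, b, c, block_size = 500L, correct_bias = FALSE) {
  check_distinct_pops(c(a, b, c))
  fr <- pop_freq_matrix(g, tibble::as_tibble(pops), c(a, b, c))
  keep <- colSums(is.na(fr)) == 0L
  site <- (fr[1, keep] - fr[2, keep]) * (fr[1, keep] - fr[3, keep])
  if (correct_bias) {
    counts <- pop_allele_counts(g, tibble::as_tibble(pops))[[a]]
    n_called <- counts$n_called[keep]
    het <- 2 * fr[1, keep] * (1 - fr[1, keep]) *
      (2 * n_called) / pmax(2 * n_called - 1, 1)
    site <- site - het / (2 * n_called)
  }
  jk <- block_jackknife(site, block_size)
  new_fstat("f3", populations = c(A = a, B = b, C = c), jk,
            block_size = block_size)
}

#' f4 tree-topology statistic
#'
#' `f4(A, B; C, D) = mean over sites of (a - b)(c - d)`. A significantly
#' positive Z indicates gene flow between A and C or B and D exceeding that
#' between A and D or B and C; a negative Z the converse. Jackknife SE as in
#' [f3()].
#'
#' @inheritParams f3
#' @param d Fourth population label.
#' @return An object of class `fstat`.
#' @export
f4 <- function(g, pops, a, b, c, d, block_size = 500L) {
  check_distinct_pops(c(a, b, c, d))
  fr <- pop_freq_matrix(g, tibble::as_tibble(pops), c(a, b, c, d))
  keep <- colSums(is.na(fr)) == 0L
  site <- (fr[1, keep] - fr[2, keep]) * (fr[3, keep] - fr[4, keep])
  jk <- block_jackknife(site, block_size)
  new_fstat("f4", populations = c(A = a, B = b, C = c, D = d), jk,
            block_size = block_size)
}

check_distinct_pops <- function(labels) {
  if (anyDuplicated(labels)) {
    stop("population labels must be distinct", call. = FALSE)
  }
}

# Delete-one block jackknife on consecutive-site blocks with the weighted
# (unequal block size) variance formula; the trailing partial block is
# merged into the final full block.
block_jackknife <- function(site_values, block_size) {
  n <- length(site_values)
  if (n < 1L) stop("no sites with all populations called", call. = FALSE)
  n_blocks <- n %/% block_size
  if (n_blocks < 2L) {
    stop("fewer than two jackknife blocks (", n, " sites, block size ",
         block_size, ")", call. = FALSE)
  }
  block <- pmin((seq_len(n) - 1L) %/% block_size + 1L, n_blocks)
  m_j <- as.numeric(table(block))
  sums <- as.numeric(rowsum(site_values, block, reorder = TRUE))
  total <- sum(sums)
  est <- total / n
  loo <- (total - sums) / (n - m_j)        # leave-one-block-out means
  h_j <- n / m_j
  pseudo <- h_j * est - (h_j - 1) * loo
  est_jack <- n_blocks * est - sum((1 - m_j / n) * loo)
  var_jack <- mean((pseudo - est_jack)^2 / (h_j - 1))
  se <- sqrt(var_jack)
  list(estimate = est, se = se, z = est / se, n_blocks = n_blocks,
       n_sites = n)
}

new_fstat <- function(statistic, populations, jk, block_size) {
  structure(
    list(statistic = statistic, populations = populations,
         estimate = jk$estimate, se = jk$se, z = jk$z,
         n_blocks = jk$n_blocks, n_sites = jk$n_sites,
         block_size = as.integer(block_size)),
    class = "fstat"
  )
}

#' @export
print.fstat <- function(x, ...) {
  pops <- paste(sprintf("%s=%s", names(x$populations), x$populations),
                collapse = ", ")
  cat(sprintf("%s(%s): %.6g  (SE %.3g, Z %.2f; %d blocks of ~%d SNPs)\n",
              x$statistic, pops, x$estimate, x$se, x$z, x$n_blocks,
              x$block_size))
  invisible(x)
}

#' Tidy an f-statistic result
#'
#' @param x An `fstat` object from [f3()] or [f4()].
#' @param ... Unused.
#' @return `tidy()`: a one-row tibble with the populations, `estimate`,
#'   `se`, `z`; `glance()`: a one-row tibble with fit metadata (`n_sites`,
#'   `n_blocks`, `block_size`).
#' @export
tidy.fstat <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(statistic = x$statistic),
    tibble::as_tibble(as.list(x$populations)),
    tibble::tibble(estimate = x$estimate, se = x$se, z = x$z)
  )
}

#' @rdname tidy.fstat
#' @export
glance.fstat <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, n_sites = x$n_sites,
                 n_blocks = x$n_blocks, block_size = x$block_size)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Run a table of f3/f4 tests
#'
#' @param g A [geno_matrix()].
#' @param pops Population map.
#' @param tests Tibble with columns `type` (`"f3"`/`"f4"`) and population
#'   columns `a`, `b`, `c` and (for f4) `d`.
#' @param block_size SNPs per jackknife block.
#' @return A tibble with one row per test (tidied results).
#' @export
fstat_table <- function(g, pops, tests, block_size = 500L) {
  purrr::pmap_dfr(tests, function(type, a, b, c, d = NA, ...) {
    res <- if (identical(type, "f3")) {
      f3(g, pops, a, b, c, block_size = block_size)
    } else {
      f4(g, pops, a, b, c, d, block_size = block_size)
    }
    tidy(res)
  })
}
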