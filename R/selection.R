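#' Per-site FST between two populations
#'
#' `1 - (p1*q1 + p2*q2) / (2 * pr * qr)` with `pr = (p1 + p2)/2`: one minus
#' the ratio of mean within-population heterozygosity to the heterozygosity
#' of the pooled frequency. Sites where the pooled frequency is fixed
#' (`pr*qr = 0`) are undefined and returned as `NA`.
#'
#' @param p1,p2 Alternate-allele frequencies in the two populations.
#' @return Numeric vector of site FST values in `[0, 1]` (or `NA`).
#' @export
fst_site <- function(p1, p2) {
  pr <- (p1 + p2) / 2
  den <- 2 * pr * (1 - pr)
  ifelse(is.na(den) | den == 0, NA_real_,
         1 - (p1 * (1 - p1) + p2 * (1 - p2)) / den)
}

#' Sliding-window FST scan
#'
#' Windowed FST between a test and a reference population. The default
#' `"site_mean"` dialect averages the per-site statistic of [fst_site()]
#' over the window's qualifying sites. The `"wc"` dialect instead forms the
#' Weir-Cockerham ratio-of-sums estimate per window, which corrects the
#' finite-sample and pooled-denominator biases and is the consistent
#' estimator of the drift parameter under an island model; use it when the
#' absolute FST level matters rather than the outlier ranking.
#'
#' @param g A [geno_matrix()].
#' @param pops Population map.
#' @param pop_test,pop_ref Distinct population labels.
#' @param window,step Window and step in bp (defaults 100 kb / 25 kb).
#' @param min_snps Windows with fewer qualifying SNPs are dropped
#'   (default 30).
#' @param dialect `"site_mean"` or `"wc"`.
#' @return A tibble per retained window: `chrom`, `start`, `end` (half-open),
#'   `n_snps`, `fst`.
#' @export
fst_windows <- function(g, pops, pop_test, pop_ref,
                        window = 1e5, step = 2.5e4, min_snps = 30L,
                        dialect = c("site_mean", "wc")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(g, "geno_matrix"))
  if (identical(pop_test, pop_ref)) {
    stop("test and reference populations must differ", call. = FALSE)
  }
  pops <- tibble::as_tibble(pops)
  counts <- pop_allele_counts(g, pops)
  for (pop in c(pop_test, pop_ref)) {
    if (!pop %in% names(counts)) stop("unknown population label: ", pop,
                                      call. = FALSE)
  }
  ct1 <- counts[[pop_test]]; ct2 <- counts[[pop_ref]]
  p1 <- ifelse(ct1$n_called > 0, ct1$n_alt / (2 * ct1$n_called), NA_real_)
  p2 <- ifelse(ct2$n_called > 0, ct2$n_alt / (2 * ct2$n_called), NA_real_)

  if (dialect == "site_mean") {
    site <- fst_site(p1, p2)
    vals <- list(fst_sum = site)
    ok <- !is.na(site)
  } else {
    wc <- wc_site_components(p1, p2, ct1, ct2)
    vals <- list(wc_a = wc$a, wc_abc = wc$abc)
    ok <- !is.na(wc$a) & !is.na(wc$abc) & wc$abc != 0
  }

  v <- g$variants
  out <- purrr::map_dfr(split(which(ok), v$chrom[ok]), function(idx) {
    ws <- window_sums(v$pos[idx], lapply(vals, `[`, idx), window, step)
    ws$chrom <- v$chrom[idx[1]]
    ws
  })
  if (nrow(out) == 0L) stop("no windows with defined FST", call. = FALSE)
  out <- dplyr::filter(out, .data$n_snps >= min_snps)
  if (nrow(out) == 0L) {
    stop("no window reaches min_snps = ", min_snps, call. = FALSE)
  }
  out$fst <- if (dialect == "site_mean") out$fst_sum / out$n_snps else
    out$wc_a / out$wc_abc
  dplyr::bind_cols(out, window_bounds(out$win, window, step)) |>
    dplyr::select("chrom", "start", "end", "n_snps", "fst") |>
    dplyr::arrange(.data$chrom, .data$start)
}

# Weir & Cockerham (1984) two-population per-site variance components;
# a = among-population, abc = total. Uses observed heterozygote counts.
wc_site_components <- function(p1, p2, ct1, ct2) {
  n1 <- ct1$n_called; n2 <- ct2$n_called
  h1 <- ifelse(n1 > 0, ct1$n_het / n1, NA_real_)
  h2 <- ifelse(n2 > 0, ct2$n_het / n2, NA_real_)
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  poly <- !is.na(pbar) & pbar > 0 & pbar < 1 & n1 > 1 & n2 > 1
  list(a = ifelse(poly, a, NA_real_),
       abc = ifelse(poly, a + b + cc, NA_real_))
}

#' Sliding-window pooled heterozygosity (Hp)
#'
#' Per window, `Hp = 2 * S_maj * S_min / (S_maj + S_min)^2` where `S_maj` and
#' `S_min` are the sums over the window's SNPs of the major- and minor-allele
#' *counts* in the population (counts, not frequencies, so sites with more
#' missing data contribute proportionally less). Windows without SNPs are
#' dropped. Ties (`p = 0.5`) assign the alternate allele as minor, which
#' cannot change Hp.
#'
#' @param g A [geno_matrix()].
#' @param pops Population map.
#' @param population Population label to scan.
#' @param window,step Window and step in bp (defaults 100 kb / 25 kb).
#' @param min_snps Minimum SNPs per retained window (default 1).
#' @return A tibble per window: `chrom`, `start`, `end`, `n_snps`,
#'   `sum_maj`, `sum_min`, `hp`.
#' @export
hp_windows <- function(g, pops, population, window = 1e5, step = 2.5e4,
                       min_snps = 1L) {
  stopifnot(inherits(g, "geno_matrix"))
  pops <- tibble::as_tibble(pops)
  counts <- pop_allele_counts(g, pops)
  if (!population %in% names(counts)) {
    stop("unknown population label: ", population, call. = FALSE)
  }
  ct <- counts[[population]]
  n_alt <- ct$n_alt
  n_ref <- 2 * ct$n_called - ct$n_alt
  n_min <- pmin(n_ref, n_alt)
  n_maj <- pmax(n_ref, n_alt)
  ok <- ct$n_called > 0

  v <- g$variants
  out <- purrr::map_dfr(split(which(ok), v$chrom[ok]), function(idx) {
    ws <- window_sums(
      v$pos[idx],
      list(sum_maj = as.numeric(n_maj[idx]), sum_min = as.numeric(n_min[idx])),
      window, step
    )
    ws$chrom <- v$chrom[idx[1]]
    ws
  })
  if (nrow(out) == 0L) stop("no windows with called genotypes", call. = FALSE)
  out |>
    dplyr::filter(.data$n_snps >= min_snps) |>
    dplyr::mutate(hp = 2 * .data$sum_maj * .data$sum_min /
                    (.data$sum_maj + .data$sum_min)^2) |>
    (\(x) dplyr::bind_cols(x, window_bounds(x$win, window, step)))() |>
    dplyr::select("chrom", "start", "end", "n_snps", "sum_maj", "sum_min",
                  "hp") |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Z-standardize a vector of window statistics
#'
#' `(x - mean(x)) / sd(x)` over the whole scan (sample SD). Errors on a
#' degenerate scan (fewer than two values, or zero variance).
#'
#' @param x Numeric vector of window statistics.
#' @param label Scan name used in error messages.
#' @return Standardized numeric vector (mean 0, SD 1).
#' @export
zscore <- function(x, label = "scan") {
  x <- as.numeric(x)
  if (length(x) < 2L) {
    stop("cannot Z-standardize ", label, ": fewer than two windows",
         call. = FALSE)
  }
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot Z-standardize ", label, ": zero variance", call. = FALSE)
  }
  (x - mean(x)) / s
}

#' Add a Z-score column to a window scan
#'
#' @param wins Window tibble (from [fst_windows()], [hp_windows()] or
#'   [nucleotide_diversity_windows()]).
#' @param col Column to standardize; defaults to the scan's statistic
#'   (`fst`, `hp` or `pi`, whichever is present).
#' @return `wins` with an added `z` column.
#' @export
zscore_windows <- function(wins, col = NULL) {
  if (is.null(col)) {
    col <- intersect(c("fst", "hp", "pi"), names(wins))[1]
    if (is.na(col)) stop("no statistic column found", call. = FALSE)
  }
  wins$z <- zscore(wins[[col]], label = col)
  wins
}

#' Number of windows in an outlier tail
#'
#' `ceiling(tail * n)`: the count of windows selected from one tail of a
#' Z-score distribution.
#'
#' @param n Number of windows in the scan.
#' @param tail Tail fraction (default 0.01).
#' @return Integer count.
#' @export
#' @examples
#' outlier_count(98660)  # 987
#' outlier_count(98573)  # 986
outlier_count <- function(n, tail = 0.01) {
  stopifnot(n >= 0, tail > 0, tail <= 1)
  as.integer(ceiling(tail * n))
}

#' Intersect FST and Hp outlier windows into candidate regions
#'
#' Selects the `ceiling(tail * N)` windows with the highest Z(FST) and, from
#' the Hp scan, the same count with the lowest Z(Hp); ranks are broken
#' deterministically by (chrom, start) at ties. Windows selected by *both*
#' scans (matched by exact window identity, so scans with different grids
#' only intersect on shared windows) are merged wherever they overlap or
#' abut into candidate selection regions.
#'
#' @param zfst FST scan with a `z` column (see [zscore_windows()]).
#' @param zhp Hp scan with a `z` column.
#' @param tail Tail fraction for each scan (default 0.01).
#' @return A tibble per candidate region: `chrom`, `start`, `end`,
#'   `n_windows`, `peak_zfst`, `trough_zhp`, with the member windows in
#'   `attr(, "windows")`.
#' @export
call_outliers <- function(zfst, zhp, tail = 0.01) {
  stopifnot(all(c("chrom", "start", "end", "z") %in% names(zfst)),
            all(c("chrom", "start", "end", "z") %in% names(zhp)))
  k_fst <- outlier_count(nrow(zfst), tail)
  k_hp <- outlier_count(nrow(zhp), tail)
  top_fst <- zfst |>
    dplyr::arrange(dplyr::desc(.data$z), .data$chrom, .data$start) |>
    dplyr::slice_head(n = k_fst)
  bot_hp <- zhp |>
    dplyr::arrange(.data$z, .data$chrom, .data$start) |>
    dplyr::slice_head(n = k_hp)

  shared <- dplyr::inner_join(
    dplyr::select(top_fst, "chrom", "start", "end", zfst = "z"),
    dplyr::select(bot_hp, "chrom", "start", "end", zhp = "z"),
    by = c("chrom", "start", "end")
  ) |>
    dplyr::arrange(.data$chrom, .data$start)

  regions <- merge_windows(shared)
  attr(regions, "windows") <- shared
  attr(regions, "n_selected") <- c(fst = k_fst, hp = k_hp)
  regions
}

# union-merge overlapping/abutting half-open windows into regions
merge_windows <- function(wins) {
  empty <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_windows = integer(),
                          peak_zfst = numeric(), trough_zhp = numeric())
  if (nrow(wins) == 0L) return(empty)
  purrr::map_dfr(split(wins, wins$chrom), function(w) {
    w <- dplyr::arrange(w, .data$start)
    grp <- cumsum(c(1, as.integer(w$start[-1] > cummax(w$end[-nrow(w)]))))
    w |>
      dplyr::mutate(.grp = grp) |>
      dplyr::group_by(.data$chrom, .data$.grp) |>
      dplyr::summarise(
        start = min(.data$start), end = max(.data$end),
        n_windows = dplyr::n(),
        peak_zfst = max(.data$zfst), trough_zhp = min(.data$zhp),
        .groups = "drop"
      ) |>
      dplyr::select(-".grp")
  }) |>
    dplyr::arrange(.data$chrom, .data$start)
}
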