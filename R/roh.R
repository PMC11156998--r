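#' Parameters for the scanning-window ROH detector
#'
#' Defaults follow the common resequencing configuration: a 50-SNP scanning
#' window allowing at most one heterozygous and one missing call, runs of at
#' least 50 SNPs and 100 kb, a minimum density of 1 SNP per 100 kb, and a
#' maximum gap of 1 Mb between consecutive SNPs in a run. The hit threshold
#' (fraction of overlapping scanning windows that must pass for a SNP to sit
#' inside a run) defaults to 0.05.
#'
#' @param min_snps Minimum SNPs per reported run.
#' @param min_length Minimum run length in bp.
#' @param max_het_per_window Max heterozygous calls per scanning window.
#' @param max_missing_per_window Max missing calls per scanning window.
#' @param min_density Minimum SNPs per bp over the run (default 1/100 kb).
#' @param max_gap Maximum bp gap between consecutive SNPs inside a run.
#' @param scan_window_snps Scanning-window size in SNPs.
#' @param window_hit_threshold Fraction of covering windows that must hit.
#' @return A named list of class `roh_params`.
#' @export
roh_params <- function(min_snps = 50L, min_length = 1e5,
                       max_het_per_window = 1L, max_missing_per_window = 1L,
                       min_density = 1 / 1e5, max_gap = 1e6,
                       scan_window_snps = 50L, window_hit_threshold = 0.05) {
  p <- list(
    min_snps = as.integer(min_snps), min_length = min_length,
    max_het_per_window = as.integer(max_het_per_window),
    max_missing_per_window = as.integer(max_missing_per_window),
    min_density = min_density, max_gap = max_gap,
    scan_window_snps = as.integer(scan_window_snps),
    window_hit_threshold = window_hit_threshold
  )
  stopifnot(
    p$min_snps > 0, p$min_length > 0, p$min_density > 0, p$max_gap > 0,
    p$scan_window_snps > 0, p$max_het_per_window >= 0,
    p$max_missing_per_window >= 0,
    p$window_hit_threshold > 0, p$window_hit_threshold <= 1
  )
  structure(p, class = "roh_params")
}

#' Detect runs of homozygosity
#'
#' Two-phase scanning-window detector. Phase 1 slides a window of
#' `scan_window_snps` SNPs along each chromosome; a window *hits* when it
#' contains at most `max_het_per_window` heterozygous and
#' `max_missing_per_window` missing calls. Phase 2 marks a SNP as inside a
#' run when at least `window_hit_threshold` of the scanning windows covering
#' it hit; maximal stretches of marked SNPs are split at inter-SNP gaps
#' larger than `max_gap` and then filtered by `min_snps`, `min_length` and
#' `min_density`. Chromosomes with fewer SNPs than the scanning window yield
#' no calls.
#'
#' @param g A [geno_matrix()].
#' @param samples Sample ids to scan (default: all).
#' @param params A [roh_params()] list.
#' @return A tibble per segment: `sample`, `chrom`, `start`, `end`
#'   (first/last SNP positions, inclusive), `length` (`end - start + 1`),
#'   `n_snps`; sorted, non-overlapping within a sample.
#' @export
detect_roh <- function(g, samples = NULL, params = roh_params()) {
  stopifnot(inherits(g, "geno_matrix"))
  if (is.null(samples)) samples <- g$samples
  unknown <- setdiff(samples, g$samples)
  if (length(unknown)) {
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  chrom_idx <- split(seq_len(n_variants(g)), g$variants$chrom)
  purrr::map_dfr(samples, function(s) {
    calls <- g$calls[match(s, g$samples), ]
    purrr::map_dfr(names(chrom_idx), function(ch) {
      idx <- chrom_idx[[ch]]
      segs <- roh_one_chrom(calls[idx], g$variants$pos[idx], params)
      if (nrow(segs)) dplyr::mutate(segs, sample = s, chrom = ch,
                                    .before = 1L) else segs
    })
  }) |>
    (\(x) if (nrow(x)) dplyr::arrange(x, .data$sample, .data$chrom,
                                      .data$start) else
      tibble::tibble(sample = character(), chrom = character(),
                     start = integer(), end = integer(),
                     length = numeric(), n_snps = integer()))()
}

# the per-(sample, chromosome) kernel; calls is a 0/1/2/NA vector over
# position-sorted SNPs
roh_one_chrom <- function(calls, pos, params) {
  empty <- tibble::tibble(start = integer(), end = integer(),
                          length = numeric(), n_snps = integer())
  m <- length(calls)
  w <- params$scan_window_snps
  if (m < w) return(empty)

  het <- as.integer(!is.na(calls) & calls == 1L)
  mis <- as.integer(is.na(calls))
  ch <- cumsum(het); cm <- cumsum(mis)
  n_win <- m - w + 1L
  i <- seq_len(n_win)
  het_in_win <- ch[i + w - 1L] - c(0L, ch)[i]
  mis_in_win <- cm[i + w - 1L] - c(0L, cm)[i]
  hit <- as.integer(het_in_win <= params$max_het_per_window &
                    mis_in_win <= params$max_missing_per_window)

  # SNP j is covered by windows max(1, j-w+1) .. min(j, n_win)
  hh <- cumsum(hit)
  j <- seq_len(m)
  lo <- pmax(1L, j - w + 1L)
  hi <- pmin(j, n_win)
  n_cover <- hi - lo + 1L
  n_hit <- hh[hi] - c(0L, hh)[lo]
  in_run <- n_hit / n_cover >= params$window_hit_threshold

  if (!any(in_run)) return(empty)

  r <- rle(in_run)
  stretch_end <- cumsum(r$lengths)
  stretch_start <- stretch_end - r$lengths + 1L
  keep <- which(r$values)
  out <- list()
  for (k in keep) {
    sub <- stretch_start[k]:stretch_end[k]
    # split at gaps > max_gap
    cuts <- which(diff(pos[sub]) > params$max_gap)
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, length(sub))
    for (q in seq_along(starts)) {
      ss <- sub[starts[q]:ends[q]]
      n_snps <- length(ss)
      len <- pos[ss[n_snps]] - pos[ss[1]] + 1
      if (n_snps >= params$min_snps && len >= params$min_length &&
          n_snps / len >= params$min_density) {
        out[[length(out) + 1L]] <- tibble::tibble(
          start = pos[ss[1]], end = pos[ss[n_snps]],
          length = len, n_snps = n_snps
        )
      }
    }
  }
  if (length(out)) dplyr::bind_rows(out) else empty
}

#' ROH-based genomic inbreeding coefficient (F_ROH)
#'
#' `F_ROH = sum(L_roh) / L_auto`: the fraction of the autosomal genome lying
#' in runs of homozygosity.
#'
#' @param segments ROH tibble from [detect_roh()].
#' @param autosome_length Autosomal genome length in bp (default 2.4e9, the
#'   approximate goat autosome length). Override for synthetic genomes.
#' @param samples Optional sample universe: ids without segments get
#'   `froh = 0`.
#' @return A tibble per sample: `n_segments`, `l_roh` (bp), `froh`.
#' @export
froh <- function(segments, autosome_length = 2.4e9, samples = NULL) {
  if (!is.numeric(autosome_length) || autosome_length <= 0) {
    stop("`autosome_length` must be positive", call. = FALSE)
  }
  if (nrow(segments) && any(segments$length <= 0)) {
    stop("segment lengths must be positive", call. = FALSE)
  }
  out <- segments |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(n_segments = dplyr::n(), l_roh = sum(.data$length),
                     .groups = "drop")
  if (!is.null(samples)) {
    out <- tibble::tibble(sample = samples) |>
      dplyr::left_join(out, by = "sample") |>
      dplyr::mutate(n_segments = dplyr::coalesce(.data$n_segments, 0L),
                    l_roh = dplyr::coalesce(.data$l_roh, 0))
  }
  dplyr::mutate(out, froh = .data$l_roh / autosome_length)
}

roh_class_levels <- c("100-150Kb", ">150-250Kb", ">250-400Kb", ">400Kb")

# length (bp) -> length-class factor; boundaries 150/250/400 kb closed below
roh_length_class <- function(length_bp) {
  cut(length_bp, breaks = c(1e5, 1.5e5, 2.5e5, 4e5, Inf),
      labels = roh_class_levels, include.lowest = TRUE, right = TRUE)
}

#' Bin ROH segments into length classes
#'
#' Classes partition (100 kb, Inf) at 150/250/400 kb with the boundary value
#' assigned to the lower class: `100-150Kb`, `>150-250Kb`, `>250-400Kb` and
#' `>400Kb`. Segments shorter than 100 kb violate the detector contract and
#' raise an error.
#'
#' @param segments ROH tibble from [detect_roh()].
#' @param pops Optional population map; counts are then per population,
#'   otherwise per sample-pool (`population = "all"`).
#' @return A tibble per population: `total`, then one count column per class.
#' @export
categorize_roh <- function(segments, pops = NULL) {
  if (nrow(segments) == 0L) {
    stop("no segments to categorize", call. = FALSE)
  }
  if (any(segments$length < 1e5)) {
    stop("segment(s) shorter than 100 kb violate the ROH length contract",
         call. = FALSE)
  }
  seg <- dplyr::mutate(segments, class = roh_length_class(.data$length))
  if (!is.null(pops)) {
    seg <- dplyr::left_join(seg, tibble::as_tibble(pops), by = "sample")
  } else {
    seg$population <- "all"
  }
  seg |>
    dplyr::count(.data$population, .data$class, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L) |>
    dplyr::mutate(total = rowSums(dplyr::across(dplyr::all_of(roh_class_levels))),
                  .after = "population")
}

#' Length-class shares of a ROH count table
#'
#' Takes a per-population count table (columns `population`, `total` and the
#' four class columns, e.g. from [categorize_roh()] or an external summary)
#' and recomputes the overall totals and the percentage share of each length
#' class, optionally for a subset of populations.
#'
#' @param counts Count tibble; class columns as in [categorize_roh()].
#' @param populations Optional subset of populations to pool (default: all).
#' @return A one-row tibble: `total`, and `<class>` / `<class>_pct` columns.
#' @export
roh_class_shares <- function(counts, populations = NULL) {
  if (!is.null(populations)) {
    missing_pop <- setdiff(populations, counts$population)
    if (length(missing_pop)) {
      stop("unknown population(s): ", paste(missing_pop, collapse = ", "),
           call. = FALSE)
    }
    counts <- counts[counts$population %in% populations, ]
  }
  sums <- colSums(counts[roh_class_levels])
  total <- sum(sums)
  stopifnot(all(counts$total == rowSums(counts[roh_class_levels])))
  out <- tibble::tibble(total = total)
  for (cl in roh_class_levels) {
    out[[cl]] <- sums[[cl]]
    out[[paste0(cl, "_pct")]] <- 100 * sums[[cl]] / total
  }
  out
}
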