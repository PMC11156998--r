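# Test fixtures and independent oracles, built in code.

# genotype matrix from a samples x variants call matrix and positions
make_geno <- function(calls, pos = NULL, chrom = "chr1",
                      samples = paste0("s", seq_len(nrow(calls)))) {
  calls <- as.matrix(calls)
  if (is.null(pos)) pos <- seq_len(ncol(calls)) * 1000L
  geno_matrix(
    calls,
    tibble::tibble(chrom = rep_len(chrom, ncol(calls)),
                   pos = as.integer(pos), ref = "A", alt = "C"),
    samples = samples
  )
}

# one population's calls realising exact per-site alt-allele counts
# (count c over n diploid samples -> floor(c/2) hom-alt + (c %% 2) het)
calls_from_alt_counts <- function(alt_counts, n_samples) {
  vapply(alt_counts, function(cc) {
    stopifnot(cc <= 2 * n_samples)
    c(rep(2L, cc %/% 2), rep(1L, cc %% 2),
      rep(0L, n_samples - cc %/% 2 - cc %% 2))
  }, integer(n_samples))
}

# multi-population geno + map realising exact alt counts per population;
# alt_counts: list of per-population count vectors (same length)
cohort_from_counts <- function(alt_counts, n_samples) {
  pops <- names(alt_counts)
  calls <- do.call(rbind, lapply(alt_counts, calls_from_alt_counts,
                                 n_samples = n_samples))
  samples <- as.vector(vapply(pops, function(p) paste0(p, "_", seq_len(n_samples)),
                              character(n_samples)))
  g <- make_geno(calls, samples = samples)
  list(g = g,
       pops = tibble::tibble(sample = samples,
                             population = rep(pops, each = n_samples)))
}

# write a small VCF from raw GT strings (variants x samples)
write_test_vcf <- function(path, chrom, pos, ref, alt, gt, samples) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT",
          apply(matrix(gt, ncol = length(samples), byrow = TRUE), 1, paste,
                collapse = "\t"),
          sep = "\t")
  )
  writeLines(lines, path)
  path
}

# line-by-line reference count of non-biallelic-SNP records in a VCF
reference_skip_count <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  sum(vapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1]]
    ref <- f[4]; alt <- f[5]
    grepl(",", alt, fixed = TRUE) || nchar(ref) != 1L || nchar(alt) != 1L
  }, logical(1)))
}

# exhaustive brute-force ROH finder implementing the same rules as
# detect_roh with naive loops: the independent oracle
roh_oracle <- function(calls, pos, params) {
  m <- length(calls)
  w <- params$scan_window_snps
  empty <- tibble::tibble(start = integer(), end = integer(),
                          length = numeric(), n_snps = integer())
  if (m < w) return(empty)
  hit <- logical(m - w + 1L)
  for (i in seq_along(hit)) {
    win <- calls[i:(i + w - 1L)]
    hit[i] <- sum(win == 1L, na.rm = TRUE) <= params$max_het_per_window &&
      sum(is.na(win)) <= params$max_missing_per_window
  }
  in_run <- logical(m)
  for (j in seq_len(m)) {
    cover <- intersect(seq_along(hit), (j - w + 1L):j)
    in_run[j] <- mean(hit[cover]) >= params$window_hit_threshold
  }
  segs <- empty
  j <- 1L
  while (j <= m) {
    if (!in_run[j]) { j <- j + 1L; next }
    k <- j
    while (k < m && in_run[k + 1L]) k <- k + 1L
    # split the stretch at large gaps
    piece_start <- j
    for (q in j:k) {
      end_piece <- q == k || (pos[q + 1L] - pos[q]) > params$max_gap
      if (end_piece) {
        n_snps <- q - piece_start + 1L
        len <- pos[q] - pos[piece_start] + 1
        if (n_snps >= params$min_snps && len >= params$min_length &&
            n_snps / len >= params$min_density) {
          segs <- rbind(segs, tibble::tibble(
            start = pos[piece_start], end = pos[q],
            length = len, n_snps = n_snps
          ))
        }
        piece_start <- q + 1L
      }
    }
    j <- k + 1L
  }
  segs
}

# per-site shared-allele IBS oracle on genotype pairs (counts shared
# ref/alt alleles explicitly)
ibs_oracle_pair <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  shared <- vapply(seq_along(a), function(i) {
    min(2 - a[i], 2 - b[i]) + min(a[i], b[i])
  }, numeric(1))
  list(ibs0 = sum(shared == 0), ibs1 = sum(shared == 1),
       ibs2 = sum(shared == 2), n = length(a))
}

# random genotype vector generator for property tests
random_calls <- function(m, p_het = 0.1, p_miss = 0.02) {
  x <- sample(c(0L, 1L, 2L, NA),  m, replace = TRUE,
              prob = c((1 - p_het - p_miss) * 0.6,
                       p_het, (1 - p_het - p_miss) * 0.4, p_miss))
  x
}
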