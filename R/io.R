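#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF 4.x file (plain or bgzipped) and returns the biallelic-SNP
#' genotype matrix. Multiallelic records and indels are skipped with a logged
#' count (or rejected, see `nonbiallelic`); phased and unphased genotypes are
#' treated identically. Variants are sorted by (chrom, pos) and duplicate
#' coordinates are an error.
#'
#' @param path Path to a VCF file.
#' @param region_filter Optional character vector of chromosome labels to keep.
#' @param nonbiallelic Either `"skip"` (default; drop multiallelic/indel
#'   records and record how many under `attr(, "n_skipped")`) or `"error"`.
#' @param quiet Suppress the skipped-record message.
#'
#' @return A [geno_matrix()] with attribute `n_skipped` (count of skipped
#'   non-biallelic-SNP records).
#' @export
read_vcf <- function(path, region_filter = NULL,
                     nonbiallelic = c("skip", "error"), quiet = FALSE) {
  nonbiallelic <- match.arg(nonbiallelic)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]

  biallelic_snp <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L
  n_skipped <- sum(!biallelic_snp)
  if (n_skipped > 0L) {
    if (nonbiallelic == "error") {
      stop(n_skipped, " record(s) are not biallelic SNPs", call. = FALSE)
    }
    if (!quiet) {
      message("read_vcf: skipped ", n_skipped, " non-biallelic-SNP record(s)")
    }
  }

  keep <- biallelic_snp
  if (!is.null(region_filter)) keep <- keep & chrom %in% region_filter
  if (!any(keep)) stop("no biallelic SNP records retained from ", path, call. = FALSE)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  chrom <- chrom[keep]; pos <- pos[keep]; ref <- ref[keep]; alt <- alt[keep]

  dup <- duplicated(paste(chrom, pos))
  if (any(dup)) {
    stop("duplicate (chrom, pos) record(s) in VCF, first at ",
         chrom[dup][1], ":", pos[dup][1], call. = FALSE)
  }

  calls <- gt_to_dosage(gt)          # variants x samples
  g <- geno_matrix(
    t(calls),
    tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt),
    samples = colnames(gt)
  )
  attr(g, "n_skipped") <- n_skipped
  g
}

# map GT strings to alt-allele dosage; phasing separator is irrelevant
gt_to_dosage <- function(gt) {
  u <- gsub("|", "/", gt, fixed = TRUE)
  out <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  out[u %in% c("0/0")] <- 0L
  out[u %in% c("0/1", "1/0")] <- 1L
  out[u %in% c("1/1")] <- 2L
  unknown <- !is.na(u) & !(u %in% c("0/0", "0/1", "1/0", "1/1", "./.", "."))
  if (any(unknown)) {
    stop("unparseable GT value(s), e.g. ", u[unknown][1], call. = FALSE)
  }
  out
}

#' Write a genotype matrix as a VCF 4.2 file
#'
#' Emits one GT-only record per variant, sorted by (chrom, pos), with
#' `##contig` headers. Round-trips through [read_vcf()].
#'
#' @param g A [geno_matrix()].
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "geno_matrix"))
  v <- g$variants
  contigs <- unique(v$chrom)
  clen <- vapply(contigs, function(ch) max(v$pos[v$chrom == ch]), numeric(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=popgenscan",
    sprintf("##contig=<ID=%s,length=%d>", contigs, as.integer(clen)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples), collapse = "\t")
  )
  gt_str <- c("0/0", "0/1", "1/1")[g$calls + 1L]
  gt_str[is.na(gt_str)] <- "./."
  gt_str <- matrix(gt_str, nrow = length(g$samples))
  body <- paste(
    v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".", "GT",
    apply(gt_str, 2, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write a sample-to-population map
#'
#' Two-column TSV (`sample`, `population`); a header line is optional on read
#' and recognised by its literal column names.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `sample` and `population`.
#' @export
read_pop_map <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- identical(strsplit(first, "\t")[[1]][1:2], c("sample", "population"))
  pm <- readr::read_tsv(
    path,
    col_names = if (has_header) TRUE else c("sample", "population"),
    col_types = readr::cols(.default = readr::col_character()),
    skip = if (has_header) 0L else 0L,
    progress = FALSE
  )
  if (has_header) pm <- pm[c("sample", "population")]
  tibble::as_tibble(pm)
}

#' @rdname read_pop_map
#' @param pops Tibble with columns `sample`, `population`.
#' @export
write_pop_map <- function(pops, path) {
  readr::write_tsv(pops[c("sample", "population")], path, progress = FALSE)
  invisible(path)
}
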