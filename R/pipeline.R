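#' Run the full diversity / ROH / selection-scan / f-statistics pipeline
#'
#' Orchestrates every stage on either a VCF + population map or a simulated
#' cohort, and writes a fixed-name report bundle under `out_dir`:
#' per-population diversity summary, per-sample Ho and F_ROH tables, ROH
#' segments and length-class summary, per-comparison FST and per-population
#' Hp scans with Z-scores, candidate selection regions (TSV + BED), an
#' f-statistics table, and a machine-readable `manifest.json` echoing every
#' parameter and the MD5 of every output. Outputs are deterministic for a
#' fixed input / simulation seed.
#'
#' @param vcf,pop_map_file Paths to a VCF and a two-column population map
#'   (mutually exclusive with `sim`).
#' @param sim A [sim_config()] to simulate the cohort instead.
#' @param out_dir Output directory (created if needed).
#' @param comparisons Tibble (`test`, `reference`) of FST comparisons;
#'   default: every other population against the last population label
#'   (reference-population design).
#' @param window,step Scan window/step in bp for FST and Hp (100 kb / 25 kb).
#' @param pi_window,pi_step Window/step for nucleotide diversity
#'   (100 kb / 50 kb).
#' @param min_snps Minimum SNPs per FST window.
#' @param tail Outlier tail fraction (default 0.01).
#' @param fst_dialect `"site_mean"` or `"wc"` (see [fst_windows()]).
#' @param roh A [roh_params()] list.
#' @param autosome_length Genome length for F_ROH; defaults to the summed
#'   simulated chromosome lengths, or 2.4e9 bp for VCF input.
#' @param fstat_tests Optional test table for [fstat_table()]; default: one
#'   f3 and (given >= 4 populations) one f4 over the first populations.
#' @return Invisibly, a list with every stage's tibbles plus the manifest.
#' @export
run_pipeline <- function(vcf = NULL, pop_map_file = NULL, sim = NULL,
                         out_dir,
                         comparisons = NULL,
                         window = 1e5, step = 2.5e4,
                         pi_window = 1e5, pi_step = 5e4,
                         min_snps = 30L, tail = 0.01,
                         fst_dialect = c("site_mean", "wc"),
                         roh = roh_params(),
                         autosome_length = NULL,
                         fstat_tests = NULL) {
  fst_dialect <- match.arg(fst_dialect)
  if (is.null(sim) == is.null(vcf)) {
    stop("supply exactly one of `vcf` + `pop_map_file` or `sim`", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (!is.null(sim)) {
    cohort <- stage("simulate", simulate_genotypes(sim))
    g <- cohort$genotypes
    pops <- cohort$pop_map
    if (is.null(autosome_length)) autosome_length <- sum(sim$chrom_lengths)
  } else {
    g <- stage("ingest", read_vcf(vcf, quiet = TRUE))
    pops <- stage("ingest", pop_map(g, read_pop_map(pop_map_file)))
    if (is.null(autosome_length)) autosome_length <- 2.4e9
  }
  pop_labels <- unique(pops$population)

  if (is.null(comparisons)) {
    ref <- pop_labels[length(pop_labels)]
    comparisons <- tibble::tibble(test = setdiff(pop_labels, ref),
                                  reference = ref)
  }
  comparisons <- tibble::as_tibble(comparisons)

  out <- list()
  tsv <- function(x, name) {
    readr::write_tsv(x, file.path(out_dir, name), progress = FALSE)
    name
  }
  files <- character()

  # --- diversity -----------------------------------------------------------
  out$roh_segments <- stage("roh", detect_roh(g, params = roh))
  out$diversity <- stage("diversity", diversity_summary(
    g, pops, roh_segments = out$roh_segments,
    autosome_length = autosome_length, window = pi_window, step = pi_step
  ))
  out$ho <- stage("diversity", observed_heterozygosity(g, pops))
  out$ibs <- stage("diversity", pairwise_ibs_distance(g, pops))
  files <- c(files,
             tsv(out$diversity, "diversity_summary.tsv"),
             tsv(out$ho, "ho_per_sample.tsv"),
             tsv(out$ibs, "ibs_pairs.tsv"))

  # --- ROH -----------------------------------------------------------------
  out$froh <- stage("roh", froh(out$roh_segments, autosome_length,
                                samples = g$samples))
  files <- c(files,
             tsv(out$roh_segments, "roh_segments.tsv"),
             tsv(out$froh, "froh_per_sample.tsv"))
  if (nrow(out$roh_segments) && all(out$roh_segments$length >= 1e5)) {
    out$roh_summary <- stage("roh", categorize_roh(out$roh_segments, pops))
    files <- c(files, tsv(out$roh_summary, "roh_summary.tsv"))
  }

  # --- selection scans -----------------------------------------------------
  out$scans <- purrr::pmap(comparisons, function(test, reference) {
    zfst <- stage(paste0("fst ", test, " vs ", reference), {
      fst_windows(g, pops, test, reference, window, step, min_snps,
                  dialect = fst_dialect) |> zscore_windows()
    })
    zhp <- stage(paste0("hp ", test), {
      hp_windows(g, pops, test, window, step) |> zscore_windows()
    })
    cand <- stage("outliers", call_outliers(zfst, zhp, tail))
    slug <- paste0(test, "_vs_", reference)
    files <<- c(files,
                tsv(zfst, paste0("fst_", slug, ".tsv")),
                tsv(zhp, paste0("hp_", test, ".tsv")),
                tsv(cand, paste0("candidates_", slug, ".tsv")))
    bed <- file.path(out_dir, paste0("candidates_", slug, ".bed"))
    writeLines(
      sprintf("%s\t%d\t%d", cand$chrom, as.integer(cand$start - 1),
              as.integer(cand$end - 1)),
      bed
    )
    files <<- c(files, basename(bed))
    list(test = test, reference = reference, zfst = zfst, zhp = zhp,
         candidates = cand)
  })

  # --- f statistics --------------------------------------------------------
  if (is.null(fstat_tests) && length(pop_labels) >= 3L) {
    fstat_tests <- tibble::tibble(
      type = "f3", a = pop_labels[1], b = pop_labels[2], c = pop_labels[3],
      d = NA_character_
    )
    if (length(pop_labels) >= 4L) {
      fstat_tests <- dplyr::bind_rows(fstat_tests, tibble::tibble(
        type = "f4", a = pop_labels[1], b = pop_labels[2],
        c = pop_labels[3], d = pop_labels[4]
      ))
    }
  }
  if (!is.null(fstat_tests)) {
    out$fstats <- stage("fstats", fstat_table(g, pops, fstat_tests))
    files <- c(files, tsv(out$fstats, "fstats.tsv"))
  }

  # --- manifest ------------------------------------------------------------
  manifest <- list(
    package = "popgenscan",
    version = as.character(utils::packageVersion("popgenscan")),
    input = if (!is.null(sim)) list(type = "simulated", seed = sim$seed)
            else list(type = "vcf", vcf = vcf, pop_map = pop_map_file),
    parameters = list(
      window = window, step = step, pi_window = pi_window, pi_step = pi_step,
      min_snps = min_snps, tail = tail, fst_dialect = fst_dialect,
      autosome_length = autosome_length, roh = unclass(roh)
    ),
    comparisons = comparisons,
    files = as.list(tools::md5sum(file.path(out_dir, files)) |>
                      stats::setNames(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}
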