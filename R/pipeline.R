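#' Run the full ZW discovery pipeline from one configuration
#'
#' Orchestrates simulate (optional) -> coverage assignment -> SNP-strata
#' detection (with reverse-polarity control) -> dosage-compensation
#' analysis -> qPCR validation, with every stage reading and writing plain
#' files in `outdir`, so any stage can be re-run or replaced by external
#' inputs. A machine-readable JSON summary is written at the end.
#'
#' The configuration is a named list (or YAML file path) with elements:
#' \describe{
#'   \item{simulate}{list of [sim_config()] arguments, or `NULL` to use
#'     pre-existing files in `outdir`.}
#'   \item{min_len}{coverage length cutoff, bp (default 5000).}
#'   \item{zones}{zone preset name (default `"default"`).}
#'   \item{min_depth, min_qual}{site filters (defaults 10, 20).}
#'   \item{min_snps, min_prop}{young-stratum thresholds (10, 0.20).}
#'   \item{cutoff}{expressed-gene RPKM cutoff (1).}
#'   \item{alpha}{sex-bias adjusted-p cutoff (0.05).}
#'   \item{reverse_control}{logical, run the XY control branch (TRUE).}
#' }
#'
#' @param config named list or path to a YAML file.
#' @param outdir working/output directory.
#' @return the summary list (also written as `summary.json`), invisibly
#'   returned.
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("zwscan_")) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg_get <- function(name, default) config[[name]] %||% default
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed (outdir: ", outdir, "): ",
           conditionMessage(e), call. = FALSE))
  }

  if (!is.null(config$simulate)) {
    sim <- stage("simulate", do.call(sim_config, config$simulate))
    stage("simulate", simulate_study(sim, outdir))
  }

  coverage <- stage("covassign", read_tsv_table(file.path(outdir, "coverage.tsv")))
  zones <- zone_spec(cfg_get("zones", "default"))
  cov <- stage("covassign",
               assign_coverage(coverage, min_len = cfg_get("min_len", 5000),
                               zones = zones))
  write_tsv_table(cov$assignments, file.path(outdir, "assignments.tsv"))

  samples <- stage("snpstrata", read_tsv_table(file.path(outdir, "samples.tsv")))
  variants <- stage("snpstrata",
                    read_variants_vcf(file.path(outdir, "variants.vcf")))
  variants <- stage("snpstrata",
                    filter_sites(variants, min_depth = cfg_get("min_depth", 10),
                                 min_qual = cfg_get("min_qual", 20)))
  strata <- stage("snpstrata",
                  reverse_control(variants, samples, cov$assignments,
                                  min_snps = cfg_get("min_snps", 10),
                                  min_prop = cfg_get("min_prop", 0.20)))
  write_tsv_table(strata$forward$scaffold_summary,
                  file.path(outdir, "scaffold_snp_summary.tsv"))
  young <- strata$forward$scaffold_summary
  young_scaffolds <- young$scaffold[young$young_flag]
  # promote flagged scaffolds in a copy of the assignment table
  final_assign <- cov$assignments
  final_assign$class[final_assign$scaffold %in% young_scaffolds] <- "young-Z"
  write_tsv_table(final_assign, file.path(outdir, "assignments_final.tsv"))

  counts_df <- stage("dosagex", read_tsv_table(file.path(outdir, "counts.tsv")))
  design <- stage("dosagex", read_tsv_table(file.path(outdir, "design.tsv")))
  tx_map <- stage("dosagex", read_tsv_table(file.path(outdir, "transcripts.tsv")))
  counts <- as.matrix(counts_df[, -1, drop = FALSE])
  rownames(counts) <- counts_df[[1]]
  mapped <- map_transcripts(cov$assignments, tx_map)
  tx_class <- stats::setNames(mapped$transcripts$class,
                              mapped$transcripts$transcript)
  lengths <- tx_map$length[match(rownames(counts), tx_map$transcript)]
  tissues <- unique(design$tissue)
  dosage <- lapply(tissues, function(tis) stage("dosagex", {
    rep <- dosage_report(counts, lengths, design, tis, tx_class,
                         cutoff = cfg_get("cutoff", 1))
    de <- call_sex_biased(counts, design, tis, alpha = cfg_get("alpha", 0.05))
    de$class <- unname(tx_class[de$transcript])
    write_tsv_table(de, file.path(outdir, paste0("sex_biased_", tis, ".tsv")))
    rpkm <- compute_rpkm(counts, lengths)
    d <- design[design$tissue == tis, ]
    tisn <- quantile_normalize(rpkm[, d$sample, drop = FALSE])
    spec <- call_sex_specific(tisn, design, tis)
    list(report = rep, de = de, sex_specific = spec)
  }))
  names(dosage) <- tissues

  qpcr_path <- file.path(outdir, "qpcr.tsv")
  qpcr <- if (file.exists(qpcr_path))
    stage("qpcrval", analyze_qpcr(read_tsv_table(qpcr_path))) else NULL
  if (!is.null(qpcr))
    write_tsv_table(qpcr$per_gene, file.path(outdir, "qpcr_calls.tsv"))

  summary <- list(
    scaffold_classes = as.list(table(final_assign$class)),
    median_log2_fm = cov$median_log2_fm,
    young_stratum = list(
      n_flagged = strata$forward$n_flagged,
      n_consistent_total = strata$forward$n_consistent_total,
      n_consistent_on_flagged = strata$forward$n_consistent_on_flagged,
      dna_assessable = strata$forward$dna$n_assessable,
      dna_consistent = strata$forward$dna$n_consistent,
      dna_proportion = strata$forward$dna$proportion,
      reverse_n_flagged = strata$reverse$n_flagged,
      reverse_n_consistent_total = strata$reverse$n_consistent_total,
      comparison_chi2 = strata$comparison$chi2,
      comparison_p = strata$comparison$p_value
    ),
    dosage = lapply(dosage, function(x) list(
      n_genes = as.list(x$report$n_genes),
      medians = as.list(x$report$medians),
      p_values = lapply(x$report$tests, `[[`, "p_value"),
      median_log2_fm_ratio_z = x$report$ratio$median_log2_z,
      median_log2_fm_ratio_a = x$report$ratio$median_log2_a,
      n_female_biased = sum(x$de$bias == "female"),
      n_male_biased = sum(x$de$bias == "male"),
      n_female_specific = length(x$sex_specific$female_specific),
      n_male_specific = length(x$sex_specific$male_specific)
    )),
    qpcr = if (!is.null(qpcr)) lapply(split(qpcr$per_gene, qpcr$per_gene$gene),
                                      function(g) list(
                                        fold = g$fold_male_over_female,
                                        call = g$call)) else NULL
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
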