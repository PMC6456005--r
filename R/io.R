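#' Read and write the pipeline's plain-text tables
#'
#' All stage contracts are tab-separated files with a header line. These
#' thin wrappers fix the dialect (no quoting, no row names, `NA` as `NA`)
#' so stages round-trip byte-identically.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_tsv_table()` returns a data.frame; `write_tsv_table()`
#'   returns `path` invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a simulated variant set as minimal VCF 4.2
#'
#' Emits one biallelic SNP record per site with per-sample `GT:AD:DP`
#' fields (AD as `ref,alt`), 1-based positions, and the site quality in
#' QUAL. The GT field is a coarse call from the allele fraction and is
#' informational only; the classification pipeline re-calls genotypes from
#' AD under its own thresholds.
#'
#' @param variants output of [simulate_variants()].
#' @param path output file path (`.vcf`, uncompressed).
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  sites <- variants$sites
  rd <- variants$ref_depth
  ad <- variants$alt_depth
  samp <- colnames(rd)
  dp <- rd + ad
  af <- ifelse(dp > 0, ad / dp, NA)
  gt <- matrix("./.", nrow(rd), ncol(rd))
  gt[!is.na(af) & af <= 0.5] <- "0/0"
  gt[!is.na(af) & af > 0.5] <- "1/1"
  gt[!is.na(af) & af > 0.25 & af <= 0.75] <- "0/1"
  field <- matrix(paste0(gt, ":", rd, ",", ad, ":", dp), nrow(rd), ncol(rd))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=zwscan-simgen",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samp), collapse = "\t")
  )
  body <- paste(sites$scaffold, sites$pos, ".", sites$ref, sites$alt,
                sites$qual, "PASS", ".", "GT:AD:DP",
                apply(field, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into the site table + allele-depth matrices used downstream
#'
#' Parses a VCF 4.2 file with per-sample `AD` fields (via `vcfR`), drops
#' indels and multiallelic records, and returns the same structure that
#' [simulate_variants()] produces so real and simulated inputs are
#' interchangeable.
#'
#' @param path VCF file path.
#' @return list with `sites` (scaffold, pos, ref, alt, qual), `ref_depth`,
#'   `alt_depth` (sites x samples integer matrices).
#' @export
read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L & !grepl(",", fix$ALT) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  fix <- fix[snp, , drop = FALSE]
  ad <- ad[snp, , drop = FALSE]
  split_ad <- function(col, which) {
    out <- suppressWarnings(
      as.integer(vapply(strsplit(ifelse(is.na(col), "0,0", col), ","),
                        `[`, "", which)))
    out[is.na(out)] <- 0L
    out
  }
  ref_depth <- apply(ad, 2, split_ad, which = 1L)
  alt_depth <- apply(ad, 2, split_ad, which = 2L)
  if (is.null(dim(ref_depth))) {  # single site edge case
    ref_depth <- matrix(ref_depth, 1, dimnames = list(NULL, colnames(ad)))
    alt_depth <- matrix(alt_depth, 1, dimnames = list(NULL, colnames(ad)))
  }
  sites <- data.frame(
    scaffold = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    stringsAsFactors = FALSE
  )
  list(sites = sites, ref_depth = ref_depth, alt_depth = alt_depth)
}

#' Write every simulated artifact of one study to a directory
#'
#' Materializes the file contract consumed by the analysis stages:
#' `coverage.tsv`, `variants.vcf`, `samples.tsv`, `counts.tsv`,
#' `design.tsv`, `transcripts.tsv`, `truth.tsv` and `qpcr.tsv`.
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory (created if absent).
#' @return named character vector of the files written, invisibly.
#' @export
simulate_study <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  genome <- simulate_genome(cfg)
  coverage <- simulate_coverage(genome, cfg)
  variants <- simulate_variants(genome, cfg)
  expr <- simulate_counts(genome, cfg)
  z_sc <- genome$scaffolds$scaffold[genome$scaffolds$true_class == "Z"]
  a_sc <- genome$scaffolds$scaffold[genome$scaffolds$true_class == "A"]
  qpcr <- simulate_qpcr(
    target_classes = c(stats::setNames(rep("Z", min(2, length(z_sc))),
                                       utils::head(z_sc, 2)),
                       stats::setNames(rep("A", min(1, length(a_sc))),
                                       utils::head(a_sc, 1))),
    seed = .artifact_seed(cfg, "qpcr"))
  counts_df <- data.frame(transcript = rownames(expr$counts),
                          expr$counts, check.names = FALSE,
                          stringsAsFactors = FALSE)
  paths <- c(
    coverage = write_tsv_table(coverage, file.path(outdir, "coverage.tsv")),
    variants = write_variants_vcf(variants, file.path(outdir, "variants.vcf")),
    samples = write_tsv_table(variants$samples, file.path(outdir, "samples.tsv")),
    counts = write_tsv_table(counts_df, file.path(outdir, "counts.tsv")),
    design = write_tsv_table(expr$design, file.path(outdir, "design.tsv")),
    transcripts = write_tsv_table(genome$transcripts,
                                  file.path(outdir, "transcripts.tsv")),
    truth = write_tsv_table(genome$scaffolds, file.path(outdir, "truth.tsv")),
    qpcr = write_tsv_table(qpcr, file.path(outdir, "qpcr.tsv"))
  )
  invisible(paths)
}
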