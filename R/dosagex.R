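#' RPKM from raw counts
#'
#' reads per kilobase of transcript per million mapped reads:
#' `count * 1e9 / (length_bp * library_size)`. Library sizes default to the
#' per-sample column sums of the count matrix.
#'
#' @param counts transcripts x samples numeric matrix (rownames =
#'   transcript ids).
#' @param lengths transcript lengths in bp, aligned with rows.
#' @param library_sizes per-sample mapped-read totals; default `colSums`.
#' @return RPKM matrix of the same shape.
#' @examples
#' compute_rpkm(matrix(10), lengths = 1000, library_sizes = 1e6)  # 10
#' @export
compute_rpkm <- function(counts, lengths, library_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts)) stop("one length per transcript required")
  if (any(lengths <= 0)) stop("transcript lengths must be > 0")
  if (any(library_sizes <= 0)) stop("library sizes must be > 0")
  t(t(counts / lengths) / library_sizes) * 1e9
}

#' Quantile normalization across samples
#'
#' Forces every column to share one empirical distribution: each sample's
#' sorted values are replaced by the across-sample mean of sorted values,
#' ties receiving the mean of their tied positions (the
#' `limma::normalizeQuantiles` convention, with `ties = TRUE`). Applied
#' within one tissue at a time in this pipeline.
#'
#' @param mat numeric matrix, transcripts x samples.
#' @return normalized matrix; identical column value multisets afterwards.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) == 1L) {
    warning("single-sample input: quantile normalization is the identity")
    return(mat)
  }
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Keep transcripts expressed in all samples of a tissue
#'
#' A transcript counts as expressed in a tissue when every one of that
#' tissue's samples has RPKM at or above the cutoff (inclusive). The
#' canonical cutoff is 1; 0, 2 and 5 are the sensitivity settings.
#'
#' @param rpkm RPKM matrix (already subset to, or containing, the tissue's
#'   samples).
#' @param tissue_samples character vector of the tissue's sample ids.
#' @param cutoff RPKM threshold, inclusive.
#' @return the row-subset RPKM matrix.
#' @export
filter_expressed <- function(rpkm, tissue_samples, cutoff = 1) {
  sub <- rpkm[, tissue_samples, drop = FALSE]
  keep <- rowSums(sub >= cutoff) == length(tissue_samples)
  rpkm[keep, , drop = FALSE]
}

#' Average replicates and renormalize per sex
#'
#' Within one tissue: arithmetic mean of the replicate columns per sex,
#' then a second quantile normalization across the two sex columns so the
#' final female and male expression vectors share one distribution.
#'
#' @param rpkm within-tissue normalized RPKM matrix.
#' @param design data.frame (sample, tissue, sex, replicate).
#' @param tissue tissue to process.
#' @return matrix with columns `female`, `male`.
#' @export
average_and_renormalize <- function(rpkm, design, tissue) {
  d <- design[design$tissue == tissue, , drop = FALSE]
  avg <- sapply(c("female", "male"), function(sx) {
    cols <- d$sample[d$sex == sx]
    rowMeans(rpkm[, cols, drop = FALSE])
  })
  quantile_normalize(avg)
}

#' Two-sided Wilcoxon comparison
#'
#' Rank-sum (unpaired) or signed-rank (paired) test; exact for small
#' untied samples, tie-corrected normal approximation otherwise. Completely
#' tied data yield p = 1.
#'
#' @param values_a,values_b numeric vectors.
#' @param paired logical.
#' @return list(statistic, p_value).
#' @export
wilcoxon_compare <- function(values_a, values_b, paired = FALSE) {
  if (length(values_a) == 0L || length(values_b) == 0L)
    stop("both groups must be nonempty")
  if (all(c(values_a, values_b) == c(values_a, values_b)[1]))
    return(list(statistic = NA_real_, p_value = 1))
  res <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, paired = paired,
                       alternative = "two.sided",
                       exact = length(values_a) + length(values_b) < 25))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Per-gene female:male expression ratios, Z vs autosomes
#'
#' From the averaged, renormalized per-sex matrix: per-gene
#' `log2(female / male)` (the expressed-gene filter guarantees no zeros),
#' split by scaffold class, compared by an unpaired Wilcoxon test.
#'
#' @param avg matrix with `female`, `male` columns (rownames = transcripts).
#' @param tx_class named character vector transcript -> coverage class.
#' @return list(ratios = data.frame(transcript, class, log2_fm_ratio,
#'   fm_ratio), test = wilcoxon result Z vs autosome, median_log2_z,
#'   median_log2_a).
#' @export
fm_ratio_compare <- function(avg, tx_class) {
  cls <- tx_class[rownames(avg)]
  ratio <- log2(avg[, "female"] / avg[, "male"])
  ratios <- data.frame(transcript = rownames(avg), class = unname(cls),
                       log2_fm_ratio = unname(ratio),
                       fm_ratio = unname(2^ratio),
                       stringsAsFactors = FALSE)
  z <- ratio[!is.na(cls) & cls == "Z"]
  a <- ratio[!is.na(cls) & cls == "autosome"]
  test <- if (length(z) > 0 && length(a) > 0) wilcoxon_compare(z, a)
          else list(statistic = NA_real_, p_value = NA_real_)
  list(ratios = ratios, test = test,
       median_log2_z = stats::median(z), median_log2_a = stats::median(a))
}

#' Sex-specific transcripts by the strict two-threshold rule
#'
#' A transcript is specific to one sex in a tissue when its RPKM is below
#' 0.1 in both replicates of the other sex and above 1 in both replicates
#' of that sex (both bounds strict).
#'
#' @param rpkm within-tissue normalized (un-averaged) RPKM matrix.
#' @param design design data.frame.
#' @param tissue tissue to scan.
#' @param off_max upper bound for "off" (strict `<`).
#' @param on_min lower bound for "on" (strict `>`).
#' @return list(female_specific, male_specific) transcript id vectors.
#' @export
call_sex_specific <- function(rpkm, design, tissue, off_max = 0.1, on_min = 1) {
  d <- design[design$tissue == tissue, , drop = FALSE]
  f <- rpkm[, d$sample[d$sex == "female"], drop = FALSE]
  m <- rpkm[, d$sample[d$sex == "male"], drop = FALSE]
  f_on <- rowSums(f > on_min) == ncol(f)
  f_off <- rowSums(f < off_max) == ncol(f)
  m_on <- rowSums(m > on_min) == ncol(m)
  m_off <- rowSums(m < off_max) == ncol(m)
  list(female_specific = rownames(rpkm)[f_on & m_off],
       male_specific = rownames(rpkm)[m_on & f_off])
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median across genes of
#' the ratio of each sample's count to the per-gene geometric mean, using
#' only genes with nonzero counts in every sample.
#'
#' @param counts transcripts x samples count matrix.
#' @return numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no gene has nonzero counts in every sample")
  lg <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  apply(exp(lg - geo), 2, stats::median)
}

#' Sex-biased transcripts (moderated-t stand-in, not DESeq2)
#'
#' Lightweight differential-expression caller for the 2 vs 2 within-tissue
#' design: counts are normalized by median-of-ratios [size_factors()],
#' log2-transformed with a 0.5 pseudocount, and tested female vs male with
#' an empirical-Bayes moderated t-test (limma) with a mean-variance trend.
#' Transcripts with Benjamini-Hochberg adjusted p below `alpha` are called
#' biased, direction by the sign of the female-minus-male log fold change.
#' This is deliberately a simple stand-in for a negative-binomial DE
#' model, adequate for threshold-policy analyses; it is not DESeq2.
#'
#' @param counts raw count matrix for one tissue (4 samples).
#' @param design design data.frame rows for those samples.
#' @param tissue tissue label (rows of `design` are subset to it).
#' @param alpha adjusted-p cutoff.
#' @return data.frame (transcript, log2_fc_fm, p_value, padj, bias in
#'   {female, male, none}); all-zero transcripts are excluded.
#' @export
call_sex_biased <- function(counts, design, tissue, alpha = 0.05) {
  d <- design[design$tissue == tissue, , drop = FALSE]
  cm <- as.matrix(counts)[, d$sample, drop = FALSE]
  cm <- cm[rowSums(cm) > 0, , drop = FALSE]
  sf <- size_factors(cm)
  lm2 <- log2(t(t(cm) / sf) + 0.5)
  sex <- factor(d$sex, levels = c("male", "female"))
  mm <- stats::model.matrix(~sex)
  fit <- limma::eBayes(limma::lmFit(lm2, mm), trend = TRUE)
  p <- fit$p.value[, "sexfemale"]
  lfc <- fit$coefficients[, "sexfemale"]
  padj <- bh_adjust(p)
  bias <- ifelse(padj < alpha, ifelse(lfc > 0, "female", "male"), "none")
  data.frame(transcript = rownames(cm), log2_fc_fm = unname(lfc),
             p_value = unname(p), padj = unname(padj), bias = unname(bias),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (`p * m / rank`, cumulative
#' minimum from the largest p, capped at 1, original order restored).
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return adjusted p-values, same order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Used for the between-tissue overlap of sex-biased genes and for Z vs
#' autosome counts of sex-biased genes.
#'
#' @param a,b,c,d the 2x2 cell counts, row-wise: `[[a, b], [c, d]]`.
#' @return list(odds_ratio, p_value).
#' @export
enrichment_fisher <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  res <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))
  list(odds_ratio = unname(res$estimate), p_value = res$p.value)
}

#' Full dosage-compensation report for one tissue
#'
#' Runs the expression pipeline for one tissue: RPKM, within-tissue
#' quantile normalization, the expressed-in-all-samples filter, replicate
#' averaging with a second normalization, then the five Wilcoxon
#' comparisons (F vs M on Z; F vs M on autosomes; Z vs A within each sex;
#' F:M ratios Z vs A) plus class medians and gene counts.
#'
#' @param counts raw count matrix (all samples).
#' @param lengths transcript lengths aligned with `counts` rows.
#' @param design design data.frame.
#' @param tissue tissue to analyse.
#' @param tx_class named vector transcript -> coverage class.
#' @param cutoff expressed-gene RPKM cutoff.
#' @return list: tissue, n_genes (per class), medians (Z/A x F/M), tests
#'   (named wilcoxon results), ratio (the [fm_ratio_compare()] output).
#' @export
dosage_report <- function(counts, lengths, design, tissue, tx_class,
                          cutoff = 1) {
  d <- design[design$tissue == tissue, , drop = FALSE]
  rpkm <- compute_rpkm(counts, lengths)
  tis <- quantile_normalize(rpkm[, d$sample, drop = FALSE])
  expressed <- filter_expressed(tis, d$sample, cutoff)
  avg <- average_and_renormalize(expressed, d, tissue)
  cls <- tx_class[rownames(avg)]
  z <- !is.na(cls) & cls == "Z"
  a <- !is.na(cls) & cls == "autosome"
  tests <- list(
    fm_on_z = wilcoxon_compare(avg[z, "female"], avg[z, "male"]),
    fm_on_a = wilcoxon_compare(avg[a, "female"], avg[a, "male"]),
    za_in_f = wilcoxon_compare(avg[z, "female"], avg[a, "female"]),
    za_in_m = wilcoxon_compare(avg[z, "male"], avg[a, "male"])
  )
  ratio <- fm_ratio_compare(avg, tx_class)
  tests$ratio_z_vs_a <- ratio$test
  list(
    tissue = tissue,
    n_genes = c(Z = sum(z), autosome = sum(a), total = nrow(avg)),
    medians = c(z_female = stats::median(avg[z, "female"]),
                z_male = stats::median(avg[z, "male"]),
                a_female = stats::median(avg[a, "female"]),
                a_male = stats::median(avg[a, "male"])),
    tests = tests,
    ratio = ratio
  )
}
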