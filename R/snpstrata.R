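#' Site and per-sample filters for pooled variant data
#'
#' Applies the variant-calling filters to a parsed site table: indels and
#' multiallelic records are dropped outright, sites with quality not
#' exceeding `min_qual` are dropped (strict `>`), and any sample whose total
#' depth at a site is below `min_depth` has that sample's data masked as
#' missing (its genotype becomes unassessable) rather than the whole site
#' being lost.
#'
#' @param variants list with `sites`, `ref_depth`, `alt_depth` as returned
#'   by [simulate_variants()] or [read_variants_vcf()].
#' @param min_depth minimum reads per sample per site (inclusive).
#' @param min_qual site Phred quality; retained only if `qual > min_qual`.
#' @return a filtered copy of `variants`; masked sample/site cells carry
#'   `NA` in both depth matrices.
#' @export
filter_sites <- function(variants, min_depth = 10, min_qual = 20) {
  sites <- variants$sites
  rd <- variants$ref_depth
  ad <- variants$alt_depth
  if (any(rd < 0, na.rm = TRUE) || any(ad < 0, na.rm = TRUE))
    stop("malformed site: negative depth")
  snp <- nchar(sites$ref) == 1L & nchar(sites$alt) == 1L &
    !grepl(",", sites$alt, fixed = TRUE)
  keep <- snp & !is.na(sites$qual) & sites$qual > min_qual
  sites <- sites[keep, , drop = FALSE]
  rd <- rd[keep, , drop = FALSE]
  ad <- ad[keep, , drop = FALSE]
  low <- (rd + ad) < min_depth
  rd[low] <- NA_integer_
  ad[low] <- NA_integer_
  out <- variants
  out$sites <- sites
  out$ref_depth <- rd
  out$alt_depth <- ad
  out
}

#' Genotype call from ref/alt read counts
#'
#' Vectorized hard-threshold caller for pooled samples. With alt fraction
#' `a = alt / (ref + alt)`: `a >= 0.85` is `hom_alt`, `a <= 0.15` is
#' `hom_ref`, and a site is `het` only when the minor allele fraction
#' strictly exceeds 0.30 — the stricter heterozygote rule that guards
#' against false heterozygotes in pooled data. Fractions in the ambiguous
#' band (0.15, 0.30] yield `no_call`. `NA` depths (masked by
#' [filter_sites()]) propagate to `NA` calls.
#'
#' @param ref_depth,alt_depth non-negative integer vectors.
#' @param het_minor_min minor-allele fraction that must be exceeded for a
#'   heterozygote call.
#' @param hom_max alt-fraction at or below which (or at or above 1 minus
#'   which) a homozygote is called.
#' @return character vector in {`hom_ref`, `het`, `hom_alt`, `no_call`, NA}.
#' @export
call_genotype <- function(ref_depth, alt_depth,
                          het_minor_min = 0.30, hom_max = 0.15) {
  tot <- ref_depth + alt_depth
  if (any(!is.na(tot) & tot == 0)) stop("zero total depth; mask such cells as NA")
  a <- alt_depth / tot
  minor <- pmin(a, 1 - a)
  out <- rep(NA_character_, length(a))
  ok <- !is.na(a)
  out[ok] <- "no_call"
  out[ok & a >= 1 - hom_max] <- "hom_alt"
  out[ok & a <= hom_max] <- "hom_ref"
  out[ok & minor > het_minor_min] <- "het"
  out
}

#' Classify one site as sex-linkage consistent
#'
#' Under ZW polarity a site is `ZW_consistent` when every female pool is
#' heterozygous and every male pool homozygous (either homozygote) — the
#' genotype pattern of a fixed Z/W difference with ZW females and ZZ males.
#' XY polarity mirrors the rule with the sexes swapped. Any `no_call` or
#' missing call among the pools makes the site `unassessable`; every other
#' pattern is `other`.
#'
#' @param female_calls,male_calls character vectors of per-pool genotype
#'   calls (one entry per pool).
#' @param polarity `"ZW"` or `"XY"`.
#' @param n_pools expected pools per sex.
#' @return one of `"ZW_consistent"`/`"XY_consistent"`, `"other"`,
#'   `"unassessable"`.
#' @export
classify_site <- function(female_calls, male_calls, polarity = c("ZW", "XY"),
                          n_pools = 4L) {
  polarity <- match.arg(polarity)
  if (length(female_calls) != n_pools || length(male_calls) != n_pools)
    stop("expected ", n_pools, " calls per sex")
  all_calls <- c(female_calls, male_calls)
  if (any(is.na(all_calls)) || any(all_calls == "no_call"))
    return("unassessable")
  het_sex <- if (polarity == "ZW") female_calls else male_calls
  hom_sex <- if (polarity == "ZW") male_calls else female_calls
  if (all(het_sex == "het") && all(hom_sex %in% c("hom_ref", "hom_alt")))
    return(paste0(polarity, "_consistent"))
  "other"
}

#' Classify every site in a filtered variant set
#'
#' Calls genotypes for the RNA pools of each sex and applies
#' [classify_site()] row-wise.
#'
#' @param variants filtered variant set ([filter_sites()]).
#' @param samples sample sheet (sample, sex, material); RNA pools are the
#'   rows with material `"RNA_pool"`.
#' @param polarity `"ZW"` or `"XY"`.
#' @return the `sites` data.frame with an added `site_class` column.
#' @export
classify_sites <- function(variants, samples, polarity = c("ZW", "XY")) {
  polarity <- match.arg(polarity)
  f_pools <- samples$sample[samples$sex == "female" & samples$material == "RNA_pool"]
  m_pools <- samples$sample[samples$sex == "male" & samples$material == "RNA_pool"]
  calls <- function(cols) {
    vapply(cols, function(s)
      call_genotype(variants$ref_depth[, s], variants$alt_depth[, s]),
      character(nrow(variants$sites)))
  }
  n <- nrow(variants$sites)
  fc <- matrix(calls(f_pools), nrow = n)
  mc <- matrix(calls(m_pools), nrow = n)
  cls <- vapply(seq_len(n), function(i)
    classify_site(fc[i, ], mc[i, ], polarity, n_pools = length(f_pools)),
    character(1))
  out <- variants$sites
  out$site_class <- cls
  out
}

#' Flag putative young-stratum scaffolds from SNP-consistency
#'
#' Scans scaffolds assigned `autosome` by the coverage pipeline (sites on
#' Z, filtered or unassigned scaffolds are excluded). Per scaffold,
#' `n_snps` counts classified (non-unassessable) sites and a scaffold is
#' flagged young when it has at least `min_snps` such SNPs of which at
#' least `min_prop` are consistent with the chosen polarity.
#'
#' @param site_classes output of [classify_sites()].
#' @param assignments the coverage `assignments` data.frame.
#' @param min_snps minimum classified SNPs per scaffold (inclusive).
#' @param min_prop minimum consistent fraction (inclusive).
#' @param polarity `"ZW"` or `"XY"` (must match the classification run).
#' @return data.frame (scaffold, n_snps, n_consistent, prop_consistent,
#'   young_flag), one row per autosome-assigned scaffold with >= 1
#'   classified SNP.
#' @export
summarize_scaffolds <- function(site_classes, assignments, min_snps = 10,
                                min_prop = 0.20, polarity = c("ZW", "XY")) {
  polarity <- match.arg(polarity)
  consistent_label <- paste0(polarity, "_consistent")
  auto <- assignments$scaffold[assignments$class == "autosome"]
  x <- site_classes[site_classes$scaffold %in% auto &
                      site_classes$site_class != "unassessable", , drop = FALSE]
  if (nrow(x) == 0L)
    return(data.frame(scaffold = character(), n_snps = integer(),
                      n_consistent = integer(), prop_consistent = numeric(),
                      young_flag = logical(), stringsAsFactors = FALSE))
  n_snps <- tapply(x$site_class, x$scaffold, length)
  n_cons <- tapply(x$site_class == consistent_label, x$scaffold, sum)
  out <- data.frame(scaffold = names(n_snps),
                    n_snps = as.integer(n_snps),
                    n_consistent = as.integer(n_cons),
                    stringsAsFactors = FALSE)
  out$prop_consistent <- out$n_consistent / out$n_snps
  out$young_flag <- out$n_snps >= min_snps & out$prop_consistent >= min_prop
  rownames(out) <- NULL
  out
}

#' Cross-validate RNA-detected consistent SNPs in the DNA individuals
#'
#' For the RNA-consistent SNPs of interest (typically those on flagged
#' young-stratum scaffolds), genotypes the single female and male DNA
#' samples at each site with the same depth and allele-fraction rules. A
#' site is assessable when both DNA samples yield a genotype call, and
#' confirmed consistent when the heterogametic sex's DNA is heterozygous
#' and the other sex's homozygous.
#'
#' @param variants filtered variant set.
#' @param site_idx integer (row) indices of the sites to cross-validate.
#' @param samples sample sheet; DNA rows have material `"DNA_individual"`.
#' @param polarity `"ZW"` or `"XY"`.
#' @return list(n_assessable, n_consistent, proportion) — proportion is NA
#'   when nothing is assessable.
#' @export
cross_validate_dna <- function(variants, site_idx, samples,
                               polarity = c("ZW", "XY")) {
  polarity <- match.arg(polarity)
  dna_f <- samples$sample[samples$sex == "female" & samples$material == "DNA_individual"]
  dna_m <- samples$sample[samples$sex == "male" & samples$material == "DNA_individual"]
  if (length(dna_f) != 1L || length(dna_m) != 1L)
    stop("need exactly one DNA individual per sex")
  if (length(site_idx) == 0L)
    return(list(n_assessable = 0L, n_consistent = 0L, proportion = NA_real_))
  gf <- call_genotype(variants$ref_depth[site_idx, dna_f],
                      variants$alt_depth[site_idx, dna_f])
  gm <- call_genotype(variants$ref_depth[site_idx, dna_m],
                      variants$alt_depth[site_idx, dna_m])
  assessable <- !is.na(gf) & !is.na(gm) & gf != "no_call" & gm != "no_call"
  het <- if (polarity == "ZW") gf else gm
  hom <- if (polarity == "ZW") gm else gf
  consistent <- assessable & het == "het" & hom %in% c("hom_ref", "hom_alt")
  n_a <- sum(assessable)
  n_c <- sum(consistent)
  list(n_assessable = as.integer(n_a), n_consistent = as.integer(n_c),
       proportion = if (n_a > 0) n_c / n_a else NA_real_)
}

#' Two-proportion chi-square test with continuity correction
#'
#' Pearson chi-square on the 2x2 table `[[k1, n1-k1], [k2, n2-k2]]` with
#' the Yates continuity correction `max(0, |O - E| - 0.5)` applied to every
#' cell, 1 degree of freedom, two-sided p-value. This is the statistic used
#' to compare the DNA-confirmation rate of young-stratum SNPs against the
#' genome-wide background, and the ZW vs XY scaffold-level consistency
#' fractions.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @return list(k1, n1, k2, n2, chi2, df, p_value).
#' @examples
#' proportion_chisq(46, 110, 5165, 145204)$chi2  # ~454.4
#' @export
proportion_chisq <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be > 0")
  if (k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2) stop("need 0 <= k <= n")
  obs <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  if (any(expd == 0)) {
    chi2 <- 0
  } else {
    chi2 <- sum(pmax(0, abs(obs - expd) - 0.5)^2 / expd)
  }
  list(k1 = k1, n1 = n1, k2 = k2, n2 = n2, chi2 = chi2, df = 1L,
       p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Young-stratum detection with reverse-polarity false-positive control
#'
#' Runs the full SNP-consistency analysis under the stated polarity and
#' again with the sexes' roles reversed (the pseudo-XY control for a ZW
#' species, whose hits can only be noise). Reports both branches
#' side-by-side plus a [proportion_chisq()] comparing the fraction of
#' consistent SNPs that land on flagged scaffolds between polarities.
#'
#' @param variants filtered variant set ([filter_sites()]).
#' @param samples sample sheet.
#' @param assignments coverage `assignments` data.frame.
#' @param min_snps,min_prop scaffold flagging thresholds.
#' @param polarity the forward polarity, `"ZW"` for a ZW species.
#' @return list with elements `forward` and `reverse` (each: polarity,
#'   site_classes, scaffold_summary, n_consistent_total,
#'   n_consistent_on_flagged, n_flagged, dna), and `comparison`
#'   (proportion_chisq of flagged-scaffold concentration, forward vs
#'   reverse).
#' @export
reverse_control <- function(variants, samples, assignments,
                            min_snps = 10, min_prop = 0.20,
                            polarity = c("ZW", "XY")) {
  polarity <- match.arg(polarity)
  other <- if (polarity == "ZW") "XY" else "ZW"
  run_branch <- function(pol) {
    cls <- classify_sites(variants, samples, pol)
    summ <- summarize_scaffolds(cls, assignments, min_snps, min_prop, pol)
    label <- paste0(pol, "_consistent")
    flagged <- summ$scaffold[summ$young_flag]
    cons_idx <- which(cls$site_class == label)
    on_flagged <- which(cls$site_class == label & cls$scaffold %in% flagged)
    dna <- cross_validate_dna(variants, on_flagged, samples, pol)
    # genome-wide DNA confirmation background over all consistent sites
    dna_all <- cross_validate_dna(variants, cons_idx, samples, pol)
    list(polarity = pol, site_classes = cls, scaffold_summary = summ,
         n_flagged = length(flagged),
         n_consistent_total = length(cons_idx),
         n_consistent_on_flagged = length(on_flagged),
         dna = dna, dna_background = dna_all)
  }
  fwd <- run_branch(polarity)
  rev <- run_branch(other)
  comparison <- proportion_chisq(fwd$n_consistent_on_flagged,
                                 max(fwd$n_consistent_total, 1L),
                                 rev$n_consistent_on_flagged,
                                 max(rev$n_consistent_total, 1L))
  list(forward = fwd, reverse = rev, comparison = comparison)
}
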