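#' Relative quantity by the delta-delta-Cq method
#'
#' `dCq = cq_target - cq_reference` (reference = mean Cq over the
#' autosomal normalizer genes of the same individual), `ddCq = dCq -
#' calibrator_delta` (calibrator = mean dCq of the female group), and
#' `fold = 2^(-ddCq)` assuming 100% amplification efficiency. Adding a
#' constant to every Cq leaves the fold unchanged.
#'
#' @param cq_target target-gene Cq (scalar or vector).
#' @param cq_reference matched reference Cq (mean over normalizer genes).
#' @param calibrator_delta the calibrator group's mean dCq.
#' @return relative quantity (fold), same length as `cq_target`.
#' @examples
#' relative_quantity(19, 20, -1)  # ddCq = 0 -> fold 1
#' @export
relative_quantity <- function(cq_target, cq_reference, calibrator_delta) {
  if (any(!is.finite(cq_target)) || any(!is.finite(cq_reference)) ||
      !is.finite(calibrator_delta))
    stop("Cq inputs must be finite")
  2^(-((cq_target - cq_reference) - calibrator_delta))
}

#' Z-linkage call from the male:female copy-number fold
#'
#' On a Z-specific locus, ZZ males carry two copies against the ZW
#' female's one, so the expected male:female fold is 2. Folds in
#' \[1.5, 3.0\] are called `Z_linked`, folds in \[0.67, 1.33\] (around the
#' equal-copy expectation) `autosomal`, anything else `indeterminate`.
#' The windows are deliberate judgment calls around the 2x and 1x
#' expectations.
#'
#' @param fold_male_over_female positive fold value(s).
#' @return character vector in {`Z_linked`, `autosomal`, `indeterminate`}.
#' @export
z_linkage_call <- function(fold_male_over_female) {
  if (any(fold_male_over_female <= 0)) stop("fold must be > 0")
  ifelse(fold_male_over_female >= 1.5 & fold_male_over_female <= 3.0,
         "Z_linked",
         ifelse(fold_male_over_female >= 0.67 & fold_male_over_female <= 1.33,
                "autosomal", "indeterminate"))
}

#' Analyze a qPCR Cq table and call Z-linkage per target gene
#'
#' Per individual, technical replicates are averaged per gene, the
#' reference Cq is the mean over all reference-role genes, and each
#' target's dCq is formed. The female group's mean dCq per target is the
#' calibrator, so female folds center on 1 and the male:female copy ratio
#' is read off the male folds.
#'
#' @param records data.frame with columns individual, sex, gene, role
#'   (`target`/`reference`), cq.
#' @return list with `per_individual` (individual, sex, gene, dcq, fold)
#'   and `per_gene` (gene, fold_male_over_female, call).
#' @export
analyze_qpcr <- function(records) {
  stopifnot(all(c("individual", "sex", "gene", "role", "cq") %in% names(records)))
  if (any(records$cq <= 0)) stop("Cq values must be > 0")
  # mean over technical replicates
  agg <- stats::aggregate(cq ~ individual + sex + gene + role, records, mean)
  refs <- agg[agg$role == "reference", , drop = FALSE]
  if (nrow(refs) == 0L) stop("no reference-gene measurements")
  ref_by_ind <- tapply(refs$cq, refs$individual, mean)
  targets <- agg[agg$role == "target", , drop = FALSE]
  if (nrow(targets) == 0L) stop("no target-gene measurements")
  if (any(!targets$individual %in% names(ref_by_ind)))
    stop("individual without reference measurement")
  targets$dcq <- targets$cq - as.numeric(ref_by_ind[targets$individual])
  per_ind <- do.call(rbind, lapply(split(targets, targets$gene), function(g) {
    calib <- mean(g$dcq[g$sex == "female"])
    g$fold <- relative_quantity(g$cq,
                                as.numeric(ref_by_ind[g$individual]),
                                calib)
    g
  }))
  rownames(per_ind) <- NULL
  per_gene <- do.call(rbind, lapply(split(per_ind, per_ind$gene), function(g) {
    fold_m <- mean(g$fold[g$sex == "male"])
    fold_f <- mean(g$fold[g$sex == "female"])
    data.frame(gene = g$gene[1],
               fold_male_over_female = fold_m / fold_f,
               call = z_linkage_call(fold_m / fold_f),
               stringsAsFactors = FALSE)
  }))
  rownames(per_gene) <- NULL
  list(per_individual = per_ind[, c("individual", "sex", "gene", "dcq", "fold")],
       per_gene = per_gene)
}
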