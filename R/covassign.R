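#' Median-anchored coverage zones for scaffold assignment
#'
#' A zone specification gives the boundaries of the Z, autosome and pseudo-X
#' coverage windows as offsets from the genome-wide median
#' log2(female:male) depth ratio. The default windows put Z-specific
#' scaffolds between median - 2 and median - 0.5 (half female dose),
#' autosomes between median - 0.5 (exclusive) and median + 2, and the
#' reverse-polarity pseudo-X control between median + 0.5 and median + 2.
#' The presets `"t1"`, `"t2"`, `"t3"` are increasingly stringent Z windows
#' (upper bound -0.6 / -0.7 / -0.8, with the autosome floor at -0.4 / -0.3 /
#' -0.2) used to check that conclusions are robust to the cutoff.
#'
#' @param z_low,z_high Z-zone offsets from the median (inclusive ends).
#' @param a_low,a_high autosome-zone offsets (both ends exclusive).
#' @param x_low,x_high pseudo-X-zone offsets (inclusive ends).
#' @param preset `"default"`, `"t1"`, `"t2"`, or `"t3"`; explicit offsets
#'   override the preset.
#' @return a `zone_spec` list.
#' @export
zone_spec <- function(preset = c("default", "t1", "t2", "t3"),
                      z_low = NULL, z_high = NULL,
                      a_low = NULL, a_high = NULL,
                      x_low = 0.5, x_high = 2) {
  preset <- match.arg(preset)
  p <- switch(preset,
              default = c(-2, -0.5, -0.5, 2),
              t1 = c(-2, -0.6, -0.4, 2),
              t2 = c(-2, -0.7, -0.3, 2),
              t3 = c(-2, -0.8, -0.2, 2))
  zs <- list(z_low = z_low %||% p[1], z_high = z_high %||% p[2],
             a_low = a_low %||% p[3], a_high = a_high %||% p[4],
             x_low = x_low, x_high = x_high)
  if (!(zs$z_low < zs$z_high && zs$z_high <= zs$a_low && zs$a_low < zs$a_high))
    stop("invalid zones: need z_low < z_high <= a_low < a_high")
  class(zs) <- "zone_spec"
  zs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter scaffolds on length and relative coverage
#'
#' Retains scaffolds longer than `min_len` (strict) whose depth in the
#' reference sex is at least 1/4 of that sex's genome-wide average and whose
#' depth in each sex is at most 4x that sex's average. The reference sex is
#' the homogametic one: male under ZW polarity, female under the XY
#' (pseudo-X control) polarity. The genome-wide "average" is the
#' length-weighted mean depth by default, or the unweighted median with
#' `center = "median"`.
#'
#' @param records data.frame with columns scaffold, length,
#'   mean_depth_female, mean_depth_male.
#' @param min_len minimum scaffold length in bp, exclusive bound.
#' @param polarity `"ZW"` (default) or `"XY"`.
#' @param center summary anchoring the 1/4 and 4x rules: `"mean"`
#'   (length-weighted) or `"median"` (unweighted).
#' @return the retained rows of `records`, with attribute `"removed"`
#'   holding the scaffold ids that were filtered out.
#' @export
coverage_filter <- function(records, min_len = 5000, polarity = c("ZW", "XY"),
                            center = c("mean", "median")) {
  polarity <- match.arg(polarity)
  center <- match.arg(center)
  if (nrow(records) == 0L) stop("no coverage records supplied")
  if (any(records$length <= 0)) stop("scaffold lengths must be > 0")
  if (any(records$mean_depth_female < 0 | records$mean_depth_male < 0))
    stop("depths must be >= 0")
  avg <- function(depth) {
    if (center == "mean") stats::weighted.mean(depth, records$length)
    else stats::median(depth)
  }
  avg_f <- avg(records$mean_depth_female)
  avg_m <- avg(records$mean_depth_male)
  ref_depth <- if (polarity == "ZW") records$mean_depth_male else records$mean_depth_female
  ref_avg <- if (polarity == "ZW") avg_m else avg_f
  keep <- records$length > min_len &
    ref_depth >= ref_avg / 4 &
    records$mean_depth_female <= 4 * avg_f &
    records$mean_depth_male <= 4 * avg_m
  if (!any(keep)) stop("no scaffolds survive filters")
  out <- records[keep, , drop = FALSE]
  attr(out, "removed") <- records$scaffold[!keep]
  out
}

#' log2(female:male) depth ratios centered on their median
#'
#' Computes the per-scaffold log2 ratio of female to male depth and the
#' unweighted median over the retained scaffolds; `centered` is the ratio
#' minus that median, the statistic all zone tests operate on.
#'
#' @param retained output of [coverage_filter()] (depths guaranteed > 0 in
#'   the reference sex; any residual zero depth in the other sex is an
#'   error).
#' @return data.frame (scaffold, length, log2_fm, centered) with attribute
#'   `"median_log2_fm"`.
#' @export
log2_ratio_table <- function(retained) {
  if (nrow(retained) == 0L) stop("empty coverage table")
  if (any(retained$mean_depth_female <= 0 | retained$mean_depth_male <= 0))
    stop("zero depth after filtering; tighten coverage_filter")
  log2_fm <- log2(retained$mean_depth_female / retained$mean_depth_male)
  med <- stats::median(log2_fm)
  out <- data.frame(scaffold = retained$scaffold, length = retained$length,
                    log2_fm = log2_fm, centered = log2_fm - med,
                    stringsAsFactors = FALSE)
  attr(out, "median_log2_fm") <- med
  out
}

#' Assign retained scaffolds to coverage classes
#'
#' A scaffold whose centered log2(F:M) ratio falls in \[z_low, z_high\] is
#' called `Z` (both ends inclusive; the shared boundary with the autosome
#' zone belongs to Z), strictly inside (a_low, a_high) is `autosome`, and
#' anything outside both windows is `unassigned`.
#'
#' @param ratios output of [log2_ratio_table()].
#' @param zones a [zone_spec()].
#' @return data.frame (scaffold, length, log2_fm, centered, class).
#' @export
assign_scaffolds <- function(ratios, zones = zone_spec()) {
  stopifnot(inherits(zones, "zone_spec"))
  cls <- rep("unassigned", nrow(ratios))
  cls[ratios$centered > zones$a_low & ratios$centered < zones$a_high] <- "autosome"
  cls[ratios$centered >= zones$z_low & ratios$centered <= zones$z_high] <- "Z"
  out <- ratios
  out$class <- cls
  out
}

#' Pseudo-X scaffolds under reversed polarity
#'
#' The false-positive yardstick: scaffolds whose centered ratio lies in the
#' mirror-image window \[x_low, x_high\] look like a differentiated X
#' chromosome, which a ZW species cannot have, so any hits measure noise.
#' Input ratios should come from an XY-polarity [coverage_filter()] run.
#'
#' @param ratios output of [log2_ratio_table()].
#' @param zones a [zone_spec()].
#' @return character vector of pseudo-X scaffold ids.
#' @export
pseudo_x_assignment <- function(ratios, zones = zone_spec()) {
  stopifnot(inherits(zones, "zone_spec"))
  ratios$scaffold[ratios$centered >= zones$x_low & ratios$centered <= zones$x_high]
}

#' Full coverage-based assignment of every input scaffold
#'
#' Convenience wrapper chaining [coverage_filter()], [log2_ratio_table()]
#' and [assign_scaffolds()], and folding the filtered-out scaffolds back in
#' with class `filtered`, so each input scaffold appears exactly once.
#'
#' @inheritParams coverage_filter
#' @param zones a [zone_spec()].
#' @return list with `assignments` (scaffold, class, log2_fm, centered;
#'   NA ratios for filtered scaffolds), `ratios` (the retained-ratio table)
#'   and `median_log2_fm`.
#' @export
assign_coverage <- function(records, min_len = 5000, zones = zone_spec(),
                            polarity = c("ZW", "XY"),
                            center = c("mean", "median")) {
  polarity <- match.arg(polarity)
  center <- match.arg(center)
  retained <- coverage_filter(records, min_len = min_len, polarity = polarity,
                              center = center)
  ratios <- log2_ratio_table(retained)
  assigned <- assign_scaffolds(ratios, zones)
  if (polarity == "XY") {
    px <- pseudo_x_assignment(ratios, zones)
    assigned$class[assigned$scaffold %in% px] <- "pseudo-X"
  }
  removed <- attr(retained, "removed")
  filtered <- data.frame(scaffold = removed,
                         length = records$length[match(removed, records$scaffold)],
                         log2_fm = rep(NA_real_, length(removed)),
                         centered = rep(NA_real_, length(removed)),
                         class = rep("filtered", length(removed)),
                         stringsAsFactors = FALSE)
  assignments <- rbind(assigned, filtered)
  assignments <- assignments[match(records$scaffold, assignments$scaffold), ]
  rownames(assignments) <- NULL
  list(assignments = assignments, ratios = ratios,
       median_log2_fm = attr(ratios, "median_log2_fm"))
}

#' Map transcripts onto scaffold classes
#'
#' Each transcript inherits the coverage class of its scaffold; transcripts
#' whose scaffold is absent from the assignment table are reported as
#' `unplaced`.
#'
#' @param assignments the `assignments` data.frame from [assign_coverage()].
#' @param transcript_map data.frame with columns transcript, scaffold (and
#'   optionally length).
#' @return list with `transcripts` (the map plus a `class` column) and
#'   `class_counts` (named integer vector).
#' @export
map_transcripts <- function(assignments, transcript_map) {
  if (anyDuplicated(transcript_map$transcript))
    stop("duplicate transcript ids in transcript map")
  cls <- assignments$class[match(transcript_map$scaffold, assignments$scaffold)]
  cls[is.na(cls)] <- "unplaced"
  out <- transcript_map
  out$class <- cls
  list(transcripts = out, class_counts = table(factor(cls)))
}

#' Locate candidate genes on the coverage assignment
#'
#' Reports, for each gene of interest, its scaffold, the scaffold's raw and
#' centered log2(F:M) ratio and its class. Genes mapping to scaffolds not
#' present in the assignment (or with no scaffold at all) are reported as
#' `no assignment`.
#'
#' @param assignments the `assignments` data.frame from [assign_coverage()].
#' @param gene_map data.frame with columns gene, scaffold (NA scaffold
#'   allowed).
#' @return data.frame (gene, scaffold, log2_fm, centered, class).
#' @export
locate_genes <- function(assignments, gene_map) {
  idx <- match(gene_map$scaffold, assignments$scaffold)
  out <- data.frame(
    gene = gene_map$gene,
    scaffold = ifelse(is.na(idx), "no assignment", gene_map$scaffold),
    log2_fm = assignments$log2_fm[idx],
    centered = assignments$centered[idx],
    class = ifelse(is.na(idx), "no assignment", assignments$class[idx]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
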