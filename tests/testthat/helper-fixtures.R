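# In-code fixtures and independent oracles shared across test files.

# A minimal variant set (the structure simulate_variants() emits) built from
# explicit per-sample depths. `rows` is a list of lists with fields
# scaffold, pos, qual, ref, alt and a depth matrix row c(ref..., alt...).
make_variants <- function(ref_depth, alt_depth, scaffold, pos = NULL,
                          ref = "A", alt = "G", qual = 50) {
  n <- nrow(ref_depth)
  samples <- data.frame(
    sample = colnames(ref_depth),
    sex = c(rep("female", 4), rep("male", 4), "female", "male"),
    material = c(rep("RNA_pool", 8), rep("DNA_individual", 2)),
    stringsAsFactors = FALSE
  )
  list(
    sites = data.frame(scaffold = scaffold,
                       pos = pos %||% seq_len(n),
                       ref = rep_len(ref, n), alt = rep_len(alt, n),
                       qual = rep_len(qual, n), stringsAsFactors = FALSE),
    ref_depth = ref_depth, alt_depth = alt_depth, samples = samples
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

std_samples <- c(paste0("F", 1:4), paste0("M", 1:4), "DNA_F", "DNA_M")

# depth rows: 30/0 = clean hom_ref, 15/15 = clean het
depth_row <- function(f = "het", m = "hom", dna_f = "het", dna_m = "hom") {
  pick <- function(state) switch(state,
    het = c(15L, 15L), hom = c(30L, 0L), hom_alt = c(0L, 30L),
    no_call = c(24L, 6L),          # alt fraction 0.2: ambiguous band
    missing = c(4L, 2L))           # below min_depth -> masked
  states <- c(rep(f, 4), rep(m, 4), dna_f, dna_m)
  mat <- vapply(states, pick, integer(2))
  list(ref = mat[1, ], alt = mat[2, ])
}

variants_from_states <- function(state_rows, scaffold) {
  rows <- lapply(state_rows, function(s) do.call(depth_row, s))
  rd <- do.call(rbind, lapply(rows, `[[`, "ref"))
  ad <- do.call(rbind, lapply(rows, `[[`, "alt"))
  colnames(rd) <- colnames(ad) <- std_samples
  make_variants(rd, ad, scaffold)
}

# Literal zone-predicate oracle for scaffold assignment on centered ratios.
oracle_assign <- function(centered, zones) {
  vapply(centered, function(x) {
    if (x >= zones$z_low && x <= zones$z_high) "Z"
    else if (x > zones$a_low && x < zones$a_high) "autosome"
    else "unassigned"
  }, character(1))
}

# Exhaustive two-sided permutation p-value for the rank-sum statistic.
oracle_wilcox_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  idx <- utils::combn(n, length(a))
  r <- rank(pooled)
  obs <- sum(r[seq_along(a)])
  stats_all <- apply(idx, 2, function(i) sum(r[i]))
  mu <- mean(stats_all)
  mean(abs(stats_all - mu) >= abs(obs - mu) - 1e-9)
}

# Two-sided Fisher p by enumeration of all tables with fixed margins.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, n - c1, r1)
  sum(probs[probs <= stats::dhyper(a, c1, n - c1, r1) * (1 + 1e-7)])
}

# A simple coverage table: k autosome-like and j Z-like scaffolds at exact
# depths, long enough to pass the default length filter.
flat_coverage <- function(n_a = 8, n_z = 4, depth_f = 28, depth_m = 30,
                          length = 10000) {
  data.frame(
    scaffold = sprintf("s%02d", seq_len(n_a + n_z)),
    length = length,
    mean_depth_female = c(rep(depth_f, n_a), rep(depth_f / 2, n_z)),
    mean_depth_male = depth_m,
    stringsAsFactors = FALSE
  )
}
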