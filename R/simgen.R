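#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator: genome composition,
#' sequencing depths, pooled-genotype noise, RNA-seq design and the
#' dosage-compensation scenario. Defaults emulate a ZW brine-shrimp-like
#' study design: ~28x female and 30x male genomic coverage, four RNA pools
#' per sex (pools of 5 individuals), two tissues with two replicates per sex,
#' and two DNA individuals from an inbred line (six generations of full-sib
#' mating).
#'
#' @param n_autosomal_scaffolds,n_z_scaffolds,n_youngz_scaffolds counts of
#'   scaffolds per true class. Young-Z scaffolds retain a W homolog, so they
#'   show equal coverage in both sexes but carry fixed ZW allelic differences.
#' @param scaffold_length_range length-2 integer vector, bp. Scaffolds are
#'   drawn uniformly on this interval.
#' @param depth_female,depth_male mean fold-coverage of the female and male
#'   genomic samples.
#' @param depth_dispersion coefficient of variation of the per-scaffold
#'   log-normal depth noise (0 = noise free).
#' @param snps_per_kb expected SNP density on polymorphic scaffolds.
#' @param pool_count_per_sex number of RNA pools per sex (canonically 4:
#'   2 gonad + 2 head pools).
#' @param pool_size diploid individuals per RNA pool.
#' @param genotyping_error probability that a sample's true allele state at a
#'   site is replaced by a flipped one (het <-> hom) before read sampling.
#' @param dna_missing_rate probability a DNA individual has zero usable
#'   coverage at a site.
#' @param compensation_scenario `"full"` (Z expression equalized between
#'   sexes) or `"none"` (female Z expression halved with Z dose).
#' @param sexbias_fraction,sexbias_fold fraction of transcripts that are
#'   truly sex-biased, and the fold-change applied in the favoured sex.
#' @param youngz_fixed_fraction fraction of SNPs on young-Z scaffolds that
#'   are fixed ZW differences (female-het / male-hom); the remainder are
#'   ordinary polymorphisms.
#' @param transcripts_per_scaffold average number of transcripts placed on
#'   each scaffold.
#' @param transcript_length_range length-2 integer vector, bp.
#' @param count_dispersion gamma-Poisson overdispersion of RNA-seq counts
#'   (variance = mu + dispersion * mu^2).
#' @param reads_per_sample target RNA-seq library size per sample.
#' @param inbreeding_generations generations of full-sib mating behind the
#'   DNA individuals; sets their residual heterozygosity via
#'   [expected_inbreeding()].
#' @param seed master RNG seed; each output artifact derives its own stream
#'   from it so artifacts can be regenerated independently.
#'
#' @return a validated `sim_config` list.
#' @seealso [simulate_genome()], [simulate_coverage()], [simulate_variants()],
#'   [simulate_counts()], [simulate_qpcr()]
#' @export
sim_config <- function(n_autosomal_scaffolds = 400,
                       n_z_scaffolds = 80,
                       n_youngz_scaffolds = 20,
                       scaffold_length_range = c(6000L, 150000L),
                       depth_female = 28,
                       depth_male = 30,
                       depth_dispersion = 0.2,
                       snps_per_kb = 2,
                       pool_count_per_sex = 4L,
                       pool_size = 5L,
                       genotyping_error = 0.01,
                       dna_missing_rate = 0.2,
                       compensation_scenario = c("full", "none"),
                       sexbias_fraction = 0.1,
                       sexbias_fold = 8,
                       youngz_fixed_fraction = 0.5,
                       transcripts_per_scaffold = 3,
                       transcript_length_range = c(500L, 3000L),
                       count_dispersion = 0.05,
                       reads_per_sample = 2e6,
                       inbreeding_generations = 6L,
                       seed = 1L) {
  compensation_scenario <- match.arg(compensation_scenario)
  cfg <- list(
    n_autosomal_scaffolds = as.integer(n_autosomal_scaffolds),
    n_z_scaffolds = as.integer(n_z_scaffolds),
    n_youngz_scaffolds = as.integer(n_youngz_scaffolds),
    scaffold_length_range = as.integer(scaffold_length_range),
    depth_female = depth_female,
    depth_male = depth_male,
    depth_dispersion = depth_dispersion,
    snps_per_kb = snps_per_kb,
    pool_count_per_sex = as.integer(pool_count_per_sex),
    pool_size = as.integer(pool_size),
    genotyping_error = genotyping_error,
    dna_missing_rate = dna_missing_rate,
    compensation_scenario = compensation_scenario,
    sexbias_fraction = sexbias_fraction,
    sexbias_fold = sexbias_fold,
    youngz_fixed_fraction = youngz_fixed_fraction,
    transcripts_per_scaffold = transcripts_per_scaffold,
    transcript_length_range = as.integer(transcript_length_range),
    count_dispersion = count_dispersion,
    reads_per_sample = reads_per_sample,
    inbreeding_generations = as.integer(inbreeding_generations),
    seed = as.integer(seed)
  )
  counts <- c(cfg$n_autosomal_scaffolds, cfg$n_z_scaffolds, cfg$n_youngz_scaffolds)
  if (any(counts < 0)) stop("scaffold counts must be >= 0")
  if (cfg$depth_female <= 0 || cfg$depth_male <= 0) stop("depths must be > 0")
  probs <- c(cfg$genotyping_error, cfg$dna_missing_rate,
             cfg$sexbias_fraction, cfg$youngz_fixed_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$depth_dispersion < 0) stop("depth_dispersion must be >= 0")
  if (diff(cfg$scaffold_length_range) < 0 || cfg$scaffold_length_range[1] <= 0)
    stop("invalid scaffold_length_range")
  if (cfg$inbreeding_generations < 0) stop("inbreeding_generations must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic per-artifact RNG stream: each artifact gets a fixed offset
# from the master seed so regenerating one artifact never perturbs another.
# Offsets are small, keeping derived seeds well below .Machine$integer.max.
.artifact_seed <- function(cfg, artifact) {
  offsets <- c(genome = 11L, coverage = 23L, variants = 37L,
               counts = 53L, qpcr = 71L)
  cfg$seed * 101L + offsets[[artifact]]
}

#' Inbreeding coefficient under repeated full-sib mating
#'
#' Iterates the second-order recurrence for the inbreeding coefficient of a
#' line maintained by brother-sister mating,
#' \eqn{F_t = (1 + 2 F_{t-1} + F_{t-2}) / 4} with \eqn{F_0 = F_{-1} = 0}.
#' Six generations give F = 0.734375, i.e. roughly a 73% reduction in
#' heterozygosity relative to the base population.
#'
#' @param generations non-negative integer number of sib-mating generations.
#' @return the inbreeding coefficient F in [0, 1).
#' @examples
#' expected_inbreeding(0) # 0
#' expected_inbreeding(1) # 0.25
#' expected_inbreeding(6) # 0.734375
#' @export
expected_inbreeding <- function(generations) {
  if (length(generations) != 1L || is.na(generations) || generations < 0)
    stop("generations must be a single non-negative integer")
  f_prev2 <- 0; f_prev1 <- 0
  g <- as.integer(generations)
  if (g == 0L) return(0)
  for (t in seq_len(g)) {
    f <- 0.25 * (1 + 2 * f_prev1 + f_prev2)
    f_prev2 <- f_prev1
    f_prev1 <- f
  }
  f_prev1
}

#' Simulate a scaffolded genome with known sex-linkage ground truth
#'
#' Draws scaffolds of the three true classes (`A` autosomal, `Z` Z-specific,
#' `youngZ` coverage-undifferentiated ZW) with uniform lengths, and places
#' transcripts on them uniformly. A `sexbias_fraction` of transcripts is
#' marked truly male- or female-biased (half each).
#'
#' @param cfg a [sim_config()].
#' @return list with elements `scaffolds` (data.frame: scaffold, length,
#'   true_class) and `transcripts` (data.frame: transcript, scaffold, length,
#'   true_bias).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_total <- cfg$n_autosomal_scaffolds + cfg$n_z_scaffolds + cfg$n_youngz_scaffolds
  if (n_total == 0L) stop("empty genome: no scaffolds of any class")
  set.seed(.artifact_seed(cfg, "genome"))
  true_class <- rep(c("A", "Z", "youngZ"),
                    c(cfg$n_autosomal_scaffolds, cfg$n_z_scaffolds,
                      cfg$n_youngz_scaffolds))
  scaffolds <- data.frame(
    scaffold = sprintf("scaffold%05d", seq_len(n_total)),
    length = sample(cfg$scaffold_length_range[1]:cfg$scaffold_length_range[2],
                    n_total, replace = TRUE),
    true_class = true_class,
    stringsAsFactors = FALSE
  )
  n_tx <- stats::rpois(n_total, cfg$transcripts_per_scaffold)
  # guarantee at least one transcript somewhere so expression tables exist
  if (sum(n_tx) == 0L) n_tx[1] <- 1L
  tx_scaffold <- rep(scaffolds$scaffold, n_tx)
  n_tx_total <- length(tx_scaffold)
  bias <- rep("none", n_tx_total)
  n_biased <- round(cfg$sexbias_fraction * n_tx_total)
  if (n_biased > 0) {
    idx <- sample.int(n_tx_total, n_biased)
    bias[idx] <- sample(c("male", "female"), n_biased, replace = TRUE)
  }
  transcripts <- data.frame(
    transcript = sprintf("tx%06d", seq_len(n_tx_total)),
    scaffold = tx_scaffold,
    length = sample(cfg$transcript_length_range[1]:cfg$transcript_length_range[2],
                    n_tx_total, replace = TRUE),
    true_bias = bias,
    stringsAsFactors = FALSE
  )
  list(scaffolds = scaffolds, transcripts = transcripts)
}

#' Simulate per-scaffold genomic coverage for a male and a female sample
#'
#' Expected depth is the configured per-sex depth times the dose: Z-specific
#' scaffolds have dose 0.5 in females (one Z, no W homolog) and 1 in males;
#' autosomal and young-Z scaffolds have dose 1 in both sexes.
#'
#' Noise has two parts. A per-scaffold log-normal factor with mean 1 and
#' coefficient of variation `depth_dispersion` is shared by the two sexes:
#' it stands for scaffold-level coverage bias (GC content, mappability,
#' repeat density), which affects both libraries alike and therefore
#' largely cancels in the female:male ratio, as it does in real data.
#' On top of that, each sex gets an independent log-normal read-sampling
#' factor whose coefficient of variation is `1 / sqrt(depth * length /
#' 100)` — the counting noise of the reads that make up a scaffold's mean
#' depth — which is what actually scatters the log2(F:M) ratio.
#'
#' @param genome output of [simulate_genome()].
#' @param cfg the same [sim_config()].
#' @return data.frame: scaffold, length, mean_depth_female, mean_depth_male.
#' @export
simulate_coverage <- function(genome, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sc <- genome$scaffolds
  if (nrow(sc) == 0L) stop("empty genome")
  set.seed(.artifact_seed(cfg, "coverage"))
  dose_f <- ifelse(sc$true_class == "Z", 0.5, 1)
  n <- nrow(sc)
  lognorm <- function(cv) {
    if (all(cv == 0)) return(rep(1, n))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  shared <- lognorm(rep(cfg$depth_dispersion, n))
  if (cfg$depth_dispersion == 0) {
    samp_f <- samp_m <- rep(1, n)
  } else {
    # read-counting noise of the per-scaffold mean depth (~100 bp reads)
    samp_f <- lognorm(1 / sqrt(cfg$depth_female * dose_f * sc$length / 100))
    samp_m <- lognorm(1 / sqrt(cfg$depth_male * sc$length / 100))
  }
  data.frame(
    scaffold = sc$scaffold,
    length = sc$length,
    mean_depth_female = cfg$depth_female * dose_f * shared * samp_f,
    mean_depth_male = cfg$depth_male * shared * samp_m,
    stringsAsFactors = FALSE
  )
}

# Per-sample expected alt-allele fractions at one site.
# kind "zw_fixed": W carries the alt allele -> females (ZW) 0.5, males (ZZ) 0.
# kind "poly": ordinary polymorphism; pools draw allele counts binomially
# from the population frequency, DNA individuals follow HWE with residual
# heterozygosity scaled by (1 - F) for the inbred line.
.site_fractions <- function(kind, n_pools_per_sex, pool_size, inbreeding_f) {
  chrom_per_pool <- 2L * pool_size
  if (kind == "zw_fixed") {
    list(pool_f = rep(0.5, n_pools_per_sex),
         pool_m = rep(0, n_pools_per_sex),
         dna_f = 0.5, dna_m = 0)
  } else {
    p <- stats::runif(1, 0.05, 0.5)
    pool_f <- stats::rbinom(n_pools_per_sex, chrom_per_pool, p) / chrom_per_pool
    pool_m <- stats::rbinom(n_pools_per_sex, chrom_per_pool, p) / chrom_per_pool
    dna_geno <- function() {
      het <- 2 * p * (1 - p) * (1 - inbreeding_f)
      # conditional on not-het, alt homozygote in proportion to p
      if (stats::runif(1) < het) 0.5 else if (stats::runif(1) < p) 1 else 0
    }
    list(pool_f = pool_f, pool_m = pool_m, dna_f = dna_geno(), dna_m = dna_geno())
  }
}

# with probability err, replace an allele fraction by a flipped state
.flip_fraction <- function(frac, err) {
  flip <- stats::runif(length(frac)) < err
  flipped <- ifelse(frac == 0.5, sample(c(0, 1), length(frac), replace = TRUE), 0.5)
  ifelse(flip, flipped, frac)
}

#' Simulate pooled RNA and individual DNA genotypes as a variant-site table
#'
#' Generates biallelic SNPs along every scaffold at density `snps_per_kb`.
#' Young-Z scaffolds carry a `youngz_fixed_fraction` of fixed ZW differences
#' (truth: heterozygous in every female pool, homozygous reference in every
#' male pool, and likewise in the DNA individuals); all remaining sites are
#' ordinary sex-independent polymorphisms. Read support per sample is
#' Poisson-depth with binomial allele sampling; `genotyping_error` flips a
#' sample's underlying allele state, and `dna_missing_rate` zeroes a DNA
#' individual's coverage at a site.
#'
#' Samples are named `F1..F<k>`, `M1..M<k>` (RNA pools) plus `DNA_F`,
#' `DNA_M`.
#'
#' @param genome output of [simulate_genome()].
#' @param cfg the same [sim_config()].
#' @return list with `sites` (data.frame: scaffold, pos, ref, alt, qual,
#'   truth), `ref_depth` and `alt_depth` (integer matrices, sites x samples),
#'   and `samples` (data.frame: sample, sex, material).
#' @export
simulate_variants <- function(genome, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$snps_per_kb <= 0) stop("snps_per_kb must be > 0")
  set.seed(.artifact_seed(cfg, "variants"))
  sc <- genome$scaffolds
  n_sites_per <- stats::rpois(nrow(sc), cfg$snps_per_kb * sc$length / 1000)
  scaffold <- rep(sc$scaffold, n_sites_per)
  cls <- rep(sc$true_class, n_sites_per)
  lens <- rep(sc$length, n_sites_per)
  n <- length(scaffold)
  if (n == 0L) stop("no variant sites generated; increase snps_per_kb")
  pos <- as.integer(ceiling(stats::runif(n) * lens))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  truth <- ifelse(cls == "youngZ" &
                    stats::runif(n) < cfg$youngz_fixed_fraction,
                  "zw_fixed", "poly")

  k <- cfg$pool_count_per_sex
  samples <- data.frame(
    sample = c(paste0("F", seq_len(k)), paste0("M", seq_len(k)), "DNA_F", "DNA_M"),
    sex = c(rep("female", k), rep("male", k), "female", "male"),
    material = c(rep("RNA_pool", 2L * k), "DNA_individual", "DNA_individual"),
    stringsAsFactors = FALSE
  )
  n_samp <- nrow(samples)
  f_inb <- expected_inbreeding(cfg$inbreeding_generations)

  frac <- matrix(0, n, n_samp, dimnames = list(NULL, samples$sample))
  for (i in seq_len(n)) {
    sf <- .site_fractions(truth[i], k, cfg$pool_size, f_inb)
    frac[i, ] <- c(sf$pool_f, sf$pool_m, sf$dna_f, sf$dna_m)
  }
  if (cfg$genotyping_error > 0)
    frac[] <- .flip_fraction(as.vector(frac), cfg$genotyping_error)

  mean_depth <- rep(c(rep((cfg$depth_female + cfg$depth_male) / 2, 2L * k),
                      cfg$depth_female, cfg$depth_male), each = n)
  depth <- matrix(stats::rpois(n * n_samp, mean_depth), n, n_samp)
  if (cfg$dna_missing_rate > 0) {
    dna_cols <- which(samples$material == "DNA_individual")
    for (j in dna_cols) {
      depth[stats::runif(n) < cfg$dna_missing_rate, j] <- 0L
    }
  }
  alt_depth <- matrix(stats::rbinom(n * n_samp, as.vector(depth), as.vector(frac)),
                      n, n_samp, dimnames = list(NULL, samples$sample))
  ref_depth <- depth - alt_depth
  dimnames(ref_depth) <- dimnames(alt_depth)

  sites <- data.frame(
    scaffold = scaffold, pos = pos, ref = ref, alt = alt,
    qual = round(stats::runif(n, 30, 60), 1),
    truth = truth, stringsAsFactors = FALSE
  )
  list(sites = sites, ref_depth = ref_depth, alt_depth = alt_depth,
       samples = samples)
}

#' Simulate an RNA-seq count matrix for 2 tissues x 2 sexes x 2 replicates
#'
#' Baseline per-transcript expression is log-normal with a mild independent
#' tissue effect. Under `compensation_scenario = "none"`, female expression
#' of Z-specific transcripts is halved (the single-Z dose is passed through
#' to mRNA); under `"full"` it is untouched (compensated). Truly sex-biased
#' transcripts are multiplied by `sexbias_fold` in the favoured sex in both
#' tissues. Expected counts are proportional to expression x transcript
#' length, scaled to `reads_per_sample`; realized counts are gamma-Poisson
#' with dispersion `count_dispersion`.
#'
#' @param genome output of [simulate_genome()].
#' @param cfg the same [sim_config()].
#' @return list with `counts` (integer matrix, transcripts x 8 samples) and
#'   `design` (data.frame: sample, tissue, sex, replicate).
#' @export
simulate_counts <- function(genome, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  tx <- genome$transcripts
  if (nrow(tx) == 0L) stop("genome has no transcripts")
  set.seed(.artifact_seed(cfg, "counts"))
  design <- expand.grid(replicate = 1:2, sex = c("female", "male"),
                        tissue = c("gonad", "head"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design$sample <- with(design, paste(tissue, sex, replicate, sep = "_"))
  design <- design[, c("sample", "tissue", "sex", "replicate")]

  n_tx <- nrow(tx)
  scaffold_class <- genome$scaffolds$true_class[
    match(tx$scaffold, genome$scaffolds$scaffold)]
  base <- stats::rlnorm(n_tx, meanlog = 2, sdlog = 1.2)
  tissue_fac <- matrix(stats::rlnorm(n_tx * 2, 0, 0.2), n_tx, 2,
                       dimnames = list(NULL, c("gonad", "head")))

  counts <- matrix(0L, n_tx, nrow(design),
                   dimnames = list(tx$transcript, design$sample))
  z_dose_f <- if (cfg$compensation_scenario == "none") 0.5 else 1
  for (j in seq_len(nrow(design))) {
    sex <- design$sex[j]
    expr <- base * tissue_fac[, design$tissue[j]]
    if (sex == "female") expr[scaffold_class == "Z"] <-
        expr[scaffold_class == "Z"] * z_dose_f
    biased_here <- tx$true_bias == sex
    expr[biased_here] <- expr[biased_here] * cfg$sexbias_fold
    mu <- expr * tx$length
    mu <- mu / sum(mu) * cfg$reads_per_sample
    if (cfg$count_dispersion > 0) {
      size <- 1 / cfg$count_dispersion
      counts[, j] <- stats::rnbinom(n_tx, mu = mu, size = size)
    } else {
      counts[, j] <- stats::rpois(n_tx, mu)
    }
  }
  list(counts = counts, design = design)
}

#' Simulate a qPCR Cq table for target loci with known copy number
#'
#' Emulates relative-quantification qPCR on genomic DNA: every individual
#' gets a random baseline Cq (input-amount effect), every gene a fixed
#' offset (primer efficiency effect), and each target amplifies
#' `log2(copies / 2)` cycles earlier per doubling of template. Z-specific
#' loci have 2 copies in ZZ males and 1 in ZW females; reference and
#' autosomal loci have 2 in both sexes.
#'
#' @param target_classes character vector, `"Z"` or `"A"`, one per target
#'   locus (names become gene ids if set).
#' @param n_individuals_per_sex individuals of each sex assayed.
#' @param cq_sd Gaussian technical noise on each Cq, cycles.
#' @param n_reference number of autosomal reference (normalizer) genes.
#' @param seed RNG seed.
#' @return data.frame: individual, sex, gene, role (`target`/`reference`),
#'   cq — the input format of [analyze_qpcr()].
#' @export
simulate_qpcr <- function(target_classes = c(tZ = "Z", tA = "A"),
                          n_individuals_per_sex = 3L,
                          cq_sd = 0.1, n_reference = 2L, seed = 1L) {
  set.seed(seed)
  if (is.null(names(target_classes)))
    names(target_classes) <- paste0("target", seq_along(target_classes))
  genes <- c(names(target_classes), paste0("ref", seq_len(n_reference)))
  roles <- c(rep("target", length(target_classes)), rep("reference", n_reference))
  gene_offset <- stats::setNames(stats::runif(length(genes), -1, 1), genes)
  rows <- list()
  for (sex in c("female", "male")) {
    for (i in seq_len(n_individuals_per_sex)) {
      ind <- paste0(substr(sex, 1, 1), i)
      ind_base <- 20 + stats::runif(1, -1, 1)
      copies <- ifelse(roles == "target" & target_classes[genes] == "Z" &
                         sex == "female", 1, 2)
      cq <- ind_base + gene_offset[genes] - log2(copies / 2) +
        stats::rnorm(length(genes), 0, cq_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        individual = ind, sex = sex, gene = genes, role = roles,
        cq = as.numeric(cq), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
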