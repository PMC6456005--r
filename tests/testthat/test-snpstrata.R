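test_that("site filters drop indels, low quality, and mask shallow samples", {
  rd <- matrix(20L, 4, 10, dimnames = list(NULL, std_samples))
  ad <- matrix(20L, 4, 10, dimnames = list(NULL, std_samples))
  v <- make_variants(rd, ad, scaffold = rep("s1", 4))
  v$sites$alt[2] <- "GT"              # indel-like allele
  v$sites$qual[3] <- 20               # boundary: fails strict > 20
  v$ref_depth[4, "F1"] <- 4L          # depth 9 in one pool
  v$alt_depth[4, "F1"] <- 5L
  f <- filter_sites(v, min_depth = 10, min_qual = 20)
  expect_equal(nrow(f$sites), 2)      # indel and low-qual rows removed
  expect_true(is.na(f$ref_depth[f$sites$pos == 4, "F1"]))
  expect_false(anyNA(f$ref_depth[f$sites$pos == 1, ]))
  v$ref_depth[1, 1] <- -1L
  expect_error(filter_sites(v), "negative depth")
})

test_that("genotype calls respect the 0.15/0.85 and strict 30% rules", {
  expect_equal(call_genotype(50, 50), "het")     # minor 0.50 > 0.30
  expect_equal(call_genotype(70, 30), "no_call") # minor exactly 0.30
  expect_equal(call_genotype(95, 5), "hom_ref")  # alt 0.05 <= 0.15
  expect_equal(call_genotype(5, 95), "hom_alt")
  expect_equal(call_genotype(80, 20), "no_call") # ambiguous band (0.15, 0.30]
  expect_equal(call_genotype(c(15, 85), c(85, 15)), c("hom_alt", "hom_ref"))
  expect_equal(call_genotype(NA_integer_, NA_integer_), NA_character_)
  expect_error(call_genotype(0, 0), "zero total depth")
})

test_that("site classification demands unanimity across all eight pools", {
  het4 <- rep("het", 4); hom4 <- rep("hom_ref", 4)
  expect_equal(classify_site(het4, hom4, "ZW"), "ZW_consistent")
  expect_equal(classify_site(het4, c("hom_ref", "hom_alt", "hom_ref",
                                     "hom_alt"), "ZW"), "ZW_consistent")
  expect_equal(classify_site(het4, het4, "ZW"), "other")
  expect_equal(classify_site(c("het", "het", "het", NA), hom4, "ZW"),
               "unassessable")
  expect_equal(classify_site(c(het4[1:3], "no_call"), hom4, "ZW"),
               "unassessable")
  expect_equal(classify_site(hom4, het4, "XY"), "XY_consistent")
  expect_error(classify_site(het4[1:3], hom4, "ZW"), "4 calls")
})

test_that("swapping sex labels converts ZW-consistent into XY-consistent", {
  set.seed(21)
  states <- c("het", "hom", "hom_alt", "no_call", "missing")
  for (i in 1:25) {
    f <- sample(states, 1); m <- sample(states, 1)
    v <- variants_from_states(list(list(f = f, m = m)), "s1")
    fwd <- classify_sites(v, v$samples, "ZW")$site_class
    sw <- v
    sw$samples$sex <- ifelse(v$samples$sex == "female", "male", "female")
    rev <- classify_sites(sw, sw$samples, "XY")$site_class
    expect_equal(sub("ZW", "XY", fwd), rev)
  }
})

test_that("scaffold summaries implement the >=10 SNP / >=20% young rule", {
  asn <- data.frame(scaffold = c("a", "b", "c", "z"),
                    class = c("autosome", "autosome", "autosome", "Z"),
                    stringsAsFactors = FALSE)
  cls <- data.frame(
    scaffold = c(rep("a", 10), rep("b", 9), rep("c", 100), rep("z", 10)),
    site_class = c(rep("ZW_consistent", 2), rep("other", 8),   # a: 2/10
                   rep("ZW_consistent", 9),                    # b: 9/9
                   rep("other", 100),                          # c: 0/100
                   rep("ZW_consistent", 10)),                  # z: excluded
    stringsAsFactors = FALSE
  )
  s <- summarize_scaffolds(cls, asn, min_snps = 10, min_prop = 0.20)
  expect_setequal(s$scaffold, c("a", "b", "c"))   # Z scaffold never scanned
  expect_true(s$young_flag[s$scaffold == "a"])    # exactly 20% qualifies
  expect_false(s$young_flag[s$scaffold == "b"])   # too few SNPs
  expect_false(s$young_flag[s$scaffold == "c"])
  # unassessable sites count toward neither numerator nor denominator
  cls2 <- rbind(cls, data.frame(scaffold = rep("b", 1),
                                site_class = "unassessable"))
  s2 <- summarize_scaffolds(cls2, asn)
  expect_equal(s2$n_snps[s2$scaffold == "b"], 9L)
})

test_that("raising the consistency threshold never adds young scaffolds", {
  cfg <- sim_config(n_autosomal_scaffolds = 30, n_z_scaffolds = 0,
                    n_youngz_scaffolds = 10, genotyping_error = 0.02,
                    scaffold_length_range = c(8000L, 20000L), seed = 22)
  g <- simulate_genome(cfg)
  asn <- assign_coverage(simulate_coverage(g, cfg))$assignments
  v <- filter_sites(simulate_variants(g, cfg))
  cls <- classify_sites(v, v$samples, "ZW")
  flagged <- lapply(c(0.1, 0.2, 0.4, 0.8), function(p) {
    s <- summarize_scaffolds(cls, asn, min_prop = p)
    s$scaffold[s$young_flag]
  })
  for (i in 2:4) expect_true(all(flagged[[i]] %in% flagged[[i - 1]]))
})

test_that("DNA cross-validation counts assessable and confirmed sites", {
  v <- variants_from_states(list(
    list(f = "het", m = "hom", dna_f = "het", dna_m = "hom"),      # confirmed
    list(f = "het", m = "hom", dna_f = "hom", dna_m = "hom"),      # assessable, no
    list(f = "het", m = "hom", dna_f = "missing", dna_m = "hom"),  # not assessable
    list(f = "het", m = "hom", dna_f = "no_call", dna_m = "hom")   # not assessable
  ), "s1")
  v <- filter_sites(v)
  dna <- cross_validate_dna(v, 1:4, v$samples, "ZW")
  expect_equal(dna$n_assessable, 2L)
  expect_equal(dna$n_consistent, 1L)
  expect_equal(dna$proportion, 0.5)
  expect_true(is.na(cross_validate_dna(v, integer(0), v$samples,
                                       "ZW")$proportion))
})

test_that("two-proportion chi-square reproduces published enrichment values", {
  expect_equal(proportion_chisq(46, 110, 5165, 145204)$chi2, 454.4,
               tolerance = 1e-4)
  expect_equal(proportion_chisq(542, 1257, 30, 656)$chi2, 303.71,
               tolerance = 1e-4)
  expect_equal(proportion_chisq(5, 10, 50, 100)$chi2, 0)
  expect_error(proportion_chisq(11, 10, 5, 100), "0 <= k <= n")
})

test_that("chi-square matches prop.test on 1000 random tables", {
  set.seed(23)
  for (i in 1:1000) {
    n1 <- sample(5:500, 1); n2 <- sample(5:500, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    ours <- proportion_chisq(k1, n1, k2, n2)
    ref <- suppressWarnings(stats::prop.test(c(k1, k2), c(n1, n2)))
    expect_equal(ours$chi2, unname(ref$statistic), tolerance = 1e-6)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-6)
    sw <- proportion_chisq(k2, n2, k1, n1)
    expect_equal(ours$chi2, sw$chi2)
  }
})

test_that("reverse-polarity control sees noise while ZW sees signal", {
  cfg <- sim_config(n_autosomal_scaffolds = 40, n_z_scaffolds = 0,
                    n_youngz_scaffolds = 10, genotyping_error = 0.02,
                    scaffold_length_range = c(8000L, 20000L), seed = 24)
  g <- simulate_genome(cfg)
  asn <- assign_coverage(simulate_coverage(g, cfg))$assignments
  v <- filter_sites(simulate_variants(g, cfg))
  rc <- reverse_control(v, v$samples, asn)
  expect_gt(rc$forward$n_consistent_total, 10 * rc$reverse$n_consistent_total)
  expect_equal(rc$reverse$n_flagged, 0)
  expect_gt(rc$forward$n_flagged, 0)

  # noise-free genome: strictly zero XY-consistent sites
  cfg0 <- sim_config(n_autosomal_scaffolds = 10, n_z_scaffolds = 0,
                     n_youngz_scaffolds = 5, genotyping_error = 0,
                     dna_missing_rate = 0,
                     scaffold_length_range = c(6000L, 10000L), seed = 25)
  g0 <- simulate_genome(cfg0)
  v0 <- filter_sites(simulate_variants(g0, cfg0))
  cls0 <- classify_sites(v0, v0$samples, "XY")
  expect_equal(sum(cls0$site_class == "XY_consistent"), 0)
})
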