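test_that("RPKM follows its definition exactly", {
  expect_equal(compute_rpkm(matrix(10), 1000, 1e6)[1], 10)
  expect_equal(compute_rpkm(matrix(0), 1000, 1e6)[1], 0)
  expect_equal(compute_rpkm(matrix(25), 2500, 5e6)[1], 2)
  m <- matrix(c(10, 20, 30, 60), 2)
  expect_equal(compute_rpkm(m, c(1000, 2000), c(1e6, 2e6)),
               matrix(c(10, 10, 15, 15), 2))
  expect_error(compute_rpkm(matrix(1), 1000, 0), "library sizes")
  expect_error(compute_rpkm(matrix(1), 0, 1e6), "lengths")
})

test_that("quantile normalization equalizes column distributions", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn), cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))

  same <- cbind(x = c(5, 1, 3), y = c(5, 1, 3))
  expect_equal(quantile_normalize(same), same)

  set.seed(31)
  r <- matrix(stats::rexp(400), 100, 4)
  qr <- quantile_normalize(r)
  expect_equal(colMeans(qr), rep(mean(colMeans(qr)), 4),
               ignore_attr = TRUE)                      # equal column means
  for (j in 2:4) expect_equal(sort(qr[, 1]), sort(qr[, j]))  # same multiset
  expect_equal(quantile_normalize(qr), qr)              # idempotent
  expect_warning(quantile_normalize(r[, 1, drop = FALSE]), "single-sample")
})

test_that("expressed-gene filter is inclusive and monotone in the cutoff", {
  rpkm <- rbind(boundary = c(1, 1, 1, 1),
                dropped = c(5, 5, 5, 0.9),
                zero = c(0, 2, 2, 2),
                high = c(6, 7, 8, 9))
  colnames(rpkm) <- paste0("s", 1:4)
  expect_setequal(rownames(filter_expressed(rpkm, colnames(rpkm), 1)),
                  c("boundary", "high"))
  expect_equal(nrow(filter_expressed(rpkm, colnames(rpkm), 0)), 4)
  sets <- lapply(c(0, 1, 2, 5), function(ct)
    rownames(filter_expressed(rpkm, colnames(rpkm), ct)))
  for (i in 2:4) expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("replicate averaging precedes the second normalization", {
  design <- data.frame(sample = c("g_f_1", "g_f_2", "g_m_1", "g_m_2"),
                       tissue = "gonad", sex = rep(c("female", "male"), each = 2),
                       replicate = c(1, 2, 1, 2), stringsAsFactors = FALSE)
  m <- matrix(c(2, 10, 4, 10, 5, 20, 7, 20), 2, 4, byrow = FALSE,
              dimnames = list(c("t1", "t2"), design$sample))
  # identical replicates average to themselves
  m_id <- m; m_id[, 2] <- m_id[, 1]; m_id[, 4] <- m_id[, 3]
  avg_id <- sapply(c("female", "male"), function(sx)
    rowMeans(m_id[, design$sample[design$sex == sx]]))
  expect_equal(avg_id[, "female"], m_id[, 1])
  # replicates (2, 4) average to 3 before renormalization
  expect_equal(rowMeans(m[, 1:2])[["t1"]], 3)
  # after the sex-wise quantile normalization both columns share sorted values
  out <- average_and_renormalize(m, design, "gonad")
  expect_equal(sort(out[, "female"]), sort(out[, "male"]), ignore_attr = TRUE)
})

test_that("wilcoxon comparison is exact for small samples and handles ties", {
  expect_equal(wilcoxon_compare(1:3, 4:6)$p_value, 0.1)
  expect_equal(wilcoxon_compare(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(wilcoxon_compare(rep(2, 3), rep(2, 4))$p_value, 1)
  expect_error(wilcoxon_compare(numeric(0), 1:3), "nonempty")
})

test_that("wilcoxon p matches exhaustive permutation for small n", {
  set.seed(32)
  for (i in 1:20) {
    na <- sample(2:4, 1); nb <- sample(2:4, 1)
    vals <- sample(1000, na + nb)  # untied
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    expect_equal(wilcoxon_compare(a, b)$p_value, oracle_wilcox_p(a, b),
                 tolerance = 1e-9)
  }
})

test_that("F:M ratio comparison separates classes and is zero under equality", {
  avg <- cbind(female = c(1, 2, 3, 4), male = c(1, 2, 3, 4))
  rownames(avg) <- paste0("t", 1:4)
  cls <- stats::setNames(c("Z", "Z", "autosome", "autosome"), rownames(avg))
  fr <- fm_ratio_compare(avg, cls)
  expect_equal(fr$ratios$log2_fm_ratio, rep(0, 4))
  expect_equal(fr$test$p_value, 1)
})

test_that("sex-specific calls enforce both strict thresholds", {
  design <- data.frame(sample = paste0("s", 1:4), tissue = "gonad",
                       sex = rep(c("female", "male"), each = 2),
                       replicate = c(1, 2, 1, 2), stringsAsFactors = FALSE)
  rpkm <- rbind(male_sp = c(0.05, 0.08, 2, 3),
                not_sp = c(0.05, 0.15, 2, 3),
                weak_on = c(0, 0, 1.0, 1.0),
                female_sp = c(2, 2, 0.01, 0.02))
  colnames(rpkm) <- design$sample
  res <- call_sex_specific(rpkm, design, "gonad")
  expect_equal(res$male_specific, "male_sp")
  expect_equal(res$female_specific, "female_sp")
  expect_false("not_sp" %in% unlist(res))
  expect_false("weak_on" %in% unlist(res))   # requires strictly > 1
})

test_that("the DE stand-in is quiet under the null and finds strong bias", {
  cfg0 <- sim_config(n_autosomal_scaffolds = 150, n_z_scaffolds = 0,
                     n_youngz_scaffolds = 0, sexbias_fraction = 0, seed = 33)
  g0 <- simulate_genome(cfg0)
  s0 <- simulate_counts(g0, cfg0)
  de0 <- call_sex_biased(s0$counts, s0$design, "gonad")
  expect_lte(sum(de0$bias != "none"), ceiling(0.05 * nrow(de0)))

  cfg1 <- sim_config(n_autosomal_scaffolds = 150, n_z_scaffolds = 0,
                     n_youngz_scaffolds = 0, sexbias_fraction = 0.1,
                     sexbias_fold = 8, seed = 34)
  g1 <- simulate_genome(cfg1)
  s1 <- simulate_counts(g1, cfg1)
  de1 <- call_sex_biased(s1$counts, s1$design, "gonad")
  truth <- g1$transcripts$true_bias[match(de1$transcript,
                                          g1$transcripts$transcript)]
  biased <- truth != "none"
  expect_gte(mean(de1$bias[biased] == truth[biased]), 0.8)
  # identical female and male counts produce no calls
  dsg <- s1$design[s1$design$tissue == "gonad", ]
  eq <- s1$counts
  eq[, dsg$sample[dsg$sex == "male"]] <- eq[, dsg$sample[dsg$sex == "female"]]
  de_eq <- call_sex_biased(eq, s1$design, "gonad")
  expect_equal(sum(de_eq$bias != "none"), 0)
})

test_that("sex-specific and sex-biased calls agree in direction", {
  cfg <- sim_config(n_autosomal_scaffolds = 150, n_z_scaffolds = 0,
                    n_youngz_scaffolds = 0, sexbias_fraction = 0.15,
                    sexbias_fold = 8, seed = 35)
  g <- simulate_genome(cfg)
  s <- simulate_counts(g, cfg)
  lens <- g$transcripts$length[match(rownames(s$counts),
                                     g$transcripts$transcript)]
  rpkm <- compute_rpkm(s$counts, lens)
  d <- s$design[s$design$tissue == "gonad", ]
  tis <- quantile_normalize(rpkm[, d$sample])
  spec <- call_sex_specific(tis, s$design, "gonad")
  de <- call_sex_biased(s$counts, s$design, "gonad")
  f_bias <- de$transcript[de$bias == "female"]
  m_bias <- de$transcript[de$bias == "male"]
  expect_true(all(!spec$female_specific %in% m_bias))
  expect_true(all(!spec$male_specific %in% f_bias))
})

test_that("BH adjustment matches the hand-computed step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # order restored
  p <- c(0.03, 0.001, 0.5, 0.02)
  expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  f0 <- enrichment_fisher(5, 5, 5, 5)
  expect_equal(f0$p_value, 1)
  expect_equal(enrichment_fisher(10, 0, 0, 10)$p_value, 2 / choose(20, 10),
               tolerance = 1e-12)
  set.seed(36)
  for (i in 1:50) {
    cells <- as.integer(stats::rmultinom(1, sample(10:40, 1), rep(0.25, 4)))
    ours <- enrichment_fisher(cells[1], cells[2], cells[3], cells[4])
    expect_equal(ours$p_value,
                 oracle_fisher_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
  }
  expect_error(enrichment_fisher(-1, 2, 3, 4), "non-negative")
})
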