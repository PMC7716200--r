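# call confidence, agreement metrics, pass rates, identity, PCA, QC filters

test_that("call confidence matches hand-computed phred values", {
  expect_equal(call_confidence(c(1.0, 0.99, 0.999)), 25)
  expect_equal(call_confidence(rep(0.9, 5)), 10)
  expect_equal(call_confidence(c(1, 1, 1)), 100)        # cap
  expect_equal(call_confidence(0.99996), 100)           # rounds to certain
  expect_equal(call_confidence(0.99994), -10 * log10(1 - 0.9999))
})

test_that("added uncertainty never raises CC", {
  # demoting a certain call to gp_max = 0.95 (13 phred) cannot raise the
  # mean as long as the existing uncertain calls sit at or above 13 phred
  set.seed(4)
  for (i in 1:10) {
    g <- c(rep(1, 10), runif(10, 0.95, 0.9999))
    cc0 <- call_confidence(g)
    g2 <- g; g2[sample(which(g == 1), 1)] <- 0.95
    expect_lte(call_confidence(g2), cc0)
  }
  expect_lt(call_confidence(c(1, 1, 0.95)), call_confidence(c(1, 1, 1)))
})

test_that("genotype agreement handles the worked examples", {
  expect_equal(genotype_agreement(c(0, 1, 2), c(0, 1, 2)),
               list(r = 1, concordance = 1, n_shared = 3L))
  ag <- genotype_agreement(c(0, 1, 2, 0), c(2, 1, 0, 2))
  expect_equal(ag$r, -1)
  expect_equal(ag$concordance, 0.25)
  agc <- genotype_agreement(c(0, 1, 2), c(1, 1, 1))
  expect_true(is.na(agc$r))
  expect_equal(agc$concordance, 1 / 3)
  # missing handling
  agm <- genotype_agreement(c(0, NA, 2), c(0, 1, NA))
  expect_identical(agm$n_shared, 1L)
  expect_true(is.na(agm$r))
})

test_that("MAF-binned agreement bins on the comparator and flags empty bins", {
  set.seed(12)
  n <- 40; V <- 300
  truth <- matrix(rbinom(n * V, 2, rep(runif(V, 0.02, 0.5), each = n)), n, V)
  bins <- maf_binned_agreement(truth, truth, min_compared = 35)
  expect_identical(nrow(bins), 50L)
  nz <- bins$n_variants > 0
  expect_true(any(nz))
  expect_true(all(abs(bins$mean_r[nz] - 1) < 1e-8, na.rm = TRUE))
  expect_true(all(bins$mean_concordance[nz] == 1))
  expect_true(all(is.na(bins$mean_r[!nz])))
  expect_equal(sum(bins$n_variants), sum(colMeans(truth) / 2 > 0 &
                                           colMeans(truth) / 2 < 1))

  # permuted calls: near-zero mean correlation per well-filled bin
  truth2 <- matrix(rbinom(200 * 800, 2, 0.3), 200, 800)
  calls2 <- apply(truth2, 2L, sample)
  bins2 <- maf_binned_agreement(calls2, truth2, min_compared = 35)
  filled <- which(bins2$n_variants >= 100)
  expect_true(length(filled) >= 1)
  expect_true(all(abs(bins2$mean_r[filled]) < 0.1))

  # binning rule: MAF 0.005 lands in (0, 0.01]
  t3 <- matrix(rbinom(400, 2, 0.005), 400, 1)
  while (sum(t3) == 0) t3 <- matrix(rbinom(400, 2, 0.005), 400, 1)
  b3 <- maf_binned_agreement(t3, t3, min_compared = 35)
  expect_gte(b3$n_variants[1], 1)
})

test_that("window pass rates count low-pass variants per 1-Mb window", {
  vt <- data.frame(chrom = "1", pos = c(1, 45, 89, 1e6 + 10),
                   ref = "A", alt = "C")
  pass <- rbind(c(TRUE, TRUE, TRUE, TRUE), c(TRUE, TRUE, TRUE, TRUE))
  wr <- window_pass_rates(pass, vt)
  expect_true(all(wr$by_window$frac_low_pass == 0))
  expect_equal(wr$by_window$mean_spacing[1], 44)

  # 4 variants with pass rates 1.0, 0.96, 0.94, 0.90 -> half below 0.95
  pass2 <- sapply(c(1, 0.96, 0.94, 0.90), function(p)
    c(rep(TRUE, round(p * 50)), rep(FALSE, 50 - round(p * 50))))
  vt2 <- data.frame(chrom = "1", pos = c(10, 20, 30, 40), ref = "A", alt = "C")
  wr2 <- window_pass_rates(pass2, vt2)
  expect_equal(wr2$by_window$frac_low_pass, 0.5)
})

test_that("identity verification finds swaps and mixtures", {
  set.seed(30)
  g <- matrix(rbinom(6 * 500, 2, 0.4), 6, 500,
              dimnames = list(sprintf("s%d", 1:6), NULL))
  self <- verify_identity(g, g)
  expect_true(all(self$best_match == self$library))
  expect_true(all(self$best_concordance == 1))
  expect_false(any(self$flagged))

  swapped <- g[c(2, 1, 3:6), ]
  rownames(swapped) <- rownames(g)           # s1 now carries s2's genotypes
  sw <- verify_identity(swapped, g)
  expect_true(all(sw$flagged[1:2]))
  expect_false(any(sw$flagged[3:6]))
  expect_identical(sw$best_match[1], "s2")
  expect_identical(sw$best_match[2], "s1")
})

test_that("chimeric mixtures depress CC and best concordance", {
  w <- tiny_world(n_target_animals = 4, pedigree_depth = 1, coverage = 2,
                  n_variants = 300)
  pu <- simulate_reads(w$truth, w$cfg)
  mix_ids <- c("A0001", "A0002")
  a <- pu[pu$animal == mix_ids[1], ]; b <- pu[pu$animal == mix_ids[2], ]
  set.seed(17)
  take_a <- rbinom(nrow(a), 1, 0.5) == 1
  mixed <- a
  mixed$ref_count <- ifelse(take_a, a$ref_count, b$ref_count)
  mixed$alt_count <- ifelse(take_a, a$alt_count, b$alt_count)
  gl_pure <- animal_likelihoods(pu, mix_ids[1], w$cfg$base_error)
  gl_mix <- genotype_likelihood(mixed$ref_count, mixed$alt_count,
                                w$cfg$base_error)
  gl_mix$pos <- mixed$pos
  post_pure <- impute_sample(gl_pure, w$panel)
  post_mix <- impute_sample(gl_mix, w$panel)
  expect_lt(call_confidence(post_mix), call_confidence(post_pure))
  truth1 <- w$truth$true_genotypes[mix_ids[1], ]
  expect_lt(mean(post_mix$hard_call == truth1),
            mean(post_pure$hard_call == truth1))
})

test_that("panel PCA separates diverged populations and respects nulls", {
  p <- simulate_panel(sim_config(n_panel_haplotypes = 80, n_variants = 2000,
                                 divergence = 0.3, seed = 9))
  pc <- panel_pca(p, n_snps = 1500, seed = 2)
  s1 <- pc$scores[pc$pop_label == "pop1", 1]
  s2 <- pc$scores[pc$pop_label == "pop2", 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))

  p0 <- simulate_panel(sim_config(n_panel_haplotypes = 80, n_variants = 2000,
                                  divergence = 0, seed = 9))
  pc0 <- panel_pca(p0, n_snps = 1500, seed = 2)
  expect_lt(pc0$var_frac[1], 2 * pc0$var_frac[2])

  # duplicated haplotypes get identical scores
  dup <- haplotype_panel(rbind(p$alleles, p$alleles), p$variant_table,
                         c(p$pop_label, p$pop_label))
  pcd <- panel_pca(dup, n_snps = 1500, seed = 2)
  H <- nrow(p$alleles)
  expect_equal(pcd$scores[1:H, ], pcd$scores[H + 1:H, ], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("genotype QC filter applies call-rate and MAF rules", {
  set.seed(2)
  g <- matrix(rbinom(40 * 30, 2, 0.3), 40, 30)
  f <- filter_genotypes(g)
  expect_identical(dim(f$genotypes), dim(g))
  expect_true(all(f$removed == 0))

  g2 <- g
  g2[1:5, 3] <- NA                        # variant call rate 35/40 < 0.95
  g2[7, 1:10] <- NA                       # animal call rate 20/30 < 0.95
  g2[, 5] <- 0; g2[2, 5] <- 1             # MAF 1/80 ~ 0.0125 > 0.005 kept
  g2[, 6] <- 0                            # monomorphic: MAF 0 removed
  f2 <- filter_genotypes(g2)
  expect_identical(unname(f2$removed["variants_call_rate"]), 1L)
  expect_identical(unname(f2$removed["animals_call_rate"]), 1L)
  expect_identical(unname(f2$removed["variants_maf"]), 1L)
  expect_identical(dim(f2$genotypes), c(39L, 28L))
})
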