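# synthetic-data generator: panel drift, mosaic pedigrees, phenotypes, reads

test_that("sim_config validates fields and names the offender", {
  expect_error(sim_config(n_panel_haplotypes = 3), "n_panel_haplotypes")
  expect_error(sim_config(divergence = 1.2), "divergence")
  expect_error(sim_config(h2_true = 0), "h2_true")
  expect_error(sim_config(h2_true = 1), "h2_true")
  expect_error(sim_config(coverage = -1), "coverage")
  expect_error(sim_config(n_qtl = 10, n_variants = 5), "n_qtl")
  expect_error(sim_config(pedigree_depth = 0), "pedigree_depth")
})

test_that("panel simulation is deterministic and respects divergence", {
  cfg <- sim_config(n_panel_haplotypes = 40, n_variants = 10000,
                    divergence = 0, seed = 7)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$alleles, p2$alleles)
  expect_identical(p1$variant_table, p2$variant_table)

  # divergence 0: allele-frequency difference between populations ~ 0
  f1 <- colMeans(p1$alleles[p1$pop_label == "pop1", ])
  f2 <- colMeans(p1$alleles[p1$pop_label == "pop2", ])
  expect_lt(abs(mean(f1 - f2)), 0.01)

  # stronger drift -> larger mean squared frequency difference
  msd <- function(div) {
    p <- simulate_panel(sim_config(n_panel_haplotypes = 100,
                                   n_variants = 5000,
                                   divergence = div, seed = 11))
    fa <- colMeans(p$alleles[p$pop_label == "pop1", ])
    fb <- colMeans(p$alleles[p$pop_label == "pop2", ])
    mean((fa - fb)^2)
  }
  expect_gt(msd(0.3), msd(0.01))
})

test_that("panel invariants hold", {
  p <- simulate_panel(tiny_cfg())
  expect_true(all(p$alleles %in% 0:1))
  expect_true(all(diff(p$variant_table$pos) > 0))
  expect_identical(nrow(p$alleles) %% 2L, 0L)
})

test_that("founders copy panel haplotypes exactly when recomb_rate = 0", {
  w <- tiny_world(recomb_rate = 0, n_target_animals = 6, pedigree_depth = 1)
  hap_str <- apply(w$panel$alleles, 1L, paste, collapse = "")
  for (i in seq_len(6)) {
    expect_true(paste(w$truth$true_haplotypes$hap1[i, ], collapse = "") %in% hap_str)
    expect_true(paste(w$truth$true_haplotypes$hap2[i, ], collapse = "") %in% hap_str)
  }
})

test_that("offspring are Mendelian-consistent with their parents", {
  w <- tiny_world(n_target_animals = 20, pedigree_depth = 3)
  ped <- w$pedigree
  g <- w$truth$true_genotypes
  kids <- which(ped$sire != "0")
  expect_gt(length(kids), 0)
  for (i in kids) {
    for (par in c(ped$sire[i], ped$dam[i])) {
      # a homozygous parent always passes that allele: 0 vs 2 is impossible
      expect_false(any(abs(g[i, ] - g[par, ]) == 2))
    }
  }
})

test_that("crossover count per transmitted gamete matches the Poisson rate", {
  rate <- 2e-6; L <- 1e6   # expect 2 crossovers per gamete
  set.seed(99)
  n <- 300
  counts <- replicate(n, {
    lpeval:::.gamete(rep(0L, 10), rep(1L, 10),
                     seq(1, L, length.out = 10), L, rate)$n_cross
  })
  expect_lt(abs(mean(counts) - rate * L), 3 * sqrt(rate * L / n))
})

test_that("true breeding values reproduce exactly from genotypes and effects", {
  w <- tiny_world()
  qe <- w$truth$qtl_effects
  Zq <- sweep(w$truth$true_genotypes[, qe$variant, drop = FALSE], 2L,
              2 * qe$freq)
  expect_equal(unname(drop(Zq %*% qe$effect)),
               unname(w$truth$true_breeding_values), tolerance = 1e-12)
})

test_that("phenotypes hit the target heritability and have no hidden order", {
  w <- tiny_world(n_target_animals = 400, pedigree_depth = 1,
                  n_panel_haplotypes = 60, n_variants = 300, n_qtl = 40,
                  h2_true = 0.999)
  ph <- simulate_phenotypes(w$truth, w$cfg)
  expect_gt(cor(ph$y - attr(ph, "xbeta"), w$truth$true_breeding_values), 0.99)

  # realized variance ratio near 0.5 at h2 = 0.5
  w2 <- tiny_world(n_target_animals = 2000, pedigree_depth = 1,
                   n_panel_haplotypes = 60, n_variants = 300, n_qtl = 40,
                   h2_true = 0.5, seed = 5)
  ph2 <- simulate_phenotypes(w2$truth, w2$cfg)
  u <- w2$truth$true_breeding_values
  e <- ph2$y - attr(ph2, "xbeta") - u
  ratio <- var(u) / (var(u) + var(e))
  expect_gt(ratio, 0.45); expect_lt(ratio, 0.55)
})

test_that("read simulation obeys the depth and error model", {
  w0 <- tiny_world(coverage = 0)
  pu0 <- simulate_reads(w0$truth, w0$cfg)
  expect_true(all(pu0$ref_count == 0 & pu0$alt_count == 0))

  w <- tiny_world(n_target_animals = 4, n_variants = 12500, coverage = 1,
                  chromosome_length = 2e6)
  pu <- simulate_reads(w$truth, w$cfg)
  md <- mean(pu$ref_count + pu$alt_count)   # 50,000 site draws
  expect_gt(md, 0.97); expect_lt(md, 1.03)

  # eps = 0 impossible by config (open range); near-zero at a het site
  whet <- tiny_world(coverage = 30, base_error = 1e-6, n_target_animals = 3)
  puh <- simulate_reads(whet$truth, whet$cfg)
  g <- whet$truth$true_genotypes
  a1 <- puh[puh$animal == rownames(g)[1] & puh$pos %in%
              whet$panel$variant_table$pos[g[1, ] == 1], ]
  deep <- a1[a1$ref_count + a1$alt_count >= 10, ]
  expect_true(all(deep$ref_count > 0 & deep$alt_count > 0))
})
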