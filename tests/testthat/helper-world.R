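# shared fixture builders; everything is generated in code at test time

tiny_cfg <- function(...) {
  args <- modifyList(list(
    n_panel_haplotypes = 60L, n_variants = 400L, chromosome_length = 1e6,
    n_populations = 2L, divergence = 0.15, recomb_rate = 1e-8,
    n_target_animals = 12L, pedigree_depth = 2L, n_qtl = 20L,
    h2_true = 0.5, fixed_effect_levels = 3L, coverage = 1.0,
    base_error = 0.01, seed = 101L), list(...))
  do.call(sim_config, args)
}

tiny_world <- function(...) {
  cfg <- tiny_cfg(...)
  panel <- simulate_panel(cfg)
  ind <- simulate_individuals(panel, cfg)
  list(cfg = cfg, panel = panel, pedigree = ind$pedigree, truth = ind$truth)
}

# genotype likelihoods for one animal from a pileup, aligned to the panel
animal_likelihoods <- function(pileup, id, error = 0.01) {
  pa <- pileup[pileup$animal == id, ]
  pa <- pa[order(pa$pos), ]
  gl <- genotype_likelihood(pa$ref_count, pa$alt_count, error)
  gl$pos <- pa$pos
  gl
}

# impute one animal end to end; returns the site_posterior
impute_animal <- function(world, id, coverage = NULL, icfg = impute_config(),
                          seed_tag = "reads") {
  cfg <- world$cfg
  if (!is.null(coverage)) {
    cfg <- do.call(sim_config, modifyList(
      unclass(cfg), list(coverage = coverage)))
  }
  pu <- simulate_reads(world$truth, cfg)
  gl <- animal_likelihoods(pu, id, cfg$base_error)
  impute_sample(gl, world$panel, icfg)
}

# flat likelihoods (no reads) for a panel
flat_likelihoods <- function(panel) {
  data.frame(pos = panel$variant_table$pos, l_rr = 1, l_ra = 1, l_aa = 1)
}
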