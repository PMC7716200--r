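# Run configuration and the end-to-end pipeline:
# simulate -> downsample -> impute -> agreement -> gblup -> effects.

#' Default run configuration
#'
#' Nested list of every stage's parameters; round-trips losslessly through
#' JSON.  Unknown keys in a config file are rejected.
#'
#' @param ... named overrides of top-level sections (partial lists allowed,
#'   merged over the defaults).
#' @return object of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    sim = list(n_panel_haplotypes = 200L, n_variants = 5000L,
               chromosome_length = 1e7, n_populations = 2L,
               divergence = 0.15, recomb_rate = 1e-8,
               n_target_animals = 50L, pedigree_depth = 2L,
               founder_generations = 30L,
               n_qtl = 50L, h2_true = 0.5, fixed_effect_levels = 5L,
               coverage = 1.0, base_error = 0.01),
    downsample = list(fraction = 1.0),
    impute = list(rho = 1e-6, mismatch = 1e-3, max_panel = 100L),
    agreement = list(gpmax_threshold = 0.9, pass_rate_threshold = 0.95,
                     maf_bin = 0.01, min_compared = 35L, window_bp = 1e6,
                     pca_n_snps = 150000L, pca_maf_min = 0.05),
    gblup = list(reml_max_iter = 500L, reml_tol = 1e-8),
    effects = list(holdout_fraction = 0.3, n_perm = 100L,
                   subset_fraction = 0.1))
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config sections: ", paste(bad, collapse = ", "))
  for (nm in names(over)) {
    if (is.list(cfg[[nm]])) {
      bad <- setdiff(names(over[[nm]]), names(cfg[[nm]]))
      if (length(bad))
        stop(sprintf("unknown config keys in '%s': %s", nm,
                     paste(bad, collapse = ", ")))
      cfg[[nm]] <- modifyList(cfg[[nm]], over[[nm]])
    } else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration (JSON)
#'
#' @param path JSON file.
#' @return a `run_config` (read); `path` invisibly (write).
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(default_config, c(list(seed = raw$seed %||% 1L),
                            raw[setdiff(names(raw), "seed")]))
}

#' @rdname read_config
#' @param cfg a `run_config`.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full evaluation pipeline
#'
#' Simulates the stated world, downsamples and imputes every target animal,
#' computes the agreement report, fits pedigree and genomic BLUP with REML
#' variance components, and runs the leave-out molecular-breeding-value
#' validation over three variant sets (all variants, a permutation-selected
#' subset, a size-matched random subset) and two genotype sources (true
#' "array" genotypes and low-pass imputed dosages).  Every artifact is a
#' plain-text file under `out_dir` and a manifest records child seeds and
#' row/variant counts.  Rerunning with the same config is numerically
#' identical.
#'
#' @param cfg a `run_config` (or path to a JSON config).
#' @param out_dir output directory (created).
#' @param seed optional master-seed override.
#' @return invisible list of in-memory results (panel, truth, posteriors,
#'   agreement, variance estimates, validation grid, manifest).
#' @export
run_pipeline <- function(cfg = default_config(), out_dir, seed = NULL) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed, config = unclass(cfg), stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  # -- simulate ---------------------------------------------------------
  sc <- do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
  panel <- simulate_panel(sc)
  ind <- simulate_individuals(panel, sc)
  truth <- ind$truth
  phen <- simulate_phenotypes(truth, sc)
  pileup <- simulate_reads(truth, sc)
  write_panel_vcf(panel, file.path(out_dir, "panel.vcf"))
  data.table::fwrite(ind$pedigree, file.path(out_dir, "pedigree.csv"))
  data.table::fwrite(phen, file.path(out_dir, "phenotypes.csv"))
  data.table::fwrite(data.table::data.table(animal = names(truth$true_breeding_values),
                                            true_bv = truth$true_breeding_values),
                     file.path(out_dir, "true_breeding_values.csv"))
  write_pileup(pileup, file.path(out_dir, "pileup.tsv"))
  note("simulate", seed = child_seed(cfg$seed, "panel"),
       n_variants = ncol(panel$alleles), n_haplotypes = nrow(panel$alleles),
       n_animals = nrow(truth$true_genotypes))

  # -- downsample -------------------------------------------------------
  if (cfg$downsample$fraction < 1) {
    pileup <- downsample_reads(pileup, fraction = cfg$downsample$fraction,
                               seed = cfg$seed)
    write_pileup(pileup, file.path(out_dir, "pileup_downsampled.tsv"))
  }
  note("downsample", fraction = cfg$downsample$fraction,
       mean_depth = mean(pileup$ref_count + pileup$alt_count))

  # -- impute -----------------------------------------------------------
  icfg <- do.call(impute_config, cfg$impute)
  animals <- rownames(truth$true_genotypes)
  V <- ncol(truth$true_genotypes)
  calls <- dosages <- matrix(NA_real_, length(animals), V,
                             dimnames = list(animals, NULL))
  pass <- matrix(FALSE, length(animals), V, dimnames = list(animals, NULL))
  gpmax <- matrix(NA_real_, length(animals), V)
  pu <- data.table::as.data.table(pileup)
  data.table::setkey(pu, animal, pos)
  imp_dir <- file.path(out_dir, "imputed")
  dir.create(imp_dir, showWarnings = FALSE)
  for (i in seq_along(animals)) {
    pa <- pu[list(animals[i])]
    gl <- genotype_likelihood(pa$ref_count, pa$alt_count, sc$base_error)
    gl$pos <- pa$pos
    post <- impute_sample(gl, panel, icfg,
                          threshold = cfg$agreement$gpmax_threshold)
    calls[i, ] <- post$hard_call
    dosages[i, ] <- post$dosage
    pass[i, ] <- post$pass
    gpmax[i, ] <- post$gp_max
    write_imputed_vcf(post, panel$variant_table, animals[i],
                      file.path(imp_dir, paste0(animals[i], ".vcf")))
  }
  note("impute", n_imputed = length(animals), max_panel = icfg$max_panel)

  # -- agreement --------------------------------------------------------
  ag <- cfg$agreement
  cc <- apply(gpmax, 1L, call_confidence)
  truth_g <- truth$true_genotypes
  calls_pass <- calls
  calls_pass[!pass] <- NA
  per_lib <- t(vapply(seq_along(animals), function(i) {
    a <- genotype_agreement(calls_pass[i, ], truth_g[i, ])
    c(r = a$r %||% NA_real_, concordance = a$concordance,
      n_shared = a$n_shared)
  }, numeric(3)))
  lib_report <- data.frame(animal = animals, cc = cc,
                           r_overall = per_lib[, 1],
                           concordance_overall = per_lib[, 2],
                           n_shared = per_lib[, 3],
                           pass_rate = rowMeans(pass))
  min_cmp <- min(ag$min_compared, length(animals))
  by_maf <- maf_binned_agreement(calls_pass, truth_g, bin_width = ag$maf_bin,
                                 min_compared = min_cmp)
  wpr <- window_pass_rates(pass, panel$variant_table, window_bp = ag$window_bp,
                           pass_rate_min = ag$pass_rate_threshold)
  ident <- verify_identity(calls, truth_g)
  pca <- panel_pca(panel, n_snps = ag$pca_n_snps, maf_min = ag$pca_maf_min,
                   seed = cfg$seed)
  data.table::fwrite(lib_report, file.path(out_dir, "library_agreement.csv"))
  data.table::fwrite(by_maf, file.path(out_dir, "agreement_by_maf.csv"))
  data.table::fwrite(wpr$by_window, file.path(out_dir, "window_pass_rates.csv"))
  data.table::fwrite(ident, file.path(out_dir, "identity_check.csv"))
  data.table::fwrite(
    data.frame(haplotype = seq_len(nrow(pca$scores)), pop = pca$pop_label,
               pca$scores[, seq_len(min(4L, ncol(pca$scores))), drop = FALSE]),
    file.path(out_dir, "panel_pca.csv"))
  note("agreement", mean_cc = mean(cc), mean_pass_rate = mean(pass),
       pca_snps = pca$n_snps_used)

  # -- gblup ------------------------------------------------------------
  Xmm <- stats::model.matrix(~ ., data = phen[, grep("^cg", names(phen)),
                                              drop = FALSE])
  keepc <- qr(Xmm)$pivot[seq_len(qr(Xmm)$rank)]
  Xmm <- Xmm[, keepc, drop = FALSE]
  Z <- diag(length(animals))
  A <- build_A(ind$pedigree)[animals, animals]
  Gs <- stabilize_G(build_G(truth_g))
  vcA <- reml(phen$y, Xmm, Z, A, max_iter = cfg$gblup$reml_max_iter,
              tol = cfg$gblup$reml_tol)
  vcG <- reml(phen$y, Xmm, Z, Gs, max_iter = cfg$gblup$reml_max_iter,
              tol = cfg$gblup$reml_tol)
  ebv <- fit_blup(phen$y, Xmm, Z, A, vcA$sigma_g2, vcA$sigma_e2)
  gebv <- fit_blup(phen$y, Xmm, Z, Gs, vcG$sigma_g2, vcG$sigma_e2)
  data.table::fwrite(
    data.frame(relationship = c("A", "Gstar"),
               sigma_g2 = c(vcA$sigma_g2, vcG$sigma_g2),
               sigma_e2 = c(vcA$sigma_e2, vcG$sigma_e2),
               h2 = c(vcA$h2, vcG$h2), se_h2 = c(vcA$se_h2, vcG$se_h2),
               converged = c(vcA$converged, vcG$converged)),
    file.path(out_dir, "variance_components.csv"))
  data.table::fwrite(
    data.frame(animal = animals, ebv = ebv$u, gebv = gebv$u,
               true_bv = truth$true_breeding_values),
    file.path(out_dir, "breeding_values.csv"))
  note("gblup", h2_A = vcA$h2, h2_G = vcG$h2)

  # -- effects / leave-out validation -----------------------------------
  ef <- cfg$effects
  colnames(truth_g) <- sprintf("v%d", seq_len(V))
  colnames(dosages) <- colnames(truth_g)
  n_hold <- max(2L, round(ef$holdout_fraction * length(animals)))
  set.seed(child_seed(cfg$seed, "holdout"))
  holdout <- sort(sample(animals, n_hold))
  train <- setdiff(animals, holdout)
  n_keep <- max(2L, round(ef$subset_fraction * V))
  psel <- permutation_select(truth_g[train, , drop = FALSE],
                             phen$y[match(train, animals)],
                             X = Xmm[match(train, animals), , drop = FALSE],
                             sigma_g2 = vcG$sigma_g2, sigma_e2 = vcG$sigma_e2,
                             n_perm = ef$n_perm, n_keep = n_keep,
                             seed = cfg$seed)
  set.seed(child_seed(cfg$seed, "random_subset"))
  rand_set <- sort(sample(colnames(truth_g), n_keep))
  grid <- leave_out_validate(
    truth_g, phen$y, Xmm, ind$pedigree, holdout,
    variant_sets = list(all = colnames(truth_g),
                        perm_subset = psel$selected,
                        random_subset = rand_set),
    genotype_sources = list(array = truth_g, lowpass = dosages),
    sigma_g2 = vcG$sigma_g2, sigma_e2 = vcG$sigma_e2)
  data.table::fwrite(grid, file.path(out_dir, "mbv_validation.csv"))
  data.table::fwrite(psel$table, file.path(out_dir, "permutation_selection.csv"))
  note("effects", n_holdout = n_hold, n_keep = n_keep, n_perm = ef$n_perm)

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(panel = panel, pedigree = ind$pedigree, truth = truth,
                 phenotypes = phen, lib_report = lib_report, by_maf = by_maf,
                 windows = wpr, identity = ident, pca = pca,
                 varcomp = list(A = vcA, G = vcG),
                 ebv = ebv, gebv = gebv, validation = grid,
                 manifest = manifest))
}
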