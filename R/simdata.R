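# Synthetic-data generator: haplotype panel, pedigreed mosaic individuals,
# additive phenotypes, and low-coverage read counts, all with known truth.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator and validates ranges.
#' Defaults describe the desk-scale world the package is tested in: a
#' two-cluster (taurine/indicine-like) panel of 200 haplotypes, 5,000
#' variants on a 10-Mb chromosome, 50 pedigreed target animals sequenced at
#' 1X with 1% base error, and a moderately heritable (h2 = 0.5) additive
#' trait with one 5-level contemporary-group factor.
#'
#' @param n_panel_haplotypes even number of phased panel haplotypes.
#' @param n_variants number of biallelic variants on the chromosome.
#' @param chromosome_length chromosome length in bp.
#' @param n_populations number of panel populations (breeds/clusters).
#' @param divergence Balding-Nichols drift (Fst-like) between populations,
#'   in `[0, 1)`. 0.15 roughly matches a taurine/indicine split.
#' @param recomb_rate per-bp crossover probability (default 1e-8 = 1 cM/Mb).
#' @param n_target_animals number of pedigreed target animals.
#' @param pedigree_depth number of generations (1 = founders only).
#' @param founder_generations effective generations of ancestry separating
#'   founders from the panel; founder chromosomes are mosaics with
#'   `recomb_rate * founder_generations` expected crossovers per bp, so
#'   larger values mean shorter shared segments and harder imputation
#'   (default 30, which puts 1X imputation accuracy in the high-0.99s
#'   rather than at saturation).
#' @param n_qtl number of causal variants.
#' @param h2_true narrow-sense heritability in (0, 1).
#' @param fixed_effect_levels integer vector, number of levels per
#'   fixed-effect factor (contemporary-group-like).
#' @param coverage mean sequencing depth (X).
#' @param base_error per-read error probability.
#' @param seed master seed; every stage derives a child seed from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_panel_haplotypes = 200L, n_variants = 5000L,
                       chromosome_length = 1e7, n_populations = 2L,
                       divergence = 0.15, recomb_rate = 1e-8,
                       n_target_animals = 50L, pedigree_depth = 2L,
                       founder_generations = 30L,
                       n_qtl = 50L, h2_true = 0.5,
                       fixed_effect_levels = 5L,
                       coverage = 1.0, base_error = 0.01, seed = 1L) {
  n_panel_haplotypes <- check_count(n_panel_haplotypes, "n_panel_haplotypes", 2L)
  if (n_panel_haplotypes %% 2L != 0L)
    stop_config("n_panel_haplotypes", "must be even (diploid panel)")
  n_variants <- check_count(n_variants, "n_variants", 2L)
  chromosome_length <- check_count(chromosome_length, "chromosome_length", n_variants)
  n_populations <- check_count(n_populations, "n_populations", 1L)
  check_prob(divergence, "divergence", 0, 1, open_hi = TRUE)
  check_prob(recomb_rate, "recomb_rate", 0, 1)
  n_target_animals <- check_count(n_target_animals, "n_target_animals", 1L)
  pedigree_depth <- check_count(pedigree_depth, "pedigree_depth", 1L)
  founder_generations <- check_count(founder_generations, "founder_generations", 0L)
  n_qtl <- check_count(n_qtl, "n_qtl", 1L)
  if (n_qtl > n_variants) stop_config("n_qtl", "must be <= n_variants")
  check_prob(h2_true, "h2_true", 0, 1, open_lo = TRUE, open_hi = TRUE)
  fixed_effect_levels <- vapply(seq_along(fixed_effect_levels), function(i)
    check_count(fixed_effect_levels[i], "fixed_effect_levels", 1L), integer(1))
  if (!is.numeric(coverage) || coverage < 0)
    stop_config("coverage", "must be >= 0")
  check_prob(base_error, "base_error", 0, 0.5, open_hi = TRUE)
  seed <- check_count(seed, "seed", 0L)
  structure(list(
    n_panel_haplotypes = n_panel_haplotypes, n_variants = n_variants,
    chromosome_length = chromosome_length, n_populations = n_populations,
    divergence = divergence, recomb_rate = recomb_rate,
    n_target_animals = n_target_animals, pedigree_depth = pedigree_depth,
    founder_generations = founder_generations,
    n_qtl = n_qtl, h2_true = h2_true,
    fixed_effect_levels = fixed_effect_levels,
    coverage = coverage, base_error = base_error, seed = seed),
    class = "sim_config")
}

#' Construct a haplotype panel object
#'
#' @param alleles haplotypes x variants matrix of 0/1 alleles.
#' @param variant_table data.frame with columns chrom, pos (1-based bp,
#'   strictly increasing within chrom), ref, alt.
#' @param pop_label character vector, one population label per haplotype.
#' @return object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, variant_table, pop_label) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) < 2L) stop("panel needs at least 2 haplotypes")
  if (!all(alleles %in% c(0L, 1L))) stop("panel alleles must be 0/1")
  stopifnot(is.data.frame(variant_table),
            all(c("chrom", "pos", "ref", "alt") %in% names(variant_table)),
            nrow(variant_table) == ncol(alleles),
            length(pop_label) == nrow(alleles))
  for (ch in unique(variant_table$chrom)) {
    p <- variant_table$pos[variant_table$chrom == ch]
    if (any(diff(p) <= 0))
      stop("variant positions must be strictly increasing within a chromosome")
  }
  structure(list(alleles = alleles,
                 variant_table = as.data.frame(variant_table),
                 pop_label = as.character(pop_label)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes x %d variants; populations: %s\n",
              nrow(x$alleles), ncol(x$alleles),
              paste(sprintf("%s (%d)", names(table(x$pop_label)),
                            table(x$pop_label)), collapse = ", ")))
  invisible(x)
}

#' Panel alternate-allele frequencies
#' @param panel a `haplotype_panel`.
#' @return numeric vector of per-variant alt-allele frequencies.
#' @export
panel_freqs <- function(panel) colMeans(panel$alleles)

#' Simulate a multi-population phased haplotype panel
#'
#' Ancestral allele frequencies are drawn uniformly on (0.05, 0.95); each
#' population drifts away from them by a Balding-Nichols Beta draw with the
#' configured divergence (an Fst-like parameter), and haplotypes are then
#' sampled binomially within population.  Haplotypes are split as evenly as
#' possible across populations (pairs kept within one population so the
#' panel can be emitted as diploid VCF samples).
#'
#' @param cfg a [sim_config()].
#' @return a [haplotype_panel()].
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(child_seed(cfg$seed, "panel"))
  V <- cfg$n_variants
  H <- cfg$n_panel_haplotypes
  P <- cfg$n_populations
  p_anc <- runif(V, 0.05, 0.95)
  fst <- cfg$divergence
  # pairs of haplotypes per population, evenly split
  pairs_per_pop <- diff(round(seq(0, H / 2, length.out = P + 1L)))
  pop_label <- rep(sprintf("pop%d", seq_len(P)), times = 2L * pairs_per_pop)
  alleles <- matrix(0L, H, V)
  row0 <- 0L
  for (k in seq_len(P)) {
    nh <- 2L * pairs_per_pop[k]
    if (nh == 0L) next
    pk <- if (fst > 0) {
      shape <- (1 - fst) / fst
      rbeta(V, p_anc * shape, (1 - p_anc) * shape)
    } else p_anc
    alleles[row0 + seq_len(nh), ] <-
      matrix(rbinom(nh * V, 1L, rep(pk, each = nh)), nh, V)
    row0 <- row0 + nh
  }
  pos <- sort(sample.int(cfg$chromosome_length, V))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, V, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  vt <- data.frame(chrom = "1", pos = pos, ref = ref, alt = alt,
                   stringsAsFactors = FALSE)
  haplotype_panel(alleles, vt, pop_label)
}

# one gamete from a diploid pair of haplotypes: Poisson crossovers, random
# starting chromatid, alternation at each crossover
.gamete <- function(hap1, hap2, positions, chrom_length, recomb_rate) {
  n_x <- rpois(1L, recomb_rate * chrom_length)
  start <- sample.int(2L, 1L)
  if (n_x == 0L) {
    g <- if (start == 1L) hap1 else hap2
    return(list(hap = g, n_cross = 0L))
  }
  xpos <- sort(runif(n_x, 0, chrom_length))
  seg <- findInterval(positions, xpos)          # crossovers before the site
  use1 <- (seg %% 2L == 0L) == (start == 1L)    # alternate at each crossover
  g <- ifelse(use1, hap1, hap2)
  list(hap = as.integer(g), n_cross = n_x)
}

# founder haplotype: recombinant mosaic of panel haplotypes (fresh source
# haplotype per segment); returns haplotype + per-population copied fraction
.mosaic_hap <- function(panel, cfg) {
  V <- ncol(panel$alleles)
  L <- cfg$chromosome_length
  n_x <- rpois(1L, cfg$recomb_rate * max(cfg$founder_generations, 1L) * L)
  brk <- if (n_x > 0L) sort(runif(n_x, 0, L)) else numeric(0)
  src <- sample.int(nrow(panel$alleles), n_x + 1L, replace = TRUE)
  seg <- findInterval(panel$variant_table$pos, brk) + 1L
  hap <- panel$alleles[cbind(src[seg], seq_len(V))]
  seg_len <- diff(c(0, brk, L)) / L
  pops <- sort(unique(panel$pop_label))
  frac <- vapply(pops, function(p)
    sum(seg_len[panel$pop_label[src] == p]), numeric(1))
  list(hap = as.integer(hap), breed_frac = frac)
}

#' Simulate pedigreed target animals as mosaics of panel haplotypes
#'
#' Founders carry recombinant mosaics of panel haplotypes (so they are
#' related to, but not members of, the panel); later generations inherit
#' recombinant gametes from a sire and dam of the previous generation.
#' Animals are split as evenly as possible across `pedigree_depth`
#' generations and sexes alternate within generation so matings are always
#' possible.  QTL are drawn from panel variants with MAF > 0.01; their
#' effects are standard normal, rescaled so the realized additive values
#' have unit variance, and true breeding values are exactly the centered
#' QTL genotypes times the effects.
#'
#' @param panel a [haplotype_panel()].
#' @param cfg a [sim_config()].
#' @param reference_sires number of founders whose two haplotypes are
#'   verbatim panel haplotypes (the "sire in the reference panel" contrast);
#'   default 0.
#' @return list with `pedigree` (data.frame animal/sire/dam/generation/sex,
#'   0 = unknown parent) and `truth` (a `truth_set`: true_genotypes,
#'   true_haplotypes, true_breeding_values, qtl_effects, breed_fraction).
#' @export
simulate_individuals <- function(panel, cfg, reference_sires = 0L) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(cfg, "sim_config"))
  if (cfg$pedigree_depth < 1L) stop_config("pedigree_depth", "must be >= 1")
  set.seed(child_seed(cfg$seed, "individuals"))
  V <- ncol(panel$alleles)
  n <- cfg$n_target_animals
  depth <- cfg$pedigree_depth
  pops <- sort(unique(panel$pop_label))
  gen_sizes <- diff(round(seq(0, n, length.out = depth + 1L)))
  gen_sizes[gen_sizes == 0L] <- 1L
  gen_sizes[1] <- max(gen_sizes[1], min(n, 2L))  # need 2 founders to mate
  while (sum(gen_sizes) > n) gen_sizes[which.max(gen_sizes)] <-
      gen_sizes[which.max(gen_sizes)] - 1L
  ids <- sprintf("A%04d", seq_len(sum(gen_sizes)))
  pedigree <- data.frame(animal = ids, sire = "0", dam = "0",
                         generation = rep(seq_len(depth), gen_sizes),
                         sex = rep_len(c("M", "F"), sum(gen_sizes)),
                         stringsAsFactors = FALSE)
  hap1 <- matrix(0L, length(ids), V)
  hap2 <- matrix(0L, length(ids), V)
  breed_fraction <- matrix(0, length(ids), length(pops),
                           dimnames = list(ids, pops))
  for (i in seq_along(ids)) {
    g <- pedigree$generation[i]
    if (g == 1L) {
      if (i <= reference_sires) {
        src <- sample.int(nrow(panel$alleles), 2L)
        hap1[i, ] <- panel$alleles[src[1], ]
        hap2[i, ] <- panel$alleles[src[2], ]
        for (s in src) {
          j <- match(panel$pop_label[s], pops)
          breed_fraction[i, j] <- breed_fraction[i, j] + 0.5
        }
      } else {
        m1 <- .mosaic_hap(panel, cfg); m2 <- .mosaic_hap(panel, cfg)
        hap1[i, ] <- m1$hap; hap2[i, ] <- m2$hap
        breed_fraction[i, ] <- (m1$breed_frac + m2$breed_frac) / 2
      }
    } else {
      prev <- which(pedigree$generation == g - 1L)
      males <- prev[pedigree$sex[prev] == "M"]
      females <- prev[pedigree$sex[prev] == "F"]
      if (length(males) == 0L) males <- prev
      if (length(females) == 0L) females <- prev
      s <- males[sample.int(length(males), 1L)]
      d <- females[sample.int(length(females), 1L)]
      if (s == d) d <- prev[sample.int(length(prev), 1L)]
      pedigree$sire[i] <- ids[s]
      pedigree$dam[i] <- ids[d]
      gs <- .gamete(hap1[s, ], hap2[s, ], panel$variant_table$pos,
                    cfg$chromosome_length, cfg$recomb_rate)
      gd <- .gamete(hap1[d, ], hap2[d, ], panel$variant_table$pos,
                    cfg$chromosome_length, cfg$recomb_rate)
      hap1[i, ] <- gs$hap; hap2[i, ] <- gd$hap
      breed_fraction[i, ] <- (breed_fraction[s, ] + breed_fraction[d, ]) / 2
    }
  }
  geno <- hap1 + hap2
  rownames(geno) <- ids
  # QTL and true breeding values
  pf <- panel_freqs(panel)
  maf <- pmin(pf, 1 - pf)
  eligible <- which(maf > 0.01)
  if (length(eligible) < cfg$n_qtl)
    stop_config("n_qtl", "exceeds panel variants with MAF > 0.01")
  qtl <- sort(sample(eligible, cfg$n_qtl))
  a <- rnorm(cfg$n_qtl)
  pq <- colMeans(geno[, qtl, drop = FALSE]) / 2
  Zq <- sweep(geno[, qtl, drop = FALSE], 2L, 2 * pq)
  u_raw <- drop(Zq %*% a)
  s_u <- sd(u_raw)
  if (s_u > 0) a <- a / s_u
  u_true <- drop(Zq %*% a)
  names(u_true) <- ids
  truth <- structure(list(
    true_genotypes = geno,
    true_haplotypes = list(hap1 = hap1, hap2 = hap2),
    true_breeding_values = u_true,
    qtl_effects = data.frame(variant = qtl, effect = a, freq = pq),
    breed_fraction = breed_fraction,
    variant_table = panel$variant_table), class = "truth_set")
  list(pedigree = pedigree, truth = truth)
}

#' Simulate additive phenotypes under the animal model
#'
#' Generates y = Xb + u + e: contemporary-group-like fixed factors with
#' standard-normal level effects (first level constrained to 0), the true
#' breeding values from the truth set, and residuals scaled so that
#' `var(u) / (var(u) + sigma_e^2) = h2_true` on the realized genetic
#' variance.
#'
#' @param truth a `truth_set` from [simulate_individuals()].
#' @param cfg a [sim_config()].
#' @return data.frame (animal, fixed-effect factors, y) with attributes
#'   `true_beta`, `sigma_e2` and `xbeta`.
#' @export
simulate_phenotypes <- function(truth, cfg) {
  stopifnot(inherits(truth, "truth_set"), inherits(cfg, "sim_config"))
  check_prob(cfg$h2_true, "h2_true", 0, 1, open_lo = TRUE, open_hi = TRUE)
  set.seed(child_seed(cfg$seed, "phenotypes"))
  u <- truth$true_breeding_values
  n <- length(u)
  df <- data.frame(animal = names(u), stringsAsFactors = FALSE)
  xbeta <- numeric(n)
  true_beta <- list()
  for (f in seq_along(cfg$fixed_effect_levels)) {
    L <- cfg$fixed_effect_levels[f]
    lev <- sample.int(L, n, replace = TRUE)
    beta <- c(0, rnorm(L - 1L))
    nm <- sprintf("cg%d", f)
    df[[nm]] <- factor(sprintf("%s_%d", nm, lev),
                       levels = sprintf("%s_%d", nm, seq_len(L)))
    xbeta <- xbeta + beta[lev]
    true_beta[[nm]] <- beta
  }
  vu <- var(u)
  sigma_e2 <- vu * (1 - cfg$h2_true) / cfg$h2_true
  if (!is.finite(sigma_e2) || vu == 0) sigma_e2 <- 1 - cfg$h2_true
  e <- rnorm(n, 0, sqrt(sigma_e2))
  df$y <- xbeta + u + e
  attr(df, "true_beta") <- true_beta
  attr(df, "sigma_e2") <- sigma_e2
  attr(df, "xbeta") <- xbeta
  df
}

#' Simulate per-site read counts at low coverage
#'
#' Depth at each animal x site is Poisson(coverage); each read reports the
#' true allele with probability 1 - base_error and the other allele
#' otherwise.  Sites with zero depth are retained (zero counts) so the
#' pileup always covers every panel variant.
#'
#' @param truth a `truth_set`.
#' @param cfg a [sim_config()].
#' @return data.table pileup with columns animal, chrom, pos, ref_count,
#'   alt_count.
#' @export
simulate_reads <- function(truth, cfg) {
  stopifnot(inherits(truth, "truth_set"), inherits(cfg, "sim_config"))
  if (cfg$coverage < 0) stop_config("coverage", "must be >= 0")
  set.seed(child_seed(cfg$seed, "reads"))
  geno <- truth$true_genotypes
  vt <- truth$variant_table
  n <- nrow(geno); V <- ncol(geno)
  eps <- cfg$base_error
  depth <- matrix(rpois(n * V, cfg$coverage), n, V)
  p_alt <- geno / 2 * (1 - eps) + (1 - geno / 2) * eps
  alt <- matrix(rbinom(n * V, depth, p_alt), n, V)
  data.table::data.table(
    animal = rep(rownames(geno), each = V),
    chrom = rep(vt$chrom, n),
    pos = rep(vt$pos, n),
    ref_count = as.integer(t(depth - alt)),
    alt_count = as.integer(t(alt)))
}
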