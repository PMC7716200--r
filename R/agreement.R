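# Imputation-quality metrics: call confidence, pass rates, MAF-stratified
# agreement, identity verification, panel PCA, and genotype QC filters.

#' Phred-scaled call confidence for one library
#'
#' CC summarises the imputed genotype probabilities of a library as the mean
#' of `-10 * log10(1 - GP_max)` over its uncertain calls.  "Uncertain" is
#' judged after rounding GP_max to the 4-decimal precision the VCF carries,
#' so a GP_max of 0.99996 counts as certain.  A library with no uncertain
#' calls gets the cap (100 phred).
#'
#' @param gp_max numeric vector of per-site GP_max values (or a
#'   `site_posterior` data.frame, whose gp_max column is used).
#' @param cap CC for a library with no uncertain calls (default 100).
#' @param digits rounding precision defining "certain" (default 4, the VCF
#'   GP precision).
#' @return scalar CC in phred units.
#' @export
call_confidence <- function(gp_max, cap = 100, digits = 4L) {
  if (is.data.frame(gp_max)) gp_max <- gp_max$gp_max
  stopifnot(length(gp_max) >= 1L, all(is.finite(gp_max)))
  g <- round(gp_max, digits)
  unc <- g < 1
  if (!any(unc)) return(cap)
  mean(-10 * log10(1 - g[unc]))
}

#' Agreement between two genotype call vectors
#'
#' Pearson correlation of 0/1/2 codes and fraction of identical calls over
#' shared non-missing sites.  The correlation is reported as NA when either
#' vector is constant on the shared sites (undefined variance) or fewer than
#' 2 shared sites exist; concordance is still computed from 1 shared site up.
#'
#' @param a,b numeric vectors of 0/1/2 genotype codes, NA = missing.
#' @return list with r, concordance, n_shared.
#' @export
genotype_agreement <- function(a, b) {
  stopifnot(length(a) == length(b))
  sh <- !is.na(a) & !is.na(b)
  n <- sum(sh)
  if (n == 0L) return(list(r = NA_real_, concordance = NA_real_, n_shared = 0L))
  aa <- a[sh]; bb <- b[sh]
  conc <- mean(aa == bb)
  r <- if (n >= 2L && sd(aa) > 0 && sd(bb) > 0) cor(aa, bb) else NA_real_
  list(r = r, concordance = conc, n_shared = n)
}

#' Per-variant agreement averaged within minor-allele-frequency bins
#'
#' For each variant, the correlation and concordance between imputed calls
#' and comparator genotypes are computed across libraries (variants with
#' fewer than `min_compared` non-missing comparisons are dropped), then
#' averaged within half-open MAF bins (lo, hi] of width `bin_width` covering
#' (0, 0.5].  MAF is always taken from the comparator matrix, a property of
#' the variant rather than of any library.  Empty bins are retained with
#' n_variants = 0 and NA means.
#'
#' @param calls libraries x variants matrix of imputed 0/1/2 calls (NA for
#'   missing/non-passing).
#' @param truth libraries x variants comparator matrix, same shape.
#' @param bin_width MAF bin width (default 0.01).
#' @param min_compared minimum non-missing comparisons per variant
#'   (default 35).
#' @return data.frame: bin_lo, bin_hi, n_variants, mean_r, mean_concordance.
#' @export
maf_binned_agreement <- function(calls, truth, bin_width = 0.01,
                                 min_compared = 35L) {
  stopifnot(is.matrix(calls), is.matrix(truth), all(dim(calls) == dim(truth)))
  V <- ncol(calls)
  p <- colMeans(truth, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  n_cmp <- colSums(!is.na(calls) & !is.na(truth))
  r_v <- conc_v <- rep(NA_real_, V)
  for (v in seq_len(V)) {
    if (n_cmp[v] < min_compared) next
    ag <- genotype_agreement(calls[, v], truth[, v])
    r_v[v] <- ag$r
    conc_v[v] <- ag$concordance
  }
  usable <- n_cmp >= min_compared & maf > 0
  lo <- seq(0, 0.5 - bin_width, by = bin_width)
  hi <- lo + bin_width
  bin <- ceiling(maf / bin_width - 1e-12)      # (lo, hi] binning
  out <- data.frame(bin_lo = lo, bin_hi = hi, n_variants = 0L,
                    mean_r = NA_real_, mean_concordance = NA_real_)
  for (k in seq_along(lo)) {
    idx <- which(usable & bin == k)
    out$n_variants[k] <- length(idx)
    if (length(idx) > 0L) {
      out$mean_r[k] <- mean(r_v[idx], na.rm = TRUE)
      out$mean_concordance[k] <- mean(conc_v[idx], na.rm = TRUE)
    }
  }
  out
}

#' Pass-rate summaries per variant and per genomic window
#'
#' Computes the across-library pass rate of each variant and, within each
#' contiguous window (window k covers positions `[k*w + 1, (k+1)*w]`,
#' default w = 1 Mb), the fraction of variants whose pass rate falls below
#' `pass_rate_min`, plus the mean inter-variant spacing.
#'
#' @param pass libraries x variants logical matrix of pass flags.
#' @param variant_table data.frame with chrom and pos for the variants.
#' @param window_bp window size in bp (default 1e6).
#' @param pass_rate_min per-variant pass-rate threshold (default 0.95).
#' @return list with `by_variant` (chrom, pos, pass_rate) and `by_window`
#'   (chrom, window, start, end, n_variants, frac_low_pass, mean_spacing).
#' @export
window_pass_rates <- function(pass, variant_table, window_bp = 1e6,
                              pass_rate_min = 0.95) {
  stopifnot(is.matrix(pass), ncol(pass) == nrow(variant_table))
  rate <- colMeans(pass)
  bv <- data.frame(chrom = variant_table$chrom, pos = variant_table$pos,
                   pass_rate = rate)
  win <- (variant_table$pos - 1) %/% window_bp
  key <- paste(variant_table$chrom, win)
  by <- lapply(split(seq_len(nrow(bv)), key), function(idx) {
    pos <- sort(variant_table$pos[idx])
    data.frame(chrom = variant_table$chrom[idx[1]],
               window = win[idx[1]],
               start = win[idx[1]] * window_bp + 1,
               end = (win[idx[1]] + 1) * window_bp,
               n_variants = length(idx),
               frac_low_pass = mean(rate[idx] < pass_rate_min),
               mean_spacing = if (length(pos) > 1) mean(diff(pos)) else NA_real_)
  })
  bw <- do.call(rbind, by)
  bw <- bw[order(bw$chrom, bw$window), , drop = FALSE]
  rownames(bw) <- NULL
  list(by_variant = bv, by_window = bw)
}

#' Verify library identity against comparator genotypes
#'
#' For each imputed library, finds the comparator sample with the highest
#' call concordance; a library is flagged when its best match is not its
#' declared identity or the best concordance is below `min_concordance`
#' (sample swaps, contamination/chimerism).
#'
#' @param imputed libraries x variants matrix of imputed 0/1/2 calls,
#'   rownames = declared identities.
#' @param comparator samples x variants matrix of comparator genotypes,
#'   rownames = sample ids.
#' @param min_concordance flagging threshold (default 0.9).
#' @return data.frame: library, best_match, best_concordance,
#'   declared_concordance, flagged.
#' @export
verify_identity <- function(imputed, comparator, min_concordance = 0.9) {
  stopifnot(is.matrix(imputed), is.matrix(comparator),
            ncol(imputed) == ncol(comparator))
  libs <- rownames(imputed) %||% sprintf("lib%d", seq_len(nrow(imputed)))
  samps <- rownames(comparator) %||% sprintf("s%d", seq_len(nrow(comparator)))
  out <- lapply(seq_len(nrow(imputed)), function(i) {
    conc <- vapply(seq_len(nrow(comparator)), function(j)
      genotype_agreement(imputed[i, ], comparator[j, ])$concordance, numeric(1))
    best <- which.max(conc)
    decl <- match(libs[i], samps)
    data.frame(library = libs[i], best_match = samps[best],
               best_concordance = conc[best],
               declared_concordance = if (is.na(decl)) NA_real_ else conc[decl],
               flagged = samps[best] != libs[i] ||
                 conc[best] < min_concordance)
  })
  do.call(rbind, out)
}

#' Principal components of the haplotype panel
#'
#' Centered PCA of the panel haplotypes (rows = haplotypes, columns = 0/1
#' alleles) on a random subset of variants with panel-wide MAF above
#' `maf_min`, capped at `n_snps` (mirroring the usual PCA screen of a
#' sequence panel: 150,000 random biallelic SNPs, MAF > 5%).
#'
#' @param panel a [haplotype_panel()].
#' @param n_snps maximum number of variants used (default 150000).
#' @param maf_min panel-wide MAF threshold (default 0.05).
#' @param seed seed for the variant subsample.
#' @return list with `scores` (haplotypes x up to 10 PCs), `var_frac`
#'   (explained-variance fractions), `pop_label`, `n_snps_used`.
#' @export
panel_pca <- function(panel, n_snps = 150000L, maf_min = 0.05, seed = 1L) {
  stopifnot(inherits(panel, "haplotype_panel"))
  f <- panel_freqs(panel)
  ok <- which(pmin(f, 1 - f) > maf_min)
  if (length(ok) < 2L) stop("fewer than 2 variants pass the MAF screen")
  set.seed(child_seed(seed, "panel_pca"))
  if (length(ok) > n_snps) ok <- sort(sample(ok, n_snps))
  X <- panel$alleles[, ok, drop = FALSE]
  X <- sweep(X, 2L, colMeans(X))
  k <- min(10L, nrow(X) - 1L, ncol(X))
  pc <- prcomp(X, center = FALSE, rank. = k)
  ev <- pc$sdev^2
  list(scores = pc$x, var_frac = (ev / sum(ev))[seq_len(k)],
       pop_label = panel$pop_label, n_snps_used = length(ok))
}

#' Filter a genotype matrix on call rate and minor allele frequency
#'
#' One pass each in the order variants, animals, variants on call rate
#' (strictly greater than `call_rate_min` kept), then a MAF filter
#' (strictly greater than `maf_min` kept) computed on the remaining
#' animals.  Counts removed by each rule are logged.
#'
#' @param g animals x variants matrix of 0/1/2 codes with NA for missing.
#' @param call_rate_min call-rate threshold (default 0.95).
#' @param maf_min MAF threshold (default 0.005).
#' @return list with `genotypes` (filtered matrix) and `removed` (named
#'   counts per rule).
#' @export
filter_genotypes <- function(g, call_rate_min = 0.95, maf_min = 0.005) {
  stopifnot(is.matrix(g))
  removed <- c(variants_call_rate = 0L, animals_call_rate = 0L,
               variants_maf = 0L)
  drop_var <- function(g) {
    cr <- colMeans(!is.na(g))
    keep <- cr > call_rate_min
    removed["variants_call_rate"] <<- removed["variants_call_rate"] +
      sum(!keep)
    g[, keep, drop = FALSE]
  }
  g <- drop_var(g)
  cr_a <- rowMeans(!is.na(g))
  keep_a <- cr_a > call_rate_min
  removed["animals_call_rate"] <- sum(!keep_a)
  g <- g[keep_a, , drop = FALSE]
  g <- drop_var(g)
  p <- colMeans(g, na.rm = TRUE) / 2
  keep_m <- pmin(p, 1 - p) > maf_min
  keep_m[is.na(keep_m)] <- FALSE
  removed["variants_maf"] <- sum(!keep_m)
  list(genotypes = g[, keep_m, drop = FALSE], removed = removed)
}
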