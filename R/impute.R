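# Diploid Li-Stephens imputation of genotype posteriors from low-coverage
# read likelihoods against a phased haplotype panel.

#' Imputation (haplotype-copying HMM) configuration
#'
#' @param rho per-bp switch intensity; the per-interval switch probability
#'   is `s = 1 - exp(-rho * d)` for inter-site distance d bp. Default 1e-6.
#' @param mismatch copying-error (allelic mismatch) probability, default 1e-3.
#' @param max_panel cap on panel haplotypes used per target (the closest by
#'   shared rare alleles are kept); computational cost is quadratic in this.
#' @return object of class `impute_config`.
#' @export
impute_config <- function(rho = 1e-6, mismatch = 1e-3, max_panel = 100L) {
  check_prob(rho, "rho", 0, 1, open_lo = TRUE)
  check_prob(mismatch, "mismatch", 0, 1, open_lo = TRUE, open_hi = TRUE)
  max_panel <- check_count(max_panel, "max_panel", 2L)
  structure(list(rho = rho, mismatch = mismatch, max_panel = max_panel),
            class = "impute_config")
}

# rank panel haplotypes by evidence-weighted sharing of rare alleles with
# the target's reads; returns indices of the kept haplotypes
.select_panel <- function(panel, lik, max_panel) {
  K <- nrow(panel$alleles)
  if (K <= max_panel) return(seq_len(K))
  f <- panel_freqs(panel)
  # observed allele per site from the likelihoods (informative sites only)
  obs <- rep(NA_integer_, nrow(lik))
  obs[lik$l_rr > lik$l_aa & lik$l_rr > lik$l_ra] <- 0L
  obs[lik$l_aa > lik$l_rr & lik$l_aa > lik$l_ra] <- 1L
  keep <- which(!is.na(obs))
  if (length(keep) == 0L) return(seq_len(max_panel))
  fo <- ifelse(obs[keep] == 1L, f[keep], 1 - f[keep])
  w <- pmax(0, -log(pmax(fo, 1e-6)))        # rarer shared allele = higher weight
  agree <- panel$alleles[, keep, drop = FALSE] ==
    matrix(obs[keep], K, length(keep), byrow = TRUE)
  score <- drop(agree %*% w)
  order(score, decreasing = TRUE)[seq_len(max_panel)]
}

#' Impute genotype posteriors for one low-coverage target
#'
#' Runs a diploid Li-Stephens forward-backward HMM: the hidden state is an
#' ordered pair of panel haplotypes, the two copying processes switch
#' independently between sites with probability `1 - exp(-rho * d)`, and the
#' emission combines per-haplotype copying fidelity (`1 - mismatch` /
#' `mismatch`) with the site genotype likelihoods.  State posteriors are
#' collapsed to the three-genotype probability (GP) triple per site.
#'
#' @param likelihoods data.frame with columns pos, l_rr, l_ra, l_aa (one row
#'   per panel variant, position-matched), e.g. from
#'   [genotype_likelihood()] plus the pileup positions.
#' @param panel a [haplotype_panel()].
#' @param cfg an [impute_config()].
#' @param threshold GP_max pass threshold applied to the hard calls
#'   (default 0.9).
#' @return a `site_posterior` data.frame: chrom, pos, gp_rr, gp_ra, gp_aa,
#'   gp_max, dosage, hard_call, pass.
#' @export
impute_sample <- function(likelihoods, panel, cfg = impute_config(),
                          threshold = 0.9) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(cfg, "impute_config"))
  req <- c("pos", "l_rr", "l_ra", "l_aa")
  if (!all(req %in% names(likelihoods)))
    stop("likelihoods must have columns pos, l_rr, l_ra, l_aa")
  vt <- panel$variant_table
  if (nrow(likelihoods) != nrow(vt) || any(likelihoods$pos != vt$pos)) {
    bad <- if (nrow(likelihoods) != nrow(vt)) NA_integer_ else
      vt$pos[which(likelihoods$pos != vt$pos)[1L]]
    stop(sprintf(
      "likelihood sites do not align with panel variants (first offending position: %s)",
      ifelse(is.na(bad), sprintf("site count %d vs %d", nrow(likelihoods), nrow(vt)),
             bad)))
  }
  keep <- .select_panel(panel, likelihoods, cfg$max_panel)
  hap <- panel$alleles[keep, , drop = FALSE]       # K x T
  lik <- t(as.matrix(likelihoods[, c("l_rr", "l_ra", "l_aa")]))
  d <- diff(vt$pos)
  srate <- 1 - exp(-cfg$rho * pmax(d, 0))
  gp <- .ls_fwbw(hap, lik, srate, cfg$mismatch)
  post <- data.frame(chrom = vt$chrom, pos = vt$pos,
                     gp_rr = gp[1, ], gp_ra = gp[2, ], gp_aa = gp[3, ])
  post <- call_genotypes(post, threshold = threshold)
  class(post) <- c("site_posterior", "data.frame")
  post
}

#' Hard-call genotypes from posteriors and flag passing calls
#'
#' The hard call is the argmax genotype (ties broken toward the lowest
#' genotype index, RR < RA < AA); a call passes when GP_max exceeds the
#' threshold (strictly), the rule used to declare imputed genotypes usable.
#' Non-passing calls are flagged but retained.
#'
#' @param posteriors data.frame with gp_rr, gp_ra, gp_aa columns.
#' @param threshold GP_max pass threshold (default 0.9).
#' @return the posteriors with gp_max, dosage, hard_call and pass columns
#'   recomputed.
#' @export
call_genotypes <- function(posteriors, threshold = 0.9) {
  gp <- as.matrix(posteriors[, c("gp_rr", "gp_ra", "gp_aa")])
  posteriors$gp_max <- apply(gp, 1L, max)
  posteriors$dosage <- gp[, 2L] + 2 * gp[, 3L]
  posteriors$hard_call <- max.col(gp, ties.method = "first") - 1L
  posteriors$pass <- posteriors$gp_max > threshold
  posteriors
}

# Exhaustive-path oracle for the diploid Li-Stephens posterior: sums over
# all (K^2)^T state paths.  Only for tiny instances; used by the tests to
# pin the forward-backward implementation down.
.ls_posterior_brute <- function(hap, lik, srate, mu) {
  K <- nrow(hap); T <- ncol(hap)
  states <- as.matrix(expand.grid(j = seq_len(K), k = seq_len(K)))
  S <- nrow(states)
  emis <- function(t, j, k) {
    pj <- ifelse(hap[j, t] == 1L, 1 - mu, mu)
    pk <- ifelse(hap[k, t] == 1L, 1 - mu, mu)
    c((1 - pj) * (1 - pk), pj * (1 - pk) + (1 - pj) * pk, pj * pk) %*%
      lik[, t]
  }
  trans1 <- function(s) {
    m <- matrix(s / K, K, K); diag(m) <- diag(m) + (1 - s); m
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), T)))
  gp <- matrix(0, 3, T)
  for (r in seq_len(nrow(paths))) {
    pth <- paths[r, ]
    w <- 1 / S
    for (t in seq_len(T)) {
      j <- states[pth[t], 1]; k <- states[pth[t], 2]
      if (t > 1) {
        A <- trans1(srate[t - 1])
        jp <- states[pth[t - 1], 1]; kp <- states[pth[t - 1], 2]
        w <- w * A[jp, j] * A[kp, k]
      }
      w <- w * drop(emis(t, j, k))
    }
    if (w == 0) next
    # genotype posterior contribution: split emission back into components
    for (t in seq_len(T)) {
      j <- states[pth[t], 1]; k <- states[pth[t], 2]
      pj <- ifelse(hap[j, t] == 1L, 1 - mu, mu)
      pk <- ifelse(hap[k, t] == 1L, 1 - mu, mu)
      mix <- c((1 - pj) * (1 - pk), pj * (1 - pk) + (1 - pj) * pk, pj * pk) *
        lik[, t]
      gp[, t] <- gp[, t] + w * mix / sum(mix)
    }
  }
  sweep(gp, 2L, colSums(gp), "/")
}
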