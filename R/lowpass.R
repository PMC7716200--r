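# Read-count downsampling and the biallelic genotype-likelihood model.

#' Downsample a read pileup by binomial thinning
#'
#' Each read is retained independently with the given probability, which is
#' equivalent in distribution to random read sampling (seqtk-style) under
#' the count representation used here.  Exactly one of `fraction` and
#' `target_mean_depth` must be given; in the latter case the retention
#' probability is `target_mean_depth / current mean depth` (capped at 1).
#'
#' @param pileup data.table/data.frame with ref_count and alt_count columns.
#' @param fraction retention probability in `[0, 1]`.
#' @param target_mean_depth desired mean depth after thinning.
#' @param seed integer seed (thinning is deterministic given it).
#' @return a pileup of the same shape; counts never increase.
#' @export
downsample_reads <- function(pileup, fraction = NULL, target_mean_depth = NULL,
                             seed = 1L) {
  stopifnot(all(c("ref_count", "alt_count") %in% names(pileup)))
  if (any(pileup$ref_count < 0) || any(pileup$alt_count < 0))
    stop("read counts must be non-negative")
  if (is.null(fraction) == is.null(target_mean_depth))
    stop("give exactly one of 'fraction' and 'target_mean_depth'")
  if (is.null(fraction)) {
    cur <- mean(pileup$ref_count + pileup$alt_count)
    if (cur == 0) return(pileup)
    fraction <- min(1, target_mean_depth / cur)
  }
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction > 1)
    stop("'fraction' must be in [0, 1]")
  out <- data.table::as.data.table(pileup)
  if (fraction == 1) return(out)
  set.seed(child_seed(seed, "downsample"))
  out[, `:=`(ref_count = rbinom(.N, ref_count, fraction),
             alt_count = rbinom(.N, alt_count, fraction))]
  out[]
}

#' Genotype likelihoods from biallelic read counts
#'
#' Standard independent-read model: with per-read error `error`, a
#' homozygous-reference site emits a ref read with probability 1 - error,
#' a heterozygous site with probability 1/2, a homozygous-alternate site
#' with probability `error`.  Computed in log space with a floor of -745
#' natural-log units and returned normalized so the largest likelihood is 1
#' (all three equal 1 at zero depth).
#'
#' @param ref_count,alt_count non-negative integer read counts (vectorized).
#' @param error per-read error probability in (0, 0.5).
#' @return data.frame with columns l_rr, l_ra, l_aa, depth.
#' @export
genotype_likelihood <- function(ref_count, alt_count, error = 0.01) {
  if (!is.numeric(error) || length(error) != 1L || error <= 0 || error >= 0.5)
    stop("'error' must be in (0, 0.5)")
  if (any(ref_count < 0) || any(alt_count < 0))
    stop("read counts must be non-negative")
  n <- max(length(ref_count), length(alt_count))
  r <- rep_len(as.numeric(ref_count), n)
  a <- rep_len(as.numeric(alt_count), n)
  ll <- cbind(l_rr = r * log1p(-error) + a * log(error),
              l_ra = (r + a) * log(0.5),
              l_aa = r * log(error) + a * log1p(-error))
  ll <- ll - apply(ll, 1L, max)      # normalize: max likelihood = 1
  ll[ll < -745] <- -745              # exp() underflow floor
  out <- as.data.frame(exp(ll))
  out$depth <- as.integer(r + a)
  out
}

#' Phred-scaled genotype likelihoods (PL convention)
#'
#' @param gl data.frame from [genotype_likelihood()].
#' @return integer matrix of PL values (RR, RA, AA order), min 0 per site.
#' @export
gl_to_phred <- function(gl) {
  m <- -10 * log10(as.matrix(gl[, c("l_rr", "l_ra", "l_aa")]))
  m <- round(m - apply(m, 1L, min))
  storage.mode(m) <- "integer"
  colnames(m) <- c("PL_RR", "PL_RA", "PL_AA")
  m
}
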