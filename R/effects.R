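# Backsolving marker effects from genomic breeding values, molecular
# breeding values for held-out animals, permutation-based variant-subset
# selection, and the leave-out validation grid.

#' Backsolve per-variant effects from genomic breeding values
#'
#' The textbook solution `alpha = M' [M M']^-1 u` is singular for centered
#' M; the default route is the numerically equivalent well-conditioned form
#' `alpha = Z' (G*)^-1 u / k` with Z the 2p-centered genotype matrix, k the
#' VanRaden divisor `2 sum(p (1 - p))`, and G* the (optionally stabilized)
#' genomic relationship matrix of the GBLUP fit that produced u.  A literal
#' pseudoinverse mode is available for oracle checks.
#'
#' @param M_train animals x variants 0/1/2 matrix used in the GBLUP fit.
#' @param u_hat breeding values of the training animals (same order).
#' @param freqs per-variant allele frequencies of the fit; computed from
#'   M_train when absent.
#' @param stabilize use `G* = 0.99 G + 0.01 I` (must match the fit;
#'   default TRUE).
#' @param method "gstar" (default) or "pseudoinverse" (literal formula on
#'   the centered matrix).
#' @param center center by 2p (default TRUE; FALSE treats M_train as
#'   already centered/designed, for oracle instances).
#' @param divisor override the VanRaden divisor k (default
#'   `2 sum(p (1 - p))`); must match the divisor of the G used in the fit.
#' @return object of class `marker_effects`: data.frame (variant, alpha,
#'   freq) with attributes `divisor` and `freqs`.
#' @export
backsolve_effects <- function(M_train, u_hat, freqs = NULL, stabilize = TRUE,
                              method = c("gstar", "pseudoinverse"),
                              center = TRUE, divisor = NULL) {
  method <- match.arg(method)
  M_train <- as.matrix(M_train)
  u_hat <- as.numeric(u_hat)
  stopifnot(nrow(M_train) == length(u_hat))
  p <- freqs %||% (colMeans(M_train) / 2)
  if (length(p) != ncol(M_train))
    stop("freqs length does not match the training variants of the fit")
  Z <- if (center) sweep(M_train, 2L, 2 * p) else M_train
  k <- divisor %||% (2 * sum(p * (1 - p)))
  if (k <= 0) stop("all variants monomorphic: zero VanRaden divisor")
  alpha <- if (method == "pseudoinverse") {
    drop(crossprod(Z, pinv(tcrossprod(Z)) %*% u_hat))
  } else {
    G <- tcrossprod(Z) / k
    if (stabilize) G <- stabilize_G(G)
    drop(crossprod(Z, solve(G, u_hat))) / k
  }
  ids <- colnames(M_train) %||% sprintf("v%d", seq_len(ncol(M_train)))
  structure(data.frame(variant = ids, alpha = alpha, freq = p,
                       row.names = NULL),
            class = c("marker_effects", "data.frame"),
            divisor = k, freqs = p)
}

#' Molecular breeding values from marker effects
#'
#' `MBV = Zs alpha` with Zs the target genotypes centered by the training
#' frequencies.  Effect variants absent from the target matrix are dropped
#' with a logged count; fewer than 50% present is an error.
#'
#' @param Ms animals x variants 0/1/2 matrix (colnames = variant ids).
#' @param effects a `marker_effects` object.
#' @param source tag recorded with the result (e.g. "array-imputed",
#'   "lowpass-imputed").
#' @return data.frame (animal, mbv, source) with attribute
#'   `n_variants_dropped`.
#' @export
predict_mbv <- function(Ms, effects, source = "array-imputed") {
  stopifnot(inherits(effects, "marker_effects"))
  Ms <- as.matrix(Ms)
  cols <- colnames(Ms) %||% sprintf("v%d", seq_len(ncol(Ms)))
  idx <- match(effects$variant, cols)
  present <- !is.na(idx)
  if (mean(present) < 0.5)
    stop(sprintf("only %.0f%% of effect variants present in the genotypes",
                 100 * mean(present)))
  n_drop <- sum(!present)
  if (n_drop > 0)
    message(sprintf("predict_mbv: %d effect variants absent, dropped", n_drop))
  Zs <- sweep(Ms[, idx[present], drop = FALSE], 2L,
              2 * effects$freq[present])
  mbv <- drop(Zs %*% effects$alpha[present])
  out <- data.frame(animal = rownames(Ms) %||% seq_len(nrow(Ms)),
                    mbv = mbv, source = source, row.names = NULL)
  attr(out, "n_variants_dropped") <- n_drop
  out
}

#' Select a trait-specific variant subset by permutation
#'
#' Fits GBLUP on the observed phenotypes, backsolves observed effects, then
#' builds a per-variant null by refitting on permuted phenotype labels and
#' backsolving each time.  Variants are ranked by the exceedance of their
#' observed |alpha| over their own null `quantile` (default 99th
#' percentile); ties break by observed |alpha| then variant order.
#'
#' @param M animals x variants 0/1/2 matrix.
#' @param y phenotypes (same animals, same order).
#' @param X fixed-effect incidence (default intercept only).
#' @param sigma_g2,sigma_e2 variance components; estimated by [reml()] when
#'   missing.
#' @param n_perm number of permutations (>= 100 at desk scale; 5000 at full
#'   scale).
#' @param n_keep subset size to select.
#' @param quantile null quantile for the exceedance (default 0.99).
#' @param stabilize stabilized G in the fits (default TRUE).
#' @param seed seed for the permutations.
#' @return list with `selected` (variant ids), `table` (per-variant
#'   observed |alpha|, null quantile, exceedance, rank).
#' @export
permutation_select <- function(M, y, X = NULL, sigma_g2 = NULL,
                               sigma_e2 = NULL, n_perm = 200L, n_keep,
                               quantile = 0.99, stabilize = TRUE, seed = 1L) {
  M <- as.matrix(M)
  n <- nrow(M)
  if (is.null(colnames(M))) colnames(M) <- sprintf("v%d", seq_len(ncol(M)))
  if (n_keep > ncol(M)) stop("n_keep exceeds the number of variants")
  if (n_perm < 2L) stop("n_perm must be at least 2")
  X <- X %||% matrix(1, n, 1)
  Z <- diag(n)
  p <- colMeans(M) / 2
  G <- build_G(M, freqs = p)
  Gs <- if (stabilize) stabilize_G(G) else G
  if (is.null(sigma_g2) || is.null(sigma_e2)) {
    vc <- reml(y, X, Z, Gs)
    sigma_g2 <- vc$sigma_g2; sigma_e2 <- vc$sigma_e2
  }
  solve_alpha <- function(yy) {
    fit <- fit_blup(yy, X, Z, Gs, sigma_g2, sigma_e2)
    backsolve_effects(M, fit$u, freqs = p, stabilize = stabilize)$alpha
  }
  a_obs <- abs(solve_alpha(y))
  set.seed(child_seed(seed, "permutation_select"))
  null_abs <- matrix(0, n_perm, ncol(M))
  for (b in seq_len(n_perm))
    null_abs[b, ] <- abs(solve_alpha(y[sample.int(n)]))
  q99 <- apply(null_abs, 2L, stats::quantile, probs = quantile, names = FALSE)
  exceed <- a_obs - q99
  ord <- order(-exceed, -a_obs, seq_len(ncol(M)))
  tab <- data.frame(variant = colnames(M), obs_abs_alpha = a_obs,
                    null_q = q99, exceedance = exceed,
                    rank = match(seq_len(ncol(M)), ord), row.names = NULL)
  list(selected = colnames(M)[ord[seq_len(n_keep)]], table = tab)
}

#' Leave-out validation of molecular breeding values
#'
#' Structures the holdout experiment: for each variant set, GBLUP is fit
#' without the holdout animals' phenotypes, effects are backsolved, and
#' MBV are predicted for the holdouts from each genotype source; the MBV
#' are then correlated with the holdouts' full-data pedigree EBV and
#' full-data GEBV (all animals, all variants), with
#' `SE = sqrt((1 - r^2) / (n - 2))`.
#'
#' @param M animals x variants 0/1/2 matrix for all animals (rownames ids).
#' @param y named phenotype vector for all animals (same order as M rows).
#' @param X fixed-effect incidence for all animals.
#' @param pedigree pedigree data.frame covering all animals.
#' @param holdout_ids animal ids excluded from effect training.
#' @param variant_sets named list of column-index/name vectors into M.
#' @param genotype_sources named list of holdout genotype matrices
#'   (holdouts x variants, colnames = variant ids); e.g. truth vs imputed
#'   dosages.
#' @param sigma_g2,sigma_e2 variance components reused across fits;
#'   estimated once on the full data with G when missing.
#' @return data.frame grid: variant_set, source, r_pedigree_ebv, se_pedigree,
#'   r_gebv, se_gebv, n_holdout.
#' @export
leave_out_validate <- function(M, y, X, pedigree, holdout_ids, variant_sets,
                               genotype_sources, sigma_g2 = NULL,
                               sigma_e2 = NULL) {
  M <- as.matrix(M)
  ids <- rownames(M)
  stopifnot(!is.null(ids), all(holdout_ids %in% ids))
  n <- nrow(M)
  X <- as.matrix(X)
  Z <- diag(n)
  hold <- ids %in% holdout_ids
  # full-data reference predictions
  A <- build_A(pedigree)
  A <- A[ids, ids]
  Gall <- stabilize_G(build_G(M))
  if (is.null(sigma_g2) || is.null(sigma_e2)) {
    vc <- reml(y, X, Z, Gall)
    sigma_g2 <- vc$sigma_g2; sigma_e2 <- vc$sigma_e2
  }
  ebv <- fit_blup(y, X, Z, A, sigma_g2, sigma_e2)$u[hold]
  gebv <- fit_blup(y, X, Z, Gall, sigma_g2, sigma_e2)$u[hold]
  train <- which(!hold)
  se_r <- function(r, n) sqrt((1 - r^2) / (n - 2))
  rows <- list()
  for (vs in names(variant_sets)) {
    cols <- variant_sets[[vs]]
    Mtr <- M[train, cols, drop = FALSE]
    ptr <- colMeans(Mtr) / 2
    Gtr <- stabilize_G(build_G(Mtr, freqs = ptr))
    fit <- fit_blup(y[train], X[train, , drop = FALSE],
                    diag(length(train)), Gtr, sigma_g2, sigma_e2)
    eff <- backsolve_effects(Mtr, fit$u, freqs = ptr)
    for (src in names(genotype_sources)) {
      Ms <- genotype_sources[[src]]
      mbv <- predict_mbv(Ms[holdout_ids, , drop = FALSE], eff, source = src)
      mv <- mbv$mbv[match(names(ebv), mbv$animal)]
      r1 <- cor(mv, ebv); r2 <- cor(mv, gebv)
      rows[[length(rows) + 1L]] <- data.frame(
        variant_set = vs, source = src,
        r_pedigree_ebv = r1, se_pedigree = se_r(r1, length(ebv)),
        r_gebv = r2, se_gebv = se_r(r2, length(ebv)),
        n_holdout = length(ebv))
    }
  }
  do.call(rbind, rows)
}
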