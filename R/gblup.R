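# Pedigree and genomic BLUP: relationship matrices, Henderson's mixed-model
# equations, EM/AI restricted maximum likelihood, and the postweaning-gain
# phenotype projection.

#' Numerator relationship matrix from a pedigree (tabular method)
#'
#' Recursive tabular construction with inbreeding; unknown parents ("0" or
#' NA) are treated as unrelated non-inbred founders.  The pedigree is
#' topologically sorted internally; a cycle is an error naming the animals
#' involved.
#'
#' @param pedigree data.frame with columns animal, sire, dam (ids as
#'   character; "0"/NA = unknown).
#' @return symmetric matrix A with dimnames = animal ids, pedigree order.
#' @export
build_A <- function(pedigree) {
  stopifnot(all(c("animal", "sire", "dam") %in% names(pedigree)))
  ids <- as.character(pedigree$animal)
  if (anyDuplicated(ids)) stop("duplicate animal ids in pedigree")
  par <- function(x) {
    x <- as.character(x); x[is.na(x) | x == "0"] <- NA; match(x, ids)
  }
  s <- par(pedigree$sire); d <- par(pedigree$dam)
  n <- length(ids)
  # topological sort (Kahn); leftover nodes form a cycle
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) for (p in c(s[i], d[i])) if (!is.na(p)) {
    indeg[i] <- indeg[i] + 1L
    kids[[p]] <- c(kids[[p]], i)
  }
  order_ <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    order_ <- c(order_, i)
    for (k in kids[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(order_) < n)
    stop(sprintf("pedigree contains a cycle involving: %s",
                 paste(ids[setdiff(seq_len(n), order_)], collapse = ", ")))
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in order_) {
    si <- s[i]; di <- d[i]
    A[i, i] <- 1 + 0.5 * (if (!is.na(si) && !is.na(di)) A[si, di] else 0)
    for (j in order_) {
      if (j == i) break
      aij <- 0.5 * ((if (!is.na(si)) A[j, si] else 0) +
                    (if (!is.na(di)) A[j, di] else 0))
      A[i, j] <- A[j, i] <- aij
    }
  }
  A
}

# independent oracle: memoized coancestry recursion, a(i,j) = 2 f(i,j)
.kinship_A <- function(pedigree) {
  ids <- as.character(pedigree$animal)
  par <- function(x) {
    x <- as.character(x); x[is.na(x) | x == "0"] <- NA; match(x, ids)
  }
  s <- par(pedigree$sire); d <- par(pedigree$dam)
  n <- length(ids)
  memo <- new.env(hash = TRUE)
  f <- function(i, j) {
    if (i > j) { t <- i; i <- j; j <- t }
    key <- paste(i, j)
    if (!is.null(v <- memo[[key]])) return(v)
    v <- if (i == j) {
      0.5 * (1 + (if (!is.na(s[i]) && !is.na(d[i])) f(s[i], d[i]) else 0))
    } else {
      # recurse on the later-born animal (topological order assumed)
      a <- j
      0.5 * ((if (!is.na(s[a])) f(i, s[a]) else 0) +
             (if (!is.na(d[a])) f(i, d[a]) else 0))
    }
    memo[[key]] <- v
    v
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in i:n) A[i, j] <- A[j, i] <- 2 * f(i, j)
  A
}

#' Genomic relationship matrix (VanRaden)
#'
#' `G = Z Z' / (2 * sum(p * (1 - p)))` with Z the genotype matrix centered
#' by twice the allele frequency.  Missing genotypes are imputed to `2p`
#' (count reported via a message); animals missing more than 5% of sites
#' are rejected.  With `center = FALSE` the raw 0/1/2 codes are
#' cross-multiplied instead (the literal uncentered form; not a relationship
#' matrix, provided for comparison only).
#'
#' @param M animals x variants matrix of 0/1/2 codes (NA = missing).
#' @param freqs optional per-variant B-allele frequencies; computed from M
#'   when absent.
#' @param center center columns by 2p before the cross-product (default
#'   TRUE).
#' @return symmetric matrix G with a `freqs` attribute (the frequencies
#'   used) and a `divisor` attribute.
#' @export
build_G <- function(M, freqs = NULL, center = TRUE) {
  stopifnot(is.matrix(M))
  miss <- is.na(M)
  if (any(rowMeans(miss) > 0.05))
    stop("animals missing more than 5% of genotypes: ",
         paste(rownames(M)[rowMeans(miss) > 0.05], collapse = ", "))
  p <- freqs %||% (colMeans(M, na.rm = TRUE) / 2)
  if (length(p) != ncol(M)) stop("freqs length must equal ncol(M)")
  if (any(miss)) {
    message(sprintf("build_G: imputed %d missing genotypes to 2p", sum(miss)))
    M[miss] <- rep(2 * p, each = nrow(M))[miss]
  }
  k <- 2 * sum(p * (1 - p))
  if (k <= 0) stop("all variants monomorphic: zero divisor 2*sum(p*(1-p))")
  Z <- if (center) sweep(M, 2L, 2 * p) else M
  G <- tcrossprod(Z) / k
  attr(G, "freqs") <- p
  attr(G, "divisor") <- k
  G
}

#' Stabilize a genomic relationship matrix
#'
#' `G* = 0.99 G + 0.01 I`, the standard bend that keeps G invertible when
#' animals are duplicated or variants are few.
#'
#' @param G square symmetric matrix.
#' @return G* of the same shape (attributes of G preserved).
#' @export
stabilize_G <- function(G) {
  stopifnot(is.matrix(G), nrow(G) == ncol(G))
  Gs <- 0.99 * G + 0.01 * diag(nrow(G))
  attributes(Gs)[c("freqs", "divisor")] <- attributes(G)[c("freqs", "divisor")]
  dimnames(Gs) <- dimnames(G)
  Gs
}

#' BLUP solutions of Henderson's mixed-model equations
#'
#' Solves for fixed effects and breeding values given variance components:
#' `[X'X, X'Z; Z'X, Z'Z + lambda K^-1] [b; u] = [X'y; Z'y]` with
#' `lambda = sigma_e2 / sigma_g2`.  Animals present in K but without
#' records are predicted through their relationships.
#'
#' @param y numeric phenotype vector (n records).
#' @param X n x p fixed-effect incidence (full column rank).
#' @param Z n x q incidence mapping records to the animals of K.
#' @param K q x q relationship matrix (A, G or G*); must be invertible.
#' @param sigma_g2,sigma_e2 additive and residual variances.
#' @return list with `beta` (fixed-effect solutions), `u` (named breeding
#'   values for all animals in K) and `Cuu` (the u-block of the inverse
#'   coefficient matrix times sigma_e2, for reliabilities).
#' @export
fit_blup <- function(y, X, Z, K, sigma_g2, sigma_e2) {
  y <- as.numeric(y); X <- as.matrix(X); Z <- as.matrix(Z); K <- as.matrix(K)
  n <- length(y); p <- ncol(X); q <- ncol(Z)
  stopifnot(nrow(X) == n, nrow(Z) == n, nrow(K) == q, ncol(K) == q,
            sigma_g2 > 0, sigma_e2 > 0)
  if (qr(X)$rank < p) stop("X is not full column rank; drop aliased levels")
  Kinv <- tryCatch(solve(K), error = function(e)
    stop("K is not invertible; consider stabilize_G()", call. = FALSE))
  lambda <- sigma_e2 / sigma_g2
  Cmat <- rbind(cbind(crossprod(X), crossprod(X, Z)),
                cbind(crossprod(Z, X), crossprod(Z) + lambda * Kinv))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  Cinv <- solve(Cmat)
  sol <- drop(Cinv %*% rhs)
  beta <- sol[seq_len(p)]
  u <- sol[p + seq_len(q)]
  names(u) <- colnames(K) %||% colnames(Z)
  names(beta) <- colnames(X)
  list(beta = beta, u = u,
       Cuu = Cinv[p + seq_len(q), p + seq_len(q), drop = FALSE] * sigma_e2)
}

# restricted log-likelihood of (sigma_g2, sigma_e2), dense
.reml_loglik <- function(y, X, H, sg, se) {
  n <- length(y)
  V <- sg * H
  diag(V) <- diag(V) + se
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  W <- crossprod(X, Vi_X)
  chW <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(chW)) return(-Inf)
  logdetW <- 2 * sum(log(diag(chW)))
  b <- backsolve(chW, forwardsolve(t(chW), crossprod(X, Vi_y)))
  yPy <- sum(y * Vi_y) - sum(crossprod(X, Vi_y) * b)
  -0.5 * (logdetV + logdetW + yPy)
}

#' REML variance components for the animal model
#'
#' EM-REML through the mixed-model equations, with optional
#' average-information (AI) acceleration: an AI/Newton step is attempted
#' once warmed up and is accepted only when it keeps both variances
#' positive and does not decrease the restricted log-likelihood; otherwise
#' the guaranteed-monotone EM update is taken.  Convergence when the
#' relative change of both components is below `tol` (default 1e-8) or
#' after `max_iter` (default 500) iterations; variances floored at 1e-10.
#'
#' @param y,X,Z,K as in [fit_blup()].
#' @param init optional c(sigma_g2, sigma_e2) starting values (default:
#'   half the phenotypic variance each).
#' @param max_iter,tol iteration cap and relative-change tolerance.
#' @param ai use AI acceleration (default TRUE).
#' @return object of class `variance_estimates`: sigma_g2, sigma_e2, h2,
#'   se_h2 (information-based approximation; NA if the AI matrix is not
#'   usable), n_records, converged, iterations, loglik (trace).
#' @export
reml <- function(y, X, Z, K, init = NULL, max_iter = 500L, tol = 1e-8,
                 ai = TRUE) {
  y <- as.numeric(y); X <- as.matrix(X); Z <- as.matrix(Z); K <- as.matrix(K)
  n <- length(y); p <- ncol(X); q <- ncol(Z)
  if (n <= p + 1L) stop("need more records than fixed effects + 1")
  if (qr(X)$rank < p) stop("X is not full column rank; drop aliased levels")
  Kinv <- tryCatch(solve(K), error = function(e)
    stop("K is not invertible; consider stabilize_G()", call. = FALSE))
  H <- Z %*% K %*% t(Z)
  vp <- var(y)
  sg <- init[1] %||% (vp / 2)
  se <- if (length(init) >= 2) init[2] else vp / 2
  XtX <- crossprod(X); XtZ <- crossprod(X, Z); ZtZ <- crossprod(Z)
  Xty <- crossprod(X, y); Zty <- crossprod(Z, y)
  ll <- .reml_loglik(y, X, H, sg, se)
  trace <- ll
  converged <- FALSE
  it <- 0L
  ai_info <- NULL
  floor_v <- 1e-10
  em_step <- function(sg, se) {
    lambda <- se / sg
    Cmat <- rbind(cbind(XtX, XtZ), cbind(t(XtZ), ZtZ + lambda * Kinv))
    Cinv <- solve(Cmat)
    sol <- drop(Cinv %*% c(Xty, Zty))
    beta <- sol[seq_len(p)]; u <- sol[p + seq_len(q)]
    Cuu <- Cinv[p + seq_len(q), p + seq_len(q), drop = FALSE]
    sg_new <- (drop(crossprod(u, Kinv %*% u)) +
                 se * sum(Kinv * Cuu)) / q
    se_new <- drop(sum(y^2) - sum(beta * Xty) - sum(u * Zty)) / (n - p)
    c(max(sg_new, floor_v), max(se_new, floor_v))
  }
  ai_step <- function(sg, se) {
    V <- sg * H; diag(V) <- diag(V) + se
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    P <- Vi - ViX %*% solve(crossprod(X, ViX), t(ViX))
    Py <- P %*% y
    HPy <- H %*% Py
    PHPy <- P %*% HPy
    PPy <- P %*% Py
    AI <- matrix(c(sum(HPy * PHPy), sum(HPy * PPy),
                   sum(HPy * PPy), sum(Py * PPy)), 2, 2) / 2
    grad <- c(-0.5 * (sum(P * H) - sum(Py * HPy)),
              -0.5 * (sum(diag(P)) - sum(Py * Py)))
    step <- tryCatch(solve(AI, grad), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    list(theta = c(sg, se) + step, AI = AI)
  }
  for (it in seq_len(max_iter)) {
    theta_old <- c(sg, se)
    accepted <- FALSE
    if (ai && it > 2L) {
      st <- ai_step(sg, se)
      if (!is.null(st) && all(st$theta > floor_v)) {
        ll_new <- .reml_loglik(y, X, H, st$theta[1], st$theta[2])
        if (is.finite(ll_new) && ll_new >= ll - 1e-12) {
          sg <- st$theta[1]; se <- st$theta[2]
          ll <- ll_new
          ai_info <- st$AI
          accepted <- TRUE
        }
      }
    }
    if (!accepted) {
      th <- em_step(sg, se)
      sg <- th[1]; se <- th[2]
      ll <- .reml_loglik(y, X, H, sg, se)
    }
    trace <- c(trace, ll)
    if (max(abs(c(sg, se) - theta_old) / pmax(theta_old, floor_v)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf("REML did not converge in %d iterations", max_iter))
  h2 <- sg / (sg + se)
  se_h2 <- NA_real_
  if (is.null(ai_info)) {
    st <- ai_step(sg, se)
    if (!is.null(st)) ai_info <- st$AI
  }
  if (!is.null(ai_info)) {
    Sig <- tryCatch(solve(ai_info), error = function(e) NULL)
    if (!is.null(Sig)) {
      dgr <- c(se, -sg) / (sg + se)^2       # delta method for h2
      v <- drop(t(dgr) %*% Sig %*% dgr)
      if (is.finite(v) && v >= 0) se_h2 <- sqrt(v)
    }
  }
  structure(list(sigma_g2 = sg, sigma_e2 = se, h2 = h2, se_h2 = se_h2,
                 n_records = n, converged = converged, iterations = it,
                 loglik = trace), class = "variance_estimates")
}

#' @export
print.variance_estimates <- function(x, ...) {
  cat(sprintf(
    "REML variance components (n = %d, %d iterations, %s)\n  sigma_g2 = %.6g  sigma_e2 = %.6g  h2 = %.4f (SE %.4f)\n",
    x$n_records, x$iterations,
    if (x$converged) "converged" else "NOT converged",
    x$sigma_g2, x$sigma_e2, x$h2, x$se_h2))
  invisible(x)
}

#' Postweaning-gain projection from serial weights
#'
#' Fits a per-animal least-squares quadratic of weight on age and projects
#' the average daily gain over the 160 days following weaning:
#' `ADG = (w(wean_age + 160) - w(wean_age)) / 160`.
#'
#' @param ages numeric vector of ages (days), at least 3 distinct values.
#' @param weights numeric vector of weights (kg), same length.
#' @param wean_age weaning age in days (default 205).
#' @return projected average daily gain (kg/day).
#' @export
project_pwg <- function(ages, weights, wean_age = 205) {
  stopifnot(length(ages) == length(weights))
  ok <- is.finite(ages) & is.finite(weights)
  ages <- ages[ok]; weights <- weights[ok]
  if (length(ages) < 3L) stop("need at least 3 weight records")
  if (length(unique(ages)) < 3L)
    stop("degenerate design: need 3 distinct ages for a quadratic")
  fit <- lm(weights ~ ages + I(ages^2))
  w <- function(t) sum(coef(fit) * c(1, t, t^2))
  (w(wean_age + 160) - w(wean_age)) / 160
}
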