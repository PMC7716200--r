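#' @useDynLib lpeval, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
#' @importFrom stats cor cov dist lm na.omit prcomp qnorm quantile rbeta rbinom
#'   rnorm rpois runif sd setNames var coef
#' @importFrom utils head modifyList tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic child seed from a master seed and a stage name
#'
#' All randomness in the package flows from one master seed; each stage
#' derives its own stream so that adding a stage never perturbs another
#' stage's draws.  The derivation is a small multiplicative hash kept below
#' 2^31 so the result is always a valid R integer seed.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return integer seed in [0, 2^31).
#' @export
child_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- as.double(master %% 2147483647)
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: '%s' %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field, lo = 0, hi = 1, open_lo = FALSE, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_lo) x > lo else x >= lo) && (if (open_hi) x < hi else x <= hi)
  if (!ok) stop_config(field, sprintf("must be in %s%g, %g%s",
                                      if (open_lo) "(" else "[", lo, hi,
                                      if (open_hi) ")" else "]"))
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == floor(x)
  if (!ok) stop_config(field, sprintf("must be an integer >= %d", min))
  invisible(as.integer(x))
}

# svd-based Moore-Penrose pseudoinverse (literal backsolve formula mode)
pinv <- function(A, tol = sqrt(.Machine$double.eps)) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
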