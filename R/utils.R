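#' @useDynLib rbmscore, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats acf cor dcauchy dnorm mad median plogis pnorm qchisq
#'   qlogis qnorm quantile rbeta rbinom rexp rgamma rlnorm rnorm runif sd var
#' @importFrom utils head read.csv write.csv packageVersion
#' @importFrom graphics abline axis barplot image par points segments
NULL

logit <- function(p) qlogis(p)
inv_logit <- function(x) plogis(x)

log1pexp <- function(x) {
  # numerically stable log(1 + exp(x))
  out <- x
  idx <- x < 18
  out[idx] <- log1p(exp(x[idx]))
  out
}

#' Derive a reproducible RNG substream seed
#'
#' Each (site, indicator) pair receives an independent substream derived
#' from the master seed, so adding or dropping a site never perturbs the
#' posterior draws of other sites.
#'
#' @param seed master integer seed.
#' @param i,j nonnegative stream indices (e.g. site index, indicator index).
#' @return An integer seed below 2^31.
#' @keywords internal
substream_seed <- function(seed, i, j = 0L) {
  as.integer((abs(as.numeric(seed)) + as.numeric(i) * 100003 +
                as.numeric(j) * 59359) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
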