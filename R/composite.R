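# Stage 2 (robust standardization) and Stage 3 (composite scoring).
#
# Anchors (site-level posterior means per indicator) define a robust
# center (median across sites) and scale (1.4826 * MAD, consistent with
# the SD under normality); every posterior draw is standardized with the
# same affine map, so the composite lives in robust risk-z units.

#' Composite configuration
#'
#' @param mode `"linear"` (convex combination, the default), `"softmax"`
#'   ("OR-leaning": emphasizes any single very high-risk indicator), or
#'   `"geomean"` ("AND-leaning": down-weights sites not consistently
#'   risky).
#' @param lambda softmax sharpness (> 0); larger values move the softmax
#'   toward `max_k w_k z_k`.
#' @param shift geometric-mean offset `c`; must exceed `-min(z)` over
#'   every draw entering the composite (checked at call time).
#' @param tau decision threshold on the composite scale for exceedance
#'   probabilities.
#' @param top_k rank cutoff for `Pr(Top-K)`.
#' @return A list of class `composite_config`.
#' @export
composite_config <- function(mode = c("linear", "softmax", "geomean"),
                             lambda = 2, shift = 10, tau = 1.5, top_k = 5L) {
  mode <- match.arg(mode)
  if (mode == "softmax" && lambda <= 0) stopf("lambda must be > 0")
  structure(list(mode = mode, lambda = lambda, shift = shift, tau = tau,
                 top_k = as.integer(top_k)), class = "composite_config")
}

#' Fit the robust standardization (Stage 2)
#'
#' Per indicator: center = median of the site anchors, scale = 1.4826 *
#' MAD.  When the MAD is 0 (anchors tie, e.g. a binary indicator with no
#' drifted site in the majority) the sample SD is used; when the SD is
#' also 0 the scale falls back to 1 with a warning.
#'
#' @param anchor_means sites-by-indicators matrix of posterior-mean
#'   anchors (>= 2 sites).
#' @return A list with `center` and `scale` vectors named by indicator.
#' @export
fit_standardization <- function(anchor_means) {
  anchor_means <- as.matrix(anchor_means)
  if (nrow(anchor_means) < 2L) {
    stopf("standardization is undefined for a single site")
  }
  center <- apply(anchor_means, 2, median)
  scale <- apply(anchor_means, 2, mad)  # mad() already includes 1.4826
  for (k in seq_along(scale)) {
    if (scale[k] == 0) {
      s <- sd(anchor_means[, k])
      if (is.na(s) || s == 0) {
        warnf("indicator '%s': anchors are constant; scale set to 1",
              colnames(anchor_means)[k] %||% as.character(k))
        s <- 1
      }
      scale[k] <- s
    }
  }
  list(center = center, scale = scale)
}

#' Standardize posterior draws (Stage 2)
#'
#' Applies the per-indicator affine map `(draw - center_k) / scale_k` to
#' every draw.
#'
#' @param draws named list of sites-by-draws matrices (one per indicator)
#'   or a single matrix together with `indicator`.
#' @param params a fitted standardization ([fit_standardization()]).
#' @param indicator indicator name when `draws` is a single matrix.
#' @return Standardized draws in the same shape as `draws`.
#' @export
standardize_draws <- function(draws, params, indicator = NULL) {
  one <- function(mat, k) {
    if (!k %in% names(params$center)) {
      stopf("indicator '%s' missing from standardization parameters", k)
    }
    (mat - params$center[[k]]) / params$scale[[k]]
  }
  if (is.list(draws) && !is.data.frame(draws)) {
    out <- lapply(names(draws), function(k) one(draws[[k]], k))
    names(out) <- names(draws)
    out
  } else {
    if (is.null(indicator)) stopf("indicator name required for a single matrix")
    one(draws, indicator)
  }
}

#' Compose standardized indicator scores into a site score
#'
#' Given a vector of standardized indicator scores `z` (one draw for one
#' site) or a sites-by-indicators matrix (one draw per row set), returns
#' the composite:
#' linear `sum_k w_k z_k`; softmax
#' `(1/lambda) log sum_k exp(lambda w_k z_k)`; geometric
#' `prod_k (c + z_k)^{w_k} - c`.
#'
#' @param z numeric vector (length K) or matrix (n x K) of standardized
#'   scores.
#' @param w weight vector on the simplex (auto-normalized nonnegative
#'   weights are accepted).
#' @param cfg a [composite_config()].
#' @return Composite score(s): scalar or length-n vector.
#' @export
compose <- function(z, w, cfg = composite_config()) {
  z <- if (is.matrix(z)) z else matrix(z, nrow = 1)
  if (length(w) != ncol(z)) stopf("weight length must equal indicator count")
  if (any(w < 0)) stopf("weights must be nonnegative")
  w <- w / sum(w)
  out <- switch(cfg$mode,
    linear = drop(z %*% w),
    softmax = {
      a <- sweep(z, 2, w, `*`) * cfg$lambda
      amax <- apply(a, 1, max)
      (amax + log(rowSums(exp(a - amax)))) / cfg$lambda
    },
    geomean = {
      if (any(cfg$shift + z <= 0)) {
        bad <- which(cfg$shift + z <= 0, arr.ind = TRUE)[1, ]
        stopf("geometric composite undefined: c + z <= 0 at row %d, indicator %d (need larger shift c)",
              bad[1], bad[2])
      }
      exp(drop(log(cfg$shift + z) %*% w)) - cfg$shift
    })
  unname(out)
}

#' Dirichlet draws of indicator weights
#'
#' Samples `M` weight vectors from `Dirichlet(alpha)`; concentrations
#' encode critical-to-quality priorities (e.g. safety-critical 4,
#' data-quality 2, generalizability 1).  Weight draw `m` is paired 1:1
#' with score draw `m` downstream.
#'
#' @param alpha positive concentration vector.
#' @param M number of draws.
#' @param seed RNG seed.
#' @return M-by-K matrix of simplex weight vectors.
#' @export
sample_weights <- function(alpha, M = 1000, seed = 1L) {
  if (any(alpha <= 0)) stopf("Dirichlet concentrations must be > 0")
  set.seed(seed)
  g <- matrix(rgamma(M * length(alpha), shape = rep(alpha, each = M)),
              nrow = M)
  g / rowSums(g)
}

#' Dispersion-rewarding (entropy-style) weights
#'
#' Data-driven weights proportional to the robust cross-site dispersion
#' (MAD) of each indicator's anchors: indicators that separate sites get
#' more weight, constant indicators get none.
#'
#' @param z_anchor_matrix sites-by-indicators anchor matrix (>= 2 sites).
#' @return A simplex weight vector named by indicator.
#' @export
entropy_weights <- function(z_anchor_matrix) {
  z_anchor_matrix <- as.matrix(z_anchor_matrix)
  if (nrow(z_anchor_matrix) < 2L) stopf("need >= 2 sites")
  disp <- apply(z_anchor_matrix, 2, mad)
  if (all(disp == 0)) {
    warnf("all indicator dispersions are zero; falling back to uniform weights")
    disp <- rep(1, ncol(z_anchor_matrix))
  }
  w <- disp / sum(disp)
  names(w) <- colnames(z_anchor_matrix)
  w
}

#' Posterior summaries of the composite score
#'
#' Per site: posterior mean, equal-tailed 95% credible interval (2.5 and
#' 97.5 percentiles), exceedance probability `Pr(S > tau)`, `Pr(Top-K)`
#' from per-draw descending-score ranks, and the rank by posterior mean.
#' Rank ties (within a draw and in the posterior-mean ordering) are
#' broken deterministically by site order.
#'
#' @param S_draws sites-by-draws composite matrix (rownames = site ids).
#' @param cfg a [composite_config()] providing `tau` and `top_k`.
#' @return A list with `summary` (data.frame `site`, `mean_S`, `crI_lo`,
#'   `crI_hi`, `pr_exceed`, `pr_topk`, `rank`) and `rank_draws`
#'   (sites-by-draws rank matrix).
#' @export
summarize_composite <- function(S_draws, cfg = composite_config()) {
  if (ncol(S_draws) < 100) stopf("need at least 100 draws to summarize")
  if (is.null(cfg$tau)) stopf("tau is required for exceedance probabilities")
  sites <- rownames(S_draws) %||% as.character(seq_len(nrow(S_draws)))
  mean_S <- rowMeans(S_draws)
  qs <- apply(S_draws, 1, quantile, probs = c(0.025, 0.975), names = FALSE)
  pr_exceed <- rowMeans(S_draws > cfg$tau)
  # per-draw ranks: 1 = highest score; ties broken by site order
  rank_draws <- apply(-S_draws, 2, rank, ties.method = "first")
  pr_topk <- rowMeans(rank_draws <= cfg$top_k)
  ord_rank <- rank(-mean_S, ties.method = "first")
  res <- data.frame(site = sites, mean_S = unname(mean_S),
                    crI_lo = unname(qs[1, ]), crI_hi = unname(qs[2, ]),
                    pr_exceed = unname(pr_exceed),
                    pr_topk = unname(pr_topk), rank = unname(ord_rank),
                    stringsAsFactors = FALSE)
  rownames(rank_draws) <- sites
  list(summary = res, rank_draws = rank_draws)
}
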