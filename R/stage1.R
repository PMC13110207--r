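# Stage 1: map each indicator observation to posterior draws on a
# transformed, risk-aligned scale.
#
# Proportions and the binary drift flag get conjugate Beta posteriors
# (Beta(1,1) prior: weak regularization, no degenerate 0/1 logits);
# screening duration and the eligibility distance are bootstrapped.
# Each (site, indicator) pair uses its own RNG substream derived from the
# master seed, so draws for one site never depend on how many other
# sites are present.

#' Stage-1 prior and draw configuration
#'
#' @param beta_a,beta_b Beta prior shapes for proportion indicators
#'   (default Beta(1, 1)).
#' @param draws number of posterior draws `M` (>= 100).
#' @param seed master RNG seed.
#' @return A list with elements `beta_a`, `beta_b`, `draws`, `seed`.
#' @export
prior_config <- function(beta_a = 1, beta_b = 1, draws = 1000, seed = 1L) {
  if (beta_a <= 0 || beta_b <= 0) stopf("Beta prior shapes must be > 0")
  if (draws < 100) stopf("draws must be >= 100")
  list(beta_a = beta_a, beta_b = beta_b, draws = as.integer(draws),
       seed = as.integer(seed))
}

#' Beta posterior draws of logit(pi)
#'
#' Conjugate update for a proportion indicator: with prior
#' `Beta(a, b)` and data `y` successes out of `n`, draws are taken from
#' `Beta(a + y, b + n - y)` and logit-transformed.
#'
#' @param y,n counts with `0 <= y <= n`.
#' @param prior a [prior_config()].
#' @param seed optional seed overriding `prior$seed`.
#' @return Numeric vector of `prior$draws` draws of `logit(pi)`.
#' @export
beta_posterior_draws <- function(y, n, prior = prior_config(), seed = NULL) {
  if (length(y) != 1L || length(n) != 1L || is.na(y) || is.na(n) ||
      y < 0 || n < 0 || y > n) {
    stopf("invalid counts: need 0 <= y <= n")
  }
  set.seed(seed %||% prior$seed)
  logit(rbeta(prior$draws, prior$beta_a + y, prior$beta_b + n - y))
}

#' Analytic posterior mean of logit(pi) under a Beta posterior
#'
#' `E[logit(pi)] = digamma(a + y) - digamma(b + n - y)`; used as the
#' Stage-2 anchor for conjugate indicators so that identical posteriors
#' yield exactly tied anchors (which makes the MAD = 0 -> SD fallback of
#' the robust standardization reachable, notably for the binary SFPS
#' indicator).
#'
#' @inheritParams beta_posterior_draws
#' @return The exact posterior mean of `logit(pi)`.
#' @export
beta_logit_mean <- function(y, n, prior = prior_config()) {
  digamma(prior$beta_a + y) - digamma(prior$beta_b + n - y)
}

#' Bootstrap draws of the median log screening time
#'
#' Nonparametric bootstrap (resample with replacement, same size) of the
#' median of `log(t)` for one site's screening times.
#'
#' @param times strictly positive screening times (days) for one site.
#' @param M number of bootstrap draws.
#' @param seed RNG seed.
#' @return Numeric vector of `M` draws of `median(log t)`.
#' @export
bootstrap_log_median <- function(times, M = 1000, seed = 1L) {
  if (!length(times)) stopf("empty input: no screening times")
  if (any(times <= 0)) stopf("screening times must be > 0")
  set.seed(seed)
  .cpp_boot_median(log(as.numeric(times)), as.integer(M))
}

#' Bootstrap draws of the log two-sample distance
#'
#' Each draw independently resamples both the focal-site sample and the
#' pooled other-site sample (with replacement, same sizes), recomputes
#' the distance, clamps it at `cfg$floor` and takes the log:
#' `log(max(D, floor))`.
#'
#' @param site_values,pool_values as in [compute_edd()].
#' @param cfg a [distance_config()].
#' @param M number of bootstrap draws.
#' @param seed RNG seed.
#' @return Numeric vector of `M` draws of the log distance.
#' @export
bootstrap_log_distance <- function(site_values, pool_values,
                                   cfg = distance_config(), M = 1000,
                                   seed = 1L) {
  if (!length(site_values)) stopf("site_values is empty")
  if (!length(pool_values)) {
    stopf("pool of other sites is empty: EDD is undefined for a single-site trial")
  }
  set.seed(seed)
  .cpp_dist_boot(as.numeric(site_values), as.numeric(pool_values),
                 as.integer(M), cfg$floor,
                 if (cfg$method == "ks") 0L else 1L)
}

#' Beta posterior draws of logit(psi) for a binary drift flag
#'
#' With a Beta(1, 1) prior and the single Bernoulli observation
#' `m in {0, 1}`, the posterior is `Beta(1 + m, 2 - m)`; draws are
#' logit-transformed.
#'
#' @param m binary drift flag (0 or 1).
#' @param M number of draws.
#' @param seed RNG seed.
#' @return Numeric vector of `M` draws of `logit(psi)`.
#' @export
bernoulli_beta_draws <- function(m, M = 1000, seed = 1L) {
  if (length(m) != 1L || is.na(m) || !(m %in% c(0, 1))) {
    stopf("m must be 0 or 1")
  }
  set.seed(seed)
  logit(rbeta(M, 1 + m, 1 + 1 - m))
}

#' Align a draw matrix with the higher-is-risk direction
#'
#' Multiplies the transformed draws by -1 when the indicator's direction
#' is -1 (lower raw value means higher risk); identity otherwise.  All
#' default indicators are constructed already risk-aligned (violations
#' are counted rather than adherence), so this is usually the identity.
#'
#' @param draws sites-by-draws matrix on the transformed scale.
#' @param direction +1 or -1 (or an [indicator_spec()] row).
#' @return The aligned draw matrix.
#' @export
align_direction <- function(draws, direction) {
  if (is.data.frame(direction) || is.list(direction)) {
    direction <- direction$direction
  }
  if (!direction %in% c(-1, 1)) stopf("direction must be +1 or -1")
  if (direction < 0) -draws else draws
}

# Build the full Stage-1 state for a trial: per-indicator sites x M draw
# matrices plus anchor vectors (analytic posterior means for conjugate
# indicators, empirical bootstrap means otherwise).  Sites whose
# denominators make an indicator undefined are dropped from that
# indicator (with a warning) and from the composite.
stage1_draws <- function(trial, prior = prior_config(),
                         dist_cfg = distance_config(),
                         spec = indicator_spec()) {
  agg <- trial$site_agg
  sites <- agg$site
  M <- prior$draws
  seed <- prior$seed
  S <- length(sites)
  ind_names <- spec$name
  draws <- list()
  anchors <- list()

  usable <- agg$n_screen > 0 & agg$n_enrolled > 0 & agg$n_bii > 0
  if (any(!usable)) {
    warnf("dropping site(s) with zero denominators from scoring: %s",
          paste(sites[!usable], collapse = ", "))
    agg <- agg[usable, , drop = FALSE]
    sites <- agg$site
    S <- length(sites)
  }

  idx <- function(k) match(k, c("bii", "fail_rate", "window", "duration",
                                "edd", "sfps", "cmg"))

  beta_block <- function(kname, y, n) {
    mat <- matrix(NA_real_, S, M)
    for (i in seq_len(S)) {
      mat[i, ] <- beta_posterior_draws(y[i], n[i], prior,
                                       seed = substream_seed(seed, i, idx(kname)))
    }
    rownames(mat) <- sites
    draws[[kname]] <<- mat
    anchors[[kname]] <<- vapply(seq_len(S), function(i)
      beta_logit_mean(y[i], n[i], prior), numeric(1))
  }

  beta_block("bii", agg$y_bii, agg$n_bii)
  beta_block("fail_rate", agg$y_fail, agg$n_screen)
  beta_block("window", agg$y_window, agg$n_enrolled)

  # duration: bootstrap median log time per site
  dur <- matrix(NA_real_, S, M, dimnames = list(sites, NULL))
  for (i in seq_len(S)) {
    t_s <- trial$times$screening_time[trial$times$site == sites[i]]
    dur[i, ] <- bootstrap_log_median(t_s, M,
                                     seed = substream_seed(seed, i, idx("duration")))
  }
  draws$duration <- dur
  anchors$duration <- rowMeans(dur)

  # EDD: bootstrap log KS (or energy) distance, focal site vs pooled others
  edd <- matrix(NA_real_, S, M, dimnames = list(sites, NULL))
  lab_site <- trial$labs$site
  lab_val <- trial$labs$lab_value
  for (i in seq_len(S)) {
    v <- lab_val[lab_site == sites[i]]
    pool <- lab_val[lab_site != sites[i] & lab_site %in% sites]
    edd[i, ] <- bootstrap_log_distance(v, pool, dist_cfg, M,
                                       seed = substream_seed(seed, i, idx("edd")))
  }
  draws$edd <- edd
  anchors$edd <- rowMeans(edd)

  # SFPS: Beta posterior for the binary drift flag
  sf <- matrix(NA_real_, S, M, dimnames = list(sites, NULL))
  for (i in seq_len(S)) {
    sf[i, ] <- bernoulli_beta_draws(agg$m_shift[i], M,
                                    seed = substream_seed(seed, i, idx("sfps")))
  }
  draws$sfps <- sf
  anchors$sfps <- vapply(agg$m_shift, function(m)
    digamma(1 + m) - digamma(2 - m), numeric(1))

  for (k in names(draws)) {
    dir_k <- spec$direction[spec$name == k]
    draws[[k]] <- align_direction(draws[[k]], dir_k)
    anchors[[k]] <- as.numeric(dir_k) * anchors[[k]]
  }

  anchor_mat <- do.call(cbind, anchors)
  rownames(anchor_mat) <- sites
  list(sites = sites, draws = draws[ind_names[ind_names %in% names(draws)]],
       anchors = anchor_mat[, ind_names[ind_names %in% names(draws)],
                            drop = FALSE],
       M = M, seed = seed)
}

#' Export Stage-1 posterior draws in long format
#'
#' Writes `posterior_draws.csv` with columns
#' `site`, `indicator`, `draw_index`, `value` — the full analysis state.
#'
#' @param score an `rbm_score` object.
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
write_posterior_draws <- function(score, path) {
  blocks <- lapply(names(score$stage1$draws), function(k) {
    mat <- score$stage1$draws[[k]]
    data.frame(site = rep(rownames(mat), times = ncol(mat)),
               indicator = k,
               draw_index = rep(seq_len(ncol(mat)), each = nrow(mat)),
               value = as.vector(mat), stringsAsFactors = FALSE)
  })
  S <- score$S_draws
  blocks[[length(blocks) + 1L]] <-
    data.frame(site = rep(rownames(S), times = ncol(S)),
               indicator = "composite",
               draw_index = rep(seq_len(ncol(S)), each = nrow(S)),
               value = as.vector(S), stringsAsFactors = FALSE)
  write.csv(do.call(rbind, blocks), path, row.names = FALSE)
  invisible(path)
}
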