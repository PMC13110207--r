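# One-factor Bayesian hierarchical integration: a latent continuous site
# risk R_s co-varies with all indicators through layer-specific
# generalized linear links.
#
#   binomial layers : y_ks ~ Binom(n_ks, invlogit(eta_ks)),
#                     eta_ks ~ N(b0_k + load_k R_s, sigma_k^2)
#   normal layers   : x_ks ~ N(mu_ks, sigma_obs_k^2),
#                     mu_ks ~ N(g0_k + load_k R_s, sigma_res_k^2)
#   bernoulli layer : m_s ~ Bern(invlogit(d0 + load_d R_s))   (no residual)
#   R_s ~ N(0, 1)
#
# Priors: intercepts N(0, 5^2); loadings half-Normal(0, 1) (nonnegative,
# so higher R_s always means higher risk and no sign flip exists);
# scales Half-Cauchy(0, 1).  Sampler: Metropolis-within-Gibbs with
# conjugate Gibbs draws where exact (latent mu, intercepts, nonnegative
# loadings of the Gaussian layers via truncated normals) and adaptive
# random-walk Metropolis elsewhere (latent eta, R_s, scales on the log
# scale, Bernoulli-layer parameters).

#' MCMC configuration
#'
#' @param chains number of chains (>= 2 for split-Rhat diagnostics).
#' @param iter total iterations per chain (warmup included).
#' @param warmup adaptation iterations discarded from the draws.
#' @param thin keep every `thin`-th post-warmup iteration.
#' @param seed RNG seed (each chain derives a substream).
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 2L, iter = 2000L, warmup = 500L,
                        thin = 1L, seed = 1L) {
  if (iter <= warmup || warmup < 0) stopf("need iter > warmup >= 0")
  if (chains < 2) warnf("chains < 2: split-Rhat diagnostics are unreliable")
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), thin = as.integer(thin),
                 seed = as.integer(seed)), class = "mcmc_config")
}

# truncated-normal (>= 0) sampler, robust far in the tail
rtnorm0 <- function(m, s) {
  p0 <- pnorm(0, m, s)
  if (p0 < 1 - 1e-10) {
    qnorm(runif(1, p0, 1), m, s)
  } else {
    # m << 0: density on [0, Inf) is approximately Exp(|m| / s^2)
    rexp(1, rate = abs(m) / s^2)
  }
}

dhalfcauchy <- function(x) log(2) + dcauchy(x, log = TRUE)

#' Fit the one-factor site-risk model
#'
#' Adaptive Metropolis-within-Gibbs sampler for the latent-factor model
#' described above.  Per-parameter split-Rhat and a crude effective
#' sample size are reported; non-convergence (any Rhat > 1.1) raises a
#' prominent warning and sets `converged = FALSE`, never failing
#' silently.
#'
#' @param data a list with elements `binom` (named list of `list(y, n)`
#'   per binomial layer, each a length-S vector pair), `normal` (named
#'   list of length-S observation vectors), `bern` (length-S binary
#'   vector or `NULL`), and `sites` (site identifiers).
#' @param mcmc an [mcmc_config()].
#' @return An object of class `rbm_latent`: posterior draws of all
#'   parameters and of `R_s`, layer-wise `Z*` draws (risk-aligned latent
#'   contributions), diagnostics, and the input data.
#' @export
fit_one_factor <- function(data, mcmc = mcmc_config()) {
  sites <- data$sites
  S <- length(sites)
  if (S < 5) stopf("need >= 5 sites to fit the latent-factor model")
  KB <- length(data$binom); KN <- length(data$normal)
  if (KB + KN + as.integer(!is.null(data$bern)) < 2L) {
    stopf("need at least two indicators with data")
  }
  yB <- if (KB) do.call(rbind, lapply(data$binom, `[[`, "y")) else NULL
  nB <- if (KB) do.call(rbind, lapply(data$binom, `[[`, "n")) else NULL
  xN <- if (KN) do.call(rbind, data$normal) else NULL
  m <- data$bern
  has_bern <- !is.null(m)

  n_keep <- (mcmc$iter - mcmc$warmup) %/% mcmc$thin
  chains <- vector("list", mcmc$chains)

  for (ch in seq_len(mcmc$chains)) {
    set.seed(substream_seed(mcmc$seed, ch, 7L))
    # initial state
    R <- rnorm(S, 0, 0.5)
    b0 <- rep(0, KB); lb <- rep(0.5, KB); sb <- rep(0.5, KB)
    eta <- if (KB) {
      t(vapply(seq_len(KB), function(k)
        logit((yB[k, ] + 0.5) / (nB[k, ] + 1)), numeric(S)))
    } else NULL
    g0 <- if (KN) vapply(data$normal, mean, numeric(1)) else numeric(0)
    lg <- rep(0.5, KN); so <- rep(0.5, KN); sr <- rep(0.5, KN)
    mu <- if (KN) xN else NULL
    d0 <- 0; ld <- 0.5

    step_eta <- rep(0.5, KB)
    step_sb <- rep(0.3, KB); step_so <- rep(0.3, KN); step_sr <- rep(0.3, KN)
    step_d0 <- 0.5; step_ld <- 0.5
    acc <- new.env()
    tick <- function(name, rate) {
      cur <- get0(name, envir = acc, ifnotfound = c(0, 0))
      assign(name, cur + c(rate, 1), envir = acc)
    }
    adapt <- function(name, step) {
      cur <- get0(name, envir = acc, ifnotfound = c(0, 1))
      rate <- cur[1] / cur[2]
      assign(name, c(0, 0), envir = acc)
      step * exp(0.6 * (rate - 0.44))
    }

    draws <- list(
      R = matrix(NA_real_, n_keep, S),
      eta = if (KB) array(NA_real_, c(n_keep, KB, S)) else NULL,
      mu = if (KN) array(NA_real_, c(n_keep, KN, S)) else NULL,
      pars = matrix(NA_real_, n_keep,
                    3 * KB + 4 * KN + if (has_bern) 2 else 0))
    keep_i <- 0L

    for (it in seq_len(mcmc$iter)) {
      # --- binomial layers ---
      for (k in seq_len(KB)) {
        mk <- b0[k] + lb[k] * R
        # several cheap elementwise sweeps loosen the eta <-> R coupling
        for (rep_eta in 1:3) {
          prop <- eta[k, ] + step_eta[k] * rnorm(S)
          lr <- (yB[k, ] * prop - nB[k, ] * log1pexp(prop) +
                   dnorm(prop, mk, sb[k], log = TRUE)) -
                (yB[k, ] * eta[k, ] - nB[k, ] * log1pexp(eta[k, ]) +
                   dnorm(eta[k, ], mk, sb[k], log = TRUE))
          ok <- log(runif(S)) < lr
          eta[k, ok] <- prop[ok]
          tick(paste0("eta", k), mean(ok))
        }
        # intercept (Gibbs, prior N(0, 25))
        prec <- S / sb[k]^2 + 1 / 25
        mhat <- sum(eta[k, ] - lb[k] * R) / sb[k]^2 / prec
        b0[k] <- rnorm(1, mhat, sqrt(1 / prec))
        # loading (Gibbs, half-normal prior -> truncated normal)
        d <- eta[k, ] - b0[k]
        prec <- sum(R^2) / sb[k]^2 + 1
        mhat <- sum(R * d) / sb[k]^2 / prec
        lb[k] <- rtnorm0(mhat, sqrt(1 / prec))
        # residual scale (log-scale MH, Half-Cauchy prior)
        resid <- eta[k, ] - b0[k] - lb[k] * R
        props <- sb[k] * exp(step_sb[k] * rnorm(1))
        lr <- sum(dnorm(resid, 0, props, log = TRUE)) + dhalfcauchy(props) +
          log(props) -
          (sum(dnorm(resid, 0, sb[k], log = TRUE)) + dhalfcauchy(sb[k]) +
             log(sb[k]))
        if (log(runif(1)) < lr) { sb[k] <- props; tick(paste0("sb", k), 1) }
        else tick(paste0("sb", k), 0)
      }
      # --- normal layers ---
      for (k in seq_len(KN)) {
        prec <- 1 / so[k]^2 + 1 / sr[k]^2
        mhat <- (xN[k, ] / so[k]^2 + (g0[k] + lg[k] * R) / sr[k]^2) / prec
        mu[k, ] <- rnorm(S, mhat, sqrt(1 / prec))
        prec <- S / sr[k]^2 + 1 / 25
        mhat <- sum(mu[k, ] - lg[k] * R) / sr[k]^2 / prec
        g0[k] <- rnorm(1, mhat, sqrt(1 / prec))
        d <- mu[k, ] - g0[k]
        prec <- sum(R^2) / sr[k]^2 + 1
        mhat <- sum(R * d) / sr[k]^2 / prec
        lg[k] <- rtnorm0(mhat, sqrt(1 / prec))
        # observation scale
        resid <- xN[k, ] - mu[k, ]
        props <- so[k] * exp(step_so[k] * rnorm(1))
        lr <- sum(dnorm(resid, 0, props, log = TRUE)) + dhalfcauchy(props) +
          log(props) -
          (sum(dnorm(resid, 0, so[k], log = TRUE)) + dhalfcauchy(so[k]) +
             log(so[k]))
        if (log(runif(1)) < lr) { so[k] <- props; tick(paste0("so", k), 1) }
        else tick(paste0("so", k), 0)
        # residual scale
        resid <- mu[k, ] - g0[k] - lg[k] * R
        props <- sr[k] * exp(step_sr[k] * rnorm(1))
        lr <- sum(dnorm(resid, 0, props, log = TRUE)) + dhalfcauchy(props) +
          log(props) -
          (sum(dnorm(resid, 0, sr[k], log = TRUE)) + dhalfcauchy(sr[k]) +
             log(sr[k]))
        if (log(runif(1)) < lr) { sr[k] <- props; tick(paste0("sr", k), 1) }
        else tick(paste0("sr", k), 0)
      }
      # --- bernoulli layer (no residual, per the model) ---
      if (has_bern) {
        lin <- d0 + ld * R
        ll0 <- sum(m * lin - log1pexp(lin))
        propd <- d0 + step_d0 * rnorm(1)
        linp <- propd + ld * R
        lr <- sum(m * linp - log1pexp(linp)) + dnorm(propd, 0, 5, log = TRUE) -
          ll0 - dnorm(d0, 0, 5, log = TRUE)
        if (log(runif(1)) < lr) { d0 <- propd; tick("d0", 1) } else tick("d0", 0)
        lin <- d0 + ld * R
        ll0 <- sum(m * lin - log1pexp(lin))
        propl <- ld * exp(step_ld * rnorm(1))
        linp <- d0 + propl * R
        # half-normal prior with log-scale proposal Jacobian
        lr <- sum(m * linp - log1pexp(linp)) - propl^2 / 2 + log(propl) -
          (ll0 - ld^2 / 2 + log(ld))
        if (log(runif(1)) < lr) { ld <- propl; tick("ld", 1) } else tick("ld", 0)
      }
      # --- latent site risk ---
      # The full conditional of R_s given the layer latents is Gaussian
      # except for the (residual-free) Bernoulli layer: propose from the
      # exact Gaussian conditional and Metropolis-correct only for the
      # Bernoulli likelihood (exact Gibbs when that layer is absent).
      prec <- rep(1, S)
      mnum <- rep(0, S)
      for (k in seq_len(KB)) {
        prec <- prec + lb[k]^2 / sb[k]^2
        mnum <- mnum + lb[k] * (eta[k, ] - b0[k]) / sb[k]^2
      }
      for (k in seq_len(KN)) {
        prec <- prec + lg[k]^2 / sr[k]^2
        mnum <- mnum + lg[k] * (mu[k, ] - g0[k]) / sr[k]^2
      }
      prop <- rnorm(S, mnum / prec, sqrt(1 / prec))
      if (has_bern) {
        linp <- d0 + ld * prop; lin <- d0 + ld * R
        lr <- (m * linp - log1pexp(linp)) - (m * lin - log1pexp(lin))
        ok <- log(runif(S)) < lr
        R[ok] <- prop[ok]
        tick("R", mean(ok))
      } else {
        R <- prop
      }

      # --- warmup adaptation ---
      if (it <= mcmc$warmup && it %% 25 == 0) {
        for (k in seq_len(KB)) {
          step_eta[k] <- adapt(paste0("eta", k), step_eta[k])
          step_sb[k] <- adapt(paste0("sb", k), step_sb[k])
        }
        for (k in seq_len(KN)) {
          step_so[k] <- adapt(paste0("so", k), step_so[k])
          step_sr[k] <- adapt(paste0("sr", k), step_sr[k])
        }
        if (has_bern) {
          step_d0 <- adapt("d0", step_d0)
          step_ld <- adapt("ld", step_ld)
        }
      }
      # --- record ---
      if (it > mcmc$warmup && (it - mcmc$warmup) %% mcmc$thin == 0) {
        keep_i <- keep_i + 1L
        draws$R[keep_i, ] <- R
        if (KB) draws$eta[keep_i, , ] <- eta
        if (KN) draws$mu[keep_i, , ] <- mu
        draws$pars[keep_i, ] <- c(b0, lb, sb, g0, lg, so, sr,
                                  if (has_bern) c(d0, ld))
      }
    }
    chains[[ch]] <- draws
  }

  par_names <- c(
    if (KB) c(paste0("b0_", names(data$binom)),
              paste0("load_", names(data$binom)),
              paste0("sigma_", names(data$binom))),
    if (KN) c(paste0("g0_", names(data$normal)),
              paste0("load_", names(data$normal)),
              paste0("sigma_obs_", names(data$normal)),
              paste0("sigma_res_", names(data$normal))),
    if (has_bern) c("d0_sfps", "load_sfps"))
  for (ch in seq_along(chains)) colnames(chains[[ch]]$pars) <- par_names

  diag <- .mcmc_diagnostics(chains, S, par_names)
  converged <- all(diag$rhat <= 1.1, na.rm = TRUE)
  if (!converged) {
    warnf("MCMC did not converge: max split-Rhat = %.3f (parameters: %s); interpret posteriors with caution",
          max(diag$rhat, na.rm = TRUE),
          paste(head(diag$parameter[order(-diag$rhat)], 3), collapse = ", "))
  }
  structure(list(chains = chains, sites = sites, data = data,
                 par_names = par_names, diagnostics = diag,
                 converged = converged, mcmc = mcmc),
            class = "rbm_latent")
}

# split-Rhat and a crude ESS (initial-positive-sequence estimator) over
# all chains, for R_s and the global parameters
.mcmc_diagnostics <- function(chains, S, par_names) {
  get_mat <- function(f) lapply(chains, f)
  one <- function(mats) {
    halves <- list()
    for (mm in mats) {
      n2 <- floor(length(mm) / 2)
      halves <- c(halves, list(mm[seq_len(n2)], mm[seq_len(n2) + n2]))
    }
    mns <- vapply(halves, mean, numeric(1))
    vrs <- vapply(halves, var, numeric(1))
    n <- length(halves[[1]])
    W <- mean(vrs); B <- n * var(mns)
    rhat <- if (W > 0) sqrt(((n - 1) / n * W + B / n) / W) else NA_real_
    # crude ESS from chain 1
    x <- mats[[1]]
    if (var(x) == 0) return(c(rhat, length(x) * length(mats)))
    ac <- acf(x, lag.max = min(100, length(x) - 1), plot = FALSE)$acf[-1]
    pos <- which(ac < 0)[1]
    if (!is.na(pos)) ac <- ac[seq_len(pos - 1)]
    ess <- length(x) * length(mats) / (1 + 2 * sum(ac))
    c(rhat, max(ess, 1))
  }
  rows <- list()
  for (s in seq_len(S)) {
    v <- one(get_mat(function(d) d$R[, s]))
    rows[[length(rows) + 1L]] <- data.frame(parameter = paste0("R[", s, "]"),
                                            rhat = v[1], ess = v[2])
  }
  for (p in par_names) {
    v <- one(get_mat(function(d) d$pars[, p]))
    rows[[length(rows) + 1L]] <- data.frame(parameter = p, rhat = v[1],
                                            ess = v[2])
  }
  do.call(rbind, rows)
}

#' Fit the latent-factor model to a trial dataset
#'
#' Builds the layer data from a trial (binomial layers: BII,
#' screen-failure rate, window violations; normal layers: median log
#' screening duration and log site-vs-pool eligibility distance;
#' Bernoulli layer: the drift flag) and fits [fit_one_factor()].
#'
#' @param trial an `rbm_trial`.
#' @param mcmc an [mcmc_config()].
#' @param dist_cfg a [distance_config()] for the EDD observation.
#' @return An `rbm_latent` fit.
#' @export
rbm_latent <- function(trial, mcmc = mcmc_config(),
                       dist_cfg = distance_config()) {
  agg <- trial$site_agg
  usable <- agg$n_screen > 0 & agg$n_enrolled > 0 & agg$n_bii > 0
  if (any(!usable)) {
    warnf("dropping site(s) with zero denominators: %s",
          paste(agg$site[!usable], collapse = ", "))
    agg <- agg[usable, , drop = FALSE]
  }
  sites <- agg$site
  dur <- compute_duration_stat(trial$times)
  dur <- dur$median_log_time[match(sites, dur$site)]
  edd <- vapply(sites, function(s) {
    v <- trial$labs$lab_value[trial$labs$site == s]
    pool <- trial$labs$lab_value[trial$labs$site != s &
                                   trial$labs$site %in% sites]
    log(max(compute_edd(v, pool, dist_cfg), dist_cfg$floor))
  }, numeric(1))
  data <- list(
    binom = list(bii = list(y = agg$y_bii, n = agg$n_bii),
                 fail_rate = list(y = agg$y_fail, n = agg$n_screen),
                 window = list(y = agg$y_window, n = agg$n_enrolled)),
    normal = list(duration = dur, edd = unname(edd)),
    bern = agg$m_shift, sites = sites)
  fit_one_factor(data, mcmc)
}

#' Simulate data from the one-factor model
#'
#' Generates site-level data directly from the latent-factor model
#' (used for parameter-recovery and calibration checks): draws
#' `R_s ~ N(0, 1)` (unless supplied), then each layer from its
#' likelihood.
#'
#' @param n_sites number of sites.
#' @param n_obs binomial denominator per site.
#' @param n_binom,n_normal number of binomial / normal layers.
#' @param bern include the Bernoulli drift layer.
#' @param intercepts,loadings scalar or per-layer values recycled over
#'   layers (order: binomial, normal, bernoulli).
#' @param sigma residual scale of the binomial/normal layers.
#' @param sigma_obs observation scale of the normal layers.
#' @param R optional fixed latent risk vector.
#' @param seed RNG seed.
#' @return A list with `data` (as consumed by [fit_one_factor()]) and
#'   `truth` (all generating parameters, including `R`).
#' @export
simulate_latent_data <- function(n_sites = 50L, n_obs = 200L,
                                 n_binom = 2L, n_normal = 0L, bern = FALSE,
                                 intercepts = -1, loadings = 1,
                                 sigma = 0.3, sigma_obs = 0.3, R = NULL,
                                 seed = 1L) {
  set.seed(seed)
  S <- n_sites
  K <- n_binom + n_normal + as.integer(bern)
  intercepts <- rep(intercepts, length.out = K)
  loadings <- rep(loadings, length.out = K)
  R <- R %||% rnorm(S)
  binom <- list(); normal <- list(); mlab <- NULL
  j <- 0L
  for (k in seq_len(n_binom)) {
    j <- j + 1L
    eta <- intercepts[j] + loadings[j] * R + rnorm(S, 0, sigma)
    binom[[paste0("b", k)]] <- list(y = rbinom(S, n_obs, inv_logit(eta)),
                                    n = rep(n_obs, S))
  }
  for (k in seq_len(n_normal)) {
    j <- j + 1L
    mu <- intercepts[j] + loadings[j] * R + rnorm(S, 0, sigma)
    normal[[paste0("g", k)]] <- mu + rnorm(S, 0, sigma_obs)
  }
  if (bern) {
    j <- j + 1L
    mlab <- rbinom(S, 1L, inv_logit(intercepts[j] + loadings[j] * R))
  }
  list(data = list(binom = binom,
                   normal = if (n_normal) normal else list(),
                   bern = mlab,
                   sites = sprintf("S%03d", seq_len(S))),
       truth = list(R = R, intercepts = intercepts, loadings = loadings,
                    sigma = sigma, sigma_obs = sigma_obs))
}

# Stack post-warmup draws over chains: draws x S matrix for R_s, or a
# named layer of Z* draws.
latent_draws <- function(fit, what = "R", layer = NULL) {
  if (what == "R") {
    do.call(rbind, lapply(fit$chains, `[[`, "R"))
  } else if (what == "pars") {
    do.call(rbind, lapply(fit$chains, `[[`, "pars"))
  } else if (what == "zstar") {
    KB <- length(fit$data$binom); KN <- length(fit$data$normal)
    nm <- c(names(fit$data$binom), names(fit$data$normal),
            if (!is.null(fit$data$bern)) "sfps")
    k <- match(layer, nm)
    if (is.na(k)) stopf("unknown layer '%s'", layer)
    if (k <= KB) {
      do.call(rbind, lapply(fit$chains, function(d) d$eta[, k, ]))
    } else if (k <= KB + KN) {
      do.call(rbind, lapply(fit$chains, function(d) d$mu[, k - KB, ]))
    } else {
      do.call(rbind, lapply(fit$chains, function(d) {
        # linear predictor d0 + load * R per draw (vectors recycle down
        # the draw dimension of the draws x S matrix)
        d$R * d$pars[, "load_sfps"] + d$pars[, "d0_sfps"]
      }))
    }
  }
}

#' Posterior composite from the latent-factor fit
#'
#' Builds the posterior composite from the model's risk-aligned latent
#' contributions `Z*` (the latent logit proportion for binomial layers,
#' the latent mean for log-time/log-distance layers, and the linear
#' predictor of the drift layer), standardized by robust trial-level
#' centers and scales (median and 1.4826*MAD of the site posterior-mean
#' `Z*`, mirroring Stage 2) and combined with simplex weights:
#' `S_Bayes = sum_k w_k (Z*_ks - center_k) / scale_k` per draw.
#'
#' @param fit an `rbm_latent` object.
#' @param weights fixed weights (default uniform over layers).
#' @param cfg a [composite_config()] for the summaries.
#' @param trial_centers optional list with `center` and `scale` vectors
#'   overriding the robust trial-level defaults.
#' @return A list with `summary`/`rank_draws` (as
#'   [summarize_composite()]) and the per-site draw matrix `S_draws`.
#' @export
bayes_composite <- function(fit, weights = NULL, cfg = composite_config(),
                            trial_centers = NULL) {
  layers <- c(names(fit$data$binom), names(fit$data$normal),
              if (!is.null(fit$data$bern)) "sfps")
  z <- lapply(layers, function(l) t(latent_draws(fit, "zstar", l)))  # S x M
  names(z) <- layers
  K <- length(layers)
  weights <- weights %||% rep(1 / K, K)
  if (length(weights) != K) stopf("weights length must equal layer count (%d)", K)
  weights <- weights / sum(weights)
  anchors <- vapply(z, rowMeans, numeric(length(fit$sites)))
  if (is.null(trial_centers)) {
    trial_centers <- fit_standardization(anchors)
  } else if (is.null(trial_centers$center) || is.null(trial_centers$scale)) {
    stopf("trial_centers must provide 'center' and 'scale'")
  }
  Sd <- matrix(0, length(fit$sites), ncol(z[[1]]))
  for (k in seq_len(K)) {
    Sd <- Sd + weights[k] *
      (z[[k]] - trial_centers$center[[k]]) / trial_centers$scale[[k]]
  }
  rownames(Sd) <- fit$sites
  out <- summarize_composite(Sd, cfg)
  out$S_draws <- Sd
  out$trial_centers <- trial_centers
  out$weights <- structure(weights, names = layers)
  out
}

#' @export
print.rbm_latent <- function(x, ...) {
  cat(sprintf("One-factor Bayesian site-risk model (%d sites; %d binomial, %d normal%s layers)\n",
              length(x$sites), length(x$data$binom), length(x$data$normal),
              if (!is.null(x$data$bern)) ", 1 Bernoulli" else ""))
  cat(sprintf("Chains: %d;  kept draws: %d;  converged: %s (max Rhat %.3f)\n",
              x$mcmc$chains, nrow(x$chains[[1]]$R) * x$mcmc$chains,
              x$converged, max(x$diagnostics$rhat, na.rm = TRUE)))
  Rm <- colMeans(latent_draws(x, "R"))
  top <- order(-Rm)[seq_len(min(5, length(Rm)))]
  cat("Highest latent risk (posterior mean R_s):\n")
  print(data.frame(site = x$sites[top], R = round(Rm[top], 3)),
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.rbm_latent <- function(object, ...) {
  pars <- latent_draws(object, "pars")
  tab <- data.frame(parameter = colnames(pars),
                    mean = colMeans(pars),
                    sd = apply(pars, 2, sd),
                    q2.5 = apply(pars, 2, quantile, 0.025),
                    q97.5 = apply(pars, 2, quantile, 0.975))
  tab <- merge(tab, object$diagnostics, by = "parameter", sort = FALSE)
  rownames(tab) <- NULL
  tab
}

#' @export
coef.rbm_latent <- function(object, ...) {
  structure(colMeans(latent_draws(object, "R")), names = object$sites)
}

#' @export
plot.rbm_latent <- function(x, ...) {
  R <- latent_draws(x, "R")
  mns <- colMeans(R)
  qs <- apply(R, 2, quantile, c(0.025, 0.975))
  ord <- order(mns)
  n <- length(mns)
  plot(mns[ord], seq_len(n), xlim = range(qs), yaxt = "n", pch = 19,
       xlab = "Latent site risk R (posterior mean, 95% CrI)", ylab = "", ...)
  segments(qs[1, ord], seq_len(n), qs[2, ord], seq_len(n))
  axis(2, at = seq_len(n), labels = x$sites[ord], las = 2, cex.axis = 0.6)
  abline(v = 0, lty = 2)
  invisible(x)
}
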