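test_that("the one-factor model recovers a simulated latent risk ordering", {
  sim <- simulate_latent_data(n_sites = 30, n_obs = 150, n_binom = 2,
                              n_normal = 1, bern = FALSE,
                              intercepts = c(-2, -1, 1), loadings = 1,
                              sigma = 0.3, sigma_obs = 0.2, seed = 41)
  fit <- suppressWarnings(
    fit_one_factor(sim$data, mcmc_config(chains = 2, iter = 1500,
                                         warmup = 500, seed = 8)))
  expect_gt(cor(coef(fit), sim$truth$R), 0.8)
  expect_true(all(c("b0_b1", "load_b1", "sigma_b1", "g0_g1")
                  %in% fit$par_names))
  # loadings respect the nonnegativity constraint in every draw
  pars <- rbmscore:::latent_draws(fit, "pars")
  expect_true(all(pars[, "load_b1"] >= 0))
  expect_true(all(pars[, "load_g1"] >= 0))
})

test_that("posterior spread of R matches an independent JAGS fit", {
  library(rjags)
  sim0 <- simulate_latent_data(n_sites = 5, n_obs = 200, n_binom = 2,
                               bern = FALSE, intercepts = -1,
                               loadings = 0, sigma = 1, seed = 2)
  fit <- suppressWarnings(
    fit_one_factor(sim0$data, mcmc_config(chains = 2, iter = 5000,
                                          warmup = 1000, seed = 4)))
  Rd <- rbmscore:::latent_draws(fit, "R")

  model <- "
  model {
    for (k in 1:2) {
      b0[k] ~ dnorm(0, 1/25)
      lb[k] ~ dnorm(0, 1) T(0,)
      sb[k] ~ dt(0, 1, 1) T(0,)
      for (s in 1:S) {
        eta[k,s] ~ dnorm(b0[k] + lb[k]*R[s], 1/(sb[k]^2))
        y[k,s] ~ dbin(ilogit(eta[k,s]), n[k,s])
      }
    }
    for (s in 1:S) { R[s] ~ dnorm(0, 1) }
  }"
  y <- rbind(sim0$data$binom$b1$y, sim0$data$binom$b2$y)
  n <- rbind(sim0$data$binom$b1$n, sim0$data$binom$b2$n)
  jm <- jags.model(textConnection(model),
                   data = list(y = y, n = n, S = 5),
                   n.chains = 2, quiet = TRUE,
                   inits = list(.RNG.name = "base::Mersenne-Twister",
                                .RNG.seed = 7))
  update(jm, 4000)
  samp <- as.matrix(coda.samples(jm, "R", n.iter = 20000, thin = 5))

  expect_equal(apply(Rd, 2, sd), unname(apply(samp, 2, sd)),
               tolerance = 0.12)
  expect_equal(colMeans(Rd), unname(colMeans(samp)), tolerance = 0.15)
})

test_that("posterior mean risk responds monotonically to one site's data", {
  base <- simulate_latent_data(n_sites = 8, n_obs = 100, n_binom = 2,
                               bern = FALSE, intercepts = -1,
                               loadings = 1, sigma = 0.3, seed = 12)
  worse <- base
  worse$data$binom$b1$y[1] <- min(worse$data$binom$b1$y[1] + 30, 100)
  worse$data$binom$b2$y[1] <- min(worse$data$binom$b2$y[1] + 30, 100)
  mc <- mcmc_config(chains = 2, iter = 1500, warmup = 500, seed = 5)
  f1 <- suppressWarnings(fit_one_factor(base$data, mc))
  f2 <- suppressWarnings(fit_one_factor(worse$data, mc))
  expect_gt(coef(f2)[1], coef(f1)[1])
})

test_that("site relabeling permutes the posterior accordingly", {
  sim <- simulate_latent_data(n_sites = 10, n_obs = 150, n_binom = 2,
                              bern = FALSE, intercepts = -1, loadings = 1,
                              sigma = 0.3, seed = 33)
  perm <- c(4, 1, 3, 2, 6, 5, 8, 7, 10, 9)
  permuted <- sim$data
  for (k in names(permuted$binom)) {
    permuted$binom[[k]]$y <- permuted$binom[[k]]$y[perm]
    permuted$binom[[k]]$n <- permuted$binom[[k]]$n[perm]
  }
  permuted$sites <- permuted$sites[perm]
  mc <- mcmc_config(chains = 2, iter = 2500, warmup = 500, seed = 3)
  f1 <- suppressWarnings(fit_one_factor(sim$data, mc))
  f2 <- suppressWarnings(fit_one_factor(permuted, mc))
  r1 <- coef(f1); r2 <- coef(f2)
  expect_equal(unname(r2[sim$sites]), unname(r1[sim$sites]),
               tolerance = 0.15)
})

test_that("rank statistics of prior-drawn parameters are uniform (SBC)", {
  set.seed(99)
  nrep <- 60
  ranks <- matrix(NA_real_, nrep, 2)
  nb <- NA_integer_
  for (r in seq_len(nrep)) {
    b0 <- rnorm(2, 0, 5); lb <- abs(rnorm(2)); sb <- abs(rcauchy(2))
    R <- rnorm(10)
    d <- list(binom = list(), normal = list(), bern = NULL,
              sites = sprintf("S%02d", 1:10))
    for (k in 1:2) {
      eta <- b0[k] + lb[k] * R + rnorm(10, 0, sb[k])
      d$binom[[paste0("b", k)]] <- list(y = rbinom(10, 50, plogis(eta)),
                                        n = rep(50L, 10))
    }
    fit <- suppressWarnings(
      fit_one_factor(d, mcmc_config(chains = 2, iter = 1300, warmup = 500,
                                    thin = 16, seed = r)))
    Rd <- rbmscore:::latent_draws(fit, "R")[, 1]
    ld <- rbmscore:::latent_draws(fit, "pars")[, "load_b1"]
    nb <- length(Rd)
    ranks[r, 1] <- sum(Rd < R[1])
    ranks[r, 2] <- sum(ld < lb[1])
  }
  for (j in 1:2) {
    tab <- table(cut(ranks[, j], breaks = seq(0, nb, length.out = 6),
                     include.lowest = TRUE))
    expect_gt(chisq.test(tab)$p.value, 0.01)
  }
})

test_that("the model-based composite standardizes latent contributions", {
  trial <- simulate_trial(trial_config(n_sites = 12), seed = 19)
  fit <- suppressWarnings(
    rbm_latent(trial, mcmc_config(chains = 2, iter = 1200, warmup = 400,
                                  seed = 6)))
  comp <- bayes_composite(fit, cfg = composite_config(tau = 1, top_k = 3))
  expect_equal(nrow(comp$summary), 12L)
  expect_true(all(comp$summary$crI_lo <= comp$summary$mean_S))
  expect_true(all(comp$summary$mean_S <= comp$summary$crI_hi))
  expect_lt(abs(sum(comp$summary$pr_topk) - 3), 1e-10)

  # single layer with weight 1 and unit scale: the composite is the
  # centered Z* draw-for-draw
  z <- t(rbmscore:::latent_draws(fit, "zstar", "bii"))
  ctr <- list(center = c(bii = 1.5), scale = c(bii = 1))
  w <- c(1, 0, 0, 0, 0, 0)
  comp2 <- bayes_composite(fit, weights = w, trial_centers = list(
    center = c(bii = 1.5, fail_rate = 0, window = 0, duration = 0,
               edd = 0, sfps = 0),
    scale = c(bii = 1, fail_rate = 1, window = 1, duration = 1,
              edd = 1, sfps = 1)))
  expect_equal(unname(comp2$S_draws), unname(z - 1.5))

  # doubling an indicator's scale halves its contribution
  comp3 <- bayes_composite(fit, weights = w, trial_centers = list(
    center = c(bii = 1.5, fail_rate = 0, window = 0, duration = 0,
               edd = 0, sfps = 0),
    scale = c(bii = 2, fail_rate = 1, window = 1, duration = 1,
              edd = 1, sfps = 1)))
  expect_equal(unname(comp3$S_draws), unname((z - 1.5) / 2))

  # all Z* draws equal to the center give an identically zero composite
  fake <- fit
  for (ch in seq_along(fake$chains)) {
    fake$chains[[ch]]$eta[] <- 0.7
    fake$chains[[ch]]$mu[] <- 0.7
    fake$chains[[ch]]$pars[, "d0_sfps"] <- 0.7
    fake$chains[[ch]]$pars[, "load_sfps"] <- 0
  }
  nm <- c("bii", "fail_rate", "window", "duration", "edd", "sfps")
  ctr0 <- list(center = structure(rep(0.7, 6), names = nm),
               scale = structure(rep(1, 6), names = nm))
  comp0 <- bayes_composite(fake, trial_centers = ctr0)
  expect_true(all(abs(comp0$S_draws) < 1e-12))
})
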