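# Multicenter-trial simulator with known atypical sites.
#
# Per site: screened count ~ DiscreteUniform(20, 100); each screened
# participant gets an eligibility lab value ~ N(80, 15) (atypical sites:
# mean shifted by -12 toward the 60 mL/min threshold, inflating
# borderline inclusions); screen failure combines the eligibility
# channel (lab <= 60) with an independent non-lab channel whose
# site-level probability is Beta-distributed with mean ~ U(0.10, 0.40);
# screening durations are log-normal (median 7 d, sdlog 0.4; atypical
# medians x1.30); window violations ~ Binomial(n_enrolled, 1 - theta_s)
# with theta_s ~ U(0.80, 0.95); the drift flag is Bernoulli with
# baseline probability 0.05 (atypical 0.50).

#' Trial simulator configuration
#'
#' Defaults encode the reference study conditions; every knob is exposed
#' for sensitivity analyses.
#'
#' @param n_sites number of sites S.
#' @param screen_range discrete-uniform range of screened participants
#'   per site.
#' @param lab_mean,lab_sd eligibility-value distribution (e.g. creatinine
#'   clearance, mL/min).
#' @param tau_lab protocol eligibility threshold (enrollment requires
#'   `lab > tau_lab`).
#' @param atypical_frac fraction of sites designated atypical (in [0, 1)).
#' @param atypical_shift additive shift of the atypical sites' lab mean.
#' @param fail_mean_range range of site-specific non-lab screen-failure
#'   means (Beta-Binomial channel).
#' @param fail_conc Beta concentration of the non-lab failure channel.
#' @param dur_median median screening duration in days.
#' @param dur_sdlog log-scale SD of screening durations.
#' @param atypical_dur_mult multiplicative median-duration factor for
#'   atypical sites.
#' @param window_adherence range of site window-adherence probabilities
#'   `theta_s`; violations are Binomial(n_enrolled, 1 - theta_s).
#' @param drift_prob,drift_prob_atypical Bernoulli drift-flag
#'   probabilities for typical and atypical sites.
#' @param delta borderline half-width for the BII band
#'   `[tau_lab - delta, tau_lab + delta]`.
#' @return A list of class `trial_config`.
#' @export
trial_config <- function(n_sites = 50L, screen_range = c(20L, 100L),
                         lab_mean = 80, lab_sd = 15, tau_lab = 60,
                         atypical_frac = 0.10, atypical_shift = -12,
                         fail_mean_range = c(0.10, 0.40), fail_conc = 20,
                         dur_median = 7, dur_sdlog = 0.4,
                         atypical_dur_mult = 1.30,
                         window_adherence = c(0.80, 0.95),
                         drift_prob = 0.05, drift_prob_atypical = 0.50,
                         delta = 5) {
  stopifnot(n_sites >= 1, screen_range[1] <= screen_range[2],
            lab_sd > 0, dur_sdlog > 0,
            atypical_frac >= 0, atypical_frac < 1,
            fail_mean_range[1] <= fail_mean_range[2],
            window_adherence[1] <= window_adherence[2], delta > 0)
  structure(as.list(environment()), class = "trial_config")
}

# Draw the site-level generating configuration (held fixed across
# replicates in rank-stability runs).
draw_site_config <- function(cfg) {
  S <- cfg$n_sites
  n_atyp <- if (cfg$atypical_frac * S < 1) {
    if (cfg$atypical_frac > 0) {
      warnf("atypical_frac * n_sites < 1: simulating zero atypical sites")
    }
    0L
  } else {
    as.integer(ceiling(cfg$atypical_frac * S))
  }
  atypical <- rep(FALSE, S)
  if (n_atyp > 0) atypical[sample.int(S, n_atyp)] <- TRUE
  wd <- max(2L, nchar(as.character(S)))
  u <- runif(S, cfg$fail_mean_range[1], cfg$fail_mean_range[2])
  data.frame(
    site = sprintf(paste0("S%0", wd, "d"), seq_len(S)),
    atypical = atypical,
    n_screen = sample(seq(cfg$screen_range[1], cfg$screen_range[2]), S,
                      replace = TRUE),
    lab_mean = cfg$lab_mean + ifelse(atypical, cfg$atypical_shift, 0),
    fail_prob = rbeta(S, u * cfg$fail_conc, (1 - u) * cfg$fail_conc),
    theta = runif(S, cfg$window_adherence[1], cfg$window_adherence[2]),
    drift_prob = ifelse(atypical, cfg$drift_prob_atypical, cfg$drift_prob),
    dur_meanlog = log(cfg$dur_median) +
      ifelse(atypical, log(cfg$atypical_dur_mult), 0),
    stringsAsFactors = FALSE)
}

#' Simulate a multicenter trial with known atypical sites
#'
#' Generates a complete trial dataset (aggregate counts, enrolled-lab
#' long table, screening-time long table) plus the ground-truth labels
#' and generating parameters.  Identical `(cfg, seed)` give identical
#' datasets.
#'
#' @param cfg a [trial_config()].
#' @param seed integer RNG seed.
#' @param site_config optional fixed site-level configuration (as
#'   returned in `$truth`): when supplied, only participant-level data
#'   are redrawn — the device used for rank-stability evaluation.
#' @return An object of class `rbm_trial`: list with `site_agg`, `labs`,
#'   `times`, `truth`, `config` and a passing `validation` report.
#' @export
simulate_trial <- function(cfg = trial_config(), seed = 1L,
                           site_config = NULL) {
  set.seed(seed)
  sc <- site_config %||% draw_site_config(cfg)
  S <- nrow(sc)
  lo <- cfg$tau_lab - cfg$delta
  hi <- cfg$tau_lab + cfg$delta
  agg <- vector("list", S); labs <- vector("list", S); times <- vector("list", S)
  for (i in seq_len(S)) {
    n <- sc$n_screen[i]
    lab <- rnorm(n, sc$lab_mean[i], cfg$lab_sd)
    nonlab_fail <- runif(n) < sc$fail_prob[i]
    enrolled <- lab > cfg$tau_lab & !nonlab_fail
    n_enr <- sum(enrolled)
    v_enr <- lab[enrolled]
    t_scr <- rlnorm(n, sc$dur_meanlog[i], cfg$dur_sdlog)
    agg[[i]] <- data.frame(
      site = sc$site[i], n_screen = n, n_enrolled = n_enr,
      y_fail = n - n_enr,
      y_window = if (n_enr > 0) rbinom(1L, n_enr, 1 - sc$theta[i]) else 0L,
      y_bii = sum(v_enr >= lo & v_enr <= hi), n_bii = n_enr,
      m_shift = rbinom(1L, 1L, sc$drift_prob[i]),
      stringsAsFactors = FALSE)
    labs[[i]] <- if (n_enr > 0) {
      data.frame(site = sc$site[i], lab_value = v_enr,
                 stringsAsFactors = FALSE)
    } else NULL
    times[[i]] <- data.frame(site = sc$site[i], screening_time = t_scr,
                             stringsAsFactors = FALSE)
  }
  agg <- do.call(rbind, agg)
  labs <- do.call(rbind, labs[!vapply(labs, is.null, logical(1))])
  if (is.null(labs)) {
    labs <- data.frame(site = character(), lab_value = numeric(),
                       stringsAsFactors = FALSE)
  }
  times <- do.call(rbind, times)
  rownames(agg) <- rownames(labs) <- rownames(times) <- NULL
  trial <- structure(list(site_agg = agg, labs = labs, times = times,
                          truth = sc, config = cfg,
                          validation = NULL, seed = as.integer(seed)),
                     class = "rbm_trial")
  trial$validation <- validate_dataset(agg, labs, times)
  trial
}

#' Simulate a null trial (no atypical sites)
#'
#' As [simulate_trial()] with the atypical fraction forced to 0; used
#' for false-positive-rate and FDR-calibration checks.
#'
#' @inheritParams simulate_trial
#' @return An `rbm_trial` whose truth labels are all `FALSE`.
#' @export
simulate_null_trial <- function(cfg = trial_config(), seed = 1L) {
  cfg$atypical_frac <- 0
  simulate_trial(cfg, seed)
}

#' @export
print.rbm_trial <- function(x, ...) {
  cat(sprintf("Simulated multicenter trial: %d sites, %d screened, %d enrolled\n",
              nrow(x$site_agg), sum(x$site_agg$n_screen),
              sum(x$site_agg$n_enrolled)))
  if (!is.null(x$truth)) {
    cat(sprintf("Atypical sites (%d): %s\n", sum(x$truth$atypical),
                paste(x$truth$site[x$truth$atypical], collapse = ", ")))
  }
  if (!is.null(x$validation)) {
    cat(sprintf("Validation: %s\n", if (x$validation$pass) "PASS" else "FAIL"))
  }
  invisible(x)
}
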