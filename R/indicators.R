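# The six monitored enrollment-integrity indicators (plus the optional
# benchmark-referenced CMG).  All indicators are risk-aligned: larger
# values mean higher risk.  Count-based indicators pass (y, n) pairs
# through untouched so that Stage-1 Beta posteriors see the raw evidence;
# no point division happens on the pipeline path.

#' Indicator specification table
#'
#' One row per monitored indicator: the Stage-1 likelihood, the monotone
#' transform placing it on an additive scale, and the risk direction
#' (+1 higher-is-risk; adherence-style metrics are realized by counting
#' violations, so every default indicator already points in the +1
#' direction).
#'
#' @param cmg include the optional benchmark-referenced CMG indicator.
#' @return A data.frame with columns `name`, `likelihood`, `transform`,
#'   `direction`.
#' @export
indicator_spec <- function(cmg = FALSE) {
  spec <- data.frame(
    name = c("bii", "fail_rate", "window", "duration", "edd", "sfps"),
    likelihood = c("binomial", "binomial", "binomial", "normal_log",
                   "lognormal_distance", "bernoulli"),
    transform = c("logit", "logit", "logit", "identity", "log", "logit"),
    direction = c(1L, 1L, 1L, 1L, 1L, 1L),
    stringsAsFactors = FALSE)
  if (cmg) {
    spec <- rbind(spec, data.frame(name = "cmg", likelihood = "binomial",
                                   transform = "logit", direction = 1L,
                                   stringsAsFactors = FALSE))
  }
  spec
}

#' Borderline-inclusion configuration
#'
#' @param tau_lab protocol eligibility threshold, in the units of the lab
#'   value (e.g. 60 mL/min for creatinine clearance).
#' @param delta borderline half-width in the same units; the borderline
#'   band is the closed interval `[tau_lab - delta, tau_lab + delta]`.
#'   Defaults to 5% of `tau_lab` when not given.
#' @return A list with elements `tau_lab`, `delta`.
#' @export
bii_config <- function(tau_lab, delta = NULL) {
  delta <- delta %||% (0.05 * tau_lab)
  if (delta <= 0) stopf("delta must be > 0")
  list(tau_lab = tau_lab, delta = delta)
}

#' Distance configuration for the eligibility distribution divergence
#'
#' @param method `"ks"` (two-sample Kolmogorov-Smirnov sup-norm distance,
#'   the default) or `"energy"` (energy distance, sensitive to mean,
#'   variance and shape differences).
#' @param floor positive lower clamp applied to the distance before the
#'   log transform (numerical stability when a resampled distance is 0).
#' @return A list with elements `method`, `floor`.
#' @export
distance_config <- function(method = c("ks", "energy"), floor = 1e-6) {
  method <- match.arg(method)
  if (!(floor > 0)) stopf("floor must be > 0")
  list(method = method, floor = floor)
}

#' Borderline Inclusion Index counts
#'
#' Counts, per site, the enrolled participants whose eligibility value
#' falls in the closed borderline band `[tau_lab - delta, tau_lab + delta]`
#' around the protocol threshold.  A high fraction signals over-reliance
#' on borderline inclusions.
#'
#' @param labs long lab table `(site, lab_value)` of enrolled participants.
#' @param cfg a [bii_config()].
#' @return data.frame `site`, `y_bii` (borderline count), `n_bii`
#'   (assessed count).  Sites with no lab records are excluded with a
#'   warning.
#' @export
compute_bii <- function(labs, cfg) {
  sites <- unique(labs$site)
  lo <- cfg$tau_lab - cfg$delta
  hi <- cfg$tau_lab + cfg$delta
  y <- vapply(sites, function(s) {
    v <- labs$lab_value[labs$site == s]
    sum(v >= lo & v <= hi)
  }, integer(1))
  n <- vapply(sites, function(s) sum(labs$site == s), integer(1))
  keep <- n > 0
  if (any(!keep)) {
    warnf("compute_bii: excluding site(s) with no lab values: %s",
          paste(sites[!keep], collapse = ", "))
  }
  data.frame(site = sites[keep], y_bii = unname(y[keep]),
             n_bii = unname(n[keep]), stringsAsFactors = FALSE)
}

#' Screen-failure rate counts
#'
#' Passes `(y_fail, n_screen)` through for the Stage-1 Beta posterior;
#' the point rate `y_fail / n_screen` is returned only as a summary.
#'
#' @param agg per-site aggregate table.
#' @return data.frame `site`, `y`, `n`, `rate`.  Sites with
#'   `n_screen = 0` are excluded with a warning.
#' @export
compute_fail_rate <- function(agg) {
  keep <- agg$n_screen > 0
  if (any(!keep)) {
    warnf("compute_fail_rate: excluding site(s) with n_screen = 0: %s",
          paste(agg$site[!keep], collapse = ", "))
  }
  data.frame(site = agg$site[keep], y = agg$y_fail[keep],
             n = agg$n_screen[keep],
             rate = agg$y_fail[keep] / agg$n_screen[keep],
             stringsAsFactors = FALSE)
}

#' Window-violation risk counts
#'
#' Window adherence is flipped into a higher-is-risk proportion by
#' counting violations: `y_window` out of `n_enrolled`.
#'
#' @param agg per-site aggregate table.
#' @return data.frame `site`, `y`, `n`, `rate`.  Sites with
#'   `n_enrolled = 0` are excluded with a warning.
#' @export
compute_window_risk <- function(agg) {
  if (any(agg$y_window > agg$n_enrolled)) {
    stopf("y_window exceeds n_enrolled for site(s): %s",
          paste(agg$site[agg$y_window > agg$n_enrolled], collapse = ", "))
  }
  keep <- agg$n_enrolled > 0
  if (any(!keep)) {
    warnf("compute_window_risk: excluding site(s) with n_enrolled = 0: %s",
          paste(agg$site[!keep], collapse = ", "))
  }
  data.frame(site = agg$site[keep], y = agg$y_window[keep],
             n = agg$n_enrolled[keep],
             rate = agg$y_window[keep] / agg$n_enrolled[keep],
             stringsAsFactors = FALSE)
}

#' Median log screening duration
#'
#' The site-level screening-duration statistic: the median of per-screened
#' participant screening times on the log scale.  Even-count medians use
#' the midpoint of the central pair.
#'
#' @param times long table `(site, screening_time)` with strictly positive
#'   times (days).
#' @return data.frame `site`, `median_log_time`.
#' @export
compute_duration_stat <- function(times) {
  if (any(times$screening_time <= 0)) stopf("screening times must be > 0")
  sites <- unique(times$site)
  m <- vapply(sites, function(s) {
    median(log(times$screening_time[times$site == s]))
  }, numeric(1))
  data.frame(site = sites, median_log_time = unname(m),
             stringsAsFactors = FALSE)
}

#' Eligibility distribution divergence
#'
#' Two-sample distance between the focal site's eligibility-value
#' distribution and the pooled distribution of all *other* sites (the
#' focal site must be excluded from the pool by the caller to avoid
#' self-comparison bias).  `"ks"` returns the sup-norm ECDF distance in
#' [0, 1]; `"energy"` returns `2 E|X-Y| - E|X-X'| - E|Y-Y'| >= 0`.
#'
#' @param site_values lab values at the focal site.
#' @param pool_values lab values pooled over the other sites.
#' @param cfg a [distance_config()].
#' @return The nonnegative distance `D_s`.
#' @export
compute_edd <- function(site_values, pool_values, cfg = distance_config()) {
  if (!length(site_values)) stopf("site_values is empty")
  if (!length(pool_values)) {
    stopf("pool of other sites is empty: EDD is undefined for a single-site trial")
  }
  if (cfg$method == "ks") {
    .cpp_ks_stat(as.numeric(site_values), as.numeric(pool_values))
  } else {
    .cpp_energy_stat(as.numeric(site_values), as.numeric(pool_values))
  }
}

#' Screen-failure pattern-shift detector
#'
#' A deliberately simple two-window change detector for one site: periods
#' are split into earlier and later halves, reason counts are pooled
#' within each half, and a Pearson chi-square statistic on the resulting
#' 2 x R table is compared against the upper-`alpha` chi-square quantile
#' with R - 1 degrees of freedom.  Reason categories with zero total
#' count are dropped first.
#'
#' @param reason_counts matrix of per-period screen-failure reason counts
#'   (rows = periods in time order, columns = reason categories).
#' @param alpha significance level of the shift test (default 0.05).
#' @return `m_s`, a binary drift flag in \{0, 1\}.
#' @export
detect_sfps <- function(reason_counts, alpha = 0.05) {
  reason_counts <- as.matrix(reason_counts)
  if (nrow(reason_counts) < 2L) stopf("detect_sfps needs >= 2 periods")
  keep <- colSums(reason_counts) > 0
  reason_counts <- reason_counts[, keep, drop = FALSE]
  if (ncol(reason_counts) < 2L) {
    warnf("detect_sfps: fewer than 2 nonzero reason categories; no composition to shift")
    return(0L)
  }
  p <- nrow(reason_counts)
  early <- seq_len(ceiling(p / 2))
  tab <- rbind(colSums(reason_counts[early, , drop = FALSE]),
               colSums(reason_counts[-early, , drop = FALSE]))
  if (any(rowSums(tab) == 0)) return(0L)
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expd)^2 / expd)
  df <- ncol(tab) - 1L
  as.integer(stat > qchisq(1 - alpha, df))
}

#' Consistency-with-modernized-guidance counts
#'
#' Passes through the per-site count of exclusions attributed to
#' modernized criteria (criteria contemporary guidance deems unnecessarily
#' restrictive, e.g. controlled HIV or stable brain metastases) together
#' with the benchmark proportion `rho0`; Stage 1 centers the logit
#' posterior at `logit(rho0)` so excess exclusion is higher risk.
#'
#' @param y_modern_excl per-site count of modernized-criteria exclusions.
#' @param n_excl per-site total exclusions.
#' @param benchmark expected proportion `rho0` in (0, 1).
#' @param site optional site identifiers.
#' @return data.frame `site`, `y`, `n`, `benchmark`.  Sites with
#'   `n_excl = 0` are excluded with a warning.
#' @export
compute_cmg <- function(y_modern_excl, n_excl, benchmark,
                        site = seq_along(y_modern_excl)) {
  if (!(benchmark > 0 && benchmark < 1)) stopf("benchmark must be in (0, 1)")
  if (any(y_modern_excl < 0 | y_modern_excl > n_excl)) {
    stopf("need 0 <= y_modern_excl <= n_excl")
  }
  keep <- n_excl > 0
  if (any(!keep)) {
    warnf("compute_cmg: excluding site(s) with no exclusions: %s",
          paste(site[!keep], collapse = ", "))
  }
  data.frame(site = as.character(site[keep]), y = y_modern_excl[keep],
             n = n_excl[keep], benchmark = benchmark,
             stringsAsFactors = FALSE)
}
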