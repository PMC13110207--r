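# Dual-key escalation and Bayesian false-discovery-rate control.
#
# A site is escalated only when the composite exceedance probability and
# an operational corroborator both exceed their thresholds (strictly),
# which guards against single-metric anomalies.  The Bayesian FDR of a
# flag set is the posterior expected false-discovery proportion: the
# mean, over flagged sites, of Pr(S_s <= tau | data).

#' Dual-key flag policy
#'
#' @param tau composite threshold for the exceedance key.
#' @param p_star exceedance confidence in (0, 1) (default 0.8): key 1 is
#'   `Pr(S_s > tau) > p_star`.
#' @param corroborator indicator acting as operational corroborator
#'   (default `"fail_rate"`).
#' @param cut threshold on the corroborator's posterior-mean standardized
#'   score (default 0.5): key 2 is `zbar > cut`.
#' @param q Bayesian FDR bound used by [calibrate_policy()].
#' @return A list of class `flag_policy`.
#' @export
flag_policy <- function(tau = 1.5, p_star = 0.8, corroborator = "fail_rate",
                        cut = 0.5, q = 0.10) {
  if (!(p_star > 0 && p_star < 1)) stopf("p_star must be in (0, 1)")
  if (!(q > 0 && q < 1)) stopf("q must be in (0, 1)")
  structure(list(tau = tau, p_star = p_star, corroborator = corroborator,
                 cut = cut, q = q), class = "flag_policy")
}

#' Dual-key flagging
#'
#' Flags site s iff `Pr(S_s > tau | data) > p_star` (strict) AND the
#' corroborator's posterior-mean standardized score exceeds `cut`
#' (strict).  Both key values are reported for every site as an audit
#' trail.  Exceedance probabilities are recomputed from the composite
#' draws at the policy's `tau`.
#'
#' @param result an `rbm_score` object.
#' @param policy a [flag_policy()].
#' @return An object of class `rbm_flags`: data.frame `flags` with
#'   per-site `pr_exceed`, `corroborator_z`, `flagged`; the flagged site
#'   set; and the estimated Bayesian FDR of that set.
#' @export
dual_key_flag <- function(result, policy = flag_policy()) {
  if (!inherits(result, "rbm_score")) {
    stopf("result must be an rbm_score object")
  }
  if (!policy$corroborator %in% colnames(result$comp_means)) {
    stopf("unknown corroborator '%s'; available indicators: %s",
          policy$corroborator,
          paste(colnames(result$comp_means), collapse = ", "))
  }
  pr <- rowMeans(result$S_draws > policy$tau)
  cz <- result$comp_means[, policy$corroborator]
  flagged <- pr > policy$p_star & cz > policy$cut
  flags <- data.frame(site = rownames(result$S_draws),
                      pr_exceed = unname(pr), corroborator_z = unname(cz),
                      flagged = unname(flagged),
                      tau = policy$tau, p_star = policy$p_star,
                      corroborator = policy$corroborator, cut = policy$cut,
                      stringsAsFactors = FALSE)
  fdr <- bayesian_fdr(result, flags$site[flags$flagged], tau = policy$tau)
  structure(list(flags = flags, flagged = flags$site[flags$flagged],
                 fdr = fdr, policy = policy), class = "rbm_flags")
}

#' Bayesian FDR of a candidate flag set
#'
#' The posterior expected false-discovery proportion: the mean over
#' flagged sites of `Pr(S_s <= tau | data)`.  An empty set has FDR 0 by
#' convention (with a warning).
#'
#' @param result an `rbm_score` object.
#' @param candidate_flags character vector of flagged site ids.
#' @param tau composite threshold (defaults to the score's `tau`).
#' @return The estimated Bayesian FDR in [0, 1].
#' @export
bayesian_fdr <- function(result, candidate_flags, tau = NULL) {
  tau <- tau %||% result$cfg$tau
  if (!length(candidate_flags)) {
    warnf("empty flag set: Bayesian FDR defined as 0")
    return(0)
  }
  missing <- setdiff(candidate_flags, rownames(result$S_draws))
  if (length(missing)) {
    stopf("unknown site(s) in flag set: %s", paste(missing, collapse = ", "))
  }
  pr_non <- rowMeans(result$S_draws[candidate_flags, , drop = FALSE] <= tau)
  mean(pr_non)
}

#' Calibrate the dual-key policy against a Bayesian FDR bound
#'
#' Searches a grid of `(tau, p_star)` pairs, keeps those whose dual-key
#' flag set has estimated Bayesian FDR <= q, and among them returns the
#' policy flagging the most sites (ties broken toward larger `p_star`,
#' the more conservative choice).  When no grid point satisfies the
#' bound, a policy flagging nothing is returned with a warning.
#'
#' @param result an `rbm_score` object.
#' @param q Bayesian FDR bound.
#' @param grid data.frame with columns `tau` and `p_star`.
#' @param corroborator,cut corroborator key held fixed during the search.
#' @return The selected [flag_policy()], with attributes `n_flagged` and
#'   `fdr`.
#' @export
calibrate_policy <- function(result, q = 0.10,
                             grid = expand.grid(tau = c(1, 1.5, 2),
                                                p_star = c(0.6, 0.7, 0.8, 0.9)),
                             corroborator = "fail_rate", cut = 0.5) {
  if (!nrow(grid)) stopf("empty calibration grid")
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    pol <- flag_policy(tau = grid$tau[i], p_star = grid$p_star[i],
                       corroborator = corroborator, cut = cut, q = q)
    fr <- suppressWarnings(dual_key_flag(result, pol))
    if (length(fr$flagged) && fr$fdr <= q) {
      cand <- list(policy = pol, n = length(fr$flagged), fdr = fr$fdr)
      if (is.null(best) || cand$n > best$n ||
          (cand$n == best$n && pol$p_star > best$policy$p_star)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    warnf("no grid point satisfies the FDR bound q = %g; returning a policy that flags nothing",
          q)
    pol <- flag_policy(tau = max(grid$tau), p_star = 1 - 1e-9,
                       corroborator = corroborator, cut = cut, q = q)
    attr(pol, "n_flagged") <- 0L
    attr(pol, "fdr") <- 0
    return(pol)
  }
  pol <- best$policy
  attr(pol, "n_flagged") <- best$n
  attr(pol, "fdr") <- best$fdr
  pol
}

#' @export
print.rbm_flags <- function(x, ...) {
  cat(sprintf("Dual-key flag report (tau = %g, p* = %g, corroborator = %s > %g)\n",
              x$policy$tau, x$policy$p_star, x$policy$corroborator,
              x$policy$cut))
  if (length(x$flagged)) {
    cat(sprintf("Flagged sites (%d): %s\n", length(x$flagged),
                paste(x$flagged, collapse = ", ")))
    cat(sprintf("Estimated Bayesian FDR of the flag set: %.3f\n", x$fdr))
  } else {
    cat("No sites flagged.\n")
  }
  invisible(x)
}

#' Write the flag report
#'
#' Writes `flags.csv` with per-site key values, decisions, and the policy
#' parameters echoed as columns.
#'
#' @param flags an `rbm_flags` object.
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
write_flags <- function(flags, path) {
  write.csv(flags$flags, path, row.names = FALSE)
  invisible(path)
}
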