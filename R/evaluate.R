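# Monte-Carlo evaluation harness: operating characteristics of the full
# pipeline (simulate -> indicators -> Stage 1-3 -> classify) against the
# simulator's ground-truth atypical labels.

#' Evaluation configuration
#'
#' @param n_replicates Monte-Carlo replicates (>= 2).
#' @param draws posterior draws per replicate.
#' @param tau standardized composite risk threshold used to classify a
#'   site as atypical.
#' @param rule `"mean"` classifies when the posterior mean composite
#'   exceeds `tau`; `"exceedance"` classifies when
#'   `Pr(S > tau) > p_star`.
#' @param p_star exceedance confidence for `rule = "exceedance"`.
#' @param fixed_config hold the site-level generating configuration
#'   fixed across replicates (fresh participant data each replicate);
#'   required for rank-stability summaries.
#' @param seed master seed; every replicate derives its own substreams.
#' @return A list of class `eval_config`.
#' @export
eval_config <- function(n_replicates = 500L, draws = 1000L, tau = 1.5,
                        rule = c("mean", "exceedance"), p_star = 0.8,
                        fixed_config = FALSE, seed = 1L) {
  rule <- match.arg(rule)
  if (n_replicates < 2) stopf("n_replicates must be >= 2")
  # -Inf/Inf are admitted as degenerate flag-everything/nothing thresholds
  if (is.na(tau)) stopf("tau must be a number")
  structure(list(n_replicates = as.integer(n_replicates),
                 draws = as.integer(draws), tau = tau, rule = rule,
                 p_star = p_star, fixed_config = isTRUE(fixed_config),
                 seed = as.integer(seed)), class = "eval_config")
}

#' Classification operating characteristics for one replicate
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `FDR = FP / max(TP + FP, 1)` (an empty flag set has FDR 0).  When the
#' truth contains no atypical sites, sensitivity is undefined and
#' returned as `NA`.
#'
#' @param flagged character vector of sites classified atypical.
#' @param truth data.frame with columns `site` and `atypical`, covering
#'   all sites.
#' @return Named numeric vector `sensitivity`, `specificity`, `fdr`.
#' @export
classification_metrics <- function(flagged, truth) {
  missing <- setdiff(flagged, truth$site)
  if (length(missing)) {
    stopf("flagged site(s) absent from truth: %s",
          paste(missing, collapse = ", "))
  }
  pos <- truth$site[truth$atypical]
  neg <- truth$site[!truth$atypical]
  tp <- length(intersect(flagged, pos))
  fp <- length(intersect(flagged, neg))
  fn <- length(pos) - tp
  tn <- length(neg) - fp
  c(sensitivity = if (length(pos)) tp / (tp + fn) else NA_real_,
    specificity = if (length(neg)) tn / (tn + fp) else NA_real_,
    fdr = fp / max(tp + fp, 1))
}

#' Ranking stability across replicates
#'
#' Mean pairwise Spearman rank correlation of per-replicate posterior-mean
#' score vectors over a fixed site set (average ranks for ties).
#'
#' @param score_vectors matrix (replicates x sites, identically named
#'   columns) or list of identically named score vectors.
#' @return Mean pairwise Spearman rho.
#' @export
rank_stability <- function(score_vectors) {
  if (is.list(score_vectors) && !is.data.frame(score_vectors)) {
    sets <- lapply(score_vectors, names)
    if (length(unique(vapply(sets, paste, character(1), collapse = "\r"))) != 1L) {
      stopf("replicates must cover identical site sets")
    }
    score_vectors <- do.call(rbind, score_vectors)
  }
  if (nrow(score_vectors) < 2L) stopf("need >= 2 replicates")
  rho <- cor(t(score_vectors), method = "spearman")
  mean(rho[upper.tri(rho)])
}

#' Run the Monte-Carlo evaluation
#'
#' Per replicate: simulate a trial, run the full scoring pipeline, and
#' classify each site as atypical when its posterior mean composite
#' exceeds `eval_cfg$tau` (or by exceedance probability, per the rule);
#' score the classification against the known truth.  Aggregates
#' sensitivity, specificity and FDR with Monte-Carlo standard errors,
#' plus rank stability and top-rank capture when the site configuration
#' is held fixed.
#'
#' @param trial_cfg a [trial_config()].
#' @param eval_cfg an [eval_config()].
#' @param weights fixed indicator weights (default uniform).
#' @param cfg a [composite_config()]; its `tau` is aligned with
#'   `eval_cfg$tau`.
#' @param null_truth evaluate against a null simulator
#'   ([simulate_null_trial()]).
#' @param progress print a progress line every 50 replicates.
#' @return An object of class `rbm_eval`: `metrics` (mean and MC
#'   standard error for each operating characteristic), `replicates`
#'   (per-replicate long table), `rank_stability` and `top_capture`
#'   (fixed-config runs only), and the score matrix.
#' @export
run_replicates <- function(trial_cfg = trial_config(),
                           eval_cfg = eval_config(), weights = NULL,
                           cfg = composite_config(), null_truth = FALSE,
                           progress = FALSE) {
  R <- eval_cfg$n_replicates
  cfg$tau <- eval_cfg$tau
  site_config <- NULL
  if (eval_cfg$fixed_config) {
    set.seed(substream_seed(eval_cfg$seed, 0L, 3L))
    if (null_truth) trial_cfg$atypical_frac <- 0
    site_config <- draw_site_config(trial_cfg)
  }
  res <- vector("list", R)
  scores <- NULL
  for (r in seq_len(R)) {
    sim_seed <- substream_seed(eval_cfg$seed, r, 1L)
    trial <- tryCatch({
      if (null_truth && !eval_cfg$fixed_config) {
        simulate_null_trial(trial_cfg, sim_seed)
      } else {
        simulate_trial(trial_cfg, sim_seed, site_config = site_config)
      }
    }, error = function(e) {
      stopf("replicate %d (seed %d) failed in simulation: %s", r, sim_seed,
            conditionMessage(e))
    })
    fit <- tryCatch(
      suppressWarnings(rbm_score(
        trial, weights = weights, cfg = cfg,
        prior = prior_config(draws = eval_cfg$draws,
                             seed = substream_seed(eval_cfg$seed, r, 2L)))),
      error = function(e) {
        stopf("replicate %d (seed %d) failed in scoring: %s", r, sim_seed,
              conditionMessage(e))
      })
    flagged <- if (eval_cfg$rule == "mean") {
      fit$summary$site[fit$summary$mean_S > eval_cfg$tau]
    } else {
      fit$summary$site[fit$summary$pr_exceed > eval_cfg$p_star]
    }
    m <- classification_metrics(flagged, trial$truth)
    res[[r]] <- data.frame(replicate = r, sensitivity = m[["sensitivity"]],
                           specificity = m[["specificity"]],
                           fdr = m[["fdr"]], n_flagged = length(flagged))
    if (eval_cfg$fixed_config) {
      v <- structure(fit$summary$mean_S, names = fit$summary$site)
      if (is.null(scores)) {
        scores <- matrix(NA_real_, R, length(v),
                         dimnames = list(NULL, names(v)))
      }
      scores[r, names(v)] <- v
    }
    if (progress && r %% 50 == 0) {
      message(sprintf("replicate %d / %d", r, R))
    }
  }
  rep_tab <- do.call(rbind, res)
  agg <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(mean = NA_real_, se = NA_real_))
    c(mean = mean(x), se = sd(x) / sqrt(length(x)))
  }
  metrics <- rbind(sensitivity = agg(rep_tab$sensitivity),
                   specificity = agg(rep_tab$specificity),
                   fdr = agg(rep_tab$fdr))
  out <- list(metrics = as.data.frame(metrics), replicates = rep_tab,
              rank_stability = NULL, top_capture = NULL, scores = scores,
              trial_cfg = trial_cfg, eval_cfg = eval_cfg)
  if (eval_cfg$fixed_config && !is.null(scores) && !anyNA(scores)) {
    out$rank_stability <- rank_stability(scores)
    truth_atyp <- site_config$site[site_config$atypical]
    if (length(truth_atyp)) {
      # "ranking accuracy" companion: probability that every truly
      # atypical site ranks within the top 2 x (true count)
      lim <- 2L * length(truth_atyp)
      hit <- apply(scores, 1, function(v) {
        all(truth_atyp %in% names(sort(v, decreasing = TRUE))[seq_len(lim)])
      })
      out$top_capture <- mean(hit)
    }
  }
  structure(out, class = "rbm_eval")
}

#' @export
print.rbm_eval <- function(x, ...) {
  cat(sprintf("Monte-Carlo operating characteristics (%d replicates, %d sites, tau = %g, rule = %s)\n",
              x$eval_cfg$n_replicates, x$trial_cfg$n_sites, x$eval_cfg$tau,
              x$eval_cfg$rule))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    if (is.na(m$mean[i])) {
      cat(sprintf("  %-12s undefined (no qualifying replicates)\n",
                  rownames(m)[i]))
    } else {
      cat(sprintf("  %-12s %.3f (MC se %.4f)\n", rownames(m)[i],
                  m$mean[i], m$se[i]))
    }
  }
  if (!is.null(x$rank_stability)) {
    cat(sprintf("  %-12s %.3f (mean pairwise Spearman rho)\n",
                "stability", x$rank_stability))
  }
  if (!is.null(x$top_capture)) {
    cat(sprintf("  %-12s %.3f (all atypical in top 2x)\n", "top-capture",
                x$top_capture))
  }
  invisible(x)
}

#' Write evaluation metrics
#'
#' Writes `metrics.csv` (aggregates) and, optionally, the per-replicate
#' long table for audit.
#'
#' @param eval an `rbm_eval` object.
#' @param dir output directory.
#' @param replicates also write `replicates.csv`.
#' @return Invisibly, the paths written.
#' @export
write_eval_outputs <- function(eval, dir, replicates = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- data.frame(metric = rownames(eval$metrics), eval$metrics,
                  stringsAsFactors = FALSE)
  if (!is.null(eval$rank_stability)) {
    m <- rbind(m, data.frame(metric = "rank_stability",
                             mean = eval$rank_stability, se = NA_real_))
  }
  paths <- c(metrics = file.path(dir, "metrics.csv"))
  write.csv(m, paths[["metrics"]], row.names = FALSE)
  if (replicates) {
    paths <- c(paths, replicates = file.path(dir, "replicates.csv"))
    write.csv(eval$replicates, paths[["replicates"]], row.names = FALSE)
  }
  invisible(paths)
}
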