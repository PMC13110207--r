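# The central fitting function: the three-stage posterior composite.

#' Fit the composite Bayesian site risk score
#'
#' Runs the full three-stage pipeline on a trial dataset:
#' \enumerate{
#'   \item \strong{Stage 1} — per-site posterior draws for the six
#'     indicators: conjugate Beta posteriors (logit scale) for BII,
#'     screen-failure rate, window violations and the SFPS drift flag;
#'     bootstrap draws for the median log screening duration and the log
#'     site-vs-pool eligibility distance.
#'   \item \strong{Stage 2} — robust standardization of every draw using
#'     the median and 1.4826*MAD of the site-level posterior-mean
#'     anchors (SD fallback when the MAD is 0).
#'   \item \strong{Stage 3} — composite score per draw (linear, softmax
#'     or geometric-mean aggregation; fixed weights or Dirichlet weight
#'     draws paired 1:1 with score draws), summarized by posterior mean,
#'     95% credible interval, `Pr(S > tau)` and `Pr(Top-K)`.
#' }
#'
#' @param trial an `rbm_trial` ([simulate_trial()], [read_trial()]) or a
#'   list with `site_agg`, `labs`, `times`.
#' @param weights fixed indicator weights (any nonnegative vector;
#'   auto-normalized to the simplex).  Default: uniform.
#' @param alpha optional Dirichlet concentrations; when given, weight
#'   uncertainty is propagated by pairing weight draw m with score draw m.
#' @param cfg a [composite_config()] (aggregation mode, `tau`, `top_k`).
#' @param prior a [prior_config()] (Beta prior, number of draws, seed).
#' @param dist_cfg a [distance_config()] for the EDD indicator.
#' @param seed optional master seed overriding `prior$seed`.
#' @return An object of class `rbm_score` with components `summary`
#'   (per-site posterior summaries), `comp_means` (posterior-mean
#'   standardized component scores), `contributions` (`w_k * zbar`),
#'   `S_draws`, `rank_draws`, `weights`, `std` (center/scale), `stage1`,
#'   and the configurations used.
#' @seealso [dual_key_flag()], [plot.rbm_score()], [write_score_outputs()]
#' @examples
#' trial <- simulate_trial(trial_config(n_sites = 12), seed = 42)
#' fit <- rbm_score(trial, prior = prior_config(draws = 400, seed = 42))
#' fit
#' head(as.data.frame(fit))
#' @export
rbm_score <- function(trial, weights = NULL, alpha = NULL,
                      cfg = composite_config(), prior = prior_config(),
                      dist_cfg = distance_config(), seed = NULL) {
  if (!is.null(seed)) prior$seed <- as.integer(seed)
  st1 <- stage1_draws(trial, prior = prior, dist_cfg = dist_cfg)
  K <- ncol(st1$anchors)
  ind_names <- colnames(st1$anchors)

  std <- fit_standardization(st1$anchors)
  z_std <- standardize_draws(st1$draws, std)

  weight_draws <- NULL
  if (!is.null(alpha)) {
    if (length(alpha) != K) stopf("alpha length must equal indicator count (%d)", K)
    weight_draws <- sample_weights(alpha, M = st1$M,
                                   seed = substream_seed(prior$seed, 0L, 99L))
    w_mean <- colMeans(weight_draws)
  } else {
    weights <- weights %||% rep(1, K)
    if (length(weights) != K) {
      stopf("weights length must equal indicator count (%d)", K)
    }
    if (any(weights < 0)) stopf("weights must be nonnegative")
    w_mean <- weights / sum(weights)
  }
  names(w_mean) <- ind_names

  S_draws <- .compose_draws(z_std, w_mean, weight_draws, cfg)
  rownames(S_draws) <- st1$sites

  summ <- summarize_composite(S_draws, cfg)
  comp_means <- vapply(z_std, rowMeans, numeric(length(st1$sites)))
  rownames(comp_means) <- st1$sites
  contributions <- sweep(comp_means, 2, w_mean, `*`)

  structure(list(summary = summ$summary, rank_draws = summ$rank_draws,
                 S_draws = S_draws, comp_means = comp_means,
                 contributions = contributions, weights = w_mean,
                 weight_draws = weight_draws, std = std, stage1 = st1,
                 cfg = cfg, prior = prior, dist_cfg = dist_cfg),
            class = "rbm_score")
}

# Per-draw composite over a list of standardized draw matrices.  With
# Dirichlet weight draws, weight draw m multiplies score draw m.
.compose_draws <- function(z_std, w, weight_draws, cfg) {
  S <- nrow(z_std[[1]]); M <- ncol(z_std[[1]])
  wk <- function(k) {
    if (is.null(weight_draws)) w[k]
    else matrix(weight_draws[, k], S, M, byrow = TRUE)
  }
  if (cfg$mode == "linear") {
    out <- matrix(0, S, M)
    for (k in seq_along(z_std)) out <- out + z_std[[k]] * wk(k)
    out
  } else if (cfg$mode == "softmax") {
    A <- lapply(seq_along(z_std), function(k) cfg$lambda * wk(k) * z_std[[k]])
    amax <- Reduce(pmax, A)
    acc <- matrix(0, S, M)
    for (a in A) acc <- acc + exp(a - amax)
    (amax + log(acc)) / cfg$lambda
  } else {
    out <- matrix(0, S, M)
    for (k in seq_along(z_std)) {
      zk <- z_std[[k]]
      if (any(cfg$shift + zk <= 0)) {
        bad <- which(cfg$shift + zk <= 0, arr.ind = TRUE)[1, ]
        stopf("geometric composite undefined: c + z <= 0 (site row %d, draw %d); increase shift c",
              bad[1], bad[2])
      }
      out <- out + log(cfg$shift + zk) * wk(k)
    }
    exp(out) - cfg$shift
  }
}

#' @export
print.rbm_score <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Composite Bayesian site risk score (%d sites, %d indicators, %d draws)\n",
              nrow(s), length(x$weights), ncol(x$S_draws)))
  cat(sprintf("Aggregation: %s;  tau = %g;  Top-K = %d\n",
              x$cfg$mode, x$cfg$tau, x$cfg$top_k))
  cat(sprintf("Weights: %s\n",
              paste(sprintf("%s=%.3f", names(x$weights), x$weights),
                    collapse = ", ")))
  top <- s[order(s$rank), ][seq_len(min(5L, nrow(s))), ]
  cat("Highest-risk sites (by posterior mean):\n")
  print(format(top, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
summary.rbm_score <- function(object, ...) {
  out <- object$summary[order(object$summary$rank), ]
  rownames(out) <- NULL
  structure(list(table = out, weights = object$weights,
                 std = object$std, cfg = object$cfg),
            class = "summary.rbm_score")
}

#' @export
print.summary.rbm_score <- function(x, ...) {
  cat("Per-site posterior summaries (ordered by posterior mean):\n")
  print(format(x$table, digits = 3), row.names = FALSE)
  cat(sprintf("\nStandardization centers: %s\n",
              paste(sprintf("%s=%.3f", names(x$std$center), x$std$center),
                    collapse = ", ")))
  cat(sprintf("Standardization scales:  %s\n",
              paste(sprintf("%s=%.3f", names(x$std$scale), x$std$scale),
                    collapse = ", ")))
  invisible(x)
}

#' @export
coef.rbm_score <- function(object, ...) {
  structure(object$summary$mean_S, names = object$summary$site)
}

#' @export
as.data.frame.rbm_score <- function(x, ...) x$summary

#' Plot a fitted site risk score
#'
#' `type = "forest"`: posterior mean with 95% credible interval per site,
#' ordered by rank.  `type = "heatmap"`: weighted component contributions
#' (diverging around 0) by site and indicator.  `type = "drivers"`:
#' component contributions for the `n_top` highest-risk sites.
#'
#' @param x an `rbm_score` object.
#' @param type `"forest"`, `"heatmap"` or `"drivers"`.
#' @param n_top number of sites shown by `"drivers"`.
#' @param ... passed to the underlying graphics calls.
#' @return Invisibly, `x`.
#' @export
plot.rbm_score <- function(x, type = c("forest", "heatmap", "drivers"),
                           n_top = 4L, ...) {
  type <- match.arg(type)
  s <- x$summary[order(x$summary$rank, decreasing = TRUE), ]
  if (type == "forest") {
    n <- nrow(s)
    plot(s$mean_S, seq_len(n), xlim = range(c(s$crI_lo, s$crI_hi)),
         yaxt = "n", xlab = "Composite risk score S (posterior mean, 95% CrI)",
         ylab = "", pch = 19, ...)
    segments(s$crI_lo, seq_len(n), s$crI_hi, seq_len(n))
    axis(2, at = seq_len(n), labels = s$site, las = 2, cex.axis = 0.6)
    abline(v = x$cfg$tau, lty = 2)
  } else if (type == "heatmap") {
    m <- x$contributions[s$site, , drop = FALSE]
    image(seq_len(ncol(m)), seq_len(nrow(m)), t(m), xaxt = "n", yaxt = "n",
          xlab = "", ylab = "", ...)
    axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
         cex.axis = 0.7)
    axis(2, at = seq_len(nrow(m)), labels = rownames(m), las = 2,
         cex.axis = 0.6)
  } else {
    top <- x$summary[order(x$summary$rank), ][seq_len(min(n_top, nrow(s))), ]
    old <- par(mfrow = c(1, nrow(top)))
    on.exit(par(old))
    for (i in seq_len(nrow(top))) {
      contr <- x$contributions[top$site[i], ]
      contr <- contr[order(abs(contr))]
      barplot(contr, horiz = TRUE, las = 1, main = top$site[i],
              cex.names = 0.7, ...)
      abline(v = 0)
    }
  }
  invisible(x)
}

#' Write the standard score exports
#'
#' Writes `site_summary.csv`, `component_means.csv` and
#' `posterior_draws.csv` into `dir`.
#'
#' @param score an `rbm_score` object.
#' @param dir output directory (created if needed).
#' @param draws also write the (large) long-format posterior draws.
#' @return Invisibly, the paths written.
#' @export
write_score_outputs <- function(score, dir, draws = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(site_summary = file.path(dir, "site_summary.csv"),
             component_means = file.path(dir, "component_means.csv"))
  write.csv(score$summary, paths[["site_summary"]], row.names = FALSE)
  cm <- data.frame(site = rownames(score$comp_means), score$comp_means,
                   stringsAsFactors = FALSE, check.names = FALSE)
  write.csv(cm, paths[["component_means"]], row.names = FALSE)
  if (draws) {
    paths <- c(paths, posterior_draws = file.path(dir, "posterior_draws.csv"))
    write_posterior_draws(score, paths[["posterior_draws"]])
  }
  invisible(paths)
}
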