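# Shared fixtures and independent oracles, built in code.

# A small, fully consistent trial built by hand (3 sites).
tiny_trial <- function() {
  agg <- data.frame(
    site = c("A", "B", "C"),
    n_screen = c(10L, 8L, 12L),
    n_enrolled = c(6L, 5L, 9L),
    y_fail = c(4L, 3L, 3L),
    y_window = c(1L, 0L, 2L),
    y_bii = c(2L, 1L, 0L),
    n_bii = c(6L, 5L, 9L),
    m_shift = c(0L, 1L, 0L),
    stringsAsFactors = FALSE)
  set.seed(5)
  labs <- data.frame(
    site = rep(agg$site, agg$n_enrolled),
    lab_value = round(rnorm(sum(agg$n_enrolled), 80, 15), 2),
    stringsAsFactors = FALSE)
  times <- data.frame(
    site = rep(agg$site, agg$n_screen),
    screening_time = round(rlnorm(sum(agg$n_screen), log(7), 0.4), 3),
    stringsAsFactors = FALSE)
  list(site_agg = agg, labs = labs, times = times)
}

# Independent brute-force oracles for the two-sample distances.
ks_oracle <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  fx <- vapply(grid, function(g) mean(x <= g), numeric(1))
  fy <- vapply(grid, function(g) mean(y <= g), numeric(1))
  max(abs(fx - fy))
}

energy_oracle <- function(x, y) {
  exy <- mean(outer(x, y, function(a, b) abs(a - b)))
  exx <- mean(outer(x, x, function(a, b) abs(a - b)))
  eyy <- mean(outer(y, y, function(a, b) abs(a - b)))
  2 * exy - exx - eyy
}

# All multisets of a given size over a small support.
multisets <- function(support, size) {
  idx <- do.call(expand.grid, rep(list(seq_along(support)), size))
  idx <- idx[!apply(idx, 1, is.unsorted), , drop = FALSE]
  lapply(seq_len(nrow(idx)), function(i) support[as.integer(idx[i, ])])
}

# Minimal stand-in for an rbm_score object with prescribed composite
# draws and component means (for exact flagging arithmetic).
fake_score <- function(S_draws, comp_means = NULL, tau = 1.5) {
  sites <- rownames(S_draws)
  if (is.null(comp_means)) {
    comp_means <- matrix(0, nrow(S_draws), 1,
                         dimnames = list(sites, "fail_rate"))
  }
  structure(list(S_draws = S_draws, comp_means = comp_means,
                 summary = data.frame(site = sites,
                                      mean_S = rowMeans(S_draws)),
                 cfg = composite_config(tau = tau)),
            class = "rbm_score")
}
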