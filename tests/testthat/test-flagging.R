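test_that("dual-key rule follows its truth table with strict inequalities", {
  M <- 200
  # pr_exceed at tau=1.5: A 0.9, B 0.9, C 0.7
  mk <- function(p) c(rep(2, round(p * M)), rep(0, M - round(p * M)))
  S <- rbind(A = mk(0.9), B = mk(0.9), C = mk(0.7))
  cm <- matrix(c(0.6, 0.4, 0.9), 3, 1,
               dimnames = list(c("A", "B", "C"), "fail_rate"))
  sc <- fake_score(S, cm)
  fr <- suppressWarnings(
    dual_key_flag(sc, flag_policy(tau = 1.5, p_star = 0.8, cut = 0.5)))
  expect_identical(fr$flagged, "A")            # both keys pass
  tab <- fr$flags
  expect_false(tab$flagged[tab$site == "B"])   # corroborator fails
  expect_false(tab$flagged[tab$site == "C"])   # exceedance fails
  expect_equal(tab$pr_exceed, c(0.9, 0.9, 0.7))
  expect_error(dual_key_flag(sc, flag_policy(corroborator = "nope")),
               "available indicators")
})

test_that("Bayesian FDR is the mean posterior non-exceedance of the flag set", {
  M <- 100
  mk <- function(p_non) c(rep(0, round(p_non * M)),
                          rep(2, M - round(p_non * M)))
  S <- rbind(A = mk(0.05), B = mk(0.15), C = mk(0.5), D = mk(0))
  sc <- fake_score(S, tau = 1.5)
  expect_equal(bayesian_fdr(sc, c("A", "B"), tau = 1.5), 0.10)
  expect_equal(bayesian_fdr(sc, "D", tau = 1.5), 0)
  expect_equal(bayesian_fdr(sc, "C", tau = 1.5), 0.5)
  expect_warning(f0 <- bayesian_fdr(sc, character(0)), "empty")
  expect_equal(f0, 0)
  expect_error(bayesian_fdr(sc, "ZZ", tau = 1.5), "unknown site")
})

test_that("raising either key threshold never adds a flag", {
  set.seed(12)
  S <- matrix(rnorm(10 * 400, mean = rep(seq(-1, 2.5, length.out = 10), 400)),
              10, dimnames = list(sprintf("S%02d", 1:10)))
  cm <- matrix(rnorm(10), 10, 1,
               dimnames = list(rownames(S), "fail_rate"))
  sc <- fake_score(S, cm)
  prev_by_p <- NULL
  for (p in c(0.5, 0.6, 0.7, 0.8, 0.9)) {
    fl <- suppressWarnings(
      dual_key_flag(sc, flag_policy(tau = 0.5, p_star = p, cut = 0)))$flagged
    if (!is.null(prev_by_p)) expect_true(all(fl %in% prev_by_p))
    prev_by_p <- fl
  }
  prev_by_c <- NULL
  for (cc in c(-1, -0.5, 0, 0.5, 1)) {
    fl <- suppressWarnings(
      dual_key_flag(sc, flag_policy(tau = 0.5, p_star = 0.6, cut = cc)))$flagged
    if (!is.null(prev_by_c)) expect_true(all(fl %in% prev_by_c))
    prev_by_c <- fl
  }
})

test_that("any key-1 flag set has Bayesian FDR at most 1 - p_star", {
  set.seed(13)
  for (i in 1:10) {
    S <- matrix(rnorm(8 * 300, rep(rnorm(8, 0.5, 1), 300)), 8,
                dimnames = list(sprintf("S%02d", 1:8)))
    sc <- fake_score(S)
    p_star <- runif(1, 0.5, 0.95)
    pr <- rowMeans(S > 1)
    key1 <- rownames(S)[pr > p_star]
    if (length(key1)) {
      expect_lte(bayesian_fdr(sc, key1, tau = 1), 1 - p_star)
    }
  }
})

test_that("policy calibration maximizes flags under the FDR bound", {
  M <- 200
  mk <- function(p) c(rep(2, round(p * M)), rep(0, M - round(p * M)))
  S <- rbind(A = mk(0.99), B = mk(0.95), C = mk(0.85), D = mk(0.2))
  cm <- matrix(1, 4, 1, dimnames = list(rownames(S), "fail_rate"))
  sc <- fake_score(S, cm)
  grid <- expand.grid(tau = 1.5, p_star = c(0.6, 0.8, 0.9))

  pol <- calibrate_policy(sc, q = 0.10, grid = grid, cut = 0.5)
  expect_equal(attr(pol, "n_flagged"), 3L)
  expect_lte(attr(pol, "fdr"), 0.10)

  # q = 1: the bound is vacuous, keep the point flagging the most sites
  pol1 <- calibrate_policy(sc, q = 0.999, grid = grid, cut = 0.5)
  expect_equal(attr(pol1, "n_flagged"), 3L)
  expect_equal(pol1$p_star, 0.8)  # tie on count broken toward larger p*

  # an unattainable bound flags nothing, with a warning
  expect_warning(pol0 <- calibrate_policy(sc, q = 1e-6, grid = grid),
                 "flags nothing")
  expect_equal(attr(pol0, "n_flagged"), 0L)
})

test_that("flag reports echo policy parameters in the export", {
  S <- rbind(A = rep(2, 100), B = rep(0, 100))
  cm <- matrix(c(1, -1), 2, 1, dimnames = list(c("A", "B"), "fail_rate"))
  fr <- suppressWarnings(dual_key_flag(fake_score(S, cm), flag_policy()))
  path <- withr::local_tempfile(fileext = ".csv")
  write_flags(fr, path)
  back <- read.csv(path)
  expect_identical(names(back),
                   c("site", "pr_exceed", "corroborator_z", "flagged",
                     "tau", "p_star", "corroborator", "cut"))
  expect_identical(back$flagged, c(TRUE, FALSE))
})
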