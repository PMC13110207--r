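test_that("robust standardization uses median and 1.4826*MAD with fallbacks", {
  a <- cbind(k1 = c(1, 2, 3, 4, 5))
  p <- fit_standardization(a)
  expect_equal(unname(p$center), 3)
  expect_equal(unname(p$scale), 1.4826)  # MAD of {2,1,0,1,2} is 1

  expect_warning(p2 <- fit_standardization(cbind(k1 = rep(2, 4))),
                 "constant")
  expect_equal(unname(p2$scale), 1)

  p3 <- fit_standardization(cbind(k1 = c(0, 0, 0, 100)))
  expect_equal(unname(p3$center), 0)
  expect_equal(unname(p3$scale), 50)  # MAD 0 -> SD fallback

  expect_error(fit_standardization(cbind(k1 = 1)), "single site")
})

test_that("standardization is the stated affine map and centers anchors", {
  p <- list(center = c(k1 = 0), scale = c(k1 = 2))
  expect_equal(standardize_draws(matrix(3), p, "k1"), matrix(1.5))
  expect_equal(standardize_draws(matrix(0), p, "k1"), matrix(0))
  expect_error(standardize_draws(matrix(1), p, "zz"), "missing")

  set.seed(2)
  anchors <- cbind(a = rnorm(9), b = runif(9))
  prm <- fit_standardization(anchors)
  z <- standardize_draws(list(a = anchors[, "a", drop = FALSE],
                              b = anchors[, "b", drop = FALSE]), prm)
  expect_equal(median(z$a), 0)
  expect_equal(median(z$b), 0)
})

test_that("composite modes evaluate their closed forms on the toy example", {
  z <- c(1.0, 0.0, 2.0, -1.0)
  w <- rep(0.25, 4)
  expect_identical(compose(z, w, composite_config("linear")), 0.5)

  # softmax at lambda = 2, evaluated directly from its formula
  manual <- log(sum(exp(2 * w * z))) / 2
  expect_equal(compose(z, w, composite_config("softmax", lambda = 2)),
               manual)
  expect_equal(manual, 0.8937, tolerance = 1e-4)

  expect_equal(compose(z, w, composite_config("geomean", shift = 2)),
               24^0.25 - 2)
  expect_error(compose(z, w, composite_config("geomean", shift = 0.5)),
               "c \\+ z <= 0")
})

test_that("softmax bounds and temperature limits hold", {
  set.seed(6)
  for (i in 1:20) {
    z <- rnorm(5, 0, 2)
    w <- as.vector(sample_weights(rep(1, 5), 1, seed = i))
    hi <- max(w * z)
    vals <- vapply(c(0.5, 1, 2, 4, 8, 32, 128), function(l)
      compose(z, w, composite_config("softmax", lambda = l)), numeric(1))
    expect_true(all(vals >= hi - 1e-12))
    expect_true(all(diff(vals) <= 1e-12))  # nonincreasing in lambda
    expect_equal(vals[length(vals)], hi, tolerance = 1e-2)
  }
})

test_that("linear composite is permutation-equivariant and ignores zero weights", {
  set.seed(7)
  z <- matrix(rnorm(30), 6, 5)
  w <- c(0.4, 0.1, 0.2, 0.2, 0.1)
  s0 <- compose(z, w, composite_config())
  perm <- sample(5)
  expect_equal(compose(z[, perm], w[perm], composite_config()), s0)
  expect_equal(compose(cbind(z, rnorm(6)), c(w, 0), composite_config()), s0)
})

test_that("geometric composite returns a common score unchanged", {
  for (z0 in c(-0.5, 0, 1.7)) {
    expect_equal(compose(rep(z0, 4), rep(0.25, 4),
                         composite_config("geomean", shift = 3)), z0)
  }
})

test_that("Dirichlet weights live on the simplex with mean alpha/sum(alpha)", {
  w <- sample_weights(c(4, 2, 1), M = 10000, seed = 13)
  expect_true(all(w >= 0))
  expect_equal(rowSums(w), rep(1, nrow(w)), tolerance = 1e-12)
  expect_equal(colMeans(w), c(4, 2, 1) / 7, tolerance = 0.01)
  w2 <- sample_weights(c(1, 1, 1), M = 10000, seed = 14)
  expect_equal(colMeans(w2), rep(1 / 3, 3), tolerance = 0.01)
  expect_error(sample_weights(c(1, 0), 10), "> 0")
})

test_that("dispersion weights reward spread and degrade gracefully", {
  a <- cbind(flat = rep(1, 6), spread = c(1, 2, 3, 4, 5, 6))
  w <- entropy_weights(a)
  expect_equal(unname(w["flat"]), 0)
  expect_equal(unname(w["spread"]), 1)

  b <- cbind(x = c(1, 2, 3, 4), y = c(4, 3, 2, 1))
  expect_equal(unname(entropy_weights(b)), c(0.5, 0.5))

  # dispersions 1 and 3 (MAD-proportional) -> weights 0.25 / 0.75
  cc <- cbind(x = c(-1, 0, 1), y = c(-3, 0, 3))
  expect_equal(unname(entropy_weights(cc)), c(0.25, 0.75))

  expect_warning(wu <- entropy_weights(cbind(x = rep(1, 3), y = rep(2, 3))),
                 "uniform")
  expect_equal(unname(wu), c(0.5, 0.5))
})

test_that("composite summaries report exceedance, intervals and valid ranks", {
  S <- rbind(A = c(0, 1, 2, 3), B = c(2, 2, 2, 2))
  S <- S[, rep(1:4, 50)]  # 200 draws
  out <- summarize_composite(S, composite_config(tau = 1.5, top_k = 1))
  expect_equal(out$summary$pr_exceed[out$summary$site == "A"], 0.5)
  expect_equal(out$summary$crI_lo[out$summary$site == "B"], 2)
  expect_equal(out$summary$crI_hi[out$summary$site == "B"], 2)

  # a site strictly highest in every draw owns Top-1
  S2 <- rbind(A = rep(5, 200), B = rnorm(200), C = rnorm(200))
  out2 <- summarize_composite(S2, composite_config(tau = 0, top_k = 1))
  expect_equal(out2$summary$pr_topk[out2$summary$site == "A"], 1)
  expect_equal(sum(out2$summary$pr_topk[out2$summary$site != "A"]), 0)
})

test_that("per-draw ranks are permutations and Top-K probabilities sum to K", {
  set.seed(9)
  S <- matrix(rnorm(12 * 300), 12, dimnames = list(sprintf("S%02d", 1:12)))
  for (K in c(1, 3, 5)) {
    out <- summarize_composite(S, composite_config(tau = 0.5, top_k = K))
    expect_true(all(apply(out$rank_draws, 2, sort) == seq_len(12)))
    expect_lt(abs(sum(out$summary$pr_topk) - K), 1e-10)
  }
})
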