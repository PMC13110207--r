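test_that("borderline inclusion counts use the closed band", {
  labs <- data.frame(site = "A", lab_value = c(61, 75, 90, 62))
  cfg <- bii_config(tau_lab = 60, delta = 5)
  out <- compute_bii(labs, cfg)
  expect_equal(out$y_bii, 2L)
  expect_equal(out$n_bii, 4L)

  # everything far above the band
  labs2 <- data.frame(site = "A", lab_value = c(71, 80, 95))
  expect_equal(compute_bii(labs2, cfg)$y_bii, 0L)

  # the band is closed: a value exactly at tau + delta is borderline
  labs3 <- data.frame(site = "A", lab_value = c(65, 55))
  expect_equal(compute_bii(labs3, cfg)$y_bii, 2L)
})

test_that("borderline counts are order-invariant and monotone in delta", {
  set.seed(3)
  vals <- rnorm(40, 62, 6)
  labs <- data.frame(site = "A", lab_value = vals)
  labs_perm <- labs[sample(nrow(labs)), ]
  for (d in c(1, 2, 5, 8)) {
    cfg <- bii_config(60, d)
    expect_equal(compute_bii(labs, cfg)$y_bii,
                 compute_bii(labs_perm, cfg)$y_bii)
  }
  ys <- vapply(c(0.5, 1, 2, 4, 8, 16),
               function(d) compute_bii(labs, bii_config(60, d))$y_bii,
               integer(1))
  expect_true(all(diff(ys) >= 0))
})

test_that("count indicators pass evidence through and drop empty sites", {
  agg <- data.frame(site = c("A", "B"), n_screen = c(20L, 0L),
                    n_enrolled = c(15L, 0L), y_fail = c(5L, 0L),
                    y_window = c(2L, 0L), y_bii = c(1L, 0L),
                    n_bii = c(15L, 0L), m_shift = c(0L, 0L))
  expect_warning(fr <- compute_fail_rate(agg), "n_screen = 0")
  expect_equal(fr$rate, 0.25)
  expect_equal(fr$y, 5L)
  expect_warning(wr <- compute_window_risk(agg), "n_enrolled = 0")
  expect_equal(wr$rate, 2 / 15)

  agg$y_fail <- c(0L, 0L); agg$n_screen <- c(20L, 10L)
  expect_equal(compute_fail_rate(agg)$rate, c(0, 0))
  agg$y_fail <- agg$n_screen
  expect_equal(compute_fail_rate(agg)$rate, c(1, 1))
})

test_that("duration statistic is the median of log times", {
  times <- data.frame(site = "A", screening_time = exp(c(1, 2, 3)))
  expect_equal(compute_duration_stat(times)$median_log_time, 2)
  expect_equal(compute_duration_stat(
    data.frame(site = "A", screening_time = exp(5)))$median_log_time, 5)
  expect_equal(compute_duration_stat(
    data.frame(site = "A", screening_time = rep(1, 4)))$median_log_time, 0)
  # even count: midpoint of the central pair (of logs)
  times4 <- data.frame(site = "A", screening_time = exp(c(1, 2, 4, 9)))
  expect_equal(compute_duration_stat(times4)$median_log_time, 3)
})

test_that("distance statistics match brute-force oracles on small samples", {
  expect_equal(compute_edd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(compute_edd(c(1, 3), c(2, 4)), 0.5)
  expect_equal(compute_edd(0, 1, distance_config("energy")), 2)

  # exhaustive: all multisets of sizes 1..4 over a 3-point support
  sets <- unlist(lapply(1:4, function(sz) multisets(c(0, 1, 2), sz)),
                 recursive = FALSE)
  ecfg <- distance_config("energy")
  for (x in sets) {
    for (y in sets) {
      expect_equal(compute_edd(x, y), ks_oracle(x, y), tolerance = 1e-12)
      expect_equal(compute_edd(x, y, ecfg), energy_oracle(x, y),
                   tolerance = 1e-12)
    }
  }
})

test_that("KS distance is bounded, maximal under separation, and monotone-invariant", {
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(sample(2:12, 1))
    y <- rnorm(sample(2:12, 1), 1)
    d <- compute_edd(x, y)
    expect_gte(d, 0); expect_lte(d, 1)
    # joint strictly monotone transform leaves the KS distance unchanged
    expect_equal(compute_edd(exp(x), exp(y)), d)
  }
  expect_equal(compute_edd(c(1, 2), c(5, 6, 7)), 1)
})

test_that("energy distance is nonnegative and zero iff identical multisets", {
  sets <- multisets(c(0, 1, 2), 3)
  ecfg <- distance_config("energy")
  for (x in sets) {
    for (y in sets) {
      d <- compute_edd(x, y, ecfg)
      if (identical(sort(x), sort(y))) {
        expect_equal(d, 0)
      } else {
        expect_gt(d, 0)
      }
    }
  }
})

test_that("pattern-shift detector applies the two-window chi-square rule", {
  same <- rbind(c(10, 5, 5), c(10, 5, 5))
  expect_equal(detect_sfps(same), 0L)

  flip <- rbind(c(20, 0), c(0, 20))
  expect_equal(detect_sfps(flip), 1L)
  # hand-check: expected counts are all 10, statistic = 4 * 100/10 = 40
  cs <- suppressWarnings(chisq.test(flip, correct = FALSE))
  expect_equal(unname(cs$statistic), 40)
  expect_gt(40, qchisq(0.95, 1))

  one_reason <- rbind(c(12, 0), c(30, 0))
  expect_warning(m <- detect_sfps(one_reason), "fewer than 2")
  expect_equal(m, 0L)
})

test_that("pattern-shift detection is invariant to category relabeling", {
  set.seed(8)
  for (i in 1:15) {
    tab <- matrix(rpois(4 * 3, 6), 4, 3)
    perm <- sample(3)
    expect_equal(suppressWarnings(detect_sfps(tab)),
                 suppressWarnings(detect_sfps(tab[, perm])))
  }
})

test_that("modernized-guidance indicator centers risk at the benchmark", {
  out <- compute_cmg(c(10, 0, 8), c(20, 20, 20), benchmark = 0.5,
                     site = c("A", "B", "C"))
  prior <- prior_config()
  centered <- vapply(seq_len(nrow(out)), function(i) {
    beta_logit_mean(out$y[i], out$n[i], prior) - qlogis(out$benchmark[i])
  }, numeric(1))
  expect_equal(centered[1], 0)       # on benchmark
  expect_lt(centered[2], 0)          # below benchmark
  expect_lt(centered[3], 0)          # 8/20 is still below rho0 = 0.5
  # above-benchmark exclusion rate gives positive centered risk
  expect_gt(beta_logit_mean(8, 20, prior) - qlogis(0.1), 0)
  expect_warning(compute_cmg(c(1, 0), c(2, 0), 0.5), "no exclusions")
})
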