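test_that("exact_cooling matches the closed form and its limits", {
  # Initial condition and asymptote, any k
  expect_equal(exact_cooling(0, t0 = 300, t_ambient = 280, k = 0.37), 300)
  expect_equal(exact_cooling(1e6, t0 = 300, t_ambient = 280, k = 0.1), 280)
  # Independent evaluation of the closed form (frozen)
  expect_equal(exact_cooling(12, t0 = 300, t_ambient = 0, k = 0.1),
               90.35826357366064, tolerance = 1e-12)
  # Monotone non-increasing when cooling
  tt <- seq(0, 48, by = 0.5)
  temps <- exact_cooling(tt, 300, 280, 0.05)
  expect_true(all(diff(temps) <= 0))
  expect_error(exact_cooling(-1, 300, 280, 0.1),
               class = "thermdecay_domain_error")
  expect_error(exact_cooling(1, -5, 280, 0.1),
               class = "thermdecay_domain_error")
})

test_that("rdk_estimate inverts the cooling ratio", {
  expect_equal(rdk_estimate(300, 300, 12), 0)
  expect_equal(rdk_estimate(300, 290, 12), 0.0028251293063067846,
               tolerance = 1e-12)
  # Algebraic inversion: t_day = t_night * exp(k * dt) recovers k exactly
  for (k in c(0.001, 0.01, 0.05)) {
    tn <- 280
    expect_equal(rdk_estimate(tn * exp(k * 12), tn, 12), k,
                 tolerance = 1e-14)
  }
  # NA propagates, errors on bad domains
  expect_true(is.na(rdk_estimate(NA, 290, 12)))
  expect_error(rdk_estimate(-300, 290, 12),
               class = "thermdecay_domain_error")
  expect_error(rdk_estimate(300, 290, 0), class = "thermdecay_domain_error")
  expect_error(rdk_estimate(30, 29, 12), class = "thermdecay_domain_error")
})

test_that("estimator is scale-covariant but not offset-covariant", {
  set.seed(11)
  td <- runif(50, 290, 320)
  tn <- runif(50, 270, 300)
  base <- rdk_estimate(td, tn, 12, warn_warm_nights = FALSE)
  expect_equal(rdk_estimate(1.7 * td, 1.7 * tn, 12,
                            warn_warm_nights = FALSE), base)
  shifted <- rdk_estimate(td + 40, tn + 40, 12, warn_warm_nights = FALSE)
  expect_false(isTRUE(all.equal(shifted, base)))
})

test_that("warm nights return negative values with a flag", {
  expect_warning(r <- rdk_estimate(290, 300, 12),
                 class = "thermdecay_warm_night")
  expect_lt(r, 0)
  expect_true(is.na(rdk_estimate(290, 300, 12, mask_warm_nights = TRUE,
                                 warn_warm_nights = FALSE)))
})

test_that("rdk_annual averages valid pairs and enforces min_pairs", {
  # Mean of constants
  const <- tibble::tibble(t_day = rep(300, 46), t_night = rep(290, 46))
  out <- rdk_annual(const, min_pairs = 10)
  expect_equal(out$n_pairs, 46)
  expect_equal(out$rdk, rdk_estimate(300, 290, 12))

  # Invalid pairs excluded; matches naive loop oracle
  pairs <- tibble::tibble(
    t_day = c(300, 305, 310, 299),
    t_night = c(290, 280, 300, 295),
    valid = c(TRUE, TRUE, FALSE, TRUE)
  )
  out <- rdk_annual(pairs, min_pairs = 1)
  manual <- mean(log(pairs$t_day[pairs$valid] / pairs$t_night[pairs$valid]) / 12)
  expect_equal(out$rdk, manual)
  expect_equal(out$n_pairs, 3)

  # Below min_pairs: sentinel, count still recorded
  out <- rdk_annual(pairs, min_pairs = 5)
  expect_true(is.na(out$rdk))
  expect_equal(out$n_pairs, 3)

  # Permutation invariance
  set.seed(3)
  big <- tibble::tibble(t_day = runif(40, 300, 320),
                        t_night = runif(40, 280, 299))
  shuf <- big[sample(nrow(big)), ]
  expect_equal(rdk_annual(big)$rdk, rdk_annual(shuf)$rdk)

  # Grouped periods
  grouped <- tibble::tibble(
    year = rep(2003:2004, each = 12),
    t_day = rep(c(300, 310), each = 12),
    t_night = rep(290, 24)
  )
  out <- rdk_annual(grouped, year, min_pairs = 10)
  expect_equal(out$year, 2003:2004)
  expect_equal(out$rdk,
               c(rdk_estimate(300, 290, 12), rdk_estimate(310, 290, 12)))
})

test_that("annual mean recovers k exactly when ambient temperature is zero", {
  # The ratio approximation is exact in the T_a = 0 limit.
  k <- 0.01
  hours <- seq(0, 10, by = 0.5)
  pairs <- tibble::tibble(
    t_day = exact_cooling(hours, t0 = 320, t_ambient = 0, k = k),
    t_night = exact_cooling(hours + 12, t0 = 320, t_ambient = 0, k = k)
  )
  out <- rdk_annual(pairs, min_pairs = 10)
  expect_equal(out$rdk, k, tolerance = 1e-14)
})

test_that("theoretical_rdk scales as the thermal-mass formula", {
  expect_equal(theoretical_rdk(10, 1000, 4000, 0.1), 2.5e-5)
  base <- theoretical_rdk(7, 850, 3100, 0.2)
  expect_equal(theoretical_rdk(14, 850, 3100, 0.2), 2 * base)
  expect_equal(theoretical_rdk(7, 1700, 3100, 0.2), base / 2)
  expect_equal(theoretical_rdk(7, 850, 6200, 0.2), base / 2)
  expect_equal(theoretical_rdk(7, 850, 3100, 0.4), base / 2)
  expect_error(theoretical_rdk(0, 850, 3100, 0.2),
               class = "thermdecay_domain_error")
})

test_that("approximation_bias is zero at T_a = 0 and grows with T_a", {
  # Exact in the limit, over a grid of states
  for (t0 in c(295, 310, 330)) {
    for (k in c(0.005, 0.02, 0.08)) {
      for (dt in c(9, 12)) {
        expect_equal(approximation_bias(t0, 0, k, dt), 0, tolerance = 1e-15)
      }
    }
  }
  # Independent closed-form evaluation (frozen)
  expect_equal(approximation_bias(310, 280, 0.05, 12),
               -0.04627955621235297, tolerance = 1e-12)
  expect_lt(approximation_bias(310, 280, 0.05, 12), 0)
  # Magnitude monotone in t_ambient at fixed t0, k, dt
  tas <- seq(0, 300, by = 20)
  mags <- abs(approximation_bias(310, tas, 0.05, 12))
  expect_true(all(diff(mags) > 0))
})

test_that("dtr is the day-night difference with the same aggregation", {
  expect_equal(dtr(300, 290), 10)
  expect_equal(dtr(287.3, 287.3), 0)
  pairs <- tibble::tibble(t_day = c(298, 300, 302),
                          t_night = rep(290, 3))
  expect_equal(rdk_annual(pairs, min_pairs = 3)$dtr, 10)
})

test_that("rdk_pairs appends derived columns and respects validity", {
  pairs <- tibble::tibble(t_day = c(300, 290, 305),
                          t_night = c(290, 300, 295),
                          valid = c(TRUE, TRUE, FALSE))
  out <- rdk_pairs(pairs, warn_warm_nights = FALSE)
  expect_named(out, c("t_day", "t_night", "valid", "rdk", "dtr",
                      "warm_night"))
  expect_true(is.na(out$rdk[3]))
  expect_lt(out$rdk[2], 0)
  expect_true(out$warm_night[2])
})
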