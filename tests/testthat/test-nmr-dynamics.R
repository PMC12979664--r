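# Relaxation fitting, IVW aggregation, propagated comparisons, the paired
# sign test, CSP and intensity ratios.

test_that("noiseless decays are fitted exactly", {
  t <- c(0, 0.1, 0.5)
  s <- tibble::tibble(delay_s = t, intensity = 100 * exp(-2 * t))
  f <- fit_rate(s, n_mc = 10, seed = 1)
  expect_equal(f$rate, 2, tolerance = 1e-8)
  expect_equal(f$i0, 100, tolerance = 1e-6)
  expect_lt(f$residual_norm, 1e-8)
  expect_false(f$flagged)

  # constant intensities decay at rate zero
  s0 <- tibble::tibble(delay_s = c(0, 0.1, 0.2, 0.5), intensity = rep(50, 4))
  f0 <- fit_rate(s0, n_mc = 10, seed = 1)
  expect_equal(f0$rate, 0, tolerance = 1e-8)

  expect_error(
    fit_rate(tibble::tibble(delay_s = c(0, 1), intensity = c(1, 0.5))),
    "3 distinct"
  )
})

test_that("the vectorized Monte Carlo refitter agrees with nlsLM", {
  set.seed(99)
  t <- c(0, 0.01, 0.03, 0.05, 0.09, 0.13, 0.17, 0.25)
  for (i in 1:15) {
    r_true <- runif(1, 1, 25)
    y <- 100 * exp(-r_true * t) + rnorm(length(t), 0, 1)
    start <- galidr:::loglin_start(t, y)
    mine <- galidr:::fit_exp_many(t, matrix(y, ncol = 1), start$i0, start$rate)
    ref <- minpack.lm::nlsLM(
      y ~ i0 * exp(-rate * t),
      start = list(i0 = start$i0, rate = start$rate)
    )
    expect_equal(mine$rate, coef(ref)[["rate"]], tolerance = 1e-5)
    expect_equal(mine$i0, coef(ref)[["i0"]], tolerance = 1e-5)
  }
})

test_that("Monte Carlo standard errors are stable in n_mc", {
  t <- c(0, 0.01, 0.03, 0.05, 0.09, 0.13, 0.17, 0.25)
  set.seed(7)
  y <- 100 * exp(-18 * t) + rnorm(length(t), 0, 1)
  s <- tibble::tibble(delay_s = t, intensity = y)
  se1 <- fit_rate(s, n_mc = 500, seed = 11)$se
  se2 <- fit_rate(s, n_mc = 1000, seed = 12)$se
  expect_lt(abs(se2 - se1) / se1, 0.10)
})

test_that("IVW combination reproduces closed-form values and properties", {
  two <- ivw_combine(tibble::tibble(rate = c(10, 20), se = c(1, 2)))
  expect_equal(two$mean, 12.000, tolerance = 1e-9)
  expect_equal(two$se, sqrt(1 / 1.25), tolerance = 1e-9)

  one <- ivw_combine(tibble::tibble(rate = 7, se = 0.3))
  expect_equal(one$mean, 7)
  expect_equal(one$se, 0.3)

  # equal SEs reduce to the arithmetic mean; result bounded by the inputs
  set.seed(12)
  for (i in 1:50) {
    x <- rnorm(sample(2:10, 1), 15, 3)
    eq <- ivw_combine(tibble::tibble(rate = x, se = rep(0.5, length(x))))
    expect_equal(eq$mean, mean(x), tolerance = 1e-12)
    s <- runif(length(x), 0.1, 2)
    g <- ivw_combine(tibble::tibble(rate = x, se = s))
    expect_gte(g$mean, min(x))
    expect_lte(g$mean, max(x))
  }

  # flagged estimates are excluded; empty input errors
  fl <- ivw_combine(tibble::tibble(
    rate = c(10, 1000), se = c(1, 1), flagged = c(FALSE, TRUE)
  ))
  expect_equal(fl$mean, 10)
  expect_error(
    ivw_combine(tibble::tibble(rate = 1, se = 1, flagged = TRUE)),
    "no usable"
  )
})

test_that("condition comparison propagates errors as stated", {
  est <- tibble::tibble(
    condition = rep(c("lo", "hi"), each = 2),
    rate_type = rep(c("R2", "R1"), 2),
    rate = c(20, 2, 25, 2.5),
    se = c(0.4, 0.1, 0.4, 0.1)
  )
  st <- condition_stats(est)
  # ratio 20/2 = 10 with SE 10 * sqrt((0.4/20)^2 + (0.1/2)^2)
  lo <- st[st$condition == "lo", ]
  expect_equal(lo$r2_over_r1, 10.000, tolerance = 1e-9)
  expect_equal(lo$r2_over_r1_se, 10 * sqrt(0.02^2 + 0.05^2), tolerance = 1e-9)

  cmp <- condition_compare(st, low = "lo", high = "hi")
  expect_equal(cmp$d_r2, 5)
  expect_equal(cmp$d_r2_se, sqrt(2 * 0.4^2), tolerance = 1e-12)

  # identical conditions give zero differences
  st2 <- st
  st2[2, -1] <- st2[1, -1]
  cmp0 <- condition_compare(st2, low = "lo", high = "hi")
  expect_equal(cmp0$d_r2, 0)
  expect_equal(cmp0$d_ratio, 0)
})

test_that("published-style condition tables are internally consistent", {
  # zfGal-style printed aggregates: R2 17.03 +/- 0.29 at 40 uM vs
  # 21.05 +/- 0.31 at 400 uM print |dR2| 4.03 +/- 0.43; recomputing the
  # difference from the printed means must agree within display rounding
  st <- tibble::tibble(
    condition = c("40uM", "400uM"),
    r2 = c(17.03, 21.05), r2_se = c(0.29, 0.31),
    r1 = c(0.82, 0.72), r1_se = c(0.01, 0.01),
    r2_over_r1 = c(17.03 / 0.82, 21.05 / 0.72),
    r2_over_r1_se = c(0.46, 0.54)
  )
  cmp <- condition_compare(st, low = "40uM", high = "400uM")
  expect_lt(abs(cmp$d_r2 - 4.03), 0.015)
  expect_lt(abs(cmp$d_r2_se - 0.43), 0.01)
  expect_lt(abs(cmp$d_r1 - 0.10), 0.005)
})

test_that("sign test p-values equal the exact binomial tail", {
  all_pos <- ddr2_sign_test(
    tibble::tibble(residue = 1:10, delta = 2),
    tibble::tibble(residue = 1:10, delta = 1)
  )
  expect_equal(all_pos$p_value, 0.5^10, tolerance = 1e-12)
  expect_equal(all_pos$n_positive, 10L)

  # 8 of 10 positive
  d <- c(rep(1, 8), rep(-1, 2))
  mixed <- ddr2_sign_test(
    tibble::tibble(residue = 1:10, delta = d),
    tibble::tibble(residue = 1:10, delta = 0)
  )
  expect_equal(mixed$p_value, 56 / 1024, tolerance = 1e-12)

  # ties are dropped; all ties is an error
  expect_error(
    ddr2_sign_test(
      tibble::tibble(residue = 1:5, delta = 1),
      tibble::tibble(residue = 1:5, delta = 1)
    ),
    "ties"
  )

  # exhaustive oracle sweep over n <= 20
  for (n in 1:20) {
    for (k in 0:n) {
      delta <- c(rep(1, k), rep(-1, n - k))
      if (k == 0 && n == 0) next
      got <- ddr2_sign_test(
        tibble::tibble(residue = seq_len(n), delta = delta),
        tibble::tibble(residue = seq_len(n), delta = 0)
      )
      expect_equal(got$p_value, oracle_binom_tail(k, n), tolerance = 1e-12)
    }
  }
})

test_that("CSP combines proton and nitrogen shifts with the 0.14 weighting", {
  a <- tibble::tibble(assignment = "R5N-H", n_ppm = 120, h_ppm = 8)
  b <- tibble::tibble(assignment = "R5N-H", n_ppm = 120.1, h_ppm = 8.01)
  got <- csp(a, b)
  expect_equal(got$csp, sqrt(0.01^2 + (0.14 * 0.1)^2), tolerance = 1e-12)
  expect_true(got$flagged)

  # alpha = 0 reduces the CSP to |ddH|
  got0 <- csp(a, b, alpha = 0)
  expect_equal(got0$csp, 0.01, tolerance = 1e-12)

  # identical lists: zero everywhere, nothing flagged
  same <- csp(a, a)
  expect_equal(same$csp, 0)
  expect_false(same$flagged)

  # duplicate assignments are an error; unmatched peaks are reported aside
  expect_error(csp(dplyr::bind_rows(a, a), b), "duplicate")
  extra <- dplyr::bind_rows(
    b, tibble::tibble(assignment = "R6N-H", n_ppm = 110, h_ppm = 7.5)
  )
  got2 <- csp(a, extra)
  expect_equal(attr(got2, "n_unmatched"), 1L)
  expect_equal(attr(got2, "unmatched")$assignment, "R6N-H")
})

test_that("intensity ratios recover planted attenuation", {
  pk <- sim_peaklists(
    30,
    shifted_subset = integer(),
    attenuated_subset = 1:6, attenuation = 0.4, seed = 9
  )
  # reference / perturbed: attenuated residues have high a/b ratio
  got <- intensity_ratio(pk$perturbed, pk$reference)
  low <- got$residue[order(got$ratio)][1:6]
  expect_setequal(low, 1:6)

  ident <- intensity_ratio(pk$reference, pk$reference)
  expect_equal(ident$ratio, rep(1, 30))

  b2 <- pk$reference
  b2$intensity <- 2 * b2$intensity
  expect_equal(intensity_ratio(pk$reference, b2)$ratio, rep(0.5, 30))

  # zero denominators are flagged and excluded
  bz <- pk$reference
  bz$intensity[1] <- 0
  gz <- intensity_ratio(pk$reference, bz)
  expect_true(gz$zero_denominator[gz$residue == bz$residue[1]])
  expect_true(is.na(gz$ratio[gz$residue == bz$residue[1]]))
})

test_that("rate fit coverage: true rate within 3 MC standard errors", {
  # moderate-size check of the Monte Carlo error calibration
  tr <- relax_truth(
    rates = tibble::tibble(
      condition = "c", residue = 1:40,
      rate = runif(40, 10, 25)
    ),
    i0 = 100, noise_sigma = 0.01
  )
  set.seed(31)
  dat <- sim_relaxation(tr, seed = 31)
  est <- fit_rates(dat, n_mc = 200, seed = 17)
  j <- dplyr::inner_join(est, tr$rates, by = c("condition", "residue"))
  covered <- abs(j$rate.x - j$rate.y) < 3 * j$se
  expect_gte(mean(covered), 0.95)
})
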