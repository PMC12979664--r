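# CD conversion, Bradford calibration, agglutination fractions, replicate
# summaries.

test_that("delta-epsilon conversion is exact and homogeneous", {
  expect_equal(delta_epsilon(0, 110, 0.01, 1), 0)
  expect_equal(
    delta_epsilon(10000, mrw = 110, l = 0.01, conc = 1),
    10000 * 0.1 * 110 / (0.01 * 1 * 3298),
    tolerance = 1e-12
  )
  # the worked value rounds to 3335.4
  expect_equal(round(delta_epsilon(10000, 110, 0.01, 1), 1), 3335.4)

  set.seed(4)
  theta <- rnorm(10, 0, 5000)
  expect_equal(
    delta_epsilon(2 * theta, 110, 0.01, 1),
    2 * delta_epsilon(theta, 110, 0.01, 1)
  )
  expect_equal(
    delta_epsilon(theta, 110, 0.02, 1),
    delta_epsilon(theta, 110, 0.01, 1) / 2
  )
  expect_equal(
    delta_epsilon(theta, 110, 0.01, 2),
    delta_epsilon(theta, 110, 0.01, 1) / 2
  )
  expect_error(delta_epsilon(1, -110, 0.01, 1), "positive")

  spec <- tibble::tibble(wavelength = 190:260, theta = rnorm(71))
  conv <- cd_convert(spec, mrw = 110, l = 0.01, conc = 1)
  expect_equal(conv$delta_epsilon, delta_epsilon(spec$theta, 110, 0.01, 1))
  expect_error(
    cd_convert(tibble::tibble(wavelength = c(200, 200), theta = 1:2), 110, 0.01, 1),
    "increasing"
  )
})

test_that("Bradford calibration recovers an exact line and flags extrapolation", {
  std <- tibble::tibble(ratio = c(0.5, 1, 1.5, 2), conc = 20 * c(0.5, 1, 1.5, 2) - 10)
  cal <- bradford_fit(std)
  expect_equal(cal$slope, 20, tolerance = 1e-9)
  expect_equal(cal$intercept, -10, tolerance = 1e-9)
  expect_lt(max(abs(resid(cal$fit))), 1e-9)

  pred <- bradford_predict(cal, tibble::tibble(ratio = c(1.25, 0.5, 5)))
  expect_equal(pred$conc[1], 15.0, tolerance = 1e-9)
  expect_equal(pred$conc[2], 0, tolerance = 1e-9) # a standard's own ratio
  expect_equal(pred$extrapolated, c(FALSE, FALSE, TRUE))

  expect_error(bradford_fit(tibble::tibble(ratio = c(1, 1), conc = 1:2)), "distinct")
})

test_that("noisy Bradford standards recover the slope within its SE band", {
  at <- sim_assays(slope = 20, intercept = -10, noise = 0.01, seed = 23)
  cal <- bradford_fit(at$standards)
  slope_se <- tidy(cal)$std.error[tidy(cal)$term == "ratio"]
  expect_lt(abs(cal$slope - 20), 3 * slope_se)
  expect_gt(cal$r_squared, 0.99)
})

test_that("agglutination fractions and anomaly flags", {
  ag <- agglutination_fraction(20, c(5, 5, 5), construct = "zfGal")
  expect_equal(ag$fraction, 0.25)
  expect_equal(ag$fraction_sd, 0)
  expect_false(ag$anomalous)

  over <- agglutination_fraction(20, c(25, 26, 24))
  expect_true(over$anomalous)
  expect_error(agglutination_fraction(0, 5), "positive")
})

test_that("synthetic assay round trip: S/T and ordering recovered", {
  truth_st <- c(hGal3 = 0.05, zfGalWY = 0.45, zfGal = 0.30)
  at <- sim_assays(s_over_t = truth_st, noise = 0.01, seed = 31)
  cal <- bradford_fit(at$standards)
  pred <- bradford_predict(cal, at$samples)
  ag <- agglutination_table(
    tibble::tibble(
      construct = pred$construct,
      s_conc = pred$conc / at$truth$ug_per_um
    ),
    total = at$truth$total_um
  )
  for (cons in names(truth_st)) {
    row <- ag[ag$construct == cons, ]
    expect_lt(abs(row$fraction - truth_st[[cons]]), 3 * max(row$fraction_sd, 0.01))
  }
  # stronger planted agglutination (lower S/T) gives the same ordering
  expect_equal(ag$construct, names(sort(truth_st)))
})

test_that("replicate summaries match a two-pass oracle", {
  set.seed(6)
  df <- tidyr::expand_grid(condition = c("a", "b", "c"), replicate = 1:5)
  df$od600 <- runif(nrow(df), 0, 2)
  got <- replicate_summary(df, "od600", group = "condition")
  for (cond in c("a", "b", "c")) {
    want <- oracle_mean_sd(df$od600[df$condition == cond])
    expect_equal(got$mean[got$condition == cond], want$mean)
    expect_equal(got$sd[got$condition == cond], want$sd)
  }
  expect_equal(got$n, rep(5L, 3))
})
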