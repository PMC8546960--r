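test_that("growth-rate fit recovers an exact exponential", {
  t <- seq(0, 5, by = 0.5)
  fit <- fit_growth_rate(t, 0.07 * exp(0.30 * t))
  expect_equal(fit$lambda, 0.30)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$od0, 0.07)

  flat <- fit_growth_rate(t, rep(0.2, length(t)))
  expect_equal(flat$lambda, 0)
})

test_that("growth-rate fit matches least squares under multiplicative noise", {
  set.seed(101)
  t <- seq(0, 4.5, by = 0.5)
  for (i in 1:20) {
    od <- 0.07 * exp(0.25 * t) * exp(rnorm(length(t), 0, 0.02))
    fit <- fit_growth_rate(t, od)
    expect_lt(abs(fit$lambda - 0.25), 3 * fit$se)
    # oracle: direct least squares on the log series
    expect_equal(fit$lambda, unname(coef(lm(log(od) ~ t))[2]))
  }
})

test_that("growth-rate fit rejects bad input and ignores OD rescaling", {
  t <- 0:5
  expect_error(fit_growth_rate(t, c(0.1, -0.1, 0.2, 0.3, 0.4, 0.5)), "> 0")
  expect_error(fit_growth_rate(0:1, c(0.1, 0.2)), "3 points")
  od <- 0.07 * exp(0.3 * t) * exp(rnorm(6, 0, 0.01))
  expect_equal(fit_growth_rate(t, od)$lambda,
               fit_growth_rate(t, 17.3 * od)$lambda)
})

test_that("automatic window selection finds the log-linear phase", {
  t <- seq(0, 8, by = 0.5)
  # exponential until t = 4, then stationary
  od <- ifelse(t <= 4, 0.07 * exp(0.4 * t), 0.07 * exp(0.4 * 4))
  w <- find_exponential_window(t, od, r2_min = 0.9999)
  expect_equal(w[1], 0)
  expect_equal(w[2], 4)
  expect_equal(fit_growth_rate(t, od, window = w)$lambda, 0.4)
})

test_that("OD converts linearly to dry cell weight", {
  expect_equal(od_to_dcw(1.0), 0.44)
  expect_equal(od_to_dcw(0), 0)
  expect_equal(od_to_dcw(2.0), 0.88)
  expect_error(od_to_dcw(-1), ">= 0")
})

test_that("specific rates follow q = lambda * |dS/dX| / M", {
  # glucose falls 2 g/L while biomass rises 0.1 g/L: slope -20 g/g
  X <- c(0.05, 0.10, 0.15)
  S <- 2 - 20 * (X - 0.05)
  q <- specific_rate(S, X, lambda = 0.26, molar_mass = 180.16)
  expect_equal(q$rate, 0.26 * 20 / 180.16 * 1000)
  expect_equal(q$direction, "uptake")

  flat <- specific_rate(rep(1.5, 3), X, 0.26, 180.16)
  expect_equal(flat$rate, 0)

  # linearity: doubling all concentrations doubles the rate
  q2 <- specific_rate(2 * S, X, 0.26, 180.16)
  expect_equal(q2$rate, 2 * q$rate)

  # secretion: product increases with biomass
  P <- 0.1 + 5 * (X - 0.05)
  qs <- specific_rate(P, X, 0.26, 60.05)
  expect_equal(qs$direction, "secretion")
  expect_equal(qs$rate_mass, 0.26 * 5)

  expect_error(specific_rate(S, X[1:2], 0.26, 180.16), "same points")
})

test_that("yields are rate ratios on a mass basis", {
  expect_equal(compute_yields(c(acetate = 2.0), 2.0), c(acetate = 1.0))
  expect_equal(compute_yields(c(lactate = 0), 2.0), c(lactate = 0))
  expect_equal(compute_yields(c(acetate = 0.5), 2.0), c(acetate = 0.25))
  expect_error(compute_yields(c(acetate = 0.5), 0), "> 0")
  # invariance to absolute biomass: rates scale together
  expect_equal(compute_yields(c(a = 0.5) * 3, 2.0 * 3),
               compute_yields(c(a = 0.5), 2.0))
})

test_that("characterize_physiology recovers planted rates from a bundle strain", {
  b <- noise_free_bundle()
  truth <- b$truth$config
  od <- b$od_series[b$od_series$strain == "WT" & b$od_series$bio_rep == 1, ]
  cs <- b$substrate_series[b$substrate_series$strain == "WT" &
                             b$substrate_series$bio_rep == 1, ]
  mm <- c(glucose = 180.16, ammonia = 17.03, formate = 46.03,
          acetate = 60.05, ethanol = 46.07, lactate = 90.08,
          succinate = 118.09)
  ph <- characterize_physiology(
    data.frame(time = od$time, od = od$od),
    data.frame(time = cs$time, species = cs$species,
               concentration = cs$concentration), mm)
  expect_equal(ph$lambda, truth$sectors$lambda[1], tolerance = 1e-8)
  expect_equal(ph$q_glc, truth$q_glc[["WT"]], tolerance = 1e-6)
  expect_equal(unname(ph$yields["lactate"]),
               truth$yields$lactate[truth$yields$strain == "WT"],
               tolerance = 1e-6)
})
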