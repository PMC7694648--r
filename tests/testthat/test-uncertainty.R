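glyc_fit <- function(meas = NULL, tracer = tracer_spec(Glc = c(1, 2)),
                     n_starts = 4, seed = 1) {
  model <- upper_glycolysis_model()
  if (is.null(meas)) meas <- printed_fbp_measurements()
  mfa_fit(model, meas, tracer, fixed = c(f1 = 100),
          n_starts = n_starts, seed = seed)
}

test_that("chi-square cutoffs come from the quantile function", {
  expect_equal(chi2_cutoff(0.95, 1), 3.84, tolerance = 0.005)
  expect_equal(chi2_cutoff(0.99, 1), 6.63, tolerance = 0.005)
  expect_lt(chi2_cutoff(1e-12, 1), 1e-10)
  expect_error(chi2_cutoff(1.2, 1), "alpha")
  expect_error(chi2_cutoff(0.95, 0), "df")
})

test_that("profile CIs reproduce the 95% flux ranges of the fixture", {
  fit <- glyc_fit()
  ci <- confint(fit, level = 0.95)
  f3 <- ci[ci$parameter == "f3", ]
  f5 <- ci[ci$parameter == "f5", ]
  expect_equal(f3$lower, 43.5, tolerance = 0.02)
  expect_equal(f3$upper, 57.5, tolerance = 0.02)
  expect_equal(f5$lower, 75, tolerance = 0.02)
  expect_equal(f5$upper, 330, tolerance = 0.02)
  expect_false(any(f3$hit_lower_bound, f3$hit_upper_bound,
                   f5$hit_lower_bound, f5$hit_upper_bound))
  # interval brackets the estimate
  expect_true(all(ci$lower <= ci$estimate & ci$estimate <= ci$upper))
})

test_that("CIs nest across levels and narrow with measurement precision", {
  fit <- glyc_fit()
  ci95 <- confint(fit, parm = "f3", level = 0.95)
  ci99 <- confint(fit, parm = "f3", level = 0.99)
  expect_lte(ci99$lower, ci95$lower)
  expect_gte(ci99$upper, ci95$upper)

  tight <- glyc_fit(meas = printed_fbp_measurements(sd = 0.005))
  ci_tight <- confint(tight, parm = "f3", level = 0.95)
  expect_gt(ci_tight$lower, ci95$lower)
  expect_lt(ci_tight$upper, ci95$upper)
})

test_that("an uninformative tracer leaves f5 pinned at its bounds", {
  model <- upper_glycolysis_model()
  mix <- tracer_u13c_mix()
  meas <- simulate_measurements(model, glyc_fluxes(50, 150), mix,
                                "FBP[1-6]", sd = 0, seed = 1)
  meas$sd <- 0.01
  fit <- mfa_fit(model, meas, mix, fixed = c(f1 = 100), n_starts = 4, seed = 1)
  # SSR is numerically flat along f5 at fixed f3
  spec <- free_flux_spec(model, fixed = c(f1 = 100))
  ssrs <- vapply(seq(5, 2000, length.out = 15), function(f5)
    mid_ssr(predict_mids(model, complete_fluxes(spec, c(50, f5)), mix,
                         "FBP[1-6]"), meas), 0)
  expect_lt(max(abs(diff(ssrs))), 1e-10)
  ci <- confint(fit, parm = "f5", level = 0.95)
  expect_true(ci$hit_lower_bound)
  expect_true(ci$hit_upper_bound)
  expect_equal(ci$lower, fit$bounds["lower", "f5"])
  expect_equal(ci$upper, fit$bounds["upper", "f5"])
  # f3 remains identifiable
  ci3 <- confint(fit, parm = "f3", level = 0.95)
  expect_false(ci3$hit_lower_bound || ci3$hit_upper_bound)
  expect_lt(ci3$upper - ci3$lower, 50)
})

test_that("the 2-D confidence region matches the profile intervals", {
  fit <- glyc_fit()
  rg <- ssr_region(fit, c("f3", "f5"), xlim = c(35, 65), ylim = c(20, 450),
                   resolution = c(61, 87), level = 0.95)
  # accepted/rejected worked points
  ssr_at <- function(f3, f5) {
    i <- which.min(abs(rg$x - f3)); j <- which.min(abs(rg$y - f5))
    rg$ssr[i, j]
  }
  expect_true(ssr_at(48, 210) <= rg$threshold)   # chi2 = 1.33 < 3.84
  expect_true(ssr_at(50, 150) <= rg$threshold)
  expect_gt(ssr_at(35, 20), rg$threshold)

  bounds <- region_bounds(rg)
  ci <- confint(fit, level = 0.95)
  cell <- c(diff(rg$x[1:2]), diff(rg$y[1:2]))
  expect_lt(abs(bounds["f3", "lower"] - ci$lower[ci$parameter == "f3"]), cell[1])
  expect_lt(abs(bounds["f3", "upper"] - ci$upper[ci$parameter == "f3"]), cell[1])
  expect_lt(abs(bounds["f5", "lower"] - ci$lower[ci$parameter == "f5"]), cell[2])
  expect_lt(abs(bounds["f5", "upper"] - ci$upper[ci$parameter == "f5"]), cell[2])

  df <- as.data.frame(rg)
  expect_named(df, c("f3", "f5", "ssr", "in_region"))
  expect_equal(sum(df$in_region), sum(rg$mask))
})

test_that("an unlabeled tracer accepts the entire grid", {
  model <- upper_glycolysis_model()
  meas <- simulate_measurements(model, glyc_fluxes(50, 150), tracer_spec(),
                                "FBP[1-6]", sd = 0, seed = 1)
  meas$sd <- 0.01
  fit <- mfa_fit(model, meas, tracer_spec(), fixed = c(f1 = 100),
                 n_starts = 2, seed = 1)
  rg <- ssr_region(fit, c("f3", "f5"), xlim = c(10, 100), ylim = c(10, 300),
                   resolution = 7, level = 0.95)
  expect_true(all(rg$mask))
  expect_true(all(rg$ssr < 1e-12))
})

test_that("Monte-Carlo samplers agree with the profile intervals", {
  fit <- glyc_fit()
  ci <- confint(fit, parm = "f3", level = 0.95)

  mc <- mfa_mcmc(fit, n = 1500, seed = 4, method = "metropolis")
  expect_equal(dim(mc$samples), c(1500, 2))
  expect_lt(abs(mc$intervals["f3", 1] - ci$lower) / ci$lower, 0.15)
  expect_lt(abs(mc$intervals["f3", 2] - ci$upper) / ci$upper, 0.15)
  expect_true(mc$acceptance > 0.05 && mc$acceptance < 0.8)

  mp <- mfa_mcmc(fit, n = 60, seed = 4, method = "perturbation")
  expect_true(mp$intervals["f3", 1] < 50 && mp$intervals["f3", 2] > 50)
  # reproducible given the seed
  mp2 <- mfa_mcmc(fit, n = 60, seed = 4, method = "perturbation")
  expect_identical(mp$samples, mp2$samples)

  # vanishing measurement error concentrates the samples at (50, 150)
  tight <- glyc_fit(meas = printed_fbp_measurements(sd = 5e-4))
  mc2 <- mfa_mcmc(tight, n = 800, seed = 5, method = "metropolis")
  expect_lt(abs(stats::median(mc2$samples$f3) - 50), 1.5)
})
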