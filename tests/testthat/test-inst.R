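test_that("a single pool labels with the closed-form exponential", {
  m <- read_flux_model(text = c(
    "A, 1, source", "B, 1, balanced", "C, 1, sink",
    "fin: A (a) -> B (a)", "fout: B (a) -> C (a)"))
  # influx 100 nmol/h of fully labeled substrate into a 50 nmol pool:
  # labeled fraction = 1 - exp(-f t / c)
  times <- c(0.1, 0.25, 0.5, 1)
  traj <- simulate_timecourse(m, c(fin = 100, fout = 100), c(B = 50),
                              tracer_spec(A = 1), times, targets = "B[1]")
  for (t in times)
    expect_equal(trajectory_at(traj, t)[["B[1]"]][2], 1 - exp(-100 * t / 50),
                 tolerance = 1e-6)
  expect_equal(trajectory_at(traj, 0)[["B[1]"]], c(1, 0))
})

test_that("the trajectory converges to the steady-state solve", {
  gf <- inst_glycolysis_fixture(400)
  ss <- predict_mids(gf$model, gf$fluxes, gf$tracer, "FBP[1-6]")
  late <- simulate_to_steady(gf$model, gf$fluxes, gf$pools, gf$tracer,
                             targets = "FBP[1-6]")
  expect_equal(late[["FBP[1-6]"]], ss[["FBP[1-6]"]], tolerance = 1e-6)

  # steady state is independent of the pool sizes
  big <- inst_glycolysis_fixture(3000)
  late2 <- simulate_to_steady(big$model, big$fluxes, big$pools, big$tracer,
                              targets = "FBP[1-6]")
  expect_equal(late2[["FBP[1-6]"]], late[["FBP[1-6]"]], tolerance = 1e-6)

  expect_error(simulate_timecourse(gf$model, gf$fluxes,
                                   gf$pools[c("FBP", "DHAP", "GAP")],
                                   gf$tracer, 1:3, targets = "FBP[1-6]"),
               "missing pool")
})

test_that("a larger upstream pool slows downstream labeling at all times", {
  small <- inst_glycolysis_fixture(400)
  big <- inst_glycolysis_fixture(3000)
  times <- c(1, 2, 5, 10, 20, 40, 80)
  tr_s <- simulate_timecourse(small$model, small$fluxes, small$pools,
                              small$tracer, times, targets = "FBP[1-6]")
  tr_b <- simulate_timecourse(big$model, big$fluxes, big$pools,
                              big$tracer, times, targets = "FBP[1-6]")
  for (t in times) {
    m2_small <- trajectory_at(tr_s, t)[["FBP[1-6]"]][3]
    m2_big <- trajectory_at(tr_b, t)[["FBP[1-6]"]][3]
    expect_gt(m2_small, m2_big)
  }
})

test_that("scaling all pools by k rescales time by k", {
  gf <- inst_glycolysis_fixture(400)
  times <- c(2, 5, 10)
  base <- simulate_timecourse(gf$model, gf$fluxes, gf$pools, gf$tracer,
                              times, targets = "FBP[1-6]")
  for (k in c(0.5, 2)) {
    scaled <- simulate_timecourse(gf$model, gf$fluxes, gf$pools * k,
                                  gf$tracer, times * k, targets = "FBP[1-6]")
    for (i in seq_along(times))
      expect_equal(trajectory_at(scaled, times[i] * k)[["FBP[1-6]"]],
                   trajectory_at(base, times[i])[["FBP[1-6]"]],
                   tolerance = 1e-6)
  }
})

test_that("trajectories stay normalized within integrator tolerance", {
  gf <- inst_glycolysis_fixture(400)
  traj <- simulate_timecourse(gf$model, gf$fluxes, gf$pools, gf$tracer,
                              seq(0, 50, 5))
  for (lb in names(traj$mids)) {
    m <- traj$mids[[lb]]
    expect_true(all(m >= 0 & m <= 1))
    expect_equal(rowSums(m), rep(1, nrow(m)), tolerance = 1e-7)
  }
})

test_that("evolving pools reduce to the static case when balanced", {
  gf <- inst_glycolysis_fixture(400)
  times <- c(1, 3, 6)
  static <- simulate_timecourse(gf$model, gf$fluxes, gf$pools, gf$tracer,
                                times, targets = "FBP[1-6]")
  evolving <- simulate_nonstationary_pools(gf$model, gf$fluxes, gf$pools,
                                           gf$tracer, times,
                                           targets = "FBP[1-6]")
  for (t in times)
    expect_equal(trajectory_at(evolving, t)[["FBP[1-6]"]],
                 trajectory_at(static, t)[["FBP[1-6]"]], tolerance = 1e-7)
  # balanced fluxes: pools stay constant
  expect_equal(max(abs(sweep(evolving$pools, 2,
                             gf$pools[colnames(evolving$pools)]))), 0,
               tolerance = 1e-8)
})

test_that("net production grows pools linearly and dilutes labeling", {
  gf <- inst_glycolysis_fixture(400)
  fl <- gf$fluxes
  fl["f6"] <- 150   # GAP now accumulates at 50 nmol/h
  times <- seq(1, 8, 1)
  traj <- simulate_nonstationary_pools(gf$model, fl, gf$pools, gf$tracer,
                                       times, targets = "GAP[1-3]")
  expect_equal(unname(traj$pools[, "GAP"]), 1000 + 50 * traj$times,
               tolerance = 1e-6)

  # growth dilutes: the growing pool lags the static pool of the same
  # initial size
  static <- simulate_timecourse(gf$model, gf$fluxes, gf$pools, gf$tracer,
                                times, targets = "GAP[1-3]")
  for (t in c(4, 8))
    expect_lt(1 - trajectory_at(traj, t)[["GAP[1-3]"]][1],
              1 - trajectory_at(static, t)[["GAP[1-3]"]][1])

  # draining a pool to zero stops the integration with an error
  fl2 <- gf$fluxes
  fl2["f6"] <- 500  # GAP net production -300 nmol/h, empty in ~3.3 h
  expect_error(simulate_nonstationary_pools(gf$model, fl2, gf$pools,
                                            gf$tracer, seq(1, 10),
                                            targets = "GAP[1-3]"),
               "pool")
})

test_that("time-course fitting recovers fluxes and the free pool", {
  gf <- inst_glycolysis_fixture(400)
  meas <- simulate_measurements(gf$model, gf$fluxes, gf$tracer, "FBP[1-6]",
                                sd = 0, seed = 1, times = c(1, 2, 4, 8, 16, 32),
                                pools = gf$pools)
  fit <- mfa_fit(gf$model, meas, gf$tracer, fixed = c(f0 = 100),
                 pools = gf$pools[c("FBP", "DHAP", "GAP")],
                 free_pools = "Glc6P", n_starts = 3, seed = 7,
                 pool_bounds = c(10, 1e5))
  expect_equal(coef(fit)[["f3"]], 50, tolerance = 0.01)
  expect_equal(coef(fit)[["f5"]], 150, tolerance = 0.01)
  expect_equal(unname(coef(fit, "pools")["Glc6P"]), 400, tolerance = 0.05)

  # reproducible given the seed
  fit2 <- mfa_fit(gf$model, meas, gf$tracer, fixed = c(f0 = 100),
                  pools = gf$pools[c("FBP", "DHAP", "GAP")],
                  free_pools = "Glc6P", n_starts = 3, seed = 7,
                  pool_bounds = c(10, 1e5))
  expect_identical(coef(fit2, "free"), coef(fit, "free"))
})

test_that("steady-state-time measurements leave pool sizes unidentified", {
  gf <- inst_glycolysis_fixture(400)
  # sample only after isotopic steady state is reached
  meas <- simulate_measurements(gf$model, gf$fluxes, gf$tracer, "FBP[1-6]",
                                sd = 0, seed = 1, times = c(400, 500),
                                pools = gf$pools)
  meas$sd <- 0.01
  spec <- free_flux_spec(gf$model, fixed = c(f0 = 100))
  ssr_at_pool <- function(p) {
    traj <- simulate_timecourse(gf$model, gf$fluxes,
                                c(Glc6P = p, FBP = 1000, DHAP = 1000,
                                  GAP = 1000), gf$tracer, c(400, 500),
                                targets = "FBP[1-6]")
    df <- as.data.frame(traj)
    mid_ssr(df, meas)
  }
  ssrs <- vapply(c(100, 400, 2000), ssr_at_pool, 0)
  expect_lt(max(ssrs) - min(ssrs), 1e-8)
})
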