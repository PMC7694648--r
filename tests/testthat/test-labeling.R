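test_that("MID convolution matches the worked condensation example", {
  dhap <- c(0.3, 0, 0.7, 0)
  gap <- c(0.5, 0, 0.5, 0)
  conv <- mid_convolve(dhap, gap)
  expect_equal(conv[c(1, 3, 5)], c(0.15, 0.50, 0.35))
  expect_equal(sum(conv), 1)

  # unlabeled fragment is the identity element (zero-padded)
  x <- c(0.2, 0.5, 0.3)
  expect_equal(mid_convolve(x, c(1, 0, 0)), c(x, 0, 0))
  # fully labeled atoms add their mass shifts
  expect_equal(mid_convolve(c(0, 1), c(0, 1)), c(0, 0, 1))
  # commutative and associative
  y <- c(0.6, 0.1, 0.3); z <- c(0.25, 0.75)
  expect_equal(mid_convolve(x, y), mid_convolve(y, x))
  expect_equal(mid_convolve(mid_convolve(x, y), z),
               mid_convolve(x, mid_convolve(y, z)))
})

test_that("steady-state solve reproduces the worked glycolysis labeling", {
  model <- upper_glycolysis_model()
  tracer <- tracer_spec(Glc = c(1, 2))
  fluxes <- glyc_fluxes(50, 150)
  sol <- predict_mids(model, fluxes, tracer,
                      c("FBP[1-3]", "FBP[4-6]", "DHAP[1-3]", "GAP[1-3]",
                        "FBP[1-6]"))
  expect_equal(sol[["FBP[1-3]"]][c(1, 3)], c(0.1000, 0.9000), tolerance = 1e-6)
  expect_equal(sol[["FBP[4-6]"]][c(1, 3)], c(0.8333, 0.1667), tolerance = 1e-4)
  expect_equal(sol[["DHAP[1-3]"]][c(1, 3)], c(0.3000, 0.7000), tolerance = 1e-6)
  expect_equal(sol[["GAP[1-3]"]][c(1, 3)], c(0.5000, 0.5000), tolerance = 1e-6)
  expect_equal(sol[["FBP[1-6]"]][c(1, 3, 5)], c(0.0500, 0.8333, 0.1167),
               tolerance = 1e-4)

  # unlabeled tracer: every EMU sits at M+0
  sol0 <- predict_mids(model, fluxes, tracer_spec(), "FBP[1-6]")
  expect_equal(sol0[["FBP[1-6]"]], c(1, rep(0, 6)))

  # hand-solved M+2 system at (f3 = 48, f5 = 210)
  sol2 <- predict_mids(model, glyc_fluxes(48, 210), tracer, "FBP[1-6]")
  expect_lt(max(abs(sol2[["FBP[1-6]"]][c(1, 3, 5)] -
                      c(0.0549, 0.8378, 0.1072))), 1e-4)
})

test_that("solver errors identify EMUs without labeled inflow", {
  model <- chain_model()
  expect_error(
    predict_mids(model, c(fAB = 0, fBC = 0), tracer_spec(A = 1), "B[1]"),
    "zero total inflow")
})

test_that("enrichment follows the average-atom definition", {
  fbp <- c(0.05, 0, 0.8333, 0, 0.1167, 0, 0)
  expect_equal(enrichment(fbp), 0.35556, tolerance = 1e-4)
  expect_equal(enrichment(c(1, 0, 0)), 0)
  expect_equal(enrichment(c(0, 0, 0, 1)), 1)
  # enrichment of a condensation product is the atom-weighted average
  dhap <- c(0.3, 0, 0.7, 0); gap <- c(0.5, 0, 0.5, 0)
  expect_equal(enrichment(mid_convolve(dhap, gap)),
               (3 * enrichment(dhap) + 3 * enrichment(gap)) / 6)
})

test_that("positional enrichments equal size-1 EMU solves", {
  model <- upper_glycolysis_model()
  tracer <- tracer_spec(Glc = c(1, 2))
  fluxes <- glyc_fluxes(50, 150)
  # C2 of DHAP is co-labeled with C1 under the 1,2-13C2 tracer
  expect_equal(positional_enrichment(model, fluxes, tracer, "DHAP", 2), 0.7,
               tolerance = 1e-9)
  # no atom path delivers label to DHAP C3
  expect_equal(positional_enrichment(model, fluxes, tracer, "DHAP", 3), 0)
  expect_equal(positional_enrichment(model, fluxes, tracer_spec(), "DHAP", 1), 0)
  expect_error(positional_enrichment(model, fluxes, tracer, "DHAP", 4),
               "position must be in")
})

test_that("EMU solver agrees with the brute-force isotopomer oracle", {
  model <- upper_glycolysis_model()
  tracer <- tracer_spec(Glc = c(1, 2))
  for (free in list(c(50, 150), c(48, 210), c(12, 7))) {
    fluxes <- glyc_fluxes(free[1], free[2])
    iso <- isotopomer_steady(model, fluxes, tracer)
    sol <- predict_mids(model, fluxes, tracer,
                        c("FBP[1-6]", "FBP[1-3]", "DHAP[1-3]", "GAP[1-3]"))
    for (emu in names(sol))
      expect_equal(sol[[emu]], isotopomer_mid(iso, emu), tolerance = 1e-6)
  }
  # trivial one-carbon chain with a 50% labeled source
  m1 <- read_flux_model(text = c(
    "A, 1, source", "B, 1, balanced", "C, 1, sink",
    "fin: A (a) -> B (a)", "fout: B (a) -> C (a)"))
  half <- tracer_spec(A = list(list(positions = 1, fraction = 0.5),
                               list(positions = integer(), fraction = 0.5)))
  iso1 <- isotopomer_steady(m1, c(fin = 5, fout = 5), half)
  expect_equal(as.numeric(iso1$B), c(0.5, 0.5), tolerance = 1e-6)

  # the oracle also honors molecular symmetry
  sym <- symmetric_model()
  iso2 <- isotopomer_steady(sym, c(fin = 10, fout = 10), tracer_spec(A = 1))
  expect_equal(isotopomer_mid(iso2, "S[1]"), c(0.5, 0.5), tolerance = 1e-6)

  expect_error(isotopomer_steady(chain_model(), c(fAB = 1, fBC = 1),
                                 tracer_spec(), max_states = 4),
               "cap exceeded")
})

test_that("steady-state MIDs are flux-scale invariant and normalized", {
  model <- upper_glycolysis_model()
  tracer <- tracer_spec(Glc = c(1, 2))
  set.seed(21)
  for (i in 1:8) {
    u <- exp(runif(2, log(5), log(500)))
    base <- predict_mids(model, glyc_fluxes(u[1], u[2]), tracer, "FBP[1-6]")
    for (lambda in c(0.1, 17)) {
      spec <- free_flux_spec(model, fixed = c(f1 = 100 * lambda))
      scaled <- predict_mids(model, complete_fluxes(spec, u * lambda),
                             tracer, "FBP[1-6]")
      expect_equal(scaled[["FBP[1-6]"]], base[["FBP[1-6]"]], tolerance = 1e-9)
    }
    expect_equal(sum(base[["FBP[1-6]"]]), 1, tolerance = 1e-9)
    expect_true(all(base[["FBP[1-6]"]] >= 0))
  }
})

test_that("a metabolite's MID depends only on its production fluxes", {
  model <- branch_model()
  tracer <- tracer_spec(A = 1)
  mid_at <- function(fBC) {
    fluxes <- c(fAB = 10, fBC = fBC, fBD = 10 - fBC)
    predict_mids(model, fluxes, tracer, "B[1-2]")[["B[1-2]"]]
  }
  expect_equal(mid_at(2), mid_at(8), tolerance = 1e-12)
})
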