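## Built-in example networks and the synthetic measurement generator.
##
## The upper-glycolysis network: glucose enters via hexokinase/PGI (lumped
## into f1), aldolase splits FBP into DHAP + GAP reversibly (f2 forward,
## f3 reverse), triose phosphate isomerase interconverts DHAP and GAP
## reversibly (f4 forward, f5 reverse), and GAP leaves to lower glycolysis
## (f6). With glucose uptake fixed at 100 nmol/h the reverse fluxes f3 and
## f5 are the two free fluxes; the reference state uses f3 = 50, f5 = 150.

upper_glycolysis_text <- c(
  "# upper glycolysis, traced carbons only",
  "Glc, 6, source",
  "FBP, 6, balanced",
  "DHAP, 3, balanced",
  "GAP, 3, balanced",
  "LowerGlycolysis, 3, sink",
  "f1: Glc (abcdef) -> FBP (abcdef)",
  "f2: FBP (abcdef) -> DHAP (abc) + GAP (def)",
  "f3: DHAP (abc) + GAP (def) -> FBP (abcdef)",
  "f4: DHAP (abc) -> GAP (cba)",
  "f5: GAP (abc) -> DHAP (cba)",
  "f6: GAP (abc) -> LowerGlycolysis (abc)")

#' The upper-glycolysis example network
#'
#' Six traced-carbon metabolites and six reaction steps; the aldolase and
#' triose phosphate isomerase (TPI) reactions are reversible and are written
#' as forward/reverse step pairs (f2/f3 and f4/f5). The TPI atom map uses
#' the chemically correct orientation (DHAP C1 to GAP C3, C2 to C2, C3 to
#' GAP C1).
#'
#' @return A [flux_model()].
#' @export
upper_glycolysis_model <- function() {
  read_flux_model(text = upper_glycolysis_text, name = "upper_glycolysis")
}

#' The upper-glycolysis fixture bundle
#'
#' The example network together with the 1,2-13C2-glucose tracer, the
#' reference flux state (f1 = 100 nmol/h fixed, f3 = 50, f5 = 150, the rest
#' from balance) and the reference FBP[1-6] measurement it predicts
#' (M+0 = 0.05, M+2 = 0.8333, M+4 = 0.1167, SD 0.01 per labeled fraction).
#'
#' @param sd Per-fraction measurement SD attached to the reference MID.
#' @return List with `model`, `tracer`, `fixed`, `free_values`, `fluxes`
#'   (full reference flux vector) and `measurements`.
#' @export
upper_glycolysis_fixture <- function(sd = 0.01) {
  model <- upper_glycolysis_model()
  tracer <- tracer_spec(Glc = c(1, 2))
  spec <- free_flux_spec(model, fixed = c(f1 = 100))
  free_values <- c(f3 = 50, f5 = 150)
  fluxes <- complete_fluxes(spec, free_values)
  mids <- predict_mids(model, fluxes, tracer, "FBP[1-6]")
  meas <- as.data.frame(mids)
  meas <- meas[meas$fraction > 1e-12, ]
  meas$sd <- sd
  list(model = model, tracer = tracer, fixed = c(f1 = 100),
       free_values = free_values, fluxes = fluxes,
       measurements = mid_measurements(meas))
}

#' Upper glycolysis with an explicit Glc6P pool (non-stationary fixture)
#'
#' Splits the lumped glucose-uptake step so that glucose-6-phosphate
#' (Fruc6P lumped in) is an explicit balanced intermediate whose pool size
#' delays FBP labeling after the tracer switch. Pools: FBP, DHAP and GAP at
#' 1000 nmol each; Glc6P as given (400 or 3000 nmol in the worked
#' comparison). Flux values reuse the steady-state reference ratios
#' (f1 = 100, f3 = 50, f5 = 150).
#'
#' @param glc6p_pool Glc6P pool amount in nmol.
#' @return List with `model`, `tracer`, `fixed`, `free_values`, `fluxes` and
#'   `pools`.
#' @export
inst_glycolysis_fixture <- function(glc6p_pool = 400) {
  if (glc6p_pool <= 0) stop("glc6p_pool must be > 0")
  text <- c(
    "# upper glycolysis with explicit Glc6P (Fruc6P lumped in)",
    "Glc, 6, source",
    "Glc6P, 6, balanced",
    "FBP, 6, balanced",
    "DHAP, 3, balanced",
    "GAP, 3, balanced",
    "LowerGlycolysis, 3, sink",
    "f0: Glc (abcdef) -> Glc6P (abcdef)",
    "f1: Glc6P (abcdef) -> FBP (abcdef)",
    "f2: FBP (abcdef) -> DHAP (abc) + GAP (def)",
    "f3: DHAP (abc) + GAP (def) -> FBP (abcdef)",
    "f4: DHAP (abc) -> GAP (cba)",
    "f5: GAP (abc) -> DHAP (cba)",
    "f6: GAP (abc) -> LowerGlycolysis (abc)")
  model <- read_flux_model(text = text, name = "upper_glycolysis_glc6p")
  spec <- free_flux_spec(model, fixed = c(f0 = 100))
  free_values <- c(f3 = 50, f5 = 150)
  fluxes <- complete_fluxes(spec, free_values)
  list(model = model, tracer = tracer_spec(Glc = c(1, 2)),
       fixed = c(f0 = 100), free_values = free_values, fluxes = fluxes,
       pools = c(Glc6P = glc6p_pool, FBP = 1000, DHAP = 1000, GAP = 1000))
}

#' Generate synthetic noisy MID measurements
#'
#' Predicts the target MIDs (steady state, or a time course when `times` is
#' given) and adds independent Gaussian noise of standard deviation `sd` per
#' fraction; negatives are clipped at zero and each MID renormalized. The
#' `sd` column of the output records the nominal noise level.
#'
#' @param model A [flux_model()].
#' @param fluxes Named numeric flux vector (balanced).
#' @param tracer A [tracer_spec()].
#' @param targets Character vector of EMU labels to "measure".
#' @param sd Gaussian noise SD per fraction (0 gives exact predictions). The
#'   recorded `sd` column is `max(sd, sd_floor)` so downstream weighting is
#'   always defined.
#' @param seed Integer seed.
#' @param times Optional time points; requires `pools`.
#' @param pools Pool amounts for the time-course case.
#' @param sd_floor Smallest SD recorded in the output.
#' @return A [mid_measurements()] data frame.
#' @export
simulate_measurements <- function(model, fluxes, tracer, targets, sd = 0.01,
                                  seed = 1L, times = NULL, pools = NULL,
                                  sd_floor = 1e-6) {
  if (sd < 0) stop("sd must be >= 0")
  if (is.null(times)) {
    pred <- as.data.frame(predict_mids(model, fluxes, tracer, targets))
    pred$time <- NA_real_
  } else {
    traj <- simulate_timecourse(model, fluxes, pools, tracer, times,
                                targets = targets)
    pred <- as.data.frame(traj)
    pred <- pred[pred$time %in% times, , drop = FALSE]  # drop the implicit t=0
  }
  ## structural zeros (no atom path) are not measurable fractions; keeping
  ## them would only inject clipped noise
  pred <- pred[pred$fraction > 1e-12, , drop = FALSE]
  pred <- with_seed(seed, {
    pred$fraction <- pred$fraction + stats::rnorm(nrow(pred), 0, sd)
    pred
  })
  grp <- paste(pred$emu, pred$time, sep = "\r")
  for (g in unique(grp)) {
    idx <- grp == g
    v <- pmax(pred$fraction[idx], 0)
    pred$fraction[idx] <- v / sum(v)
  }
  pred$sd <- max(sd, sd_floor)
  mid_measurements(pred[, c("emu", "mass_shift", "fraction", "sd", "time")])
}
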