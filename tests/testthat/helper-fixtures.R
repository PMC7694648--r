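# Small networks used across the test files; everything is built in code.

# linear chain A -> B -> C(sink), one balance equation
chain_model <- function() {
  read_flux_model(text = c(
    "A, 3, source",
    "B, 3, balanced",
    "C, 3, sink",
    "fAB: A (abc) -> B (abc)",
    "fBC: B (abc) -> C (abc)"), name = "chain")
}

# B has two consumers; its MID must not depend on how they split
branch_model <- function() {
  read_flux_model(text = c(
    "A, 2, source",
    "B, 2, balanced",
    "C, 2, sink",
    "D, 2, sink",
    "fAB: A (ab) -> B (ab)",
    "fBC: B (ab) -> C (ab)",
    "fBD: B (ab) -> D (ab)"), name = "branch")
}

# 4-carbon symmetric metabolite (succinate-like, involution 4321)
symmetric_model <- function(symmetric = TRUE) {
  read_flux_model(text = c(
    "A, 4, source",
    sprintf("S, 4, balanced%s", if (symmetric) ", symmetry=4321" else ""),
    "Out, 4, sink",
    "fin: A (abcd) -> S (abcd)",
    "fout: S (abcd) -> Out (abcd)"),
    name = if (symmetric) "symmetric" else "prochiral")
}

# 50% U-13C glucose + 50% unlabeled glucose
tracer_u13c_mix <- function() {
  tracer_spec(Glc = list(list(positions = 1:6, fraction = 0.5),
                         list(positions = integer(), fraction = 0.5)))
}

glyc_spec <- function(model) free_flux_spec(model, fixed = c(f1 = 100))

glyc_fluxes <- function(f3, f5, model = upper_glycolysis_model())
  complete_fluxes(glyc_spec(model), c(f3 = f3, f5 = f5))

# the paper's printed FBP measurement (1% SD per labeled fraction)
printed_fbp_measurements <- function(sd = 0.01) {
  mid_measurements(data.frame(
    emu = "FBP[1-6]", mass_shift = c(0, 2, 4),
    fraction = c(0.0500, 0.8333, 0.1167), sd = sd))
}
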