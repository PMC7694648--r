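## Measured mass isotopomer distributions.
##
## A measurement set is a long-format table keyed by (EMU label, mass shift,
## time); steady-state rows carry NA time. Each observed MID must sum to 1
## within 0.02 and is renormalized exactly; standard deviations are kept as
## given (the SSR of the fit weights residuals by them).

#' Construct a measurement set of mass isotopomer distributions
#'
#' @param data A data frame with columns `emu` (EMU label such as
#'   `"FBP[1-6]"`), `mass_shift` (integer k for the M+k fraction), `fraction`,
#'   `sd` and optionally `time` (NA or absent for steady state).
#' @return A data frame of class `"mid_measurements"` with fractions
#'   renormalized to sum exactly 1 per (emu, time) group.
#' @export
mid_measurements <- function(data) {
  need <- c("emu", "mass_shift", "fraction", "sd")
  if (!all(need %in% names(data)))
    stop("measurements need columns: ", paste(need, collapse = ", "))
  if (!"time" %in% names(data)) data$time <- NA_real_
  data <- data[, c("emu", "mass_shift", "fraction", "sd", "time")]
  data$emu <- as.character(data$emu)
  for (col in c("mass_shift", "fraction", "sd", "time")) {
    v <- data[[col]]
    if (!is.numeric(v) && !all(is.na(v)))
      stop("non-numeric values in column '", col, "'")
    data[[col]] <- as.numeric(v)
  }
  if (any(!is.finite(data$fraction)) || any(!is.finite(data$sd)))
    stop("non-numeric values in 'fraction' or 'sd'")
  if (any(data$sd <= 0)) stop("all SDs must be > 0")
  key <- paste(data$emu, data$mass_shift, data$time, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate measurement for ",
         sub("\r", " M+", key[duplicated(key)][1L]))
  grp <- paste(data$emu, data$time, sep = "\r")
  for (g in unique(grp)) {
    idx <- grp == g
    s <- sum(data$fraction[idx])
    if (s < 0.98 || s > 1.02)
      stop(sprintf("MID of %s sums to %.4f (must be within [0.98, 1.02])",
                   data$emu[idx][1L], s))
    data$fraction[idx] <- data$fraction[idx] / s
  }
  class(data) <- c("mid_measurements", "data.frame")
  data
}

#' Read measured MIDs from a CSV file
#'
#' Expected columns: `emu`, `mass_shift`, `fraction`, `sd` and optionally
#' `time` (blank for steady state).
#'
#' @param file CSV path.
#' @return A [mid_measurements()] data frame.
#' @export
read_mid_measurements <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  mid_measurements(df)
}

#' Write a measurement set (or predicted MIDs) to CSV
#'
#' @param x A `mid_measurements` data frame.
#' @param file Output path.
#' @export
write_mid_measurements <- function(x, file) {
  utils::write.csv(x, file, row.names = FALSE, quote = FALSE, na = "")
  invisible(x)
}

## split "FBP[1-3,5]" into list(met, atoms)
parse_emu_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z0-9_.]+)\\[([0-9,\\-]+)\\]$", label))[[1]]
  if (length(m) != 3L) stop("cannot parse EMU label '", label, "'")
  parts <- strsplit(m[3], ",", fixed = TRUE)[[1]]
  atoms <- unlist(lapply(parts, function(p) {
    if (grepl("-", p, fixed = TRUE)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
      seq(ab[1], ab[2])
    } else as.integer(p)
  }))
  if (anyDuplicated(atoms)) stop("duplicate atom in EMU label '", label, "'")
  list(met = m[2], atoms = sort(atoms))
}

## canonical text form: runs collapsed, "FBP[1-3]" / "FBP[1,3]" / "FBP[1-2,4]"
format_emu_label <- function(met, atoms) {
  atoms <- sort(as.integer(atoms))
  runs <- split(atoms, cumsum(c(1L, diff(atoms) != 1L)))
  txt <- vapply(runs, function(r)
    if (length(r) > 1L) sprintf("%d-%d", r[1L], r[length(r)])
    else as.character(r), "")
  sprintf("%s[%s]", met, paste(txt, collapse = ","))
}
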