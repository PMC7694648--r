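## Flux estimation by variance-weighted least squares.
##
## The fit minimizes the SSR -- the sum over measured MID fractions of
## ((measured - predicted)/SD)^2, i.e. a diagonal measurement covariance --
## over the free fluxes (and, for time-resolved data, any metabolite pools
## declared free). Because the SSR landscape can have local minima, the
## bounded Levenberg-Marquardt search is restarted from several random
## initial points; all endpoints are retained.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Variance-weighted sum of squared residuals
#'
#' @param predicted Predicted MIDs: a `mid_set` (steady state) or a data
#'   frame with columns `emu`, `mass_shift`, `fraction` and optionally
#'   `time`.
#' @param measured A [mid_measurements()] data frame.
#' @return The SSR: `sum(((measured - predicted)/sd)^2)`.
#' @export
mid_ssr <- function(predicted, measured) {
  if (inherits(predicted, "mid_set")) predicted <- as.data.frame(predicted)
  if (!"time" %in% names(predicted)) predicted$time <- NA_real_
  pk <- paste(predicted$emu, predicted$mass_shift, predicted$time, sep = "\r")
  mk <- paste(measured$emu, measured$mass_shift, measured$time, sep = "\r")
  pos <- match(mk, pk)
  if (anyNA(pos))
    stop("missing prediction for measured fraction ",
         sub("\r", " M+", mk[is.na(pos)][1L]))
  sum(((measured$fraction - predicted$fraction[pos]) / measured$sd)^2)
}

## build the residual closure shared by mfa_fit, profile CIs and regions
make_residual_fn <- function(model, measurements, tracer, spec,
                             pools = NULL, free_pools = character(),
                             times = NULL) {
  targets <- unique(measurements$emu)
  emunet <- emu_decompose(model, targets)
  canon <- vapply(targets, function(tg) emu_canonical(model, tg)$label, "")
  names(canon) <- targets
  sizes <- stats::setNames(emunet$nodes$size, emunet$nodes$label)
  bad <- measurements$mass_shift > sizes[canon[measurements$emu]] |
    measurements$mass_shift < 0
  if (any(bad))
    stop("measured mass shift exceeds EMU size for ",
         measurements$emu[bad][1L])
  row_node <- canon[measurements$emu]
  row_k <- measurements$mass_shift + 1L
  inst <- !is.null(times)
  n_par <- length(spec$free) + length(free_pools)
  n_res <- nrow(measurements)

  if (inst) {
    row_time <- measurements$time
    needed <- needed_pools(model, emunet)
    static <- setdiff(needed, free_pools)
    miss <- static[vapply(static, function(m)
      is.null(pools[[m]]), NA)]
    if (length(miss))
      stop("missing pool size for: ", paste(miss, collapse = ", "))
  }

  function(par) {
    u <- par[seq_along(spec$free)]
    fluxes <- complete_fluxes(spec, u)
    if (any(fluxes < -1e-9))
      return(rep(1e3 * (1 + sum(pmax(-fluxes, 0))), n_res))
    res <- try({
      if (!inst) {
        sol <- solve_emu_network(emunet, fluxes, tracer)
        pred <- vapply(seq_len(n_res), function(i)
          sol[[row_node[i]]][row_k[i]], 0)
      } else {
        pl <- as.list(pools)
        if (length(free_pools))
          pl[free_pools] <- par[length(spec$free) + seq_along(free_pools)]
        traj <- integrate_emu_ode(model, emunet, fluxes, unlist(pl), tracer,
                                  sort(unique(c(0, times))))
        pred <- vapply(seq_len(n_res), function(i)
          traj$interp(row_node[i], row_k[i], row_time[i]), 0)
      }
      (pred - measurements$fraction) / measurements$sd
    }, silent = TRUE)
    if (inherits(res, "try-error")) rep(1e3, n_res) else res
  }
}

#' Fit metabolic fluxes to measured mass isotopomer distributions
#'
#' The central estimator. For steady-state measurements (no `time` column or
#' all `NA`) the free fluxes of the network are fitted by multi-start bounded
#' Levenberg-Marquardt least squares on the variance-weighted residuals. For
#' time-stamped measurements the EMU labeling ODE is integrated and metabolite
#' pool sizes govern the labeling kinetics; pools named in `free_pools` are
#' estimated alongside the fluxes.
#'
#' @param model A [flux_model()].
#' @param measurements A [mid_measurements()] data frame (or plain data frame
#'   with the same columns).
#' @param tracer A [tracer_spec()].
#' @param fixed Named numeric vector of fixed fluxes, e.g. `c(f1 = 100)`.
#' @param free Optional explicit choice of free fluxes (see
#'   [free_flux_spec()]).
#' @param pools Named numeric vector/list of pool sizes (nmol); required for
#'   time-resolved fits, for every balanced metabolite on the EMU paths.
#' @param free_pools Character vector of pool names to estimate.
#' @param n_starts Number of random restarts.
#' @param seed Integer seed making the restarts reproducible.
#' @param bounds Length-2 box bounds for every free flux.
#' @param pool_bounds Length-2 box bounds for every free pool.
#' @param start Optional numeric vector: use this single start instead of
#'   random ones (length `n_free + length(free_pools)`).
#' @return An object of class `"mfa_fit"`; see [coef.mfa_fit()],
#'   [confint.mfa_fit()], [predict.mfa_fit()], [simulate.mfa_fit()].
#' @examples
#' fx <- upper_glycolysis_fixture()
#' fit <- mfa_fit(fx$model, fx$measurements, fx$tracer, fixed = c(f1 = 100),
#'                n_starts = 3, seed = 1)
#' coef(fit)
#' @export
mfa_fit <- function(model, measurements, tracer,
                    fixed = numeric(), free = NULL,
                    pools = NULL, free_pools = character(),
                    n_starts = 10, seed = 1L,
                    bounds = c(0, 1e4), pool_bounds = c(1, 1e6),
                    start = NULL) {
  if (!inherits(measurements, "mid_measurements"))
    measurements <- mid_measurements(measurements)
  if (nrow(measurements) == 0L) stop("no measurements")
  spec <- free_flux_spec(model, fixed = fixed, free = free, bounds = bounds)
  has_time <- !all(is.na(measurements$time))
  if (has_time && anyNA(measurements$time))
    stop("mix of timed and steady-state rows; split the measurement set")
  times <- if (has_time) sort(unique(measurements$time)) else NULL
  if (!has_time && length(free_pools))
    stop("free pools require time-resolved measurements")
  resid_fn <- make_residual_fn(model, measurements, tracer, spec,
                               pools = pools, free_pools = free_pools,
                               times = times)
  n_free <- length(spec$free)
  par_names <- c(spec$free, if (length(free_pools))
    paste0("pool.", free_pools))
  lower <- c(spec$bounds["lower", ], rep(pool_bounds[1], length(free_pools)))
  upper <- c(spec$bounds["upper", ], rep(pool_bounds[2], length(free_pools)))
  n_par <- length(par_names)

  if (n_par == 0L) {   # fully determined network: just evaluate
    r <- resid_fn(numeric(0))
    fluxes <- complete_fluxes(spec, numeric(0))
    fit <- list(par = numeric(0), ssr = sum(r^2), starts = NULL)
  } else {
    ## log-uniform random starts within the box (floor well above zero)
    lo_eff <- pmax(lower, upper * 1e-4)
    starts <- if (!is.null(start)) matrix(start, nrow = 1) else
      with_seed(seed, matrix(exp(stats::runif(n_starts * n_par,
                                              log(lo_eff), log(upper))),
                             ncol = n_par, byrow = TRUE))
    recs <- vector("list", nrow(starts))
    for (i in seq_len(nrow(starts))) {
      ## nls.lm warns on degenerate zero-residual fits; the info code in the
      ## result already records convergence
      res <- try(suppressWarnings(minpack.lm::nls.lm(
        par = starts[i, ], lower = lower, upper = upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                             maxiter = 300))), silent = TRUE)
      recs[[i]] <- if (inherits(res, "try-error"))
        list(final = rep(NA_real_, n_par), ssr = Inf, converged = FALSE)
      else list(final = res$par, ssr = sum(res$fvec^2),
                converged = res$info %in% 1:4)
    }
    ssrs <- vapply(recs, `[[`, 0, "ssr")
    if (!any(is.finite(ssrs)))
      stop("no optimization start converged; check model, bounds and measurements")
    ## tie-break near-equal SSRs by the smallest parameter norm
    best_ssr <- min(ssrs)
    cand <- which(ssrs <= best_ssr + 1e-9)
    norms <- vapply(cand, function(i) sqrt(sum(recs[[i]]$final^2)), 0)
    ibest <- cand[which.min(norms)]
    starts_df <- data.frame(
      start = seq_len(nrow(starts)),
      matrix(starts, nrow(starts), dimnames = list(NULL, paste0("init.", par_names))),
      matrix(t(vapply(recs, `[[`, numeric(n_par), "final")), nrow(starts),
             dimnames = list(NULL, paste0("final.", par_names))),
      ssr = ssrs,
      converged = vapply(recs, `[[`, NA, "converged"))
    fit <- list(par = stats::setNames(recs[[ibest]]$final, par_names),
                ssr = recs[[ibest]]$ssr, starts = starts_df)
    fluxes <- complete_fluxes(spec, fit$par[seq_len(n_free)])
  }

  pools_hat <- NULL
  if (has_time) {
    pools_hat <- unlist(as.list(pools))
    if (length(free_pools))
      pools_hat[free_pools] <- fit$par[n_free + seq_along(free_pools)]
  }
  object <- structure(list(
    model = model, tracer = tracer, measurements = measurements,
    spec = spec, par = fit$par, par_names = par_names,
    free_pools = free_pools, pools = pools_hat,
    fluxes = fluxes, ssr = fit$ssr, starts = fit$starts,
    times = times, seed = seed, bounds = rbind(lower = lower, upper = upper),
    call = match.call()), class = "mfa_fit")
  object$predicted <- predict(object)
  object
}

## balanced metabolites whose pools the EMU ODE needs
needed_pools <- function(model, emunet) {
  unique(emunet$nodes$met[!emunet$nodes$is_source])
}

#' @export
print.mfa_fit <- function(x, digits = 4, ...) {
  cat("MFA fit (", x$model$name, ")\n", sep = "")
  cat("  SSR:", format(x$ssr, digits = digits), "on",
      nrow(x$measurements) - length(x$par), "residual degrees of freedom\n")
  cat("  fluxes:\n")
  print(round(x$fluxes, digits))
  if (length(x$free_pools)) {
    cat("  fitted pools (nmol):\n")
    print(round(x$pools[x$free_pools], digits))
  }
  if (!is.null(x$starts))
    cat(sprintf("  %d/%d starts converged\n", sum(x$starts$converged),
                nrow(x$starts)))
  invisible(x)
}

#' @export
summary.mfa_fit <- function(object, level = 0.95, ...) {
  df <- nrow(object$measurements) - length(object$par)
  out <- list(fit = object, df = df,
              chi2_cutoff = chi2_cutoff(level, max(df, 1)),
              level = level)
  class(out) <- "summary.mfa_fit"
  out
}

#' @export
print.summary.mfa_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  goodness of fit: SSR = %.4g vs chi-square(%.2g, df=%d) = %.4g%s\n",
              x$fit$ssr, x$level, x$df, x$chi2_cutoff,
              if (x$fit$ssr <= x$chi2_cutoff) " (acceptable)" else " (rejected)"))
  if (!is.null(x$fit$starts)) {
    cat("  multi-start endpoints:\n")
    print(x$fit$starts[, c("start", "ssr", "converged")], row.names = FALSE)
  }
  invisible(x)
}

#' Extract fitted fluxes (or free parameters) from an MFA fit
#'
#' @param object An `mfa_fit`.
#' @param type `"fluxes"` (full flux vector, default), `"free"` (free
#'   parameters, including any free pools) or `"pools"`.
#' @param ... Unused.
#' @return Named numeric vector.
#' @export
coef.mfa_fit <- function(object, type = c("fluxes", "free", "pools"), ...) {
  switch(match.arg(type),
         fluxes = object$fluxes,
         free = object$par,
         pools = object$pools)
}

#' @export
deviance.mfa_fit <- function(object, ...) object$ssr

#' Predicted MIDs at the fitted (or supplied) fluxes
#'
#' @param object An `mfa_fit`.
#' @param fluxes Optional full flux vector overriding the fitted one.
#' @param ... Unused.
#' @return Data frame `emu`, `mass_shift`, `time`, `fraction` aligned with
#'   the measurement set.
#' @export
predict.mfa_fit <- function(object, fluxes = NULL, ...) {
  if (is.null(fluxes)) fluxes <- object$fluxes
  meas <- object$measurements
  if (is.null(object$times)) {
    sol <- predict_mids(object$model, fluxes, object$tracer,
                        unique(meas$emu))
    pred <- as.data.frame(sol)
    pred$time <- NA_real_
  } else {
    traj <- simulate_timecourse(object$model, fluxes, object$pools,
                                object$tracer,
                                sort(unique(c(0, object$times))),
                                targets = unique(meas$emu))
    pred <- as.data.frame(traj)
  }
  key <- paste(pred$emu, pred$mass_shift, pred$time, sep = "\r")
  mkey <- paste(meas$emu, meas$mass_shift, meas$time, sep = "\r")
  ## canonical EMU labels can differ from measured spellings
  if (anyNA(match(mkey, key))) {
    canon <- vapply(unique(meas$emu), function(tg)
      emu_canonical(object$model, tg)$label, "")
    mkey <- paste(canon[meas$emu], meas$mass_shift, meas$time, sep = "\r")
  }
  data.frame(emu = meas$emu, mass_shift = meas$mass_shift, time = meas$time,
             fraction = pred$fraction[match(mkey, key)],
             stringsAsFactors = FALSE)
}

#' Weighted residuals of an MFA fit
#'
#' @param object An `mfa_fit`.
#' @param ... Unused.
#' @return Numeric vector `(measured - predicted)/sd`, one per measured
#'   fraction.
#' @export
residuals.mfa_fit <- function(object, ...) {
  (object$measurements$fraction - object$predicted$fraction) /
    object$measurements$sd
}

#' Simulate measurement replicates from a fitted model
#'
#' Draws synthetic measurement sets at the fitted fluxes: Gaussian noise with
#' the measurement SDs is added per fraction, negatives are clipped and each
#' MID renormalized.
#'
#' @param object An `mfa_fit`.
#' @param nsim Number of replicate measurement sets.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `mid_measurements` data frames of length `nsim`.
#' @export
simulate.mfa_fit <- function(object, nsim = 1, seed = 1L, ...) {
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    df <- object$measurements
    df$fraction <- object$predicted$fraction +
      stats::rnorm(nrow(df), 0, df$sd)
    grp <- paste(df$emu, df$time, sep = "\r")
    for (g in unique(grp)) {
      idx <- grp == g
      v <- pmax(df$fraction[idx], 0)
      df$fraction[idx] <- v / sum(v)
    }
    class(df) <- c("mid_measurements", "data.frame")
    df
  }))
}

#' Plot measured versus predicted MID fractions
#'
#' @param x An `mfa_fit`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.mfa_fit <- function(x, ...) {
  m <- x$measurements
  lab <- paste0(m$emu, " M+", m$mass_shift,
                ifelse(is.na(m$time), "", paste0(" t=", m$time)))
  h <- rbind(measured = m$fraction, predicted = x$predicted$fraction)
  graphics::barplot(h, beside = TRUE, names.arg = lab, las = 2,
                    legend.text = rownames(h), ylab = "MID fraction", ...)
  invisible(x)
}
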