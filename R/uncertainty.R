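## Flux uncertainty: chi-square cutoffs, profile-likelihood confidence
## intervals, 2-D confidence-region rasters, and Monte-Carlo sampling.
##
## A sub-optimal flux combination is statistically acceptable while its SSR
## stays below SSR_min + chi-square(alpha, df). Following the worked
## glycolysis example, df = 1 is the default for both per-flux profiles and
## the 2-D region raster; the conventional df = 2 region is available via
## the `df` argument.

#' Chi-square quantile used as an SSR acceptance cutoff
#'
#' @param alpha Confidence level in (0, 1), e.g. 0.95.
#' @param df Degrees of freedom (>= 1).
#' @return The `alpha` quantile of the chi-square distribution with `df`
#'   degrees of freedom.
#' @export
chi2_cutoff <- function(alpha, df) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (df < 1) stop("df must be >= 1")
  stats::qchisq(alpha, df)
}

## SSR profile over one parameter with the others re-optimized
make_profile_fn <- function(object) {
  resid_fn <- make_residual_fn(object$model, object$measurements,
                               object$tracer, object$spec,
                               pools = object$pools,
                               free_pools = object$free_pools,
                               times = object$times)
  n_par <- length(object$par)
  lower <- object$bounds["lower", ]
  upper <- object$bounds["upper", ]
  function(j, v, warm) {
    full <- warm
    full[j] <- v
    if (n_par == 1L)
      return(list(ssr = sum(resid_fn(full)^2), par = full))
    sub_fn <- function(q) {
      full[-j] <- q
      resid_fn(full)
    }
    res <- minpack.lm::nls.lm(
      par = warm[-j], lower = lower[-j], upper = upper[-j], fn = sub_fn,
      control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                           maxiter = 300))
    full[-j] <- res$par
    list(ssr = sum(res$fvec^2), par = full)
  }
}

#' Profile-likelihood confidence intervals for fitted parameters
#'
#' Implements the classic three-step procedure: step the target parameter
#' away from its best-fit value, re-optimize all other free parameters, and
#' repeat until the SSR crosses `SSR_min + chi2_cutoff(level, df = 1)`. The
#' crossing is then located by bisection to three significant figures. When
#' the profile reaches an optimization bound before crossing, the bound is
#' reported and flagged.
#'
#' @param object An [mfa_fit()].
#' @param parm Parameter names to profile (default: all free parameters).
#' @param level Confidence level.
#' @param df Degrees of freedom of the cutoff (default 1).
#' @param ... Unused.
#' @return A data frame of class `"mfa_confint"` with columns `estimate`,
#'   `lower`, `upper`, `hit_lower_bound`, `hit_upper_bound`.
#' @export
confint.mfa_fit <- function(object, parm = NULL, level = 0.95, df = 1, ...) {
  if (is.null(parm)) parm <- object$par_names
  if (!all(parm %in% object$par_names))
    stop("not a free parameter: ",
         paste(setdiff(parm, object$par_names), collapse = ", "))
  profile <- make_profile_fn(object)
  threshold <- object$ssr + chi2_cutoff(level, df)
  lower_b <- object$bounds["lower", ]
  upper_b <- object$bounds["upper", ]
  rows <- lapply(parm, function(pn) {
    j <- match(pn, object$par_names)
    best <- object$par[j]
    one_side <- function(dir) {   # dir = -1 lower, +1 upper
      bound <- if (dir < 0) lower_b[j] else upper_b[j]
      step <- 0.01 * abs(best)
      if (step == 0) step <- 1
      v_in <- best; warm <- object$par; hit <- FALSE
      repeat {
        v <- best + dir * step
        at_bound <- (dir < 0 && v <= bound) || (dir > 0 && v >= bound)
        if (at_bound) v <- bound
        pr <- profile(j, v, warm)
        if (pr$ssr > threshold) { v_out <- v; break }
        v_in <- v; warm <- pr$par
        if (at_bound) { hit <- TRUE; v_out <- v; break }
        step <- step * 2
      }
      if (hit) return(list(value = bound, hit = TRUE))
      ## bisection to ~3 significant figures
      while (abs(v_out - v_in) > 5e-4 * max(abs(v_in), abs(v_out), 1e-6)) {
        mid <- (v_in + v_out) / 2
        pr <- profile(j, mid, warm)
        if (pr$ssr > threshold) v_out <- mid
        else { v_in <- mid; warm <- pr$par }
      }
      list(value = (v_in + v_out) / 2, hit = FALSE)
    }
    lo <- one_side(-1); hi <- one_side(1)
    data.frame(parameter = pn, estimate = unname(best),
               lower = lo$value, upper = hi$value,
               hit_lower_bound = lo$hit, hit_upper_bound = hi$hit,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "level") <- level
  attr(out, "df") <- df
  class(out) <- c("mfa_confint", "data.frame")
  out
}

#' @export
print.mfa_confint <- function(x, digits = 4, ...) {
  cat(sprintf("%g%% profile-likelihood confidence intervals (df = %d)\n",
              100 * attr(x, "level"), attr(x, "df")))
  df <- as.data.frame(x)
  df$lower <- signif(df$lower, digits); df$upper <- signif(df$upper, digits)
  df$estimate <- signif(df$estimate, digits)
  flag <- ifelse(df$hit_lower_bound | df$hit_upper_bound, " (at bound)", "")
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-10s %g  [%g, %g]%s\n", df$parameter[i], df$estimate[i],
                df$lower[i], df$upper[i], flag[i]))
  invisible(x)
}

#' SSR raster over two free parameters (confidence region)
#'
#' Evaluates the SSR on a rectangular grid of two free parameters; any other
#' free parameters are re-optimized per cell. Grid cells with
#' `SSR <= SSR_min + chi2_cutoff(level, df)` form the confidence region.
#' Plotting the region shows which flux directions the measurement
#' constrains -- the basis of tracer evaluation.
#'
#' @param object An [mfa_fit()].
#' @param pair Character vector of two free parameter names.
#' @param xlim,ylim Ranges for the two parameters.
#' @param resolution Number of grid points per axis (length 1 or 2).
#' @param level Confidence level.
#' @param df Degrees of freedom of the cutoff (default 1, matching the
#'   per-flux convention; use 2 for the joint-coverage convention).
#' @return Object of class `"mfa_region"`: grid axes `x`, `y`, matrix `ssr`,
#'   `threshold` and logical `mask`.
#' @export
ssr_region <- function(object, pair, xlim, ylim, resolution = 61,
                       level = 0.95, df = 1) {
  if (length(pair) != 2L || !all(pair %in% object$par_names))
    stop("pair must name two free parameters")
  resolution <- rep(resolution, length.out = 2L)
  xs <- seq(xlim[1], xlim[2], length.out = resolution[1])
  ys <- seq(ylim[1], ylim[2], length.out = resolution[2])
  resid_fn <- make_residual_fn(object$model, object$measurements,
                               object$tracer, object$spec,
                               pools = object$pools,
                               free_pools = object$free_pools,
                               times = object$times)
  jx <- match(pair[1], object$par_names)
  jy <- match(pair[2], object$par_names)
  others <- setdiff(seq_along(object$par), c(jx, jy))
  lower <- object$bounds["lower", ]; upper <- object$bounds["upper", ]
  ssr <- matrix(NA_real_, length(xs), length(ys))
  warm_col <- object$par
  for (ix in seq_along(xs)) {
    warm <- warm_col
    for (iy in seq_along(ys)) {
      full <- warm
      full[jx] <- xs[ix]; full[jy] <- ys[iy]
      if (length(others) == 0L) {
        ssr[ix, iy] <- sum(resid_fn(full)^2)
      } else {
        sub_fn <- function(q) { full[others] <- q; resid_fn(full) }
        res <- minpack.lm::nls.lm(
          par = warm[others], lower = lower[others], upper = upper[others],
          fn = sub_fn,
          control = minpack.lm::nls.lm.control(ftol = 1e-9, ptol = 1e-9,
                                               maxiter = 200))
        ssr[ix, iy] <- sum(res$fvec^2)
        full[others] <- res$par
        warm <- full
        if (iy == 1L) warm_col <- full
      }
    }
  }
  threshold <- object$ssr + chi2_cutoff(level, df)
  mask <- ssr <= threshold
  if (!any(mask))
    warning("confidence region is empty on this grid")
  structure(list(x = xs, y = ys, ssr = ssr, threshold = threshold,
                 mask = mask, pair = pair, level = level, df = df),
            class = "mfa_region")
}

#' @export
print.mfa_region <- function(x, ...) {
  cat(sprintf("%g%% confidence region of (%s, %s): %d x %d grid, threshold %.4g\n",
              100 * x$level, x$pair[1], x$pair[2],
              length(x$x), length(x$y), x$threshold))
  if (any(x$mask)) {
    ix <- which(x$mask, arr.ind = TRUE)
    cat(sprintf("  member cells: %d; %s in [%g, %g], %s in [%g, %g]\n",
                sum(x$mask),
                x$pair[1], min(x$x[ix[, 1]]), max(x$x[ix[, 1]]),
                x$pair[2], min(x$y[ix[, 2]]), max(x$y[ix[, 2]])))
  } else cat("  empty region on this grid\n")
  invisible(x)
}

#' @export
as.data.frame.mfa_region <- function(x, ...) {
  grid <- expand.grid(x = x$x, y = x$y)
  names(grid) <- x$pair
  grid$ssr <- as.numeric(x$ssr)
  grid$in_region <- as.logical(x$mask)
  grid
}

#' Parameter ranges spanned by a confidence region
#'
#' @param x An [ssr_region()] result.
#' @return Matrix with one row per parameter of the pair and columns
#'   `lower`, `upper`: the extreme grid values inside the region.
#' @export
region_bounds <- function(x) {
  if (!any(x$mask)) stop("confidence region is empty")
  ix <- which(x$mask, arr.ind = TRUE)
  out <- rbind(c(min(x$x[ix[, 1]]), max(x$x[ix[, 1]])),
               c(min(x$y[ix[, 2]]), max(x$y[ix[, 2]])))
  dimnames(out) <- list(x$pair, c("lower", "upper"))
  out
}

#' @export
plot.mfa_region <- function(x, ...) {
  graphics::image(x$x, x$y, x$mask * 1, col = c("white", "#31688e"),
                  xlab = x$pair[1], ylab = x$pair[2], ...)
  graphics::contour(x$x, x$y, x$ssr, levels = x$threshold, add = TRUE,
                    drawlabels = FALSE)
  invisible(x)
}

#' Monte-Carlo sampling of flux uncertainty
#'
#' Two samplers are provided. `"metropolis"`: random-walk Metropolis in the
#' free-parameter space with log-density `-SSR/2` (the Gaussian measurement
#' likelihood), proposal scale adapted during burn-in. `"perturbation"`:
#' repeatedly add Gaussian noise (the measurement SDs) to the measured MIDs,
#' renormalize, and refit from the best-fit point; the spread of the refits
#' approximates the flux distribution.
#'
#' @param object An [mfa_fit()].
#' @param n Number of samples (post burn-in draws, or refits).
#' @param seed Integer seed.
#' @param method `"metropolis"` or `"perturbation"`.
#' @param burn_in Burn-in iterations for the Metropolis sampler.
#' @return List with `samples` (data frame, one column per free parameter),
#'   `intervals` (2.5/97.5% quantiles), `method`, and for Metropolis the
#'   post-adaptation `acceptance` rate.
#' @export
mfa_mcmc <- function(object, n = 1000, seed = 1L,
                     method = c("metropolis", "perturbation"),
                     burn_in = 500) {
  method <- match.arg(method)
  resid_fn <- make_residual_fn(object$model, object$measurements,
                               object$tracer, object$spec,
                               pools = object$pools,
                               free_pools = object$free_pools,
                               times = object$times)
  n_par <- length(object$par)
  lower <- object$bounds["lower", ]; upper <- object$bounds["upper", ]
  samples <- with_seed(seed, {
    if (method == "metropolis") {
      cur <- object$par
      cur_ll <- -sum(resid_fn(cur)^2) / 2
      prop_sd <- pmax(0.05 * abs(cur), 0.5)
      acc_window <- 0; acc_total <- 0
      draws <- matrix(NA_real_, n, n_par)
      for (it in seq_len(burn_in + n)) {
        cand <- cur + stats::rnorm(n_par, 0, prop_sd)
        ok <- all(cand >= lower & cand <= upper)
        if (ok) {
          cand_ll <- -sum(resid_fn(cand)^2) / 2
          if (log(stats::runif(1)) < cand_ll - cur_ll) {
            cur <- cand; cur_ll <- cand_ll
            acc_window <- acc_window + 1
            if (it > burn_in) acc_total <- acc_total + 1
          }
        }
        if (it <= burn_in && it %% 50 == 0) {   # adapt toward ~30% acceptance
          rate <- acc_window / 50
          prop_sd <- prop_sd * exp(rate - 0.3)
          acc_window <- 0
        }
        if (it > burn_in) draws[it - burn_in, ] <- cur
      }
      attr(draws, "acceptance") <- acc_total / n
      draws
    } else {
      base <- object$measurements
      draws <- matrix(NA_real_, n, n_par)
      for (it in seq_len(n)) {
        pert <- base
        pert$fraction <- pert$fraction + stats::rnorm(nrow(pert), 0, pert$sd)
        grp <- paste(pert$emu, pert$time, sep = "\r")
        for (g in unique(grp)) {
          idx <- grp == g
          v <- pmax(pert$fraction[idx], 0)
          pert$fraction[idx] <- v / sum(v)
        }
        pert_fn <- make_residual_fn(object$model, pert, object$tracer,
                                    object$spec, pools = object$pools,
                                    free_pools = object$free_pools,
                                    times = object$times)
        res <- minpack.lm::nls.lm(
          par = object$par, lower = lower, upper = upper, fn = pert_fn,
          control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                               maxiter = 300))
        draws[it, ] <- res$par
      }
      draws
    }
  })
  acceptance <- attr(samples, "acceptance")
  if (!is.null(acceptance) && (acceptance < 0.05 || acceptance > 0.8))
    warning(sprintf("Metropolis acceptance rate %.2f outside [0.05, 0.8]",
                    acceptance))
  colnames(samples) <- object$par_names
  intervals <- t(apply(samples, 2, stats::quantile, c(0.025, 0.975)))
  list(samples = as.data.frame(samples), intervals = intervals,
       method = method, acceptance = acceptance)
}
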