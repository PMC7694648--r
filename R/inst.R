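## Isotopically non-stationary labeling simulation.
##
## After switching a source to a labeled tracer at t = 0, each EMU's MID
## relaxes according to dm/dt = sum_i f_i (m_i - m) / c, where c is the pool
## amount (concentration x volume, nmol) of the metabolite the EMU belongs
## to. Pools set the labeling time constants but not the eventual steady
## state. When metabolic steady state is not assumed, the pool itself evolves
## as d(cV)/dt = f_NetPro and the same labeling equation holds with
## time-varying c.

## shared integrator; `evolve_pools` switches between constant and evolving
## pool amounts. Returns per-node MID matrices (time x mass shift).
integrate_emu_ode <- function(model, emunet, fluxes, pools, tracer, times,
                              init = NULL, evolve_pools = FALSE,
                              rtol = 1e-8, atol = 1e-10) {
  nodes <- emunet$nodes[!emunet$nodes$is_source, , drop = FALSE]
  labels <- nodes$label
  sizes <- stats::setNames(nodes$size, labels)
  mets <- stats::setNames(nodes$met, labels)
  need <- unique(nodes$met)
  pools <- unlist(as.list(pools))
  miss <- setdiff(need, names(pools))
  if (length(miss))
    stop("missing pool size for: ", paste(miss, collapse = ", "))
  if (any(pools[need] <= 0)) stop("pool sizes must be > 0")
  offsets <- c(0L, cumsum(sizes + 1L))
  idx <- lapply(seq_along(labels), function(i)
    seq.int(offsets[i] + 1L, offsets[i + 1L]))
  names(idx) <- labels
  n_mid <- offsets[length(offsets)]

  src <- list()
  for (i in which(emunet$nodes$is_source))
    src[[emunet$nodes$label[i]]] <-
      tracer_mid(tracer, emunet$nodes$met[i],
                 emunet$atoms[[emunet$nodes$label[i]]])
  edges_by_target <- split(emunet$edges,
                           vapply(emunet$edges, `[[`, "", "target"))
  npro <- if (evolve_pools) net_production(model, fluxes) else NULL

  y0 <- numeric(n_mid)
  for (lb in labels) y0[idx[[lb]][1L]] <- 1   # unlabeled before the switch
  if (!is.null(init))
    for (lb in names(init)) y0[idx[[lb]]] <- init[[lb]]
  if (evolve_pools) y0 <- c(y0, pools[need])

  deriv <- function(t, y, parms) {
    cur <- lapply(idx, function(ii) y[ii])
    pool_now <- if (evolve_pools)
      stats::setNames(y[n_mid + seq_along(need)], need) else pools
    dy <- numeric(length(y))
    for (lb in labels) {
      m <- cur[[lb]]
      acc <- numeric(length(m))
      for (e in edges_by_target[[lb]]) {
        f <- e$weight * fluxes[[e$flux_id]]
        m_src <- if (length(e$sources) == 1L) {
          if (!is.null(src[[e$sources]])) src[[e$sources]] else cur[[e$sources]]
        } else {
          Reduce(function(a, b) {
            la <- length(a); lb2 <- length(b)
            out <- numeric(la + lb2 - 1L)
            for (i in seq_len(la))
              out[i:(i + lb2 - 1L)] <- out[i:(i + lb2 - 1L)] + a[i] * b
            out
          }, lapply(e$sources, function(s)
            if (!is.null(src[[s]])) src[[s]] else cur[[s]]))
        }
        acc <- acc + f * (m_src - m)
      }
      dy[idx[[lb]]] <- acc / pool_now[[mets[[lb]]]]
    }
    if (evolve_pools)
      dy[n_mid + seq_along(need)] <- npro[need]
    list(dy)
  }

  out <- if (evolve_pools) {
    deSolve::lsodar(y0, times, deriv, parms = NULL, rtol = rtol, atol = atol,
                    rootfunc = function(t, y, parms)
                      min(y[n_mid + seq_along(need)]) - 1e-9)
  } else {
    deSolve::lsoda(y0, times, deriv, parms = NULL, rtol = rtol, atol = atol)
  }
  if (nrow(out) < length(times))
    stop("integration stopped early",
         if (evolve_pools) " (a pool amount reached zero)" else "")
  tcol <- out[, 1L]
  mids <- lapply(labels, function(lb) {
    m <- out[, idx[[lb]] + 1L, drop = FALSE]
    dimnames(m) <- NULL
    m[m < 0 & m > -1e-7] <- 0
    m / rowSums(m)   # renormalization guard against integrator drift
  })
  names(mids) <- labels
  pool_traj <- if (evolve_pools)
    out[, n_mid + seq_along(need) + 1L, drop = FALSE] else NULL
  if (!is.null(pool_traj)) colnames(pool_traj) <- need
  list(times = tcol, mids = mids, pools = pool_traj,
       interp = function(label, k, t) {
         i <- which(abs(tcol - t) < 1e-12 * max(1, abs(t)))[1L]
         if (is.na(i)) stop("time ", t, " was not simulated")
         mids[[label]][i, k]
       })
}

#' Simulate a labeling time course at metabolic steady state
#'
#' Integrates the EMU labeling ODE after a switch from unlabeled medium to
#' the tracer at t = 0. Fluxes must satisfy the balance constraints; pool
#' amounts (nmol) are required for every metabolite on the EMU paths to the
#' targets.
#'
#' @param model A [flux_model()].
#' @param fluxes Named numeric flux vector (balanced).
#' @param pools Named numeric vector/list of pool amounts in nmol.
#' @param tracer A [tracer_spec()] in effect from t = 0.
#' @param times Numeric vector of requested time points (same time unit as
#'   the fluxes).
#' @param targets Character vector of EMU labels (default: full-molecule EMUs
#'   of all balanced metabolites).
#' @param init Optional pre-labeled initial state: named list mapping EMU
#'   labels to MID vectors (default fully unlabeled).
#' @return Object of class `"mid_trajectory"`.
#' @export
simulate_timecourse <- function(model, fluxes, pools, tracer, times,
                                targets = NULL, init = NULL) {
  flux_state(model, fluxes)
  if (is.null(targets)) {
    roles <- metabolite_roles(model)
    mets <- names(roles)[roles == "balanced"]
    targets <- vapply(mets, function(m)
      format_emu_label(m, seq_len(n_atoms_of(model, m))), "")
  }
  emunet <- emu_decompose(model, targets)
  times <- sort(unique(c(0, times)))
  res <- integrate_emu_ode(model, emunet, fluxes, pools, tracer, times,
                           init = init)
  new_trajectory(res, model, targets)
}

#' Simulate labeling with evolving metabolite pools
#'
#' Drops the metabolic steady-state assumption: each balanced metabolite's
#' pool amount changes at its net production flux, d(cV)/dt = f_NetPro, and
#' the labeling ODE uses the time-varying pool. Integration stops with an
#' error if a pool is exhausted within the horizon.
#'
#' @inheritParams simulate_timecourse
#' @param initial_pools Named pool amounts (nmol) at t = 0.
#' @param fluxes Named numeric flux vector; need not satisfy balance.
#' @return Object of class `"mid_trajectory"` whose `pools` attribute holds
#'   the pool amounts over time.
#' @export
simulate_nonstationary_pools <- function(model, fluxes, initial_pools, tracer,
                                         times, targets = NULL, init = NULL) {
  if (is.null(targets)) {
    roles <- metabolite_roles(model)
    mets <- names(roles)[roles == "balanced"]
    targets <- vapply(mets, function(m)
      format_emu_label(m, seq_len(n_atoms_of(model, m))), "")
  }
  emunet <- emu_decompose(model, targets)
  times <- sort(unique(c(0, times)))
  res <- integrate_emu_ode(model, emunet, fluxes, initial_pools, tracer,
                           times, init = init, evolve_pools = TRUE)
  new_trajectory(res, model, targets)
}

new_trajectory <- function(res, model, targets) {
  structure(list(times = res$times, mids = res$mids, pools = res$pools,
                 interp = res$interp, targets = targets,
                 model_name = model$name),
            class = "mid_trajectory")
}

#' @export
print.mid_trajectory <- function(x, ...) {
  cat(sprintf("Labeling trajectory (%s): %d time points in [%g, %g], EMUs: %s\n",
              x$model_name, length(x$times), min(x$times), max(x$times),
              paste(names(x$mids), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.mid_trajectory <- function(x, ...) {
  do.call(rbind, lapply(names(x$mids), function(lb) {
    m <- x$mids[[lb]]
    data.frame(time = rep(x$times, ncol(m)),
               emu = lb,
               mass_shift = rep(seq_len(ncol(m)) - 1L, each = nrow(m)),
               fraction = as.numeric(m),
               stringsAsFactors = FALSE)
  }))
}

#' MIDs of a trajectory at one time point
#'
#' @param x A `mid_trajectory`.
#' @param time One of the simulated time points.
#' @return A `mid_set` of the trajectory MIDs at that time.
#' @export
trajectory_at <- function(x, time) {
  i <- which(abs(x$times - time) < 1e-12 * max(1, abs(time)))[1L]
  if (is.na(i)) stop("time ", time, " was not simulated")
  structure(lapply(x$mids, function(m) m[i, ]), class = "mid_set")
}

#' Plot a labeling trajectory
#'
#' One panel of M+k curves per EMU.
#'
#' @param x A `mid_trajectory`.
#' @param emu EMU label(s) to plot (default: all).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.mid_trajectory <- function(x, emu = names(x$mids), ...) {
  old <- graphics::par(mfrow = c(1, length(emu)))
  on.exit(graphics::par(old))
  for (lb in emu) {
    m <- x$mids[[lb]]
    graphics::matplot(x$times, m, type = "l", lty = 1,
                      xlab = "time", ylab = "MID fraction", main = lb, ...)
    graphics::legend("right", legend = paste0("M+", seq_len(ncol(m)) - 1L),
                     col = seq_len(ncol(m)), lty = 1, bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' Integrate the labeling ODE until isotopic steady state
#'
#' Integrates in chunks of ten upstream turnover times until the largest
#' labeling derivative falls below `tol` (or 50 turnovers elapse), then
#' returns the final MIDs. At convergence these match the steady-state
#' linear solve.
#'
#' @inheritParams simulate_timecourse
#' @param tol Steady-state criterion on `max |dm/dt|`.
#' @return A `mid_set` with attribute `"time"` (the horizon reached).
#' @export
simulate_to_steady <- function(model, fluxes, pools, tracer, targets = NULL,
                               tol = 1e-9) {
  if (is.null(targets)) {
    roles <- metabolite_roles(model)
    mets <- names(roles)[roles == "balanced"]
    targets <- vapply(mets, function(m)
      format_emu_label(m, seq_len(n_atoms_of(model, m))), "")
  }
  emunet <- emu_decompose(model, targets)
  need <- needed_pools(model, emunet)
  pools <- unlist(as.list(pools))
  inflow <- vapply(need, function(m) {
    prod <- sum(vapply(model$reactions, function(r)
      fluxes[[r$flux_id]] * sum(vapply(r$products, function(p)
        p$met == m, NA)), 0))
    prod
  }, 0)
  turnover <- max(pools[need] / inflow)
  t_now <- 0; chunk <- 10 * turnover
  init <- NULL
  repeat {
    res <- integrate_emu_ode(model, emunet, fluxes, pools, tracer,
                             c(0, chunk), init = init)
    final <- lapply(res$mids, function(m) m[nrow(m), ])
    prev <- if (is.null(init)) lapply(final, function(v) NA) else init
    t_now <- t_now + chunk
    rate <- if (is.null(init)) Inf else
      max(vapply(names(final), function(lb)
        max(abs(final[[lb]] - prev[[lb]])) / chunk, 0))
    init <- final
    if (rate < tol || t_now >= 50 * turnover) break
  }
  structure(init, class = "mid_set", time = t_now)
}
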