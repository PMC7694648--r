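## Brute-force isotopomer simulator.
##
## Tracks the full isotopomer distribution (2^n states per metabolite) and
## integrates the master equations with unit pools to steady state. It is
## exponentially more expensive than the EMU solver and exists as an
## independent cross-check of it; only tiny networks are accepted.

## bits of x at 1-based positions `pos`, packed into a small pattern integer
bits_at <- function(x, pos) {
  q <- integer(length(x))
  for (k in seq_along(pos))
    q <- q + bitwAnd(bitwShiftR(x, pos[k] - 1L), 1L) * 2L^(k - 1L)
  q
}

popcount <- function(x, nbits) {
  out <- integer(length(x))
  for (k in seq_len(nbits)) out <- out + bitwAnd(bitwShiftR(x, k - 1L), 1L)
  out
}

tracer_isotopomers <- function(tracer, met, n_atoms) {
  p <- numeric(2^n_atoms)
  comps <- if (met %in% names(tracer)) tracer[[met]] else
    list(list(positions = integer(), fraction = 1))
  for (cmp in comps) {
    pat <- sum(2L^(cmp$positions - 1L))
    p[pat + 1L] <- p[pat + 1L] + cmp$fraction
  }
  p
}

#' Steady-state isotopomer distributions by brute force
#'
#' Integrates the full isotopomer master equations (every metabolite gets a
#' unit pool) from the unlabeled state until the labeling derivative is
#' negligible. Intended as a test oracle for [solve_emu_network()]; the
#' state space is capped.
#'
#' @param model A [flux_model()].
#' @param fluxes Named numeric flux vector satisfying balance.
#' @param tracer A [tracer_spec()].
#' @param max_states Per-metabolite isotopomer cap (default `2^10`).
#' @return Object of class `"isotopomer_set"`: named list of isotopomer
#'   probability vectors (length `2^n_atoms`, index = bit pattern + 1) for
#'   every non-source metabolite.
#' @export
isotopomer_steady <- function(model, fluxes, tracer, max_states = 1024L) {
  flux_state(model, fluxes)
  roles <- metabolite_roles(model)
  mets <- names(roles)[roles != "source"]
  n_at <- vapply(mets, function(m) n_atoms_of(model, m), 0L)
  if (any(2^n_at > max_states))
    stop("isotopomer state-space cap exceeded for: ",
         paste(mets[2^n_at > max_states], collapse = ", "))
  offsets <- c(0L, cumsum(2L^n_at))
  idx_of <- function(m) {
    i <- match(m, mets)
    seq.int(offsets[i] + 1L, offsets[i + 1L])
  }
  source_dists <- lapply(names(roles)[roles == "source"], function(m)
    tracer_isotopomers(tracer, m, n_atoms_of(model, m)))
  names(source_dists) <- names(roles)[roles == "source"]

  ## precompute production machinery per (reaction, product occurrence)
  prods <- list()
  for (r in model$reactions) {
    for (p in r$products) {
      if (roles[[p$met]] == "source") next
      np <- length(p$atoms)
      occs <- list()
      for (s in r$substrates) {
        used <- which(s$atoms %in% p$atoms)
        if (!length(used)) next
        prodpos <- match(s$atoms[used], p$atoms)
        ns <- n_atoms_of(model, s$met)
        grp <- bits_at(0:(2L^ns - 1L), used)
        ppat <- vapply(0:(2L^length(used) - 1L), function(q)
          sum(bitwAnd(bitwShiftR(q, seq_along(used) - 1L), 1L) *
                2L^(prodpos - 1L)), 0)
        occs[[length(occs) + 1L]] <-
          list(met = s$met, grp = grp, ppat = as.integer(ppat),
               is_source = roles[[s$met]] == "source")
      }
      sym <- model$metabolites[[p$met]]$symmetry
      perm <- NULL
      if (!is.null(sym)) {
        states <- 0:(2L^np - 1L)
        perm <- integer(length(states))
        for (j in seq_len(np))
          perm <- perm + bitwAnd(bitwShiftR(states, j - 1L), 1L) * 2L^(sym[j] - 1L)
        perm <- perm + 1L   # 1-based index of the symmetry image
      }
      prods[[length(prods) + 1L]] <-
        list(flux_id = r$flux_id, met = p$met, np = np, occs = occs,
             perm = perm)
    }
  }
  inflow <- stats::setNames(numeric(length(mets)), mets)
  for (pr in prods) inflow[pr$met] <- inflow[pr$met] + fluxes[[pr$flux_id]]
  if (any(inflow <= 0))
    stop("no inflow for: ", paste(mets[inflow <= 0], collapse = ", "))

  deriv <- function(t, y, parms) {
    dy <- numeric(length(y))
    dists <- lapply(mets, function(m) y[idx_of(m)])
    names(dists) <- mets
    for (pr in prods) {
      v <- numeric(2L^pr$np); v[1L] <- 1
      for (oc in pr$occs) {
        pdist <- if (oc$is_source) source_dists[[oc$met]] else dists[[oc$met]]
        marg <- as.numeric(rowsum(pdist, oc$grp))
        nz <- which(v != 0)
        vn <- numeric(length(v))
        for (q in seq_along(marg))
          vn[nz + oc$ppat[q]] <- vn[nz + oc$ppat[q]] + v[nz] * marg[q]
        v <- vn
      }
      if (!is.null(pr$perm)) v <- 0.5 * (v + v[pr$perm])
      ii <- idx_of(pr$met)
      dy[ii] <- dy[ii] + fluxes[[pr$flux_id]] * v
    }
    for (m in mets) {
      ii <- idx_of(m)
      dy[ii] <- dy[ii] - inflow[m] * y[ii]
    }
    list(dy)
  }

  y0 <- numeric(offsets[length(offsets)])
  for (m in mets) y0[idx_of(m)[1L]] <- 1    # fully unlabeled start
  t_turn <- max(1 / inflow)
  t_end <- 50 * t_turn
  for (round in 1:4) {
    out <- deSolve::lsoda(y0, c(0, t_end), deriv, parms = NULL,
                          rtol = 1e-10, atol = 1e-12)
    y0 <- as.numeric(out[nrow(out), -1L])
    if (max(abs(deriv(0, y0, NULL)[[1]])) < 1e-9) break
    t_end <- t_end * 4
  }
  dists <- lapply(mets, function(m) {
    v <- y0[idx_of(m)]
    v[v < 0] <- 0
    v / sum(v)
  })
  structure(stats::setNames(dists, mets),
            n_atoms = stats::setNames(n_at, mets),
            class = "isotopomer_set")
}

#' Marginal MID of an EMU from an isotopomer distribution
#'
#' @param iso An [isotopomer_steady()] result.
#' @param emu EMU label, e.g. `"FBP[1-3]"` (the metabolite must be in `iso`).
#' @return Numeric MID vector of length `size + 1`.
#' @export
isotopomer_mid <- function(iso, emu) {
  e <- parse_emu_label(emu)
  p <- iso[[e$met]]
  if (is.null(p)) stop("metabolite '", e$met, "' not in isotopomer set")
  n <- attr(iso, "n_atoms")[[e$met]]
  states <- 0:(2L^n - 1L)
  k <- popcount(bits_at(states, e$atoms), length(e$atoms))
  mid <- as.numeric(rowsum(p, k))
  full <- numeric(length(e$atoms) + 1L)
  full[sort(unique(k)) + 1L] <- mid
  full / sum(full)
}
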