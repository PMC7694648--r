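## Steady-state labeling-balance solver on an EMU network.
##
## At metabolic and isotopic steady state every EMU's MID is the flux-
## weighted average of its substrates' MIDs: sum_i f_i (m_i - m) = 0. Within
## each EMU size this is a linear system (convolution inputs come from
## already-solved smaller sizes), so sizes are processed in ascending order
## and each size is solved with one dense direct solve -- this handles
## cycles such as the DHAP/GAP interconversion without iteration.

#' Solve steady-state labeling on an EMU network
#'
#' @param emunet An [emu_decompose()] network.
#' @param fluxes Named numeric flux vector (must satisfy the model's balance;
#'   see [flux_state()]).
#' @param tracer A [tracer_spec()] fixing source-metabolite labeling.
#' @return A named list of MID vectors (class `"mid_set"`), one per EMU node.
#' @export
solve_emu_network <- function(emunet, fluxes, tracer) {
  mids <- list()
  nodes <- emunet$nodes
  for (i in which(nodes$is_source))
    mids[[nodes$label[i]]] <-
      tracer_mid(tracer, nodes$met[i], emunet$atoms[[nodes$label[i]]])
  edges_by_target <- split(emunet$edges,
                           vapply(emunet$edges, `[[`, "", "target"))
  for (s in sort(unique(nodes$size[!nodes$is_source]))) {
    unknown <- nodes$label[nodes$size == s & !nodes$is_source]
    if (length(unknown) == 0L) next
    k <- length(unknown)
    A <- matrix(0, k, k, dimnames = list(unknown, unknown))
    B <- matrix(0, k, s + 1L, dimnames = list(unknown, NULL))
    for (u in unknown) {
      inflow <- 0
      for (e in edges_by_target[[u]]) {
        f <- e$weight * fluxes[[e$flux_id]]
        inflow <- inflow + f
        if (length(e$sources) == 1L && e$sources %in% unknown) {
          A[u, e$sources] <- A[u, e$sources] - f
        } else {
          src_mid <- if (length(e$sources) == 1L) mids[[e$sources]]
            else Reduce(mid_convolve, mids[e$sources])
          B[u, ] <- B[u, ] + f * src_mid
        }
      }
      A[u, u] <- A[u, u] + inflow
      if (inflow <= 0) {
        infl <- vapply(edges_by_target[[u]], `[[`, "", "flux_id")
        stop("EMU ", u, " has zero total inflow (fluxes: ",
             paste(unique(infl), collapse = ", "), ")")
      }
    }
    X <- tryCatch(solve(A, B), error = function(e)
      stop("singular labeling-balance system at EMU size ", s, ": ",
           conditionMessage(e)))
    for (j in seq_len(k)) mids[[unknown[j]]] <- mid_check(X[j, ])
  }
  structure(mids, class = "mid_set")
}

#' @export
print.mid_set <- function(x, digits = 4, ...) {
  for (label in names(x)) {
    v <- x[[label]]
    cat(sprintf("%-12s %s\n", label,
                paste(sprintf("M+%d=%.*f", seq_along(v) - 1L, digits, v),
                      collapse = "  ")))
  }
  invisible(x)
}

#' @export
as.data.frame.mid_set <- function(x, ...) {
  do.call(rbind, lapply(names(x), function(label)
    data.frame(emu = label, mass_shift = seq_along(x[[label]]) - 1L,
               fraction = as.numeric(x[[label]]),
               stringsAsFactors = FALSE)))
}

#' Predict steady-state MIDs for target EMUs
#'
#' Convenience wrapper: decomposes the network for the targets, checks the
#' flux vector, and solves the labeling balance.
#'
#' @param model A [flux_model()].
#' @param fluxes Named numeric flux vector over all flux ids.
#' @param tracer A [tracer_spec()].
#' @param targets Character vector of EMU labels (default: the full-molecule
#'   EMU of every balanced metabolite).
#' @return A `mid_set` restricted to the requested targets.
#' @export
predict_mids <- function(model, fluxes, tracer, targets = NULL) {
  if (is.null(targets)) {
    roles <- metabolite_roles(model)
    mets <- names(roles)[roles == "balanced"]
    targets <- vapply(mets, function(m)
      format_emu_label(m, seq_len(n_atoms_of(model, m))), "")
  }
  flux_state(model, fluxes)
  net <- emu_decompose(model, targets)
  sol <- solve_emu_network(net, fluxes, tracer)
  canon <- vapply(targets, function(tg) emu_canonical(model, tg)$label, "")
  structure(stats::setNames(sol[canon], targets), class = "mid_set")
}

#' Positional enrichment (weight-1 cumomer) of a single atom
#'
#' The probability that a given atom position is labeled, regardless of the
#' other positions; equals the M+1 fraction of the size-1 EMU at that
#' position.
#'
#' @param model A [flux_model()].
#' @param fluxes Named numeric flux vector.
#' @param tracer A [tracer_spec()].
#' @param metabolite Metabolite name.
#' @param position 1-based atom index.
#' @return Labeled fraction in `[0, 1]`.
#' @export
positional_enrichment <- function(model, fluxes, tracer, metabolite, position) {
  spec <- model$metabolites[[metabolite]]
  if (is.null(spec)) stop("unknown metabolite '", metabolite, "'")
  if (position < 1L || position > spec$n_atoms)
    stop("position must be in 1..", spec$n_atoms)
  label <- format_emu_label(metabolite, position)
  predict_mids(model, fluxes, tracer, label)[[label]][2L]
}
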