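## Stoichiometric balance and the free-flux parameterization.
##
## At metabolic steady state every balanced metabolite satisfies
## sum(producing fluxes) = sum(consuming fluxes). These homogeneous linear
## constraints (plus any fixed fluxes) leave a small number of free fluxes;
## the full flux vector is an affine function of the free ones.

#' Stoichiometric balance constraints of a model
#'
#' One homogeneous equation per balanced metabolite: the sum of its producing
#' fluxes minus the sum of its consuming fluxes is zero. Source and sink
#' metabolites contribute no equation.
#'
#' @param model A [flux_model()].
#' @return A matrix with one row per balanced metabolite and one column per
#'   flux id; `S %*% f = 0` expresses the balance.
#' @export
balance_constraints <- function(model) {
  ids <- flux_ids(model)
  roles <- metabolite_roles(model)
  balanced <- names(roles)[roles == "balanced"]
  S <- matrix(0, length(balanced), length(ids),
              dimnames = list(balanced, ids))
  for (r in model$reactions) {
    for (t in r$products)
      if (t$met %in% balanced) S[t$met, r$flux_id] <- S[t$met, r$flux_id] + 1
    for (t in r$substrates)
      if (t$met %in% balanced) S[t$met, r$flux_id] <- S[t$met, r$flux_id] - 1
  }
  S
}

#' Derive the free-flux parameterization
#'
#' Combines the balance constraints with any fixed flux values and selects a
#' deterministic set of free fluxes such that every flux is an affine function
#' of the free ones. Free fluxes are chosen greedily preferring later flux ids
#' (so for a network written as forward/reverse pairs the reverse--exchange--
#' fluxes come out free); pass `free` to override the choice.
#'
#' @param model A [flux_model()].
#' @param fixed Named numeric vector of fixed flux values, e.g. `c(f1 = 100)`.
#' @param free Optional character vector naming the free fluxes to use.
#' @param bounds Length-2 numeric, default box bounds for each free flux.
#' @return An object of class `"free_flux_spec"` with elements `free`
#'   (free flux ids), `fixed`, `offset` and `basis` such that the full flux
#'   vector is `offset + basis %*% u` for free values `u`, and `bounds`
#'   (2 x n_free matrix).
#' @export
free_flux_spec <- function(model, fixed = numeric(), free = NULL,
                           bounds = c(0, 1e4)) {
  ids <- flux_ids(model)
  n <- length(ids)
  S <- balance_constraints(model)
  if (length(fixed)) {
    if (!all(names(fixed) %in% ids))
      stop("fixed flux not in model: ",
           paste(setdiff(names(fixed), ids), collapse = ", "))
    Ef <- matrix(0, length(fixed), n, dimnames = list(names(fixed), ids))
    Ef[cbind(seq_along(fixed), match(names(fixed), ids))] <- 1
    A <- rbind(S, Ef)
    b <- c(rep(0, nrow(S)), unname(fixed))
  } else {
    A <- S
    b <- rep(0, nrow(S))
  }
  qa <- qr(A)
  n_free <- n - qa$rank
  rank_of <- function(M) if (nrow(M) == 0L) 0L else qr(M)$rank
  if (is.null(free)) {
    ## greedy completion, preferring later flux ids as free
    free <- character()
    M <- A
    for (j in rev(seq_len(n))) {
      if (length(free) == n_free) break
      e <- matrix(0, 1, n); e[1, j] <- 1
      if (rank_of(rbind(M, e)) > rank_of(M)) {
        free <- c(ids[j], free)
        M <- rbind(M, e)
      }
    }
  } else {
    if (!all(free %in% ids))
      stop("free flux not in model: ", paste(setdiff(free, ids), collapse = ", "))
    if (length(free) != n_free)
      stop(sprintf("model has %d free fluxes, got %d", n_free, length(free)))
  }
  Efree <- matrix(0, length(free), n, dimnames = list(free, ids))
  Efree[cbind(seq_along(free), match(free, ids))] <- 1
  M <- rbind(A, Efree)
  if (qr(M)$rank < n)
    stop("selected free fluxes do not determine the remaining fluxes: ",
         paste(free, collapse = ", "))
  qM <- qr(M)
  solve_ls <- function(rhs) qr.coef(qM, rhs)
  offset <- solve_ls(c(b, rep(0, length(free))))
  if (max(abs(M %*% offset - c(b, rep(0, length(free))))) >
      1e-8 * max(1, max(abs(b))))
    stop("fixed flux values are inconsistent with the balance constraints")
  basis <- matrix(0, n, length(free), dimnames = list(ids, free))
  for (k in seq_along(free)) {
    rhs <- c(rep(0, nrow(A)), as.numeric(seq_along(free) == k))
    basis[, k] <- solve_ls(rhs)
    if (max(abs(M %*% basis[, k] - rhs)) > 1e-8)
      stop("free-flux basis is inconsistent with the balance constraints")
  }
  bmat <- matrix(rep(bounds, length(free)), nrow = 2,
                 dimnames = list(c("lower", "upper"), free))
  structure(list(flux_ids = ids, free = free, fixed = fixed,
                 offset = stats::setNames(as.numeric(offset), ids),
                 basis = basis, bounds = bmat, model_name = model$name),
            class = "free_flux_spec")
}

#' @export
print.free_flux_spec <- function(x, ...) {
  cat("Free-flux parameterization (", x$model_name, ")\n", sep = "")
  cat("  free  :", paste(x$free, collapse = ", "), "\n")
  if (length(x$fixed))
    cat("  fixed :", paste(sprintf("%s = %g", names(x$fixed), x$fixed),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Complete a full flux vector from free-flux values
#'
#' @param spec A [free_flux_spec()].
#' @param free_values Numeric vector of free-flux values, in `spec$free`
#'   order (names, if present, are matched).
#' @return Named numeric vector over all flux ids, satisfying every balance
#'   constraint.
#' @export
complete_fluxes <- function(spec, free_values) {
  if (!is.null(names(free_values)))
    free_values <- free_values[spec$free]
  if (length(free_values) != length(spec$free))
    stop(sprintf("expected %d free-flux values", length(spec$free)))
  v <- spec$offset + as.numeric(spec$basis %*% as.numeric(free_values))
  stats::setNames(v, spec$flux_ids)
}

#' Validate a full flux vector against a model
#'
#' Checks nonnegativity and, for steady-state use, that every balanced
#' metabolite satisfies its balance to relative tolerance `tol`.
#'
#' @param model A [flux_model()].
#' @param fluxes Named numeric vector over the model's flux ids.
#' @param tol Relative balance tolerance.
#' @return The flux vector, invisibly, reordered to the model's flux ids.
#' @export
flux_state <- function(model, fluxes, tol = 1e-9) {
  ids <- flux_ids(model)
  if (!all(ids %in% names(fluxes)))
    stop("missing flux value for: ",
         paste(setdiff(ids, names(fluxes)), collapse = ", "))
  f <- fluxes[ids]
  if (any(f < 0)) stop("fluxes must be nonnegative")
  S <- balance_constraints(model)
  resid <- as.numeric(S %*% f)
  scale <- pmax(abs(S) %*% f, 1)
  bad <- abs(resid) / scale > tol
  if (any(bad))
    stop("flux vector violates balance for: ",
         paste(rownames(S)[bad], collapse = ", "))
  invisible(f)
}

#' Net production flux per balanced metabolite
#'
#' `sum(producing) - sum(consuming)` for each balanced metabolite; zero
#' everywhere at metabolic steady state.
#'
#' @inheritParams flux_state
#' @return Named numeric vector over balanced metabolites.
#' @export
net_production <- function(model, fluxes) {
  S <- balance_constraints(model)
  stats::setNames(as.numeric(S %*% fluxes[colnames(S)]), rownames(S))
}
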