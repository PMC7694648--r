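## Atom-transition network models ------------------------------------------
##
## A flux model is a set of metabolites (each with a count of traced atoms and
## a role) plus irreversible reaction steps whose atom transitions are written
## with letter strings, e.g. `f2: FBP (abcdef) -> DHAP (abc) + GAP (def)`.
## Reversible reactions are two steps (forward/reverse), each with its own
## flux id, so labeling-balance equations can be written per direction.

#' Construct a metabolite specification
#'
#' @param name Metabolite identifier.
#' @param n_atoms Number of traced atoms (carbon positions, typically).
#' @param role One of `"balanced"` (mass-balanced intracellular pool),
#'   `"source"` (labeling fixed by the tracer, no balance equation) or
#'   `"sink"` (absorbing, no balance equation).
#' @param pool_size Optional pool amount in nmol (concentration times volume),
#'   used by non-stationary simulation.
#' @param symmetry Optional integer permutation of `1:n_atoms` describing
#'   molecular symmetry (e.g. `c(4,3,2,1)` for a succinate-like molecule).
#'   Must be an involution: applying it twice is the identity.
#' @return A list of class `"metabolite_spec"`.
#' @export
metabolite_spec <- function(name, n_atoms, role = c("balanced", "source", "sink"),
                            pool_size = NULL, symmetry = NULL) {
  role <- match.arg(role)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("metabolite name must be a non-empty string")
  n_atoms <- as.integer(n_atoms)
  if (is.na(n_atoms) || n_atoms < 1L)
    stop("n_atoms must be a positive integer for metabolite '", name, "'")
  if (!is.null(pool_size)) {
    pool_size <- as.numeric(pool_size)
    if (!is.finite(pool_size) || pool_size <= 0)
      stop("pool_size must be > 0 for metabolite '", name, "'")
  }
  if (!is.null(symmetry)) {
    symmetry <- as.integer(symmetry)
    if (length(symmetry) != n_atoms || !setequal(symmetry, seq_len(n_atoms)))
      stop("symmetry of '", name, "' must be a permutation of 1..", n_atoms)
    if (!identical(symmetry[symmetry], seq_len(n_atoms)))
      stop("symmetry of '", name, "' must be an involution")
  }
  structure(list(name = name, n_atoms = n_atoms, role = role,
                 pool_size = pool_size, symmetry = symmetry),
            class = "metabolite_spec")
}

#' Construct a reaction step
#'
#' One irreversible step of an atom-transition network. Atom transitions are
#' letter strings: each letter names one traced atom; a letter appearing in a
#' product string must appear exactly once among the substrate strings.
#'
#' @param flux_id Flux identifier (e.g. `"f3"`).
#' @param substrates,products Lists of `list(met = <name>, atoms = <string>)`,
#'   or a character vector like `c(FBP = "abcdef")`.
#' @return A list of class `"reaction_step"`.
#' @export
reaction_step <- function(flux_id, substrates, products) {
  norm_side <- function(x) {
    if (is.character(x))
      x <- mapply(function(m, a) list(met = m, atoms = a), names(x), x,
                  SIMPLIFY = FALSE, USE.NAMES = FALSE)
    lapply(x, function(t) list(met = as.character(t$met),
                               atoms = strsplit(as.character(t$atoms), "")[[1]]))
  }
  if (!is.character(flux_id) || length(flux_id) != 1L || !nzchar(flux_id))
    stop("flux_id must be a non-empty string")
  structure(list(flux_id = flux_id, substrates = norm_side(substrates),
                 products = norm_side(products)),
            class = "reaction_step")
}

#' Construct and validate an atom-transition network model
#'
#' @param name Model name.
#' @param metabolites List of [metabolite_spec()] objects.
#' @param reactions List of [reaction_step()] objects.
#' @return A validated object of class `"flux_model"`.
#' @seealso [read_flux_model()], [balance_constraints()], [emu_decompose()]
#' @export
flux_model <- function(name, metabolites, reactions) {
  model <- structure(list(name = name,
                          metabolites = stats::setNames(metabolites,
                            vapply(metabolites, `[[`, "", "name")),
                          reactions = reactions),
                     class = "flux_model")
  validate_flux_model(model)
  model
}

#' @export
print.flux_model <- function(x, ...) {
  cat("Atom-transition network model:", x$name, "\n")
  cat(sprintf("  %d metabolites (%d balanced), %d reaction steps\n",
              length(x$metabolites),
              sum(metabolite_roles(x) == "balanced"),
              length(x$reactions)))
  for (r in x$reactions) cat(" ", format_reaction(r), "\n")
  invisible(x)
}

metabolite_roles <- function(model)
  vapply(model$metabolites, `[[`, "", "role")

n_atoms_of <- function(model, met) model$metabolites[[met]]$n_atoms

format_reaction <- function(r) {
  side <- function(terms)
    paste(vapply(terms, function(t)
      sprintf("%s (%s)", t$met, paste(t$atoms, collapse = "")), ""),
      collapse = " + ")
  sprintf("%s: %s -> %s", r$flux_id, side(r$substrates), side(r$products))
}

#' Flux identifiers of a model, in declaration order
#' @param model A [flux_model()].
#' @return Character vector of flux ids.
#' @export
flux_ids <- function(model) vapply(model$reactions, `[[`, "", "flux_id")

validate_flux_model <- function(model, line_of = NULL) {
  fail <- function(msg, what = NULL) {
    if (!is.null(line_of) && !is.null(what) && !is.na(line_of[what]))
      stop(sprintf("line %d: %s", line_of[what], msg), call. = FALSE)
    stop(msg, call. = FALSE)
  }
  if (length(model$reactions) == 0L) fail("no reactions in model")
  ids <- flux_ids(model)
  if (anyDuplicated(ids))
    fail(sprintf("duplicate flux_id '%s'", ids[duplicated(ids)][1L]),
         ids[duplicated(ids)][1L])
  for (r in model$reactions) {
    for (t in c(r$substrates, r$products)) {
      if (is.null(model$metabolites[[t$met]]))
        fail(sprintf("reaction %s: unknown metabolite '%s'", r$flux_id, t$met),
             r$flux_id)
      if (length(t$atoms) != n_atoms_of(model, t$met))
        fail(sprintf("reaction %s: atom string '%s' has %d letters but %s has %d atoms",
                     r$flux_id, paste(t$atoms, collapse = ""), length(t$atoms),
                     t$met, n_atoms_of(model, t$met)), r$flux_id)
    }
    sub_letters <- unlist(lapply(r$substrates, `[[`, "atoms"))
    prod_letters <- unlist(lapply(r$products, `[[`, "atoms"))
    if (anyDuplicated(sub_letters))
      fail(sprintf("reaction %s: substrate atom letter '%s' appears more than once",
                   r$flux_id, sub_letters[duplicated(sub_letters)][1L]), r$flux_id)
    if (anyDuplicated(prod_letters))
      fail(sprintf("reaction %s: product atom letter '%s' appears more than once",
                   r$flux_id, prod_letters[duplicated(prod_letters)][1L]), r$flux_id)
    missing <- setdiff(prod_letters, sub_letters)
    if (length(missing))
      fail(sprintf("reaction %s: product atom letter '%s' does not appear among the substrates",
                   r$flux_id, missing[1L]), r$flux_id)
    if (length(r$substrates) == 0L)
      fail(sprintf("reaction %s: no substrates", r$flux_id), r$flux_id)
  }
  roles <- metabolite_roles(model)
  for (met in names(roles)[roles == "balanced"]) {
    produced <- any(vapply(model$reactions, function(r)
      met %in% vapply(r$products, `[[`, "", "met"), NA))
    consumed <- any(vapply(model$reactions, function(r)
      met %in% vapply(r$substrates, `[[`, "", "met"), NA))
    if (!produced || !consumed)
      fail(sprintf("balanced metabolite '%s' must have at least one producing and one consuming reaction",
                   met), met)
  }
  invisible(model)
}

#' Parse an atom-transition network model from text
#'
#' The plain-text dialect has one record per line. Metabolite lines are
#' `name, n_atoms, role[, pool=<nmol>][, symmetry=<digits, e.g. 4321>]` and
#' reaction lines are `flux_id: M1 (abc) + M2 (de) -> M3 (abcde)`. `#` starts
#' a comment. Reversible reactions are written as two lines with distinct
#' flux ids.
#'
#' @param file Path to a model file (or a connection).
#' @param text Model text as a character vector (alternative to `file`).
#' @param name Model name; defaults to the file base name.
#' @return A validated [flux_model()].
#' @export
read_flux_model <- function(file = NULL, text = NULL, name = NULL) {
  if (is.null(text)) {
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(file))
    text <- readLines(file, warn = FALSE)
  }
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (is.null(name)) name <- "model"
  stripped <- sub("#.*$", "", text)
  mets <- list(); reactions <- list(); line_of <- integer()
  for (i in seq_along(stripped)) {
    ln <- trimws(stripped[i])
    if (!nzchar(ln)) next
    if (grepl("->", ln, fixed = TRUE)) {
      r <- parse_reaction_line(ln, i)
      reactions[[length(reactions) + 1L]] <- r
      line_of[r$flux_id] <- i
    } else {
      m <- parse_metabolite_line(ln, i)
      if (!is.null(mets[[m$name]]))
        stop(sprintf("line %d: metabolite '%s' declared twice", i, m$name),
             call. = FALSE)
      mets[[m$name]] <- m
      line_of[m$name] <- i
    }
  }
  model <- structure(list(name = name, metabolites = mets, reactions = reactions),
                     class = "flux_model")
  validate_flux_model(model, line_of = line_of)
  model
}

parse_metabolite_line <- function(ln, i) {
  parts <- trimws(strsplit(ln, ",", fixed = TRUE)[[1]])
  if (length(parts) < 3L)
    stop(sprintf("line %d: metabolite line needs 'name, n_atoms, role'", i),
         call. = FALSE)
  n_atoms <- suppressWarnings(as.integer(parts[2]))
  if (is.na(n_atoms))
    stop(sprintf("line %d: n_atoms '%s' is not an integer", i, parts[2]),
         call. = FALSE)
  pool <- NULL; symmetry <- NULL
  for (extra in parts[-(1:3)]) {
    kv <- strsplit(extra, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop(sprintf("line %d: cannot parse option '%s'", i, extra), call. = FALSE)
    key <- trimws(kv[1])
    if (key == "pool") pool <- as.numeric(kv[2])
    else if (key == "symmetry") symmetry <- as.integer(strsplit(trimws(kv[2]), "")[[1]])
    else stop(sprintf("line %d: unknown metabolite option '%s'", i, key),
              call. = FALSE)
  }
  tryCatch(metabolite_spec(parts[1], n_atoms, parts[3], pool, symmetry),
           error = function(e) stop(sprintf("line %d: %s", i, conditionMessage(e)),
                                    call. = FALSE))
}

parse_reaction_line <- function(ln, i) {
  m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*?)\\s*->\\s*(.*)$", ln))[[1]]
  if (length(m) != 4L)
    stop(sprintf("line %d: cannot parse reaction '%s'", i, ln), call. = FALSE)
  parse_side <- function(s) {
    if (!nzchar(trimws(s))) return(list())
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    lapply(terms, function(t) {
      tm <- regmatches(t, regexec("^([A-Za-z0-9_.]+)\\s*\\(([A-Za-z]+)\\)$", t))[[1]]
      if (length(tm) != 3L)
        stop(sprintf("line %d: cannot parse term '%s' (expected 'Met (abc)')", i, t),
             call. = FALSE)
      list(met = tm[2], atoms = tm[3])
    })
  }
  subs <- parse_side(m[3]); prods <- parse_side(m[4])
  tryCatch(reaction_step(m[2], subs, prods),
           error = function(e) stop(sprintf("line %d: %s", i, conditionMessage(e)),
                                    call. = FALSE))
}

#' Serialize a flux model to its plain-text dialect
#'
#' `read_flux_model(text = write_flux_model(m))` round-trips to an equivalent
#' model.
#'
#' @param model A [flux_model()].
#' @param file Optional path; when given the text is written there.
#' @return The model text, invisibly when `file` is given.
#' @export
write_flux_model <- function(model, file = NULL) {
  met_lines <- vapply(model$metabolites, function(m) {
    ln <- sprintf("%s, %d, %s", m$name, m$n_atoms, m$role)
    if (!is.null(m$pool_size)) ln <- sprintf("%s, pool=%g", ln, m$pool_size)
    if (!is.null(m$symmetry))
      ln <- sprintf("%s, symmetry=%s", ln, paste(m$symmetry, collapse = ""))
    ln
  }, "")
  txt <- c(paste("#", model$name), met_lines,
           vapply(model$reactions, format_reaction, ""))
  if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
  txt
}
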