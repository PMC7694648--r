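## Elementary metabolite unit (EMU) decomposition.
##
## An EMU is a distinct subset of a metabolite's traced atoms. Backward
## tracing from the measured target EMUs through the atom transitions yields
## the minimal EMU reaction network needed to predict the target MIDs:
## cleavage steps map an EMU to a same-size EMU of a substrate, condensation
## steps to a convolution of smaller EMUs. Molecular symmetry is handled by
## orientation-averaging: producing edges into a symmetric metabolite are
## split 50/50 between the two atom orderings, the exact limit of an
## infinitely fast "flipping" flux.

#' Canonical representative of an EMU under molecular symmetry
#'
#' For a metabolite with a symmetry involution, the EMU on atom set `A` and
#' the EMU on the image set `sigma(A)` carry identical labeling; both are
#' represented by the lexicographically smaller atom set. Asymmetric
#' metabolites are returned unchanged.
#'
#' @param model A [flux_model()].
#' @param emu EMU label (e.g. `"Suc[1]"`) or a `list(met=, atoms=)`.
#' @return A list with `label` (representative), `orientations` (list of the
#'   distinct atom sets to trace, 1 or 2 of them) and `weight` (1 or 0.5, the
#'   share of each orientation).
#' @export
emu_canonical <- function(model, emu) {
  if (is.character(emu)) emu <- parse_emu_label(emu)
  met <- emu$met
  atoms <- sort(as.integer(emu$atoms))
  spec <- model$metabolites[[met]]
  if (is.null(spec)) stop("unknown metabolite '", met, "'")
  if (length(atoms) == 0L || any(atoms < 1L) || any(atoms > spec$n_atoms) ||
      anyDuplicated(atoms))
    stop("EMU atoms of '", met, "' must be distinct indices in 1..",
         spec$n_atoms)
  sym <- spec$symmetry
  if (is.null(sym))
    return(list(label = format_emu_label(met, atoms),
                orientations = list(atoms), weight = 1))
  image <- sort(match(atoms, sym))  # positions mapping onto `atoms`
  if (identical(image, atoms))
    return(list(label = format_emu_label(met, atoms),
                orientations = list(atoms), weight = 1))
  rep_atoms <- if (paste(atoms, collapse = ",") < paste(image, collapse = ","))
    atoms else image
  list(label = format_emu_label(met, rep_atoms),
       orientations = list(atoms, image)[order(c(
         paste(atoms, collapse = ","), paste(image, collapse = ",")))],
       weight = 0.5)
}

#' Decompose a network into the minimal EMU reaction network
#'
#' Backward-traces the target EMUs through the atom transitions, collecting
#' every EMU whose labeling is needed, with flux-weighted edges. Condensation
#' reactions produce convolution source terms (ordered lists of smaller
#' EMUs). Source-metabolite EMUs are leaves whose MIDs come from the tracer.
#'
#' @param model A [flux_model()].
#' @param targets Character vector of EMU labels, e.g. `"FBP[1-6]"`.
#' @return An object of class `"emu_network"`: `nodes` is a data frame
#'   (`label`, `met`, `size`, `is_source`), `edges` a list of
#'   `list(flux_id, weight, sources, target)` with `sources` a character
#'   vector of node labels (length > 1 means convolution).
#' @export
emu_decompose <- function(model, targets) {
  roles <- metabolite_roles(model)
  nodes <- list()
  edges <- list()
  queue <- character()
  add_node <- function(label, met, atoms) {
    if (!is.null(nodes[[label]])) return()
    nodes[[label]] <<- list(label = label, met = met, atoms = atoms,
                            size = length(atoms),
                            is_source = roles[[met]] == "source")
    if (!nodes[[label]]$is_source) queue <<- c(queue, label)
  }
  for (tg in targets) {
    can <- emu_canonical(model, tg)
    e <- parse_emu_label(can$label)
    add_node(can$label, e$met, e$atoms)
  }
  while (length(queue)) {
    label <- queue[1L]; queue <- queue[-1L]
    node <- nodes[[label]]
    can <- emu_canonical(model, list(met = node$met, atoms = node$atoms))
    found_producer <- FALSE
    for (orient in can$orientations) {
      for (r in model$reactions) {
        for (p in r$products) {
          if (p$met != node$met) next
          found_producer <- TRUE
          letters_needed <- p$atoms[orient]
          srcs <- list()
          for (s in r$substrates) {
            idx <- sort(which(s$atoms %in% letters_needed))
            if (length(idx)) {
              sc <- emu_canonical(model, list(met = s$met, atoms = idx))
              srcs[[length(srcs) + 1L]] <- sc$label
            }
          }
          if (length(srcs) == 0L)
            stop("EMU ", label, " has a producing reaction ", r$flux_id,
                 " with no substrate atoms; malformed atom map")
          src_labels <- sort(unlist(srcs))
          for (sl in src_labels) {
            e <- parse_emu_label(sl)
            add_node(sl, e$met, e$atoms)
          }
          edges[[length(edges) + 1L]] <-
            list(flux_id = r$flux_id, weight = can$weight,
                 sources = src_labels, target = label)
        }
      }
    }
    if (!found_producer)
      stop("EMU ", label, " is unreachable from any source: metabolite '",
           node$met, "' has no producing reaction on these atoms")
  }
  ## every EMU must be forward-reachable from a tracer source, or its
  ## labeling is undefined (e.g. an isolated interconversion cycle)
  reachable <- names(nodes)[vapply(nodes, `[[`, NA, "is_source")]
  repeat {
    grew <- FALSE
    for (e in edges) {
      if (e$target %in% reachable) next
      if (all(e$sources %in% reachable)) {
        reachable <- c(reachable, e$target)
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  dead <- setdiff(names(nodes), reachable)
  if (length(dead))
    stop("EMU(s) unreachable from any tracer source: ",
         paste(sort(dead), collapse = ", "))

  ## merge duplicate edges (same flux, sources, target), summing weights
  key <- vapply(edges, function(e)
    paste(e$flux_id, paste(e$sources, collapse = "+"), e$target, sep = "|"), "")
  merged <- lapply(split(seq_along(edges), key), function(ix) {
    e <- edges[[ix[1L]]]
    e$weight <- sum(vapply(edges[ix], `[[`, 0, "weight"))
    e
  })
  ord <- order(vapply(nodes, `[[`, 0L, "size"), names(nodes))
  nodes <- nodes[ord]
  nd <- data.frame(label = names(nodes),
                   met = vapply(nodes, `[[`, "", "met"),
                   size = vapply(nodes, `[[`, 0L, "size"),
                   is_source = vapply(nodes, `[[`, NA, "is_source"),
                   row.names = NULL, stringsAsFactors = FALSE)
  merged <- merged[order(vapply(merged, `[[`, "", "target"),
                         vapply(merged, `[[`, "", "flux_id"))]
  structure(list(nodes = nd, atoms = lapply(nodes, `[[`, "atoms"),
                 edges = unname(merged), targets = targets),
            class = "emu_network")
}

#' @export
print.emu_network <- function(x, ...) {
  cat(sprintf("EMU network: %d EMUs (sizes %s), %d edges\n",
              nrow(x$nodes),
              paste(sort(unique(x$nodes$size)), collapse = ", "),
              length(x$edges)))
  writeLines(format_emu_edges(x))
  invisible(x)
}

#' Text edge list of an EMU network
#'
#' One line per edge, `target <- flux_id : source1 ⊕ source2 [x weight]`;
#' useful for debugging and golden tests.
#'
#' @param x An `emu_network`.
#' @return Character vector of edge lines.
#' @export
format_emu_edges <- function(x) {
  vapply(x$edges, function(e) {
    line <- sprintf("%s <- %s : %s", e$target, e$flux_id,
                    paste(e$sources, collapse = " \u2295 "))
    if (e$weight != 1) line <- sprintf("%s [x %g]", line, e$weight)
    line
  }, "")
}
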