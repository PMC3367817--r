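# Reaction-network generation: species closure under the merged semantics
# and reactivity classification.

#' Build the closed reaction network of a system
#'
#' Computes the least fixpoint of [merged_reactions()] starting from the
#' system's initial species: new product species are fed back until no new
#' species or reactions arise.  Ordering is deterministic (breadth-first over
#' sorted species keys).
#'
#' @param sys a `dsd_system` (expanded and well formed).
#' @param rates a [rate_model()].
#' @param species_cap abort if the closure exceeds this many species (guards
#'   against potentially unbounded networks).
#' @return a `dsd_network`: list with `species` (character vector of keys),
#'   `reactions` (list of `list(reactants, products, rate, toehold)`),
#'   `reactive` (named logical), `registry`, and the originating `sys`.
#' @export
build_network <- function(sys, rates = rate_model(), species_cap = 10000L) {
  wf <- check_well_formed(sys)
  if (length(wf))
    stop(paste(c("system is not well formed:", wf), collapse = "\n  "))
  registry <- new.env(parent = emptyenv())
  for (k in names(sys$species_counts)) registry[[k]] <- sys$registry[[k]]

  species <- sort(names(sys$species_counts))
  reactions <- list()
  seen_rxn <- character(0)
  done_pairs <- new.env(parent = emptyenv())
  frontier <- species

  while (length(frontier)) {
    # pairs: frontier x (all current species), including self-pairs
    all_sp <- species
    new_frontier <- character(0)
    for (a in frontier) {
      for (b in all_sp) {
        pk <- paste(sort(c(a, b)), collapse = " ~ ")
        if (!is.null(done_pairs[[pk]])) next
        done_pairs[[pk]] <- TRUE
        spa <- registry[[a]]; spb <- registry[[b]]
        if (is_gate(spa) && is_gate(spb)) next  # no gate-gate rule
        rxns <- merged_reactions(spa, spb, rates, registry)
        for (r in rxns) {
          sig <- paste(paste(r$reactants, collapse = "+"), "->",
                       paste(r$products, collapse = "+"), r$toehold)
          if (sig %in% seen_rxn) next
          seen_rxn <- c(seen_rxn, sig)
          reactions[[length(reactions) + 1L]] <- r
          for (p in r$products) {
            if (!p %in% species && !p %in% new_frontier)
              new_frontier <- c(new_frontier, p)
          }
        }
      }
    }
    species <- c(species, sort(new_frontier))
    if (length(species) > species_cap)
      stop(sprintf("species cap exceeded (%d): potentially unbounded network",
                   species_cap))
    frontier <- sort(new_frontier)
  }

  net <- list(species = species, reactions = reactions,
              registry = registry, sys = sys)
  class(net) <- "dsd_network"
  net$reactive <- classify_reactive(net)
  net
}

#' Classify species reactivity
#'
#' A species is reactive when it occurs as a reactant of at least one merged
#' reaction of the closed network (i.e. it can take part in a strand
#' displacement against the species universe).  `overrides` forces the flag
#' for named species (used by the catalyst case studies' fairness
#' adjustments).
#'
#' @param net a `dsd_network`.
#' @param overrides named logical vector keyed by species string.
#' @return named logical vector over `net$species`.
#' @export
classify_reactive <- function(net, overrides = logical(0)) {
  reactive <- setNames(rep(FALSE, length(net$species)), net$species)
  for (r in net$reactions) reactive[r$reactants] <- TRUE
  for (k in names(overrides)) {
    if (!k %in% names(reactive))
      stop(sprintf("reactivity override for unknown species: %s", k))
    reactive[k] <- overrides[[k]]
  }
  reactive
}

#' Serialise a network to reaction lines
#'
#' One reaction per line, `rate: A + B -> C + D`.
#'
#' @param net a `dsd_network`.
#' @return character vector.
#' @export
network_lines <- function(net) {
  vapply(net$reactions, function(r) {
    sprintf("%g: %s -> %s", r$rate,
            paste(r$reactants, collapse = " + "),
            paste(r$products, collapse = " + "))
  }, "")
}

#' Serialise a network to a JSON string
#' @param net a `dsd_network`.
#' @return a JSON string with species, initial counts, constants, reactions.
#' @export
network_json <- function(net) {
  sys <- net$sys
  counts <- integer(length(net$species))
  names(counts) <- net$species
  counts[names(sys$species_counts)] <- sys$species_counts
  obj <- list(
    species = net$species,
    initial = unname(counts),
    constant = sys$constant,
    reactive = unname(net$reactive[net$species]),
    reactions = lapply(net$reactions, function(r)
      list(reactants = r$reactants, products = r$products,
           rate = r$rate, toehold = r$toehold)))
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
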