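# Population CTMC construction: breadth-first state enumeration with
# stochastic mass-action propensities, labels and reward structures.
#
# A state is the vector of populations of the *varying* species; species
# declared constant contribute their fixed count to every propensity and are
# neither incremented nor decremented.

#' Build the population CTMC of a reaction network
#'
#' Propensity of a reaction with stochastic rate constant k:
#' `k * nA * nB` for distinct reactants, `k * nA * (nA - 1) / 2` for a
#' homodimer. Parallel reactions between the same pair of states sum their
#' rates.
#'
#' @param net a `dsd_network`.
#' @param state_cap abort if more reachable states than this.
#' @param drop_inert drop species that no reaction ever changes from the
#'   state vector (their population is constant anyway).
#' @return a `dsd_ctmc`: list with `species` (tracked, varying), `states`
#'   (integer matrix, one row per state), `init` (index), `trans`
#'   (data.frame from,to,rate), `exit` (numeric), `net`.
#' @export
build_ctmc <- function(net, state_cap = 2e6, drop_inert = TRUE) {
  sys <- net$sys
  counts <- setNames(integer(length(net$species)), net$species)
  counts[names(sys$species_counts)] <- sys$species_counts
  const <- setNames(rep(FALSE, length(net$species)), net$species)
  const[sys$constant] <- TRUE

  nr <- length(net$reactions)
  sp_all <- net$species

  # net state change per reaction over non-constant species
  delta <- matrix(0L, nrow = nr, ncol = length(sp_all),
                  dimnames = list(NULL, sp_all))
  for (i in seq_len(nr)) {
    r <- net$reactions[[i]]
    for (x in r$reactants) if (!const[[x]]) delta[i, x] <- delta[i, x] - 1L
    for (x in r$products) if (!const[[x]]) delta[i, x] <- delta[i, x] + 1L
  }

  # tracked species: varying ones (optionally only those some reaction moves)
  varying <- sp_all[!const[sp_all]]
  if (drop_inert) {
    moved <- colnames(delta)[colSums(delta != 0L) > 0L]
    varying <- intersect(varying, moved)
  }
  nv <- length(varying)
  vidx <- setNames(seq_len(nv), varying)

  # per-reaction propensity recipe
  r1 <- integer(nr); r2 <- integer(nr)  # tracked reactant indices (0 = none)
  cmul <- numeric(nr)                   # constant multiplier
  homo <- logical(nr)
  keep <- logical(nr)
  D <- matrix(0L, nrow = nr, ncol = nv, dimnames = list(NULL, varying))
  for (i in seq_len(nr)) {
    r <- net$reactions[[i]]
    cmul[i] <- r$rate
    tracked <- character(0)
    for (x in r$reactants) {
      if (x %in% varying) tracked <- c(tracked, x)
      else {
        cnt <- counts[[x]]  # constant (or untracked invariant) population
        cmul[i] <- cmul[i] * cnt
      }
    }
    if (length(tracked) == 2L && tracked[1L] == tracked[2L]) {
      homo[i] <- TRUE
      r1[i] <- vidx[[tracked[1L]]]
    } else {
      if (length(tracked) >= 1L) r1[i] <- vidx[[tracked[1L]]]
      if (length(tracked) == 2L) r2[i] <- vidx[[tracked[2L]]]
    }
    dd <- delta[i, varying, drop = TRUE]
    D[i, ] <- dd
    # a reaction is relevant to the chain if it changes the state and can fire
    keep[i] <- any(dd != 0L) && cmul[i] > 0
  }
  ridx <- which(keep)

  init <- unname(counts[varying])
  statekey <- function(s) paste(s, collapse = ",")
  index <- new.env(parent = emptyenv())
  states <- vector("list", 1024L)
  nstates <- 1L
  states[[1L]] <- init
  index[[statekey(init)]] <- 1L

  from_v <- integer(4096L); to_v <- integer(4096L); rate_v <- numeric(4096L)
  ntr <- 0L
  push_tr <- function(f, t, rt) {
    if (ntr == length(from_v)) {
      from_v <<- c(from_v, integer(length(from_v)))
      to_v <<- c(to_v, integer(length(to_v)))
      rate_v <<- c(rate_v, numeric(length(rate_v)))
    }
    ntr <<- ntr + 1L
    from_v[ntr] <<- f; to_v[ntr] <<- t; rate_v[ntr] <<- rt
  }

  qhead <- 1L
  while (qhead <= nstates) {
    s <- states[[qhead]]
    for (i in ridx) {
      a <- r1[i]
      if (a > 0L) {
        na <- s[a]
        if (na == 0L) next
        if (homo[i]) {
          if (na < 2L) next
          prop <- cmul[i] * na * (na - 1) / 2
        } else {
          b <- r2[i]
          if (b > 0L) {
            nb <- s[b]
            if (nb == 0L) next
            prop <- cmul[i] * na * nb
          } else prop <- cmul[i] * na
        }
      } else prop <- cmul[i]
      s2 <- s + D[i, ]
      if (any(s2 < 0L)) next
      k2 <- statekey(s2)
      j <- index[[k2]]
      if (is.null(j)) {
        nstates <- nstates + 1L
        if (nstates > state_cap)
          stop(sprintf("state cap exceeded (%g states)", state_cap))
        if (nstates > length(states)) states <- c(states, vector("list", length(states)))
        states[[nstates]] <- s2
        index[[k2]] <- nstates
        j <- nstates
      }
      push_tr(qhead, j, prop)
    }
    qhead <- qhead + 1L
  }

  tr <- data.frame(from = from_v[seq_len(ntr)], to = to_v[seq_len(ntr)],
                   rate = rate_v[seq_len(ntr)])
  # merge parallel transitions
  if (nrow(tr)) {
    key <- paste(tr$from, tr$to)
    agg <- rowsum(tr$rate, key, reorder = FALSE)
    parts <- strsplit(rownames(agg), " ", fixed = TRUE)
    tr <- data.frame(from = as.integer(vapply(parts, `[`, "", 1L)),
                     to = as.integer(vapply(parts, `[`, "", 2L)),
                     rate = as.numeric(agg))
  }
  smat <- do.call(rbind, states[seq_len(nstates)])
  colnames(smat) <- varying
  exit <- numeric(nstates)
  if (nrow(tr)) {
    ex <- rowsum(tr$rate, tr$from, reorder = FALSE)
    exit[as.integer(rownames(ex))] <- as.numeric(ex)
  }
  m <- list(species = varying, states = smat, init = 1L, trans = tr,
            exit = exit, net = net, all_counts = counts)
  class(m) <- "dsd_ctmc"
  m
}

#' Sparse transition-rate matrix of a CTMC
#' @param m a `dsd_ctmc`.
#' @return `dgCMatrix` R with `R[s, s2]` the transition rate.
#' @export
rate_matrix <- function(m) {
  n <- nrow(m$states)
  Matrix::sparseMatrix(i = m$trans$from, j = m$trans$to, x = m$trans$rate,
                       dims = c(n, n))
}

# ---- labels ---------------------------------------------------------------

#' Build state labels for a model
#'
#' Standard labels:
#'  * `strands_reactive`, `gates_reactive`: population totals of reactive
#'    strand-shaped / gate-shaped species (after reactivity overrides),
#'  * `deadlock`: no outgoing transition,
#'  * one integer labeller per entry of `outputs` (weighted population sums;
#'    used for output counts, consensus totals etc.),
#'  * `all_done`: a case-study recipe over the other labels.
#'
#' @param m a `dsd_ctmc`.
#' @param outputs named list; each element is a named numeric vector of
#'   per-species weights (e.g. `list(output = c("<t^ x2>" = 1))`).
#' @param overrides reactivity overrides, see [classify_reactive()].
#' @param all_done function(labels_df) returning logical, or NULL.
#' @return data.frame with one row per state.
#' @export
make_labels <- function(m, outputs = list(), overrides = logical(0),
                        all_done = NULL) {
  reactive <- classify_reactive(m$net, overrides)
  kind_gate <- vapply(m$net$species,
                      function(k) is_gate(m$net$registry[[k]]), TRUE)
  pop_of <- function(keys, weights = NULL) {
    tot <- numeric(nrow(m$states))
    for (i in seq_along(keys)) {
      k <- keys[i]
      w <- if (is.null(weights)) 1 else weights[i]
      if (k %in% colnames(m$states)) tot <- tot + w * m$states[, k]
      else if (k %in% names(m$all_counts))
        tot <- tot + w * m$all_counts[[k]]  # constant/untracked species
      else stop(sprintf("unknown species in label: %s", k))
    }
    tot
  }
  lab <- data.frame(row.names = seq_len(nrow(m$states)))
  rs <- names(reactive)[reactive & !kind_gate[names(reactive)]]
  gs <- names(reactive)[reactive & kind_gate[names(reactive)]]
  lab$strands_reactive <- pop_of(rs)
  lab$gates_reactive <- pop_of(gs)
  lab$deadlock <- m$exit == 0
  for (nm in names(outputs)) {
    w <- outputs[[nm]]
    lab[[nm]] <- pop_of(names(w), unname(w))
  }
  if (!is.null(all_done)) lab$all_done <- all_done(lab)
  lab
}

#' Time reward structure
#'
#' State reward 1 everywhere, transition rewards 0: accumulated reward along
#' a path equals elapsed time.
#'
#' @param m a `dsd_ctmc`.
#' @return list(state = numeric vector, trans = numeric vector).
#' @export
time_reward <- function(m) {
  list(state = rep(1, nrow(m$states)), trans = rep(0, nrow(m$trans)))
}

# ---- explicit-state export ------------------------------------------------

#' Export a CTMC in explicit-state format
#'
#' Writes `<base>.sta` (state vectors), `<base>.tra` (transitions
#' `from to rate`, 1-based states, with a header line `#states #transitions`)
#' and `<base>.lab` (label truth table) - the explicit-engine interchange
#' format of common probabilistic model checkers.
#'
#' @param m a `dsd_ctmc`.
#' @param base output path prefix.
#' @param labels optional data.frame from [make_labels()].
#' @return invisibly, the written file names.
#' @export
export_explicit <- function(m, base, labels = NULL) {
  sta <- file.path(paste0(base, ".sta"))
  tra <- file.path(paste0(base, ".tra"))
  files <- c(sta, tra)
  hdr <- paste0("(", paste(m$species, collapse = ","), ")")
  rows <- apply(m$states, 1L, function(s)
    paste0("(", paste(s, collapse = ","), ")"))
  writeLines(c(hdr, paste0(seq_len(nrow(m$states)) - 1L, ":", rows)), sta)
  tr <- m$trans[order(m$trans$from, m$trans$to), , drop = FALSE]
  writeLines(c(sprintf("%d %d", nrow(m$states), nrow(tr)),
               sprintf("%d %d %.12g", tr$from - 1L, tr$to - 1L, tr$rate)), tra)
  if (!is.null(labels)) {
    labf <- file.path(paste0(base, ".lab"))
    files <- c(files, labf)
    lns <- character(0)
    logicals <- names(labels)[vapply(labels, is.logical, TRUE)]
    hdr <- paste(sprintf("%d=\"%s\"", seq_along(logicals) - 1L, logicals),
                 collapse = " ")
    body <- vapply(seq_len(nrow(labels)), function(i) {
      on <- which(vapply(logicals, function(nm) isTRUE(labels[[nm]][i]), TRUE))
      if (!length(on)) return(NA_character_)
      paste0(i - 1L, ": ", paste(on - 1L, collapse = " "))
    }, "")
    writeLines(c(hdr, body[!is.na(body)]), labf)
  }
  invisible(files)
}
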