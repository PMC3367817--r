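# Gillespie stochastic simulation over the merged reaction network: the
# independent oracle for the numeric engine (same propensity definitions,
# different computational path).

#' Exact stochastic simulation of a reaction network
#'
#' Direct-method SSA over the network's species counts; constant species
#' contribute to propensities but never change.  Reproducible per seed.
#'
#' @param net a `dsd_network`.
#' @param seed integer seed.
#' @param t_max stop time (simulated seconds).
#' @param max_events event-count guard.
#' @param record keep the full event list?
#' @return a `dsd_trajectory`: list with `seed`, `events` (data.frame time /
#'   reaction / event index), `final` (named counts), `t_end`.
#' @export
ssa_run <- function(net, seed, t_max = Inf, max_events = 1e6,
                    record = FALSE) {
  sys <- net$sys
  counts <- stats::setNames(numeric(length(net$species)), net$species)
  counts[names(sys$species_counts)] <- sys$species_counts
  const <- stats::setNames(rep(FALSE, length(net$species)), net$species)
  const[sys$constant] <- TRUE

  nr <- length(net$reactions)
  re1 <- character(nr); re2 <- character(nr); rate <- numeric(nr)
  for (i in seq_len(nr)) {
    r <- net$reactions[[i]]
    re1[i] <- r$reactants[1L]; re2[i] <- r$reactants[2L]
    rate[i] <- r$rate
  }
  prods <- lapply(net$reactions, function(r) r$products)

  rng <- local({ set.seed(seed); NULL })
  t <- 0; nev <- 0L
  ev_t <- numeric(0); ev_r <- integer(0)
  repeat {
    prop <- numeric(nr)
    for (i in seq_len(nr)) {
      n1 <- counts[[re1[i]]]; n2 <- counts[[re2[i]]]
      prop[i] <- if (re1[i] == re2[i]) rate[i] * n1 * (n1 - 1) / 2
                 else rate[i] * n1 * n2
    }
    tot <- sum(prop)
    if (tot <= 0) break
    dt <- stats::rexp(1, tot)
    if (t + dt > t_max) { t <- t_max; break }
    t <- t + dt
    i <- sample.int(nr, 1L, prob = prop)
    for (x in net$reactions[[i]]$reactants)
      if (!const[[x]]) counts[[x]] <- counts[[x]] - 1
    for (x in prods[[i]]) {
      if (!x %in% names(counts)) {
        counts[[x]] <- 0; const[[x]] <- FALSE  # defensive; closure is complete
      }
      if (!const[[x]]) counts[[x]] <- counts[[x]] + 1
    }
    nev <- nev + 1L
    if (record) { ev_t <- c(ev_t, t); ev_r <- c(ev_r, i) }
    if (nev >= max_events) break
  }
  structure(list(seed = seed,
                 events = data.frame(time = ev_t, reaction = ev_r),
                 n_events = nev, final = counts, t_end = t),
            class = "dsd_trajectory")
}

#' Monte-Carlo estimate of a reachability probability
#'
#' Runs `n_runs` simulations until absorption (or `t_max`) and reports the
#' fraction whose final state satisfies the predicate, with a binomial
#' standard error.
#'
#' @param net a `dsd_network`.
#' @param pred function(named final counts) -> logical.
#' @param n_runs number of trajectories.
#' @param seed base seed; run `i` uses `seed + i`.
#' @param t_max per-run stop time.
#' @return list(estimate, se, n).
#' @export
estimate_reach_probability <- function(net, pred, n_runs = 1000L, seed = 1L,
                                       t_max = Inf) {
  hits <- 0L
  for (i in seq_len(n_runs)) {
    tr <- ssa_run(net, seed = seed + i, t_max = t_max)
    if (isTRUE(pred(tr$final))) hits <- hits + 1L
  }
  p <- hits / n_runs
  list(estimate = p, se = sqrt(p * (1 - p) / n_runs), n = n_runs)
}

#' Mean first-passage time estimate by simulation
#'
#' @param net a `dsd_network`.
#' @param pred function(named counts) -> logical, evaluated on the final
#'   (absorbing) state to validate the run; the recorded time is the run's
#'   absorption time.
#' @param n_runs,seed as in [estimate_reach_probability()].
#' @return list(mean, se, n).
#' @export
estimate_time_to_absorption <- function(net, n_runs = 200L, seed = 1L) {
  ts <- numeric(n_runs)
  for (i in seq_len(n_runs)) ts[i] <- ssa_run(net, seed = seed + i)$t_end
  list(mean = mean(ts), se = stats::sd(ts) / sqrt(n_runs), n = n_runs)
}
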