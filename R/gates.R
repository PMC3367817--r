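# Executable builders for the two-domain case-study circuits: signal
# strands, transducers (buggy and corrected), catalysts with and without
# garbage collection, the constant-fuel catalyst abstraction, and the
# approximate-majority voting system; plus the random fixture generator used
# by the property tests.
#
# Conventions.  A signal X is the strand <t^ x> (global toehold t^, long
# recognition domain x).  A transducer/catalyst instance is two gate
# complexes plus two fuel strands, all at population N:
#
#   input complex   {t^*}[x t^]:[a t^]:(tail)   consumes the input signal(s)
#                   and, driven by fuel <t^ a>, irreversibly ejects the
#                   intermediate strand <a t^>
#   output complex  (head):[t^ y]:[t^ a]{t^*}   consumes <a t^> from the
#                   right end and, driven by fuel <y t^>, ejects the output
#                   signal <t^ y>
#
# In the garbage-collecting variants the input complex's tail [a] is sealed
# by the recovered <t^ a> strand and the output complex's head [x] collects
# the spent <x t^> strand, leaving every toehold sequestered.  In the no-GC
# variants both positions carry an inert private cap [c] instead: the
# finished gates keep one exposed toehold, which is unproductive because c
# is private, and the spent strands stay in solution.

t_hold <- "t^"

#' Signal strand population
#'
#' @param N copies.
#' @param x long domain name.
#' @return a `dsd_system` of `N * <t^ x>`.
#' @export
S <- function(N, x) {
  stopifnot(N >= 0)
  if (N == 0) return(make_system(list(), integer(0)))
  make_system(list(strand(t_hold, x)), counts = N)
}

transducer_parts <- function(x, y, a) {
  list(
    I = gate(list(list(ll = "t^*", d = c(x, t_hold)),
                  list(d = c(a, t_hold)),
                  list(d = a))),
    O = gate(list(list(d = x),
                  list(d = c(t_hold, y)),
                  list(d = c(t_hold, a), lr = "t^*"))),
    F1 = strand(t_hold, a),
    F2 = strand(y, t_hold))
}

#' Transducer gate populations (buggy design: shared recognition domain 'a')
#'
#' `N` parallel copies of the X -> Y transducer: two complexes and two fuel
#' strands.  All instances share the recognition domain `a`, which causes
#' crosstalk between transducers in series.
#'
#' @param N copies.
#' @param x,y input/output long domain names.
#' @return a `dsd_system`.
#' @export
T_buggy <- function(N, x, y) {
  p <- transducer_parts(x, y, "a")
  make_system(list(p$I, p$O, p$F1, p$F2), counts = N)
}

.fresh_counter <- new.env(); .fresh_counter$k <- 0L

fresh_dom <- function(base) {
  .fresh_counter$k <- .fresh_counter$k + 1L
  paste0(base, ".", .fresh_counter$k)
}

#' Corrected transducer (private recognition domain)
#'
#' Like [T_buggy()] but the recognition domain `a` is freshly named per
#' instantiation, so two transducers cannot interfere.
#'
#' @inheritParams T_buggy
#' @return a `dsd_system`.
#' @export
T2 <- function(N, x, y) {
  a <- fresh_dom("a")
  p <- transducer_parts(x, y, a)
  make_system(list(p$I, p$O, p$F1, p$F2), counts = N,
              new_domains = a)
}

catalyst_parts <- function(x, y, z, a, c, gc) {
  I_tail <- if (gc) list(d = a) else list(d = c)
  O_head <- if (gc) list(d = x) else list(d = c)
  list(
    I = gate(list(list(ll = "t^*", d = c(x, t_hold)),
                  list(d = c(y, t_hold)),
                  list(d = c(a, t_hold)),
                  I_tail)),
    O = gate(list(O_head,
                  list(d = c(t_hold, z)),
                  list(d = c(t_hold, y)),
                  list(d = c(t_hold, a), lr = "t^*"))),
    F1 = strand(t_hold, a),
    F2 = strand(z, t_hold))
}

#' Catalyst gate populations
#'
#' `N` copies of a gate implementing X + Y -> Y + Z: the catalyst signal Y is
#' consumed and an identical strand re-emitted.  `C_gc` performs the garbage
#' collection reactions that seal the finished gates completely; [C_NoGC()]
#' omits them, leaving inert-capped gates with one exposed (unproductive)
#' toehold and spent strands in solution.  Both use private `a` and `c`
#' domains per instantiation.
#'
#' @param N copies.
#' @param x,y,z input, catalyst and output long domain names.
#' @return a `dsd_system`.
#' @export
C_gc <- function(N, x, y, z) {
  a <- fresh_dom("a"); c <- fresh_dom("c")
  p <- catalyst_parts(x, y, z, a, c, gc = TRUE)
  make_system(list(p$I, p$O, p$F1, p$F2), counts = N, new_domains = c(a, c))
}

#' @rdname C_gc
#' @export
C_NoGC <- function(N, x, y, z) {
  a <- fresh_dom("a"); c <- fresh_dom("c")
  p <- catalyst_parts(x, y, z, a, c, gc = FALSE)
  make_system(list(p$I, p$O, p$F1, p$F2), counts = N, new_domains = c(a, c))
}

#' Constant-fuel catalyst (state-space abstraction)
#'
#' The no-GC catalyst with its fuel populations (both complexes, both fuel
#' strands) declared `constant`, and its committed waste forms declared as
#' constant species with population 0, abstracting away fuel depletion and
#' waste accumulation.
#'
#' @inheritParams C_gc
#' @return a `dsd_system`.
#' @export
C_const <- function(N, x, y, z) {
  a <- fresh_dom("a"); c <- fresh_dom("c")
  p <- catalyst_parts(x, y, z, a, c, gc = FALSE)
  # committed input complex (all three strands accepted, tail cap intact)
  I_done <- gate(list(list(d = c(t_hold, x)),
                      list(d = c(t_hold, y)),
                      list(d = c(t_hold, a), lr = "t^*"),
                      list(d = c)))
  # finished output complex (everything ejected, cap intact)
  O_done <- gate(list(list(d = c),
                      list(d = c(z, t_hold), ll = "t^*"),
                      list(d = c(y, t_hold)),
                      list(d = c(a, t_hold))))
  make_system(list(p$I, p$O, p$F1, p$F2, I_done, O_done),
              counts = c(N, N, N, N, 0L, 0L),
              constant = TRUE,
              new_domains = c(a, c))
}

#' Reset the fresh-domain counter (reproducible builders)
#' @export
reset_domains <- function() { .fresh_counter$k <- 0L; invisible() }

# ---- case-study assemblies -------------------------------------------------

#' The transducer pair case study
#'
#' `S(N,x0) | T(N,x0,x1) | T(N,x1,x2)` with the buggy (shared-`a`) or
#' corrected (private-`a`) transducer design, compiled to network, CTMC and
#' labels, with the standard `all_done` recipe: all outputs produced, no
#' reactive gates, and no reactive strands besides the outputs.
#'
#' @param N parallel copies.
#' @param corrected use [T2()] instead of [T_buggy()].
#' @param rates,state_cap passed through.
#' @return list with `sys`, `net`, `ctmc`, `labels`.
#' @export
transducer_pair <- function(N = 1L, corrected = FALSE,
                            rates = rate_model(), state_cap = 2e6) {
  reset_domains()
  Tf <- if (corrected) T2 else T_buggy
  sys <- sys_par(S(N, "x0"), Tf(N, "x0", "x1"), Tf(N, "x1", "x2"))
  compile_study(sys, output = species_key(strand(t_hold, "x2")), N = N,
                rates = rates, state_cap = state_cap)
}

#' A chain of corrected transducers
#'
#' `S(1,x0) | T2(1,x0,x1) | ... | T2(1,x{k-1},xk)`.
#'
#' @param k chain length.
#' @param rates,state_cap passed through.
#' @return list with `sys`, `net`, `ctmc`, `labels`.
#' @export
transducer_chain <- function(k, rates = rate_model(), state_cap = 2e6) {
  reset_domains()
  parts <- list(S(1L, "x0"))
  for (i in seq_len(k))
    parts[[i + 1L]] <- T2(1L, paste0("x", i - 1L), paste0("x", i))
  sys <- do.call(sys_par, parts)
  compile_study(sys, output = species_key(strand(t_hold, paste0("x", k))),
                N = 1L, rates = rates, state_cap = state_cap)
}

compile_study <- function(sys, output, N, rates, state_cap) {
  net <- build_network(sys, rates)
  m <- build_ctmc(net, state_cap = state_cap)
  outs <- list(output = stats::setNames(1, output))
  lab <- make_labels(m, outputs = outs,
                     all_done = function(L)
                       L$output == N & L$gates_reactive == 0 &
                       L$strands_reactive == L$output)
  list(sys = sys, net = net, ctmc = m, labels = lab)
}

#' The catalyst case study
#'
#' `S(N,x) | S(N,y) | C(N,x,y,z)` with or without garbage collection,
#' including the fairness adjustments: the penultimate (pre-garbage-
#' collection) gate forms of the GC design and the finished capped gates of
#' the no-GC design are designated unreactive, and `all_done` requires both
#' outputs and no reactive gates (reactive leftover strands are allowed).
#'
#' @param N copies.
#' @param gc garbage-collecting design?
#' @param rates,state_cap passed through.
#' @return list with `sys`, `net`, `ctmc`, `labels`, `overrides`.
#' @export
catalyst_study <- function(N = 1L, gc = TRUE,
                           rates = rate_model(), state_cap = 2e6) {
  reset_domains()
  Cf <- if (gc) C_gc else C_NoGC
  sys <- sys_par(S(N, "x"), S(N, "y"), Cf(N, "x", "y", "z"))
  net <- build_network(sys, rates)
  m <- build_ctmc(net, state_cap = state_cap)
  a <- "a.1"; cdom <- "c.2"
  overrides <- catalyst_overrides(net, "x", "y", "z", a, cdom, gc)
  outs <- list(
    output1 = stats::setNames(1, species_key(strand(t_hold, "y"))),
    output2 = stats::setNames(1, species_key(strand(t_hold, "z"))))
  lab <- make_labels(m, outputs = outs, overrides = overrides,
                     all_done = function(L)
                       L$output1 == N & L$output2 == N & L$gates_reactive == 0)
  list(sys = sys, net = net, ctmc = m, labels = lab, overrides = overrides)
}

# fairness overrides for the catalyst designs (unreactive finished /
# penultimate forms), matching structures against the computed network
catalyst_overrides <- function(net, x, y, z, a, cdom, gc) {
  ov <- logical(0)
  if (gc) {
    # penultimate input complex: awaiting the recovered <t^ a> tail seal
    I_pen <- gate(list(list(d = c(t_hold, x)),
                       list(d = c(t_hold, y)),
                       list(d = c(t_hold, a), lr = "t^*"),
                       list(d = a)))
    # penultimate output complex: awaiting the spent <x t^> collection
    O_pen <- gate(list(list(d = x),
                       list(d = c(z, t_hold), ll = "t^*"),
                       list(d = c(y, t_hold)),
                       list(d = c(a, t_hold))))
    for (k in c(species_key(I_pen), species_key(O_pen)))
      if (k %in% net$species) ov[k] <- FALSE
  } else {
    I_done <- gate(list(list(d = c(t_hold, x)),
                        list(d = c(t_hold, y)),
                        list(d = c(t_hold, a), lr = "t^*"),
                        list(d = cdom)))
    O_done <- gate(list(list(d = cdom),
                        list(d = c(z, t_hold), ll = "t^*"),
                        list(d = c(y, t_hold)),
                        list(d = c(a, t_hold))))
    for (k in c(species_key(I_done), species_key(O_done)))
      if (k %in% net$species) ov[k] <- FALSE
  }
  ov
}

#' The approximate-majority case study
#'
#' Four constant-fuel catalysts implementing
#' X+Y -> B+Y, X+Y -> X+B, B+X -> X+X, B+Y -> Y+Y over signal populations
#' `x0`, `y0`, with consensus totals `output_x`/`output_y` that count free
#' signals plus signals speculatively bound to fuel gates.
#'
#' @param x0,y0 initial signal populations (>= 1).
#' @param Nf fuel population per catalyst (held constant).  The default of
#'   10 is the figure-borne population of the paper-described system,
#'   recovered by validating the reconstruction against its printed
#'   consensus-probability table and reachable-state counts (fuel counts
#'   scale propensities only; the state space is unaffected).
#' @param rates,state_cap passed through.
#' @return list with `sys`, `net`, `ctmc`, `labels`, `total`.
#' @export
approx_majority <- function(x0, y0, Nf = 10L,
                            rates = rate_model(), state_cap = 2e6) {
  stopifnot(x0 >= 1, y0 >= 1)
  reset_domains()
  sys <- sys_par(S(x0, "x"), S(y0, "y"),
                 C_const(Nf, "x", "y", "b"),   # X + Y -> B + Y
                 C_const(Nf, "y", "x", "b"),   # X + Y -> X + B
                 C_const(Nf, "b", "x", "x"),   # B + X -> X + X
                 C_const(Nf, "b", "y", "y"))   # B + Y -> Y + Y
  net <- build_network(sys, rates)
  m <- build_ctmc(net, state_cap = state_cap)
  outs <- list(output_x = signal_weights(net, "x"),
               output_y = signal_weights(net, "y"),
               output_b = signal_weights(net, "b"))
  lab <- make_labels(m, outputs = outs)
  list(sys = sys, net = net, ctmc = m, labels = lab, total = x0 + y0)
}

# weights counting free signals plus signals bound as a gate input: a bound
# form is any non-constant gate produced by a reaction that consumed the
# signal and can reverse back to it (speculative toehold binding)
signal_weights <- function(net, x) {
  sig <- species_key(strand(t_hold, x))
  w <- stats::setNames(1, sig)
  const <- net$sys$constant
  for (r in net$reactions) {
    if (!sig %in% r$reactants) next
    rev_exists <- any(vapply(net$reactions, function(r2)
      identical(sort(r2$reactants), sort(r$products)) &&
      identical(sort(r2$products), sort(r$reactants)), TRUE))
    if (!rev_exists) next
    for (p in r$products) {
      if (is_gate(net$registry[[p]]) && !p %in% const && !p %in% names(w))
        w[p] <- 1
    }
  }
  w
}

# ---- random fixture generator ---------------------------------------------

#' Generate a random well-formed two-domain system
#'
#' Reproducible per seed.  Systems combine signal strands and sealed gates
#' with exposed end toeholds; all unbound long domains are unstarred, so
#' well-formedness holds by construction (verified in the property tests).
#'
#' @param seed integer seed.
#' @param size approximate number of species.
#' @return a `dsd_system`.
#' @export
generate_fixture <- function(seed, size = 4L) {
  set.seed(seed)
  doms <- paste0("d", 1:6)
  species <- list()
  for (i in seq_len(size)) {
    kind <- sample(c("strand", "gate"), 1L)
    if (kind == "strand") {
      n <- sample(1:3, 1L)
      sdoms <- unlist(lapply(seq_len(n), function(j) {
        d <- sample(doms, 1L)
        if (stats::runif(1) < 0.4) c(t_hold, d) else d
      }))
      species[[length(species) + 1L]] <- strand(sdoms)
    } else {
      nseg <- sample(1:3, 1L)
      segs <- lapply(seq_len(nseg), function(j) {
        d <- sample(doms, 1L)
        list(d = if (stats::runif(1) < 0.5) c(d, t_hold) else c(t_hold, d))
      })
      if (stats::runif(1) < 0.5) segs[[1L]]$ll <- "t^*"
      if (stats::runif(1) < 0.5) segs[[nseg]]$lr <- "t^*"
      species[[length(species) + 1L]] <- gate(segs)
    }
  }
  make_system(species, counts = sample(1:3, length(species), replace = TRUE))
}
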