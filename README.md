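# dsdverify

Compilation and probabilistic verification of two-domain DNA strand
displacement (DSD) circuits.

DNA strand displacement is a paradigm for building molecular devices:
single strands carry signals, nicked double-stranded *gates* transform
signal populations through toehold-mediated branch migration, and a circuit
is just an initial soup of such species.  Designs fail in subtle ways -
molecules that share a recognition domain can interfere across component
boundaries - and stochastic effects at low copy numbers make single
simulations unreliable diagnostics.  `dsdverify` is for circuit designers
who want *exhaustive* answers at the design stage: it compiles a textual DSD
description into its induced chemical reaction network, builds the
continuous-time Markov chain (CTMC) over population states, and answers
correctness, reliability and performance queries by model checking rather
than sampling.

## The method

Species are two-domain strands `<t^ x>` (toehold + recognition domain) and
gate complexes such as `{t^*}[x t^]:[a t^]:[a]`, identified up to rotation
and branch migration.  Under the *merged* (toehold-limited) semantics every
reaction is initiated by a reversible toehold binding (rule RB) and closed
instantaneously over unbinding, hybridisation and displacement (RU, RC, RD),
so each productive binding becomes a single stochastic reaction with rate
constant equal to the toehold association rate.  The species-closure of an
initial system gives a finite network; breadth-first enumeration of
population vectors gives a CTMC `(S, R, L)` with mass-action propensities,
state labels (reactive-species counts, output totals, `all_done`,
`deadlock`) and reward structures.  Queries are solved on the embedded jump
chain `P(s,s') = R(s,s')/E(s)`:

* CTL checks `A[G](deadlock => all_done)` and `E[F all_done]` with
  counterexample paths,
* unbounded reachability probabilities (sparse linear solve after prob-0
  graph analysis),
* time-bounded probabilities by uniformisation,
* expected hitting times (the accumulated reward of the unit state-reward
  structure), and
* absorption distributions over deadlocks.

An exact Gillespie simulator over the same propensities serves as an
independent stochastic oracle in the test suite.

## Worked example

The classic debugging story: a signal driving two transducers in series,
`S(1,x0) | T(1,x0,x1) | T(1,x1,x2)`, where every transducer shares the
recognition domain `a`.

```r
library(dsdverify)

st <- transducer_pair(1, corrected = FALSE)   # compile + CTMC + labels
nrow(st$ctmc$states)
#> [1] 56
length(find_deadlocks(st$ctmc))
#> [1] 2
check_deadlock_invariant(st$ctmc, st$labels$all_done)$value
#> [1] FALSE
check_reachable(st$ctmc, st$labels$all_done)$value
#> [1] TRUE
prob_reach(st$ctmc, st$labels$deadlock & !st$labels$all_done)$value
#> [1] 0.4656404
```

The model has two terminal states: one where both transducers completed
(`all_done`), and one where the intermediate `<a t^>` released by the first
transducer entered the *second* transducer's output complex - the output
appears anyway, but parts of both transducers are left reactive.  The
deadlock-invariant check fails and returns the counterexample path; the
race between the correct and the crosstalk entry makes the bad outcome
nearly a coin flip.  Privatising `a` removes the interference:

```r
st2 <- transducer_pair(1, corrected = TRUE)
check_deadlock_invariant(st2$ctmc, st2$labels$all_done)$value
#> [1] TRUE
```

Quantitative queries work the same way.  The approximate-majority voter -
four constant-fuel catalyst gates implementing `X+Y -> B+Y`, `X+Y -> X+B`,
`B+X -> 2X`, `B+Y -> 2Y` - converges to an all-X or all-Y consensus with a
probability that amplifies the initial majority:

```r
am <- approx_majority(2, 1)
prob_reach(am$ctmc, am$labels$output_x == am$total)$value
#> [1] 0.7467617
prob_reach(am$ctmc, am$labels$output_x == am$total |
                    am$labels$output_y == am$total)$value
#> [1] 1
```

With three-against-five inputs the chain has 240,286 reachable states and is
still solved exactly - the regime where the distribution of outcomes, not
the mean trajectory, is the quantity of interest.

## Command line

```sh
Rscript inst/cli/dsdverify compile  model.dsd out      # network report
Rscript inst/cli/dsdverify check    model.dsd q.json   # JSON queries
Rscript inst/cli/dsdverify casestudy am 2 1            # built-in studies
Rscript inst/cli/dsdverify export   model.dsd out      # .sta/.tra/.lab/.sm
Rscript inst/cli/dsdverify simulate model.dsd 7        # one SSA trajectory
```

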