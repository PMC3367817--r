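Package: dsdverify
Title: Compilation and Probabilistic Verification of Two-Domain DNA Strand
    Displacement Systems
Version: 0.1.0
Authors@R: person("dsdverify", "maintainers", email = "dsdverify@example.org",
    role = c("aut", "cre"))
Description: A compiler and verifier for two-domain DNA strand displacement
    (DSD) circuits. Parses a textual DSD dialect describing strands, gates,
    modules and populations; derives the chemical reaction network induced by
    the merged (toehold-limited) reduction semantics of the DSD calculus;
    builds the population continuous-time Markov chain with state labels and
    reward structures; and answers correctness, reliability and performance
    queries: deadlock analysis, CTL reachability, unbounded and time-bounded
    reachability probabilities, expected hitting times and absorption
    distributions. Ships executable builders for transducer, catalyst and
    approximate-majority case-study circuits, a Gillespie simulator used as an
    independent oracle, and explicit-state model export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
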