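# Data model, parser/printer, canonicalisation, module expansion and
# well-formedness.

test_that("parsing single productions and the worked two-species system", {
  s1 <- parse_system("<t^ x>")
  expect_equal(unname(s1$species_counts), 1L)
  expect_equal(names(s1$species_counts), "<t^ x>")

  s2 <- parse_system("<t^ x u^> | {t^*}[x]{u^*}")
  want_gate <- dsdverify:::species_key(
    gate(list(list(ll = "t^*", d = "x", lr = "u^*"))))
  expect_setequal(names(s2$species_counts), c("<t^ x u^>", want_gate))

  # population and constant syntax
  s3 <- parse_system("3 * <t^ x> | constant 2 * <t^ y>")
  expect_equal(s3$species_counts[["<t^ x>"]], 3L)
  expect_equal(s3$species_counts[["<t^ y>"]], 2L)
  expect_equal(s3$constant, "<t^ y>")

  # syntax errors carry a position
  expect_error(parse_system("<t^ x"), "syntax error")
  expect_error(parse_system("T(1, x)"), "unknown module")
})

test_that("print/parse round-trip holds on 500 generated systems", {
  for (seed in 1:500) {
    sys <- generate_fixture(seed, size = 3L)
    txt <- print_system(sys)
    sys2 <- parse_system(txt)
    expect_identical(sys2$species_counts, sys$species_counts,
                     label = sprintf("seed %d (%s)", seed, txt))
    expect_identical(print_system(sys2), txt)
  }
})

test_that("generated fixtures are well formed", {
  for (seed in 1:500) {
    sys <- generate_fixture(seed, size = 3L)
    expect_length(check_well_formed(sys), 0L)
  }
})

test_that("canonicalize is idempotent and constant on rotation orbits", {
  for (seed in 1:50) {
    sys <- generate_fixture(seed, size = 2L)
    for (k in names(sys$species_counts)) {
      sp <- sys$registry[[k]]
      rot <- dsdverify:::rotate_species(sp)
      expect_identical(dsdverify:::species_key(canonicalize(rot)), k)
      expect_identical(dsdverify:::species_key(canonicalize(canonicalize(sp))), k)
    }
  }
  # free strands: rotation re-normalises to the same upper strand, and
  # reversed strands stay distinct species
  expect_identical(dsdverify:::species_key(strand("x", "t^")), "<x t^>")
  expect_false(identical(dsdverify:::species_key(strand("x", "t^")),
                         dsdverify:::species_key(strand("t^", "x"))))
})

test_that("branch migration is folded into the canonical form", {
  # a migration that displaces nothing: an invading overhang and the
  # incumbent strand exchange one duplex position; the pre- and post-states
  # are the same species (the junction wobbles between the two alignments)
  pre <- gate(list(list(d = "t^", ur = "x"),
                   list(d = c("x", "y"))))
  post <- gate(list(list(d = c("t^", "x")),
                    list(d = "y", ul = "x")))
  expect_identical(dsdverify:::species_key(pre),
                   dsdverify:::species_key(post))
  # and canonicalisation is idempotent there
  expect_identical(dsdverify:::species_key(canonicalize(pre)),
                   dsdverify:::species_key(pre))
})

test_that("module expansion freshens private domains per instantiation", {
  src <- "
    def S(N, x) = N * <t^ x>
    def T(N, x, y) = new c (
      N * {t^*}[x t^]:[c t^]:[c]
    | N * [x]:[t^ y]:[t^ c]{t^*}
    | N * <t^ c>
    | N * <y t^> )
    S(1, x0) | T(1, x0, x1) | T(1, x1, x2)
  "
  sys <- parse_system(src)
  ks <- names(sys$species_counts)
  # the two instantiations must use disjoint fresh names for c
  cs <- unique(unlist(regmatches(ks, gregexpr("c\\.[0-9]+", ks))))
  expect_length(cs, 2L)
  # but share every free domain: x1 appears in species of both instances
  expect_true(any(grepl("x1", ks)))
  # expansion is idempotent on module-free systems
  expect_identical(print_system(expand_modules(sys)), print_system(sys))
  # zero-parameter module expands to its body
  sys0 <- parse_system("def M() = 2 * <t^ z>\nM()")
  expect_equal(sys0$species_counts[["<t^ z>"]], 2L)
  # arity mismatch and recursion are rejected
  expect_error(parse_system("def M(x) = <t^ x>\nM()"), "1 argument")
  expect_error(parse_system("def M(x) = M(x)\nM(y)"), "recursive")
})

test_that("well-formedness flags exposed long-domain complements", {
  sys <- parse_system("<t^ x> | [y]{x* t^*}")
  v <- check_well_formed(sys)
  expect_length(v, 1L)
  expect_match(v, "'x'")
  expect_length(check_well_formed(parse_system("")), 0L)
  # every initial case-study system passes
  reset_domains()
  for (sys in list(sys_par(S(1, "x0"), T_buggy(1, "x0", "x1")),
                   sys_par(S(1, "x"), S(1, "y"), C_gc(1, "x", "y", "z")),
                   sys_par(S(1, "x"), S(1, "y"), C_NoGC(1, "x", "y", "z")),
                   approx_majority(1, 1)$sys)) {
    expect_length(check_well_formed(sys), 0L)
  }
})
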