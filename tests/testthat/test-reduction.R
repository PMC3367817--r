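# Elementary rules and the merged reaction semantics.

rts <- rate_model(bind = c(.default = 1e-3))

rxn_strings <- function(rxns) {
  sort(vapply(rxns, function(r)
    paste(paste(r$reactants, collapse = " + "), "->",
          paste(r$products, collapse = " + ")), ""))
}

test_that("the toehold-binding cascade collapses to a single merged reaction", {
  # <t^ x u^> invading {t^*}[x]{u^*}: binding, displacement and the final
  # toehold hybridisation merge into one reaction releasing the inert <x>
  s <- strand("t^", "x", "u^")
  g <- gate(list(list(ll = "t^*", d = "x", lr = "u^*")))
  rxns <- merged_reactions(s, g, rts)
  prods <- unique(lapply(rxns, `[[`, "products"))
  expect_length(prods, 1L)
  expect_identical(prods[[1L]],
                   sort(c(dsdverify:::species_key(gate(list(list(d = c("t^", "x", "u^"))))),
                          "<x>")))
  # both toeholds can initiate; each initiating toehold is reported
  expect_setequal(vapply(rxns, `[[`, "", "toehold"), c("t", "u"))
  expect_true(all(vapply(rxns, `[[`, 1, "rate") == 1e-3))
})

test_that("toehold-only attachments unbind (RU) and are filtered as unproductive", {
  # a strand whose long domain mismatches the adjacent duplex binds but can
  # only fall off again: no merged reaction
  s <- strand("t^", "w")
  g <- gate(list(list(ll = "t^*", d = "x", lr = "u^*")))
  expect_length(merged_reactions(s, g, rts), 0L)
  # same with a bare toehold strand
  expect_length(merged_reactions(strand("t^"), g, rts), 0L)
})

test_that("elementary steps: RB/RU structure on a bound intermediate", {
  g <- gate(list(list(ll = "t^*", d = "x", lr = "u^*")))
  steps <- elementary_steps(list(strand("t^", "w"), g))
  expect_setequal(vapply(steps, `[[`, "", "rule"), "RB")
  bound <- steps[[1L]]$produced
  # the bound intermediate's only non-binding move is RU, straight back
  reg <- new.env(parent = emptyenv())
  b <- dsdverify:::rb_bindings(strand("t^", "w"), g)[[1L]]$bound
  ops <- dsdverify:::ops_nonRB(b)
  expect_length(ops, 1L)
  expect_identical(ops[[1L]]$rule, "RU")
})

test_that("reaction rates equal the initiating toehold's binding rate and rescale linearly", {
  s <- strand("t^", "x", "u^")
  g <- gate(list(list(ll = "t^*", d = "x", lr = "u^*")))
  r1 <- merged_reactions(s, g, rate_model(bind = c(t = 2e-3, u = 5e-4)))
  rate_by_th <- stats::setNames(vapply(r1, `[[`, 1, "rate"),
                                vapply(r1, `[[`, "", "toehold"))
  expect_equal(rate_by_th[["t"]], 2e-3)
  expect_equal(rate_by_th[["u"]], 5e-4)
  r2 <- merged_reactions(s, g, rate_model(bind = c(t = 6e-3, u = 15e-4)))
  expect_equal(vapply(r2, `[[`, 1, "rate") / vapply(r1, `[[`, 1, "rate"),
               rep(3, length(r1)))
})

test_that("merged_reactions is symmetric in its arguments and skips identities", {
  s <- strand("t^", "x")
  I <- gate(list(list(ll = "t^*", d = c("x", "t^")),
                 list(d = c("a", "t^")), list(d = "a")))
  a <- rxn_strings(merged_reactions(s, I, rts))
  b <- rxn_strings(merged_reactions(I, s, rts))
  expect_identical(a, b)
  for (r in merged_reactions(s, I, rts))
    expect_false(identical(sort(r$reactants), sort(r$products)))
})

test_that("merged products equal the elementary-graph oracle on small gates", {
  skip_if_not_installed("igraph")
  # pairs covering: plain displacement, reversible exchange, unproductive
  # binding, entry from the right end, and a fixture-generated gate
  cases <- list(
    list(strand("t^", "x", "u^"), gate(list(list(ll = "t^*", d = "x", lr = "u^*")))),
    list(strand("t^", "x"),
         gate(list(list(ll = "t^*", d = c("x", "t^")), list(d = c("a", "t^")),
                   list(d = "a")))),
    list(strand("t^", "w"), gate(list(list(ll = "t^*", d = "x", lr = "u^*")))),
    list(strand("a", "t^"),
         gate(list(list(d = "x"), list(d = c("t^", "y")),
                   list(d = c("t^", "a"), lr = "t^*")))),
    list(strand("t^", "a"),
         gate(list(list(d = c("t^", "x"), lr = "t^*"), list(d = c("a", "t^")),
                   list(d = "a")))))
  for (cs in cases) {
    got <- unique(lapply(merged_reactions(cs[[1L]], cs[[2L]], rts),
                         `[[`, "products"))
    want <- oracle_merged_products(cs[[1L]], cs[[2L]])
    expect_setequal(vapply(got, paste, "", collapse = " + "),
                    vapply(want, paste, "", collapse = " + "))
  }
})

test_that("strand-strand toehold contacts are unproductive in well-formed systems", {
  # two free strands can only share complementary toeholds (well-formedness
  # bars complementary long domains from being simultaneously unbound), and
  # a toehold-only duplex just falls apart again: no merged reaction
  s1 <- strand("t^", "x")
  s2 <- strand("y", "t^*")
  b <- dsdverify:::rb_bindings(s1, s2)
  expect_gte(length(b), 1L)                      # the binding itself exists
  expect_length(merged_reactions(s1, s2, rts), 0L)  # but it is unproductive
})
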