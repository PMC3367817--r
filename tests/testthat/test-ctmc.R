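# Population CTMC construction: propensities, constant species, labels,
# rewards and export.

# a hand-made two-reaction network over abstract species (the CTMC layer
# only consumes keys, so species structures can be simple strands)
toy_net <- function(constantB = FALSE) {
  A <- strand("t^", "A"); B <- strand("t^", "B"); C <- strand("t^", "C")
  sys <- make_system(list(A, B, C), counts = c(2L, 3L, 0L),
                     constant = c(FALSE, constantB, FALSE))
  net <- list(species = names(sys$species_counts),
              reactions = list(list(
                reactants = sort(c("<t^ A>", "<t^ B>")),
                products = "<t^ C>", rate = 0.5, toehold = "t")),
              registry = sys$registry, sys = sys)
  class(net) <- "dsd_network"
  net$reactive <- classify_reactive(net)
  net
}

test_that("mass-action propensities: k * nA * nB for distinct reactants", {
  m <- build_ctmc(toy_net())
  tr0 <- m$trans[m$trans$from == m$init, ]
  expect_equal(nrow(tr0), 1L)
  expect_equal(tr0$rate, 0.5 * 2 * 3)   # k nA nB
  # successor: one A and one B consumed, one C produced
  d <- m$states[tr0$to, ] - m$states[m$init, ]
  expect_equal(unname(d[c("<t^ A>", "<t^ B>", "<t^ C>")]), c(-1, -1, 1))
  # chain: 2 A's can react twice, then deadlock
  expect_equal(nrow(m$states), 3L)
  expect_equal(sum(m$exit == 0), 1L)
})

test_that("constant species contribute their count but never change", {
  m <- build_ctmc(toy_net(constantB = TRUE))
  expect_false("<t^ B>" %in% colnames(m$states))
  tr0 <- m$trans[m$trans$from == m$init, ]
  expect_equal(tr0$rate, 0.5 * 2 * 3)   # B enters as a fixed factor of 3
  s2 <- m$states[tr0$to, ]
  expect_equal(unname(s2[["<t^ A>"]]), 1)
  expect_equal(unname(s2[["<t^ C>"]]), 1)
})

test_that("homodimer propensity uses n(n-1)/2", {
  A <- strand("t^", "A"); D <- strand("t^", "D")
  sys <- make_system(list(A, D), counts = c(3L, 0L))
  net <- list(species = names(sys$species_counts),
              reactions = list(list(reactants = c("<t^ A>", "<t^ A>"),
                                    products = "<t^ D>", rate = 2,
                                    toehold = "t")),
              registry = sys$registry, sys = sys)
  class(net) <- "dsd_network"
  net$reactive <- classify_reactive(net)
  m <- build_ctmc(net)
  tr0 <- m$trans[m$trans$from == m$init, ]
  expect_equal(tr0$rate, 2 * 3 * 2 / 2)
})

test_that("exit rates are row sums and jump probabilities sum to one", {
  m <- get_study("faulty1")$ctmc
  agg <- rowsum(m$trans$rate, m$trans$from)
  expect_equal(unname(m$exit[as.integer(rownames(agg))]), as.numeric(agg))
  P <- dsdverify:::embedded_P(m)
  live <- which(m$exit > 0)
  expect_equal(unname(Matrix::rowSums(P)[live]), rep(1, length(live)))
  expect_equal(sum(Matrix::rowSums(P)[m$exit == 0]), 0)
})

test_that("state count is invariant under species permutation", {
  st <- get_study("faulty1")
  net <- st$net
  net2 <- net
  perm <- rev(seq_along(net$species))
  net2$species <- net$species[perm]
  net2$reactions <- rev(net$reactions)
  m1 <- build_ctmc(net)
  m2 <- build_ctmc(net2)
  expect_equal(nrow(m1$states), nrow(m2$states))
  expect_equal(nrow(m1$trans), nrow(m2$trans))
})

test_that("labels: outputs, all_done and deadlock behave per the recipe", {
  st <- get_study("faulty1")
  m <- st$ctmc; lab <- st$labels
  expect_equal(lab$output[m$init], 0)
  expect_false(lab$all_done[m$init])
  dl <- find_deadlocks(m)
  expect_length(dl, 2L)
  expect_setequal(lab$all_done[dl], c(TRUE, FALSE))
  # all_done implies deadlock for the transducer recipe
  expect_true(all(lab$deadlock[lab$all_done]))
  expect_error(make_labels(m, outputs = list(o = c("<zzz>" = 1))),
               "unknown species")
})

test_that("time reward accumulates elapsed time", {
  m <- get_study("faulty1")$ctmc
  rw <- time_reward(m)
  expect_true(all(rw$state == 1))
  expect_true(all(rw$trans == 0))
})

test_that("explicit-state export round-trips counts and rates", {
  m <- build_ctmc(toy_net())
  base <- file.path(tempdir(), "toy")
  files <- export_explicit(m, base, labels = make_labels(m))
  tra <- readLines(paste0(base, ".tra"))
  hdr <- as.integer(strsplit(tra[1L], " ")[[1L]])
  expect_equal(hdr, c(nrow(m$states), nrow(m$trans)))
  sta <- readLines(paste0(base, ".sta"))
  expect_length(sta, nrow(m$states) + 1L)
  expect_match(sta[1L], "<t^ A>", fixed = TRUE)
})
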