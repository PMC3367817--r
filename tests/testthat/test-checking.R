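# Verification engine: deadlocks, CTL checks, reachability probabilities,
# expected times, absorption distributions; cross-checked against dense
# base-R oracles and closed forms.

two_state_model <- function(r = 2.5) {
  # one species, one unimolecular-looking decay realised as A + B with B
  # constant: A -> C at rate r
  A <- strand("t^", "A"); B <- strand("t^", "B"); C <- strand("t^", "C")
  sys <- make_system(list(A, B, C), counts = c(1L, 1L, 0L),
                     constant = c(FALSE, TRUE, FALSE))
  net <- list(species = names(sys$species_counts),
              reactions = list(list(reactants = sort(c("<t^ A>", "<t^ B>")),
                                    products = sort(c("<t^ C>", "<t^ B>")),
                                    rate = r, toehold = "t")),
              registry = sys$registry, sys = sys)
  class(net) <- "dsd_network"
  net$reactive <- classify_reactive(net)
  build_ctmc(net)
}

test_that("deadlock detection and the CTL checks on the transducer pairs", {
  mf <- get_study("faulty1")$ctmc; lf <- get_study("faulty1")$labels
  expect_length(find_deadlocks(mf), 2L)
  inv <- check_deadlock_invariant(mf, lf$all_done)
  expect_false(inv$value)
  # the counterexample is a real path ending in a violating deadlock
  w <- inv$witness
  expect_identical(w[1L], mf$init)
  expect_true(lf$deadlock[w[length(w)]] && !lf$all_done[w[length(w)]])
  for (i in seq_len(length(w) - 1L))
    expect_true(any(mf$trans$from == w[i] & mf$trans$to == w[i + 1L]))
  expect_true(check_reachable(mf, lf$all_done)$value)
  expect_true(check_deadlock_invariant(mf, rep(TRUE, nrow(mf$states)))$value)
  expect_false(check_reachable(mf, rep(FALSE, nrow(mf$states)))$value)

  mc <- get_study("corrected1")$ctmc; lc <- get_study("corrected1")$labels
  expect_true(check_deadlock_invariant(mc, lc$all_done)$value)
  expect_true(check_reachable(mc, lc$all_done)$value)
})

test_that("reachability agrees with a graph-search oracle on the pair model", {
  m <- get_study("faulty1")$ctmc
  set.seed(42)
  adj <- split(m$trans$to, m$trans$from)
  bfs_reach <- function(targets) {
    seen <- logical(nrow(m$states)); seen[m$init] <- TRUE; q <- m$init
    while (length(q)) {
      s <- q[[1L]]; q <- q[-1L]
      if (s %in% targets) return(TRUE)
      for (t in adj[[as.character(s)]])
        if (!seen[t]) { seen[t] <- TRUE; q <- c(q, t) }
    }
    FALSE
  }
  for (i in 1:20) {
    pred <- stats::runif(nrow(m$states)) < 0.05
    expect_identical(check_reachable(m, pred)$value, bfs_reach(which(pred)))
  }
})

test_that("prob_reach matches the dense value-iteration oracle", {
  st <- get_study("faulty1")
  m <- st$ctmc; lab <- st$labels
  tgt <- which(lab$deadlock & !lab$all_done)
  expect_equal(prob_reach(m, lab$deadlock & !lab$all_done)$value,
               oracle_prob_reach_dense(m, tgt), tolerance = 1e-8)
  # a mid-execution predicate too
  pred <- lab$output == 1
  expect_equal(prob_reach(m, pred)$value,
               oracle_prob_reach_dense(m, which(pred)), tolerance = 1e-8)
  # complementary deadlock probabilities sum to one
  p1 <- prob_reach(m, lab$deadlock & !lab$all_done)$value
  p2 <- prob_reach(m, lab$deadlock & lab$all_done)$value
  expect_equal(p1 + p2, 1, tolerance = 1e-10)
})

test_that("expected time: exponential closed form and dense oracle", {
  m <- two_state_model(r = 2.5)
  tgt <- m$states[, "<t^ C>"] == 1
  expect_equal(expected_time_to(m, tgt)$value, 1 / 2.5, tolerance = 1e-12)
  st <- get_study("faulty1")
  lab <- st$labels
  et <- expected_time_to(st$ctmc, lab$deadlock)
  expect_equal(et$value,
               oracle_expected_time_dense(st$ctmc, which(lab$deadlock)),
               tolerance = 1e-6)
  # infinite when the target is not almost surely reached
  bad <- expected_time_to(st$ctmc, lab$deadlock & lab$all_done)
  expect_identical(bad$value, Inf)
})

test_that("time-bounded reachability: limits, monotonicity, dense oracle", {
  m <- two_state_model(r = 2.5)
  tgt <- m$states[, "<t^ C>"] == 1
  expect_equal(prob_reach_within(m, tgt, 0)$value, 0)
  expect_equal(prob_reach_within(m, tgt, 1)$value, 1 - exp(-2.5),
               tolerance = 1e-9)
  init_pred <- seq_len(nrow(m$states)) == m$init
  expect_equal(prob_reach_within(m, init_pred, 0)$value, 1)

  st <- get_study("faulty1")
  lab <- st$labels
  err <- lab$deadlock & !lab$all_done
  times <- c(500, 2000, 10000, 1e6)
  ps <- vapply(times, function(tt)
    prob_reach_within(st$ctmc, err, tt)$value, 1)
  expect_true(all(diff(ps) >= -1e-12))
  expect_equal(ps[length(ps)], prob_reach(st$ctmc, err)$value,
               tolerance = 1e-6)
  expect_equal(ps[2L], oracle_transient_dense(st$ctmc, which(err), 2000),
               tolerance = 1e-3)
})

test_that("absorption distribution sums to one and matches per-target solves", {
  st <- get_study("faulty1")
  m <- st$ctmc
  ad <- absorption_distribution(m)
  expect_equal(sum(ad$per_state), 1, tolerance = 1e-10)
  for (d in as.integer(names(ad$per_state))) {
    expect_equal(unname(ad$per_state[[as.character(d)]]),
                 prob_reach(m, seq_len(nrow(m$states)) == d)$value,
                 tolerance = 1e-9)
  }
  # the AM model has recurrent consensus classes, not deadlocks
  am <- get_study("am21")
  expect_error(absorption_distribution(am$ctmc), "absorption undefined")
})

test_that("probabilities are invariant under global rate rescaling; times divide", {
  st <- transducer_pair(1, corrected = FALSE,
                        rates = rate_model(bind = c(.default = 5e-3)))
  base <- get_study("faulty1")
  lab <- st$labels; lab0 <- base$labels
  err <- function(L) L$deadlock & !L$all_done
  expect_equal(prob_reach(st$ctmc, err(lab))$value,
               prob_reach(base$ctmc, err(lab0))$value, tolerance = 1e-9)
  t1 <- expected_time_to(st$ctmc, lab$deadlock)$value
  t0 <- expected_time_to(base$ctmc, lab0$deadlock)$value
  expect_equal(t0 / t1, 5, tolerance = 1e-9)
})
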