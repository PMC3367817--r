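# Case-study builders: species inventories, privacy of refreshed domains,
# catalyst correctness, and the constant-fuel abstraction.

test_that("transducer and signal inventories match the described populations", {
  reset_domains()
  tt <- T_buggy(1, "x0", "x1")
  ks <- names(tt$species_counts)
  expect_length(ks, 4L)
  kinds <- vapply(ks, function(k) tt$registry[[k]]$kind, "")
  expect_equal(sum(kinds == "gate"), 2L)    # two complexes
  expect_equal(sum(kinds == "strand"), 2L)  # two fuel strands
  expect_true(all(tt$species_counts == 1L))
  t3 <- T_buggy(3, "x0", "x1")
  expect_true(all(t3$species_counts == 3L))
  expect_length(S(0, "x")$species_counts, 0L)
  expect_equal(unname(S(2, "x")$species_counts), 2L)
})

test_that("buggy transducers share domain 'a'; corrected ones do not", {
  reset_domains()
  doms_of <- function(sys) {
    uniq <- unique(unlist(lapply(names(sys$species_counts), function(k) {
      sp <- sys$registry[[k]]
      if (sp$kind == "strand") sp$domains else unlist(sp$segs)
    })))
    dsdverify:::dom_base(uniq)
  }
  a1 <- doms_of(T_buggy(1, "x0", "x1")); a2 <- doms_of(T_buggy(1, "x1", "x2"))
  expect_true("a" %in% intersect(a1, a2))
  b1 <- doms_of(T2(1, "x0", "x1")); b2 <- doms_of(T2(1, "x1", "x2"))
  shared <- intersect(grep("^a", b1, value = TRUE),
                      grep("^a", b2, value = TRUE))
  expect_length(shared, 0L)
})

test_that("both catalyst designs satisfy the transducer correctness pair", {
  for (gc in c(TRUE, FALSE)) {
    st <- catalyst_study(1, gc = gc)
    expect_true(check_deadlock_invariant(st$ctmc, st$labels$all_done)$value,
                label = sprintf("gc=%s invariant", gc))
    expect_true(check_reachable(st$ctmc, st$labels$all_done)$value,
                label = sprintf("gc=%s reachable", gc))
  }
})

test_that("no-GC finished gates are auto-unreactive; GC penultimate forms need overrides", {
  st <- catalyst_study(1, gc = FALSE)
  reactive <- classify_reactive(st$net)   # without overrides
  done_keys <- names(st$overrides)
  expect_length(done_keys, 2L)
  expect_true(all(done_keys %in% st$net$species))
  # both finished forms are reactive in the raw universe-level
  # classification (the <a t^> intermediate can re-invade the input complex;
  # the output signal can re-invade the output complex) - exactly why the
  # fairness adjustment designates them unreactive
  lab_r <- classify_reactive(st$net, st$overrides)
  expect_true(all(!lab_r[done_keys]))
  stgc <- catalyst_study(1, gc = TRUE)
  raw <- classify_reactive(stgc$net)
  expect_true(all(names(stgc$overrides) %in% stgc$net$species))
  expect_true(any(raw[names(stgc$overrides)]))  # overrides actually bite
})

test_that("the constant-fuel waste forms are the engine's own products", {
  # the two waste species declared by C_const must be exactly what running
  # the no-GC catalyst to completion produces
  reset_domains()
  sysc <- C_const(1, "x", "y", "z")
  declared <- names(sysc$species_counts)[sysc$species_counts == 0L]
  reset_domains()
  run <- catalyst_study(1, gc = FALSE)
  # the no-GC model deadlocks nowhere (finished capped gates keep shuffling
  # reversibly with the leftover strands), so look at the all_done states
  done <- which(run$labels$all_done)
  expect_gt(length(done), 0L)
  present <- colnames(run$ctmc$states)[
    colSums(run$ctmc$states[done, , drop = FALSE] > 0) > 0]
  # same fresh-domain numbering in both builders (a.1 / c.2)
  expect_true(all(declared %in% present),
              info = paste("declared:", paste(declared, collapse = " | ")))
})

test_that("AM consensus classes: no B and no opposite signal; fixture determinism", {
  am <- get_study("am21")
  lab <- am$labels
  m <- am$ctmc
  consX <- which(lab$output_x == am$total)
  expect_gt(length(consX), 0L)
  expect_true(all(lab$output_y[consX] == 0))
  expect_true(all(lab$output_b[consX] == 0))
  # the two consensus outcomes are exhaustive and exclusive
  px <- prob_reach(m, lab$output_x == am$total)$value
  py <- prob_reach(m, lab$output_y == am$total)$value
  expect_equal(px + py, 1, tolerance = 1e-9)
  expect_false(any(lab$output_x == am$total & lab$output_y == am$total))
  expect_identical(print_system(generate_fixture(11)),
                   print_system(generate_fixture(11)))
})
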