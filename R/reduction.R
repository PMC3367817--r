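# Elementary reduction rules and the merged (toehold-limited) reaction
# semantics.
#
# Rules, applied closed under rotation of species and at any position:
#   RB  toehold-mediated binding of a free strand to an exposed complementary
#       toehold on a gate (or to another free strand) - the only bimolecular
#       rule, and the only one with a finite rate under the merged semantics
#   RU  spontaneous unbinding of a strand held by a single toehold
#   RC  hybridisation of complementary unpaired toeholds flush at a junction
#   RD  strand displacement: branch migration that completely detaches a
#       strand
#   RM  branch migration that displaces nothing; folded into structural
#       congruence (species are equivalent up to branch migration), so RM
#       connects states with equal canonical forms
#
# A merged reaction takes one RB instance and exhaustively closes it under
# the instantaneous rules {RU, RC, RD} to the terminal configurations in
# which only further RB steps are possible.  Each distinct non-identity
# terminal yields one reaction whose stochastic rate constant is the binding
# rate of the initiating toehold; the identity outcome (the strand just
# unbinds again) is an unproductive binding and yields no reaction.

# ---- rate model ------------------------------------------------------------

#' Kinetic rate model
#'
#' Under the merged semantics only the toehold association rates parametrise
#' reactions; unbinding and migration rates are retained for the elementary
#' rules' documentation and for future finite-rate semantics.
#'
#' @param bind named numeric vector of association rates per toehold base
#'   name; entry `".default"` applies to unnamed toeholds.  Association rates
#'   are used directly as stochastic rate constants in a unit volume.
#' @param unbind,migrate named numeric vectors (unused by the merged
#'   semantics).
#' @return a `dsd_rates` object.
#' @export
rate_model <- function(bind = c(.default = 1e-3),
                       unbind = c(.default = 0.1),
                       migrate = c(.default = 1)) {
  stopifnot(all(bind > 0), all(unbind > 0), all(migrate > 0))
  structure(list(bind = bind, unbind = unbind, migrate = migrate),
            class = "dsd_rates")
}

bind_rate <- function(rates, toehold) {
  b <- rates$bind
  base <- dom_base(toehold)
  if (base %in% names(b)) unname(b[[base]]) else unname(b[[".default"]])
}

# ---- species registry / cache ---------------------------------------------

.dsd_cache <- new.env(parent = emptyenv())

cache_reset <- function() {
  rm(list = ls(.dsd_cache), envir = .dsd_cache)
}

canonical_sp <- function(sp, bm = TRUE) {
  if (bm) return(canonicalize(sp))
  a <- sp; b <- rotate_species(sp)
  ka <- print_species(a); kb <- print_species(b)
  if (kb < ka) { sp <- b; k <- kb } else { sp <- a; k <- ka }
  attr(sp, "key") <- k
  sp
}

reg_get <- function(registry, key) registry[[key]]

reg_put <- function(registry, sp) {
  k <- species_key(sp)
  if (is.null(registry[[k]])) registry[[k]] <- sp
  k
}

# ---- single-species (non-RB) operations -----------------------------------

# RU: release every strand held by a single toehold.
enum_RU <- function(g, bm = TRUE) {
  out <- list()
  if (is_strand(g)) return(out)
  n <- length(g$segs)
  runs <- upper_runs(g)
  for (run in runs) {
    if (length(run) != 1L) next
    j <- run[[1L]]
    seg <- g$segs[[j]]
    if (length(seg) != 1L || !dom_is_toehold(seg)) next
    ldang <- if (j == 1L) g$lend$u else g$gaps[[j - 1L]]$u$r
    rdang <- if (j == n) g$rend$u else g$gaps[[j]]$u$l
    strand <- new_strand(c(ldang, seg, rdang))
    lower_d <- dom_complement(seg)
    if (n == 1L) {
      lower <- c(g$lend$lo, lower_d, g$rend$lo)
      rest <- new_strand(rev(lower))
      out[[length(out) + 1L]] <- list(rule = "RU",
                                      products = list(strand, rest))
      next
    }
    if (j == 1L) {
      gp <- g$gaps[[1L]]
      if (gp$lo$type != "cont") next  # would have been disconnected
      g2 <- g
      g2$segs[[1L]] <- NULL; g2$gaps[[1L]] <- NULL
      g2$lend <- list(u = gp$u$r, lo = c(g$lend$lo, lower_d, gp$lo$s))
      out[[length(out) + 1L]] <- list(rule = "RU", products = list(strand, g2))
      next
    }
    if (j == n) {
      gp <- g$gaps[[n - 1L]]
      if (gp$lo$type != "cont") next
      g2 <- g
      g2$segs[[n]] <- NULL; g2$gaps[[n - 1L]] <- NULL
      g2$rend <- list(u = gp$u$l, lo = c(gp$lo$s, lower_d, g$rend$lo))
      out[[length(out) + 1L]] <- list(rule = "RU", products = list(strand, g2))
      next
    }
    gl <- g$gaps[[j - 1L]]; gr <- g$gaps[[j]]
    if (gl$lo$type != "cont" || gr$lo$type != "cont") next
    g2 <- g
    g2$segs[[j]] <- NULL
    g2$gaps[[j]] <- NULL
    g2$gaps[[j - 1L]] <- new_gap(
      u = gap_nick(l = gl$u$l, r = gr$u$r),
      lo = gap_cont(s = c(gl$lo$s, lower_d, gr$lo$s)))
    out[[length(out) + 1L]] <- list(rule = "RU", products = list(strand, g2))
  }
  out
}

# RD rightward at junction j: the left upper strand's dangle invades the
# next duplex; returns NULL unless at least one strand is fully displaced.
try_displace_right <- function(g, j) {
  released <- list()
  repeat {
    if (j > length(g$gaps)) break
    gp <- g$gaps[[j]]
    if (gp$u$type != "nick" || gp$lo$type != "cont" || length(gp$lo$s) != 0L)
      break
    l <- gp$u$l
    if (length(l) == 0L || length(g$segs) < j + 1L) break
    if (l[1L] != g$segs[[j + 1L]][1L]) break
    # single migration move
    d <- g$segs[[j + 1L]][1L]
    g$segs[[j]] <- c(g$segs[[j]], d)
    g$segs[[j + 1L]] <- g$segs[[j + 1L]][-1L]
    g$gaps[[j]]$u$l <- l[-1L]
    g$gaps[[j]]$u$r <- c(g$gaps[[j]]$u$r, d)
    if (length(g$segs[[j + 1L]]) > 0L) next
    # the invaded duplex is used up; what happens to its upper strand?
    n <- length(g$segs)
    if (j + 1L == n) {
      # ends at the right end of the gate
      released[[length(released) + 1L]] <-
        new_strand(c(g$gaps[[j]]$u$r, g$rend$u))
      newrend <- list(u = g$gaps[[j]]$u$l, lo = g$rend$lo)
      g$segs[[j + 1L]] <- NULL
      g$gaps[[j]] <- NULL
      g$rend <- newrend
      break
    }
    gnext <- g$gaps[[j + 1L]]
    if (gnext$u$type == "nick") {
      released[[length(released) + 1L]] <-
        new_strand(c(g$gaps[[j]]$u$r, gnext$u$l))
      merged <- new_gap(
        u = gap_nick(l = g$gaps[[j]]$u$l, r = gnext$u$r),
        lo = if (gnext$lo$type == "cont") gap_cont(gnext$lo$s)
             else gap_nick(l = gnext$lo$l, r = gnext$lo$r))
      g$segs[[j + 1L]] <- NULL
      g$gaps[[j + 1L]] <- NULL
      g$gaps[[j]] <- merged
      if (merged$lo$type == "nick") break  # track strand broken: stop
      next
    }
    # incumbent continues into the following duplex; keep walking if the
    # lower track is continuous
    if (gnext$lo$type != "cont") break
    merged <- new_gap(
      u = gap_nick(l = g$gaps[[j]]$u$l, r = c(g$gaps[[j]]$u$r, gnext$u$s)),
      lo = gap_cont(s = gnext$lo$s))
    g$segs[[j + 1L]] <- NULL
    g$gaps[[j + 1L]] <- NULL
    g$gaps[[j]] <- merged
  }
  if (length(released) == 0L) return(NULL)
  list(gate = g, released = released)
}

unflip_result <- function(res) {
  res$gate <- flip_species(res$gate)
  res$released <- lapply(res$released, function(s) new_strand(rev(s$domains)))
  res
}

enum_RD <- function(g, bm = TRUE) {
  out <- list()
  if (is_strand(g)) return(out)
  for (j in seq_along(g$gaps)) {
    res <- try_displace_right(g, j)
    if (!is.null(res))
      out[[length(out) + 1L]] <- list(rule = "RD",
                                      products = c(list(res$gate), res$released))
  }
  gf <- flip_species(g)
  for (j in seq_along(gf$gaps)) {
    res <- try_displace_right(gf, j)
    if (!is.null(res)) {
      res <- unflip_result(res)
      out[[length(out) + 1L]] <- list(rule = "RD",
                                      products = c(list(res$gate), res$released))
    }
  }
  out
}

# RC: hybridise complementary toeholds lying flush at a junction or end.
enum_RC <- function(g, bm = TRUE) {
  out <- list()
  if (is_strand(g)) return(out)
  n <- length(g$segs)
  # right end
  if (length(g$rend$u) && length(g$rend$lo) &&
      dom_is_toehold(g$rend$u[1L]) &&
      g$rend$lo[1L] == dom_complement(g$rend$u[1L])) {
    g2 <- g
    g2$segs[[n]] <- c(g2$segs[[n]], g$rend$u[1L])
    g2$rend <- list(u = g$rend$u[-1L], lo = g$rend$lo[-1L])
    out[[length(out) + 1L]] <- list(rule = "RC", products = list(g2))
  }
  # left end
  lu <- g$lend$u; llo <- g$lend$lo
  if (length(lu) && length(llo) &&
      dom_is_toehold(lu[length(lu)]) &&
      llo[length(llo)] == dom_complement(lu[length(lu)])) {
    g2 <- g
    g2$segs[[1L]] <- c(lu[length(lu)], g2$segs[[1L]])
    g2$lend <- list(u = lu[-length(lu)], lo = llo[-length(llo)])
    out[[length(out) + 1L]] <- list(rule = "RC", products = list(g2))
  }
  # junctions: flush against the left duplex (uses the first elements of the
  # right-facing dangles) and against the right duplex (last elements)
  for (j in seq_along(g$gaps)) {
    gp <- g$gaps[[j]]
    useq <- if (gp$u$type == "nick") gp$u$l else gp$u$s
    loseq <- if (gp$lo$type == "nick") gp$lo$l else gp$lo$s
    if (length(useq) && length(loseq) &&
        dom_is_toehold(useq[1L]) &&
        loseq[1L] == dom_complement(useq[1L])) {
      g2 <- g
      g2$segs[[j]] <- c(g2$segs[[j]], useq[1L])
      if (gp$u$type == "nick") g2$gaps[[j]]$u$l <- gp$u$l[-1L]
      else g2$gaps[[j]]$u$s <- gp$u$s[-1L]
      if (gp$lo$type == "nick") g2$gaps[[j]]$lo$l <- gp$lo$l[-1L]
      else g2$gaps[[j]]$lo$s <- gp$lo$s[-1L]
      out[[length(out) + 1L]] <- list(rule = "RC", products = list(g2))
    }
    useq2 <- if (gp$u$type == "nick") gp$u$r else gp$u$s
    loseq2 <- if (gp$lo$type == "nick") gp$lo$r else gp$lo$s
    nu <- length(useq2); nl <- length(loseq2)
    if (nu && nl && dom_is_toehold(useq2[nu]) &&
        loseq2[nl] == dom_complement(useq2[nu])) {
      g2 <- g
      g2$segs[[j + 1L]] <- c(useq2[nu], g2$segs[[j + 1L]])
      if (gp$u$type == "nick") g2$gaps[[j]]$u$r <- useq2[-nu]
      else g2$gaps[[j]]$u$s <- useq2[-nu]
      if (gp$lo$type == "nick") g2$gaps[[j]]$lo$r <- loseq2[-nl]
      else g2$gaps[[j]]$lo$s <- loseq2[-nl]
      out[[length(out) + 1L]] <- list(rule = "RC", products = list(g2))
    }
  }
  out
}

# RM: single branch-migration moves (only meaningful with bm = FALSE, where
# branch migration is not folded into the canonical form).
enum_RM <- function(g, bm = TRUE) {
  if (bm || is_strand(g)) return(list())
  out <- list()
  for (j in seq_along(g$gaps)) {
    g2 <- migrate_left_step(g, j)
    if (!is.null(g2)) out[[length(out) + 1L]] <- list(rule = "RM",
                                                     products = list(g2))
  }
  gf <- flip_species(g)
  for (j in seq_along(gf$gaps)) {
    g2 <- migrate_left_step(gf, j)
    if (!is.null(g2))
      out[[length(out) + 1L]] <- list(rule = "RM",
                                      products = list(flip_species(g2)))
  }
  out
}

migrate_right_step <- function(g, j) {
  gf <- flip_species(g)
  jf <- length(gf$gaps) + 1L - j
  res <- migrate_left_step(gf, jf)
  if (is.null(res)) NULL else flip_species(res)
}

# all representatives of a gate's branch-migration equivalence class (within
# one orientation); ops must be enumerated on each because e.g. RU only
# applies at the extreme of a migration walk
rm_class <- function(g) {
  out <- list(g)
  seen <- print_species(g)
  i <- 1L
  while (i <= length(out)) {
    h <- out[[i]]
    for (j in seq_along(h$gaps)) {
      for (nx in list(migrate_left_step(h, j), migrate_right_step(h, j))) {
        if (is.null(nx)) next
        k <- print_species(nx)
        if (!k %in% seen) { seen <- c(seen, k); out[[length(out) + 1L]] <- nx }
      }
    }
    i <- i + 1L
    if (i > 200L) stop("branch-migration class unexpectedly large")
  }
  out
}

# all non-RB operations available on one species, products canonicalised;
# enumerated on both orientations (lower-strand events) and over the whole
# branch-migration class (ops that need the junction pushed the other way)
ops_nonRB <- function(sp, bm = TRUE) {
  key <- paste0(if (bm) "B:" else "E:", species_key(canonical_sp(sp, bm)))
  hit <- .dsd_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- list(); seen <- character(0)
  reps <- list(sp, rotate_species(sp))
  if (bm && is_gate(sp)) {
    reps <- c(lapply(rm_class(sp), identity),
              lapply(rm_class(rotate_species(sp)), identity))
  }
  for (h in reps) {
    if (is_strand(h)) next
    ops <- c(enum_RU(h, bm), enum_RD(h, bm), enum_RC(h, bm), enum_RM(h, bm))
    for (op in ops) {
      prods <- list()
      for (p in op$products) prods <- c(prods, gate_tidy(p))
      prods <- lapply(prods, canonical_sp, bm = bm)
      keys <- sort(vapply(prods, species_key, ""))
      sig <- paste(op$rule, paste(keys, collapse = " + "))
      if (sig %in% seen) next
      seen <- c(seen, sig)
      out[[length(out) + 1L]] <- list(rule = op$rule, products = prods)
    }
  }
  .dsd_cache[[key]] <- out
  out
}

# ---- RB enumeration --------------------------------------------------------

# binding sites: exposed toeholds on the lower side of a gate (both ends and
# ":"-junction slack); enumerate on both orientations for upper-side sites
rb_sites_lower <- function(g) {
  sites <- list()
  if (is_strand(g)) return(sites)
  add <- function(where, j, seq) {
    for (m in seq_along(seq)) {
      if (dom_is_toehold(seq[m]))
        sites[[length(sites) + 1L]] <<- list(where = where, j = j, m = m,
                                             dom = seq[m])
    }
  }
  add("lend", 0L, g$lend$lo)
  add("rend", 0L, g$rend$lo)
  for (j in seq_along(g$gaps)) {
    gp <- g$gaps[[j]]
    if (gp$u$type == "nick" && gp$lo$type == "cont") add("gap", j, gp$lo$s)
  }
  sites
}

rb_bind_at <- function(g, site, sdoms, k) {
  pre <- if (k > 1L) sdoms[seq_len(k - 1L)] else chr0
  post <- if (k < length(sdoms)) sdoms[seq(k + 1L, length(sdoms))] else chr0
  newseg <- sdoms[k]
  if (site$where == "lend") {
    lo <- g$lend$lo
    m <- site$m
    gap <- new_gap(u = gap_nick(l = post, r = g$lend$u),
                   lo = gap_cont(s = if (m < length(lo)) lo[seq(m + 1L, length(lo))] else chr0))
    g$segs <- c(list(newseg), g$segs)
    g$gaps <- c(list(gap), g$gaps)
    g$lend <- list(u = pre, lo = if (m > 1L) lo[seq_len(m - 1L)] else chr0)
    return(g)
  }
  if (site$where == "rend") {
    lo <- g$rend$lo
    m <- site$m
    gap <- new_gap(u = gap_nick(l = g$rend$u, r = pre),
                   lo = gap_cont(s = if (m > 1L) lo[seq_len(m - 1L)] else chr0))
    g$segs <- c(g$segs, list(newseg))
    g$gaps <- c(g$gaps, list(gap))
    g$rend <- list(u = post, lo = if (m < length(lo)) lo[seq(m + 1L, length(lo))] else chr0)
    return(g)
  }
  j <- site$j; m <- site$m
  gp <- g$gaps[[j]]
  s0 <- gp$lo$s
  gl <- new_gap(u = gap_nick(l = gp$u$l, r = pre),
                lo = gap_cont(s = if (m > 1L) s0[seq_len(m - 1L)] else chr0))
  gr <- new_gap(u = gap_nick(l = post, r = gp$u$r),
                lo = gap_cont(s = if (m < length(s0)) s0[seq(m + 1L, length(s0))] else chr0))
  g$segs <- append(g$segs, list(newseg), after = j)
  g$gaps <- append(g$gaps[-j], list(gl, gr), after = j - 1L)
  g
}

# all RB bindings between two species (at least one must be a strand);
# returns list of list(bound = species, toehold = initiating toehold base)
rb_bindings <- function(sp1, sp2, bm = TRUE) {
  out <- list(); seen <- character(0)
  pairs <- list(list(a = sp1, b = sp2), list(a = sp2, b = sp1))
  for (pr in pairs) {
    s <- pr$a; g <- pr$b
    if (!is_strand(s)) next
    sdoms <- s$domains
    if (is_strand(g)) {
      # strand-strand binding: s as upper, g as lower (rotated)
      lo <- rev(g$domains)
      for (k in seq_along(sdoms)) {
        if (!dom_is_toehold(sdoms[k])) next
        for (m in seq_along(lo)) {
          if (lo[m] != dom_complement(sdoms[k])) next
          pre <- if (k > 1L) sdoms[seq_len(k - 1L)] else chr0
          post <- if (k < length(sdoms)) sdoms[seq(k + 1L, length(sdoms))] else chr0
          gb <- new_gate(
            segs = list(sdoms[k]), gaps = list(),
            lend = list(u = pre, lo = if (m > 1L) lo[seq_len(m - 1L)] else chr0),
            rend = list(u = post, lo = if (m < length(lo)) lo[seq(m + 1L, length(lo))] else chr0))
          cb <- canonical_sp(gb, bm)
          sig <- species_key(cb)
          if (sig %in% seen) next
          seen <- c(seen, sig)
          out[[length(out) + 1L]] <- list(bound = cb,
                                          toehold = dom_base(sdoms[k]))
        }
      }
      next
    }
    for (h in list(g, rotate_species(g))) {
      sites <- rb_sites_lower(h)
      for (site in sites) {
        for (k in seq_along(sdoms)) {
          if (sdoms[k] != dom_complement(site$dom)) next
          if (!dom_is_toehold(sdoms[k])) next
          gb <- rb_bind_at(h, site, sdoms, k)
          pieces <- gate_tidy(gb)
          stopifnot(length(pieces) == 1L)
          cb <- canonical_sp(pieces[[1L]], bm)
          sig <- species_key(cb)
          if (sig %in% seen) next
          seen <- c(seen, sig)
          out[[length(out) + 1L]] <- list(bound = cb,
                                          toehold = dom_base(sdoms[k]))
        }
      }
    }
  }
  out
}

# ---- elementary step listing (exported; oracle support) -------------------

#' Enumerate elementary reduction steps
#'
#' Lists all instances of the elementary rules available in a configuration
#' (a list of species).  With `bm = TRUE` (the default) branch migration is
#' part of structural congruence, so no `RM` steps are reported and all
#' species are branch-migration normal forms; with `bm = FALSE` raw states
#' are kept and single `RM` moves are listed, which is what the brute-force
#' elementary-semantics oracle in the test-suite consumes.
#'
#' @param config list of species structures.
#' @param bm fold branch migration into canonical forms?
#' @return list of steps `list(rule, consumed, produced, toehold)`, where
#'   `consumed`/`produced` are character vectors of canonical species keys.
#' @export
elementary_steps <- function(config, bm = TRUE) {
  config <- lapply(config, canonical_sp, bm = bm)
  keys <- vapply(config, species_key, "")
  steps <- list()
  for (i in seq_along(config)) {
    for (op in ops_nonRB(config[[i]], bm = bm)) {
      steps[[length(steps) + 1L]] <- list(
        rule = op$rule, consumed = keys[i],
        produced = vapply(op$products, species_key, ""),
        toehold = NA_character_)
    }
  }
  if (length(config) >= 2L) {
    for (i in seq_len(length(config) - 1L)) {
      for (j in seq(i + 1L, length(config))) {
        for (b in rb_bindings(config[[i]], config[[j]], bm = bm)) {
          steps[[length(steps) + 1L]] <- list(
            rule = "RB", consumed = c(keys[i], keys[j]),
            produced = species_key(b$bound), toehold = b$toehold)
        }
      }
    }
  }
  steps
}

# ---- merged reactions ------------------------------------------------------

# close a configuration (multiset of species) under non-RB rules; returns
# list(terminals = list of key vectors, registry updated)
closure_terminals <- function(pieces, registry) {
  key_of <- function(ps) paste(sort(vapply(ps, species_key, "")), collapse = " | ")
  start <- lapply(pieces, canonicalize)
  for (p in start) reg_put(registry, p)
  seen <- new.env(parent = emptyenv())
  terminals <- list()
  queue <- list(start)
  seen[[key_of(start)]] <- TRUE
  guard <- 0L
  while (length(queue)) {
    cfg <- queue[[1L]]; queue <- queue[-1L]
    guard <- guard + 1L
    if (guard > 10000L) stop("closure did not terminate (possible polymerisation)")
    any_op <- FALSE
    for (i in seq_along(cfg)) {
      ops <- ops_nonRB(cfg[[i]])
      if (length(ops) == 0L) next
      any_op <- TRUE
      for (op in ops) {
        nxt <- c(cfg[-i], op$products)
        for (p in op$products) reg_put(registry, p)
        k <- key_of(nxt)
        if (is.null(seen[[k]])) {
          seen[[k]] <- TRUE
          queue[[length(queue) + 1L]] <- nxt
        }
      }
    }
    if (!any_op) {
      terminals[[length(terminals) + 1L]] <-
        sort(vapply(cfg, species_key, ""))
    }
  }
  unique(terminals)
}

#' Merged reactions between species
#'
#' Computes the merged-semantics reactions with the given reactant pair (or a
#' species with itself): every toehold binding is closed over the
#' instantaneous rules to its terminal configurations; identity outcomes
#' (unproductive bindings) are discarded; every other terminal yields one
#' reaction at the initiating toehold's association rate.
#'
#' @param sp1,sp2 canonical species structures.
#' @param rates a [rate_model()].
#' @param registry optional environment collecting species structures by key.
#' @return list of reactions `list(reactants, products, rate, toehold)` with
#'   `reactants`/`products` sorted key vectors.
#' @export
merged_reactions <- function(sp1, sp2, rates = rate_model(),
                             registry = new.env(parent = emptyenv())) {
  sp1 <- canonicalize(sp1); sp2 <- canonicalize(sp2)
  reg_put(registry, sp1); reg_put(registry, sp2)
  identity_key <- sort(c(species_key(sp1), species_key(sp2)))
  out <- list(); seen <- character(0)
  for (b in rb_bindings(sp1, sp2)) {
    terms <- closure_terminals(list(b$bound), registry)
    non_id <- Filter(function(t) !identical(t, identity_key), terms)
    if (length(non_id) == 0L) next
    if (length(non_id) > 1L) {
      stop(sprintf(
        "non-confluent merged reduction for %s + %s via toehold %s:\n  %s",
        species_key(sp1), species_key(sp2), b$toehold,
        paste(vapply(non_id, paste, "", collapse = " + "), collapse = "\n  ")))
    }
    sig <- paste(b$toehold, paste(non_id[[1L]], collapse = " + "))
    if (sig %in% seen) next
    seen <- c(seen, sig)
    out[[length(out) + 1L]] <- list(
      reactants = identity_key,
      products = non_id[[1L]],
      rate = bind_rate(rates, b$toehold),
      toehold = b$toehold)
  }
  out
}
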