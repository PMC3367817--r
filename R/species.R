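# Core data model for two-domain DSD species.
#
# A domain is a string: a name, optionally suffixed by "^" (toehold) and "*"
# (Watson-Crick complement), e.g. "x", "t^", "t^*", "a.2".
#
# A free strand is stored as a character vector of domains in page order,
# canonically as an upper strand <...> (a lower strand {S} is the rotation of
# the upper strand <rev(S)>, so rotation normalisation always yields "upper").
#
# A gate is a double-stranded complex: an ordered run of duplexed segments
# separated by junction gaps, plus single-stranded overhangs at both ends.
# Everything is kept in page order; duplexes store the upper-strand identity
# (the lower strand is the implied complement).
#
#   gate$segs  : list of character vectors (duplex domains, page order)
#   gate$gaps  : list (length nseg-1); gap$u and gap$lo are each either
#                list(type="nick", l=chr, r=chr)  - strand break; l dangles
#                   from the left segment, r from the right, both page order
#                list(type="cont", s=chr)         - continuous strand with
#                   unpaired slack s between the duplexes
#   gate$lend / gate$rend : list(u=chr, lo=chr) unpaired overhangs at the ends
#
# Structural identity of species is canonical-string equality: branch
# migration is normalised away and rotation (the only physical symmetry of a
# planar complex) is collapsed by taking the lexicographically smaller of the
# two printed orientations.

dom_is_toehold <- function(d) grepl("\\^", d)

dom_is_complement <- function(d) grepl("\\*$", d)

dom_complement <- function(d) {
  starred <- grepl("\\*$", d)
  ifelse(starred, sub("\\*$", "", d), paste0(d, "*"))
}

dom_base <- function(d) sub("\\*$", "", sub("\\^", "", d))

chr0 <- character(0)

new_strand <- function(domains) {
  stopifnot(length(domains) >= 1)
  structure(list(kind = "strand", domains = as.character(domains)),
            class = "dsd_species")
}

new_gap <- function(u = gap_nick(), lo = gap_cont()) list(u = u, lo = lo)

gap_nick <- function(l = chr0, r = chr0) list(type = "nick", l = l, r = r)

gap_cont <- function(s = chr0) list(type = "cont", s = s)

new_gate <- function(segs, gaps, lend = list(u = chr0, lo = chr0),
                     rend = list(u = chr0, lo = chr0)) {
  structure(list(kind = "gate", segs = segs, gaps = gaps,
                 lend = lend, rend = rend),
            class = "dsd_species")
}

is_strand <- function(sp) sp$kind == "strand"
is_gate <- function(sp) sp$kind == "gate"

# ---- rotation (180 degrees in the plane; the physical symmetry) -----------

rotate_species <- function(sp) {
  if (is_strand(sp)) {
    # rotating an upper strand gives a lower strand with reversed page order,
    # which re-normalises to the same upper strand: a no-op on free strands
    return(sp)
  }
  n <- length(sp$segs)
  segs <- lapply(rev(sp$segs), function(d) rev(dom_complement(d)))
  rot_side <- function(side) {
    if (side$type == "nick") gap_nick(l = rev(side$r), r = rev(side$l))
    else gap_cont(s = rev(side$s))
  }
  gaps <- lapply(rev(sp$gaps), function(g) new_gap(u = rot_side(g$lo),
                                                  lo = rot_side(g$u)))
  lend <- list(u = rev(sp$rend$lo), lo = rev(sp$rend$u))
  rend <- list(u = rev(sp$lend$lo), lo = rev(sp$lend$u))
  new_gate(segs, gaps, lend, rend)
}

# ---- page-order flip (a pure representation transform, not a symmetry) ----
# Used so that left-acting rule mechanics can reuse the right-acting code.

flip_species <- function(sp) {
  if (is_strand(sp)) return(new_strand(rev(sp$domains)))
  flip_side <- function(side) {
    if (side$type == "nick") gap_nick(l = rev(side$r), r = rev(side$l))
    else gap_cont(s = rev(side$s))
  }
  segs <- lapply(rev(sp$segs), rev)
  gaps <- lapply(rev(sp$gaps), function(g) new_gap(u = flip_side(g$u),
                                                  lo = flip_side(g$lo)))
  lend <- list(u = rev(sp$rend$u), lo = rev(sp$rend$lo))
  rend <- list(u = rev(sp$lend$u), lo = rev(sp$lend$lo))
  new_gate(segs, gaps, lend, rend)
}

# ---- structural tidy-up ---------------------------------------------------
# Merges degenerate junctions, drops empty segments (splitting the complex if
# a junction loses both strands), and converts gates with no duplex left into
# free strands.  Returns a list of species (a gate can fall apart).

gate_tidy <- function(g) {
  if (is_strand(g)) return(list(g))
  n <- length(g$segs)
  # drop empty segments (can arise transiently inside rule application)
  keep <- vapply(g$segs, length, 1L) > 0L
  if (!all(keep)) stop("internal: empty segment reached gate_tidy")

  # merge junctions where both strands are continuous with no slack
  i <- 1L
  while (i <= length(g$gaps)) {
    gp <- g$gaps[[i]]
    if (gp$u$type == "cont" && gp$lo$type == "cont" &&
        length(gp$u$s) == 0L && length(gp$lo$s) == 0L) {
      g$segs[[i]] <- c(g$segs[[i]], g$segs[[i + 1L]])
      g$segs[[i + 1L]] <- NULL
      g$gaps[[i]] <- NULL
    } else i <- i + 1L
  }

  # split where a junction has breaks in both strands
  for (i in seq_along(g$gaps)) {
    gp <- g$gaps[[i]]
    if (gp$u$type == "nick" && gp$lo$type == "nick") {
      left <- new_gate(g$segs[seq_len(i)], g$gaps[seq_len(i - 1L)],
                       lend = g$lend,
                       rend = list(u = gp$u$l, lo = gp$lo$l))
      right <- new_gate(g$segs[seq(i + 1L, length(g$segs))],
                        if (i + 1L <= length(g$gaps))
                          g$gaps[seq(i + 1L, length(g$gaps))] else list(),
                        lend = list(u = gp$u$r, lo = gp$lo$r),
                        rend = g$rend)
      return(c(gate_tidy(left), gate_tidy(right)))
    }
  }
  list(g)
}

# ---- branch-migration normal form -----------------------------------------
# Pushes every junction maximally leftward (domains migrate from the left
# duplex to the right one) without ever completing a displacement; together
# with rotation-minimisation this gives one representative per
# branch-migration equivalence class.

upper_runs <- function(g) {
  # maximal runs of segments whose upper strand is one physical strand
  n <- length(g$segs)
  runs <- list(); cur <- 1L
  if (n == 0L) return(runs)
  for (i in seq_len(max(n - 1L, 0L))) {
    if (g$gaps[[i]]$u$type == "nick") { runs[[length(runs) + 1L]] <- cur:i; cur <- i + 1L }
  }
  runs[[length(runs) + 1L]] <- cur:n
  runs
}

lower_runs <- function(g) {
  n <- length(g$segs)
  runs <- list(); cur <- 1L
  if (n == 0L) return(runs)
  for (i in seq_len(max(n - 1L, 0L))) {
    if (g$gaps[[i]]$lo$type == "nick") { runs[[length(runs) + 1L]] <- cur:i; cur <- i + 1L }
  }
  runs[[length(runs) + 1L]] <- cur:n
  runs
}

run_of <- function(runs, j) runs[[which(vapply(runs, function(r) j %in% r, TRUE))]]

# one leftward migration move at junction j if possible; NULL otherwise
migrate_left_step <- function(g, j) {
  gp <- g$gaps[[j]]
  # case 1: upper nicked, lower continuous without slack: right upper strand
  # invades the left duplex
  if (gp$u$type == "nick" && gp$lo$type == "cont" && length(gp$lo$s) == 0L) {
    r <- gp$u$r
    dl <- g$segs[[j]]
    if (length(r) > 0L && r[length(r)] == dl[length(dl)]) {
      # refuse the move if it would strip the left upper strand's last paired
      # domain (that is a displacement, i.e. a reaction, not congruence)
      run <- run_of(upper_runs(g), j)
      paired <- sum(vapply(g$segs[run], length, 1L))
      if (paired <= 1L) return(NULL)
      d <- dl[length(dl)]
      g$segs[[j]] <- dl[-length(dl)]
      g$segs[[j + 1L]] <- c(d, g$segs[[j + 1L]])
      g$gaps[[j]]$u$l <- c(d, gp$u$l)
      g$gaps[[j]]$u$r <- r[-length(r)]
      if (length(g$segs[[j]]) == 0L) g <- absorb_empty_seg(g, j, "left")
      return(g)
    }
  }
  # case 2: lower nicked, upper continuous without slack: right lower strand
  # invades under the left duplex
  if (gp$lo$type == "nick" && gp$u$type == "cont" && length(gp$u$s) == 0L) {
    r <- gp$lo$r
    dl <- g$segs[[j]]
    want <- dom_complement(dl[length(dl)])
    if (length(r) > 0L && r[length(r)] == want) {
      run <- run_of(lower_runs(g), j)
      paired <- sum(vapply(g$segs[run], length, 1L))
      if (paired <= 1L) return(NULL)
      d <- dl[length(dl)]
      g$segs[[j]] <- dl[-length(dl)]
      g$segs[[j + 1L]] <- c(d, g$segs[[j + 1L]])
      g$gaps[[j]]$lo$l <- c(want, gp$lo$l)
      g$gaps[[j]]$lo$r <- r[-length(r)]
      if (length(g$segs[[j]]) == 0L) g <- absorb_empty_seg(g, j, "left")
      return(g)
    }
  }
  NULL
}

# remove segment j which has become empty during migration, merging its two
# neighbouring gaps; `side` says which direction the pairing drained to.
absorb_empty_seg <- function(g, j, side) {
  n <- length(g$segs)
  merge_sides <- function(a, b) {
    # a = gap side left of the empty segment, b = right of it
    if (a$type == "cont" && b$type == "cont") return(gap_cont(c(a$s, b$s)))
    if (a$type == "nick" && b$type == "cont") return(gap_nick(l = a$l, r = c(a$r, b$s)))
    if (a$type == "cont" && b$type == "nick") return(gap_nick(l = c(a$s, b$l), r = b$r))
    gap_nick(l = a$l, r = c(a$r, b$l, b$r)) # both nicked: caller splits later
  }
  if (j == 1L || j == n) stop("internal: end segment drained by migration")
  left <- g$gaps[[j - 1L]]; right <- g$gaps[[j]]
  newgap <- new_gap(u = merge_sides(left$u, right$u),
                    lo = merge_sides(left$lo, right$lo))
  g$segs[[j]] <- NULL
  g$gaps[[j]] <- NULL
  g$gaps[[j - 1L]] <- newgap
  g
}

bm_normalise <- function(g) {
  if (is_strand(g)) return(g)
  repeat {
    moved <- FALSE
    j <- 1L
    while (j <= length(g$gaps)) {
      g2 <- migrate_left_step(g, j)
      if (!is.null(g2)) { g <- g2; moved <- TRUE } else j <- j + 1L
    }
    if (!moved) break
  }
  g
}

# ---- printing -------------------------------------------------------------

fmt_seq <- function(x) paste(x, collapse = " ")

print_species <- function(sp) {
  if (is_strand(sp)) return(paste0("<", fmt_seq(sp$domains), ">"))
  n <- length(sp$segs)
  parts <- character(n)
  for (i in seq_len(n)) {
    ll <- chr0; ul <- chr0; ur <- chr0; lr <- chr0
    if (i == 1L) { ll <- sp$lend$lo; ul <- sp$lend$u }
    else {
      gp <- sp$gaps[[i - 1L]]
      if (gp$u$type == "nick") ul <- gp$u$r
      if (gp$lo$type == "nick") ll <- gp$lo$r
    }
    if (i == n) { lr <- sp$rend$lo; ur <- sp$rend$u }
    else {
      gp <- sp$gaps[[i]]
      if (gp$u$type == "nick") ur <- gp$u$l else ur <- gp$u$s
      if (gp$lo$type == "nick") lr <- gp$lo$l else lr <- gp$lo$s
    }
    s <- ""
    if (length(ll)) s <- paste0(s, "{", fmt_seq(ll), "}")
    if (length(ul)) s <- paste0(s, "<", fmt_seq(ul), ">")
    s <- paste0(s, "[", fmt_seq(sp$segs[[i]]), "]")
    if (length(ur)) s <- paste0(s, "<", fmt_seq(ur), ">")
    if (length(lr)) s <- paste0(s, "{", fmt_seq(lr), "}")
    parts[i] <- s
  }
  conns <- character(0)
  if (n > 1L) {
    conns <- vapply(sp$gaps, function(gp) {
      if (gp$lo$type == "cont") ":" else "::"
    }, "")
  }
  out <- parts[1L]
  for (i in seq_len(n - 1L)) out <- paste0(out, conns[i], parts[i + 1L])
  out
}

#' Canonicalise a DSD species
#'
#' Reduces a strand or gate to its canonical representative: branch-migration
#' normal form, with rotation collapsed by taking the lexicographically
#' smaller of the two printed orientations.  Canonicalisation is idempotent
#' and constant on rotation/branch-migration orbits; species equality in the
#' package is equality of canonical strings.
#'
#' @param sp a species structure (see [strand()] and [gate()]).
#' @return the canonical species structure, with the canonical string in
#'   attribute `"key"`.
#' @export
canonicalize <- function(sp) {
  a <- bm_normalise(sp)
  b <- bm_normalise(rotate_species(sp))
  ka <- print_species(a); kb <- print_species(b)
  if (kb < ka) { sp <- b; k <- kb } else { sp <- a; k <- ka }
  attr(sp, "key") <- k
  sp
}

species_key <- function(sp) {
  k <- attr(sp, "key")
  if (is.null(k)) k <- attr(canonicalize(sp), "key")
  k
}

#' Construct a free signal strand
#'
#' @param ... domain names in page (5' to 3') order, e.g. `strand("t^", "x")`.
#' @return canonical species.
#' @export
strand <- function(...) canonicalize(new_strand(c(...)))

#' Construct a gate from segment descriptions
#'
#' `segments` is a list; each element is a list with fields `ll`, `ul`, `d`,
#' `ur`, `lr` (character vectors of domains; `d` mandatory), matching the
#' textual form `{ll}<ul>[d]<ur>{lr}`.  `conn` gives the connectors between
#' consecutive segments: `":"` shares the lower strand, `"::"` the upper.
#'
#' @param segments list of segment descriptions.
#' @param conn character vector of connectors, length `length(segments) - 1`.
#' @return canonical species.
#' @export
gate <- function(segments, conn = rep(":", length(segments) - 1L)) {
  n <- length(segments)
  stopifnot(n >= 1L, length(conn) == n - 1L)
  seg_field <- function(s, f) if (is.null(s[[f]])) chr0 else as.character(s[[f]])
  segs <- lapply(segments, function(s) as.character(s$d))
  gaps <- vector("list", max(n - 1L, 0L))
  for (i in seq_len(n - 1L)) {
    a <- segments[[i]]; b <- segments[[i + 1L]]
    if (conn[i] == ":") {
      gaps[[i]] <- new_gap(
        u = gap_nick(l = seg_field(a, "ur"), r = seg_field(b, "ul")),
        lo = gap_cont(s = c(seg_field(a, "lr"), seg_field(b, "ll"))))
    } else {
      gaps[[i]] <- new_gap(
        u = gap_cont(s = c(seg_field(a, "ur"), seg_field(b, "ul"))),
        lo = gap_nick(l = seg_field(a, "lr"), r = seg_field(b, "ll")))
    }
  }
  lend <- list(u = seg_field(segments[[1L]], "ul"),
               lo = seg_field(segments[[1L]], "ll"))
  rend <- list(u = seg_field(segments[[n]], "ur"),
               lo = seg_field(segments[[n]], "lr"))
  canonicalize(new_gate(segs, gaps, lend, rend))
}

#' @export
format.dsd_species <- function(x, ...) print_species(x)

#' @export
print.dsd_species <- function(x, ...) {
  cat(print_species(x), "\n")
  invisible(x)
}
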