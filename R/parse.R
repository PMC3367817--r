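# Parser for the textual DSD dialect and system-level operations.
#
# Dialect (ASCII rendering of the standard DSD syntax):
#   <t^ x>                       upper strand
#   {x t^}                       lower strand
#   {t^*}[x t^]:[a t^]<y>{u^*}   gate; ":" joins along the lower strand,
#                                "::" along the upper strand
#   D1 | D2                      parallel composition
#   3 * SPECIES                  population count
#   constant 10 * SPECIES        population held constant
#   new c ( D )                  domain restriction (alpha-renamed fresh on
#                                module expansion)
#   def T(N, x, y) = D           module definition (non-recursive)
#   T(2, x0, x1)                 module instantiation
#
# Comments run from "//" to end of line.

# ---- tokenizer ------------------------------------------------------------

dsd_tokenize <- function(text) {
  text <- gsub("//[^\n]*", "", text)
  pat <- paste0(
    "(::|[|:()=,*]|\\[|\\]|<|>|\\{|\\}|",
    "[A-Za-z_][A-Za-z0-9_.']*(\\^\\*|\\^|\\*)?|[0-9]+)")
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  toks <- character(0); tline <- integer(0); tcol <- integer(0)
  for (ln in seq_along(lines)) {
    s <- lines[[ln]]; pos <- 1L
    while (pos <= nchar(s)) {
      rest <- substring(s, pos)
      ws <- regmatches(rest, regexpr("^[ \t\r]+", rest))
      if (length(ws) == 1L) { pos <- pos + nchar(ws); next }
      m <- regmatches(rest, regexpr(paste0("^", pat), rest))
      if (length(m) == 0L)
        stop(sprintf("DSD syntax error at line %d, column %d: unexpected '%s'",
                     ln, pos, substring(rest, 1L, 1L)), call. = FALSE)
      toks <- c(toks, m); tline <- c(tline, ln); tcol <- c(tcol, pos)
      pos <- pos + nchar(m)
    }
  }
  list(toks = toks, line = tline, col = tcol, i = 1L)
}

tk_peek <- function(st) if (st$i <= length(st$toks)) st$toks[[st$i]] else ""

tk_error <- function(st, msg) {
  if (st$i <= length(st$toks))
    stop(sprintf("DSD syntax error at line %d, column %d: %s (near '%s')",
                 st$line[st$i], st$col[st$i], msg, st$toks[st$i]), call. = FALSE)
  stop(sprintf("DSD syntax error at end of input: %s", msg), call. = FALSE)
}

tk_take <- function(st, what = NULL) {
  if (st$i > length(st$toks)) tk_error(st, paste("expected", what))
  t <- st$toks[[st$i]]
  if (!is.null(what) && t != what) tk_error(st, paste("expected", what))
  st$i <- st$i + 1L
  assign("st", st, envir = parent.frame())
  t
}

is_ident <- function(t) grepl("^[A-Za-z_][A-Za-z0-9_.']*(\\^\\*|\\^|\\*)?$", t)
is_int <- function(t) grepl("^[0-9]+$", t)

# ---- grammar --------------------------------------------------------------
# AST nodes: list(node = "par"|"count"|"constant"|"new"|"species"|"call", ...)

parse_domain_seq <- function(st, closer) {
  doms <- character(0)
  while (tk_peek(st) != closer) {
    t <- tk_peek(st)
    if (!is_ident(t)) tk_error(st, "expected a domain name")
    doms <- c(doms, tk_take(st))
  }
  assign("st", st, envir = parent.frame())
  doms
}

parse_species_tok <- function(st) {
  t <- tk_peek(st)
  if (t == "<") {
    # lookahead: "<...>" followed by "[" or "{" is a gate's leading overhang
    j <- st$i + 1L
    while (j <= length(st$toks) && st$toks[[j]] != ">") j <- j + 1L
    nxt <- if (j + 1L <= length(st$toks)) st$toks[[j + 1L]] else ""
    if (!nxt %in% c("[", "{")) {
      tk_take(st, "<"); doms <- parse_domain_seq(st, ">"); tk_take(st, ">")
      if (length(doms) == 0L) tk_error(st, "empty strand")
      assign("st", st, envir = parent.frame())
      return(list(node = "species", value = canonicalize(new_strand(doms))))
    }
  }
  if (t == "<" || t == "{" || t == "[") {
    segs <- list(); conns <- character(0)
    repeat {
      seg <- list(ll = chr0, ul = chr0, d = NULL, ur = chr0, lr = chr0)
      if (tk_peek(st) == "{") { tk_take(st, "{"); seg$ll <- parse_domain_seq(st, "}"); tk_take(st, "}") }
      if (tk_peek(st) == "<") { tk_take(st, "<"); seg$ul <- parse_domain_seq(st, ">"); tk_take(st, ">") }
      if (tk_peek(st) == "[") { tk_take(st, "["); seg$d <- parse_domain_seq(st, "]"); tk_take(st, "]") }
      else if (length(segs) == 0L && length(seg$ul) == 0L && length(seg$ll) > 0L &&
               tk_peek(st) != "[") {
        # "{S}" alone: a free lower strand (rotation of an upper strand)
        assign("st", st, envir = parent.frame())
        return(list(node = "species",
                    value = canonicalize(new_strand(rev(seg$ll)))))
      } else tk_error(st, "expected '[' duplex")
      if (length(seg$d) == 0L) tk_error(st, "empty duplex")
      if (tk_peek(st) == "<") { tk_take(st, "<"); seg$ur <- parse_domain_seq(st, ">"); tk_take(st, ">") }
      if (tk_peek(st) == "{") { tk_take(st, "{"); seg$lr <- parse_domain_seq(st, "}"); tk_take(st, "}") }
      segs[[length(segs) + 1L]] <- seg
      if (tk_peek(st) %in% c(":", "::")) conns <- c(conns, tk_take(st)) else break
    }
    assign("st", st, envir = parent.frame())
    return(list(node = "species", value = gate(segs, conns)))
  }
  tk_error(st, "expected a species")
}

parse_term <- function(st, defs) {
  t <- tk_peek(st)
  if (t == "new") {
    tk_take(st, "new")
    nm <- tk_take(st)
    if (!is_ident(nm)) tk_error(st, "expected a domain name after 'new'")
    body <- parse_term(st, defs)
    assign("st", st, envir = parent.frame())
    return(list(node = "new", name = nm, body = body))
  }
  if (t == "constant") {
    tk_take(st, "constant")
    body <- parse_term(st, defs)
    assign("st", st, envir = parent.frame())
    return(list(node = "constant", body = body))
  }
  if (t == "(") {
    tk_take(st, "(")
    e <- parse_expr(st, defs)
    tk_take(st, ")")
    assign("st", st, envir = parent.frame())
    return(e)
  }
  if (is_int(t)) {
    n <- as.integer(tk_take(st))
    tk_take(st, "*")
    body <- parse_term(st, defs)
    assign("st", st, envir = parent.frame())
    return(list(node = "count", n = n, body = body))
  }
  if (is_ident(t) && st$i < length(st$toks) && st$toks[[st$i + 1L]] == "*" &&
      !grepl("\\*$", t)) {
    # count given by a module parameter: N * SPECIES
    nm <- tk_take(st)
    tk_take(st, "*")
    body <- parse_term(st, defs)
    assign("st", st, envir = parent.frame())
    return(list(node = "count", n = nm, body = body))
  }
  if (is_ident(t) && st$i < length(st$toks) && st$toks[[st$i + 1L]] == "(") {
    nm <- tk_take(st)
    tk_take(st, "(")
    args <- list()
    if (tk_peek(st) != ")") {
      repeat {
        a <- tk_peek(st)
        if (is_int(a)) args[[length(args) + 1L]] <- as.integer(tk_take(st))
        else if (is_ident(a)) args[[length(args) + 1L]] <- tk_take(st)
        else tk_error(st, "expected argument")
        if (tk_peek(st) == ",") tk_take(st, ",") else break
      }
    }
    tk_take(st, ")")
    assign("st", st, envir = parent.frame())
    return(list(node = "call", name = nm, args = args))
  }
  sp <- parse_species_tok(st)
  assign("st", st, envir = parent.frame())
  sp
}

parse_expr <- function(st, defs) {
  terms <- list(parse_term(st, defs))
  while (tk_peek(st) == "|") {
    tk_take(st, "|")
    terms[[length(terms) + 1L]] <- parse_term(st, defs)
  }
  assign("st", st, envir = parent.frame())
  if (length(terms) == 1L) terms[[1L]] else list(node = "par", terms = terms)
}

#' Parse a DSD program into a system specification
#'
#' @param text DSD source text (see the package vignette for the dialect).
#' @return an object of class `dsd_system`: a list with `species_counts`
#'   (named integer vector keyed by canonical species string), `constant`
#'   (character vector of constant species), `new_domains` (bound domain
#'   names), `module_defs`, and `registry` (environment mapping canonical
#'   strings to species structures).
#' @export
parse_system <- function(text) {
  st <- dsd_tokenize(text)
  defs <- list()
  while (tk_peek(st) == "def") {
    tk_take(st, "def")
    nm <- tk_take(st)
    if (!is_ident(nm)) tk_error(st, "expected module name")
    tk_take(st, "(")
    params <- character(0)
    if (tk_peek(st) != ")") {
      repeat {
        params <- c(params, tk_take(st))
        if (tk_peek(st) == ",") tk_take(st, ",") else break
      }
    }
    tk_take(st, ")")
    tk_take(st, "=")
    body <- parse_expr(st, defs)
    defs[[nm]] <- list(params = params, body = body)
  }
  ast <- if (st$i > length(st$toks)) list(node = "par", terms = list())
         else parse_expr(st, defs)
  if (st$i <= length(st$toks)) tk_error(st, "trailing input")
  check_no_recursion(defs)
  sys <- list(ast = ast, module_defs = defs)
  class(sys) <- "dsd_system_ast"
  expand_modules(sys)
}

check_no_recursion <- function(defs) {
  calls_in <- function(node) {
    if (node$node == "call") return(c(node$name, unlist(lapply(
      Filter(function(a) FALSE, node$args), calls_in))))
    if (node$node == "par") return(unlist(lapply(node$terms, calls_in)))
    if (node$node %in% c("new", "constant", "count")) return(calls_in(node$body))
    character(0)
  }
  seen <- new.env()
  visit <- function(nm, stack) {
    if (nm %in% stack)
      stop(sprintf("recursive module definition: %s", nm), call. = FALSE)
    if (is.null(defs[[nm]])) return(invisible())
    for (cal in calls_in(defs[[nm]]$body)) visit(cal, c(stack, nm))
  }
  for (nm in names(defs)) visit(nm, character(0))
}

# ---- module expansion -----------------------------------------------------

# substitute domain names (base-name level) in a species structure
subst_species <- function(sp, map) {
  ren <- function(v) {
    if (length(v) == 0L) return(v)
    base <- sub("(\\^\\*|\\^|\\*)$", "", v)
    suff <- substring(v, nchar(base) + 1L)
    hit <- base %in% names(map)
    base[hit] <- unlist(map[base[hit]])
    paste0(base, suff)
  }
  if (is_strand(sp)) return(new_strand(ren(sp$domains)))
  sp$segs <- lapply(sp$segs, ren)
  sp$gaps <- lapply(sp$gaps, function(g) {
    fix <- function(side) {
      if (side$type == "nick") gap_nick(ren(side$l), ren(side$r))
      else gap_cont(ren(side$s))
    }
    new_gap(u = fix(g$u), lo = fix(g$lo))
  })
  sp$lend <- list(u = ren(sp$lend$u), lo = ren(sp$lend$lo))
  sp$rend <- list(u = ren(sp$rend$u), lo = ren(sp$rend$lo))
  attr(sp, "key") <- NULL
  sp
}

#' Expand module instantiations and `new` binders
#'
#' Every `new`-bound domain is alpha-renamed to a globally fresh name
#' (`base.k`, `k` counting binder instances in expansion order), so two
#' instantiations of a module never share a private domain while free domains
#' remain shared.  Idempotent on module-free systems.
#'
#' @param sys a parsed system (internal AST form) or an expanded `dsd_system`.
#' @return an expanded `dsd_system`.
#' @export
expand_modules <- function(sys) {
  if (inherits(sys, "dsd_system")) return(sys)
  defs <- sys$module_defs
  counter <- new.env(); counter$k <- 0L
  counts <- new.env(); consts <- new.env(); newdoms <- character(0)
  registry <- new.env(parent = emptyenv())

  add_species <- function(sp, n, const) {
    sp <- canonicalize(sp)
    k <- species_key(sp)
    if (is.null(registry[[k]])) registry[[k]] <- sp
    prev <- if (is.null(counts[[k]])) 0L else counts[[k]]
    counts[[k]] <- prev + n
    if (const) consts[[k]] <- TRUE
  }

  walk <- function(node, map, mult, const) {
    switch(node$node,
      par = for (t in node$terms) walk(t, map, mult, const),
      count = {
        if (is.character(node$n))
          stop(sprintf("count parameter %s not bound to an integer", node$n),
               call. = FALSE)
        walk(node$body, map, mult * node$n, const)
      },
      constant = walk(node$body, map, mult, TRUE),
      new = {
        counter$k <- counter$k + 1L
        fresh <- paste0(resolve_name(node$name, map), ".", counter$k)
        newdoms <<- c(newdoms, fresh)
        map2 <- map; map2[[node$name]] <- fresh
        walk(node$body, map2, mult, const)
      },
      species = add_species(subst_species(node$value, map), mult, const),
      call = {
        def <- defs[[node$name]]
        if (is.null(def))
          stop(sprintf("unknown module name: %s", node$name), call. = FALSE)
        if (length(node$args) != length(def$params))
          stop(sprintf("module %s expects %d argument(s), got %d",
                       node$name, length(def$params), length(node$args)),
               call. = FALSE)
        map2 <- list(); mult2 <- mult
        for (i in seq_along(def$params)) {
          a <- node$args[[i]]
          if (is.character(a)) a <- resolve_name(a, map)
          map2[[def$params[i]]] <- a
        }
        # integer arguments can only be used as counts inside the body
        walk_subst_ints(def$body, map2, mult, const)
      },
      stop("internal: unknown AST node"))
  }

  resolve_name <- function(nm, map) {
    if (nm %in% names(map)) {
      v <- map[[nm]]
      if (is.character(v)) return(v)
    }
    nm
  }

  walk_subst_ints <- function(node, map, mult, const) {
    # like walk, but "count" nodes whose body mentions an integer-valued
    # parameter are resolved: the parser stores `N * sp` with N literal or a
    # parameter name resolved here
    if (node$node == "count" && is.character(node$n)) {
      v <- map[[node$n]]
      if (is.null(v) || !is.numeric(v))
        stop(sprintf("count parameter %s not bound to an integer", node$n),
             call. = FALSE)
      node$n <- as.integer(v)
    }
    dommap <- Filter(is.character, map)
    switch(node$node,
      par = for (t in node$terms) walk_subst_ints(t, map, mult, const),
      count = {
        n <- node$n
        if (is.character(n)) {
          v <- map[[n]]; n <- as.integer(v)
        }
        walk_subst_ints(node$body, map, mult * n, const)
      },
      constant = walk_subst_ints(node$body, map, mult, TRUE),
      new = {
        counter$k <- counter$k + 1L
        fresh <- paste0(node$name, ".", counter$k)
        newdoms <<- c(newdoms, fresh)
        map2 <- map; map2[[node$name]] <- fresh
        walk_subst_ints(node$body, map2, mult, const)
      },
      species = add_species(subst_species(node$value, dommap), mult, const),
      call = {
        def <- defs[[node$name]]
        if (is.null(def))
          stop(sprintf("unknown module name: %s", node$name), call. = FALSE)
        if (length(node$args) != length(def$params))
          stop(sprintf("module %s expects %d argument(s), got %d",
                       node$name, length(def$params), length(node$args)),
               call. = FALSE)
        map2 <- list()
        for (i in seq_along(def$params)) {
          a <- node$args[[i]]
          if (is.character(a) && a %in% names(map)) a <- map[[a]]
          map2[[def$params[i]]] <- a
        }
        walk_subst_ints(def$body, map2, mult, const)
      },
      stop("internal: unknown AST node"))
  }

  walk(sys$ast, list(), 1L, FALSE)

  keys <- sort(ls(counts))
  sc <- vapply(keys, function(k) counts[[k]], 1L)
  sys_out <- list(
    species_counts = sc,
    constant = sort(ls(consts)),
    new_domains = newdoms,
    module_defs = defs,
    registry = registry)
  class(sys_out) <- "dsd_system"
  sys_out
}

# ---- programmatic system construction (used by the gate library) ----------

#' Build a system specification directly from species
#'
#' @param species list of canonical species (from [strand()] / [gate()]).
#' @param counts integer vector of initial counts, recycled.
#' @param constant logical vector, which entries are held constant.
#' @param new_domains character vector of private domain names (bookkeeping).
#' @return a `dsd_system`.
#' @export
make_system <- function(species, counts = 1L,
                        constant = FALSE, new_domains = character(0)) {
  counts <- rep_len(as.integer(counts), length(species))
  constant <- rep_len(constant, length(species))
  registry <- new.env(parent = emptyenv())
  acc <- new.env(); consts <- new.env()
  for (i in seq_along(species)) {
    sp <- canonicalize(species[[i]])
    k <- species_key(sp)
    if (is.null(registry[[k]])) registry[[k]] <- sp
    prev <- if (is.null(acc[[k]])) 0L else acc[[k]]
    acc[[k]] <- prev + counts[i]
    if (constant[i]) consts[[k]] <- TRUE
  }
  keys <- sort(ls(acc))
  out <- list(species_counts = vapply(keys, function(k) acc[[k]], 1L),
              constant = sort(ls(consts)),
              new_domains = new_domains,
              module_defs = list(),
              registry = registry)
  class(out) <- "dsd_system"
  out
}

#' Merge systems (parallel composition)
#' @param ... `dsd_system` objects.
#' @return the combined `dsd_system`.
#' @export
sys_par <- function(...) {
  parts <- list(...)
  registry <- new.env(parent = emptyenv())
  acc <- new.env(); consts <- new.env(); nd <- character(0)
  for (p in parts) {
    for (k in names(p$species_counts)) {
      if (is.null(registry[[k]])) registry[[k]] <- p$registry[[k]]
      prev <- if (is.null(acc[[k]])) 0L else acc[[k]]
      acc[[k]] <- prev + p$species_counts[[k]]
    }
    for (k in p$constant) consts[[k]] <- TRUE
    nd <- c(nd, p$new_domains)
  }
  keys <- sort(ls(acc))
  out <- list(species_counts = vapply(keys, function(k) acc[[k]], 1L),
              constant = sort(ls(consts)),
              new_domains = nd,
              module_defs = list(),
              registry = registry)
  class(out) <- "dsd_system"
  out
}

#' Pretty-print a system back to DSD source
#' @param sys a `dsd_system`.
#' @return a single string in the package's DSD dialect.
#' @export
print_system <- function(sys) {
  ks <- names(sys$species_counts)
  parts <- vapply(ks, function(k) {
    n <- sys$species_counts[[k]]
    s <- if (n == 1L) k else paste0(n, " * ", k)
    if (k %in% sys$constant) s <- paste("constant", s)
    s
  }, "")
  paste(parts, collapse = " | ")
}

# ---- well-formedness ------------------------------------------------------

unbound_domains <- function(sp) {
  if (is_strand(sp)) return(sp$domains)
  out <- c(sp$lend$u, sp$lend$lo, sp$rend$u, sp$rend$lo)
  for (g in sp$gaps) {
    for (side in list(g$u, g$lo)) {
      out <- c(out, if (side$type == "nick") c(side$l, side$r) else side$s)
    }
  }
  out
}

#' Check the two-domain well-formedness restriction
#'
#' A system is well formed when no long domain and its complement are
#' simultaneously unbound anywhere: species may then only interact through
#' complementary toeholds.
#'
#' @param sys a `dsd_system`.
#' @return character vector of violations (empty when well formed).
#' @export
check_well_formed <- function(sys) {
  ks <- names(sys$species_counts)
  per <- lapply(ks, function(k) unique(unbound_domains(sys$registry[[k]])))
  all_unbound <- unique(unlist(per))
  longs <- all_unbound[!dom_is_toehold(all_unbound)]
  bad <- longs[dom_complement(longs) %in% all_unbound]
  bad <- unique(dom_base(bad))
  vapply(sort(bad), function(b) {
    sprintf("long domain '%s' and its complement are both unbound", b)
  }, "")
}
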