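# Verification engine: deadlock/CTL checks, reachability probabilities
# (unbounded and time-bounded), expected rewards and absorption
# distributions over the population CTMC.

#' @importFrom Matrix sparseMatrix rowSums t solve Diagonal colSums
NULL

qresult <- function(value, witness = NULL, per_state = NULL, diag = NULL) {
  structure(list(value = value, witness = witness, per_state = per_state,
                 diagnostics = diag), class = "dsd_query_result")
}

#' @export
print.dsd_query_result <- function(x, ...) {
  cat("query result:", format(x$value), "\n")
  if (!is.null(x$witness))
    cat("witness path through", length(x$witness), "states\n")
  invisible(x)
}

as_pred <- function(m, pred, labels = NULL) {
  # pred: logical vector over states, or function(labels) -> logical
  if (is.function(pred)) {
    if (is.null(labels)) stop("predicate needs labels; pass labels=")
    v <- pred(labels)
  } else v <- pred
  stopifnot(is.logical(v), length(v) == nrow(m$states))
  v
}

#' Deadlock states of a model
#' @param m a `dsd_ctmc`.
#' @return integer vector of state indices with no outgoing transition.
#' @export
find_deadlocks <- function(m) which(m$exit == 0)

# shortest path (BFS) from init to any state in `targets`; NULL if none
bfs_path <- function(m, targets) {
  n <- nrow(m$states)
  if (!length(targets)) return(NULL)
  is_t <- logical(n); is_t[targets] <- TRUE
  pred <- integer(n); seen <- logical(n)
  adj_from <- split(m$trans$to, factor(m$trans$from, levels = seq_len(n)))
  queue <- integer(n); queue[1L] <- m$init; head <- 1L; tail <- 1L
  seen[m$init] <- TRUE
  while (head <= tail) {
    s <- queue[head]; head <- head + 1L
    if (is_t[s]) {
      path <- s
      while (s != m$init) { s <- pred[s]; path <- c(s, path) }
      return(path)
    }
    for (t in adj_from[[s]]) {
      if (!seen[t]) {
        seen[t] <- TRUE; pred[t] <- s
        tail <- tail + 1L; queue[tail] <- t
      }
    }
  }
  NULL
}

#' Check that every reachable deadlock satisfies a predicate
#'
#' CTL `A[G](deadlock => pred)`.  On failure the witness is a shortest path
#' from the initial state to a violating deadlock.
#'
#' @param m a `dsd_ctmc`.
#' @param pred logical vector over states or function of the label frame.
#' @param labels labels from [make_labels()] if `pred` is a function.
#' @return a query result with logical `value` and optional `witness`
#'   (vector of state indices).
#' @export
check_deadlock_invariant <- function(m, pred, labels = NULL) {
  p <- as_pred(m, pred, labels)
  bad <- setdiff(find_deadlocks(m), which(p))
  if (!length(bad)) return(qresult(TRUE))
  qresult(FALSE, witness = bfs_path(m, bad))
}

#' Check reachability of a predicate
#'
#' CTL `E[F pred]`; all states of the model are reachable by construction.
#'
#' @inheritParams check_deadlock_invariant
#' @return query result with logical `value` and a witness path when true.
#' @export
check_reachable <- function(m, pred, labels = NULL) {
  p <- as_pred(m, pred, labels)
  if (!any(p)) return(qresult(FALSE))
  qresult(TRUE, witness = bfs_path(m, which(p)))
}

# embedded jump probabilities as a sparse matrix restricted to rows `rows`
embedded_P <- function(m) {
  n <- nrow(m$states)
  rt <- m$trans$rate / m$exit[m$trans$from]
  Matrix::sparseMatrix(i = m$trans$from, j = m$trans$to, x = rt,
                       dims = c(n, n))
}

# states that cannot reach the target set (prob-0 states), by backward BFS
prob0_states <- function(m, target) {
  n <- nrow(m$states)
  can <- logical(n); can[target] <- TRUE
  adj_to <- split(m$trans$from, factor(m$trans$to, levels = seq_len(n)))
  queue <- integer(n); nt <- length(target)
  queue[seq_len(nt)] <- target; head <- 1L; tail <- nt
  while (head <= tail) {
    s <- queue[head]; head <- head + 1L
    for (f in adj_to[[s]]) {
      if (!can[f]) {
        can[f] <- TRUE
        tail <- tail + 1L; queue[tail] <- f
      }
    }
  }
  which(!can)
}

# solve x = P x + b on the given state subset with x known elsewhere
reach_solve <- function(m, target, value_in_target = 1) {
  n <- nrow(m$states)
  x <- numeric(n)
  x[target] <- value_in_target
  z <- prob0_states(m, target)
  rest <- setdiff(seq_len(n), union(target, z))
  if (length(rest)) {
    P <- embedded_P(m)
    A <- Matrix::Diagonal(length(rest)) - P[rest, rest, drop = FALSE]
    b <- P[rest, target, drop = FALSE] %*% x[target]
    x[rest] <- as.numeric(Matrix::solve(A, b))
  }
  x
}

#' Probability of eventually reaching a predicate
#'
#' Unbounded reachability on the embedded jump chain: prob-0 states are
#' removed by graph analysis and the remaining linear system is solved by a
#' sparse direct factorisation.
#'
#' @inheritParams check_deadlock_invariant
#' @return query result with the probability from the initial state and the
#'   full per-state vector in `per_state`.
#' @export
prob_reach <- function(m, pred, labels = NULL) {
  p <- as_pred(m, pred, labels)
  target <- which(p)
  if (!length(target)) return(qresult(0))
  x <- reach_solve(m, target)
  qresult(unname(x[m$init]), per_state = x)
}

#' Probability of reaching a predicate within a time bound
#'
#' Transient analysis by uniformisation: target states are made absorbing,
#' the chain is subordinated to a Poisson process of rate
#' `1.02 * max(exit rate)` and the Poisson sum is truncated so the neglected
#' tail is below `eps`.
#'
#' @inheritParams check_deadlock_invariant
#' @param time nonnegative time bound (seconds).
#' @param eps truncation error bound.
#' @return query result with the probability from the initial state.
#' @export
prob_reach_within <- function(m, pred, time, labels = NULL, eps = 1e-9) {
  stopifnot(time >= 0)
  p <- as_pred(m, pred, labels)
  target <- which(p)
  if (!length(target)) return(qresult(0))
  if (p[m$init] || time == 0)
    return(qresult(as.numeric(p[m$init])))
  n <- nrow(m$states)
  keep <- !(m$trans$from %in% target)
  tr <- m$trans[keep, , drop = FALSE]
  exit <- numeric(n)
  if (nrow(tr)) {
    ex <- rowsum(tr$rate, tr$from, reorder = FALSE)
    exit[as.integer(rownames(ex))] <- as.numeric(ex)
  }
  q <- 1.02 * max(exit, 1e-300)
  # uniformised one-jump matrix (targets absorbing)
  P <- Matrix::sparseMatrix(i = tr$from, j = tr$to, x = tr$rate / q,
                            dims = c(n, n))
  diag_stay <- 1 - exit / q
  lambda <- q * time
  kmax <- max(10L, stats::qpois(1 - eps, lambda) + 10L)
  # Poisson weights by recurrence (stable in log space)
  lw <- stats::dpois(0:kmax, lambda, log = TRUE)
  w <- exp(lw)
  v <- numeric(n); v[m$init] <- 1
  acc <- w[1L] * sum(v[target])
  for (k in seq_len(kmax)) {
    v <- as.numeric(Matrix::t(P) %*% v) + diag_stay * v
    acc <- acc + w[k + 1L] * sum(v[target])
  }
  qresult(acc, diag = list(q = q, kmax = kmax))
}

#' Expected time until a predicate first holds
#'
#' Expected accumulated time-reward before hitting the target; defined (and
#' finite) when the target is reached with probability 1, otherwise reported
#' as infinite.
#'
#' @inheritParams check_deadlock_invariant
#' @param tol tolerance on the almost-sure-reachability precondition.
#' @return query result with the expectation from the initial state.
#' @export
expected_time_to <- function(m, pred, labels = NULL, tol = 1e-6) {
  p <- as_pred(m, pred, labels)
  target <- which(p)
  pr <- prob_reach(m, p)
  if (abs(pr$value - 1) > tol)
    return(qresult(Inf, diag = list(prob_reach = pr$value)))
  n <- nrow(m$states)
  rest <- setdiff(seq_len(n), target)
  # restrict to states that are reached before the target with positive
  # probability from init (others do not matter but must not make the
  # system singular: prob-0-of-target states are excluded by pr == 1)
  x <- numeric(n)
  if (length(rest)) {
    P <- embedded_P(m)
    A <- Matrix::Diagonal(length(rest)) - P[rest, rest, drop = FALSE]
    b <- 1 / m$exit[rest]
    x[rest] <- as.numeric(Matrix::solve(A, b))
  }
  qresult(unname(x[m$init]), per_state = x)
}

#' Absorption distribution over deadlock states
#'
#' Requires every bottom strongly-connected component to be a single
#' deadlock state (true for the transducer and catalyst case studies).
#' Returns the probability of ending in each deadlock and, optionally, the
#' expectation of a function of the final state.
#'
#' @param m a `dsd_ctmc`.
#' @param f optional numeric vector over states (e.g. a label column).
#' @return query result: `value` is the expectation of `f` (or NA), with
#'   `per_state` the named absorption probabilities keyed by deadlock index.
#' @export
absorption_distribution <- function(m, f = NULL) {
  dl <- find_deadlocks(m)
  if (!length(dl)) stop("no deadlock states: absorption undefined")
  # non-deadlock recurrent class check: every state must reach a deadlock
  no_reach <- prob0_states(m, dl)
  if (length(no_reach))
    stop("non-deadlock recurrent class detected: absorption undefined")
  n <- nrow(m$states)
  rest <- setdiff(seq_len(n), dl)
  if (m$init %in% dl) {
    probs <- as.numeric(dl == m$init)
  } else {
    # one sparse factorisation, one right-hand side per deadlock
    P <- embedded_P(m)
    A <- Matrix::Diagonal(length(rest)) - P[rest, rest, drop = FALSE]
    B <- P[rest, dl, drop = FALSE]
    X <- Matrix::solve(A, B)
    probs <- as.numeric(X[match(m$init, rest), ])
  }
  names(probs) <- dl
  tot <- sum(probs)
  if (abs(tot - 1) > 1e-6)
    warning(sprintf("absorption probabilities sum to %.8f", tot))
  val <- if (is.null(f)) NA_real_ else sum(probs * f[dl])
  qresult(val, per_state = probs)
}
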