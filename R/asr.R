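# Ancestral reconstruction.
#
# Continuous traits: maximum-likelihood reconstruction under Brownian
# motion. The joint ML node states solve the weighted tree-Laplacian
# system (edge weights 1/branch length, tips clamped to their values);
# because the conditional distribution is Gaussian, the joint mode
# equals the per-node marginal GLS estimates, i.e. the familiar
# re-rooting estimator, and the root solves (1'C^-1 1)^-1 1'C^-1 x.
#
# Discrete locomotion: equal-rates (ER) continuous-time Markov model,
# fitted by the pruning algorithm with a uniform root prior, then
# stochastic character maps sampled conditional on the tips: node
# states from the conditional joint distribution (root down), edge
# histories by rejection sampling with a uniformization fallback.

#' Maximum-likelihood ancestral states for a continuous trait
#'
#' @param tree A `phylo`.
#' @param trait Named numeric vector covering every tip (prune first if
#'   some species lack the measurement).
#' @return A numeric vector of reconstructed values for internal nodes,
#'   named by ape node id (n+1 ... n+m, root first).
#' @export
asr_continuous <- function(tree, trait) {
  validate_phylogeny(tree)
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  miss <- setdiff(tree$tip.label, names(trait))
  if (length(miss)) {
    stop("missing trait values for tips: ", paste(miss, collapse = ", "),
         "; prune the tree first", call. = FALSE)
  }
  x <- as.numeric(trait[tree$tip.label])
  edge <- tree$edge
  w <- 1 / pmax(tree$edge.length, 1e-12)
  # weighted Laplacian system over internal nodes (ids n+1 .. n+m)
  A <- matrix(0, m, m)
  b <- numeric(m)
  for (e in seq_len(nrow(edge))) {
    u <- edge[e, 1]; v <- edge[e, 2]
    iu <- u - n
    A[iu, iu] <- A[iu, iu] + w[e]
    if (v > n) {
      iv <- v - n
      A[iv, iv] <- A[iv, iv] + w[e]
      A[iu, iv] <- A[iu, iv] - w[e]
      A[iv, iu] <- A[iv, iu] - w[e]
    } else {
      b[iu] <- b[iu] + w[e] * x[v]
    }
  }
  est <- solve(A, b)
  stats::setNames(est, as.character(n + seq_len(m)))
}

# ER transition probability matrix: P_ii = 1/k + (k-1)/k e^{-kqt},
# P_ij = 1/k (1 - e^{-kqt}).
er_pmatrix <- function(q, t, k) {
  e <- exp(-k * q * t)
  P <- matrix((1 - e) / k, k, k)
  diag(P) <- (1 + (k - 1) * e) / k
  P
}

# pruning pass: per-node conditional likelihood partials, scaled.
# Returns list(partials = (n+m) x k matrix, loglik, scale)
mk_er_partials <- function(tree, state_idx, q, k) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  partial <- matrix(0, n + m, k)
  partial[cbind(seq_len(n), state_idx)] <- 1
  logscale <- 0
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  len <- po$edge.length
  # message from child v to parent u: P(t) %*% partial[v, ]
  msg <- matrix(1, n + m, k)  # accumulated products at internal nodes
  child_msg <- matrix(NA_real_, nrow(edge), k)
  for (e in seq_len(nrow(edge))) {
    v <- edge[e, 2]
    P <- er_pmatrix(q, len[e], k)
    child_msg[e, ] <- as.numeric(P %*% partial[v, ])
    u <- edge[e, 1]
    msg[u, ] <- msg[u, ] * child_msg[e, ]
    # when all children of u are processed (postorder guarantees the
    # last edge into u comes after all edges below), finalize lazily:
    partial[u, ] <- msg[u, ]
  }
  # rescale only at the end per node is fine for small trees; guard
  # against underflow by rescaling the root if needed
  root <- n + 1L
  s <- sum(partial[root, ])
  if (s <= 0 || !is.finite(s)) {
    stop("numerical underflow in pruning likelihood", call. = FALSE)
  }
  loglik <- log(mean(partial[root, ]))  # uniform root prior
  list(partials = partial, loglik = loglik, child_msg = child_msg,
       edge = edge, len = len)
}

#' Fit the equal-rates Mk model to tip states
#'
#' Off-diagonal entries of Q all equal q (diagonal -(k-1) q); the
#' likelihood is computed by the pruning algorithm with a uniform root
#' prior and maximized over q by Brent optimization.
#'
#' @param tree A `phylo`.
#' @param states Named factor/character vector of tip states.
#' @param q_bounds Search interval for q (per Myr); default lower bound
#'   1e-8, upper 100 / tree height.
#' @return A list of class `mk_er_fit`: `q`, `logLik`, `k`, `states`
#'   (level order), `Q`, `partials` (conditional likelihoods per node).
#' @export
mk_er_fit <- function(tree, states, q_bounds = NULL) {
  validate_phylogeny(tree)
  states <- states[tree$tip.label]
  if (anyNA(states)) stop("missing states for some tips", call. = FALSE)
  f <- factor(as.character(states))
  levs <- levels(f)
  k <- length(levs)
  idx <- as.integer(f)
  height <- max(node_heights(tree))
  if (is.null(q_bounds)) q_bounds <- c(1e-8, 100 / height)
  if (k < 2) {
    warning("single observed state; q fixed at the lower bound")
    q_hat <- q_bounds[1]
  } else {
    obj <- function(q) mk_er_partials(tree, idx, q, max(k, 2))$loglik
    opt <- stats::optimize(obj, interval = q_bounds, maximum = TRUE,
                           tol = 1e-10)
    q_hat <- opt$maximum
    # boundary check: optimize never tries the interval ends
    if (obj(q_bounds[1]) > opt$objective) q_hat <- q_bounds[1]
  }
  kk <- max(k, 2)
  parts <- mk_er_partials(tree, idx, q_hat, kk)
  Q <- matrix(q_hat, kk, kk)
  diag(Q) <- -(kk - 1) * q_hat
  structure(list(q = q_hat, logLik = parts$loglik, k = kk,
                 states = if (k < 2) c(levs, ".absent") else levs,
                 Q = Q, partials = parts$partials,
                 tip_index = idx, tree = tree),
            class = "mk_er_fit")
}

#' @export
print.mk_er_fit <- function(x, ...) {
  cat(sprintf("Mk equal-rates fit: k = %d states, q = %.6g /Myr, lnL = %.4f\n",
              x$k, x$q, x$logLik))
  invisible(x)
}

# simulate an unconditioned ER history from a starting state over time t;
# returns list(times, states_after) of jumps and the end state
er_simulate_path <- function(start, t, q, k) {
  rate <- (k - 1) * q
  times <- numeric(0); sts <- integer(0)
  cur <- start; at <- 0
  repeat {
    at <- at + stats::rexp(1, rate)
    if (at >= t) break
    cur <- sample(setdiff(seq_len(k), cur), 1)
    times <- c(times, at); sts <- c(sts, cur)
  }
  list(times = times, states = sts, end = cur)
}

# n-step probability of the uniformized jump chain (zero diagonal,
# uniform off-diagonal): closed form.
er_jump_power <- function(n, same, k) {
  r <- (-1 / (k - 1))^n
  if (same) (1 + (k - 1) * r) / k else (1 - r) / k
}

# sample a conditioned ER path a -> b over time t by uniformization
er_bridge_uniformized <- function(a, b, t, q, k) {
  mu <- (k - 1) * q
  pt <- er_pmatrix(q, t, k)[a, b]
  nmax <- max(20, ceiling(mu * t + 10 * sqrt(mu * t + 1) + 20))
  lw <- stats::dpois(0:nmax, mu * t, log = TRUE) +
    log(pmax(vapply(0:nmax, function(n) er_jump_power(n, a == b, k), 0), 0))
  lw[!is.finite(lw)] <- -Inf
  w <- exp(lw - max(lw))
  nev <- sample(0:nmax, 1, prob = w / sum(w))
  if (nev == 0) return(list(times = numeric(0), states = integer(0), end = b))
  times <- sort(stats::runif(nev, 0, t))
  sts <- integer(nev)
  cur <- a
  for (j in seq_len(nev)) {
    remaining <- nev - j
    cand <- setdiff(seq_len(k), cur)
    pr <- vapply(cand, function(c2) {
      er_jump_power(remaining, c2 == b, k) / (k - 1)
    }, 0)
    if (sum(pr) <= 0) {
      cur <- b  # numerically degenerate; the endpoint is forced
    } else {
      cur <- if (length(cand) == 1) cand else sample(cand, 1, prob = pr)
    }
    sts[j] <- cur
  }
  # last state must equal b by construction of the weights; enforce
  if (sts[nev] != b) sts[nev] <- b
  list(times = times, states = sts, end = b)
}

# conditioned ER path by rejection with bounded budget, uniformization
# fallback; returns the path plus whether the fallback was used
er_bridge <- function(a, b, t, q, k, budget = 100) {
  for (i in seq_len(budget)) {
    path <- er_simulate_path(a, t, q, k)
    if (path$end == b) return(c(path, list(fallback = FALSE)))
  }
  c(er_bridge_uniformized(a, b, t, q, k), list(fallback = TRUE))
}

#' Sample stochastic character maps under the fitted ER model
#'
#' Joint node states are drawn root-down from the conditional
#' distribution given the tips (uniform root prior, pruning partials);
#' the substitution history on each edge is then simulated conditioned
#' on its endpoint states. Summaries are per-node state frequencies
#' across maps, expected dwell time per state and change counts.
#'
#' @param tree A `phylo`.
#' @param states Named tip states (as in [mk_er_fit()]).
#' @param q ER rate; by default refitted via [mk_er_fit()] (the
#'   "empirical Q" convention).
#' @param n_maps Number of maps (study default 1000).
#' @param seed Integer seed.
#' @param keep_maps Keep per-map node states and edge histories
#'   (memory-heavy; used by tests).
#' @return A list of class `simmap_summary`: `node_probs` (internal
#'   nodes x states), `state_times` (expected dwell time per state, Myr),
#'   `changes` (per-map change counts), `q`, `n_maps`,
#'   `n_fallback` (edges where rejection sampling hit its budget), and
#'   optionally `maps`.
#' @export
simmap_sample <- function(tree, states, q = NULL, n_maps = 1000, seed,
                          keep_maps = FALSE) {
  set.seed(as.integer(seed))
  fit <- mk_er_fit(tree, states)
  if (is.null(q)) q <- fit$q
  k <- fit$k
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  parts <- mk_er_partials(tree, fit$tip_index, q, k)
  partial <- parts$partials
  # pre-order edges (parents before children)
  pre <- ape::reorder.phylo(tree, "cladewise")
  edge <- pre$edge; len <- pre$edge.length
  node_counts <- matrix(0, m, k,
                        dimnames = list(as.character(n + seq_len(m)),
                                        fit$states))
  state_time <- stats::setNames(numeric(k), fit$states)
  changes <- integer(n_maps)
  n_fallback <- 0L
  maps <- if (keep_maps) vector("list", n_maps) else NULL
  root <- n + 1L
  for (mp in seq_len(n_maps)) {
    node_state <- integer(n + m)
    pr_root <- partial[root, ]
    node_state[root] <- sample.int(k, 1, prob = pr_root / sum(pr_root))
    histories <- if (keep_maps) vector("list", nrow(edge)) else NULL
    nch <- 0L
    for (e in seq_len(nrow(edge))) {
      u <- edge[e, 1]; v <- edge[e, 2]
      P <- er_pmatrix(q, len[e], k)
      pv <- P[node_state[u], ] * partial[v, ]
      node_state[v] <- sample.int(k, 1, prob = pv / sum(pv))
      path <- er_bridge(node_state[u], node_state[v], len[e], q, k)
      if (path$fallback) n_fallback <- n_fallback + 1L
      # dwell times along this edge; every sampled jump is a real
      # state change (the ER jump chain has zero diagonal)
      sts <- c(node_state[u], path$states)
      tms <- c(0, path$times, len[e])
      dw <- diff(tms)
      for (j in seq_along(sts)) {
        state_time[sts[j]] <- state_time[sts[j]] + dw[j]
      }
      nch <- nch + length(path$states)
      if (keep_maps) {
        histories[[e]] <- list(times = path$times, states = path$states)
      }
    }
    # recount changes robustly from the per-edge paths
    node_counts[cbind(seq_len(m), node_state[n + seq_len(m)])] <-
      node_counts[cbind(seq_len(m), node_state[n + seq_len(m)])] + 1
    changes[mp] <- nch
    if (keep_maps) {
      maps[[mp]] <- list(node_state = node_state, histories = histories,
                         edge = edge)
    }
  }
  structure(list(node_probs = node_counts / n_maps,
                 state_times = state_time / n_maps,
                 changes = changes,
                 q = q, n_maps = n_maps, n_fallback = n_fallback,
                 states = fit$states, maps = maps,
                 tree = tree),
            class = "simmap_summary")
}

#' @export
print.simmap_summary <- function(x, ...) {
  cat(sprintf("Stochastic character maps: %d maps, q = %.5g, mean changes = %.2f\n",
              x$n_maps, x$q, mean(x$changes)))
  cat("Root state probabilities:\n")
  print(round(x$node_probs[1, ], 3))
  invisible(x)
}

#' Export node-value tables for continuous reconstructions
#'
#' One row per internal node, keyed by node id, with the tip set
#' defining the node and one column per reconstructed trait.
#'
#' @param tree A `phylo`.
#' @param recon Named list of [asr_continuous()] outputs (one per trait).
#' @param path Output CSV path.
#' @return The data.frame, invisibly.
#' @export
write_asr_table <- function(tree, recon, path) {
  n <- ape::Ntip(tree)
  ids <- n + seq_len(tree$Nnode)
  clades <- vapply(ids, function(i) {
    tips <- ape::extract.clade(tree, i)$tip.label
    paste(tips[c(1, length(tips))], collapse = "|")
  }, "")
  out <- data.frame(node = ids, clade_span = clades)
  for (nm in names(recon)) {
    out[[nm]] <- as.numeric(recon[[nm]][as.character(ids)])
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
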