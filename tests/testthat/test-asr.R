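test_that("continuous ASR hits closed forms and stays in the tip range", {
  tr <- three_tip()
  const <- stats::setNames(rep(4.2, 3), tr$tip.label)
  rec <- asr_continuous(tr, const)
  expect_equal(unname(rec), rep(4.2, 2), tolerance = 1e-10)

  # two-tip closed form: inverse-branch-length weighted mean
  t2 <- parse_newick("(A:2,B:5);")
  x2 <- c(A = 1, B = 4)
  root <- asr_continuous(t2, x2)
  expect_equal(unname(root), (1 / 2 + 4 / 5) / (1 / 2 + 1 / 5),
               tolerance = 1e-12)

  # root equals the GLS mean (1' C^-1 1)^-1 1' C^-1 x
  tr10 <- random_tree(10, 51)
  x <- stats::setNames(rnorm(10), tr10$tip.label)
  C <- shared_path_matrix(tr10)
  ones <- rep(1, 10)
  gls_root <- sum(solve(C, x[rownames(C)])) / sum(solve(C, ones))
  rec10 <- asr_continuous(tr10, x)
  expect_equal(unname(rec10["11"]), gls_root, tolerance = 1e-10)
  expect_true(all(rec10 >= min(x) - 1e-9 & rec10 <= max(x) + 1e-9))

  expect_error(asr_continuous(tr10, x[-1]), "prune")
})

test_that("continuous ASR matches an independent implementation", {
  skip_if_not_installed("phytools")
  set.seed(52)
  for (r in 1:50) {
    tr <- ape::rtree(10)
    x <- stats::setNames(rnorm(10, sd = 2), tr$tip.label)
    ours <- asr_continuous(tr, x)
    ref <- phytools::fastAnc(tr, x)
    expect_lt(max(abs(ours - ref[names(ours)])), 1e-8)
  }
})

test_that("ER pruning likelihood equals brute-force enumeration", {
  t3 <- parse_newick("((A:1,B:2):1.5,C:3);")
  idx <- c(1L, 2L, 1L)  # states of A, B, C
  set.seed(53)
  for (q in runif(20, 0.01, 2)) {
    P <- function(t) sciurognath:::er_pmatrix(q, t, 2)
    brute <- 0
    for (root_s in 1:2) for (mid_s in 1:2) {
      brute <- brute + 0.5 * P(1.5)[root_s, mid_s] *
        P(1)[mid_s, 1] * P(2)[mid_s, 2] * P(3)[root_s, 1]
    }
    ours <- sciurognath:::mk_er_partials(t3, idx, q, 2)$loglik
    expect_equal(ours, log(brute), tolerance = 1e-10)
  }
})

test_that("two-state ER on a two-tip tree matches the closed form", {
  t2 <- parse_newick("(A:1.3,B:0.9);")
  # P(same state at both tips) marginalized over a uniform root:
  # sum_r pi_r P_{r,a}(t1) P_{r,a}(t2) with the spectral ER form
  for (q in c(0.05, 0.4, 1.7)) {
    lik <- exp(sciurognath:::mk_er_partials(t2, c(1L, 1L), q, 2)$loglik)
    p_same <- function(t) (1 + exp(-2 * q * t)) / 2
    hand <- 0.5 * (p_same(1.3) * p_same(0.9) +
                   (1 - p_same(1.3)) * (1 - p_same(0.9)))
    expect_equal(lik, hand, tolerance = 1e-12)
  }
})

test_that("monomorphic tips drive q to its lower bound", {
  tr <- random_tree(6, 54)
  st <- stats::setNames(rep("arboreal", 6), tr$tip.label)
  expect_warning(fit <- mk_er_fit(tr, st), "single observed state")
  expect_equal(fit$q, 1e-8)
})

test_that("ML rate maximizes the pruning likelihood", {
  ds <- small_synth(seed = 55)
  loco <- stats::setNames(as.character(ds$traits$locomotion),
                          ds$traits$species)
  fit <- mk_er_fit(ds$tree, loco)
  expect_gt(fit$q, 0)
  grid <- seq(1e-4, 0.1, length.out = 60)
  ll <- vapply(grid, function(q) {
    sciurognath:::mk_er_partials(ds$tree, fit$tip_index, q, fit$k)$loglik
  }, 0)
  expect_gte(fit$logLik, max(ll) - 1e-6)
})

test_that("sampled maps are internally consistent", {
  ds <- small_synth(seed = 56)
  loco <- stats::setNames(as.character(ds$traits$locomotion),
                          ds$traits$species)
  sm <- simmap_sample(ds$tree, loco, n_maps = 20, seed = 8,
                      keep_maps = TRUE)
  n <- ape::Ntip(ds$tree)
  tip_idx <- match(ds$tree$tip.label, names(loco))
  for (mp in sm$maps) {
    # tips keep their observed states
    got <- sm$states[mp$node_state[seq_len(n)]]
    expect_identical(unname(got), unname(loco[ds$tree$tip.label]))
    # the state at each edge's child end equals the child node state
    for (e in seq_len(nrow(mp$edge))) {
      u <- mp$edge[e, 1]; v <- mp$edge[e, 2]
      h <- mp$histories[[e]]
      end_state <- if (length(h$states)) h$states[length(h$states)]
                   else mp$node_state[u]
      expect_equal(end_state, mp$node_state[v])
    }
  }
  # node probabilities sum to one
  expect_equal(unname(rowSums(sm$node_probs)),
               rep(1, nrow(sm$node_probs)), tolerance = 1e-9)
  # dwell times sum to tree length
  expect_equal(sum(sm$state_times), sum(ds$tree$edge.length),
               tolerance = 1e-8)
})

test_that("near-zero rate with monomorphic tips gives point-mass nodes", {
  tr <- random_tree(5, 57)
  st <- stats::setNames(rep("fossorial", 5), tr$tip.label)
  suppressWarnings(
    sm <- simmap_sample(tr, st, q = 1e-9, n_maps = 25, seed = 4))
  expect_true(all(sm$node_probs[, 1] == 1))
  expect_true(all(sm$changes == 0))
})

test_that("mean changes per map increase with q", {
  ds <- small_synth(seed = 58)
  loco <- stats::setNames(as.character(ds$traits$locomotion),
                          ds$traits$species)
  q0 <- mk_er_fit(ds$tree, loco)$q
  mean_changes <- vapply(c(q0, 2 * q0, 4 * q0), function(q) {
    mean(simmap_sample(ds$tree, loco, q = q, n_maps = 60,
                       seed = 12)$changes)
  }, 0)
  expect_true(all(diff(mean_changes) > 0))
})

test_that("simmap root frequencies match the analytic conditional", {
  t2 <- parse_newick("(A:0.5,B:2);")
  st <- c(A = "x", B = "y")
  q <- 0.3
  n_maps <- 3000
  sm <- simmap_sample(t2, st, q = q, n_maps = n_maps, seed = 19)
  P1 <- sciurognath:::er_pmatrix(q, 0.5, 2)
  P2 <- sciurognath:::er_pmatrix(q, 2, 2)
  w <- c(P1[1, 1] * P2[1, 2], P1[2, 1] * P2[2, 2])  # uniform prior cancels
  p_analytic <- w / sum(w)
  se <- sqrt(p_analytic[1] * (1 - p_analytic[1]) / n_maps)
  expect_lt(abs(sm$node_probs[1, "x"] - p_analytic[1]), 3 * se)
})
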