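test_that("GLS with identity covariance reproduces OLS exactly", {
  set.seed(11)
  n <- 24
  X <- cbind("(Intercept)" = 1, pred1 = rnorm(n), z = rnorm(n))
  y <- 1 + 0.5 * X[, 2] + rnorm(n)
  fit <- gls_fit(y, X, diag(n))
  ref <- lm(y ~ X[, 2] + X[, 3])
  expect_lt(max(abs(fit$coefficients - coef(ref))), 1e-10)
  expect_equal(fit$logLik, as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_equal(fit$AIC, AIC(ref), tolerance = 1e-8)
  expect_equal(fit$AIC, -2 * fit$logLik + 2 * fit$k)

  # intercept-only at identity = arithmetic mean
  f0 <- gls_fit(y, matrix(1, n, 1), diag(n))
  expect_equal(unname(f0$coefficients), mean(y))
})

test_that("GLS estimator matches explicit matrix inversion on 3 tips", {
  tr <- three_tip()
  V <- shared_path_matrix(tr)
  y <- c(1, 2, 3)
  ones <- matrix(1, 3, 1)
  beta_hand <- solve(t(ones) %*% solve(V) %*% ones) %*%
    t(ones) %*% solve(V) %*% y
  fit <- gls_fit(y, ones, V)
  expect_equal(unname(fit$coefficients), as.numeric(beta_hand),
               tolerance = 1e-12)
})

test_that("rank-deficient designs fail with the collinear columns named", {
  set.seed(2)
  X <- cbind(a = 1, b = rnorm(10))
  X <- cbind(X, c = X[, "b"])
  expect_error(gls_fit(rnorm(10), X, diag(10)), "collinear")
})

test_that("profile optimum beats a dense parameter grid", {
  ds <- small_synth(seed = 5)
  tab <- ds$traits[match(ds$tree$tip.label, ds$traits$species), ]
  y <- log10(tab$endocranial_volume)
  X <- cbind("(Intercept)" = 1, pred1 = log10(tab$body_mass))
  for (model in c("lambda", "ou", "early_burst")) {
    fit <- profile_fit(y, X, ds$tree, model)
    bounds <- sciurognath:::param_bounds(model, ds$tree)
    grid <- seq(bounds[1], bounds[2], length.out = 101)
    grid_ll <- vapply(grid, function(p) {
      gls_fit(y, X, model_covariance(ds$tree,
                                     cov_model_spec(model, p)))$logLik
    }, 0)
    expect_gte(fit$logLik, max(grid_ll) - 1e-6)
  }
})

test_that("lambda is recovered from data simulated under lambda = 1", {
  # Brownian data on a sizeable tree: the lambda profile should sit
  # near the upper bound in the large majority of replicates
  tr <- random_tree(120, 8)
  C <- shared_path_matrix(tr)
  L <- t(chol(C))
  hits <- 0L
  n_rep <- 40
  set.seed(21)
  for (r in seq_len(n_rep)) {
    y <- 2 + as.numeric(L %*% rnorm(120)) * 0.3
    X <- matrix(1, 120, 1)
    fit <- profile_fit(y, X, tr, "lambda")
    if (fit$model_spec$parameter > 0.9) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("AIC selection prefers the interaction only when it is real", {
  ds <- small_synth(seed = 9)
  tab <- ds$traits[match(ds$tree$tip.label, ds$traits$species), ]
  d_a <- build_design(tab, regression_spec("1.EB", "a"))
  d_b <- build_design(tab, regression_spec("1.EB", "b"))

  # identical designs -> tie broken toward formula a
  sel_same <- select_model(d_a, d_a, ds$tree)
  expect_identical(sel_same$formula, "a")
  expect_equal(nrow(sel_same$trace), 8L)
  expect_true(all(abs(sel_same$trace$AIC -
                      (-2 * sel_same$trace$logLik +
                       2 * (ncol(d_a$X) + 1 +
                            (sel_same$trace$model != "brownian")))) < 1e-8))

  # a strong simulated interaction (3x residual SD per unit of pred1)
  # should drive selection to formula b in most replicates
  C <- shared_path_matrix(ds$tree)
  L <- t(chol(C / mean(diag(C))))
  sd_res <- 0.103
  hits <- 0L
  n_rep <- 25
  set.seed(33)
  x1 <- d_b$X[, "pred1"]
  inter_cols <- d_b$terms$interaction
  for (r in seq_len(n_rep)) {
    beta_int <- 3 * sd_res * c(1, -1, 1, -1)[seq_along(inter_cols)]
    y <- 0.5 + 0.57 * x1 +
      as.numeric(d_b$X[, inter_cols] %*% beta_int) +
      as.numeric(L %*% rnorm(nrow(d_b$X))) * sd_res
    sel <- select_model(
      list(y = y, X = d_a$X, terms = d_a$terms),
      list(y = y, X = d_b$X, terms = d_b$terms), ds$tree)
    if (sel$formula == "b") hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("sequential F tests agree with classical ANOVA at identity", {
  set.seed(14)
  g <- factor(rep(letters[1:3], each = 8))
  x <- rnorm(24)
  y <- 1 + 0.4 * x + c(a = 0, b = 1, c = 2)[g] + rnorm(24)
  X <- stats::model.matrix(~ x + g)
  colnames(X)[2] <- "pred1"
  terms <- list(pred1 = 2L, locomotion = 3:4)
  fit <- gls_fit(y, X, diag(24), terms = terms)
  pv <- sequential_pvalues(fit)
  ref <- anova(lm(y ~ x + g))
  expect_equal(pv$F, ref$`F value`[1:2], tolerance = 1e-10)
  expect_equal(pv$p, ref$`Pr(>F)`[1:2], tolerance = 1e-10)
})

test_that("a predictor orthogonal to the response has p near 1", {
  set.seed(15)
  n <- 40
  x <- rnorm(n)
  y <- 2 + x  # exactly explained by pred1
  z <- residuals(lm(rnorm(n) ~ x))  # orthogonal to x by construction
  # make the extra column orthogonal to y's residual space too
  z <- z - sum(z * y) / sum(y * y) * y
  X <- cbind("(Intercept)" = 1, pred1 = x, extra = z)
  yn <- y + rnorm(n, sd = 1e-6)
  fit <- gls_fit(yn, X, diag(n), terms = list(pred1 = 2L, extra = 3L))
  pv <- sequential_pvalues(fit)
  expect_gt(pv$p[pv$term == "extra"], 0.95)
})

test_that("design construction encodes locomotion and interactions", {
  ds <- small_synth(seed = 13)
  tab <- ds$traits
  d_a <- build_design(tab, regression_spec("2.NE", "a"))
  expect_equal(ncol(d_a$X), 6L)
  d_b <- build_design(tab, regression_spec("2.NE", "b"))
  expect_equal(ncol(d_b$X), 10L)
  # interaction columns are elementwise products
  expect_equal(unname(d_b$X[, 7]), unname(d_b$X[, 3] * d_b$X[, 2]))

  # petrosal regressions drop the species with missing measurements
  expect_warning(
    d_pl <- build_design(tab, regression_spec("1.PB", "a")),
    "missing")
  expect_equal(length(d_pl$y), nrow(tab) - 1L)

  # absent locomotion level is an error naming the observed levels
  tab5 <- tab[tab$locomotion != "glider", ]
  expect_error(build_design(tab5, regression_spec("1.EB", "a")),
               "absent")
})

test_that("residual diagnostic flags phylogenetic clustering only", {
  tr <- random_tree(38, 6)
  # constant residuals: score 0, no flag
  const <- stats::setNames(rep(1, 38), tr$tip.label)
  d0 <- phylo_residual_diagnostic(const, tr)
  expect_equal(d0$score, 0)
  expect_false(d0$use_pgls)

  # iid residuals: close-to-nominal flag rate
  set.seed(20)
  flags <- vapply(1:400, function(r) {
    res <- stats::setNames(rnorm(38), tr$tip.label)
    phylo_residual_diagnostic(res, tr, n_perm = 199)$use_pgls
  }, NA)
  expect_gt(mean(flags), 0.02)
  expect_lt(mean(flags), 0.09)

  # BM-simulated residuals: flagged most of the time
  L <- t(chol(shared_path_matrix(tr)))
  set.seed(21)
  flags_bm <- vapply(1:150, function(r) {
    res <- stats::setNames(as.numeric(L %*% rnorm(38)), tr$tip.label)
    phylo_residual_diagnostic(res, tr, n_perm = 199)$use_pgls
  }, NA)
  expect_gte(mean(flags_bm), 0.8)
})
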