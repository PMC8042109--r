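# Phylogenetic generalized least squares with profile maximum
# likelihood over the covariance-model parameter, AIC-based selection
# across four evolutionary models x two formulas, and sequential
# (Type-I) F tests in formula order.
#
# ML (not REML) is used throughout: formulas with different fixed
# effects are compared by AIC, which is only valid under ML. k counts
# fixed effects + sigma^2 + any covariance parameter.

REGRESSION_IDS <- c("1.EB", "1.PB", "1.OB", "2.PE", "2.NE", "2.OE")

REGRESSION_VARS <- list(
  "1.EB" = c(response = "endocranial_volume",  predictor1 = "body_mass"),
  "1.PB" = c(response = "petrosal_lobule_volume", predictor1 = "body_mass"),
  "1.OB" = c(response = "olfactory_bulb_volume", predictor1 = "body_mass"),
  "2.PE" = c(response = "petrosal_lobule_volume",
             predictor1 = "endocranial_volume"),
  "2.NE" = c(response = "neocortex_surface",
             predictor1 = "endocranial_surface"),
  "2.OE" = c(response = "olfactory_bulb_volume",
             predictor1 = "endocranial_volume")
)

#' Specify one of the six study regressions
#'
#' Set 1 regresses a brain measurement on log10 body mass and
#' locomotion; set 2 uses log10 endocranial size as the allometric
#' predictor. Formula `"a"` is additive; `"b"` adds the
#' predictor1 x locomotion interaction.
#'
#' @param id One of `"1.EB"`, `"1.PB"`, `"1.OB"`, `"2.PE"`, `"2.NE"`,
#'   `"2.OE"`.
#' @param formula `"a"` (additive) or `"b"` (interaction).
#' @return A list of class `regression_spec`.
#' @export
regression_spec <- function(id, formula = c("a", "b")) {
  id <- match.arg(id, REGRESSION_IDS)
  formula <- match.arg(formula)
  vars <- REGRESSION_VARS[[id]]
  structure(list(id = id, formula = formula,
                 response = unname(vars["response"]),
                 predictor1 = unname(vars["predictor1"])),
            class = "regression_spec")
}

#' Build the design matrix and response for a regression
#'
#' All variables are log10-transformed. Locomotion uses treatment
#' coding with `"arboreal"` as the reference level; interaction columns
#' are elementwise products. Rows with a missing response or predictor
#' are dropped with a warning (the petrosal-lobule regressions run on 37
#' of the 38 study species for this reason).
#'
#' @param table A [trait_table()].
#' @param spec A [regression_spec()].
#' @return A list with `y` (log10 response), `X` (design matrix),
#'   `species` (kept rows), `terms` (named list of column indices for
#'   the sequential tests) and `spec`.
#' @export
build_design <- function(table, spec) {
  stopifnot(inherits(spec, "regression_spec"))
  y_raw <- table[[spec$response]]
  x_raw <- table[[spec$predictor1]]
  keep <- !is.na(y_raw) & !is.na(x_raw) & !is.na(table$locomotion)
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " row(s) with missing values: ",
            paste(table$species[!keep], collapse = ", "))
  }
  tab <- table[keep, , drop = FALSE]
  present <- levels(droplevels(tab$locomotion))
  if (length(present) < length(LOCOMOTOR_LEVELS)) {
    stop("locomotion level(s) absent from data; observed: ",
         paste(present, collapse = ", "), call. = FALSE)
  }
  y <- log10(tab[[spec$response]])
  x1 <- log10(tab[[spec$predictor1]])
  loco <- stats::model.matrix(~locomotion, data = tab)[, -1, drop = FALSE]
  X <- cbind("(Intercept)" = 1, pred1 = x1, loco)
  terms <- list(pred1 = 2L, locomotion = 2L + seq_len(ncol(loco)))
  if (spec$formula == "b") {
    inter <- loco * x1
    colnames(inter) <- paste0(colnames(loco), ":pred1")
    X <- cbind(X, inter)
    terms$interaction <- (ncol(X) - ncol(inter) + 1):ncol(X)
  }
  list(y = y, X = X, species = tab$species, terms = terms, spec = spec)
}

# Cholesky of V with a single jitter attempt; returns upper-triangular L
# with V = t(L) %*% L, or fails.
chol_jitter <- function(V) {
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) {
    V <- V + diag(1e-10 * mean(diag(V)), nrow(V))
    L <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(L)) stop("covariance matrix not positive definite",
                         call. = FALSE)
  }
  L
}

#' Generalized least squares fit with Gaussian ML likelihood
#'
#' Computes beta = (X' V^-1 X)^-1 X' V^-1 y via Cholesky whitening, the
#' ML variance sigma^2 = r' V^-1 r / n, and the profile log-likelihood.
#' `AIC = -2 lnL + 2 k` with `k = ncol(X) + 1 + n_cov_params`.
#'
#' @param y Response vector.
#' @param X Design matrix (with intercept column).
#' @param V Covariance matrix up to the sigma^2 scalar.
#' @param n_cov_params Number of free covariance-model parameters
#'   counted in k (0 for Brownian/identity, 1 for lambda/OU/EB).
#' @param spec Optional [cov_model_spec()] recorded in the result.
#' @param terms Optional term-index list from [build_design()].
#' @return A list of class `gls_fit`: `coefficients`, `sigma2`, `logLik`,
#'   `AIC`, `k`, `RSE`, `df` (pair n, n - p), residuals, whitened data,
#'   `model_spec`, `terms`.
#' @export
gls_fit <- function(y, X, V, n_cov_params = 0L, spec = NULL, terms = NULL) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  stopifnot(nrow(X) == n, nrow(V) == n, ncol(V) == n)
  if (n <= p) stop("more coefficients than observations", call. = FALSE)
  L <- chol_jitter(V)
  # whiten: z = L'^-1 y so that cov(z) = sigma^2 I
  yw <- forwardsolve(t(L), y)
  Xw <- forwardsolve(t(L), X)
  qrX <- qr(Xw)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, yw)
  rw <- yw - Xw %*% beta
  rss <- sum(rw^2)
  sigma2 <- rss / n
  logdetV <- 2 * sum(log(diag(L)))
  lnL <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdetV + n)
  k <- p + 1L + as.integer(n_cov_params)
  structure(list(
    coefficients = stats::setNames(as.numeric(beta), colnames(X)),
    sigma2 = sigma2,
    logLik = lnL,
    AIC = -2 * lnL + 2 * k,
    k = k,
    RSE = sqrt(rss / (n - p)),
    df = c(n = n, residual = n - p),
    residuals = as.numeric(y - X %*% beta),
    yw = as.numeric(yw), Xw = Xw,
    model_spec = spec, terms = terms
  ), class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  mod <- if (is.null(x$model_spec)) "identity" else x$model_spec$model
  cat("GLS fit (", mod, "), n = ", x$df["n"],
      ", lnL = ", format(x$logLik, digits = 6),
      ", AIC = ", format(x$AIC, digits = 6), "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

# parameter bounds per model, scaled by tree height as documented
param_bounds <- function(model, tree) {
  height <- max(node_heights(tree))
  switch(model,
    lambda      = c(0, 1),
    ou          = c(1e-6, 50 / height),
    early_burst = c(-10 / height, 0)
  )
}

#' Profile-ML fit of one evolutionary model
#'
#' Maximizes the GLS profile log-likelihood over the single
#' covariance-model parameter (lambda in \[0, 1\], alpha in
#' (1e-6, 50/height\], r in \[-10/height, 0\]) by Brent optimization,
#' with the boundary values checked explicitly. Brownian motion has no
#' free covariance parameter.
#'
#' @param y,X Response and design (see [build_design()]).
#' @param tree A calibrated `phylo` whose tip order matches `y`.
#' @param model One of `"brownian"`, `"lambda"`, `"early_burst"`, `"ou"`.
#' @param terms Optional term-index list carried into the fit.
#' @return A `gls_fit` with `model_spec` set to the fitted model.
#' @export
profile_fit <- function(y, X, tree, model = c("brownian", "lambda",
                                              "early_burst", "ou"),
                        terms = NULL) {
  model <- match.arg(model)
  if (model == "brownian") {
    V <- model_covariance(tree, cov_model_spec("brownian"))
    return(gls_fit(y, X, V, n_cov_params = 0L,
                   spec = cov_model_spec("brownian"), terms = terms))
  }
  bounds <- param_bounds(model, tree)
  obj <- function(par) {
    V <- model_covariance(tree, cov_model_spec(model, par))
    fit <- tryCatch(gls_fit(y, X, V), error = function(e) NULL)
    if (is.null(fit)) return(-1e10)
    fit$logLik
  }
  opt <- stats::optimize(obj, interval = bounds, maximum = TRUE,
                         tol = 1e-8)
  # optimize() never evaluates the interval ends; check them explicitly
  cand <- c(opt$maximum, bounds)
  vals <- c(opt$objective, obj(bounds[1]), obj(bounds[2]))
  best <- cand[which.max(vals)]
  if (max(vals) <= -1e9) {
    stop("profile optimization failed for model '", model,
         "'; best parameter tried: ", format(best), call. = FALSE)
  }
  spec <- cov_model_spec(model, best)
  V <- model_covariance(tree, spec)
  gls_fit(y, X, V, n_cov_params = 1L, spec = spec, terms = terms)
}

#' Fit all models for both formulas and select by AIC
#'
#' Fits the four evolutionary models for the additive formula and for
#' the interaction formula, takes each formula's AIC-minimal model, and
#' returns the overall AIC-minimal fit (ties broken toward the simpler
#' additive formula). The full 8-fit AIC table is returned as the trace.
#'
#' @param design_a,design_b [build_design()] outputs for formulas a and b.
#' @param tree Calibrated `phylo` matching the design rows.
#' @return A list: `fit` (the selected `gls_fit`), `formula` (`"a"` or
#'   `"b"`), `model`, `trace` (data.frame of formula, model, AIC, logLik,
#'   parameter, error).
#' @export
select_model <- function(design_a, design_b, tree) {
  models <- c("brownian", "lambda", "early_burst", "ou")
  grid <- expand.grid(formula = c("a", "b"), model = models,
                      stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  trace <- grid
  trace$AIC <- NA_real_; trace$logLik <- NA_real_
  trace$parameter <- NA_real_; trace$error <- NA_character_
  for (i in seq_len(nrow(grid))) {
    d <- if (grid$formula[i] == "a") design_a else design_b
    fit <- tryCatch(
      profile_fit(d$y, d$X, tree, grid$model[i], terms = d$terms),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      trace$error[i] <- conditionMessage(fit)
    } else {
      fits[[i]] <- fit
      trace$AIC[i] <- fit$AIC
      trace$logLik[i] <- fit$logLik
      if (!is.null(fit$model_spec$parameter)) {
        trace$parameter[i] <- fit$model_spec$parameter
      }
    }
  }
  if (all(is.na(trace$AIC))) {
    stop("all constituent fits failed; first error: ",
         stats::na.omit(trace$error)[1], call. = FALSE)
  }
  pick_in <- function(f) {
    idx <- which(trace$formula == f & !is.na(trace$AIC))
    if (!length(idx)) return(NA_integer_)
    idx[which.min(trace$AIC[idx])]
  }
  ia <- pick_in("a"); ib <- pick_in("b")
  # overall minimum; exact ties (and near-ties to numerical noise) go to a
  best <- if (is.na(ib)) ia
          else if (is.na(ia)) ib
          else if (trace$AIC[ia] <= trace$AIC[ib] + 1e-9) ia else ib
  list(fit = fits[[best]], formula = trace$formula[best],
       model = trace$model[best], trace = trace)
}

#' Sequential (Type-I) F tests in formula order
#'
#' Terms are added in the order predictor1, locomotion, interaction;
#' each F statistic compares generalized residual sums of squares under
#' the fitted covariance, against the full-model residual mean square.
#'
#' @param fit A `gls_fit` carrying whitened data and a `terms` list.
#' @return A data.frame with term, df, F and p columns.
#' @export
sequential_pvalues <- function(fit) {
  stopifnot(inherits(fit, "gls_fit"))
  if (is.null(fit$terms)) stop("fit carries no term structure", call. = FALSE)
  yw <- fit$yw; Xw <- fit$Xw
  n <- length(yw)
  p_full <- ncol(Xw)
  rss_full <- sum(qr.resid(qr(Xw), yw)^2)
  mse <- rss_full / (n - p_full)
  cols <- 1L  # intercept
  rss_prev <- sum(qr.resid(qr(Xw[, cols, drop = FALSE]), yw)^2)
  out <- data.frame(term = names(fit$terms), df = NA_integer_,
                    F = NA_real_, p = NA_real_)
  for (j in seq_along(fit$terms)) {
    cols <- c(cols, fit$terms[[j]])
    rss_j <- sum(qr.resid(qr(Xw[, cols, drop = FALSE]), yw)^2)
    df_j <- length(fit$terms[[j]])
    Fj <- ((rss_prev - rss_j) / df_j) / mse
    out$df[j] <- df_j
    out$F[j] <- Fj
    out$p[j] <- stats::pf(Fj, df_j, n - p_full, lower.tail = FALSE)
    rss_prev <- rss_j
  }
  out
}

#' Phylogenetic clustering diagnostic for OLS residuals
#'
#' Orders residuals by the tree's tip sequence and compares the mean
#' absolute difference between phylogenetically adjacent residuals with
#' its permutation distribution under random tip orderings. Clustered
#' residuals (related species alike) give a small observed score; a
#' permutation p-value at or below `alpha` flags that PGLS should be
#' used instead of OLS.
#'
#' @param residuals Named numeric vector (names = species).
#' @param tree A `phylo` containing those species as tips.
#' @param n_perm Number of permutations (default 999).
#' @param alpha Flagging level (default 0.05).
#' @param seed Optional seed for the permutations.
#' @return A list: `score`, `p`, `use_pgls`, `ordered` (residuals in tip
#'   order).
#' @export
phylo_residual_diagnostic <- function(residuals, tree, n_perm = 999,
                                      alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  tips <- tree$tip.label
  stopifnot(all(tips %in% names(residuals)))
  r <- residuals[tips]  # ape tip order = plotted phylogenetic order
  score <- function(v) mean(abs(diff(v)))
  obs <- score(r)
  if (obs == 0) {
    return(list(score = 0, p = 1, use_pgls = FALSE, ordered = r))
  }
  perm <- replicate(n_perm, score(sample(r)))
  p <- (sum(perm <= obs) + 1) / (n_perm + 1)
  list(score = obs, p = p, use_pgls = p <= alpha, ordered = r)
}

#' Export a table of selected PGLS fits as CSV
#'
#' One row per regression: chosen formula and model, AIC, intercept and
#' slopes, sequential p-values, lambda (from the lambda-model fit), RSE
#' and the (n, n - p) degrees-of-freedom pair.
#'
#' @param results Named list (by regression id) of [select_model()]
#'   outputs, each augmented with a `lambda` element.
#' @param path Output CSV path.
#' @return The assembled data.frame, invisibly.
#' @export
write_pgls_table <- function(results, path) {
  rows <- lapply(names(results), function(id) {
    res <- results[[id]]
    fit <- res$fit
    pv <- sequential_pvalues(fit)
    getp <- function(tm) if (tm %in% pv$term) pv$p[pv$term == tm] else NA_real_
    data.frame(
      regression = id,
      formula = res$formula,
      model = res$model,
      AIC = fit$AIC,
      intercept = unname(fit$coefficients[1]),
      slope_pred1 = unname(fit$coefficients["pred1"]),
      p_pred1 = getp("pred1"),
      p_locomotion = getp("locomotion"),
      p_interaction = getp("interaction"),
      lambda = if (!is.null(res$lambda)) res$lambda else NA_real_,
      RSE = fit$RSE,
      df_n = unname(fit$df["n"]),
      df_resid = unname(fit$df["residual"])
    )
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
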