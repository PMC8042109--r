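# Non-phylogenetic ANOVA via residual randomization in a permutation
# procedure (RRPP): for each term, residuals of the reduced (term
# excluded) model are permuted uniformly at random and added back to
# the reduced fitted values, the model is refit, and the term's F
# statistic recomputed. The identity permutation is iteration 0, so
# p = (count of permuted F >= observed + 1) / (iterations + 1).
# Sums of squares are Type I (sequential, formula order).

# Orthonormal basis of the column space (for fast projections)
ortho_basis <- function(X) {
  q <- qr(X)
  qr.Q(q)[, seq_len(q$rank), drop = FALSE]
}

#' Residual-randomization ANOVA
#'
#' @param y Response vector.
#' @param X Full design matrix, intercept first.
#' @param terms Named list of column-index vectors (beyond the
#'   intercept), in formula order, as produced by [build_design()].
#' @param iterations Number of random permutations (>= 99; default 999).
#' @param seed Integer seed (mandatory: results are resampling-based).
#' @return A list of class `rrpp_fit`: `table` (term, df, SS, F, p),
#'   `ss_total`, `ss_residual`, `iterations`, `seed`, plus the inputs
#'   needed by [rrpp_pairwise()].
#' @export
rrpp_anova <- function(y, X, terms, iterations = 999, seed) {
  stopifnot(iterations >= 99)
  set.seed(as.integer(seed))
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  p_full <- qr(X)$rank
  if (p_full < ncol(X)) stop("rank-deficient design", call. = FALSE)
  # nested sequence of bases: intercept, +term1, +term2, ...
  cols <- 1L
  bases <- list(ortho_basis(X[, cols, drop = FALSE]))
  for (j in seq_along(terms)) {
    cols <- c(cols, terms[[j]])
    bases[[j + 1]] <- ortho_basis(X[, cols, drop = FALSE])
  }
  rss <- function(Q, v) sum(v^2) - sum(crossprod(Q, v)^2)
  fstat_all <- function(v) {
    r <- vapply(bases, rss, 0, v = v)
    mse <- r[length(r)] / (n - p_full)
    vapply(seq_along(terms), function(j) {
      ((r[j] - r[j + 1]) / length(terms[[j]])) / mse
    }, 0)
  }
  f_obs <- fstat_all(y)
  count <- rep(1L, length(terms))  # identity permutation included
  for (it in seq_len(iterations)) {
    perm <- sample.int(n)
    for (j in seq_along(terms)) {
      Qr <- bases[[j]]                     # reduced model for term j
      fit_red <- Qr %*% crossprod(Qr, y)
      res_red <- y - fit_red
      y_star <- fit_red + res_red[perm]
      r_red  <- rss(bases[[j]], y_star)
      r_term <- rss(bases[[j + 1]], y_star)
      r_full <- rss(bases[[length(bases)]], y_star)
      f_star <- ((r_red - r_term) / length(terms[[j]])) /
        (r_full / (n - p_full))
      if (f_star >= f_obs[j] - 1e-12) count[j] <- count[j] + 1L
    }
  }
  rss_seq <- vapply(bases, rss, 0, v = y)
  tab <- data.frame(
    term = names(terms),
    df = vapply(terms, length, 0L),
    SS = -diff(rss_seq),
    F = f_obs,
    p = count / (iterations + 1)
  )
  structure(list(table = tab,
                 ss_total = rss_seq[1],
                 ss_residual = rss_seq[length(rss_seq)],
                 iterations = iterations, seed = as.integer(seed),
                 y = y, X = X, terms = terms, bases = bases),
            class = "rrpp_fit")
}

#' @export
print.rrpp_fit <- function(x, ...) {
  cat("RRPP ANOVA (", x$iterations, " permutations, seed ", x$seed,
      ")\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Post-hoc pairwise comparisons from an RRPP fit
#'
#' The statistic per group pair is the absolute distance between
#' adjusted least-squares means (groups evaluated at the mean of the
#' continuous predictor; slope-adjusted automatically when the design
#' carries interaction columns). The null distribution permutes the
#' residuals of the no-group reduced model, mirroring the term test.
#' P-values are unadjusted, as in the study's post-hoc tables;
#' Benjamini-Hochberg values are appended for reference.
#'
#' @param fit An `rrpp_fit` whose design contains a `locomotion` term.
#' @param groups Factor of group membership, aligned with the fit rows.
#' @param x1 The continuous predictor (log10 scale), aligned likewise.
#' @return A data.frame: group1, group2, distance, p, p_adjusted.
#' @export
rrpp_pairwise <- function(fit, groups, x1) {
  stopifnot(inherits(fit, "rrpp_fit"))
  groups <- droplevels(factor(groups))
  levs <- levels(groups)
  X <- fit$X
  y <- fit$y
  n <- length(y)
  set.seed(fit$seed + 1L)  # distinct substream from the term tests
  # prediction design: one row per group at the mean covariate
  xbar <- mean(x1)
  pred_rows <- vapply(levs, function(g) {
    template <- X[which(groups == g)[1], ]
    out <- template
    if ("pred1" %in% names(template)) out["pred1"] <- xbar
    inter <- grep(":pred1$", names(template))
    if (length(inter)) out[inter] <- (template[inter] != 0) * xbar
    out
  }, numeric(ncol(X)))
  pred_rows <- t(pred_rows)  # levs x p
  qrX <- qr(X)
  ls_means <- function(v) as.numeric(pred_rows %*% qr.coef(qrX, v))
  dist_pairs <- function(mns) {
    prs <- utils::combn(seq_along(levs), 2)
    abs(mns[prs[1, ]] - mns[prs[2, ]])
  }
  d_obs <- dist_pairs(ls_means(y))
  # reduced model: everything except group-dependent columns
  grp_cols <- unlist(fit$terms[names(fit$terms) != "pred1"])
  Qr <- ortho_basis(X[, setdiff(seq_len(ncol(X)), grp_cols), drop = FALSE])
  fit_red <- Qr %*% crossprod(Qr, y)
  res_red <- as.numeric(y - fit_red)
  count <- rep(1L, length(d_obs))
  for (it in seq_len(fit$iterations)) {
    y_star <- as.numeric(fit_red) + res_red[sample.int(n)]
    d_star <- dist_pairs(ls_means(y_star))
    count <- count + (d_star >= d_obs - 1e-12)
  }
  prs <- utils::combn(levs, 2)
  out <- data.frame(group1 = prs[1, ], group2 = prs[2, ],
                    distance = d_obs,
                    p = count / (fit$iterations + 1))
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Export RRPP pairwise tables as CSV
#'
#' @param tables Named list (by regression id) of [rrpp_pairwise()]
#'   outputs.
#' @param path Output CSV path.
#' @return The combined data.frame, invisibly.
#' @export
write_rrpp_table <- function(tables, path) {
  rows <- lapply(names(tables), function(id) {
    cbind(regression = id, tables[[id]])
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
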