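# Fisher-Pitman permutation tests on the raw values (not ranks). The
# K-sample test uses the asymptotic quadratic form of the group-sum
# linear statistic: with exact permutation moments
#   E[T_g]       = n_g * ybar
#   Cov(T_g,T_h) = SS / (N (N-1)) * (N * delta_gh * n_g - n_g n_h),
# where SS = sum (y - ybar)^2, the statistic (T - mu)' Sigma^- (T - mu)
# is chi-squared with k - 1 df under the permutation null. An
# exact-enumeration mode over all label assignments serves as the test
# oracle for small n.

#' Asymptotic K-sample Fisher-Pitman permutation test
#'
#' @param values Numeric vector of per-species values.
#' @param groups Factor (or coercible) of group labels, same length.
#' @return A list of class `perm_test`: `statistic` (chi-squared), `df`,
#'   `p`, `group_sizes`, `method`.
#' @export
fp_ksample <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(factor(groups[ok]))
  k <- nlevels(groups)
  if (k < 2) stop("need >= 2 non-empty groups", call. = FALSE)
  N <- length(values)
  ss <- sum((values - mean(values))^2)
  if (ss == 0) {
    return(structure(list(statistic = 0, df = k - 1L, p = 1,
                          group_sizes = table(groups),
                          method = "asymptotic"), class = "perm_test"))
  }
  n_g <- as.numeric(table(groups))
  T_g <- as.numeric(tapply(values, groups, sum))
  mu <- n_g * mean(values)
  Sigma <- ss / (N * (N - 1)) * (N * diag(n_g) - outer(n_g, n_g))
  stat <- as.numeric(t(T_g - mu) %*% pseudo_inverse(Sigma) %*% (T_g - mu))
  df <- k - 1L
  structure(list(statistic = stat, df = df,
                 p = stats::pchisq(stat, df, lower.tail = FALSE),
                 group_sizes = table(groups),
                 method = "asymptotic"), class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Fisher-Pitman permutation test (%s): chi^2 = %.3f, df = %d, p = %.4g\n",
              x$method, x$statistic, x$df, x$p))
  invisible(x)
}

# Moore-Penrose pseudo-inverse via eigendecomposition (Sigma symmetric)
pseudo_inverse <- function(S, tol = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  pos <- e$values > tol * max(abs(e$values))
  if (!any(pos)) return(matrix(0, nrow(S), ncol(S)))
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

#' Exact-enumeration K-sample permutation p-value
#'
#' Enumerates every distinct assignment of the observed values to the
#' group sizes and returns P(statistic >= observed). Feasible for total
#' n <= 12; used as the independent oracle for [fp_ksample()].
#'
#' @inheritParams fp_ksample
#' @return The exact permutation p-value.
#' @export
fp_exact_pvalue <- function(values, groups) {
  groups <- droplevels(factor(groups))
  N <- length(values)
  if (N > 12) stop("exact enumeration limited to n <= 12", call. = FALSE)
  n_g <- as.numeric(table(groups))
  k <- length(n_g)
  obs <- fp_ksample(values, groups)$statistic
  # precompute the permutation moments once; the statistic for each
  # assignment is then a k x k quadratic form of the group sums
  ss <- sum((values - mean(values))^2)
  if (ss == 0) return(1)
  mu <- n_g * mean(values)
  Sigma <- ss / (N * (N - 1)) * (N * diag(n_g) - outer(n_g, n_g))
  Sinv <- pseudo_inverse(Sigma)
  stat_of <- function(chosen, last) {
    T_g <- c(vapply(chosen, function(ix) sum(values[ix]), 0),
             sum(values[last]))
    d <- T_g - mu
    as.numeric(t(d) %*% Sinv %*% d)
  }
  count <- 0L; total <- 0L
  chosen <- vector("list", k - 1)
  assign_rec <- function(remaining, g) {
    if (g == k) {
      total <<- total + 1L
      if (stat_of(chosen, remaining) >= obs - 1e-9) count <<- count + 1L
      return(invisible())
    }
    for (cmb in utils::combn(remaining, n_g[g], simplify = FALSE)) {
      chosen[[g]] <<- cmb
      assign_rec(setdiff(remaining, cmb), g + 1L)
    }
  }
  assign_rec(seq_len(N), 1L)
  count / total
}

#' Pairwise two-sample permutation tests with BH adjustment
#'
#' Every unordered pair of groups is tested with the standardized
#' two-sample linear statistic Z = (T_1 - E[T_1]) / sd(T_1) computed on
#' that pair's values only, with a two-sided asymptotic normal p-value;
#' Benjamini-Hochberg step-up adjustment is applied across the pairs.
#' Positive Z means the first-named group has the larger values.
#'
#' @inheritParams fp_ksample
#' @return A data.frame: group1, group2, statistic, p, p_adjusted.
#' @export
fp_pairwise <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(factor(groups[ok]))
  levs <- levels(groups)
  if (length(levs) < 2) stop("need >= 2 non-empty groups", call. = FALSE)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    sel <- groups %in% pr
    y <- values[sel]
    g <- droplevels(groups[sel])
    N <- length(y)
    n1 <- sum(g == pr[1])
    ss <- sum((y - mean(y))^2)
    if (ss == 0) {
      z <- 0; p <- 1
    } else {
      T1 <- sum(y[g == pr[1]])
      mu <- n1 * mean(y)
      v <- ss / (N * (N - 1)) * n1 * (N - n1)
      z <- (T1 - mu) / sqrt(v)
      p <- 2 * stats::pnorm(-abs(z))
    }
    data.frame(group1 = pr[1], group2 = pr[2], statistic = z, p = p)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Normality and variance-homogeneity preconditions
#'
#' Shapiro-Wilk normality on the group-centred values decides the
#' route: non-normal data go to a Levene test on centred absolute
#' deviations (median centring, the Brown-Forsythe variant, by
#' default), normal data to Bartlett's test. Groups of size < 2 are
#' excluded with a warning.
#'
#' @inheritParams fp_ksample
#' @param center `"median"` (Brown-Forsythe) or `"mean"` for the Levene
#'   route.
#' @param alpha Normality level used to pick the route.
#' @return A list: `shapiro_p`, `route` (`"levene"` or `"bartlett"`),
#'   `homogeneity_stat`, `homogeneity_p`, `homogeneous`.
#' @export
variance_checks <- function(values, groups, center = c("median", "mean"),
                            alpha = 0.05) {
  center <- match.arg(center)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(factor(groups[ok]))
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding group(s) of size < 2: ",
            paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) stop("need >= 2 groups of size >= 2",
                                call. = FALSE)
  centred <- values - stats::ave(values, groups)
  if (stats::sd(centred) == 0) {
    # constant within every group: variances are trivially equal
    return(list(shapiro_p = 1, route = "bartlett",
                homogeneity_stat = 0, homogeneity_p = 1,
                homogeneous = TRUE))
  }
  shapiro_p <- stats::shapiro.test(centred)$p.value
  if (shapiro_p < alpha) {
    cfun <- if (center == "median") stats::median else mean
    dev <- abs(values - stats::ave(values, groups, FUN = cfun))
    if (stats::sd(dev) == 0) {
      stat <- 0; p <- 1
    } else {
      aov_tab <- stats::anova(stats::lm(dev ~ groups))
      stat <- aov_tab$`F value`[1]
      p <- aov_tab$`Pr(>F)`[1]
    }
    route <- "levene"
  } else {
    bt <- stats::bartlett.test(values, groups)
    stat <- unname(bt$statistic)
    p <- bt$p.value
    route <- "bartlett"
  }
  list(shapiro_p = shapiro_p, route = route, homogeneity_stat = stat,
       homogeneity_p = p, homogeneous = p >= alpha)
}

#' Run the full permutation-test block for one response
#'
#' Convenience wrapper producing the K-sample test, the pairwise table
#' and the variance preconditions; a heterogeneity warning is attached
#' to the result when the homogeneity test rejects.
#'
#' @inheritParams fp_ksample
#' @param label Name of the response (for the exported table).
#' @return A list: `label`, `ksample`, `pairwise`, `checks`, `warning`.
#' @export
permutation_block <- function(values, groups, label = "response") {
  checks <- variance_checks(values, groups)
  res <- list(label = label,
              ksample = fp_ksample(values, groups),
              pairwise = fp_pairwise(values, groups),
              checks = checks,
              warning = if (!checks$homogeneous)
                paste0("variance homogeneity rejected for ", label,
                       " (p = ", format(checks$homogeneity_p, digits = 3),
                       "); interpret group-mean comparisons with caution")
              else NULL)
  if (!is.null(res$warning)) warning(res$warning, call. = FALSE)
  res
}

#' Export permutation-test blocks as a Table-1-shaped CSV
#'
#' @param blocks List of [permutation_block()] results.
#' @param path Output CSV path.
#' @return The data.frame, invisibly.
#' @export
write_permutation_table <- function(blocks, path) {
  rows <- lapply(blocks, function(b) {
    ks <- data.frame(response = b$label, comparison = "K-sample",
                     statistic = b$ksample$statistic,
                     df = b$ksample$df, p = b$ksample$p,
                     p_adjusted = NA_real_)
    pw <- data.frame(response = b$label,
                     comparison = paste(b$pairwise$group1, "-",
                                        b$pairwise$group2),
                     statistic = b$pairwise$statistic, df = NA_integer_,
                     p = b$pairwise$p, p_adjusted = b$pairwise$p_adjusted)
    rbind(ks, pw)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
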