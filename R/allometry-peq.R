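# Encephalization quotients. The classical EQ divides observed
# endocranial volume by the expectation from Jerison's allometry
# E_c = 0.12 M^0.67. The phylogenetic EQ (PEQ) replaces that reference
# line with the PGLS allometry fitted on the study sample itself, so
# the expectation accounts for shared ancestry. The coefficient a is
# unit-dependent (package default: mass in g, volume in mm^3); the
# exponent b is not.

JERISON_A <- 0.12
JERISON_B <- 0.67

#' Fit the endocranial-volume allometry by PGLS
#'
#' Regresses log10 endocranial volume on log10 body mass (no locomotion
#' terms) under the AIC-selected evolutionary model; the power-law
#' coefficient is `a = 10^intercept` and the exponent the PGLS slope.
#'
#' @param table A [trait_table()] with `body_mass` and
#'   `endocranial_volume` for every species.
#' @param tree Calibrated `phylo` containing all species.
#' @param model `"select"` (default: AIC over the four models) or one
#'   model name.
#' @return A list of class `allometric_model`: `a`, `b`, `model`,
#'   `parameter`, `fit`, `units`.
#' @export
fit_allometry <- function(table, tree, model = "select") {
  if (any(is.na(table$body_mass)) || any(is.na(table$endocranial_volume))) {
    stop("body_mass and endocranial_volume must be complete", call. = FALSE)
  }
  tab <- table[match(tree$tip.label, table$species), ]
  if (any(is.na(tab$species))) {
    stop("tree tips missing from trait table", call. = FALSE)
  }
  y <- log10(tab$endocranial_volume)
  X <- cbind("(Intercept)" = 1, pred1 = log10(tab$body_mass))
  if (model == "select") {
    models <- c("brownian", "lambda", "early_burst", "ou")
    fits <- lapply(models, function(m) profile_fit(y, X, tree, m))
    best <- which.min(vapply(fits, function(f) f$AIC, 0))
    fit <- fits[[best]]
  } else {
    fit <- profile_fit(y, X, tree, model)
  }
  structure(list(
    a = 10^unname(fit$coefficients[1]),
    b = unname(fit$coefficients["pred1"]),
    model = fit$model_spec$model,
    parameter = fit$model_spec$parameter,
    fit = fit,
    units = c(mass = "g", volume = "mm^3")
  ), class = "allometric_model")
}

#' @export
print.allometric_model <- function(x, ...) {
  cat(sprintf("E_c = %.4g (Body mass)^%.4g  [%s model; mass %s, volume %s]\n",
              x$a, x$b, x$model, x$units["mass"], x$units["volume"]))
  invisible(x)
}

#' Per-species encephalization quotients
#'
#' `compute_peq()` uses the sample's own PGLS allometry; `compute_eq()`
#' uses Jerison's E_c = 0.12 M^0.67.
#'
#' @param table A [trait_table()].
#' @param model An `allometric_model` from [fit_allometry()].
#' @return Named numeric vector of quotients (observed / expected).
#' @export
compute_peq <- function(table, model) {
  stopifnot(inherits(model, "allometric_model"))
  quotient(table, model$a, model$b)
}

#' @rdname compute_peq
#' @export
compute_eq <- function(table) {
  quotient(table, JERISON_A, JERISON_B)
}

quotient <- function(table, a, b) {
  M <- table$body_mass
  E <- table$endocranial_volume
  if (any(!is.na(M) & M <= 0) || any(!is.na(E) & E <= 0)) {
    stop("non-positive mass or endocranial volume", call. = FALSE)
  }
  stats::setNames(E / (a * M^b), table$species)
}

#' Brain-component percentages
#'
#' OB% = 100 V_OB / E_i, PL% = 100 V_PL / E_i (volumes), and
#' Neo% = 100 SA_N / SA_E (surfaces). Missing inputs yield missing
#' outputs, never zeros.
#'
#' @param table A [trait_table()].
#' @return A data.frame: species, OB_pct, PL_pct, Neo_pct.
#' @export
compute_percentages <- function(table) {
  data.frame(
    species = table$species,
    OB_pct  = 100 * table$olfactory_bulb_volume / table$endocranial_volume,
    PL_pct  = 100 * table$petrosal_lobule_volume / table$endocranial_volume,
    Neo_pct = 100 * table$neocortex_surface / table$endocranial_surface
  )
}

#' Export quotients and percentages as CSV
#'
#' @param table A [trait_table()].
#' @param model An `allometric_model`.
#' @param path Output CSV path.
#' @return The data.frame, invisibly.
#' @export
write_peq_table <- function(table, model, path) {
  pct <- compute_percentages(table)
  out <- data.frame(species = table$species,
                    PEQ = unname(compute_peq(table, model)),
                    EQ = unname(compute_eq(table)),
                    pct[, c("OB_pct", "PL_pct", "Neo_pct")])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
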