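# End-to-end orchestration: calibrate -> average -> allometry/PEQ ->
# permutation tests -> six PGLS regressions with model selection ->
# RRPP + post hoc -> continuous ASR -> stochastic character maps.
# All randomness flows from the master seed through fixed offsets:
# calibration uses the seed itself, RRPP seed + 1000 + regression
# index, simmap seed + 2000.

#' Pipeline configuration
#'
#' @param traits A [trait_table()] or path to its CSV.
#' @param topology A `phylo`/Newick path: the (uncalibrated) topology.
#' @param age_bins An [age_bin_matrix()] or path to its CSV.
#' @param out_dir Output directory for the CSV bundle.
#' @param seed Master seed (mandatory).
#' @param n_calibration_trees Number of calibrated trees (default 100).
#' @param rrpp_iterations RRPP permutations (default 999).
#' @param n_simmaps Stochastic character maps (default 1000).
#' @param mbl Minimum branch length for calibration, Myr.
#' @return A list of class `run_config`.
#' @export
run_config <- function(traits, topology, age_bins, out_dir, seed,
                       n_calibration_trees = 100, rrpp_iterations = 999,
                       n_simmaps = 1000, mbl = 0.1) {
  if (is.character(traits)) traits <- read_trait_table(traits)
  if (is.character(topology)) {
    topology <- parse_newick(paste(readLines(topology), collapse = ""))
  }
  if (is.character(age_bins)) age_bins <- read_age_bins(age_bins)
  stopifnot(!missing(seed))
  structure(list(traits = traits, topology = topology,
                 age_bins = age_bins, out_dir = out_dir,
                 seed = as.integer(seed),
                 n_calibration_trees = n_calibration_trees,
                 rrpp_iterations = rrpp_iterations,
                 n_simmaps = n_simmaps, mbl = mbl),
            class = "run_config")
}

# fit one regression id on the appropriate (possibly pruned) tree;
# returns the selection result plus lambda report and the design used
fit_regression <- function(traits, tree, id) {
  spec_a <- regression_spec(id, "a")
  resp <- spec_a$response
  pred <- spec_a$predictor1
  keep <- !is.na(traits[[resp]]) & !is.na(traits[[pred]])
  tr <- if (all(keep)) tree else
    prune_tree(tree, traits$species[!keep])
  tab <- traits[match(tr$tip.label, traits$species), ]
  design_a <- build_design(tab, spec_a)
  design_b <- build_design(tab, regression_spec(id, "b"))
  sel <- select_model(design_a, design_b, tr)
  # lambda column: ML lambda under the selected formula's lambda model
  lam_rows <- sel$trace[sel$trace$model == "lambda" &
                        sel$trace$formula == sel$formula, ]
  sel$lambda <- lam_rows$parameter[1]
  sel$design <- if (sel$formula == "a") design_a else design_b
  sel$tree <- tr
  sel$table <- tab
  sel
}

#' Run the full analysis and export the study-shaped tables
#'
#' Writes `table1.csv` (permutation blocks for PEQ, PL%, Neo%, OB%),
#' `table2.csv` (six selected PGLS fits), `table2_trace.csv` (all 8
#' fits per regression), `table3.csv` (RRPP pairwise),
#' `rrpp_anova.csv`, `peq.csv`, `asr_nodes.csv` (+ `asr_nodes_pl.csv`
#' on the pruned petrosal tree), `simmap_nodes.csv`,
#' `average_tree.nwk`, `calibrated_trees.nwk` and `run_log.txt` to
#' `cfg$out_dir`. Identical config + seed give an identical bundle.
#'
#' @param cfg A [run_config()].
#' @return A list with every stage's result, invisibly classed
#'   `analysis_bundle`.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$out_dir, "run_log.txt")
  log_lines <- c(paste("master seed:", cfg$seed),
                 paste("calibration trees:", cfg$n_calibration_trees),
                 paste("rrpp iterations:", cfg$rrpp_iterations),
                 paste("simmaps:", cfg$n_simmaps))
  traits <- cfg$traits

  # 1. calibration
  trees <- sample_calibrated_trees(cfg$topology, cfg$age_bins,
                                   n_trees = cfg$n_calibration_trees,
                                   master_seed = cfg$seed, mbl = cfg$mbl)
  avg <- average_tree(trees)
  ape::write.tree(trees, file.path(cfg$out_dir, "calibrated_trees.nwk"))
  cat(write_newick(avg), "\n", sep = "",
      file = file.path(cfg$out_dir, "average_tree.nwk"))
  log_lines <- c(log_lines, paste("average tree root age:",
                                  format(max(node_heights(avg)))))

  # 2. allometry + PEQ
  allom <- fit_allometry(traits, avg)
  peq <- compute_peq(traits, allom)
  pct <- compute_percentages(traits)
  write_peq_table(traits, allom, file.path(cfg$out_dir, "peq.csv"))
  log_lines <- c(log_lines,
                 sprintf("allometry: a = %.4g, b = %.4g (%s model)",
                         allom$a, allom$b, allom$model))

  # 3. permutation blocks
  groups <- traits$locomotion
  blocks <- list(
    permutation_block(unname(peq), groups, "PEQ"),
    permutation_block(pct$PL_pct, groups, "PL_pct"),
    permutation_block(pct$Neo_pct, groups, "Neo_pct"),
    permutation_block(pct$OB_pct, groups, "OB_pct")
  )
  write_permutation_table(blocks, file.path(cfg$out_dir, "table1.csv"))
  for (b in blocks) {
    if (!is.null(b$warning)) log_lines <- c(log_lines, b$warning)
  }

  # 4. six PGLS regressions
  regressions <- lapply(stats::setNames(REGRESSION_IDS, REGRESSION_IDS),
                        function(id) fit_regression(traits, avg, id))
  write_pgls_table(regressions, file.path(cfg$out_dir, "table2.csv"))
  trace <- do.call(rbind, lapply(names(regressions), function(id) {
    cbind(regression = id, regressions[[id]]$trace)
  }))
  utils::write.csv(trace, file.path(cfg$out_dir, "table2_trace.csv"),
                   row.names = FALSE)

  # 5. RRPP ANOVA + pairwise (non-phylogenetic)
  rrpp_fits <- list(); rrpp_pw <- list()
  for (i in seq_along(regressions)) {
    id <- names(regressions)[i]
    d <- regressions[[id]]$design
    fit <- rrpp_anova(d$y, d$X, d$terms,
                      iterations = cfg$rrpp_iterations,
                      seed = cfg$seed + 1000L + i)
    grp <- regressions[[id]]$table$locomotion
    rrpp_fits[[id]] <- fit
    rrpp_pw[[id]] <- rrpp_pairwise(fit, grp, d$X[, "pred1"])
  }
  anova_tab <- do.call(rbind, lapply(names(rrpp_fits), function(id) {
    cbind(regression = id, rrpp_fits[[id]]$table)
  }))
  utils::write.csv(anova_tab, file.path(cfg$out_dir, "rrpp_anova.csv"),
                   row.names = FALSE)
  write_rrpp_table(rrpp_pw, file.path(cfg$out_dir, "table3.csv"))

  # 6. continuous ASR (PL% on the pruned tree when a species lacks it)
  named <- function(v) stats::setNames(v, traits$species)
  # allometry residuals come out in the average tree's tip order
  resid_1eb <- stats::setNames(allom$fit$residuals, avg$tip.label)
  cont <- list(
    PEQ = peq,
    residual = resid_1eb,
    log10_brain = named(log10(traits$endocranial_volume)),
    log10_mass = named(log10(traits$body_mass)),
    OB_pct = named(pct$OB_pct),
    Neo_pct = named(pct$Neo_pct)
  )
  recon <- lapply(cont, function(tr) asr_continuous(avg, tr))
  write_asr_table(avg, recon, file.path(cfg$out_dir, "asr_nodes.csv"))
  pl <- named(pct$PL_pct)
  pl_missing <- names(pl)[is.na(pl)]
  tree_pl <- if (length(pl_missing)) prune_tree(avg, pl_missing) else avg
  recon_pl <- list(PL_pct = asr_continuous(tree_pl, pl[!is.na(pl)]))
  write_asr_table(tree_pl, recon_pl,
                  file.path(cfg$out_dir, "asr_nodes_pl.csv"))

  # 7. stochastic character maps
  loco <- stats::setNames(as.character(traits$locomotion), traits$species)
  simmap <- simmap_sample(avg, loco, n_maps = cfg$n_simmaps,
                          seed = cfg$seed + 2000L)
  utils::write.csv(
    data.frame(node = rownames(simmap$node_probs), simmap$node_probs,
               check.names = FALSE),
    file.path(cfg$out_dir, "simmap_nodes.csv"), row.names = FALSE)
  utils::write.csv(data.frame(map = seq_along(simmap$changes),
                              changes = simmap$changes),
                   file.path(cfg$out_dir, "simmap_changes.csv"),
                   row.names = FALSE)
  log_lines <- c(log_lines,
                 sprintf("simmap: q = %.5g, %d/%d edges used uniformization",
                         simmap$q, simmap$n_fallback,
                         nrow(avg$edge) * cfg$n_simmaps))
  writeLines(log_lines, logf)

  invisible(structure(list(
    trees = trees, average_tree = avg, allometry = allom, peq = peq,
    percentages = pct, permutation = blocks, regressions = regressions,
    rrpp = rrpp_fits, rrpp_pairwise = rrpp_pw, asr = recon,
    asr_pl = recon_pl, tree_pl = tree_pl, simmap = simmap,
    config = cfg), class = "analysis_bundle"))
}

#' Compare results across two topologies
#'
#' Runs the calibration, allometry, regression-selection and simmap
#' stages under each topology and reports side-by-side values with
#' absolute differences.
#'
#' @param cfg A [run_config()] (its `topology` is topology 1).
#' @param topology2 The alternate topology (`phylo` or Newick path).
#' @return A data.frame: quantity, value1, value2, abs_diff.
#' @export
compare_topologies <- function(cfg, topology2) {
  if (is.character(topology2)) {
    topology2 <- parse_newick(paste(readLines(topology2), collapse = ""))
  }
  one <- function(topo) {
    trees <- sample_calibrated_trees(topo, cfg$age_bins,
                                     n_trees = cfg$n_calibration_trees,
                                     master_seed = cfg$seed,
                                     mbl = cfg$mbl)
    avg <- average_tree(trees)
    allom <- fit_allometry(cfg$traits, avg)
    regs <- lapply(stats::setNames(REGRESSION_IDS, REGRESSION_IDS),
                   function(id) fit_regression(cfg$traits, avg, id))
    loco <- stats::setNames(as.character(cfg$traits$locomotion),
                            cfg$traits$species)
    sm <- simmap_sample(avg, loco, n_maps = max(100, cfg$n_simmaps %/% 10),
                        seed = cfg$seed + 2000L)
    vals <- c(allometry_a = allom$a, allometry_b = allom$b)
    for (id in REGRESSION_IDS) {
      vals[paste0(id, "_AIC")] <- regs[[id]]$fit$AIC
      vals[paste0(id, "_slope")] <- unname(regs[[id]]$fit$coefficients["pred1"])
      vals[paste0(id, "_lambda")] <- regs[[id]]$lambda
    }
    root_probs <- sm$node_probs[1, ]
    names(root_probs) <- paste0("root_p_", names(root_probs))
    c(vals, root_probs)
  }
  v1 <- one(cfg$topology)
  v2 <- one(topology2)
  common <- intersect(names(v1), names(v2))
  data.frame(quantity = common, value1 = v1[common], value2 = v2[common],
             abs_diff = abs(v1[common] - v2[common]), row.names = NULL)
}
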