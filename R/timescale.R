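# Stochastic time-calibration of a fixed topology from stratigraphic
# age bins. Calibration likelihoods that estimate branching, extinction
# and sampling rates are deliberately not used: tip ages are drawn
# uniformly within their first-appearance bins and node ages are built
# root-ward with a minimum branch length plus stochastic waiting
# increments. Downstream analyses consume only a dated tree, so this
# keeps the pipeline's interface without that rate machinery.

# Extant tips sit at age 0; this shared Pleistocene first-appearance bin
# is used only for feasibility checking of supplied age matrices.
PLEISTOCENE_BIN <- c(FAD_early = 2.58, FAD_late = 0.0117)

#' Assemble and validate an age-bin matrix
#'
#' One row per tip with first/last-appearance interval bounds in Ma
#' (older = larger). Extant tips carry zeros (or the shared Pleistocene
#' first-appearance bin).
#'
#' @param df A data.frame with columns `tip`, `FAD_early`, `FAD_late`,
#'   `LAD_early`, `LAD_late` (Ma).
#' @return The validated data.frame, class `age_bin_matrix`.
#' @export
age_bin_matrix <- function(df) {
  need <- c("tip", "FAD_early", "FAD_late", "LAD_early", "LAD_late")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("age-bin matrix missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[need]
  if (anyDuplicated(df$tip)) stop("duplicate tips in age-bin matrix",
                                  call. = FALSE)
  bad <- df$FAD_early < df$FAD_late | df$LAD_early < df$LAD_late |
    df$FAD_late < df$LAD_late | df$FAD_early < df$LAD_early
  if (any(bad)) {
    stop("inconsistent bounds (earliest >= latest, FAD >= LAD required) ",
         "for tips: ", paste(df$tip[bad], collapse = ", "), call. = FALSE)
  }
  if (any(df$LAD_late < 0)) stop("negative ages", call. = FALSE)
  class(df) <- c("age_bin_matrix", "data.frame")
  df
}

#' Read an age-bin matrix from CSV
#' @param path CSV with columns tip, FAD_early, FAD_late, LAD_early, LAD_late.
#' @return A validated `age_bin_matrix`.
#' @export
read_age_bins <- function(path) {
  age_bin_matrix(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Draw one time-calibrated tree from age bins
#'
#' Tip ages are sampled uniformly within each tip's first-appearance bin
#' (`FAD_early` to `FAD_late`); node ages are then assigned in
#' post-order as `max(child ages) + mbl + Exp(mean = incr_mean)`, so
#' every edge is at least `mbl` Myr long and node ages are strictly
#' monotone root-ward. Deterministic for a fixed `seed`.
#'
#' @param topology A rooted `phylo`; branch lengths, if present, are
#'   ignored.
#' @param ages An [age_bin_matrix()] covering every tip.
#' @param mbl Minimum branch length in Myr (> 0).
#' @param seed Integer seed.
#' @param incr_mean Mean of the exponential waiting increment added
#'   above the minimum, Myr.
#' @return A calibrated `phylo` with the same topology.
#' @export
sample_calibrated_tree <- function(topology, ages, mbl = 0.1, seed,
                                   incr_mean = 2) {
  stopifnot(inherits(ages, "age_bin_matrix"), mbl > 0, incr_mean >= 0)
  if (!missing(seed)) set.seed(as.integer(seed))
  tips <- topology$tip.label
  miss <- setdiff(tips, ages$tip)
  if (length(miss)) {
    stop("tips missing from age-bin matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  rows <- ages[match(tips, ages$tip), ]
  n <- ape::Ntip(topology)
  m <- topology$Nnode
  tip_age <- stats::runif(n, min = rows$FAD_late, max = rows$FAD_early)

  # node ages in ape numbering: 1..n tips, (n+1)..(n+m) internal
  node_age <- c(tip_age, rep(NA_real_, m))
  edge <- topology$edge
  # post-order: children before parents
  po <- ape::reorder.phylo(topology, "postorder")$edge
  for (k in seq_len(nrow(po))) {
    parent <- po[k, 1]; child <- po[k, 2]
    floor_age <- node_age[child] + mbl
    cand <- floor_age + stats::rexp(1, rate = 1 / incr_mean)
    if (is.na(node_age[parent]) || node_age[parent] < cand) {
      node_age[parent] <- cand
    }
    if (node_age[parent] < floor_age) node_age[parent] <- floor_age
  }
  out <- topology
  out$edge.length <- node_age[edge[, 1]] - node_age[edge[, 2]]
  if (any(out$edge.length < mbl - 1e-9)) {
    stop("internal error: edge below minimum branch length", call. = FALSE)
  }
  out$root.time <- node_age[n + 1]
  validate_phylogeny(out)
  out
}

#' Generate a set of calibrated trees from one master seed
#'
#' Per-tree seeds are `master_seed * 1000 + i` for tree i (a documented
#' counter scheme), so any single tree can be regenerated in isolation.
#'
#' @param topology,ages,mbl,incr_mean As in [sample_calibrated_tree()].
#' @param n_trees Number of trees (study default 100).
#' @param master_seed Integer master seed; keep below ~2e6 so derived
#'   seeds stay within integer range.
#' @return A list of `phylo` objects (class `multiPhylo`).
#' @export
sample_calibrated_trees <- function(topology, ages, n_trees = 100,
                                    master_seed, mbl = 0.1, incr_mean = 2) {
  trees <- lapply(seq_len(n_trees), function(i) {
    sample_calibrated_tree(topology, ages, mbl = mbl,
                           seed = (as.integer(master_seed) %% 2000000L) * 1000L + i,
                           incr_mean = incr_mean)
  })
  class(trees) <- "multiPhylo"
  trees
}

# node ages (Ma before present) for a calibrated tree, using the oldest
# tip--or root.time if set--as the anchor.
node_ages <- function(tree) {
  h <- node_heights(tree)
  anchor <- if (!is.null(tree$root.time)) tree$root.time else max(h)
  anchor - h
}

#' Average a set of calibrated trees on a shared topology
#'
#' Node ages are averaged arithmetically per node on the fixed topology
#' and edge lengths recomputed from the mean ages; monotonicity is
#' inherited from the inputs.
#'
#' @param trees A list/`multiPhylo` of calibrated trees with identical
#'   topologies (same edge matrix and tip labels).
#' @return A single calibrated `phylo`.
#' @export
average_tree <- function(trees) {
  stopifnot(length(trees) >= 1)
  ref <- trees[[1]]
  for (tr in trees) {
    if (!identical(tr$edge, ref$edge) ||
        !identical(tr$tip.label, ref$tip.label)) {
      stop("topology mismatch among input trees", call. = FALSE)
    }
  }
  ages <- rowMeans(vapply(trees, node_ages,
                          numeric(ape::Ntip(ref) + ref$Nnode)))
  out <- ref
  out$edge.length <- ages[ref$edge[, 1]] - ages[ref$edge[, 2]]
  out$root.time <- ages[ape::Ntip(ref) + 1]
  validate_phylogeny(out)
  out
}

#' Drop tips from a calibrated tree
#'
#' Removes the listed tips, suppresses the resulting degree-2 nodes and
#' preserves path lengths among the remaining tips (ape's `drop.tip`).
#'
#' @param tree A `phylo`.
#' @param drop Character vector of tip labels to remove.
#' @return The pruned `phylo`.
#' @export
prune_tree <- function(tree, drop) {
  if (length(drop) == 0) return(tree)
  unknown <- setdiff(drop, tree$tip.label)
  if (length(unknown)) {
    stop("tips not in tree: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(drop) >= ape::Ntip(tree)) {
    stop("cannot drop all tips", call. = FALSE)
  }
  out <- ape::drop.tip(tree, drop)
  out$root.time <- NULL  # anchor no longer well defined after pruning
  validate_phylogeny(out)
  out
}
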