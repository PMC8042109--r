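# Shared fixtures, all built in code.

three_tip <- function() parse_newick("((A:1,B:1):1,C:2);")

# brute-force shared-path matrix: pairwise MRCA depth by path walking
brute_shared_paths <- function(tree) {
  n <- ape::Ntip(tree)
  h <- node_heights(tree)
  parent_of <- integer(n + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  path_to_root <- function(i) {
    p <- i
    while (i != n + 1L) {
      i <- parent_of[i]
      p <- c(p, i)
    }
    p
  }
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    pi <- path_to_root(i)
    for (j in seq_len(n)) {
      mrca <- intersect(pi, path_to_root(j))[1]
      C[i, j] <- h[mrca]
    }
    C[i, i] <- h[i]
  }
  C
}

# random dated tree with given tip count
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.1
  tr
}

# quick all-extant age-bin matrix for a set of tips
extant_bins <- function(tips) {
  age_bin_matrix(data.frame(tip = tips, FAD_early = 0, FAD_late = 0,
                            LAD_early = 0, LAD_late = 0))
}

# tip ages anchored at the tree's recorded root age
node_ages_of <- function(tree) {
  stats::setNames(
    sciurognath:::node_ages(tree)[seq_len(ape::Ntip(tree))],
    tree$tip.label)
}

small_synth <- function(seed = 42, ...) {
  simulate_dataset(synth_config(seed = seed, ...))
}
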