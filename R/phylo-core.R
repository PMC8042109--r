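#' @keywords internal
"_PACKAGE"

# Trees are held as ape "phylo" objects throughout: tips are numbered
# 1..n in input order, the root is n+1 and internal nodes follow ape's
# cladewise numbering, which is stable across read/write round trips.

#' Parse a Newick string into a rooted phylogeny
#'
#' Thin, validating wrapper around [ape::read.tree()]. The tree must be
#' rooted, carry branch lengths (in Myr for this package's pipeline) and
#' have unique tip labels.
#'
#' @param text A Newick string (terminating `;` required).
#' @return An object of class `phylo`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tip_ages(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tree <- tryCatch(
    ape::read.tree(text = text),
    warning = function(w) NULL,
    error = function(e) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("malformed Newick string (near character ",
         newick_error_offset(text), "): could not parse", call. = FALSE)
  }
  validate_phylogeny(tree)
  tree
}

# Best-effort offset of the first structural problem, for error messages.
newick_error_offset <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) return(i)
  }
  if (depth != 0L) return(length(chars))
  length(chars)
}

#' Serialize a phylogeny to Newick
#'
#' @param tree A `phylo` object.
#' @param digits Number of significant digits for branch lengths.
#' @return A Newick string.
#' @export
write_newick <- function(tree, digits = 12) {
  validate_phylogeny(tree)
  ape::write.tree(tree, digits = digits)
}

#' Validate the package's phylogeny invariants
#'
#' Checks rootedness, unique tip labels, presence and non-negativity of
#' branch lengths, and reachability of all tips. Called by every consumer
#' of a tree; errors carry the offending labels.
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("negative or non-finite edge length", call. = FALSE)
  }
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup)) {
    stop("duplicate tip labels: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  # exactly one root node (basal polytomies, e.g. star trees, are fine)
  roots <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(roots) != 1L) {
    stop("tree must have a single root", call. = FALSE)
  }
  invisible(tree)
}

#' Node heights and tip ages
#'
#' `node_heights()` returns the distance from the root to every node
#' (tips first, ape numbering). `tip_ages()` converts heights to ages in
#' Myr before present, taking the deepest tip as age 0.
#'
#' @param tree A `phylo` object.
#' @return `node_heights()`: numeric vector over all nodes; `tip_ages()`:
#'   named numeric vector over tips.
#' @export
node_heights <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' @rdname node_heights
#' @export
tip_ages <- function(tree) {
  h <- node_heights(tree)
  n <- ape::Ntip(tree)
  ages <- max(h[seq_len(n)]) - h[seq_len(n)]
  names(ages) <- tree$tip.label
  ages
}

#' Shared-path (Brownian) covariance matrix
#'
#' C[i, j] is the height above the root of the most recent common
#' ancestor of tips i and j; the diagonal holds root-to-tip path
#' lengths. Under Brownian motion the trait covariance is sigma^2 * C.
#'
#' @param tree A `phylo` object with >= 2 tips.
#' @return A symmetric n x n matrix with tip labels as dimnames, Myr units.
#' @export
shared_path_matrix <- function(tree) {
  validate_phylogeny(tree)
  if (ape::Ntip(tree) < 2L) stop("need >= 2 tips", call. = FALSE)
  ape::vcv.phylo(tree)
}

#' Specify an evolutionary covariance model
#'
#' @param model One of `"brownian"`, `"lambda"`, `"early_burst"`, `"ou"`.
#' @param parameter Pagel's lambda in \[0, 1\] for `"lambda"`; rate-change
#'   exponent r <= 0 per Myr for `"early_burst"`; selection strength
#'   alpha > 0 per Myr for `"ou"`; ignored for `"brownian"`.
#' @return A list of class `cov_model_spec`.
#' @export
cov_model_spec <- function(model = c("brownian", "lambda", "early_burst", "ou"),
                           parameter = NULL) {
  model <- match.arg(model)
  if (model == "brownian") {
    parameter <- NULL
  } else {
    if (is.null(parameter) || !is.finite(parameter)) {
      stop("model '", model, "' requires a finite parameter", call. = FALSE)
    }
    ok <- switch(model,
      lambda      = parameter >= 0 && parameter <= 1,
      early_burst = parameter <= 0,
      ou          = parameter > 0
    )
    if (!ok) {
      stop("parameter ", format(parameter), " out of bounds for model '",
           model, "'", call. = FALSE)
    }
  }
  structure(list(model = model, parameter = parameter),
            class = "cov_model_spec")
}

#' Phylogenetic covariance under an evolutionary model
#'
#' Builds the among-tip covariance (up to the rate scalar sigma^2, which
#' is profiled out during fitting) implied by a model of trait evolution:
#' \describe{
#'   \item{brownian}{the shared-path matrix C.}
#'   \item{lambda}{C with off-diagonals multiplied by lambda, diagonal
#'     unchanged.}
#'   \item{early_burst}{each edge spanning root-height interval
#'     \[t0, t1\] is rescaled to (exp(r t1) - exp(r t0)) / r before
#'     computing C; the r -> 0 limit recovers Brownian motion.}
#'   \item{ou}{the stationary correlation exp(-alpha * d_ij) with unit
#'     diagonal, where d is the patristic distance. This convention (that
#'     of nlme's Martins-Hansen correlation structure) is well defined on
#'     non-ultrametric, fossil-bearing trees; other OU parameterizations
#'     exist and differ away from ultrametricity.}
#' }
#'
#' @param tree A `phylo` object.
#' @param spec A [cov_model_spec()].
#' @return A symmetric positive semi-definite matrix with tip dimnames.
#' @export
model_covariance <- function(tree, spec) {
  stopifnot(inherits(spec, "cov_model_spec"))
  validate_phylogeny(tree)
  switch(spec$model,
    brownian = shared_path_matrix(tree),
    lambda = {
      C <- shared_path_matrix(tree)
      d <- diag(C)
      C <- C * spec$parameter
      diag(C) <- d
      C
    },
    early_burst = {
      r <- spec$parameter
      tr <- tree
      if (abs(r) > 1e-12) {
        h <- node_heights(tree)
        t0 <- h[tree$edge[, 1]]
        t1 <- h[tree$edge[, 2]]
        tr$edge.length <- (exp(r * t1) - exp(r * t0)) / r
      }
      V <- ape::vcv.phylo(tr)
      dimnames(V) <- list(tree$tip.label, tree$tip.label)
      V
    },
    ou = {
      D <- stats::cophenetic(tree)
      D <- D[tree$tip.label, tree$tip.label]
      V <- exp(-spec$parameter * D)
      diag(V) <- 1
      V
    }
  )
}

#' Export a labelled covariance matrix as CSV
#'
#' @param V A matrix with dimnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_covariance_csv <- function(V, path) {
  utils::write.csv(as.data.frame(V), path, row.names = TRUE)
  invisible(path)
}
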