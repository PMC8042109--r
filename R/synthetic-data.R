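# Study-shaped synthetic datasets with known ground truth: a
# birth-death tree with 25 extant and 13 fossil tips, a five-state
# locomotor character evolving under an equal-rates Markov process, and
# log-scale brain traits built as allometry + locomotor offsets +
# phylogenetically correlated (lambda-transformed) noise. Component
# traits (OB%, PL%, Neo%) are simulated on the logit of the percentage
# so the (0, 100) bounds hold by construction. The numeric anchors
# (slope 0.57, lambda 0.72, residual SD 0.103, root baselines
# Neo 18.3%, PL 1.25%, OB 5.8%) are the study conditions the generator
# emulates; they are defaults, not dials.

#' Configuration for the synthetic-data generator
#'
#' @param n_extant,n_fossil Tip counts (defaults 25 and 13).
#' @param birth,death Birth-death rates per Myr.
#' @param origin Age of the root, Ma.
#' @param fossil_window Admissible extinction ages for fossil tips, Ma
#'   (Eocene-Miocene by default).
#' @param q_true Equal-rates transition rate of the locomotor
#'   character, per Myr.
#' @param a_true,b_true Allometric coefficient (mm^3 g^-b) and exponent.
#' @param lambda_true Pagel's lambda of the residual covariance.
#' @param resid_sd Residual SD of the log10 allometry.
#' @param loco_offsets Named offsets (log10 units) added to the brain
#'   allometry per locomotor category; defaults are -2 residual SD for
#'   fossorial, +1 residual SD for arboreal, 0 otherwise.
#' @param root_pct Root-state percentages for OB, PL and Neo.
#' @param pct_logit_sd Tip SD of the logit-scale component noise.
#' @param pct_offsets Per-category logit offsets for each component
#'   (list with elements OB, PL, Neo of named vectors).
#' @param mass_root log10 body mass at the root (g).
#' @param mass_tip_sd Target tip SD of log10 body mass under BM.
#' @param missing_pl Give one glider tip a missing petrosal-lobule
#'   volume (emulating the study's 37-species petrosal subset).
#' @param require_all_categories Resample the locomotor character until
#'   all five categories are observed (the study sample contains all
#'   five); disable for experiments at very small `q_true`.
#' @param seed Master seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_extant = 25, n_fossil = 13,
                         birth = 0.12, death = 0.06,
                         origin = 53,
                         fossil_window = c(5, 50),
                         q_true = 0.01,
                         a_true = 0.42, b_true = 0.57,
                         lambda_true = 0.72, resid_sd = 0.103,
                         loco_offsets = c(arboreal = 0.103,
                                          fossorial = -0.206,
                                          glider = 0, scansorial = 0,
                                          terrestrial = 0),
                         root_pct = c(OB = 5.8, PL = 1.25, Neo = 18.3),
                         pct_logit_sd = 0.25,
                         pct_offsets = list(
                           OB  = c(arboreal = -0.10, fossorial = 0.15,
                                   glider = 0, scansorial = 0,
                                   terrestrial = 0),
                           PL  = c(arboreal = 0.15, fossorial = -0.30,
                                   glider = -0.10, scansorial = 0,
                                   terrestrial = 0),
                           Neo = c(arboreal = 0.15, fossorial = -0.30,
                                   glider = 0, scansorial = 0,
                                   terrestrial = 0)),
                         mass_root = 2.5, mass_tip_sd = 0.5,
                         missing_pl = TRUE,
                         require_all_categories = TRUE,
                         seed = 1) {
  stopifnot(birth > 0, death >= 0, b_true > 0, b_true < 1,
            q_true > 0, resid_sd >= 0, all(is.finite(loco_offsets)))
  structure(as.list(environment()), class = "synth_config")
}

# draw a birth-death tree with the required extant/fossil tip counts,
# with bounded retries
synth_tree <- function(cfg, max_attempts = 200) {
  for (att in seq_len(max_attempts)) {
    full <- ape::rlineage(cfg$birth, cfg$death, Tmax = cfg$origin)
    if (is.null(full) || !inherits(full, "phylo") ||
        ape::Ntip(full) < cfg$n_extant + cfg$n_fossil) next
    ages <- tip_ages(full)
    extant <- names(ages)[ages < 1e-8]
    fossil <- names(ages)[ages >= cfg$fossil_window[1] &
                          ages <= cfg$fossil_window[2]]
    if (length(extant) < cfg$n_extant || length(fossil) < cfg$n_fossil)
      next
    keep <- c(sample(extant, cfg$n_extant), sample(fossil, cfg$n_fossil))
    tree <- ape::keep.tip(full, keep)
    tree$tip.label <- sprintf("sp%02d", seq_len(ape::Ntip(tree)))
    tree$root.time <- max(node_heights(tree))
    return(tree)
  }
  stop("could not realize ", cfg$n_extant, " extant + ", cfg$n_fossil,
       " fossil tips in ", max_attempts,
       " attempts; adjust birth/death rates", call. = FALSE)
}

# simulate the ER locomotor character down the tree, retrying until all
# five categories are observed (the study sample contains all five)
synth_locomotion <- function(tree, q, max_attempts = 500,
                             require_all = TRUE) {
  k <- length(LOCOMOTOR_LEVELS)
  n <- ape::Ntip(tree)
  pre <- ape::reorder.phylo(tree, "cladewise")
  if (!require_all) max_attempts <- 1L
  for (att in seq_len(max_attempts)) {
    node_state <- integer(n + tree$Nnode)
    node_state[n + 1L] <- sample.int(k, 1)
    n_changes <- 0L
    for (e in seq_len(nrow(pre$edge))) {
      u <- pre$edge[e, 1]; v <- pre$edge[e, 2]
      path <- er_simulate_path(node_state[u], pre$edge.length[e], q, k)
      node_state[v] <- path$end
      n_changes <- n_changes + length(path$states)
    }
    tip_states <- node_state[seq_len(n)]
    if (!require_all || length(unique(tip_states)) == k) {
      return(list(
        tips = stats::setNames(LOCOMOTOR_LEVELS[tip_states],
                               tree$tip.label),
        node_states = stats::setNames(
          LOCOMOTOR_LEVELS[node_state[n + seq_len(tree$Nnode)]],
          as.character(n + seq_len(tree$Nnode))),
        n_changes = n_changes
      ))
    }
  }
  stop("locomotor simulation never produced all five categories; ",
       "increase q_true", call. = FALSE)
}

# correlated noise: z ~ MVN(0, sd^2 * Vlam / mean(diag(Vlam)))
lambda_noise <- function(tree, lambda, sd) {
  V <- model_covariance(tree, cov_model_spec("lambda", lambda))
  V <- V / mean(diag(V))
  as.numeric(t(chol_jitter(V)) %*% stats::rnorm(ape::Ntip(tree))) * sd
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Simulate a complete study-shaped dataset
#'
#' @param cfg A [synth_config()].
#' @return A list: `tree` (true calibrated tree), `age_bins`
#'   ([age_bin_matrix()]), `traits` ([trait_table()]), `truth` (latent
#'   values: locomotor node states and change count, true residuals,
#'   per-component root logits, generator parameters).
#' @export
simulate_dataset <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(as.integer(cfg$seed))
  tree <- synth_tree(cfg)
  n <- ape::Ntip(tree)
  ages <- tip_ages(tree)
  status <- ifelse(ages < 1e-8, "extant", "extinct")
  ages[status == "extant"] <- 0

  loco <- synth_locomotion(tree, cfg$q_true,
                           require_all = cfg$require_all_categories)

  # body mass: BM with tip SD scaled to mass_tip_sd
  C <- shared_path_matrix(tree)
  bm_scale <- cfg$mass_tip_sd / sqrt(mean(diag(C)))
  log_mass <- cfg$mass_root +
    as.numeric(t(chol_jitter(C)) %*% stats::rnorm(n)) * bm_scale
  names(log_mass) <- tree$tip.label

  # endocranial volume: allometry + category offset + lambda noise
  resid <- lambda_noise(tree, cfg$lambda_true, cfg$resid_sd)
  offs <- cfg$loco_offsets[loco$tips]
  log_E <- log10(cfg$a_true) + cfg$b_true * log_mass + offs + resid
  E <- 10^log_E

  # endocranial surface from volume (spheroid scaling, mild noise)
  log_SAE <- log10(4.836) + (2 / 3) * log_E + stats::rnorm(n, 0, 0.02)
  SAE <- 10^log_SAE

  # component percentages on logit scale
  pct <- lapply(c(OB = "OB", PL = "PL", Neo = "Neo"), function(cmp) {
    root_logit <- logit(cfg$root_pct[[cmp]] / 100)
    x <- root_logit + cfg$pct_offsets[[cmp]][loco$tips] +
      lambda_noise(tree, cfg$lambda_true, cfg$pct_logit_sd)
    100 * inv_logit(x)
  })

  V_OB <- E * pct$OB / 100
  V_PL <- E * pct$PL / 100
  SA_N <- SAE * pct$Neo / 100
  if (cfg$missing_pl) {
    gliders <- which(loco$tips == "glider" & status == "extant")
    if (!length(gliders)) gliders <- which(status == "extant")
    V_PL[gliders[1]] <- NA_real_
  }

  traits <- trait_table(data.frame(
    species = tree$tip.label,
    status = status,
    locomotion = unname(loco$tips),
    body_mass = 10^log_mass,
    endocranial_volume = E,
    endocranial_surface = SAE,
    neocortex_surface = SA_N,
    olfactory_bulb_volume = V_OB,
    petrosal_lobule_volume = V_PL
  ))

  # age bins: fossils get 2-5 Myr bins containing the true age
  w_up <- stats::runif(n, 1, 2.5)
  w_dn <- stats::runif(n, 1, 2.5)
  fad_early <- ifelse(status == "extant", 0, ages + w_up)
  fad_late  <- ifelse(status == "extant", 0, pmax(ages - w_dn, 0))
  bins <- age_bin_matrix(data.frame(
    tip = tree$tip.label,
    FAD_early = fad_early, FAD_late = fad_late,
    LAD_early = fad_late, LAD_late = pmax(fad_late - 0.5, 0)
  ))

  list(tree = tree, age_bins = bins, traits = traits,
       truth = list(
         locomotion_nodes = loco$node_states,
         locomotion_changes = loco$n_changes,
         residuals = stats::setNames(resid, tree$tip.label),
         tip_ages = ages,
         a = cfg$a_true, b = cfg$b_true, lambda = cfg$lambda_true,
         resid_sd = cfg$resid_sd, root_pct = cfg$root_pct,
         config = cfg))
}

#' Write a simulated dataset to disk in pipeline formats
#'
#' Tree as Newick, traits and age bins as CSV, truth record as a
#' separate CSV that the pipeline never reads.
#'
#' @param ds A [simulate_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cat(write_newick(ds$tree), "\n", sep = "",
      file = file.path(dir, "tree.nwk"))
  write_trait_table(ds$traits, file.path(dir, "traits.csv"))
  utils::write.csv(as.data.frame(ds$age_bins),
                   file.path(dir, "age_bins.csv"), row.names = FALSE)
  truth <- data.frame(species = names(ds$truth$residuals),
                      true_residual = ds$truth$residuals,
                      true_age = ds$truth$tip_ages)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Hand-sized six-tip fixture for oracle tests
#'
#' A fixed tree and trait values small enough that permutation
#' enumeration and explicit matrix inversion are practical.
#'
#' @return A list: `tree`, `traits`, `groups`.
#' @export
fixture_small <- function() {
  tree <- parse_newick(
    "(((A:2,B:2):3,(C:1,D:1):4):5,(E:4,F:4):6);")
  traits <- trait_table(data.frame(
    species = LETTERS[1:6],
    status = "extant",
    locomotion = c("arboreal", "arboreal", "arboreal",
                   "fossorial", "fossorial", "fossorial"),
    body_mass = c(120, 150, 300, 450, 800, 1000),
    endocranial_volume = c(1800, 2100, 3400, 3900, 5600, 6400),
    endocranial_surface = c(710, 790, 1090, 1200, 1530, 1680),
    neocortex_surface = c(240, 260, 340, 300, 370, 400),
    olfactory_bulb_volume = c(95, 110, 180, 260, 350, 410),
    petrosal_lobule_volume = c(24, 28, 44, 40, 56, 62)
  ))
  list(tree = tree, traits = traits,
       groups = stats::setNames(traits$locomotion, traits$species))
}
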