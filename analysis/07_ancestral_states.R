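#!/usr/bin/env Rscript
# Stage 7: ancestral reconstruction. Continuous traits (PEQ, allometric
# residuals, log10 brain and body size, component percentages) are
# reconstructed by maximum likelihood under Brownian motion; the
# petrosal percentage uses the tree pruned of the species lacking that
# measurement. The five-state locomotor character is reconstructed by
# stochastic character mapping: an equal-rates Markov model fitted by
# ML, then 1000 maps sampled conditional on the tip states.

suppressMessages(library(sciurognath))

MASTER_SEED <- 2026L
traits <- read_trait_table("results/data/traits.csv")
avg <- parse_newick(paste(readLines("results/trees/average.nwk"),
                          collapse = ""))
peq_tab <- read.csv("results/peq.csv")
pct <- compute_percentages(traits)

allom <- fit_allometry(traits, avg)
resid <- stats::setNames(allom$fit$residuals, avg$tip.label)
named <- function(v) stats::setNames(v, traits$species)

cont <- list(
  PEQ = named(peq_tab$PEQ[match(traits$species, peq_tab$species)]),
  residual = resid,
  log10_brain = named(log10(traits$endocranial_volume)),
  log10_mass = named(log10(traits$body_mass)),
  OB_pct = named(pct$OB_pct),
  Neo_pct = named(pct$Neo_pct)
)
recon <- lapply(cont, function(x) asr_continuous(avg, x))
write_asr_table(avg, recon, "results/asr_nodes.csv")

pl <- named(pct$PL_pct)
tree_pl <- prune_tree(avg, names(pl)[is.na(pl)])
recon_pl <- list(PL_pct = asr_continuous(tree_pl, pl[!is.na(pl)]))
write_asr_table(tree_pl, recon_pl, "results/asr_nodes_pl.csv")

root <- as.character(ape::Ntip(avg) + 1L)
cat(sprintf("Root reconstruction: Neo %.1f%%, OB %.1f%%, PL %.2f%%, PEQ %.2f\n",
            recon$Neo_pct[root], recon$OB_pct[root],
            recon_pl$PL_pct[as.character(ape::Ntip(tree_pl) + 1L)],
            recon$PEQ[root]))

loco <- stats::setNames(as.character(traits$locomotion), traits$species)
sm <- simmap_sample(avg, loco, n_maps = 1000, seed = MASTER_SEED + 2000L)
write.csv(data.frame(node = rownames(sm$node_probs), sm$node_probs,
                     check.names = FALSE),
          "results/simmap_nodes.csv", row.names = FALSE)
write.csv(data.frame(map = seq_along(sm$changes), changes = sm$changes),
          "results/simmap_changes.csv", row.names = FALSE)
cat(sprintf("Mk-ER rate q = %.4g /Myr; mean %.1f state changes per map\n",
            sm$q, mean(sm$changes)))
cat("Root state probabilities:\n")
print(round(sm$node_probs[1, ], 3))
cat("Wrote results/asr_nodes*.csv, results/simmap_*.csv\n")
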