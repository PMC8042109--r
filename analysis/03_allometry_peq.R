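#!/usr/bin/env Rscript
# Stage 3: the phylogenetic allometry and encephalization quotients.
# PGLS of log10 endocranial volume on log10 body mass (AIC-selected
# covariance model) defines the expected brain size E_c = a M^b; PEQ is
# the observed/expected ratio, and the classical Jerison EQ
# (E_c = 0.12 M^0.67) is exported alongside for comparison.

suppressMessages(library(sciurognath))

traits <- read_trait_table("results/data/traits.csv")
avg <- parse_newick(paste(readLines("results/trees/average.nwk"),
                          collapse = ""))

allom <- fit_allometry(traits, avg)
print(allom)

tab <- write_peq_table(traits, allom, "results/peq.csv")
cat(sprintf("PEQ range %.2f-%.2f; highest: %s, lowest: %s\n",
            min(tab$PEQ), max(tab$PEQ),
            tab$species[which.max(tab$PEQ)],
            tab$species[which.min(tab$PEQ)]))
cat("Wrote results/peq.csv\n")
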