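#!/usr/bin/env Rscript
# Randomized-sequence null test: are the unassigned ORFs of the M genome
# distinguishable from unrelated sequence when compared with the seven
# nadh genes of the F reference? Each pair's observed amino-acid
# p-distance is ranked against distances to shuffled copies.

suppressMessages(library(mitocomp))

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 7L
m <- read_genbank("results/data/M_sim.gb")
f <- read_genbank("results/data/F_sim.gb")

orfs <- names(Filter(function(x) x$kind == "ORF", m$features))
nadh <- grep("^nad", names(f$features), value = TRUE)
grid <- homology_screen(m, orfs, f, nadh, n_reps = 99, seed = seed)

dir.create("results", showWarnings = FALSE)
write.table(grid, "results/homology_grid.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

n_sup <- sum(grid$verdict == "homology-supported")
message(sprintf("%d ORF x nadh pairs screened; %d homology-supported at Bonferroni-corrected alpha = 0.05",
                nrow(grid), n_sup))
message(sprintf("observed aa distances %.3f-%.3f vs null means %.3f-%.3f",
                min(grid$observed_d), max(grid$observed_d),
                min(grid$null_mean), max(grid$null_mean)))
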