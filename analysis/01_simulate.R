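#!/usr/bin/env Rscript
# Stage 1 — build the synthetic world: an annotated circular genome with
# AT islands / essential genes / ribosomal operons, an insertion landscape
# with dosage + AT biases, and a clone cohort with single-cell expression.
# Writes the standard-format inputs consumed by the later stages.

suppressPackageStartupMessages(library(insertionfate))

seed <- 1234
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synth_config()
ag <- make_genome(cfg, seed = seed)
cat("genome:", format(ag$genome$length_bp, big.mark = ","), "bp;",
    length(ag$intervals$hns_targets), "AT islands,",
    length(ag$intervals$essential), "essential genes,",
    length(ag$intervals$rrn), "ribosomal operons\n")

write_genome_sequence(ag$sequence, file.path(out, "genome.fasta"))
stamp <- c(paste0("seed=", seed), paste0("alpha=", cfg$insertions$alpha))
for (nm in names(ag$intervals)) {
  write_intervals(ag$intervals[[nm]], file.path(out, paste0(nm, ".bed")),
                  comments = stamp)
}

coh <- clone_cohort(ag, cfg, seed = seed)
phen <- coh$phenotypes
print(phen)
write_insertions(population_insertions(phen, rep(1 / phen$n, phen$n),
                                       genome = ag$genome),
                 file.path(out, "insertions.tsv"), comments = stamp)

# per-cell table for a manageable subset of clones (all three classes)
pick <- unlist(lapply(split(seq_len(phen$n), phen$class), head, 60))
cells <- do.call(rbind, lapply(pick, function(i) {
  cl <- coh$clones[[i]]
  data.frame(clone_id = cl$clone_id, cell_id = seq_along(cl$cells),
             fluorescence = round(cl$cells, 3), medium = cl$medium,
             growth_rate = cl$growth_rate)
}))
write_cells(cells, file.path(out, "cells_subset.tsv"), comments = stamp)
cat("wrote", file.path(out, "cells_subset.tsv"), "with",
    length(pick), "clones\n")
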