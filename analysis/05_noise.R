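#!/usr/bin/env Rscript
# Stage 5 — clone-level expression noise: sd-vs-mean scaling, robust
# steep-noise outlier classification, the copy-number closed loop, and the
# growth-rate trend separating switching clones from ordinary ones.

suppressPackageStartupMessages(library(insertionfate))

seed <- 1234
cfg <- synth_config()

cells <- read_cells("results/data/cells_subset.tsv")
st <- do.call(rbind, lapply(split(cells, cells$clone_id), function(d) {
  clone_stats(d$fluorescence, d$clone_id[1])
}))
fit <- fit_noise_scaling(st)
print(fit)
st$outlier <- st$clone_id %in% fit$outlier_ids
# the steep-noise outliers should be the switching (and multi-insertion)
# clones; check against the generated classes
cfg_tmp <- synth_config()
ag_tmp <- make_genome(cfg_tmp, seed = seed)
coh_tmp <- clone_cohort(ag_tmp, cfg_tmp, seed = seed)
cls <- coh_tmp$phenotypes$class[match(st$clone_id, coh_tmp$phenotypes$clone_id)]
cat("outliers by clone class:\n")
print(table(class = cls, outlier = st$outlier))
insertionfate:::write_tsv_commented(st, "results/clone_noise_stats.tsv",
                                    paste0("seed=", seed))

# growth-rate trend per class, across the two media
ag <- make_genome(cfg, seed = seed)
coh <- clone_cohort(ag, cfg, seed = seed)
phen <- coh$phenotypes
gr <- cfg$expression$media$growth_rate
trend_rows <- lapply(c("normal", "rrn_switching"), function(cls) {
  idx <- head(which(phen$class == cls), 20)
  means <- vapply(cfg$expression$media$medium, function(med) {
    mean(vapply(idx, function(i) {
      rec <- insertionfate:::clone_record(phen, i)
      mean(sample_cell_expression(rec, 300, med, cfg,
                                  seed = derive_seed(seed, paste0(med, i)))$cells)
    }, numeric(1)))
  }, numeric(1))
  tr <- growth_trend(gr, means)
  cat(sprintf("%-14s mean expression %s with growth rate (slope %.1f)\n",
              cls, tr$label, tr$slope))
  data.frame(class = cls, slope = tr$slope, label = tr$label)
})
insertionfate:::write_tsv_commented(do.call(rbind, trend_rows),
                                    "results/growth_trend.tsv",
                                    paste0("seed=", seed))
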