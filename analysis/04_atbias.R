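#!/usr/bin/env Rscript
# Stage 4 — AT-content bias: one-tailed Kolmogorov-Smirnov comparison of
# the AT fraction in 1 kb windows around insertions against uniformly
# sampled background windows.

suppressPackageStartupMessages(library(insertionfate))

seed <- 1234
cfg <- synth_config()
g <- genome_spec(cfg$genome$length_bp, cfg$genome$ori_pos, cfg$genome$ter_pos)
gen_seq <- read_genome_sequence("results/data/genome.fasta")
ins <- read_insertions("results/data/insertions.tsv", g)

ks <- insertion_at_bias_test(ins, gen_seq, g, window_bp = 1000,
                             n_background = length(ins), seed = seed)
print(ks)
cat(sprintf("insertion windows are AT-richer than background: D = %.3f, log10 p = %.1f\n",
            ks$d_stat, ks$log10_p))

insertionfate:::write_tsv_commented(
  data.frame(d_stat = ks$d_stat, p_value = ks$p_value, log10_p = ks$log10_p,
             n_insertion = ks$n_insertion, n_background = ks$n_background,
             window_bp = ks$window_bp),
  "results/at_bias.tsv", paste0("seed=", seed))
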