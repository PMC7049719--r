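# End-to-end orchestration: runs the enabled stages in dependency order
# (simulate -> coverage -> dosage_fit -> enrich -> atbias -> noise ->
# lineage), writes every stage output as commented TSV under the output
# directory, and records a manifest with md5 checksums so reruns can be
# verified byte-identical. One master seed; per-stage substreams are
# derived with derive_seed(seed, stage), so stage reordering cannot change
# results.

#' Pipeline configuration
#'
#' @param outdir Output directory (created if missing).
#' @param seed Master seed; every stage derives its own substream.
#' @param config A [synth_config()] defining the synthetic world.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "coverage", "dosage_fit", "enrich", "atbias", "noise",
#'   "lineage")` (default: all). Stages are always executed in dependency
#'   order regardless of the order given.
#' @param insertions_path,fasta_path Optional paths to externally provided
#'   inputs, used when `"simulate"` is not among the stages.
#' @param n_shuffles Shuffle count for the enrichment stage (default 5000).
#' @param n_colonies Microcolonies per clone class for the lineage stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1, config = synth_config(),
                            stages = c("simulate", "coverage", "dosage_fit",
                                       "enrich", "atbias", "noise", "lineage"),
                            insertions_path = NULL, fasta_path = NULL,
                            n_shuffles = 5000, n_colonies = 5) {
  order <- c("simulate", "coverage", "dosage_fit", "enrich", "atbias",
             "noise", "lineage")
  abort_if(!all(stages %in% order), "unknown stage name",
           class = "insertionfate_validation_error")
  structure(list(outdir = outdir, seed = as.integer(seed), config = config,
                 stages = order[order %in% stages],
                 insertions_path = insertions_path, fasta_path = fasta_path,
                 n_shuffles = n_shuffles, n_colonies = n_colonies),
            class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order and writes a manifest
#' (`manifest.tsv`: stage, file, md5) plus one TSV per stage output.
#' Identical configuration + seed reproduce byte-identical outputs.
#'
#' @param pcfg A [pipeline_config()].
#' @return Invisibly, the manifest data frame.
#' @export
run_pipeline <- function(pcfg) {
  dir.create(pcfg$outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- pcfg$config
  seed <- pcfg$seed
  stamp <- c(paste0("seed=", seed),
             paste0("genome_length_bp=", cfg$genome$length_bp),
             paste0("alpha=", cfg$insertions$alpha))
  outputs <- list()
  add_out <- function(stage, path) outputs[[length(outputs) + 1L]] <<-
    data.frame(stage = stage, file = basename(path), stringsAsFactors = FALSE)
  p <- function(f) file.path(pcfg$outdir, f)
  on <- function(s) s %in% pcfg$stages

  agenome <- NULL; ins <- NULL; cohort <- NULL
  if (on("simulate")) {
    agenome <- make_genome(cfg, seed = derive_seed(seed, "simulate"))
    ins <- sample_insertions(agenome, cfg, seed = derive_seed(seed, "simulate"))
    write_genome_sequence(agenome$sequence, p("genome.fasta"))
    add_out("simulate", p("genome.fasta"))
    for (nm in names(agenome$intervals)) {
      write_intervals(agenome$intervals[[nm]], p(paste0(nm, ".bed")),
                      comments = stamp)
      add_out("simulate", p(paste0(nm, ".bed")))
    }
    write_insertions(ins, p("insertions.tsv"), comments = stamp)
    add_out("simulate", p("insertions.tsv"))
  } else {
    abort_if(is.null(pcfg$insertions_path) &&
               any(vapply(c("coverage", "dosage_fit", "enrich", "atbias"),
                          on, logical(1))),
             "stage requires insertions: enable 'simulate' or give insertions_path",
             class = "insertionfate_stage_error")
    if (!is.null(pcfg$insertions_path)) {
      g <- genome_spec(cfg$genome$length_bp, cfg$genome$ori_pos,
                       cfg$genome$ter_pos)
      ins <- read_insertions(pcfg$insertions_path, g)
      agenome <- list(genome = g,
                      sequence = if (!is.null(pcfg$fasta_path))
                        read_genome_sequence(pcfg$fasta_path) else NULL,
                      intervals = list())
    }
  }

  profile <- NULL
  if (on("coverage")) {
    profile <- sliding_coverage(ins, agenome$genome)
    asym <- oriter_asymmetry(profile, agenome$genome)
    write_tsv_commented(
      data.frame(bin_start = profile$centers - floor(profile$window_bp / 2),
                 bin_center = profile$centers, value = profile$values),
      p("coverage.tsv"), c(stamp, paste0("oriter_asymmetry=", signif(asym, 6))))
    add_out("coverage", p("coverage.tsv"))
  }

  if (on("dosage_fit")) {
    step <- 3000
    centers <- seq(step / 2, agenome$genome$length_bp - 1, by = step)
    obs <- sliding_coverage(ins, agenome$genome, window_bp = step, step_bp = step)
    pred <- dosage_profile(agenome$genome, cfg$dosage, centers = obs$centers)
    fit <- fit_dosage_exponent(obs, pred)
    write_tsv_commented(
      data.frame(alpha = fit$alpha, alpha_stderr = fit$alpha_stderr,
                 intercept = fit$intercept, n_bins = fit$n_bins,
                 n_dropped = fit$n_dropped),
      p("dosage_fit.tsv"), stamp)
    add_out("dosage_fit", p("dosage_fit.tsv"))
  }

  if (on("enrich")) {
    abort_if(!length(agenome$intervals),
             "stage 'enrich' requires gene lists from the simulate stage",
             class = "insertionfate_stage_error")
    background <- sliding_coverage(ins, agenome$genome)
    rows <- lapply(names(agenome$intervals), function(nm) {
      r <- enrichment_z(ins, agenome$intervals[[nm]], agenome$genome,
                        background, n_shuffles = pcfg$n_shuffles,
                        seed = derive_seed(seed, paste0("enrich:", nm)))
      data.frame(list_name = nm, observed = r$observed, null_mean = r$null_mean,
                 null_sd = r$null_sd, z = r$z, p_emp = r$p_emp,
                 n_shuffles = r$n_shuffles, degenerate = r$degenerate)
    })
    write_tsv_commented(do.call(rbind, rows), p("enrichment.tsv"), stamp)
    add_out("enrich", p("enrichment.tsv"))
  }

  if (on("atbias")) {
    abort_if(is.null(agenome$sequence),
             "stage 'atbias' requires a genome sequence",
             class = "insertionfate_stage_error")
    ks <- insertion_at_bias_test(ins, agenome$sequence, agenome$genome,
                                 seed = derive_seed(seed, "atbias"))
    write_tsv_commented(
      data.frame(d_stat = ks$d_stat, p_value = ks$p_value,
                 n_insertion = ks$n_insertion, n_background = ks$n_background,
                 window_bp = ks$window_bp),
      p("atbias.tsv"), stamp)
    add_out("atbias", p("atbias.tsv"))
  }

  if (on("noise")) {
    abort_if(!on("simulate"), "stage 'noise' requires the simulate stage",
             class = "insertionfate_stage_error")
    cohort <- clone_cohort(agenome, cfg, seed = derive_seed(seed, "noise"))
    st <- cohort_stats(cohort$clones)
    fit <- fit_noise_scaling(st)
    st$outlier <- st$clone_id %in% fit$outlier_ids
    write_tsv_commented(st, p("clone_stats.tsv"), stamp)
    write_tsv_commented(
      data.frame(slope_c = fit$slope_c, residual_scale = fit$residual_scale,
                 free_slope = fit$free_slope, n_clones = fit$n_clones,
                 n_outliers = length(fit$outlier_ids)),
      p("noise_fit.tsv"), stamp)
    add_out("noise", p("clone_stats.tsv"))
    add_out("noise", p("noise_fit.tsv"))
  }

  if (on("lineage")) {
    abort_if(is.null(cohort), "stage 'lineage' requires the noise stage",
             class = "insertionfate_stage_error")
    phen <- cohort$phenotypes
    pick <- function(cls) which(phen$class == cls)[seq_len(pcfg$n_colonies)]
    rows <- list()
    for (cls in c("normal", "rrn_switching")) {
      idx <- pick(cls)
      idx <- idx[!is.na(idx)]
      for (i in idx) {
        tr <- simulate_microcolony(clone_record(phen, i), cfg,
                                   seed = derive_seed(seed, paste0("lineage:", i)))
        dv <- sister_divergence(tr)
        rows[[length(rows) + 1L]] <- data.frame(
          colony_id = dv$colony_id, class = cls,
          divergence = dv$colony_divergence, n_pairs = dv$n_pairs)
      }
    }
    write_tsv_commented(do.call(rbind, rows), p("lineage_divergence.tsv"), stamp)
    add_out("lineage", p("lineage_divergence.tsv"))
  }

  manifest <- do.call(rbind, outputs)
  manifest$md5 <- unname(tools::md5sum(file.path(pcfg$outdir, manifest$file)))
  write_tsv_commented(manifest, file.path(pcfg$outdir, "manifest.tsv"), stamp)
  invisible(manifest)
}
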