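# Configuration of the synthetic world: a scaled-down circular genome with
# AT-rich islands (identified with silencer-protein binding tracts in this
# synthetic world), essential genes, seven ribosomal operons, a
# dosage/AT-biased insertion landscape, clone expression with extrinsic
# noise plus a telegraph-switching subpopulation, sorting gates, and
# microcolony lineages.

#' Configuration for the synthetic-data generator
#'
#' Returns the full default configuration, with any field overridable by
#' name (nested fields via the group lists). Defaults define the study
#' conditions the generators emulate: a 500 kb circular genome (a
#' scaled-down chromosome that keeps every stage fast; the full 4.6 Mb is
#' supported by configuration), canonical fast-growth cell-cycle
#' parameters (C = 40, D = 20, tau = 30 min), an insertion-density
#' exponent of 3 on dosage, AT-island attraction, strong depletion inside
#' essential genes, seven ribosomal operons, extrinsic noise CV 0.3, a
#' slow telegraph switch (stable off state) for ribosomal-interference
#' clones, and up to three insertions in a minority of clones.
#'
#' @param ... Named overrides for any top-level group (`genome`, `dosage`,
#'   `insertions`, `expression`, `sort`, `lineage`); each given list is
#'   merged over the defaults of its group.
#' @return A nested list of class `synth_config`.
#' @export
synth_config <- function(...) {
  cfg <- list(
    genome = list(
      length_bp = 500000,
      ori_pos = 100000,
      ter_pos = 350000,
      at_background = 0.50,   # genome-wide AT level outside islands
      at_island = 0.70,       # AT level inside islands
      n_islands = 40,
      island_len_range = c(500, 2500),
      n_essential = 60,
      essential_len = 1000,
      n_rrn = 7,              # ribosomal operon copies
      rrn_len = 5000
    ),
    dosage = dosage_params(C_min = 40, D_min = 20, tau_min = 30),
    insertions = list(
      n = 3000,
      alpha = 3,              # density exponent on dosage
      at_boost = 3,           # island density multiplier is (1 + at_boost)
      essential_survival = 0.1
    ),
    expression = list(
      expr_scale = 200,       # mean a.u. per unit growth rate, normal clones
      silencing_factor = 0.15,
      hns_proximity_bp = 2000,
      cv_ext = 0.3,           # extrinsic coefficient of variation
      multi_insertion_fraction = 0.03,
      multi_max = 3,
      opposite_orientation_prob = 0.8,
      interference_scale = 60, # on-state a.u. at unit growth rate (decreasing)
      level_off = 2,
      k_on = 0.02,            # 1/min; off-state dwell 50 min (stable off)
      k_off = 0.05,           # 1/min; on-state dwell 20 min
      media = data.frame(medium = c("slow", "fast"),
                         growth_rate = c(0.7, 1.4))
    ),
    sort = list(
      low_gate = c(0, 60),
      high_gate = c(120, Inf),
      rounds = 4,             # sorting is performed over four rounds
      n_cells_per_clone = 500
    ),
    lineage = list(
      generations = 3,
      dt_min = 3,
      division_min = 30,      # equals tau; no division-time variability
      ou_relax_min = 30       # relaxation time of extrinsic fluctuations
    )
  )
  over <- list(...)
  for (nm in names(over)) {
    abort_if(!nm %in% names(cfg), "unknown config group '", nm, "'")
    if (is.list(over[[nm]]) && !is.data.frame(over[[nm]]) &&
        !inherits(over[[nm]], "dosage_params")) {
      for (k in names(over[[nm]])) {
        abort_if(!k %in% names(cfg[[nm]]),
                 "unknown config field '", nm, "$", k, "'")
        cfg[[nm]][[k]] <- over[[nm]][[k]]
      }
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  g <- cfg$genome; e <- cfg$expression; i <- cfg$insertions
  abort_if(g$at_background < 0 || g$at_background > 1 ||
             g$at_island < 0 || g$at_island > 1, "AT levels must be in [0, 1]")
  abort_if(i$essential_survival < 0 || i$essential_survival > 1,
           "essential_survival must be a probability")
  abort_if(e$multi_insertion_fraction < 0 || e$multi_insertion_fraction > 1,
           "multi_insertion_fraction must be a probability")
  abort_if(e$opposite_orientation_prob < 0 || e$opposite_orientation_prob > 1,
           "opposite_orientation_prob must be a probability")
  abort_if(e$k_on < 0 || e$k_off < 0 || e$cv_ext < 0,
           "rates and cv must be >= 0")
  abort_if(i$at_boost < 0 || i$alpha < 0, "alpha and at_boost must be >= 0")
  need <- (g$n_islands * max(g$island_len_range) +
             g$n_essential * g$essential_len + g$n_rrn * g$rrn_len)
  abort_if(need > 0.9 * g$length_bp,
           "requested intervals exceed the genome (placement infeasible)")
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config> %s bp genome, %d insertions (alpha = %g, at_boost = %g), cv_ext = %g\n",
              format(x$genome$length_bp, big.mark = ","), x$insertions$n,
              x$insertions$alpha, x$insertions$at_boost, x$expression$cv_ext))
  invisible(x)
}
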