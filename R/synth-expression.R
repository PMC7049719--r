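# Clone phenotypes, single-cell expression, sorting and microcolony
# lineages for the synthetic world. Three clone classes by insertion
# position: 'silenced' near an AT island (reduced mean), 'rrn_switching'
# inside a ribosomal operon in the opposite orientation (telegraph
# switching with a stable off state, mean decreasing with growth rate,
# mimicking transcriptional interference from the host operon), and
# 'normal' otherwise (mean increasing with growth rate). A configured
# fraction of clones carries 2-3 insertions; their expression is the sum
# of per-insertion contributions.

# Circular distance from each position to the nearest arc of a merged set
# (0 if inside).
distance_to_arcs <- function(pos, arcs, genome) {
  if (!nrow(arcs)) return(rep(Inf, length(pos)))
  d <- rep(Inf, length(pos))
  for (i in seq_len(nrow(arcs))) {
    di <- pmin(circular_distance(pos, arcs$start[i], genome),
               circular_distance(pos, arcs$end[i] - 1, genome))
    d <- pmin(d, di)
  }
  d[positions_in_arcs(pos, arcs)] <- 0
  d
}

classify_position <- function(pos, orientation, agenome, config) {
  g <- agenome$genome
  rrn_arcs <- merge_intervals(agenome$intervals$rrn, g)
  isl_arcs <- merge_intervals(agenome$intervals$hns_targets, g)
  in_rrn <- positions_in_arcs(pos, rrn_arcs)
  near_isl <- distance_to_arcs(pos, isl_arcs, g) <= config$expression$hns_proximity_bp
  ifelse(in_rrn & orientation == "opposite", "rrn_switching",
         ifelse(near_isl, "silenced", "normal"))
}

#' Assign clone phenotypes from insertion positions
#'
#' One clone per insertion site. Class follows position: `rrn_switching`
#' inside a ribosomal operon when the cassette orientation (drawn with the
#' configured probability, default favouring opposite) opposes the operon;
#' `silenced` within the proximity threshold of an AT island; `normal`
#' otherwise. A configured fraction of clones receives 1-2 extra insertion
#' positions drawn from the same landscape density (copy number up to 3).
#'
#' @param insertions An [insertion_set()] of primary positions.
#' @param agenome An `annotated_genome`.
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @return Data-frame-backed list of class `clone_phenotypes`: one row per
#'   clone with `clone_id`, `class` (of the primary insertion),
#'   `orientation`, `copy_number`, plus list-columns `positions` and
#'   `pos_classes`.
#' @export
assign_clone_phenotypes <- function(insertions, agenome, config, seed = 1) {
  e <- config$expression
  n <- length(insertions$positions)
  with_seed(derive_seed(seed, "phenotypes"), {
    orientation <- ifelse(stats::runif(n) < e$opposite_orientation_prob,
                          "opposite", "same")
    cls <- classify_position(insertions$positions, orientation, agenome, config)
    extra_n <- ifelse(stats::runif(n) < e$multi_insertion_fraction,
                      sample(seq_len(e$multi_max - 1L), n, replace = TRUE), 0L)
    extra_pool <- if (sum(extra_n) > 0) {
      sample_insertions(agenome, config, seed = derive_seed(seed, "extra_pos"),
                        n = sum(extra_n))$positions
    } else {
      numeric(0)
    }
    offs <- cumsum(c(0L, extra_n))
    positions <- lapply(seq_len(n), function(i) {
      c(insertions$positions[i],
        if (extra_n[i] > 0) extra_pool[(offs[i] + 1):(offs[i] + extra_n[i])])
    })
    pos_classes <- lapply(seq_len(n), function(i) {
      k <- length(positions[[i]])
      # extra cassettes land in their own orientation context; reuse the
      # clone's drawn orientation for simplicity of the synthetic world
      classify_position(positions[[i]], rep(orientation[i], k), agenome, config)
    })
    structure(list(
      clone_id = sprintf("clone_%04d", seq_len(n)),
      class = cls,
      orientation = orientation,
      copy_number = lengths(positions),
      positions = positions,
      pos_classes = pos_classes,
      n = n
    ), class = "clone_phenotypes")
  })
}

#' @export
print.clone_phenotypes <- function(x, ...) {
  tab <- table(x$class)
  cat(sprintf("<clone_phenotypes> %d clones (%s); %d multi-insertion\n",
              x$n, paste(names(tab), tab, sep = ": ", collapse = ", "),
              sum(x$copy_number > 1)))
  invisible(x)
}

# Extract one clone record (a plain list) from the phenotype table.
clone_record <- function(phen, i) {
  list(clone_id = phen$clone_id[i], class = phen$class[i],
       orientation = phen$orientation[i], positions = phen$positions[[i]],
       pos_classes = phen$pos_classes[[i]])
}

# Mean expression contribution of one cassette of a given class at a given
# growth rate: normal rises with growth rate, silenced is the normal level
# times the silencing factor, the interference on-level falls with growth
# rate (the competing operon fires harder in fast growth).
class_mean_level <- function(class, growth_rate, e) {
  switch(class,
         normal = e$expr_scale * growth_rate,
         silenced = e$expr_scale * growth_rate * e$silencing_factor,
         rrn_switching = e$interference_scale / growth_rate,
         stop("unknown clone class '", class, "'"))
}

telegraph_p_on <- function(e) {
  if (e$k_on + e$k_off == 0) return(1) # rates zero: state frozen on
  e$k_on / (e$k_on + e$k_off)
}

#' Sample single-cell expression for one clone
#'
#' Normal and silenced cassettes contribute their class mean; switching
#' cassettes draw a per-cell telegraph state from the stationary occupancy
#' `k_on/(k_on + k_off)` and contribute the on/off level. The per-cell
#' total is multiplied by a shared extrinsic factor `(1 + eta)`,
#' `eta ~ N(0, cv_ext)`, and truncated at zero (fluorescence cannot be
#' negative). Multi-insertion clones sum per-cassette contributions, but
#' their arrays are unstable: the number of cassettes contributing in a
#' given cell is drawn uniformly from 1 to the copy number (recorded in
#' `cell_copies`), which inflates their cell-to-cell variability beyond
#' the extrinsic baseline — the mechanism by which multi-insertion clones
#' become steep-noise outliers, removable by
#' [normalize_expression_by_copy_number()].
#'
#' @param clone A clone record (from [assign_clone_phenotypes()], one
#'   element) or an index into a `clone_phenotypes` object passed as
#'   `phen`.
#' @param n_cells Number of cells to draw.
#' @param medium Medium label; its growth rate is looked up in
#'   `config$expression$media`.
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @return A [clone_expression()].
#' @export
sample_cell_expression <- function(clone, n_cells, medium, config, seed = 1) {
  abort_if(n_cells < 1, "n_cells must be >= 1")
  e <- config$expression
  gr <- e$media$growth_rate[match(medium, e$media$medium)]
  abort_if(is.na(gr), "unknown medium '", medium, "'")
  with_seed(derive_seed(seed, paste0("cells:", clone$clone_id, ":", medium)), {
    k_tot <- length(clone$positions)
    # unstable multi-cassette arrays: cells carry 1..k contributing copies
    cell_copies <- if (k_tot > 1) {
      sample.int(k_tot, n_cells, replace = TRUE)
    } else {
      rep(1L, n_cells)
    }
    base <- numeric(n_cells)
    for (k in seq_len(k_tot)) {
      cls <- clone$pos_classes[k]
      active <- cell_copies >= k
      contrib <- if (cls == "rrn_switching") {
        on <- stats::runif(n_cells) < telegraph_p_on(e)
        ifelse(on, class_mean_level(cls, gr, e), e$level_off)
      } else {
        rep(class_mean_level(cls, gr, e), n_cells)
      }
      base <- base + contrib * active
    }
    eta <- stats::rnorm(n_cells, 0, e$cv_ext)
    cells <- pmax(base * (1 + eta), 0)
    clone_expression(clone$clone_id, clone$positions, medium, gr, cells,
                     cell_copies = if (k_tot > 1) cell_copies else NULL)
  })
}

#' Generate a full clone cohort with expression
#'
#' Convenience wrapper: insertion landscape, phenotypes, and one
#' [clone_expression()] per clone in the given medium.
#'
#' @param agenome An `annotated_genome`.
#' @param config A [synth_config()].
#' @param medium Medium label.
#' @param seed Integer seed.
#' @param n_cells Cells per clone (default `config$sort$n_cells_per_clone`).
#' @return List with `phenotypes`, `clones` (list of [clone_expression()])
#'   and `insertions`.
#' @export
clone_cohort <- function(agenome, config, medium = "fast", seed = 1,
                         n_cells = NULL) {
  n_cells <- n_cells %||% config$sort$n_cells_per_clone
  ins <- sample_insertions(agenome, config, seed = derive_seed(seed, "cohort_ins"))
  phen <- assign_clone_phenotypes(ins, agenome, config,
                                  seed = derive_seed(seed, "cohort_phen"))
  clones <- lapply(seq_len(phen$n), function(i) {
    sample_cell_expression(clone_record(phen, i), n_cells, medium, config,
                           seed = derive_seed(seed, paste0("cohort_cells:", i)))
  })
  list(phenotypes = phen, clones = clones, insertions = ins)
}

#' Sort a clone population through a fluorescence gate
#'
#' Emulates one round of fluorescence-activated sorting: each clone's
#' frequency is multiplied by the fraction of its cells falling inside the
#' half-open gate `[low, high)` and the result renormalized. Repeatable
#' for multiple rounds.
#'
#' @param clones List of [clone_expression()].
#' @param frequencies Clone frequencies summing to 1.
#' @param gate Numeric `c(low, high)`, `low < high`.
#' @param rounds Number of successive sorting rounds (default 1; the
#'   emulated protocol sorts over four rounds, see
#'   `synth_config()$sort$rounds`).
#' @return Updated frequency vector (sums to 1).
#' @export
sort_population <- function(clones, frequencies, gate, rounds = 1) {
  abort_if(gate[1] >= gate[2], "gate low must be < high")
  abort_if(abs(sum(frequencies) - 1) > 1e-6, "frequencies must sum to 1")
  frac <- vapply(clones, function(cl) {
    mean(cl$cells >= gate[1] & cl$cells < gate[2])
  }, numeric(1))
  new <- frequencies
  for (r in seq_len(rounds)) {
    new <- new * frac
    abort_if(sum(new) == 0, "no cell in any clone passes the gate",
             class = "insertionfate_validation_error")
    new <- new / sum(new)
  }
  new
}

#' Insertion sites detectable in a (sorted) population
#'
#' Emulates population sequencing after sorting: clones whose frequency
#' stays at or above `min_freq` (default: half the uniform share) have
#' their insertion positions reported.
#'
#' @param phen A `clone_phenotypes` object.
#' @param frequencies Clone frequencies summing to 1.
#' @param min_freq Detection threshold (default `0.5 / n_clones`).
#' @param genome Optional [genome_spec()] for validation.
#' @return An [insertion_set()] of the detectable primary positions,
#'   labelled by clone.
#' @export
population_insertions <- function(phen, frequencies, min_freq = NULL,
                                  genome = NULL) {
  min_freq <- min_freq %||% (0.5 / phen$n)
  keep <- which(frequencies >= min_freq)
  insertion_set(vapply(keep, function(i) phen$positions[[i]][1], numeric(1)),
                labels = phen$clone_id[keep], genome = genome)
}

#' Simulate a microcolony lineage tree with expression dynamics
#'
#' Binary tree with division every `division_min` minutes for `generations`
#' generations, expression sampled every `dt_min`. Normal and silenced
#' clones follow a mean-reverting (Ornstein-Uhlenbeck) extrinsic
#' fluctuation around their class mean, inherited at division so sisters
#' start correlated; switching clones follow the two-state telegraph
#' process (state inherited at division) with expression relaxing towards
#' the state level on the same timescale.
#'
#' @param clone A clone record (see [sample_cell_expression()]).
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @param generations Number of generations in `[1, 6]`.
#' @param medium Medium label for the growth rate.
#' @return A [lineage_tree()].
#' @export
simulate_microcolony <- function(clone, config, seed = 1, generations = NULL,
                                 medium = "fast") {
  lin <- config$lineage
  e <- config$expression
  generations <- generations %||% lin$generations
  abort_if(generations < 1 || generations > 6, "generations must be in [1, 6]")
  gr <- e$media$growth_rate[match(medium, e$media$medium)]
  abort_if(is.na(gr), "unknown medium '", medium, "'")
  tdiv <- lin$division_min
  dt <- lin$dt_min
  # `generations` rounds of division; the 2^generations leaf cells are then
  # observed for one further division time, so every sister pair has a
  # post-division window
  total <- (generations + 1) * tdiv
  grid <- seq(0, total, by = dt)
  switching <- clone$class == "rrn_switching"
  mu_on <- class_mean_level(clone$class, gr, e)
  mu_off <- if (switching) e$level_off else mu_on
  sd_ext <- e$cv_ext * mu_on
  relax <- lin$ou_relax_min
  p_on <- telegraph_p_on(e)
  with_seed(derive_seed(seed, paste0("colony:", clone$clone_id)), {
    nodes <- data.frame(id = character(), parent = character(),
                        birth_min = numeric(), end_min = numeric(),
                        stringsAsFactors = FALSE)
    series <- list()
    # state: list(expr, on); evolve over one cell lifetime on the grid
    evolve <- function(id, parent, birth, depth, state) {
      end <- min(birth + tdiv, total)
      times <- grid[grid >= birth - 1e-9 & grid <= end + 1e-9]
      expr <- numeric(length(times))
      on <- state$on
      x <- state$expr
      for (j in seq_along(times)) {
        if (j > 1) {
          step <- times[j] - times[j - 1]
          if (switching) {
            # telegraph state update over dt
            p_switch <- if (on) 1 - exp(-e$k_off * step) else 1 - exp(-e$k_on * step)
            if (stats::runif(1) < p_switch) on <- !on
          }
          target <- if (switching) (if (on) mu_on else mu_off) else mu_on
          a <- exp(-step / relax)
          innov_sd <- sd_ext * sqrt(1 - a^2)
          x <- target + (x - target) * a + stats::rnorm(1, 0, innov_sd)
        }
        expr[j] <- max(x, 0)
      }
      nodes <<- rbind(nodes, data.frame(id = id, parent = parent,
                                        birth_min = birth, end_min = end,
                                        stringsAsFactors = FALSE))
      series[[id]] <<- data.frame(id = id, time_min = times, expression = expr,
                                  stringsAsFactors = FALSE)
      if (depth < generations) {
        for (d in 1:2) {
          evolve(paste0(id, ".", d), id, end, depth + 1L,
                 list(expr = x, on = on))
        }
      }
    }
    init_on <- stats::runif(1) < p_on
    init_expr <- if (switching) {
      (if (init_on) mu_on else mu_off) + stats::rnorm(1, 0, sd_ext)
    } else {
      mu_on + stats::rnorm(1, 0, sd_ext)
    }
    evolve("c", NA_character_, 0, 0L, list(expr = max(init_expr, 0), on = init_on))
    lineage_tree(nodes, do.call(rbind, series),
                 colony_id = paste0(clone$clone_id, ":", clone$class))
  })
}
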