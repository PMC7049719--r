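# Synthetic annotated genomes and insertion landscapes. The genome carries
# AT-rich islands (the synthetic stand-in for silencer-protein binding
# tracts: AT-rich tracts are the preferred binding targets, and the
# generative rule here simply identifies the two — a modelling choice, not
# a biological claim), essential genes placed outside islands, and seven
# ribosomal operons with orientation labels.

#' Generate an annotated synthetic genome
#'
#' Draws the sequence per-base with island-dependent AT probability and
#' places the labelled interval sets: AT islands (`hns_targets`), essential
#' genes (never inside islands) and ribosomal operons at evenly spread
#' positions with alternating orientation. Deterministic given `(config,
#' seed)`.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @return An object of class `annotated_genome`: `genome`
#'   ([genome_spec()]), `sequence` (character string) and `intervals`
#'   (named list of [interval_set()]s: `hns_targets`, `essential`, `rrn`).
#' @export
make_genome <- function(config, seed = 1) {
  g <- config$genome
  L <- g$length_bp
  genome <- genome_spec(L, ori_pos = g$ori_pos, ter_pos = g$ter_pos)
  with_seed(derive_seed(seed, "make_genome"), {
    island_len <- floor(stats::runif(g$n_islands, g$island_len_range[1],
                                     g$island_len_range[2] + 1))
    islands <- place_nonoverlapping(island_len, L, avoid = NULL)
    ess <- place_nonoverlapping(rep(g$essential_len, g$n_essential), L,
                                avoid = islands)
    # ribosomal operons: evenly spread, alternating strand, jitter-free so
    # the configured count is exact and placement is deterministic
    rrn_start <- floor((seq_len(g$n_rrn) - 0.5) / g$n_rrn * L)
    rrn <- data.frame(start = rrn_start,
                      end = pmin(rrn_start + g$rrn_len, L))
    in_island <- logical(L)
    for (i in seq_len(nrow(islands))) {
      in_island[(islands$start[i] + 1):islands$end[i]] <- TRUE
    }
    p_at <- ifelse(in_island, g$at_island, g$at_background)
    is_at <- stats::runif(L) < p_at
    pick <- stats::runif(L) < 0.5
    bases <- character(L)
    bases[is_at] <- ifelse(pick[is_at], "A", "T")
    bases[!is_at] <- ifelse(pick[!is_at], "G", "C")
    structure(list(
      genome = genome,
      sequence = paste(bases, collapse = ""),
      intervals = list(
        hns_targets = interval_set(islands$start, islands$end,
                                   id = seq_ids("island", nrow(islands)),
                                   name = "hns_targets", genome = genome),
        essential = interval_set(ess$start, ess$end,
                                 id = seq_ids("ess", nrow(ess)),
                                 name = "essential", genome = genome),
        rrn = interval_set(rrn$start, rrn$end,
                           id = paste0("rrn", LETTERS[seq_len(g$n_rrn)]),
                           strand = rep(c("+", "-"), length.out = g$n_rrn),
                           name = "rrn", genome = genome)
      )
    ), class = "annotated_genome")
  })
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s bp; %s\n",
              format(x$genome$length_bp, big.mark = ","),
              paste(sprintf("%s: %d", names(x$intervals),
                            vapply(x$intervals, length, integer(1))),
                    collapse = ", ")))
  invisible(x)
}

# Rejection placement of non-overlapping intervals, optionally avoiding an
# existing set. Errors out if the genome cannot host the request.
place_nonoverlapping <- function(lengths, L, avoid = NULL, max_tries = 10000L) {
  placed <- if (is.null(avoid)) {
    data.frame(start = numeric(), end = numeric())
  } else {
    avoid[, c("start", "end"), drop = FALSE]
  }
  out_s <- numeric(0); out_e <- numeric(0)
  for (len in lengths) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      s <- floor(stats::runif(1) * (L - len))
      e <- s + len
      if (!any(placed$start < e & placed$end > s)) {
        placed <- rbind(placed, data.frame(start = s, end = e))
        out_s <- c(out_s, s); out_e <- c(out_e, e)
        ok <- TRUE
        break
      }
    }
    abort_if(!ok, "infeasible placement: requested intervals exceed the genome",
             class = "insertionfate_validation_error")
  }
  ord <- order(out_s)
  data.frame(start = out_s[ord], end = out_e[ord])
}

# Per-bp insertion density over the whole genome: dosage^alpha, boosted
# inside AT islands, thinned inside essential genes by the survival
# probability. Returns an unnormalized numeric vector of length L.
insertion_density <- function(agenome, config) {
  L <- agenome$genome$length_bp
  pos <- seq_len(L) - 1
  m <- locus_relative_position(pos, agenome$genome)
  w <- mean_copy_number(m, config$dosage)^config$insertions$alpha
  isl <- positions_in_arcs(pos, merge_intervals(agenome$intervals$hns_targets,
                                                agenome$genome))
  w <- w * (1 + config$insertions$at_boost * isl)
  ess <- positions_in_arcs(pos, merge_intervals(agenome$intervals$essential,
                                                agenome$genome))
  w[ess] <- w[ess] * config$insertions$essential_survival
  w
}

#' Sample an insertion landscape over the synthetic genome
#'
#' Position density proportional to `dosage(m)^alpha * (1 + at_boost)` on
#' AT islands, with candidates inside essential genes retained with the
#' configured survival probability (implemented as density thinning, so
#' exactly `n` sites are returned). Deterministic given `(config, seed)`.
#'
#' @param agenome An `annotated_genome` from [make_genome()].
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @param n Number of insertions (default `config$insertions$n`).
#' @return An [insertion_set()] of `n` unit-weight positions.
#' @export
sample_insertions <- function(agenome, config, seed = 1, n = NULL) {
  n <- n %||% config$insertions$n
  abort_if(n < 0, "n must be >= 0")
  if (n == 0) return(insertion_set(numeric(), genome = agenome$genome))
  w <- insertion_density(agenome, config)
  cum <- cumsum(w) / sum(w)
  with_seed(derive_seed(seed, "sample_insertions"), {
    idx <- findInterval(stats::runif(n), cum) + 1L
    insertion_set(idx - 1, genome = agenome$genome)
  })
}
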