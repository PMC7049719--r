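# Circular-genome coordinate system and the domain containers shared by all
# analysis stages. Coordinates are 0-based, half-open, on a single circular
# replicon; all position arithmetic is modulo the genome length.

#' Circular genome specification
#'
#' Describes a single circular replicon by its length and the positions of
#' the replication origin (*oriC*) and terminus (*ter*). The two arcs from
#' origin to terminus are the replichores; the "right" replichore is the arc
#' from `ori_pos` towards increasing coordinate (modulo `length_bp`) to
#' `ter_pos`, the "left" replichore is the other arc.
#'
#' @param length_bp Positive integer, genome length in bp.
#' @param ori_pos Integer position of the replication origin in `[0, length_bp)`.
#' @param ter_pos Integer position of the terminus; defaults to the antipode
#'   of `ori_pos`. Real chromosomes have slightly unequal replichores, so it
#'   is an explicit field.
#' @return An object of class `genome_spec`.
#' @export
#' @examples
#' g <- genome_spec(4600000, ori_pos = 3925000)
#' circular_distance(10, 4599990, g)
genome_spec <- function(length_bp, ori_pos = 0, ter_pos = NULL) {
  abort_if(length(length_bp) != 1L || is.na(length_bp) || length_bp < 2,
           "length_bp must be a positive integer >= 2")
  length_bp <- as.numeric(length_bp)
  ter_pos <- ter_pos %||% ((ori_pos + floor(length_bp / 2)) %% length_bp)
  for (nm in c("ori_pos", "ter_pos")) {
    v <- get(nm)
    abort_if(length(v) != 1L || is.na(v) || v < 0 || v >= length_bp,
             nm, " must lie in [0, length_bp)")
  }
  abort_if(ori_pos == ter_pos, "ori_pos and ter_pos must differ")
  structure(
    list(length_bp = length_bp, ori_pos = as.numeric(ori_pos),
         ter_pos = as.numeric(ter_pos), circular = TRUE),
    class = "genome_spec"
  )
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("<genome_spec> circular, %s bp; ori = %s, ter = %s\n",
              format(x$length_bp, big.mark = ","), x$ori_pos, x$ter_pos))
  invisible(x)
}

#' Shortest distance between two positions on the circle
#'
#' @param a,b Positions in bp (vectors recycle).
#' @param genome A [genome_spec()].
#' @return `min((a - b) mod L, (b - a) mod L)`, always `<= L/2`.
#' @export
circular_distance <- function(a, b, genome) {
  L <- genome$length_bp
  d <- (a - b) %% L
  pmin(d, L - d)
}

#' Relative replichore position of a locus
#'
#' Maps a genomic position to the dosage coordinate `m` in `[0, 1]`: the
#' circular distance from the origin to the locus along the replichore that
#' contains it, divided by that replichore's length. `m = 0` at *oriC* and
#' `m = 1` at *ter*, on both replichores.
#'
#' @param p Position(s) in bp.
#' @param genome A [genome_spec()].
#' @return Numeric vector of `m` values in `[0, 1]`.
#' @export
locus_relative_position <- function(p, genome) {
  L <- genome$length_bp
  len_right <- (genome$ter_pos - genome$ori_pos) %% L
  len_left <- L - len_right
  d_fwd <- (p - genome$ori_pos) %% L
  ifelse(d_fwd <= len_right, d_fwd / len_right, (L - d_fwd) / len_left)
}

# TRUE where position p falls on the right replichore (ori -> ter in
# increasing coordinate). Positions exactly at ori count as right, exactly
# at ter as right too (boundary of measure zero for all statistics here).
on_right_replichore <- function(p, genome) {
  L <- genome$length_bp
  ((p - genome$ori_pos) %% L) <= ((genome$ter_pos - genome$ori_pos) %% L)
}

#' Named set of genomic intervals
#'
#' 0-based, half-open intervals on the circular genome. An interval crossing
#' the origin is stored as two records sharing an `id`; overlap logic treats
#' shared-id records as one feature.
#'
#' @param start,end Integer vectors, `0 <= start < end <= length_bp`.
#' @param id Feature identifiers (default `iv1, iv2, ...`).
#' @param strand Strand labels in `{+, -, .}` (default `.`).
#' @param name Label for the set.
#' @param genome Optional [genome_spec()] used to validate coordinates.
#' @return An object of class `interval_set` wrapping a data frame.
#' @export
interval_set <- function(start, end, id = NULL, strand = NULL,
                         name = "intervals", genome = NULL) {
  n <- length(start)
  abort_if(length(end) != n, "start and end must have equal length")
  id <- id %||% seq_ids("iv", n)
  strand <- strand %||% rep(".", n)
  abort_if(!all(strand %in% c("+", "-", ".")), "strand must be one of +, -, .")
  abort_if(any(end <= start), "every interval must satisfy end > start")
  abort_if(any(start < 0), "interval start must be >= 0")
  if (!is.null(genome)) {
    abort_if(any(end > genome$length_bp),
             "interval end exceeds genome length (origin-crossing features ",
             "must be stored as two records sharing an id)")
  }
  structure(
    list(name = name,
         intervals = data.frame(start = as.numeric(start), end = as.numeric(end),
                                id = as.character(id), strand = as.character(strand),
                                stringsAsFactors = FALSE)),
    class = "interval_set"
  )
}

#' @export
print.interval_set <- function(x, ...) {
  iv <- x$intervals
  cat(sprintf("<interval_set> '%s': %d records (%d features), %s bp covered\n",
              x$name, nrow(iv), length(unique(iv$id)),
              format(sum(iv$end - iv$start), big.mark = ",")))
  invisible(x)
}

#' @export
length.interval_set <- function(x) nrow(x$intervals)

#' Set of insertion sites on the circular genome
#'
#' Positions of reporter-cassette insertions, optionally weighted by read
#' counts and labelled by clone. Weights default to 1 when absent; every
#' counting operation in the package sums weights.
#'
#' @param positions Integer positions in `[0, length_bp)`.
#' @param weights Optional non-negative weights (same length).
#' @param labels Optional clone identifiers (same length).
#' @param genome Optional [genome_spec()] used to validate positions.
#' @return An object of class `insertion_set`.
#' @export
insertion_set <- function(positions, weights = NULL, labels = NULL, genome = NULL) {
  positions <- as.numeric(positions)
  if (!is.null(weights)) {
    abort_if(length(weights) != length(positions),
             "weights must match positions in length")
    abort_if(any(weights < 0), "weights must be non-negative")
  }
  if (!is.null(labels)) {
    abort_if(length(labels) != length(positions),
             "labels must match positions in length")
  }
  abort_if(any(positions < 0), "positions must be >= 0")
  if (!is.null(genome)) {
    abort_if(any(positions >= genome$length_bp),
             "positions must lie in [0, length_bp) (half-open convention)")
  }
  structure(list(positions = positions, weights = weights,
                 labels = labels),
            class = "insertion_set")
}

#' @export
print.insertion_set <- function(x, ...) {
  cat(sprintf("<insertion_set> %d sites, total weight %g\n",
              length(x$positions), sum(insertion_weights(x))))
  invisible(x)
}

#' @export
length.insertion_set <- function(x) length(x$positions)

# Effective weights (all-1 when absent).
insertion_weights <- function(x) x$weights %||% rep(1, length(x$positions))

#' Per-clone single-cell fluorescence sample
#'
#' @param clone_id Clone label.
#' @param insertion_positions Integer positions of the clone's cassette
#'   copies (length = promoter copy number, >= 1).
#' @param medium Growth-medium label.
#' @param growth_rate Growth rate in 1/h.
#' @param cells Non-negative per-cell fluorescence values (a.u.).
#' @param cell_copies Optional per-cell count of contributing cassette
#'   copies (same length as `cells`); defaults to the clone copy number
#'   for every cell. Multi-insertion arrays can be unstable, so the count
#'   may vary cell to cell.
#' @return An object of class `clone_expression`.
#' @export
clone_expression <- function(clone_id, insertion_positions, medium,
                             growth_rate, cells, cell_copies = NULL) {
  abort_if(length(insertion_positions) < 1, "copy number must be >= 1")
  abort_if(any(cells < 0), "fluorescence values must be non-negative")
  if (!is.null(cell_copies)) {
    abort_if(length(cell_copies) != length(cells),
             "cell_copies must match cells in length")
    abort_if(any(cell_copies < 1), "cell_copies must be >= 1")
  }
  structure(list(clone_id = as.character(clone_id),
                 insertion_positions = as.numeric(insertion_positions),
                 medium = as.character(medium),
                 growth_rate = as.numeric(growth_rate),
                 cells = as.numeric(cells),
                 cell_copies = cell_copies),
            class = "clone_expression")
}

#' Microcolony lineage tree with expression time series
#'
#' A binary division tree: `nodes` holds one row per cell (`id`, `parent`
#' — `NA` for the root —, `birth_min`, `end_min`); `series` holds the
#' per-cell expression time series (`id`, `time_min`, `expression`) on a
#' common sampling grid.
#'
#' @param nodes Data frame with columns `id`, `parent`, `birth_min`, `end_min`.
#' @param series Data frame with columns `id`, `time_min`, `expression`.
#' @param colony_id Label for the colony.
#' @return An object of class `lineage_tree`.
#' @export
lineage_tree <- function(nodes, series, colony_id = "colony") {
  abort_if(!all(c("id", "parent", "birth_min", "end_min") %in% names(nodes)),
           "nodes needs columns id, parent, birth_min, end_min")
  abort_if(!all(c("id", "time_min", "expression") %in% names(series)),
           "series needs columns id, time_min, expression")
  nodes$id <- as.character(nodes$id)
  nodes$parent <- as.character(nodes$parent)
  series$id <- as.character(series$id)
  abort_if(anyDuplicated(nodes$id) > 0, "cell ids must be unique")
  roots <- nodes$id[is.na(nodes$parent)]
  abort_if(length(roots) != 1L, "tree must have exactly one root")
  abort_if(!all(nodes$parent[!is.na(nodes$parent)] %in% nodes$id),
           "every non-root must name an existing parent")
  kids <- table(nodes$parent[!is.na(nodes$parent)])
  abort_if(any(!kids %in% c(2L)),
           "each dividing cell must have exactly two children")
  abort_if(!all(series$id %in% nodes$id), "series reference unknown cells")
  born <- nodes$birth_min[match(series$id, nodes$id)]
  ended <- nodes$end_min[match(series$id, nodes$id)]
  abort_if(any(series$time_min < born - 1e-9 | series$time_min > ended + 1e-9),
           "series times must lie within [birth, end] of the owning cell")
  structure(list(colony_id = as.character(colony_id),
                 nodes = nodes, series = series),
            class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  n_div <- sum(x$nodes$id %in% x$nodes$parent)
  cat(sprintf("<lineage_tree> '%s': %d cells, %d divisions, %d series points\n",
              x$colony_id, nrow(x$nodes), n_div, nrow(x$series)))
  invisible(x)
}
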