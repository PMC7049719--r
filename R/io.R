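# Readers/writers for the plain-text formats the pipeline touches: BED
# interval lists, insertion TSVs, FASTA genome sequences, per-cell
# expression TSVs and lineage edge-list + long-format series TSVs. All
# outputs carry a '# key=value' comment block recording seed and parameters.

#' Read a BED file of genomic intervals
#'
#' Accepts 3+ column BED (0-based, half-open). The chromosome column is
#' accepted but must name a single sequence; it is otherwise ignored
#' (single circular replicon). Column 4, when present, becomes the feature
#' id and column 6 the strand.
#'
#' @param path Path to a BED file. Lines starting with `#`, `track` or
#'   `browser` are skipped.
#' @param genome A [genome_spec()] used to validate coordinates.
#' @param name Label for the returned set (default: file base name).
#' @return An [interval_set()].
#' @export
read_intervals <- function(path, genome, name = NULL) {
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b|$)", lines)
  if (!any(keep)) return(interval_set(numeric(), numeric(), name = name))
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(ncols < 3L)
  abort_if(length(bad) > 0, "malformed BED line ", idx[bad[1]],
           ": fewer than 3 tab-separated columns", class = "insertionfate_parse_error")
  chrom <- vapply(fields, `[[`, "", 1L)
  abort_if(length(unique(chrom)) > 1L,
           "BED names multiple chromosomes; a single circular replicon is expected",
           class = "insertionfate_validation_error")
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  abort_if(length(bad) > 0, "malformed BED line ", idx[bad[1]],
           ": non-numeric coordinate", class = "insertionfate_parse_error")
  id <- if (all(ncols >= 4L)) vapply(fields, `[[`, "", 4L) else NULL
  strand <- if (all(ncols >= 6L)) vapply(fields, `[[`, "", 6L) else NULL
  bad <- which(start < 0 | end > genome$length_bp)
  abort_if(length(bad) > 0, "BED line ", idx[bad[1]],
           ": coordinate outside [0, genome length]",
           class = "insertionfate_validation_error")
  bad <- which(end <= start)
  abort_if(length(bad) > 0, "BED line ", idx[bad[1]],
           ": end <= start", class = "insertionfate_validation_error")
  interval_set(start, end, id = id, strand = strand, name = name, genome = genome)
}

#' Write an interval set as BED
#'
#' @param x An [interval_set()].
#' @param path Output path.
#' @param chrom Chromosome name to emit (default `"chr"`).
#' @param comments Optional character vector written as `# ` lines.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path, chrom = "chr", comments = character()) {
  iv <- x$intervals
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  if (length(comments)) writeLines(paste0("# ", comments), con)
  if (nrow(iv)) {
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", chrom, as.integer(iv$start),
                       as.integer(iv$end), iv$id, iv$strand), con)
  }
  invisible(path)
}

#' Read an insertion-site table
#'
#' TSV with a header and columns `position[, weight][, clone_id]`; the
#' processed stand-in for transposon insertion-site sequencing output.
#' Missing weights are treated as all-1.
#'
#' @param path Path to the TSV.
#' @param genome A [genome_spec()] used to validate positions.
#' @return An [insertion_set()].
#' @export
read_insertions <- function(path, genome) {
  df <- read_tsv_commented(path)
  abort_if(!"position" %in% names(df), "insertion table needs a 'position' column",
           class = "insertionfate_parse_error")
  w <- if ("weight" %in% names(df)) df$weight else NULL
  lab <- if ("clone_id" %in% names(df)) as.character(df$clone_id) else NULL
  insertion_set(df$position, weights = w, labels = lab, genome = genome)
}

#' Write an insertion-site table
#'
#' @inheritParams write_intervals
#' @param x An [insertion_set()].
#' @return `path`, invisibly.
#' @export
write_insertions <- function(x, path, comments = character()) {
  df <- data.frame(position = x$positions)
  if (!is.null(x$weights)) df$weight <- x$weights
  if (!is.null(x$labels)) df$clone_id <- x$labels
  write_tsv_commented(df, path, comments)
}

#' Read a genome sequence from FASTA
#'
#' @param path Path to a FASTA file holding a single sequence.
#' @return Upper-case character string of the sequence.
#' @export
read_genome_sequence <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  abort_if(length(ss) != 1L, "FASTA must hold exactly one sequence",
           class = "insertionfate_validation_error")
  toupper(as.character(ss[[1]]))
}

#' Write a genome sequence as FASTA
#'
#' @param seq Character string of bases.
#' @param path Output path.
#' @param name Sequence header name.
#' @return `path`, invisibly.
#' @export
write_genome_sequence <- function(seq, path, name = "chr") {
  ss <- Biostrings::DNAStringSet(seq)
  names(ss) <- name
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read / write per-cell expression tables
#'
#' Long-format TSV with columns `clone_id`, `cell_id`, `fluorescence`,
#' `medium`, `growth_rate`.
#'
#' @param path Path to the TSV.
#' @return `read_cells`: a data frame. `write_cells`: `path`, invisibly.
#' @export
read_cells <- function(path) {
  df <- read_tsv_commented(path)
  need <- c("clone_id", "cell_id", "fluorescence", "medium", "growth_rate")
  abort_if(!all(need %in% names(df)),
           "cell table needs columns ", paste(need, collapse = ", "),
           class = "insertionfate_parse_error")
  abort_if(any(df$fluorescence < 0), "fluorescence must be non-negative",
           class = "insertionfate_validation_error")
  df
}

#' @rdname read_cells
#' @param df Data frame as returned by [read_cells()].
#' @param comments Optional `# ` comment lines.
#' @export
write_cells <- function(df, path, comments = character()) {
  write_tsv_commented(df, path, comments)
}

#' Read / write lineage trees
#'
#' A lineage is stored as two TSVs: an edge list (`cell_id`, `parent_id`,
#' `birth_min`, `end_min`; root has empty parent) and a long-format series
#' table (`cell_id`, `time_min`, `expression`).
#'
#' @param edges_path,series_path Paths to the two TSVs.
#' @param colony_id Label for the colony.
#' @return `read_lineage`: a [lineage_tree()]. `write_lineage`: invisibly,
#'   the two paths.
#' @export
read_lineage <- function(edges_path, series_path, colony_id = "colony") {
  ed <- read_tsv_commented(edges_path, colClasses = c(parent_id = "character"))
  sr <- read_tsv_commented(series_path)
  nodes <- data.frame(id = as.character(ed$cell_id),
                      parent = ifelse(ed$parent_id == "" | is.na(ed$parent_id),
                                      NA_character_, as.character(ed$parent_id)),
                      birth_min = ed$birth_min, end_min = ed$end_min,
                      stringsAsFactors = FALSE)
  series <- data.frame(id = as.character(sr$cell_id), time_min = sr$time_min,
                       expression = sr$expression, stringsAsFactors = FALSE)
  lineage_tree(nodes, series, colony_id = colony_id)
}

#' @rdname read_lineage
#' @param tree A [lineage_tree()].
#' @param comments Optional `# ` comment lines.
#' @export
write_lineage <- function(tree, edges_path, series_path, comments = character()) {
  ed <- data.frame(cell_id = tree$nodes$id,
                   parent_id = ifelse(is.na(tree$nodes$parent), "", tree$nodes$parent),
                   birth_min = tree$nodes$birth_min, end_min = tree$nodes$end_min)
  sr <- data.frame(cell_id = tree$series$id, time_min = tree$series$time_min,
                   expression = tree$series$expression)
  write_tsv_commented(ed, edges_path, comments)
  write_tsv_commented(sr, series_path, comments)
  invisible(c(edges_path, series_path))
}
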