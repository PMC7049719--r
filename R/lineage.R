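# Sister-lineage divergence of gene expression on microcolony trees:
# the time average of the absolute expression difference between the two
# lineages emanating from each division. "Sister cells" extend to sister
# sub-lineages by averaging expression over all live descendants of each
# child at each time point, which keeps the statistic well-defined after
# further divisions; a sisters-only mode restricts to the two children's
# own lifetimes.

#' Sister-lineage expression divergence of a microcolony
#'
#' For every division in the tree, the two descendant lineages are followed
#' (averaging expression over all live descendants of each child at each
#' shared time point); the pair divergence is the time average of
#' `|E1(t) - E2(t)|` and the colony divergence is the mean over division
#' pairs.
#'
#' @param tree A [lineage_tree()] with at least one division, series on a
#'   common sampling grid.
#' @param mode `"sublineages"` (default) follows full sub-lineages;
#'   `"sisters"` uses only the two children until their own division.
#' @param normalize Divide divergences by the colony mean expression (for
#'   cross-clone comparison)?
#' @return An object of class `divergence_result`: `colony_id`, `per_pair`
#'   (data frame `ancestor`, `divergence`, `n_times`), `colony_divergence`
#'   (mean over pairs), `n_pairs`.
#' @export
sister_divergence <- function(tree, mode = c("sublineages", "sisters"),
                              normalize = FALSE) {
  mode <- match.arg(mode)
  nodes <- tree$nodes
  series <- tree$series
  parents <- unique(nodes$parent[!is.na(nodes$parent)])
  abort_if(length(parents) == 0, "tree has no divisions",
           class = "insertionfate_validation_error")
  children_of <- split(nodes$id, factor(nodes$parent, levels = parents))
  desc_of <- function(id) { # id plus all descendants
    out <- id
    frontier <- id
    repeat {
      nxt <- nodes$id[!is.na(nodes$parent) & nodes$parent %in% frontier]
      if (!length(nxt)) break
      out <- c(out, nxt)
      frontier <- nxt
    }
    out
  }
  series_by_time <- function(ids, t_min) {
    sub <- series[series$id %in% ids & series$time_min >= t_min - 1e-9, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    agg <- tapply(sub$expression, sub$time_min, mean)
    data.frame(time = as.numeric(names(agg)), expr = as.numeric(agg))
  }
  pairs <- lapply(parents, function(p) {
    kids <- children_of[[p]]
    t_div <- nodes$birth_min[match(kids[1], nodes$id)]
    ids1 <- if (mode == "sublineages") desc_of(kids[1]) else kids[1]
    ids2 <- if (mode == "sublineages") desc_of(kids[2]) else kids[2]
    e1 <- series_by_time(ids1, t_div)
    e2 <- series_by_time(ids2, t_div)
    if (is.null(e1) || is.null(e2)) return(NULL)
    shared <- intersect(e1$time, e2$time)
    if (!length(shared)) {
      warning("no shared time points for division at '", p, "'; pair skipped")
      return(NULL)
    }
    d <- mean(abs(e1$expr[match(shared, e1$time)] - e2$expr[match(shared, e2$time)]))
    data.frame(ancestor = p, divergence = d, n_times = length(shared),
               stringsAsFactors = FALSE)
  })
  per_pair <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  abort_if(is.null(per_pair) || !nrow(per_pair),
           "no division pair with shared time points",
           class = "insertionfate_insufficient_data")
  if (normalize) {
    colony_mean <- mean(series$expression)
    abort_if(colony_mean <= 0, "colony mean expression must be > 0 to normalize")
    per_pair$divergence <- per_pair$divergence / colony_mean
  }
  structure(list(colony_id = tree$colony_id, per_pair = per_pair,
                 colony_divergence = mean(per_pair$divergence),
                 n_pairs = nrow(per_pair)),
            class = "divergence_result")
}

#' @export
print.divergence_result <- function(x, ...) {
  cat(sprintf("<divergence_result> '%s': colony divergence %.4g over %d division pairs\n",
              x$colony_id, x$colony_divergence, x$n_pairs))
  invisible(x)
}

#' Compare lineage divergence between two groups of colonies
#'
#' Ratio of mean colony divergence (a over b) with a two-sample Wilcoxon
#' rank-sum p-value.
#'
#' @param results_a,results_b Lists of `divergence_result` objects (or
#'   numeric vectors of colony divergences).
#' @return List with `ratio`, `p_value`, `n_a`, `n_b`, `mean_a`, `mean_b`.
#' @export
compare_divergence <- function(results_a, results_b) {
  pull <- function(x) {
    if (is.numeric(x)) return(x)
    vapply(x, function(r) r$colony_divergence, numeric(1))
  }
  a <- pull(results_a); b <- pull(results_b)
  abort_if(!length(a) || !length(b), "both groups must be non-empty",
           class = "insertionfate_validation_error")
  p <- if (length(a) > 1 && length(b) > 1 && (stats::sd(c(a, b)) > 0)) {
    suppressWarnings(stats::wilcox.test(a, b)$p.value)
  } else {
    1
  }
  list(ratio = mean(a) / mean(b), p_value = p, n_a = length(a),
       n_b = length(b), mean_a = mean(a), mean_b = mean(b))
}
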