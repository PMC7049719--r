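# Clone-level expression statistics and noise-scaling classification.
# In the extrinsic-noise regime the standard deviation of expression is
# proportional to the mean (constant CV); clones whose sd scales more
# steeply are flagged as robust outliers of the log(sd/mean) residual
# distribution, and copy-number normalization is provided to test whether
# multi-insertion clones alone explain them.

#' Per-clone summary statistics
#'
#' Mean, sample standard deviation (n-1 denominator) and squared
#' coefficient of variation of a clone's single-cell fluorescence values.
#'
#' @param cells Numeric vector of per-cell fluorescence (a.u.), `n >= 2`.
#' @param clone_id Clone label.
#' @param copy_number Promoter copy number (>= 1).
#' @return One-row data frame with columns `clone_id`, `mean`, `sd`, `cv2`,
#'   `n_cells`, `copy_number`. `cv2` is `NA` when `mean <= 0`.
#' @export
clone_stats <- function(cells, clone_id = "clone", copy_number = 1) {
  abort_if(length(cells) < 2, "need at least 2 cells",
           class = "insertionfate_insufficient_data")
  abort_if(copy_number < 1, "copy_number must be >= 1",
           class = "insertionfate_validation_error")
  m <- mean(cells)
  s <- stats::sd(cells)
  data.frame(clone_id = as.character(clone_id), mean = m, sd = s,
             cv2 = if (m > 0) (s / m)^2 else NA_real_,
             n_cells = length(cells), copy_number = as.integer(copy_number),
             stringsAsFactors = FALSE)
}

#' Summarise a list of clones into a stats table
#'
#' @param clones List of [clone_expression()] objects.
#' @return Data frame with one [clone_stats()] row per clone; copy number
#'   is the number of insertion positions.
#' @export
cohort_stats <- function(clones) {
  do.call(rbind, lapply(clones, function(cl) {
    clone_stats(cl$cells, cl$clone_id, length(cl$insertion_positions))
  }))
}

#' Fit the extrinsic noise-scaling law and flag steep-noise outliers
#'
#' Fits `sd = c * mean` (slope fixed at 1 in log space, the pure extrinsic
#' regime) by the median of `log(sd/mean)`, with the MAD of the residuals
#' as robust scale, so that the outliers under study cannot leak into the
#' baseline. Clones whose positive residual exceeds
#' `threshold_k * residual_scale` are flagged. A free-slope least-squares
#' fit of `log(sd) ~ log(mean)` is reported as a diagnostic.
#'
#' @param stats Data frame as from [cohort_stats()] (columns `clone_id`,
#'   `mean`, `sd`, at least); needs `>= 5` clones with `mean > 0`.
#' @param threshold_k Robust outlier cutoff in MAD-sigma units
#'   (default 3.5, the conventional robust threshold).
#' @return An object of class `noise_scaling_fit`: `slope_c`,
#'   `residual_scale`, `outlier_ids`, `threshold_k`, `free_slope`,
#'   `n_clones`.
#' @export
fit_noise_scaling <- function(stats, threshold_k = 3.5) {
  use <- stats$mean > 0 & stats$sd > 0
  abort_if(sum(use) < 5, "need at least 5 clones with positive mean and sd",
           class = "insertionfate_insufficient_data")
  st <- stats[use, , drop = FALSE]
  r <- log(st$sd / st$mean)
  med <- stats::median(r)
  scale <- stats::mad(r, center = med)  # 1.4826 * MAD, sigma-equivalent
  resid <- r - med
  out <- if (scale > 0) resid > threshold_k * scale else resid > 0
  free <- stats::lm(log(st$sd) ~ log(st$mean))
  structure(list(slope_c = exp(med), residual_scale = scale,
                 outlier_ids = st$clone_id[out], threshold_k = threshold_k,
                 free_slope = unname(stats::coef(free)[2]),
                 n_clones = nrow(st)),
            class = "noise_scaling_fit")
}

#' @export
print.noise_scaling_fit <- function(x, ...) {
  cat(sprintf("<noise_scaling_fit> sd = %.3f * mean (%d clones); free slope %.2f; %d outliers at k = %g\n",
              x$slope_c, x$n_clones, x$free_slope, length(x$outlier_ids),
              x$threshold_k))
  invisible(x)
}

#' Normalize clone statistics by promoter copy number
#'
#' Divides mean and sd by the copy number (cv2 is unchanged) and resets
#' copy number to 1 — the operation that tests whether multi-insertion
#' clones alone explain steep-noise outliers.
#'
#' @param stats Data frame of clone statistics (as [clone_stats()] /
#'   [cohort_stats()]).
#' @return The normalized data frame.
#' @export
normalize_by_copy_number <- function(stats) {
  abort_if(any(stats$copy_number < 1), "copy_number must be >= 1",
           class = "insertionfate_validation_error")
  stats$mean <- stats$mean / stats$copy_number
  stats$sd <- stats$sd / stats$copy_number
  stats$copy_number <- 1L
  stats
}

#' Normalize per-cell expression by promoter copy number
#'
#' Divides each cell's fluorescence by the number of cassette copies
#' contributing in that cell (`cell_copies`; the clone copy number when
#' per-cell counts are absent). Note the distinction from
#' [normalize_by_copy_number()], which rescales clone-level summary
#' statistics: rescaling mean and sd by the same constant leaves sd/mean
#' unchanged, so only the per-cell form can remove variance contributed by
#' cell-to-cell cassette-count heterogeneity in multi-insertion clones.
#'
#' @param clone A [clone_expression()].
#' @return A [clone_expression()] with normalized cells and
#'   `cell_copies` reset.
#' @export
normalize_expression_by_copy_number <- function(clone) {
  copies <- clone$cell_copies %||% rep(length(clone$insertion_positions),
                                       length(clone$cells))
  clone_expression(clone$clone_id, clone$insertion_positions, clone$medium,
                   clone$growth_rate, clone$cells / copies)
}

#' Growth-rate trend of mean expression
#'
#' Least-squares slope of mean expression on growth rate, with a
#' three-way label. The trend separates ordinary clones (expression rises
#' with growth rate, as for a ribosomal promoter) from
#' interference-switching clones (expression falls as the competing operon
#' is transcribed harder).
#'
#' @param growth_rate Growth rates in 1/h (>= 2 distinct values).
#' @param mean_expr Mean expression values (a.u.), same length.
#' @param flat_frac Threshold: the label is `"flat"` when `|slope|` is
#'   below `flat_frac * mean(mean_expr)` per unit growth rate
#'   (default 0.05).
#' @return List with `slope`, `label` in
#'   `{"increasing", "decreasing", "flat"}`, `intercept`.
#' @export
growth_trend <- function(growth_rate, mean_expr, flat_frac = 0.05) {
  abort_if(length(growth_rate) != length(mean_expr), "length mismatch")
  abort_if(length(unique(growth_rate)) < 2,
           "need at least 2 distinct growth rates",
           class = "insertionfate_validation_error")
  fit <- stats::lm(mean_expr ~ growth_rate)
  slope <- unname(stats::coef(fit)[2])
  tol <- flat_frac * mean(mean_expr)
  label <- if (abs(slope) < tol) "flat" else if (slope > 0) "increasing" else "decreasing"
  list(slope = slope, label = label, intercept = unname(stats::coef(fit)[1]))
}
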