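# Circular sliding-window insertion coverage and origin-symmetry
# diagnostics. Windows are centered, width window_bp, half-open
# [c - floor(w/2), c - floor(w/2) + w) on the circle.

#' Circular coverage profile
#'
#' Sliding-window insertion density (insertions per bp, or dimensionless
#' once normalized) at a set of strictly increasing centers on the circle.
#' Also serves as the empirical background for the shuffle null.
#'
#' @param centers Strictly increasing positions in `[0, length_bp)`.
#' @param values Non-negative values, one per center.
#' @param window_bp,step_bp Window width and center spacing in bp.
#' @param normalized Has the profile been divided by its mean?
#' @return An object of class `coverage_profile`.
#' @export
coverage_profile <- function(centers, values, window_bp, step_bp,
                             normalized = FALSE) {
  abort_if(length(values) != length(centers), "centers/values length mismatch")
  abort_if(is.unsorted(centers, strictly = TRUE), "centers must be strictly increasing")
  abort_if(any(values < 0), "values must be non-negative")
  structure(list(centers = as.numeric(centers), values = as.numeric(values),
                 window_bp = window_bp, step_bp = step_bp,
                 normalized = isTRUE(normalized)),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %d windows (w = %g bp, step = %g bp)%s; mean %.4g\n",
              length(x$centers), x$window_bp, x$step_bp,
              if (x$normalized) ", normalized" else "", mean(x$values)))
  invisible(x)
}

# Weighted count of insertions within circular arcs [lo, lo + w) (vectorized
# over lo). Positions are pre-sorted with a parallel cumulative weight.
circular_arc_weight <- function(sorted_pos, cum_w, L, lo, w) {
  S <- function(x) { # total weight of (integer) positions < x, for x in [0, L]
    out <- numeric(length(x))
    if (!length(sorted_pos)) return(out)
    i <- findInterval(x - 0.5, sorted_pos)
    nz <- i > 0
    out[nz] <- cum_w[i[nz]]
    out
  }
  hi <- lo + w
  wrap <- hi > L
  out <- numeric(length(lo))
  out[!wrap] <- S(hi[!wrap]) - S(lo[!wrap])
  if (any(wrap)) {
    total <- if (length(cum_w)) cum_w[length(cum_w)] else 0
    out[wrap] <- (total - S(lo[wrap])) + S(hi[wrap] - L)
  }
  out
}

#' Sliding circular insertion coverage
#'
#' Insertion weight per bp in windows of width `window_bp` centered every
#' `step_bp` around the circle; windows wrap across the origin. This is the
#' profile the study design smooths at 3 kb.
#'
#' @param insertions An [insertion_set()].
#' @param genome A [genome_spec()].
#' @param window_bp Window width (default 3000 bp).
#' @param step_bp Center spacing (default 1000 bp).
#' @return A [coverage_profile()] in insertions per bp.
#' @export
sliding_coverage <- function(insertions, genome, window_bp = 3000, step_bp = 1000) {
  abort_if(window_bp < 1 || step_bp < 1, "window_bp and step_bp must be >= 1")
  abort_if(window_bp > genome$length_bp, "window_bp exceeds genome length",
           class = "insertionfate_validation_error")
  L <- genome$length_bp
  centers <- seq(0, L - 1, by = step_bp)
  ord <- order(insertions$positions)
  sorted_pos <- insertions$positions[ord]
  cum_w <- cumsum(insertion_weights(insertions)[ord])
  lo <- (centers - floor(window_bp / 2)) %% L
  vals <- circular_arc_weight(sorted_pos, cum_w, L, lo, window_bp) / window_bp
  coverage_profile(centers, vals, window_bp = window_bp, step_bp = step_bp)
}

#' Normalize a coverage profile to mean 1
#'
#' Idempotent rescaling used before cross-profile comparison ("y-axis
#' rescaled for comparison").
#'
#' @param profile A [coverage_profile()].
#' @return The profile divided by its mean, with `normalized = TRUE`.
#' @export
normalize_profile <- function(profile) {
  m <- mean(profile$values)
  abort_if(m <= 0, "cannot normalize an all-zero profile",
           class = "insertionfate_validation_error")
  coverage_profile(profile$centers, profile$values / m,
                   window_bp = profile$window_bp, step_bp = profile$step_bp,
                   normalized = TRUE)
}

#' Origin left-right asymmetry of a coverage profile
#'
#' Scale-free diagnostic of the slight left-right insertion-density
#' asymmetry about the origin: `(mean over right replichore - mean over
#' left replichore) / overall mean`, computed on the normalized profile.
#' "Right" is the replichore running from ori towards ter in increasing
#' coordinate.
#'
#' @param profile A [coverage_profile()] covering the genome.
#' @param genome A [genome_spec()].
#' @return Signed asymmetry (0 for an ori-symmetric profile).
#' @export
oriter_asymmetry <- function(profile, genome) {
  prof <- if (profile$normalized) profile else normalize_profile(profile)
  L <- genome$length_bp
  d_fwd <- (prof$centers - genome$ori_pos) %% L
  len_right <- (genome$ter_pos - genome$ori_pos) %% L
  at_boundary <- d_fwd == 0 | d_fwd == len_right
  right <- d_fwd < len_right & !at_boundary
  left <- d_fwd > len_right & !at_boundary
  abort_if(!any(right) || !any(left), "profile does not cover both replichores")
  vals <- prof$values[!at_boundary]
  overall <- mean(vals)
  abort_if(overall <= 0, "zero overall mean", class = "insertionfate_validation_error")
  (mean(prof$values[right]) - mean(prof$values[left])) / overall
}
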