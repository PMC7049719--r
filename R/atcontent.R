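# AT-content bias around insertion sites: AT fraction of insertion-flanking
# windows versus uniformly sampled background windows, compared with a
# one-tailed Kolmogorov-Smirnov test. The KS statistic is computed by an
# exact brute-force ECDF sweep (no binning); the p-value uses the one-sided
# asymptotic formula exp(-2 D^2 nA nB / (nA + nB)).

#' AT fraction of a nucleotide sequence
#'
#' `(A + T) / (A + C + G + T)`, case-insensitive; `N` bases are excluded
#' from numerator and denominator.
#'
#' @param seq Character vector of nucleotide strings over `{A,C,G,T,N}`.
#' @return Numeric vector of AT fractions in `[0, 1]`.
#' @export
#' @examples
#' at_fraction(c("ATAT", "GCGC", "ATGC"))
at_fraction <- function(seq) {
  seq <- toupper(seq)
  n_at <- nchar(gsub("[^AT]", "", seq))
  n_acgt <- nchar(gsub("[^ACGT]", "", seq))
  abort_if(any(n_acgt == 0), "sequence has zero non-N length",
           class = "insertionfate_validation_error")
  n_at / n_acgt
}

#' AT fraction of circular windows centered at given positions
#'
#' Cumulative-sum implementation: O(L) preprocessing, O(1) per window;
#' windows are half-open `[c - floor(w/2), c - floor(w/2) + w)` and wrap
#' around the origin.
#'
#' @param genome_seq Genome sequence as a single character string.
#' @param centers Integer window centers (0-based).
#' @param window_bp Window width in bp.
#' @return Numeric vector of AT fractions, one per center.
#' @export
window_at_fractions <- function(genome_seq, centers, window_bp) {
  L <- nchar(genome_seq)
  abort_if(window_bp < 1 || window_bp > L, "window_bp must be in [1, genome length]")
  chars <- strsplit(toupper(genome_seq), "", fixed = TRUE)[[1]]
  is_at <- as.integer(chars %in% c("A", "T"))
  is_acgt <- as.integer(chars %in% c("A", "C", "G", "T"))
  # pad by one window so wrapped windows read off the same cumsums
  pad <- seq_len(min(window_bp, L))
  cum_at <- c(0, cumsum(c(is_at, is_at[pad])))
  cum_acgt <- c(0, cumsum(c(is_acgt, is_acgt[pad])))
  lo <- (centers - floor(window_bp / 2)) %% L   # 0-based window start
  hi <- lo + window_bp
  at <- cum_at[hi + 1] - cum_at[lo + 1]
  acgt <- cum_acgt[hi + 1] - cum_acgt[lo + 1]
  abort_if(any(acgt == 0), "window has zero non-N length",
           class = "insertionfate_validation_error")
  at / acgt
}

#' One-sided Kolmogorov-Smirnov comparison of two samples
#'
#' Exact brute-force ECDF sweep: `D = sup_x (F_b(x) - F_a(x))`, the
#' one-sided statistic for the alternative "sample `a` is stochastically
#' greater than sample `b`". The p-value uses the asymptotic one-sided
#' formula `exp(-2 D^2 n_a n_b / (n_a + n_b))`.
#'
#' @param a,b Numeric samples.
#' @return List with `d_stat`, `p_value`, `log10_p` (base-10 log of the
#'   asymptotic p, safe from underflow), `n_a`, `n_b`.
#' @export
ks_one_sided <- function(a, b) {
  na <- length(a); nb <- length(b)
  abort_if(na < 1 || nb < 1, "both samples must be non-empty")
  xs <- sort(unique(c(a, b)))
  Fa <- findInterval(xs, sort(a)) / na
  Fb <- findInterval(xs, sort(b)) / nb
  d <- max(c(Fb - Fa, 0))
  log_p <- -2 * d^2 * na * nb / (na + nb)     # natural-log tail, no underflow
  list(d_stat = d, p_value = min(1, exp(log_p)), log10_p = log_p / log(10),
       n_a = na, n_b = nb)
}

#' AT-bias test of insertion-flanking windows
#'
#' Compares the distribution of AT fraction in windows centered on the
#' insertions (sample A) against windows centered at uniformly random
#' background positions (sample B), with a one-tailed KS test of the
#' hard-coded alternative "insertion windows are richer in AT"
#' (`D = sup_x (F_B(x) - F_A(x))`).
#'
#' @param insertions An [insertion_set()].
#' @param genome_seq Genome sequence (character string, length = genome
#'   length).
#' @param genome A [genome_spec()].
#' @param window_bp Window width in bp (default 1000, the scale of typical
#'   silencer-protein binding tracts).
#' @param n_background Number of background windows (default: as many as
#'   there are insertions).
#' @param seed Integer seed for the background sample.
#' @return An object of class `ks_result`: `d_stat`, `p_value`,
#'   `n_insertion`, `n_background`, `window_bp`.
#' @export
insertion_at_bias_test <- function(insertions, genome_seq, genome,
                                   window_bp = 1000, n_background = NULL,
                                   seed = 1) {
  abort_if(window_bp < 10, "window_bp must be >= 10")
  abort_if(nchar(genome_seq) != genome$length_bp,
           "genome_seq length must equal genome length",
           class = "insertionfate_validation_error")
  n_background <- n_background %||% length(insertions$positions)
  abort_if(length(insertions$positions) < 5 || n_background < 5,
           "fewer than 5 windows in a sample",
           class = "insertionfate_insufficient_data")
  bg_pos <- with_seed(derive_seed(seed, "at_background"),
                      floor(stats::runif(n_background) * genome$length_bp))
  a <- window_at_fractions(genome_seq, insertions$positions, window_bp)
  b <- window_at_fractions(genome_seq, bg_pos, window_bp)
  ks <- ks_one_sided(a, b)
  structure(list(d_stat = ks$d_stat, p_value = ks$p_value,
                 log10_p = ks$log10_p,
                 n_insertion = ks$n_a, n_background = ks$n_b,
                 window_bp = window_bp),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("<ks_result> D = %.4f, p = %.3g (%d insertion vs %d background windows of %d bp)\n",
              x$d_stat, x$p_value, x$n_insertion, x$n_background, x$window_bp))
  invisible(x)
}
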