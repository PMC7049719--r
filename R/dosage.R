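# Cooper-Helmstetter age-structured gene dosage: closed-form population
# average, an explicit fork-level simulator used as an internal oracle,
# dosage profiles over the genome, log-log exponent fitting of observed
# insertion density against predicted dosage, and an age-structured
# insertion simulator with an optional power-law-in-time hazard.
#
# Model: in steady exponential growth with doubling time tau, replication
# period C and division period D, a locus at relative replichore position m
# (0 at ori, 1 at ter) is replicated C*(1-m) + D minutes before division.
# A cell of age a carries 2^floor((a + C*(1-m) + D)/tau) copies, and the
# steady-state age density u(a) = (2*log(2)/tau) * 2^(-a/tau) on [0, tau)
# averages this to exactly 2^((C*(1-m) + D)/tau).

#' Cooper-Helmstetter cell-cycle parameters
#'
#' @param C_min Replication period C in minutes (time to replicate one
#'   replichore arm). Default 40, the canonical fast-growth value.
#' @param D_min Division period D in minutes (gap between replication
#'   termination and division). Default 20.
#' @param tau_min Population doubling time in minutes. Default 30
#'   (LB-like fast growth).
#' @return An object of class `dosage_params`.
#' @export
dosage_params <- function(C_min = 40, D_min = 20, tau_min = 30) {
  abort_if(C_min < 0 || D_min < 0, "C_min and D_min must be >= 0")
  abort_if(tau_min <= 0, "tau_min must be > 0")
  structure(list(C_min = C_min, D_min = D_min, tau_min = tau_min),
            class = "dosage_params")
}

#' Power-law-in-time insertion-rate model
#'
#' Describes an insertion hazard per locus copy growing as `age^beta` over
#' the observation window; `beta = 0` recovers the pure-dosage model.
#'
#' @param beta Dimensionless exponent, `>= 0`.
#' @param horizon_min Observation window in minutes.
#' @return An object of class `time_rate_model`.
#' @export
time_rate_model <- function(beta = 0, horizon_min = 60) {
  abort_if(beta < 0, "beta must be >= 0")
  abort_if(horizon_min <= 0, "horizon_min must be > 0")
  structure(list(beta = beta, horizon_min = horizon_min),
            class = "time_rate_model")
}

#' Population-average copy number of a locus
#'
#' Closed-form Cooper-Helmstetter steady-state average
#' `2^((C*(1-m) + D)/tau)` for a locus at relative position `m`.
#'
#' @param m Relative replichore position(s) in `[0, 1]`
#'   (see [locus_relative_position()]).
#' @param params A [dosage_params()].
#' @return Mean copies per cell, `>= 1`.
#' @export
#' @examples
#' mean_copy_number(0, dosage_params(40, 20, 30)) # 2^2 = 4 at the origin
mean_copy_number <- function(m, params) {
  2^((params$C_min * (1 - m) + params$D_min) / params$tau_min)
}

# Copy number carried by a single cell of age a (minutes since birth):
# one ancestral copy, doubled by every replication round whose fork has
# already passed the locus. Exact, used by the fork oracle.
copy_number_at_age <- function(m, age_min, params) {
  2^floor((age_min + params$C_min * (1 - m) + params$D_min) / params$tau_min)
}

# Draw cell ages from the steady-state exponential age distribution
# u(a) = (2 log 2 / tau) 2^(-a/tau) on [0, tau), by inverse CDF.
sample_cell_ages <- function(n, tau_min) {
  u <- stats::runif(n)
  tau_min * (1 - log2(2 - u))
}

#' Fork-level simulation of locus copy number
#'
#' Explicit age-structured oracle for [mean_copy_number()]: draws cell ages
#' from the steady-state age distribution, reconstructs per-cell fork state
#' and averages the resulting copy numbers. Used to validate the closed
#' form, never to replace it.
#'
#' @param m Relative position(s) in `[0, 1]`.
#' @param params A [dosage_params()].
#' @param n_cells Number of cells to simulate.
#' @param seed Integer seed.
#' @return A data frame with columns `m`, `mean`, `se` (standard error of
#'   the mean).
#' @export
simulate_copy_number_fork <- function(m, params, n_cells = 1e5, seed = 1) {
  ages <- with_seed(seed, sample_cell_ages(n_cells, params$tau_min))
  res <- vapply(m, function(mi) {
    cn <- copy_number_at_age(mi, ages, params)
    c(mean(cn), stats::sd(cn) / sqrt(n_cells))
  }, numeric(2))
  data.frame(m = m, mean = res[1, ], se = res[2, ])
}

#' Expected dosage profile along the genome
#'
#' Evaluates [mean_copy_number()] at bin centers around the circle (or at
#' caller-supplied centers, e.g. to match an observed coverage profile).
#'
#' @param genome A [genome_spec()].
#' @param params A [dosage_params()].
#' @param n_bins Number of equal bins (>= 2); ignored when `centers` given.
#' @param centers Optional explicit bin centers in bp.
#' @param normalized Divide the profile by its mean?
#' @return A [coverage_profile()].
#' @export
dosage_profile <- function(genome, params, n_bins = 100, centers = NULL,
                           normalized = FALSE) {
  if (is.null(centers)) {
    abort_if(n_bins < 2, "n_bins must be >= 2")
    step <- genome$length_bp / n_bins
    centers <- (seq_len(n_bins) - 0.5) * step
    window <- step
  } else {
    window <- if (length(centers) > 1) centers[2] - centers[1] else genome$length_bp
  }
  vals <- mean_copy_number(locus_relative_position(centers, genome), params)
  if (normalized) vals <- vals / mean(vals)
  coverage_profile(centers, vals, window_bp = window, step_bp = window,
                   normalized = normalized)
}

#' Fit the exponent linking observed insertion density to expected dosage
#'
#' Least-squares fit of `log(observed) = intercept + alpha * log(predicted)`
#' over bins, after normalizing both profiles to mean 1 (the fit is thereby
#' scale-invariant). Zero observed bins are dropped, not pseudo-counted;
#' the dropped count is reported.
#'
#' @param observed,predicted [coverage_profile()]s on identical bins;
#'   `predicted` must be strictly positive.
#' @return An object of class `exponent_fit`: `alpha`, `alpha_stderr`,
#'   `intercept`, `n_bins` (bins used), `n_dropped`.
#' @export
fit_dosage_exponent <- function(observed, predicted) {
  abort_if(length(observed$centers) != length(predicted$centers) ||
             any(abs(observed$centers - predicted$centers) > 1e-6),
           "profiles must share identical bins")
  abort_if(any(predicted$values <= 0), "predicted values must all be > 0")
  abort_if(any(observed$values < 0), "observed values must be >= 0")
  obs <- observed$values / mean(observed$values)
  pred <- predicted$values / mean(predicted$values)
  use <- obs > 0
  n_dropped <- sum(!use)
  abort_if(sum(use) < 3, "fewer than 3 usable bins for the log-log fit",
           class = "insertionfate_insufficient_data")
  fit <- stats::lm(log(obs[use]) ~ log(pred[use]))
  # noise-free profiles fit exactly; the perfect-fit warning is expected
  cf <- suppressWarnings(summary(fit))$coefficients
  structure(list(alpha = unname(cf[2, 1]), alpha_stderr = unname(cf[2, 2]),
                 intercept = unname(cf[1, 1]), n_bins = sum(use),
                 n_dropped = n_dropped),
            class = "exponent_fit")
}

#' @export
print.exponent_fit <- function(x, ...) {
  cat(sprintf("<exponent_fit> alpha = %.3f +/- %.3f (%d bins, %d dropped)\n",
              x$alpha, x$alpha_stderr, x$n_bins, x$n_dropped))
  invisible(x)
}

#' Simulate insertions in an age-structured growing population
#'
#' Explicit generative model for the insertion landscape. Each insertion
#' event samples a cell from the steady-state age distribution and a
#' uniform hazard per locus copy: the cell's fork state (a locus is
#' present in `2^k` copies once passed by `k` active rounds) selects the
#' target locus, and the position is placed uniformly within the selected
#' dosage stratum of a replichore chosen in proportion to its length, so
#' that with `beta = 0` the position density equals the closed-form dosage
#' profile exactly (the oracle relation). For `beta > 0` the insertion
#' rate grows as a power law across the outgrowth window; in a steadily
#' growing population a purely time-dependent per-copy rate leaves the
#' position marginal untouched, so the observable consequence modelled
#' here is the compounding of the per-cycle dosage advantage of
#' origin-proximal loci through the rounds of outgrowth the rate growth
#' weights: the retained density is tilted to `dosage^(1 + beta)`,
#' implemented as an exact rejection layer over the fork-level simulator.
#' `beta > 0` therefore strictly and monotonically steepens the ori/ter
#' density ratio; `beta` is a free simulator parameter, not a fitted one.
#'
#' @param genome A [genome_spec()].
#' @param params A [dosage_params()].
#' @param model A [time_rate_model()].
#' @param n Number of insertions to draw.
#' @param seed Integer seed.
#' @return An [insertion_set()] of `n` positions (unit weights).
#' @export
simulate_age_structured_insertions <- function(genome, params,
                                               model = time_rate_model(),
                                               n, seed = 1) {
  abort_if(n < 0, "n must be >= 0")
  if (n == 0) return(insertion_set(numeric(), genome = genome))
  C <- params$C_min; D <- params$D_min; tau <- params$tau_min
  L <- genome$length_bp
  len_right <- (genome$ter_pos - genome$ori_pos) %% L
  len_left <- L - len_right
  # Given ages, tabulate the dosage strata over m: copy number is piecewise
  # constant with breakpoints where floor((a + C*(1-m) + D)/tau) steps.
  strata <- function(ages) {
    nn <- length(ages)
    k_lo <- floor((ages + D) / tau)            # value at m = 1
    k_hi <- floor((ages + D + C) / tau)        # value at m = 0
    kmax <- max(k_hi - k_lo)
    seg_w <- matrix(0, nn, kmax + 1L)
    seg_a <- matrix(0, nn, kmax + 1L)          # segment lower m bound
    seg_b <- matrix(0, nn, kmax + 1L)          # segment upper m bound
    for (j in 0:kmax) {
      k <- k_lo + j
      lo <- if (C > 0) 1 - ((k + 1) * tau - ages - D) / C else rep(0, nn)
      hi <- if (C > 0) 1 - (k * tau - ages - D) / C else rep(1, nn)
      lo <- pmin(pmax(lo, 0), 1); hi <- pmin(pmax(hi, 0), 1)
      len <- pmax(hi - lo, 0)
      if (C == 0) len <- as.numeric(j == 0)
      seg_a[, j + 1L] <- lo; seg_b[, j + 1L] <- hi
      seg_w[, j + 1L] <- 2^k * len
    }
    list(a = seg_a, b = seg_b, w = seg_w,
         tot = rowSums(seg_w))                 # Z(a) = integral of n(m, a) dm
  }
  # upper bound on Z(a): n(m, a) <= 2^((a + C + D)/tau) <= 2^(1 + (C + D)/tau)
  z_bound <- 2^(1 + (C + D) / tau)
  d_max <- mean_copy_number(0, params)
  with_seed(seed, {
    draw_batch <- function(nn) {
      # (a, m) ~ u(a) * n(m, a): sample a by exact rejection with weight
      # prop. to Z(a), then m within the accepted age's dosage strata.
      ages <- numeric(0)
      while (length(ages) < nn) {
        cand <- sample_cell_ages(2L * (nn - length(ages)) + 16L, tau)
        acc <- strata(cand)$tot / z_bound
        ages <- c(ages, cand[stats::runif(length(cand)) < acc])
      }
      ages <- ages[seq_len(nn)]
      sg <- strata(ages)
      cum <- t(apply(sg$w, 1L, cumsum))
      u <- stats::runif(nn) * sg$tot
      pick <- rowSums(u > cum) + 1L
      idx <- cbind(seq_len(nn), pick)
      sg$a[idx] + stats::runif(nn) * (sg$b[idx] - sg$a[idx])
    }
    m <- numeric(0)
    while (length(m) < n) {
      cand <- draw_batch(n - length(m))
      if (model$beta > 0) {
        # outgrowth compounding: retain with prob (d(m)/d_max)^beta, so the
        # final density is dosage^(1 + beta) (exact rejection)
        keep <- stats::runif(length(cand)) <
          (mean_copy_number(cand, params) / d_max)^model$beta
        cand <- cand[keep]
      }
      m <- c(m, cand)
    }
    m <- m[seq_len(n)]
    right <- stats::runif(n) < len_right / L
    pos <- ifelse(right,
                  (genome$ori_pos + floor(m * len_right)) %% L,
                  (genome$ori_pos - floor(m * len_left)) %% L)
    insertion_set(pos, genome = genome)
  })
}
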