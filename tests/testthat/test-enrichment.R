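test_that("overlap score counts flanked, merged, half-open circular intervals", {
  g <- genome_spec(100, 0, 50)
  iv <- interval_set(10, 20, name = "t")
  ins <- insertion_set(c(5, 15, 25), genome = g)
  expect_equal(overlap_score(ins, iv, g, flank_bp = 0), 1)
  expect_equal(overlap_score(ins, iv, g, flank_bp = 5), 2) # [5,25): 25 excluded
  empty <- interval_set(numeric(), numeric(), name = "e")
  expect_equal(overlap_score(ins, empty, g), 0)
  # merging prevents double counting of overlapping extended intervals
  iv2 <- interval_set(c(10, 12), c(20, 22), name = "o")
  expect_equal(overlap_score(ins, iv2, g, flank_bp = 0), 1)
  # weights are summed
  insw <- insertion_set(c(15, 16), weights = c(2.5, 4), genome = g)
  expect_equal(overlap_score(insw, iv, g), 6.5)
  # wraparound: interval crossing the origin stored as two records, one id
  ivw <- interval_set(c(95, 0), c(100, 5), id = c("w", "w"), name = "w")
  expect_equal(overlap_score(insertion_set(c(97, 3, 10), genome = g), ivw, g), 2)
  # gene-level mode counts features hit
  ivg <- interval_set(c(10, 60), c(20, 70), id = c("g1", "g2"), name = "g")
  expect_equal(overlap_score(insertion_set(c(11, 12), genome = g), ivg, g,
                             mode = "genes"), 1)
})

test_that("merge_intervals handles flanks that wrap and whole-genome coverage", {
  g <- genome_spec(100, 0, 50)
  arcs <- merge_intervals(interval_set(2, 6, name = "x"), g, flank_bp = 4)
  # [-2, 10) wraps: arcs [0,10) and [98,100)
  expect_equal(sum(arcs$end - arcs$start), 12)
  all_arcs <- merge_intervals(interval_set(10, 20, name = "x"), g, flank_bp = 60)
  expect_equal(all_arcs, data.frame(start = 0, end = 100))
})

test_that("density-preserving shuffle follows its background", {
  g <- genome_spec(100000, 0)
  centers <- seq(2500, 99999, by = 5000)
  expect_length(density_preserving_shuffle(0, coverage_profile(centers,
    rep(1, 20), 5000, 5000), g, seed = 1), 0)
  # uniform background -> uniform positions (chi-square GOF)
  unif <- coverage_profile(centers, rep(1, 20), 5000, 5000)
  pos <- density_preserving_shuffle(5e4, unif, g, seed = 5)$positions
  counts <- as.numeric(table(cut(pos, seq(0, 1e5, by = 5000))))
  chi <- sum((counts - 2500)^2 / 2500)
  expect_gt(stats::pchisq(chi, df = 19, lower.tail = FALSE), 0.01)
  # all mass in one bin -> all positions in that bin
  onebin <- coverage_profile(centers, c(rep(0, 7), 1, rep(0, 12)), 5000, 5000)
  pos1 <- density_preserving_shuffle(500, onebin, g, seed = 2)$positions
  expect_true(all(pos1 >= 35000 & pos1 < 40000))
  expect_error(density_preserving_shuffle(10, coverage_profile(centers,
    rep(0, 20), 5000, 5000), g, seed = 1), class = "insertionfate_validation_error")
})

test_that("enrichment Z matches the binomial closed form and flags degenerate nulls", {
  g <- genome_spec(100000, 0)
  bg <- coverage_profile(seq(500, 99999, by = 1000), rep(1, 100), 1000, 1000)
  iv <- interval_set(0, 10000, name = "tenpct")
  set.seed(9)
  ins <- insertion_set(c(sample(0:9999, 200, TRUE), sample(10000:99999, 800, TRUE)),
                       genome = g)
  r <- enrichment_z(ins, iv, g, bg, n_shuffles = 2000, seed = 4)
  # expected Z = (200 - 100) / sqrt(1000 * 0.1 * 0.9) = 10.54
  expect_equal(r$z, 10.54, tolerance = 0.08)
  expect_lt(r$p_emp, 0.001)
  # whole-genome list: every shuffle scores n -> degenerate
  rd <- enrichment_z(ins, interval_set(0, 100000, name = "all"), g, bg,
                     n_shuffles = 50, seed = 1)
  expect_true(rd$degenerate)
  expect_true(is.na(rd$z))
})

test_that("adding an interval containing observed insertions never lowers the score", {
  g <- genome_spec(10000, 0)
  set.seed(21)
  ins <- insertion_set(sample(0:9999, 300, TRUE), genome = g)
  iv1 <- interval_set(1000, 2000, name = "a")
  s1 <- overlap_score(ins, iv1, g)
  iv2 <- interval_set(c(1000, 5000), c(2000, 5500), name = "ab")
  expect_gte(overlap_score(ins, iv2, g), s1)
})

test_that("the empirical p tail is selectable and depletion is detectable", {
  g <- genome_spec(10000, 0)
  bg <- coverage_profile(seq(250, 9999, by = 500), rep(1, 20), 500, 500)
  iv <- interval_set(0, 2000, name = "x")
  dep <- insertion_set(seq(2500, 9900, length.out = 100), genome = g) # depleted
  r <- enrichment_z(dep, iv, g, bg, n_shuffles = 500, seed = 3, alternative = "less")
  expect_lt(r$z, 0)
  expect_lt(r$p_emp, 0.05) # counted on the depletion side
  r_auto <- enrichment_z(dep, iv, g, bg, n_shuffles = 500, seed = 3,
                         alternative = "auto")
  expect_equal(r_auto$p_emp, r$p_emp)
  # default (enrichment tail): a depleted list gives p near 1
  r_g <- enrichment_z(dep, iv, g, bg, n_shuffles = 500, seed = 3)
  expect_gt(r_g$p_emp, 0.5)
})

test_that("flank coverage statistic matches the hand-computed toy", {
  g <- genome_spec(100, 0, 50)
  iv <- interval_set(50, 55, name = "f")
  bg <- coverage_profile(seq(5, 99, by = 10), rep(1, 10), 10, 10)
  r <- flank_coverage_enrichment(insertion_set(50, genome = g), iv, g,
                                 flank_bp = 10, background = bg,
                                 n_shuffles = 200, seed = 2)
  expect_equal(r$observed, 0.5) # window [45, 55) half-covered by [50, 55)
  # whole-genome interval set: observed 1 and degenerate
  r1 <- flank_coverage_enrichment(insertion_set(50, genome = g),
                                  interval_set(0, 100, name = "all"), g,
                                  flank_bp = 10, background = bg,
                                  n_shuffles = 50, seed = 2)
  expect_equal(r1$observed, 1)
  expect_true(r1$degenerate)
})
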