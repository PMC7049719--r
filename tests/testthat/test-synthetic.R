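test_that("synthetic genomes honor their configuration and are deterministic", {
  cfg <- small_config()
  ag <- make_genome(cfg, seed = 3)
  expect_equal(length(ag$intervals$rrn), 7)
  expect_equal(length(ag$intervals$hns_targets), 20)
  expect_equal(nchar(ag$sequence), cfg$genome$length_bp)
  ag2 <- make_genome(cfg, seed = 3)
  expect_identical(ag$sequence, ag2$sequence)
  expect_identical(ag$intervals$hns_targets$intervals, ag2$intervals$hns_targets$intervals)
  expect_false(identical(ag$sequence, make_genome(cfg, seed = 4)$sequence))
  # no islands -> genome-wide AT matches the background level within 1%
  ag0 <- make_genome(small_config(genome = list(n_islands = 0)), seed = 5)
  expect_equal(at_fraction(ag0$sequence), 0.5, tolerance = 0.01)
  # islands are AT-enriched relative to background
  arcs <- merge_intervals(ag$intervals$hns_targets, ag$genome)
  isl_at <- window_at_fractions(ag$sequence,
                                floor((arcs$start + arcs$end) / 2), 300)
  expect_gt(mean(isl_at), 0.6)
  # essential genes never sit inside islands
  ess <- ag$intervals$essential$intervals
  mids <- floor((ess$start + ess$end) / 2)
  expect_false(any(insertionfate:::positions_in_arcs(mids, arcs)))
})

test_that("insertion sampling follows its configured biases", {
  cfg <- small_config()
  ag <- make_genome(cfg, seed = 6)
  # null case: alpha = 0, no AT boost, full survival -> uniform positions
  cfg_null <- small_config(insertions = list(alpha = 0, at_boost = 0,
                                             essential_survival = 1))
  pos <- sample_insertions(ag, cfg_null, seed = 7, n = 2e4)$positions
  counts <- as.numeric(table(cut(pos, seq(0, 2e5, by = 1e4))))
  chi <- sum((counts - 1000)^2 / 1000)
  expect_gt(stats::pchisq(chi, df = 19, lower.tail = FALSE), 0.01)
  # zero survival -> no insertions inside essential genes
  cfg_s0 <- small_config(insertions = list(essential_survival = 0))
  ins0 <- sample_insertions(ag, cfg_s0, seed = 8)
  ess_arcs <- merge_intervals(ag$intervals$essential, ag$genome)
  expect_equal(sum(insertionfate:::positions_in_arcs(ins0$positions, ess_arcs)), 0)
  # determinism
  expect_identical(sample_insertions(ag, cfg, seed = 9)$positions,
                   sample_insertions(ag, cfg, seed = 9)$positions)
  expect_length(sample_insertions(ag, cfg, seed = 1, n = 0), 0)
})

test_that("clone classes follow position and orientation rules", {
  cfg <- small_config()
  ag <- make_genome(cfg, seed = 10)
  rrn <- ag$intervals$rrn$intervals
  isl <- ag$intervals$hns_targets$intervals
  far <- 0:(ag$genome$length_bp - 1)
  rrn_arcs <- merge_intervals(ag$intervals$rrn, ag$genome, flank_bp = 0)
  isl_near <- merge_intervals(ag$intervals$hns_targets, ag$genome,
                              flank_bp = cfg$expression$hns_proximity_bp)
  outside <- far[!insertionfate:::positions_in_arcs(far, rrn_arcs) &
                   !insertionfate:::positions_in_arcs(far, isl_near)]
  cls <- insertionfate:::classify_position(
    c(rrn$start[1] + 10, isl$start[1] + 5, outside[1]),
    c("opposite", "same", "same"), ag, cfg)
  expect_equal(cls, c("rrn_switching", "silenced", "normal"))
  # same-orientation rrn insertion is not switching
  cls2 <- insertionfate:::classify_position(rrn$start[1] + 10, "same", ag, cfg)
  expect_false(cls2 == "rrn_switching")
  # multi-insertion fraction 0 -> all single
  cfg_m0 <- small_config(expression = list(multi_insertion_fraction = 0))
  ins <- sample_insertions(ag, cfg_m0, seed = 2, n = 200)
  phen <- assign_clone_phenotypes(ins, ag, cfg_m0, seed = 3)
  expect_true(all(phen$copy_number == 1))
})

test_that("telegraph occupancy and expression means follow the model", {
  cfg <- synth_config()
  # k_on = k_off -> half the cells in the high state
  cfg_eq <- synth_config(expression = list(k_on = 0.05, k_off = 0.05, cv_ext = 0))
  ce <- sample_cell_expression(toy_clone(class = "rrn_switching"), 1e4, "fast",
                               cfg_eq, seed = 20)
  p_on <- mean(ce$cells > cfg_eq$expression$level_off + 1)
  expect_equal(p_on, 0.5, tolerance = 3 * sqrt(0.25 / 1e4) / 0.5)
  # cv_ext = 0, normal clone -> all cells exactly at the class mean
  cfg0 <- synth_config(expression = list(cv_ext = 0))
  cn <- sample_cell_expression(toy_clone(), 100, "fast", cfg0, seed = 21)
  expect_equal(unique(cn$cells), cfg0$expression$expr_scale * 1.4)
  # silenced mean is the silencing factor times the normal mean
  cs <- sample_cell_expression(toy_clone(class = "silenced"), 100, "fast", cfg0, seed = 22)
  expect_equal(unique(cs$cells),
               cfg0$expression$expr_scale * 1.4 * cfg0$expression$silencing_factor)
  # switching clones fall with growth rate, normal clones rise
  e <- cfg$expression
  gr <- e$media$growth_rate
  mu_rrn <- e$interference_scale / gr
  expect_equal(growth_trend(gr, mu_rrn)$label, "decreasing")
  expect_equal(growth_trend(gr, e$expr_scale * gr)$label, "increasing")
})

test_that("noise-scaling recovery closes the loop on a generated cohort", {
  cfg <- synth_config()
  clones <- lapply(1:100, function(i) {
    sample_cell_expression(toy_clone(sprintf("n%03d", i)), 1000, "fast", cfg,
                           seed = 600 + i)
  })
  fit <- fit_noise_scaling(cohort_stats(clones))
  expect_equal(fit$slope_c, cfg$expression$cv_ext, tolerance = 0.05 * 0.3)
})

test_that("sorting reweights clone frequencies through the gate", {
  cfg <- small_config()
  clones <- list(
    clone_expression("lo", 1, "fast", 1.4, rep(10, 50)),
    clone_expression("mid", 2, "fast", 1.4, rep(100, 50)),
    clone_expression("hi", 3, "fast", 1.4, rep(300, 50))
  )
  f0 <- rep(1 / 3, 3)
  expect_equal(sort_population(clones, f0, c(0, Inf)), f0)
  f_ex <- sort_population(clones, f0, c(50, Inf))
  expect_equal(f_ex, c(0, 0.5, 0.5))
  # multiple rounds sharpen relative enrichment of partial passers
  part <- list(
    clone_expression("a", 1, "fast", 1.4, c(rep(1, 90), rep(100, 10))),
    clone_expression("b", 2, "fast", 1.4, rep(100, 100))
  )
  f1 <- sort_population(part, c(0.5, 0.5), c(50, Inf), rounds = 1)
  f4 <- sort_population(part, c(0.5, 0.5), c(50, Inf), rounds = 4)
  expect_lt(f4[1], f1[1])
  expect_error(sort_population(clones, f0, c(1000, 2000)),
               class = "insertionfate_validation_error")
})

test_that("low-gate sorting enriches silenced and switching clones", {
  cfg <- small_config()
  ag <- make_genome(cfg, seed = 30)
  for (s in c(1, 2)) {
    coh <- clone_cohort(ag, cfg, seed = 30 + s, n_cells = 300)
    phen <- coh$phenotypes
    f0 <- rep(1 / phen$n, phen$n)
    f_low <- sort_population(coh$clones, f0, cfg$sort$low_gate)
    lowexp <- phen$class %in% c("silenced", "rrn_switching")
    expect_gt(sum(f_low[lowexp]), sum(f0[lowexp]))
  }
})

test_that("microcolony trees have the right shape and inherit state at division", {
  cfg <- synth_config()
  tr <- simulate_microcolony(toy_clone(), cfg, seed = 40, generations = 3)
  leaves <- setdiff(tr$nodes$id, tr$nodes$parent)
  expect_length(leaves, 8)
  expect_equal(sum(tr$nodes$id %in% tr$nodes$parent), 7)
  # deterministic given seed
  tr2 <- simulate_microcolony(toy_clone(), cfg, seed = 40, generations = 3)
  expect_identical(tr$series, tr2$series)
  # sisters share their value at the division time point
  div_parents <- unique(tr$nodes$parent[!is.na(tr$nodes$parent)])
  for (p in div_parents[1:3]) {
    kids <- tr$nodes$id[!is.na(tr$nodes$parent) & tr$nodes$parent == p]
    tb <- tr$nodes$birth_min[tr$nodes$id == kids[1]]
    e1 <- tr$series$expression[tr$series$id == kids[1] & tr$series$time_min == tb]
    e2 <- tr$series$expression[tr$series$id == kids[2] & tr$series$time_min == tb]
    expect_equal(e1, e2)
  }
  # frozen-on switch with no extrinsic noise -> constant expression, zero divergence
  cfg_frozen <- synth_config(expression = list(k_on = 1, k_off = 0, cv_ext = 0))
  trf <- simulate_microcolony(toy_clone(class = "rrn_switching"), cfg_frozen,
                              seed = 41, generations = 2)
  expect_equal(stats::sd(trf$series$expression), 0)
  expect_equal(sister_divergence(trf)$colony_divergence, 0)
})

test_that("telegraph colonies diverge more than matched-mean extrinsic colonies", {
  cfg <- synth_config()
  e <- cfg$expression
  gr <- 1.4
  tel_mean <- insertionfate:::telegraph_p_on(e) * (e$interference_scale / gr) +
    (1 - insertionfate:::telegraph_p_on(e)) * e$level_off
  cfg_match <- synth_config(expression = list(expr_scale = tel_mean / gr))
  dv_tel <- vapply(1:12, function(i) {
    sister_divergence(simulate_microcolony(toy_clone(class = "rrn_switching"),
                                           cfg, seed = 700 + i))$colony_divergence
  }, numeric(1))
  dv_nor <- vapply(1:12, function(i) {
    sister_divergence(simulate_microcolony(toy_clone(), cfg_match,
                                           seed = 800 + i))$colony_divergence
  }, numeric(1))
  cmp <- compare_divergence(dv_tel, dv_nor)
  expect_gt(cmp$ratio, 2)
  expect_lt(cmp$p_value, 0.01)
})

test_that("population sequencing reports clones above the detection threshold", {
  phen <- structure(list(clone_id = c("a", "b", "c"), class = rep("normal", 3),
                         orientation = rep("same", 3), copy_number = c(1, 1, 1),
                         positions = list(10, 20, 30),
                         pos_classes = list("normal", "normal", "normal"),
                         n = 3L), class = "clone_phenotypes")
  ins <- population_insertions(phen, c(0.6, 0.399, 0.001))
  expect_equal(ins$positions, c(10, 20))
  expect_equal(ins$labels, c("a", "b"))
})
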