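test_that("circular distance wraps, is symmetric and obeys the triangle inequality", {
  g <- toy_genome()
  expect_equal(circular_distance(10, 90, g), 20)
  expect_equal(circular_distance(5, 5, g), 0)
  expect_equal(circular_distance(0, 50, g), 50)
  set.seed(11)
  a <- sample(0:99, 60, TRUE); b <- sample(0:99, 60, TRUE); c <- sample(0:99, 60, TRUE)
  expect_equal(circular_distance(a, b, g), circular_distance(b, a, g))
  expect_true(all(circular_distance(a, c, g) <=
                    circular_distance(a, b, g) + circular_distance(b, c, g)))
  expect_true(all(circular_distance(a, b, g) <= g$length_bp / 2))
})

test_that("relative replichore position maps ori to 0, ter to 1 on both arcs", {
  g <- toy_genome()
  expect_equal(locus_relative_position(0, g), 0)
  expect_equal(locus_relative_position(50, g), 1)
  expect_equal(locus_relative_position(75, g), 0.5) # left replichore, 25 of 50
  expect_equal(locus_relative_position(25, g), 0.5)
  # unequal replichores
  gu <- genome_spec(100, ori_pos = 0, ter_pos = 40)
  expect_equal(locus_relative_position(20, gu), 0.5)
  expect_equal(locus_relative_position(70, gu), 0.5) # left arc is 60 bp
})

test_that("domain constructors enforce their invariants", {
  expect_error(genome_spec(100, 30, 30), "must differ")
  expect_error(genome_spec(100, 120), "lie in")
  expect_error(interval_set(10, 10), "end > start")
  expect_error(interval_set(10, 120, genome = toy_genome()), "exceeds genome length")
  expect_error(insertion_set(100, genome = toy_genome()), "half-open")
  expect_error(insertion_set(c(1, 2), weights = c(1, -1)), "non-negative")
  expect_error(clone_expression("c", numeric(0), "m", 1, c(1, 2)), "copy number")
  # lineage invariants: one parent each, binary divisions, series in lifespan
  nodes <- data.frame(id = c("r", "a"), parent = c(NA, "r"),
                      birth_min = c(0, 5), end_min = c(5, 10))
  ser <- data.frame(id = "a", time_min = 7, expression = 1)
  expect_error(lineage_tree(nodes, ser), "exactly two children")
  nodes2 <- rbind(nodes, data.frame(id = "b", parent = "r", birth_min = 5, end_min = 10))
  expect_s3_class(lineage_tree(nodes2, ser), "lineage_tree")
  bad <- data.frame(id = "a", time_min = 20, expression = 1)
  expect_error(lineage_tree(nodes2, bad), "within")
})

test_that("BED parsing validates coordinates and names offending lines", {
  g <- toy_genome()
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr\t10\t20\tgeneA", f)
  iv <- read_intervals(f, g)
  expect_equal(iv$intervals$start, 10)
  expect_equal(iv$intervals$end, 20)
  expect_equal(iv$intervals$id, "geneA")

  writeLines(character(), f)
  expect_equal(length(read_intervals(f, g)), 0)

  writeLines(c("chr\t10\t20", "chr\t30\t25"), f)
  expect_error(read_intervals(f, g), "line 2")

  writeLines("chr\t10", f)
  expect_error(read_intervals(f, g), "fewer than 3")

  writeLines("chr\t10\t200", f)
  expect_error(read_intervals(f, g), "outside")
})

test_that("insertion tables round-trip and default weights to 1", {
  g <- genome_spec(1000)
  f <- withr::local_tempfile(fileext = ".tsv")
  x <- insertion_set(c(100, 200), weights = c(5, 2), labels = c("a", "b"), genome = g)
  write_insertions(x, f, comments = c("seed=1"))
  y <- read_insertions(f, g)
  expect_equal(y$positions, x$positions)
  expect_equal(y$weights, x$weights)
  expect_equal(y$labels, x$labels)
  # missing weight column -> all-1 weights
  writeLines(c("position", "100", "200"), f)
  z <- read_insertions(f, g)
  expect_null(z$weights)
  expect_equal(insertionfate:::insertion_weights(z), c(1, 1))
  # out-of-range position rejected
  writeLines(c("position", "1000"), f)
  expect_error(read_insertions(f, g), "half-open")
})

test_that("interval, FASTA, cell and lineage writers round-trip exactly", {
  g <- genome_spec(5000)
  dir <- withr::local_tempdir()
  iv <- interval_set(c(10, 400), c(200, 600), id = c("x", "y"),
                     strand = c("+", "-"), name = "lists", genome = g)
  bed <- file.path(dir, "iv.bed")
  write_intervals(iv, bed, comments = "k=v")
  iv2 <- read_intervals(bed, g, name = "lists")
  expect_equal(iv2$intervals, iv$intervals)

  seq <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  fa <- file.path(dir, "g.fasta")
  write_genome_sequence(seq, fa)
  expect_equal(read_genome_sequence(fa), seq)

  cells <- data.frame(clone_id = "c1", cell_id = 1:3, fluorescence = c(1.5, 2, 0),
                      medium = "fast", growth_rate = 1.4)
  cf <- file.path(dir, "cells.tsv")
  write_cells(cells, cf)
  expect_equal(read_cells(cf), cells)

  tr <- toy_tree(c(1, 3), c(2, 2))
  ep <- file.path(dir, "edges.tsv"); sp <- file.path(dir, "series.tsv")
  write_lineage(tr, ep, sp)
  tr2 <- read_lineage(ep, sp)
  expect_equal(tr2$nodes, tr$nodes)
  expect_equal(tr2$series, tr$series)
})

test_that("derived seeds are deterministic, distinct per stage and below 2^31", {
  s1 <- derive_seed(1L, "simulate")
  expect_identical(s1, derive_seed(1L, "simulate"))
  expect_false(s1 == derive_seed(1L, "enrich"))
  expect_false(s1 == derive_seed(2L, "simulate"))
  big <- vapply(1:200, function(i) derive_seed(i, "x"), integer(1))
  expect_true(all(big > 0 & big < 2^31))
})
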