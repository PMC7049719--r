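# Shared fixtures: tiny genomes, toy lineage trees, reduced synthetic
# configurations. Everything is built in code at test time.

toy_genome <- function(L = 100, ori = 0, ter = 50) genome_spec(L, ori, ter)

# Small synthetic world for fast integration tests.
small_config <- function(genome = list(), insertions = list(), ...) {
  synth_config(
    genome = utils::modifyList(
      list(length_bp = 200000, ori_pos = 40000, ter_pos = 140000,
           n_islands = 20, n_essential = 25), genome),
    insertions = utils::modifyList(list(n = 500), insertions),
    ...
  )
}

# Two-leaf lineage: root r on [0, 10], children a/b on [10, 20], with
# expression values supplied per child at times 10 and 15.
toy_tree <- function(ea, eb, root_expr = 1) {
  nodes <- data.frame(id = c("r", "a", "b"), parent = c(NA, "r", "r"),
                      birth_min = c(0, 10, 10), end_min = c(10, 20, 20),
                      stringsAsFactors = FALSE)
  series <- rbind(
    data.frame(id = "r", time_min = c(0, 5, 10), expression = root_expr),
    data.frame(id = "a", time_min = c(10, 15), expression = ea),
    data.frame(id = "b", time_min = c(10, 15), expression = eb)
  )
  lineage_tree(nodes, series)
}

# Uniform random positions on a genome under a local seed.
with_seed_positions <- function(genome, n, seed) {
  withr::local_seed(seed)
  floor(runif(n) * genome$length_bp)
}

# Clone phenotype record for direct expression sampling.
toy_clone <- function(id = "c1", class = "normal", k = 1, pos = 1000,
                      orientation = "same") {
  list(clone_id = id, class = class, orientation = orientation,
       positions = rep(pos, k), pos_classes = rep(class, k))
}
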