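# Shared fixtures: small synthetic cohorts and graphs built in code.

balanced_config <- function(donors = 10L, seed = 1L, ...) {
  cohort_config(
    donors_per_class = stats::setNames(rep(as.integer(donors), 7),
                                       phenotype_levels()),
    seed = seed, ...
  )
}

small_config <- function(seed = 1L, ...) {
  balanced_config(
    donors = 6L, seed = seed, n_probes = 320L, n_genes = 300L,
    planted_modules = data.frame(
      phenotype = c("DryAMD", "Global"), region = c("macula", "both"),
      direction = c("Up", "Up"), n_genes = c(15L, 10L), effect = 1.5,
      tissue = "RPE-choroid", stringsAsFactors = FALSE
    ),
    ...
  )
}

# deterministic toy two-block significance matrix
block_matrix <- function(n_per_block = 10, noise_sd = 0.1, seed = 99) {
  set.seed(seed)
  up <- matrix(rep(c(3, 3, 3, 0, 0, 0), each = n_per_block), n_per_block)
  down <- matrix(rep(c(0, 0, 0, -3, -3, -3), each = n_per_block), n_per_block)
  M <- rbind(up, down) + matrix(rnorm(2 * n_per_block * 6, 0, noise_sd),
                                2 * n_per_block)
  rownames(M) <- sprintf("g%02d", seq_len(2 * n_per_block))
  colnames(M) <- sprintf("c%d", 1:6)
  M
}

# tiny deterministic graph: triangle + path + isolated node
toy_graph <- function() {
  interaction_graph(
    data.frame(node1 = c("A", "B", "A", "D"), node2 = c("B", "C", "C", "E"),
               score = 1, source = "synthetic"),
    nodes = c("A", "B", "C", "D", "E", "F")
  )
}
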