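# Shared simulation runs, computed once per test session.

.run_cache <- new.env(parent = emptyenv())

# Study-scale run: 50 genes, 3 subgenomes, 2% divergence, 0.1% indels.
study_run <- function() {
  if (is.null(.run_cache$study)) {
    sim <- simulate_polyploid(sim_config(n_genes = 50, seed = 7))
    run <- run_pipeline(sim$queries, sim$genome)
    .run_cache$study <- list(sim = sim, run = run)
  }
  .run_cache$study
}

# Small run reused by structural tests: 4 genes.
small_run <- function() {
  if (is.null(.run_cache$small)) {
    sim <- simulate_polyploid(sim_config(n_genes = 4, seed = 13))
    run <- run_pipeline(sim$queries, sim$genome)
    .run_cache$small <- list(sim = sim, run = run)
  }
  .run_cache$small
}

# Null-model run: zero divergence, identical subgenome copies.
null_run <- function() {
  if (is.null(.run_cache$null)) {
    sim <- simulate_polyploid(sim_config(n_genes = 5, divergence = 0,
                                         indel_rate = 0, seed = 3))
    run <- run_pipeline(sim$queries, sim$genome)
    .run_cache$null <- list(sim = sim, run = run)
  }
  .run_cache$null
}
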