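# Shared fixtures, built once per test run.

.fixture_env <- new.env()

## Small allotetraploid used by several module tests (2 pairs x 100 kb).
small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$cfg <- sim_config(seed = 42, n_pairs = 2, chrom_len = 1e5,
                                   n_genes_per_chrom = 40, diag_copies = 60)
    .fixture_env$sim <- simulate_tetraploid(.fixture_env$cfg)
  }
  .fixture_env$sim
}

small_cfg <- function() { small_sim(); .fixture_env$cfg }

## Noiseless expression fixture for exact fate/bias checks.
noiseless_expr <- function() {
  if (is.null(.fixture_env$expr0)) {
    cfg <- sim_config(seed = 21, n_pairs = 2, chrom_len = 2e5,
                      n_genes_per_chrom = 150, gene_len = 500, noise_sd = 0,
                      diag_copies = 30)
    sim <- simulate_tetraploid(cfg)
    .fixture_env$expr0 <- list(sim = sim, expr = simulate_expression(sim))
  }
  .fixture_env$expr0
}
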